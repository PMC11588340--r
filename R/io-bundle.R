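#' Write a session bundle to disk
#'
#' Serialises a session as a directory of plain-text tables plus a JSON
#' truth record: `kinematics.csv`, `emg.csv`, `events_truth.csv`,
#' `stims.csv`, `truth.json`.
#'
#' @param session A `cg_session`.
#' @param path Target directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_bundle <- function(session, path) {
  stopifnot(inherits(session, "cg_session"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(session$kinematics, file.path(path, "kinematics.csv"),
                   row.names = FALSE)
  utils::write.csv(session$emg, file.path(path, "emg.csv"),
                   row.names = FALSE)
  utils::write.csv(session$events_truth, file.path(path, "events_truth.csv"),
                   row.names = FALSE)
  utils::write.csv(session$stims, file.path(path, "stims.csv"),
                   row.names = FALSE)
  truth <- session$truth
  truth$gait_params <- unclass(truth$gait_params)
  truth$injury <- unclass(truth$injury)
  truth$emg_params <- unclass(truth$emg_params)
  truth$stim_model <- if (!is.null(truth$stim_model))
    unclass(truth$stim_model) else NULL
  jsonlite::write_json(truth, file.path(path, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read and validate a session bundle
#'
#' Loads the tables written by [write_bundle()] and validates their schemas:
#' required columns present, time columns strictly increasing, no missing
#' values in required columns. Validation failures raise descriptive errors
#' naming the offending file and column. The truth record is optional (it
#' only exists for synthetic bundles).
#'
#' @param path Bundle directory.
#' @param require_emg,require_kinematics Set `FALSE` to allow partial
#'   bundles.
#' @return A list of class `cg_bundle` with `kinematics`, `emg`,
#'   `events_truth`, `stims`, `truth` (NULL when absent), `path`.
#' @export
read_bundle <- function(path, require_emg = TRUE, require_kinematics = TRUE) {
  stop_unless(dir.exists(path), paste0("bundle directory not found: ", path))
  read_table <- function(file, required, time_col = "time_s") {
    f <- file.path(path, file)
    if (!file.exists(f)) {
      if (required) stop("missing required file '", file, "' in bundle ",
                         path, call. = FALSE)
      return(NULL)
    }
    d <- utils::read.csv(f, stringsAsFactors = FALSE)
    if (!is.null(time_col) && time_col %in% names(d) && nrow(d) > 1) {
      if (is.unsorted(d[[time_col]], strictly = TRUE)) {
        stop("file '", file, "': column '", time_col,
             "' is not strictly increasing", call. = FALSE)
      }
    }
    num <- vapply(d, is.numeric, logical(1))
    bad <- names(d)[num][vapply(d[num], function(x) any(!is.finite(x)),
                                logical(1))]
    if (length(bad) > 0) {
      stop("file '", file, "': missing or non-finite values in column '",
           bad[1], "'", call. = FALSE)
    }
    d
  }
  kin <- read_table("kinematics.csv", require_kinematics)
  emg <- read_table("emg.csv", require_emg)
  ev <- read_table("events_truth.csv", FALSE, time_col = NULL)
  stims <- read_table("stims.csv", FALSE, time_col = NULL)
  truth <- NULL
  tf <- file.path(path, "truth.json")
  if (file.exists(tf)) truth <- jsonlite::read_json(tf, simplifyVector = TRUE)
  structure(list(kinematics = kin, emg = emg, events_truth = ev,
                 stims = stims, truth = truth, path = path),
            class = "cg_bundle")
}

#' @export
print.cg_bundle <- function(x, ...) {
  cat(sprintf("<cg_bundle: %s>\n", x$path))
  for (nm in c("kinematics", "emg", "events_truth", "stims")) {
    if (!is.null(x[[nm]])) cat(sprintf("  %s: %d rows\n", nm, nrow(x[[nm]])))
  }
  invisible(x)
}
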