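#' Descending threshold search for one array site
#'
#' Replicates the awake-mapping protocol: testing starts at `start_uA`
#' (100 uA); if no response is evoked there the site is non-responding and
#' testing stops. Otherwise the amplitude is decreased in `step_uA` steps
#' until the response disappears (or the floor is reached); the threshold is
#' the lowest tested amplitude that still evoked a response.
#'
#' @param respond A response oracle: `function(amplitude_uA) -> logical`,
#'   assumed monotone (a response at `A` implies a response at any
#'   `A' >= A`). See [twitch_oracle()].
#' @param start_uA Starting amplitude, uA.
#' @param step_uA Step size, uA.
#' @param floor_uA Lowest amplitude tested, uA.
#' @param check_monotone If `TRUE`, the whole descending grid is tested and
#'   a non-monotone response pattern is flagged.
#' @return A list with `threshold_uA` (`NA` if no response at `start_uA`),
#'   `clamped` (`TRUE` when the site still responded at the floor), and
#'   `non_monotone` (only meaningful with `check_monotone`).
#' @export
find_threshold <- function(respond, start_uA = 100, step_uA = 10,
                           floor_uA = 10, check_monotone = FALSE) {
  stop_unless(start_uA > floor_uA && floor_uA > 0,
              "need start_uA > floor_uA > 0")
  stop_unless(step_uA > 0, "step_uA must be > 0")
  grid <- seq(start_uA, floor_uA, by = -step_uA)
  if (check_monotone) {
    resp <- vapply(grid, function(a) isTRUE(respond(a)), logical(1))
    non_monotone <- any(diff(resp) > 0)  # a response reappearing lower down
    if (!resp[1]) {
      return(list(threshold_uA = NA_real_, clamped = FALSE,
                  non_monotone = non_monotone))
    }
    last <- if (all(resp)) length(grid) else which(!resp)[1] - 1L
    return(list(threshold_uA = grid[last], clamped = all(resp),
                non_monotone = non_monotone))
  }
  if (!isTRUE(respond(grid[1]))) {
    return(list(threshold_uA = NA_real_, clamped = FALSE,
                non_monotone = FALSE))
  }
  thr <- grid[1]
  for (a in grid[-1]) {
    if (!isTRUE(respond(a))) {
      return(list(threshold_uA = thr, clamped = FALSE, non_monotone = FALSE))
    }
    thr <- a
  }
  list(threshold_uA = thr, clamped = TRUE, non_monotone = FALSE)
}

#' Motor-map size: responding sites on the array
#'
#' @param map A site-response data.frame (as from
#'   [generate_motor_map_truth()] or a scored map) with `category` and
#'   `side` columns.
#' @param side Optional side filter: `"ipsi"` or `"contra"` (bilateral sites
#'   count for both sides); `NULL` counts all responding sites.
#' @return A list with `count` and `fraction` of responding sites.
#' @export
map_size <- function(map, side = NULL) {
  responding <- map$category != "none"
  if (!is.null(side)) {
    side <- match.arg(side, c("ipsi", "contra"))
    responding <- responding & !is.na(map$side) &
      (map$side == side | map$side == "bilateral")
  }
  list(count = sum(responding), fraction = sum(responding) / nrow(map))
}

#' Joint population motor map
#'
#' Per-site modal response across animals: the most frequent (category,
#' side) pair and its frequency. Ties are broken by a declared priority
#' (distal over proximal over none; bilateral over contra over ipsi) and
#' flagged.
#'
#' @param maps List of site-response data.frames sharing the same layout
#'   (site order).
#' @return A data.frame: `row`, `col`, `modal_category`, `modal_side`,
#'   `probability`, `tie`.
#' @export
joint_population_map <- function(maps) {
  stop_unless(length(maps) >= 1, "need at least one map")
  n <- nrow(maps[[1]])
  same <- vapply(maps, function(m) nrow(m) == n &&
                   all(m$row == maps[[1]]$row & m$col == maps[[1]]$col),
                 logical(1))
  stop_unless(all(same), "maps do not share the same array layout")

  cat_rank <- c(distal = 1, proximal = 2, none = 3)
  side_rank <- c(bilateral = 1, contra = 2, ipsi = 3)
  out <- maps[[1]][, c("row", "col")]
  out$modal_category <- NA_character_
  out$modal_side <- NA_character_
  out$probability <- NA_real_
  out$tie <- FALSE
  for (i in seq_len(n)) {
    cats <- vapply(maps, function(m) m$category[i], character(1))
    sides <- vapply(maps, function(m)
      ifelse(is.na(m$side[i]), "none", m$side[i]), character(1))
    key <- paste(cats, sides, sep = "|")
    tab <- table(key)
    top <- names(tab)[tab == max(tab)]
    tie <- length(top) > 1
    parts <- strsplit(top, "|", fixed = TRUE)
    ord <- order(vapply(parts, function(p) cat_rank[[p[1]]], numeric(1)),
                 vapply(parts, function(p)
                   side_rank[p[2]] %||na% 4, numeric(1)))
    pick <- parts[[ord[1]]]
    out$modal_category[i] <- pick[1]
    out$modal_side[i] <- if (pick[2] == "none") NA_character_ else pick[2]
    out$probability[i] <- max(tab) / length(maps)
    out$tie[i] <- tie
  }
  out
}

`%||na%` <- function(a, b) if (length(a) == 0 || is.na(a)) b else a

#' Ipsilateral dominance of evoked muscle responses
#'
#' Ratio (in percent) of the mean baseline-normalized ipsilateral (left)
#' tibialis anterior evoked response to the contralateral (right) one. Each
#' side's responses are first normalized to that muscle's spontaneous
#' locomotion baseline.
#'
#' @param ipsi_responses,contra_responses Evoked response magnitudes per side.
#' @param ipsi_baseline,contra_baseline Baseline (spontaneous locomotion)
#'   magnitudes for the same muscles.
#' @return A list with `dominance_pct` and `saturated` (`TRUE` with a
#'   dominance of `Inf` when the contralateral response is zero).
#' @export
ipsilateral_dominance <- function(ipsi_responses, contra_responses,
                                  ipsi_baseline, contra_baseline) {
  stop_unless(length(ipsi_responses) >= 1 && length(contra_responses) >= 1,
              "need at least one evoked response per side")
  ni <- mean(normalize_to_baseline(ipsi_responses, ipsi_baseline)$fraction)
  nc <- mean(normalize_to_baseline(contra_responses, contra_baseline)$fraction)
  if (nc <= 0) {
    return(list(dominance_pct = Inf, saturated = TRUE))
  }
  list(dominance_pct = 100 * ni / nc, saturated = FALSE)
}

#' Longitudinal motor-map trajectory
#'
#' Percent change of map size versus the intact timepoint, and size as a
#' percent of the final (chronic) timepoint.
#'
#' @param maps Named list of site-response data.frames, one per timepoint;
#'   must include an `"intact"` entry. Order is the temporal order, with the
#'   last entry the chronic endpoint.
#' @param side Optional side filter passed to [map_size()].
#' @return A data.frame: `timepoint`, `count`, `pct_change_vs_intact`,
#'   `pct_of_final`.
#' @export
longitudinal_trajectory <- function(maps, side = NULL) {
  stop_unless("intact" %in% names(maps), "maps must include 'intact'")
  counts <- vapply(maps, function(m) map_size(m, side)$count, numeric(1))
  n_intact <- counts[["intact"]]
  stop_unless(n_intact > 0, "intact map size is zero")
  final <- counts[[length(counts)]]
  data.frame(timepoint = names(maps),
             count = as.numeric(counts),
             pct_change_vs_intact = 100 * (counts - n_intact) / n_intact,
             pct_of_final = if (final > 0) 100 * counts / final else NA_real_,
             row.names = NULL)
}
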