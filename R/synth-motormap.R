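#' Electrode array layout
#'
#' The chronic intracortical implant used for awake motor mapping: a
#' 32-channel array of 8 rows by 4 columns covering 1.125 x 1.75 mm, placed
#' in the left hindlimb motor cortex with its top-right site at
#' (-1.1 mm AP, 1.1 mm ML) from bregma.
#'
#' @param n_rows,n_cols Grid dimensions.
#' @param extent_mm Physical extent `c(width, height)` in mm.
#' @param origin_mm Stereotaxic offset of the reference site from bregma, mm.
#' @return An object of class `electrode_layout`.
#' @export
electrode_layout <- function(n_rows = 8, n_cols = 4,
                             extent_mm = c(1.125, 1.75),
                             origin_mm = c(-1.1, 1.1)) {
  stop_unless(n_rows >= 1 && n_cols >= 1, "grid dimensions must be >= 1")
  stop_unless(all(extent_mm > 0), "extents must be > 0")
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 n_sites = as.integer(n_rows) * as.integer(n_cols),
                 extent_mm = extent_mm, origin_mm = origin_mm),
            class = "electrode_layout")
}

#' @export
print.electrode_layout <- function(x, ...) {
  cat(sprintf("<electrode_layout: %d x %d = %d sites, %.3g x %.3g mm>\n",
              x$n_rows, x$n_cols, x$n_sites, x$extent_mm[1], x$extent_mm[2]))
  invisible(x)
}

# scenario multipliers of the intact responding fractions, per side.
# Longitudinal course after hemisection: about -90% ipsilateral and -53%
# contralateral transmission at day 5; contralateral map +264% by week 2 and
# +250% at week 8; ipsilateral +115% chronically with most of the rise in
# weeks 1-2.
map_scenarios <- function() {
  list(intact = c(ipsi = 1.00, contra = 1.00),
       day5   = c(ipsi = 0.10, contra = 0.47),
       week2  = c(ipsi = 1.95, contra = 3.64),
       week8  = c(ipsi = 2.15, contra = 3.50))
}

#' Generate ground-truth motor-map responses for a scenario
#'
#' Draws a per-site true response (category, side, threshold) on the
#' electrode grid. The number of responding sites per side is
#' `round(multiplier * intact_fraction * n_sites)` with scenario multipliers
#' following the longitudinal transmission course after hemisection (see
#' Details); responding sites are placed at random, thresholds are uniform
#' within the searchable amplitude range.
#'
#' @param layout An [electrode_layout()].
#' @param scenario One of `"intact"`, `"day5"`, `"week2"`, `"week8"`.
#' @param seed Integer seed.
#' @param intact_fraction Responding-site fraction per side in the intact
#'   condition (default 0.25 of the array per side).
#' @param threshold_range True-threshold range, uA.
#' @return A data.frame with one row per site: `row`, `col`, `category`
#'   (`"none"`, `"proximal"`, `"distal"`), `side` (`NA`, `"ipsi"`, `"contra"`,
#'   `"bilateral"`), `threshold_uA` (`NA` for non-responding sites), and
#'   `timepoint`.
#' @export
generate_motor_map_truth <- function(layout = electrode_layout(),
                                     scenario = "intact", seed = 1L,
                                     intact_fraction = 0.25,
                                     threshold_range = c(15, 95)) {
  stopifnot(inherits(layout, "electrode_layout"))
  sc <- map_scenarios()
  if (!scenario %in% names(sc)) {
    stop("unknown scenario '", scenario, "'; use one of ",
         paste(names(sc), collapse = ", "), call. = FALSE)
  }
  mult <- sc[[scenario]]
  n <- layout$n_sites
  n_ipsi <- min(n, round(mult[["ipsi"]] * intact_fraction * n))
  n_contra <- min(n, round(mult[["contra"]] * intact_fraction * n))

  with_seed(seed, {
    sites_ipsi <- sample.int(n, n_ipsi)
    sites_contra <- sample.int(n, n_contra)
    side <- rep(NA_character_, n)
    side[sites_contra] <- "contra"
    side[sites_ipsi] <- ifelse(seq_len(n)[sites_ipsi] %in% sites_contra,
                               "bilateral", "ipsi")
    responding <- !is.na(side)
    category <- rep("none", n)
    category[responding] <- sample(c("distal", "proximal"), sum(responding),
                                   replace = TRUE, prob = c(0.6, 0.4))
    threshold <- rep(NA_real_, n)
    threshold[responding] <- stats::runif(sum(responding),
                                          threshold_range[1],
                                          threshold_range[2])
    data.frame(row = rep(seq_len(layout$n_rows), layout$n_cols),
               col = rep(seq_len(layout$n_cols), each = layout$n_rows),
               category = category, side = side,
               threshold_uA = threshold, timepoint = scenario,
               stringsAsFactors = FALSE)
  })
}

#' Build a twitch-response oracle from a true threshold
#'
#' In synthetic mode a "visible twitch" is an evoked EMG deflection whose
#' peak exceeds 4 noise SDs within 60 ms of train onset. The evoked peak
#' grows linearly above the true threshold, so the oracle is monotone by
#' construction: it responds at amplitude `A` whenever the noisy evoked peak
#' clears the detection criterion.
#'
#' @param true_threshold_uA True site threshold, uA (or `NA` for a
#'   non-responding site).
#' @param noise_sd Baseline EMG noise SD, mV.
#' @param gain Evoked peak growth per uA above threshold, mV/uA.
#' @param deterministic If `TRUE` (default) the oracle ignores measurement
#'   noise and responds exactly at `A >= true_threshold_uA`.
#' @param seed Seed for the noisy oracle.
#' @return A function `f(amplitude_uA) -> logical`.
#' @export
twitch_oracle <- function(true_threshold_uA, noise_sd = 0.01, gain = 0.02,
                          deterministic = TRUE, seed = 1L) {
  if (is.na(true_threshold_uA)) return(function(amplitude_uA) FALSE)
  if (deterministic) {
    return(function(amplitude_uA) amplitude_uA >= true_threshold_uA)
  }
  counter <- 0L
  function(amplitude_uA) {
    counter <<- counter + 1L
    peak <- max(0, gain * (amplitude_uA - true_threshold_uA)) +
      with_seed(child_seed(seed, counter),
                abs(stats::rnorm(1, 0, noise_sd)))
    peak > 4 * noise_sd
  }
}
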