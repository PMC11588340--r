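test_that("descending threshold search matches an exhaustive grid scan", {
  for (true_thr in c(12, 37, 60, 85, 100)) {
    oracle <- twitch_oracle(true_thr)
    res <- find_threshold(oracle)
    grid <- seq(100, 10, by = -10)
    responding <- grid[vapply(grid, oracle, logical(1))]
    brute <- if (length(responding) == 0) NA_real_ else min(responding)
    expect_equal(res$threshold_uA, brute)
    # the oracle responds at the result but not one step below (unless clamped)
    if (!is.na(res$threshold_uA) && !res$clamped) {
      expect_true(oracle(res$threshold_uA))
      expect_false(oracle(res$threshold_uA - 10))
    }
  }
})

test_that("threshold search handles no-response and floor clamping", {
  none <- find_threshold(twitch_oracle(150))  # above the starting amplitude
  expect_true(is.na(none$threshold_uA))
  clamped <- find_threshold(twitch_oracle(5))  # below the floor
  expect_equal(clamped$threshold_uA, 10)
  expect_true(clamped$clamped)
  # a non-monotone oracle is flagged when the full grid is scanned
  weird <- function(a) a >= 90 || (a <= 40 && a >= 30)
  res <- find_threshold(weird, check_monotone = TRUE)
  expect_true(res$non_monotone)
})

test_that("map size counts responding sites with side filters", {
  lay <- electrode_layout()
  m <- generate_motor_map_truth(lay, "intact", seed = 1)
  allnone <- m
  allnone$category <- "none"
  allnone$side <- NA
  expect_equal(map_size(allnone)$count, 0)
  half <- allnone
  half$category[1:16] <- "distal"
  half$side[1:16] <- "contra"
  expect_equal(map_size(half)$fraction, 0.5)
  expect_equal(map_size(half, "contra")$count, 16)
  expect_equal(map_size(half, "ipsi")$count, 0)
  # monotone under adding a responding site
  plus <- half
  plus$category[20] <- "proximal"; plus$side[20] <- "ipsi"
  expect_gt(map_size(plus)$count, map_size(half)$count)
})

test_that("joint population maps take the modal response with declared tie-breaks", {
  lay <- electrode_layout(2, 2)
  mk <- function(cats, sides) {
    data.frame(row = c(1, 2, 1, 2), col = c(1, 1, 2, 2),
               category = cats, side = sides,
               threshold_uA = ifelse(cats == "none", NA, 50),
               timepoint = "intact")
  }
  m1 <- mk(c("distal", "proximal", "none", "distal"),
           c("contra", "ipsi", NA, "contra"))
  jm_same <- joint_population_map(list(m1, m1, m1))
  expect_equal(jm_same$modal_category, m1$category)
  expect_equal(jm_same$probability, rep(1, 4))
  # site 1: {distal, distal, proximal} -> distal with probability 2/3
  m2 <- mk(c("distal", "proximal", "none", "distal"),
           c("contra", "ipsi", NA, "contra"))
  m3 <- mk(c("proximal", "proximal", "none", "distal"),
           c("contra", "ipsi", NA, "contra"))
  jm <- joint_population_map(list(m1, m2, m3))
  expect_equal(jm$modal_category[1], "distal")
  expect_equal(jm$probability[1], 2 / 3)
  # a proximal/distal tie resolves to distal and is flagged
  m4 <- mk(c("proximal", "none", "none", "none"), c("contra", NA, NA, NA))
  jm2 <- joint_population_map(list(m1, m4))
  expect_equal(jm2$modal_category[1], "distal")
  expect_true(jm2$tie[1])
  # mismatched layouts error
  expect_error(joint_population_map(list(m1, m1[1:3, ])), "layout")
})

test_that("ipsilateral dominance is a baseline-normalized ratio with saturation flag", {
  eq <- ipsilateral_dominance(c(1, 1), c(1, 1), 1, 1)
  expect_equal(eq$dominance_pct, 100)
  r <- ipsilateral_dominance(2.71, 1, 1, 1)
  expect_equal(r$dominance_pct, 271)
  # different baselines are normalized out
  r2 <- ipsilateral_dominance(2.71 * 0.4, 1 * 0.8, 0.4, 0.8)
  expect_equal(r2$dominance_pct, 271, tolerance = 1e-9)
  sat <- ipsilateral_dominance(1, 0, 1, 1)
  expect_true(sat$saturated)
})

test_that("longitudinal trajectories express the printed percent-change scheme", {
  lay <- electrode_layout()
  mk_n <- function(n) {
    m <- generate_motor_map_truth(lay, "intact", seed = 1)
    m$category <- "none"; m$side <- NA; m$threshold_uA <- NA
    if (n > 0) { m$category[seq_len(n)] <- "distal"
                 m$side[seq_len(n)] <- "contra" }
    m
  }
  maps <- list(intact = mk_n(20), day5 = mk_n(2), week8 = mk_n(20))
  tr <- longitudinal_trajectory(maps)
  expect_equal(tr$pct_change_vs_intact[tr$timepoint == "day5"], -90)
  expect_equal(tr$pct_change_vs_intact[tr$timepoint == "intact"], 0)
  expect_equal(tr$pct_of_final[tr$timepoint == "week8"], 100)
  expect_error(longitudinal_trajectory(list(day5 = mk_n(2))), "intact")
  # generator scenarios: chronic contralateral expansion in the +150..300% range
  sc <- lapply(c(intact = "intact", day5 = "day5", week2 = "week2",
                 week8 = "week8"),
               function(x) generate_motor_map_truth(lay, x, seed = 4,
                                                    intact_fraction = 0.25))
  tr2 <- longitudinal_trajectory(sc, side = "contra")
  wk8 <- tr2$pct_change_vs_intact[tr2$timepoint == "week8"]
  expect_gte(wk8, 150); expect_lte(wk8, 300)
})
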