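test_that("linear fits recover exact lines and beat a grid-search oracle", {
  x <- c(30, 70, 110, 150)
  fit <- linear_fit_vaf(x, 2 * x + 1)
  expect_equal(fit$slope, 2, tolerance = 1e-10)
  expect_equal(fit$intercept, 1, tolerance = 1e-8)
  expect_equal(fit$vaf, 100, tolerance = 1e-10)

  # least-squares optimality against a brute-force (slope, intercept) grid
  set.seed(11)
  y <- 0.5 * x + rnorm(4, sd = 5)
  fit2 <- linear_fit_vaf(x, y)
  grid <- expand.grid(b = seq(-2, 3, by = 0.02), a = seq(-50, 50, by = 0.5))
  grid_ss <- vapply(seq_len(nrow(grid)), function(i)
    sum((y - (grid$a[i] + grid$b[i] * x))^2), numeric(1))
  ss_fit <- sum((y - (fit2$intercept + fit2$slope * x))^2)
  expect_lte(ss_fit, min(grid_ss) + 1e-9)
})

test_that("VAF behaves at the degenerate and null extremes", {
  set.seed(21)
  x <- rep(seq(0, 100, length.out = 10), 20)
  y <- rnorm(length(x))  # independent of x
  fit <- linear_fit_vaf(x, y)
  expect_lt(abs(fit$vaf), 5)
  expect_lt(abs(fit$slope), 0.01)
  # all-y-equal: flat perfect fit, flagged
  deg <- linear_fit_vaf(c(1, 2, 3), c(4, 4, 4))
  expect_true(deg$degenerate)
  expect_equal(deg$vaf, 100)
  expect_equal(deg$slope, 0)
  expect_error(linear_fit_vaf(c(1, 1, 1), c(1, 2, 3)), "equal")
  expect_error(linear_fit_vaf(1:2, 1:2), "3 points")
  # VAF invariant to affine rescaling of x
  set.seed(22)
  y2 <- 1:8 + rnorm(8)
  expect_equal(linear_fit_vaf(1:8, y2)$vaf,
               linear_fit_vaf(100 + 5 * (1:8), y2)$vaf, tolerance = 1e-9)
})

test_that("phase-binned profiles localise kernel-confined effects", {
  set.seed(3)
  offs <- runif(120, -0.2, 0.2)
  ph <- data.frame(onset_s = offs + 5, phase = NA, offset_s = offs,
                   phase_coherent = abs(offs) <= 0.075, excluded = FALSE)
  vals <- 1 + 2 * phase_kernel(offs) + rnorm(120, sd = 0.05)
  prof <- phase_binned_effects(ph, vals)
  expect_true(prof$phase_coherent[which.max(prof$mean)])
  # uniform effect: flat within SEM
  flat <- phase_binned_effects(ph, rep(2, 120))
  expect_lt(diff(range(flat$mean[flat$n > 0])), 1e-12)
  # no stimuli at all: empty profile
  none <- phase_binned_effects(ph[0, ], numeric(0))
  expect_equal(nrow(none), 0)
  # bin means are permutation invariant
  o <- sample(120)
  prof2 <- phase_binned_effects(ph[o, ], vals[o])
  expect_equal(prof2$mean, prof$mean, tolerance = 1e-12)
})

test_that("test selection follows the normality gate and sidedness", {
  set.seed(5)
  a <- rnorm(12, 1); b <- rnorm(12, 0)
  r <- select_and_run_test(a, b, paired = TRUE)
  expect_equal(r$test, "paired t")
  r2 <- select_and_run_test(a, b, paired = FALSE)
  expect_equal(r2$test, "unpaired t")
  # trivially non-normal zero-inflated data goes non-parametric
  drag_a <- c(rep(0, 9), 0.4, 0.5, 0.2)
  drag_b <- c(rep(0, 8), 0.6, 0.7, 0.3, 0.2)
  r3 <- select_and_run_test(drag_a, drag_b, force_nonparametric = TRUE)
  expect_equal(r3$test, "Wilcoxon rank-sum")
  r4 <- select_and_run_test(drag_a, drag_b, paired = TRUE,
                            force_nonparametric = TRUE)
  expect_equal(r4$test, "Wilcoxon signed-rank")
  # identical samples are never significant
  same <- rnorm(10)
  r5 <- select_and_run_test(same, same + 0, paired = FALSE)
  expect_gte(r5$p, 0.05)
  expect_error(select_and_run_test(1:2, 1:5), "at least 3")
})

test_that("paired t power reproduces the design numbers and its properties", {
  # the two study-design scenarios reach the target power
  expect_gte(power_paired_t(2.5, 5, alpha = 0.05), 0.8)
  expect_gte(power_paired_t(1.5, 7, alpha = 0.05), 0.8)
  # null case: power equals alpha
  expect_equal(power_paired_t(0, 5, alpha = 0.05), 0.05, tolerance = 1e-10)
  expect_equal(power_paired_t(0, 12, alpha = 0.01), 0.01, tolerance = 1e-10)
  # monotone in effect size and n
  es <- seq(0, 3, by = 0.5)
  expect_true(all(diff(vapply(es, power_paired_t, numeric(1), n = 6)) > 0))
  ns <- c(3, 5, 8, 12)
  expect_true(all(diff(vapply(ns, function(n)
    power_paired_t(1.5, n), numeric(1))) > 0))
  expect_error(power_paired_t(1, 1), "pairs")
})

test_that("Monte-Carlo power agrees with the noncentral-t analytic value", {
  for (cfg in list(c(2.5, 5), c(1.5, 7))) {
    an <- power_paired_t(cfg[1], cfg[2])
    mc <- power_paired_t(cfg[1], cfg[2], method = "monte_carlo",
                         n_rep = 1e5, seed = 9)
    expect_lt(abs(an - mc), 0.01)
  }
})
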