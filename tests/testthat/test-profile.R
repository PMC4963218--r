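# Reference stats reused across model tests (fixed synthetic table).
ref_lys <- compute_reference_stats(simulate_bmrb_table(n = 300, seed = 17),
                                   "LYS", "CE")

test_that("model specs encode the stated priors", {
  sA <- rnorm(50, -10.1, 1)
  spec <- build_model_spec(sA, rnorm(50, 0, 1), ref_lys, seed = 1)
  expect_equal(spec$states$A$mean_loc, mean(sA))
  expect_identical(spec$mean_scale, 0.35)
  expect_identical(spec$nu_mean, 30)
  expect_equal(spec$sd_prior$mean, ref_lys$sd)
  expect_equal(spec$state_priors, c(0.5, 0.5))
  # Gamma moment matching: mean 2, sd 1 -> shape 4, rate 2
  g <- gamma_from_moments(2, 1)
  expect_identical(g$shape, 4)
  expect_identical(g$rate, 2)
  bad_ref <- ref_lys; bad_ref$sd <- 0
  expect_error(build_model_spec(sA, rnorm(50), bad_ref), "positive")
})

test_that("the posterior recovers known Gaussian parameters", {
  set.seed(100)
  yA <- rnorm(500, -10, 2)
  yB <- rnorm(500, 0, 1)
  spec <- build_model_spec(yA, yB, ref_lys, chains = 2, draws = 500,
                           warmup = 500, seed = 7)
  draws <- suppressWarnings(fit_state_model(spec))
  expect_lt(abs(mean(draws$A$mu) - (-10)), 0.3)
  expect_lt(abs(mean(draws$B$mu) - 0), 0.3)
  expect_true(all(draws$A$sigma > 0))
  expect_true(all(draws$A$nu > 0))
  expect_true(all(is.finite(draws$diagnostics$rhat)))
  # seed determinism
  d2 <- suppressWarnings(fit_state_model(spec))
  expect_identical(draws$A, d2$A)
  expect_identical(draws$B, d2$B)
  # generative calibration: data from state A score higher under A
  prof <- probability_profile(draws)
  pa <- approx(prof$grid, prof$mean, xout = yA[abs(yA - mean(yA)) < 4])$y
  expect_gt(mean(pa), 1 - mean(pa))
})

test_that("too-few samples and the student-t alternate are handled", {
  expect_error(
    fit_state_model(build_model_spec(rnorm(5), rnorm(50), ref_lys)),
    "at least 10")
  set.seed(8)
  spec <- build_model_spec(rnorm(100, -5, 1), rnorm(100, 0, 1), ref_lys,
                           likelihood = "student_t", chains = 2,
                           draws = 300, warmup = 300, seed = 2)
  draws <- suppressWarnings(fit_state_model(spec))
  expect_lt(abs(mean(draws$A$mu) - (-5)), 0.5)
})

test_that("probability profiles are normalized, symmetric and match the closed form", {
  draws <- collapsed_draws(-1, 1)
  grid <- seq(-4, 4, length.out = 801)
  prof <- probability_profile(draws, grid = grid, state_priors = c(0.5, 0.5))
  expect_true(all(prof$mean >= 0 & prof$mean <= 1))
  expect_true(all(prof$draw_curves >= 0 & prof$draw_curves <= 1))
  # symmetric case: P = 0.5 at Delta = 0
  expect_equal(prof$mean[grid == 0], 0.5, tolerance = 1e-12)
  # unit-variance means -/+1: P_A(Delta) = logistic(-2 Delta)
  want <- plogis(-2 * grid)
  expect_equal(prof$mean, want, tolerance = 1e-12)
  expect_equal(approx(grid, prof$mean, xout = -log(4) / 2)$y, 0.8,
               tolerance = 1e-3)
  # complementary state: swapping A and B gives 1 - P pointwise per draw
  swapped <- probability_profile(collapsed_draws(1, -1), grid = grid,
                                 state_priors = c(0.5, 0.5))
  expect_equal(swapped$draw_curves + prof$draw_curves,
               matrix(1, nrow(prof$draw_curves), ncol(prof$draw_curves)),
               tolerance = 1e-12)
  # monotone between the means for equal sigmas
  between <- grid >= -1 & grid <= 1
  expect_true(all(diff(prof$mean[between]) <= 1e-12))
})

test_that("threshold queries invert the profile correctly", {
  draws <- collapsed_draws(1, -1)  # state A on the positive side
  grid <- seq(-4, 4, length.out = 2001)
  prof <- probability_profile(draws, grid = grid)
  reg <- threshold_query(prof, 0.8, "A")
  expect_identical(nrow(reg), 1L)
  expect_equal(reg$lo, log(4) / 2, tolerance = 0.01)
  expect_equal(reg$hi, 4, tolerance = 1e-9)
  # level above the maximum -> empty region
  expect_identical(nrow(threshold_query(prof, 1 - 1e-12, "A")), 0L)
  # constant-1 profile covers the entire grid
  flat <- prof; flat$mean <- rep(1, length(grid))
  all_reg <- threshold_query(flat, 0.8, "A")
  expect_equal(c(all_reg$lo, all_reg$hi), range(grid))
  expect_error(threshold_query(prof, 1.2, "A"))
})

test_that("classification re-references, looks up the profile and guards the range", {
  draws <- collapsed_draws(-10, 0)
  grid <- seq(-15, 5, length.out = 1001)
  prof <- probability_profile(draws, grid = grid)
  # shift equal to the reference mean -> Delta 0
  cl0 <- classify_observation(ref_lys$mean, "DSS", ref_lys, prof)
  expect_equal(cl0$delta, 0, tolerance = 1e-12)
  expect_equal(cl0$p_A, approx(grid, prof$mean, xout = 0)$y, tolerance = 1e-12)
  expect_equal(cl0$p_A + cl0$p_B, 1, tolerance = 1e-12)
  # TMS-referenced observation: Delta = (x - 1.7) - ref mean
  x <- ref_lys$mean - 6
  cl <- classify_observation(x, "TMS", ref_lys, prof)
  expect_equal(cl$delta, -6 - 1.7, tolerance = 1e-12)
  expect_equal(cl$p_A, approx(grid, prof$mean, xout = cl$delta)$y,
               tolerance = 1e-12)
  expect_error(classify_observation(ref_lys$mean + 50, "DSS", ref_lys, prof),
               "out of calibrated range")
})

test_that("uncertainty bands shrink with more data", {
  set.seed(200)
  fit_band <- function(n) {
    spec <- build_model_spec(rnorm(n, -6, 1.5), rnorm(n, 0, 1.5), ref_lys,
                             chains = 2, draws = 400, warmup = 400, seed = 31)
    prof <- probability_profile(suppressWarnings(fit_state_model(spec)),
                                grid = seq(-9, 3, length.out = 201))
    mean(prof$band_hi - prof$band_lo)
  }
  expect_lt(fit_band(500), fit_band(50))
})

test_that("credible intervals cover the true mean at near-nominal rate", {
  truth <- -10
  hits <- vapply(1:20, function(s) {
    set.seed(4000 + s)
    y <- rnorm(100, truth, 2)
    spec <- build_model_spec(y, rnorm(100, 0, 1), ref_lys, chains = 2,
                             draws = 400, warmup = 300, seed = s)
    draws <- suppressWarnings(fit_state_model(spec))
    ci <- quantile(draws$A$mu, c(0.025, 0.975))
    ci[1] <= truth && truth <= ci[2]
  }, TRUE)
  expect_gte(sum(hits), 15)
})
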