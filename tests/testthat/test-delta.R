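test_that("rotamer averaging matches a group-mean oracle and passes singles through", {
  pair <- tiny_lys_pair()
  rec <- simulate_shift_records(pair, params = surrogate_params(seed = 4))
  avg <- average_over_rotamers(rec$modified, pair$scheme)
  expect_identical(nrow(avg), length(pair$unmodified))
  want <- tapply(rec$modified$value, rec$modified$backbone_index, mean)
  expect_equal(avg$value[order(avg$backbone_index)],
               as.numeric(want[order(as.integer(names(want)))]),
               tolerance = 1e-12)
  # single-rotamer records pass through unchanged
  expect_identical(average_over_rotamers(rec$unmodified), rec$unmodified)
})

test_that("incomplete rotamer coverage is reported with the missing labels", {
  pair <- tiny_lys_pair()
  rec <- simulate_shift_records(pair, params = surrogate_params(seed = 4))
  broken <- rec$modified[-1, ]  # drop one rotamer of backbone 1
  expect_error(average_over_rotamers(broken, pair$scheme), "missing")
})

test_that("unmodified Delta is centered at exactly zero and counts are conserved", {
  pair <- tiny_lys_pair()
  rec <- simulate_shift_records(pair, params = surrogate_params(seed = 1))
  d <- compute_delta(average_over_rotamers(rec$modified, pair$scheme),
                     rec$unmodified)
  expect_equal(mean(d$unmodified$delta), 0, tolerance = 1e-12)
  expect_identical(nrow(d$modified), length(pair$unmodified))
  expect_identical(nrow(d$unmodified), length(pair$unmodified))
})

test_that("mismatched nuclei or value kinds are rejected", {
  a <- data.frame(backbone_index = 1:2, residue = "LYS", state = "x",
                  nucleus = "CE", value = c(1, 2), kind = "shift")
  b <- a; b$nucleus <- "CB"
  expect_error(compute_delta(a, b), "nucleus mismatch")
  c <- a; c$kind <- "shielding"
  expect_error(compute_delta(a, c), "shift space")
})

test_that("rotamer averaging reduces Delta variance (law of total variance)", {
  pair <- generate_paired_ensembles(ptm_state("LYS", "dimethyl"), 60, seed = 12)
  rec <- simulate_shift_records(pair, params = surrogate_params(seed = 12))
  d_avg <- compute_delta(average_over_rotamers(rec$modified, pair$scheme),
                         rec$unmodified)
  d_raw <- compute_delta(rec$modified, rec$unmodified)
  expect_lt(var(d_avg$modified$delta), var(d_raw$modified$delta))
})

test_that("KDE densities normalize and reproduce sample moments", {
  set.seed(5)
  x <- rnorm(400, -10, 2)
  k <- kde_density(x)
  dx <- diff(k$kde$grid[1:2])
  expect_equal(sum(k$kde$density) * dx, 1, tolerance = 1e-3)
  expect_equal(k$summary$mean, mean(x), tolerance = 1e-2)
  expect_true(all(k$kde$density >= 0))
  # grid spans samples +- 4 bandwidths
  expect_equal(min(k$kde$grid), min(x) - 4 * k$kde$bandwidth, tolerance = 1e-9)
  expect_equal(max(k$kde$grid), max(x) + 4 * k$kde$bandwidth, tolerance = 1e-9)
  expect_error(kde_density(1), "at least 2")
})

test_that("KDE mode finds the density peak of a standard normal", {
  # mode estimation converges slowly; average the sampling oracle over
  # a few replicates at n = 1e4
  modes <- vapply(1:5, function(s) {
    set.seed(s)
    abs(kde_density(rnorm(1e4))$summary$mode)
  }, 0)
  expect_lt(mean(modes), 0.1)
})

test_that("explicit bandwidths override Silverman's rule", {
  x <- c(-1, 0, 1, 2)
  k <- kde_density(x, bandwidth = 0.5)
  expect_identical(k$kde$bandwidth, 0.5)
  expect_equal(kde_density(x)$kde$bandwidth, stats::bw.nrd0(x))
})

test_that("pooling concatenates samples and preserves mass", {
  d1 <- kde_density(rnorm(100, -3), state = "a", nucleus = "CZ")
  d2 <- kde_density(rnorm(150, 3), state = "b", nucleus = "CZ")
  pooled <- pool_states(list(d1, d2), label = "monomethylated")
  expect_identical(pooled$summary$n, 250L)
  expect_identical(pooled$state, "monomethylated")
  dx <- diff(pooled$kde$grid[1:2])
  expect_equal(sum(pooled$kde$density) * dx, 1, tolerance = 1e-3)
  # disjoint single points -> bimodal with equal masses
  bim <- pool_states(list(kde_density(c(-5, -5 + 1e-9)),
                          kde_density(c(5, 5 + 1e-9))))
  mass_lo <- sum(bim$kde$density[bim$kde$grid < 0])
  mass_hi <- sum(bim$kde$density[bim$kde$grid >= 0])
  expect_equal(mass_lo / mass_hi, 1, tolerance = 0.05)
  d3 <- kde_density(rnorm(50), state = "c", nucleus = "CE")
  expect_error(pool_states(list(d1, d3)), "nucleus mismatch")
})
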