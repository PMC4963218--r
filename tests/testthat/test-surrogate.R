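test_that("the default calibration carries the anchored Lys effects", {
  cal <- load_calibration()
  ce <- function(s) calibration_entry(cal, ptm_state("LYS", s))
  expect_identical(ce("acetyl")$effect, 1.5)
  expect_identical(ce("monomethyl")$effect, -10.1)
  expect_identical(ce("dimethyl")$effect, -19.1)
  expect_identical(ce("trimethyl")$effect, -25.8)
  expect_identical(ce("monomethyl")$anchor, "calibrated")
  # every entry's rotamer offsets sum to zero
  sums <- vapply(cal$rotamer_offsets, sum, 0)
  expect_true(all(abs(sums) < 1e-9))
})

test_that("calibration entries with non-zero-sum offsets are rejected", {
  bad <- list(entries = list(list(
    residue = "LYS", state = "acetyl", nucleus = "CE", effect = 1.5,
    rotamer_offsets = list(`0` = 1, `180` = 1),
    anchor = "calibrated", note = "broken")))
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(bad, path, auto_unbox = TRUE)
  expect_error(load_calibration(path), "sum to zero")
})

test_that("degenerate surrogate reproduces effect plus rotamer offset exactly", {
  pair <- tiny_lys_pair()
  params <- surrogate_params(torsion_amplitude = 0, noise_sd = 0)
  rec <- simulate_shift_records(pair, params = params)
  d <- compute_delta(rec$modified, rec$unmodified)
  ent <- calibration_entry(load_calibration(), pair$state)
  want <- ent$effect + unname(ent$rotamer_offsets[rec$modified$rotamer])
  expect_equal(d$modified$delta, want, tolerance = 1e-12)
  expect_equal(d$unmodified$delta, rep(0, nrow(rec$unmodified)), tolerance = 1e-12)
})

test_that("surrogate shifts are reproducible under the seed", {
  pair <- tiny_lys_pair()
  r1 <- simulate_shift_records(pair, params = surrogate_params(seed = 5))
  r2 <- simulate_shift_records(pair, params = surrogate_params(seed = 5))
  r3 <- simulate_shift_records(pair, params = surrogate_params(seed = 6))
  expect_identical(r1, r2)
  expect_false(identical(r1$modified$value, r3$modified$value))
})

test_that("mean Delta agrees with the calibrated effect within standard error", {
  pair <- generate_paired_ensembles(ptm_state("LYS", "trimethyl"), 200, seed = 8)
  params <- surrogate_params(noise_sd = 0.5, seed = 3)
  rec <- simulate_shift_records(pair, params = params)
  d <- compute_delta(average_over_rotamers(rec$modified, pair$scheme),
                     rec$unmodified)
  n <- length(pair$unmodified)
  se <- sqrt(var(d$modified$delta) / n + params$noise_sd^2 / n)
  expect_lt(abs(mean(d$modified$delta) - (-25.8)), 3 * se)
})

test_that("shift/shielding conversion obeys delta = sigma_ref - sigma", {
  rec <- data.frame(value = 30, kind = "shift")
  sh <- to_shielding(rec, 180)
  expect_identical(sh$value, 150)
  expect_identical(sh$kind, "shielding")
  back <- to_shift(sh, 180)
  expect_identical(back$value, 30)
  expect_error(to_shielding(sh, 180), "not in shift space")
})

test_that("Delta from shifts equals minus Delta from shieldings", {
  pair <- tiny_lys_pair()
  rec <- simulate_shift_records(pair, params = surrogate_params(seed = 2))
  d_shift <- compute_delta(rec$modified, rec$unmodified)$modified$delta
  sig_mod <- to_shielding(rec$modified, 184.5)
  sig_unm <- to_shielding(rec$unmodified, 184.5)
  d_sigma <- sig_mod$value - mean(sig_unm$value)
  expect_equal(d_shift, -d_sigma, tolerance = 1e-12)
})

test_that("global reference constants cancel end-to-end", {
  pair <- tiny_lys_pair()
  rec <- simulate_shift_records(pair, params = surrogate_params(seed = 2))
  shifted <- rec
  shifted$modified$value <- shifted$modified$value + 7.3
  shifted$unmodified$value <- shifted$unmodified$value + 7.3
  d0 <- compute_delta(rec$modified, rec$unmodified)
  d1 <- compute_delta(shifted$modified, shifted$unmodified)
  expect_equal(d0$modified$delta, d1$modified$delta, tolerance = 1e-10)
  expect_equal(d0$unmodified$delta, d1$unmodified$delta, tolerance = 1e-10)
})

test_that("shielding logs parse to records matching the fixture values", {
  rec <- parse_shielding_log(test_path("fixtures", "shield.log"))
  expect_identical(nrow(rec), 3L)
  expect_identical(rec$value, c(158.4521, 21.8812, 201.3377))
  expect_identical(unique(rec$kind), "shielding")
  expect_identical(unique(rec$provenance), "parsed-log")
  trunc <- withr::local_tempfile(fileext = ".log")
  writeLines("SCF Done: no shieldings here", trunc)
  expect_error(parse_shielding_log(trunc), "no isotropic shielding block")
})
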