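#' Moment-match a Gamma distribution
#'
#' @param mean,sd target mean and standard deviation (> 0).
#' @return list with `shape` and `rate` (shape = (mean/sd)^2,
#'   rate = mean/sd^2).
#' @export
gamma_from_moments <- function(mean, sd) {
  stopifnot(mean > 0, sd > 0)
  list(shape = (mean / sd)^2, rate = mean / sd^2)
}

#' Build the two-state Bayesian model specification
#'
#' Each state's Delta samples are modelled as Gaussian with unknown mean
#' and standard deviation.  The prior on the mean is a student-t centred
#' at the state's empirical Delta mean with scale 0.35 ppm (the
#' theory-vs-experiment agreement established for the Lys validation
#' data) and degrees of freedom given an Exponential hyper-prior with
#' mean 30 (near-Gaussian unless the data demand heavy tails).  The
#' prior on the standard deviation is a Gamma moment-matched to the
#' experimental reference statistics.
#'
#' @param deltaA,deltaB [kde_density()] distributions (or numeric
#'   vectors) of the two states' Delta samples.
#' @param ref a [compute_reference_stats()] result (its `sd` must be
#'   positive); sets the Gamma prior moments on sigma.
#' @param mean_scale scale of the student-t prior on the mean (ppm).
#' @param nu_mean mean of the Exponential hyper-prior on the degrees of
#'   freedom.
#' @param sd_prior_mean,sd_prior_sd moments of the Gamma prior on sigma;
#'   default both to `ref$sd`.
#' @param state_priors prior state probabilities (sum to 1).
#' @param likelihood `"gaussian"` (default; the student-t enters as the
#'   prior on the mean) or `"student_t"` (alternate reading: student-t
#'   likelihood with the Exponential hyper-prior on its degrees of
#'   freedom).
#' @param chains,draws,warmup,seed sampler settings.
#' @return object of class `two_state_spec`.
#' @export
build_model_spec <- function(deltaA, deltaB, ref,
                             mean_scale = 0.35, nu_mean = 30,
                             sd_prior_mean = NULL, sd_prior_sd = NULL,
                             state_priors = c(0.5, 0.5),
                             likelihood = c("gaussian", "student_t"),
                             chains = 4L, draws = 1000L, warmup = 1000L,
                             seed = 1L) {
  likelihood <- match.arg(likelihood)
  sA <- if (inherits(deltaA, "delta_distribution")) deltaA$samples else as.numeric(deltaA)
  sB <- if (inherits(deltaB, "delta_distribution")) deltaB$samples else as.numeric(deltaB)
  if (!length(sA) || !length(sB)) stop("both Delta distributions must be nonempty")
  if (is.null(sd_prior_mean)) sd_prior_mean <- ref$sd
  if (is.null(sd_prior_sd)) sd_prior_sd <- ref$sd
  if (!is.finite(sd_prior_mean) || sd_prior_mean <= 0) {
    stop("reference sd must be positive to set the Gamma prior on sigma")
  }
  stopifnot(mean_scale > 0, abs(sum(state_priors) - 1) < 1e-9)
  g <- gamma_from_moments(sd_prior_mean, sd_prior_sd)
  structure(list(
    states = list(
      A = list(samples = sA, mean_loc = mean(sA)),
      B = list(samples = sB, mean_loc = mean(sB))
    ),
    mean_scale = mean_scale, nu_mean = nu_mean,
    sd_prior = list(mean = sd_prior_mean, sd = sd_prior_sd,
                    shape = g$shape, rate = g$rate),
    state_priors = state_priors, likelihood = likelihood,
    sampler = list(chains = as.integer(chains), draws = as.integer(draws),
                   warmup = as.integer(warmup), seed = as.integer(seed))
  ), class = "two_state_spec")
}

.JAGS_GAUSSIAN <- "
model {
  for (i in 1:N) { y[i] ~ dnorm(mu, tau) }
  mu ~ dt(loc, prec_scale, nu)
  nu ~ dexp(lambda)
  sigma ~ dgamma(shape, rate)
  tau <- pow(sigma, -2)
}"

.JAGS_STUDENT_T <- "
model {
  for (i in 1:N) { y[i] ~ dt(mu, tau, nu) }
  mu ~ dnorm(loc, prec_scale)
  nu ~ dexp(lambda)
  sigma ~ dgamma(shape, rate)
  tau <- pow(sigma, -2)
}"

.fit_one_state <- function(y, loc, spec, seed) {
  data <- list(y = y, N = length(y), loc = loc,
               prec_scale = 1 / spec$mean_scale^2,
               lambda = 1 / spec$nu_mean,
               shape = spec$sd_prior$shape, rate = spec$sd_prior$rate)
  model_str <- if (spec$likelihood == "gaussian") .JAGS_GAUSSIAN else .JAGS_STUDENT_T
  inits <- lapply(seq_len(spec$sampler$chains), function(ch) list(
    mu = loc, sigma = spec$sd_prior$mean, nu = spec$nu_mean,
    .RNG.name = "base::Mersenne-Twister",
    .RNG.seed = .fan_seed(seed, ch)
  ))
  jm <- rjags::jags.model(textConnection(model_str), data = data,
                          inits = inits, n.chains = spec$sampler$chains,
                          n.adapt = spec$sampler$warmup, quiet = TRUE)
  post <- rjags::coda.samples(jm, c("mu", "sigma", "nu"),
                              n.iter = spec$sampler$draws)
  rhat <- if (spec$sampler$chains > 1) {
    unname(coda::gelman.diag(post, autoburnin = FALSE,
                             multivariate = FALSE)$psrf[, 1])
  } else rep(NA_real_, 3)
  ess <- unname(coda::effectiveSize(post))
  mat <- as.matrix(post)
  list(draws = data.frame(mu = mat[, "mu"], sigma = mat[, "sigma"],
                          nu = mat[, "nu"]),
       diagnostics = data.frame(parameter = c("mu", "nu", "sigma"),
                                rhat = rhat, ess = ess))
}

#' Fit the two-state model by MCMC
#'
#' Fits each state's Delta samples independently (no shared parameters)
#' with JAGS, recording split-Rhat and effective sample size.
#'
#' @param spec a [build_model_spec()].
#' @param strict escalate convergence warnings (Rhat > 1.05) to errors.
#' @return object of class `posterior_draws`: per-state draw tables
#'   (`mu`, `sigma`, `nu`) and diagnostics.
#' @export
fit_state_model <- function(spec, strict = FALSE) {
  stopifnot(inherits(spec, "two_state_spec"))
  if (length(spec$states$A$samples) < 10 || length(spec$states$B$samples) < 10) {
    stop("need at least 10 Delta samples per state")
  }
  fits <- list(
    A = .fit_one_state(spec$states$A$samples, spec$states$A$mean_loc, spec,
                       .fan_seed(spec$sampler$seed, 101L)),
    B = .fit_one_state(spec$states$B$samples, spec$states$B$mean_loc, spec,
                       .fan_seed(spec$sampler$seed, 202L))
  )
  diag <- rbind(cbind(state = "A", fits$A$diagnostics),
                cbind(state = "B", fits$B$diagnostics))
  bad <- diag$rhat[is.finite(diag$rhat)] > 1.05
  if (any(bad)) {
    msg <- sprintf("MCMC convergence suspect: max Rhat = %.3f", max(diag$rhat, na.rm = TRUE))
    if (strict) stop(msg) else warning(msg)
  }
  structure(list(A = fits$A$draws, B = fits$B$draws, diagnostics = diag,
                 spec = spec), class = "posterior_draws")
}

#' @export
print.posterior_draws <- function(x, ...) {
  cat(sprintf("posterior_draws: %d draws/state; mu_A %.2f, mu_B %.2f; max Rhat %.3f\n",
              nrow(x$A), mean(x$A$mu), mean(x$B$mu),
              max(x$diagnostics$rhat, na.rm = TRUE)))
  invisible(x)
}

#' Posterior probability profile P(state A | Delta)
#'
#' For each retained posterior draw the two states' predictive Gaussian
#' densities are combined by Bayes' rule with the state prior
#' probabilities; the mean curve is the average over draw curves and
#' the uncertainty band the 5th/95th percentile of the draw curves at
#' each grid point.
#'
#' @param draws a [fit_state_model()] result.
#' @param grid sorted Delta grid (ppm); defaults to a 512-point span of
#'   both states' samples.
#' @param state_priors prior probabilities of states A and B.
#' @param band band quantiles (default 0.05/0.95).
#' @return object of class `probability_profile`: `grid`, `mean`
#'   (P_A), `band_lo`, `band_hi`, `draw_curves` (matrix), priors.
#' @export
probability_profile <- function(draws, grid = NULL,
                                state_priors = draws$spec$state_priors,
                                band = c(0.05, 0.95)) {
  stopifnot(inherits(draws, "posterior_draws"))
  if (is.null(grid)) {
    all_s <- c(draws$spec$states$A$samples, draws$spec$states$B$samples)
    pad <- 2 * stats::sd(all_s)
    grid <- seq(min(all_s) - pad, max(all_s) + pad, length.out = 512L)
  }
  if (is.unsorted(grid)) stop("grid must be sorted")
  n <- min(nrow(draws$A), nrow(draws$B))
  # log-space Bayes ratio: stable where both densities underflow
  lA <- outer(seq_len(n), grid, function(k, x)
    stats::dnorm(x, draws$A$mu[k], draws$A$sigma[k], log = TRUE))
  lB <- outer(seq_len(n), grid, function(k, x)
    stats::dnorm(x, draws$B$mu[k], draws$B$sigma[k], log = TRUE))
  pA <- stats::plogis(lA - lB + log(state_priors[1] / state_priors[2]))
  q <- apply(pA, 2, stats::quantile, probs = band)
  structure(list(grid = grid, mean = colMeans(pA),
                 band_lo = q[1, ], band_hi = q[2, ],
                 draw_curves = pA, state_priors = state_priors,
                 band_probs = band), class = "probability_profile")
}

#' @export
print.probability_profile <- function(x, ...) {
  cat(sprintf("probability_profile: %d grid points in [%.2f, %.2f] ppm, %d draw curves\n",
              length(x$grid), min(x$grid), max(x$grid), nrow(x$draw_curves)))
  invisible(x)
}

#' Plot a probability profile
#'
#' Mean curve with draw-quantile uncertainty band.
#'
#' @param x a `probability_profile`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.probability_profile <- function(x, ...) {
  graphics::plot(x$grid, x$mean, type = "n", ylim = c(0, 1),
                 xlab = expression(Delta ~ "(ppm)"), ylab = "P(state A)", ...)
  graphics::polygon(c(x$grid, rev(x$grid)), c(x$band_lo, rev(x$band_hi)),
                    col = grDevices::adjustcolor("steelblue", 0.3), border = NA)
  graphics::lines(x$grid, x$mean, col = "red", lwd = 2)
  invisible(x)
}

#' Delta regions exceeding a probability level
#'
#' Maximal grid sub-intervals on which the mean probability curve of the
#' requested state is at least `level`; possibly several (unequal
#' posterior sigmas make both tails favour the wider state), possibly
#' none.
#'
#' @param profile a [probability_profile()].
#' @param level probability threshold in (0, 1), e.g. 0.8.
#' @param state `"A"` or `"B"`.
#' @return data frame with columns `lo`, `hi` (ppm), zero rows if the
#'   level is never reached.
#' @export
threshold_query <- function(profile, level, state = c("A", "B")) {
  stopifnot(level > 0, level < 1)
  state <- match.arg(state)
  curve <- if (state == "A") profile$mean else 1 - profile$mean
  ok <- curve >= level
  if (!any(ok)) return(data.frame(lo = numeric(0), hi = numeric(0)))
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(lo = profile$grid[starts[keep]], hi = profile$grid[ends[keep]])
}

#' Classify an observed chemical shift
#'
#' Re-references the observed shift to DSS, converts it to a Delta
#' value against the experimental reference mean of the unmodified
#' residue, and reads the state probabilities off the profile's mean
#' curve (linear interpolation) with its uncertainty band.
#'
#' @param observed_shift observed shift (ppm).
#' @param standard reference standard of the observation
#'   (`"DSS"`/`"TMS"`/`"TSP"`).
#' @param ref [compute_reference_stats()] for the unmodified residue and
#'   report nucleus.
#' @param profile [probability_profile()] for the state pair of
#'   interest.
#' @return list with `delta`, `p_A`, `p_B`, `band` (lo/hi at Delta).
#' @export
classify_observation <- function(observed_shift, standard, ref, profile) {
  delta <- rereference_shift(observed_shift, standard) - ref$mean
  rng <- range(profile$grid)
  if (delta < rng[1] || delta > rng[2]) {
    stop(sprintf("Delta = %.2f ppm is out of calibrated range [%.2f, %.2f]: extrapolation refused",
                 delta, rng[1], rng[2]))
  }
  pa <- stats::approx(profile$grid, profile$mean, xout = delta)$y
  lo <- stats::approx(profile$grid, profile$band_lo, xout = delta)$y
  hi <- stats::approx(profile$grid, profile$band_hi, xout = delta)$y
  list(delta = delta, p_A = pa, p_B = 1 - pa, band = c(lo = lo, hi = hi))
}
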