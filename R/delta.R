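#' Average shift records over rotamer states
#'
#' Added methyl/acetyl groups make the molecule asymmetric, so shifts
#' are computed per rotamer and averaged (arithmetic mean) per backbone
#' index before any Delta statistics.  Single-rotamer states pass
#' through unchanged.
#'
#' @param records shift-record data frame (one state).
#' @param scheme optional [enumerate_rotamer_scheme()] used to check
#'   that every backbone index carries every rotamer.
#' @return shift-record data frame with one row per backbone index
#'   (rotamer label `"avg"` where averaging occurred).
#' @export
average_over_rotamers <- function(records, scheme = NULL) {
  rot_labels <- unique(records$rotamer)
  if (!is.null(scheme)) rot_labels <- scheme$rotamers$label
  if (length(rot_labels) <= 1) return(records)
  tab <- table(records$backbone_index)
  cover <- tapply(records$rotamer, records$backbone_index,
                  function(r) setdiff(rot_labels, r))
  missing <- Filter(length, cover)
  if (length(missing)) {
    stop("incomplete rotamer coverage for backbone index ",
         names(missing)[1], ": missing ",
         paste(missing[[1]], collapse = ", "))
  }
  agg <- stats::aggregate(value ~ backbone_index, data = records, FUN = mean)
  first <- records[!duplicated(records$backbone_index), ]
  first <- first[order(first$backbone_index), ]
  agg <- agg[order(agg$backbone_index), ]
  first$value <- agg$value
  first$rotamer <- "avg"
  first$conformation_id <- sprintf("%s-%s-b%04d-avg", first$residue,
                                   first$state, first$backbone_index)
  rownames(first) <- NULL
  first
}

#' Compute Delta samples from paired shift records
#'
#' Delta is each conformation's shift minus the mean shift of the
#' unmodified ensemble; it is emitted for both ensembles, so the
#' unmodified Delta distribution has mean exactly zero by construction
#' and Delta is invariant to any global reference constant.
#'
#' @param modified,unmodified shift-record data frames (same nucleus,
#'   shift kind; convert shieldings with [to_shift()] first).
#' @return list of two data frames (`modified`, `unmodified`) with
#'   columns `backbone_index`, `residue`, `state`, `nucleus`, `delta`.
#' @export
compute_delta <- function(modified, unmodified) {
  if (nrow(modified) == 0 || nrow(unmodified) == 0) stop("empty ensemble")
  if (!identical(unique(modified$nucleus), unique(unmodified$nucleus))) {
    stop("nucleus mismatch between ensembles")
  }
  if (any(c(modified$kind, unmodified$kind) != "shift")) {
    stop("records must be in shift space; convert shieldings with to_shift()")
  }
  ref <- mean(unmodified$value)
  one <- function(df) data.frame(
    backbone_index = df$backbone_index, residue = df$residue,
    state = df$state, nucleus = df$nucleus, delta = df$value - ref,
    stringsAsFactors = FALSE)
  list(modified = one(modified), unmodified = one(unmodified))
}

#' Kernel density summary of Delta samples
#'
#' Gaussian-kernel KDE on a uniform 512-point grid spanning the samples
#' plus/minus four bandwidths; bandwidth by Silverman's rule unless
#' given.  The summary mean is the trapezoid first moment of the density
#' (for a Gaussian kernel this equals the sample mean up to grid
#' truncation); the mode is the grid argmax with ties broken toward
#' smaller Delta.
#'
#' @param samples numeric Delta values (>= 2) or a data frame with a
#'   `delta` column.
#' @param bandwidth numeric bandwidth (ppm) or `"silverman"`.
#' @param n_grid grid size (default 512).
#' @param state,nucleus optional labels carried on the result.
#' @return object of class `delta_distribution` with `samples`, `kde`
#'   (`grid`, `density`, `bandwidth`) and `summary` (mean/sd/mode).
#' @export
kde_density <- function(samples, bandwidth = "silverman", n_grid = 512L,
                        state = NULL, nucleus = NULL) {
  if (is.data.frame(samples)) {
    if (is.null(state) && nrow(samples)) state <- samples$state[1]
    if (is.null(nucleus) && nrow(samples)) nucleus <- samples$nucleus[1]
    samples <- samples$delta
  }
  if (length(samples) < 2) stop("need at least 2 samples for a KDE")
  bw <- if (identical(bandwidth, "silverman")) stats::bw.nrd0(samples) else bandwidth
  lo <- min(samples) - 4 * bw
  hi <- max(samples) + 4 * bw
  d <- stats::density(samples, bw = bw, kernel = "gaussian",
                      from = lo, to = hi, n = n_grid)
  dx <- diff(d$x[1:2])
  mode_idx <- which(d$y == max(d$y))[1]  # ties: smallest grid value wins
  structure(list(
    state = state, nucleus = nucleus, samples = samples,
    kde = list(grid = d$x, density = d$y, bandwidth = bw),
    summary = list(
      mean = sum(d$x * d$y) * dx / (sum(d$y) * dx),
      sd = stats::sd(samples),
      mode = d$x[mode_idx],
      integral = sum(d$y) * dx,
      n = length(samples)
    )
  ), class = "delta_distribution")
}

#' @export
print.delta_distribution <- function(x, ...) {
  cat(sprintf("delta_distribution%s: n=%d, mean %.3f ppm, sd %.3f ppm, mode %.3f ppm (bw %.3f)\n",
              if (!is.null(x$state)) paste0(" [", x$state, "]") else "",
              x$summary$n, x$summary$mean, x$summary$sd, x$summary$mode,
              x$kde$bandwidth))
  invisible(x)
}

#' Plot Delta density overlays
#'
#' @param x a `delta_distribution`.
#' @param add overlay on an existing plot.
#' @param ... passed to [graphics::plot()]/[graphics::lines()].
#' @export
plot.delta_distribution <- function(x, add = FALSE, ...) {
  if (add) graphics::lines(x$kde$grid, x$kde$density, ...)
  else graphics::plot(x$kde$grid, x$kde$density, type = "l",
                      xlab = expression(Delta ~ "(ppm)"), ylab = "density", ...)
  invisible(x)
}

#' Pool Delta distributions that are spectroscopically indistinguishable
#'
#' Concatenates the Delta samples of several distributions (e.g. the
#' two mono-methylation sites of Arg) and re-estimates the KDE.
#'
#' @param distributions list of `delta_distribution` objects sharing a
#'   nucleus.
#' @param label label for the pooled state.
#' @param ... passed to [kde_density()].
#' @return a `delta_distribution`.
#' @export
pool_states <- function(distributions, label = "pooled", ...) {
  nuc <- unique(vapply(distributions, function(d)
    if (is.null(d$nucleus)) NA_character_ else d$nucleus, ""))
  nuc <- nuc[!is.na(nuc)]
  if (length(nuc) > 1) stop("nucleus mismatch: ", paste(nuc, collapse = ", "))
  pooled <- unlist(lapply(distributions, `[[`, "samples"))
  kde_density(pooled, state = label,
              nucleus = if (length(nuc)) nuc else NULL, ...)
}
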