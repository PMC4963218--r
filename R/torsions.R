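#' Normalize angles to (-180, 180]
#'
#' @param x numeric vector of angles in degrees.
#' @return angles wrapped into the half-open interval (-180, 180].
#' @export
wrap_angle <- function(x) {
  w <- x - 360 * floor((x + 180) / 360)
  # floor() maps +180 to -180; put it back on the closed end
  w[w == -180] <- 180
  w
}

# Packaged backbone torsion library: a Ramachandran-region Gaussian mixture
# per residue plus empirical chi-rotamer weights.  It stands in for a
# non-redundant X-ray torsion database, which is not distributed; it only
# needs to be a representative, reproducible sample of accessible torsions.
.BASINS <- data.frame(
  basin = c("alphaR", "beta", "ppII", "alphaL"),
  phi   = c(-63, -120, -75, 57),
  psi   = c(-43, 135, 150, 47),
  sd_phi = c(10, 20, 12, 10),
  sd_psi = c(10, 20, 12, 10),
  stringsAsFactors = FALSE
)

.BASIN_WEIGHTS <- list(
  LYS = c(alphaR = 0.42, beta = 0.26, ppII = 0.27, alphaL = 0.05),
  ARG = c(alphaR = 0.42, beta = 0.26, ppII = 0.27, alphaL = 0.05),
  SER = c(alphaR = 0.34, beta = 0.29, ppII = 0.30, alphaL = 0.07),
  THR = c(alphaR = 0.32, beta = 0.36, ppII = 0.27, alphaL = 0.05),
  ASN = c(alphaR = 0.32, beta = 0.24, ppII = 0.26, alphaL = 0.18)
)

# chi rotamer positions (deg), weights and circular sd per sampled chi
.CHI_ROTAMERS <- list(
  values  = c(m60 = -60, t = 180, p60 = 60),
  weights = c(m60 = 0.52, t = 0.33, p60 = 0.15),
  sd      = 9
)

# number of side-chain torsions sampled from the library per residue
.N_CHI <- c(LYS = 4, ARG = 4, SER = 1, THR = 1, ASN = 2)

#' Packaged torsion-library parameters
#'
#' Returns the parameters of the packaged backbone/side-chain torsion
#' library for one residue type: a four-basin Ramachandran Gaussian
#' mixture (alpha-R, beta, polyproline-II, alpha-L) and the chi-rotamer
#' positions/weights used by [sample_torsions()].  Tests use this as the
#' reference density the sampler must reproduce.
#'
#' @param residue one of `"LYS"`, `"ARG"`, `"SER"`, `"THR"`, `"ASN"`.
#' @return list with elements `basins` (data frame), `weights`,
#'   `chi` (positions/weights/sd) and `n_chi`.
#' @export
torsion_library <- function(residue) {
  residue <- match.arg(toupper(residue), names(.BASIN_WEIGHTS))
  list(
    basins = .BASINS,
    weights = .BASIN_WEIGHTS[[residue]],
    chi = .CHI_ROTAMERS,
    n_chi = unname(.N_CHI[residue])
  )
}

#' Sample backbone and side-chain torsions for a residue
#'
#' Draws `n` torsion sets for the central residue of a capped model
#' tripeptide from the packaged torsion library.  Each torsion set holds
#' phi/psi, the residue's chi angles, and the terminal-cap dihedrals.
#' Sampling is fully reproducible under `seed`.
#'
#' @param residue residue type (`"LYS"`, `"ARG"`, `"SER"`, `"THR"`, `"ASN"`).
#' @param n number of torsion sets (>= 0).
#' @param seed integer seed.
#' @return list of `torsion_set` objects (fields `phi`, `psi`, `chi`,
#'   `caps`), all angles in degrees in (-180, 180].
#' @export
sample_torsions <- function(residue, n, seed = 1L) {
  residue <- toupper(residue)
  if (!residue %in% names(.BASIN_WEIGHTS)) {
    stop("unsupported residue '", residue, "'; supported: ",
         paste(names(.BASIN_WEIGHTS), collapse = ", "))
  }
  stopifnot(n >= 0)
  lib <- torsion_library(residue)
  if (n == 0) return(list())
  old <- .Random.seed_exists()
  on.exit(.restore_seed(old), add = TRUE)
  set.seed(as.integer(seed))
  basin_idx <- sample.int(nrow(lib$basins), n, replace = TRUE,
                          prob = lib$weights[lib$basins$basin])
  phi <- wrap_angle(stats::rnorm(n, lib$basins$phi[basin_idx],
                                 lib$basins$sd_phi[basin_idx]))
  psi <- wrap_angle(stats::rnorm(n, lib$basins$psi[basin_idx],
                                 lib$basins$sd_psi[basin_idx]))
  nchi <- lib$n_chi
  chi_mat <- matrix(0, nrow = n, ncol = nchi)
  for (k in seq_len(nchi)) {
    rot <- sample.int(3L, n, replace = TRUE, prob = lib$chi$weights)
    chi_mat[, k] <- wrap_angle(stats::rnorm(n, lib$chi$values[rot], lib$chi$sd))
  }
  lapply(seq_len(n), function(i) {
    torsion_set(phi = phi[i], psi = psi[i],
                chi = chi_mat[i, ],
                caps = c(ace = 180, nme = 180))
  })
}

#' Construct a torsion set
#'
#' @param phi,psi backbone dihedrals in degrees.
#' @param chi numeric vector of side-chain dihedrals (chi1, chi2, ...).
#' @param caps named terminal-cap dihedrals (degrees).
#' @return object of class `torsion_set`.
#' @export
torsion_set <- function(phi, psi, chi = numeric(0), caps = c(ace = 180, nme = 180)) {
  ang <- c(phi, psi, chi, caps)
  stopifnot(all(is.finite(ang)))
  if (any(ang <= -180 | ang > 180)) stop("angles must lie in (-180, 180]")
  structure(list(phi = phi, psi = psi, chi = as.numeric(chi), caps = caps),
            class = "torsion_set")
}

#' @export
print.torsion_set <- function(x, ...) {
  cat(sprintf("torsion_set: phi=%.1f psi=%.1f chi=[%s]\n", x$phi, x$psi,
              paste(sprintf("%.1f", x$chi), collapse = ", ")))
  invisible(x)
}

# Save/restore the global RNG state so samplers honour explicit seeds
# without perturbing the caller's random stream.
.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# Evaluate a sub-task seed from a base seed, keeping it inside 32-bit range.
.fan_seed <- function(seed, k) {
  as.integer((as.double(seed) * 1103L + k * 7919L) %% 2147483629)
}
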