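# Baseline 13C shifts (ppm, DSS scale) of the report nucleus in the
# unmodified residue; realistic values so surrogate shifts land in the
# right spectral region.  Delta is invariant to them by construction.
.BASE_SHIFT <- c("LYS.CE" = 41.9, "ARG.CZ" = 159.8, "SER.CB" = 63.8,
                 "THR.CB" = 69.6, "ASN.CG" = 176.8)

#' Surrogate model parameters
#'
#' The surrogate emits per-conformation shifts with the statistical
#' structure a shielding computation would produce: a smooth torsion
#' response shared by paired twins (so it cancels in Delta), zero-sum
#' per-rotamer offsets, the calibrated additive modification effect and
#' i.i.d. Gaussian observation noise.
#'
#' @param torsion_amplitude amplitude (ppm) of the low-order periodic
#'   torsion response; the default 1 gives an unmodified shift sd of
#'   about 1 ppm.
#' @param rotamer_spread target mean absolute per-rotamer deviation
#'   (ppm); calibration offsets are scaled by `rotamer_spread / 1.3`.
#' @param noise_sd Gaussian observation noise sd (ppm, >= 0).
#' @param sigma_ref reference shielding constant (ppm) for the
#'   shift/shielding conversion delta = sigma_ref - sigma.
#' @param seed integer seed for the noise draws.
#' @return object of class `surrogate_params`.
#' @export
surrogate_params <- function(torsion_amplitude = 1.0, rotamer_spread = 1.3,
                             noise_sd = 0.5, sigma_ref = 184.5, seed = 1L) {
  stopifnot(torsion_amplitude >= 0, noise_sd >= 0, rotamer_spread >= 0)
  structure(list(torsion_amplitude = torsion_amplitude,
                 rotamer_spread = rotamer_spread,
                 noise_sd = noise_sd, sigma_ref = sigma_ref,
                 seed = as.integer(seed)),
            class = "surrogate_params")
}

# Smooth low-order periodic torsion response (ppm at unit amplitude).
# Identical for paired twins because they share phi/psi/chi1.
.torsion_response <- function(ts, amplitude) {
  rad <- pi / 180
  chi1 <- if (length(ts$chi)) ts$chi[1] else 0
  amplitude * (sin(ts$phi * rad) + cos(ts$psi * rad) + 0.5 * sin(chi1 * rad))
}

#' Simulate shift records for a paired ensemble
#'
#' Each record's value is `base + t(torsions) + rotamer offset + effect +
#' noise`, in shift space (ppm).  The torsion response `t` is identical
#' for paired modified/unmodified conformations, the rotamer offsets are
#' zero-sum within a state, `effect` is the calibrated modification
#' effect (zero on the unmodified side) and the noise is i.i.d.
#' Gaussian.  Reproducible under `params$seed`.
#'
#' @param pair an [generate_paired_ensembles()] result.
#' @param calibration a [load_calibration()] table covering the pair's
#'   state.
#' @param params a [surrogate_params()].
#' @return list with `modified` and `unmodified` shift-record data
#'   frames (columns `conformation_id`, `backbone_index`, `rotamer`,
#'   `residue`, `state`, `nucleus`, `value`, `kind`, `provenance`).
#' @export
simulate_shift_records <- function(pair, calibration = load_calibration(),
                                   params = surrogate_params()) {
  st <- pair$state
  un <- unmodified_state(st)
  ent <- calibration_entry(calibration, st)
  ent_un <- calibration_entry(calibration, un)
  base <- .BASE_SHIFT[paste(st$residue, st$nucleus, sep = ".")]
  if (is.na(base)) stop("no baseline shift for ", st$residue, "/", st$nucleus)
  scale_off <- params$rotamer_spread / 1.3

  one_side <- function(confs, state, entry) {
    n <- length(confs)
    t_resp <- vapply(confs, function(cf)
      .torsion_response(cf$torsions, params$torsion_amplitude), 0)
    offs <- vapply(confs, function(cf) {
      o <- entry$rotamer_offsets[as.character(cf$rotamer)]
      if (is.na(o)) stop("calibration entry ", state$state,
                         " lacks rotamer offset for '", cf$rotamer, "'")
      unname(o)
    }, 0)
    data.frame(
      conformation_id = vapply(confs, function(cf)
        sprintf("%s-%s-b%04d-r%s", state$residue, state$state,
                cf$backbone_index, cf$rotamer), ""),
      backbone_index = vapply(confs, `[[`, 0L, "backbone_index"),
      rotamer = vapply(confs, `[[`, "", "rotamer"),
      residue = state$residue, state = state$state, nucleus = st$nucleus,
      value = base + t_resp + offs * scale_off + entry$effect,
      kind = "shift", provenance = "surrogate",
      stringsAsFactors = FALSE
    )
  }

  mod <- one_side(pair$modified, st, ent)
  unm <- one_side(pair$unmodified, un, ent_un)
  old <- .Random.seed_exists()
  on.exit(.restore_seed(old), add = TRUE)
  set.seed(.fan_seed(params$seed, 77L))
  if (params$noise_sd > 0) {
    mod$value <- mod$value + stats::rnorm(nrow(mod), 0, params$noise_sd)
    unm$value <- unm$value + stats::rnorm(nrow(unm), 0, params$noise_sd)
  }
  list(modified = mod, unmodified = unm)
}

#' Convert shift records between shift and shielding
#'
#' Uses the defining identity delta = sigma_ref - sigma; converting
#' twice is the identity.
#'
#' @param records shift-record data frame.
#' @param sigma_ref reference shielding constant (ppm).
#' @return records with `value` converted and `kind` flipped.
#' @export
to_shielding <- function(records, sigma_ref) {
  if (any(records$kind != "shift")) stop("records are not in shift space")
  records$value <- sigma_ref - records$value
  records$kind <- "shielding"
  records
}

#' @rdname to_shielding
#' @export
to_shift <- function(records, sigma_ref) {
  if (any(records$kind != "shielding")) stop("records are not in shielding space")
  records$value <- sigma_ref - records$value
  records$kind <- "shift"
  records
}

#' Parse isotropic shieldings from a quantum-chemistry log
#'
#' Extracts per-atom isotropic shielding lines of the form
#' `"  12  C  Isotropic =  150.1234  Anisotropy = ..."` from a GIAO
#' shielding-job text log.
#'
#' @param path log file.
#' @param conf optional `conformation` whose atom names (by log atom
#'   index) annotate the records.
#' @param nuclei optional atom names to keep (requires `conf`).
#' @return shift-record data frame with `kind = "shielding"`,
#'   `provenance = "parsed-log"`.
#' @export
parse_shielding_log <- function(path, conf = NULL, nuclei = NULL) {
  lines <- readLines(path)
  pat <- "^\\s*(\\d+)\\s+([A-Za-z]{1,2})\\s+Isotropic\\s*=\\s*(-?[0-9.]+)"
  hits <- regmatches(lines, regexec(pat, lines))
  hits <- hits[lengths(hits) == 4]
  if (!length(hits)) {
    stop("no isotropic shielding block found in '", path, "'")
  }
  idx <- vapply(hits, function(h) as.integer(h[2]), 0L)
  elem <- vapply(hits, function(h) h[3], "")
  val <- vapply(hits, function(h) as.numeric(h[4]), 0)
  name <- if (!is.null(conf)) conf$atoms$name[idx] else NA_character_
  rec <- data.frame(
    conformation_id = NA_character_, backbone_index = NA_integer_,
    rotamer = NA_character_, residue = NA_character_, state = NA_character_,
    nucleus = if (!is.null(conf)) name else paste0(elem, idx),
    value = val, kind = "shielding", provenance = "parsed-log",
    stringsAsFactors = FALSE
  )
  if (!is.null(nuclei)) {
    if (is.null(conf)) stop("'nuclei' filtering requires 'conf'")
    rec <- rec[rec$nucleus %in% nuclei, , drop = FALSE]
  }
  rec
}
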