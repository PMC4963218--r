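# Extend library torsions with the extra dihedrals a modification state
# introduces into the torsion set itself (glycan linkage torsions,
# sampled at the three staggered positions; the Asn amide linkage is
# planar and fixed trans).
.extend_torsions <- function(ts, state, glyco_draw) {
  if (!state$modified || state$residue %in% c("LYS", "ARG")) return(ts)
  pos <- c(60, -60, 180)
  if (state$residue %in% c("SER", "THR")) {
    torsion_set(ts$phi, ts$psi, c(ts$chi[1], pos[glyco_draw[1]], pos[glyco_draw[2]]),
                ts$caps)
  } else { # ASN: chi3 planar amide, chi4 sampled
    torsion_set(ts$phi, ts$psi, c(ts$chi[1:2], 180, pos[glyco_draw[1]]), ts$caps)
  }
}

# Truncate a modified state's torsion set back to the unmodified arity
# (glycan removal keeps every remaining torsion identical).
.truncate_torsions <- function(ts, residue) {
  n <- switch(residue, LYS = 4L, ARG = 4L, SER = 1L, THR = 1L, ASN = 2L)
  torsion_set(ts$phi, ts$psi, ts$chi[seq_len(n)], ts$caps)
}

#' Generate paired modified/unmodified conformational ensembles
#'
#' Rejection-samples backbone/side-chain torsions from the packaged
#' library, builds the unmodified conformation and every rotamer of the
#' modified state on each candidate torsion set, and accepts a backbone
#' only when all of its conformations are free of atomic overlaps.
#' Accepted pairs share identical backbone and side-chain torsions, so
#' conformational contributions to the chemical shift cancel exactly in
#' the Delta statistic.  For glycosylation states the unmodified twin is
#' the monosaccharide-removed conformation with identical remaining
#' torsions.
#'
#' @param state a modified [ptm_state()].
#' @param n_backbones number of accepted backbone conformations (>= 1);
#'   each rotamer of the state is built on every accepted backbone.
#' @param seed integer seed; the ensemble is reproducible under it.
#' @param overlap_factor,bond_exclusion_depth clash criterion, see
#'   [detect_clashes()].
#' @param acceptance_floor abort if the clash-acceptance rate drops below
#'   this after 200 candidates.
#' @return object of class `ensemble_pair`: `unmodified` and `modified`
#'   conformation lists, a `pairing` table (backbone index, rotamer,
#'   list positions), the rotamer scheme and the seed.
#' @export
generate_paired_ensembles <- function(state, n_backbones, seed = 1L,
                                      overlap_factor = 0.5,
                                      bond_exclusion_depth = 3L,
                                      acceptance_floor = 0.02) {
  stopifnot(inherits(state, "ptm_state"), n_backbones >= 1)
  if (!state$modified) stop("state must be a modified form; its unmodified twin is generated automatically")
  res <- .generate_study(state$residue, list(state), n_backbones, seed,
                         overlap_factor, bond_exclusion_depth, acceptance_floor)
  res$pairs[[1]]
}

#' Generate the full paired study for one residue
#'
#' Builds one shared unmodified ensemble and an [generate_paired_ensembles()]
#' pair for every modified state of the residue, all on the same accepted
#' backbone torsion sets, so the whole study shares a single set of
#' torsions.  With 500 backbones this yields the canonical conformer
#' bookkeeping: 5,000 conformations for Lys (500 + 1,000 + 1,500 + 1,500
#' + 500) and 6,000 for Arg (500 + 2,500 + 3,000).
#'
#' @inheritParams generate_paired_ensembles
#' @param residue residue type.
#' @return list with `unmodified` (shared ensemble), `pairs` (named list
#'   of `ensemble_pair`), `n_total` (distinct conformations: shared
#'   unmodified + all modified), `seed`.
#' @export
generate_residue_study <- function(residue, n_backbones = 500L, seed = 1L,
                                   overlap_factor = 0.5,
                                   bond_exclusion_depth = 3L,
                                   acceptance_floor = 0.02) {
  residue <- toupper(residue)
  tab <- ptm_states()
  states <- lapply(tab$state[tab$residue == residue & tab$modified],
                   function(s) ptm_state(residue, s))
  if (!length(states)) stop("unsupported residue '", residue, "'")
  .generate_study(residue, states, n_backbones, seed,
                  overlap_factor, bond_exclusion_depth, acceptance_floor)
}

.generate_study <- function(residue, states, n_backbones, seed,
                            overlap_factor, bond_exclusion_depth,
                            acceptance_floor) {
  unmod_state <- unmodified_state(states[[1]])
  schemes <- lapply(states, enumerate_rotamer_scheme,
                    conformers_per_rotamer = n_backbones)

  accepted <- list()   # per accepted backbone: torsions + built conformations
  n_cand <- 0L; n_acc <- 0L; batch <- 0L
  while (n_acc < n_backbones) {
    batch <- batch + 1L
    want <- max(32L, ceiling((n_backbones - n_acc) * 1.2))
    cands <- sample_torsions(residue, want, seed = .fan_seed(seed, batch))
    # glycan-torsion draws for this batch, deterministic under the seed
    old <- .Random.seed_exists(); set.seed(.fan_seed(seed, 10000L + batch))
    gdraw <- matrix(sample.int(3L, want * 2L, replace = TRUE), ncol = 2L)
    .restore_seed(old)
    for (ci in seq_along(cands)) {
      if (n_acc >= n_backbones) break
      n_cand <- n_cand + 1L
      bi <- n_acc + 1L
      ok <- TRUE
      mods <- list()
      tors_by_state <- list()
      for (si in seq_along(states)) {
        st <- states[[si]]
        ts_mod <- .extend_torsions(cands[[ci]], st, gdraw[ci, ])
        tors_by_state[[si]] <- ts_mod
        confs <- list()
        for (ri in seq_len(nrow(schemes[[si]]$rotamers))) {
          cf <- build_conformation(st, ts_mod, schemes[[si]]$rotamers$label[ri],
                                   backbone_index = bi)
          if (!is_clash_free(cf, overlap_factor, bond_exclusion_depth)) {
            ok <- FALSE; break
          }
          confs[[ri]] <- cf
        }
        if (!ok) break
        mods[[si]] <- confs
      }
      if (!ok) next
      un <- build_conformation(unmod_state, .truncate_torsions(cands[[ci]], residue),
                               "-", backbone_index = bi)
      if (!is_clash_free(un, overlap_factor, bond_exclusion_depth)) next
      n_acc <- n_acc + 1L
      accepted[[n_acc]] <- list(unmod = un, mods = mods, torsions = tors_by_state)
    }
    if (n_cand >= 200L && n_acc / n_cand < acceptance_floor) {
      stop(sprintf(paste0("clash rejection too severe: %d/%d candidates accepted ",
                          "(rate %.3f < floor %.3f)"),
                   n_acc, n_cand, n_acc / n_cand, acceptance_floor))
    }
  }

  unmodified <- lapply(accepted, `[[`, "unmod")
  pairs <- vector("list", length(states))
  for (si in seq_along(states)) {
    scheme <- schemes[[si]]
    modified <- list()
    pairing <- list()
    for (bi in seq_len(n_backbones)) {
      for (ri in seq_len(nrow(scheme$rotamers))) {
        modified[[length(modified) + 1L]] <- accepted[[bi]]$mods[[si]][[ri]]
        pairing[[length(pairing) + 1L]] <- data.frame(
          backbone_index = bi, rotamer = scheme$rotamers$label[ri],
          mod_idx = length(modified), unmod_idx = bi,
          stringsAsFactors = FALSE)
      }
    }
    pairs[[si]] <- structure(list(
      state = states[[si]],
      unmodified = unmodified,
      modified = modified,
      pairing = do.call(rbind, pairing),
      scheme = scheme,
      seed = seed,
      n_candidates = n_cand
    ), class = "ensemble_pair")
  }
  names(pairs) <- vapply(states, `[[`, "", "state")
  list(unmodified = unmodified, pairs = pairs,
       n_total = length(unmodified) +
         sum(vapply(pairs, function(p) length(p$modified), 0L)),
       seed = seed, acceptance_rate = n_acc / n_cand)
}

#' @export
print.ensemble_pair <- function(x, ...) {
  cat(sprintf("ensemble_pair: %s/%s, %d unmodified + %d modified conformations (%d rotamers)\n",
              x$state$residue, x$state$state, length(x$unmodified),
              length(x$modified), nrow(x$scheme$rotamers)))
  invisible(x)
}

#' Serialize an ensemble-pair manifest to JSON
#'
#' Writes torsions, rotamer labels and the pairing map (not coordinates;
#' use [write_pdb()] for those).
#'
#' @param pair an `ensemble_pair`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ensemble_manifest <- function(pair, path) {
  tors <- lapply(pair$modified, function(cf) {
    list(backbone_index = cf$backbone_index, rotamer = cf$rotamer,
         phi = cf$torsions$phi, psi = cf$torsions$psi, chi = cf$torsions$chi)
  })
  obj <- list(
    residue = pair$state$residue, state = pair$state$state,
    nucleus = pair$state$nucleus, seed = pair$seed,
    n_backbones = length(pair$unmodified),
    rotamers = pair$scheme$rotamers$label,
    pairing = pair$pairing,
    modified_torsions = tors
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
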