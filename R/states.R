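# Supported (residue, modification state) combinations and the 13C
# nucleus each analysis senses: Cepsilon for Lys, Czeta for Arg,
# Cbeta for Ser/Thr, Cgamma for Asn.
.STATE_TABLE <- data.frame(
  residue = c(rep("LYS", 5), rep("ARG", 5), rep("SER", 3), rep("THR", 3), "ASN", "ASN"),
  state = c("charged", "acetyl", "monomethyl", "dimethyl", "trimethyl",
            "charged", "monomethyl-NE", "monomethyl-NH", "dimethyl-sym", "dimethyl-asym",
            "unmodified", "GalNAc-alpha", "GlcNAc-beta",
            "unmodified", "GalNAc-alpha", "GlcNAc-beta",
            "unmodified", "GlcNAc-beta"),
  nucleus = c(rep("CE", 5), rep("CZ", 5), rep("CB", 3), rep("CB", 3), "CG", "CG"),
  modified = c(FALSE, TRUE, TRUE, TRUE, TRUE,
               FALSE, TRUE, TRUE, TRUE, TRUE,
               FALSE, TRUE, TRUE,
               FALSE, TRUE, TRUE,
               FALSE, TRUE),
  stringsAsFactors = FALSE
)

#' Modification states known to the package
#'
#' @return data frame of supported (residue, state, nucleus) combinations.
#' @export
ptm_states <- function() .STATE_TABLE

#' Construct a modification-state descriptor
#'
#' @param residue `"LYS"`, `"ARG"`, `"SER"`, `"THR"` or `"ASN"`.
#' @param state state label; see [ptm_states()] for the allowed
#'   combinations (e.g. `"charged"`, `"acetyl"`, `"monomethyl"`,
#'   `"dimethyl-sym"`, `"GalNAc-alpha"`, ...).
#' @return object of class `ptm_state` with fields `residue`, `state`,
#'   `nucleus` (the sensed report nucleus) and `modified`.
#' @export
ptm_state <- function(residue, state) {
  residue <- toupper(residue)
  hit <- which(.STATE_TABLE$residue == residue & .STATE_TABLE$state == state)
  if (length(hit) != 1) {
    ok <- .STATE_TABLE[.STATE_TABLE$residue == residue, "state"]
    stop(sprintf("unknown state '%s' for residue '%s'; allowed: %s",
                 state, residue,
                 if (length(ok)) paste(ok, collapse = ", ") else "none (unknown residue)"))
  }
  structure(as.list(.STATE_TABLE[hit, ]), class = "ptm_state")
}

#' @export
print.ptm_state <- function(x, ...) {
  cat(sprintf("ptm_state: %s/%s (nucleus %s, %s)\n", x$residue, x$state,
              x$nucleus, if (x$modified) "modified" else "unmodified"))
  invisible(x)
}

#' Unmodified counterpart of a state
#'
#' @param state a `ptm_state`.
#' @return the `ptm_state` for the same residue's unmodified form.
#' @export
unmodified_state <- function(state) {
  tab <- .STATE_TABLE
  base <- tab[tab$residue == state$residue & !tab$modified, "state"]
  ptm_state(state$residue, base)
}

#' Enumerate the rotamer scheme for a modification state
#'
#' Modified groups introduce a new dihedral whose most frequent positions
#' are enumerated as discrete rotamers: 0/180 degrees for the acetyl
#' amide plane, +60/-60/180 for N-methyl groups on sp3 nitrogen, and
#' site/orientation combinations for methyls on the planar Arg
#' guanidinium nitrogens.  Unmodified and symmetric states have a single
#' trivial rotamer.
#'
#' @param state a [ptm_state()].
#' @param conformers_per_rotamer conformations generated per rotamer
#'   (default 500).
#' @return object of class `rotamer_scheme`: data frame of rotamer labels
#'   and dihedral values plus the total conformer count.
#' @export
enumerate_rotamer_scheme <- function(state, conformers_per_rotamer = 500L) {
  stopifnot(inherits(state, "ptm_state"))
  key <- paste(state$residue, state$state, sep = "/")
  rot <- switch(key,
    "LYS/charged" = data.frame(label = "-", angle = NA_real_),
    "LYS/acetyl" = data.frame(label = c("0", "180"), angle = c(0, 180)),
    "LYS/monomethyl" = ,
    "LYS/dimethyl" = data.frame(label = c("60", "-60", "180"), angle = c(60, -60, 180)),
    "LYS/trimethyl" = data.frame(label = "-", angle = 180),
    "ARG/charged" = data.frame(label = "-", angle = NA_real_),
    "ARG/monomethyl-NE" = data.frame(label = "-", angle = NA_real_),
    "ARG/monomethyl-NH" = data.frame(
      label = c("NH1:0", "NH1:180", "NH2:0", "NH2:180"),
      angle = c(0, 180, 0, 180)),
    "ARG/dimethyl-sym" = data.frame(label = c("0", "180"), angle = c(0, 180)),
    "ARG/dimethyl-asym" = data.frame(
      label = c("NH1:a", "NH1:b", "NH2:a", "NH2:b"),
      angle = NA_real_),
    # glycosylation: the new linkage torsions are carried in the torsion
    # set itself (sampled at +60/-60/180); a single scheme rotamer
    data.frame(label = "-", angle = NA_real_)
  )
  structure(list(
    state = state,
    rotamers = rot,
    conformers_per_rotamer = as.integer(conformers_per_rotamer),
    total = nrow(rot) * as.integer(conformers_per_rotamer)
  ), class = "rotamer_scheme")
}

#' @export
print.rotamer_scheme <- function(x, ...) {
  cat(sprintf("rotamer_scheme: %s/%s, %d rotamer(s) x %d = %d conformers\n",
              x$state$residue, x$state$state, nrow(x$rotamers),
              x$conformers_per_rotamer, x$total))
  invisible(x)
}
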