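#' Write a locally-dense-basis shielding job input
#'
#' Emits a quantum-chemistry input file (GIAO isotropic-shielding job)
#' using the locally dense basis scheme: the focus nucleus and every
#' atom within `neighbor_shell` bonds of it get the large basis, all
#' remaining atoms the small one.  The basis partition is exhaustive and
#' disjoint by construction.  No quantum-chemistry engine is run by this
#' package; the file is an interchange artifact.
#'
#' @param conf a `conformation` built by [build_conformation()].
#' @param focus_nucleus atom name of the nucleus of interest (e.g.
#'   `"CE"`); must exist in the conformation.
#' @param neighbor_shell bond distance within which neighbors share the
#'   large basis (0 = focus atom only).
#' @param basis_high,basis_low basis-set names (defaults
#'   `"6-311+G(2d,p)"` and `"3-21G"`).
#' @param functional exchange-correlation functional string written into
#'   the route line (default `"B98"`; free-form).
#' @param path output file.
#' @return invisibly, a list with the `high` and `low` atom index sets.
#' @export
write_qc_input <- function(conf, focus_nucleus, neighbor_shell = 1L,
                           basis_high = "6-311+G(2d,p)", basis_low = "3-21G",
                           functional = "B98", path) {
  at <- conf$atoms
  focus <- which(at$name == focus_nucleus & at$resid == 3L)
  if (length(focus) == 0) focus <- which(at$name == focus_nucleus)
  if (length(focus) == 0) {
    stop("unknown nucleus name '", focus_nucleus, "' in conformation")
  }
  focus <- focus[1]
  bd <- .bond_distances(conf)
  high <- which(bd[focus, ] <= neighbor_shell)
  low <- setdiff(seq_len(nrow(at)), high)

  lines <- c(
    sprintf("#P %s/gen NMR=GIAO", functional),
    "",
    sprintf("isotropic shieldings: %s %s/%s rotamer %s focus %s",
            conf$sequence, conf$state$residue, conf$state$state,
            conf$rotamer, focus_nucleus),
    "",
    "0 1",
    sprintf("%-2s %14.8f %14.8f %14.8f", at$element, at$x, at$y, at$z),
    "",
    paste(c(high, "0"), collapse = " "),
    basis_high,
    "****"
  )
  if (length(low)) {
    lines <- c(lines, paste(c(low, "0"), collapse = " "), basis_low, "****")
  }
  lines <- c(lines, "")
  writeLines(lines, path)
  invisible(list(high = high, low = low, focus = focus))
}
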