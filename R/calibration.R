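#' Load a calibration table of modification shift effects
#'
#' The calibration assigns each modification state an additive effect on
#' the report nucleus' chemical shift (ppm, shift space) plus zero-sum
#' per-rotamer offsets, so the state mean is carried entirely by
#' `effect`.  The packaged default anchors the four Lys states to
#' published mean Delta values (+1.5 / -10.1 / -19.1 / -25.8 ppm for
#' acetyl / mono- / di- / tri-methyl on 13C-epsilon); Arg and glycan
#' entries are illustrative defaults meant to be overridden.
#'
#' @param source `"default"` for the packaged table, or a path to a JSON
#'   file with the same schema.
#' @return object of class `ptm_calibration` (data frame of entries with
#'   a `rotamer_offsets` list column).
#' @export
load_calibration <- function(source = "default") {
  path <- if (identical(source, "default")) {
    system.file("extdata", "ptm_calibration.json", package = "ptmdelta",
                mustWork = TRUE)
  } else source
  raw <- jsonlite::read_json(path)
  entries <- lapply(raw$entries, function(e) {
    off <- unlist(e$rotamer_offsets)
    if (abs(sum(off)) > 1e-9) {
      stop(sprintf("calibration entry %s/%s: rotamer offsets must sum to zero (got %g)",
                   e$residue, e$state, sum(off)))
    }
    data.frame(residue = e$residue, state = e$state, nucleus = e$nucleus,
               effect = e$effect, anchor = e$anchor, note = e$note,
               rotamer_offsets = I(list(off)), stringsAsFactors = FALSE)
  })
  cal <- do.call(rbind, entries)
  anchored <- cal$state[cal$residue == "LYS" & cal$anchor == "calibrated" &
                          cal$state != "charged"]
  need <- c("acetyl", "monomethyl", "dimethyl", "trimethyl")
  if (!all(need %in% anchored)) {
    stop("calibration must carry calibrated anchors for the four modified Lys states")
  }
  structure(cal, class = c("ptm_calibration", "data.frame"))
}

#' Look up one calibration entry
#'
#' @param calibration a `ptm_calibration`.
#' @param state a [ptm_state()].
#' @return list with `effect` (ppm) and named `rotamer_offsets`.
#' @export
calibration_entry <- function(calibration, state) {
  hit <- which(calibration$residue == state$residue &
                 calibration$state == state$state)
  if (length(hit) != 1) {
    stop(sprintf("missing calibration entry for %s/%s", state$residue, state$state))
  }
  list(effect = calibration$effect[hit],
       rotamer_offsets = calibration$rotamer_offsets[[hit]],
       nucleus = calibration$nucleus[hit],
       anchor = calibration$anchor[hit])
}
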