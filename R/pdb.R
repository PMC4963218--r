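#' Write conformations as a multi-MODEL PDB file
#'
#' One MODEL record per conformation; peptide atoms as ATOM, glycan
#' atoms as HETATM.  Coordinates are written at PDB precision (1e-3
#' Angstrom), so a write/read round trip preserves them to that
#' tolerance.  Output is byte-deterministic for a given ensemble.
#'
#' @param conformations a `conformation` or list of them (may be empty).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(conformations, path) {
  if (inherits(conformations, "conformation")) conformations <- list(conformations)
  con <- file(path, "wb")  # binary mode: stable newlines across platforms
  on.exit(close(con))
  lines <- character(0)
  for (m in seq_along(conformations)) {
    at <- conformations[[m]]$atoms
    lines <- c(lines, sprintf("MODEL     %4d", m))
    nm <- ifelse(nchar(at$name) < 4, paste0(" ", at$name), at$name)
    lines <- c(lines, sprintf(
      "%-6s%5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      ifelse(at$het, "HETATM", "ATOM"), seq_len(nrow(at)), nm,
      substr(at$resname, 1, 3), "A", at$resid, at$x, at$y, at$z, 1, 0,
      at$element))
    lines <- c(lines, "ENDMDL")
  }
  lines <- c(lines, "END")
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Read a multi-MODEL PDB file
#'
#' Parses ATOM/HETATM records into bare `conformation` objects (atom
#' table only; torsions/state are not recoverable from coordinates
#' alone and are left unset).
#'
#' @param path PDB file.
#' @return list of `conformation` objects, one per MODEL (possibly empty).
#' @export
read_pdb <- function(path) {
  lines <- readLines(path)
  models <- list()
  cur <- NULL
  for (ln in seq_along(lines)) {
    line <- lines[ln]
    rec <- substr(line, 1, 6)
    if (grepl("^MODEL", rec)) {
      cur <- list()
    } else if (grepl("^ENDMDL", rec)) {
      if (is.null(cur)) stop("PDB parse error at line ", ln, ": ENDMDL without MODEL")
      models[[length(models) + 1L]] <- cur
      cur <- NULL
    } else if (rec %in% c("ATOM  ", "HETATM")) {
      if (nchar(line) < 54) stop("PDB parse error at line ", ln, ": truncated record")
      xyz <- suppressWarnings(as.numeric(c(substr(line, 31, 38),
                                           substr(line, 39, 46),
                                           substr(line, 47, 54))))
      if (anyNA(xyz)) stop("PDB parse error at line ", ln, ": bad coordinates")
      row <- data.frame(
        name = trimws(substr(line, 13, 16)),
        element = trimws(substr(line, 77, 78)),
        resid = as.integer(substr(line, 23, 26)),
        resname = trimws(substr(line, 18, 20)),
        het = rec == "HETATM",
        x = xyz[1], y = xyz[2], z = xyz[3],
        stringsAsFactors = FALSE
      )
      if (is.null(cur)) cur <- list()  # tolerate single-model files without MODEL
      cur[[length(cur) + 1L]] <- row
    }
  }
  if (!is.null(cur) && length(cur)) models[[length(models) + 1L]] <- cur
  lapply(models, function(rows) {
    structure(list(sequence = NA_character_, atoms = do.call(rbind, rows),
                   bonds = NULL, torsions = NULL, rotamer = NA_character_,
                   state = NULL, backbone_index = NA_integer_),
              class = "conformation")
  })
}
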