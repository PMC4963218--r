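.REREF_OFFSETS <- c(DSS = 0, TSP = 0.12, TMS = -1.7)

#' Re-reference a chemical shift to the DSS scale
#'
#' Shifts referenced to TSP gain +0.12 ppm, TMS-referenced shifts
#' -1.7 ppm; DSS-referenced values pass unchanged.  Any other standard
#' is an error: the reference analysis is restricted to entries
#' referenced to DSS, TMS or TSP.
#'
#' @param value shift value(s) in ppm.
#' @param standard reference standard, one of `"DSS"`, `"TMS"`, `"TSP"`
#'   (recycled against `value`).
#' @return value(s) on the DSS scale.
#' @export
rereference_shift <- function(value, standard) {
  standard <- toupper(standard)
  bad <- setdiff(unique(standard), names(.REREF_OFFSETS))
  if (length(bad)) {
    stop("unsupported reference standard(s): ", paste(bad, collapse = ", "),
         "; analysis is restricted to DSS, TMS or TSP")
  }
  value + unname(.REREF_OFFSETS[standard])
}

#' Parse a chemical-shift table
#'
#' Reads shift observations from CSV (columns `entry_id`, `residue`,
#' `nucleus`, `value_ppm`, `reference_standard`) or from a minimal
#' NMR-STAR v3 chemical-shift loop subset (tags
#' `_Atom_chem_shift.Entry_ID`, `.Comp_ID`, `.Atom_ID`, `.Val`,
#' `.Chem_shift_reference`).
#'
#' @param path input file.
#' @param format `"csv"` or `"nmrstar"`.
#' @return data frame of observations (`entry_id`, `residue`, `nucleus`,
#'   `value`, `standard`).
#' @export
parse_shift_table <- function(path, format = c("csv", "nmrstar")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("entry_id", "residue", "nucleus", "value_ppm", "reference_standard")
    miss <- setdiff(need, names(df))
    if (length(miss)) stop("CSV is missing column(s): ", paste(miss, collapse = ", "))
    bad <- which(!is.finite(suppressWarnings(as.numeric(df$value_ppm))))
    if (length(bad)) stop("malformed shift value in CSV row ", bad[1])
    data.frame(entry_id = as.character(df$entry_id),
               residue = toupper(df$residue), nucleus = toupper(df$nucleus),
               value = as.numeric(df$value_ppm),
               standard = toupper(df$reference_standard),
               stringsAsFactors = FALSE)
  } else {
    .parse_star_shift_loop(path)
  }
}

# Minimal NMR-STAR v3 loop reader for the chemical-shift loop subset.
# Finds the loop_ whose tags include _Atom_chem_shift.Val, maps the tag
# order onto columns and reads whitespace-separated rows until stop_.
.parse_star_shift_loop <- function(path) {
  lines <- readLines(path)
  lt <- trimws(lines)
  loop_starts <- which(lt == "loop_")
  if (!length(loop_starts)) stop("no loop_ found in NMR-STAR file '", path, "'")
  for (ls in loop_starts) {
    i <- ls + 1L
    tags <- character(0)
    while (i <= length(lt) && startsWith(lt[i], "_")) {
      tags <- c(tags, lt[i]); i <- i + 1L
    }
    if (!any(grepl("^_Atom_chem_shift\\.Val$", tags, ignore.case = TRUE))) next
    rows <- list()
    while (i <= length(lt) && lt[i] != "stop_") {
      if (nzchar(lt[i]) && !startsWith(lt[i], "#")) {
        fields <- strsplit(lt[i], "\\s+")[[1]]
        if (length(fields) != length(tags)) {
          stop("malformed NMR-STAR loop row at line ", i, ": expected ",
               length(tags), " fields, got ", length(fields))
        }
        rows[[length(rows) + 1L]] <- fields
      }
      i <- i + 1L
    }
    m <- do.call(rbind, rows)
    colnames(m) <- sub("^_Atom_chem_shift\\.", "", tags, ignore.case = TRUE)
    pick <- function(nm, default = NA_character_) {
      hit <- which(tolower(colnames(m)) == tolower(nm))
      if (length(hit)) m[, hit[1]] else rep(default, nrow(m))
    }
    val <- suppressWarnings(as.numeric(pick("Val")))
    if (anyNA(val)) stop("malformed shift value in NMR-STAR loop row ", which(is.na(val))[1])
    return(data.frame(
      entry_id = pick("Entry_ID", "unknown"),
      residue = toupper(pick("Comp_ID")),
      nucleus = toupper(pick("Atom_ID")),
      value = val,
      standard = toupper(pick("Chem_shift_reference", "DSS")),
      stringsAsFactors = FALSE
    ))
  }
  stop("no chemical-shift loop (_Atom_chem_shift.Val) found in '", path, "'")
}

#' Tukey-fence outlier filter
#'
#' Removes values outside `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]` with quartiles
#' by linear interpolation of order statistics (quantile type 7).  The
#' fences are closed intervals and the filter is applied exactly once.
#' Groups with fewer than 4 values pass through unfiltered with a
#' warning (quartiles are ill-defined).
#'
#' @param values numeric vector (non-empty).
#' @param k fence multiplier (default 1.5).
#' @return list with `kept`, `removed`, `fences` (length-2), `q` (Q1, Q3).
#' @export
iqr_filter <- function(values, k = 1.5) {
  if (length(values) == 0) stop("empty input")
  if (length(values) < 4) {
    warning("fewer than 4 values: quartiles ill-defined, passing through unfiltered")
    return(list(kept = values, removed = numeric(0),
                fences = c(-Inf, Inf), q = c(NA_real_, NA_real_)))
  }
  q <- unname(stats::quantile(values, c(0.25, 0.75), type = 7))
  iqr <- q[2] - q[1]
  fences <- c(q[1] - k * iqr, q[2] + k * iqr)
  keep <- values >= fences[1] & values <= fences[2]
  list(kept = values[keep], removed = values[!keep], fences = fences, q = q)
}

#' Reference statistics for one residue/nucleus group
#'
#' Pipeline (fixed order): restrict to recognized reference standards
#' (DSS/TMS/TSP), re-reference to DSS, remove Tukey-fence outliers, then
#' compute the sample mean and standard deviation (n-1 denominator).
#'
#' @param observations data frame from [parse_shift_table()].
#' @param residue,nucleus group selectors.
#' @return object of class `reference_stats`: `residue`, `nucleus`,
#'   `n_kept`, `n_removed`, `mean`, `sd`, `q1`, `q3`, `fences`.
#' @export
compute_reference_stats <- function(observations, residue, nucleus) {
  residue <- toupper(residue); nucleus <- toupper(nucleus)
  grp <- observations[observations$residue == residue &
                        observations$nucleus == nucleus, , drop = FALSE]
  grp <- grp[grp$standard %in% names(.REREF_OFFSETS), , drop = FALSE]
  if (nrow(grp) == 0) {
    stop(sprintf("no %s/%s observations with a supported reference standard",
                 residue, nucleus))
  }
  v <- rereference_shift(grp$value, grp$standard)
  f <- iqr_filter(v)
  structure(list(
    residue = residue, nucleus = nucleus,
    n_kept = length(f$kept), n_removed = length(f$removed),
    mean = mean(f$kept),
    sd = if (length(f$kept) > 1) stats::sd(f$kept) else 0,
    q1 = f$q[1], q3 = f$q[2], fences = f$fences
  ), class = "reference_stats")
}

#' @export
print.reference_stats <- function(x, ...) {
  cat(sprintf("reference_stats: %s/%s mean %.3f ppm, sd %.3f ppm (n=%d kept, %d outliers removed)\n",
              x$residue, x$nucleus, x$mean, x$sd, x$n_kept, x$n_removed))
  invisible(x)
}

#' Synthetic experimental-style shift table
#'
#' Emulates a repository snapshot of per-residue/nucleus 13C shifts:
#' Gaussian bulk around a realistic mean, a configurable fraction of
#' gross outliers, and a mixture of DSS/TMS/TSP reference standards
#' (non-DSS values are stored on their native scale so re-referencing is
#' exercised).  This is a synthetic stand-in for a live repository
#' download, which the package never performs.
#'
#' @param n observations per (residue, nucleus) group.
#' @param seed integer seed.
#' @param outlier_frac fraction of planted gross outliers (default 0.02).
#' @param standards_prob mixing probabilities for DSS/TMS/TSP.
#' @return observation data frame as from [parse_shift_table()].
#' @export
simulate_bmrb_table <- function(n = 400L, seed = 1L, outlier_frac = 0.02,
                                standards_prob = c(DSS = 0.8, TMS = 0.1, TSP = 0.1)) {
  groups <- data.frame(
    residue = c("LYS", "ARG", "SER", "THR", "ASN"),
    nucleus = c("CE", "CZ", "CB", "CB", "CG"),
    mean = c(41.9, 159.8, 63.8, 69.6, 176.8),
    sd = c(0.8, 0.9, 1.5, 1.7, 1.3),
    stringsAsFactors = FALSE
  )
  old <- .Random.seed_exists()
  on.exit(.restore_seed(old), add = TRUE)
  set.seed(as.integer(seed))
  out <- lapply(seq_len(nrow(groups)), function(g) {
    std <- sample(names(standards_prob), n, replace = TRUE, prob = standards_prob)
    v_dss <- stats::rnorm(n, groups$mean[g], groups$sd[g])
    is_out <- stats::runif(n) < outlier_frac
    v_dss[is_out] <- v_dss[is_out] + sample(c(-1, 1), sum(is_out), TRUE) *
      stats::runif(sum(is_out), 8, 25)
    # store on the native scale of each entry's standard
    v_native <- v_dss - unname(.REREF_OFFSETS[std])
    data.frame(entry_id = sprintf("syn%05d", (g - 1L) * n + seq_len(n)),
               residue = groups$residue[g], nucleus = groups$nucleus[g],
               value = v_native, standard = std, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
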