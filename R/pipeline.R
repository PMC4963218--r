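.CONFIG_KEYS <- c("residue", "states", "n_backbones", "seed", "surrogate",
                  "sampler", "out_dir", "strict", "fit_profiles",
                  "reference_table_n")
.SURROGATE_KEYS <- c("torsion_amplitude", "rotamer_spread", "noise_sd",
                     "sigma_ref")
.SAMPLER_KEYS <- c("chains", "draws", "warmup")

#' Validate a run configuration
#'
#' @param config named list; unknown keys are rejected.
#' @return the validated config with defaults filled in.
#' @export
validate_config <- function(config) {
  unknown <- setdiff(names(config), .CONFIG_KEYS)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  if (!is.null(config$surrogate)) {
    bad <- setdiff(names(config$surrogate), .SURROGATE_KEYS)
    if (length(bad)) stop("unknown surrogate key(s): ", paste(bad, collapse = ", "))
  }
  if (!is.null(config$sampler)) {
    bad <- setdiff(names(config$sampler), .SAMPLER_KEYS)
    if (length(bad)) stop("unknown sampler key(s): ", paste(bad, collapse = ", "))
  }
  defaults <- list(residue = "LYS", states = NULL, n_backbones = 500L,
                   seed = 42L, surrogate = list(), sampler = list(),
                   out_dir = tempfile("ptmdelta_run_"), strict = FALSE,
                   fit_profiles = TRUE, reference_table_n = 400L)
  utils::modifyList(defaults, config)
}

#' Run the full synthetic Delta analysis
#'
#' Executes the stages in order: paired-ensemble generation, surrogate
#' shift simulation, rotamer averaging, Delta computation, KDE,
#' experimental-style reference statistics, Bayesian two-state fits and
#' probability profiles, and a run report.  Every artifact is written
#' under `config$out_dir` with full provenance (config, seed, package
#' version); identical configs give identical outputs.
#'
#' @param config named list, see [validate_config()]: `residue`,
#'   optional `states` subset, `n_backbones`, `seed`, `surrogate`
#'   parameter overrides, `sampler` settings, `out_dir`, `strict`,
#'   `fit_profiles`.
#' @return invisibly, a list with the run directory, per-state Delta
#'   summaries and the report.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- validate_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage_dirs <- file.path(cfg$out_dir, c("ensembles", "shifts", "deltas", "profiles"))
  for (d in stage_dirs) dir.create(d, showWarnings = FALSE)

  cfg_path <- file.path(cfg$out_dir, "config.json")
  jsonlite::write_json(cfg[order(names(cfg))], cfg_path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  prov <- list(package = "ptmdelta",
               version = as.character(utils::packageVersion("ptmdelta")),
               config_md5 = unname(tools::md5sum(cfg_path)),
               seed = cfg$seed)
  jsonlite::write_json(prov, file.path(cfg$out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  # stage 1: ensembles
  study <- generate_residue_study(cfg$residue, cfg$n_backbones, seed = cfg$seed)
  pairs <- study$pairs
  if (!is.null(cfg$states)) pairs <- pairs[unlist(cfg$states)]
  for (nm in names(pairs)) {
    write_ensemble_manifest(pairs[[nm]],
                            file.path(cfg$out_dir, "ensembles",
                                      paste0(nm, "_manifest.json")))
  }

  # stage 2-3: surrogate shifts, rotamer averaging
  cal <- load_calibration()
  sp <- do.call(surrogate_params, c(cfg$surrogate, list(seed = cfg$seed)))
  shifts <- lapply(pairs, simulate_shift_records, calibration = cal, params = sp)
  for (nm in names(shifts)) {
    utils::write.csv(shifts[[nm]]$modified,
                     file.path(cfg$out_dir, "shifts", paste0(nm, "_mod.csv")),
                     row.names = FALSE)
    utils::write.csv(shifts[[nm]]$unmodified,
                     file.path(cfg$out_dir, "shifts", paste0(nm, "_unmod.csv")),
                     row.names = FALSE)
  }
  averaged <- lapply(names(shifts), function(nm)
    average_over_rotamers(shifts[[nm]]$modified, pairs[[nm]]$scheme))
  names(averaged) <- names(shifts)

  # stage 4-5: Delta and KDE
  deltas <- lapply(names(averaged), function(nm)
    compute_delta(averaged[[nm]], shifts[[nm]]$unmodified))
  names(deltas) <- names(averaged)
  kdes <- lapply(names(deltas), function(nm) kde_density(deltas[[nm]]$modified))
  names(kdes) <- names(deltas)
  unmod_kde <- kde_density(deltas[[1]]$unmodified)
  for (nm in names(deltas)) {
    utils::write.csv(deltas[[nm]]$modified,
                     file.path(cfg$out_dir, "deltas", paste0(nm, "_delta.csv")),
                     row.names = FALSE)
    s <- kdes[[nm]]$summary
    jsonlite::write_json(s, file.path(cfg$out_dir, "deltas", paste0(nm, "_kde.json")),
                         auto_unbox = TRUE, digits = NA)
  }

  # stage 6: reference statistics from the synthetic experimental table
  obs <- simulate_bmrb_table(n = cfg$reference_table_n, seed = cfg$seed)
  unmod <- unmodified_state(pairs[[1]]$state)
  ref <- compute_reference_stats(obs, unmod$residue, unmod$nucleus)
  jsonlite::write_json(unclass(ref), file.path(cfg$out_dir, "reference_stats.json"),
                       auto_unbox = TRUE, digits = NA)

  # stage 7: two-state fits (each modified state vs unmodified)
  profiles <- list()
  if (isTRUE(cfg$fit_profiles)) {
    for (nm in names(deltas)) {
      spec <- do.call(build_model_spec, c(
        list(deltaA = deltas[[nm]]$modified$delta,
             deltaB = deltas[[nm]]$unmodified$delta,
             ref = ref, seed = cfg$seed),
        cfg$sampler))
      draws <- fit_state_model(spec, strict = isTRUE(cfg$strict))
      prof <- probability_profile(draws)
      profiles[[nm]] <- prof
      utils::write.csv(
        data.frame(delta = prof$grid, p_modified = prof$mean,
                   band_lo = prof$band_lo, band_hi = prof$band_hi),
        file.path(cfg$out_dir, "profiles", paste0(nm, "_profile.csv")),
        row.names = FALSE)
    }
  }

  report <- make_report(cfg$out_dir)
  invisible(list(out_dir = cfg$out_dir, study = study, deltas = deltas,
                 kdes = kdes, unmod_kde = unmod_kde, ref = ref,
                 profiles = profiles, report = report))
}

#' Summarize a completed run directory
#'
#' Builds a human-readable report (per-state Delta means/sds, 80%
#' threshold regions, conformer bookkeeping) plus a machine-readable
#' JSON twin from the artifacts a [run_pipeline()] run wrote.
#'
#' @param run_dir run directory.
#' @return invisibly, the report list (also written as `report.txt` and
#'   `report.json` in `run_dir`).
#' @export
make_report <- function(run_dir) {
  cfg_path <- file.path(run_dir, "config.json")
  if (!file.exists(cfg_path)) stop("incomplete run directory: missing config.json")
  cfg <- jsonlite::read_json(cfg_path)
  kde_files <- list.files(file.path(run_dir, "deltas"), pattern = "_kde\\.json$",
                          full.names = TRUE)
  if (!length(kde_files)) stop("incomplete run directory: no KDE summaries")
  states <- sub("_kde\\.json$", "", basename(kde_files))
  summaries <- lapply(kde_files, jsonlite::read_json)
  names(summaries) <- states

  manifest_files <- list.files(file.path(run_dir, "ensembles"),
                               pattern = "_manifest\\.json$", full.names = TRUE)
  n_mod <- vapply(manifest_files, function(f) {
    m <- jsonlite::read_json(f)
    length(m$rotamers) * m$n_backbones
  }, 0)
  n_unmod <- if (length(manifest_files)) {
    jsonlite::read_json(manifest_files[1])$n_backbones
  } else 0
  n_total <- n_unmod + sum(n_mod)

  thresholds <- list()
  if (isTRUE(as.logical(cfg$fit_profiles))) {
    for (st in states) {
      pf <- file.path(run_dir, "profiles", paste0(st, "_profile.csv"))
      if (!file.exists(pf)) stop("incomplete run directory: missing profile for ", st)
      prof <- utils::read.csv(pf)
      ok <- prof$p_modified >= 0.8
      thresholds[[st]] <- if (any(ok)) {
        r <- rle(ok); e <- cumsum(r$lengths); s <- e - r$lengths + 1L
        data.frame(lo = prof$delta[s[r$values]], hi = prof$delta[e[r$values]])
      } else data.frame(lo = numeric(0), hi = numeric(0))
    }
  }

  report <- list(residue = cfg$residue, n_conformations = n_total,
                 states = summaries, threshold_80 = thresholds)
  jsonlite::write_json(report, file.path(run_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  lines <- c(
    sprintf("ptmdelta run report: residue %s", cfg$residue),
    sprintf("conformations generated: %d (%d unmodified + %d modified)",
            n_total, n_unmod, sum(n_mod)),
    "",
    "state                mean Delta (ppm)   sd (ppm)    n",
    vapply(states, function(st) {
      s <- summaries[[st]]
      sprintf("%-20s %12.2f %10.2f %6d", st, s$mean, s$sd, s$n)
    }, "")
  )
  if (length(thresholds)) {
    lines <- c(lines, "", "Delta regions with >80% probability of the modified state:")
    for (st in states) {
      th <- thresholds[[st]]
      reg <- if (nrow(th)) paste(sprintf("[%.1f, %.1f]", th$lo, th$hi),
                                 collapse = ", ") else "none"
      lines <- c(lines, sprintf("  %-20s %s", st, reg))
    }
  }
  writeLines(lines, file.path(run_dir, "report.txt"))
  invisible(report)
}
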