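#' Analysis configuration for the full workflow
#'
#' @param bands named list of [band_spec] (default the four canonical bands).
#' @param stats_bands band names entering the statistical comparisons;
#'   delta is computed and reported but excluded from the statistical family
#'   by default.
#' @param fdr_q FDR levels to flag (default 0.05 and 0.10).
#' @param total_lo,total_hi total-power range for relative power (Hz).
#' @param trans_hz FIR transition width (Hz).
#' @param reference apply average reference before analysis (default TRUE).
#' @param seed seed recorded in provenance (the analysis itself is
#'   deterministic; the seed documents the generating study).
#' @return list of class `analysis_config`.
#' @export
analysis_config <- function(bands = default_bands(),
                            stats_bands = c("theta", "alpha", "beta"),
                            fdr_q = c(0.05, 0.10),
                            total_lo = 0.5, total_hi = 30,
                            trans_hz = 2, reference = TRUE, seed = NA_integer_) {
  stopifnot(all(stats_bands %in% names(bands)))
  structure(list(bands = bands, stats_bands = stats_bands, fdr_q = fdr_q,
                 total_lo = total_lo, total_hi = total_hi,
                 trans_hz = trans_hz, reference = reference, seed = seed),
            class = "analysis_config")
}

# djb2 hash of the serialized configuration, for provenance lines
config_hash <- function(config) {
  bytes <- as.integer(serialize(config, NULL, ascii = TRUE))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483648
  sprintf("%08x", as.integer(h))
}

#' Subject-level measures for one recording
#'
#' Average-references the recording, computes relative power per band from
#' the broadband data, then band-passes and computes mean total PLI and the
#' epoch-averaged MST metrics per band.
#'
#' @param rec an [eeg_recording].
#' @param config an [analysis_config].
#' @return data.frame, one row per band: subject metadata, `band`,
#'   `rel_power`, `pli`, the MST metrics, `n_epochs_used`.
#' @export
analyze_recording <- function(rec, config = analysis_config()) {
  if (config$reference) rec <- average_reference(rec)
  rows <- lapply(names(config$bands), function(bn) {
    band <- config$bands[[bn]]
    rp <- relative_power(rec, band, config$total_lo, config$total_hi)
    rec_b <- bandpass(rec, band, trans_hz = config$trans_hz)
    met <- subject_band_metrics(rec_b)
    cbind(data.frame(subject_id = rec$subject_id, group = rec$group,
                     condition = rec$condition, band = bn,
                     rel_power = rp$relative_power,
                     stringsAsFactors = FALSE),
          met, n_epochs_used = n_epochs(rec))
  })
  do.call(rbind, rows)
}

#' Subject-level measures for every recording of a study
#'
#' Applies [analyze_recording] to each subject-by-condition recording. A
#' failing recording is reported per subject and skipped; the analysis
#' continues with the rest.
#'
#' @param design a [study_design].
#' @param config an [analysis_config].
#' @param verbose print per-stage progress messages.
#' @return data.frame, one row per recording x band (see [analyze_recording]).
#' @export
analyze_study <- function(design, config = analysis_config(), verbose = FALSE) {
  t0 <- Sys.time()
  keys <- names(design$recordings)
  subject_level <- list()
  for (k in keys) {
    rec <- design$recordings[[k]]
    res <- tryCatch(analyze_recording(rec, config), error = function(e) {
      warning(sprintf("recording %s failed: %s", k, conditionMessage(e)),
              call. = FALSE)
      NULL
    })
    if (!is.null(res)) subject_level[[k]] <- res
  }
  subject_level <- do.call(rbind, subject_level)
  rownames(subject_level) <- NULL
  if (verbose)
    message(sprintf("subject-level measures: %d recordings, %.1f s",
                    length(keys), as.numeric(Sys.time() - t0, units = "secs")))
  subject_level
}

#' Group-by-condition statistics over a subject-level table
#'
#' Per band in `stats_bands` and per measure: the 2x2 mixed ANOVA
#' (condition, condition-by-group interaction, group) with partial eta
#' squared and FDR flags within each band-by-effect family; per-condition
#' group follow-up contrasts with group means; and the
#' PLI-on-relative-power regression per band and condition.
#'
#' @param subject_level table from [analyze_study] (or read back from CSV).
#' @param groups named vector mapping subject_id to group.
#' @param config an [analysis_config].
#' @param measures which subject-level measures enter the statistics
#'   (default: PLI plus the MST metric suite).
#' @param conditions condition labels (default baseline, task).
#' @return list with `omnibus`, `followups`, `regressions` data.frames.
#' @export
group_statistics <- function(subject_level, groups,
                             config = analysis_config(),
                             measures = c("pli", metric_names()),
                             conditions = c("baseline", "task")) {
  conds <- conditions
  omnibus <- list(); followups <- list(); regressions <- list()
  for (bn in config$stats_bands) {
    sl <- subject_level[subject_level$band == bn, ]
    for (ms in measures) {
      vals <- data.frame(subject_id = sl$subject_id, condition = sl$condition,
                         value = sl[[ms]])
      an <- tryCatch(
        suppressWarnings(mixed_anova_2x2(vals, groups)),
        error = function(e) NULL)
      if (is.null(an)) next
      an$band <- bn; an$measure <- ms
      omnibus[[paste(bn, ms)]] <- an
      for (cond in conds) {
        sub <- vals[vals$condition == cond & !is.na(vals$value), ]
        ft <- per_condition_group_test(sub$value, groups[sub$subject_id])
        ft$band <- bn; ft$measure <- ms; ft$condition <- cond
        # group means for the direction of any difference
        gm <- tapply(sub$value, groups[sub$subject_id], mean)
        for (gname in names(gm)) ft[[paste0("mean_", gname)]] <- gm[[gname]]
        followups[[paste(bn, ms, cond)]] <- ft
      }
    }
    for (cond in conds) {
      sc <- sl[sl$condition == cond, ]
      reg <- tryCatch(regress_pli_on_power(sc$pli, sc$rel_power),
                      error = function(e) NULL)
      if (!is.null(reg))
        regressions[[paste(bn, cond)]] <-
          data.frame(band = bn, condition = cond, R = reg$R, R2 = reg$R2,
                     p = reg$p, n = reg$n)
    }
  }
  omnibus <- do.call(rbind, omnibus)
  rownames(omnibus) <- NULL
  # FDR within each band x effect family of measures
  for (q in config$fdr_q) {
    col <- sprintf("fdr_q%02d", round(100 * q))
    omnibus[[col]] <- NA
    for (bn in unique(omnibus$band)) for (ef in unique(omnibus$effect)) {
      sel <- omnibus$band == bn & omnibus$effect == ef
      omnibus[[col]][sel] <- bh_fdr(omnibus$p[sel], q = q)
    }
  }
  followups <- do.call(rbind, followups)
  regressions <- do.call(rbind, regressions)
  rownames(followups) <- rownames(regressions) <- NULL
  list(omnibus = omnibus, followups = followups, regressions = regressions)
}

#' Run the full group analysis on a study
#'
#' [analyze_study] followed by [group_statistics], with provenance. The
#' whole chain is deterministic given the study and configuration.
#'
#' @param design a [study_design].
#' @param config an [analysis_config].
#' @param measures which subject-level measures enter the statistics.
#' @param verbose print per-stage progress messages.
#' @return list of class `pli_mst_results`: `subject_level`, `omnibus`,
#'   `followups`, `regressions`, `config`, `provenance`.
#' @export
run_full_analysis <- function(design, config = analysis_config(),
                              measures = c("pli", metric_names()),
                              verbose = FALSE) {
  subject_level <- analyze_study(design, config, verbose = verbose)
  groups <- stats::setNames(design$subjects$group, design$subjects$subject_id)
  gs <- group_statistics(subject_level, groups, config, measures,
                         conditions = design$conditions)
  prov <- sprintf("config %s seed %s", config_hash(config), config$seed)
  structure(c(list(subject_level = subject_level), gs,
              list(config = config, provenance = prov)),
            class = "pli_mst_results")
}

#' @export
print.pli_mst_results <- function(x, ...) {
  cat(sprintf("<pli_mst_results> %d subject-level rows; omnibus %d tests; %s\n",
              nrow(x$subject_level), nrow(x$omnibus), x$provenance))
  invisible(x)
}

#' Stepwise regressions of outcomes on EEG measures per group
#'
#' For each outcome column, and within each group separately, runs
#' [stepwise_regression] of the outcome on the per-subject EEG predictors
#' (one column per band x condition x measure from the subject-level table).
#'
#' @param subject_level the `subject_level` table of [run_full_analysis].
#' @param outcomes data.frame: `subject_id` plus one column per outcome.
#' @param measures which EEG measures serve as candidate predictors.
#' @param p_in,p_out stepwise entry/removal thresholds.
#' @return data.frame in the stepwise-table shape: group, outcome, step,
#'   predictor, `se`, `adj_r2`, `delta_r2`, `f_change`, `p_change`.
#' @export
stepwise_tables <- function(subject_level, outcomes,
                            measures = c("rel_power", "pli", "tree_hierarchy",
                                         "bc_max", "kappa",
                                         "degree_correlation", "mst_mean"),
                            p_in = 0.05, p_out = 0.10) {
  sl <- subject_level
  preds <- list()
  for (bn in unique(sl$band)) for (cond in unique(sl$condition))
    for (ms in measures) {
      v <- sl[sl$band == bn & sl$condition == cond, c("subject_id", ms)]
      preds[[sprintf("%s_%s_%s", cond, bn, ms)]] <-
        stats::setNames(v[[ms]], v$subject_id)
    }
  groups <- unique(sl$group)
  rows <- list()
  for (g in groups) {
    ids <- unique(sl$subject_id[sl$group == g])
    ids <- intersect(ids, outcomes$subject_id)
    X <- as.data.frame(lapply(preds, function(p) p[ids]))
    for (oc in setdiff(names(outcomes), "subject_id")) {
      y <- outcomes[[oc]][match(ids, outcomes$subject_id)]
      ok <- stats::complete.cases(cbind(y, X))
      if (sum(ok) < 5) next
      sw <- stepwise_regression(y[ok], X[ok, , drop = FALSE],
                                p_in = p_in, p_out = p_out)
      if (nrow(sw$steps) == 0L) next
      st <- sw$steps
      st$step <- seq_len(nrow(st))
      st$group <- g; st$outcome <- oc; st$se <- sw$se_estimate
      rows[[paste(g, oc)]] <- st
    }
  }
  if (!length(rows))
    return(data.frame(group = character(0), outcome = character(0),
                      step = integer(0), action = character(0),
                      predictor = character(0), se = numeric(0),
                      adj_r2 = numeric(0), delta_r2 = numeric(0),
                      f_change = numeric(0), p_change = numeric(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[, c("group", "outcome", "step", "action", "predictor", "se",
          "adj_r2", "delta_r2", "f_change", "p_change")]
}

# write a CSV with a provenance comment header
write_provenance_csv <- function(df, path, provenance) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# provenance: %s", provenance), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Export the group-analysis tables as CSV files
#'
#' Writes three CSVs mirroring the omnibus comparisons (condition,
#' interaction and group effects with F, p, partial eta squared and FDR
#' flags), the per-condition follow-up contrasts, and optionally the
#' stepwise-regression steps. Every file carries a provenance comment line
#' (config hash + seed); identical provenance implies byte-identical output.
#'
#' @param results a [run_full_analysis] result.
#' @param dir output directory (created if needed).
#' @param stepwise optional result of [stepwise_tables].
#' @return named character vector of written paths, invisibly.
#' @export
export_tables <- function(results, dir, stepwise = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    omnibus = file.path(dir, "omnibus_anova.csv"),
    followups = file.path(dir, "per_condition_contrasts.csv"),
    regressions = file.path(dir, "pli_power_regressions.csv"))
  write_provenance_csv(results$omnibus %||% data.frame(),
                       paths["omnibus"], results$provenance)
  write_provenance_csv(results$followups %||% data.frame(),
                       paths["followups"], results$provenance)
  write_provenance_csv(results$regressions %||% data.frame(),
                       paths["regressions"], results$provenance)
  if (!is.null(stepwise)) {
    paths["stepwise"] <- file.path(dir, "stepwise_regressions.csv")
    write_provenance_csv(stepwise, paths["stepwise"], results$provenance)
  }
  invisible(paths)
}
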