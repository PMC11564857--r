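# Result assembly: significant-fraction arithmetic and the end-to-end
# pipeline with plain-text outputs.

# half-away-from-zero rounding (report style; base round() is half-to-even)
round_half_up <- function(x, digits = 0) {
  sign(x) * floor(abs(x) * 10^digits + 0.5) / 10^digits
}

#' Significant-comparison fractions by modality
#'
#' Given the per-metric counts of significant tracts, computes the fraction
#' of significant comparisons for the 4 DTI metrics, the 7 DKI metrics, and
#' all 11 together (out of `n_tracts` tests per metric, 792 in the complete
#' 72-tract design).  Report percentages are rounded half away from zero;
#' raw fractions are retained.
#'
#' @param per_metric_counts named numeric vector, metric -> count of
#'   significant tracts; names must be metric identifiers from
#'   [wm_metrics()] and every count `<= n_tracts`.
#' @param n_tracts tracts per metric (default 72).
#' @return data.frame with rows `dti`, `dki`, `total`: `n_significant`,
#'   `n_tests`, `fraction`, `pct`.
#' @export
summarize_significance <- function(per_metric_counts, n_tracts = 72) {
  counts <- per_metric_counts
  unknown <- setdiff(names(counts), wm_metrics())
  if (length(unknown)) {
    stop("unknown metric key(s): ", paste(unknown, collapse = ", "))
  }
  if (is.null(names(counts)) || any(!nzchar(names(counts)))) {
    stop("per_metric_counts must be a named vector")
  }
  if (any(counts < 0) || any(counts > n_tracts)) {
    stop("counts must lie in [0, n_tracts]")
  }
  groups <- list(dti = dti_metrics(), dki = dki_metrics(),
                 total = wm_metrics())
  rows <- lapply(names(groups), function(g) {
    mets <- intersect(groups[[g]], names(counts))
    n_sig <- sum(counts[mets])
    n_tests <- n_tracts * length(groups[[g]])
    data.frame(modality = g, n_significant = n_sig, n_tests = n_tests,
               fraction = n_sig / n_tests,
               pct = round_half_up(100 * n_sig / n_tests),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes, in order: per-tract comparisons, the single-WM-ROI summary,
#' the permutation omnibus, the effect-size map, the correlation grid, the
#' Z-score battery, and the significant-fraction summary.  With `out_dir`
#' set, writes every result table as TSV plus a run manifest recording the
#' seed and thresholds; identical inputs and seed give byte-identical
#' numeric outputs.
#'
#' @param panel long-format tract panel.
#' @param profiles subject profile table (NULL to skip correlations and
#'   Z-scoring).
#' @param norms normative table for the Z-score battery.
#' @param alphas per-tract significance levels; the first is used for the
#'   significant-fraction summary.
#' @param B permutations for the omnibus.
#' @param seed integer seed for the permutation draws.
#' @param bound_method effect-size bound method, see [null_effect_bound()].
#' @param p_rule omnibus p-value rule, see [omnibus_p()].
#' @param out_dir optional output directory.
#' @param mode per-tract test mode for [compare_tracts()] /
#'   [single_wm_roi()].
#' @return list: `tract_stats`, `single_roi`, `omnibus`, `effects`,
#'   `correlations`, `deficits`, `significance`, `manifest`.
#' @export
run_pipeline <- function(panel, profiles = NULL, norms = default_norms(),
                         alphas = c(0.05, 0.01), B = 10000, seed = 1L,
                         bound_method = "normal",
                         p_rule = "ge_plus_one", out_dir = NULL,
                         mode = "auto") {
  validate_panel(panel)
  tract_stats <- compare_tracts(panel, alphas = alphas, mode = mode)
  single_roi <- single_wm_roi(panel, mode = mode)
  omnibus <- run_omnibus(panel, alphas = alphas, B = B, seed = seed,
                         rule = p_rule)
  effects <- effect_map(panel, alpha = alphas[1], method = bound_method)
  correlations <- NULL; deficits <- NULL
  if (!is.null(profiles)) {
    correlations <- correlation_table(panel, profiles, norms = norms)
    deficits <- zscore_battery(
      profiles[profiles$group == "athlete",
               c("subject_id", intersect(norms$test, names(profiles)))],
      norms = norms
    )
  }
  sig_col <- paste0("sig_", alphas[1])
  counts <- tapply(tract_stats[[sig_col]], tract_stats$metric, sum)
  n_tracts <- max(tapply(tract_stats$tract_id, tract_stats$metric,
                         function(t) length(unique(t))))
  significance <- summarize_significance(
    stats::setNames(as.numeric(counts), names(counts)), n_tracts = n_tracts
  )
  manifest <- c(
    sprintf("seed: %d", as.integer(seed)),
    sprintf("permutations: %d", as.integer(B)),
    sprintf("alphas: %s", paste(alphas, collapse = ", ")),
    sprintf("p_rule: %s", p_rule),
    sprintf("bound_method: %s", bound_method),
    sprintf("test_mode: %s", mode),
    sprintf("n_tracts: %d", as.integer(n_tracts)),
    sprintf("package_version: %s",
            as.character(utils::packageVersion("tractomnibus")))
  )
  result <- list(tract_stats = tract_stats, single_roi = single_roi,
                 omnibus = omnibus, effects = effects,
                 correlations = correlations, deficits = deficits,
                 significance = significance, manifest = manifest)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_tsv(tract_stats, file.path(out_dir, "tract_stats.tsv"))
    write_tsv(single_roi$summary, file.path(out_dir, "single_roi.tsv"))
    write_tsv(omnibus$table, file.path(out_dir, "omnibus.tsv"))
    write_tsv(effects$effects, file.path(out_dir, "effects.tsv"))
    write_tsv(effects$summary, file.path(out_dir, "effects_summary.tsv"))
    if (!is.null(correlations)) {
      write_tsv(correlations, file.path(out_dir, "correlations.tsv"))
    }
    if (!is.null(deficits)) {
      write_tsv(deficits$flags, file.path(out_dir, "deficits.tsv"))
      write_tsv(deficits$per_test,
                file.path(out_dir, "deficit_prevalence.tsv"))
    }
    write_tsv(significance, file.path(out_dir, "significance.tsv"))
    writeLines(manifest, file.path(out_dir, "run_manifest.txt"))
  }
  result
}
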