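# Spearman correlation grid, norm-based Z-scores, deficit classification.

#' Standard normal lower tail
#'
#' Fraction of a normative population scoring at or below `z` standard
#' deviations from the mean; at the deficit cutoff z = -1.5 this is 0.0668,
#' i.e. about 6.7\% of the general population.
#'
#' @param z finite numeric.
#' @return lower-tail probability.
#' @export
normal_lower_tail <- function(z) {
  if (any(!is.finite(z))) stop("normal_lower_tail: non-finite input")
  stats::pnorm(z)
}

#' Norm-based Z-scores and deficit flags
#'
#' Converts raw test scores to standard Z-scores against a normative table,
#' `z = (raw - norm_mean) / norm_sd`, sign-flipped for tests where a lower
#' raw score means better performance, so negative z always means worse
#' than the norm.  A deficit is `z <= cutoff` (boundary inclusive; default
#' -1.5, i.e. 1.5 SD below the normative mean).
#'
#' @param raws data.frame with `subject_id` and one column per test (wide),
#'   e.g. the profiles table from [generate_cohort()].  Tests without a
#'   norms row are skipped with a message.
#' @param norms normative table, see [default_norms()].
#' @param cutoff deficit cutoff on the z scale.
#' @return list with `flags` (long data.frame `subject_id`, `test`, `raw`,
#'   `z`, `deficit`), `per_test` (deficit fraction per test), and
#'   `prevalence` (fraction of subjects with at least one deficit, among
#'   subjects with any scored test).
#' @export
zscore_battery <- function(raws, norms = default_norms(), cutoff = -1.5) {
  stopifnot("subject_id" %in% names(raws))
  tests <- intersect(norms$test, names(raws))
  unscored <- setdiff(norms$test, tests)
  if (length(unscored)) {
    message("zscore_battery: no raw scores for ",
            paste(unscored, collapse = ", "), "; skipped")
  }
  flags <- list()
  for (tst in tests) {
    nr <- norms[norms$test == tst, ]
    z <- (raws[[tst]] - nr$norm_mean) / nr$norm_sd
    if (!nr$higher_is_better) z <- -z
    flags[[tst]] <- data.frame(
      subject_id = raws$subject_id, test = tst, raw = raws[[tst]], z = z,
      deficit = !is.na(z) & z <= cutoff, stringsAsFactors = FALSE
    )
  }
  if (length(flags) == 0) stop("no test in `raws` has a norms entry")
  flags <- do.call(rbind, c(flags, make.row.names = FALSE))
  scored <- flags[!is.na(flags$z), , drop = FALSE]
  per_test <- stats::aggregate(deficit ~ test, data = scored, FUN = mean)
  names(per_test) <- c("test", "deficit_fraction")
  any_def <- tapply(scored$deficit, scored$subject_id, any)
  list(flags = flags, per_test = per_test,
       prevalence = mean(any_def))
}

#' Correlation grid of global metrics against outcomes
#'
#' Spearman correlations between each metric's single-WM-ROI value (the
#' per-subject mean over all tracts) and each outcome column, computed
#' within the athlete group by default.  Missing values are deleted
#' pairwise, so each cell reports its own `n`; cells with fewer than 3
#' complete pairs are returned with `NA` correlation and flagged.
#'
#' @param panel long-format tract panel.
#' @param profiles subject profile table (must contain `subject_id`,
#'   `group`, and the outcome columns).
#' @param outcomes character vector of profile columns to correlate;
#'   default: every test in `norms` present in the profiles plus `NfL` and
#'   `GFAP`.
#' @param group `"athlete"` (default, matching the study design) or
#'   `"all"`.
#' @param norms normative table used to pick default outcomes.
#' @param method p-value method passed to [spearman_test()].
#' @return data.frame grid: `metric`, `outcome`, `r_s`, `p`, `n`,
#'   `computable`.
#' @export
correlation_table <- function(panel, profiles, outcomes = NULL,
                              group = c("athlete", "all"),
                              norms = default_norms(), method = "auto") {
  group <- match.arg(group)
  if (is.null(outcomes)) {
    outcomes <- c(intersect(norms$test, names(profiles)),
                  intersect(c("NfL", "GFAP"), names(profiles)))
  }
  stopifnot(all(outcomes %in% names(profiles)))
  roi <- single_wm_roi(panel)$subject_values
  keep <- if (group == "athlete") profiles$group == "athlete" else TRUE
  prof <- profiles[keep, , drop = FALSE]
  rows <- list()
  for (metric in sort(unique(roi$metric))) {
    mv <- roi[roi$metric == metric, , drop = FALSE]
    merged <- merge(prof, mv[, c("subject_id", "value")], by = "subject_id")
    for (oc in outcomes) {
      x <- merged$value; y <- merged[[oc]]
      ok <- is.finite(x) & is.finite(y)
      if (sum(ok) < 3) {
        rows[[length(rows) + 1]] <- data.frame(
          metric = metric, outcome = oc, r_s = NA_real_, p = NA_real_,
          n = sum(ok), computable = FALSE, stringsAsFactors = FALSE
        )
        next
      }
      st <- spearman_test(x[ok], y[ok], method = method)
      rows[[length(rows) + 1]] <- data.frame(
        metric = metric, outcome = oc, r_s = st$r_s, p = st$p, n = st$n,
        computable = !st$degenerate, stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
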