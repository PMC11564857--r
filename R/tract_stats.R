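# Per-tract and whole-white-matter group comparison.
#
# Quantile convention throughout: linear interpolation between order
# statistics (quantile type 7, the common statistical-software default).
# Significance is strict: p < alpha.

# subjects x tracts value matrix for one metric; optionally only subjects
# with complete tract coverage
panel_matrix <- function(panel, metric, complete_only = TRUE) {
  sub <- panel[panel$metric == metric, , drop = FALSE]
  if (nrow(sub) == 0) return(NULL)
  tracts <- sort(unique(sub$tract_id))
  subjects <- unique(sub$subject_id)
  M <- matrix(NA_real_, length(subjects), length(tracts),
              dimnames = list(subjects, tracts))
  M[cbind(match(sub$subject_id, subjects), match(sub$tract_id, tracts))] <-
    sub$value
  grp <- sub$group[match(subjects, sub$subject_id)]
  if (complete_only) {
    keep <- stats::complete.cases(M)
    M <- M[keep, , drop = FALSE]
    grp <- grp[keep]
  }
  list(values = M, group = grp, tracts = tracts)
}

q7 <- function(x, p) unname(stats::quantile(x, p, type = 7))

#' Per-tract group comparison
#'
#' One Mann-Whitney U test per (metric, tract): medians and interquartile
#' ranges per group, the U statistic and two-sided p, and a significance
#' flag per alpha level (strict `p < alpha`).  Subjects missing a metric are
#' excluded listwise for that metric; a tract present in only one group is
#' excluded with a warning.
#'
#' @param panel long-format tract panel (see [generate_cohort()]).
#' @param alphas numeric vector of per-tract significance levels.
#' @param mode test mode passed to [mann_whitney()].
#' @return data.frame with one row per metric x tract: group medians and
#'   quartiles, `U`, `p`, and logical columns `sig_<alpha>`.
#' @export
compare_tracts <- function(panel, alphas = c(0.05, 0.01), mode = "auto") {
  validate_panel(panel)
  rows <- list()
  for (metric in sort(unique(panel$metric))) {
    sub <- panel[panel$metric == metric, , drop = FALSE]
    for (tract in sort(unique(sub$tract_id))) {
      tr <- sub[sub$tract_id == tract, , drop = FALSE]
      x <- tr$value[tr$group == "athlete"]
      y <- tr$value[tr$group == "control"]
      if (length(x) < 2 || length(y) < 2) {
        warning("metric ", metric, " tract ", tract,
                " lacks both groups; excluded")
        next
      }
      mw <- mann_whitney(x, y, mode = mode)
      row <- data.frame(
        metric = metric, tract_id = tract,
        n_athlete = length(x), n_control = length(y),
        median_athlete = q7(x, 0.5), q25_athlete = q7(x, 0.25),
        q75_athlete = q7(x, 0.75),
        median_control = q7(y, 0.5), q25_control = q7(y, 0.25),
        q75_control = q7(y, 0.75),
        U = mw$U, p = mw$p, stringsAsFactors = FALSE
      )
      for (a in alphas) row[[paste0("sig_", a)]] <- mw$p < a
      rows[[length(rows) + 1]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Whole-white-matter single-ROI summary
#'
#' For each metric, averages every subject's tract values into one global
#' "single WM ROI" value (sum over tracts divided by the tract count; 72
#' when the tract set is complete), then compares the groups with a
#' Mann-Whitney U test.  Subjects with partial tract coverage are dropped
#' for that metric; a metric with an empty group is skipped with a message.
#'
#' @param panel long-format tract panel.
#' @param mode test mode passed to [mann_whitney()].
#' @return list with `summary` (one row per metric: group medians/quartiles
#'   of the global value, `U`, `p`, subject counts) and `subject_values`
#'   (long data.frame `subject_id`, `group`, `metric`, `value`).
#' @export
single_wm_roi <- function(panel, mode = "auto") {
  validate_panel(panel)
  summaries <- list(); subj_rows <- list()
  for (metric in sort(unique(panel$metric))) {
    pm <- panel_matrix(panel, metric, complete_only = TRUE)
    if (is.null(pm) || nrow(pm$values) == 0) next
    v <- rowMeans(pm$values)
    x <- v[pm$group == "athlete"]; y <- v[pm$group == "control"]
    subj_rows[[metric]] <- data.frame(
      subject_id = rownames(pm$values), group = pm$group, metric = metric,
      value = unname(v), stringsAsFactors = FALSE
    )
    if (length(x) < 2 || length(y) < 2) {
      message("single_wm_roi: metric ", metric,
              " lacks a full group after exclusions; comparison skipped")
      next
    }
    mw <- mann_whitney(x, y, mode = mode)
    summaries[[metric]] <- data.frame(
      metric = metric, n_tracts = length(pm$tracts),
      n_athlete = length(x), n_control = length(y),
      median_athlete = q7(x, 0.5), q25_athlete = q7(x, 0.25),
      q75_athlete = q7(x, 0.75),
      median_control = q7(y, 0.5), q25_control = q7(y, 0.25),
      q75_control = q7(y, 0.75),
      U = mw$U, p = mw$p, stringsAsFactors = FALSE
    )
  }
  summary <- do.call(rbind, summaries)
  rownames(summary) <- NULL
  list(summary = summary,
       subject_values = do.call(rbind, c(subj_rows, make.row.names = FALSE)))
}
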