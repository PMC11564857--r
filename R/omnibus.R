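# Permutation omnibus on the count of significant tracts.
#
# The multiplicity device: per metric, count how many of the per-tract
# rank-sum tests are significant at a fixed alpha, then compare that count
# with its distribution under random relabelling of the subjects.  Because
# group labels are permuted jointly across tracts, the null distribution
# respects the (unknown) inter-tract dependence; its 95th percentile is the
# largest number of significant tracts expected by chance alone.
#
# Engine note: midranks and the tie-corrected U variance per tract depend
# only on the data, not on the labels, so a permutation's 72 U statistics
# are one matrix product (ranks x label-indicator).  The per-tract test
# inside the engine is therefore the tie-corrected, continuity-corrected
# normal approximation; the observed count is computed with the identical
# test so observed and null statistics are exchangeable under H0.

#' Count significant p-values
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @param alpha significance level; counting is strict (`p < alpha`).
#' @return integer count.
#' @export
count_significant <- function(p_values, alpha) {
  if (length(p_values) == 0) {
    warning("count_significant: empty p-value list")
    return(0L)
  }
  if (any(!is.finite(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    stop("count_significant: p-values must be finite and in [0, 1]")
  }
  sum(p_values < alpha)
}

# per-tract asymptotic p-values for an indicator matrix of group-1 labels.
# R: n x T midrank matrix (per-tract column ranks); sigma: length-T
# tie-corrected U standard deviations; G: n x B 0/1 indicator matrix with
# column sums n1.  Returns T x B matrix of two-sided p-values.
engine_p_matrix <- function(R, sigma, G, n1, n2) {
  U <- crossprod(R, G) - n1 * (n1 + 1) / 2   # T x B rank-sum statistics
  mu <- n1 * n2 / 2
  Z <- pmax(abs(U - mu) - 0.5, 0) / ifelse(sigma == 0, Inf, sigma)
  P <- 2 * stats::pnorm(-Z)
  P[sigma == 0, ] <- 1
  pmin(P, 1)
}

# midranks and tie sigmas for a subjects x tracts value matrix
engine_rank_stats <- function(M, n1, n2) {
  R <- apply(M, 2, rank, ties.method = "average")
  sigma <- apply(M, 2, u_sigma, n1 = n1, n2 = n2)
  list(R = R, sigma = sigma)
}

# B random group-size-preserving label assignments as an n x B 0/1 matrix
perm_indicators <- function(n, n1, B) {
  G <- matrix(0, n, B)
  for (b in seq_len(B)) G[sample.int(n, n1), b] <- 1
  G
}

#' Permutation null distribution of the significant-tract count
#'
#' Shuffles group labels uniformly at random over subjects (preserving
#' group sizes), recomputes every per-tract U test, and records the count
#' of tracts significant at `alpha`, `B` times.  Deterministic under a
#' fixed seed.
#'
#' @param panel long-format tract panel.
#' @param metric metric identifier.
#' @param alpha per-tract significance level.
#' @param B number of permutations (>= 1).
#' @param seed integer seed.
#' @return integer vector of `B` null counts.
#' @export
null_count_distribution <- function(panel, metric, alpha, B = 10000,
                                    seed = 1L) {
  stopifnot(B >= 1)
  pm <- panel_matrix(panel, metric, complete_only = TRUE)
  if (is.null(pm)) stop("metric not present in panel: ", metric)
  n1 <- sum(pm$group == "athlete"); n2 <- sum(pm$group == "control")
  if (n1 < 2 || n2 < 2) stop("both groups must be present for ", metric)
  rs <- engine_rank_stats(pm$values, n1, n2)
  set.seed(seed)
  G <- perm_indicators(n1 + n2, n1, B)
  P <- engine_p_matrix(rs$R, rs$sigma, G, n1, n2)
  as.integer(colSums(P < alpha))
}

#' Permutation p-value for the omnibus count
#'
#' Two rules are provided.  `strict_greater` follows the verbal definition
#' "fraction of permutations whose count exceeds the observed count" and can
#' return exactly 0; `ge_plus_one` is the add-one estimator
#' `(1 + #\{null >= T_obs\}) / (B + 1)`, never 0, and is the default.
#'
#' @param T_obs observed significant-tract count.
#' @param null_counts integer vector of null counts.
#' @param rule `"ge_plus_one"` or `"strict_greater"`.
#' @return probability.
#' @export
omnibus_p <- function(T_obs, null_counts,
                      rule = c("ge_plus_one", "strict_greater")) {
  rule <- match.arg(rule)
  if (length(null_counts) == 0) stop("omnibus_p: empty null distribution")
  if (rule == "strict_greater") {
    mean(null_counts > T_obs)
  } else {
    (1 + sum(null_counts >= T_obs)) / (length(null_counts) + 1)
  }
}

#' 95th percentile of the null count
#'
#' Empirical-CDF convention: the smallest integer `q` such that at least
#' 95\% of the null counts are `<= q` — the largest number of false-positive
#' tracts expected under the null.
#'
#' @param null_counts integer vector.
#' @param prob percentile (default 0.95).
#' @return integer.
#' @export
null_q95 <- function(null_counts, prob = 0.95) {
  if (length(null_counts) == 0) stop("null_q95: empty null distribution")
  as.integer(stats::quantile(null_counts, prob, type = 1, names = FALSE))
}

#' Run the permutation omnibus for every metric and alpha
#'
#' For each metric: the observed count of significant tracts at each alpha,
#' the permutation null distribution of that count, its permutation
#' p-value, and the null 95th percentile.  A metric is flagged as exceeding
#' the null when `T_obs > q95_null` and `p_perm < 0.05`.  For a given seed
#' the same `B` label permutations are reused across metrics that share a
#' subject set (metrics with different missingness patterns get their own
#' draws); this induces dependence between per-metric omnibus p-values and
#' is documented behaviour.
#'
#' @param panel long-format tract panel.
#' @param alphas per-tract significance levels.
#' @param B number of permutations.
#' @param seed integer seed.
#' @param rule p-value rule, see [omnibus_p()].
#' @return list with `table` (one row per metric x alpha: `metric`, `alpha`,
#'   `T_obs`, `p_perm`, `q95_null`, `B`, `rule`, `flagged`) and
#'   `null_counts` (named list of integer vectors, `"<metric>@<alpha>"`).
#' @export
run_omnibus <- function(panel, alphas = c(0.05, 0.01), B = 10000, seed = 1L,
                        rule = c("ge_plus_one", "strict_greater")) {
  rule <- match.arg(rule)
  validate_panel(panel)
  set.seed(seed)
  metrics <- sort(unique(panel$metric))
  perm_cache <- list()
  rows <- list(); nulls <- list()
  for (metric in metrics) {
    pm <- panel_matrix(panel, metric, complete_only = TRUE)
    n1 <- sum(pm$group == "athlete"); n2 <- sum(pm$group == "control")
    if (n1 < 2 || n2 < 2) {
      message("run_omnibus: metric ", metric, " lacks both groups; skipped")
      next
    }
    key <- paste(c(n1, sort(rownames(pm$values))), collapse = "|")
    if (is.null(perm_cache[[key]])) {
      perm_cache[[key]] <- perm_indicators(n1 + n2, n1, B)
    }
    G <- perm_cache[[key]]
    rs <- engine_rank_stats(pm$values, n1, n2)
    g_obs <- matrix(as.numeric(pm$group == "athlete"), ncol = 1)
    p_obs <- engine_p_matrix(rs$R, rs$sigma, g_obs, n1, n2)[, 1]
    P <- engine_p_matrix(rs$R, rs$sigma, G, n1, n2)
    for (a in alphas) {
      T_obs <- count_significant(p_obs, a)
      nc <- as.integer(colSums(P < a))
      p_perm <- omnibus_p(T_obs, nc, rule)
      q95 <- null_q95(nc)
      nulls[[paste0(metric, "@", a)]] <- nc
      rows[[length(rows) + 1]] <- data.frame(
        metric = metric, alpha = a, T_obs = T_obs, p_perm = p_perm,
        q95_null = q95, B = B, rule = rule,
        flagged = (T_obs > q95) && (p_perm < 0.05),
        stringsAsFactors = FALSE
      )
    }
  }
  table <- do.call(rbind, rows)
  rownames(table) <- NULL
  list(table = table, null_counts = nulls, seed = seed, rule = rule)
}
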