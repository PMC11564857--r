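# Rank-sum machinery: midranks, tie-corrected Mann-Whitney U (exact and
# normal-approximation modes), and Spearman correlation with exact
# enumeration for tiny n.
#
# Conventions: U is the statistic of the first sample, U = R1 - n1(n1+1)/2
# with R1 the midrank sum of x, so 0 <= U <= n1*n2 and the two one-sided
# statistics satisfy U1 + U2 = n1*n2.  All p-values are two-sided.

#' Midranks
#'
#' Ranks with tied values receiving the mean of the rank positions they
#' span; ranks always sum to n(n+1)/2.
#'
#' @param values non-empty numeric vector, all finite.
#' @return numeric vector of midranks.
#' @export
midranks <- function(values) {
  if (length(values) == 0) stop("midranks: empty input")
  if (any(!is.finite(values))) stop("midranks: non-finite input")
  rank(values, ties.method = "average")
}

# tie-corrected standard deviation of U under H0 for a pooled sample
u_sigma <- function(pooled, n1, n2) {
  n <- n1 + n2
  tie <- tabulate(match(pooled, unique(pooled)))
  correction <- sum(tie^3 - tie) / (n * (n - 1))
  v <- n1 * n2 / 12 * ((n + 1) - correction)
  sqrt(max(v, 0))
}

# two-sided normal-approximation p with continuity correction
u_asymptotic_p <- function(U, n1, n2, sigma) {
  mu <- n1 * n2 / 2
  z <- pmax(abs(U - mu) - 0.5, 0) / sigma
  p <- 2 * stats::pnorm(-z)
  p[sigma == 0] <- 1
  pmin(p, 1)
}

# exact two-sided p by enumerating all C(n1+n2, n1) label assignments of the
# observed pooled values (valid with ties); two-sidedness via |U - n1*n2/2|
u_exact_enum_p <- function(U, pooled_ranks, n1, n2) {
  combos <- utils::combn(n1 + n2, n1)
  U_all <- colSums(matrix(pooled_ranks[combos], nrow = n1)) -
    n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  mean(abs(U_all - mu) >= abs(U - mu) - 1e-9)
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test of `x` vs `y` from midranks.  `exact` mode uses
#' the exact U null distribution (tie-free samples) or full enumeration of
#' all label assignments (with ties); `asymptotic` mode uses the normal
#' approximation with tie-corrected variance and a 0.5 continuity
#' correction.  `auto` picks exact when `n1 + n2 <= exact_max_n`.
#'
#' @param x,y numeric samples, each of length >= 2.
#' @param mode `"auto"`, `"exact"`, or `"asymptotic"`.
#' @param exact_max_n combined-size threshold for exact mode under `auto`.
#' @return list with `U` (statistic of `x`), `p` (two-sided), `mode_used`,
#'   and `degenerate` (TRUE when all pooled values are identical, in which
#'   case `p = 1`).
#' @export
mann_whitney <- function(x, y, mode = c("auto", "exact", "asymptotic"),
                         exact_max_n = 12) {
  mode <- match.arg(mode)
  if (length(x) < 2 || length(y) < 2) {
    stop("mann_whitney: each sample needs at least 2 values")
  }
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("mann_whitney: non-finite input")
  }
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r <- midranks(pooled)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (length(unique(pooled)) == 1) {
    return(list(U = U, p = 1, mode_used = "degenerate", degenerate = TRUE))
  }
  if (mode == "auto") {
    mode <- if (n1 + n2 <= exact_max_n) "exact" else "asymptotic"
  }
  if (mode == "exact") {
    ties <- length(unique(pooled)) < length(pooled)
    if (!ties) {
      # exact U null distribution (symmetric about n1*n2/2)
      p <- if (U > n1 * n2 / 2) {
        2 * stats::pwilcox(U - 1, n1, n2, lower.tail = FALSE)
      } else {
        2 * stats::pwilcox(U, n1, n2)
      }
      p <- min(p, 1)
    } else {
      p <- u_exact_enum_p(U, r, n1, n2)
    }
  } else {
    p <- u_asymptotic_p(U, n1, n2, u_sigma(pooled, n1, n2))
  }
  list(U = U, p = p, mode_used = mode, degenerate = FALSE)
}

# all permutations of 1..n as an (n! x n) matrix; n <= 8 intended
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 1L
  for (pos in seq_len(n)) {
    block <- cbind(sub[, seq_len(pos - 1), drop = FALSE], n,
                   sub[, seq(pos, n - 1)[seq_len(n - pos)], drop = FALSE])
    out[row:(row + nrow(sub) - 1), ] <- block
    row <- row + nrow(sub)
  }
  out
}

#' Spearman rank correlation
#'
#' `r_s` is the Pearson correlation of midranks.  The p-value uses the
#' t-transform with n - 2 degrees of freedom by default; for `n <=
#' exact_max_n` (`auto` mode) it is computed exactly by enumerating all
#' permutations of one variable's ranks.
#'
#' @param x,y paired numeric vectors; pairs with missing values are dropped.
#' @param method `"auto"`, `"t"`, or `"exact"`.
#' @param exact_max_n sample-size threshold for exact enumeration.
#' @return list with `r_s`, `p`, `n` (pairs used), `method_used`, and
#'   `degenerate` (TRUE when either variable has zero rank variance; `r_s`
#'   and `p` are then NA).
#' @export
spearman_test <- function(x, y, method = c("auto", "t", "exact"),
                          exact_max_n = 8) {
  method <- match.arg(method)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("spearman_test: fewer than 3 complete pairs")
  rx <- midranks(x); ry <- midranks(y)
  if (stats::var(rx) == 0 || stats::var(ry) == 0) {
    return(list(r_s = NA_real_, p = NA_real_, n = n,
                method_used = "degenerate", degenerate = TRUE))
  }
  r <- stats::cor(rx, ry)
  if (method == "auto") method <- if (n <= exact_max_n) "exact" else "t"
  if (method == "exact") {
    perms <- all_permutations(n)
    r_all <- apply(perms, 1, function(idx) stats::cor(rx, ry[idx]))
    p <- mean(abs(r_all) >= abs(r) - 1e-12)
  } else {
    tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(r_s = r, p = p, n = n, method_used = method, degenerate = FALSE)
}
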