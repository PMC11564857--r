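# shared fixture builders: cohorts are always generated in code, never stored

no_missing <- c(dti = 0, dki = 0, csf = 0, neuropsych = 0)

# null cohort: no group effect anywhere
null_config <- function(n_athlete = 20, n_control = 21, metrics = "DKI_FA",
                        rho = 0.5, n_tracts = 72, seed = 1L) {
  cohort_config(
    n_athlete = n_athlete, n_control = n_control, n_tracts = n_tracts,
    metrics = metrics, inter_tract_rho = rho,
    missing_rate = no_missing, seed = seed
  )
}

# single-metric cohort with delta shifting the first `n_affected` tracts
shift_config <- function(delta, n_affected, metric = "DKI_FA",
                         n_athlete = 20, n_control = 20, rho = 0.5,
                         n_tracts = 72, sign = 1, seed = 1L) {
  cohort_config(
    n_athlete = n_athlete, n_control = n_control, n_tracts = n_tracts,
    metrics = metric, inter_tract_rho = rho,
    affected = stats::setNames(list(seq_len(n_affected)), metric),
    delta = stats::setNames(delta, metric),
    effect_sign = stats::setNames(sign, metric),
    missing_rate = no_missing, seed = seed
  )
}

# tiny hand-built long panel
toy_panel <- function(values_by_group, metric = "DKI_MD", tract_id = 1L) {
  n1 <- length(values_by_group$athlete)
  n2 <- length(values_by_group$control)
  data.frame(
    subject_id = c(sprintf("a%d", seq_len(n1)), sprintf("c%d", seq_len(n2))),
    group = rep(c("athlete", "control"), c(n1, n2)),
    metric = metric, tract_id = tract_id,
    value = c(values_by_group$athlete, values_by_group$control),
    stringsAsFactors = FALSE
  )
}

# independent O(n^2) midrank oracle: r_i = #{x < x_i} + (#{x == x_i} + 1) / 2
midrank_oracle <- function(x) {
  vapply(x, function(xi) sum(x < xi) + (sum(x == xi) + 1) / 2, numeric(1))
}

# brute-force two-sided exact U-test oracle by enumerating label assignments
mw_enum_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r <- midrank_oracle(pooled)
  U_of <- function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2
  U_obs <- U_of(seq_len(n1))
  mu <- n1 * n2 / 2
  combos <- utils::combn(n1 + n2, n1)
  U_all <- apply(combos, 2, U_of)
  list(U = U_obs, p = mean(abs(U_all - mu) >= abs(U_obs - mu) - 1e-9))
}
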