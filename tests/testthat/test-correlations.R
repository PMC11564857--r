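test_that("normal lower tail matches quadrature and the deficit arithmetic", {
  expect_equal(normal_lower_tail(0), 0.5)
  expect_equal(round(100 * normal_lower_tail(-1.5), 1), 6.7)
  for (z in c(-2.5, -1.5, 0.3, 1.7)) {
    quad <- integrate(dnorm, -Inf, z, rel.tol = 1e-10)$value
    expect_equal(normal_lower_tail(z), quad, tolerance = 1e-6)
  }
  expect_error(normal_lower_tail(NA), "non-finite")
})

test_that("Z-scoring flips direction and the deficit boundary is inclusive", {
  norms <- data.frame(test = c("good_high", "good_low"),
                      norm_mean = c(100, 10), norm_sd = c(15, 4),
                      higher_is_better = c(TRUE, FALSE))
  raws <- data.frame(subject_id = c("s1", "s2", "s3"),
                     good_high = c(100, 100 - 1.5 * 15, 100 - 1.6 * 15),
                     good_low = c(10, 10 + 1.5 * 4, 10 - 2 * 4))
  zb <- zscore_battery(raws, norms)
  f <- zb$flags
  gh <- f[f$test == "good_high", ]
  expect_equal(gh$z, c(0, -1.5, -1.6))
  expect_equal(gh$deficit, c(FALSE, TRUE, TRUE))   # boundary inclusive
  gl <- f[f$test == "good_low", ]
  expect_equal(gl$z, c(0, -1.5, 2))                # sign flipped
  expect_equal(gl$deficit, c(FALSE, TRUE, FALSE))
  expect_equal(zb$prevalence, 2 / 3)
})

test_that("deficit prevalence in a normative population approaches 6.7%", {
  set.seed(10)
  n <- 1e5
  raws <- data.frame(subject_id = sprintf("s%06d", 1:n),
                     RBANS_global = rnorm(n, 100, 15))
  zb <- suppressMessages(zscore_battery(raws, default_norms()))
  frac <- zb$per_test$deficit_fraction
  expect_equal(frac, pnorm(-1.5), tolerance = 0.05)
  expect_lt(abs(frac - pnorm(-1.5)), 0.003)
})

test_that("the correlation grid is computed within athletes, pairwise", {
  coh <- generate_cohort(null_config(n_athlete = 12, n_control = 12,
                                     metrics = c("DKI_FA", "DKI_MD"),
                                     n_tracts = 10, seed = 41))
  prof <- coh$profiles
  prof$NfL[prof$subject_id == "ath01"] <- NA   # one missing biomarker
  ct <- correlation_table(coh$panel, prof, outcomes = c("NfL", "GFAP"))
  expect_equal(nrow(ct), 4)
  expect_equal(ct$n[ct$outcome == "NfL"], c(11, 11))
  expect_equal(ct$n[ct$outcome == "GFAP"], c(12, 12))
  # invariance to subject order
  ct2 <- correlation_table(coh$panel, prof[rev(seq_len(nrow(prof))), ],
                           outcomes = c("NfL", "GFAP"))
  expect_equal(ct, ct2)
  # too few pairs -> not computable
  prof$GFAP[prof$group == "athlete"][1:10] <- NA
  ct3 <- correlation_table(coh$panel, prof, outcomes = "GFAP")
  expect_false(any(ct3$computable))
})

test_that("biomarker coupling reproduces the expected correlation signs", {
  # large athlete group so the latent-factor-driven signs are deterministic:
  # NfL rises with injury, DKI FA rises, DKI MD/RD fall
  cfg <- study_config(seed = 55, missing = FALSE)
  cfg$n_athlete <- 600L
  cfg$metrics <- c("DKI_FA", "DKI_MD", "DKI_RD")
  coh <- generate_cohort(cfg)
  ct <- correlation_table(coh$panel, coh$profiles,
                          outcomes = "NfL", method = "t")
  r <- setNames(ct$r_s, ct$metric)
  expect_gt(r[["DKI_FA"]], 0)
  expect_lt(r[["DKI_MD"]], 0)
  expect_lt(r[["DKI_RD"]], 0)
  expect_lt(ct$p[ct$metric == "DKI_FA"], 0.01)
})

test_that("independent outcomes produce a nominal rate of small p-values", {
  set.seed(6)
  hits <- 0; total <- 0
  for (i in 1:20) {
    coh <- generate_cohort(null_config(n_athlete = 20, n_control = 5,
                                       metrics = c("DKI_FA", "DKI_MD"),
                                       n_tracts = 10, seed = 900 + i))
    prof <- coh$profiles
    prof$noise_outcome <- rnorm(nrow(prof))
    ct <- correlation_table(coh$panel, prof, outcomes = "noise_outcome",
                            method = "t")
    hits <- hits + sum(ct$p < 0.05)
    total <- total + nrow(ct)
  }
  expect_lt(hits / total, 0.2)   # loose: only 40 cells
})
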