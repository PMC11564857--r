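test_that("midranks handle ties and sum to n(n+1)/2", {
  expect_equal(midranks(c(3, 1, 2)), c(3, 1, 2))
  expect_equal(midranks(c(5, 5, 7)), c(1.5, 1.5, 3))
  expect_error(midranks(c(1, NA)), "non-finite")
  expect_error(midranks(numeric()), "empty")
  set.seed(42)
  for (i in 1:10) {
    x <- sample(round(rnorm(50), 1))        # injected ties
    r <- midranks(x)
    expect_equal(r, midrank_oracle(x))
    expect_equal(sum(r), 50 * 51 / 2)
  }
})

test_that("U statistic follows the rank-sum identities", {
  set.seed(7)
  for (i in 1:20) {
    x <- rnorm(sample(3:8, 1)); y <- rnorm(sample(3:8, 1))
    u1 <- mann_whitney(x, y, mode = "asymptotic")$U
    u2 <- mann_whitney(y, x, mode = "asymptotic")$U
    expect_equal(u1 + u2, length(x) * length(y))
    expect_gte(u1, 0); expect_lte(u1, length(x) * length(y))
  }
  # identical multisets: central U, p = 1 under continuity correction
  x <- c(1, 3, 5, 7)
  mw <- mann_whitney(x, x, mode = "asymptotic")
  expect_equal(mw$U, length(x)^2 / 2)
  expect_equal(mw$p, 1)
})

test_that("exact p matches full enumeration of label assignments", {
  mw <- mann_whitney(c(1, 2), c(3, 4), mode = "exact")
  expect_equal(mw$U, 0)
  expect_equal(mw$p, 2 / 6)           # enumeration over the 6 assignments
  set.seed(11)
  for (i in 1:60) {
    x <- rnorm(5); y <- rnorm(5)
    if (i %% 2 == 0) { x <- round(x); y <- round(y) }   # force ties
    got <- mann_whitney(x, y, mode = "exact")
    want <- mw_enum_oracle(x, y)
    expect_equal(got$U, want$U)
    expect_equal(got$p, want$p)
  }
})

test_that("exact and asymptotic modes agree with the reference library", {
  set.seed(5)
  for (i in 1:25) {
    x <- rnorm(8); y <- rnorm(7)        # tie-free: exact path
    got <- mann_whitney(x, y, mode = "exact")
    ref <- suppressWarnings(wilcox.test(x, y, exact = TRUE))
    expect_equal(got$U, unname(ref$statistic))
    expect_equal(got$p, ref$p.value)
    xt <- round(rnorm(15), 1); yt <- round(rnorm(12), 1)  # ties: asymptotic
    got2 <- mann_whitney(xt, yt, mode = "asymptotic")
    ref2 <- suppressWarnings(wilcox.test(xt, yt, exact = FALSE,
                                         correct = TRUE))
    expect_equal(got2$p, ref2$p.value, tolerance = 1e-12)
  }
})

test_that("exact and asymptotic p agree closely for moderate samples", {
  set.seed(9)
  worst <- 0
  for (i in 1:200) {
    x <- rnorm(10); y <- rnorm(10)
    pe <- mann_whitney(x, y, mode = "exact")$p
    pa <- mann_whitney(x, y, mode = "asymptotic")$p
    worst <- max(worst, abs(pe - pa))
  }
  expect_lt(worst, 0.02)
})

test_that("degenerate data return p = 1 with a flag", {
  mw <- mann_whitney(rep(2, 4), rep(2, 5))
  expect_true(mw$degenerate)
  expect_equal(mw$p, 1)
})

test_that("spearman matches enumeration and the reference library", {
  # perfect monotone association
  st <- spearman_test(1:10, exp(1:10), method = "t")
  expect_equal(st$r_s, 1)
  # small-sample enumeration: r = -0.5 is unremarkable among 3! orderings
  st3 <- spearman_test(c(1, 2, 3), c(3, 1, 2), method = "exact")
  expect_equal(st3$r_s, -0.5)
  expect_equal(st3$p, 1)
  set.seed(2)
  for (i in 1:10) {
    x <- rnorm(20); y <- 0.5 * x + rnorm(20)
    got <- spearman_test(x, y, method = "t")
    ref <- suppressWarnings(cor.test(x, y, method = "spearman",
                                     exact = FALSE))
    expect_equal(got$r_s, unname(ref$estimate))
    expect_equal(got$p, ref$p.value, tolerance = 1e-12)
  }
})

test_that("spearman is invariant to strictly monotone transforms", {
  set.seed(3)
  x <- rnorm(30); y <- rnorm(30)
  base <- spearman_test(x, y, method = "t")
  tr <- spearman_test(exp(x), qlogis(pnorm(y)), method = "t")
  expect_equal(tr$r_s, base$r_s)
  expect_equal(tr$p, base$p)
})

test_that("zero rank variance is flagged as degenerate", {
  st <- spearman_test(rep(1, 5), rnorm(5), method = "t")
  expect_true(st$degenerate)
  expect_true(is.na(st$r_s))
})
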