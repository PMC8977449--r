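test_that("Hedges' g matches the closed form on frozen cases", {
  # hand evaluation: d = -1, J = 1 - 3/151, se^2 = 0.1 + g^2/80
  es <- smd(20, -3, 2, 20, -1, 2)
  J <- 1 - 3 / 151
  expect_equal(es$value, -J, tolerance = 1e-12)
  expect_equal(es$value, -0.9801325, tolerance = 1e-6)
  expect_equal(es$se, sqrt(0.1 + J^2 / 80), tolerance = 1e-12)
  expect_equal(es$se, 0.3346763, tolerance = 1e-6)
  # identical arms -> exactly 0
  expect_equal(smd(15, -2, 1.5, 15, -2, 1.5)$value, 0)
  # higher-is-better scale with treatment improving more stays negative
  eb <- smd(20, 3, 2, 20, 1, 2, direction = "higher-is-better")
  expect_lt(eb$value, 0)
})

test_that("smd antisymmetry, se invariance and large-n limit hold", {
  set.seed(11)
  for (i in 1:25) {
    n1 <- sample(5:80, 1); n2 <- sample(5:80, 1)
    m1 <- rnorm(1); m2 <- rnorm(1); s1 <- runif(1, 0.5, 3); s2 <- runif(1, 0.5, 3)
    a <- smd(n1, m1, s1, n2, m2, s2)
    b <- smd(n2, m2, s2, n1, m1, s1)
    expect_equal(a$value, -b$value, tolerance = 1e-12)
    expect_equal(a$se, b$se, tolerance = 1e-12)
  }
  # J -> 1: g approaches d at n = 10^4 within 1e-3
  big <- smd(10000, -1, 2, 10000, 1, 2)
  expect_lt(abs(big$value - (-1)), 1e-3)
})

test_that("smd rejects degenerate inputs", {
  expect_error(smd(20, 1, 0, 20, 1, 0),
               class = "painnma_error_degenerate_variance")
  expect_error(smd(1, 1, 1, 20, 0, 1), class = "painnma_error_small_arm")
})

test_that("Woolf log odds ratio matches frozen cases and the continuity rule", {
  lo <- log_or(10, 20, 5, 20)
  expect_equal(exp(lo$value), 3, tolerance = 1e-12)
  expect_equal(lo$value, log(3), tolerance = 1e-12)
  expect_equal(lo$se, sqrt(1 / 10 + 1 / 10 + 1 / 5 + 1 / 15), tolerance = 1e-12)
  expect_equal(lo$se, 0.6831301, tolerance = 1e-6)
  # equal proportions -> OR exactly 1
  expect_equal(log_or(6, 24, 6, 24)$value, 0)
  # zero cell: +0.5 on all four cells, finite se
  z <- log_or(0, 20, 5, 20)
  expect_true(is.finite(z$value) && is.finite(z$se))
  expect_equal(z$value, log((0.5 * 15.5) / (20.5 * 5.5)), tolerance = 1e-12)
  expect_error(log_or(25, 20, 5, 20), class = "painnma_error_bad_events")
})

test_that("log_or is antisymmetric with invariant se", {
  set.seed(12)
  for (i in 1:25) {
    n1 <- sample(10:60, 1); n2 <- sample(10:60, 1)
    e1 <- sample(0:n1, 1); e2 <- sample(0:n2, 1)
    a <- log_or(e1, n1, e2, n2)
    b <- log_or(e2, n2, e1, n1)
    expect_equal(a$value, -b$value, tolerance = 1e-12)
    expect_equal(a$se, b$se, tolerance = 1e-12)
  }
})

test_that("study contrasts anchor on placebo, else alphabetically", {
  arms <- data.frame(
    study_id = c("s1", "s1", "s2", "s2", "s3", "s3", "s3"),
    treatment = c("gab", "placebo", "ket", "gab", "ami", "gab", "placebo"),
    n = c(20L, 20L, 25L, 25L, 28L, 26L, 25L))
  oc <- data.frame(
    study_id = arms$study_id, treatment = arms$treatment,
    outcome_id = "pain4w", followup_weeks = 4, kind = "continuous",
    events = NA_real_, mean_change = c(-2, -1, -2.2, -1.8, -2, -1.9, -1),
    sd = 1, scale_name = "VAS-10", direction = "higher-is-worse")
  ds <- nma_network(arms, oc)
  es <- study_contrasts(ds, "pain4w")
  # two-arm placebo study: 1 contrast vs placebo
  expect_equal(es$anchor[es$study_id == "s1"], "placebo")
  expect_equal(sum(es$study_id == "s1"), 1)
  # head-to-head: alphabetical anchor
  expect_equal(es$anchor[es$study_id == "s2"], "gab")
  expect_equal(es$treat[es$study_id == "s2"], "ket")
  # three-arm: k - 1 = 2 contrasts vs placebo
  expect_equal(sum(es$study_id == "s3"), 2)
  expect_setequal(es$treat[es$study_id == "s3"], c("ami", "gab"))
  # outcome unavailable -> empty
  expect_equal(nrow(study_contrasts(ds, "pain8w")), 0)
})
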