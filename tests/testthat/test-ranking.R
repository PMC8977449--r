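test_that("rank probabilities are a doubly stochastic tally of draws", {
  ds <- two_trt_network(seed = 41, k = 5)
  fit <- nma_fit(ds, "pain4w", test_spec(seed = 3))
  rp <- rank_probabilities(fit)
  expect_equal(unname(rowSums(rp)), rep(1, 2), tolerance = 1e-12)
  expect_equal(unname(colSums(rp)), rep(1, 2), tolerance = 1e-12)
  # drug dominates in (almost) every draw at d = -0.6
  su <- sucra(rp)
  expect_gt(su$sucra[su$treatment == "drug01"], 0.95)
})

test_that("degenerate posterior gives the 'always first / always last' endpoints", {
  d <- cbind(placebo = rep(0, 200), drug = rep(-1, 200))
  rp <- rank_probabilities(d)
  expect_equal(rp["drug", "1"], 1)
  expect_equal(rp["placebo", "2"], 1)
  su <- sucra(rp)
  expect_equal(su$sucra[su$treatment == "drug"], 1)
  expect_equal(su$sucra[su$treatment == "placebo"], 0)
})

test_that("rank probabilities match the brute-force recount oracle", {
  set.seed(42)
  d <- cbind(a = rnorm(1000, -0.5, 0.3), b = rnorm(1000, -0.3, 0.3),
             c = rnorm(1000, 0, 0.3), placebo = 0)
  rp <- rank_probabilities(d)
  # oracle: explicitly argsort every draw and tally counts
  oracle <- matrix(0, 4, 4, dimnames = dimnames(rp))
  for (i in 1:1000) {
    ord <- order(d[i, ])
    for (r in 1:4) oracle[ord[r], r] <- oracle[ord[r], r] + 1
  }
  oracle <- oracle / 1000
  expect_equal(rp, oracle, tolerance = 1e-12)
})

test_that("SUCRA identities hold on arbitrary valid matrices", {
  set.seed(43)
  for (rep in 1:10) {
    Tn <- sample(3:8, 1)
    d <- matrix(rnorm(200 * Tn), 200, Tn,
                dimnames = list(NULL, paste0("t", seq_len(Tn))))
    rp <- rank_probabilities(d)
    su <- sucra(rp)
    expect_equal(sum(su$sucra), Tn / 2, tolerance = 1e-9)
    expect_equal(su$sucra, (Tn - su$mean_rank) / (Tn - 1), tolerance = 1e-9)
    # direction flip maps sucra -> 1 - sucra exactly
    su_flip <- sucra(rank_probabilities(d, lower_better = FALSE))
    expect_equal(su_flip$sucra, 1 - su$sucra, tolerance = 1e-9)
    # relabeling invariance
    perm <- sample(Tn)
    su_perm <- sucra(rank_probabilities(d[, perm]))
    expect_equal(su_perm$sucra[match(su$treatment, su_perm$treatment)],
                 su$sucra, tolerance = 1e-9)
  }
})

test_that("uniform rank probabilities give sucra 0.5 and mean rank (T+1)/2", {
  Tn <- 5
  rp <- matrix(1 / Tn, Tn, Tn, dimnames = list(paste0("t", 1:Tn), 1:Tn))
  su <- sucra(rp)
  expect_equal(su$sucra, rep(0.5, Tn))
  expect_equal(su$mean_rank, rep((Tn + 1) / 2, Tn))
})

test_that("exact ties split probability mass deterministically", {
  d <- cbind(a = rep(-1, 10), b = rep(-1, 10), c = rep(0, 10))
  rp <- rank_probabilities(d)
  expect_equal(rp["a", ], c(`1` = 0.5, `2` = 0.5, `3` = 0))
  expect_equal(rp["b", ], c(`1` = 0.5, `2` = 0.5, `3` = 0))
  expect_equal(rp["c", ], c(`1` = 0, `2` = 0, `3` = 1))
  expect_equal(unname(rowSums(rp)), rep(1, 3))
})

test_that("heat-map aggregation averages available outcomes and keeps NA", {
  mk <- function(outcome, treatments, sucras) {
    structure(list(outcome_id = outcome, direction = "lower-better",
                   rank_probs = NULL,
                   sucra = data.frame(treatment = treatments, sucra = sucras,
                                      mean_rank = 1)),
              class = "ranking_result")
  }
  r1 <- mk("pain4w", c("a", "b", "placebo"), c(0.9, 0.3, 0.3))
  r2 <- mk("adverse_events", c("a", "b", "placebo"), c(0.7, 0.5, 0.3))
  r3 <- mk("pain8w", c("b", "placebo"), c(0.8, 0.2))
  hm <- sucra_heatmap(list(r1, r2, r3))
  expect_equal(unname(hm$overall[["a"]]), 0.8)             # mean(0.9, 0.7)
  expect_true(is.na(hm$sucra["pain8w", "a"]))              # NA preserved
  expect_equal(unname(hm$overall[["b"]]), mean(c(0.3, 0.5, 0.8)))
  # single outcome: ordering equals that outcome's SUCRA ordering
  hm1 <- sucra_heatmap(list(r1))
  expect_equal(hm1$order, c("a", "b", "placebo"))
})
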