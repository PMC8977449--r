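test_that("bundled fixture loads with the published composition", {
  ds <- sci_pain_network()
  expect_s3_class(ds, "nma_network")
  expect_equal(length(unique(ds$arms$study_id)), 20)
  expect_equal(nrow(ds$treatments), 12)
  expect_equal(sum(ds$treatments$is_reference), 1)
  expect_equal(ds$reference, "placebo")
  s <- network_summary(ds)
  expect_equal(s$total_participants, 1198)
  expect_equal(s$intervention_participants + s$comparison_participants,
               s$total_participants)
  expect_equal(s$n_two_arm + s$n_three_arm, s$n_studies)
})

test_that("loading is order-invariant", {
  path <- system.file("extdata", "sci_np_trials.csv", package = "painnma")
  raw <- read.csv(path, stringsAsFactors = FALSE)
  shuffled <- raw[sample(nrow(raw)), ]
  tmp <- tempfile(fileext = ".csv")
  write.csv(shuffled, tmp, row.names = FALSE, na = "")
  expect_identical(load_network(tmp), load_network(path))
})

test_that("validation failures are distinct classed errors", {
  arms <- toy_arms()
  expect_error(nma_network(arms[, c("study_id", "treatment")]),
               class = "painnma_error_missing_column")
  expect_error(nma_network(rbind(arms, arms[1, ])),
               class = "painnma_error_duplicate_arm")
  bad_n <- arms; bad_n$n <- c("x", 1, 2, 3)
  expect_error(nma_network(bad_n), class = "painnma_error_bad_n")
  one_arm <- arms[c(1, 3, 4), ]
  expect_error(nma_network(one_arm), class = "painnma_error_single_arm")
  disc <- data.frame(study_id = c("s1", "s1", "s2", "s2"),
                     treatment = c("a", "b", "c", "d"), n = 10)
  expect_error(nma_network(disc, reference = "a"),
               class = "painnma_error_disconnected")
  ev <- toy_outcomes()
  ev$kind <- "dichotomous"; ev$events <- c(99, 1, 1, 1)
  ev$mean_change <- NA; ev$sd <- NA
  expect_error(nma_network(arms, ev), class = "painnma_error_bad_events")
})

test_that("minimal two-arm study forms a valid connected network", {
  ds <- nma_network(toy_arms()[1:2, ], reference = "placebo")
  expect_equal(nrow(ds$treatments), 2)
  expect_equal(length(unique(ds$arms$study_id)), 1)
})

test_that("time-point selection follows nearest-then-earlier and the window", {
  rec <- toy_outcomes(weeks = c(3, 3, 7, 7))
  picked <- select_timepoint(rec[rec$study_id == "s1", ])
  expect_equal(unique(picked$followup_weeks), 3)
  # records at 3 and 7 for one study
  two <- rbind(toy_outcomes(weeks = rep(3, 4))[1:2, ],
               toy_outcomes(weeks = rep(7, 4))[1:2, ])
  expect_equal(unique(select_timepoint(two)$followup_weeks), 3)
  # exact match is identity
  exact <- toy_outcomes(weeks = rep(4, 4))[1:2, ]
  expect_identical(select_timepoint(exact), exact)
  # tie 3 vs 5 -> earlier
  tie <- rbind(toy_outcomes(weeks = rep(3, 4))[1:2, ],
               toy_outcomes(weeks = rep(5, 4))[1:2, ])
  expect_equal(unique(select_timepoint(tie)$followup_weeks), 3)
  # outside window -> NULL, study excluded from outcome only
  far <- toy_outcomes(weeks = rep(24, 4))[1:2, ]
  expect_null(select_timepoint(far))
  # idempotent and never outside the window
  picked2 <- select_timepoint(picked)
  expect_identical(picked2, picked)
  expect_true(all(picked$followup_weeks >= 3 & picked$followup_weeks <= 17))
})

test_that("single-study summary uses the sd = 0 convention", {
  ds <- nma_network(data.frame(study_id = "s1",
                               treatment = c("a", "placebo"),
                               n = c(10L, 10L)))
  s <- network_summary(ds)
  expect_equal(s$total_participants, 20)
  expect_equal(s$mean_study_size, 20)
  expect_equal(s$sd_study_size, 0)
})

test_that("comparison graph counts edges and participants", {
  # single three-arm study -> 3 edges, one study each
  arms3 <- data.frame(study_id = "s1", treatment = c("a", "b", "placebo"),
                      n = c(10L, 11L, 12L))
  g3 <- comparison_graph(nma_network(arms3))
  expect_equal(nrow(g3), 3)
  expect_true(all(g3$n_studies == 1))
  # two identical A-vs-placebo studies -> one edge with count 2
  arms2 <- data.frame(study_id = c("s1", "s1", "s2", "s2"),
                      treatment = c("a", "placebo", "a", "placebo"),
                      n = 10L)
  g2 <- comparison_graph(nma_network(arms2))
  expect_equal(nrow(g2), 1)
  expect_equal(g2$n_studies, 2)
  # fixture: placebo carries the largest randomized total
  ds <- sci_pain_network()
  g <- comparison_graph(ds, "pain4w")
  nodes <- attr(g, "nodes")
  expect_equal(names(which.max(nodes)), "placebo")
  # unknown outcome -> empty graph flagged
  expect_warning(ge <- comparison_graph(ds, "no_such_outcome"),
                 "empty graph")
  expect_equal(nrow(ge), 0)
})
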