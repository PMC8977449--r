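test_that("star networks have no loop-informed comparisons", {
  sc <- nma_scenario(n_treatments = 4, geometry = "star",
                     trials_per_edge = 2, seed = 31)
  ds <- generate_network(sc)
  ns <- node_split(ds, "pain4w", c("drug01", "placebo"), test_spec())
  expect_false(ns$in_loop)
  expect_true(is.na(ns$p_value))
  expect_null(ns$if_value)
  tab <- node_split_all(ds, "pain4w", test_spec())
  expect_equal(nrow(tab), 0)
})

test_that("triangle node split returns direct, indirect, IF and p", {
  ds <- generate_network(triangle_scenario(seed = 32, tau = 0.1))
  ns <- node_split(ds, "pain4w", c("drug01", "placebo"), test_spec(seed = 7))
  expect_true(ns$in_loop)
  expect_true(ns$p_value >= 0 && ns$p_value <= 1)
  expect_lt(ns$if_value$ci95[1], ns$if_value$ci95[2])
  # consistent data at this seed: CrI covers 0 and p is unremarkable
  expect_true(ns$if_value$ci95[1] < 0 && ns$if_value$ci95[2] > 0)
  # all three edges are loop-informed
  tab <- node_split_all(ds, "pain4w", test_spec(seed = 7))
  expect_equal(nrow(tab), 3)
})

test_that("p is invariant to comparison relabeling up to MC error", {
  ds <- generate_network(triangle_scenario(seed = 33, tau = 0.1))
  sp <- test_spec(seed = 8, samples = 4000)
  ns1 <- node_split(ds, "pain4w", c("drug01", "placebo"), sp)
  ns2 <- node_split(ds, "pain4w", c("placebo", "drug01"), sp)
  expect_lt(abs(ns1$p_value - ns2$p_value), 0.1)
  expect_equal(ns1$if_value$median, -ns2$if_value$median, tolerance = 0.1)
})

test_that("single direct study: split direct posterior tracks that study", {
  # one A-P trial plus an indirect path through B
  trials <- list(c("placebo", "drug01"), c("placebo", "drug02"),
                 c("placebo", "drug02"), c("drug01", "drug02"),
                 c("drug01", "drug02"))
  sc <- nma_scenario(geometry = "custom", trials = trials,
                     arm_size = c(100, 140), d = c(drug01 = -0.6, drug02 = -0.3),
                     tau = 0, seed = 34)
  ds <- generate_network(sc)
  es <- study_contrasts(ds, "pain4w")
  direct_y <- es$value[es$study_id == "trial001"]
  sp <- test_spec(seed = 9, tau_prior = list(family = "fixed", value = 0.01))
  ns <- node_split(ds, "pain4w", c("drug01", "placebo"), sp)
  expect_lt(abs(ns$direct$median - direct_y), 0.1)
})

test_that("global consistency check: loopless delta is exactly 0, loops compared", {
  sc <- nma_scenario(n_treatments = 3, geometry = "star",
                     trials_per_edge = 2, seed = 35)
  ds <- generate_network(sc)
  g <- global_consistency(ds, "pain4w", test_spec(seed = 4))
  expect_true(g$loopless)
  expect_identical(g$delta, 0)
  expect_equal(g$label, "consistent")
  # determinism
  ds2 <- generate_network(triangle_scenario(seed = 36))
  g1 <- global_consistency(ds2, "pain4w", test_spec(seed = 5))
  g2 <- global_consistency(ds2, "pain4w", test_spec(seed = 5))
  expect_identical(g1$delta, g2$delta)
  expect_false(g1$loopless)
})

test_that("merged direct and indirect evidence approximates the full NMA", {
  ds <- generate_network(triangle_scenario(seed = 37, tau = 0.05,
                                           trials_per_edge = 5))
  sp <- test_spec(seed = 6, samples = 4000)
  full <- nma_fit(ds, "pain4w", sp)
  ns <- node_split(ds, "pain4w", c("drug01", "placebo"), sp)
  # precision-weighted merge of direct and indirect
  pw <- function(su) (diff(su$ci95) / (2 * 1.96))^-2
  wd <- pw(ns$direct); wi <- pw(ns$indirect)
  merged <- (wd * ns$direct$median + wi * ns$indirect$median) / (wd + wi)
  expect_lt(abs(merged - median(full$d[, "drug01"])), 0.1)
})
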