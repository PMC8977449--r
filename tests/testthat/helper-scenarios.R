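# shared fixtures: all synthetic, built in code at test time

# reduced sampler layout for fast tests; strict off because tau's R-hat is
# noisy at these lengths
test_spec <- function(seed = 1, burn_in = 1500, samples = 2500,
                      n_chains = 2, ...) {
  model_spec(profile = "test", seed = seed, burn_in = burn_in,
             samples = samples, n_chains = n_chains, strict = FALSE, ...)
}

# two-treatment network: k trials of drug01 vs placebo
two_trt_network <- function(seed = 1, k = 8, d = -0.6, tau = 0.2,
                            arm_size = c(40, 80)) {
  sc <- nma_scenario(n_treatments = 2, geometry = "star",
                     trials_per_edge = k, arm_size = arm_size,
                     d = c(drug01 = d), tau = tau, seed = seed)
  generate_network(sc)
}

triangle_scenario <- function(seed = 1, tau = 0.1, trials_per_edge = 4,
                              arm_size = c(80, 120), omega = 0,
                              kind = "continuous") {
  nma_scenario(n_treatments = 3, geometry = "triangle",
               trials_per_edge = trials_per_edge, arm_size = arm_size,
               d = c(drug01 = -0.5, drug02 = -0.2), tau = tau,
               omega = omega,
               omega_edge = if (omega != 0) c("drug01", "placebo") else NULL,
               kind = kind, seed = seed)
}

# minimal hand-built arm/outcome tables for loader tests
toy_arms <- function() {
  data.frame(
    study_id = c("s1", "s1", "s2", "s2"),
    treatment = c("a", "placebo", "b", "placebo"),
    n = c(10L, 12L, 20L, 18L),
    stringsAsFactors = FALSE
  )
}

toy_outcomes <- function(weeks = c(4, 4, 4, 4)) {
  data.frame(
    study_id = c("s1", "s1", "s2", "s2"),
    treatment = c("a", "placebo", "b", "placebo"),
    outcome_id = "pain4w", followup_weeks = weeks, kind = "continuous",
    events = NA_real_, mean_change = c(-2, -1, -1.5, -1), sd = 1,
    scale_name = "VAS-10", direction = "higher-is-worse",
    stringsAsFactors = FALSE
  )
}
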