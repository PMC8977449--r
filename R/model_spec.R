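#' Specification of the Bayesian NMA model and sampler
#'
#' Collects priors, chain layout and seed for [nma_fit()]. Defaults follow
#' the production profile: 3 chains, 50,000 burn-in iterations and 50,000
#' retained updates per chain (i.e. 100,000 total updates of which the
#' first 50,000 are discarded), vague Normal(0, 100^2) priors on basic
#' parameters and study baselines, and a Uniform(0, 5) prior on the
#' between-trial SD tau. The `"test"` profile is a scaled-down layout
#' (3 chains x 10,000 updates, 5,000 discarded) for test suites and
#' simulation studies.
#'
#' @param profile `"paper"` (production defaults) or `"test"`
#'   (reduced iterations).
#' @param kind likelihood: `NULL` (auto from the outcome data),
#'   `"normal"` (contrast-level SMDs) or `"binomial"` (arm-level events).
#' @param reference reference treatment id; `NULL` uses the dataset's.
#' @param prior_sd prior SD of effect parameters and study baselines.
#' @param tau_prior either `list(family = "uniform", lower, upper)` or
#'   `list(family = "fixed", value)`; `value = 0` collapses the model to
#'   fixed effect.
#' @param n_chains number of chains (>= 2).
#' @param burn_in discarded iterations per chain.
#' @param samples retained iterations per chain.
#' @param thin thinning interval.
#' @param seed integer seed; chain c runs under `seed + 7919 * c`.
#' @param rhat_threshold split-chain R-hat convergence threshold.
#' @param strict if `TRUE`, [nma_fit()] errors (rather than warns) when
#'   R-hat exceeds the threshold.
#' @return list of class `model_spec`.
#' @export
model_spec <- function(profile = c("paper", "test"), kind = NULL,
                       reference = NULL, prior_sd = 100,
                       tau_prior = list(family = "uniform", lower = 0,
                                        upper = 5),
                       n_chains = 3, burn_in = NULL, samples = NULL,
                       thin = 1, seed = 1, rhat_threshold = 1.05,
                       strict = NULL) {
  profile <- match.arg(profile)
  if (is.null(burn_in)) burn_in <- if (profile == "paper") 50000L else 5000L
  if (is.null(samples)) samples <- if (profile == "paper") 50000L else 5000L
  if (is.null(strict)) strict <- profile == "paper"
  if (n_chains < 2) pn_stop("need at least 2 chains", "painnma_error_bad_spec")
  if (burn_in <= 0 || samples <= 0) {
    pn_stop("burn_in and samples must be positive", "painnma_error_bad_spec")
  }
  if (!is.null(kind)) kind <- match.arg(kind, c("normal", "binomial"))
  fam <- tau_prior$family
  if (!fam %in% c("uniform", "fixed")) {
    pn_stop("tau_prior family must be 'uniform' or 'fixed'",
            "painnma_error_bad_spec")
  }
  structure(list(profile = profile, kind = kind, reference = reference,
                 prior_sd = prior_sd, tau_prior = tau_prior,
                 n_chains = as.integer(n_chains),
                 burn_in = as.integer(burn_in),
                 samples = as.integer(samples), thin = as.integer(thin),
                 seed = as.integer(seed),
                 rhat_threshold = rhat_threshold, strict = strict),
            class = "model_spec")
}

# split-chain potential scale reduction factor
split_rhat <- function(draws_by_chain) {
  halves <- list()
  for (x in draws_by_chain) {
    n <- length(x)
    h <- n %/% 2
    halves[[length(halves) + 1]] <- x[seq_len(h)]
    halves[[length(halves) + 1]] <- x[(h + 1):(2 * h)]
  }
  m <- length(halves)
  n <- length(halves[[1]])
  means <- vapply(halves, mean, 0)
  vars <- vapply(halves, var, 0)
  W <- mean(vars)
  B <- n * var(means)
  if (W < .Machine$double.eps) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

# batch-means Monte Carlo standard error of the combined-chain mean
batch_mcse <- function(draws_by_chain) {
  per_chain_var <- vapply(draws_by_chain, function(x) {
    n <- length(x)
    nb <- max(2, floor(sqrt(n)))
    bs <- n %/% nb
    bm <- vapply(seq_len(nb), function(i) mean(x[((i - 1) * bs + 1):(i * bs)]), 0)
    var(bm) * bs / n  # variance of the chain mean
  }, 0)
  sqrt(sum(per_chain_var)) / length(draws_by_chain)
}
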