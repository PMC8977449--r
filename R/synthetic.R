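#' Define a synthetic trial-network scenario
#'
#' A scenario states the ground truth of a simulated network: treatments,
#' geometry, trials per comparison, arm-size range, true basic parameters
#' `d` (reference fixed at 0), between-trial SD `tau`, outcome kind and
#' baseline, and an optional loop-inconsistency offset `omega` applied to
#' the direct evidence of one designated comparison.
#'
#' @param n_treatments total number of treatments including the reference.
#' @param geometry `"star"` (every drug vs reference),
#'   `"star-plus-edges"` (star plus `extra_edges` head-to-head
#'   comparisons between consecutive drugs), `"triangle"`
#'   (3 treatments, all pairs), `"complete"` (all pairs) or `"custom"`
#'   (supply `trials`).
#' @param trials_per_edge trials on each comparison.
#' @param extra_edges head-to-head comparisons added to a star.
#' @param arm_size inclusive integer range `(low, high)` participants per
#'   arm are drawn from.
#' @param d named numeric vector of true effects vs the reference for the
#'   non-reference treatments (default 0 for all).
#' @param tau between-trial SD (>= 0) of trial-specific effects.
#' @param kind `"continuous"` (change scores, summarized to mean/SD) or
#'   `"dichotomous"` (arm events).
#' @param baseline `list(mean=, sd=)` for continuous (control-arm change
#'   score distribution; default mean -0.5, sd 1) or `list(risk=)` for
#'   dichotomous (default 0.3).
#' @param omega additive inconsistency offset on the linear-predictor
#'   scale for the designated comparison's direct trials.
#' @param omega_edge character `c(a, b)`: `omega` inflates the effect of
#'   `a` relative to `b` in trials comparing exactly these two arms.
#' @param reference reference treatment id (default `"placebo"`).
#' @param trials custom geometry: list of character vectors, one per
#'   trial, each the trial's treatment set.
#' @param outcome_id outcome label for the generated records (defaults to
#'   `"pain4w"` / `"adverse_events"` by kind).
#' @param seed integer seed of the scenario's generator stream.
#' @return list of class `nma_scenario`.
#' @export
nma_scenario <- function(n_treatments = 3,
                         geometry = c("star", "star-plus-edges", "triangle",
                                      "complete", "custom"),
                         trials_per_edge = 1, extra_edges = 1,
                         arm_size = c(20, 60), d = NULL, tau = 0,
                         kind = c("continuous", "dichotomous"),
                         baseline = NULL, omega = 0, omega_edge = NULL,
                         reference = "placebo", trials = NULL,
                         outcome_id = NULL, seed = 1) {
  geometry <- match.arg(geometry)
  kind <- match.arg(kind)
  problems <- character(0)

  if (geometry == "custom") {
    if (is.null(trials)) problems <- c(problems, "custom geometry needs `trials`")
  } else {
    if (geometry == "triangle" && n_treatments != 3) {
      problems <- c(problems, "triangle geometry needs n_treatments = 3")
    }
    if (n_treatments < 2) problems <- c(problems, "need >= 2 treatments")
    drugs <- sprintf("drug%02d", seq_len(max(n_treatments - 1, 1)))
    edges <- switch(geometry,
      star = lapply(drugs, function(dr) c(reference, dr)),
      triangle = list(c(reference, drugs[1]), c(reference, drugs[2]),
                      c(drugs[1], drugs[2])),
      complete = {
        trts <- c(reference, drugs)
        pr <- utils::combn(trts, 2)
        lapply(seq_len(ncol(pr)), function(j) pr[, j])
      },
      `star-plus-edges` = {
        st <- lapply(drugs, function(dr) c(reference, dr))
        ne <- min(extra_edges, length(drugs) - 1)
        hh <- lapply(seq_len(ne), function(j) c(drugs[j], drugs[j + 1]))
        c(st, hh)
      })
    trials <- rep(edges, each = trials_per_edge)
  }
  treatments <- sort(unique(unlist(trials)))
  if (!reference %in% treatments) {
    problems <- c(problems, "reference treatment appears in no trial")
  }
  drugs <- setdiff(treatments, reference)
  if (is.null(d)) d <- setNames(rep(0, length(drugs)), drugs)
  if (is.null(names(d))) {
    if (length(d) != length(drugs)) {
      problems <- c(problems, "unnamed `d` must have one value per non-reference treatment")
    } else names(d) <- drugs
  }
  if (!all(drugs %in% names(d))) {
    problems <- c(problems, "`d` missing values for some treatments")
  }
  if (reference %in% names(d) && d[[reference]] != 0) {
    problems <- c(problems, "d[reference] must be 0")
  }
  if (tau < 0) problems <- c(problems, "tau must be >= 0")
  if (length(arm_size) != 2 || arm_size[1] < 2 || arm_size[2] < arm_size[1]) {
    problems <- c(problems, "arm_size must be an increasing range with low >= 2")
  }
  if (omega != 0) {
    if (is.null(omega_edge) || length(omega_edge) != 2) {
      problems <- c(problems, "omega != 0 needs omega_edge = c(a, b)")
    } else {
      on_edge <- vapply(trials, function(tr)
        length(tr) == 2 && setequal(tr, omega_edge), TRUE)
      if (!any(on_edge)) {
        problems <- c(problems, "omega_edge matches no two-arm trial in the geometry")
      }
    }
  }
  if (is.null(baseline)) {
    baseline <- if (kind == "continuous") list(mean = -0.5, sd = 1) else
      list(risk = 0.3)
  }
  if (kind == "continuous" && (is.null(baseline$sd) || baseline$sd <= 0)) {
    problems <- c(problems, "continuous baseline needs sd > 0")
  }
  if (kind == "dichotomous" &&
      (is.null(baseline$risk) || baseline$risk <= 0 || baseline$risk >= 1)) {
    problems <- c(problems, "dichotomous baseline needs risk in (0, 1)")
  }
  if (length(problems) > 0) {
    pn_stop(paste0("invalid scenario:\n  - ",
                   paste(problems, collapse = "\n  - ")),
            "painnma_error_bad_scenario")
  }
  if (is.null(outcome_id)) {
    outcome_id <- if (kind == "continuous") "pain4w" else "adverse_events"
  }
  structure(list(treatments = treatments, reference = reference,
                 trials = trials, arm_size = as.integer(arm_size),
                 d = d[drugs], tau = tau, kind = kind, baseline = baseline,
                 omega = omega, omega_edge = omega_edge,
                 outcome_id = outcome_id, seed = as.integer(seed)),
            class = "nma_scenario")
}

#' Generate a trial network from a scenario
#'
#' Draws a complete arm-level dataset: per trial, a trial-specific effect
#' vector theta is drawn around the consistency means `d[k] - d[b]` (plus
#' `omega` on the designated comparison) with SD `tau` and 0.5 pairwise
#' correlation for multi-arm trials. Continuous arms draw participant-
#' level change scores `Normal(baseline_mean + theta * baseline_sd,
#' baseline_sd^2)` summarized to mean/SD/n; dichotomous arms draw events
#' `Binomial(n, expit(logit(risk) + theta))`. The scenario seed makes the
#' dataset fully reproducible; the global RNG state is restored.
#'
#' @param sc an [nma_scenario()].
#' @param seed optional override of `sc$seed`.
#' @return an [nma_network()] with attribute `"truth"` holding `d`,
#'   `tau`, `omega`, `omega_edge`.
#' @export
generate_network <- function(sc, seed = NULL) {
  stopifnot(inherits(sc, "nma_scenario"))
  seed <- seed %||% sc$seed
  d_full <- c(setNames(0, sc$reference), sc$d)
  arms_rows <- list()
  out_rows <- list()
  withr::with_seed(seed, {
    for (i in seq_along(sc$trials)) {
      trt <- sort(sc$trials[[i]])
      sid <- sprintf("trial%03d", i)
      anchor <- study_anchor(trt, sc$reference)
      others <- setdiff(trt, anchor)
      m <- length(others)
      mu_th <- d_full[others] - d_full[[anchor]]
      if (sc$omega != 0 && length(trt) == 2 &&
          setequal(trt, sc$omega_edge)) {
        if (anchor == sc$omega_edge[2]) {
          mu_th[sc$omega_edge[1]] <- mu_th[sc$omega_edge[1]] + sc$omega
        } else {
          mu_th[sc$omega_edge[2]] <- mu_th[sc$omega_edge[2]] - sc$omega
        }
      }
      # 0.5-correlated multivariate random effect via a shared component
      z0 <- rnorm(1)
      theta <- mu_th + sc$tau / sqrt(2) * (z0 + rnorm(m))
      ns <- sc$arm_size[1] - 1L +
        sample.int(sc$arm_size[2] - sc$arm_size[1] + 1L, length(trt),
                   replace = TRUE)
      names(ns) <- trt
      for (tr in trt) {
        arms_rows[[length(arms_rows) + 1]] <- data.frame(
          study_id = sid, treatment = tr,
          role = if (tr == anchor) "C" else "I", n = ns[[tr]],
          stringsAsFactors = FALSE)
        lin <- if (tr == anchor) 0 else theta[[tr]]
        if (sc$kind == "continuous") {
          scores <- rnorm(ns[[tr]], sc$baseline$mean + lin * sc$baseline$sd,
                          sc$baseline$sd)
          out_rows[[length(out_rows) + 1]] <- data.frame(
            study_id = sid, treatment = tr, outcome_id = sc$outcome_id,
            followup_weeks = 4, kind = "continuous", events = NA_real_,
            mean_change = mean(scores), sd = sd(scores),
            scale_name = "synthetic", direction = "higher-is-worse",
            stringsAsFactors = FALSE)
        } else {
          pr <- stats::plogis(stats::qlogis(sc$baseline$risk) + lin)
          ev <- rbinom(1, ns[[tr]], pr)
          out_rows[[length(out_rows) + 1]] <- data.frame(
            study_id = sid, treatment = tr, outcome_id = sc$outcome_id,
            followup_weeks = 4, kind = "dichotomous", events = ev,
            mean_change = NA_real_, sd = NA_real_,
            scale_name = "synthetic", direction = "higher-is-worse",
            stringsAsFactors = FALSE)
        }
      }
    }
  })
  ds <- nma_network(do.call(rbind, arms_rows), do.call(rbind, out_rows),
                    reference = sc$reference)
  attr(ds, "truth") <- list(d = sc$d, tau = sc$tau, omega = sc$omega,
                            omega_edge = sc$omega_edge)
  ds
}

#' Scenario emulating the bundled 20-trial pain network
#'
#' A 12-treatment scenario with the bundled network's geometry: 14
#' placebo-anchored two-arm trials, 5 head-to-head two-arm trials and one
#' three-arm (two drugs + placebo) trial, 20 trials in all. Arm sizes are
#' drawn uniformly from 5-55 so the expected total is about 1,200
#' randomized participants. True effects default to values spanning 0 to
#' -1.2 across the 11 drugs with between-trial SD `tau`.
#'
#' @param tau between-trial SD (default 0.2).
#' @param d optional named effect vector (defaults to an even spread over
#'   0 to -1.2).
#' @param arm_size per-arm size range (default `c(5, 55)`).
#' @param kind outcome kind (default continuous).
#' @param seed scenario seed.
#' @return an [nma_scenario()].
#' @export
sci_like_scenario <- function(tau = 0.2, d = NULL, arm_size = c(5, 55),
                              kind = "continuous", seed = 1) {
  trials <- c(
    # 14 placebo-anchored two-arm trials
    rep(list(c("placebo", "cannabinoids")), 3),
    rep(list(c("placebo", "pregabalin")), 3),
    rep(list(c("placebo", "gabapentin")), 2),
    rep(list(c("placebo", "btxa")), 2),
    list(c("placebo", "duloxetine"), c("placebo", "carbamazepine"),
         c("placebo", "levetiracetam"), c("placebo", "tramadol")),
    # 5 head-to-head two-arm trials
    list(c("amitriptyline", "lamotrigine")),
    rep(list(c("ketamine", "gabapentin")), 2),
    rep(list(c("pregabalin", "gabapentin")), 2),
    # the single three-arm trial
    list(c("amitriptyline", "gabapentin", "placebo"))
  )
  drugs <- sort(setdiff(unique(unlist(trials)), "placebo"))
  if (is.null(d)) d <- setNames(seq(0, -1.2, length.out = length(drugs)), drugs)
  nma_scenario(geometry = "custom", trials = trials, arm_size = arm_size,
               d = d, tau = tau, kind = kind, seed = seed)
}
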