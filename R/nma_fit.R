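#' Fit the Bayesian random-effects network meta-analysis model
#'
#' Fits the arm-based consistency model: each arm k of study i has linear
#' predictor \eqn{\mu_i + \delta_{i,bk}} where the trial-specific effects
#' \eqn{\delta} of non-anchor arms follow a random-effects distribution
#' centered on \eqn{d_k - d_{b(i)}} with SD \eqn{\tau} shared across
#' comparisons; multi-arm trials use the multivariate random effect with
#' 0.5 pairwise correlation. Continuous outcomes enter as anchor-based
#' standardized mean differences with a normal likelihood (scales differ
#' across trials); dichotomous outcomes enter as raw arm events with a
#' binomial-logit likelihood. `n_chains` chains start from over-dispersed
#' initials; the burn-in is discarded and `samples` updates retained per
#' chain. Split-chain R-hat, Monte Carlo errors and the DIC are computed.
#'
#' @param ds an [nma_network()].
#' @param outcome_id outcome to analyse.
#' @param spec a [model_spec()].
#' @param model `"consistency"` (default) or `"ume"`, the
#'   unrelated-mean-effects inconsistency model with one mean parameter
#'   per observed design comparison.
#' @param split optional length-2 character vector `c(a, b)`: give the
#'   direct evidence on comparison a-vs-b its own parameter `d_direct`
#'   (node splitting; used by [node_split()]).
#' @param target_weeks,window time-point selection rule, see
#'   [select_timepoint()].
#' @return object of class `nma_fit`; see Details.
#' @details The returned object carries `d` (retained draws of the basic
#'   parameters, one column per treatment with the reference identically
#'   0), `theta` (raw effect-parameter draws), `tau`, `deviance`, `dic`
#'   (`Dbar`, `pD`, `DIC`), `rhat`, `mcse`, `treatments`, `measure`
#'   (`"SMD"` or `"logOR"`) and the dropped-treatment log. Treatments
#'   without data for the outcome are dropped from that outcome's network
#'   with a warning. A disconnected outcome network is an error; R-hat
#'   above the threshold errors under `spec$strict`, otherwise warns.
#' @export
nma_fit <- function(ds, outcome_id, spec = model_spec(),
                    model = c("consistency", "ume"), split = NULL,
                    target_weeks = 4, window = c(3, 17)) {
  model <- match.arg(model)
  stopifnot(inherits(ds, "nma_network"))
  prep <- build_blocks(ds, outcome_id, spec, model = model, split = split,
                       target_weeks = target_weeks, window = window)
  run_chains(prep, spec, ds, outcome_id, model, split)
}

# ---- data preparation -------------------------------------------------------

build_blocks <- function(ds, outcome_id, spec, model = "consistency",
                         split = NULL, target_weeks = 4, window = c(3, 17)) {
  oc <- ds$outcomes[ds$outcomes$outcome_id == outcome_id &
                      ds$outcomes$has_values, , drop = FALSE]
  if (nrow(oc) == 0) {
    pn_stop(sprintf("no outcome values for '%s'", outcome_id),
            "painnma_error_empty_outcome")
  }
  kind <- unique(oc$kind)
  if (length(kind) > 1) {
    pn_stop("mixed outcome kinds across studies for one outcome",
            "painnma_error_mixed_kind")
  }
  if (!is.null(spec$kind) &&
      spec$kind != c(continuous = "normal", dichotomous = "binomial")[[kind]]) {
    pn_stop("spec likelihood does not match the outcome kind",
            "painnma_error_bad_spec")
  }
  reference <- spec$reference %||% ds$reference
  arm_n <- setNames(ds$arms$n, paste(ds$arms$study_id, ds$arms$treatment,
                                     sep = "\r"))

  # per-study selected records
  recs <- list()
  for (sid in sort(unique(oc$study_id))) {
    rec <- select_timepoint(oc[oc$study_id == sid, , drop = FALSE],
                            target_weeks, window)
    if (!is.null(rec) && nrow(rec) >= 2) recs[[sid]] <- rec
  }
  if (length(recs) == 0) {
    pn_stop(sprintf("no study has usable records for '%s' in the window",
                    outcome_id), "painnma_error_empty_outcome")
  }
  present <- sort(unique(unlist(lapply(recs, function(r) r$treatment))))
  dropped <- setdiff(ds$treatments$id, present)
  if (length(dropped) > 0) {
    warning(sprintf("treatment(s) without data for outcome '%s' dropped: %s",
                    outcome_id, paste(dropped, collapse = ", ")),
            call. = FALSE)
  }
  if (!reference %in% present) {
    pn_stop(sprintf("reference '%s' has no data for outcome '%s'",
                    reference, outcome_id), "painnma_error_no_reference")
  }
  comp <- graph_components(present, lapply(recs, function(r) r$treatment))
  if (length(unique(comp)) > 1) {
    pn_stop(sprintf("outcome '%s' network is disconnected", outcome_id),
            "painnma_error_disconnected")
  }

  treatments <- c(reference, setdiff(present, reference))
  basic <- setdiff(treatments, reference)

  # effect-parameter layout
  if (model == "consistency") {
    param_names <- paste0("d[", basic, "]")
  } else {
    pairs <- character(0)
    for (sid in names(recs)) {
      anch <- study_anchor(recs[[sid]]$treatment, reference)
      others <- setdiff(recs[[sid]]$treatment, anch)
      pairs <- c(pairs, paste0("d[", anch, ":", others, "]"))
    }
    param_names <- sort(unique(pairs))
  }
  has_split <- !is.null(split)
  if (has_split) {
    if (model != "consistency") {
      pn_stop("node splitting applies to the consistency model",
              "painnma_error_bad_spec")
    }
    param_names <- c(param_names, "d_direct")
  }
  p <- length(param_names)
  pidx <- setNames(seq_len(p), param_names)

  xrow_consistency <- function(treat, anchor) {
    x <- numeric(p)
    if (treat != reference) x[pidx[[paste0("d[", treat, "]")]]] <- 1
    if (anchor != reference) x[pidx[[paste0("d[", anchor, "]")]]] <- -1
    x
  }

  blocks <- list()
  block_meta <- list()
  for (sid in names(recs)) {
    rec <- recs[[sid]]
    is_direct <- has_split && all(split %in% rec$treatment)
    anch <- if (is_direct) split[2] else study_anchor(rec$treatment, reference)
    others <- sort(setdiff(rec$treatment, anch))
    m <- length(others)
    X <- matrix(0, m, p)
    for (j in seq_len(m)) {
      if (is_direct && others[j] == split[1]) {
        X[j, pidx[["d_direct"]]] <- 1
      } else if (model == "consistency") {
        X[j, ] <- xrow_consistency(others[j], anch)
      } else {
        X[j, pidx[[paste0("d[", anch, ":", others[j], "]")]]] <- 1
      }
    }
    ra <- rec[rec$treatment == anch, ]
    na <- arm_n[[paste(sid, anch, sep = "\r")]]
    if (kind == "continuous") {
      val <- se <- numeric(m)
      for (j in seq_len(m)) {
        ri <- rec[rec$treatment == others[j], ]
        ni <- arm_n[[paste(sid, others[j], sep = "\r")]]
        es <- smd(ni, ri$mean_change, ri$sd, na, ra$mean_change, ra$sd,
                  direction = ri$direction)
        val[j] <- es$value
        se[j] <- es$se
      }
      S <- diag(se^2, nrow = m)
      if (m > 1) S[upper.tri(S) | lower.tri(S)] <- 1 / na
      blocks[[sid]] <- list(y = val, Sinv = solve(S), X = X)
      block_meta[[sid]] <- list(study = sid, arms = others, anchor = anch,
                                y = val, S = S)
    } else {
      r_vec <- n_vec <- numeric(m + 1)
      r_vec[1] <- rec$events[rec$treatment == anch]
      n_vec[1] <- na
      for (j in seq_len(m)) {
        r_vec[j + 1] <- rec$events[rec$treatment == others[j]]
        n_vec[j + 1] <- arm_n[[paste(sid, others[j], sep = "\r")]]
      }
      blocks[[sid]] <- list(r = r_vec, n = n_vec, X = X)
      block_meta[[sid]] <- list(study = sid, arms = others, anchor = anch,
                                r = r_vec, n = n_vec)
    }
  }

  list(mode = if (kind == "continuous") 0L else 1L,
       kind = kind,
       measure = if (kind == "continuous") "SMD" else "logOR",
       blocks = blocks, block_meta = block_meta,
       param_names = param_names, treatments = treatments,
       reference = reference, dropped = dropped)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- sampling and assembly --------------------------------------------------

run_chains <- function(prep, spec, ds, outcome_id, model, split) {
  p <- length(prep$param_names)
  tau_is_fixed <- spec$tau_prior$family == "fixed"
  dat <- list(mode = prep$mode, p = p, prior_sd = spec$prior_sd,
              tau_is_fixed = tau_is_fixed,
              tau_fixed = if (tau_is_fixed) spec$tau_prior$value else 0,
              tau_lower = spec$tau_prior$lower %||% 0,
              tau_upper = spec$tau_prior$upper %||% 5,
              blocks = unname(prep$blocks))

  n_chains <- spec$n_chains
  offsets <- seq(-1, 1, length.out = n_chains)
  tau_inits <- rep(c(0.2, 0.8, 0.4, 1.2, 0.1), length.out = n_chains)
  chains <- vector("list", n_chains)
  for (ch in seq_len(n_chains)) {
    mu0 <- vapply(dat$blocks, function(b) {
      if (prep$mode == 1L) log((b$r[1] + 0.5) / (b$n[1] - b$r[1] + 0.5)) else 0
    }, 0)
    ctl <- list(burn_in = spec$burn_in, samples = spec$samples,
                thin = spec$thin,
                theta_init = rep(offsets[ch] * 0.5, p),
                tau_init = min(max(tau_inits[ch], dat$tau_lower + 1e-3),
                               dat$tau_upper - 1e-3),
                mu_init = mu0 + offsets[ch] * 0.5)
    set.seed(spec$seed + 7919L * ch)
    chains[[ch]] <- .nma_chain_cpp(dat, ctl)
  }

  theta <- do.call(rbind, lapply(chains, `[[`, "theta"))
  colnames(theta) <- prep$param_names
  tau <- unlist(lapply(chains, `[[`, "tau"))
  deviance <- unlist(lapply(chains, `[[`, "deviance"))
  chain_id <- rep(seq_len(n_chains), each = spec$samples)

  # DIC at the overall posterior means of the fitted effects
  kept_tot <- sum(vapply(chains, `[[`, 0, "kept"))
  nb <- length(dat$blocks)
  delta_mean <- lapply(seq_len(nb), function(i) {
    Reduce(`+`, lapply(chains, function(cc) cc$delta_sum[[i]])) / kept_tot
  })
  mu_mean <- Reduce(`+`, lapply(chains, `[[`, "mu_mean")) / kept_tot
  dhat <- deviance_at(dat$blocks, prep$mode, delta_mean, mu_mean)
  dbar <- mean(deviance)
  pD <- dbar - dhat
  dic <- list(Dbar = dbar, pD = pD, DIC = dbar + pD)

  # diagnostics
  by_chain <- function(x) split(x, chain_id)
  rhat <- vapply(seq_len(p), function(j) split_rhat(by_chain(theta[, j])), 0)
  names(rhat) <- prep$param_names
  if (!tau_is_fixed) rhat <- c(rhat, tau = split_rhat(by_chain(tau)))
  mcse <- vapply(seq_len(p), function(j) batch_mcse(by_chain(theta[, j])), 0)
  names(mcse) <- prep$param_names

  bad <- rhat[is.finite(rhat)] > spec$rhat_threshold
  if (any(bad)) {
    msg <- sprintf("non-convergence: R-hat > %.3f for %s",
                   spec$rhat_threshold,
                   paste(names(rhat)[is.finite(rhat)][bad], collapse = ", "))
    if (isTRUE(spec$strict)) {
      cond <- structure(
        class = c("painnma_error_nonconvergence", "painnma_error",
                  "error", "condition"),
        list(message = msg, call = sys.call(-1), rhat = rhat))
      stop(cond)
    }
    warning(msg, call. = FALSE)
  }

  # basic-parameter draw matrix (reference column fixed at 0)
  d <- NULL
  if (model == "consistency") {
    d <- matrix(0, nrow(theta), length(prep$treatments),
                dimnames = list(NULL, prep$treatments))
    for (tr in setdiff(prep$treatments, prep$reference)) {
      d[, tr] <- theta[, paste0("d[", tr, "]")]
    }
  }

  structure(list(
    d = d, theta = theta, tau = tau, deviance = deviance,
    chain_id = chain_id, dic = dic, rhat = rhat, mcse = mcse,
    treatments = prep$treatments, reference = prep$reference,
    measure = prep$measure, kind = prep$kind, outcome_id = outcome_id,
    model = model, split = split, spec = spec, dropped = prep$dropped,
    block_meta = prep$block_meta, delta_mean = delta_mean
  ), class = "nma_fit")
}

# deviance at plugged-in posterior means (mirrors the C++ formulas)
deviance_at <- function(blocks, mode, delta_mean, mu_mean) {
  dev <- 0
  for (i in seq_along(blocks)) {
    b <- blocks[[i]]
    db <- delta_mean[[i]]
    if (mode == 0L) {
      r0 <- b$y - db
      dev <- dev + drop(t(r0) %*% b$Sinv %*% r0)
    } else {
      eta <- c(mu_mean[i], mu_mean[i] + db)
      pr <- pmin(pmax(stats::plogis(eta), 1e-12), 1 - 1e-12)
      r <- b$r
      n <- b$n
      term <- ifelse(r > 0, r * log(r / (n * pr)), 0) +
        ifelse(r < n, (n - r) * log((n - r) / (n - n * pr)), 0)
      dev <- dev + 2 * sum(term)
    }
  }
  dev
}

#' Deviance information criterion of a fit
#'
#' @param fit an [nma_fit()] object.
#' @return list with `Dbar` (posterior mean deviance), `pD` (effective
#'   number of parameters, `Dbar - D(posterior means)`) and
#'   `DIC = Dbar + pD`.
#' @export
dic <- function(fit) {
  stopifnot(inherits(fit, "nma_fit"))
  fit$dic
}

#' Posterior summary of one relative effect
#'
#' Draw-wise contrast `d[a] - d[b]` (effect of `a` relative to `b`).
#'
#' @param fit an [nma_fit()] (consistency model).
#' @param a,b treatment ids.
#' @return list: `median`, `mean`, `ci95`, `draws`.
#' @export
relative_effects <- function(fit, a, b) {
  stopifnot(inherits(fit, "nma_fit"), !is.null(fit$d))
  if (!all(c(a, b) %in% colnames(fit$d))) {
    pn_stop("treatment not in this outcome's network",
            "painnma_error_unknown_treatment")
  }
  dr <- fit$d[, a] - fit$d[, b]
  list(median = median(dr), mean = mean(dr),
       ci95 = unname(quantile(dr, c(0.025, 0.975))), draws = dr)
}

#' League table of all pairwise relative effects
#'
#' All ordered treatment pairs with posterior median and central 95%
#' credible interval of the column-defining treatment relative to the
#' row-defining treatment. Odds-ratio cells are exponentiated, so
#' `cell(a,b) = 1/cell(b,a)`; SMD cells obey `cell(a,b) = -cell(b,a)`.
#'
#' @param fit an [nma_fit()] consistency fit.
#' @param order optional character vector giving the display order (e.g.
#'   by SUCRA); defaults to the fit's treatment order.
#' @return data frame of class `league_table` with columns `row`, `col`,
#'   `median`, `ci_low`, `ci_high`, `significant` (CrI excludes the null).
#' @export
league_table <- function(fit, order = NULL) {
  stopifnot(inherits(fit, "nma_fit"), !is.null(fit$d))
  trts <- order %||% fit$treatments
  stopifnot(setequal(trts, fit$treatments))
  cells <- list()
  null_val <- if (fit$measure == "logOR") 1 else 0
  for (rw in trts) for (cl in trts) {
    if (rw == cl) next
    dr <- fit$d[, cl] - fit$d[, rw]
    if (fit$measure == "logOR") dr <- exp(dr)
    qs <- quantile(dr, c(0.025, 0.5, 0.975))
    cells[[length(cells) + 1]] <- data.frame(
      row = rw, col = cl, median = unname(qs[2]),
      ci_low = unname(qs[1]), ci_high = unname(qs[3]),
      significant = qs[1] > null_val | qs[3] < null_val,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, cells)
  attr(out, "order") <- trts
  attr(out, "measure") <- fit$measure
  class(out) <- c("league_table", class(out))
  out
}

#' @export
print.league_table <- function(x, digits = 2, ...) {
  trts <- attr(x, "order")
  m <- matrix("", length(trts), length(trts), dimnames = list(trts, trts))
  diag(m) <- trts
  for (i in seq_len(nrow(x))) {
    m[x$row[i], x$col[i]] <- sprintf(
      paste0("%.", digits, "f (%.", digits, "f, %.", digits, "f)%s"),
      x$median[i], x$ci_low[i], x$ci_high[i],
      if (x$significant[i]) "*" else "")
  }
  cat(sprintf("League table (%s, column vs row; * = 95%% CrI excludes null)\n",
              attr(x, "measure")))
  print(m, quote = FALSE)
  invisible(x)
}

#' @export
print.nma_fit <- function(x, ...) {
  cat(sprintf("<nma_fit> outcome '%s' (%s, %s model), %d treatments\n",
              x$outcome_id, x$measure, x$model, length(x$treatments)))
  cat(sprintf("  %d chains x %d retained draws; max R-hat %.3f; DIC %.1f (pD %.1f)\n",
              x$spec$n_chains, x$spec$samples,
              max(x$rhat[is.finite(x$rhat)]), x$dic$DIC, x$dic$pD))
  invisible(x)
}

#' @export
summary.nma_fit <- function(object, ...) {
  trts <- setdiff(object$treatments, object$reference)
  tab <- do.call(rbind, lapply(trts, function(tr) {
    dr <- object$d[, tr]
    data.frame(treatment = tr, median = median(dr), mean = mean(dr),
               sd = sd(dr),
               ci_low = unname(quantile(dr, 0.025)),
               ci_high = unname(quantile(dr, 0.975)),
               rhat = unname(object$rhat[paste0("d[", tr, "]")]),
               mcse = unname(object$mcse[paste0("d[", tr, "]")]),
               stringsAsFactors = FALSE)
  }))
  tau_sum <- c(median = median(object$tau),
               ci_low = unname(quantile(object$tau, 0.025)),
               ci_high = unname(quantile(object$tau, 0.975)))
  out <- list(effects = tab, tau = tau_sum, dic = object$dic,
              reference = object$reference, measure = object$measure)
  class(out) <- "summary.nma_fit"
  out
}

#' @export
print.summary.nma_fit <- function(x, ...) {
  cat(sprintf("Basic parameters (%s vs %s):\n", x$measure, x$reference))
  print(x$effects, row.names = FALSE, digits = 3)
  cat(sprintf("tau: %.3f (95%% CrI %.3f to %.3f)\n",
              x$tau[["median"]], x$tau[["ci_low"]], x$tau[["ci_high"]]))
  cat(sprintf("DIC %.1f (Dbar %.1f, pD %.1f)\n",
              x$dic$DIC, x$dic$Dbar, x$dic$pD))
  invisible(x)
}
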