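#' DerSimonian-Laird random-effects pooling
#'
#' Closed-form random-effects meta-analysis of one comparison:
#' \eqn{\tau^2 = \max(0, (Q - df)/C)} with \eqn{C = \sum w - \sum w^2/\sum w},
#' \eqn{w = 1/se^2}; the pooled value uses \eqn{w^* = 1/(se^2+\tau^2)}, and
#' the 95% CI is normal-based. Serves both as the "pairwise" column of a
#' forest table and as a deterministic oracle for the Bayesian engine.
#'
#' @param value,se numeric vectors of study effects (same comparison,
#'   same orientation, same measure) and standard errors.
#' @return list of class `pooled_effect`: `k`, `value`, `se`, `ci95`,
#'   `tau2`, `q`, `df`, `i2`.
#' @export
dl_pool <- function(value, se) {
  if (length(value) != length(se) || length(value) < 1) {
    pn_stop("need k >= 1 effects with matching standard errors",
            "painnma_error_bad_input")
  }
  if (any(se <= 0)) pn_stop("non-positive standard error", "painnma_error_bad_se")
  k <- length(value)
  w <- 1 / se^2
  ybar <- sum(w * value) / sum(w)
  q <- sum(w * (value - ybar)^2)
  df <- k - 1
  tau2 <- 0
  if (k > 1) {
    cc <- sum(w) - sum(w^2) / sum(w)
    tau2 <- max(0, (q - df) / cc)
  }
  ws <- 1 / (se^2 + tau2)
  pooled <- sum(ws * value) / sum(ws)
  pse <- sqrt(1 / sum(ws))
  i2 <- if (k > 1 && q > 0) max(0, (q - df) / q) * 100 else 0
  structure(list(k = k, value = pooled, se = pse,
                 ci95 = c(pooled - qnorm(0.975) * pse,
                          pooled + qnorm(0.975) * pse),
                 tau2 = tau2, q = q, df = df, i2 = i2),
            class = "pooled_effect")
}

#' @export
print.pooled_effect <- function(x, ...) {
  cat(sprintf("pooled effect %.3f (95%% CI %.3f to %.3f), k = %d, tau2 = %.4f, I2 = %.1f%%\n",
              x$value, x$ci95[1], x$ci95[2], x$k, x$tau2, x$i2))
  invisible(x)
}

#' Pairwise forest table for one outcome
#'
#' DerSimonian-Laird pooled effect per observed comparison (anchor-based
#' contrasts grouped by treatment pair).
#'
#' @param ds an [nma_network()].
#' @param outcome_id outcome id.
#' @param ... passed to [study_contrasts()].
#' @return data frame: `treat`, `anchor`, `measure`, `k`, `value`, `se`,
#'   `ci_low`, `ci_high`, `tau2`, `i2`.
#' @export
pairwise_forest <- function(ds, outcome_id, ...) {
  es <- study_contrasts(ds, outcome_id, ...)
  if (nrow(es) == 0) {
    return(data.frame(treat = character(), anchor = character(),
                      measure = character(), k = integer(),
                      value = numeric(), se = numeric(),
                      ci_low = numeric(), ci_high = numeric(),
                      tau2 = numeric(), i2 = numeric(),
                      stringsAsFactors = FALSE))
  }
  key <- paste(es$treat, es$anchor, sep = "\r")
  out <- lapply(unique(key), function(kk) {
    sub <- es[key == kk, ]
    p <- dl_pool(sub$value, sub$se)
    data.frame(treat = sub$treat[1], anchor = sub$anchor[1],
               measure = sub$measure[1], k = p$k, value = p$value,
               se = p$se, ci_low = p$ci95[1], ci_high = p$ci95[2],
               tau2 = p$tau2, i2 = p$i2, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Comparison-adjusted funnel points
#'
#' Each study effect centered on its own comparison's DerSimonian-Laird
#' pooled value, paired with its standard error, for small-study /
#' publication-bias inspection. Comparisons informed by a single study
#' self-center to 0 and are flagged as uninformative.
#'
#' @param ds an [nma_network()].
#' @param outcome_id outcome id.
#' @param ... passed to [study_contrasts()].
#' @return data frame: `study_id`, `comparison`, `centered_effect`, `se`,
#'   `informative` (FALSE for single-study comparisons).
#' @export
funnel_points <- function(ds, outcome_id, ...) {
  es <- study_contrasts(ds, outcome_id, ...)
  if (nrow(es) == 0) {
    return(data.frame(study_id = character(), comparison = character(),
                      centered_effect = numeric(), se = numeric(),
                      informative = logical(), stringsAsFactors = FALSE))
  }
  comparison <- paste(es$treat, "vs", es$anchor)
  centered <- numeric(nrow(es))
  informative <- logical(nrow(es))
  for (cmp in unique(comparison)) {
    idx <- comparison == cmp
    p <- dl_pool(es$value[idx], es$se[idx])
    centered[idx] <- es$value[idx] - p$value
    informative[idx] <- sum(idx) > 1
  }
  data.frame(study_id = es$study_id, comparison = comparison,
             centered_effect = centered, se = es$se,
             informative = informative, stringsAsFactors = FALSE)
}

#' Egger-style funnel asymmetry regression
#'
#' Ordinary least-squares regression of the comparison-centered effects on
#' their standard errors. Under symmetry (no small-study effects) the slope
#' is 0; the 95% CI is reported descriptively, mirroring the usual
#' "publication bias under control" reading of a net funnel.
#'
#' @param points output of [funnel_points()].
#' @return list: `slope`, `ci95`, `n` (informative points used);
#'   `NA` values when fewer than 3 informative points exist.
#' @export
funnel_regression <- function(points) {
  pts <- points[points$informative, , drop = FALSE]
  if (nrow(pts) < 3) {
    return(list(slope = NA_real_, ci95 = c(NA_real_, NA_real_),
                n = nrow(pts)))
  }
  fit <- lm(centered_effect ~ se, data = pts)
  ci <- suppressMessages(confint(fit))["se", ]
  list(slope = unname(coef(fit)[["se"]]), ci95 = unname(ci), n = nrow(pts))
}
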