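#' Standardized mean difference (Hedges' g) between two arms
#'
#' Computes the bias-corrected standardized mean difference of change
#' scores between a treatment and a comparison arm:
#' \deqn{g = J \cdot (\bar{\Delta}_t - \bar{\Delta}_c)/s_p,\quad
#'       J = 1 - \frac{3}{4(n_t+n_c-2)-1}}
#' with pooled SD \eqn{s_p} and sampling variance
#' \eqn{se^2 = 1/n_t + 1/n_c + g^2 / (2(n_t+n_c))}.
#'
#' Orientation is normalized so that a negative SMD always means greater
#' symptom relief in the treatment arm: on a `"higher-is-better"` scale the
#' raw difference is negated.
#'
#' @param n_t,mean_t,sd_t treatment arm size, mean change, SD of change.
#' @param n_c,mean_c,sd_c comparison arm.
#' @param direction `"higher-is-worse"` (default; pain intensity scales)
#'   or `"higher-is-better"`.
#' @return list with `measure = "SMD"`, `value`, `se`, `oriented`.
#' @export
smd <- function(n_t, mean_t, sd_t, n_c, mean_c, sd_c,
                direction = c("higher-is-worse", "higher-is-better")) {
  direction <- match.arg(direction)
  if (n_t < 2 || n_c < 2) {
    pn_stop("SMD needs n >= 2 in both arms", "painnma_error_small_arm")
  }
  if (sd_t < 0 || sd_c < 0) pn_stop("negative SD", "painnma_error_bad_sd")
  df <- n_t + n_c - 2
  s_pooled <- sqrt(((n_t - 1) * sd_t^2 + (n_c - 1) * sd_c^2) / df)
  if (s_pooled <= 0) {
    pn_stop("zero pooled SD: cannot standardize", "painnma_error_degenerate_variance")
  }
  d <- (mean_t - mean_c) / s_pooled
  if (direction == "higher-is-better") d <- -d
  J <- 1 - 3 / (4 * df - 1)
  g <- J * d
  se <- sqrt(1 / n_t + 1 / n_c + g^2 / (2 * (n_t + n_c)))
  list(measure = "SMD", value = g, se = se, oriented = TRUE)
}

#' Log odds ratio between two arms
#'
#' Woolf log odds ratio of events (treatment vs comparison) with
#' \eqn{se = \sqrt{\sum 1/\mathrm{cell}}}. If any of the four 2x2 cells is
#' zero, 0.5 is added to all four cells of that study's table (Haldane
#' continuity correction) before computing. A log-OR below 0 means fewer
#' events under treatment.
#'
#' @param events_t,n_t treatment arm events and size.
#' @param events_c,n_c comparison arm.
#' @return list with `measure = "logOR"`, `value`, `se`, `oriented`.
#' @export
log_or <- function(events_t, n_t, events_c, n_c) {
  if (n_t <= 0 || n_c <= 0) pn_stop("empty arm", "painnma_error_small_arm")
  if (events_t < 0 || events_t > n_t || events_c < 0 || events_c > n_c) {
    pn_stop("events outside [0, n]", "painnma_error_bad_events")
  }
  a <- events_t; b <- n_t - events_t
  c_ <- events_c; d <- n_c - events_c
  if (min(a, b, c_, d) == 0) {
    a <- a + 0.5; b <- b + 0.5; c_ <- c_ + 0.5; d <- d + 0.5
  }
  list(measure = "logOR",
       value = log(a * d / (b * c_)),
       se = sqrt(1 / a + 1 / b + 1 / c_ + 1 / d),
       oriented = TRUE)
}

# anchor arm of one study for one outcome: reference if present, else the
# alphabetically first treatment
study_anchor <- function(treatments, reference) {
  if (reference %in% treatments) reference else sort(treatments)[1]
}

#' Contrast-level effect estimates for a network outcome
#'
#' Converts arm-level outcome values into anchor-based contrasts, one row
#' per non-anchor arm: Hedges' g for continuous outcomes, Woolf log-OR for
#' dichotomous ones. The anchor is the study's placebo arm when present,
#' otherwise the alphabetically first treatment. The time-point rule
#' ([select_timepoint()]) picks one record per study; studies without a
#' usable record are skipped.
#'
#' @param ds an [nma_network()].
#' @param outcome_id outcome to extract.
#' @param target_weeks,window passed to [select_timepoint()].
#' @return data frame: `study_id`, `treat`, `anchor`, `measure`, `value`,
#'   `se`, `n_anchor` (for multi-arm covariance), `kind`.
#' @export
study_contrasts <- function(ds, outcome_id, target_weeks = 4,
                            window = c(3, 17)) {
  stopifnot(inherits(ds, "nma_network"))
  oc <- ds$outcomes[ds$outcomes$outcome_id == outcome_id &
                      ds$outcomes$has_values, , drop = FALSE]
  if (nrow(oc) == 0) {
    return(data.frame(study_id = character(), treat = character(),
                      anchor = character(), measure = character(),
                      value = numeric(), se = numeric(),
                      n_anchor = integer(), kind = character(),
                      stringsAsFactors = FALSE))
  }
  arm_n <- setNames(ds$arms$n, paste(ds$arms$study_id, ds$arms$treatment,
                                     sep = "\r"))
  rows <- list()
  for (sid in sort(unique(oc$study_id))) {
    rec <- select_timepoint(oc[oc$study_id == sid, , drop = FALSE],
                            target_weeks, window)
    if (is.null(rec) || nrow(rec) < 2) next
    anchor <- study_anchor(rec$treatment, ds$reference)
    ra <- rec[rec$treatment == anchor, ]
    na <- arm_n[[paste(sid, anchor, sep = "\r")]]
    for (i in which(rec$treatment != anchor)) {
      ri <- rec[i, ]
      ni <- arm_n[[paste(sid, ri$treatment, sep = "\r")]]
      if (ri$kind == "continuous") {
        es <- smd(ni, ri$mean_change, ri$sd, na, ra$mean_change, ra$sd,
                  direction = ri$direction)
      } else {
        es <- log_or(ri$events, ni, ra$events, na)
      }
      rows[[length(rows) + 1]] <- data.frame(
        study_id = sid, treat = ri$treatment, anchor = anchor,
        measure = es$measure, value = es$value, se = es$se,
        n_anchor = na, kind = ri$kind, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(study_id = character(), treat = character(),
               anchor = character(), measure = character(),
               value = numeric(), se = numeric(), n_anchor = integer(),
               kind = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
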