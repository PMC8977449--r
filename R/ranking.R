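#' Rank-probability matrix of a fitted network
#'
#' For every retained draw the treatments are ranked by their oriented
#' basic parameter (rank 1 = best). Ties within a draw share averaged
#' ranks, each tied treatment splitting its probability mass uniformly
#' over the tied positions. Probabilities are frequencies over draws, so
#' every row and every column sums to 1.
#'
#' @param fit an [nma_fit()] consistency fit, or a draws matrix with one
#'   column per treatment.
#' @param lower_better `TRUE` (default) when a lower effect is better
#'   (SMD for pain relief, log-OR for adverse events).
#' @return T x T matrix; `rank_probs[t, r] = P(treatment t has rank r)`.
#' @export
rank_probabilities <- function(fit, lower_better = TRUE) {
  d <- if (inherits(fit, "nma_fit")) fit$d else as.matrix(fit)
  if (is.null(d)) pn_stop("fit has no basic-parameter draws",
                          "painnma_error_bad_input")
  or <- if (lower_better) d else -d
  Tn <- ncol(or)
  ranks <- t(apply(or, 1, rank, ties.method = "average"))
  rp <- matrix(0, Tn, Tn, dimnames = list(colnames(d), seq_len(Tn)))
  whole <- ranks == round(ranks)
  tied_draws <- which(!apply(whole, 1, all))
  clean <- setdiff(seq_len(nrow(or)), tied_draws)
  for (t in seq_len(Tn)) {
    rp[t, ] <- tabulate(ranks[clean, t], nbins = Tn)
  }
  for (i in tied_draws) {
    r <- ranks[i, ]
    for (t in seq_len(Tn)) {
      g <- which(abs(or[i, ] - or[i, t]) < .Machine$double.eps)
      lo <- min(r[g]) - (length(g) - 1) / 2
      pos <- seq(lo, lo + length(g) - 1)
      rp[t, pos] <- rp[t, pos] + 1 / length(g)
    }
  }
  rp / nrow(or)
}

#' SUCRA and mean ranks from a rank-probability matrix
#'
#' The surface under the cumulative ranking curve,
#' \eqn{SUCRA_t = \sum_{r=1}^{T-1} F_t(r) / (T-1)} with \eqn{F_t} the
#' cumulative rank distribution, equals \eqn{(T - \bar{r}_t)/(T-1)}.
#' SUCRA 1 means a treatment is certainly best, 0 certainly worst;
#' the values always sum to T/2.
#'
#' @param rank_probs matrix from [rank_probabilities()].
#' @return data frame: `treatment`, `sucra`, `mean_rank`.
#' @export
sucra <- function(rank_probs) {
  Tn <- ncol(rank_probs)
  cum <- t(apply(rank_probs, 1, cumsum))
  s <- rowSums(cum[, seq_len(Tn - 1), drop = FALSE]) / (Tn - 1)
  mr <- as.vector(rank_probs %*% seq_len(Tn))
  data.frame(treatment = rownames(rank_probs), sucra = unname(s),
             mean_rank = mr, stringsAsFactors = FALSE)
}

#' Ranking result for one outcome
#'
#' Convenience wrapper bundling rank probabilities, SUCRA and mean ranks
#' with the outcome id and the orientation used.
#'
#' @param fit an [nma_fit()].
#' @param lower_better orientation, see [rank_probabilities()].
#' @return list of class `ranking_result`: `outcome_id`, `direction`,
#'   `rank_probs`, `sucra` (data frame).
#' @export
ranking_result <- function(fit, lower_better = TRUE) {
  rp <- rank_probabilities(fit, lower_better)
  structure(list(outcome_id = fit$outcome_id,
                 direction = if (lower_better) "lower-better" else "higher-better",
                 rank_probs = rp, sucra = sucra(rp)),
            class = "ranking_result")
}

#' @export
print.ranking_result <- function(x, ...) {
  cat(sprintf("Ranking for outcome '%s' (%s):\n", x$outcome_id, x$direction))
  tab <- x$sucra[order(-x$sucra$sucra), ]
  print(tab, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Multi-outcome SUCRA heat-map matrix
#'
#' Assembles per-outcome SUCRA values into an outcomes x treatments grid.
#' Treatments absent from an outcome's network stay `NA` (never imputed);
#' the overall ordering is the unweighted mean of each treatment's
#' available SUCRA values.
#'
#' @param results list of [ranking_result()] objects (one per outcome).
#' @return list of class `sucra_heatmap`: `sucra` (matrix with `NA`
#'   markers), `mean_rank` (same shape), `overall` (named vector sorted
#'   decreasing), `order` (treatments by overall mean SUCRA).
#' @export
sucra_heatmap <- function(results) {
  stopifnot(length(results) >= 1)
  treatments <- sort(unique(unlist(lapply(results, function(r)
    r$sucra$treatment))))
  outcomes <- vapply(results, function(r) r$outcome_id, "")
  s <- mr <- matrix(NA_real_, length(outcomes), length(treatments),
                    dimnames = list(outcomes, treatments))
  for (i in seq_along(results)) {
    su <- results[[i]]$sucra
    s[i, su$treatment] <- su$sucra
    mr[i, su$treatment] <- su$mean_rank
  }
  overall <- colMeans(s, na.rm = TRUE)
  ord <- names(sort(overall, decreasing = TRUE))
  structure(list(sucra = s, mean_rank = mr,
                 overall = overall[ord], order = ord),
            class = "sucra_heatmap")
}

#' @export
print.sucra_heatmap <- function(x, digits = 2, ...) {
  cat("Mean SUCRA by outcome (NA = treatment not in that outcome's network):\n")
  print(round(x$sucra[, x$order, drop = FALSE], digits))
  cat("Overall order (mean SUCRA over available outcomes):\n")
  print(round(x$overall, digits))
  invisible(x)
}
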