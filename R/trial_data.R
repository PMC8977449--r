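#' Arm-level trial network data model
#'
#' An `nma_network` bundles the arm table (one row per randomized arm),
#' the outcome-measurement table (one row per arm x outcome x time point)
#' and the treatment list of a connected trial network. Placebo (or another
#' declared treatment) acts as the network reference.
#'
#' @param arms data frame with at least `study_id`, `treatment`, `n`
#'   (randomized participants per arm). Optional columns: `role`
#'   (`"I"`/`"C"` intervention vs comparison, used for participant splits),
#'   `country`, `risk_of_bias`.
#' @param outcomes data frame of outcome measurements with columns
#'   `study_id`, `treatment`, `outcome_id`, `followup_weeks`, `kind`
#'   (`"continuous"` or `"dichotomous"`) and, when values are available,
#'   `events` (dichotomous) or `mean_change` + `sd` (continuous), plus
#'   optional `scale_name` and `direction` (`"higher-is-worse"`, the
#'   default for pain scales, or `"higher-is-better"`). May be `NULL`.
#' @param reference treatment id of the network reference (default
#'   `"placebo"`); must occur in `arms` unless the network has no placebo,
#'   in which case pass one of the treatments explicitly.
#' @return An object of class `nma_network` with elements `arms`,
#'   `outcomes`, `treatments` (data frame `id`, `name`, `is_reference`)
#'   and `reference`.
#' @details Validation enforces: unique (study, treatment) pairs, >= 2
#'   distinct arms per study, positive integer `n`, dichotomous
#'   `events <= n`, and a connected comparison graph. Rows may arrive in
#'   any order; the stored tables are sorted so loading is
#'   order-invariant.
#' @export
nma_network <- function(arms, outcomes = NULL, reference = "placebo") {
  if (!is.data.frame(arms)) pn_stop("`arms` must be a data frame", "painnma_error_type")
  need <- c("study_id", "treatment", "n")
  miss <- setdiff(need, names(arms))
  if (length(miss) > 0) {
    pn_stop(paste0("missing required column(s): ", paste(miss, collapse = ", ")),
            "painnma_error_missing_column")
  }
  arms$study_id <- as.character(arms$study_id)
  arms$treatment <- as.character(arms$treatment)
  n_num <- suppressWarnings(as.numeric(arms$n))
  if (anyNA(n_num)) {
    pn_stop("non-numeric or missing arm size `n`", "painnma_error_bad_n")
  }
  if (any(n_num <= 0) || any(n_num != round(n_num))) {
    pn_stop("arm sizes `n` must be positive integers", "painnma_error_bad_n")
  }
  arms$n <- as.integer(round(n_num))
  key <- paste(arms$study_id, arms$treatment, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- unique(key[duplicated(key)])
    pn_stop(paste0("duplicate (study, treatment) pair: ",
                   gsub("\r", " / ", dup[1])),
            "painnma_error_duplicate_arm")
  }
  narms <- table(arms$study_id)
  if (any(narms < 2)) {
    pn_stop(paste0("study with < 2 arms: ",
                   paste(names(narms)[narms < 2], collapse = ", ")),
            "painnma_error_single_arm")
  }
  if (!"role" %in% names(arms)) {
    arms$role <- ifelse(arms$treatment == reference, "C", "I")
  }
  if (!"country" %in% names(arms)) arms$country <- NA_character_
  if (!"risk_of_bias" %in% names(arms)) arms$risk_of_bias <- NA_character_

  treatments <- sort(unique(arms$treatment))
  if (!reference %in% treatments) {
    pn_stop(paste0("reference treatment '", reference, "' not present in any arm"),
            "painnma_error_no_reference")
  }

  # connectivity of the comparison graph
  comp <- graph_components(treatments, split(arms$treatment, arms$study_id))
  if (length(unique(comp)) > 1) {
    pn_stop("treatment comparison graph is disconnected",
            "painnma_error_disconnected")
  }

  if (!is.null(outcomes) && nrow(outcomes) > 0) {
    outcomes <- validate_outcomes(outcomes, arms)
  } else {
    outcomes <- empty_outcomes()
  }

  ord <- order(arms$study_id, arms$treatment)
  arms <- arms[ord, c("study_id", "treatment", "role", "n", "country",
                      "risk_of_bias")]
  rownames(arms) <- NULL

  ds <- structure(list(
    arms = arms,
    outcomes = outcomes,
    treatments = data.frame(
      id = treatments,
      name = treatments,
      is_reference = treatments == reference,
      stringsAsFactors = FALSE
    ),
    reference = reference
  ), class = "nma_network")
  ds
}

empty_outcomes <- function() {
  data.frame(study_id = character(), treatment = character(),
             outcome_id = character(), followup_weeks = numeric(),
             kind = character(), events = integer(),
             mean_change = numeric(), sd = numeric(),
             scale_name = character(), direction = character(),
             has_values = logical(), stringsAsFactors = FALSE)
}

validate_outcomes <- function(outcomes, arms) {
  need <- c("study_id", "treatment", "outcome_id", "followup_weeks", "kind")
  miss <- setdiff(need, names(outcomes))
  if (length(miss) > 0) {
    pn_stop(paste0("outcomes table missing column(s): ",
                   paste(miss, collapse = ", ")),
            "painnma_error_missing_column")
  }
  for (col in c("events", "mean_change", "sd")) {
    if (!col %in% names(outcomes)) outcomes[[col]] <- NA_real_
    outcomes[[col]] <- suppressWarnings(as.numeric(outcomes[[col]]))
  }
  if (!"scale_name" %in% names(outcomes)) outcomes$scale_name <- NA_character_
  if (!"direction" %in% names(outcomes)) outcomes$direction <- "higher-is-worse"
  outcomes$direction[is.na(outcomes$direction) | outcomes$direction == ""] <-
    "higher-is-worse"
  outcomes$study_id <- as.character(outcomes$study_id)
  outcomes$treatment <- as.character(outcomes$treatment)
  outcomes$followup_weeks <- as.numeric(outcomes$followup_weeks)

  akey <- paste(arms$study_id, arms$treatment, sep = "\r")
  okey <- paste(outcomes$study_id, outcomes$treatment, sep = "\r")
  if (!all(okey %in% akey)) {
    pn_stop("outcome row refers to an unknown (study, treatment) arm",
            "painnma_error_orphan_outcome")
  }
  bad_kind <- !outcomes$kind %in% c("continuous", "dichotomous")
  if (any(bad_kind)) {
    pn_stop("outcome `kind` must be 'continuous' or 'dichotomous'",
            "painnma_error_bad_kind")
  }
  # one outcome kind per (study, outcome_id)
  kinds <- unique(outcomes[, c("study_id", "outcome_id", "kind")])
  kk <- paste(kinds$study_id, kinds$outcome_id)
  if (anyDuplicated(kk)) {
    pn_stop("mixed outcome kinds within one study/outcome",
            "painnma_error_mixed_kind")
  }
  arm_n <- setNames(arms$n, akey)
  is_dich <- outcomes$kind == "dichotomous"
  ev <- outcomes$events[is_dich]
  nn <- arm_n[okey[is_dich]]
  if (any(!is.na(ev) & (ev < 0 | ev > nn))) {
    pn_stop("dichotomous events outside [0, n]", "painnma_error_bad_events")
  }
  has_cont <- !is.na(outcomes$mean_change) & !is.na(outcomes$sd)
  if (any(has_cont & outcomes$sd <= 0)) {
    pn_stop("continuous outcome with sd <= 0", "painnma_error_bad_sd")
  }
  outcomes$has_values <- ifelse(is_dich, !is.na(outcomes$events), has_cont)
  ord <- order(outcomes$study_id, outcomes$outcome_id,
               outcomes$followup_weeks, outcomes$treatment)
  outcomes <- outcomes[ord, c("study_id", "treatment", "outcome_id",
                              "followup_weeks", "kind", "events",
                              "mean_change", "sd", "scale_name", "direction",
                              "has_values")]
  rownames(outcomes) <- NULL
  outcomes
}

# connected-component labels for treatments given per-study arm sets
graph_components <- function(treatments, study_arm_sets) {
  comp <- seq_along(treatments)
  names(comp) <- treatments
  for (arms_i in study_arm_sets) {
    ids <- unique(arms_i)
    root <- min(comp[ids])
    comp[comp %in% comp[ids]] <- root
  }
  # iterate to fixed point (small graphs; a second pass suffices rarely, so loop)
  repeat {
    changed <- FALSE
    for (arms_i in study_arm_sets) {
      ids <- unique(arms_i)
      root <- min(comp[ids])
      if (any(comp[ids] != root)) {
        comp[comp %in% comp[ids]] <- root
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  comp
}

#' Read an arm-level trial table from a delimited file
#'
#' Expects a UTF-8 CSV with a header; one row per study arm (and per
#' outcome time point when a study reports several). Recognized columns:
#' `study_id`, `treatment`, `n`, `outcome_id`, `followup_weeks`, `kind`,
#' `events`, `mean_change`, `sd`, `scale_name`, `direction`, `role`,
#' `country`, `risk_of_bias`. Missing numeric cells must be empty, not 0.
#' Rows repeating an arm for additional outcomes/time points must repeat
#' the same `n`.
#'
#' @param path file path.
#' @param reference reference treatment id (default `"placebo"`).
#' @param schema optional named character vector mapping canonical column
#'   names to the file's column names, e.g. `c(study_id = "trial")`.
#' @return An [nma_network()].
#' @export
load_network <- function(path, reference = "placebo", schema = NULL) {
  if (!file.exists(path)) {
    pn_stop(paste0("file not found: ", path), "painnma_error_missing_file")
  }
  raw <- read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  if (!is.null(schema)) {
    for (canon in names(schema)) {
      if (schema[[canon]] %in% names(raw)) {
        names(raw)[names(raw) == schema[[canon]]] <- canon
      }
    }
  }
  need <- c("study_id", "treatment", "n")
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0) {
    pn_stop(paste0("missing required column(s): ", paste(miss, collapse = ", ")),
            "painnma_error_missing_column")
  }
  raw$study_id <- as.character(raw$study_id)
  raw$treatment <- as.character(raw$treatment)
  arm_cols <- intersect(c("study_id", "treatment", "n", "role", "country",
                          "risk_of_bias"), names(raw))
  arms <- unique(raw[, arm_cols, drop = FALSE])
  key <- paste(arms$study_id, arms$treatment, sep = "\r")
  if (anyDuplicated(key)) {
    pn_stop("conflicting metadata rows for one (study, treatment) arm",
            "painnma_error_duplicate_arm")
  }
  outcomes <- NULL
  if ("outcome_id" %in% names(raw) && any(!is.na(raw$outcome_id))) {
    outcomes <- raw[!is.na(raw$outcome_id),
                    intersect(c("study_id", "treatment", "outcome_id",
                                "followup_weeks", "kind", "events",
                                "mean_change", "sd", "scale_name",
                                "direction"), names(raw)),
                    drop = FALSE]
  }
  nma_network(arms, outcomes, reference = reference)
}

#' Bundled 20-trial neuropathic-pain network
#'
#' Arm-level transcription of the 20 randomized controlled trials
#' (11 drugs + placebo, 1,198 randomized participants) that form the
#' post-spinal-cord-injury neuropathic-pain evidence network shipped with
#' the package. Per-arm outcome values are not public; the fixture carries
#' composition (arms, sizes, follow-up, scales, risk of bias) only, so it
#' supports network summaries and geometry but not effect estimation.
#'
#' @return An [nma_network()] with 20 studies and 12 treatment nodes.
#' @export
sci_pain_network <- function() {
  path <- system.file("extdata", "sci_np_trials.csv", package = "painnma")
  load_network(path)
}

#' @export
print.nma_network <- function(x, ...) {
  cat(sprintf("<nma_network> %d studies, %d treatments (reference: %s)\n",
              length(unique(x$arms$study_id)), nrow(x$treatments),
              x$reference))
  cat(sprintf("  %d randomized participants; %d outcome rows (%d with values)\n",
              sum(x$arms$n), nrow(x$outcomes), sum(x$outcomes$has_values)))
  invisible(x)
}

#' Pick the outcome record closest to a target follow-up time
#'
#' Applies the time-point selection rule: among records inside the window,
#' choose the one minimizing the absolute distance to `target_weeks`; ties
#' break toward the earlier time point. Returns `NULL` when nothing falls
#' inside the window (the study is then unavailable for that outcome, but
#' stays in the dataset).
#'
#' @param records data frame of outcome rows for one study/outcome (as in
#'   `nma_network$outcomes`), possibly spanning several `followup_weeks`.
#' @param target_weeks target follow-up (default 4).
#' @param window numeric length-2 inclusive window in weeks (default
#'   `c(3, 17)`).
#' @return The subset of `records` at the selected time point, or `NULL`.
#' @export
select_timepoint <- function(records, target_weeks = 4, window = c(3, 17)) {
  if (is.null(records) || nrow(records) == 0) return(NULL)
  wk <- unique(records$followup_weeks)
  wk <- wk[wk >= window[1] & wk <= window[2]]
  if (length(wk) == 0) return(NULL)
  dist <- abs(wk - target_weeks)
  best <- wk[dist == min(dist)]
  best <- min(best)  # tie-break: earlier time point
  records[records$followup_weeks == best, , drop = FALSE]
}

#' Network composition summary
#'
#' Counts and participant totals of the trial network: total, intervention
#' and comparison participants (from the per-arm `role` labels), mean and
#' sample SD of study sizes, two-/three-arm counts, and placebo-controlled
#' vs head-to-head counts among two-arm trials.
#'
#' @param ds an [nma_network()].
#' @return A list of class `nma_summary`.
#' @export
network_summary <- function(ds) {
  stopifnot(inherits(ds, "nma_network"))
  arms <- ds$arms
  sizes <- tapply(arms$n, arms$study_id, sum)
  arm_counts <- tapply(arms$treatment, arms$study_id, length)
  two_arm <- names(arm_counts)[arm_counts == 2]
  has_ref <- tapply(arms$treatment == ds$reference, arms$study_id, any)
  n_studies <- length(sizes)
  out <- list(
    n_studies = n_studies,
    n_treatments = sum(!ds$treatments$is_reference),
    total_participants = sum(arms$n),
    intervention_participants = sum(arms$n[arms$role == "I"]),
    comparison_participants = sum(arms$n[arms$role == "C"]),
    mean_study_size = mean(sizes),
    mean_study_size_rounded = round(mean(sizes)),
    sd_study_size = if (n_studies > 1) sd(sizes) else 0,
    sd_study_size_rounded = if (n_studies > 1) round(sd(sizes)) else 0,
    n_two_arm = sum(arm_counts == 2),
    n_three_arm = sum(arm_counts == 3),
    n_placebo_controlled = sum(has_ref[two_arm]),
    n_head_to_head = sum(!has_ref[two_arm])
  )
  class(out) <- "nma_summary"
  out
}

#' @export
print.nma_summary <- function(x, ...) {
  cat(sprintf("%d studies, %d active treatments\n", x$n_studies, x$n_treatments))
  cat(sprintf("participants: %d total (%d intervention / %d comparison)\n",
              x$total_participants, x$intervention_participants,
              x$comparison_participants))
  cat(sprintf("study size: mean %.1f (rounded %d), SD %.1f (rounded %d)\n",
              x$mean_study_size, x$mean_study_size_rounded,
              x$sd_study_size, x$sd_study_size_rounded))
  cat(sprintf("%d two-arm (%d placebo-controlled, %d head-to-head), %d three-arm\n",
              x$n_two_arm, x$n_placebo_controlled, x$n_head_to_head,
              x$n_three_arm))
  invisible(x)
}

#' Comparison graph for one outcome
#'
#' Undirected edge list of the treatment network restricted to studies
#' reporting `outcome_id` (or all studies when `outcome_id` is `NULL`).
#' A three-arm study contributes all three pairwise edges. Node totals sum
#' randomized participants over the contributing studies.
#'
#' @param ds an [nma_network()].
#' @param outcome_id outcome id or `NULL`.
#' @return data frame with `treat_a`, `treat_b` (a < b), `n_studies`;
#'   attribute `"nodes"` holds per-treatment randomized totals. Zero rows
#'   (with a warning) if no study reports the outcome.
#' @export
comparison_graph <- function(ds, outcome_id = NULL) {
  stopifnot(inherits(ds, "nma_network"))
  arms <- ds$arms
  if (!is.null(outcome_id)) {
    keep <- unique(ds$outcomes$study_id[ds$outcomes$outcome_id == outcome_id])
    if (length(keep) == 0) {
      warning(sprintf("no study reports outcome '%s'; empty graph", outcome_id),
              call. = FALSE)
    }
    arms <- arms[arms$study_id %in% keep, , drop = FALSE]
  }
  edges <- list()
  for (sid in unique(arms$study_id)) {
    tr <- sort(arms$treatment[arms$study_id == sid])
    if (length(tr) < 2) next
    pr <- utils::combn(tr, 2)
    edges[[sid]] <- data.frame(treat_a = pr[1, ], treat_b = pr[2, ],
                               stringsAsFactors = FALSE)
  }
  if (length(edges) == 0) {
    out <- data.frame(treat_a = character(), treat_b = character(),
                      n_studies = integer(), stringsAsFactors = FALSE)
  } else {
    all_e <- do.call(rbind, edges)
    key <- paste(all_e$treat_a, all_e$treat_b, sep = "\r")
    tab <- table(key)
    parts <- strsplit(names(tab), "\r", fixed = TRUE)
    out <- data.frame(
      treat_a = vapply(parts, `[`, "", 1),
      treat_b = vapply(parts, `[`, "", 2),
      n_studies = as.integer(tab),
      stringsAsFactors = FALSE
    )
    out <- out[order(out$treat_a, out$treat_b), ]
    rownames(out) <- NULL
  }
  attr(out, "nodes") <- tapply(arms$n, arms$treatment, sum)
  out
}

# internal: arm sets per study, optionally restricted to an outcome with values
study_arm_sets <- function(ds, outcome_id = NULL, values_only = FALSE) {
  if (is.null(outcome_id)) return(split(ds$arms$treatment, ds$arms$study_id))
  oc <- ds$outcomes[ds$outcomes$outcome_id == outcome_id, , drop = FALSE]
  if (values_only) oc <- oc[oc$has_values, , drop = FALSE]
  split(oc$treatment, oc$study_id)
}
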