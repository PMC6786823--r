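#' Score retrieval outcomes as successes
#'
#' In `"accuracy"` mode a trial is a success iff it was answered correctly.
#' In `"confidence"` mode a trial is a success iff it was answered correctly
#' *and* rated with high confidence (>= `confidence_high`); incorrect or
#' low-confidence trials, and trials without a recorded confidence, count as
#' failures.
#'
#' @param outcomes data.frame with logical `correct` and (for confidence
#'   mode) integer `confidence`.
#' @param mode `"accuracy"` or `"confidence"`.
#' @param confidence_high threshold for a high-confidence rating (2, 3 or 4).
#' @return logical vector of per-trial successes.
#' @export
score_outcomes <- function(outcomes, mode = c("accuracy", "confidence"),
                           confidence_high = 3L) {
  mode <- match.arg(mode)
  if (!"correct" %in% names(outcomes))
    stop_ld("outcomes must contain a `correct` column")
  if (mode == "accuracy") return(as.logical(outcomes$correct))
  if (!confidence_high %in% 2:4)
    stop_ld("`confidence_high` must be 2, 3 or 4")
  if (!"confidence" %in% names(outcomes))
    stop_ld("confidence mode requires a `confidence` column")
  conf <- outcomes$confidence
  as.logical(outcomes$correct) & !is.na(conf) & conf >= confidence_high
}

#' Construct a contingency table of paired retrieval outcomes
#'
#' Each row of the table is one event's pair of successes/failures on two
#' retrieval trials that share an element in the anchoring role (cue-based
#' tables: same cue, different targets; target-based tables: same target,
#' different cues).
#'
#' @param outcome1,outcome2 logical vectors of per-event outcomes on the two
#'   trial types.
#' @param event_id optional event labels.
#' @param category anchoring element category.
#' @param role `"cue"` or `"target"`.
#' @param loop_type `"closed"` or `"open"`.
#' @param participant_id optional participant label.
#' @return object of class `loopdep_contingency` with counts `n11`, `n10`,
#'   `n01`, `n00` and `N`.
#' @export
contingency_table <- function(outcome1, outcome2,
                              event_id = seq_along(outcome1),
                              category = NA_character_,
                              role = NA_character_,
                              loop_type = NA_character_,
                              participant_id = NA_character_) {
  stopifnot(length(outcome1) == length(outcome2))
  o1 <- as.logical(outcome1); o2 <- as.logical(outcome2)
  structure(list(
    pairs = data.frame(event_id = event_id, o1 = o1, o2 = o2,
                       stringsAsFactors = FALSE),
    n11 = sum(o1 & o2), n10 = sum(o1 & !o2),
    n01 = sum(!o1 & o2), n00 = sum(!o1 & !o2),
    N = length(o1), category = category, role = role,
    loop_type = loop_type, participant_id = participant_id),
    class = "loopdep_contingency")
}

#' @export
print.loopdep_contingency <- function(x, ...) {
  cat(sprintf(
    "<loopdep_contingency> %s/%s (%s-loop): n11=%d n10=%d n01=%d n00=%d N=%d\n",
    x$category, x$role, x$loop_type, x$n11, x$n10, x$n01, x$n00, x$N))
  invisible(x)
}

#' Build a participant's contingency tables for one loop condition
#'
#' For every element that anchors two retrieval trials of the same event in
#' the same role (cue or target), the two trials (chronological order) form
#' one paired outcome. Pairs are collected into tables keyed by the anchoring
#' element's category and role. For closed-loop events categories are merged
#' (object/animal collapsed), yielding the six canonical tables (3 categories
#' x cue/target). For open-loop events only middle elements of the chain
#' qualify, and tables are keyed by fine category so that no event
#' contributes more than one pair to a table (an open-loop event contains
#' both an object and an animal element, which would collide after merging).
#'
#' @param scored data.frame of trials for one participant with columns
#'   `event_id`, `loop_type`, `cue_id`, `target_id`, `cue_category`,
#'   `target_category`, `block` and logical `success` (see
#'   [score_outcomes()]); for open loops also `cue_fine_category`,
#'   `target_fine_category`.
#' @param loop_type which loop condition to build tables for.
#' @param participant_id optional label.
#' @return list of `loopdep_contingency` objects.
#' @export
build_tables <- function(scored, loop_type = c("closed", "open"),
                         participant_id = NA_character_) {
  loop_type <- match.arg(loop_type)
  if (!"success" %in% names(scored))
    stop_ld("`scored` must carry a logical `success` column")
  dat <- scored[scored$loop_type == loop_type, , drop = FALSE]
  if (!nrow(dat)) return(list())
  fine <- loop_type == "open"
  tables <- list()
  for (role in c("cue", "target")) {
    elem <- dat[[paste0(role, "_id")]]
    catcol <- if (fine) paste0(role, "_fine_category")
              else paste0(role, "_category")
    if (!catcol %in% names(dat))
      stop_ld("`scored` lacks required column `%s`", catcol)
    grp <- paste(dat$event_id, elem, sep = "\r")
    idx <- split(seq_len(nrow(dat)), grp)
    idx <- idx[lengths(idx) >= 2L]
    if (!length(idx)) next
    first <- integer(length(idx)); second <- integer(length(idx))
    for (k in seq_along(idx)) {
      ii <- idx[[k]][order(dat$block[idx[[k]]])]
      first[k] <- ii[1L]; second[k] <- ii[2L]
    }
    cat_key <- dat[[catcol]][first]
    for (cc in unique(cat_key)) {
      sel <- cat_key == cc
      tables[[length(tables) + 1L]] <- contingency_table(
        dat$success[first[sel]], dat$success[second[sel]],
        event_id = dat$event_id[first[sel]],
        category = cc, role = role, loop_type = loop_type,
        participant_id = participant_id)
    }
  }
  if (!length(tables))
    warning(sprintf("no contingency tables could be built for %s-loop data",
                    loop_type))
  tables
}

#' Observed retrieval dependency
#'
#' The proportion of events for which both trials of the pair were retrieved
#' successfully or both unsuccessfully: `(n11 + n00) / N`.
#'
#' @param table a `loopdep_contingency`.
#' @return proportion in \[0, 1\].
#' @export
observed_dependency <- function(table) {
  stopifnot(inherits(table, "loopdep_contingency"))
  if (table$N == 0L)
    stop_ld("observed dependency undefined for an empty table")
  (table$n11 + table$n00) / table$N
}

table_marginals <- function(table) {
  c(P1 = mean(table$pairs$o1), P2 = mean(table$pairs$o2))
}

#' Independent-model expected dependency
#'
#' Expected proportion of events with concordant outcomes if the two trial
#' types are retrieved independently at the participant's marginal success
#' rates within the table: `P1 P2 + (1 - P1)(1 - P2)`.
#'
#' @param table a `loopdep_contingency`.
#' @param marginals optional numeric `c(P1, P2)`; defaults to the table's
#'   column means.
#' @return expected proportion in \[0, 1\].
#' @export
independent_model <- function(table, marginals = NULL) {
  stopifnot(inherits(table, "loopdep_contingency"))
  m <- marginals %||% table_marginals(table)
  p1 <- m[[1]]; p2 <- m[[2]]
  p1 * p2 + (1 - p1) * (1 - p2)
}

#' Dependent-model expected dependency with guessing correction
#'
#' The dependent model starts from the independent model but weights each
#' event by an episodic factor capturing that event's performance relative
#' to overall performance, after correcting both for the 4AFC guessing
#' floor `g`:
#' \deqn{m_i = \max(0, (A_i - g)/(1 - g)), \quad
#'       \bar m = \max(0, (\bar A - g)/(1 - g)), \quad
#'       E_i = m_i / \bar m}
#' (with \eqn{E_i = 1} when \eqn{\bar m = 0}), and predicts per-trial-type
#' success \eqn{p_{t,i} = g + (1-g)\min\{1, E_i \max(0, (P_t-g)/(1-g))\}}.
#' The expected dependency is the mean over the table's events of
#' \eqn{p_{1,i} p_{2,i} + (1-p_{1,i})(1-p_{2,i})}.
#'
#' When every episodic factor equals 1 and the marginals are at or above
#' chance, the dependent model reduces exactly to the independent model.
#'
#' @param table a `loopdep_contingency`.
#' @param event_accuracy named numeric vector of per-event accuracy `A_i`
#'   covering at least the table's events; its grand mean over all supplied
#'   events of the loop condition defines \eqn{\bar A}.
#' @param marginals optional `c(P1, P2)`, defaulting to the table's means.
#' @param g guessing rate (chance level), default 0.25.
#' @return expected proportion in \[0, 1\].
#' @export
dependent_model <- function(table, event_accuracy, marginals = NULL,
                            g = 0.25) {
  stopifnot(inherits(table, "loopdep_contingency"))
  if (!length(event_accuracy)) stop_ld("`event_accuracy` is empty")
  ev <- table$pairs$event_id
  if (!all(as.character(ev) %in% names(event_accuracy)))
    stop_ld("`event_accuracy` must cover every event in the table")
  A <- event_accuracy[as.character(ev)]
  A_bar <- mean(event_accuracy)
  m_i <- pmax(0, (A - g) / (1 - g))
  m_bar <- max(0, (A_bar - g) / (1 - g))
  E_i <- if (m_bar == 0) rep(1, length(m_i)) else m_i / m_bar
  m <- marginals %||% table_marginals(table)
  strength <- pmax(0, (m - g) / (1 - g))  # length 2
  p1 <- g + (1 - g) * pmin(1, E_i * strength[[1]])
  p2 <- g + (1 - g) * pmin(1, E_i * strength[[2]])
  mean(p1 * p2 + (1 - p1) * (1 - p2))
}

#' Per-event accuracy under the active scoring mode
#'
#' @param scored one participant's trials with `success`, `event_id`,
#'   `loop_type`.
#' @param loop_type loop condition.
#' @return named numeric vector of per-event success proportions.
#' @export
event_accuracy <- function(scored, loop_type) {
  dat <- scored[scored$loop_type == loop_type, , drop = FALSE]
  vapply(split(dat$success, dat$event_id), mean, numeric(1))
}

#' Summarize retrieval dependency per participant and loop condition
#'
#' Builds all contingency tables for each participant x loop condition and
#' averages the observed, independent-model and dependent-model dependency
#' across tables. The evidence for dependency is `D_obs - D_ind`.
#'
#' @param outcomes trial outcomes (multiple participants allowed) with
#'   `participant_id`, `correct`, `confidence` and schedule columns.
#' @param mode scoring mode, see [score_outcomes()].
#' @param confidence_high high-confidence threshold.
#' @param g guessing rate.
#' @param episodic_factor_source `"all_trials"` (per-event accuracy from all
#'   six retrieval trials of the event) or `"exclude_table_trials"` (for each
#'   table, recompute per-event accuracy leaving out that table's two
#'   trials).
#' @return data.frame with one row per participant x loop: `D_obs`, `D_ind`,
#'   `D_dep`, `evidence`, `n_tables`, `accuracy`.
#' @export
summarize_dependency <- function(outcomes, mode = "accuracy",
                                 confidence_high = 3L, g = 0.25,
                                 episodic_factor_source =
                                   c("all_trials", "exclude_table_trials")) {
  episodic_factor_source <- match.arg(episodic_factor_source)
  outcomes$success <- score_outcomes(outcomes, mode, confidence_high)
  res <- list()
  for (pid in unique(outcomes$participant_id)) {
    sub <- outcomes[outcomes$participant_id == pid, , drop = FALSE]
    for (loop in intersect(c("closed", "open"), unique(sub$loop_type))) {
      tabs <- build_tables(sub, loop, participant_id = pid)
      if (!length(tabs)) next
      acc <- event_accuracy(sub, loop)
      d_obs <- vapply(tabs, observed_dependency, numeric(1))
      d_ind <- vapply(tabs, independent_model, numeric(1))
      d_dep <- vapply(tabs, function(tb) {
        a <- acc
        if (episodic_factor_source == "exclude_table_trials") {
          sub_l <- sub[sub$loop_type == loop, , drop = FALSE]
          drop2 <- table_trial_index(sub_l, tb)
          a <- event_accuracy(sub_l[-drop2, , drop = FALSE], loop)
          miss <- setdiff(as.character(tb$pairs$event_id), names(a))
          if (length(miss)) a[miss] <- g  # event fully consumed by the table
        }
        dependent_model(tb, a, g = g)
      }, numeric(1))
      res[[length(res) + 1L]] <- data.frame(
        participant_id = pid, loop_type = loop,
        n_tables = length(tabs),
        D_obs = mean(d_obs), D_ind = mean(d_ind), D_dep = mean(d_dep),
        evidence = mean(d_obs) - mean(d_ind),
        accuracy = mean(sub$correct[sub$loop_type == loop]),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, res)
}

# row indices (within sub_l) of the two trials behind each pair of `tb`
table_trial_index <- function(sub_l, tb) {
  elemcol <- paste0(tb$role, "_id")
  out <- integer(0)
  for (ev in tb$pairs$event_id) {
    ii <- which(sub_l$event_id == ev)
    elems <- sub_l[[elemcol]][ii]
    anchor <- names(which(table(elems) >= 2))
    cand <- ii[elems %in% anchor]
    cand <- cand[order(sub_l$block[cand])][1:2]
    out <- c(out, cand)
  }
  unique(out)
}

#' Group-level paired tests on dependency summaries
#'
#' Paired-sample t-tests comparing (i) the evidence for dependency
#' (`D_obs - D_ind`) between closed- and open-loop events and (ii) observed
#' vs dependent-model dependency within each loop condition. Two-tailed
#' p-values. A zero-variance difference vector is flagged and its p omitted.
#'
#' @param summaries output of [summarize_dependency()].
#' @return data.frame with `comparison`, `t`, `df`, `p`, `mean_diff`,
#'   `degenerate`.
#' @export
paired_tests <- function(summaries) {
  wide <- merge(summaries[summaries$loop_type == "closed", ],
                summaries[summaries$loop_type == "open", ],
                by = "participant_id", suffixes = c("_closed", "_open"))
  if (nrow(wide) < 2L)
    stop_ld("paired tests require at least 2 participants with both loops")
  one <- function(label, a, b) {
    d <- a - b
    if (stats::sd(d) == 0) {
      # all-zero differences: no effect, p = 1 by convention; a constant
      # nonzero difference has no valid t — flagged, p omitted
      zero <- all(d == 0)
      return(data.frame(comparison = label,
                        t = if (zero) 0 else NA_real_,
                        df = length(d) - 1L,
                        p = if (zero) 1 else NA_real_,
                        mean_diff = mean(d), degenerate = TRUE,
                        stringsAsFactors = FALSE))
    }
    tt <- stats::t.test(a, b, paired = TRUE)
    data.frame(comparison = label, t = unname(tt$statistic),
               df = unname(tt$parameter), p = tt$p.value,
               mean_diff = mean(d), degenerate = FALSE,
               stringsAsFactors = FALSE)
  }
  rbind(
    one("evidence: closed vs open",
        wide$evidence_closed, wide$evidence_open),
    one("closed: observed vs dependent model",
        wide$D_obs_closed, wide$D_dep_closed),
    one("open: observed vs dependent model",
        wide$D_obs_open, wide$D_dep_open),
    one("accuracy: closed vs open",
        wide$accuracy_closed, wide$accuracy_open))
}

#' Per-participant accuracy by loop condition
#'
#' @param outcomes trial outcomes.
#' @return data.frame of accuracies (proportions) per participant with
#'   closed, open and overall columns.
#' @export
accuracy_by_loop <- function(outcomes) {
  sp <- split(outcomes, outcomes$participant_id)
  do.call(rbind, lapply(sp, function(sub) {
    data.frame(
      participant_id = sub$participant_id[1],
      accuracy_closed = mean(sub$correct[sub$loop_type == "closed"]),
      accuracy_open = mean(sub$correct[sub$loop_type == "open"]),
      accuracy_overall = mean(sub$correct),
      row.names = NULL, stringsAsFactors = FALSE)
  }))
}
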