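test_that("scoring modes classify trials as specified", {
  out <- data.frame(correct = c(TRUE, TRUE, FALSE, TRUE, TRUE),
                    confidence = c(4L, 2L, 4L, 3L, NA))
  expect_equal(score_outcomes(out, "accuracy"),
               c(TRUE, TRUE, FALSE, TRUE, TRUE))
  # high confidence = 3 or 4; low confidence or incorrect (or missing) fail
  expect_equal(score_outcomes(out, "confidence"),
               c(TRUE, FALSE, FALSE, TRUE, FALSE))
  expect_error(score_outcomes(out[, "correct", drop = FALSE], "confidence"),
               "confidence")
})

test_that("closed loops yield the six canonical tables, open loops only middle-element tables", {
  es <- default_fixture_set()
  ret <- build_retrieval_schedule(es)
  out <- simulate_behavior(ret, generative_config(), seed = 1L)
  out$success <- score_outcomes(out, "accuracy")

  closed <- build_tables(out, "closed")
  expect_length(closed, 6L)
  keys <- vapply(closed, function(tb) paste(tb$category, tb$role), character(1))
  expect_setequal(keys, as.vector(outer(c("location", "people", "object"),
                                        c("cue", "target"), paste)))
  # every closed table pairs all 18 events, one pair each
  expect_true(all(vapply(closed, function(tb) tb$N, numeric(1)) == 18L))
  for (tb in closed)
    expect_false(any(duplicated(tb$pairs$event_id)))

  open <- build_tables(out, "open")
  # only middle elements anchor pairs; 18 events x 2 middle elements per role
  expect_equal(sum(vapply(open, function(tb) tb$N, numeric(1))), 18L * 2L * 2L)
  for (tb in open)
    expect_false(any(duplicated(tb$pairs$event_id)))
  # end elements contribute no cue-based pairs: each pair's anchor is a middle
  mids <- es$elements$element_id[es$elements$position %in% c(2L, 3L) &
                                   es$elements$event_id %in%
                                   es$events$event_id[es$events$loop_type == "open"]]
  open_sub <- out[out$loop_type == "open", ]
  cue_twice <- names(which(table(paste(open_sub$event_id, open_sub$cue_id)) == 2))
  expect_true(all(vapply(strsplit(cue_twice, " "), `[`, character(1), 2) %in% mids))
})

test_that("a toy set of all-correct events fills the n11 cell", {
  scored <- toy_scored_pair_trials(c(TRUE, TRUE), c(TRUE, TRUE))
  tabs <- build_tables(scored, "closed")
  expect_length(tabs, 1L)  # both trials share the location cue
  expect_equal(tabs[[1]]$n11, 2L)
  expect_equal(tabs[[1]]$N, 2L)
  expect_equal(observed_dependency(tabs[[1]]), 1.0)
})

test_that("observed dependency is the concordant-event proportion", {
  tb <- contingency_table(c(rep(TRUE, 8), rep(FALSE, 2)),
                          c(rep(TRUE, 6), FALSE, FALSE, TRUE, FALSE))
  # n11=6, n10=2, n01=1, n00=1
  expect_equal(c(tb$n11, tb$n10, tb$n01, tb$n00), c(6L, 2L, 1L, 1L))
  expect_equal(observed_dependency(tb), 0.7)

  all_disc <- contingency_table(c(TRUE, TRUE, TRUE, TRUE, TRUE,
                                  FALSE, FALSE, FALSE, FALSE, FALSE),
                                c(FALSE, FALSE, FALSE, FALSE, FALSE,
                                  TRUE, TRUE, TRUE, TRUE, TRUE))
  expect_equal(observed_dependency(all_disc), 0.0)
  expect_error(observed_dependency(contingency_table(logical(0), logical(0))),
               "empty")
})

test_that("independent model follows the closed form", {
  tb <- contingency_table(rep(TRUE, 4), rep(TRUE, 4))  # placeholder pairs
  expect_equal(independent_model(tb, marginals = c(0.5, 0.5)), 0.5)
  expect_equal(independent_model(tb, marginals = c(1.0, 0.8)), 0.8)
  expect_equal(independent_model(tb, marginals = c(0.9, 0.8)), 0.74)
  # default marginals are the table's column means
  tb2 <- contingency_table(c(TRUE, TRUE, FALSE, FALSE),
                           c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(independent_model(tb2), 0.5)
})

test_that("dependent model reduces to the independent model for uniform events", {
  tb <- contingency_table(c(TRUE, TRUE, TRUE, FALSE),
                          c(TRUE, TRUE, FALSE, TRUE),
                          event_id = paste0("e", 1:4))
  A <- setNames(rep(0.8, 4), paste0("e", 1:4))
  expect_equal(dependent_model(tb, A), independent_model(tb),
               tolerance = 1e-15)
})

test_that("an at-chance event is predicted at the guessing floor", {
  g <- 0.25
  tb <- contingency_table(c(FALSE, TRUE), c(FALSE, TRUE),
                          event_id = c("e1", "e2"))
  A <- c(e1 = g, e2 = 0.9)
  # event e1 has m_i = 0, so both predicted successes equal g; its
  # concordance term is g^2 + (1-g)^2
  got <- dependent_model(tb, A, marginals = c(0.6, 0.7))
  m_bar <- max(0, (mean(A) - g) / (1 - g))
  E2 <- (max(0, (0.9 - g) / (1 - g))) / m_bar
  p1 <- g + (1 - g) * min(1, E2 * (0.6 - g) / (1 - g))
  p2 <- g + (1 - g) * min(1, E2 * (0.7 - g) / (1 - g))
  manual <- ((g^2 + (1 - g)^2) + (p1 * p2 + (1 - p1) * (1 - p2))) / 2
  expect_equal(got, manual, tolerance = 1e-15)
})

test_that("dependent model matches the brute-force enumeration oracle", {
  o1 <- c(TRUE, TRUE, FALSE, TRUE)
  o2 <- c(TRUE, FALSE, FALSE, TRUE)
  tb <- contingency_table(o1, o2, event_id = paste0("e", 1:4))
  # heterogeneous per-event accuracies (6 trials per event)
  A <- c(e1 = 1.0, e2 = 4 / 6, e3 = 2 / 6, e4 = 5 / 6)
  expect_equal(dependent_model(tb, A),
               oracle_dependent_model(o1, o2, A, mean(A)),
               tolerance = 1e-12)
  # and with an extreme event that clips the episodic prediction at 1
  A2 <- c(e1 = 1.0, e2 = 1.0, e3 = 0.25, e4 = 0.3)
  expect_equal(dependent_model(tb, A2),
               oracle_dependent_model(o1, o2, A2, mean(A2)),
               tolerance = 1e-12)
})

test_that("observed dependency matches exhaustive counting on a hand-built toy", {
  # 4 events, 2 participants; outcomes chosen by hand
  p1 <- toy_scored_pair_trials(c(TRUE, TRUE, FALSE, TRUE),
                               c(TRUE, FALSE, FALSE, TRUE))
  p2 <- toy_scored_pair_trials(c(TRUE, FALSE, TRUE, FALSE),
                               c(TRUE, TRUE, TRUE, FALSE))
  # hand enumeration: p1 pairs (TT, TF, FF, TT) -> concordant 3/4
  expect_equal(observed_dependency(build_tables(p1, "closed")[[1]]), 3 / 4)
  # p2 pairs (TT, FT, TT, FF) -> concordant 3/4
  expect_equal(observed_dependency(build_tables(p2, "closed")[[1]]), 3 / 4)
})

test_that("dependency summaries stay within their ranges on random cohorts", {
  co <- fixture_cohort(n = 4L, seed = 31L)
  for (mode in c("accuracy", "confidence")) {
    summ <- summarize_dependency(co$outcomes, mode = mode)
    expect_true(all(summ$D_obs >= 0 & summ$D_obs <= 1))
    expect_true(all(summ$D_ind >= 0 & summ$D_ind <= 1))
    expect_true(all(summ$D_dep >= 0 & summ$D_dep <= 1))
    expect_true(all(abs(summ$evidence) <= 1))
    expect_equal(summ$n_tables[summ$loop_type == "closed"], rep(6L, 4L))
  }
})

test_that("an all-correct participant sits at the dependency ceiling", {
  es <- default_fixture_set()
  ret <- build_retrieval_schedule(es)
  out <- simulate_behavior(ret, generative_config(p_trace_closed = 1,
                                                  p_trace_pair = 1,
                                                  p_hit_given_trace = 1),
                           seed = 1L)
  summ <- summarize_dependency(out)
  expect_equal(summ$D_obs, c(1, 1))
  expect_equal(summ$D_ind, c(1, 1))
  expect_equal(summ$evidence, c(0, 0))
})

test_that("paired tests flag degenerate difference vectors", {
  summ <- data.frame(
    participant_id = rep(sprintf("s%d", 1:5), 2),
    loop_type = rep(c("closed", "open"), each = 5),
    n_tables = 6L,
    D_obs = rep(0.8, 10), D_ind = rep(0.7, 10), D_dep = rep(0.75, 10),
    evidence = rep(0.1, 10), accuracy = rep(0.85, 10))
  tests <- paired_tests(summ)
  ev <- tests[tests$comparison == "evidence: closed vs open", ]
  expect_equal(ev$t, 0)
  expect_equal(ev$p, 1)
  expect_true(ev$degenerate)
  # constant nonzero difference: flagged, p omitted
  obs <- tests[tests$comparison == "closed: observed vs dependent model", ]
  expect_true(obs$degenerate)
  expect_true(is.na(obs$p))
})

test_that("the exclude-table-trials episodic source changes only D_dep", {
  co <- fixture_cohort(n = 2L, seed = 13L)
  a <- summarize_dependency(co$outcomes, episodic_factor_source = "all_trials")
  b <- summarize_dependency(co$outcomes,
                            episodic_factor_source = "exclude_table_trials")
  expect_equal(a$D_obs, b$D_obs)
  expect_equal(a$D_ind, b$D_ind)
  expect_true(all(b$D_dep >= 0 & b$D_dep <= 1))
})
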