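# shared fixtures, all generated in code

default_fixture_set <- function(seed = 42L) {
  build_event_set(design_config(seed = seed))
}

# a scored trial table for hand-built toys: one closed-loop "event" per row
# pair, with explicit outcomes on the two trials of a single cue-based table
toy_scored_pair_trials <- function(o1, o2, loop_type = "closed") {
  n <- length(o1)
  ev <- sprintf("ev%02d", seq_len(n))
  data.frame(
    participant_id = "sub-01",
    event_id = rep(ev, each = 2L),
    loop_type = loop_type,
    block = rep(1:2, n),
    cue_id = rep(paste0("loc_", seq_len(n)), each = 2L),
    target_id = paste0(rep(c("obj_", "ppl_"), n), rep(seq_len(n), each = 2L)),
    cue_category = "location", target_category = rep(c("object", "people"), n),
    cue_fine_category = "location",
    target_fine_category = rep(c("object", "people"), n),
    success = as.logical(rbind(o1, o2)),
    stringsAsFactors = FALSE)
}

# small simulated cohort reused across tests
fixture_cohort <- function(n = 6L, seed = 7L, config = generative_config()) {
  config$n_participants <- as.integer(n)
  simulate_cohort(design_config(seed = seed), config, seed = seed)
}

# brute-force dependent-model oracle: direct per-event enumeration of the
# published algebra, independent of the package implementation
oracle_dependent_model <- function(o1, o2, A, A_bar, g = 0.25) {
  P1 <- mean(o1); P2 <- mean(o2)
  total <- 0
  for (i in seq_along(o1)) {
    m_i <- max(0, (A[i] - g) / (1 - g))
    m_bar <- max(0, (A_bar - g) / (1 - g))
    E_i <- if (m_bar == 0) 1 else m_i / m_bar
    p1 <- g + (1 - g) * min(1, E_i * max(0, (P1 - g) / (1 - g)))
    p2 <- g + (1 - g) * min(1, E_i * max(0, (P2 - g) / (1 - g)))
    total <- total + p1 * p2 + (1 - p1) * (1 - p2)
  }
  total / length(o1)
}
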