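test_that("default design reproduces the study's combinatorial counts", {
  es <- default_fixture_set()
  expect_equal(nrow(es$events), 36L)
  expect_equal(sum(es$events$loop_type == "open"), 18L)
  expect_equal(sum(es$events$loop_type == "closed"), 18L)
  # closed events split into two 9-event sub-pools by category composition
  expect_equal(unname(table(es$events$subpool[es$events$loop_type == "closed"])),
               c(9L, 9L), ignore_attr = TRUE)
  # element counts: 3 per closed, 4 per open event; none reused
  expect_equal(nrow(es$elements), 18L * 3L + 18L * 4L)
  expect_false(any(duplicated(es$elements$element_id)))

  enc <- build_encoding_schedule(es)
  expect_equal(nrow(enc), 108L)
  expect_equal(unname(table(enc$block)), rep(36L, 3), ignore_attr = TRUE)

  ret <- build_retrieval_schedule(es)
  expect_equal(nrow(ret), 216L)
  expect_true(all(table(ret$event_id) == 6L))
  expect_true(all(table(ret$block) == 36L))
})

test_that("a single closed-loop event is a 3-cycle", {
  es <- build_event_set(design_config(n_closed = 1L, n_open = 0L, seed = 5L))
  expect_equal(nrow(es$events), 1L)
  expect_equal(nrow(es$elements), 3L)
  expect_equal(nrow(es$associations), 3L)
  # every element appears in exactly 2 associations (a cycle)
  deg <- table(c(es$associations$elem1, es$associations$elem2))
  expect_true(all(deg == 2L))
})

test_that("encoding schedule satisfies the overlap and block-3 constraints", {
  es <- default_fixture_set(seed = 11L)
  enc <- build_encoding_schedule(es)
  catmap <- setNames(es$elements$category, es$elements$element_id)

  for (ev in es$events$event_id) {
    rows <- enc[enc$event_id == ev, ]
    rows <- rows[order(rows$block), ]
    # one pair per block, consecutive blocks share exactly one element
    expect_equal(nrow(rows), 3L)
    for (b in 1:2) {
      shared <- intersect(c(rows$elem1[b], rows$elem2[b]),
                          c(rows$elem1[b + 1], rows$elem2[b + 1]))
      expect_length(shared, 1L)
    }
  }
  # closed events schedule exactly their three associations
  closed <- es$events$event_id[es$events$loop_type == "closed"]
  for (ev in closed[1:5]) {
    sched <- enc[enc$event_id == ev, ]
    want <- es$associations[es$associations$event_id == ev, ]
    key <- function(a, b) paste(pmin(a, b), pmax(a, b))
    expect_setequal(key(sched$elem1, sched$elem2), key(want$elem1, want$elem2))
  }
  # block 3 pairs are location-object/animal or people-object/animal
  b3 <- enc[enc$block == 3L, ]
  m1 <- catmap[b3$elem1]; m2 <- catmap[b3$elem2]
  expect_true(all((m1 == "object") != (m2 == "object")))
  expect_true(all(m1 == "object" | m1 %in% c("location", "people")))
})

test_that("retrieval schedule is bidirectional with correct cue multiplicities", {
  es <- default_fixture_set(seed = 3L)
  ret <- build_retrieval_schedule(es)

  # every association appears exactly once per direction
  for (i in seq_len(nrow(es$associations))) {
    a <- es$associations[i, ]
    fwd <- sum(ret$cue_id == a$elem1 & ret$target_id == a$elem2)
    bwd <- sum(ret$cue_id == a$elem2 & ret$target_id == a$elem1)
    expect_equal(fwd, 1L)
    expect_equal(bwd, 1L)
  }

  # closed-loop elements: cue exactly twice and target exactly twice
  closed_el <- es$elements$element_id[
    es$elements$event_id %in% es$events$event_id[es$events$loop_type == "closed"]]
  expect_true(all(table(ret$cue_id[ret$cue_id %in% closed_el]) == 2L))
  expect_true(all(table(ret$target_id[ret$target_id %in% closed_el]) == 2L))

  # open-loop chain: end elements cue once, middle elements twice
  open_ev <- es$events$event_id[es$events$loop_type == "open"]
  el <- es$elements[es$elements$event_id %in% open_ev, ]
  ends <- el$element_id[el$position %in% c(1L, 4L)]
  mids <- el$element_id[el$position %in% c(2L, 3L)]
  cue_counts <- table(factor(ret$cue_id, levels = el$element_id))
  expect_true(all(cue_counts[ends] == 1L))
  expect_true(all(cue_counts[mids] == 2L))
})

test_that("lures share the target category and never come from the cued event", {
  es <- default_fixture_set(seed = 9L)
  ret <- build_retrieval_schedule(es)
  catmap <- setNames(es$elements$category, es$elements$element_id)
  evmap <- setNames(es$elements$event_id, es$elements$element_id)
  for (l in c("lure1", "lure2", "lure3")) {
    expect_true(all(catmap[ret[[l]]] == ret$target_category))
    expect_true(all(evmap[ret[[l]]] != ret$event_id))
  }
  # the three lures of a trial are distinct
  expect_true(all(apply(ret[, c("lure1", "lure2", "lure3")], 1,
                        function(x) length(unique(x)) == 3L)))
})

test_that("generation is seed-deterministic and seed-sensitive", {
  a <- build_event_set(design_config(seed = 21L))
  b <- build_event_set(design_config(seed = 21L))
  expect_identical(serialize(a, NULL), serialize(b, NULL))
  expect_identical(build_retrieval_schedule(a), build_retrieval_schedule(b))
  c <- build_event_set(design_config(seed = 22L))
  expect_false(identical(a$events$loop_type, c$events$loop_type) &&
                 identical(a$elements$element_id, c$elements$element_id))
})

test_that("pool exhaustion raises an error naming the category", {
  cfg <- design_config(pool_sizes = c(location = 2, object = 50,
                                      animal = 50, people = 50))
  expect_error(build_event_set(cfg), "location")
})
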