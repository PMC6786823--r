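#' Design configuration for a multi-element event experiment
#'
#' The default configuration reproduces the study design: 36 events, of which
#' 18 follow a closed-loop structure (3 elements associated as a cycle,
#' AB-BC-CA) and 18 an open-loop structure (4 elements associated as a chain,
#' AB-BC-CD). Closed-loop events split into two 9-event sub-pools
#' (location-object-people and location-animal-people); open-loop events draw
#' one element from each of the four stimulus categories (location, object,
#' animal, people). For analysis the object and animal pools are merged into a
#' single "object" category; the fine category is retained because the third
#' encoding block is constrained to location-object/animal or
#' people-object/animal pairings.
#'
#' @param n_closed,n_open number of closed- and open-loop events.
#' @param seed integer seed governing the design stream.
#' @param shared_event_set if `TRUE`, one event set is generated and reused
#'   across participants; if `FALSE` each participant gets their own seeded
#'   set (a strict generalization of the study's four counterbalanced sets).
#' @param encode_duration,retrieval_max,confidence_window,isi,fixation timing
#'   constants in seconds.
#' @param pool_sizes optional named integer vector giving the number of
#'   available stimuli per fine category (`location`, `object`, `animal`,
#'   `people`); defaults to exactly the number required.
#' @return A list of class `loopdep_design_config`.
#' @export
design_config <- function(n_closed = 18L, n_open = 18L, seed = 1L,
                          shared_event_set = TRUE,
                          encode_duration = 6, retrieval_max = 6,
                          confidence_window = 6, isi = 1.5, fixation = 0.5,
                          pool_sizes = NULL) {
  stopifnot(n_closed >= 0, n_open >= 0, n_closed + n_open >= 1)
  cfg <- list(n_closed = as.integer(n_closed), n_open = as.integer(n_open),
              seed = as.integer(seed), shared_event_set = shared_event_set,
              encode_duration = encode_duration,
              retrieval_max = retrieval_max,
              confidence_window = confidence_window,
              isi = isi, fixation = fixation, pool_sizes = pool_sizes)
  class(cfg) <- "loopdep_design_config"
  cfg
}

MERGED_CATEGORIES <- c("location", "people", "object")
FINE_CATEGORIES   <- c("location", "people", "object", "animal")

merge_category <- function(fine) {
  ifelse(fine == "animal", "object", fine)
}

cat_abbrev <- c(location = "loc", people = "ppl", object = "obj")

# a pair is admissible in encoding block 3 iff it pairs location or people
# with an object/animal element
block3_ok <- function(cat1, cat2) {
  m1 <- merge_category(cat1); m2 <- merge_category(cat2)
  (m1 == "object") != (m2 == "object")  # exactly one object/animal member
}

#' Build a multi-element event set
#'
#' Generates events with their elements and associations. Closed-loop events
#' have 3 elements and 3 associations forming a cycle; open-loop events have
#' 4 elements and 3 associations forming a chain. No stimulus element is
#' reused across events. Open-loop chain orders are randomized subject to at
#' least one end pair being admissible in encoding block 3 (see
#' [design_config()]).
#'
#' @param config a [design_config()].
#' @param seed optional seed overriding `config$seed`.
#' @return A list of class `loopdep_event_set` with data.frames `events`,
#'   `elements` and `associations`.
#' @export
build_event_set <- function(config = design_config(), seed = NULL) {
  stopifnot(inherits(config, "loopdep_design_config"))
  seed <- seed %||% config$seed
  with_seed(derive_seed(seed, "design/events"), {
    n_c <- config$n_closed; n_o <- config$n_open
    # closed sub-pools: half object, half animal as middle category
    n_c_obj <- n_c %/% 2L
    n_c_ani <- n_c - n_c_obj
    need <- c(location = n_c + n_o, people = n_c + n_o,
              object = n_c_obj + n_o, animal = n_c_ani + n_o)
    pool_sizes <- config$pool_sizes %||% need
    for (cat in FINE_CATEGORIES) {
      avail <- pool_sizes[[cat]] %||% 0L
      if (avail < need[[cat]])
        stop_ld("stimulus pool exhausted for category '%s': need %d, have %d",
                cat, need[[cat]], avail)
    }
    pools <- lapply(FINE_CATEGORIES, function(cat) {
      sample(sprintf("%s_%03d", cat_fine_prefix(cat), seq_len(pool_sizes[[cat]])))
    })
    names(pools) <- FINE_CATEGORIES
    take <- function(cat) {
      el <- pools[[cat]][1L]
      pools[[cat]] <<- pools[[cat]][-1L]
      el
    }

    n_ev <- n_c + n_o
    event_id <- sprintf("ev%02d", seq_len(n_ev))
    loop_type <- sample(rep(c("closed", "open"), c(n_c, n_o)))
    # assign closed events to the two category sub-pools
    closed_ids <- event_id[loop_type == "closed"]
    subpool <- rep(NA_character_, n_ev)
    subpool[match(sample(closed_ids), event_id)] <-
      rep(c("object", "animal"), c(n_c_obj, n_c_ani))

    elements <- vector("list", n_ev)
    for (i in seq_len(n_ev)) {
      if (loop_type[i] == "closed") {
        cats <- sample(c("location", subpool[i], "people"))  # cycle order
      } else {
        repeat {  # chain order with an admissible end pair for block 3
          cats <- sample(FINE_CATEGORIES)
          if (block3_ok(cats[1], cats[2]) || block3_ok(cats[3], cats[4]))
            break
        }
      }
      elements[[i]] <- data.frame(
        element_id = vapply(cats, take, character(1)),
        event_id = event_id[i], position = seq_along(cats),
        fine_category = cats, category = merge_category(cats),
        animal_flag = cats == "animal", row.names = NULL,
        stringsAsFactors = FALSE)
    }
    elements <- do.call(rbind, elements)

    associations <- do.call(rbind, lapply(seq_len(n_ev), function(i) {
      el <- elements[elements$event_id == event_id[i], ]
      k <- nrow(el)
      idx1 <- if (loop_type[i] == "closed") c(1L, 2L, 3L) else c(1L, 2L, 3L)
      idx2 <- if (loop_type[i] == "closed") c(2L, 3L, 1L) else c(2L, 3L, 4L)
      data.frame(event_id = event_id[i], pair_index = seq_len(3L),
                 elem1 = el$element_id[idx1], elem2 = el$element_id[idx2],
                 stringsAsFactors = FALSE)
    }))

    structure(list(
      events = data.frame(event_id = event_id, loop_type = loop_type,
                          subpool = subpool, stringsAsFactors = FALSE),
      elements = elements, associations = associations,
      config = config, seed = seed),
      class = "loopdep_event_set")
  })
}

cat_fine_prefix <- function(cat) {
  c(location = "loc", people = "ppl", object = "obj", animal = "ani")[[cat]]
}

#' @export
print.loopdep_event_set <- function(x, ...) {
  cat(sprintf("<loopdep_event_set> %d events (%d closed, %d open), %d elements\n",
              nrow(x$events), sum(x$events$loop_type == "closed"),
              sum(x$events$loop_type == "open"), nrow(x$elements)))
  invisible(x)
}

element_lookup <- function(event_set) {
  el <- event_set$elements
  stats::setNames(split(el, seq_len(nrow(el))), el$element_id)
}

# merged category of each element_id
element_category <- function(event_set) {
  stats::setNames(event_set$elements$category, event_set$elements$element_id)
}

element_fine_category <- function(event_set) {
  stats::setNames(event_set$elements$fine_category,
                  event_set$elements$element_id)
}

pair_trial_type <- function(event_set, id1, id2) {
  catmap <- element_category(event_set)
  paste(cat_abbrev[catmap[id1]], cat_abbrev[catmap[id2]], sep = "-")
}

#' Build the pairwise-associative encoding schedule
#'
#' Three blocks with one associative pair per event each. Within an event,
#' consecutive blocks share exactly one element, and the block-3 pair is
#' constrained to a location-object/animal or people-object/animal category
#' pairing. Trial order within a block is randomized; onsets lie on a regular
#' grid of `duration + isi + fixation` seconds.
#'
#' @param event_set a [build_event_set()] result.
#' @param seed optional seed (defaults to the event set's design seed).
#' @return data.frame of encoding trials (one row per block x event).
#' @export
build_encoding_schedule <- function(event_set, seed = NULL) {
  stopifnot(inherits(event_set, "loopdep_event_set"))
  cfg <- event_set$config
  seed <- seed %||% event_set$seed
  with_seed(derive_seed(seed, "design/encoding"), {
    catmap <- element_category(event_set)
    assign_blocks <- function(ev) {
      as_ev <- event_set$associations[event_set$associations$event_id == ev, ]
      loop <- event_set$events$loop_type[event_set$events$event_id == ev]
      ok3 <- block3_ok(catmap[as_ev$elem1], catmap[as_ev$elem2])
      if (loop == "open") ok3[2] <- FALSE  # middle pair must sit in block 2
      if (!any(ok3))
        stop_ld("event %s has no admissible block-3 pair", ev)
      b3 <- if (sum(ok3) == 1L) which(ok3) else sample(which(ok3), 1L)
      if (loop == "closed") {
        rest <- sample(setdiff(1:3, b3))
      } else {
        rest <- c(setdiff(c(1L, 3L), b3), 2L)  # end pair first, then middle
      }
      ord <- c(rest, b3)
      data.frame(block = 1:3, event_id = ev,
                 elem1 = as_ev$elem1[ord], elem2 = as_ev$elem2[ord],
                 stringsAsFactors = FALSE)
    }
    trials <- do.call(rbind, lapply(event_set$events$event_id, assign_blocks))
    trials <- trials[order(trials$block), ]
    # shuffle within block
    trials <- do.call(rbind, lapply(split(trials, trials$block),
                                    function(b) b[sample(nrow(b)), ]))
    rownames(trials) <- NULL
    step <- cfg$encode_duration + cfg$isi + cfg$fixation
    trials$onset <- cfg$fixation + (seq_len(nrow(trials)) - 1L) * step
    trials$duration <- cfg$encode_duration
    trials$isi <- cfg$isi
    trials$trial_type <- pair_trial_type(event_set, trials$elem1, trials$elem2)
    trials
  })
}

#' Build the bidirectional 4AFC retrieval schedule
#'
#' Six blocks with one trial per event each; across the six blocks every
#' association of an event is tested exactly twice, once in each cue-target
#' direction. Lures share the target's (merged) category and are drawn
#' without replacement from elements of other events.
#'
#' @inheritParams build_encoding_schedule
#' @return data.frame of retrieval trials with columns `block`, `event_id`,
#'   `loop_type`, `cue_id`, `target_id`, `pair_index`, `lure1..3`, onset and
#'   timing columns.
#' @export
build_retrieval_schedule <- function(event_set, seed = NULL) {
  stopifnot(inherits(event_set, "loopdep_event_set"))
  cfg <- event_set$config
  seed <- seed %||% event_set$seed
  with_seed(derive_seed(seed, "design/retrieval"), {
    catmap <- element_category(event_set)
    per_event <- lapply(event_set$events$event_id, function(ev) {
      as_ev <- event_set$associations[event_set$associations$event_id == ev, ]
      directed <- rbind(
        data.frame(cue_id = as_ev$elem1, target_id = as_ev$elem2,
                   pair_index = as_ev$pair_index, stringsAsFactors = FALSE),
        data.frame(cue_id = as_ev$elem2, target_id = as_ev$elem1,
                   pair_index = as_ev$pair_index, stringsAsFactors = FALSE))
      directed <- directed[sample(nrow(directed)), ]
      directed$block <- 1:6
      directed$event_id <- ev
      directed
    })
    trials <- do.call(rbind, per_event)
    trials <- do.call(rbind, lapply(split(trials, trials$block),
                                    function(b) b[sample(nrow(b)), ]))
    rownames(trials) <- NULL
    trials$loop_type <- event_set$events$loop_type[
      match(trials$event_id, event_set$events$event_id)]

    # lures: same merged category, other events, sampled without replacement
    el <- event_set$elements
    lures <- t(vapply(seq_len(nrow(trials)), function(i) {
      tgt <- trials$target_id[i]
      cands <- el$element_id[el$category == catmap[tgt] &
                             el$event_id != trials$event_id[i]]
      if (length(cands) < 3L)
        stop_ld("fewer than 3 same-category lure candidates for target %s (%s)",
                tgt, catmap[tgt])
      sample(cands, 3L)
    }, character(3)))
    trials$lure1 <- lures[, 1]; trials$lure2 <- lures[, 2]
    trials$lure3 <- lures[, 3]

    step <- cfg$retrieval_max + cfg$isi + cfg$fixation
    trials$onset <- cfg$fixation + (seq_len(nrow(trials)) - 1L) * step
    trials$max_duration <- cfg$retrieval_max
    trials$confidence_window <- cfg$confidence_window
    finemap <- element_fine_category(event_set)
    trials$cue_category <- unname(catmap[trials$cue_id])
    trials$target_category <- unname(catmap[trials$target_id])
    trials$cue_fine_category <- unname(finemap[trials$cue_id])
    trials$target_fine_category <- unname(finemap[trials$target_id])
    trials$trial_type <- pair_trial_type(event_set, trials$cue_id,
                                         trials$target_id)
    trials[, c("block", "event_id", "loop_type", "pair_index", "cue_id",
               "target_id", "cue_category", "target_category",
               "cue_fine_category", "target_fine_category", "trial_type",
               "lure1", "lure2", "lure3", "onset", "max_duration",
               "confidence_window")]
  })
}
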