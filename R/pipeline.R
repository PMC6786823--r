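#' Run the full synthetic analysis pipeline
#'
#' Executes simulate -> dependency -> (glm) -> reinstatement ->
#' brain-behaviour and returns (and optionally writes) a report bundle. All
#' randomness derives from `config$seed` via named child streams, so a
#' fixed configuration reproduces every output byte-identically.
#'
#' @param config a [pipeline_config()].
#' @param outdir optional output directory; when given, per-stage TSV/CSV
#'   files and a `summary.json` are written.
#' @param quiet suppress per-stage log messages.
#' @return list with `accuracy`, `dependency` (per-mode summaries and
#'   paired tests), `reinstatement` (scores, loop differences, tests,
#'   ANOVA), `brain_behavior` (subfield correlations and dependent
#'   correlation z-tests), optional `glm`, and `summary` (the flat summary
#'   list written as JSON).
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = NULL,
                         quiet = FALSE) {
  stopifnot(inherits(config, "loopdep_pipeline_config"))
  say <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
  if (!is.null(outdir) && !dir.exists(outdir))
    dir.create(outdir, recursive = TRUE)
  emit <- function(obj, file, writer = utils::write.csv) {
    if (!is.null(outdir))
      writer(obj, file.path(outdir, file))
  }

  # --- simulate -------------------------------------------------------
  cohort <- simulate_cohort(config$design, config$generative,
                            seed = config$seed)
  n_sub <- config$generative$n_participants
  say("simulate: %d participants, %d trials", n_sub, nrow(cohort$outcomes))
  if (!is.null(outdir))
    write_events_tsv(cohort$outcomes, file.path(outdir, "outcomes.tsv"))

  acc <- accuracy_by_loop(cohort$outcomes)
  emit(acc, "accuracy.csv", function(x, f)
    utils::write.csv(x, f, row.names = FALSE))

  # --- dependency -----------------------------------------------------
  modes <- if (config$dependency_mode == "both") c("accuracy", "confidence")
           else config$dependency_mode
  dependency <- list()
  for (mode in modes) {
    summ <- summarize_dependency(cohort$outcomes, mode = mode,
                                 confidence_high = config$confidence_high,
                                 g = config$generative$g)
    tests <- if (n_sub >= 2L) paired_tests(summ) else {
      warning("fewer than 2 participants: dependency group tests skipped")
      NULL
    }
    dependency[[mode]] <- list(summary = summ, tests = tests)
    emit(summ, paste0("dependency_", mode, ".csv"), function(x, f)
      utils::write.csv(x, f, row.names = FALSE))
    say("dependency (%s): mean closed evidence %.4f, open %.4f", mode,
        mean(summ$evidence[summ$loop_type == "closed"]),
        mean(summ$evidence[summ$loop_type == "open"]))
  }

  # --- glm (optional, small recovery demonstration) -------------------
  glm_stage <- NULL
  if (config$run_glm) {
    glm_stage <- pipeline_glm_stage(config)
    say("glm: max |beta error| %.2e (noiseless %s)",
        glm_stage$max_beta_error, "recovery")
  }

  # --- neural + reinstatement ----------------------------------------
  neural <- simulate_neural(cohort$latents, config$generative,
                            seed = config$seed, roi_map = config$roi_map)
  if (!is.null(outdir))
    utils::write.csv(neural$beta_table,
                     file.path(outdir, "roi_betas.csv"), row.names = FALSE)
  std <- zscore_within_roi(neural$beta_table)
  overall <- element_function_scores(std, config$roi_map)
  split <- loop_split_scores(std, config$roi_map)
  reinstatement <- list(overall = overall, loop = split,
                        anova = NULL, loop_tests = NULL)
  if (n_sub >= 2L) {
    reinstatement$loop_tests <- one_sample_tests(split$differences)
    reinstatement$anova <- anova_element_function(overall)
  } else {
    warning("fewer than 2 participants: reinstatement group tests skipped")
  }
  emit(overall, "reinstatement_scores.csv", function(x, f)
    utils::write.csv(x, f, row.names = FALSE))
  say("reinstatement: mean nontarget closed-open diff %.3f",
      mean(split$differences$nontarget))

  # --- brain-behaviour ------------------------------------------------
  bb <- NULL
  if (n_sub >= 4L) {
    sf <- neural$subfields[match(overall$participant_id,
                                 neural$subfields$participant_id), ]
    ca3 <- roi_brain_behavior(sf$CA3_ant_R, overall$nontarget)
    dg <- roi_brain_behavior(sf$DG_ant_R, overall$nontarget)
    z_ca3_dg <- compare_dependent_correlations(overall$nontarget,
                                               sf$CA3_ant_R, sf$DG_ant_R)
    z_nt_cue <- compare_dependent_correlations(sf$CA3_ant_R,
                                               overall$nontarget,
                                               overall$cue)
    z_nt_target <- compare_dependent_correlations(sf$CA3_ant_R,
                                                  overall$nontarget,
                                                  overall$target)
    bb <- list(ca3 = ca3, dg = dg, z_ca3_vs_dg = z_ca3_dg,
               z_nontarget_vs_cue = z_nt_cue,
               z_nontarget_vs_target = z_nt_target)
    say("brain-behavior: R2 CA3 %.3f, DG %.3f, z(CA3>DG) %.3f",
        ca3$r_squared, dg$r_squared, z_ca3_dg$z)
  } else {
    warning("fewer than 4 participants: brain-behaviour stage skipped")
  }

  summary <- pipeline_summary(acc, dependency, reinstatement, bb, glm_stage,
                              config)
  if (!is.null(outdir))
    jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(accuracy = acc, dependency = dependency,
                 reinstatement = reinstatement, brain_behavior = bb,
                 glm = glm_stage, summary = summary,
                 outcomes = cohort$outcomes, neural = neural))
}

# small, fully synthetic GLM recovery stage: builds a design from the first
# encoding block of a fresh event set and checks noiseless beta recovery
pipeline_glm_stage <- function(config) {
  es <- build_event_set(config$design, seed = derive_seed(config$seed, "glm"))
  enc <- build_encoding_schedule(es)
  enc <- enc[enc$block == 1L, ]
  tr <- 2
  n_scans <- ceiling((max(enc$onset) + 6 + 32) / tr)
  conds <- lapply(split(enc, enc$trial_type), function(tt)
    list(onsets = tt$onset, durations = tt$duration))
  spec <- design_spec(tr = tr, n_scans = n_scans, conditions = conds)
  X <- build_design_matrix(spec)
  true_b <- seq_len(ncol(X)) / ncol(X)
  Y <- simulate_bold(X, true_b, noise_sd = 0,
                     seed = derive_seed(config$seed, "glm/bold"))
  fit <- fit_glm(Y, X)
  list(n_scans = n_scans, conditions = names(conds),
       max_beta_error = max(abs(fit$betas - true_b)))
}

pipeline_summary <- function(acc, dependency, reinstatement, bb, glm_stage,
                             config) {
  s <- list(
    seed = config$seed,
    n_participants = config$generative$n_participants,
    accuracy_overall_pct = 100 * mean(acc$accuracy_overall),
    accuracy_closed_pct = 100 * mean(acc$accuracy_closed),
    accuracy_open_pct = 100 * mean(acc$accuracy_open))
  for (mode in names(dependency)) {
    d <- dependency[[mode]]
    cl <- d$summary[d$summary$loop_type == "closed", ]
    op <- d$summary[d$summary$loop_type == "open", ]
    s[[paste0("evidence_closed_", mode)]] <- mean(cl$evidence)
    s[[paste0("evidence_open_", mode)]] <- mean(op$evidence)
    if (!is.null(d$tests)) {
      ev <- d$tests[d$tests$comparison == "evidence: closed vs open", ]
      s[[paste0("evidence_t_", mode)]] <- ev$t
      s[[paste0("evidence_p_", mode)]] <- ev$p
    }
  }
  if (!is.null(reinstatement$anova)) {
    s$anova_F <- reinstatement$anova$F
    s$anova_p <- reinstatement$anova$p
  }
  if (!is.null(reinstatement$loop_tests)) {
    lt <- reinstatement$loop_tests
    for (fn in lt$element_function) {
      s[[paste0("loopdiff_", fn, "_t")]] <- lt$t[lt$element_function == fn]
      s[[paste0("loopdiff_", fn, "_p")]] <- lt$p[lt$element_function == fn]
    }
  }
  if (!is.null(bb)) {
    s$r2_ca3 <- bb$ca3$r_squared
    s$r2_dg <- bb$dg$r_squared
    s$z_ca3_vs_dg <- bb$z_ca3_vs_dg$z
    s$z_nontarget_vs_cue <- bb$z_nontarget_vs_cue$z
    s$z_nontarget_vs_target <- bb$z_nontarget_vs_target$z
  }
  if (!is.null(glm_stage)) s$glm_max_beta_error <- glm_stage$max_beta_error
  s
}
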