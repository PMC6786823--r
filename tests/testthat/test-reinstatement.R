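make_beta_table <- function(n_sub = 5, loop = FALSE, seed = 1,
                            config = generative_config()) {
  set.seed(seed)
  lat <- data.frame(participant_id = sprintf("s%02d", seq_len(n_sub)),
                    trace_frac_closed = rbinom(n_sub, 18, 0.85) / 18)
  nd <- simulate_neural(lat, config, seed = seed)
  bt <- nd$beta_table
  if (!loop) bt$loop <- NULL
  list(bt = bt, nd = nd)
}

test_that("z-standardization is exact within each participant-ROI cell", {
  bt <- make_beta_table(loop = TRUE)$bt
  std <- zscore_within_roi(bt)
  for (pid in unique(std$participant_id)[1:2]) {
    for (roi in unique(std$roi)) {
      v <- std$beta[std$participant_id == pid & std$roi == roi]
      expect_lt(abs(mean(v)), 1e-12)
      expect_lt(abs(sd(v) - 1), 1e-12)
    }
  }
  # affine transforms of the raw estimates leave z-scores unchanged
  bt2 <- bt
  bt2$beta <- 3.7 * bt2$beta - 11
  expect_equal(zscore_within_roi(bt2)$beta, std$beta, tolerance = 1e-10)
})

test_that("a two-condition cell standardizes to +/- 0.707", {
  bt <- data.frame(participant_id = "s01", roi = "PHC",
                   condition = c("loc-obj", "obj-loc"), beta = c(2, 5))
  std <- zscore_within_roi(bt)
  expect_equal(std$beta, c(-1, 1) / sqrt(2), tolerance = 1e-12)
})

test_that("zero-variance cells raise an error naming the cell", {
  bt <- data.frame(participant_id = "s01", roi = "PHC",
                   condition = c("loc-obj", "obj-loc"), beta = c(1, 1))
  expect_error(zscore_within_roi(bt), "s01/PHC")
})

test_that("element functions map conditions to cue, target and nontarget", {
  # location ROI: nontarget conditions are exactly people-object/object-people
  conds <- c("loc-obj", "obj-loc", "loc-ppl", "ppl-loc", "obj-ppl", "ppl-obj")
  bt <- data.frame(participant_id = "s01", roi = "PHC", condition = conds,
                   beta = c(10, 20, 10, 20, -5, -5))
  std <- zscore_within_roi(bt)
  scores <- element_function_scores(std, c(PHC = "location"))
  expect_equal(scores$cue,
               mean(std$beta[std$condition %in% c("loc-obj", "loc-ppl")]))
  expect_equal(scores$target,
               mean(std$beta[std$condition %in% c("obj-loc", "ppl-loc")]))
  expect_equal(scores$nontarget,
               mean(std$beta[std$condition %in% c("obj-ppl", "ppl-obj")]))
  expect_error(element_function_scores(std, c(XXX = "location")), "unmapped")
})

test_that("the generator's element-function ordering is recovered", {
  res <- make_beta_table(n_sub = 12, loop = TRUE, seed = 3)
  std <- zscore_within_roi(res$bt)
  scores <- element_function_scores(std)
  # construction: target > cue > nontarget on average
  expect_gt(mean(scores$target), mean(scores$cue))
  expect_gt(mean(scores$cue), mean(scores$nontarget))
})

test_that("averaging across ROIs and conditions commutes for balanced tables", {
  res <- make_beta_table(n_sub = 4, loop = TRUE, seed = 9)
  std <- zscore_within_roi(res$bt)
  std$element_function <- NULL
  scores <- element_function_scores(std)
  # manual reverse order: average over ROIs first, then conditions
  roi_map <- default_roi_map()
  for (pid in scores$participant_id) {
    sub <- std[std$participant_id == pid, ]
    abb <- setNames(names(loopdep:::cat_abbrev), loopdep:::cat_abbrev)
    first <- abb[sub("-.*", "", sub$condition)]
    second <- abb[sub(".*-", "", sub$condition)]
    roi_cat <- roi_map[sub$roi]
    fn <- ifelse(roi_cat == first, "cue",
                 ifelse(roi_cat == second, "target", "nontarget"))
    manual <- tapply(sub$beta, fn, mean)  # balanced: flat mean equals nested
    expect_equal(scores$nontarget[scores$participant_id == pid],
                 unname(manual["nontarget"]), tolerance = 1e-12)
  }
})

test_that("identical closed and open tables give zero differences and t = 0", {
  bt <- make_beta_table(n_sub = 4, loop = TRUE, seed = 5)$bt
  closed <- bt[bt$loop == "closed", ]
  open <- closed
  open$loop <- "open"
  sym <- rbind(closed, open)
  std <- zscore_within_roi(sym)
  split <- loop_split_scores(std)
  expect_true(all(abs(split$differences$nontarget) < 1e-12))
  tests <- one_sample_tests(split$differences)
  expect_equal(tests$t, rep(0, 3))
  expect_equal(tests$p, rep(1, 3))
})

test_that("loop-split scoring validates its inputs", {
  bt <- make_beta_table(n_sub = 3, loop = TRUE)$bt
  expect_error(loop_split_scores(bt[bt$loop == "closed", ]), "loop")
  one <- loop_split_scores(zscore_within_roi(
    bt[bt$participant_id == "s01", ]))
  expect_error(one_sample_tests(one$differences), "2 participants")
})

test_that("the element-function ANOVA behaves at its extremes", {
  scores <- data.frame(participant_id = sprintf("s%02d", 1:8),
                       cue = 0.3, target = 0.3, nontarget = 0.3)
  res <- anova_element_function(scores)
  expect_equal(res$F, 0)
  expect_equal(res$p, 1)

  set.seed(2)
  strong <- data.frame(participant_id = sprintf("s%02d", 1:20),
                       cue = rnorm(20, 0, 0.01),
                       target = rnorm(20, 5, 0.01),
                       nontarget = rnorm(20, -5, 0.01))
  res2 <- anova_element_function(strong)
  expect_lt(res2$p, 1e-6)
  expect_equal(res2$df1, 2L)
  expect_equal(res2$df2, 2L * 19L)     # repeated measures: 2(n-1)
  res3 <- anova_element_function(strong, mode = "oneway")
  expect_equal(res3$df2, 3L * 20L - 3L)  # independent groups: 3n-3
})

test_that("the repeated-measures F matches the direct sum-of-squares formula", {
  set.seed(8)
  n <- 10
  scores <- data.frame(participant_id = sprintf("s%02d", 1:n),
                       cue = rnorm(n), target = rnorm(n), nontarget = rnorm(n))
  res <- anova_element_function(scores)
  m <- as.matrix(scores[, c("cue", "target", "nontarget")])
  grand <- mean(m)
  ss_cond <- n * sum((colMeans(m) - grand)^2)
  ss_sub <- 3 * sum((rowMeans(m) - grand)^2)
  ss_tot <- sum((m - grand)^2)
  ss_err <- ss_tot - ss_cond - ss_sub
  F_manual <- (ss_cond / 2) / (ss_err / (2 * (n - 1)))
  expect_equal(res$F, F_manual, tolerance = 1e-10)
})
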