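#' Z-standardize parameter estimates within participant and ROI
#'
#' Each (participant, ROI) cell's condition estimates are centred and scaled
#' to unit sample standard deviation (n - 1 convention, as in `scale()`);
#' with only two conditions this yields scores of +/- 0.707. Scores are
#' invariant to affine rescaling of the raw estimates.
#'
#' @param beta_table long data.frame with `participant_id`, `roi`,
#'   `condition`, `beta` and optionally `loop`.
#' @return the table with `beta` replaced by its within-cell z-score.
#' @export
zscore_within_roi <- function(beta_table) {
  need <- c("participant_id", "roi", "condition", "beta")
  if (!all(need %in% names(beta_table)))
    stop_ld("beta_table must contain columns: %s", paste(need, collapse = ", "))
  key <- paste(beta_table$participant_id, beta_table$roi, sep = "\r")
  for (cell in unique(key)) {
    ii <- which(key == cell)
    if (length(ii) < 2L)
      stop_ld("cell %s has fewer than 2 condition estimates",
              gsub("\r", "/", cell))
    s <- stats::sd(beta_table$beta[ii])
    if (s == 0)
      stop_ld("zero variance across conditions in cell %s",
              gsub("\r", "/", cell))
    beta_table$beta[ii] <- (beta_table$beta[ii] -
                              mean(beta_table$beta[ii])) / s
  }
  beta_table
}

# element function of each row of a beta table given the ROI->category map
beta_element_function <- function(beta_table, roi_map) {
  unmapped <- setdiff(unique(beta_table$roi), names(roi_map))
  if (length(unmapped))
    stop_ld("unmapped ROI(s): %s", paste(unmapped, collapse = ", "))
  abb <- stats::setNames(names(cat_abbrev), cat_abbrev)
  first <- abb[sub("-.*", "", beta_table$condition)]
  second <- abb[sub(".*-", "", beta_table$condition)]
  roi_cat <- roi_map[beta_table$roi]
  ifelse(roi_cat == first, "cue",
         ifelse(roi_cat == second, "target", "nontarget"))
}

#' Cue/target/nontarget reinstatement scores
#'
#' For the ROI mapped to category X, conditions with X as the first (cue)
#' element contribute to the cue score, X as the second (target) element to
#' the target score, and conditions not containing X to the nontarget score
#' (e.g. the location ROI's nontarget conditions are people-object and
#' object-people). Scores are averaged over conditions within ROI and then
#' over the three ROIs.
#'
#' @param std_table z-standardized beta table (see [zscore_within_roi()]);
#'   conditions must be ordered category pairs like `"loc-obj"`.
#' @param roi_map named character vector, ROI name -> category.
#' @return data.frame per participant with `cue`, `target`, `nontarget`
#'   columns (z units).
#' @export
element_function_scores <- function(std_table, roi_map = default_roi_map()) {
  std_table$element_function <- beta_element_function(std_table, roi_map)
  # mean over conditions within (participant, roi, function), then over ROIs
  agg1 <- stats::aggregate(
    beta ~ participant_id + roi + element_function, std_table, mean)
  agg2 <- stats::aggregate(beta ~ participant_id + element_function,
                           agg1, mean)
  wide <- stats::reshape(agg2, idvar = "participant_id",
                         timevar = "element_function", direction = "wide")
  names(wide) <- sub("^beta\\.", "", names(wide))
  rownames(wide) <- NULL
  wide[, c("participant_id", "cue", "target", "nontarget")]
}

#' Loop-split reinstatement scores and closed-open differences
#'
#' Computes cue/target/nontarget scores separately for closed- and open-loop
#' conditions from a beta table whose rows carry a `loop` column, and the
#' closed minus open difference per element function and participant.
#'
#' @inheritParams element_function_scores
#' @return list with `scores` (per participant x loop) and `differences`
#'   (per participant: `cue`, `target`, `nontarget` closed-open differences).
#' @export
loop_split_scores <- function(std_table, roi_map = default_roi_map()) {
  if (!"loop" %in% names(std_table))
    stop_ld("loop-split scoring requires a `loop` column")
  miss <- stats::aggregate(
    loop ~ participant_id + roi + condition, std_table,
    function(l) length(unique(l)))
  if (any(miss$loop < 2L))
    stop_ld("missing loop cell: every (participant, ROI, condition) needs both closed and open estimates")
  per_loop <- lapply(split(std_table, std_table$loop),
                     element_function_scores, roi_map = roi_map)
  for (l in names(per_loop)) per_loop[[l]]$loop <- l
  scores <- do.call(rbind, per_loop)
  rownames(scores) <- NULL
  cl <- per_loop[["closed"]]; op <- per_loop[["open"]]
  op <- op[match(cl$participant_id, op$participant_id), ]
  differences <- data.frame(participant_id = cl$participant_id,
                            cue = cl$cue - op$cue,
                            target = cl$target - op$target,
                            nontarget = cl$nontarget - op$nontarget,
                            stringsAsFactors = FALSE)
  list(scores = scores, differences = differences)
}

#' One-sample t-tests of closed-open reinstatement differences
#'
#' Tests each element function's closed minus open difference against zero.
#'
#' @param differences the `differences` element of [loop_split_scores()].
#' @return data.frame with `element_function`, `mean`, `t`, `df`, `p`
#'   (two-tailed).
#' @export
one_sample_tests <- function(differences) {
  if (nrow(differences) < 2L)
    stop_ld("group test requires at least 2 participants")
  do.call(rbind, lapply(c("cue", "target", "nontarget"), function(fn) {
    x <- differences[[fn]]
    if (stats::sd(x) == 0) {
      # constant differences: t = 0 / p = 1 when exactly zero, else no test
      zero <- all(x == 0)
      return(data.frame(element_function = fn, mean = mean(x),
                        t = if (zero) 0 else NA_real_,
                        df = length(x) - 1L,
                        p = if (zero) 1 else NA_real_,
                        stringsAsFactors = FALSE))
    }
    tt <- stats::t.test(x, mu = 0)
    data.frame(element_function = fn, mean = mean(x),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, stringsAsFactors = FALSE)
  }))
}

#' ANOVA of overall reinstatement across element functions
#'
#' `mode = "repeated"` fits a one-way repeated-measures ANOVA (participant
#' as blocking factor, error df `2(n-1)`); `mode = "oneway"` treats element
#' functions as independent groups (error df `3n-3`).
#'
#' @param scores output of [element_function_scores()].
#' @param mode `"repeated"` or `"oneway"`.
#' @return list with `F`, `df1`, `df2`, `p`.
#' @export
anova_element_function <- function(scores, mode = c("repeated", "oneway")) {
  mode <- match.arg(mode)
  need <- c("cue", "target", "nontarget")
  if (!all(need %in% names(scores)) || anyNA(scores[need]))
    stop_ld("scores must contain complete cue/target/nontarget columns")
  long <- data.frame(
    participant_id = factor(rep(scores$participant_id, 3)),
    fn = factor(rep(need, each = nrow(scores))),
    score = c(scores$cue, scores$target, scores$nontarget))
  if (mode == "repeated") {
    fit <- stats::aov(score ~ fn + Error(participant_id / fn), data = long)
    tab <- summary(fit)[["Error: participant_id:fn"]][[1]]
  } else {
    fit <- stats::aov(score ~ fn, data = long)
    tab <- summary(fit)[[1]]
  }
  rn <- trimws(rownames(tab))
  Fval <- tab[rn == "fn", "F value"]
  df1 <- tab[rn == "fn", "Df"]
  df2 <- tab[rn == "Residuals", "Df"]
  p <- tab[rn == "fn", "Pr(>F)"]
  scale <- mean(long$score^2) + 1
  if (tab[rn == "fn", "Mean Sq"] < 1e-12 * scale) {
    Fval <- 0; p <- 1  # no between-function variance at all
  }
  list(F = unname(Fval), df1 = unname(df1), df2 = unname(df2),
       p = unname(p))
}
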