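#' Pearson correlation of subfield activity with a behavioural covariate
#'
#' Correlates per-participant closed minus open activity differences (e.g.
#' mean beta difference in right anterior CA3) with a covariate such as the
#' overall nontarget reinstatement score. The p-value derives from
#' `t = r sqrt(n-2) / sqrt(1-r^2)` on `n - 2` degrees of freedom.
#'
#' @param activity,covariate paired numeric vectors (n >= 4, finite).
#' @param tail `"two.sided"` (default) or `"greater"` for a one-tailed test
#'   of positive correlation.
#' @return list with `r`, `r_squared`, `t`, `df`, `p`, `n`.
#' @export
roi_brain_behavior <- function(activity, covariate,
                               tail = c("two.sided", "greater")) {
  tail <- match.arg(tail)
  stopifnot(length(activity) == length(covariate))
  ok <- is.finite(activity) & is.finite(covariate)
  x <- activity[ok]; y <- covariate[ok]
  n <- length(x)
  if (n < 4L) stop_ld("need at least 4 complete pairs, got %d", n)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop_ld("zero variance in activity or covariate")
  r <- stats::cor(x, y)
  t <- r * sqrt(n - 2) / sqrt(1 - r^2)
  p <- if (tail == "two.sided") 2 * stats::pt(-abs(t), n - 2)
       else stats::pt(t, n - 2, lower.tail = FALSE)
  list(r = r, r_squared = r^2, t = t, df = n - 2L, p = min(p, 1), n = n)
}

#' Compare two dependent correlations sharing one variable
#'
#' Meng-Rosenthal-Rubin z-test for whether `cor(x, y1)` exceeds `cor(x, y2)`
#' when both correlations share the variable `x`:
#' \deqn{z = (\hat z_1 - \hat z_2)\sqrt{\frac{n-3}{2(1-r_{12})h}}}
#' with Fisher-transformed correlations \eqn{\hat z}, \eqn{\bar r^2 =
#' (r_{j1}^2 + r_{j2}^2)/2}, \eqn{f = \min\{1, (1-r_{12})/(2(1-\bar
#' r^2))\}} and \eqn{h = (1 - f\bar r^2)/(1-\bar r^2)}. The one-tailed
#' p-value refers to the alternative `cor(x, y1) > cor(x, y2)`; swapping
#' `y1` and `y2` negates `z`.
#'
#' @param x_shared the shared variable.
#' @param y1,y2 the two non-shared variables.
#' @return list of class `loopdep_corcomp`: `r_j1`, `r_j2`, `r_12`, `n`,
#'   `z`, `p` (one-tailed).
#' @export
compare_dependent_correlations <- function(x_shared, y1, y2) {
  n <- length(x_shared)
  stopifnot(length(y1) == n, length(y2) == n)
  if (n < 4L) stop_ld("need at least 4 observations")
  r_j1 <- stats::cor(x_shared, y1)
  r_j2 <- stats::cor(x_shared, y2)
  r_12 <- stats::cor(y1, y2)
  if (any(abs(c(r_j1, r_j2)) >= 1))
    stop_ld("a correlation of +/-1 has an undefined Fisher transform")
  rbar2 <- (r_j1^2 + r_j2^2) / 2
  f <- min(1, (1 - r_12) / (2 * (1 - rbar2)))
  h <- (1 - f * rbar2) / (1 - rbar2)
  z <- (atanh(r_j1) - atanh(r_j2)) *
    sqrt((n - 3) / (2 * (1 - r_12) * h))
  structure(list(r_j1 = r_j1, r_j2 = r_j2, r_12 = r_12, n = n,
                 z = z, p = stats::pnorm(z, lower.tail = FALSE)),
            class = "loopdep_corcomp")
}

#' @export
print.loopdep_corcomp <- function(x, ...) {
  cat(sprintf(
    "<loopdep_corcomp> r_j1=%.3f r_j2=%.3f r_12=%.3f n=%d z=%.3f p(one-tailed)=%.4f\n",
    x$r_j1, x$r_j2, x$r_12, x$n, x$z, x$p))
  invisible(x)
}

#' Voxelwise covariate correlation map with cluster extraction
#'
#' Correlates each voxel's per-participant values (e.g. closed minus open
#' contrast estimates) with a covariate, thresholds the map at an
#' uncorrected cluster-defining p (one-sided positive by default, matching a
#' directional search), and extracts face-connected (6-neighbourhood)
#' suprathreshold clusters.
#'
#' @param volumes 4-D array (x, y, z, participant).
#' @param covariate numeric vector, one value per participant.
#' @param threshold_p cluster-defining p threshold (default 0.005).
#' @param mask optional logical/0-1 3-D array restricting the search.
#' @param k_min minimum cluster extent in voxels (default 1).
#' @param tail `"greater"` (positive correlations, default) or
#'   `"two.sided"`.
#' @return list with `t_map`, `p_map`, `suprathreshold` (logical array) and
#'   `clusters` (data.frame: `cluster`, `k`, peak coordinates, `peak_t`).
#' @export
group_covariate_map <- function(volumes, covariate, threshold_p = 0.005,
                                mask = NULL, k_min = 1L,
                                tail = c("greater", "two.sided")) {
  tail <- match.arg(tail)
  dm <- dim(volumes)
  if (length(dm) != 4L) stop_ld("`volumes` must be a 4-D array")
  n <- dm[4]
  if (length(covariate) != n)
    stop_ld("covariate length (%d) does not match participant dimension (%d)",
            length(covariate), n)
  if (n < 4L) stop_ld("need at least 4 participants")
  if (is.null(mask)) mask <- array(TRUE, dm[1:3])
  mask <- array(as.logical(mask), dm[1:3])
  if (!any(mask)) stop_ld("the mask is empty")

  V <- matrix(volumes, prod(dm[1:3]), n)
  vox <- which(mask)
  Vm <- V[vox, , drop = FALSE]
  xc <- covariate - mean(covariate)
  xs <- sqrt(sum(xc^2))
  Vc <- Vm - rowMeans(Vm)
  num <- as.vector(Vc %*% xc)
  den <- sqrt(rowSums(Vc^2)) * xs
  r <- ifelse(den > 0, num / den, 0)
  r <- pmin(pmax(r, -1), 1)
  tval <- r * sqrt(n - 2) / sqrt(pmax(1 - r^2, .Machine$double.eps))
  p <- if (tail == "greater") stats::pt(tval, n - 2, lower.tail = FALSE)
       else 2 * stats::pt(-abs(tval), n - 2)

  t_map <- array(NA_real_, dm[1:3]); t_map[vox] <- tval
  p_map <- array(NA_real_, dm[1:3]); p_map[vox] <- p
  supra <- array(FALSE, dm[1:3]); supra[vox] <- p < threshold_p

  lab <- label_components(supra)
  clusters <- summarize_clusters(lab, t_map, k_min)
  list(t_map = t_map, p_map = p_map, suprathreshold = supra,
       clusters = clusters)
}

# face-connected (6-neighbourhood) component labelling of a logical 3-D array
label_components <- function(mask) {
  dm <- dim(mask)
  lab <- array(0L, dm)
  nxt <- 0L
  idx <- which(mask)
  if (!length(idx)) return(lab)
  coords <- arrayInd(idx, dm)
  key <- function(co) (co[, 3] - 1L) * dm[1] * dm[2] +
    (co[, 2] - 1L) * dm[1] + co[, 1]
  for (start in idx) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    while (length(queue)) {
      cur <- queue[1L]; queue <- queue[-1L]
      co <- arrayInd(cur, dm)
      for (d in 1:3) {
        for (s in c(-1L, 1L)) {
          nb <- co
          nb[d] <- nb[d] + s
          if (nb[d] < 1L || nb[d] > dm[d]) next
          ni <- key(matrix(nb, 1))
          if (mask[ni] && lab[ni] == 0L) {
            lab[ni] <- nxt
            queue <- c(queue, ni)
          }
        }
      }
    }
  }
  lab
}

summarize_clusters <- function(lab, t_map, k_min = 1L) {
  ids <- setdiff(unique(as.vector(lab)), 0L)
  rows <- lapply(ids, function(id) {
    vox <- which(lab == id)
    if (length(vox) < k_min) return(NULL)
    ts <- t_map[vox]
    peak <- vox[which.max(ts)]
    co <- arrayInd(peak, dim(lab))
    data.frame(cluster = id, k = length(vox),
               peak_x = co[1], peak_y = co[2], peak_z = co[3],
               peak_t = max(ts), stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    return(data.frame(cluster = integer(0), k = integer(0),
                      peak_x = integer(0), peak_y = integer(0),
                      peak_z = integer(0), peak_t = numeric(0)))
  out <- do.call(rbind, rows)
  out[order(-out$k), , drop = FALSE]
}

#' Split a mask at half its longitudinal extent
#'
#' Partitions a binary 3-D mask into an anterior and a posterior part at the
#' plane halfway along the designated axis within the mask's extent. The
#' boundary slice is assigned to the posterior part.
#'
#' @param mask logical/0-1 3-D array.
#' @param axis longitudinal axis (1, 2 or 3; default 3, the z direction).
#' @param anterior_low if `TRUE` (default) the low-index half is labelled
#'   anterior.
#' @return list with logical arrays `anterior` and `posterior` (a disjoint
#'   partition of the input mask).
#' @export
split_mask_longitudinal <- function(mask, axis = 3L, anterior_low = TRUE) {
  dm <- dim(mask)
  if (length(dm) != 3L) stop_ld("`mask` must be a 3-D array")
  m <- array(as.logical(mask), dm)
  if (!any(m)) stop_ld("the mask is empty")
  idx_axis <- apply(m, axis, any)
  slices <- which(idx_axis)
  lo <- min(slices); hi <- max(slices)
  len <- hi - lo + 1L
  if (len < 2L) stop_ld("mask spans a single slice along axis %d", axis)
  cut <- lo + len %/% 2L  # boundary slice -> posterior
  slice_index <- slice.index(m, axis)
  low <- m & slice_index < cut
  high <- m & slice_index >= cut
  if (anterior_low) list(anterior = low, posterior = high)
  else list(anterior = high, posterior = low)
}
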