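#' Canonical double-gamma haemodynamic response function
#'
#' Conventional double-gamma parameterization: peak delay 6 s, undershoot
#' delay 16 s, both dispersions 1, peak:undershoot ratio 6:1, kernel length
#' 32 s. The kernel is normalized to unit peak.
#'
#' @param dt sampling interval in seconds.
#' @param length_s kernel length in seconds.
#' @return numeric kernel sampled at `dt`.
#' @export
canonical_hrf <- function(dt, length_s = 32) {
  stopifnot(dt > 0)
  t <- seq(0, length_s, by = dt)
  h <- stats::dgamma(t, shape = 6, rate = 1) -
    stats::dgamma(t, shape = 16, rate = 1) / 6
  h / max(h)
}

#' Design specification for a first-level GLM
#'
#' @param tr repetition time in seconds.
#' @param n_scans number of volumes.
#' @param conditions named list; each entry a list with numeric `onsets` and
#'   `durations` (seconds, recycled).
#' @param motion optional n_scans x 6 matrix of motion parameters.
#' @param isi optional list with `onsets`/`durations` for an interstimulus
#'   interval regressor.
#' @param outlier_scans integer indices (1-based) of scans to receive unit
#'   indicator regressors.
#' @param intercept include an intercept column (default TRUE).
#' @return list of class `loopdep_design_spec`.
#' @export
design_spec <- function(tr, n_scans, conditions, motion = NULL, isi = NULL,
                        outlier_scans = integer(0), intercept = TRUE) {
  stopifnot(tr > 0, n_scans >= 1)
  dur <- n_scans * tr
  for (nm in names(conditions)) {
    co <- conditions[[nm]]
    if (any(co$onsets + co$durations > dur))
      stop_ld("condition '%s' extends beyond the scan duration (%g s)",
              nm, dur)
  }
  if (!is.null(motion)) {
    motion <- as.matrix(motion)
    if (nrow(motion) != n_scans || ncol(motion) != 6L)
      stop_ld("motion must be an n_scans x 6 matrix")
  }
  structure(list(tr = tr, n_scans = as.integer(n_scans),
                 conditions = conditions, motion = motion, isi = isi,
                 outlier_scans = as.integer(outlier_scans),
                 intercept = isTRUE(intercept)),
            class = "loopdep_design_spec")
}

# boxcar sampled on a fine grid, convolved with the HRF, resampled at scan
# onsets
convolved_regressor <- function(onsets, durations, tr, n_scans, dt = 0.1) {
  durations <- rep_len(durations, length(onsets))
  grid_len <- ceiling(n_scans * tr / dt) + 1L
  box <- numeric(grid_len)
  tg <- (seq_len(grid_len) - 1L) * dt
  for (i in seq_along(onsets)) {
    on <- onsets[i]; off <- onsets[i] + durations[i]
    box[tg >= on & tg < off] <- 1
  }
  h <- canonical_hrf(dt)
  conv <- stats::convolve(box, rev(h), type = "open")[seq_len(grid_len)]
  scan_t <- (seq_len(n_scans) - 1L) * tr
  conv[pmin(grid_len, floor(scan_t / dt) + 1L)]
}

#' Build a first-level design matrix
#'
#' Condition columns are stimulus boxcars convolved with the canonical HRF
#' and sampled at scan onsets; nuisance columns (ISI regressor, six motion
#' parameters, one unit indicator per flagged outlier scan) and an intercept
#' follow.
#'
#' @param spec a [design_spec()].
#' @param dt fine-grid sampling interval used for the convolution (seconds).
#' @return numeric matrix (n_scans x p) with named columns.
#' @export
build_design_matrix <- function(spec, dt = 0.1) {
  stopifnot(inherits(spec, "loopdep_design_spec"))
  cols <- list()
  for (nm in names(spec$conditions)) {
    co <- spec$conditions[[nm]]
    cols[[nm]] <- convolved_regressor(co$onsets, co$durations, spec$tr,
                                      spec$n_scans, dt)
  }
  if (!is.null(spec$isi))
    cols[["isi"]] <- convolved_regressor(spec$isi$onsets, spec$isi$durations,
                                         spec$tr, spec$n_scans, dt)
  if (!is.null(spec$motion)) {
    m <- spec$motion
    colnames(m) <- paste0("motion", 1:6)
    for (j in 1:6) cols[[colnames(m)[j]]] <- m[, j]
  }
  for (k in spec$outlier_scans) {
    col <- numeric(spec$n_scans); col[k] <- 1
    cols[[sprintf("outlier_scan%03d", k)]] <- col
  }
  if (spec$intercept) cols[["intercept"]] <- rep(1, spec$n_scans)
  X <- do.call(cbind, cols)
  if (qr(X)$rank < ncol(X))
    warning("design matrix is rank deficient; fits use the pseudo-inverse")
  X
}

#' Fit an ordinary-least-squares GLM to voxel time series
#'
#' @param Y n_scans x V matrix (or vector) of signals.
#' @param X design matrix.
#' @return list of class `loopdep_glm_fit` with `betas` (p x V),
#'   `sigma2` (residual variance per voxel), `dof`, `XtXinv` and the design.
#' @export
fit_glm <- function(Y, X) {
  Y <- as.matrix(Y); X <- as.matrix(X)
  if (nrow(Y) != nrow(X))
    stop_ld("dimension mismatch: Y has %d rows, X has %d", nrow(Y), nrow(X))
  qx <- qr(X)
  rank <- qx$rank
  if (rank < ncol(X)) {
    XtXinv <- mp_pinv(crossprod(X))
    betas <- XtXinv %*% crossprod(X, Y)
  } else {
    betas <- qr.coef(qx, Y)
    XtXinv <- chol2inv(qr.R(qx))
  }
  resid <- Y - X %*% betas
  dof <- nrow(X) - rank
  sigma2 <- colSums(resid^2) / max(dof, 1L)
  rownames(betas) <- colnames(X)
  structure(list(betas = betas, sigma2 = sigma2, dof = dof,
                 XtXinv = XtXinv, rank = rank, X = X),
            class = "loopdep_glm_fit")
}

# Moore-Penrose pseudo-inverse of a symmetric matrix
mp_pinv <- function(A, tol = 1e-10) {
  e <- eigen(A, symmetric = TRUE)
  pos <- e$values > tol * max(e$values)
  e$vectors[, pos, drop = FALSE] %*%
    (t(e$vectors[, pos, drop = FALSE]) / e$values[pos])
}

#' Linear contrast of GLM parameter estimates
#'
#' @param fit a [fit_glm()] result.
#' @param weights numeric contrast vector (length p) or named vector matched
#'   to design columns (unnamed columns get weight 0).
#' @return list with per-voxel `value` (`c'beta`), `t` statistic and `dof`.
#' @export
contrast <- function(fit, weights) {
  stopifnot(inherits(fit, "loopdep_glm_fit"))
  p <- nrow(fit$betas)
  if (!is.null(names(weights))) {
    w <- numeric(p); names(w) <- rownames(fit$betas)
    missing <- setdiff(names(weights), names(w))
    if (length(missing))
      stop_ld("unknown design column(s): %s", paste(missing, collapse = ", "))
    w[names(weights)] <- weights
  } else {
    if (length(weights) != p)
      stop_ld("contrast weights must have length %d", p)
    w <- as.numeric(weights)
  }
  if (all(w == 0)) stop_ld("contrast weights are all zero")
  value <- drop(crossprod(w, fit$betas))
  se <- sqrt(fit$sigma2 * drop(crossprod(w, fit$XtXinv %*% w)))
  list(value = value, t = value / se, dof = fit$dof)
}

#' Category contrast weights
#'
#' Contrasts conditions containing a category against those that do not,
#' e.g. location = (location-object, object-location, location-people,
#' people-location) minus (object-people, people-object). Weights sum to 0.
#'
#' @param condition_names character vector of ordered-pair condition names
#'   (e.g. `"loc-obj"`).
#' @param category merged category (`"location"`, `"people"`, `"object"`).
#' @return named numeric contrast vector over `condition_names`.
#' @export
category_contrast <- function(condition_names, category) {
  abb <- cat_abbrev[[category]]
  if (is.null(abb)) stop_ld("unknown category '%s'", category)
  has <- grepl(abb, condition_names, fixed = TRUE)
  if (!any(has) || all(has))
    stop_ld("category '%s' must appear in some but not all conditions",
            category)
  w <- ifelse(has, 1 / sum(has), -1 / sum(!has))
  stats::setNames(w, condition_names)
}

#' ART-style scan-outlier detection
#'
#' A scan is flagged if the frame-to-frame displacement exceeds
#' `motion_threshold` (mm) or the global-signal z-score exceeds
#' `global_threshold` in absolute value. Displacement is the maximum over
#' the six motion parameters of the absolute between-scan difference, with
#' rotations (radians) converted to arc length at a 65 mm head radius.
#'
#' @param motion n_scans x 6 matrix (3 translations in mm, 3 rotations in
#'   radians), or an n_scans vector of precomputed displacements.
#' @param global_signal numeric vector of per-scan global signal.
#' @param motion_threshold displacement threshold in mm (default 2).
#' @param global_threshold global-signal z threshold (default 9).
#' @param head_radius_mm rotation-to-arc conversion radius.
#' @return list of class `loopdep_outlier_report`: `flagged_scans`,
#'   `fraction_flagged`, thresholds and the displacement trace.
#' @export
detect_outliers <- function(motion, global_signal = NULL,
                            motion_threshold = 2, global_threshold = 9,
                            head_radius_mm = 65) {
  if (is.matrix(motion)) {
    if (ncol(motion) != 6L) stop_ld("motion matrix must have 6 columns")
    m <- motion
    m[, 4:6] <- m[, 4:6] * head_radius_mm
    d <- rbind(0, abs(diff(m)))
    displacement <- apply(d, 1, max)
  } else {
    displacement <- as.numeric(motion)
  }
  n <- length(displacement)
  flagged <- displacement > motion_threshold
  if (!is.null(global_signal)) {
    if (length(global_signal) != n)
      stop_ld("global_signal length (%d) does not match motion length (%d)",
              length(global_signal), n)
    s <- stats::sd(global_signal)
    z <- if (s == 0) rep(0, n) else
      (global_signal - mean(global_signal)) / s
    flagged <- flagged | abs(z) > global_threshold
  }
  structure(list(flagged_scans = which(flagged),
                 fraction_flagged = mean(flagged),
                 n_scans = n,
                 motion_threshold = motion_threshold,
                 global_threshold = global_threshold,
                 displacement = displacement),
            class = "loopdep_outlier_report")
}

#' Participant exclusion by outlier burden
#'
#' Participants whose fraction of flagged scans strictly exceeds
#' `max_fraction` (default 10%) are excluded; exactly 10% is kept.
#'
#' @param reports named list of `loopdep_outlier_report`s.
#' @param max_fraction exclusion boundary.
#' @return character vector of kept participant names.
#' @export
apply_exclusion <- function(reports, max_fraction = 0.10) {
  frac <- vapply(reports, function(r) r$fraction_flagged, numeric(1))
  names(frac)[frac <= max_fraction]
}
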