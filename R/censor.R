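#' Build a censor mask from a motion metric trace
#'
#' Frame i is removed iff the metric strictly exceeds `threshold`; frames at
#' exactly the threshold are retained. Frame 1 is never removed by the metric
#' alone (the metric is 0 there by definition), though `extend_before` can
#' remove it when frame 2 is censored.
#'
#' @param metric_trace an [fd_trace()] or a `dvars_trace`.
#' @param threshold censoring threshold (mm for FD; dimensionless for sDVARS).
#' @param extend_before also remove the frame immediately preceding each
#'   suprathreshold frame (the displacement is a property of the transition).
#' @return a [censor_mask()].
#' @export
make_censor_mask <- function(metric_trace, threshold, extend_before = FALSE) {
  if (inherits(metric_trace, "fd_trace")) {
    v <- metric_trace$fd; metric <- "fd"
  } else if (inherits(metric_trace, "dvars_trace")) {
    v <- metric_trace$sdvars; metric <- "sdvars"
  } else stopf("metric_trace must be an fd_trace or dvars_trace")
  rem <- v > threshold
  if (extend_before) {
    prev <- which(rem) - 1L
    rem[prev[prev >= 1L]] <- TRUE
  }
  censor_mask(!rem, threshold, metric)
}

#' Combine two censor masks (frame kept only if kept by both)
#' @param m1,m2 [censor_mask()] objects of equal length.
#' @return a [censor_mask()] with metric `"fd_and_sdvars"`; the stored
#'   threshold is `m1`'s.
#' @export
combine_censor_masks <- function(m1, m2) {
  if (length(m1$keep) != length(m2$keep)) stopf("mask lengths differ")
  censor_mask(m1$keep & m2$keep, m1$threshold, "fd_and_sdvars")
}

#' Motion regressor sets (6 / 12 / 24 / 36)
#'
#' Builds the standard expansions of the six rigid-body parameters R
#' (rotations pre-converted to mm via `radius_mm`):
#' 6 = \[R\]; 12 = \[R, R'\] with R' the backward difference (first row 0);
#' 24 = \[R, R^2, R_(t-1), R_(t-1)^2\] (Volterra expansion); 36 additionally
#' \[R_(t-2), R_(t-2)^2\]. Lagged columns are zero-padded at the start so the
#' matrix stays row-aligned with the data for censoring.
#'
#' @param motion a [motion_trace()].
#' @param motion_set one of 6, 12, 24, 36.
#' @param radius_mm radius for rotation-to-mm conversion.
#' @return numeric matrix frames x motion_set with descriptive column names.
#' @export
build_motion_regressors <- function(motion, motion_set = 12, radius_mm = 35) {
  if (!motion_set %in% c(6, 12, 24, 36)) stopf("motion_set must be 6, 12, 24 or 36")
  if (motion$frames < 3) stopf("need >= 3 frames for motion regressors")
  R <- motion$params
  R[, 4:6] <- R[, 4:6] * radius_mm
  colnames(R) <- c("tx", "ty", "tz", "rx", "ry", "rz")
  n <- nrow(R)
  lag_mat <- function(m, k) rbind(matrix(0, k, ncol(m)), m[seq_len(n - k), , drop = FALSE])
  out <- R
  if (motion_set == 12) {
    d <- rbind(0, diff(R))
    colnames(d) <- paste0("d_", colnames(R))
    out <- cbind(R, d)
  } else if (motion_set >= 24) {
    R2 <- R^2; colnames(R2) <- paste0(colnames(R), "_sq")
    L1 <- lag_mat(R, 1L); colnames(L1) <- paste0(colnames(R), "_lag1")
    L1s <- L1^2; colnames(L1s) <- paste0(colnames(R), "_lag1_sq")
    out <- cbind(R, R2, L1, L1s)
    if (motion_set == 36) {
      L2 <- lag_mat(R, 2L); colnames(L2) <- paste0(colnames(R), "_lag2")
      L2s <- L2^2; colnames(L2s) <- paste0(colnames(R), "_lag2_sq")
      out <- cbind(out, L2, L2s)
    }
  }
  out
}

#' Tissue principal-component time courses
#'
#' First `n_pcs` principal components of tissue (white-matter / ventricle)
#' signals, columns centered first, each component scaled to unit variance.
#'
#' @param signals frames x m matrix of tissue-voxel or tissue-ROI signals.
#' @param n_pcs number of components (default 3, the conventional choice).
#' @return frames x n_pcs matrix, columns `tissue_pc1 ...`.
#' @export
tissue_pcs <- function(signals, n_pcs = 3) {
  signals <- as.matrix(signals)
  if (ncol(signals) < n_pcs) stopf("need at least n_pcs = %d tissue columns", n_pcs)
  if (nrow(signals) <= n_pcs) stopf("need more frames than components")
  pc <- prcomp(signals, center = TRUE, scale. = FALSE)
  if (sum(pc$sdev > max(pc$sdev) * 1e-10) < n_pcs)
    stopf("tissue signals have rank < %d; cannot extract PCs", n_pcs)
  scores <- pc$x[, seq_len(n_pcs), drop = FALSE]
  scores <- sweep(scores, 2, apply(scores, 2, sd), "/")
  colnames(scores) <- paste0("tissue_pc", seq_len(n_pcs))
  scores
}

#' Spectral basis implementing band-pass-by-regression
#'
#' Sine/cosine pairs at every DFT frequency of the original frame grid that
#' falls strictly outside `band_hz`, plus a linear trend. Regressing these
#' out on retained frames implements band-pass filtering jointly with
#' censoring, with no interpolation and no leakage from censored frames.
#'
#' @param frames number of frames N.
#' @param tr_seconds repetition time (s); DFT frequencies are k/(N*tr).
#' @param band_hz `c(low, high)` pass band in Hz (default 0.01-0.1).
#' @return matrix frames x k with named columns (`trend`, `cos_k`, `sin_k`).
#' @export
spectral_basis <- function(frames, tr_seconds, band_hz = c(0.01, 0.1)) {
  nyq <- 1 / (2 * tr_seconds)
  if (band_hz[1] < 0 || band_hz[2] <= band_hz[1] || band_hz[2] > nyq + 1e-12)
    stopf("band must satisfy 0 <= low < high <= Nyquist = %g Hz", nyq)
  t_idx <- seq_len(frames) - 1
  trend <- scale(t_idx, center = TRUE, scale = TRUE)[, 1]
  cols <- list(trend = trend)
  kmax <- floor(frames / 2)
  for (k in seq_len(kmax)) {
    f <- k / (frames * tr_seconds)
    if (f >= band_hz[1] && f <= band_hz[2]) next
    cols[[paste0("cos_", k)]] <- cos(2 * pi * k * t_idx / frames)
    if (k < frames / 2)  # at Nyquist (even N) the sine column is identically 0
      cols[[paste0("sin_", k)]] <- sin(2 * pi * k * t_idx / frames)
  }
  do.call(cbind, cols)
}

#' Assemble a full nuisance design
#'
#' Intercept + spectral basis (trend and out-of-band sin/cos columns) + motion
#' regressor set + tissue PCs. Constant or zero columns other than the
#' intercept are dropped (with their labels recorded) so the design satisfies
#' its rank contract on degenerate traces.
#'
#' @param motion a [motion_trace()].
#' @param motion_set 6, 12, 24 or 36.
#' @param tissue_signals optional frames x m tissue signal matrix.
#' @param n_tissue_pcs PCs to extract from `tissue_signals` (default 3).
#' @param band_hz pass band (Hz).
#' @param radius_mm rotation-to-mm radius.
#' @return object of class `nuisance_design` with `matrix`, `column_labels`,
#'   `motion_set`, `n_tissue_pcs`, `band_hz`, `dropped`.
#' @export
build_nuisance_design <- function(motion, motion_set = 12, tissue_signals = NULL,
                                  n_tissue_pcs = 3, band_hz = c(0.01, 0.1),
                                  radius_mm = 35) {
  n <- motion$frames
  spec <- spectral_basis(n, motion$tr_seconds, band_hz)
  mreg <- build_motion_regressors(motion, motion_set, radius_mm)
  tpcs <- NULL
  if (!is.null(tissue_signals)) {
    tpcs <- tissue_pcs(tissue_signals, n_tissue_pcs)
  } else n_tissue_pcs <- 0
  X <- cbind(intercept = rep(1, n), spec, mreg, tpcs)
  keep <- c(TRUE, apply(X[, -1, drop = FALSE], 2, function(col) sd(col) > 1e-12))
  dropped <- colnames(X)[!keep]
  if (length(dropped)) log_info("design: dropped constant columns: %s", paste(dropped, collapse = ", "))
  X <- X[, keep, drop = FALSE]
  structure(list(matrix = X, column_labels = colnames(X), motion_set = motion_set,
                 n_tissue_pcs = n_tissue_pcs, band_hz = band_hz, dropped = dropped),
            class = "nuisance_design")
}

#' Simultaneous censoring + nuisance regression + band-pass
#'
#' Restricts both the data and the design (built on the original frame grid)
#' to retained frames and fits ordinary least squares per ROI. Because
#' censored rows never enter the fit, high-motion frames cannot leak into the
#' residuals of neighboring frames — the point of the one-step formulation.
#'
#' @param ts a [roi_timeseries()].
#' @param design a [build_nuisance_design()] result (rows = `ts` frames).
#' @param mask optional [censor_mask()]; `NULL` keeps all frames.
#' @return object of class `clean_series` with `data` (retained x n_roi
#'   residuals), `retained_index`, `dof` (retained frames minus design rank),
#'   `roi_ids`, `tr_seconds`.
#' @export
clean_timeseries <- function(ts, design, mask = NULL) {
  if (!inherits(ts, "roi_timeseries")) stopf("clean_timeseries expects a roi_timeseries")
  X <- design$matrix
  if (nrow(X) != nrow(ts$data)) stopf("design rows (%d) != frames (%d)", nrow(X), nrow(ts$data))
  keep <- if (is.null(mask)) rep(TRUE, nrow(X)) else mask$keep
  if (length(keep) != nrow(X)) stopf("mask length != frames")
  idx <- which(keep)
  Xr <- X[idx, , drop = FALSE]
  qrX <- qr(Xr)
  rk <- qrX$rank
  if (length(idx) <= rk)
    stopf("rank deficiency: %d retained frames <= design rank %d (dof deficit %d)",
          length(idx), rk, rk - length(idx) + 1, class = "motionscrub_dof_error")
  resid <- qr.resid(qrX, ts$data[idx, , drop = FALSE])
  structure(list(data = resid, retained_index = idx, dof = length(idx) - rk,
                 design_rank = rk, roi_ids = ts$roi_ids, tr_seconds = ts$tr_seconds,
                 column_labels = design$column_labels),
            class = "clean_series")
}

#' Clean a volume series (voxel-level wrapper around [clean_timeseries()])
#'
#' @param vols a [volume_series()].
#' @param design a nuisance design with rows = frames.
#' @param mask optional [censor_mask()].
#' @return a [volume_series()] holding residuals on retained frames, with the
#'   original masks; `retained_index` and `dof` attached as attributes.
#' @export
clean_volumes <- function(vols, design, mask = NULL) {
  nt <- vols$frames
  mat <- matrix(vols$data, ncol = nt)              # voxels x frames
  ts <- roi_timeseries(t(mat), roi_ids = paste0("v", seq_len(nrow(mat))),
                       tr_seconds = vols$tr_seconds)
  cl <- clean_timeseries(ts, design, mask)
  arr <- array(t(cl$data), dim = c(dim(vols$data)[1:3], nrow(cl$data)))
  out <- volume_series(arr, masks = vols$masks, affine = vols$affine,
                       tr_seconds = vols$tr_seconds)
  attr(out, "retained_index") <- cl$retained_index
  attr(out, "dof") <- cl$dof
  out
}
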