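#' Framewise displacement
#'
#' FD at frame i is the sum of absolute backward differences of the three
#' translations plus the three rotations converted from radians to mm as arc
#' length on a sphere of radius `radius_mm`:
#' \deqn{FD_i = |\Delta d_{ix}| + |\Delta d_{iy}| + |\Delta d_{iz}| +
#'   r\,(|\Delta\phi_i| + |\Delta\theta_i| + |\Delta\psi_i|)}
#' with \eqn{FD_0 = 0} (the first frame has no predecessor).
#'
#' @param motion a [motion_trace()].
#' @param radius_mm assumed brain radius in mm (default 35, a typical
#'   late-gestation fetal head; configurable per scan).
#' @return an [fd_trace()].
#' @export
compute_fd <- function(motion, radius_mm = 35) {
  if (!inherits(motion, "motion_trace")) stopf("compute_fd expects a motion_trace")
  if (!is_scalar_num(radius_mm) || radius_mm <= 0) stopf("radius_mm must be positive")
  d <- abs(diff(motion$params))
  fd <- c(0, d[, 1] + d[, 2] + d[, 3] + radius_mm * (d[, 4] + d[, 5] + d[, 6]))
  fd_trace(fd, radius_mm)
}

#' Scaled DVARS
#'
#' Per frame t >= 2, the root-mean-square over mask voxels of the temporal
#' difference I_t - I_(t-1), divided by the grand mean intensity of the mask
#' voxels over all frames (so the measure is scale-free and comparable across
#' scans). Frame 1 is defined as 0.
#'
#' @param vols a [volume_series()] with the named mask present.
#' @param mask_name which mask to use (default `"gray_matter"`).
#' @return list of class `dvars_trace` with `sdvars` and `mask_name`.
#' @export
compute_sdvars <- function(vols, mask_name = "gray_matter") {
  if (!inherits(vols, "volume_series")) stopf("compute_sdvars expects a volume_series")
  m <- vols$masks[[mask_name]]
  if (is.null(m)) stopf("mask '%s' not present in volume series", mask_name)
  if (!any(m)) stopf("mask '%s' is empty", mask_name)
  nt <- vols$frames
  mat <- matrix(vols$data, ncol = nt)[as.vector(m), , drop = FALSE]  # voxels x frames
  gmean <- mean(mat)
  if (abs(gmean) < .Machine$double.eps * 1e3) stopf("grand mean intensity is zero; cannot scale DVARS")
  dmat <- mat[, -1, drop = FALSE] - mat[, -nt, drop = FALSE]
  sdv <- c(0, sqrt(colMeans(dmat^2)) / gmean)
  structure(list(sdvars = sdv, mask_name = mask_name), class = "dvars_trace")
}

#' Temporal signal-to-noise ratio map
#'
#' Voxelwise temporal mean divided by temporal standard deviation (sample SD,
#' n-1 denominator), averaged within the brain mask for a scan-quality scalar.
#' Zero-SD voxels are excluded from the average and counted.
#'
#' @param vols a [volume_series()] with a `brain` mask.
#' @return list of class `tsnr_map` with `voxel_tsnr` (3-D array, NA outside
#'   brain/degenerate voxels), `mean_tsnr`, `n_excluded`.
#' @export
compute_tsnr <- function(vols) {
  if (!inherits(vols, "volume_series")) stopf("compute_tsnr expects a volume_series")
  if (vols$frames < 3) stopf("need frames >= 3 for tSNR")
  m <- vols$masks[["brain"]]
  if (is.null(m)) stopf("brain mask not present")
  nt <- vols$frames
  mat <- matrix(vols$data, ncol = nt)
  mu <- rowMeans(mat)
  sdv <- sqrt(rowSums((mat - mu)^2) / (nt - 1))
  tsnr <- rep(NA_real_, length(mu))
  ok <- sdv > 0
  tsnr[ok] <- mu[ok] / sdv[ok]
  vox <- array(tsnr, dim = dim(vols$data)[1:3])
  vox[!m] <- NA_real_
  inmask <- tsnr[as.vector(m)]
  n_excl <- sum(!is.finite(inmask))
  vals <- inmask[is.finite(inmask)]
  if (length(vals) == 0) stopf("no voxel with positive temporal SD inside brain mask")
  structure(list(voxel_tsnr = vox, mean_tsnr = mean(vals), n_excluded = n_excl),
            class = "tsnr_map")
}

#' Post-censoring motion summary
#'
#' Mean/max FD over retained frames and the lengths of contiguous retained
#' runs. By default the original FD values of retained frames are reused (the
#' literal reading of "mean FD across the preserved volumes"); with
#' `recompute_gaps = TRUE` and the original motion trace supplied,
#' displacements are recomputed between newly adjacent retained frames.
#'
#' @param fd an [fd_trace()].
#' @param mask a [censor_mask()] of the same length.
#' @param recompute_gaps recompute FD across censoring gaps (needs `motion`).
#' @param motion the originating [motion_trace()] (only for `recompute_gaps`).
#' @return a [motion_summary()].
#' @export
summarize_motion <- function(fd, mask, recompute_gaps = FALSE, motion = NULL) {
  if (length(fd$fd) != length(mask$keep)) stopf("fd and mask lengths differ")
  keep <- mask$keep
  if (!any(keep))
    stopf("all frames censored; scan must be excluded", class = "motionscrub_all_censored")
  if (recompute_gaps) {
    if (is.null(motion)) stopf("recompute_gaps = TRUE requires the motion trace")
    idx <- which(keep)
    p <- motion$params[idx, , drop = FALSE]
    d <- abs(diff(p))
    vals <- c(0, rowSums(d[, 1:3, drop = FALSE]) + fd$radius_mm * rowSums(d[, 4:6, drop = FALSE]))
  } else {
    vals <- fd$fd[keep]
  }
  r <- rle(keep)
  chunks <- r$lengths[r$values]
  motion_summary(fd_ave = mean(vals), fd_max = max(vals),
                 n_retained = sum(keep), chunks = chunks)
}

#' FD vs sDVARS concordance curve
#'
#' Treating `FD > fd_ref` as the positive (high-motion) class, computes
#' sensitivity and specificity of `sdvars > s` over a grid of sDVARS
#' thresholds. Frame 1 is excluded (both metrics are defined 0 there).
#'
#' @param fd an [fd_trace()].
#' @param dv a `dvars_trace` from [compute_sdvars()].
#' @param fd_ref reference FD threshold in mm (default 1.5).
#' @param sdvars_grid grid of sDVARS thresholds.
#' @return data.frame of class `concordance_curve` with columns
#'   `threshold`, `sensitivity`, `specificity`; sensitivity is `NA` when no
#'   frame exceeds `fd_ref`.
#' @export
fd_sdvars_concordance <- function(fd, dv, fd_ref = 1.5,
                                  sdvars_grid = seq(0.01, 0.5, by = 0.01)) {
  if (length(fd$fd) != length(dv$sdvars)) stopf("fd and sdvars lengths differ")
  f <- fd$fd[-1]
  s <- dv$sdvars[-1]
  pos <- f > fd_ref
  out <- data.frame(threshold = sdvars_grid,
                    sensitivity = NA_real_, specificity = NA_real_)
  for (k in seq_along(sdvars_grid)) {
    th <- sdvars_grid[k]
    if (any(pos)) out$sensitivity[k] <- mean(s[pos] > th)
    if (any(!pos)) out$specificity[k] <- mean(s[!pos] <= th)
  }
  class(out) <- c("concordance_curve", "data.frame")
  out
}
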