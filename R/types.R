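#' Rigid-body motion trace
#'
#' Per-frame 6-parameter rigid head motion: three translations (mm) and three
#' rotations (radians), one row per acquired volume. The raw input to all
#' motion metrics.
#'
#' @param params numeric matrix, frames x 6, columns in the order
#'   `dx, dy, dz, phi, theta, psi` (translations mm, rotations rad).
#' @param tr_seconds repetition time in seconds (> 0).
#' @return an object of class `motion_trace` with elements `params`, `frames`,
#'   `tr_seconds`.
#' @export
motion_trace <- function(params, tr_seconds) {
  params <- as.matrix(params)
  if (ncol(params) != 6) stopf("motion trace needs 6 columns, got %d", ncol(params))
  if (nrow(params) < 2) stopf("motion trace needs >= 2 frames, got %d", nrow(params))
  if (!all(is.finite(params))) stopf("motion trace contains non-finite values")
  if (!is_scalar_num(tr_seconds) || tr_seconds <= 0) stopf("tr_seconds must be a positive number")
  colnames(params) <- c("dx", "dy", "dz", "phi", "theta", "psi")
  structure(list(params = params, frames = nrow(params), tr_seconds = tr_seconds),
            class = "motion_trace")
}

#' @export
print.motion_trace <- function(x, ...) {
  cat(sprintf("<motion_trace> %d frames, TR = %gs\n", x$frames, x$tr_seconds))
  invisible(x)
}

#' Framewise-displacement trace
#'
#' @param fd per-frame FD in mm; `fd[1]` must be 0 (no predecessor frame).
#' @param radius_mm brain radius used to convert rotations to mm.
#' @return object of class `fd_trace`.
#' @seealso [compute_fd()]
#' @export
fd_trace <- function(fd, radius_mm) {
  fd <- as.numeric(fd)
  if (length(fd) < 2) stopf("fd trace needs >= 2 frames")
  if (!all(is.finite(fd)) || any(fd < 0)) stopf("fd values must be finite and >= 0")
  if (fd[1] != 0) stopf("fd[1] must be 0 by definition")
  if (!is_scalar_num(radius_mm) || radius_mm <= 0) stopf("radius_mm must be positive")
  structure(list(fd = fd, radius_mm = radius_mm), class = "fd_trace")
}

#' Frame-retention (censor) mask
#'
#' @param keep logical vector, one entry per frame; TRUE = frame retained.
#' @param threshold threshold applied to the metric (mm for FD, dimensionless
#'   for sDVARS).
#' @param metric which metric produced the mask: `"fd"`, `"sdvars"` or
#'   `"fd_and_sdvars"`.
#' @return object of class `censor_mask`.
#' @export
censor_mask <- function(keep, threshold, metric = c("fd", "sdvars", "fd_and_sdvars")) {
  metric <- match.arg(metric)
  keep <- as.logical(keep)
  if (anyNA(keep)) stopf("censor mask contains NA")
  if (!(is.numeric(threshold) && length(threshold) == 1 && !is.na(threshold) &&
        threshold > 0)) stopf("threshold must be positive")  # Inf = no censoring
  structure(list(keep = keep, threshold = threshold, metric = metric),
            class = "censor_mask")
}

#' Post-censoring motion summary
#'
#' Mean and maximum FD over retained frames plus the lengths of contiguous
#' retained runs ("chunks"), the quantities a censoring study reports per scan.
#'
#' @param fd_ave,fd_max mean/max FD over retained frames (mm).
#' @param n_retained number of retained frames.
#' @param chunks integer vector of maximal retained-run lengths.
#' @return object of class `motion_summary`.
#' @export
motion_summary <- function(fd_ave, fd_max, n_retained, chunks) {
  if (fd_max < fd_ave || fd_ave < 0) stopf("need fd_max >= fd_ave >= 0")
  if (sum(chunks) != n_retained) stopf("sum(chunks) must equal n_retained")
  structure(list(fd_ave = fd_ave, fd_max = fd_max,
                 n_retained = as.integer(n_retained), chunks = as.integer(chunks)),
            class = "motion_summary")
}

#' ROI BOLD time-series container
#'
#' @param data numeric matrix frames x n_roi, no missing values.
#' @param roi_ids region labels (defaults to column names or `roi_1 ...`).
#' @param tr_seconds repetition time (s).
#' @return object of class `roi_timeseries`.
#' @export
roi_timeseries <- function(data, roi_ids = NULL, tr_seconds) {
  data <- as.matrix(data)
  if (anyNA(data) || !all(is.finite(data))) stopf("ROI time series contains missing/non-finite values")
  if (ncol(data) < 2) stopf("need n_roi >= 2")
  if (nrow(data) < 2) stopf("need frames >= 2")
  if (is.null(roi_ids)) roi_ids <- colnames(data)
  if (is.null(roi_ids)) roi_ids <- paste0("roi_", seq_len(ncol(data)))
  if (length(roi_ids) != ncol(data)) stopf("roi_ids length mismatch")
  if (!is_scalar_num(tr_seconds) || tr_seconds <= 0) stopf("tr_seconds must be positive")
  colnames(data) <- roi_ids
  structure(list(data = data, roi_ids = roi_ids, tr_seconds = tr_seconds),
            class = "roi_timeseries")
}

#' 4-D volume series with tissue masks
#'
#' @param data 4-D numeric array (x, y, z, frames).
#' @param masks named list of logical 3-D arrays on the same grid; conventional
#'   names: `brain`, `gray_matter`, `white_matter`, `ventricles`.
#' @param affine 4x4 voxel-to-mm map (defaults to identity).
#' @param tr_seconds repetition time (s).
#' @return object of class `volume_series`.
#' @export
volume_series <- function(data, masks = list(), affine = diag(4), tr_seconds = 3) {
  if (length(dim(data)) != 4) stopf("data must be a 4-D array")
  if (dim(data)[4] < 2) stopf("need frames >= 2")
  sp <- dim(data)[1:3]
  for (nm in names(masks)) {
    m <- masks[[nm]]
    if (!identical(dim(m), as.integer(sp)) && !identical(dim(m), sp))
      stopf("mask '%s' grid %s does not match image grid %s",
            nm, paste(dim(m), collapse = "x"), paste(sp, collapse = "x"))
    masks[[nm]] <- array(as.logical(m), dim = sp)
  }
  if (!identical(dim(affine), c(4L, 4L))) stopf("affine must be 4x4")
  structure(list(data = data, masks = masks, affine = affine, tr_seconds = tr_seconds,
                 frames = dim(data)[4]),
            class = "volume_series")
}

#' Per-scan metadata table
#'
#' @param scan_id,subject_id character identifiers.
#' @param ga_weeks gestational age (weeks).
#' @param sex `"M"` or `"F"`.
#' @param ga_range plausible GA window used for validation.
#' @return a `data.frame` with class `scan_records`.
#' @export
scan_records <- function(scan_id, ga_weeks, sex, subject_id = scan_id,
                         ga_range = c(18, 42)) {
  sex <- as.character(sex)
  if (!all(sex %in% c("M", "F"))) stopf("sex must be 'M' or 'F'")
  if (any(ga_weeks < ga_range[1] | ga_weeks > ga_range[2]))
    stopf("ga_weeks outside plausible range [%g, %g]", ga_range[1], ga_range[2])
  out <- data.frame(scan_id = as.character(scan_id), ga_weeks = as.numeric(ga_weeks),
                    sex = sex, subject_id = as.character(subject_id),
                    stringsAsFactors = FALSE)
  class(out) <- c("scan_records", "data.frame")
  out
}

#' ROI centroid geometry
#'
#' @param centroids n_roi x 3 matrix of centroid coordinates in mm.
#' @return object of class `roi_geometry`.
#' @export
roi_geometry <- function(centroids) {
  centroids <- as.matrix(centroids)
  if (ncol(centroids) != 3) stopf("centroids must have 3 columns (x, y, z mm)")
  if (!all(is.finite(centroids))) stopf("centroids must be finite")
  colnames(centroids) <- c("x", "y", "z")
  structure(list(centroids = centroids, n_roi = nrow(centroids)), class = "roi_geometry")
}

#' Pairwise Euclidean distances between ROI centroids, edge order matching
#' [fc_profile()] (row-major upper triangle).
#' @param geometry a [roi_geometry()].
#' @return numeric vector of length n_roi*(n_roi-1)/2, in mm.
#' @export
edge_distances <- function(geometry) {
  d <- as.matrix(stats::dist(geometry$centroids))
  upper_tri_rowmajor(d)
}

# row-major upper-triangle vectorization (and its pair index)
upper_tri_rowmajor <- function(m) t(m)[lower.tri(m)]

upper_tri_pairs <- function(n) {
  i <- rep(seq_len(n - 1), times = (n - 1):1)
  j <- unlist(lapply(seq_len(n - 1), function(k) (k + 1):n))
  data.frame(i = i, j = j)
}
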