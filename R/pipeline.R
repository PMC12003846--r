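# High-level drivers chaining censoring, cleaning and FC-profile construction
# for a whole dataset at one censoring condition.

#' Clean one scan at a censoring threshold
#'
#' Computes FD, builds the censor mask (NULL threshold = no censoring),
#' assembles the nuisance design (motion set + tissue PCs + spectral basis)
#' and runs the one-step censor/regress/filter.
#'
#' @param motion a [motion_trace()].
#' @param ts a [roi_timeseries()].
#' @param tissue optional tissue signal matrix for tissue PCs.
#' @param threshold FD censoring threshold in mm, or `NULL` for no censoring.
#' @param motion_set motion regressor count (6/12/24/36; default 12).
#' @param band_hz pass band (default 0.01-0.1 Hz).
#' @param radius_mm FD radius.
#' @param extend_before also censor the frame before each spike.
#' @return list with `clean` (a `clean_series`), `fd`, `mask`, `summary`
#'   (a [motion_summary()]), `design`.
#' @export
process_scan <- function(motion, ts, tissue = NULL, threshold = NULL,
                         motion_set = 12, band_hz = c(0.01, 0.1),
                         radius_mm = 35, extend_before = FALSE) {
  fd <- compute_fd(motion, radius_mm)
  mask <- if (!is.null(threshold)) make_censor_mask(fd, threshold, extend_before)
          else censor_mask(rep(TRUE, motion$frames), Inf, "fd")
  design <- build_nuisance_design(motion, motion_set = motion_set,
                                  tissue_signals = tissue, band_hz = band_hz,
                                  radius_mm = radius_mm)
  smry <- summarize_motion(fd, mask)
  clean <- clean_timeseries(ts, design, mask)
  list(clean = clean, fd = fd, mask = mask, summary = smry, design = design)
}

#' Build FC profiles for a dataset at one censoring condition
#'
#' Applies [process_scan()] to every scan, drops scans whose retained length
#' falls below `min_retained` frames (default 40 = two minutes at TR 3 s) or
#' whose retained frames cannot support the design, and returns the stacked
#' profile matrix with matching summaries and records.
#'
#' @param dataset a [simulate_dataset()] result (or a compatible list).
#' @param threshold FD threshold (mm) or `NULL` for no censoring.
#' @param min_retained scan-level minimum retained frames.
#' @param correction z correction passed to [compute_fc()].
#' @param use_tissue include tissue PCs in the design.
#' @param ... further arguments to [process_scan()].
#' @return list with `profiles` (scans x edges matrix of z values),
#'   `summaries` (data.frame scan_id, fd_ave, fd_max, n_retained, dof),
#'   `records` (kept rows), `dropped` (ids and reasons).
#' @export
build_profiles <- function(dataset, threshold = NULL, min_retained = 40,
                           correction = "corrected", use_tissue = TRUE, ...) {
  ids <- names(dataset$scans)
  rows <- list(); smry <- list(); dropped <- list()
  for (id in ids) {
    sc <- dataset$scans[[id]]
    res <- tryCatch(
      process_scan(sc$motion, sc$ts,
                   tissue = if (use_tissue) sc$tissue else NULL,
                   threshold = threshold, ...),
      error = function(e) e)
    if (inherits(res, "error")) { dropped[[id]] <- conditionMessage(res); next }
    if (res$summary$n_retained < min_retained) {
      dropped[[id]] <- sprintf("retained %d < %d frames", res$summary$n_retained, min_retained)
      next
    }
    fc <- compute_fc(res$clean, correction = correction)
    rows[[id]] <- fc_profile(fc)$values
    smry[[id]] <- data.frame(scan_id = id, fd_ave = res$summary$fd_ave,
                             fd_max = res$summary$fd_max,
                             n_retained = res$summary$n_retained,
                             dof = res$clean$dof, stringsAsFactors = FALSE)
  }
  if (length(dropped))
    log_info("build_profiles: dropped %d scan(s): %s", length(dropped),
             paste(names(dropped), collapse = ", "))
  kept <- names(rows)
  list(profiles = do.call(rbind, rows),
       summaries = do.call(rbind, smry),
       records = dataset$records[match(kept, dataset$records$scan_id), , drop = FALSE],
       dropped = dropped)
}
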