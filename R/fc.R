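#' Functional connectivity matrix with autocorrelation-corrected Fisher z
#'
#' Pairwise Pearson correlation over retained frames, converted to a z-score
#' comparable across scans of different censored lengths:
#' `z = atanh(r) * sqrt(n_eff - 3)`, where `n_eff` is a per-pair effective
#' sample size. With `correction = "corrected"`, `n_eff` shrinks the nominal
#' frame count by a tapered (Bartlett-windowed) sum of the two series' sample
#' autocorrelations — the standard variance inflation of a correlation between
#' serially dependent series; negative estimates are floored at 4 and values
#' above the frame count are capped. With `"naive"`, `n_eff` is the retained
#' frame count.
#'
#' @param clean a `clean_series` (or a plain frames x n_roi matrix).
#' @param correction `"corrected"` (default) or `"naive"`.
#' @param max_lag truncation lag for the autocovariance sum; default
#'   `floor(3 * sqrt(n))`.
#' @param r_cap cap on |r| before atanh (finite z on degenerate input).
#' @return object of class `fc_matrix` with `r`, `z`, `dof_effective`, `n`.
#' @export
compute_fc <- function(clean, correction = c("corrected", "naive"),
                       max_lag = NULL, r_cap = 1 - 1e-7) {
  correction <- match.arg(correction)
  Y <- if (inherits(clean, "clean_series")) clean$data else as.matrix(clean)
  n <- nrow(Y)
  p <- ncol(Y)
  if (n < 10) stopf("need >= 10 retained frames for FC, got %d", n)
  sds <- apply(Y, 2, sd)
  if (any(sds == 0)) {
    bad <- colnames(Y)[sds == 0]
    if (is.null(bad)) bad <- which(sds == 0)
    stopf("zero-variance ROI(s): %s", paste(bad, collapse = ", "))
  }
  r <- cor(Y)
  if (correction == "corrected") {
    M <- if (is.null(max_lag)) min(n - 2L, floor(3 * sqrt(n))) else min(max_lag, n - 2L)
    A <- acf_matrix(Y, M)                         # M x p sample autocorrelations
    w <- 1 - seq_len(M) / (M + 1)                 # Bartlett taper
    B <- A * sqrt(w)
    infl <- 1 + 2 * crossprod(B)                  # p x p variance inflation
    n_eff <- n / infl
    n_eff <- pmin(pmax(n_eff, 4), n)
  } else {
    n_eff <- matrix(n, p, p)
  }
  z <- atanh_capped(r, r_cap) * sqrt(n_eff - 3)
  diag(z) <- 0
  dimnames(z) <- dimnames(r)
  dimnames(n_eff) <- dimnames(r)
  structure(list(r = r, z = z, dof_effective = n_eff, n = n,
                 correction = correction), class = "fc_matrix")
}

# sample autocorrelations for each column, lags 1..M (M x p matrix)
acf_matrix <- function(Y, M) {
  n <- nrow(Y)
  Yc <- sweep(Y, 2, colMeans(Y))
  denom <- colSums(Yc^2)
  out <- matrix(0, M, ncol(Y))
  for (k in seq_len(M)) {
    out[k, ] <- colSums(Yc[seq_len(n - k), , drop = FALSE] *
                        Yc[(k + 1):n, , drop = FALSE]) / denom
  }
  out
}

#' Two-sided normal p-values for the z entries of an fc_matrix
#' @param fc an `fc_matrix`.
#' @return symmetric matrix of p-values (diagonal 1).
#' @export
fc_pvalues <- function(fc) {
  p <- 2 * pnorm(-abs(fc$z))
  diag(p) <- 1
  p
}

#' Vectorize an FC matrix into a profile
#'
#' Row-major upper-triangle order, the package's canonical edge order (so
#' profiles are comparable across scans and runs). Length n*(n-1)/2.
#'
#' @param fc an `fc_matrix` or a symmetric matrix.
#' @param what `"z"` (default) or `"r"` when given an `fc_matrix`.
#' @return object of class `fc_profile`: list with `values` and `pair_index`
#'   (data.frame of i, j).
#' @export
fc_profile <- function(fc, what = c("z", "r")) {
  what <- match.arg(what)
  m <- if (inherits(fc, "fc_matrix")) fc[[what]] else as.matrix(fc)
  n <- nrow(m)
  structure(list(values = upper_tri_rowmajor(m), pair_index = upper_tri_pairs(n),
                 n_roi = n), class = "fc_profile")
}

#' Rebuild a symmetric matrix from a profile (inverse of [fc_profile()])
#' @param profile an `fc_profile` or bare vector (with `n_roi` supplied).
#' @param n_roi required when `profile` is a bare vector.
#' @param diag_value diagonal fill (default 0).
#' @return n_roi x n_roi symmetric matrix.
#' @export
profile_to_matrix <- function(profile, n_roi = NULL, diag_value = 0) {
  if (inherits(profile, "fc_profile")) {
    v <- profile$values; n_roi <- profile$n_roi
  } else v <- as.numeric(profile)
  if (is.null(n_roi)) stopf("n_roi required for a bare profile vector")
  if (length(v) != n_roi * (n_roi - 1) / 2) stopf("profile length != n*(n-1)/2")
  m <- matrix(diag_value, n_roi, n_roi)
  tm <- t(m)
  tm[lower.tri(tm)] <- v
  m <- t(tm)
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  m
}

#' Benjamini-Hochberg step-up rejection
#' @param pvals vector of p-values in (0, 1].
#' @param q FDR level (default 0.05).
#' @return logical vector, TRUE = rejected.
#' @export
bh_fdr <- function(pvals, q = 0.05) {
  m <- length(pvals)
  if (m == 0) return(logical(0))
  if (any(pvals <= 0 | pvals > 1, na.rm = TRUE)) stopf("p-values must lie in (0, 1]")
  o <- order(pvals)
  ps <- pvals[o]
  ok <- which(ps <= q * seq_len(m) / m)
  rej <- logical(m)
  if (length(ok)) rej[o[seq_len(max(ok))]] <- TRUE
  rej
}

#' Association between FD and region-wise BOLD fluctuations (one scan)
#'
#' Correlates the FD trace with each ROI's cleaned BOLD series over retained
#' frames. Because the residuals live in the nuisance-orthogonal subspace of
#' dimension `dof`, naive p-values are mis-calibrated; with `partial = TRUE`
#' (default) the FD trace is projected onto the same subspace first and
#' p-values use `dof - 1` degrees of freedom, which is calibrated under the
#' null (see the methods vignette). `partial = FALSE` gives the naive Pearson
#' test on raw FD.
#'
#' @param clean a `clean_series`.
#' @param fd an [fd_trace()] on the original (uncensored) frame grid.
#' @param design the [build_nuisance_design()] used to produce `clean`
#'   (required for `partial = TRUE`).
#' @param fixed_length if set, only the first `fixed_length` retained frames
#'   are used (data-length control); scans with fewer raise a condition of
#'   class `motionscrub_too_short`.
#' @param partial project FD onto the residual subspace before correlating.
#' @return data.frame of class `association_table`: `roi`, `r`, `r2`, `p_unc`.
#' @export
fd_bold_association <- function(clean, fd, design = NULL, fixed_length = NULL,
                                partial = TRUE) {
  idx <- clean$retained_index
  Y <- clean$data
  f <- fd$fd[idx]
  if (partial) {
    # project FD onto the nuisance-orthogonal subspace the residuals live in
    # (p-values with df = dof - 1 are then calibrated under the null)
    if (is.null(design)) stopf("partial = TRUE requires the design matrix")
    qrX <- qr(design$matrix[idx, , drop = FALSE])
    f <- qr.resid(qrX, f)
    df_t <- (length(idx) - qrX$rank) - 1
  } else {
    df_t <- length(f) - 2
  }
  if (!is.null(fixed_length)) {
    # data-length control: first fixed_length retained frames, ordinary df
    if (length(idx) < fixed_length)
      stopf("scan has %d retained frames < fixed_length %d", length(idx), fixed_length,
            class = "motionscrub_too_short")
    sel <- seq_len(fixed_length)
    Y <- Y[sel, , drop = FALSE]; f <- f[sel]
    df_t <- fixed_length - 2
  }
  if (length(f) < 10)
    stopf("fewer than 10 aligned frames", class = "motionscrub_too_short")
  if (df_t < 2) stopf("not enough residual degrees of freedom (%d)", df_t,
                      class = "motionscrub_too_short")
  if (sd(f) == 0) stopf("FD constant over analyzed frames")
  r <- as.vector(cor(f, Y))
  tstat <- r * sqrt(df_t / pmax(1 - r^2, 1e-12))
  p <- 2 * pt(-abs(tstat), df_t)
  out <- data.frame(roi = clean$roi_ids, r = r, r2 = r^2, p_unc = p,
                    stringsAsFactors = FALSE)
  class(out) <- c("association_table", "data.frame")
  out
}

#' Pool per-scan association tables into the family-level summary
#'
#' @param tables list of `association_table`s (one per scan).
#' @param q FDR level for the pooled BH family.
#' @return list with `table` (all tests, with `scan` and `p_fdr` columns) and
#'   `summary` (mean r^2 per scan and per unit, fractions significant at
#'   p_unc < 0.05, < 0.01 and BH-FDR < q over the pooled family).
#' @export
pool_associations <- function(tables, q = 0.05) {
  if (is.null(names(tables))) names(tables) <- paste0("scan_", seq_along(tables))
  all <- do.call(rbind, lapply(names(tables), function(nm) {
    tb <- tables[[nm]]; tb$scan <- nm; tb
  }))
  rej <- bh_fdr(all$p_unc, q)
  all$p_fdr_sig <- rej
  unit_col <- if ("roi" %in% names(all)) "roi" else "edge"
  summary <- list(
    mean_r2_per_scan = tapply(all$r2, all$scan, mean),
    mean_r2_per_unit = tapply(all$r2, all[[unit_col]], mean),
    frac_p05 = mean(all$p_unc < 0.05),
    frac_p01 = mean(all$p_unc < 0.01),
    frac_fdr = mean(rej),
    n_tests = nrow(all))
  list(table = all, summary = summary)
}

#' Across-scan association between edge strength and motion summaries
#'
#' For every edge, the Pearson correlation across scans between FC strength
#' and `fd_ave` / `fd_max`, with two-sided p-values and the percent of edges
#' significant at the usual thresholds.
#'
#' @param profiles scans x edges matrix (rows = scans), or list of
#'   `fc_profile`s.
#' @param summaries list of [motion_summary()] (or data.frame with `fd_ave`,
#'   `fd_max`).
#' @param q FDR level.
#' @return list with `table` (edge, r_fd_ave, p_fd_ave, r_fd_max, p_fd_max)
#'   and `summary` (percent significant per criterion and motion measure,
#'   `n_skipped` constant edges).
#' @export
fd_fc_association <- function(profiles, summaries, q = 0.05) {
  P <- profiles_as_matrix(profiles)
  if (is.data.frame(summaries)) {
    fa <- summaries$fd_ave; fm <- summaries$fd_max
  } else {
    fa <- vapply(summaries, function(s) s$fd_ave, 0)
    fm <- vapply(summaries, function(s) s$fd_max, 0)
  }
  ns <- nrow(P)
  if (ns < 10) stopf("need >= 10 scans for across-scan association")
  if (length(fa) != ns) stopf("summaries length != number of scans")
  sds <- apply(P, 2, sd)
  keep <- sds > 0
  n_skipped <- sum(!keep)
  Pk <- P[, keep, drop = FALSE]
  corp <- function(y) {
    r <- as.vector(cor(y, Pk))
    tstat <- r * sqrt((ns - 2) / pmax(1 - r^2, 1e-12))
    list(r = r, p = 2 * pt(-abs(tstat), ns - 2))
  }
  ca <- corp(fa); cm <- corp(fm)
  tab <- data.frame(edge = which(keep), r_fd_ave = ca$r, p_fd_ave = ca$p,
                    r_fd_max = cm$r, p_fd_max = cm$p)
  pct <- function(p) c(p05 = 100 * mean(p < 0.05), p01 = 100 * mean(p < 0.01),
                       fdr = 100 * mean(bh_fdr(p, q)))
  list(table = tab,
       summary = list(fd_ave = pct(ca$p), fd_max = pct(cm$p), n_skipped = n_skipped,
                      n_edges = ncol(P)))
}

profiles_as_matrix <- function(profiles) {
  if (is.matrix(profiles)) return(profiles)
  do.call(rbind, lapply(profiles, function(p)
    if (inherits(p, "fc_profile")) p$values else as.numeric(p)))
}

#' FC strength versus inter-ROI distance
#'
#' Relates edge strength of a (group-mean) FC profile to the Euclidean
#' distance between ROI centroids; optionally contrasts two conditions by
#' correlating their per-edge difference with distance (the signature of
#' distance-dependent motion artifact and its removal).
#'
#' @param mean_profile `fc_profile` or vector of edge strengths.
#' @param geometry a [roi_geometry()].
#' @param profile2 optional second condition; the difference reported is
#'   `mean_profile - profile2`.
#' @return list with `table` (edge, distance_mm, strength, and `difference`
#'   if given), `r_strength` (+p), `slope` (per mm), and for two conditions
#'   `r_difference` (+p).
#' @export
distance_analysis <- function(mean_profile, geometry, profile2 = NULL) {
  v <- if (inherits(mean_profile, "fc_profile")) mean_profile$values else as.numeric(mean_profile)
  d <- edge_distances(geometry)
  if (length(v) != length(d)) stopf("profile length != edge count for this geometry")
  ct <- stats::cor.test(d, v)
  out <- list(table = data.frame(edge = seq_along(v), distance_mm = d, strength = v),
              r_strength = unname(ct$estimate), p_strength = ct$p.value,
              slope = unname(stats::coef(stats::lm(v ~ d))[2]))
  if (!is.null(profile2)) {
    v2 <- if (inherits(profile2, "fc_profile")) profile2$values else as.numeric(profile2)
    diffv <- v - v2
    ct2 <- stats::cor.test(d, diffv)
    out$table$difference <- diffv
    out$r_difference <- unname(ct2$estimate)
    out$p_difference <- ct2$p.value
  }
  out
}
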