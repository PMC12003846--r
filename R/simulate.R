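#' Simulation configuration
#'
#' The stated world of the synthetic generator: scan counts and lengths match
#' the standard acquisition (144 volumes at TR = 3 s), motion is an AR(1)
#' low-amplitude baseline plus sparse Poisson spike events with exponential
#' amplitudes and per-scan rate heterogeneity (so scans separate into low and
#' high movers), BOLD artifacts enter additively and linearly in FD with
#' ROI loadings that decay exponentially with distance from a per-event focus,
#' and covariate effects (a continuous GA-like and a binary sex-like effect)
#' act on disjoint designated edge sets. Defaults are calibrated once so that
#' the uncensored FD_ave is about 0.9 mm with a heavy-tailed FD_max (see the
#' methods vignette); they are not tuned per analysis.
#'
#' @param n_scans number of scans (default 120).
#' @param n_roi number of ROIs (default 200).
#' @param frames frames per scan (default 144).
#' @param tr_seconds repetition time (default 3).
#' @param spike_rate expected high-motion events per scan (default 14).
#' @param spike_amp_mm mean spike amplitude, exponential (default 1.2 mm).
#' @param rate_shape gamma shape of the per-scan rate multiplier (mean 1);
#'   smaller = more between-scan heterogeneity (default 2).
#' @param baseline_ar AR(1) coefficient of the low-amplitude baseline motion.
#' @param baseline_sd_mm stationary SD of each baseline axis (mm).
#' @param artifact_gain BOLD contamination per mm of FD (default 2.2).
#'   Spike frames corrupt the signal grossly, as in real data.
#' @param artifact_jitter sdlog of the per-frame multiplicative lognormal
#'   jitter on the artifact amplitude (default 0.75). Motion artifacts in real
#'   data are not deterministic functions of the realignment parameters
#'   (spin history, intra-volume corruption); without jitter the simulated
#'   artifact would lie in the linear span of the motion regressors and be
#'   removed entirely by regression, which no empirical study observes.
#' @param artifact_decay_mm length scale of the distance-dependent artifact
#'   loading (default 22 mm). The per-frame ROI loading mixes a global
#'   component with the focal distance-decaying one,
#'   `w = 0.27 + 0.73 * exp(-d/decay)`: gross intensity corruption hits the
#'   whole brain (global dilution that masks weak covariate effects in
#'   high-motion scans) while the focal part induces the distance-dependent
#'   FC bias.
#' @param ga_effect multiplicative modulation of designated GA edges per SD of
#'   GA (default 0.25).
#' @param sex_effect additive correlation shift on designated sex edges for
#'   male scans (default 0.07).
#' @param n_signal_edges affected connections per covariate; default 5% of all
#'   edges.
#' @param noise_sd observation noise SD on BOLD (signal has unit SD).
#' @param bold_ar temporal AR(1) coefficient of the network signal.
#' @param ga_range GA sampling window in weeks (default 19-40).
#' @param radius_mm brain radius for FD and rotation scaling.
#' @param seed master seed; all per-scan randomness derives from it.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(n_scans = 120, n_roi = 200, frames = 144,
                              tr_seconds = 3, spike_rate = 14, spike_amp_mm = 1.2,
                              rate_shape = 2, baseline_ar = 0.9,
                              baseline_sd_mm = 0.33, artifact_gain = 2.2,
                              artifact_jitter = 0.75,
                              artifact_decay_mm = 22, ga_effect = 0.25,
                              sex_effect = 0.07, n_signal_edges = NULL,
                              noise_sd = 0.5, bold_ar = 0.4,
                              ga_range = c(19, 40), radius_mm = 35, seed = 1) {
  if (!is_count(n_scans) || !is_count(n_roi) || !is_count(frames))
    stopf("counts must be positive integers")
  if (baseline_ar < 0 || baseline_ar >= 1) stopf("need 0 <= baseline_ar < 1")
  if (spike_rate < 0) stopf("spike_rate must be >= 0")
  if (artifact_decay_mm <= 0) stopf("artifact_decay_mm must be > 0")
  n_edges <- n_roi * (n_roi - 1) / 2
  if (is.null(n_signal_edges))
    n_signal_edges <- min(max(1, round(0.05 * n_edges)), floor(n_edges / 2))
  if (2 * n_signal_edges > n_edges) stopf("n_signal_edges too large for this parcellation")
  structure(list(n_scans = n_scans, n_roi = n_roi, frames = frames,
                 tr_seconds = tr_seconds, spike_rate = spike_rate,
                 spike_amp_mm = spike_amp_mm, rate_shape = rate_shape,
                 baseline_ar = baseline_ar, baseline_sd_mm = baseline_sd_mm,
                 artifact_gain = artifact_gain, artifact_jitter = artifact_jitter,
                 artifact_decay_mm = artifact_decay_mm,
                 ga_effect = ga_effect, sex_effect = sex_effect,
                 n_signal_edges = n_signal_edges, noise_sd = noise_sd,
                 bold_ar = bold_ar, ga_range = ga_range, radius_mm = radius_mm,
                 seed = seed),
            class = "simulation_config")
}

#' Simulate one scan's motion trace
#'
#' AR(1) baseline on each of the six axes plus sparse spike events: event
#' count Poisson at a per-scan gamma-dispersed rate, amplitudes exponential,
#' random sign and random split across the six axes, injected as a one-frame
#' positional pulse (so FD spikes at the event frame and the frame after).
#' Deterministic given `(config$seed, scan_index)`.
#'
#' @param config a [simulation_config()].
#' @param scan_index scan number (1-based).
#' @return a [motion_trace()] with a `spike_events` attribute
#'   (data.frame of `frame`, `amp_mm`).
#' @export
simulate_motion <- function(config, scan_index = 1) {
  set.seed(sub_seed(config$seed, scan_index, salt = 1))
  n <- config$frames
  ar <- config$baseline_ar
  sd_st <- config$baseline_sd_mm
  params <- matrix(0, n, 6)
  if (sd_st > 0) {
    inn <- sd_st * sqrt(1 - ar^2)
    for (a in 1:6) {
      e <- rnorm(n, 0, inn)
      x <- as.numeric(stats::filter(e, ar, method = "recursive",
                                    init = rnorm(1, 0, sd_st)))
      # baseline drawn on the mm scale for every axis; rotations stored in rad
      params[, a] <- if (a >= 4) x / config$radius_mm else x
    }
  }
  events <- data.frame(frame = integer(0), amp_mm = numeric(0))
  if (config$spike_rate > 0) {
    rate_s <- config$spike_rate * rgamma(1, shape = config$rate_shape,
                                         rate = config$rate_shape)
    n_ev <- min(rpois(1, rate_s), n - 1)
    if (n_ev > 0) {
      frames_ev <- sort(sample(2:n, n_ev))
      amps <- rexp(n_ev, 1 / config$spike_amp_mm)
      for (k in seq_len(n_ev)) {
        wts <- rexp(6); wts <- wts / sum(wts)
        sgn <- sample(c(-1, 1), 6, replace = TRUE)
        delta <- sgn * wts * amps[k]
        delta[4:6] <- delta[4:6] / config$radius_mm   # rotations back to radians
        params[frames_ev[k], ] <- params[frames_ev[k], ] + delta
      }
      events <- data.frame(frame = frames_ev, amp_mm = amps)
    }
  }
  out <- motion_trace(params, config$tr_seconds)
  attr(out, "spike_events") <- events
  attr(out, "scan_index") <- scan_index
  out
}

#' Ground truth for a synthetic dataset
#'
#' Latent FC built from a low-rank spatial factor model: factor loadings are
#' Gaussian-process draws over ROI centroids (length scale 40 mm), so true
#' connectivity decays with inter-ROI distance as in real cortex. Designated
#' GA and sex edge sets are disjoint; GA edges are drawn among the stronger
#' half of connections (a multiplicative effect needs a nonzero base).
#'
#' @param config a [simulation_config()].
#' @return object of class `synthetic_truth` with `latent_fc`, `ga_edges`,
#'   `sex_edges`, `geometry`.
#' @export
simulate_truth <- function(config) {
  set.seed(sub_seed(config$seed, 0, salt = 2))
  p <- config$n_roi
  # centroids uniform in a 45 mm ball
  u <- matrix(rnorm(p * 3), p, 3)
  u <- u / sqrt(rowSums(u^2)) * (45 * runif(p)^(1 / 3))
  geom <- roi_geometry(u)
  D <- as.matrix(stats::dist(u))
  K <- exp(-D / 40)
  Lk <- t(chol(K + diag(1e-6, p)))
  q <- 6
  B <- Lk %*% matrix(rnorm(p * q), p, q)
  C <- tcrossprod(B)
  R0 <- stats::cov2cor(C)
  latent <- 0.55 * R0 + 0.45 * diag(p)
  ev <- eigen(latent, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) stopf("latent FC not PSD (min eigenvalue %g)", min(ev))
  n_edges <- p * (p - 1) / 2
  vals <- upper_tri_rowmajor(latent)
  strong <- which(abs(vals) >= stats::median(abs(vals)))
  ga_edges <- sort(sample(strong, min(config$n_signal_edges, length(strong))))
  sex_pool <- setdiff(seq_len(n_edges), ga_edges)
  sex_edges <- sort(sample(sex_pool, config$n_signal_edges))
  structure(list(latent_fc = latent, ga_edges = ga_edges, sex_edges = sex_edges,
                 geometry = geom),
            class = "synthetic_truth")
}

#' Simulate one scan's ROI BOLD series
#'
#' BOLD = network signal (AR(1)-in-time draws with the scan's
#' covariate-modulated latent correlation) + spike-locked artifact
#' (`artifact_gain * FD_t * w_r`, ROI loading decaying exponentially with
#' distance from a per-event random focus) + two smooth tissue nuisance
#' components with random ROI loadings + white observation noise. The tissue
#' source signals are attached as attribute `tissue_signals` (frames x 10),
#' standing in for white-matter/ventricle voxel signals.
#'
#' @param config a [simulation_config()].
#' @param truth a [simulate_truth()] result.
#' @param motion the scan's [motion_trace()] (spike events read from its
#'   attribute when present).
#' @param record one-row data.frame with `ga_weeks`, `sex` and `scan_index`.
#' @return a [roi_timeseries()] with attribute `tissue_signals`.
#' @export
simulate_scan <- function(config, truth, motion, record) {
  scan_index <- if (!is.null(record$scan_index)) record$scan_index else 1L
  set.seed(sub_seed(config$seed, scan_index, salt = 3))
  p <- config$n_roi
  n <- config$frames
  # covariate-modulated per-scan correlation target
  z_ga <- (record$ga_weeks - mean(config$ga_range)) /
    (diff(config$ga_range) / sqrt(12))
  sig <- truth$latent_fc
  pr <- upper_tri_pairs(p)
  if (config$ga_effect != 0 && length(truth$ga_edges)) {
    ij <- pr[truth$ga_edges, ]
    v <- sig[cbind(ij$i, ij$j)] * (1 + config$ga_effect * z_ga)
    v <- pmin(pmax(v, -0.97), 0.97)
    sig[cbind(ij$i, ij$j)] <- v; sig[cbind(ij$j, ij$i)] <- v
  }
  if (config$sex_effect != 0 && record$sex == "M" && length(truth$sex_edges)) {
    ij <- pr[truth$sex_edges, ]
    v <- pmin(pmax(sig[cbind(ij$i, ij$j)] + config$sex_effect, -0.97), 0.97)
    sig[cbind(ij$i, ij$j)] <- v; sig[cbind(ij$j, ij$i)] <- v
  }
  sig <- nearest_psd_corr(sig)
  # temporally autocorrelated network signal with cross-correlation sig
  E <- matrix(rnorm(n * p), n, p)
  if (config$bold_ar > 0) {
    E <- apply(E, 2, function(e)
      as.numeric(stats::filter(e, config$bold_ar, method = "recursive"))) *
      sqrt(1 - config$bold_ar^2)
  }
  bold <- E %*% chol(sig)
  # distance-dependent, spike-locked artifact
  if (config$artifact_gain > 0) {
    fd <- compute_fd(motion, config$radius_mm)$fd
    cent <- truth$geometry$centroids
    events <- attr(motion, "spike_events")
    foci_frame <- rep(1L, n)     # focus regime per frame (1 = scan-level focus)
    foci <- matrix(rnorm(3, 0, 20), 1, 3)
    if (!is.null(events) && nrow(events) > 0) {
      for (k in seq_len(nrow(events))) {
        foci <- rbind(foci, rnorm(3, 0, 20))
        foci_frame[events$frame[k]:n] <- k + 1L
      }
    }
    W <- matrix(0, n, p)
    for (g in unique(foci_frame)) {
      dst <- sqrt(colSums((t(cent) - foci[g, ])^2))
      wr <- 0.27 + 0.73 * exp(-dst / config$artifact_decay_mm)
      W[foci_frame == g, ] <- matrix(wr, sum(foci_frame == g), p, byrow = TRUE)
    }
    jit <- exp(rnorm(n, 0, config$artifact_jitter) - config$artifact_jitter^2 / 2)
    bold <- bold + config$artifact_gain * (fd * jit) * W
  }
  # smooth tissue nuisance components
  s <- vapply(1:2, function(k) {
    x <- as.numeric(stats::filter(rnorm(n), 0.95, method = "recursive"))
    (x - mean(x)) / sd(x)
  }, numeric(n))
  load_roi <- matrix(rnorm(p * 2, 0, 0.3), p, 2)
  bold <- bold + s %*% t(load_roi)
  if (config$noise_sd > 0) bold <- bold + matrix(rnorm(n * p, 0, config$noise_sd), n, p)
  load_tis <- matrix(rnorm(10 * 2, 0.5, 0.3), 10, 2)
  tissue <- s %*% t(load_tis) + matrix(rnorm(n * 10, 0, 0.3), n, 10)
  out <- roi_timeseries(bold, roi_ids = paste0("roi_", seq_len(p)),
                        tr_seconds = config$tr_seconds)
  attr(out, "tissue_signals") <- tissue
  out
}

# eigenvalue clipping + rescale to unit diagonal
nearest_psd_corr <- function(m) {
  e <- eigen(m, symmetric = TRUE)
  if (min(e$values) >= 1e-8) return(m)
  v <- pmax(e$values, 1e-6)
  m2 <- e$vectors %*% (v * t(e$vectors))
  stats::cov2cor(m2)
}

#' Simulate a full multi-scan dataset
#'
#' GA uniform over the config window, sex balanced, one motion trace and one
#' ROI BOLD series per scan, with the ground truth and geometry attached.
#' Byte-identical output for identical seeds.
#'
#' @param config a [simulation_config()].
#' @return object of class `synthetic_dataset`: list with `scans` (each a list
#'   `motion`, `ts`, `tissue`, `record`), `records` ([scan_records()] with a
#'   `scan_index` column), `truth`, `geometry`, `config`.
#' @export
simulate_dataset <- function(config) {
  truth <- simulate_truth(config)
  set.seed(sub_seed(config$seed, 0, salt = 4))
  n <- config$n_scans
  ga <- runif(n, config$ga_range[1], config$ga_range[2])
  sex <- sample(rep(c("M", "F"), length.out = n))
  ids <- sprintf("scan_%03d", seq_len(n))
  records <- scan_records(ids, ga, sex, ga_range = config$ga_range + c(-1, 1))
  records$scan_index <- seq_len(n)
  scans <- lapply(seq_len(n), function(i) {
    motion <- simulate_motion(config, i)
    ts <- simulate_scan(config, truth, motion, records[i, ])
    list(motion = motion, ts = ts, tissue = attr(ts, "tissue_signals"),
         record = records[i, ])
  })
  names(scans) <- ids
  structure(list(scans = scans, records = records, truth = truth,
                 geometry = truth$geometry, config = config),
            class = "synthetic_dataset")
}

#' Write a synthetic dataset to disk via the package readers' formats
#'
#' Motion as 6-column `.par`-style TSV, BOLD and tissue as TSV with headers,
#' metadata and centroids as TSV, truth (edge sets, latent FC) as JSON.
#'
#' @param dataset a [simulate_dataset()] result.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_dataset <- function(dataset, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (id in names(dataset$scans)) {
    sc <- dataset$scans[[id]]
    write_motion_trace(sc$motion, file.path(out_dir, paste0(id, "_motion.par")))
    write_roi_timeseries(sc$ts, file.path(out_dir, paste0(id, "_bold.tsv")))
    tis <- sc$tissue
    colnames(tis) <- paste0("tissue_", seq_len(ncol(tis)))
    write_roi_timeseries(tis, file.path(out_dir, paste0(id, "_tissue.tsv")))
  }
  write_tsv(dataset$records, file.path(out_dir, "metadata.tsv"))
  cent <- as.data.frame(dataset$geometry$centroids)
  cent$roi <- paste0("roi_", seq_len(nrow(cent)))
  write_tsv(cent[, c("roi", "x", "y", "z")], file.path(out_dir, "centroids.tsv"))
  write_json_report(list(ga_edges = dataset$truth$ga_edges,
                         sex_edges = dataset$truth$sex_edges,
                         latent_fc = dataset$truth$latent_fc),
                    file.path(out_dir, "truth.json"))
  invisible(out_dir)
}

#' Simulate a small 4-D volume series tied to a motion trace
#'
#' Desk-scale volumes for sDVARS/tSNR/cluster testing: a 16 x 16 x 8 grid with
#' a brain mask, four gray-matter signal blocks (blocks 1 and 2 share a
#' network signal; 3 and 4 are independent), a white-matter and a ventricle
#' region, baseline intensity 100, plus an FD-locked global intensity jump
#' (`jump_gain` per mm of FD) and voxel noise.
#'
#' @param config a [simulation_config()].
#' @param motion the scan's [motion_trace()].
#' @param signal_amp amplitude of the block signals (0 disables).
#' @param noise_sd voxel noise SD (0 disables).
#' @param jump_gain intensity corruption per mm of FD (default 0.7); the
#'   voxel loading mixes a global and a focal (per-event focus) component and
#'   is amplitude-jittered per frame like the ROI-level artifact.
#' @return a [volume_series()] with masks `brain`, `gray_matter`,
#'   `white_matter`, `ventricles` and attribute `blocks` (list of voxel index
#'   arrays).
#' @export
simulate_volumes <- function(config, motion, signal_amp = 1, noise_sd = 0.5,
                             jump_gain = 0.7) {
  scan_index <- attr(motion, "scan_index")
  if (is.null(scan_index)) scan_index <- 1L
  set.seed(sub_seed(config$seed, scan_index, salt = 5))
  d <- c(16L, 16L, 8L)
  nt <- motion$frames
  brain <- array(FALSE, d); brain[3:14, 3:14, 2:7] <- TRUE
  mk_block <- function(xr, yr, zr) {
    m <- array(FALSE, d); m[xr, yr, zr] <- TRUE; m
  }
  blocks <- list(mk_block(4:7, 4:7, 3:5), mk_block(9:12, 9:12, 3:5),
                 mk_block(4:7, 9:12, 3:5), mk_block(9:12, 4:7, 3:5))
  gm <- Reduce(`|`, blocks)
  wm <- mk_block(7:10, 7:9, 6)
  vent <- mk_block(7:9, 7:8, 2)
  arsig <- function() {
    x <- as.numeric(stats::filter(rnorm(nt), 0.9, method = "recursive"))
    (x - mean(x)) / sd(x)
  }
  net <- arsig(); s3 <- arsig(); s4 <- arsig()
  fd <- compute_fd(motion, config$radius_mm)$fd
  dat <- array(100, dim = c(d, nt))
  nvox <- prod(d)
  mat <- matrix(dat, nvox, nt)
  if (signal_amp > 0) {
    sig_of <- list(net, net, s3, s4)
    for (b in 1:4)
      mat[as.vector(blocks[[b]]), ] <-
        sweep(mat[as.vector(blocks[[b]]), , drop = FALSE], 2,
              signal_amp * sig_of[[b]], "+")
  }
  if (jump_gain != 0) {
    # FD-locked intensity corruption: global + focal (per-event focus voxel),
    # amplitude jittered per frame like the ROI-level artifact
    co <- which(brain, arr.ind = TRUE)
    events <- attr(motion, "spike_events")
    foci_frame <- rep(1L, nt)
    foci <- matrix(c(8, 8, 4), 1, 3)
    if (!is.null(events) && nrow(events) > 0) {
      for (k in seq_len(nrow(events))) {
        foci <- rbind(foci, c(runif(1, 4, 13), runif(1, 4, 13), runif(1, 2, 7)))
        foci_frame[events$frame[k]:nt] <- k + 1L
      }
    }
    jit <- exp(rnorm(nt, 0, config$artifact_jitter) - config$artifact_jitter^2 / 2)
    for (g in unique(foci_frame)) {
      dst <- sqrt(rowSums(sweep(co, 2, foci[g, ])^2))
      wv <- 0.3 + 0.7 * exp(-dst / 4)
      fr <- which(foci_frame == g)
      mat[as.vector(brain), fr] <- mat[as.vector(brain), fr, drop = FALSE] +
        outer(wv, jump_gain * fd[fr] * jit[fr])
    }
  }
  if (noise_sd > 0) mat <- mat + matrix(rnorm(nvox * nt, 0, noise_sd), nvox, nt)
  out <- volume_series(array(mat, dim = c(d, nt)),
                       masks = list(brain = brain, gray_matter = gm,
                                    white_matter = wm, ventricles = vent),
                       affine = diag(c(3, 3, 3, 1)),
                       tr_seconds = config$tr_seconds)
  attr(out, "blocks") <- blocks
  out
}
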