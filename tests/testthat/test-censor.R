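# censor_regress: masks, regressor sets, tissue PCs, spectral basis,
# one-step censor + regress + band-pass

test_that("censor mask uses a strict threshold and optional back-extension", {
  fd <- fd_trace(c(0, 0.3, 1.8, 0.4), 35)
  expect_equal(make_censor_mask(fd, 1.5)$keep, c(TRUE, TRUE, FALSE, TRUE))
  expect_equal(make_censor_mask(fd, 1.5, extend_before = TRUE)$keep,
               c(TRUE, FALSE, FALSE, TRUE))
  expect_true(all(make_censor_mask(fd, 5)$keep))          # above max: keep all
  expect_true(all(make_censor_mask(fd, 1.8)$keep))        # boundary retained (strict >)
  m2 <- make_censor_mask(structure(list(sdvars = c(0, 0.2, 0.05),
                                        mask_name = "gm"), class = "dvars_trace"), 0.1)
  expect_equal(m2$metric, "sdvars")
  expect_equal(m2$keep, c(TRUE, FALSE, TRUE))
  both <- combine_censor_masks(make_censor_mask(fd, 1.5), censor_mask(c(TRUE, FALSE, TRUE, TRUE), 0.1, "sdvars"))
  expect_equal(both$keep, c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(both$metric, "fd_and_sdvars")
})

test_that("motion regressor sets have the right shape, lags and squares", {
  set.seed(21)
  mt <- motion_trace(matrix(rnorm(20 * 6), 20, 6), 3)
  for (ms in c(6, 12, 24, 36)) {
    X <- build_motion_regressors(mt, ms, radius_mm = 35)
    expect_equal(ncol(X), ms)
    expect_equal(nrow(X), 20)
  }
  X24 <- build_motion_regressors(mt, 24, radius_mm = 35)
  R <- X24[, 1:6]
  expect_equal(unname(X24[, 7:12]), unname(R^2))
  expect_equal(unname(X24[2:20, 13:18]), unname(R[1:19, ]))  # lag-1 shift identity
  expect_equal(unname(X24[1, 13:18]), rep(0, 6))             # zero-padded
  X36 <- build_motion_regressors(mt, 36, radius_mm = 35)
  expect_equal(unname(X36[3:20, 25:30]), unname(R[1:18, ]))  # lag-2

  const <- motion_trace(matrix(1, 10, 6), 3)
  X12 <- build_motion_regressors(const, 12)
  expect_true(all(X12[, 7:12] == 0))                         # R' of constant is 0
  expect_error(build_motion_regressors(mt, 13), "motion_set")
})

test_that("rotational regressors are converted to mm with the radius", {
  p <- matrix(0, 5, 6); p[, 4] <- 0.01
  X <- build_motion_regressors(motion_trace(p, 3), 6, radius_mm = 50)
  expect_equal(unname(X[, 4]), rep(0.5, 5))
})

test_that("tissue PCs recover a planted dominant component", {
  set.seed(22)
  n <- 80
  shared <- as.numeric(scale(cumsum(rnorm(n))))
  sig <- shared %*% t(runif(12, 0.8, 1.2)) + matrix(rnorm(n * 12, sd = 0.1), n, 12)
  pcs <- tissue_pcs(sig, 3)
  expect_equal(ncol(pcs), 3)
  expect_gt(abs(cor(pcs[, 1], shared)), 0.99)
  expect_equal(apply(pcs, 2, sd), setNames(rep(1, 3), colnames(pcs)))

  # orthonormal inputs: PCs span the same (centered) space
  qx <- qr.Q(qr(matrix(rnorm(n * 3), n, 3)))
  qx <- scale(qx, center = TRUE, scale = FALSE)
  pcs2 <- tissue_pcs(qx, 3)
  resid <- qr.resid(qr(pcs2), qx)
  expect_lt(max(abs(resid)), 1e-8)

  expect_error(tissue_pcs(cbind(shared, shared, shared), 3), "rank")
})

test_that("spectral basis enumerates exactly the out-of-band DFT frequencies", {
  B <- spectral_basis(144, 3, c(0.01, 0.1))
  # k/(144*3): out of band k = 1..4 and 44..72 => 33 freqs, sine dropped at Nyquist
  ks <- as.integer(sub("^(cos|sin)_", "", setdiff(colnames(B), "trend")))
  expect_setequal(unique(ks), c(1:4, 44:72))
  expect_equal(ncol(B), 1 + 2 * 33 - 1)
  expect_false("sin_72" %in% colnames(B))
  freqs <- unique(ks) / (144 * 3)
  expect_true(all(freqs < 0.01 | freqs > 0.1))

  # full-band: nothing to remove but the trend
  expect_equal(colnames(spectral_basis(100, 3, c(0, 1 / 6))), "trend")

  # columns mutually orthogonal on the full grid
  G <- crossprod(scale(B[, -1], center = TRUE, scale = FALSE))
  expect_lt(max(abs(G[upper.tri(G)])) / max(diag(G)), 1e-10)

  expect_error(spectral_basis(100, 3, c(0.05, 0.4)), "Nyquist")
})

test_that("clean_timeseries fits exactly, band-passes, and never leaks across censored frames", {
  set.seed(23)
  cfg <- tiny_config(frames = 144, n_roi = 4)
  mt <- simulate_motion(cfg, 1)
  design <- build_nuisance_design(mt, 12)

  # a design column as data => residual ~ 0
  y <- design$matrix[, c(3, 10), drop = FALSE] %*% c(1.5, -2)
  ts <- roi_timeseries(cbind(y, rnorm(144)), tr_seconds = 3)
  cl <- clean_timeseries(ts, design)
  expect_lt(max(abs(cl$data[, 1])), 1e-8)

  # out-of-band 0.15 Hz sinusoid loses >99% of its power
  t_sec <- (0:143) * 3
  sine <- sin(2 * pi * 0.15 * t_sec)
  ts2 <- roi_timeseries(cbind(sine, rnorm(144)), tr_seconds = 3)
  cl2 <- clean_timeseries(ts2, design)
  expect_lt(power_at(cl2$data[, 1], 0.15, 3) / power_at(sine, 0.15, 3), 0.01)

  # leakage oracle: artifacts confined to censored frames leave retained
  # residuals untouched
  fd <- compute_fd(mt, 35)
  mask <- make_censor_mask(fd, 1.5)
  if (sum(!mask$keep) == 0) mask$keep[c(10, 50)] <- FALSE
  base <- matrix(rnorm(144 * 4), 144, 4)
  spiked <- base
  spiked[!mask$keep, ] <- spiked[!mask$keep, ] + 100
  r1 <- clean_timeseries(roi_timeseries(base, tr_seconds = 3), design, mask)
  r2 <- clean_timeseries(roi_timeseries(spiked, tr_seconds = 3), design, mask)
  expect_lt(max(abs(r1$data - r2$data)), 1e-10)
  expect_identical(r1$retained_index, which(mask$keep))

  # residuals orthogonal to every retained design column
  Xr <- design$matrix[mask$keep, ]
  ip <- crossprod(Xr, r1$data)
  norms <- outer(sqrt(colSums(Xr^2)), sqrt(colSums(r1$data^2)))
  expect_lt(max(abs(ip) / pmax(norms, 1e-12)), 1e-8)
})

test_that("rank deficiency after censoring raises a dof error", {
  cfg <- tiny_config(frames = 100, n_roi = 3)
  mt <- simulate_motion(cfg, 2)
  design <- build_nuisance_design(mt, 36)
  keep <- rep(FALSE, 100); keep[1:20] <- TRUE     # fewer frames than design rank
  mask <- censor_mask(keep, 1, "fd")
  ts <- roi_timeseries(matrix(rnorm(300), 100, 3), tr_seconds = 3)
  expect_error(clean_timeseries(ts, design, mask), class = "motionscrub_dof_error")
})

test_that("uncensored one-step cleaning matches the classical FFT filter", {
  set.seed(24)
  f <- c(0, seq_len(143)) / (144 * 3)
  f <- pmin(f, 1 / 3 - f)          # fold to physical frequency
  keep_bin <- f >= 0.01 & f <= 0.1
  fft_filter <- function(M) apply(M, 2, function(col)
    Re(fft(fft(col) * keep_bin, inverse = TRUE)) / 144)

  # with only intercept + out-of-band sin/cos the two are the same projector
  B <- spectral_basis(144, 3, c(0.01, 0.1))
  design0 <- structure(list(matrix = cbind(intercept = 1, B[, colnames(B) != "trend"]),
                            column_labels = "spectral", motion_set = 0,
                            n_tissue_pcs = 0, band_hz = c(0.01, 0.1)),
                       class = "nuisance_design")
  Y <- matrix(rnorm(144 * 3), 144, 3)
  cl0 <- clean_timeseries(roi_timeseries(Y, tr_seconds = 3), design0)
  expect_lt(max(abs(cl0$data - fft_filter(Y))), 1e-9)

  # with trend + motion columns the joint fit and the sequential pipeline
  # differ by estimation noise; median relative power difference stays small
  dif <- c()
  for (b in 1:10) {
    cfg <- tiny_config(frames = 144, n_roi = 3, seed = 400 + b)
    mt <- simulate_motion(cfg, 3)
    design <- build_nuisance_design(mt, 12)
    Y <- matrix(rnorm(144 * 3), 144, 3)
    cl <- clean_timeseries(roi_timeseries(Y, tr_seconds = 3), design)
    Xm <- cbind(1, scale(seq_len(144)), build_motion_regressors(mt, 12))
    filt <- fft_filter(qr.resid(qr(Xm), Y))
    dif <- c(dif, abs(colSums(cl$data^2) - colSums(filt^2)) / colSums(filt^2))
  }
  expect_lt(median(dif), 0.10)
})

test_that("dof shrinks and chunks shorten as the threshold tightens", {
  cfg <- tiny_config(frames = 144, n_roi = 3, seed = 9)
  dofs <- c(); mean_chunk <- c()
  mt <- simulate_motion(cfg, 1)
  ts <- simulate_scan(cfg, simulate_truth(cfg), mt, data.frame(ga_weeks = 30, sex = "F", scan_index = 1))
  design <- build_nuisance_design(mt, 12)
  fd <- compute_fd(mt, cfg$radius_mm)
  for (thr in c(2.5, 2.0, 1.5, 1.0)) {
    mask <- make_censor_mask(fd, thr)
    cl <- clean_timeseries(ts, design, mask)
    dofs <- c(dofs, cl$dof)
    mean_chunk <- c(mean_chunk, mean(summarize_motion(fd, mask)$chunks))
  }
  expect_true(all(diff(dofs) <= 0))
  # chunk-length pattern over scans: mean strictly decreases 2.5 -> 0.5 mm
  mc <- sapply(c(2.5, 2.0, 1.5, 1.0, 0.5), function(thr) {
    mean(sapply(1:10, function(i) {
      fdi <- compute_fd(simulate_motion(cfg, i), cfg$radius_mm)
      mki <- make_censor_mask(fdi, thr)
      if (!any(mki$keep)) return(NA_real_)
      mean(summarize_motion(fdi, mki)$chunks)
    }), na.rm = TRUE)
  })
  expect_true(all(diff(mc) < 0))
})
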