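# motion_metrics: FD, sDVARS, tSNR, motion summaries, concordance

test_that("compute_fd matches hand cases and the brute-force oracle", {
  p <- matrix(0, 4, 6)
  expect_equal(compute_fd(motion_trace(p, 3))$fd, rep(0, 4))

  p[2, 1] <- 0.5                        # frame 2 moves dx by +0.5 mm
  fd <- compute_fd(motion_trace(p, 3), radius_mm = 35)$fd
  expect_equal(fd[2], 0.5)

  p2 <- matrix(0, 4, 6)
  p2[3, 4] <- 0.01                      # phi changes by 0.01 rad at frame 3
  fd2 <- compute_fd(motion_trace(p2, 3), radius_mm = 35)$fd
  expect_equal(fd2[3], 0.35)            # arc length 35 mm * 0.01 rad

  set.seed(11)
  for (b in 1:50) {
    m <- matrix(rnorm(sample(5:40, 1) * 6), ncol = 6)
    r <- runif(1, 20, 60)
    expect_identical(compute_fd(motion_trace(m, 3), r)$fd, brute_fd(m, r))
  }
})

test_that("FD is invariant to constant offsets on any parameter track", {
  set.seed(12)
  m <- matrix(rnorm(30 * 6), 30, 6)
  fd0 <- compute_fd(motion_trace(m, 3), 35)$fd
  m2 <- sweep(m, 2, rnorm(6, sd = 10), "+")
  expect_equal(compute_fd(motion_trace(m2, 3), 35)$fd, fd0)
})

test_that("sDVARS matches the hand computation and is scale invariant", {
  d <- c(2L, 1L, 1L)
  gm <- array(TRUE, d)
  # both voxels jump 1 -> 3 at frame 2; grand mean = 2 => sdvars[2] = RMS(2,2)/2 = 1
  dat <- array(0, dim = c(d, 2))
  dat[, , , 1] <- 1; dat[, , , 2] <- 3
  vs <- volume_series(dat, masks = list(gray_matter = gm))
  sdv <- compute_sdvars(vs)
  expect_equal(sdv$sdvars, c(0, 1))

  set.seed(13)
  dat2 <- array(abs(rnorm(4 * 4 * 2 * 6)) + 1, dim = c(4, 4, 2, 6))
  vs2 <- volume_series(dat2, masks = list(gray_matter = array(TRUE, c(4, 4, 2))))
  vs10 <- volume_series(dat2 * 10, masks = list(gray_matter = array(TRUE, c(4, 4, 2))))
  expect_equal(compute_sdvars(vs10)$sdvars, compute_sdvars(vs2)$sdvars)

  # identical frames => all zero
  dat3 <- array(rep(dat2[, , , 1], 6), dim = c(4, 4, 2, 6))
  vs3 <- volume_series(dat3, masks = list(gray_matter = array(TRUE, c(4, 4, 2))))
  expect_equal(compute_sdvars(vs3)$sdvars, rep(0, 6))

  expect_error(compute_sdvars(vs2, "nope"), "not present")
})

test_that("tSNR uses the sample SD and is ratio invariant", {
  d <- c(1L, 1L, 1L)
  mk <- array(TRUE, d)
  vs <- volume_series(array(c(1, 2, 3), dim = c(d, 3)), masks = list(brain = mk))
  expect_equal(compute_tsnr(vs)$mean_tsnr, 2)   # mean 2, sample SD 1

  vs2 <- volume_series(array(c(2, 4, 6), dim = c(d, 3)), masks = list(brain = mk))
  expect_equal(compute_tsnr(vs2)$mean_tsnr, 2)

  set.seed(14)
  mu <- 50; sg <- 5
  vsn <- volume_series(array(rnorm(1000, mu, sg), dim = c(1, 1, 1, 1000)),
                       masks = list(brain = mk))
  expect_lt(abs(compute_tsnr(vsn)$mean_tsnr - mu / sg) / (mu / sg), 0.10)

  vsc <- volume_series(array(7, dim = c(d, 3)), masks = list(brain = mk))
  expect_error(compute_tsnr(vsc), "positive temporal SD")
})

test_that("summarize_motion reuses retained FD values and reports chunks", {
  fd <- fd_trace(c(0, 0.3, 1.8, 0.4), 35)
  mask <- make_censor_mask(fd, 1.5)
  expect_equal(mask$keep, c(TRUE, TRUE, FALSE, TRUE))
  s <- summarize_motion(fd, mask)
  expect_equal(s$fd_ave, mean(c(0, 0.3, 0.4)))
  expect_equal(s$fd_max, 0.4)
  expect_equal(s$chunks, c(2L, 1L))
  expect_equal(s$n_retained, 3L)

  all_keep <- censor_mask(rep(TRUE, 4), 10, "fd")
  s2 <- summarize_motion(fd, all_keep)
  expect_equal(s2$chunks, 4L)
  expect_equal(s2$fd_max, 1.8)

  none <- censor_mask(rep(FALSE, 4), 0.1, "fd")
  expect_error(summarize_motion(fd, none), class = "motionscrub_all_censored")
})

test_that("recompute_gaps recomputes displacement across censoring gaps", {
  p <- matrix(0, 4, 6)
  p[, 1] <- c(0, 1, 5, 1.5)          # fd = 0, 1, 4, 3.5
  mt <- motion_trace(p, 3)
  fd <- compute_fd(mt, 35)
  mask <- make_censor_mask(fd, 3.5)  # drops frame 3 only (fd=4)
  s_orig <- summarize_motion(fd, mask)
  expect_equal(s_orig$fd_max, 3.5)   # original FD of frame 4 kept
  s_re <- summarize_motion(fd, mask, recompute_gaps = TRUE, motion = mt)
  expect_equal(s_re$fd_max, 1)       # |1.5 - 1| = 0.5 across the gap, max = 1
})

test_that("fd_ave and fd_max are non-increasing as the threshold tightens", {
  set.seed(15)
  cfg <- tiny_config(frames = 144)
  for (i in 1:5) {
    fd <- compute_fd(simulate_motion(cfg, i), 35)
    prev_a <- Inf; prev_m <- Inf
    for (thr in c(2.5, 2.0, 1.5, 1.0, 0.5)) {
      mask <- make_censor_mask(fd, thr)
      if (!any(mask$keep)) break
      s <- summarize_motion(fd, mask)
      expect_lte(s$fd_ave, prev_a + 1e-12)
      expect_lte(s$fd_max, prev_m + 1e-12)
      prev_a <- s$fd_ave; prev_m <- s$fd_max
    }
  }
})

test_that("fd/sdvars concordance behaves at the boundaries and under perfect order", {
  fd <- fd_trace(c(0, 0.2, 2.0, 0.4, 1.9, 0.1), 35)
  dvv <- structure(list(sdvars = c(0, 0.05, 0.30, 0.08, 0.28, 0.02),
                        mask_name = "gray_matter"), class = "dvars_trace")
  cc <- fd_sdvars_concordance(fd, dvv, fd_ref = 1.5,
                              sdvars_grid = seq(0.01, 0.4, 0.01))
  # sdvars ordering matches fd: some threshold separates perfectly
  expect_true(any(cc$sensitivity == 1 & cc$specificity == 1))
  # threshold below min(sdvars[-1]) => sensitivity 1, specificity 0
  cc2 <- fd_sdvars_concordance(fd, dvv, 1.5, sdvars_grid = 0.001)
  expect_equal(cc2$sensitivity, 1)
  expect_equal(cc2$specificity, 0)
  # no positive frames => sensitivity NA
  cc3 <- fd_sdvars_concordance(fd, dvv, fd_ref = 5, sdvars_grid = 0.1)
  expect_true(is.na(cc3$sensitivity))
})

test_that("independent sdvars gives sensitivity + specificity near 1", {
  set.seed(16)
  tot <- c()
  for (b in 1:40) {
    f <- c(0, abs(rnorm(99, 1, 0.8)))
    s <- c(0, abs(rnorm(99, 0.15, 0.05)))
    cc <- fd_sdvars_concordance(fd_trace(f, 35),
                                structure(list(sdvars = s, mask_name = "gm"),
                                          class = "dvars_trace"),
                                fd_ref = 1.5, sdvars_grid = 0.15)
    if (!is.na(cc$sensitivity)) tot <- c(tot, cc$sensitivity + cc$specificity)
  }
  expect_lt(abs(mean(tot) - 1), 0.1)
})

test_that("heavier motion artifacts lower mean tSNR (rank association)", {
  cfg <- tiny_config(n_scans = 50, frames = 60)
  fdave <- tsnr <- numeric(50)
  for (i in 1:50) {
    mo <- simulate_motion(cfg, i)
    vo <- simulate_volumes(cfg, mo)
    fdave[i] <- mean(compute_fd(mo, cfg$radius_mm)$fd)
    tsnr[i] <- compute_tsnr(vo)$mean_tsnr
  }
  expect_lt(cor(fdave, tsnr, method = "spearman"), 0)
})
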