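# synthetic_data: determinism, stated-world properties, ground-truth recovery

test_that("degenerate config gives a constant-zero trace and zero FD", {
  cfg <- tiny_config(spike_rate = 0, baseline_ar = 0, baseline_sd_mm = 0)
  mt <- simulate_motion(cfg, 1)
  expect_true(all(mt$params == 0))
  expect_equal(compute_fd(mt, 35)$fd, rep(0, cfg$frames))
})

test_that("motion simulation is deterministic in (seed, scan_index)", {
  cfg <- tiny_config(seed = 123)
  expect_identical(simulate_motion(cfg, 4)$params, simulate_motion(cfg, 4)$params)
  expect_false(identical(simulate_motion(cfg, 4)$params, simulate_motion(cfg, 5)$params))
})

test_that("FD threshold crossings match the closed-form event-process rate", {
  # baseline off: crossings of 1.5 mm come only from spikes; each event yields
  # two suprathreshold frames when its exponential amplitude exceeds 1.5 mm,
  # P = exp(-1.5/3). Collisions make the count deviate by well under 3 SE.
  rate <- 10; amp <- 3
  cfg <- tiny_config(frames = 144, spike_rate = rate, spike_amp_mm = amp,
                     baseline_ar = 0, baseline_sd_mm = 0, rate_shape = 2)
  crossings <- sapply(1:200, function(i) {
    cfgi <- tiny_config(frames = 144, spike_rate = rate, spike_amp_mm = amp,
                        baseline_ar = 0, baseline_sd_mm = 0, rate_shape = 2,
                        seed = 1000 + i)
    sum(compute_fd(simulate_motion(cfgi, 1), 35)$fd > 1.5)
  })
  expected <- 2 * rate * exp(-1.5 / amp)
  se <- sd(crossings) / sqrt(length(crossings))
  expect_lt(abs(mean(crossings) - expected), 3 * se + 0.5)
})

test_that("latent FC is a symmetric PSD correlation matrix with disjoint edge sets", {
  for (s in c(3, 17)) {
    cfg <- tiny_config(n_roi = 25, seed = s)
    tr <- simulate_truth(cfg)
    L <- tr$latent_fc
    expect_equal(L, t(L))
    expect_equal(unname(diag(L)), rep(1, 25))
    expect_gte(min(eigen(L, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
    expect_length(intersect(tr$ga_edges, tr$sex_edges), 0)
  }
})

test_that("sample FC converges toward latent FC as frames grow", {
  cfg_small <- tiny_config(n_roi = 10, frames = 100, artifact_gain = 0,
                           ga_effect = 0, sex_effect = 0, noise_sd = 0, seed = 70)
  cfg_big <- tiny_config(n_roi = 10, frames = 5000, artifact_gain = 0,
                         ga_effect = 0, sex_effect = 0, noise_sd = 0, seed = 70)
  tr <- simulate_truth(cfg_small)
  rec <- data.frame(ga_weeks = 30, sex = "F", scan_index = 1)
  frob <- function(cfg) {
    mo <- simulate_motion(cfg, 1)
    ts <- simulate_scan(cfg, tr, mo, rec)
    # tissue components are part of the draw; compare against their sum too
    norm(cor(ts$data) - tr$latent_fc, "F")
  }
  expect_lt(frob(cfg_big), frob(cfg_small))
})

test_that("artifact inflates short-distance FC in high-motion scans, slope negative in distance", {
  # flat latent FC isolates the contamination mechanism from the dilution of
  # true short-range structure
  cfg <- tiny_config(n_scans = 60, n_roi = 20, frames = 120, seed = 71,
                     ga_effect = 0, sex_effect = 0)
  tr <- simulate_truth(cfg)
  tr$latent_fc <- diag(cfg$n_roi)
  scans <- lapply(seq_len(cfg$n_scans), function(i) {
    mo <- simulate_motion(cfg, i)
    list(mo = mo, ts = simulate_scan(cfg, tr, mo,
                                     data.frame(ga_weeks = 30, sex = "F", scan_index = i)))
  })
  fdave <- sapply(scans, function(s) mean(compute_fd(s$mo, cfg$radius_mm)$fd))
  hi <- fdave >= median(fdave)
  rmean <- function(idx) {
    Reduce(`+`, lapply(scans[idx], function(s)
      fc_profile(cor(s$ts$data), "r")$values)) / sum(idx)
  }
  dif <- rmean(hi) - rmean(!hi)
  d <- edge_distances(tr$geometry)
  short <- d < median(d)
  expect_gt(mean(dif[short]), 0)                       # short-range inflation
  expect_lt(coef(lm(dif ~ d))[2], 0)                   # fades with distance
})

test_that("planted sex effect beats random edge sets on the ground-truth contrast", {
  set.seed(72)
  wins <- sapply(1:25, function(b) {
    cfg <- tiny_config(n_scans = 30, n_roi = 15, frames = 120, seed = 200 + b,
                       artifact_gain = 0, ga_effect = 0, sex_effect = 0.3,
                       n_signal_edges = 10)
    ds <- simulate_dataset(cfg)
    P <- do.call(rbind, lapply(ds$scans, function(s) fc_profile(cor(s$ts$data), "r")$values))
    male <- ds$records$sex == "M"
    tstat <- function(edges) {
      vals <- P[, edges, drop = FALSE]
      mean(abs(colMeans(vals[male, , drop = FALSE]) - colMeans(vals[!male, , drop = FALSE])))
    }
    rnd <- sample(setdiff(seq_len(ncol(P)), ds$truth$sex_edges), length(ds$truth$sex_edges))
    tstat(ds$truth$sex_edges) > tstat(rnd)
  })
  expect_gte(mean(wins), 0.95)
})

test_that("datasets have the documented shapes, balance and byte-stable files", {
  cfg <- tiny_config(n_scans = 4, n_roi = 6, frames = 50, seed = 73)
  ds <- simulate_dataset(cfg)
  expect_length(ds$scans, 4)
  expect_equal(sort(table(ds$records$sex), decreasing = TRUE)[[1]], 2)
  expect_true(all(ds$records$ga_weeks >= 19 & ds$records$ga_weeks <= 40))
  expect_equal(dim(ds$scans[[1]]$ts$data), c(50L, 6L))
  expect_equal(length(fc_profile(cor(ds$scans[[1]]$ts$data))$values), 15)

  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_dataset(ds, d1)
  write_dataset(simulate_dataset(cfg), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  # round trip through the readers
  mt <- read_motion_trace(file.path(d1, "scan_001_motion.par"), 3)
  expect_identical(mt$params, ds$scans[[1]]$motion$params)
  ts <- read_roi_timeseries(file.path(d1, "scan_001_bold.tsv"), 3)
  expect_identical(ts$data, ds$scans[[1]]$ts$data)
})

test_that("the 200-ROI world yields 19,900-edge profiles", {
  # profile length for the full parcellation without simulating 200-ROI BOLD
  expect_equal(length(motionscrub:::upper_tri_rowmajor(diag(200))), 19900)
  cfg <- simulation_config(n_scans = 2, n_roi = 200, frames = 20, seed = 1)
  tr <- simulate_truth(cfg)
  expect_equal(length(motionscrub:::upper_tri_rowmajor(tr$latent_fc)), 19900)
})

test_that("simulate_volumes is quiet when everything is off and jumps with FD", {
  cfg <- tiny_config(frames = 30)
  mt0 <- simulate_motion(tiny_config(frames = 30, spike_rate = 0, baseline_ar = 0,
                                     baseline_sd_mm = 0), 1)
  vo0 <- simulate_volumes(cfg, mt0, signal_amp = 0, noise_sd = 0)
  expect_equal(compute_sdvars(vo0)$sdvars, rep(0, 30))

  mt <- simulate_motion(cfg, 2)
  vo <- simulate_volumes(cfg, mt)
  expect_setequal(names(vo$masks), c("brain", "gray_matter", "white_matter", "ventricles"))
  sdv <- compute_sdvars(vo)$sdvars
  fd <- compute_fd(mt, cfg$radius_mm)$fd
  expect_gt(cor(sdv[-1], fd[-1]), 0.2)   # FD-locked intensity jumps move sDVARS
})
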