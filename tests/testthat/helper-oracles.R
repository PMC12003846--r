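# Independent oracles and tiny fixture builders used across the suite.
# Every oracle is deliberately written with a different algorithm/shape than
# the implementation it checks.

# per-frame loop FD oracle (compute_fd is vectorized)
brute_fd <- function(params, radius_mm) {
  n <- nrow(params)
  fd <- numeric(n)
  for (i in 2:n) {
    fd[i] <- (abs(params[i - 1, 1] - params[i, 1]) +
              abs(params[i - 1, 2] - params[i, 2]) +
              abs(params[i - 1, 3] - params[i, 3])) +
      radius_mm * (abs(params[i - 1, 4] - params[i, 4]) +
                   abs(params[i - 1, 5] - params[i, 5]) +
                   abs(params[i - 1, 6] - params[i, 6]))
  }
  fd
}

# step-up BH oracle via explicit k loop
brute_bh <- function(p, q) {
  m <- length(p)
  o <- order(p)
  k_max <- 0
  for (k in seq_len(m)) if (p[o[k]] <= q * k / m) k_max <- k
  rej <- logical(m)
  if (k_max > 0) rej[o[seq_len(k_max)]] <- TRUE
  rej
}

# connected-component oracle: iterative min-label propagation until stable
brute_label_sizes <- function(bin, connectivity = 6) {
  d <- dim(bin)
  offs <- switch(as.character(connectivity),
                 "6" = rbind(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1)))
  lab <- array(0, dim = d)
  lab[bin] <- seq_len(sum(bin))
  repeat {
    changed <- FALSE
    idx <- which(bin, arr.ind = TRUE)
    for (r in seq_len(nrow(idx))) {
      co <- idx[r, ]
      best <- lab[co[1], co[2], co[3]]
      for (k in seq_len(nrow(offs))) {
        nb <- co + offs[k, ]
        if (any(nb < 1) || any(nb > d)) next
        v <- lab[nb[1], nb[2], nb[3]]
        if (v > 0 && v < best) best <- v
      }
      if (best < lab[co[1], co[2], co[3]]) {
        lab[co[1], co[2], co[3]] <- best
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  sort(as.integer(table(lab[lab > 0])), decreasing = TRUE)
}

# minimal deterministic motion trace from a per-frame FD target on one axis
trace_from_fd <- function(fd_target, tr = 3) {
  p <- matrix(0, length(fd_target), 6)
  p[, 1] <- cumsum(fd_target)      # |backward diff of dx| reproduces fd_target
  motion_trace(p, tr)
}

tiny_config <- function(...) {
  args <- list(...)
  defaults <- list(n_scans = 6, n_roi = 8, frames = 60, seed = 7)
  do.call(simulation_config, utils::modifyList(defaults, args))
}

# amplitude of a sin/cos pair at frequency f in a series (least squares)
power_at <- function(x, f_hz, tr) {
  t <- (seq_along(x) - 1) * tr
  X <- cbind(sin(2 * pi * f_hz * t), cos(2 * pi * f_hz * t))
  cf <- qr.coef(qr(X), x)
  sum(cf^2)
}
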