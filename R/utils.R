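# Internal helpers shared across modules.

stopf <- function(fmt, ..., class = "motionscrub_error") {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "error", "condition")))
}

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x) && x >= 1 && x == floor(x)

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)

#' Deterministic sub-seed derivation
#'
#' All randomness in the package flows from a single master seed; per-scan and
#' per-stage sub-seeds are pure functions of (seed, index, salt) so that any
#' unit (one scan, one repeat) is reproducible in isolation. Kept below 2^31-1.
#'
#' @param seed master seed (integer-valued).
#' @param index unit index (e.g. scan number).
#' @param salt stage discriminator so different stages of the same unit do not
#'   share a stream.
#' @return an integer usable with [set.seed()].
#' @export
sub_seed <- function(seed, index, salt = 0L) {
  s <- (abs(as.double(seed)) %% 1e6) * 1009 + as.double(index) * 7919 +
    as.double(salt) * 104729 + 1
  as.integer(s %% 2147483646) + 1L
}

# verbose logging: controlled by option(motionscrub.verbose = TRUE) or an
# open connection in option(motionscrub.logfile)
log_info <- function(fmt, ...) {
  msg <- sprintf(fmt, ...)
  lf <- getOption("motionscrub.logfile", NULL)
  if (!is.null(lf)) cat(format(Sys.time(), "%H:%M:%S "), msg, "\n", file = lf, append = TRUE, sep = "")
  if (isTRUE(getOption("motionscrub.verbose", FALSE))) message("[motionscrub] ", msg)
  invisible(NULL)
}

# cap |r| away from 1 so atanh stays finite on degenerate fixtures
cap_r <- function(r, cap = 1 - 1e-7) pmin(pmax(r, -cap), cap)

# Fisher z without dof scaling
atanh_capped <- function(r, cap = 1 - 1e-7) atanh(cap_r(r, cap))
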