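# Internal numeric helpers shared across modules.

deg2rad <- function(deg) deg * pi / 180

rad2deg <- function(rad) rad * 180 / pi

# Wrap angles (degrees) onto [0, 360).
wrap_deg <- function(deg) deg %% 360

# FFT-friendly length with small prime factors.
next_fft_size <- function(n) stats::nextn(as.integer(n), c(2L, 3L, 5L))

#' Analytic signal via the frequency-domain Hilbert transform
#'
#' Returns the complex analytic signal `x + i*H(x)` of a real series. The
#' angle of the analytic signal of a band-limited trace is its instantaneous
#' phase; [instantaneous_phase()] converts it to the degree convention used
#' throughout (oscillation peak = 0 degrees).
#'
#' @param x Numeric vector (a real signal).
#' @return Complex vector of the same length.
#' @keywords internal
#' @noRd
analytic_signal <- function(x) {
  n <- length(x)
  if (n == 0L) stop("empty input", call. = FALSE)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1L] <- 1
    h[n / 2L + 1L] <- 1
    h[2L:(n / 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2L:((n + 1L) / 2L)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# Index of the maximum of x over the sliding window [i - half, i + half],
# for every centre i in [half + 1, n - half] (NA outside). Ties resolve to
# the earliest index. O(n) two-pass block cummax ("sparse table") scheme so
# megasample traces stay cheap.
rolling_argmax <- function(x, half) {
  n <- length(x)
  half <- as.integer(half)
  w <- 2L * half + 1L
  out <- rep(NA_integer_, n)
  if (n < w || half < 1L) return(out)
  nb <- ceiling(n / w)
  npad <- nb * w
  xp <- c(x, rep(-Inf, npad - n))
  pv <- matrix(xp, nrow = w)
  pidx <- matrix(seq_len(npad), nrow = w)
  sv <- pv
  sidx <- pidx
  for (r in 2:w) { # prefix running max within block, earliest tie kept (>)
    keep <- pv[r, ] > pv[r - 1L, ]
    pv[r, !keep] <- pv[r - 1L, !keep]
    pidx[r, !keep] <- pidx[r - 1L, !keep]
  }
  for (r in (w - 1L):1L) { # suffix running max, earliest tie kept (>=)
    keep <- sv[r, ] >= sv[r + 1L, ]
    sv[r, !keep] <- sv[r + 1L, !keep]
    sidx[r, !keep] <- sidx[r + 1L, !keep]
  }
  pv <- as.vector(pv); pidx <- as.vector(pidx)
  sv <- as.vector(sv); sidx <- as.vector(sidx)
  ctr <- (half + 1L):(n - half)
  L <- ctr - half
  R <- ctr + half # window width equals block width, so suffix(L)+prefix(R)
  left_wins <- sv[L] >= pv[R]
  out[ctr] <- ifelse(left_wins, sidx[L], pidx[R])
  out
}

# Sub-sample refinement of a local extremum position by fitting a parabola
# through (i-1, i, i+1). Returns a continuous 1-based index.
refine_extremum <- function(y, i) {
  n <- length(y)
  if (i <= 1L || i >= n) return(as.numeric(i))
  denom <- y[i - 1L] - 2 * y[i] + y[i + 1L]
  if (abs(denom) < .Machine$double.eps) return(as.numeric(i))
  delta <- 0.5 * (y[i - 1L] - y[i + 1L]) / denom
  delta <- max(min(delta, 0.5), -0.5)
  i + delta
}

# Local RNG scope: runs expr with set.seed(seed) and restores the caller's
# RNG state afterwards. seed = NULL leaves the global stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}
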