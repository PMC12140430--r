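# Sub-pixel drift correction by cross-correlation. The coarse shift comes
# from the FFT cross-correlation peak; sub-pixel refinement evaluates the
# cross-correlation on an upsampled grid around the coarse peak with a
# matrix-multiply DFT, so only the neighbourhood of the peak is upsampled.

# Tukey (tapered-cosine) apodization: flat over the interior so that a pure
# translation of interior content stays a pure translation (a Hann window
# biases the sub-pixel peak towards zero), tapering to zero at the edges to
# suppress wrap-around.
.tukey1 <- function(n, alpha = 0.25) {
  x <- (seq_len(n) - 1) / (n - 1)
  w <- rep(1, n)
  lo <- x < alpha / 2
  hi <- x > 1 - alpha / 2
  w[lo] <- 0.5 * (1 + cos(pi * (2 * x[lo] / alpha - 1)))
  w[hi] <- 0.5 * (1 + cos(pi * (2 * (x[hi] - 1) / alpha + 1)))
  w
}

.hann2 <- function(nr, nc) outer(.tukey1(nr), .tukey1(nc))

.fftfreq <- function(n) c(0:floor((n - 1) / 2), -(n - floor((n - 1) / 2) - 1):-1) / n

#' Estimate the translation between two images to sub-pixel precision
#'
#' Finds the shift `(dy, dx)` such that `moving` is (approximately)
#' `reference` translated by that vector. Both images are apodized with a
#' Hann window before correlation to suppress edge wrap-around bias. The
#' confidence is the normalized cross-correlation peak height in `[0, 1]`;
#' values below `reliable_threshold` indicate that no consistent
#' translation relates the two images (e.g. pure noise).
#'
#' @param reference,moving numeric matrices of identical shape.
#' @param upsample integer >= 1; the shift is refined to `1/upsample` px.
#' @param reliable_threshold confidence below which the estimate is flagged
#'   unreliable (default 0.1, calibrated on independent-noise image pairs).
#' @return List with `shift` (c(dy, dx)), `confidence`, `reliable`.
#' @export
estimate_shift <- function(reference, moving, upsample = 10L,
                           reliable_threshold = 0.1) {
  if (!all(dim(reference) == dim(moving)))
    stop("reference and moving images must have the same shape")
  if (upsample < 1L) stop("upsample must be >= 1")
  nr <- nrow(reference); nc <- ncol(reference)
  w <- .hann2(nr, nc)
  a <- (reference - mean(reference)) * w
  b <- (moving - mean(moving)) * w
  R <- fft(a) * Conj(fft(b))
  cc <- Re(fft(R, inverse = TRUE)) / (nr * nc)
  pk <- which(cc == max(cc), arr.ind = TRUE)[1, ]
  # wrap peak indices (1-based) to signed shifts; cc[1 + s] corresponds to
  # moving displaced by -s, so negate to report the displacement of moving
  dy <- pk[1] - 1L; dx <- pk[2] - 1L
  if (dy > nr / 2) dy <- dy - nr
  if (dx > nc / 2) dx <- dx - nc
  shift <- c(-dy, -dx)
  peak <- max(cc)
  if (upsample > 1L) {
    step <- 1 / upsample
    offr <- -dy + seq(-1.5, 1.5, by = step)
    offc <- -dx + seq(-1.5, 1.5, by = step)
    fy <- .fftfreq(nr); fx <- .fftfreq(nc)
    # CC(u, v) = sum_kl R[k, l] exp(2*pi*i*(fy k)(-u)) exp(2*pi*i*(fx l)(-v))
    kr <- exp(-2i * pi * outer(offr, fy))        # length(offr) x nr
    kc <- exp(-2i * pi * outer(fx, offc))        # nc x length(offc)
    ccu <- Re(kr %*% R %*% kc) / (nr * nc)
    pku <- which(ccu == max(ccu), arr.ind = TRUE)[1, ]
    shift <- c(offr[pku[1]], offc[pku[2]])
    peak <- max(ccu)
  }
  conf <- peak / sqrt(sum(a^2) * sum(b^2))
  conf <- clamp(conf, 0, 1)
  list(shift = as.numeric(shift), confidence = as.numeric(conf),
       reliable = conf >= reliable_threshold)
}

#' Register a time-lapse stack against its first frame
#'
#' Frame-to-frame shifts are estimated on a user-selected reference channel,
#' accumulated relative to frame 1, and the inverse shift is applied to all
#' channels with sub-pixel (Fourier) interpolation. Steps whose magnitude
#' exceeds `max_step`, or whose correlation confidence is unreliable, are
#' replaced by the previous accepted step and flagged.
#'
#' @param stacks either a list of per-frame matrices (single channel) or a
#'   list of such lists (one per channel, all the same length).
#' @param reference_channel index of the channel used for estimation.
#' @param upsample sub-pixel refinement factor (default 10 = 0.1 px).
#' @param max_step maximum plausible frame-to-frame drift step in pixels.
#' @return List with `aligned` (same structure as `stacks`) and `shifts`,
#'   a data frame (`frame`, `dy`, `dx`, cumulative relative to frame 1,
#'   `confidence`, `clamped`).
#' @export
register_stack <- function(stacks, reference_channel = 1L, upsample = 10L,
                           max_step = 10) {
  single <- is.matrix(stacks[[1]])
  if (single) stacks <- list(stacks)
  if (reference_channel > length(stacks))
    stop("reference_channel ", reference_channel, " not present")
  ref <- stacks[[reference_channel]]
  nT <- length(ref)
  dy <- numeric(nT); dx <- numeric(nT)
  conf <- rep(1, nT); clamped <- rep(FALSE, nT)
  prev_step <- c(0, 0)
  for (t in seq_len(nT)[-1]) {
    est <- estimate_shift(ref[[t - 1L]], ref[[t]], upsample = upsample)
    step <- est$shift
    conf[t] <- est$confidence
    if (!est$reliable || max(abs(step)) > max_step) {
      step <- prev_step
      clamped[t] <- TRUE
    } else prev_step <- step
    dy[t] <- dy[t - 1L] + step[1]
    dx[t] <- dx[t - 1L] + step[2]
  }
  # second pass: sequential estimation accumulates error like a random walk,
  # so refine each frame's cumulative shift directly against frame 1
  for (t in seq_len(nT)[-1]) {
    if (clamped[t]) next
    pre <- fourier_shift(ref[[t]], -dy[t], -dx[t], fill = median(ref[[t]]))
    res <- estimate_shift(ref[[1]], pre, upsample = upsample)
    if (res$reliable && max(abs(res$shift)) <= 1.5) {
      dy[t] <- dy[t] + res$shift[1]
      dx[t] <- dx[t] + res$shift[2]
    }
  }
  aligned <- lapply(stacks, function(ch)
    lapply(seq_len(nT), function(t) {
      if (dy[t] == 0 && dx[t] == 0) return(ch[[t]])
      fourier_shift(ch[[t]], -dy[t], -dx[t], fill = median(ch[[t]]))
    }))
  shifts <- data.frame(frame = seq_len(nT), dy = dy, dx = dx,
                       confidence = conf, clamped = clamped)
  list(aligned = if (single) aligned[[1]] else aligned, shifts = shifts)
}
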