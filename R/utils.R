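# Shared helpers: seeded substreams, small numeric utilities.

#' Derive a reproducible substream seed from a root seed and a stream name
#'
#' All randomness in the package flows from one root seed through named
#' substreams (e.g. "division", "render", "foci"), so that individual stages
#' can be re-run independently and still reproduce byte-identical output.
#'
#' @param seed integer root seed.
#' @param name character stream name.
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  h <- 0
  for (b in utf8ToInt(name)) h <- (h * 131 + b) %% 2147483647
  as.integer((abs(seed) * 2654435 + h * 97 + 12345) %% 2147483647)
}

# Evaluate expr with the RNG seeded from (seed, name), restoring the caller's
# RNG state afterwards.
with_substream <- function(seed, name, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(substream_seed(seed, name))
  expr
}

# Clamp numeric vector into [lo, hi].
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Angular difference between two axis orientations (mod pi), in radians.
axis_angle_diff <- function(a, b) {
  d <- abs(a - b) %% pi
  pmin(d, pi - d)
}

# Integer labels present in a mask (excluding background 0).
mask_labels <- function(mask) {
  u <- sort(unique(as.integer(mask)))
  u[u > 0L]
}

# Region areas as a named integer vector (names = label).
region_areas <- function(mask) {
  v <- as.integer(mask)
  v <- v[v > 0L]
  if (length(v) == 0L) return(setNames(integer(0), character(0)))
  tab <- table(v)
  setNames(as.integer(tab), names(tab))
}

# 4-neighbour shifted copies of a matrix, padded with `fill`.
shift_mat <- function(m, dr, dc, fill = 0L) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1L, 1L + dr):min(nr, nr + dr)
  cs <- max(1L, 1L + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

# Pixels of a labelled mask that touch (4-connectivity) a different label or
# the background; returns a logical matrix.
label_boundary <- function(mask) {
  b <- matrix(FALSE, nrow(mask), ncol(mask))
  for (d in list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))) {
    nb <- shift_mat(mask, d[1], d[2], fill = 0L)
    b <- b | (mask > 0L & nb != mask)
  }
  b
}

# Background pixels 4-adjacent to any cell.
background_halo <- function(mask) {
  h <- matrix(FALSE, nrow(mask), ncol(mask))
  for (d in list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))) {
    nb <- shift_mat(mask, d[1], d[2], fill = 0L)
    h <- h | (mask == 0L & nb > 0L)
  }
  h
}

# Orientation of a pixel set from second moments, in (-pi/2, pi/2].
# Measured as the angle of the major axis relative to the column (x) axis.
pixel_orientation <- function(rows, cols) {
  mr <- mean(rows); mc <- mean(cols)
  crr <- mean((rows - mr)^2); ccc <- mean((cols - mc)^2)
  crc <- mean((rows - mr) * (cols - mc))
  0.5 * atan2(2 * crc, ccc - crr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
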