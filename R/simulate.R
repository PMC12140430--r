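# Agent-based simulator of a rod-shaped bacterial microcolony growing as a
# monolayer from a single progenitor. Cells are spherocylinders (rectangle
# plus semicircular caps) that elongate exponentially, divide by binary
# fission with a slightly asymmetric septum, and are kept from overlapping
# by iterative pairwise mechanical relaxation. The simulator is the ground
# truth oracle for segmentation, linking, cytometry and evaluation tests.

#' Simulation parameters for a synthetic microcolony
#'
#' Defaults describe a typical *E. coli* agarose-pad time-lapse: 100 nm
#' pixels, a frame every 3 minutes, and exponential growth with a ~25 min
#' doubling time so that a single progenitor reaches a >100-cell microcolony
#' within 60 frames.
#'
#' @param pixel_size micrometers per pixel.
#' @param frame_interval minutes between frames.
#' @param n_frames number of frames to simulate.
#' @param image_shape integer (rows, cols) of the rendered field.
#' @param init_length progenitor pole-to-pole length, micrometers.
#' @param width cell width (diameter), micrometers.
#' @param growth_rate exponential length growth rate, 1/min.
#' @param division_length_mean mean pole-to-pole length at division, micrometers.
#' @param division_length_cv coefficient of variation of the division length.
#' @param division_asymmetry_sd standard deviation of the septum position
#'   around the midpoint (fraction of length).
#' @param seed integer root seed; all randomness flows from it.
#' @return An object of class `sim_params` (a validated list).
#' @export
sim_params <- function(pixel_size = 0.1, frame_interval = 3, n_frames = 60,
                       image_shape = c(512L, 512L), init_length = 2,
                       width = 1, growth_rate = log(2) / 25,
                       division_length_mean = 4, division_length_cv = 0.05,
                       division_asymmetry_sd = 0.02, seed = 1L) {
  p <- list(pixel_size = pixel_size, frame_interval = frame_interval,
            n_frames = as.integer(n_frames),
            image_shape = as.integer(image_shape),
            init_length = init_length, width = width,
            growth_rate = growth_rate,
            division_length_mean = division_length_mean,
            division_length_cv = division_length_cv,
            division_asymmetry_sd = division_asymmetry_sd,
            seed = as.integer(seed))
  validate_sim_params(p)
  structure(p, class = "sim_params")
}

validate_sim_params <- function(p) {
  stopifnot(p$pixel_size > 0, p$frame_interval > 0, p$n_frames >= 1L,
            length(p$image_shape) == 2L, all(p$image_shape >= 8L))
  if (p$width <= 0) stop("width must be > 0")
  if (p$init_length < p$width) stop("init_length must be >= width")
  if (p$growth_rate <= 0) stop("growth_rate must be > 0")
  # both daughters must be viable rods: half the division length >= width
  if (p$division_length_mean / 2 < p$width)
    stop("division_length_mean too small: daughters would be shorter than wide")
  invisible(p)
}

# Axis segment endpoints of a spherocylinder: the segment has length
# (length - width) so that the surface at distance width/2 spans pole-to-pole.
rod_segment <- function(x, y, theta, len, width) {
  h <- pmax(len - width, 0) / 2
  ux <- cos(theta); uy <- sin(theta)
  cbind(x1 = x - ux * h, y1 = y - uy * h, x2 = x + ux * h, y2 = y + uy * h)
}

# Closest-point distance between two segments plus the closest points
# themselves; vectorized over rows of seg1/seg2 (n x 4 matrices).
segment_distance <- function(seg1, seg2) {
  d1x <- seg1[, 3] - seg1[, 1]; d1y <- seg1[, 4] - seg1[, 2]
  d2x <- seg2[, 3] - seg2[, 1]; d2y <- seg2[, 4] - seg2[, 2]
  rx <- seg1[, 1] - seg2[, 1]; ry <- seg1[, 2] - seg2[, 2]
  a <- d1x^2 + d1y^2; e <- d2x^2 + d2y^2
  b <- d1x * d2x + d1y * d2y
  c_ <- d1x * rx + d1y * ry
  f <- d2x * rx + d2y * ry
  denom <- a * e - b^2
  s <- ifelse(denom > 1e-12, clamp((b * f - c_ * e) / denom, 0, 1), 0)
  t <- ifelse(e > 1e-12, clamp((b * s + f) / e, 0, 1), 0)
  # re-clamp s against the refined t
  s <- ifelse(a > 1e-12, clamp((b * t - c_) / a, 0, 1), 0)
  p1x <- seg1[, 1] + s * d1x; p1y <- seg1[, 2] + s * d1y
  p2x <- seg2[, 1] + t * d2x; p2y <- seg2[, 2] + t * d2y
  list(dist = sqrt((p1x - p2x)^2 + (p1y - p2y)^2),
       p1x = p1x, p1y = p1y, p2x = p2x, p2y = p2y)
}

# Iterative pairwise repulsion keeping the colony a monolayer of touching,
# non-overlapping rods. Displacement along the line of closest approach with
# a small angular torque; fixed iteration budget.
relax_rods <- function(st, max_iter = 400, tol_frac = 0.02) {
  n <- nrow(st)
  if (n < 2L) return(st)
  tol <- tol_frac * mean(st$width)
  for (it in seq_len(max_iter)) {
    seg <- rod_segment(st$x, st$y, st$theta, st$length, st$width)
    pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    i <- pairs[, 1]; j <- pairs[, 2]
    # prune pairs that cannot touch
    reach <- (st$length[i] + st$length[j]) / 2
    near <- (st$x[i] - st$x[j])^2 + (st$y[i] - st$y[j])^2 <= reach^2
    i <- i[near]; j <- j[near]
    if (length(i) == 0L) break
    sd_ <- segment_distance(seg[i, , drop = FALSE], seg[j, , drop = FALSE])
    ov <- (st$width[i] + st$width[j]) / 2 - sd_$dist
    hit <- ov > tol
    if (!any(hit)) break
    i <- i[hit]; j <- j[hit]
    ov <- ov[hit]
    dx <- sd_$p2x[hit] - sd_$p1x[hit]; dy <- sd_$p2y[hit] - sd_$p1y[hit]
    dn <- sqrt(dx^2 + dy^2)
    # coincident closest points: push along the line of centers
    z <- dn < 1e-9
    if (any(z)) {
      dx[z] <- st$x[j][z] - st$x[i][z]; dy[z] <- st$y[j][z] - st$y[i][z]
      dn[z] <- sqrt(dx[z]^2 + dy[z]^2)
      still <- dn < 1e-9
      dx[z][still] <- 1; dy[z][still] <- 0; dn[z][still] <- 1
    }
    ux <- dx / dn; uy <- dy / dn
    push <- 0.6 * ov / 2
    ddx <- numeric(n); ddy <- numeric(n); dth <- numeric(n)
    for (k in seq_along(i)) {
      a <- i[k]; b <- j[k]
      ddx[a] <- ddx[a] - ux[k] * push[k]; ddy[a] <- ddy[a] - uy[k] * push[k]
      ddx[b] <- ddx[b] + ux[k] * push[k]; ddy[b] <- ddy[b] + uy[k] * push[k]
      # torque: lever arm from center to contact point crossed with the push
      rax <- sd_$p1x[hit][k] - st$x[a]; ray <- sd_$p1y[hit][k] - st$y[a]
      rbx <- sd_$p2x[hit][k] - st$x[b]; rby <- sd_$p2y[hit][k] - st$y[b]
      dth[a] <- dth[a] + 4 * (rax * (-uy[k]) - ray * (-ux[k])) * push[k] / (st$length[a]^2 + 1e-9)
      dth[b] <- dth[b] + 4 * (rbx * uy[k] - rby * ux[k]) * push[k] / (st$length[b]^2 + 1e-9)
    }
    st$x <- st$x + ddx
    st$y <- st$y + ddy
    st$theta <- st$theta + clamp(dth, -0.05, 0.05)
  }
  st
}

# Rasterize rods onto a label image: a pixel is claimed when its center lies
# inside the rod; contested pixels go to the nearest rod axis.
rasterize_rods <- function(st, image_shape, pixel_size) {
  nr <- image_shape[1]; nc <- image_shape[2]
  lab <- matrix(0L, nr, nc)
  best <- matrix(Inf, nr, nc)
  seg <- rod_segment(st$x, st$y, st$theta, st$length, st$width)
  for (k in seq_len(nrow(st))) {
    halfw <- st$width[k] / 2
    rx <- range(seg[k, c(1, 3)]); ry <- range(seg[k, c(2, 4)])
    c0 <- max(1L, floor((rx[1] - halfw) / pixel_size) ); c1 <- min(nc, ceiling((rx[2] + halfw) / pixel_size) + 1L)
    r0 <- max(1L, floor((ry[1] - halfw) / pixel_size) ); r1 <- min(nr, ceiling((ry[2] + halfw) / pixel_size) + 1L)
    if (c0 > c1 || r0 > r1) next
    cols <- c0:c1; rows <- r0:r1
    px <- (rep(cols, each = length(rows)) - 0.5) * pixel_size
    py <- (rep(rows, times = length(cols)) - 0.5) * pixel_size
    # distance from pixel centers to the axis segment
    dxs <- seg[k, 3] - seg[k, 1]; dys <- seg[k, 4] - seg[k, 2]
    len2 <- dxs^2 + dys^2
    tt <- if (len2 < 1e-12) rep(0, length(px)) else
      clamp(((px - seg[k, 1]) * dxs + (py - seg[k, 2]) * dys) / len2, 0, 1)
    qx <- seg[k, 1] + tt * dxs; qy <- seg[k, 2] + tt * dys
    d <- sqrt((px - qx)^2 + (py - qy)^2)
    dm <- matrix(d, nrow = length(rows))
    sub_best <- best[rows, cols, drop = FALSE]
    claim <- dm <= halfw + 1e-9 & dm < sub_best
    if (any(claim)) {
      sub_lab <- lab[rows, cols, drop = FALSE]
      sub_lab[claim] <- st$cell_id[k]
      sub_best[claim] <- dm[claim]
      lab[rows, cols] <- sub_lab
      best[rows, cols] <- sub_best
    }
  }
  lab
}

# TRUE when any part of any rod (including its width) leaves the field.
rods_out_of_bounds <- function(st, image_shape, pixel_size) {
  seg <- rod_segment(st$x, st$y, st$theta, st$length, st$width)
  halfw <- st$width / 2
  xmax <- image_shape[2] * pixel_size; ymax <- image_shape[1] * pixel_size
  any(pmin(seg[, 1], seg[, 3]) - halfw < 0 | pmax(seg[, 1], seg[, 3]) + halfw > xmax |
      pmin(seg[, 2], seg[, 4]) - halfw < 0 | pmax(seg[, 2], seg[, 4]) + halfw > ymax)
}

#' Simulate a growing rod-shaped microcolony with ground truth
#'
#' Grows a monolayer colony from a single progenitor: cell lengths grow
#' exponentially at `growth_rate`, a cell divides when it reaches its target
#' division length (septum at fraction `0.5 + eps`,
#' `eps ~ N(0, division_asymmetry_sd)`, both daughters inheriting the
#' mother's orientation), and overlaps are resolved by iterative pairwise
#' repulsion so that rod interiors never overlap while contact is allowed.
#' Identical parameters and seed give bit-identical output.
#'
#' @param params a [sim_params()] object.
#' @return An object of class `colony_sim`: list with `params`, `states`
#'   (one data frame of rod geometry per frame), `masks` (one integer label
#'   matrix per frame, label = cell id), `lineage` (data frame with
#'   `cell_id`, `mother_id`, `birth_frame`, `division_frame`, `daughter1`,
#'   `daughter2`), `truncated` flag and `n_frames` realized.
#' @export
simulate_colony <- function(params) {
  validate_sim_params(params)
  p <- params
  with_substream(p$seed, "colony", {
    xmid <- p$image_shape[2] * p$pixel_size / 2
    ymid <- p$image_shape[1] * p$pixel_size / 2
    theta0 <- runif(1, 0, pi)
    st <- data.frame(cell_id = 1L, mother_id = NA_integer_, birth_frame = 1L,
                     x = xmid, y = ymid, theta = theta0,
                     length = p$init_length, width = p$width,
                     target_len = draw_target(p), new_pole_sign = 0L)
    lin <- data.frame(cell_id = 1L, mother_id = NA_integer_, birth_frame = 1L,
                      division_frame = NA_integer_,
                      daughter1 = NA_integer_, daughter2 = NA_integer_)
    next_id <- 2L
    states <- vector("list", p$n_frames)
    masks <- vector("list", p$n_frames)
    truncated <- FALSE
    dt <- p$frame_interval
    for (t in seq_len(p$n_frames)) {
      if (t > 1L) {
        st$length <- st$length * exp(p$growth_rate * dt)
        # divisions (processed in cell id order for reproducibility)
        due <- which(st$length >= st$target_len)
        due <- due[order(st$cell_id[due])]
        if (length(due) > 0L) {
          new_rows <- list()
          for (k in due) {
            m <- st[k, ]
            eps <- rnorm(1, 0, p$division_asymmetry_sd)
            f <- clamp(0.5 + eps, 0.2, 0.8)
            L1 <- f * m$length; L2 <- (1 - f) * m$length
            ux <- cos(m$theta); uy <- sin(m$theta)
            c1 <- c(m$x - ux * (m$length - L1) / 2, m$y - uy * (m$length - L1) / 2)
            c2 <- c(m$x + ux * (m$length - L2) / 2, m$y + uy * (m$length - L2) / 2)
            ids <- c(next_id, next_id + 1L)
            next_id <- next_id + 2L
            d <- data.frame(cell_id = ids, mother_id = m$cell_id,
                            birth_frame = t,
                            x = c(c1[1], c2[1]), y = c(c1[2], c2[2]),
                            theta = m$theta, length = c(L1, L2),
                            width = p$width,
                            target_len = c(draw_target(p), draw_target(p)),
                            new_pole_sign = c(1L, -1L))
            new_rows[[length(new_rows) + 1L]] <- d
            lin$division_frame[lin$cell_id == m$cell_id] <- t - 1L
            lin$daughter1[lin$cell_id == m$cell_id] <- ids[1]
            lin$daughter2[lin$cell_id == m$cell_id] <- ids[2]
            lin <- rbind(lin, data.frame(cell_id = ids, mother_id = m$cell_id,
                                         birth_frame = t,
                                         division_frame = NA_integer_,
                                         daughter1 = NA_integer_,
                                         daughter2 = NA_integer_))
          }
          st <- rbind(st[-due, ], do.call(rbind, new_rows))
          st <- st[order(st$cell_id), ]
          rownames(st) <- NULL
        }
        st <- relax_rods(st)
      }
      if (rods_out_of_bounds(st, p$image_shape, p$pixel_size)) {
        truncated <- TRUE
        warning("colony exceeded image bounds at frame ", t,
                "; simulation stopped at frame ", t - 1L)
        states <- states[seq_len(t - 1L)]
        masks <- masks[seq_len(t - 1L)]
        break
      }
      states[[t]] <- st
      masks[[t]] <- rasterize_rods(st, p$image_shape, p$pixel_size)
    }
    realized <- length(states)
    # prune lineage entries for cells born after truncation, and undo
    # division records whose daughters fell outside the realized movie
    lin <- lin[lin$birth_frame <= realized, ]
    gone <- !is.na(lin$daughter1) & !(lin$daughter1 %in% lin$cell_id)
    lin$division_frame[gone] <- NA_integer_
    lin$daughter1[gone] <- NA_integer_
    lin$daughter2[gone] <- NA_integer_
    structure(list(params = p, states = states, masks = masks,
                   lineage = lin[order(lin$cell_id), ],
                   truncated = truncated, n_frames = realized),
              class = "colony_sim")
  })
}

draw_target <- function(p) {
  if (p$division_length_cv <= 0) return(p$division_length_mean)
  max(p$division_length_mean * (1 + rnorm(1, 0, p$division_length_cv)),
      2 * p$width)
}

#' Live-cell count per frame of a simulation
#' @param sim a `colony_sim` object.
#' @return Integer vector, one count per realized frame.
#' @export
sim_cell_counts <- function(sim) {
  vapply(sim$states, nrow, integer(1))
}

#' @export
print.colony_sim <- function(x, ...) {
  cat("colony_sim:", x$n_frames, "frames,",
      nrow(x$lineage), "cells total,",
      nrow(x$states[[x$n_frames]]), "alive at end",
      if (x$truncated) "(truncated at image bounds)" else "", "\n")
  invisible(x)
}
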