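# Per-cell-per-frame and per-cell descriptors. Geometry comes from the
# medial axis: the region skeleton pruned to its longest path gives the
# cell axis, its arc length (extended to the poles) the cell length, and
# the distance transform sampled along it the cell width. Fluorescence is
# summarized per channel against a per-frame global background; foci are
# detected by band-pass filtering with sub-pixel refinement and projected
# onto the axis.

#' Cytometry parameters
#'
#' @param pixel_size micrometers per pixel.
#' @param frame_interval minutes between frames.
#' @param foci_channel channel index scanned for fluorescent foci (NA = none).
#' @param focus_sigma expected focus size (Gaussian sigma, px) for the
#'   band-pass detector.
#' @param focus_k detection threshold in units of the robust noise sd.
#' @param focus_min_amp absolute floor on the band-pass peak amplitude
#'   (intensity units on images scaled to `[0, 1]`); rejects faint residual
#'   cell-interior structure that is not a diffraction-limited focus.
#' @param min_area_px regions smaller than this get missing geometry.
#' @return A `cyto_params` list.
#' @export
cyto_params <- function(pixel_size = 0.1, frame_interval = 3,
                        foci_channel = NA_integer_, focus_sigma = 1.5,
                        focus_k = 5, focus_min_amp = 0.08, min_area_px = 5L) {
  structure(list(pixel_size = pixel_size, frame_interval = frame_interval,
                 foci_channel = foci_channel, focus_sigma = focus_sigma,
                 focus_k = focus_k, focus_min_amp = focus_min_amp,
                 min_area_px = as.integer(min_area_px)),
            class = "cyto_params")
}

# Zhang-Suen thinning of a logical matrix to a 1-px skeleton (8-connected).
skeletonize <- function(bw) {
  p <- matrix(0L, nrow(bw) + 2L, ncol(bw) + 2L)
  p[2:(nrow(bw) + 1L), 2:(ncol(bw) + 1L)] <- bw * 1L
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      # neighbours clockwise from north: P2 P3 P4 P5 P6 P7 P8 P9
      n2 <- shift_mat(p, 1L, 0L);  n3 <- shift_mat(p, 1L, -1L)
      n4 <- shift_mat(p, 0L, -1L); n5 <- shift_mat(p, -1L, -1L)
      n6 <- shift_mat(p, -1L, 0L); n7 <- shift_mat(p, -1L, 1L)
      n8 <- shift_mat(p, 0L, 1L);  n9 <- shift_mat(p, 1L, 1L)
      b <- n2 + n3 + n4 + n5 + n6 + n7 + n8 + n9
      a <- (n2 == 0L & n3 == 1L) + (n3 == 0L & n4 == 1L) +
        (n4 == 0L & n5 == 1L) + (n5 == 0L & n6 == 1L) +
        (n6 == 0L & n7 == 1L) + (n7 == 0L & n8 == 1L) +
        (n8 == 0L & n9 == 1L) + (n9 == 0L & n2 == 1L)
      if (sub == 1) {
        cond <- p == 1L & b >= 2L & b <= 6L & a == 1L &
          (n2 * n4 * n6 == 0L) & (n4 * n6 * n8 == 0L)
      } else {
        cond <- p == 1L & b >= 2L & b <= 6L & a == 1L &
          (n2 * n4 * n8 == 0L) & (n2 * n6 * n8 == 0L)
      }
      if (any(cond)) {
        p[cond] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  p[2:(nrow(bw) + 1L), 2:(ncol(bw) + 1L)] > 0L
}

# BFS over 8-connected skeleton pixels from a start node; returns distances
# and parents (indices into the coords matrix).
.skel_bfs <- function(coords, posmap, dims, start) {
  n <- nrow(coords)
  dist <- rep(NA_integer_, n); parent <- rep(NA_integer_, n)
  dist[start] <- 0L
  queue <- integer(n); queue[1] <- start; qh <- 1L; qt <- 1L
  offs <- cbind(rep(-1:1, 3), rep(-1:1, each = 3))
  offs <- offs[!(offs[, 1] == 0 & offs[, 2] == 0), ]
  while (qh <= qt) {
    cur <- queue[qh]; qh <- qh + 1L
    rr <- coords[cur, 1] + offs[, 1]; cc <- coords[cur, 2] + offs[, 2]
    ok <- rr >= 1L & rr <= dims[1] & cc >= 1L & cc <= dims[2]
    nb <- posmap[(cc[ok] - 1L) * dims[1] + rr[ok]]
    nb <- nb[nb > 0L]
    for (v in nb) if (is.na(dist[v])) {
      dist[v] <- dist[cur] + 1L
      parent[v] <- cur
      qt <- qt + 1L; queue[qt] <- v
    }
  }
  list(dist = dist, parent = parent)
}

# Longest geodesic path through the skeleton (double BFS), as an ordered
# coordinate matrix.
skeleton_longest_path <- function(skel) {
  coords <- which(skel, arr.ind = TRUE)
  n <- nrow(coords)
  if (n == 0L) return(NULL)
  if (n == 1L) return(coords)
  posmap <- integer(prod(dim(skel)))
  posmap[(coords[, 2] - 1L) * nrow(skel) + coords[, 1]] <- seq_len(n)
  b1 <- .skel_bfs(coords, posmap, dim(skel), 1L)
  far1 <- which.max(ifelse(is.na(b1$dist), -1L, b1$dist))
  b2 <- .skel_bfs(coords, posmap, dim(skel), far1)
  far2 <- which.max(ifelse(is.na(b2$dist), -1L, b2$dist))
  path <- integer(0)
  cur <- far2
  while (!is.na(cur)) {
    path <- c(path, cur)
    cur <- b2$parent[cur]
  }
  coords[path, , drop = FALSE]
}

# Moving-average smoothing of a polyline (k odd), endpoints preserved by
# reflective padding.
.smooth_polyline <- function(xy, k = 5L) {
  n <- nrow(xy)
  if (n < 3L || k < 3L) return(xy)
  k <- min(k, if (n %% 2L == 1L) n else n - 1L)
  half <- k %/% 2L
  pad <- rbind(xy[rep(1L, half), , drop = FALSE], xy,
               xy[rep(n, half), , drop = FALSE])
  out <- xy
  cs <- apply(pad, 2, cumsum)
  for (j in 1:2)
    out[, j] <- (cs[(half * 2L + 1L):(n + 2L * half), j] -
                   c(0, cs[seq_len(n - 1L), j])) / k
  out
}

#' Medial-axis geometry of one cell region
#'
#' The region skeleton is pruned to its longest path, smoothed, and
#' extended to the cell boundary at both ends along the local axis
#' direction. Length is the arc length of that polyline (pole to pole);
#' width is twice the mean distance-transform value along the axis,
#' excluding one cap-length at each end where the caps bias the distance
#' transform downward.
#'
#' @param region logical matrix (the cell's pixels, full frame or crop).
#' @param pixel_size micrometers per pixel.
#' @return List with `length_um`, `width_mean_um`, `width_max_um`,
#'   `poles` (2x2 matrix of row/col), `axis` (polyline matrix row/col in
#'   the input's coordinates), `ok` flag. Regions under 5 px give `ok =
#'   FALSE` with missing metrics.
#' @export
medial_axis_metrics <- function(region, pixel_size = 0.1) {
  bad <- list(length_um = NA_real_, width_mean_um = NA_real_,
              width_max_um = NA_real_, poles = NULL, axis = NULL, ok = FALSE)
  area <- sum(region)
  if (area < 5L) return(bad)
  rc <- which(region, arr.ind = TRUE)
  r0 <- min(rc[, 1]) - 2L; c0 <- min(rc[, 2]) - 2L
  crop <- matrix(FALSE, diff(range(rc[, 1])) + 5L, diff(range(rc[, 2])) + 5L)
  crop[cbind(rc[, 1] - r0, rc[, 2] - c0)] <- TRUE
  dt <- EBImage::imageData(EBImage::distmap(EBImage::Image(crop)))
  skel <- skeletonize(crop)
  path <- skeleton_longest_path(skel)
  if (is.null(path) || nrow(path) < 2L) {
    # near-isotropic region (e.g. a disk): the thinning collapses; fall
    # back to a single-point axis at the distance-transform maximum,
    # oriented by the pixel second moments
    ctr <- which(dt == max(dt), arr.ind = TRUE)[1, , drop = FALSE]
    th <- pixel_orientation(rc[, 1] - r0, rc[, 2] - c0)
    path <- rbind(ctr, ctr + c(sin(th), cos(th)) * 0.01)
    dimnames(path) <- NULL
  }
  path <- path[, 1:2, drop = FALSE]
  sm <- .smooth_polyline(path, 5L)
  np <- nrow(sm)
  # extend each end to the cell pole: the farthest region pixel along the
  # local axis direction within a narrow band around the ray (plus half a
  # pixel for that pixel's own extent)
  crc <- which(crop, arr.ind = TRUE)
  march <- function(endpt, dirv) {
    rel_r <- crc[, 1] - endpt[1]; rel_c <- crc[, 2] - endpt[2]
    d <- rel_r * dirv[1] + rel_c * dirv[2]
    perp <- abs(rel_r * (-dirv[2]) + rel_c * dirv[1])
    cand <- perp <= 1.5 & d >= 0
    e <- if (any(cand)) max(d[cand]) + 0.5 else 0.5
    endpt + dirv * e
  }
  ends <- list()
  for (side in c(1L, -1L)) {
    idx <- if (side == 1L) c(min(np, 4L), 1L) else c(max(1L, np - 3L), np)
    dirv <- sm[idx[2], ] - sm[idx[1], ]
    nv <- sqrt(sum(dirv^2))
    dirv <- if (nv < 1e-9) c(1, 0) else dirv / nv
    ends[[as.character(side)]] <- march(sm[idx[2], ], dirv)
  }
  axis <- rbind(ends[["1"]], sm, ends[["-1"]])
  seglen <- sqrt(rowSums((axis[-1, , drop = FALSE] -
                            axis[-nrow(axis), , drop = FALSE])^2))
  len_px <- sum(seglen)
  # width: per axis sample, distance to the nearest boundary-pixel center
  # plus half a pixel (the boundary pixel's own extent); sampling excludes
  # one cap-length at each end where the caps bias the estimate downward
  bnd <- crop
  for (d in list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L)))
    bnd <- bnd & shift_mat(crop, d[1], d[2], fill = FALSE)
  bpx <- which(crop & !bnd, arr.ind = TRUE)
  halfw <- vapply(seq_len(nrow(sm)), function(i) {
    j <- clamp(i, 2L, np) ; dirv <- sm[j, ] - sm[j - 1L, ]
    nv <- sqrt(sum(dirv^2))
    if (nv < 1e-9) dirv <- c(0, 1) else dirv <- dirv / nv
    dr <- bpx[, 1] - sm[i, 1]; dc <- bpx[, 2] - sm[i, 2]
    perp <- dr * (-dirv[2]) + dc * dirv[1]  # signed distance along the normal
    d2 <- sqrt(dr^2 + dc^2)
    pos <- perp > 0; neg <- perp < 0
    if (!any(pos) || !any(neg)) return(sqrt(min(d2)) + 0.5)
    (min(d2[pos]) + min(d2[neg]) + 1) / 2
  }, numeric(1))
  cap <- max(dt)
  arc <- c(0, cumsum(sqrt(rowSums((sm[-1, , drop = FALSE] -
                                     sm[-nrow(sm), , drop = FALSE])^2))))
  mid <- arc >= cap & arc <= max(arc) - cap
  if (!any(mid)) mid <- rep(TRUE, length(halfw))
  width_px <- 2 * mean(halfw[mid])
  dvals <- halfw
  axis_full <- axis
  axis_full[, 1] <- axis_full[, 1] + r0
  axis_full[, 2] <- axis_full[, 2] + c0
  poles <- axis_full[c(1L, nrow(axis_full)), , drop = FALSE]
  list(length_um = len_px * pixel_size,
       width_mean_um = width_px * pixel_size,
       width_max_um = 2 * max(dvals) * pixel_size,
       poles = poles, axis = axis_full, ok = TRUE)
}

# 4-connected pixel-edge perimeter of a region, in pixels.
.perimeter_px <- function(region) {
  p <- 0L
  for (d in list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L)))
    p <- p + sum(region & !shift_mat(region, d[1], d[2], fill = FALSE))
  p
}

#' Per-channel fluorescence summary of one region
#'
#' The background model is the per-frame global median of non-cell pixels;
#' the background-subtracted mean is `mean(region) - background`.
#'
#' @param region logical matrix.
#' @param channel_image numeric matrix, registered to the mask frame.
#' @param background background level (scalar); compute once per frame
#'   with `median(channel_image[mask == 0])`.
#' @return List: `mean`, `median`, `sum`, `sd`, `bgsub_mean`, `bgsub_sum`.
#' @export
fluorescence_metrics <- function(region, channel_image, background) {
  v <- channel_image[region]
  list(mean = mean(v), median = median(v), sum = sum(v),
       sd = if (length(v) > 1L) sd(v) else 0,
       bgsub_mean = mean(v) - background,
       bgsub_sum = sum(v - background))
}

#' Detect diffraction-limited foci inside one cell
#'
#' Difference-of-Gaussians band-pass filtering restricted to the region;
#' local maxima above `focus_k` times the robust noise sd are kept, refined
#' to sub-pixel position by a quadratic fit, and projected onto the cell
#' axis to get the long-axis fractional coordinate. Results are ordered by
#' axis position.
#'
#' @param channel_image numeric matrix.
#' @param region logical matrix (the cell).
#' @param axis axis polyline from [medial_axis_metrics()].
#' @param params a [cyto_params()] object.
#' @return Data frame: `row`, `col` (sub-pixel), `intensity` (band-pass
#'   amplitude), `axis_frac` in `[0, 1]`, `lateral_px`.
#' @export
detect_foci <- function(channel_image, region, axis, params = cyto_params()) {
  empty <- data.frame(row = numeric(0), col = numeric(0),
                      intensity = numeric(0), axis_frac = numeric(0),
                      lateral_px = numeric(0))
  if (is.null(axis) || sum(region) < 5L) return(empty)
  rc <- which(region, arr.ind = TRUE)
  pad <- ceiling(4 * params$focus_sigma)
  r0 <- max(1L, min(rc[, 1]) - pad); r1 <- min(nrow(region), max(rc[, 1]) + pad)
  c0 <- max(1L, min(rc[, 2]) - pad); c1 <- min(ncol(region), max(rc[, 2]) + pad)
  crop <- channel_image[r0:r1, c0:c1]
  regc <- region[r0:r1, c0:c1]
  # flatten everything outside the cell to the cell's median intensity so
  # the strong cell/background edge does not bleed band-pass response into
  # the interior (in a 10 px wide cell no pixel is far from an edge)
  crop[!regc] <- median(crop[regc])
  s1 <- params$focus_sigma
  g1 <- EBImage::imageData(EBImage::gblur(EBImage::Image(crop), s1))
  g2 <- EBImage::imageData(EBImage::gblur(EBImage::Image(crop), 1.6 * s1))
  dog <- g1 - g2
  # the band-pass filter responds strongly at the cell boundary itself, so
  # both the robust noise estimate and the peak search are restricted to
  # the eroded interior, away from edge structure
  core <- EBImage::imageData(EBImage::erode(EBImage::Image(regc),
                                            EBImage::makeBrush(5, "disc"))) > 0
  if (!any(core)) core <- regc
  # robust noise scale from the 25th percentile of absolute deviations
  # (a focus can cover half of a small cell's interior, which would
  # contaminate a plain MAD)
  dv <- dog[core]
  noise <- stats::quantile(abs(dv - median(dv)), 0.25, names = FALSE) / 0.3186
  thr <- max(params$focus_k * max(noise, 1e-9), params$focus_min_amp)
  ismax <- dog >= thr & core
  for (d in list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L),
                 c(1L, 1L), c(1L, -1L), c(-1L, 1L), c(-1L, -1L)))
    ismax <- ismax & dog >= shift_mat(dog, d[1], d[2], fill = -Inf)
  pk <- which(ismax, arr.ind = TRUE)
  if (nrow(pk) == 0L) return(empty)
  out <- empty
  # arc-length positions along the axis for projection
  axis_local <- cbind(axis[, 1] - r0 + 1, axis[, 2] - c0 + 1)
  arc <- c(0, cumsum(sqrt(rowSums((axis_local[-1, , drop = FALSE] -
                                     axis_local[-nrow(axis_local), , drop = FALSE])^2))))
  total <- max(arc)
  for (k in seq_len(nrow(pk))) {
    r <- pk[k, 1]; cc <- pk[k, 2]
    sub <- function(dr, dc) {
      rr <- clamp(r + dr, 1L, nrow(dog)); ccc <- clamp(cc + dc, 1L, ncol(dog))
      dog[rr, ccc]
    }
    den_r <- sub(-1L, 0L) - 2 * dog[r, cc] + sub(1L, 0L)
    den_c <- sub(0L, -1L) - 2 * dog[r, cc] + sub(0L, 1L)
    dr <- if (abs(den_r) > 1e-12) clamp(0.5 * (sub(-1L, 0L) - sub(1L, 0L)) / den_r, -0.5, 0.5) else 0
    dc <- if (abs(den_c) > 1e-12) clamp(0.5 * (sub(0L, -1L) - sub(0L, 1L)) / den_c, -0.5, 0.5) else 0
    rr <- r + dr; ccc <- cc + dc
    d2 <- (axis_local[, 1] - rr)^2 + (axis_local[, 2] - ccc)^2
    j <- which.min(d2)
    out <- rbind(out, data.frame(
      row = rr + r0 - 1, col = ccc + c0 - 1, intensity = dog[r, cc],
      axis_frac = if (total > 0) arc[j] / total else 0.5,
      lateral_px = sqrt(d2[j])))
  }
  out[order(out$axis_frac), , drop = FALSE]
}

#' Compute per-region cytometry for one frame
#'
#' @param mask integer label mask.
#' @param images list of channel images (channel 1 first); may be empty.
#' @param frame frame index (stored in the output).
#' @param params a [cyto_params()] object.
#' @return List with `metrics` (data frame, one row per region) and `axes`
#'   (list label -> axis polyline), `foci` (list label -> focus table).
#' @export
compute_frame_metrics <- function(mask, images = list(), frame = 1L,
                                  params = cyto_params()) {
  labs <- mask_labels(mask)
  px <- params$pixel_size
  backgrounds <- vapply(images, function(img) median(img[mask == 0L]), numeric(1))
  neighbours <- .contact_counts(mask)
  rows <- list(); axes <- list(); foci <- list()
  for (lab in labs) {
    region <- mask == lab
    rc <- which(region, arr.ind = TRUE)
    area <- nrow(rc)
    geom <- if (area >= params$min_area_px)
      medial_axis_metrics(region, px) else
        list(length_um = NA_real_, width_mean_um = NA_real_,
             width_max_um = NA_real_, poles = NULL, axis = NULL, ok = FALSE)
    ori <- pixel_orientation(rc[, 1], rc[, 2])
    row <- data.frame(
      frame = frame, region = lab,
      time_min = (frame - 1) * params$frame_interval,
      area_px = area, area_um2 = area * px^2,
      length_um = geom$length_um, width_mean_um = geom$width_mean_um,
      width_max_um = geom$width_max_um,
      perimeter_um = .perimeter_px(region) * px,
      orientation_rad = ori,
      centroid_row = mean(rc[, 1]), centroid_col = mean(rc[, 2]),
      aspect_ratio = if (geom$ok && geom$width_mean_um > 0)
        geom$length_um / geom$width_mean_um else NA_real_,
      bbox_rmin = min(rc[, 1]), bbox_rmax = max(rc[, 1]),
      bbox_cmin = min(rc[, 2]), bbox_cmax = max(rc[, 2]),
      n_neighbors = neighbours[as.character(lab)] %||% 0L,
      touches_border = region_touches_border(mask, lab, 1L),
      geom_ok = geom$ok)
    for (ch in seq_along(images)) {
      fl <- fluorescence_metrics(region, images[[ch]], backgrounds[ch])
      for (nm in names(fl)) row[[paste0("ch", ch, "_", nm)]] <- fl[[nm]]
    }
    if (!is.na(params$foci_channel) && params$foci_channel <= length(images)) {
      ft <- detect_foci(images[[params$foci_channel]], region, geom$axis, params)
      foci[[as.character(lab)]] <- ft
      row$foci_count <- nrow(ft)
      row$foci1_axis_frac <- if (nrow(ft)) ft$axis_frac[1] else NA_real_
      row$foci1_intensity <- if (nrow(ft)) ft$intensity[1] else NA_real_
    }
    axes[[as.character(lab)]] <- geom$axis
    rows[[length(rows) + 1L]] <- row
  }
  metrics <- if (length(rows)) do.call(rbind, rows) else NULL
  list(metrics = metrics, axes = axes, foci = foci)
}

# number of distinct touching neighbour labels per label
.contact_counts <- function(mask) {
  pairs <- list()
  for (d in list(c(1L, 0L), c(0L, 1L))) {
    nb <- shift_mat(mask, d[1], d[2], fill = 0L)
    sel <- mask > 0L & nb > 0L & nb != mask
    if (any(sel)) pairs[[length(pairs) + 1L]] <-
        cbind(mask[sel], nb[sel])
  }
  labs <- mask_labels(mask)
  out <- setNames(integer(length(labs)), as.character(labs))
  if (length(pairs)) {
    pr <- do.call(rbind, pairs)
    pr <- unique(rbind(pr, pr[, 2:1]))
    tab <- table(pr[, 1])
    out[names(tab)] <- as.integer(tab)
  }
  out
}

#' Summarize one cell track into a per-cell record
#'
#' The elongation rate is the slope of a least-squares fit of log(length)
#' against time (exponential growth model); `stat_0` flags cells whose
#' complete cell cycle was observed (born by a division and divided, both
#' in-movie).
#'
#' @param cell one row of the `cells` table from [assign_cell_ids()].
#' @param cell_frames per-frame metric rows of this cell, in frame order.
#' @param cells full cells table (for generation / sibling lookups).
#' @param params a [cyto_params()] object.
#' @return One-row data frame of per-cell descriptors.
#' @export
summarize_cell <- function(cell, cell_frames, cells, params = cyto_params()) {
  fi <- params$frame_interval
  nfr <- nrow(cell_frames)
  divided <- !is.na(cell$end_reason) && cell$end_reason == "divided"
  gen <- 1L
  mid <- cell$mother_id
  while (!is.na(mid)) {
    gen <- gen + 1L
    mid <- cells$mother_id[cells$cell_id == mid]
    if (length(mid) == 0L) mid <- NA_integer_
  }
  sib <- NA_integer_
  if (!is.na(cell$mother_id)) {
    ds <- cells[cells$cell_id == cell$mother_id, c("daughter1", "daughter2")]
    sib <- setdiff(as.integer(ds), cell$cell_id)[1]
  }
  len <- cell_frames$length_um
  tmin <- cell_frames$time_min
  rate <- se <- r2 <- NA_real_
  if (nfr >= 3L && sum(is.finite(len) & len > 0) >= 3L) {
    okl <- is.finite(len) & len > 0
    fit <- lm(log(len[okl]) ~ tmin[okl])
    rate <- unname(coef(fit)[2])
    se <- summary(fit)$coefficients[2, 2]
    r2 <- summary(fit)$r.squared
  }
  lin_rate <- if (nfr >= 2L && all(is.finite(len[c(1L, nfr)])))
    (len[nfr] - len[1L]) / max(tmin[nfr] - tmin[1L], fi) else NA_real_
  stat5 <- function(v) c(birth = v[1L], end = v[nfr],
                         mean = mean(v, na.rm = TRUE),
                         min = suppressWarnings(min(v, na.rm = TRUE)),
                         max = suppressWarnings(max(v, na.rm = TRUE)))
  out <- data.frame(
    cell_id = cell$cell_id, mother_id = cell$mother_id,
    daughter1_id = cell$daughter1, daughter2_id = cell$daughter2,
    sibling_id = sib, generation = gen, origin = cell$origin,
    stat_0 = isTRUE(cell$origin == "division") && divided,
    birth_frame = cell$birth_frame, birth_time_min = (cell$birth_frame - 1) * fi,
    division_frame = if (divided) cell$end_frame else NA_integer_,
    division_time_min = if (divided) (cell$end_frame - 1) * fi else NA_real_,
    end_frame = cell$end_frame, end_reason = cell$end_reason,
    lifetime_frames = cell$end_frame - cell$birth_frame + 1L,
    lifetime_min = (cell$end_frame - cell$birth_frame) * fi)
  geoms <- c(length_um = "length_um", area_um2 = "area_um2",
             area_px = "area_px", width_mean_um = "width_mean_um",
             width_max_um = "width_max_um", perimeter_um = "perimeter_um",
             aspect_ratio = "aspect_ratio")
  for (g in names(geoms)) {
    s <- stat5(cell_frames[[geoms[g]]])
    for (nm in names(s)) out[[paste0(g, "_", nm)]] <- unname(s[nm])
  }
  out$added_length_um <- len[nfr] - len[1L]
  out$added_area_um2 <- cell_frames$area_um2[nfr] - cell_frames$area_um2[1L]
  out$elongation_rate_per_min <- rate
  out$elongation_rate_se <- se
  out$elongation_fit_r2 <- r2
  out$linear_growth_rate_um_per_min <- lin_rate
  out$doubling_time_min <- if (is.finite(rate) && rate > 0) log(2) / rate else NA_real_
  dr <- diff(cell_frames$centroid_row); dc <- diff(cell_frames$centroid_col)
  out$birth_centroid_row <- cell_frames$centroid_row[1L]
  out$birth_centroid_col <- cell_frames$centroid_col[1L]
  out$end_centroid_row <- cell_frames$centroid_row[nfr]
  out$end_centroid_col <- cell_frames$centroid_col[nfr]
  out$net_displacement_px <- sqrt((cell_frames$centroid_row[nfr] - cell_frames$centroid_row[1L])^2 +
                                    (cell_frames$centroid_col[nfr] - cell_frames$centroid_col[1L])^2)
  out$path_length_px <- if (nfr > 1L) sum(sqrt(dr^2 + dc^2)) else 0
  out$mean_speed_px_per_frame <- if (nfr > 1L) out$path_length_px / (nfr - 1L) else 0
  out$mean_orientation_rad <- mean(cell_frames$orientation_rad)
  out$orientation_change_rad <-
    axis_angle_diff(cell_frames$orientation_rad[nfr], cell_frames$orientation_rad[1L])
  chs <- unique(sub("_(mean|median|sum|sd|bgsub_mean|bgsub_sum)$", "",
                    grep("^ch[0-9]+_", names(cell_frames), value = TRUE)))
  for (ch in chs) {
    mv <- cell_frames[[paste0(ch, "_mean")]]
    sv <- cell_frames[[paste0(ch, "_sum")]]
    out[[paste0(ch, "_mean_mean")]] <- mean(mv)
    out[[paste0(ch, "_mean_max")]] <- max(mv)
    out[[paste0(ch, "_mean_min")]] <- min(mv)
    out[[paste0(ch, "_mean_birth")]] <- mv[1L]
    out[[paste0(ch, "_mean_end")]] <- mv[nfr]
    out[[paste0(ch, "_sum_mean")]] <- mean(sv)
    out[[paste0(ch, "_sum_total")]] <- sum(sv)
    out[[paste0(ch, "_bgsub_mean_mean")]] <- mean(cell_frames[[paste0(ch, "_bgsub_mean")]])
    out[[paste0(ch, "_sd_mean")]] <- mean(cell_frames[[paste0(ch, "_sd")]])
  }
  if ("foci_count" %in% names(cell_frames)) {
    out$foci_count_mean <- mean(cell_frames$foci_count)
    out$foci_count_max <- max(cell_frames$foci_count)
    out$foci_count_total <- sum(cell_frames$foci_count)
    out$foci_axis_frac_mean <- mean(cell_frames$foci1_axis_frac, na.rm = TRUE)
    out$foci_intensity_mean <- mean(cell_frames$foci1_intensity, na.rm = TRUE)
  }
  out
}
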