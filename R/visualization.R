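# Visualization products: vector cell outlines, frame mosaics, kymographs,
# cell towers and lineage trees. All renderers are deterministic given data
# and style settings, so outputs are byte-stable across runs.

#' Extract the vector outline of one region
#'
#' Traces the region boundary along pixel edges at the 0.5 level of the
#' region's indicator (nearest-neighbour sense): vertices sit on pixel
#' corners at half-integer coordinates, the polygon is closed, simple, and
#' ordered counterclockwise in (x = col, y = -row) display coordinates. The
#' shoelace area of the polygon equals the region's pixel count exactly.
#'
#' @param region logical matrix.
#' @return Matrix with columns `row`, `col`: closed polygon (first vertex
#'   not repeated).
#' @export
extract_outline <- function(region) {
  rc <- which(region, arr.ind = TRUE)
  if (nrow(rc) == 0L) stop("empty region")
  # boundary edges: each cell pixel contributes its sides not shared with
  # another region pixel; an edge is stored as (from corner, to corner)
  # directed so that the region lies on the left when row grows downward
  edges <- list()
  has <- function(r, c) r >= 1 && r <= nrow(region) && c >= 1 &&
    c <= ncol(region) && region[r, c]
  for (k in seq_len(nrow(rc))) {
    r <- rc[k, 1]; c <- rc[k, 2]
    # corners: (r-0.5|r+0.5, c-0.5|c+0.5)
    if (!has(r - 1L, c))  # top edge, left-to-right
      edges[[length(edges) + 1L]] <- c(r - 0.5, c - 0.5, r - 0.5, c + 0.5)
    if (!has(r, c + 1L))  # right edge, top-to-bottom
      edges[[length(edges) + 1L]] <- c(r - 0.5, c + 0.5, r + 0.5, c + 0.5)
    if (!has(r + 1L, c))  # bottom edge, right-to-left
      edges[[length(edges) + 1L]] <- c(r + 0.5, c + 0.5, r + 0.5, c - 0.5)
    if (!has(r, c - 1L))  # left edge, bottom-to-top
      edges[[length(edges) + 1L]] <- c(r + 0.5, c - 0.5, r - 0.5, c - 0.5)
  }
  em <- do.call(rbind, edges)
  key <- function(r, c) paste(r, c)
  from <- key(em[, 1], em[, 2])
  lookup <- split(seq_len(nrow(em)), from)
  used <- rep(FALSE, nrow(em))
  loops <- list()
  for (s in seq_len(nrow(em))) {
    if (used[s]) next
    loop <- list(em[s, 1:2])
    used[s] <- TRUE
    cur <- em[s, 3:4]
    repeat {
      loop[[length(loop) + 1L]] <- cur
      cand <- lookup[[key(cur[1], cur[2])]]
      cand <- cand[!used[cand]]
      if (length(cand) == 0L) break
      nxt <- cand[1]
      used[nxt] <- TRUE
      cur <- em[nxt, 3:4]
      if (all(cur == em[s, 1:2])) break
    }
    loops[[length(loops) + 1L]] <- do.call(rbind, loop)
  }
  # outer boundary = loop with the largest absolute shoelace area
  areas <- vapply(loops, function(p) {
    x <- p[, 2]; y <- p[, 1]
    n <- nrow(p)
    abs(sum(x * y[c(2:n, 1)] - x[c(2:n, 1)] * y)) / 2
  }, numeric(1))
  poly <- loops[[which.max(areas)]]
  if (all(poly[1, ] == poly[nrow(poly), ])) poly <- poly[-nrow(poly), , drop = FALSE]
  # orient counterclockwise in (x = col, y = -row) coordinates
  x <- poly[, 2]; y <- -poly[, 1]
  n <- nrow(poly)
  if (sum(x * y[c(2:n, 1)] - x[c(2:n, 1)] * y) / 2 < 0)
    poly <- poly[n:1, , drop = FALSE]
  colnames(poly) <- c("row", "col")
  poly
}

#' Shoelace area of an outline polygon
#' @param outline matrix from [extract_outline()].
#' @return Area in px^2.
#' @export
outline_area <- function(outline) {
  x <- outline[, "col"]; y <- outline[, "row"]
  n <- nrow(outline)
  abs(sum(x * y[c(2:n, 1)] - x[c(2:n, 1)] * y)) / 2
}

# deterministic ID -> color map (golden-angle hue walk)
.id_color <- function(id) {
  h <- (id * 0.61803398875) %% 1
  grDevices::hsv(h, 0.85, 1)
}

#' Tile selected frames into a mosaic image
#'
#' Frames are placed chronologically into a grid with consistent intensity
#' scaling across tiles; optional mask outlines are drawn in per-cell-ID
#' colors that stay consistent across tiles. Written as PNG when `path`
#' is given.
#'
#' @param frames list of numeric matrices (already registered).
#' @param grid integer c(rows, cols) of the mosaic.
#' @param masks optional list of label masks (same selection as `frames`)
#'   whose region boundaries are drawn.
#' @param path optional output PNG path.
#' @param gutter pixels between tiles.
#' @return The RGB array (rows x cols x 3), invisibly if written.
#' @export
frame_mosaic <- function(frames, grid = NULL, masks = NULL, path = NULL,
                         gutter = 2L) {
  n <- length(frames)
  if (n == 0L) stop("empty frame selection")
  if (is.null(grid)) {
    gc_ <- ceiling(sqrt(n))
    grid <- c(ceiling(n / gc_), gc_)
  }
  fr <- dim(frames[[1]])[1]; fc <- dim(frames[[1]])[2]
  lo <- min(vapply(frames, min, numeric(1)))
  hi <- max(vapply(frames, max, numeric(1)))
  H <- grid[1] * fr + (grid[1] - 1L) * gutter
  W <- grid[2] * fc + (grid[2] - 1L) * gutter
  out <- array(1, dim = c(H, W, 3))
  for (k in seq_len(n)) {
    gr <- (k - 1L) %/% grid[2]; gcx <- (k - 1L) %% grid[2]
    r0 <- gr * (fr + gutter); c0 <- gcx * (fc + gutter)
    tile <- (frames[[k]] - lo) / max(hi - lo, 1e-12)
    tile <- clamp(tile, 0, 1)
    for (ch in 1:3) out[r0 + seq_len(fr), c0 + seq_len(fc), ch] <- tile
    if (!is.null(masks)) {
      b <- label_boundary(masks[[k]])
      ids <- masks[[k]][b]
      idx <- which(b, arr.ind = TRUE)
      cols <- grDevices::col2rgb(.id_color(ids)) / 255
      for (ch in 1:3)
        out[cbind(r0 + idx[, 1], c0 + idx[, 2], ch)] <- cols[ch, ]
    }
  }
  if (!is.null(path)) {
    png::writePNG(out, path)
    return(invisible(out))
  }
  out
}

#' Kymograph of one cell track
#'
#' Per frame, the cell's pixel intensities are projected onto the cell
#' axis, binned into `n_bins` equal-arc-length bins of normalized long-axis
#' position, and averaged per bin. Rows are time frames.
#'
#' @param intensities list (one per frame of the track) of numeric
#'   matrices.
#' @param regions list of logical matrices (the cell per frame).
#' @param axes list of axis polylines ([medial_axis_metrics()]).
#' @param n_bins number of long-axis bins.
#' @return Matrix `length(track) x n_bins`; frames with a missing axis give
#'   a row of `NA`.
#' @export
kymograph <- function(intensities, regions, axes, n_bins = 25L) {
  nT <- length(intensities)
  out <- matrix(NA_real_, nT, n_bins)
  for (t in seq_len(nT)) {
    ax <- axes[[t]]
    if (is.null(ax)) next
    arc <- c(0, cumsum(sqrt(rowSums((ax[-1, , drop = FALSE] -
                                       ax[-nrow(ax), , drop = FALSE])^2))))
    total <- max(arc)
    rc <- which(regions[[t]], arr.ind = TRUE)
    v <- intensities[[t]][regions[[t]]]
    # nearest axis vertex -> normalized arc position
    fr <- vapply(seq_len(nrow(rc)), function(i) {
      j <- which.min((ax[, 1] - rc[i, 1])^2 + (ax[, 2] - rc[i, 2])^2)
      if (total > 0) arc[j] / total else 0.5
    }, numeric(1))
    bin <- clamp(floor(fr * n_bins) + 1L, 1L, n_bins)
    m <- tapply(v, factor(bin, levels = seq_len(n_bins)), mean)
    out[t, ] <- as.numeric(m)
  }
  out
}

#' Cell tower: axis-aligned crops of one cell stacked over time
#'
#' Each frame's crop is rotated so the cell's long axis is horizontal,
#' centered on the cell centroid, and stacked vertically by time under a
#' common intensity scale. Orientation is disambiguated by pole identity
#' (the axis is flipped, when needed, to minimize rotation change between
#' consecutive frames), so an off-axis structure stays on the same side.
#'
#' @param intensities list of numeric matrices (one per frame of the track).
#' @param regions list of logical matrices.
#' @param orientations numeric vector of per-frame axis angles (radians).
#' @param pad_px padding around the largest cell extent.
#' @param path optional output PNG path.
#' @return Grayscale matrix (stacked rows), written as PNG if `path` given.
#' @export
cell_tower <- function(intensities, regions, orientations, pad_px = 4L,
                       path = NULL) {
  nT <- length(intensities)
  crops <- list()
  # unwrap orientations so consecutive frames do not flip by ~pi
  ors <- orientations
  for (t in seq_len(nT)[-1]) {
    while (ors[t] - ors[t - 1] > pi / 2) ors[t] <- ors[t] - pi
    while (ors[t] - ors[t - 1] < -pi / 2) ors[t] <- ors[t] + pi
  }
  lo <- Inf; hi <- -Inf
  for (t in seq_len(nT)) {
    rc <- which(regions[[t]], arr.ind = TRUE)
    img <- intensities[[t]]
    msk <- regions[[t]]
    bb <- c(range(rc[, 1]), range(rc[, 2]))
    ext <- max(bb[2] - bb[1], bb[4] - bb[3]) + 2L * pad_px
    ctr <- c(mean(rc[, 1]), mean(rc[, 2]))
    r0 <- round(ctr[1] - ext / 2); c0 <- round(ctr[2] - ext / 2)
    rows <- clamp(r0:(r0 + ext), 1L, nrow(img))
    cols <- clamp(c0:(c0 + ext), 1L, ncol(img))
    crop <- img[rows, cols] * (msk[rows, cols] > 0)
    rot <- EBImage::imageData(EBImage::rotate(EBImage::Image(crop),
                                              ors[t] * 180 / pi))
    crops[[t]] <- rot
    lo <- min(lo, min(rot)); hi <- max(hi, max(rot))
  }
  w <- max(vapply(crops, ncol, integer(1)))
  h <- max(vapply(crops, nrow, integer(1)))
  out <- matrix(0, nT * (h + 1L) - 1L, w)
  for (t in seq_len(nT)) {
    cr <- (crops[[t]] - lo) / max(hi - lo, 1e-12)
    ro <- (t - 1L) * (h + 1L) + seq_len(nrow(cr)) +
      (h - nrow(cr)) %/% 2L
    co <- seq_len(ncol(cr)) + (w - ncol(cr)) %/% 2L
    out[ro, co] <- cr
  }
  out <- clamp(out, 0, 1)
  if (!is.null(path)) {
    png::writePNG(out, path)
    return(invisible(out))
  }
  out
}

#' Layout of a lineage tree
#'
#' Computes the drawing geometry: one horizontal segment per cell from
#' birth to end frame, vertical connectors at divisions, leaves spread on
#' the y axis and internal cells centered over their daughters.
#'
#' @param cells cells table ([assign_cell_ids()] or [simulate_colony()]
#'   lineage with matching columns).
#' @param n_frames movie length (defaults to `max(end_frame)`).
#' @return List with `segments` (data frame `cell_id`, `x0`, `x1`, `y`) and
#'   `branches` (data frame `x`, `y0`, `y1`, `cell_id` of the mother).
#' @export
lineage_layout <- function(cells, n_frames = NULL) {
  if (!"end_frame" %in% names(cells)) {
    # accept a simulator lineage table
    nf <- n_frames %||% max(cells$birth_frame,
                            cells$division_frame, na.rm = TRUE)
    cells <- data.frame(cell_id = cells$cell_id, mother_id = cells$mother_id,
                        daughter1 = cells$daughter1, daughter2 = cells$daughter2,
                        birth_frame = cells$birth_frame,
                        end_frame = ifelse(is.na(cells$division_frame), nf,
                                           cells$division_frame))
  }
  y <- setNames(rep(NA_real_, nrow(cells)), cells$cell_id)
  leaf_counter <- 0
  assign_y <- function(id) {
    row <- cells[cells$cell_id == id, ]
    if (is.na(row$daughter1)) {
      leaf_counter <<- leaf_counter + 1
      y[as.character(id)] <<- leaf_counter
    } else {
      assign_y(row$daughter1)
      assign_y(row$daughter2)
      y[as.character(id)] <<-
        mean(y[as.character(c(row$daughter1, row$daughter2))])
    }
  }
  for (root in cells$cell_id[is.na(cells$mother_id)]) assign_y(root)
  segments <- data.frame(cell_id = cells$cell_id,
                         x0 = cells$birth_frame, x1 = cells$end_frame,
                         y = y[as.character(cells$cell_id)])
  div <- cells[!is.na(cells$daughter1), ]
  branches <- if (nrow(div)) data.frame(
    x = div$end_frame,
    y0 = y[as.character(div$daughter1)],
    y1 = y[as.character(div$daughter2)],
    cell_id = div$cell_id) else
      data.frame(x = numeric(0), y0 = numeric(0), y1 = numeric(0),
                 cell_id = integer(0))
  list(segments = segments, branches = branches)
}

#' Plot a lineage tree
#'
#' Horizontal time axis; each cell is a segment from birth to
#' division/end, with vertical connectors at divisions; optional per-cell
#' coloring by a metric.
#'
#' @param cells cells table (see [lineage_layout()]).
#' @param annotate optional named numeric vector (names = cell ids) mapped
#'   to segment colors.
#' @param path optional output PNG path.
#' @param frame_interval minutes per frame for the time axis.
#' @param ... passed to [graphics::plot()].
#' @return The layout, invisibly.
#' @export
plot_lineage_tree <- function(cells, annotate = NULL, path = NULL,
                              frame_interval = 1, ...) {
  lay <- lineage_layout(cells)
  draw <- function() {
    seg <- lay$segments
    graphics::plot(NULL, xlim = range(c(seg$x0, seg$x1)) * frame_interval,
                   ylim = range(seg$y) + c(-0.5, 0.5),
                   xlab = "time (min)", ylab = "", yaxt = "n", ...)
    colv <- if (!is.null(annotate)) {
      v <- annotate[as.character(seg$cell_id)]
      pal <- grDevices::hcl.colors(64, "viridis")
      pal[clamp(ceiling(63 * (v - min(v, na.rm = TRUE)) /
                          max(diff(range(v, na.rm = TRUE)), 1e-12)) + 1, 1, 64)]
    } else rep("black", nrow(seg))
    graphics::segments(seg$x0 * frame_interval, seg$y,
                       seg$x1 * frame_interval, seg$y, col = colv, lwd = 2)
    if (nrow(lay$branches))
      graphics::segments(lay$branches$x * frame_interval, lay$branches$y0,
                         lay$branches$x * frame_interval, lay$branches$y1,
                         col = "grey40")
  }
  if (!is.null(path)) {
    grDevices::png(path, width = 900, height = 600)
    draw()
    grDevices::dev.off()
  } else draw()
  invisible(lay)
}
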