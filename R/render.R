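# Rendering ground-truth masks in the contrast styles of common bacterial
# imaging modalities, plus stage drift, diffraction-limited foci, and
# controlled mask corruption. Intensities live in [0, 1]; Gaussian blur is
# applied before additive Gaussian noise so the noise stays white.

# Per-modality intensity levels. "junction" is the cell-cell contact line;
# cytoplasmic fluorescence dips there (less cytoplasm at the interface),
# phase contrast keeps the inter-cell boundary slightly brighter than the
# interior. These gradients at cell boundaries are what make the touching
# cells separable at all.
.modality_levels <- list(
  phase      = list(bg = 0.70, interior = 0.25, edge = 0.25, junction = 0.45, halo = 0.95),
  bf_under   = list(bg = 0.50, interior = 0.46, edge = 0.62, junction = 0.62, halo = 0.50),
  bf_over    = list(bg = 0.50, interior = 0.54, edge = 0.38, junction = 0.38, halo = 0.50),
  bf_focus   = list(bg = 0.50, interior = 0.505, edge = 0.52, junction = 0.52, halo = 0.50),
  cyto_fluor = list(bg = 0.08, interior = 0.85, edge = 0.85, junction = 0.60, halo = 0.08),
  mem_fluor  = list(bg = 0.08, interior = 0.35, edge = 0.90, junction = 0.90, halo = 0.08)
)

#' Supported imaging-modality names
#' @return Character vector of modality identifiers.
#' @export
modalities <- function() names(.modality_levels)

#' Render a labelled mask in the style of an imaging modality
#'
#' Produces an idealized grayscale image of the colony: phase contrast
#' (dark cells, bright halo ring), under/over-focused brightfield (low
#' contrast with opposite-sign edge relief), in-focus brightfield (nearly
#' zero interior contrast), cytoplasmic fluorescence (bright interiors with
#' dimmer inter-cell junctions) or membrane fluorescence (bright boundary
#' shell over a uniform dim interior). Gaussian blur is applied first, then
#' additive Gaussian noise; output is deterministic for a fixed seed.
#'
#' @param mask integer label matrix (ground-truth or segmented).
#' @param modality one of [modalities()].
#' @param blur_sigma Gaussian blur sigma in pixels (0 = none).
#' @param noise_sd additive Gaussian noise standard deviation (intensity
#'   units on the `[0, 1]` scale; 0 = none).
#' @param seed integer seed for the noise substream.
#' @return Numeric matrix in `[0, 1]` (values may slightly exceed the range
#'   when noise is on; they are not clipped, so noise statistics stay exact).
#' @export
render_modality <- function(mask, modality, blur_sigma = 0.8, noise_sd = 0.01,
                            seed = 1L) {
  if (!modality %in% names(.modality_levels))
    stop("unknown modality '", modality, "'; expected one of: ",
         paste(names(.modality_levels), collapse = ", "))
  lv <- .modality_levels[[modality]]
  img <- matrix(lv$bg, nrow(mask), ncol(mask))
  inside <- mask > 0L
  img[inside] <- lv$interior
  # edge: cell pixels on the outer boundary (facing background);
  # junction: cell pixels facing a *different* cell label
  edge <- matrix(FALSE, nrow(mask), ncol(mask))
  junction <- edge
  for (d in list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))) {
    nb <- shift_mat(mask, d[1], d[2], fill = 0L)
    edge <- edge | (inside & nb == 0L)
    junction <- junction | (inside & nb > 0L & nb != mask)
  }
  img[edge] <- lv$edge
  img[junction] <- lv$junction
  halo <- background_halo(mask)
  img[halo] <- lv$halo
  if (blur_sigma > 0)
    img <- EBImage::imageData(EBImage::gblur(EBImage::Image(img), sigma = blur_sigma))
  if (noise_sd > 0)
    img <- img + with_substream(seed, paste0("render_", modality),
                                matrix(rnorm(length(img), 0, noise_sd),
                                       nrow(img)))
  img
}

#' Add diffraction-limited fluorescent foci inside cells
#'
#' Each focus is an additive, sub-pixel-positioned 2D Gaussian placed inside
#' its cell; the returned table is the ground truth for focus-detection
#' tests. Positions are drawn uniformly along the central part of the cell
#' axis with a small lateral offset.
#'
#' @param image numeric matrix to add foci to.
#' @param states rod state data frame for this frame (from
#'   [simulate_colony()]).
#' @param pixel_size micrometers per pixel.
#' @param foci_per_cell number of foci per cell (integer >= 0).
#' @param focus_sigma Gaussian sigma in pixels (> 0).
#' @param focus_amplitude peak amplitude in intensity units.
#' @param seed integer seed for the foci substream.
#' @return List with `image` (foci added) and `foci`, a data frame with
#'   `cell_id`, `row`, `col` (continuous pixel coordinates), `amplitude`,
#'   `sigma`, and `axis_frac` (long-axis fractional coordinate in `[0, 1]`,
#'   0 at the pole pointing along -axis).
#' @export
add_foci <- function(image, states, pixel_size, foci_per_cell = 1L,
                     focus_sigma = 1.5, focus_amplitude = 0.5, seed = 1L) {
  if (foci_per_cell < 0L) stop("foci_per_cell must be >= 0")
  if (foci_per_cell > 0L && focus_sigma <= 0) stop("focus_sigma must be > 0")
  empty <- data.frame(cell_id = integer(0), row = numeric(0), col = numeric(0),
                      amplitude = numeric(0), sigma = numeric(0),
                      axis_frac = numeric(0))
  if (foci_per_cell == 0L || nrow(states) == 0L)
    return(list(image = image, foci = empty))
  with_substream(seed, "foci", {
    rows <- list()
    for (k in seq_len(nrow(states))) {
      s <- states[k, ]
      for (f in seq_len(foci_per_cell)) {
        u <- runif(1, 0.15, 0.85)             # long-axis fraction
        v <- runif(1, -0.2, 0.2) * s$width    # lateral offset, um
        along <- (u - 0.5) * s$length
        ux <- cos(s$theta); uy <- sin(s$theta)
        x <- s$x + ux * along - uy * v
        y <- s$y + uy * along + ux * v
        rows[[length(rows) + 1L]] <- data.frame(
          cell_id = s$cell_id, row = y / pixel_size + 0.5,
          col = x / pixel_size + 0.5, amplitude = focus_amplitude,
          sigma = focus_sigma, axis_frac = u)
      }
    }
    foci <- do.call(rbind, rows)
    for (k in seq_len(nrow(foci))) {
      r0 <- foci$row[k]; c0 <- foci$col[k]; sg <- foci$sigma[k]
      rr <- max(1L, floor(r0 - 4 * sg)):min(nrow(image), ceiling(r0 + 4 * sg))
      cc <- max(1L, floor(c0 - 4 * sg)):min(ncol(image), ceiling(c0 + 4 * sg))
      g <- outer(exp(-((rr - r0)^2) / (2 * sg^2)),
                 exp(-((cc - c0)^2) / (2 * sg^2)))
      image[rr, cc] <- image[rr, cc] + foci$amplitude[k] * g
    }
    list(image = image, foci = foci)
  })
}

# Translate one frame by (dy, dx) with sub-pixel accuracy via the Fourier
# shift theorem; the wrapped-in margins are overwritten with `fill`.
fourier_shift <- function(img, dy, dx, fill = NULL) {
  nr <- nrow(img); nc <- ncol(img)
  ky <- c(0:floor(nr / 2), -(ceiling(nr / 2) - 1):-1)[1:nr] / nr
  kx <- c(0:floor(nc / 2), -(ceiling(nc / 2) - 1):-1)[1:nc] / nc
  if (nr %% 2 == 0) ky[nr / 2 + 1] <- abs(ky[nr / 2 + 1])
  if (nc %% 2 == 0) kx[nc / 2 + 1] <- abs(kx[nc / 2 + 1])
  ph <- exp(-2i * pi * (outer(ky * dy, kx * dx, "+")))
  out <- Re(fft(fft(img) * ph, inverse = TRUE)) / (nr * nc)
  if (!is.null(fill)) {
    if (dy > 0) out[seq_len(min(nr, ceiling(dy))), ] <- fill
    if (dy < 0) out[seq(nr - min(nr, ceiling(-dy)) + 1L, nr), ] <- fill
    if (dx > 0) out[, seq_len(min(nc, ceiling(dx)))] <- fill
    if (dx < 0) out[, seq(nc - min(nc, ceiling(-dx)) + 1L, nc)] <- fill
  }
  out
}

#' Apply per-frame stage drift to an image stack
#'
#' Each frame is translated by its `(dy, dx)` vector with sub-pixel
#' (Fourier) interpolation; pixels shifted in from outside the field are
#' filled with the frame's background median.
#'
#' @param stack list of numeric matrices (one per frame).
#' @param drift numeric matrix with one row per frame and columns
#'   `(dy, dx)` in pixels.
#' @return List of shifted matrices.
#' @export
apply_drift <- function(stack, drift) {
  drift <- as.matrix(drift)
  if (nrow(drift) != length(stack))
    stop("need one (dy, dx) drift vector per frame")
  lapply(seq_along(stack), function(t) {
    dy <- drift[t, 1]; dx <- drift[t, 2]
    if (dy == 0 && dx == 0) return(stack[[t]])
    fourier_shift(stack[[t]], dy, dx, fill = median(stack[[t]]))
  })
}

#' Inject controlled segmentation errors into ground-truth masks
#'
#' Corrupts a mask sequence according to an error specification so that the
#' evaluation module's fatal-error counting can be validated against a known
#' event log. `split` bisects the target region perpendicular to its long
#' axis into two labels; `merge` relabels a touching neighbour to the target
#' label; `drop` removes the region. Each event lasts `duration` frames and
#' the region then reverts.
#'
#' @param masks list of integer label matrices (labels = cell ids).
#' @param spec data frame with columns `frame`, `type`
#'   (`"split"|"merge"|"drop"`), `cell_id`, optional `cell_id2` (merge
#'   partner; chosen automatically when `NA`), `duration` (frames).
#' @return List with `masks` (corrupted copies) and `log`, a data frame of
#'   realized events (columns of `spec` plus `realized` and `new_label`).
#' @export
inject_mask_errors <- function(masks, spec) {
  log_rows <- list()
  if (is.null(spec) || nrow(spec) == 0L)
    return(list(masks = masks, log = data.frame(
      frame = integer(0), type = character(0), cell_id = integer(0),
      cell_id2 = integer(0), duration = integer(0), realized = logical(0),
      new_label = integer(0))))
  if (is.null(spec$cell_id2)) spec$cell_id2 <- NA_integer_
  if (is.null(spec$duration)) spec$duration <- 1L
  max_label <- max(vapply(masks, max, numeric(1)))
  for (e in seq_len(nrow(spec))) {
    fr <- spec$frame[e]; type <- spec$type[e]; id <- spec$cell_id[e]
    dur <- spec$duration[e]
    frames <- fr:min(fr + dur - 1L, length(masks))
    realized <- FALSE; new_label <- NA_integer_; partner <- spec$cell_id2[e]
    for (t in frames) {
      m <- masks[[t]]
      px <- which(m == id)
      if (length(px) == 0L) next
      if (type == "split") {
        rc <- arrayInd(px, dim(m))
        th <- pixel_orientation(rc[, 1], rc[, 2])
        # project onto the long axis; bisect at the median
        proj <- (rc[, 2] - mean(rc[, 2])) * cos(th) + (rc[, 1] - mean(rc[, 1])) * sin(th)
        if (is.na(new_label)) { max_label <- max_label + 1L; new_label <- as.integer(max_label) }
        m[px[proj > median(proj)]] <- new_label
        masks[[t]] <- m
        realized <- TRUE
      } else if (type == "drop") {
        m[px] <- 0L
        masks[[t]] <- m
        realized <- TRUE
      } else if (type == "merge") {
        if (is.na(partner)) {
          # pick a touching neighbour
          nbs <- integer(0)
          for (d in list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))) {
            nb <- shift_mat(m, d[1], d[2], fill = 0L)
            nbs <- c(nbs, nb[m == id])
          }
          nbs <- setdiff(unique(nbs), c(0L, id))
          if (length(nbs) == 0L) next
          partner <- min(nbs)
        }
        # verify contact before merging
        touch <- FALSE
        for (d in list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))) {
          nb <- shift_mat(m, d[1], d[2], fill = 0L)
          if (any(m == id & nb == partner)) { touch <- TRUE; break }
        }
        if (!touch) next
        m[m == partner] <- id
        masks[[t]] <- m
        realized <- TRUE
      } else stop("unknown error type: ", type)
    }
    log_rows[[e]] <- data.frame(frame = fr, type = type, cell_id = id,
                                cell_id2 = partner, duration = dur,
                                realized = realized, new_label = new_label)
  }
  list(masks = masks, log = do.call(rbind, log_rows))
}
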