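# Per-frame instance segmentation. The baseline segmenter is a classical
# seeded-region approach: automatic (Otsu) thresholding with
# modality-dependent polarity to find foreground, core seeds from the
# intensity extremes inside cells, and Voronoi-style propagation of the
# seeds over the foreground. It exists so the pipeline runs end-to-end on
# synthetic or low-noise data; learned segmenters enter through the
# external-mask import path instead, with the same contact-tolerant label
# semantics (touching cells, distinct labels, no background gap).

#' Segmentation parameters
#'
#' @param modality modality hint controlling threshold polarity; one of
#'   [modalities()].
#' @param min_region_area smallest region kept, in pixels.
#' @param fill_holes fill interior holes of each region.
#' @param pre_blur Gaussian blur sigma (px) applied before thresholding.
#' @param core_quantile quantile (within foreground, towards the core
#'   extreme) used to pick seed pixels for splitting touching cells.
#' @return A `seg_params` list.
#' @export
seg_params <- function(modality = "phase", min_region_area = 20L,
                       fill_holes = TRUE, pre_blur = 1, core_quantile = 0.5) {
  stopifnot(min_region_area >= 1L)
  structure(list(modality = modality, min_region_area = as.integer(min_region_area),
                 fill_holes = fill_holes, pre_blur = pre_blur,
                 core_quantile = core_quantile),
            class = "seg_params")
}

# foreground polarity (is the cell body darker or brighter than background?)
# and core polarity (are cell cores the dark or the bright extreme within
# the foreground?) per modality.
.seg_polarity <- list(
  phase      = list(fg = "dark",   core = "dark",   fill = TRUE),
  bf_under   = list(fg = "deviation", core = "dark",   fill = TRUE),
  bf_over    = list(fg = "deviation", core = "bright", fill = TRUE),
  bf_focus   = list(fg = "deviation", core = "dark",   fill = TRUE),
  cyto_fluor = list(fg = "bright", core = "bright", fill = TRUE),
  mem_fluor  = list(fg = "bright", core = "dark",   fill = TRUE)
)

#' Classical baseline segmentation of one frame
#'
#' Thresholds the image (polarity set by the modality hint), fills holes,
#' then splits touching cells by seeding each cell at its intensity core
#' (cell interiors are extremal relative to the dimmer or brighter
#' junction/boundary pixels) and propagating seeds over the foreground.
#' An empty foreground yields a valid all-zero mask.
#'
#' @param image 2D numeric matrix (grayscale).
#' @param params a [seg_params()] object.
#' @return Integer label mask (`LabelMask` semantics: 0 background, labels
#'   may touch).
#' @export
baseline_segment <- function(image, params = seg_params()) {
  if (length(dim(image)) != 2L) stop("image must be a 2D grayscale matrix")
  pol <- .seg_polarity[[params$modality]]
  if (is.null(pol)) stop("unknown modality hint: ", params$modality)
  img <- image
  if (params$pre_blur > 0)
    img <- EBImage::imageData(EBImage::gblur(EBImage::Image(img), params$pre_blur))
  # working image with cells bright
  work <- switch(pol$fg,
                 bright = img,
                 dark = max(img) - img,
                 deviation = abs(img - median(img)))
  if (max(work) <= 1e-12)  # constant image: nothing to segment
    return(matrix(0L, nrow(image), ncol(image)))
  th <- EBImage::otsu(EBImage::Image(work / max(work))) * max(work)
  fg <- work > th
  if (!any(fg)) return(matrix(0L, nrow(image), ncol(image)))
  if (pol$fill) fg <- EBImage::imageData(EBImage::fillHull(EBImage::Image(fg))) > 0
  # core intensity for seeding: within the filled foreground, cores are the
  # extreme of the *original* image (e.g. dim interiors for membrane labels)
  core_img <- switch(pol$core, bright = img, dark = max(img) - img)
  vals <- core_img[fg]
  core_th <- stats::quantile(vals, params$core_quantile, names = FALSE)
  seeds <- fg & core_img > core_th
  seeds_lab <- EBImage::bwlabel(EBImage::Image(seeds))
  # drop seed specks
  seeds_lab <- EBImage::Image(prune_small(as.matrix(seeds_lab) + 0L,
                                          max(2L, params$min_region_area %/% 4L)))
  if (max(seeds_lab) == 0) {
    lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(fg)))
  } else {
    lab <- EBImage::imageData(EBImage::propagate(EBImage::Image(core_img), seeds_lab,
                                        mask = EBImage::Image(fg)))
  }
  lab <- matrix(as.integer(round(lab)), nrow(image))
  lab <- split_disconnected(lab, warn = FALSE)
  clean_mask(lab, params)
}

# remove labelled regions smaller than min_area (labels preserved otherwise)
prune_small <- function(mask, min_area) {
  ar <- region_areas(mask)
  drop <- as.integer(names(ar)[ar < min_area])
  if (length(drop)) mask[mask %in% drop] <- 0L
  mask
}

# split labels whose pixel sets are not 4-connected into separate labels
split_disconnected <- function(mask, warn = TRUE) {
  out <- mask
  next_label <- max(mask) + 1L
  for (lab in mask_labels(mask)) {
    comp <- EBImage::bwlabel(EBImage::Image(mask == lab))
    ncomp <- max(comp)
    if (ncomp > 1L) {
      if (warn)
        warning("label ", lab, " is not 4-connected; split into ",
                ncomp, " regions")
      cm <- as.matrix(comp)
      for (k in 2:ncomp) {
        out[cm == k] <- next_label
        next_label <- next_label + 1L
      }
    }
  }
  out
}

#' Import externally generated label masks
#'
#' Reads per-frame 16-bit PNG masks (e.g. produced by a learned segmenter or
#' hand-edited in an image editor), validates labels, and splits any label
#' painted as several disconnected blobs into separate labels with a
#' warning.
#'
#' @param paths character vector of PNG paths, one per frame, in frame order.
#' @param expected_frames expected number of frames (defaults to
#'   `length(paths)`).
#' @param image_shape optional (rows, cols) the masks must match.
#' @return List of integer label masks.
#' @export
import_masks <- function(paths, expected_frames = length(paths),
                         image_shape = NULL) {
  if (length(paths) != expected_frames)
    stop("expected ", expected_frames, " mask files, got ", length(paths))
  missing <- !file.exists(paths)
  if (any(missing))
    stop("missing mask file(s): ", paste(basename(paths[missing]), collapse = ", "))
  out <- vector("list", length(paths))
  for (t in seq_along(paths)) {
    m <- read_mask_png(paths[t])
    if (!is.null(image_shape) && !all(dim(m) == image_shape))
      stop("mask for frame ", t, " has shape ", nrow(m), "x", ncol(m),
           ", expected ", image_shape[1], "x", image_shape[2])
    out[[t]] <- split_disconnected(m)
  }
  out
}

#' Clean a label mask
#'
#' Removes regions below `min_region_area` and (optionally) fills interior
#' holes whose entire boundary belongs to a single region. Labels of
#' surviving regions are preserved and never merged. Idempotent.
#'
#' @param mask integer label matrix.
#' @param params a [seg_params()] object.
#' @return Cleaned integer label matrix.
#' @export
clean_mask <- function(mask, params = seg_params()) {
  out <- prune_small(mask, params$min_region_area)
  if (params$fill_holes) {
    bgcomp <- EBImage::bwlabel(EBImage::Image(out == 0L))
    bgm <- as.matrix(bgcomp)
    border <- unique(c(bgm[1, ], bgm[nrow(bgm), ], bgm[, 1], bgm[, ncol(bgm)]))
    for (h in setdiff(seq_len(max(bgm)), border)) {
      px <- which(bgm == h)
      nb <- integer(0)
      rc <- arrayInd(px, dim(out))
      for (d in list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))) {
        rr <- rc[, 1] + d[1]; cc <- rc[, 2] + d[2]
        ok <- rr >= 1L & rr <= nrow(out) & cc >= 1L & cc <= ncol(out)
        nb <- c(nb, out[cbind(rr[ok], cc[ok])])
      }
      nb <- setdiff(unique(nb), 0L)
      if (length(nb) == 1L) out[px] <- nb
    }
  }
  out
}

#' Area fraction lost to a one-pixel inter-cell boundary gap
#'
#' Quantifies the boundary artifact of gap-requiring segmenters: when
#' neighbouring cells in a microcolony must be separated by a background
#' gap, each shared lateral boundary recedes by half the gap, i.e. a
#' mid-colony cell with both lateral edges shared loses a net one-pixel-wide
#' strip along its whole long-axis extent. The cell is modelled as a rod
#' (rectangle plus semicircular caps) of the given area and width,
#' rasterized at `pixel_size`; the lost fraction is counted in pixels.
#'
#' @param cell_area cell area in square micrometers.
#' @param pixel_size micrometers per pixel.
#' @param shared_edges number of shared lateral boundaries: 0, 1 or 2.
#' @param width rod width in micrometers (default 1.0).
#' @return List with `fraction` lost, `lost_px`, `total_px`, and the rod
#'   `length` (pole-to-pole, micrometers).
#' @export
mask_boundary_recession_loss <- function(cell_area, pixel_size, shared_edges,
                                         width = 1.0) {
  if (!shared_edges %in% 0:2) stop("shared_edges must be 0, 1 or 2")
  if (pixel_size >= width)
    stop("pixel_size must be smaller than the cell width")
  straight <- (cell_area - pi * width^2 / 4) / width
  if (straight < 0) stop("cell_area too small for a rod of this width")
  len <- straight + width
  # rasterize a horizontal rod spanning x in [0, len], centered in y
  ncol_px <- ceiling(len / pixel_size) + 2L
  nrow_px <- ceiling(width / pixel_size) + 2L
  xc <- (seq_len(ncol_px) - 0.5) * pixel_size
  yc <- (seq_len(nrow_px) - 0.5) * pixel_size
  y0 <- nrow_px * pixel_size / 2
  x1 <- width / 2; x2 <- len - width / 2  # axis segment endpoints
  dist <- outer(yc, xc, function(y, x) {
    t <- clamp((x - x1) / max(x2 - x1, 1e-12), 0, 1)
    qx <- x1 + t * (x2 - x1)
    sqrt((x - qx)^2 + (y - y0)^2)
  })
  inside <- dist <= width / 2
  total_px <- sum(inside)
  # one-pixel net recession (half per shared edge) along the long-axis extent
  occupied_cols <- sum(colSums(inside) > 0)
  lost_px <- occupied_cols * shared_edges / 2
  list(fraction = lost_px / total_px, lost_px = lost_px,
       total_px = total_px, length = len)
}
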