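# Dataset discovery and the pipeline's output slicings. Time-lapse frames
# live as one TIFF per (position, time, channel) under the filename dialect
# `<base>_t<T>xy<P>c<C>.tif` (zero padding allowed, case-insensitive
# tif/tiff/png extension). Frame files and cell files are plain directories
# of CSV + image files so that everything stays editable and diffable.

#' Parse a frame filename into its (position, time, channel) key
#'
#' @param name file name following `<base>_t<T>xy<P>c<C>.<tif|tiff|png>`.
#' @return List with `base`, `time`, `position`, `channel`.
#' @export
parse_frame_filename <- function(name) {
  bn <- basename(name)
  m <- regmatches(bn, regexec(
    "^(.*)_t([0-9]+)xy([0-9]+)c([0-9]+)\\.(tif|tiff|png)$", bn,
    ignore.case = TRUE))[[1]]
  if (length(m) == 0L) {
    # name the offending token for common near-misses
    tok <- if (!grepl("_t[0-9]+", bn)) "t<time>"
    else if (!grepl("xy[0-9]+", bn)) "xy<position>"
    else if (!grepl("c[0-9]+\\.", bn, ignore.case = TRUE)) "c<channel>"
    else "extension"
    stop("cannot parse frame filename '", bn, "': missing or malformed '",
         tok, "' token")
  }
  list(base = m[2], time = as.integer(m[3]), position = as.integer(m[4]),
       channel = as.integer(m[5]))
}

#' Compose a frame filename from its key
#'
#' @param base dataset base name.
#' @param time,position,channel 1-based indices.
#' @param ext file extension (default `"tif"`).
#' @return File name string.
#' @export
frame_filename <- function(base, time, position, channel, ext = "tif") {
  sprintf("%s_t%03dxy%02dc%d.%s", base, time, position, channel, ext)
}

#' Index a directory of time-lapse frames
#'
#' Parses every file matching the filename dialect (unrelated files are
#' ignored), checks that each position has a complete time x channel grid,
#' and returns a deterministic index sorted by position, time, channel.
#'
#' @param dir dataset directory.
#' @return Object of class `dataset_index`: data frame (`position`, `time`,
#'   `channel`, `path`) with attributes `base` and `dir`.
#' @export
discover_dataset <- function(dir) {
  if (!dir.exists(dir)) stop("directory does not exist: ", dir)
  files <- list.files(dir, pattern = "\\.(tif|tiff|png)$", ignore.case = TRUE)
  rows <- list()
  for (f in files) {
    key <- tryCatch(parse_frame_filename(f), error = function(e) NULL)
    if (is.null(key)) next
    rows[[length(rows) + 1L]] <- data.frame(
      base = key$base, position = key$position, time = key$time,
      channel = key$channel, path = file.path(dir, f))
  }
  if (length(rows) == 0L)
    stop("no parseable frame files found in ", dir)
  idx <- do.call(rbind, rows)
  idx <- idx[order(idx$position, idx$time, idx$channel), ]
  rownames(idx) <- NULL
  # completeness: every position must hold a full time x channel grid
  missing <- character(0)
  for (p in unique(idx$position)) {
    sub <- idx[idx$position == p, ]
    times <- seq_len(max(sub$time))
    chans <- seq_len(max(sub$channel))
    grid <- expand.grid(time = times, channel = chans)
    have <- paste(sub$time, sub$channel)
    lack <- grid[!(paste(grid$time, grid$channel) %in% have), ]
    if (nrow(lack))
      missing <- c(missing, sprintf("position %d time %d channel %d",
                                    p, lack$time, lack$channel))
  }
  if (length(missing))
    stop("incomplete dataset grid; missing: ",
         paste(missing, collapse = "; "))
  structure(idx[, c("position", "time", "channel", "path")],
            base = idx$base[1], dir = dir, class = c("dataset_index", "data.frame"))
}

#' Read all frames of one position/channel as an image stack
#'
#' @param index a [discover_dataset()] result.
#' @param position,channel indices to read.
#' @return List of numeric matrices in time order.
#' @export
read_stack <- function(index, position = 1L, channel = 1L) {
  sub <- index[index$position == position & index$channel == channel, ]
  if (nrow(sub) == 0L)
    stop("no frames for position ", position, " channel ", channel)
  lapply(sub$path[order(sub$time)], function(p) {
    img <- if (grepl("\\.png$", p, ignore.case = TRUE))
      png::readPNG(p) else tiff::readTIFF(p)
    if (length(dim(img)) == 3L) img <- img[, , 1]
    img
  })
}

#' Write a complete synthetic dataset to disk
#'
#' Renders a simulated colony in the requested modalities (one image
#' channel per modality), writes TIFF frames in the filename dialect,
#' ground-truth masks as 16-bit PNG, the lineage and focus tables as CSV,
#' and echoes the simulation parameters to a YAML config.
#'
#' @param sim a [simulate_colony()] result.
#' @param dir output directory (created if needed).
#' @param modalities_used character vector of modality names; channel `i`
#'   is rendered in `modalities_used[i]`.
#' @param base dataset base name.
#' @param blur_sigma,noise_sd renderer settings.
#' @param foci_channel optional channel index that receives simulated foci.
#' @param foci_per_cell foci per cell for that channel.
#' @return The directory, invisibly; side effects on disk.
#' @export
write_synthetic_dataset <- function(sim, dir,
                                    modalities_used = c("phase", "cyto_fluor"),
                                    base = "colony", blur_sigma = 0.8,
                                    noise_sd = 0.01, foci_channel = NA_integer_,
                                    foci_per_cell = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), showWarnings = FALSE)
  p <- sim$params
  foci_all <- list()
  for (t in seq_len(sim$n_frames)) {
    for (ch in seq_along(modalities_used)) {
      img <- render_modality(sim$masks[[t]], modalities_used[ch],
                             blur_sigma = blur_sigma, noise_sd = noise_sd,
                             seed = substream_seed(p$seed, paste0("frame", t, "ch", ch)))
      if (!is.na(foci_channel) && ch == foci_channel && foci_per_cell > 0L) {
        fr <- add_foci(img, sim$states[[t]], p$pixel_size,
                       foci_per_cell = foci_per_cell,
                       seed = substream_seed(p$seed, paste0("foci", t)))
        img <- fr$image
        if (nrow(fr$foci)) {
          fr$foci$frame <- t
          foci_all[[length(foci_all) + 1L]] <- fr$foci
        }
      }
      tiff::writeTIFF(clamp(img, 0, 1), file.path(dir, frame_filename(base, t, 1L, ch)),
                      bits.per.sample = 16L)
    }
    write_mask_png(sim$masks[[t]],
                   file.path(dir, "masks", sprintf("%s_t%03dxy01_mask.png", base, t)))
  }
  utils::write.csv(sim$lineage, file.path(dir, "lineage.csv"), row.names = FALSE)
  if (length(foci_all))
    utils::write.csv(do.call(rbind, foci_all), file.path(dir, "foci.csv"),
                     row.names = FALSE)
  cfg <- c(unclass(p), list(modalities = modalities_used, base = base,
                            blur_sigma = blur_sigma, noise_sd = noise_sd))
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Mask file paths of a written synthetic dataset
#' @param dir dataset directory.
#' @return Character vector of PNG paths in frame order.
#' @export
list_mask_files <- function(dir) {
  f <- list.files(file.path(dir, "masks"), pattern = "_mask\\.png$",
                  full.names = TRUE)
  f[order(f)]
}

# ---- frame files / cell files -----------------------------------------

.ff_version <- "omnicyte-frame-1"

#' Write per-frame composite files
#'
#' One directory per frame holding the registered channel images (TIFF),
#' the label mask (16-bit PNG), the region table and the link table to the
#' next frame (CSV), plus a JSON header with the container version.
#'
#' @param dir output directory.
#' @param masks list of label masks.
#' @param images list (frames) of lists (channels) of matrices; may be NULL.
#' @param linkages [link_movie()] result or NULL.
#' @return `dir`, invisibly.
#' @export
write_frame_files <- function(dir, masks, images = NULL, linkages = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (t in seq_along(masks)) {
    fd <- file.path(dir, sprintf("frame%04d", t))
    dir.create(fd, showWarnings = FALSE)
    jsonlite::write_json(list(version = .ff_version, frame = t,
                              n_channels = length(images[[t]] %||% list())),
                         file.path(fd, "header.json"), auto_unbox = TRUE)
    write_mask_png(masks[[t]], file.path(fd, "mask.png"))
    ar <- region_areas(masks[[t]])
    regs <- data.frame(region = as.integer(names(ar)), area_px = as.integer(ar))
    for (r in seq_len(nrow(regs))) {
      rc <- which(masks[[t]] == regs$region[r], arr.ind = TRUE)
      regs$bbox_rmin[r] <- min(rc[, 1]); regs$bbox_rmax[r] <- max(rc[, 1])
      regs$bbox_cmin[r] <- min(rc[, 2]); regs$bbox_cmax[r] <- max(rc[, 2])
    }
    utils::write.csv(regs, file.path(fd, "regions.csv"), row.names = FALSE)
    if (!is.null(images)) for (ch in seq_along(images[[t]]))
      tiff::writeTIFF(clamp(images[[t]][[ch]], 0, 1),
                      file.path(fd, sprintf("ch%d.tif", ch)),
                      bits.per.sample = 16L)
    if (!is.null(linkages) && t <= length(linkages))
      utils::write.csv(linkages[[t]]$from, file.path(fd, "links.csv"),
                       row.names = FALSE)
  }
  invisible(dir)
}

#' Read frame files written by [write_frame_files()]
#'
#' @param dir frame-file directory.
#' @return List with `masks`, `images`, `links`, `regions`.
#' @export
read_frame_files <- function(dir) {
  fds <- sort(list.dirs(dir, recursive = FALSE))
  fds <- fds[grepl("frame[0-9]{4}$", fds)]
  masks <- list(); images <- list(); links <- list(); regions <- list()
  for (fd in fds) {
    hdr <- jsonlite::read_json(file.path(fd, "header.json"))
    if (!identical(hdr$version, .ff_version))
      stop("frame file version mismatch in ", fd, ": found '", hdr$version,
           "', expected '", .ff_version, "'")
    t <- hdr$frame
    masks[[t]] <- read_mask_png(file.path(fd, "mask.png"))
    regions[[t]] <- utils::read.csv(file.path(fd, "regions.csv"))
    chf <- sort(list.files(fd, pattern = "^ch[0-9]+\\.tif$", full.names = TRUE))
    images[[t]] <- lapply(chf, tiff::readTIFF)
    lf <- file.path(fd, "links.csv")
    if (file.exists(lf)) {
      lnk <- utils::read.csv(lf)
      for (cc in c("region", "succ1", "succ2"))
        lnk[[cc]] <- as.integer(lnk[[cc]])
      links[[t]] <- lnk
    }
  }
  list(masks = masks, images = images, links = links, regions = regions)
}

#' Write per-cell files
#'
#' One directory per cell: metadata JSON (identity, lineage, frames), the
#' per-frame metric rows (CSV), and per-frame image crops (TIFF) padded to
#' the cell's fixed bounding box across its lifetime.
#'
#' @param dir output directory.
#' @param clist a [assemble_clist()] result.
#' @param masks label masks (tracking-corrected).
#' @param tracking [track_cells()] result.
#' @param images optional list (frames) of lists (channels) for crops.
#' @return `dir`, invisibly.
#' @export
write_cell_files <- function(dir, clist, masks, tracking, images = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(nrow(clist$cells))) {
    cell <- clist$cells[i, ]
    cd <- file.path(dir, sprintf("cell%05d", cell$cell_id))
    dir.create(cd, showWarnings = FALSE)
    cf <- clist$frames[clist$frames$cell_id == cell$cell_id, , drop = FALSE]
    jsonlite::write_json(list(version = "omnicyte-cell-1",
                              cell_id = cell$cell_id,
                              mother_id = cell$mother_id,
                              daughters = c(cell$daughter1_id, cell$daughter2_id),
                              birth_frame = cell$birth_frame,
                              end_frame = cell$end_frame),
                         file.path(cd, "cell.json"), auto_unbox = TRUE)
    utils::write.csv(cf, file.path(cd, "frames.csv"), row.names = FALSE)
    if (!is.null(images)) {
      r0 <- min(cf$bbox_rmin); r1 <- max(cf$bbox_rmax)
      c0 <- min(cf$bbox_cmin); c1 <- max(cf$bbox_cmax)
      for (k in seq_len(nrow(cf))) {
        t <- cf$frame[k]
        for (ch in seq_along(images[[t]]))
          tiff::writeTIFF(clamp(images[[t]][[ch]][r0:r1, c0:c1], 0, 1),
                          file.path(cd, sprintf("t%04d_ch%d.tif", t, ch)),
                          bits.per.sample = 16L)
      }
    }
  }
  invisible(dir)
}

#' Read one cell file back
#'
#' @param dir cell-file directory.
#' @param cell_id which cell.
#' @return List with `meta`, `frames` (data frame) and `crops` (list of
#'   per-frame channel lists).
#' @export
read_cell_file <- function(dir, cell_id) {
  cd <- file.path(dir, sprintf("cell%05d", cell_id))
  if (!dir.exists(cd)) stop("no cell file for cell_id ", cell_id)
  meta <- jsonlite::read_json(file.path(cd, "cell.json"))
  frames <- utils::read.csv(file.path(cd, "frames.csv"))
  crops <- list()
  for (t in frames$frame) {
    chf <- sort(list.files(cd, pattern = sprintf("^t%04d_ch[0-9]+\\.tif$", t),
                           full.names = TRUE))
    if (length(chf)) crops[[as.character(t)]] <- lapply(chf, tiff::readTIFF)
  }
  list(meta = meta, frames = frames, crops = crops)
}
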