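# The clist: one row per cell of per-cell descriptors, plus a companion
# per-cell-per-frame table, plus a column registry documenting the name,
# unit and definition of every quantity. The registry is the package's own
# enumeration of its default descriptor set.

.reg_row <- function(name, unit, definition, class)
  data.frame(name = name, unit = unit, definition = definition, class = class)

#' Default descriptor registry
#'
#' Enumerates every per-cell descriptor and per-cell-per-frame quantity the
#' pipeline emits by default, with units and definitions. The per-cell set
#' exceeds 80 descriptors and the per-frame set exceeds 20 quantities once
#' at least one fluorescence channel is present.
#'
#' @param n_channels number of image channels quantified.
#' @param foci whether a focus-detection channel is configured.
#' @return Data frame: `name`, `unit`, `definition`, `class`
#'   (`"per_cell"` or `"per_frame"`).
#' @export
descriptor_registry <- function(n_channels = 2L, foci = TRUE) {
  pc <- list(
    c("mother_id", "id", "cell ID of the mother, NA for progenitors/orphans"),
    c("daughter1_id", "id", "cell ID of the first daughter"),
    c("daughter2_id", "id", "cell ID of the second daughter"),
    c("sibling_id", "id", "cell ID of the sister cell"),
    c("generation", "count", "distance to the progenitor in the lineage (progenitor = 1)"),
    c("origin", "category", "progenitor | division | orphan | edge-entry"),
    c("stat_0", "flag", "complete cell cycle observed (born by division and divided in-movie)"),
    c("birth_frame", "frame", "first frame of the track"),
    c("birth_time_min", "min", "time of birth"),
    c("division_frame", "frame", "last frame before division (NA if not divided)"),
    c("division_time_min", "min", "time of division"),
    c("end_frame", "frame", "last frame of the track"),
    c("end_reason", "category", "divided | lost | end-of-movie"),
    c("lifetime_frames", "frames", "track length in frames"),
    c("lifetime_min", "min", "track duration"))
  geom_defs <- c(length_um = "medial-axis pole-to-pole length (um)",
                 area_um2 = "region area (um^2)",
                 area_px = "region area (px)",
                 width_mean_um = "mean width from the distance transform along the axis (um)",
                 width_max_um = "maximum width (um)",
                 perimeter_um = "pixel-edge perimeter (um)",
                 aspect_ratio = "length / mean width")
  for (g in names(geom_defs)) for (s in c("birth", "end", "mean", "min", "max"))
    pc[[length(pc) + 1L]] <- c(paste0(g, "_", s),
                               sub(".*\\((.*)\\).*", "\\1", geom_defs[g]),
                               paste0(s, " of: ", geom_defs[g]))
  pc <- c(pc, list(
    c("added_length_um", "um", "length at end minus length at birth"),
    c("added_area_um2", "um^2", "area at end minus area at birth"),
    c("elongation_rate_per_min", "1/min", "slope of log(length) vs time (exponential fit)"),
    c("elongation_rate_se", "1/min", "standard error of the elongation rate"),
    c("elongation_fit_r2", "-", "R^2 of the exponential elongation fit"),
    c("linear_growth_rate_um_per_min", "um/min", "(end length - birth length) / lifetime"),
    c("doubling_time_min", "min", "ln(2) / elongation rate"),
    c("birth_centroid_row", "px", "centroid row at birth"),
    c("birth_centroid_col", "px", "centroid column at birth"),
    c("end_centroid_row", "px", "centroid row at end"),
    c("end_centroid_col", "px", "centroid column at end"),
    c("net_displacement_px", "px", "birth-to-end centroid displacement"),
    c("path_length_px", "px", "summed frame-to-frame centroid displacement"),
    c("mean_speed_px_per_frame", "px/frame", "path length / (lifetime frames - 1)"),
    c("mean_orientation_rad", "rad", "mean long-axis orientation"),
    c("orientation_change_rad", "rad", "axis rotation between birth and end")))
  for (ch in seq_len(n_channels)) {
    base <- paste0("ch", ch, "_")
    pc <- c(pc, list(
      c(paste0(base, "mean_mean"), "au", paste0("lifetime mean of channel ", ch, " region mean intensity")),
      c(paste0(base, "mean_max"), "au", paste0("lifetime max of channel ", ch, " region mean intensity")),
      c(paste0(base, "mean_min"), "au", paste0("lifetime min of channel ", ch, " region mean intensity")),
      c(paste0(base, "mean_birth"), "au", paste0("channel ", ch, " region mean at birth")),
      c(paste0(base, "mean_end"), "au", paste0("channel ", ch, " region mean at end")),
      c(paste0(base, "sum_mean"), "au", paste0("lifetime mean of channel ", ch, " integrated intensity")),
      c(paste0(base, "sum_total"), "au", paste0("lifetime total of channel ", ch, " integrated intensity")),
      c(paste0(base, "bgsub_mean_mean"), "au", paste0("lifetime mean of background-subtracted channel ", ch, " mean")),
      c(paste0(base, "sd_mean"), "au", paste0("lifetime mean of channel ", ch, " intensity sd"))))
  }
  if (foci) pc <- c(pc, list(
    c("foci_count_mean", "count", "mean number of detected foci per frame"),
    c("foci_count_max", "count", "max number of detected foci in a frame"),
    c("foci_count_total", "count", "total focus detections over the track"),
    c("foci_axis_frac_mean", "-", "mean long-axis fractional position of the brightest focus"),
    c("foci_intensity_mean", "au", "mean band-pass amplitude of the brightest focus")))
  pf <- list(
    c("region", "label", "region number in this frame"),
    c("time_min", "min", "frame time"),
    c("area_px", "px", "region area in pixels"),
    c("area_um2", "um^2", "region area"),
    c("length_um", "um", "medial-axis pole-to-pole length"),
    c("width_mean_um", "um", "mean width along the axis"),
    c("width_max_um", "um", "maximum width"),
    c("perimeter_um", "um", "pixel-edge perimeter"),
    c("orientation_rad", "rad", "long-axis orientation"),
    c("centroid_row", "px", "centroid row"),
    c("centroid_col", "px", "centroid column"),
    c("aspect_ratio", "-", "length / mean width"),
    c("bbox_rmin", "px", "bounding box top row"),
    c("bbox_rmax", "px", "bounding box bottom row"),
    c("bbox_cmin", "px", "bounding box left column"),
    c("bbox_cmax", "px", "bounding box right column"),
    c("n_neighbors", "count", "touching neighbour regions"),
    c("touches_border", "flag", "region touches the field border"),
    c("geom_ok", "flag", "medial-axis geometry computed"))
  for (ch in seq_len(n_channels)) {
    base <- paste0("ch", ch, "_")
    for (q in c("mean", "median", "sum", "sd", "bgsub_mean", "bgsub_sum"))
      pf[[length(pf) + 1L]] <- c(paste0(base, q), "au",
                                 paste0("channel ", ch, " region intensity ", q))
  }
  if (foci) pf <- c(pf, list(
    c("foci_count", "count", "detected foci in this frame"),
    c("foci1_axis_frac", "-", "axis position of the first focus"),
    c("foci1_intensity", "au", "band-pass amplitude of the first focus")))
  rbind(
    do.call(rbind, lapply(pc, function(x) .reg_row(x[1], x[2], x[3], "per_cell"))),
    do.call(rbind, lapply(pf, function(x) .reg_row(x[1], x[2], x[3], "per_frame"))))
}

#' Assemble the clist from tracking and per-frame metrics
#'
#' Joins per-frame region metrics onto the cell tracks, summarizes each
#' cell, and validates every emitted column against the registry.
#'
#' @param tracking result of [track_cells()].
#' @param frame_metrics list of [compute_frame_metrics()] results, one per
#'   frame.
#' @param params a [cyto_params()] object.
#' @param registry a [descriptor_registry()] data frame.
#' @return Object of class `clist`: list with `cells` (per-cell table),
#'   `frames` (per-cell-per-frame table keyed by `cell_id`, `frame`) and
#'   `registry`.
#' @export
assemble_clist <- function(tracking, frame_metrics, params = cyto_params(),
                           registry = NULL) {
  metr <- lapply(frame_metrics, `[[`, "metrics")
  long <- list()
  for (i in seq_len(nrow(tracking$tracks))) {
    t <- tracking$tracks$frame[i]; r <- tracking$tracks$region[i]
    m <- metr[[t]]
    row <- m[m$region == r, , drop = FALSE]
    if (nrow(row) != 1L)
      stop("no metrics for region ", r, " in frame ", t)
    row$cell_id <- tracking$tracks$cell_id[i]
    long[[length(long) + 1L]] <- row
  }
  frames <- do.call(rbind, long)
  frames <- frames[order(frames$cell_id, frames$frame),
                   c("cell_id", setdiff(names(frames), "cell_id"))]
  rownames(frames) <- NULL
  cells <- do.call(rbind, lapply(seq_len(nrow(tracking$cells)), function(i) {
    cell <- tracking$cells[i, ]
    cf <- frames[frames$cell_id == cell$cell_id, , drop = FALSE]
    summarize_cell(cell, cf, tracking$cells, params)
  }))
  rownames(cells) <- NULL
  if (is.null(registry)) {
    n_ch <- length(unique(sub("_(mean|median|sum|sd|bgsub_mean|bgsub_sum)$", "",
                              grep("^ch[0-9]+_", names(frames), value = TRUE))))
    registry <- descriptor_registry(n_channels = n_ch,
                                    foci = "foci_count" %in% names(frames))
  }
  unreg_c <- setdiff(names(cells), c("cell_id", registry$name[registry$class == "per_cell"]))
  unreg_f <- setdiff(names(frames), c("cell_id", "frame", registry$name[registry$class == "per_frame"]))
  if (length(unreg_c) || length(unreg_f))
    stop("columns not in the registry: ",
         paste(c(unreg_c, unreg_f), collapse = ", "))
  structure(list(cells = cells, frames = frames, registry = registry),
            class = "clist")
}

#' @export
print.clist <- function(x, ...) {
  cat("clist:", nrow(x$cells), "cells,",
      ncol(x$cells) - 1L, "per-cell descriptors;",
      nrow(x$frames), "cell-frames,",
      ncol(x$frames) - 2L, "per-frame quantities\n")
  invisible(x)
}

#' Export a clist to CSV or XLSX
#'
#' CSV export writes `<path>_cells.csv`, `<path>_frames.csv` and
#' `<path>_columns.json` (the registry). XLSX export writes one workbook
#' (`<path>.xlsx`) with `cells`, `frames` and `columns` worksheets. Values
#' are identical between the two formats.
#'
#' @param clist a [assemble_clist()] result.
#' @param path output path prefix (CSV) or file path without extension
#'   (XLSX).
#' @param format `"csv"` or `"xlsx"`.
#' @return Character vector of files written, invisibly.
#' @export
export_clist <- function(clist, path, format = c("csv", "xlsx")) {
  format <- match.arg(format)
  if (format == "csv") {
    fc <- paste0(path, "_cells.csv")
    ff <- paste0(path, "_frames.csv")
    fj <- paste0(path, "_columns.json")
    utils::write.csv(clist$cells, fc, row.names = FALSE)
    utils::write.csv(clist$frames, ff, row.names = FALSE)
    jsonlite::write_json(clist$registry, fj, dataframe = "rows", pretty = TRUE)
    invisible(c(fc, ff, fj))
  } else {
    fx <- paste0(path, ".xlsx")
    write_xlsx(list(cells = clist$cells, frames = clist$frames,
                    columns = clist$registry), fx)
    invisible(fx)
  }
}
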