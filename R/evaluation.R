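# Evaluation metrics. Cell width inferred from cell contact exploits the
# uniform rod morphology of the organism: across a stack of k side-by-side
# touching cells, the outer-boundary-to-outer-boundary span divided by k
# estimates the true width free of per-boundary segmentation bias. Fatal
# errors are the over-/under-segmentation and linking mistakes that would
# require hand-correction before trajectories can be formed; a division
# called a few frames early or late, with correctly linkable daughters, is
# exempt.

#' Width-from-contact parameters
#'
#' @param max_angle_diff maximum orientation difference (radians) between
#'   touching cells grouped as parallel.
#' @param min_group_size minimum number of stacked cells per group.
#' @param min_transects minimum along-axis bins with a valid measurement.
#' @param coverage_frac per bin, each cell must hold at least this fraction
#'   of its own maximal per-bin pixel count (drops bins near cell poles).
#' @return A `width_params` list.
#' @export
width_params <- function(max_angle_diff = 15 * pi / 180, min_group_size = 2L,
                         min_transects = 3L, coverage_frac = 0.7) {
  structure(list(max_angle_diff = max_angle_diff,
                 min_group_size = as.integer(min_group_size),
                 min_transects = as.integer(min_transects),
                 coverage_frac = coverage_frac), class = "width_params")
}

# adjacency pairs (touching labels) of a mask
.touching_pairs <- function(mask) {
  prs <- list()
  for (d in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(1L, -1L))) {
    nb <- shift_mat(mask, d[1], d[2], fill = 0L)
    sel <- mask > 0L & nb > 0L & nb != mask
    if (any(sel)) prs[[length(prs) + 1L]] <- cbind(pmin(mask[sel], nb[sel]),
                                                   pmax(mask[sel], nb[sel]))
  }
  if (!length(prs)) return(matrix(integer(0), 0, 2))
  unique(do.call(rbind, prs))
}

# connected components of an undirected edge list over given nodes
# (union-find over node indices)
.graph_components <- function(nodes, edges) {
  parent <- seq_along(nodes)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  if (nrow(edges)) for (k in seq_len(nrow(edges))) {
    a <- find(match(edges[k, 1], nodes))
    b <- find(match(edges[k, 2], nodes))
    if (a != b) parent[b] <- a
  }
  roots <- vapply(seq_along(nodes), find, integer(1))
  split(nodes, roots)
}

#' Infer the true cell width from cell contact
#'
#' Finds groups of two or more touching, near-parallel cells; for each
#' group, measures the perpendicular outer-to-outer span across the stack
#' at many positions along the shared axis, and divides each span by the
#' number of cells it crosses. The estimate is the median over all
#' measurements.
#'
#' @param mask integer label mask.
#' @param pixel_size micrometers per pixel.
#' @param params a [width_params()] object.
#' @return Object of class `width_estimate`: list with `width_um`,
#'   `n_measurements`, `n_groups`, and a data frame `measurements`
#'   (`group`, `k`, `span_um`, `width_um`).
#' @export
width_from_contact <- function(mask, pixel_size, params = width_params()) {
  labs <- mask_labels(mask)
  pix <- list(); ori <- numeric(0)
  for (l in labs) {
    rc <- which(mask == l, arr.ind = TRUE)
    pix[[as.character(l)]] <- rc
    ori[as.character(l)] <- pixel_orientation(rc[, 1], rc[, 2])
  }
  prs <- .touching_pairs(mask)
  if (nrow(prs)) {
    par_ok <- axis_angle_diff(ori[as.character(prs[, 1])],
                              ori[as.character(prs[, 2])]) <= params$max_angle_diff
    prs <- prs[par_ok, , drop = FALSE]
  }
  groups <- .graph_components(labs, prs)
  groups <- Filter(function(g) length(g) >= params$min_group_size, groups)
  meas <- list()
  gi <- 0L
  for (g in groups) {
    gi <- gi + 1L
    # mean axis direction of the group (circular mean over the half-circle)
    os <- ori[as.character(g)]
    mo <- 0.5 * atan2(mean(sin(2 * os)), mean(cos(2 * os)))
    ca <- cos(mo); sa <- sin(mo)
    # rotate pixels into (s = along axis, q = perpendicular)
    allpix <- lapply(as.character(g), function(l) pix[[l]])
    s <- lapply(allpix, function(rc) rc[, 2] * ca + rc[, 1] * sa)
    q <- lapply(allpix, function(rc) -rc[, 2] * sa + rc[, 1] * ca)
    sbins <- lapply(s, function(v) round(v))
    srange <- range(unlist(sbins))
    percell_max <- vapply(sbins, function(v) max(table(v)), numeric(1))
    for (b in srange[1]:srange[2]) {
      lo <- numeric(0); hi <- numeric(0); ok <- TRUE
      for (ci in seq_along(g)) {
        inb <- sbins[[ci]] == b
        if (!any(inb)) next
        if (sum(inb) < params$coverage_frac * percell_max[ci]) { ok <- FALSE; break }
        r <- range(q[[ci]][inb])
        lo <- c(lo, r[1]); hi <- c(hi, r[2])
      }
      kcells <- length(lo)
      if (!ok || kcells < params$min_group_size) next
      # the stacked cells must be contiguous along the transect: reject
      # bins where a gap (missing cell, background) interrupts the stack
      ordq <- order(lo)
      lo <- lo[ordq]; hi <- hi[ordq]
      if (kcells > 1L && any(lo[-1] - hi[-kcells] > 2)) next
      span <- (max(hi) - min(lo) + 1) * pixel_size
      meas[[length(meas) + 1L]] <- data.frame(
        group = gi, k = kcells, span_um = span, width_um = span / kcells)
    }
  }
  if (length(meas) < params$min_transects)
    stop("insufficient contact: no group of >= ", params$min_group_size,
         " near-parallel touching cells with >= ", params$min_transects,
         " valid transects")
  mdf <- do.call(rbind, meas)
  structure(list(width_um = median(mdf$width_um),
                 n_measurements = nrow(mdf),
                 n_groups = length(groups), measurements = mdf),
            class = "width_estimate")
}

#' Bias and spread of per-cell width measurements
#'
#' `delta_mu` is the relative bias of the mean measured width against the
#' true width; `sigma` is the population (1/n) standard deviation of the
#' measurements. Both are reported in percent and in nanometers.
#'
#' @param widths numeric vector of per-cell widths (micrometers).
#' @param true_width true width (micrometers).
#' @return List: `delta_mu_pct`, `delta_mu_nm`, `sigma_pct`, `sigma_nm`,
#'   `cv_pct` (sigma/mean), `n`.
#' @export
width_stats <- function(widths, true_width) {
  stopifnot(length(widths) >= 2L, true_width > 0)
  mu <- mean(widths)
  sig <- sqrt(mean((widths - mu)^2))
  list(delta_mu_pct = 100 * (mu - true_width) / true_width,
       delta_mu_nm = 1000 * (mu - true_width),
       sigma_pct = 100 * sig / true_width,
       sigma_nm = 1000 * sig,
       cv_pct = 100 * sig / mu,
       n = length(widths))
}

#' Fatal-error counting parameters
#'
#' @param division_tolerance frames by which a predicted division may lead
#'   or trail the true division without counting as an error.
#' @param min_region_area predicted regions smaller than this are debris,
#'   not errors.
#' @param majority_frac overlap fraction defining the predicted-to-truth
#'   correspondence.
#' @return A `fatal_params` list.
#' @export
fatal_params <- function(division_tolerance = 2L, min_region_area = 20L,
                         majority_frac = 0.5) {
  structure(list(division_tolerance = as.integer(division_tolerance),
                 min_region_area = as.integer(min_region_area),
                 majority_frac = majority_frac), class = "fatal_params")
}

#' Count cumulative fatal errors against ground truth
#'
#' Per frame, predicted regions are matched to truth cells by majority
#' pixel overlap. Three error types are counted: over-segmentation (one
#' truth cell covered by two or more predicted regions), under-segmentation
#' (one predicted region absorbing two or more truth cells), and linking
#' errors (a predicted trajectory jumping between truth cells). Each
#' contiguous erroneous episode counts once. Division-timing shifts are
#' exempt: a predicted split (or delayed merge) within
#' `division_tolerance` frames of the true division does not count.
#'
#' @param pred_masks list of predicted label masks.
#' @param truth_masks list of ground-truth masks (labels = truth cell ids).
#' @param truth_lineage ground-truth lineage data frame (from
#'   [simulate_colony()]).
#' @param pred_tracks optional tracks data frame from [track_cells()] for
#'   linking-error detection.
#' @param params a [fatal_params()] object.
#' @return Object of class `fatal_error_curve`: list with `cumulative`
#'   (integer vector per frame), `errors` (data frame: `frame`, `type`,
#'   `key`), `n_total`.
#' @export
count_fatal_errors <- function(pred_masks, truth_masks, truth_lineage,
                               pred_tracks = NULL, params = fatal_params()) {
  nT <- length(pred_masks)
  if (length(truth_masks) != nT)
    stop("predicted and truth mask sequences differ in length")
  for (t in seq_len(nT))
    if (!all(dim(pred_masks[[t]]) == dim(truth_masks[[t]])))
      stop("mask shape mismatch at frame ", t)
  tol <- params$division_tolerance
  div_frame <- setNames(truth_lineage$division_frame, truth_lineage$cell_id)
  birth_frame <- setNames(truth_lineage$birth_frame, truth_lineage$cell_id)
  mother_of <- setNames(truth_lineage$mother_id, truth_lineage$cell_id)
  events <- list()       # per frame: character keys of active error states
  owner_by_frame <- list()  # per frame: named map pred region -> truth cell
  for (t in seq_len(nT)) {
    ov <- compute_overlaps(pred_masks[[t]], truth_masks[[t]])
    keys <- character(0)
    owner <- setNames(rep(NA_integer_, length(ov$areas_t)), names(ov$areas_t))
    if (length(ov$areas_t) && length(ov$areas_t1)) {
      # owner: truth cell receiving the majority of each pred region
      for (r in names(ov$areas_t)) {
        best <- which.max(ov$counts[r, ])
        if (length(best) && ov$counts[r, best] >
            params$majority_frac * ov$areas_t[r])
          owner[r] <- as.integer(colnames(ov$counts)[best])
      }
      big <- names(ov$areas_t)[ov$areas_t >= params$min_region_area]
      # over-segmentation: >= 2 substantial pred regions owned by one cell
      # (division-timing exemptions are applied in a later pass, once it is
      # known whether a split persists into the true division)
      ocount <- table(owner[big])
      for (cid in names(ocount)[ocount >= 2L])
        keys <- c(keys, paste0("over:", cid, if (ocount[cid] == 2L) ":2" else ""))
      # under-segmentation: one pred region holding the majority of >= 2
      # truth cells
      covered <- character(0)
      for (r in names(ov$areas_t)) {
        held <- colnames(ov$counts)[ov$counts[r, ] >
                                      params$majority_frac * ov$areas_t1]
        covered <- c(covered, held)
        if (length(held) >= 2L) {
          sibs <- length(held) == 2L &&
            !is.na(mother_of[held[1]]) && !is.na(mother_of[held[2]]) &&
            mother_of[held[1]] == mother_of[held[2]]
          keys <- c(keys, paste0("under:", paste(sort(held), collapse = "+"),
                                 if (sibs) ":sib" else ""))
        }
      }
      # missed cells: a truth cell neither majority-covered by any single
      # pred region nor owning any pred region (a dropped segmentation)
      owned_cells <- as.character(owner[!is.na(owner)])
      for (cid in names(ov$areas_t1)) {
        if (ov$areas_t1[cid] < params$min_region_area) next
        if (!(cid %in% covered) && !(cid %in% owned_cells))
          keys <- c(keys, paste0("miss:", cid))
      }
    } else if (length(ov$areas_t1)) {
      for (cid in names(ov$areas_t1))
        if (ov$areas_t1[cid] >= params$min_region_area)
          keys <- c(keys, paste0("miss:", cid))
    }
    owner_by_frame[[t]] <- owner
    events[[t]] <- keys
  }
  # linking errors: a track's owner changing to a non-daughter truth cell
  if (!is.null(pred_tracks)) {
    for (id in unique(pred_tracks$cell_id)) {
      tr <- pred_tracks[pred_tracks$cell_id == id, ]
      tr <- tr[order(tr$frame), ]
      if (nrow(tr) < 2L) next
      own <- vapply(seq_len(nrow(tr)), function(k)
        owner_by_frame[[tr$frame[k]]][as.character(tr$region[k])] %||% NA_integer_,
        integer(1))
      for (k in seq_len(nrow(tr) - 1L)) {
        a <- own[k]; b <- own[k + 1L]
        if (is.na(a) || is.na(b) || a == b) next
        # following a truth daughter after (around) the true division is a
        # division-timing matter, not a linking error
        legit <- !is.na(mother_of[as.character(b)]) &&
          mother_of[as.character(b)] == a
        if (!legit)
          events[[tr$frame[k + 1L]]] <-
            c(events[[tr$frame[k + 1L]]], paste0("link:", id))
      }
    }
  }
  # division-timing exemptions. An early call is exempt when the cell is
  # split into exactly two regions at its true division frame and in the
  # preceding frames back to at most `tol` before it: a transient split
  # that reverts before the division is a real error. A late call is
  # exempt when two truth siblings share one predicted region from their
  # birth for at most `tol` frames.
  for (i in seq_len(nrow(truth_lineage))) {
    cid <- as.character(truth_lineage$cell_id[i])
    dv <- truth_lineage$division_frame[i]
    if (!is.na(dv) && dv <= nT) {
      key2 <- paste0("over:", cid, ":2")
      if (key2 %in% events[[dv]]) {
        t <- dv
        while (t >= max(1L, dv - tol) && key2 %in% events[[t]]) {
          events[[t]] <- setdiff(events[[t]], key2)
          t <- t - 1L
        }
      }
    }
    d1 <- truth_lineage$daughter1[i]
    if (!is.na(d1)) {
      d2 <- truth_lineage$daughter2[i]
      bf <- truth_lineage$birth_frame[truth_lineage$cell_id == d1]
      sibkey <- paste0("under:", paste(sort(c(d1, d2)), collapse = "+"), ":sib")
      if (bf <= nT && sibkey %in% events[[bf]]) {
        t <- bf
        while (t <= min(nT, bf + tol - 1L) && sibkey %in% events[[t]]) {
          events[[t]] <- setdiff(events[[t]], sibkey)
          t <- t + 1L
        }
      }
    }
  }
  # normalize the annotated keys back to their plain form
  events <- lapply(events, function(k) unique(sub(":(2|sib)$", "", k)))
  # collapse contiguous episodes: a key active in consecutive frames is one
  # error
  cum <- integer(nT)
  err_rows <- list()
  prev <- character(0)
  total <- 0L
  for (t in seq_len(nT)) {
    new <- setdiff(unique(events[[t]]), prev)
    total <- total + length(new)
    cum[t] <- total
    for (k in new) {
      sp <- strsplit(k, ":", fixed = TRUE)[[1]]
      err_rows[[length(err_rows) + 1L]] <-
        data.frame(frame = t, type = sp[1], key = sp[2])
    }
    prev <- unique(events[[t]])
  }
  structure(list(cumulative = cum,
                 errors = if (length(err_rows)) do.call(rbind, err_rows)
                 else data.frame(frame = integer(0), type = character(0),
                                 key = character(0)),
                 n_total = total),
            class = "fatal_error_curve")
}

#' Live-cell counts per frame
#'
#' @param x list of label masks, or a tracks data frame from
#'   [track_cells()].
#' @param n_frames required when `x` is a tracks table.
#' @return Integer vector of per-frame cell counts.
#' @export
cell_count_curve <- function(x, n_frames = NULL) {
  if (is.data.frame(x)) {
    if (is.null(n_frames)) n_frames <- max(x$frame)
    vapply(seq_len(n_frames), function(t)
      length(unique(x$cell_id[x$frame == t])), integer(1))
  } else {
    vapply(x, function(m) length(mask_labels(m)), integer(1))
  }
}
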