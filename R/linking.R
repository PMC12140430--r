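# Linking per-frame regions into persistent cell trajectories. Region
# numbers are a per-frame accident of segmentation; cell IDs persist for the
# whole time-lapse. The linker is a greedy maximum-overlap assignment with
# explicit division detection, followed by a temporal-consistency pass that
# suppresses division flicker (1 cell -> 2 cells -> 1 cell) caused by
# transient over-segmentation.

#' Linking parameters
#'
#' @param min_overlap_frac a candidate daughter must receive at least this
#'   fraction of its own area from the mother region.
#' @param area_ratio_lo,area_ratio_hi accepted range for (summed daughter
#'   area) / (mother area) at a division.
#' @param window number of frames within which a reverting division is
#'   treated as segmentation flicker and suppressed.
#' @param edge_margin px; regions appearing within this margin of the field
#'   edge are flagged `edge-entry` rather than `orphan`.
#' @return A `link_params` list.
#' @export
link_params <- function(min_overlap_frac = 0.5, area_ratio_lo = 0.6,
                        area_ratio_hi = 1.4, window = 3L, edge_margin = 2L) {
  structure(list(min_overlap_frac = min_overlap_frac,
                 area_ratio_lo = area_ratio_lo, area_ratio_hi = area_ratio_hi,
                 window = as.integer(window),
                 edge_margin = as.integer(edge_margin)),
            class = "link_params")
}

#' Shared-pixel overlap counts between two label masks
#'
#' @param mask_t,mask_t1 integer label matrices of identical shape.
#' @return List with `counts` (matrix, rows = regions in t, cols = regions
#'   in t+1, dimnames = labels), `areas_t`, `areas_t1` (named vectors).
#' @export
compute_overlaps <- function(mask_t, mask_t1) {
  if (!all(dim(mask_t) == dim(mask_t1)))
    stop("masks must have the same shape")
  a1 <- region_areas(mask_t)
  a2 <- region_areas(mask_t1)
  counts <- matrix(0L, length(a1), length(a2),
                   dimnames = list(names(a1), names(a2)))
  both <- mask_t > 0L & mask_t1 > 0L
  if (any(both)) {
    tab <- table(t = as.integer(mask_t[both]), t1 = as.integer(mask_t1[both]))
    counts[rownames(tab), colnames(tab)] <-
      counts[rownames(tab), colnames(tab)] + as.integer(tab)
  }
  list(counts = counts, areas_t = a1, areas_t1 = a2)
}

#' Link the regions of two consecutive frames
#'
#' Greedy maximum-overlap assignment: candidate links are visited in order
#' of decreasing shared-pixel count (ties broken by smaller region numbers)
#' and matched one-to-one, giving `continues` outcomes. A region in t with
#' exactly two strong successors not claimed by any other region — each
#' receiving at least `min_overlap_frac` of its own area from the mother,
#' with summed area within the accepted ratio of the mother's — is marked
#' `divides`. Unmatched regions in t end; unmatched regions in t+1 appear.
#'
#' @param overlaps result of [compute_overlaps()].
#' @param params a [link_params()] object.
#' @return List with `from` (data frame: `region`, `outcome`
#'   (`continues|divides|ends`), `succ1`, `succ2`) and `to` (data frame:
#'   `region`, `pred`; `NA` pred = appears).
#' @export
link_pair <- function(overlaps, params = link_params()) {
  counts <- overlaps$counts
  a1 <- overlaps$areas_t; a2 <- overlaps$areas_t1
  r1 <- as.integer(names(a1)); r2 <- as.integer(names(a2))
  n1 <- length(r1); n2 <- length(r2)
  from <- data.frame(region = r1, outcome = rep("ends", n1),
                     succ1 = NA_integer_, succ2 = NA_integer_)
  to <- data.frame(region = r2, pred = NA_integer_)
  if (n1 == 0L || n2 == 0L) return(list(from = from, to = to))
  idx <- which(counts > 0L, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(list(from = from, to = to))
  ord <- order(-counts[idx], r1[idx[, 1]], r2[idx[, 2]])
  idx <- idx[ord, , drop = FALSE]
  m_from <- rep(NA_integer_, n1)  # index into r2
  m_to <- rep(NA_integer_, n2)    # index into r1
  for (k in seq_len(nrow(idx))) {
    i <- idx[k, 1]; j <- idx[k, 2]
    if (is.na(m_from[i]) && is.na(m_to[j])) {
      m_from[i] <- j; m_to[j] <- i
    }
  }
  # division detection on top of the matching
  for (i in seq_len(n1)) {
    strong <- which(counts[i, ] >= params$min_overlap_frac * a2 &
                      (is.na(m_to) | m_to == i))
    if (length(strong) == 2L) {
      ratio <- sum(a2[strong]) / a1[i]
      if (ratio >= params$area_ratio_lo && ratio <= params$area_ratio_hi) {
        strong <- strong[order(r2[strong])]
        from$outcome[i] <- "divides"
        from$succ1[i] <- r2[strong[1]]
        from$succ2[i] <- r2[strong[2]]
        if (!is.na(m_from[i]) && !(m_from[i] %in% strong)) {
          # the matched successor was not one of the daughters; release it
          m_to[m_from[i]] <- NA_integer_
        }
        m_to[strong] <- i
        m_from[i] <- strong[1]
        next
      }
    }
    if (!is.na(m_from[i])) {
      from$outcome[i] <- "continues"
      from$succ1[i] <- r2[m_from[i]]
    }
  }
  to$pred <- ifelse(is.na(m_to), NA_integer_, r1[m_to])
  list(from = from, to = to)
}

#' Link every consecutive frame pair of a mask sequence
#'
#' @param masks list of integer label matrices.
#' @param params a [link_params()] object.
#' @return List of [link_pair()] results (length `length(masks) - 1`).
#' @export
link_movie <- function(masks, params = link_params()) {
  lapply(seq_len(length(masks) - 1L), function(t)
    link_pair(compute_overlaps(masks[[t]], masks[[t + 1L]]), params))
}

# Follow a region forward through `continues` links; returns the region
# number at each frame, NA once the chain breaks.
.follow <- function(linkages, region, from_frame, to_frame) {
  out <- rep(NA_integer_, to_frame - from_frame + 1L)
  out[1] <- region
  cur <- region
  if (to_frame > from_frame) for (u in from_frame:(to_frame - 1L)) {
    lk <- linkages[[u]]$from
    row <- lk[lk$region == cur, ]
    if (nrow(row) != 1L || row$outcome != "continues") return(out)
    cur <- row$succ1
    out[u - from_frame + 2L] <- cur
  }
  out
}

#' Suppress division flicker for temporal consistency
#'
#' A division whose daughters re-merge into a single region within `window`
#' frames is treated as transient over-segmentation: the daughter regions
#' are relabelled back to one region for those frames and the linkage is
#' recomputed, so the output contains no 1 -> 2 -> 1 pattern inside the
#' window. A division is re-called at the first frame from which two
#' successors persist.
#'
#' @param masks list of integer label masks.
#' @param params a [link_params()] object.
#' @return List with corrected `masks` and `linkages`, plus `n_suppressed`.
#' @export
enforce_temporal_consistency <- function(masks, params = link_params()) {
  nT <- length(masks)
  n_suppressed <- 0L
  for (pass in seq_len(25L)) {
    linkages <- link_movie(masks, params)
    changed <- FALSE
    for (t in seq_len(nT - 1L)) {
      lk <- linkages[[t]]$from
      divs <- lk[lk$outcome == "divides", ]
      for (d in seq_len(nrow(divs))) {
        s1 <- divs$succ1[d]; s2 <- divs$succ2[d]
        horizon <- min(t + params$window, nT - 1L)
        if (horizon < t + 1L) next
        ch1 <- .follow(linkages, s1, t + 1L, horizon + 1L)
        ch2 <- .follow(linkages, s2, t + 1L, horizon + 1L)
        # A genuine re-merge shows up as one daughter chain *ending* (its
        # successor claimed) while a substantial share of its pixels flows
        # into the surviving chain's continuation. Mere sliver overlaps
        # between adjacent daughters must not trigger suppression.
        merge_at <- NA_integer_
        for (u in (t + 1L):horizon) {
          k <- u - t  # chain position of frame u
          c1 <- ch1[k]; c2 <- ch2[k]
          if (is.na(c1) || is.na(c2)) break
          nxt1 <- ch1[k + 1L]; nxt2 <- ch2[k + 1L]
          if (!is.na(nxt1) && !is.na(nxt2)) next  # both persist at u+1
          if (is.na(nxt1) && is.na(nxt2)) break   # both chains lost
          dead <- if (is.na(nxt1)) c1 else c2
          m <- if (is.na(nxt1)) nxt2 else nxt1
          ov <- compute_overlaps(masks[[u]], masks[[u + 1L]])
          od <- if (as.character(dead) %in% rownames(ov$counts) &&
                    as.character(m) %in% colnames(ov$counts))
            ov$counts[as.character(dead), as.character(m)] else 0L
          am <- ov$areas_t1[as.character(m)]
          if (od >= 0.25 * am) merge_at <- u
          break
        }
        if (!is.na(merge_at)) {
          # relabel both daughter chains to one region for t+1 .. merge_at
          for (u in (t + 1L):merge_at) {
            k <- u - t
            c1 <- ch1[k]; c2 <- ch2[k]
            keep <- min(c(c1, c2), na.rm = TRUE)
            m <- masks[[u]]
            if (!is.na(c1)) m[m == c1] <- keep
            if (!is.na(c2)) m[m == c2] <- keep
            masks[[u]] <- m
          }
          n_suppressed <- n_suppressed + 1L
          changed <- TRUE
          break
        }
      }
      if (changed) break
    }
    if (!changed) break
  }
  list(masks = masks, linkages = link_movie(masks, params),
       n_suppressed = n_suppressed)
}

#' Assign persistent cell IDs and build the lineage
#'
#' Walks the per-pair linkages: regions of frame 1 become progenitor tracks
#' in region-number order; at a division the mother track ends
#' (`end_reason = "divided"`) and two new IDs are created with `mother_id`
#' set; regions appearing after frame 1 start new tracks flagged `orphan`
#' (or `edge-entry` when they touch the field border).
#'
#' @param masks list of integer label masks.
#' @param linkages result of [link_movie()] /
#'   [enforce_temporal_consistency()]`$linkages`.
#' @param params a [link_params()] object.
#' @return List with `tracks` (data frame `cell_id`, `frame`, `region`) and
#'   `cells` (data frame `cell_id`, `mother_id`, `daughter1`, `daughter2`,
#'   `birth_frame`, `end_frame`, `end_reason`, `origin`).
#' @export
assign_cell_ids <- function(masks, linkages, params = link_params()) {
  nT <- length(masks)
  next_id <- 1L
  active <- list()  # region (as character) -> cell_id, for current frame
  tracks <- list()
  cells <- list()
  new_cell <- function(mother, frame, origin) {
    id <- next_id
    next_id <<- next_id + 1L
    cells[[id]] <<- list(cell_id = id, mother_id = mother,
                         daughter1 = NA_integer_, daughter2 = NA_integer_,
                         birth_frame = frame, end_frame = NA_integer_,
                         end_reason = NA_character_, origin = origin)
    id
  }
  r1 <- mask_labels(masks[[1]])
  for (r in r1) {
    id <- new_cell(NA_integer_, 1L, "progenitor")
    active[[as.character(r)]] <- id
    tracks[[length(tracks) + 1L]] <- c(id, 1L, r)
  }
  for (t in seq_len(nT - 1L)) {
    lk <- linkages[[t]]
    nxt <- list()
    for (i in seq_len(nrow(lk$from))) {
      r <- lk$from$region[i]
      id <- active[[as.character(r)]]
      if (is.null(id)) next
      oc <- lk$from$outcome[i]
      if (oc == "continues") {
        nxt[[as.character(lk$from$succ1[i])]] <- id
      } else if (oc == "divides") {
        cells[[id]]$end_frame <- t
        cells[[id]]$end_reason <- "divided"
        d1 <- new_cell(id, t + 1L, "division")
        d2 <- new_cell(id, t + 1L, "division")
        cells[[id]]$daughter1 <- d1
        cells[[id]]$daughter2 <- d2
        nxt[[as.character(lk$from$succ1[i])]] <- d1
        nxt[[as.character(lk$from$succ2[i])]] <- d2
      } else {
        cells[[id]]$end_frame <- t
        cells[[id]]$end_reason <- "lost"
      }
    }
    appear <- lk$to$region[is.na(lk$to$pred)]
    for (r in appear) {
      origin <- if (region_touches_border(masks[[t + 1L]], r, params$edge_margin))
        "edge-entry" else "orphan"
      nxt[[as.character(r)]] <- new_cell(NA_integer_, t + 1L, origin)
    }
    for (r in names(nxt))
      tracks[[length(tracks) + 1L]] <- c(nxt[[r]], t + 1L, as.integer(r))
    active <- nxt
  }
  for (id in unlist(active)) {
    cells[[id]]$end_frame <- nT
    cells[[id]]$end_reason <- "end-of-movie"
  }
  tracks <- as.data.frame(do.call(rbind, tracks))
  names(tracks) <- c("cell_id", "frame", "region")
  tracks <- tracks[order(tracks$cell_id, tracks$frame), ]
  rownames(tracks) <- NULL
  cells <- do.call(rbind, lapply(cells, function(x)
    data.frame(x, stringsAsFactors = FALSE)))
  list(tracks = tracks, cells = cells)
}

region_touches_border <- function(mask, region, margin = 2L) {
  nr <- nrow(mask); nc <- ncol(mask)
  m <- margin
  any(mask[c(seq_len(m), nr - seq_len(m) + 1L), ] == region) ||
    any(mask[, c(seq_len(m), nc - seq_len(m) + 1L)] == region)
}

#' Run linking end-to-end on a mask sequence
#'
#' Convenience wrapper: temporal-consistency correction, then cell-ID
#' assignment.
#'
#' @param masks list of integer label masks.
#' @param params a [link_params()] object.
#' @param consistency apply flicker suppression first (default TRUE).
#' @return As [assign_cell_ids()], plus `masks` (possibly corrected),
#'   `linkages` and `n_suppressed`.
#' @export
track_cells <- function(masks, params = link_params(), consistency = TRUE) {
  if (consistency) {
    tc <- enforce_temporal_consistency(masks, params)
    masks <- tc$masks
    linkages <- tc$linkages
    n_suppressed <- tc$n_suppressed
  } else {
    linkages <- link_movie(masks, params)
    n_suppressed <- 0L
  }
  ids <- assign_cell_ids(masks, linkages, params)
  c(ids, list(masks = masks, linkages = linkages,
              n_suppressed = n_suppressed))
}

#' Rebuild cell tracks from an externally supplied table
#'
#' Supports hand-corrected or third-party tracking: the table is taken
#' verbatim after validation. Validation failures are reported itemized.
#'
#' @param table data frame with columns `frame`, `region`, `cell_id` and
#'   optionally `mother_id`.
#' @param masks optional mask list; when given, every (frame, region) must
#'   exist.
#' @return List with `tracks` and `cells` as in [assign_cell_ids()].
#' @export
relink_with_external <- function(table, masks = NULL) {
  req <- c("frame", "region", "cell_id")
  if (!all(req %in% names(table)))
    stop("tracks table needs columns: ", paste(req, collapse = ", "))
  if (is.null(table$mother_id)) table$mother_id <- NA_integer_
  problems <- character(0)
  dup <- duplicated(table[, c("frame", "region")])
  if (any(dup))
    problems <- c(problems, paste0("duplicate (frame, region): ",
                                   paste(paste0("(", table$frame[dup], ",", table$region[dup], ")"),
                                         collapse = " ")))
  two <- duplicated(table[, c("frame", "cell_id")])
  if (any(two))
    problems <- c(problems, paste0("cell_id assigned to two regions in one frame: ",
                                   paste(unique(table$cell_id[two]), collapse = " ")))
  for (id in unique(table$cell_id)) {
    fr <- sort(table$frame[table$cell_id == id])
    if (length(fr) > 1L && any(diff(fr) > 1L))
      problems <- c(problems, paste0("cell_id ", id,
                                     " reappears after a gap (frames ",
                                     paste(fr, collapse = ","), ")"))
  }
  if (!is.null(masks)) {
    for (k in seq_len(nrow(table))) {
      t <- table$frame[k]; r <- table$region[k]
      if (t < 1L || t > length(masks) || !any(masks[[t]] == r))
        problems <- c(problems,
                      paste0("region ", r, " not present in frame ", t))
    }
  }
  if (length(problems))
    stop("invalid tracks table:\n  - ", paste(problems, collapse = "\n  - "))
  tracks <- table[order(table$cell_id, table$frame), c("frame", "region", "cell_id")]
  rownames(tracks) <- NULL
  agg_birth <- tapply(table$frame, table$cell_id, min)
  agg_end <- tapply(table$frame, table$cell_id, max)
  ids <- as.integer(names(agg_birth))
  mother <- vapply(ids, function(id)
    as.integer(table$mother_id[table$cell_id == id][1]), integer(1))
  cells <- data.frame(cell_id = ids, mother_id = mother,
                      daughter1 = NA_integer_, daughter2 = NA_integer_,
                      birth_frame = as.integer(agg_birth),
                      end_frame = as.integer(agg_end),
                      end_reason = NA_character_, origin = NA_character_)
  for (i in seq_len(nrow(cells))) {
    d <- sort(cells$cell_id[!is.na(cells$mother_id) &
                              cells$mother_id == cells$cell_id[i]])
    if (length(d) >= 1L) cells$daughter1[i] <- d[1]
    if (length(d) >= 2L) cells$daughter2[i] <- d[2]
    cells$end_reason[i] <- if (length(d) == 2L) "divided" else NA_character_
  }
  nT <- max(table$frame)
  cells$end_reason[is.na(cells$end_reason)] <-
    ifelse(cells$end_frame[is.na(cells$end_reason)] == nT, "end-of-movie", "lost")
  list(tracks = tracks[, c("cell_id", "frame", "region")], cells = cells)
}

#' Export a lineage as a Newick-like tree string
#'
#' One tree per progenitor; branch lengths are lifetimes in frames.
#'
#' @param cells cells table from [assign_cell_ids()].
#' @return Character vector of Newick strings, one per root.
#' @export
lineage_newick <- function(cells) {
  rec <- function(id) {
    row <- cells[cells$cell_id == id, ]
    bl <- row$end_frame - row$birth_frame + 1L
    if (!is.na(row$daughter1))
      paste0("(", rec(row$daughter1), ",", rec(row$daughter2), ")",
             "c", id, ":", bl)
    else paste0("c", id, ":", bl)
  }
  roots <- cells$cell_id[is.na(cells$mother_id)]
  vapply(roots, function(r) paste0(rec(r), ";"), character(1))
}
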