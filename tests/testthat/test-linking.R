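toy_mask <- function(rects, shape = c(30L, 30L)) {
  m <- matrix(0L, shape[1], shape[2])
  for (k in seq_along(rects)) {
    r <- rects[[k]]
    m[r[1]:r[2], r[3]:r[4]] <- k
  }
  m
}

test_that("overlap counts match a brute-force pixel loop", {
  set.seed(5)
  for (rep in 1:5) {
    m1 <- toy_mask(list(c(2, 8, 2, 8), c(10, 16, 10, 16), c(20, 26, 5, 12)))
    m2 <- toy_mask(list(c(3, 9, 3, 9), c(9, 15, 11, 17), c(19, 25, 4, 11)))
    ov <- compute_overlaps(m1, m2)
    for (a in rownames(ov$counts)) for (b in colnames(ov$counts)) {
      brute <- sum(m1 == as.integer(a) & m2 == as.integer(b))
      expect_identical(as.integer(ov$counts[a, b]), brute)
    }
  }
  # identity and disjoint cases
  ovi <- compute_overlaps(m1, m1)
  expect_true(all(ovi$counts[cbind(seq_len(3), seq_len(3))] == ovi$areas_t))
  expect_true(all(ovi$counts[upper.tri(ovi$counts)] == 0))
  m3 <- toy_mask(list(c(28, 29, 28, 29)))
  expect_true(all(compute_overlaps(m1, m3)$counts == 0))
  expect_error(compute_overlaps(m1, matrix(0L, 5, 5)), "shape")
})

test_that("identity frames link as pure continuations", {
  m <- toy_mask(list(c(2, 8, 2, 8), c(10, 16, 10, 16)))
  lk <- link_pair(compute_overlaps(m, m))
  expect_true(all(lk$from$outcome == "continues"))
  expect_equal(lk$from$succ1, lk$from$region)
  expect_true(all(!is.na(lk$to$pred)))
})

test_that("greedy assignment attains the exhaustive-search optimum on toys", {
  set.seed(11)
  for (rep in 1:20) {
    # regions with a dominant successor (as consecutive movie frames have)
    n <- sample(2:4, 1)
    rects <- lapply(seq_len(n), function(k)
      c(1 + 7 * (k - 1), 6 + 7 * (k - 1), 2, 10))
    m1 <- toy_mask(rects, c(7 * n + 2L, 14L))
    jit <- lapply(rects, function(r) r + c(sample(-1:1, 1), sample(-1:1, 1),
                                           sample(-1:1, 1), sample(-1:1, 1)))
    m2 <- toy_mask(jit, c(7 * n + 2L, 14L))
    ov <- compute_overlaps(m1, m2)
    lk <- link_pair(ov)
    got <- sum(vapply(seq_len(nrow(lk$from)), function(i) {
      if (lk$from$outcome[i] == "ends") return(0L)
      ov$counts[as.character(lk$from$region[i]),
                as.character(lk$from$succ1[i])]
    }, integer(1)))
    # brute force over all one-to-one assignments
    perms <- function(v) if (length(v) <= 1) list(v) else
      do.call(c, lapply(seq_along(v), function(i)
        lapply(perms(v[-i]), function(p) c(v[i], p))))
    best <- 0L
    for (p in perms(seq_len(ncol(ov$counts))))
      best <- max(best, sum(ov$counts[cbind(seq_len(nrow(ov$counts)),
                                            p[seq_len(nrow(ov$counts))])]))
    expect_gte(got, best)
  }
})

test_that("a bisected mother is detected as one division", {
  sim <- fixture_sim()
  lin <- sim$lineage
  dv <- lin[!is.na(lin$division_frame) & lin$division_frame < 39, ][1, ]
  t <- dv$division_frame
  lk <- link_pair(compute_overlaps(sim$masks[[t]], sim$masks[[t + 1]]))
  row <- lk$from[lk$from$region == dv$cell_id, ]
  expect_equal(row$outcome, "divides")
  expect_setequal(c(row$succ1, row$succ2), c(dv$daughter1, dv$daughter2))
})

test_that("pixel conservation holds at accepted divisions", {
  sim <- fixture_sim()
  params <- link_params()
  linkages <- link_movie(sim$masks, params)
  for (t in seq_along(linkages)) {
    lk <- linkages[[t]]$from
    divs <- lk[lk$outcome == "divides", ]
    if (nrow(divs) == 0) next
    a1 <- omnicyte:::region_areas(sim$masks[[t]])
    a2 <- omnicyte:::region_areas(sim$masks[[t + 1]])
    for (i in seq_len(nrow(divs))) {
      mother <- a1[as.character(divs$region[i])]
      dsum <- sum(a2[as.character(c(divs$succ1[i], divs$succ2[i]))])
      expect_lte(abs(mother - dsum) / mother, 1 - params$area_ratio_lo)
    }
  }
})

test_that("division flicker is suppressed within the window", {
  # constructed flicker: 1 -> 2 -> 1 -> 2 -> 2..., division must be called
  # once, at the first persistent split
  base <- data.frame(cell_id = 1L, x = 3, y = 2, theta = 0, length = 4,
                     width = 1)
  halves <- data.frame(cell_id = c(2L, 3L), x = c(2, 4), y = 2, theta = 0,
                       length = 2, width = 1)
  one <- rasterize_fixture(base, c(40L, 60L))
  two <- rasterize_fixture(halves, c(40L, 60L))
  masks <- list(one, two, one, two, two, two)
  tc <- enforce_temporal_consistency(masks, link_params(window = 3L))
  res <- assign_cell_ids(tc$masks, tc$linkages)
  expect_gte(tc$n_suppressed, 1L)
  divs <- res$cells[!is.na(res$cells$daughter1), ]
  expect_equal(nrow(divs), 1L)
  expect_equal(nrow(res$cells), 3L)
  d1 <- res$cells[res$cells$cell_id == divs$daughter1, ]
  expect_equal(d1$birth_frame, 4L)
})

test_that("consistency correction leaves flicker-free movies unchanged", {
  sim <- fixture_sim()
  tc <- enforce_temporal_consistency(sim$masks)
  expect_equal(tc$n_suppressed, 0L)
  expect_identical(tc$masks, sim$masks)
})

test_that("an injected transient split is suppressed into a continuous track", {
  sim <- fixture_sim()
  live <- sim$states[[20]]$cell_id[1]
  err <- inject_mask_errors(sim$masks, data.frame(
    frame = 20L, type = "split", cell_id = live, duration = 1L))
  res <- track_cells(err$masks)
  expect_equal(res$n_suppressed, 1L)
  expect_equal(nrow(res$cells), nrow(sim$lineage))
  # without correction, the transient split spawns extra tracks
  res_off <- track_cells(err$masks, consistency = FALSE)
  expect_gt(nrow(res_off$cells), nrow(sim$lineage))
})

test_that("recovered lineage equals ground truth on a clean colony", {
  sim <- fixture_sim()
  masks <- shuffle_labels(sim$masks)
  res <- track_cells(masks)
  expect_equal(nrow(res$cells), nrow(sim$lineage))
  map <- purity_map(res$tracks, masks, sim$masks)
  expect_false(is.null(map))  # 100% track purity
  for (i in seq_len(nrow(res$cells))) {
    rec <- res$cells[i, ]
    tid <- map[[as.character(rec$cell_id)]]
    tru <- sim$lineage[sim$lineage$cell_id == tid, ]
    expect_equal(rec$birth_frame, tru$birth_frame)
    tmid <- if (is.na(rec$mother_id)) NA_integer_ else
      map[[as.character(rec$mother_id)]]
    expect_equal(as.integer(tmid), as.integer(tru$mother_id))
  }
})

test_that("a single cell with no division gives one track of full length", {
  st <- data.frame(cell_id = 1L, x = 3, y = 2, theta = 0.3, length = 3,
                   width = 1)
  m <- rasterize_fixture(st, c(50L, 60L))
  res <- track_cells(list(m, m, m, m))
  expect_equal(nrow(res$cells), 1L)
  expect_equal(nrow(res$tracks), 4L)
  expect_equal(res$cells$end_reason, "end-of-movie")
})

test_that("a region lost mid-movie ends its track as lost", {
  sim <- fixture_sim()
  live <- sim$states[[20]]$cell_id[1]
  # drop the cell from frame 20 to the end of a short window
  masks <- lapply(sim$masks[1:24], identity)
  for (t in 20:24) masks[[t]][masks[[t]] == live] <- 0L
  res <- track_cells(masks)
  map <- purity_map(res$tracks, masks, sim$masks[1:24])
  rec_id <- NULL
  for (k in names(map)) if (map[[k]] == live) rec_id <- as.integer(k)
  cell <- res$cells[res$cells$cell_id == rec_id, ]
  expect_equal(cell$end_reason, "lost")
  expect_equal(cell$end_frame, 19L)
})

test_that("external track tables rebuild verbatim and validate", {
  sim <- fixture_sim()
  res <- track_cells(sim$masks)
  tab <- res$tracks
  tab$mother_id <- res$cells$mother_id[match(tab$cell_id, res$cells$cell_id)]
  back <- relink_with_external(tab, sim$masks)
  expect_equal(back$tracks[, c("cell_id", "frame", "region")],
               res$tracks[, c("cell_id", "frame", "region")])
  expect_equal(back$cells$mother_id, res$cells$mother_id)
  expect_equal(back$cells$birth_frame, res$cells$birth_frame)
  # one cell_id on two regions in one frame
  bad <- rbind(tab, data.frame(cell_id = tab$cell_id[1], frame = tab$frame[1],
                               region = 999L, mother_id = NA))
  expect_error(relink_with_external(bad), "two regions")
  # ID reuse after a gap
  gap <- tab[tab$cell_id == 1L, ]
  gap <- gap[-2, ]
  expect_error(relink_with_external(gap), "gap")
  expect_error(relink_with_external(data.frame(frame = 1)), "columns")
})

test_that("lineage exports as one Newick string per progenitor", {
  sim <- fixture_sim()
  res <- track_cells(sim$masks)
  nwk <- lineage_newick(res$cells)
  expect_length(nwk, 1L)
  expect_match(nwk, "^\\(.*\\)c1:[0-9]+;$")
  # leaf count equals cells alive at the end plus lost tracks
  n_leaves <- lengths(regmatches(nwk, gregexpr("c[0-9]+:", nwk)))
  expect_equal(n_leaves, nrow(res$cells))
})
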