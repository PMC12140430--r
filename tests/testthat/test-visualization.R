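test_that("a single pixel traces to the unit square around its center", {
  r <- matrix(FALSE, 5, 5)
  r[3, 3] <- TRUE
  o <- extract_outline(r)
  expect_equal(nrow(o), 4L)
  expect_setequal(paste(o[, "row"], o[, "col"]),
                  c("2.5 2.5", "2.5 3.5", "3.5 2.5", "3.5 3.5"))
  expect_equal(outline_area(o), 1)
  expect_error(extract_outline(matrix(FALSE, 3, 3)), "empty")
})

test_that("outline shoelace area equals the pixel count", {
  sim <- fixture_sim_small()
  mask <- sim$masks[[25]]
  for (l in sim$states[[25]]$cell_id[1:5]) {
    o <- extract_outline(mask == l)
    expect_equal(outline_area(o), sum(mask == l))
  }
})

test_that("re-rasterizing an outline reproduces the region", {
  sim <- fixture_sim_small()
  mask <- sim$masks[[25]]
  l <- sim$states[[25]]$cell_id[1]
  o <- extract_outline(mask == l)
  # pixel centers strictly inside the polygon (even-odd rule)
  rc <- which(matrix(TRUE, nrow(mask), ncol(mask)), arr.ind = TRUE)
  inside <- sp_inside <- rep(FALSE, nrow(rc))
  px <- o[, "col"]; py <- o[, "row"]
  n <- nrow(o)
  for (k in seq_len(n)) {
    j <- if (k == 1) n else k - 1
    cross <- (py[k] > rc[, 1]) != (py[j] > rc[, 1])
    xint <- (px[j] - px[k]) * (rc[, 1] - py[k]) / (py[j] - py[k] + 1e-12) + px[k]
    inside <- xor(inside, cross & rc[, 2] < xint)
  }
  rast <- matrix(FALSE, nrow(mask), ncol(mask))
  rast[rc[inside, ]] <- TRUE
  iou <- sum(rast & (mask == l)) / sum(rast | (mask == l))
  expect_gte(iou, 0.95)
})

test_that("mosaics tile deterministically with expected geometry", {
  sim <- fixture_sim_small()
  frames <- lapply(sim$masks[c(10, 20, 30, 36)], render_modality,
                   modality = "phase", blur_sigma = 0.8, noise_sd = 0.01,
                   seed = 3)
  mo <- frame_mosaic(frames, grid = c(2L, 2L), gutter = 2L)
  expect_equal(dim(mo)[1:2], c(2L * 256L + 2L, 2L * 256L + 2L))
  f1 <- withr::local_tempfile(fileext = ".png")
  f2 <- withr::local_tempfile(fileext = ".png")
  frame_mosaic(frames, grid = c(2L, 2L), masks = sim$masks[c(10, 20, 30, 36)],
               path = f1)
  frame_mosaic(frames, grid = c(2L, 2L), masks = sim$masks[c(10, 20, 30, 36)],
               path = f2)
  expect_identical(readBin(f1, "raw", file.info(f1)$size),
                   readBin(f2, "raw", file.info(f2)$size))
  expect_error(frame_mosaic(list()), "empty")
})

test_that("outline colors track cell identity across tiles", {
  # the same cell id maps to the same color in every tile
  sim <- fixture_sim_small()
  sel <- c(30L, 31L)
  frames <- lapply(sim$masks[sel], render_modality, modality = "phase",
                   blur_sigma = 0, noise_sd = 0)
  mo <- frame_mosaic(frames, grid = c(1L, 2L), masks = sim$masks[sel],
                     gutter = 2L)
  id <- sim$states[[30]]$cell_id[1]
  col_of <- function(tile_offset, t_idx) {
    b <- omnicyte:::label_boundary(sim$masks[[sel[t_idx]]]) &
      sim$masks[[sel[t_idx]]] == id
    px <- which(b, arr.ind = TRUE)[1, ]
    mo[px[1], px[2] + tile_offset, ]
  }
  expect_equal(col_of(0L, 1L), col_of(256L + 2L, 2L))
})

test_that("kymographs are constant for uniform cells and track foci", {
  sim <- fixture_sim_small()
  track_frames <- 1:8
  regions <- lapply(track_frames, function(t) sim$masks[[t]] == 1L)
  axes <- lapply(track_frames, function(t)
    medial_axis_metrics(sim$masks[[t]] == 1L, 0.1)$axis)
  uni <- lapply(track_frames, function(t) {
    img <- matrix(0, 256, 256)
    img[sim$masks[[t]] == 1L] <- 0.8
    img
  })
  ky <- kymograph(uni, regions, axes, n_bins = 12L)
  expect_equal(nrow(ky), length(track_frames))
  for (t in seq_len(nrow(ky))) {
    v <- ky[t, !is.na(ky[t, ])]
    expect_lt(diff(range(v)), 1e-9)
  }
  # a focus fixed at axis fraction 0.25 lights the same bin in every row
  n_bins <- 20L
  st <- data.frame(cell_id = 1L, x = 3, y = 2, theta = 0, length = 4,
                   width = 1)
  m <- rasterize_fixture(st, c(40L, 70L))
  ax <- medial_axis_metrics(m == 1L, 0.1)$axis
  imgs <- lapply(1:6, function(i) {
    img <- matrix(0, 40, 70)
    img[m == 1L] <- 0.3
    col <- (3 + (0.25 - 0.5) * 4) / 0.1 + 0.5
    rr <- 16:24; cc <- round(col + (-4:4))
    img[rr, cc] <- img[rr, cc] + outer(exp(-((rr - 20.5)^2) / 4.5),
                                       exp(-((cc - col)^2) / 4.5))
    img
  })
  ky2 <- kymograph(imgs, rep(list(m == 1L), 6), rep(list(ax), 6), n_bins)
  peaks <- apply(ky2, 1, which.max)
  expect_equal(length(unique(peaks)), 1L)
  frac <- (peaks[1] - 0.5) / n_bins
  expect_lt(min(abs(frac - 0.25), abs(frac - 0.75)), 0.1)
  # missing axis gives a row of NA
  ky3 <- kymograph(imgs[1:2], rep(list(m == 1L), 2), list(ax, NULL), n_bins)
  expect_true(all(is.na(ky3[2, ])))
})

test_that("kymograph row sums are stable under re-binning", {
  sim <- fixture_sim_small()
  t <- 20L
  reg <- sim$masks[[t]] == sim$states[[t]]$cell_id[1]
  ax <- medial_axis_metrics(reg, 0.1)$axis
  img <- render_modality(sim$masks[[t]], "cyto_fluor", blur_sigma = 0.8,
                         noise_sd = 0)
  k1 <- kymograph(list(img), list(reg), list(ax), n_bins = 10L)
  k2 <- kymograph(list(img), list(reg), list(ax), n_bins = 40L)
  expect_equal(mean(k1, na.rm = TRUE), mean(k2, na.rm = TRUE),
               tolerance = 0.02)
})

test_that("cell towers stack one row per frame with growing extent", {
  sim <- fixture_sim_small()
  # follow the progenitor for its first 6 frames
  frames <- 1:6
  regions <- lapply(frames, function(t) sim$masks[[t]] == 1L)
  oris <- vapply(frames, function(t) {
    rc <- which(sim$masks[[t]] == 1L, arr.ind = TRUE)
    omnicyte:::pixel_orientation(rc[, 1], rc[, 2])
  }, numeric(1))
  imgs <- lapply(frames, function(t)
    render_modality(sim$masks[[t]], "cyto_fluor", blur_sigma = 0,
                    noise_sd = 0))
  tw <- cell_tower(imgs, regions, oris)
  # n stacked strips separated by 1-px gutters
  strip_h <- (nrow(tw) + 1L) / length(frames)
  expect_equal(strip_h, round(strip_h))
  # the cell's horizontal extent (length) is non-decreasing down the tower
  widths <- vapply(seq_along(frames), function(t) {
    rows <- ((t - 1L) * strip_h + 1L):(t * strip_h - 1L)
    strip <- tw[rows, , drop = FALSE]
    cols <- which(colSums(strip > 0.2) > 0)
    if (length(cols)) diff(range(cols)) + 1L else 0L
  }, numeric(1))
  expect_true(all(diff(widths) >= -2))
  expect_gt(widths[length(widths)], widths[1])
})

test_that("lineage trees lay out one segment per cell and branch per division", {
  sim <- fixture_sim()
  lay <- lineage_layout(sim$lineage, n_frames = sim$n_frames)
  expect_equal(nrow(lay$segments), nrow(sim$lineage))
  expect_equal(nrow(lay$branches), sum(!is.na(sim$lineage$daughter1)))
  # leaves = cells alive at the movie end (no truncation, no loss here)
  leaves <- sum(is.na(sim$lineage$daughter1))
  expect_equal(leaves, nrow(sim$states[[sim$n_frames]]))
  # mothers sit midway between their daughters
  for (i in which(!is.na(sim$lineage$daughter1))) {
    ds <- c(sim$lineage$daughter1[i], sim$lineage$daughter2[i])
    ym <- lay$segments$y[lay$segments$cell_id == sim$lineage$cell_id[i]]
    yd <- lay$segments$y[lay$segments$cell_id %in% ds]
    expect_equal(ym, mean(yd))
  }
  # a non-dividing cell is a single unbranched segment
  lone <- data.frame(cell_id = 1L, mother_id = NA_integer_, birth_frame = 1L,
                     division_frame = NA_integer_, daughter1 = NA_integer_,
                     daughter2 = NA_integer_)
  l1 <- lineage_layout(lone, n_frames = 10L)
  expect_equal(nrow(l1$segments), 1L)
  expect_equal(nrow(l1$branches), 0L)
  # plotting writes a file
  f <- withr::local_tempfile(fileext = ".png")
  plot_lineage_tree(sim$lineage, path = f, frame_interval = 3)
  expect_gt(file.info(f)$size, 0)
})
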