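test_that("medial-axis metrics recover analytic rod geometry", {
  # horizontal rod, 3 um x 1 um at 0.1 um/px (30 x 10 px with caps)
  st <- data.frame(cell_id = 1L, x = 3, y = 1.5, theta = 0, length = 3,
                   width = 1)
  m <- rasterize_fixture(st, c(30L, 60L))
  g <- medial_axis_metrics(m == 1L, 0.1)
  expect_true(g$ok)
  expect_equal(g$length_um, 3.0, tolerance = 0.1 / 3)
  expect_equal(g$width_mean_um, 1.0, tolerance = 0.1)
  expect_gte(g$length_um, g$width_mean_um)
})

test_that("length is rotation-invariant to within one pixel", {
  lens <- vapply(seq(0, 170, by = 22.5), function(ang) {
    st <- data.frame(cell_id = 1L, x = 3, y = 3, theta = ang * pi / 180,
                     length = 3, width = 1)
    m <- rasterize_fixture(st, c(60L, 60L))
    medial_axis_metrics(m == 1L, 0.1)$length_um
  }, numeric(1))
  expect_lt(max(lens) - min(lens), 0.2)
  expect_lt(max(abs(lens - 3)), 0.1)
})

test_that("a disk reports aspect ratio near one", {
  dsk <- matrix(FALSE, 44, 44)
  ctr <- 22.5
  for (i in 1:44) for (j in 1:44)
    if ((i - ctr)^2 + (j - ctr)^2 <= 100) dsk[i, j] <- TRUE
  g <- medial_axis_metrics(dsk, 0.1)
  expect_equal(g$length_um / g$width_mean_um, 1, tolerance = 0.15)
})

test_that("a bent filament's length is the sum of its segment lengths", {
  st <- data.frame(cell_id = c(1L, 1L), x = c(2.0, 3.3), y = c(2, 2.75),
                   theta = c(0, 30 * pi / 180), length = 3, width = 1)
  m1 <- rasterize_fixture(st[1, ], c(60L, 60L))
  m2 <- rasterize_fixture(st[2, ], c(60L, 60L))
  joined <- (m1 > 0) | (m2 > 0)
  g <- medial_axis_metrics(joined, 0.1)
  # two overlapping 3 um rods at 30 degrees: expected end-to-end arc about
  # the sum of lengths minus the overlap (~1.3 um here)
  expect_equal(g$length_um, 4.7, tolerance = 0.05 * 4.7 + 0.2)
})

test_that("tiny regions are flagged instead of measured", {
  r <- matrix(FALSE, 10, 10)
  r[5, 5:7] <- TRUE
  g <- medial_axis_metrics(r, 0.1)
  expect_false(g$ok)
  expect_true(is.na(g$length_um))
})

test_that("fluorescence metrics are exact on constant fields", {
  m <- matrix(0L, 30, 30)
  m[10:20, 10:15] <- 1L
  img <- matrix(0.2, 30, 30)
  img[m == 1L] <- 0.75
  bg <- median(img[m == 0L])
  fl <- fluorescence_metrics(m == 1L, img, bg)
  expect_equal(fl$mean, 0.75)
  expect_equal(fl$bgsub_mean, 0.55)
  expect_equal(fl$sum, 0.75 * sum(m == 1L))
  expect_equal(fl$sd, 0)
})

test_that("background-subtracted means vanish on noise-only channels", {
  sim <- fixture_sim_small()
  t <- 25L
  mask <- sim$masks[[t]]
  noise_sd <- 0.02
  set.seed(31)
  img <- matrix(rnorm(length(mask), 0.5, noise_sd), nrow(mask))
  bg <- median(img[mask == 0L])
  subs <- vapply(sim$states[[t]]$cell_id, function(l) {
    fluorescence_metrics(mask == l, img, bg)$bgsub_mean
  }, numeric(1))
  se <- noise_sd / sqrt(mean(tabulate(mask[mask > 0])[mask[mask > 0]]))
  expect_lt(abs(mean(subs)), 3 * noise_sd / sqrt(sum(mask > 0) / 3))
  expect_lt(max(abs(subs)), 5 * se)
})

test_that("injected foci are recovered on the axis at high SNR", {
  sim <- fixture_sim_small()
  t <- 36L
  st <- sim$states[[t]]
  img <- render_modality(sim$masks[[t]], "cyto_fluor", blur_sigma = 0.8,
                         noise_sd = 0.005, seed = 3)
  fr <- add_foci(img, st, 0.1, foci_per_cell = 1L, focus_sigma = 1.5,
                 focus_amplitude = 0.6, seed = 9)
  pm <- cyto_params(foci_channel = 1L)
  errs <- c(); pix_err <- c(); nfound <- 0L; null_dets <- 0L
  for (k in seq_len(nrow(st))) {
    reg <- sim$masks[[t]] == st$cell_id[k]
    ax <- medial_axis_metrics(reg, 0.1)$axis
    det <- detect_foci(fr$image, reg, ax, pm)
    tru <- fr$foci[fr$foci$cell_id == st$cell_id[k], ]
    if (nrow(det)) {
      nfound <- nfound + 1L
      e2 <- sqrt((det$row - tru$row[1])^2 + (det$col - tru$col[1])^2)
      j <- which.min(e2)
      pix_err <- c(pix_err, e2[j])
      # axis direction is arbitrary: compare against both parities
      errs <- c(errs, min(abs(det$axis_frac[j] - tru$axis_frac[1]),
                          abs(1 - det$axis_frac[j] - tru$axis_frac[1])))
    }
    null_dets <- null_dets + nrow(detect_foci(img, reg, ax, pm))
  }
  expect_equal(nfound, nrow(st))     # every focus found
  expect_equal(null_dets, 0L)        # none invented in uniform cells
  expect_lt(mean(errs), 0.05)        # long-axis fraction recovered
  expect_lt(max(pix_err), 1.0)       # sub-pixel 2D localization
})

test_that("two well-separated foci are both detected in axis order", {
  st <- data.frame(cell_id = 1L, x = 3, y = 2, theta = 0, length = 4,
                   width = 1)
  m <- rasterize_fixture(st, c(40L, 70L))
  img <- render_modality(m, "cyto_fluor", blur_sigma = 0.8, noise_sd = 0.003,
                         seed = 2)
  # place two foci by hand at axis fractions ~0.2 and ~0.8
  for (u in c(0.2, 0.8)) {
    col <- (3 + (u - 0.5) * 4) / 0.1 + 0.5
    row <- 2 / 0.1 + 0.5
    rr <- (round(row) - 6L):(round(row) + 6L)
    cc <- (round(col) - 6L):(round(col) + 6L)
    img[rr, cc] <- img[rr, cc] +
      0.6 * outer(exp(-((rr - row)^2) / (2 * 1.5^2)),
                  exp(-((cc - col)^2) / (2 * 1.5^2)))
  }
  ax <- medial_axis_metrics(m == 1L, 0.1)$axis
  det <- detect_foci(img, m == 1L, ax, cyto_params(foci_channel = 1L))
  expect_equal(nrow(det), 2L)
  expect_equal(det$axis_frac, sort(det$axis_frac))
  expect_equal(sort(pmin(det$axis_frac, 1 - det$axis_frac)),
               c(0.2, 0.2), tolerance = 0.25)
})

test_that("per-cell summaries recover the simulated elongation rate", {
  sim <- fixture_sim_small()
  res <- track_cells(sim$masks)
  pm <- cyto_params()
  fm <- lapply(seq_len(sim$n_frames), function(t)
    compute_frame_metrics(sim$masks[[t]], list(), frame = t, params = pm))
  cl <- assemble_clist(res, fm, pm)
  g <- sim$params$growth_rate
  rates <- cl$cells$elongation_rate_per_min[cl$cells$lifetime_frames >= 8]
  expect_gt(length(rates), 3)
  expect_lt(max(abs(rates / g - 1)), 0.05)
  # censoring semantics
  alive <- cl$cells[cl$cells$end_reason == "end-of-movie", ]
  expect_true(all(is.na(alive$division_frame)))
  expect_true(all(!alive$stat_0))
  # daughters of the progenitor are generation 2
  expect_true(all(cl$cells$generation[cl$cells$mother_id %in% 1L] == 2L))
  # daughter areas at birth sum to the mother's area at division
  for (i in which(!is.na(cl$cells$daughter1_id))) {
    mo <- cl$cells[i, ]
    da <- cl$cells[cl$cells$cell_id %in% c(mo$daughter1_id, mo$daughter2_id), ]
    expect_equal(sum(da$area_um2_birth), mo$area_um2_end,
                 tolerance = 1 - link_params()$area_ratio_lo)
  }
})

test_that("measured widths recover the simulated width within half a pixel", {
  sim <- fixture_sim_small()
  t <- sim$n_frames
  fmm <- compute_frame_metrics(sim$masks[[t]], list(), frame = t)
  bias <- mean(fmm$metrics$width_mean_um, na.rm = TRUE) - sim$params$width
  expect_lt(abs(bias), sim$params$pixel_size / 2)
})

test_that("the default clist meets the advertised descriptor counts", {
  sim <- fixture_sim_small()
  n <- 12L
  masks <- sim$masks[1:n]
  images <- lapply(masks, function(m) list(
    render_modality(m, "phase", blur_sigma = 0.8, noise_sd = 0.01, seed = 1),
    render_modality(m, "cyto_fluor", blur_sigma = 0.8, noise_sd = 0.01, seed = 2)))
  res <- track_cells(masks)
  pm <- cyto_params(foci_channel = 2L)
  fm <- lapply(seq_len(n), function(t)
    compute_frame_metrics(masks[[t]], images[[t]], frame = t, params = pm))
  cl <- assemble_clist(res, fm, pm)
  expect_gte(ncol(cl$cells) - 1L, 80L)           # excluding the cell_id key
  expect_gte(ncol(cl$frames) - 2L, 20L)          # excluding cell_id + frame
  # every emitted column is registered
  reg <- cl$registry
  expect_true(all(setdiff(names(cl$cells), "cell_id") %in%
                    reg$name[reg$class == "per_cell"]))
  expect_true(all(setdiff(names(cl$frames), c("cell_id", "frame")) %in%
                    reg$name[reg$class == "per_frame"]))
  # empty run still yields header-only tables
  reg0 <- descriptor_registry(n_channels = 2L, foci = TRUE)
  expect_gte(sum(reg0$class == "per_cell"), 80L)
  expect_gte(sum(reg0$class == "per_frame"), 20L)
})

test_that("CSV and XLSX clist exports agree value-by-value", {
  skip_if_not_installed("xml2")
  sim <- fixture_sim_small()
  n <- 8L
  res <- track_cells(sim$masks[1:n])
  fm <- lapply(seq_len(n), function(t)
    compute_frame_metrics(sim$masks[[t]], list(), frame = t))
  cl <- assemble_clist(res, fm)
  base <- file.path(withr::local_tempdir(), "clist")
  export_clist(cl, base, "csv")
  export_clist(cl, base, "xlsx")
  csv <- utils::read.csv(paste0(base, "_cells.csv"))
  # pull the cells sheet back out of the workbook
  xdir <- file.path(tempdir(), "xlsx_extract")
  utils::unzip(paste0(base, ".xlsx"), exdir = xdir)
  sheet <- xml2::read_xml(file.path(xdir, "xl", "worksheets", "sheet1.xml"))
  rows <- xml2::xml_find_all(sheet, ".//*[local-name()='row']")
  expect_equal(length(rows), nrow(cl$cells) + 1L)
  # spot-check a numeric column end to end (column A = cell_id)
  cells <- xml2::xml_find_all(sheet, ".//*[local-name()='c'][@t='n']")
  refs <- xml2::xml_attr(cells, "r")
  colA <- cells[grepl("^A[0-9]+$", refs)]
  vals <- as.numeric(xml2::xml_text(
    xml2::xml_find_first(colA, "./*[local-name()='v']")))
  expect_equal(vals, csv$cell_id)
  # registry written as JSON
  regj <- jsonlite::read_json(paste0(base, "_columns.json"),
                              simplifyVector = TRUE)
  expect_setequal(names(regj), c("name", "unit", "definition", "class"))
})
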