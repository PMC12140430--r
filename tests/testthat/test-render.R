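test_that("noiseless cytoplasmic render is a two-level top-hat", {
  sim <- fixture_sim_small()
  mask <- sim$masks[[10]]
  img <- render_modality(mask, "cyto_fluor", blur_sigma = 0, noise_sd = 0)
  inside <- mask > 0 & !omnicyte:::label_boundary(mask)
  halo <- omnicyte:::background_halo(mask)
  bg <- mask == 0 & !halo
  expect_equal(length(unique(img[inside])), 1L)
  expect_equal(length(unique(img[bg])), 1L)
  expect_gt(unique(img[inside])[1], unique(img[bg])[1])
  # line scan through a cell is a top-hat: constant high plateau
  rc <- which(mask == sim$states[[10]]$cell_id[1], arr.ind = TRUE)
  r <- round(mean(rc[, 1]))
  scan <- img[r, min(rc[, 2]):max(rc[, 2])]
  expect_true(all(scan >= unique(img[bg])[1]))
})

test_that("membrane render puts the boundary above the cell center", {
  sim <- fixture_sim_small()
  mask <- sim$masks[[20]]
  img <- render_modality(mask, "mem_fluor", blur_sigma = 0, noise_sd = 0)
  for (id in sim$states[[20]]$cell_id) {
    rc <- which(mask == id, arr.ind = TRUE)
    ctr <- round(colMeans(rc))
    b <- omnicyte:::label_boundary(mask) & mask == id
    expect_gt(mean(img[b]), img[ctr[1], ctr[2]])
  }
})

test_that("in-focus brightfield has near-zero contrast vs cytoplasmic", {
  sim <- fixture_sim_small()
  mask <- sim$masks[[20]]
  bf <- render_modality(mask, "bf_focus", blur_sigma = 0, noise_sd = 0)
  cf <- render_modality(mask, "cyto_fluor", blur_sigma = 0, noise_sd = 0)
  contrast <- function(img) abs(mean(img[mask > 0]) - mean(img[mask == 0]))
  expect_lt(contrast(bf), 0.2 * contrast(cf))
})

test_that("brightfield defocus has opposite-sign edge relief", {
  sim <- fixture_sim_small()
  mask <- sim$masks[[20]]
  un <- render_modality(mask, "bf_under", blur_sigma = 0, noise_sd = 0)
  ov <- render_modality(mask, "bf_over", blur_sigma = 0, noise_sd = 0)
  edge <- omnicyte:::label_boundary(mask)
  bg_un <- mean(un[mask == 0]); bg_ov <- mean(ov[mask == 0])
  expect_gt(mean(un[edge]) - bg_un, 0)
  expect_lt(mean(ov[edge]) - bg_ov, 0)
})

test_that("renders are deterministic per seed and reject unknown modalities", {
  sim <- fixture_sim_small()
  mask <- sim$masks[[5]]
  a <- render_modality(mask, "phase", blur_sigma = 0.8, noise_sd = 0.02, seed = 7)
  b <- render_modality(mask, "phase", blur_sigma = 0.8, noise_sd = 0.02, seed = 7)
  cc <- render_modality(mask, "phase", blur_sigma = 0.8, noise_sd = 0.02, seed = 8)
  expect_identical(a, b)
  expect_false(identical(a, cc))
  expect_error(render_modality(mask, "confocal"), "unknown modality")
})

test_that("foci are additive Gaussians at their recorded positions", {
  sim <- fixture_sim_small()
  t <- 20L
  mask <- sim$masks[[t]]
  img <- render_modality(mask, "cyto_fluor", blur_sigma = 0, noise_sd = 0)
  # no-op case
  r0 <- add_foci(img, sim$states[[t]], 0.1, foci_per_cell = 0L)
  expect_identical(r0$image, img)
  expect_equal(nrow(r0$foci), 0L)
  # argmax oracle: maximum within each cell at the recorded position
  A <- 0.7
  r1 <- add_foci(img, sim$states[[t]], 0.1, foci_per_cell = 1L,
                 focus_sigma = 1.5, focus_amplitude = A, seed = 11)
  for (k in seq_len(nrow(r1$foci))) {
    f <- r1$foci[k, ]
    px <- which(mask == f$cell_id)
    d <- r1$image[px] - img[px]
    j <- arrayInd(px[which.max(d)], dim(img))
    expect_lte(max(abs(c(j[1] - f$row, j[2] - f$col))), 0.5 + 1e-9)
    expect_gt(max(d), 0.85 * A)  # peak gain ~ A up to sub-pixel sampling
    expect_gte(f$axis_frac, 0); expect_lte(f$axis_frac, 1)
  }
  # determinism
  r2 <- add_foci(img, sim$states[[t]], 0.1, foci_per_cell = 1L,
                 focus_sigma = 1.5, focus_amplitude = A, seed = 11)
  expect_identical(r1$foci, r2$foci)
  expect_error(add_foci(img, sim$states[[t]], 0.1, 1L, focus_sigma = 0),
               "focus_sigma")
})

test_that("drift shifts content and round-trips within tolerance", {
  sim <- fixture_sim_small()
  img <- render_modality(sim$masks[[15]], "cyto_fluor", blur_sigma = 1,
                         noise_sd = 0)
  # identity
  same <- apply_drift(list(img), cbind(0, 0))
  expect_identical(same[[1]], img)
  # centroid oracle: a blurred spot moves by the applied shift
  spot <- matrix(0, 128, 128)
  spot[60:68, 60:68] <- 1
  spot <- EBImage::imageData(EBImage::gblur(EBImage::Image(spot), 2))
  sh <- apply_drift(list(spot), cbind(2.0, 0.0))[[1]]
  cen <- function(m) {
    w <- pmax(m, 0); rc <- which(w > 0, arr.ind = TRUE)
    c(sum(rc[, 1] * w[w > 0]) / sum(w[w > 0]),
      sum(rc[, 2] * w[w > 0]) / sum(w[w > 0]))
  }
  expect_equal(cen(sh)[1] - cen(spot)[1], 2.0, tolerance = 0.02)
  expect_equal(cen(sh)[2] - cen(spot)[2], 0.0, tolerance = 0.02)
  # forward then inverse drift restores the frame to < 1% of dynamic range
  fwd <- apply_drift(list(img), cbind(1.7, -2.3))
  back <- apply_drift(fwd, cbind(-1.7, 2.3))[[1]]
  interior <- 4:(nrow(img) - 4)
  rng <- diff(range(img))
  expect_lt(max(abs(back[interior, interior] - img[interior, interior])),
            0.01 * rng)
})

test_that("mask corruption realizes and logs the requested events", {
  sim <- fixture_sim()
  # empty spec: no-op
  r0 <- inject_mask_errors(sim$masks, NULL)
  expect_identical(r0$masks, sim$masks)
  expect_equal(nrow(r0$log), 0L)
  live <- sim$states[[20]]$cell_id[1]
  # one split of duration 1: region count +1 in that frame only
  r1 <- inject_mask_errors(sim$masks, data.frame(
    frame = 20L, type = "split", cell_id = live, duration = 1L))
  expect_true(r1$log$realized)
  n_regions <- function(m) length(unique(as.integer(m))) - 1L
  expect_equal(n_regions(r1$masks[[20]]), n_regions(sim$masks[[20]]) + 1L)
  expect_identical(r1$masks[[21]], sim$masks[[21]])
  # drop removes the region
  r2 <- inject_mask_errors(sim$masks, data.frame(
    frame = 20L, type = "drop", cell_id = live, duration = 1L))
  expect_false(any(r2$masks[[20]] == live))
  # merge with a touching neighbour shares one label
  st <- sim$states[[30]]
  r3 <- inject_mask_errors(sim$masks, data.frame(
    frame = 30L, type = "merge", cell_id = st$cell_id[1], duration = 1L))
  expect_true(r3$log$realized)
  expect_equal(n_regions(r3$masks[[30]]), n_regions(sim$masks[[30]]) - 1L)
  # merge of non-touching cells is skipped and flagged
  sep <- data.frame(cell_id = c(1L, 2L), x = c(2, 10), y = c(2, 10),
                    theta = 0, length = 3, width = 1)
  m2 <- list(rasterize_fixture(sep, c(150L, 150L)))
  r4 <- inject_mask_errors(m2, data.frame(
    frame = 1L, type = "merge", cell_id = 1L, cell_id2 = 2L, duration = 1L))
  expect_false(r4$log$realized)
  expect_identical(r4$masks, m2)
})
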