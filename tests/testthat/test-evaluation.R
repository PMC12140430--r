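test_that("width-from-contact recovers the width of stacked rods", {
  sts <- data.frame(cell_id = 1:5, x = 3, y = 1.5 + 0.9 * (0:4), theta = 0,
                    length = 3, width = 0.9)
  m <- rasterize_fixture(sts, c(80L, 60L))
  w <- width_from_contact(m, 0.1)
  expect_equal(w$width_um, 0.9, tolerance = 0.05 / 0.9)
  expect_true(all(w$measurements$k >= 2))
})

test_that("the estimate is insensitive to the number of stacked cells", {
  st2 <- data.frame(cell_id = 1:2, x = 3, y = 1.5 + 0.9 * (0:1), theta = 0,
                    length = 3, width = 0.9)
  st6 <- data.frame(cell_id = 1:6, x = 3, y = 1.5 + 0.9 * (0:5), theta = 0,
                    length = 3, width = 0.9)
  w2 <- width_from_contact(rasterize_fixture(st2, c(90L, 60L)), 0.1)
  w6 <- width_from_contact(rasterize_fixture(st6, c(90L, 60L)), 0.1)
  expect_lt(abs(w2$width_um - w6$width_um), 0.1 / 2 + 1e-9)
})

test_that("an isolated cell raises the insufficient-contact error", {
  st <- data.frame(cell_id = 1L, x = 3, y = 2, theta = 0, length = 3,
                   width = 0.9)
  expect_error(width_from_contact(rasterize_fixture(st, c(60L, 60L)), 0.1),
               "insufficient contact")
})

test_that("width-from-contact recovers the simulated colony width", {
  sim <- fixture_sim()
  w <- width_from_contact(sim$masks[[sim$n_frames]], sim$params$pixel_size)
  expect_equal(w$width_um, sim$params$width, tolerance = 0.05)
})

test_that("width statistics use the population standard deviation", {
  ws <- width_stats(c(0.8, 1.0, 1.2), 1.0)
  expect_equal(ws$delta_mu_pct, 0)
  expect_equal(ws$sigma_nm, 163, tolerance = 0.01)
  exact <- width_stats(rep(1.0, 5), 1.0)
  expect_equal(exact$delta_mu_pct, 0)
  expect_equal(exact$sigma_nm, 0)
  # sampling-distribution oracle
  set.seed(9)
  x <- rnorm(4000, 1.05, 0.06)
  ws2 <- width_stats(x, 1.0)
  expect_equal(ws2$delta_mu_nm, 50, tolerance = 3 * 60 / sqrt(4000) * 1000 / 50)
  expect_equal(ws2$sigma_nm, 60, tolerance = 0.1)
})

test_that("perfect predictions give a flat zero error curve", {
  sim <- fixture_sim()
  fe <- count_fatal_errors(sim$masks, sim$masks, sim$lineage)
  expect_equal(fe$n_total, 0L)
  expect_true(all(fe$cumulative == 0L))
  # relabeling predicted regions changes nothing
  fe2 <- count_fatal_errors(shuffle_labels(sim$masks), sim$masks, sim$lineage)
  expect_equal(fe2$n_total, 0L)
  expect_error(count_fatal_errors(sim$masks[1:3], sim$masks, sim$lineage),
               "length")
})

test_that("one transient split increments the curve by exactly one", {
  sim <- fixture_sim()
  live <- sim$states[[20]]$cell_id[1]
  err <- inject_mask_errors(sim$masks, data.frame(
    frame = 20L, type = "split", cell_id = live, duration = 1L))
  fe <- count_fatal_errors(err$masks, sim$masks, sim$lineage)
  expect_equal(fe$n_total, 1L)
  expect_equal(which(diff(c(0L, fe$cumulative)) > 0), 20L)
  expect_true(all(diff(fe$cumulative) >= 0L))
})

test_that("an early-by-one-frame division call is not an error", {
  sim <- fixture_sim()
  lin <- sim$lineage
  dv <- lin[!is.na(lin$division_frame) & lin$division_frame > 5 &
              lin$division_frame < 39, ][1, ]
  early <- inject_mask_errors(sim$masks, data.frame(
    frame = dv$division_frame, type = "split", cell_id = dv$cell_id,
    duration = 1L))
  fe <- count_fatal_errors(early$masks, sim$masks, sim$lineage)
  expect_equal(fe$n_total, 0L)
})

test_that("a late division call within tolerance is exempt too", {
  sim <- fixture_sim()
  lin <- sim$lineage
  dv <- lin[!is.na(lin$division_frame) & lin$division_frame > 5 &
              lin$division_frame < 38, ][1, ]
  # merge the daughters back for one frame after the true division
  late <- lapply(sim$masks, identity)
  t <- dv$division_frame + 1L
  late[[t]][late[[t]] == dv$daughter2] <- dv$daughter1
  fe <- count_fatal_errors(late, sim$masks, sim$lineage)
  expect_equal(fe$n_total, 0L)
})

test_that("injected error counts match the corruption log exactly", {
  sim <- fixture_sim()
  st20 <- sim$states[[20]]$cell_id
  st30 <- sim$states[[30]]$cell_id
  spec <- data.frame(
    frame = c(15L, 20L, 30L),
    type = c("split", "drop", "merge"),
    cell_id = c(sim$states[[15]]$cell_id[1], st20[2], st30[1]),
    duration = 1L)
  err <- inject_mask_errors(sim$masks, spec)
  expect_true(all(err$log$realized))
  fe <- count_fatal_errors(err$masks, sim$masks, sim$lineage)
  expect_equal(fe$n_total, nrow(spec))
  # with consistency correction ON the count never increases
  res <- track_cells(err$masks)
  fe_on <- count_fatal_errors(res$masks, sim$masks, sim$lineage,
                              pred_tracks = res$tracks)
  expect_lte(fe_on$n_total, fe$n_total)
})

test_that("cell-count curves agree between masks and tracks", {
  sim <- fixture_sim()
  expect_equal(cell_count_curve(sim$masks), sim_cell_counts(sim))
  res <- track_cells(sim$masks)
  expect_equal(cell_count_curve(res$tracks, sim$n_frames),
               sim_cell_counts(sim))
  empty <- matrix(0L, 10, 10)
  expect_equal(cell_count_curve(list(empty, empty)), c(0L, 0L))
})
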