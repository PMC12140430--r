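# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

# mid-sized colony: 40 frames, 31 cells total, ends with 16 live cells
fixture_sim <- function() {
  if (is.null(.fixture_cache$sim))
    .fixture_cache$sim <- simulate_colony(sim_params(n_frames = 40, seed = 3))
  .fixture_cache$sim
}

# smaller, 256x256 colony used where images are rendered per frame
fixture_sim_small <- function() {
  if (is.null(.fixture_cache$sim_small))
    .fixture_cache$sim_small <- simulate_colony(
      sim_params(n_frames = 36, seed = 21, image_shape = c(256L, 256L)))
  .fixture_cache$sim_small
}

# rasterize a set of parallel touching rods (direct access to the
# simulator's rasterizer for constructed-geometry oracles)
rasterize_fixture <- function(states, shape = c(80L, 60L), pixel_size = 0.1) {
  omnicyte:::rasterize_rods(states, shape, pixel_size)
}

# map recovered tracks onto ground-truth cell ids through the masks that
# were tracked; returns NULL if any track spans two truth cells
purity_map <- function(tracks, tracked_masks, truth_masks) {
  map <- list()
  for (i in seq_len(nrow(tracks))) {
    t <- tracks$frame[i]; r <- tracks$region[i]
    tid <- unique(truth_masks[[t]][tracked_masks[[t]] == r])
    tid <- tid[tid > 0]
    if (length(tid) != 1L) return(NULL)
    key <- as.character(tracks$cell_id[i])
    if (is.null(map[[key]])) map[[key]] <- tid
    else if (map[[key]] != tid) return(NULL)
  }
  map
}

# shuffle mask labels per frame deterministically (region numbers are a
# per-frame accident; tracking must not depend on them)
shuffle_labels <- function(masks, seed = 99) {
  set.seed(seed)
  lapply(masks, function(m) {
    labs <- sort(unique(as.integer(m)))
    labs <- labs[labs > 0]
    if (!length(labs)) return(m)
    perm <- sample(length(labs))
    lut <- integer(max(m) + 1L)
    lut[labs + 1L] <- perm
    matrix(ifelse(m > 0L, lut[m + 1L], 0L), nrow(m))
  })
}
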