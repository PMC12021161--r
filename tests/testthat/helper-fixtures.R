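# Shared fixtures, built in code and memoized for the duration of a test
# run so expensive scenes and tile renders happen once.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# A small scene for unit tests (fast to place and render).
small_bundle <- function() {
  memo("small_bundle", generate_scene(demo_scene_config(n_active = 20, seed = 1)))
}

# The packaged desk-scale study fixture: 200 active settlements.
study_bundle <- function() {
  memo("study_bundle", generate_scene(demo_scene_config(n_active = 200, seed = 0)))
}

study_manifest <- function() {
  memo("study_manifest", make_labeled_dataset(study_bundle(), seed = 0))
}

study_split_tiles <- function(split) {
  memo(paste0("study_tiles_", split), {
    m <- study_manifest()
    m <- m[m$split == split, , drop = FALSE]
    list(manifest = m, tiles = load_tiles(study_bundle(), m), labels = m$label)
  })
}

# Quick lists of settlement-patch pseudo-tiles for classifier unit tests
# (32 px patches train the tiny encoder in seconds).
patch_tiles <- function(n_each = 16, size = 32, seed0 = 100) {
  memo(sprintf("patch_tiles_%d_%d_%d", n_each, size, seed0), {
    act <- lapply(seq_len(n_each), function(i)
      render_settlement(TRUE, size, seed0 + i))
    ina <- lapply(seq_len(n_each), function(i)
      render_settlement(FALSE, size, seed0 + 500 + i))
    tiles <- c(act, ina)
    # strip attributes so tiles are plain matrices
    tiles <- lapply(tiles, function(m) matrix(as.vector(m), nrow(m), ncol(m)))
    list(tiles = tiles, labels = rep(c(1, 0), each = n_each))
  })
}
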