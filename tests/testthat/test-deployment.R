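# A tiny raster + untrained model are enough to exercise the scanning and
# merging machinery; the statistical behavior of trained scans is covered
# by the acceptance suite.

scan_fixture <- function() {
  memo("scan_fixture", {
    set.seed(99)
    raster <- matrix(runif(1280 * 1280), 1280, 1280)
    grid <- build_tile_grid(c(640, 640), 128, 0.5)  # 5 x 5 tiles
    model <- build_model("tiny_cnn", seed = 2)
    list(raster = raster, grid = grid, model = model)
  })
}

test_that("scans score every tile once and honor the threshold rule", {
  fx <- scan_fixture()
  sc <- scan_region(fx$model, fx$raster, fx$grid, alpha = 0)
  expect_equal(nrow(sc), 25L)
  expect_equal(attr(sc, "total_tiles"), 25L)
  expect_false(anyNA(sc$score))
  expect_true(all(sc$flagged))          # alpha = 0 flags everything
  sc1 <- scan_region(fx$model, fx$raster, fx$grid, alpha = 1)
  expect_equal(sum(sc1$flagged), 0L)    # alpha = 1 flags nothing
  expect_equal(sc$score, sc1$score)     # scores independent of alpha
})

test_that("checkpointed scans resume to identical results", {
  fx <- scan_fixture()
  dir <- withr::local_tempdir()
  ck <- file.path(dir, "scan.csv")
  full <- scan_region(fx$model, fx$raster, fx$grid, alpha = 0.5)
  # simulate an interrupted scan: checkpoint holding the first 10 tiles
  utils::write.csv(data.frame(tile_id = full$tile_id[1:10],
                              score = full$score[1:10]),
                   ck, row.names = FALSE)
  resumed <- scan_region(fx$model, fx$raster, fx$grid, alpha = 0.5,
                         checkpoint_path = ck, checkpoint_every = 5)
  expect_equal(resumed$score, full$score, tolerance = 1e-12)
  expect_identical(resumed$flagged, full$flagged)
})

test_that("a fused model refuses to scan without GDA models", {
  fx <- scan_fixture()
  mf <- build_model("tiny_cnn", "aux2", aux_dim = 3, seed = 0)
  expect_error(scan_region(mf, fx$raster, fx$grid, alpha = 0.5),
               "supply `gda_models`")
})

flags_to_scan <- function(grid, flagged_cells, scores = NULL) {
  sc <- tile_centers(grid)
  key <- paste(sc$col, sc$row)
  sc$flagged <- key %in% vapply(flagged_cells, function(p) paste(p[1], p[2]), "")
  sc$score <- if (is.null(scores)) ifelse(sc$flagged, 0.9, 0.1) else scores
  attr(sc, "total_tiles") <- nrow(sc)
  attr(sc, "alpha") <- 0.5
  sc
}

test_that("adjacent flagged tiles merge under 8-connectivity", {
  grid <- build_tile_grid(c(1280, 1280), 128, 0.5)  # 10 x 10
  # a single isolated tile detects at its center
  d1 <- merge_detections(flags_to_scan(grid, list(c(3, 4))), grid)
  expect_equal(nrow(d1), 1L)
  expect_equal(c(d1$centroid_x, d1$centroid_y),
               tile_center(grid, 3, 4))
  # a 2x2 block of 128 m tiles detects at the shared corner point
  d2 <- merge_detections(flags_to_scan(grid, list(c(1, 1), c(2, 1),
                                                  c(1, 2), c(2, 2))), grid)
  expect_equal(nrow(d2), 1L)
  expect_equal(d2$n_tiles, 4L)
  expect_equal(c(d2$centroid_x, d2$centroid_y), c(128, 128))
  # tiles touching only at a corner still merge (8-connectivity)
  d3 <- merge_detections(flags_to_scan(grid, list(c(5, 5), c(6, 6))), grid)
  expect_equal(nrow(d3), 1L)
  # but tiles two apart do not
  d4 <- merge_detections(flags_to_scan(grid, list(c(5, 5), c(8, 5))), grid)
  expect_equal(nrow(d4), 2L)
  # an L-shaped component: centroid is the mean of member tile centers,
  # which equals the area centroid of the union of equal disjoint squares
  L <- list(c(4, 4), c(4, 5), c(5, 5))
  dL <- merge_detections(flags_to_scan(grid, L), grid)
  ctrs <- sapply(L, function(p) tile_center(grid, p[1], p[2]))
  expect_equal(c(dL$centroid_x, dL$centroid_y), rowMeans(ctrs))
})

test_that("merging conserves tiles and is idempotent", {
  grid <- build_tile_grid(c(1280, 1280), 128, 0.5)
  set.seed(12)
  cells <- unique(lapply(1:30, function(i) c(sample(10, 1), sample(10, 1))))
  sc <- flags_to_scan(grid, cells)
  det <- merge_detections(sc, grid)
  expect_equal(sum(det$n_tiles), sum(sc$flagged))
  expect_setequal(unlist(det$tile_ids), sc$tile_id[sc$flagged])
  # every flagged tile belongs to exactly one detection
  expect_equal(anyDuplicated(unlist(det$tile_ids)), 0L)
  # rerunning the merge on the same flags changes nothing
  det2 <- merge_detections(sc, grid)
  expect_equal(as.data.frame(det[, 1:5]), as.data.frame(det2[, 1:5]))
  # centroids sit inside the bounding box of their member tiles
  for (i in seq_len(nrow(det))) {
    m <- sc[sc$tile_id %in% det$tile_ids[[i]], ]
    expect_gte(det$centroid_x[i], min(m$x_m) - 64)
    expect_lte(det$centroid_x[i], max(m$x_m) + 64)
  }
  # empty input merges to an empty detection set
  none <- merge_detections(flags_to_scan(grid, list()), grid)
  expect_equal(nrow(none), 0L)
})

test_that("reduction reports compute the review fold correctly", {
  rr <- reduction_report(300000, 1100)
  expect_equal(rr$fold_reduction, 300000 / 1100)
  expect_gte(rr$fold_reduction, 270)
  expect_equal(reduction_report(500, 500)$fold_reduction, 1)
  expect_equal(reduction_report(100, 1)$fold_reduction, 100)
  r0 <- reduction_report(100, 0)
  expect_true(r0$undefined)
  expect_true(is.na(r0$fold_reduction))
})

test_that("detections export to GeoJSON + CSV and round-trip", {
  dir <- withr::local_tempdir()
  grid <- build_tile_grid(c(1280, 1280), 128, 0.5)
  det <- merge_detections(
    flags_to_scan(grid, list(c(1, 1), c(5, 5), c(9, 9))), grid)
  gj <- file.path(dir, "det.geojson"); cs <- file.path(dir, "det.csv")
  export_detections(det, gj, cs)
  back <- read_detections_geojson(gj)
  expect_equal(nrow(back), 3L)
  expect_setequal(back$centroid_x, det$centroid_x)
  wl <- utils::read.csv(cs)
  expect_equal(nrow(wl), 3L)
  expect_true(all(diff(wl$max_score) <= 0))  # descending worklist
  # empty set still writes a valid FeatureCollection
  empty <- merge_detections(flags_to_scan(grid, list()), grid)
  export_detections(empty, gj, cs)
  expect_equal(nrow(read_detections_geojson(gj)), 0L)
})

test_that("ablation runners validate their inputs", {
  b <- small_bundle()
  man <- make_labeled_dataset(b, seed = 0)
  expect_error(run_resolution_ablation(b, man, c(0.25), training_config()),
               ">=")
  expect_error(run_low_data_ablation(b, man, counts = 10000,
                                     strategies = "none"),
               "exceeds")
})

test_that("a single-resolution ablation row equals a plain training run", {
  b <- small_bundle()
  man <- make_labeled_dataset(b, seed = 0)
  cfg <- training_config(max_epochs = 2, seed = 0, batch_size = 16)
  tab <- run_resolution_ablation(b, man, resolutions = 0.5, cfg,
                                 encoder_spec = "tiny_cnn")
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$resolution, 0.5)
  expect_equal(tab$split_checksum, attr(man, "split_checksum"))
  # independent reconstruction of the same cell
  tr <- herdscan:::assemble_split(b, man, "train")
  va <- herdscan:::assemble_split(b, man, "validation")
  te <- herdscan:::assemble_split(b, man, "test")
  fit <- train(build_model("tiny_cnn", seed = 0), tr$tiles, tr$labels,
               va$tiles, va$labels, cfg)
  rep <- metrics_report(predict_proba(fit$model, te$tiles), te$labels)
  expect_equal(tab$auprc, rep$auprc, tolerance = 1e-12)
  expect_equal(tab$precision_at_recall, rep$precision_at_recall,
               tolerance = 1e-12)
})

test_that("low-data cells share identical positive subsamples across strategies", {
  b <- small_bundle()
  man <- make_labeled_dataset(b, seed = 0)
  cfg <- training_config(max_epochs = 1, seed = 0)
  tab <- run_low_data_ablation(b, man, counts = 8,
                               strategies = c("none", "water"),
                               config = cfg, encoder_spec = "tiny_cnn")
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$positives_checksum[1], tab$positives_checksum[2])
  expect_equal(tab$strategy, c("none", "water"))
  expect_true(all(tab$auprc >= 0 & tab$auprc <= 1))
})
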