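test_that("identical configs and seeds reproduce scenes byte-identically", {
  cfg <- demo_scene_config(n_active = 8, seed = 42)
  b1 <- generate_scene(cfg)
  b2 <- generate_scene(cfg)
  expect_identical(b1$settlements, b2$settlements)
  expect_identical(b1$roads_x, b2$roads_x)
  s <- b1$settlements[1, ]
  w1 <- render_tile_at(b1, s$x_m, s$y_m)$pixels
  w2 <- render_tile_at(b2, s$x_m, s$y_m)$pixels
  expect_identical(w1, w2)
  # a different seed produces a different scene
  b3 <- generate_scene(demo_scene_config(n_active = 8, seed = 43))
  expect_false(identical(b1$settlements$x_m, b3$settlements$x_m))
})

test_that("windows agree with sub-blocks of the materialized raster", {
  cfg <- scene_config(region_width_m = 512, region_height_m = 512,
                      resolution_m_per_px = 0.5, n_active = 2,
                      n_roads = 1, n_waters = 1,
                      road_distance_params = c(mu0 = 150, sigma0 = 40,
                                               mu1 = 60, sigma1 = 20),
                      water_distance_params = c(mu0 = 150, sigma0 = 40,
                                                mu1 = 60, sigma1 = 20),
                      min_separation_m = 130, tile_size_m = 128, seed = 9)
  b <- generate_scene(cfg)
  full <- render_raster(b)
  expect_equal(dim(full), c(1024L, 1024L))
  win <- render_window(b, 100L, 200L, 64L, 96L)
  expect_identical(win, full[201:296, 101:164])
  expect_true(all(full >= 0 & full <= 1))
})

test_that("manifest counts and labels are conserved", {
  b <- generate_scene(demo_scene_config(
    n_active = 10, seed = 5, n_inactive = 5,
    negative_strata = c(near_settlement = 3, random_national = 4,
                        random_continental = 6)))
  man <- b$manifest
  expect_equal(sum(man$label == 1), 10L)
  expect_equal(sum(man$stratum == "inactive_settlement"), 5L)
  expect_equal(sum(man$label == 0), 18L)
  expect_equal(nrow(man), 28L)
  # labels are exactly the active stratum
  expect_equal(man$label, as.integer(man$stratum == "active_settlement"))
})

test_that("active road distances follow the truncated normal law", {
  cfg <- demo_scene_config(n_active = 500, seed = 11,
                           region_width_m = 36000, region_height_m = 36000,
                           n_roads = 6, n_waters = 6,
                           n_inactive = 0,
                           negative_strata = c(near_settlement = 0,
                                               random_national = 0,
                                               random_continental = 0))
  b <- generate_scene(cfg)
  d <- b$settlements$d_road_m
  expect_true(all(d >= 0))
  # realized distances equal the rejection-sampled targets
  expect_lt(max(abs(d - b$settlements$target_d_road)), 1e-6)
  want <- truncnorm_mean_oracle(200, 100)
  expect_lt(abs(mean(d) - want), 15)
  # water distances obey the same law independently
  expect_lt(abs(mean(b$settlements$d_water_m) -
                truncnorm_mean_oracle(200, 100)), 15)
})

test_that("GDA fit on generated distances recovers the scene parameters", {
  b <- generate_scene(demo_scene_config(n_active = 500, seed = 13,
                                        region_width_m = 36000,
                                        region_height_m = 36000,
                                        n_roads = 6, n_waters = 6,
                                        n_inactive = 0,
                                        negative_strata = c(
                                          near_settlement = 0,
                                          random_national = 250,
                                          random_continental = 0)))
  s <- b$settlements
  m <- fit_gda(s$d_road_m, s$label, "road")
  # class-1 parameters within 3 SE of the (truncation-corrected) truth
  mu_true <- truncnorm_mean_oracle(200, 100)
  expect_lt(abs(m$mu1 - mu_true), 3 * 100 / sqrt(500))
  expect_lt(abs(sqrt(m$var1) - 100), 3 * 100 * sqrt(1 / (2 * 500)) + 3)
  expect_equal(m$xi, 2 / 3, tolerance = 1e-9)
})

test_that("placement respects separation and near-settlement geometry", {
  b <- small_bundle()
  s <- b$settlements
  # pairwise Chebyshev separation >= the configured minimum: tile windows
  # of distinct points can never overlap (no label leakage across splits)
  n <- nrow(s)
  dx <- outer(s$x_m, s$x_m, "-"); dy <- outer(s$y_m, s$y_m, "-")
  cheb <- pmax(abs(dx), abs(dy))
  diag(cheb) <- Inf
  expect_gte(min(cheb), b$config$min_separation_m)
  expect_gt(b$config$min_separation_m, b$config$tile_size_m)
  # near-settlement negatives sit within 1,000 m (per axis) of an active
  act <- s[s$stratum == "active_settlement", ]
  near <- s[s$stratum == "near_settlement", ]
  for (i in seq_len(nrow(near))) {
    cheb_to_act <- pmax(abs(act$x_m - near$x_m[i]), abs(act$y_m - near$y_m[i]))
    expect_lte(min(cheb_to_act), 1000)
  }
  # all points respect region bounds with the tile-size margin
  expect_true(all(s$x_m >= 64 & s$x_m <= b$config$region_width_m - 64))
})

test_that("impossible placements fail with an explicit error", {
  cfg <- scene_config(region_width_m = 600, region_height_m = 600,
                      resolution_m_per_px = 0.5, n_active = 50,
                      n_roads = 1, n_waters = 1,
                      road_distance_params = c(mu0 = 200, sigma0 = 50,
                                               mu1 = 80, sigma1 = 30),
                      water_distance_params = c(mu0 = 200, sigma0 = 50,
                                                mu1 = 80, sigma1 = 30),
                      min_separation_m = 150, seed = 1)
  expect_error(generate_scene(cfg), "placement failure")
})

test_that("settlement patches have the advertised structure", {
  expect_error(render_settlement(TRUE, 16), ">= 32")
  p32 <- render_settlement(TRUE, 32, seed = 1)
  expect_equal(dim(p32), c(32L, 32L))
  # active: ring band at least 20% darker than the surrounding background
  for (seed in 1:5) {
    p <- render_settlement(TRUE, 64, seed)
    ring <- attr(p, "ring_mask")
    expect_lt(mean(p[ring]), 0.8 * mean(p[!ring]))
  }
  # the ring-contrast statistic separates active from inactive patches
  stats_a <- sapply(1:20, function(s) ring_contrast(render_settlement(TRUE, 64, s)))
  stats_i <- sapply(1:20, function(s) ring_contrast(render_settlement(FALSE, 64, s)))
  expect_true(all(stats_a > stats_i))
  # patches are deterministic in their seed
  expect_identical(render_settlement(FALSE, 48, 7), render_settlement(FALSE, 48, 7))
})

test_that("split assignment is exact, disjoint, and stratified", {
  # 100 tiles at (0.7, 0.15, 0.15) split 70/15/15
  b <- generate_scene(demo_scene_config(
    n_active = 100, seed = 21, n_inactive = 0,
    negative_strata = c(near_settlement = 0, random_national = 0,
                        random_continental = 0)))
  man <- make_labeled_dataset(b, seed = 0)
  expect_equal(unname(table(man$split)[c("train", "validation", "test")]),
               c(70L, 15L, 15L), ignore_attr = TRUE)
  expect_false(anyNA(man$split))
  expect_equal(anyDuplicated(man$tile_id), 0L)

  # stratified: proportions preserved within one tile per stratum
  man2 <- make_labeled_dataset(small_bundle(), seed = 1)
  for (st in unique(man2$stratum)) {
    m <- man2[man2$stratum == st, ]
    got <- table(factor(m$split, c("train", "validation", "test")))
    want <- nrow(m) * c(0.7, 0.15, 0.15)
    expect_true(all(abs(got - want) <= 1))
  }
  # deterministic and checksummed
  man3 <- make_labeled_dataset(small_bundle(), seed = 1)
  expect_identical(man2$split, man3$split)
  expect_identical(attr(man2, "split_checksum"), attr(man3, "split_checksum"))

  expect_error(make_labeled_dataset(tibble::tibble()), "empty")
  expect_error(make_labeled_dataset(small_bundle(),
                                    c(train = 0.5, test = 0.6)), "sum to 1")
})

test_that("a survey-sized positive pool splits to the printed row counts", {
  # 695 positives at the fractions of a 480/114/101 train/val/test layout
  b <- generate_scene(scene_config(
    region_width_m = 36000, region_height_m = 36000,
    resolution_m_per_px = 0.5, n_active = 695,
    n_roads = 6, n_waters = 6, seed = 3))
  man <- make_labeled_dataset(b, split_fractions = c(train = 480 / 695,
                                                     validation = 114 / 695,
                                                     test = 101 / 695),
                              seed = 0)
  pos <- man[man$label == 1, ]
  expect_equal(sum(pos$split == "train"), 480L)
  expect_equal(sum(pos$split == "validation"), 114L)
  expect_equal(sum(pos$split == "test"), 101L)
})

test_that("datasets write to plain-text formats on disk", {
  dir <- withr::local_tempdir()
  b <- generate_scene(demo_scene_config(
    n_active = 3, seed = 8, n_inactive = 2,
    negative_strata = c(near_settlement = 0, random_national = 2,
                        random_continental = 0)))
  man <- make_labeled_dataset(b, seed = 0)
  write_dataset(b, man, dir)
  got <- utils::read.csv(file.path(dir, "manifest.csv"))
  expect_equal(nrow(got), 7L)
  expect_true(all(file.exists(file.path(dir, got$path))))
  png1 <- png::readPNG(file.path(dir, got$path[1]))
  expect_equal(dim(png1), c(256L, 256L))
  cfg <- yaml::read_yaml(file.path(dir, "scene_config.yaml"))
  expect_equal(cfg$n_active, 3L)
  expect_true(file.exists(file.path(dir, "roads.geojson")))
})
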