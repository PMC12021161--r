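# Seeded generator of georeferenced synthetic scenes: background terrain,
# road and waterway networks, active and inactive settlements, and
# stratified negative sampling points, with the statistical structure the
# detection method assumes (active settlements near infrastructure).
#
# The raster is procedural and lazy: any window of the scene can be rendered
# on demand, byte-identically, from the scene seed and absolute pixel
# coordinates (value-noise terrain + per-settlement seeded patches). That
# keeps multi-kilometer scenes at 0.5 m/pixel testable without holding a
# multi-gigapixel array in memory; `render_raster()` materializes small
# scenes when an actual array (e.g. for TIFF export) is wanted.
#
# Coordinates: scene-local planar meters, origin at the raster top-left,
# y increasing southward (image convention).

# ---- configuration ---------------------------------------------------------

#' Scene configuration
#'
#' Distance parameters are per infrastructure kind and class:
#' `c(mu0, sigma0, mu1, sigma1)` in meters, where class 1 is the active
#' settlement class. Draws are truncated at 0 (and at the largest distance
#' the road/water layout can realize); the induced shift of the realized
#' mean away from `mu` is the standard truncated-normal correction
#' `mu + sigma * phi(-mu/sigma) / (1 - Phi(-mu/sigma))`.
#'
#' @param region_width_m,region_height_m Region size in meters.
#' @param resolution_m_per_px Ground sampling distance (default 0.5 m/px,
#'   the finest resolution the degradation protocol starts from).
#' @param n_active,n_inactive Settlement counts.
#' @param negative_strata Named integer vector with counts for
#'   `near_settlement`, `random_national`, `random_continental`.
#' @param road_distance_params,water_distance_params Named numeric vectors
#'   `c(mu0, sigma0, mu1, sigma1)` in meters.
#' @param n_roads,n_waters Number of (axis-parallel) roads / waterways laid
#'   across the region.
#' @param settlement_diameter_m Enclosure diameter of a typical settlement
#'   (meters); the rendered pixel footprint follows from the resolution.
#' @param min_separation_m Minimum Chebyshev (per-axis) separation between
#'   placed points; at least the tile size plus a buffer so tile windows of
#'   different points never overlap (no label leakage across splits).
#' @param tile_size_m Tile footprint (default 128 m).
#' @param seed Integer seed; identical configs and seeds reproduce the scene
#'   byte-identically.
#' @return A `scene_config` list.
#' @export
scene_config <- function(region_width_m, region_height_m,
                         resolution_m_per_px = 0.5,
                         n_active, n_inactive = 0L,
                         negative_strata = c(near_settlement = 0L,
                                             random_national = 0L,
                                             random_continental = 0L),
                         road_distance_params = c(mu0 = 2000, sigma0 = 500,
                                                  mu1 = 200, sigma1 = 100),
                         water_distance_params = c(mu0 = 2000, sigma0 = 500,
                                                   mu1 = 200, sigma1 = 100),
                         n_roads = NULL, n_waters = NULL,
                         settlement_diameter_m = 30,
                         min_separation_m = 150,
                         tile_size_m = 128,
                         seed = 1L) {
  check_number(region_width_m, "region_width_m", positive = TRUE)
  check_number(region_height_m, "region_height_m", positive = TRUE)
  check_number(resolution_m_per_px, "resolution_m_per_px", positive = TRUE)
  check_number(n_active, "n_active", min = 0)
  check_number(n_inactive, "n_inactive", min = 0)
  for (nm in c("near_settlement", "random_national", "random_continental"))
    if (is.na(negative_strata[nm])) negative_strata[nm] <- 0L
  if (any(negative_strata < 0)) stopf("stratum counts must be >= 0")
  for (p in list(road_distance_params, water_distance_params)) {
    if (!all(c("mu0", "sigma0", "mu1", "sigma1") %in% names(p)))
      stopf("distance params must be named c(mu0, sigma0, mu1, sigma1)")
    if (p[["sigma0"]] <= 0 || p[["sigma1"]] <= 0) stopf("sigma parameters must be > 0")
  }
  if (is.null(n_roads)) n_roads <- max(1L, round(region_width_m / 6000))
  if (is.null(n_waters)) n_waters <- max(1L, round(region_height_m / 6000))
  if (min_separation_m < tile_size_m)
    stopf("min_separation_m must be >= tile_size_m so tile windows cannot overlap")
  structure(
    list(region_width_m = region_width_m, region_height_m = region_height_m,
         resolution_m_per_px = resolution_m_per_px,
         n_active = as.integer(n_active), n_inactive = as.integer(n_inactive),
         negative_strata = negative_strata[c("near_settlement",
                                             "random_national",
                                             "random_continental")],
         road_distance_params = road_distance_params,
         water_distance_params = water_distance_params,
         n_roads = as.integer(n_roads), n_waters = as.integer(n_waters),
         settlement_diameter_m = settlement_diameter_m,
         min_separation_m = min_separation_m,
         tile_size_m = tile_size_m,
         seed = as.integer(seed)),
    class = "scene_config")
}

#' Packaged desk-scale scene configuration
#'
#' The fixture used throughout the test suite and worked examples: a
#' 24 x 24 km scene at 0.5 m/pixel with a 4 x 4 road/water lattice. Active
#' settlements draw infrastructure distances from N(200, 100^2) m and all
#' other strata from N(2000, 500^2) m (truncated at 0), the kind of
#' separation observed between occupied settlements and background points.
#' The negative strata keep the qualitative composition of real survey
#' manifests (continental random sample largest, then inactive settlements,
#' then national and near-settlement points) at a reduced absolute scale.
#'
#' @param n_active Number of active settlements (default 200).
#' @param seed Integer seed.
#' @param ... Overrides passed on to [scene_config()].
#' @return A `scene_config`.
#' @export
demo_scene_config <- function(n_active = 200, seed = 0, ...) {
  args <- list(
    region_width_m = 24000, region_height_m = 24000,
    resolution_m_per_px = 0.5,
    n_active = n_active,
    n_inactive = max(2L, round(n_active * 0.5)),
    negative_strata = c(near_settlement = max(2L, round(n_active * 0.3)),
                        random_national = max(2L, round(n_active * 0.4)),
                        random_continental = max(2L, round(n_active * 0.8))),
    n_roads = 4L, n_waters = 4L,
    seed = seed)
  override <- list(...)
  args[names(override)] <- override
  do.call(scene_config, args)
}

# ---- deterministic procedural texture --------------------------------------

# Uniform-looking hash of integer lattice coordinates; fully deterministic
# in IEEE doubles, so window renders are byte-identical across calls.
hash01 <- function(ix, iy, seed) {
  v <- sin(ix * 127.1 + iy * 311.7 + seed * 0.618033988749895 + 0.12345) *
    43758.5453123
  v - floor(v)
}

# Smooth value noise on an L-pixel lattice, evaluated at absolute pixel
# coordinates PX, PY (matrices of equal dim).
value_noise <- function(PX, PY, L, seed) {
  gx <- PX / L; gy <- PY / L
  ix <- floor(gx); iy <- floor(gy)
  fx <- gx - ix; fy <- gy - iy
  ux <- fx * fx * (3 - 2 * fx)
  uy <- fy * fy * (3 - 2 * fy)
  h00 <- hash01(ix, iy, seed);     h10 <- hash01(ix + 1, iy, seed)
  h01 <- hash01(ix, iy + 1, seed); h11 <- hash01(ix + 1, iy + 1, seed)
  a <- h00 + (h10 - h00) * ux
  b <- h01 + (h11 - h01) * ux
  a + (b - a) * uy
}

# Texture palettes: base level and noise amplitudes (drift, low, mid,
# speckle). Palette 0 is the default scrubland; 1..3 are the distinct
# palettes used for the geographically diverse continental stratum.
scene_palettes <- list(
  c(base = 0.55, drift = 0.05, low = 0.07, mid = 0.05, speckle = 0.030),
  c(base = 0.72, drift = 0.03, low = 0.05, mid = 0.04, speckle = 0.020),
  c(base = 0.40, drift = 0.04, low = 0.06, mid = 0.05, speckle = 0.030),
  c(base = 0.50, drift = 0.06, low = 0.09, mid = 0.06, speckle = 0.025)
)

render_background <- function(PX, PY, seed, palette) {
  p <- scene_palettes[[palette + 1L]]
  out <- p[["base"]] +
    p[["drift"]]   * (value_noise(PX, PY, 1024, seed + 11) - 0.5) * 2 +
    p[["low"]]     * (value_noise(PX, PY, 256, seed + 23) - 0.5) * 2 +
    p[["mid"]]     * (value_noise(PX, PY, 48, seed + 37) - 0.5) * 2 +
    p[["speckle"]] * (hash01(PX, PY, seed + 51) - 0.5) * 2
  # scattered shrub/tree clutter: clustered dark blobs typical of scrubland
  shrub <- value_noise(PX, PY, 14, seed + 63) *
    (0.6 + 0.4 * value_noise(PX, PY, 180, seed + 67))
  dense <- shrub > 0.78
  out[dense] <- out[dense] * 0.55
  mild <- shrub > 0.70 & !dense
  out[mild] <- out[mild] * 0.8
  out
}

# ---- settlement patch rendering --------------------------------------------

#' Render a single settlement image patch
#'
#' Active settlements are drawn as a dark, slightly irregular circular
#' livestock enclosure (kraal) around grazed bare ground with a few hut
#' blobs. Inactive settlements show dark burn-mark blotches and vegetation
#' overgrowth speckle, with no intact enclosure ring.
#'
#' @param active Logical; `TRUE` for an active settlement.
#' @param size_px Patch side length in pixels (>= 32).
#' @param seed Integer seed controlling the patch's random details.
#' @return A `size_px` x `size_px` numeric matrix in `[0, 1]` composited
#'   over neutral terrain, with attributes `mask` (alpha matrix used when
#'   compositing into a scene) and `ring_mask` (logical matrix marking the
#'   canonical annulus band, used by the ring-contrast detector statistic).
#' @export
render_settlement <- function(active, size_px, seed = 0) {
  if (size_px < 32) stopf("size_px must be >= 32 (got %s)", size_px)
  s <- as.integer(size_px)
  with_seed(seed, {
    cx <- (s + 1) / 2
    xs <- matrix(rep(seq_len(s), each = s), s, s)   # column index
    ys <- matrix(rep(seq_len(s), times = s), s, s)  # row index
    r <- sqrt((xs - cx)^2 + (ys - cx)^2) / s        # radius in patch units
    ang <- atan2(ys - cx, xs - cx)
    val <- matrix(0.55, s, s)
    alpha <- matrix(0, s, s)
    r_out <- 0.40; tk <- 0.10
    ring_mask <- r >= (r_out - tk) & r <= r_out
    if (active) {
      k <- sample(3:6, 1); phase <- stats::runif(1, 0, 2 * pi)
      scale <- stats::runif(1, 0.80, 1.15)       # settlement size variability
      ring_val <- stats::runif(1, 0.18, 0.32)    # fence darkness variability
      wob <- scale * (1 + 0.05 * sin(k * ang + phase))
      ro <- r_out * wob; ri <- (r_out - tk) * wob
      in_ring <- r >= ri & r <= ro
      interior <- r < ri
      # grazed bare ground inside the enclosure
      val[interior] <- 0.62 + 0.05 * (hash01(xs, ys, seed + 3) - 0.5)[interior]
      alpha[interior] <- 0.85
      # dark enclosure ring
      val[in_ring] <- ring_val + 0.04 * (hash01(xs, ys, seed + 5) - 0.5)[in_ring]
      alpha[in_ring] <- 1
      # trampled halo just outside the ring
      halo <- r > ro & r < ro * 1.15
      val[halo] <- 0.60
      alpha[halo] <- pmax(alpha[halo], 0.30)
      # hut blobs inside the enclosure
      n_huts <- sample(2:5, 1)
      for (h in seq_len(n_huts)) {
        hr <- stats::runif(1, 0.08, 0.22) * (r_out - tk)
        ha <- stats::runif(1, 0, 2 * pi)
        hx <- cx + hr * s * cos(ha) * 2; hy <- cx + hr * s * sin(ha) * 2
        hd <- sqrt((xs - hx)^2 + (ys - hy)^2) / s
        hut <- hd < 0.045
        val[hut] <- 0.30
        alpha[hut] <- 1
        roof <- hd < 0.018
        val[roof] <- 0.78
      }
    } else {
      # abandoned enclosure: a faded, broken ring remnant (arc gaps where
      # the fence has collapsed / revegetated) -- the visually hard negative
      k <- sample(3:6, 1); phase <- stats::runif(1, 0, 2 * pi)
      scale <- stats::runif(1, 0.80, 1.15)
      wob <- scale * (1 + 0.05 * sin(k * ang + phase))
      ro <- r_out * wob; ri <- (r_out - tk) * wob
      k2 <- sample(2:4, 1); phase2 <- stats::runif(1, 0, 2 * pi)
      cut <- stats::runif(1, -0.35, 0.05)
      arc <- sin(k2 * ang + phase2) > cut  # 40-65% arc coverage, never intact
      remnant <- r >= ri & r <= ro & arc
      rem_val <- stats::runif(1, 0.30, 0.42)
      val[remnant] <- rem_val + 0.05 * (hash01(xs, ys, seed + 5) - 0.5)[remnant]
      alpha[remnant] <- 0.55
      interior <- r < ri
      val[interior] <- 0.58 + 0.05 * (hash01(xs, ys, seed + 3) - 0.5)[interior]
      alpha[interior] <- 0.45
      # burn marks: dark blotches with soft falloff
      n_b <- sample(2:4, 1)
      for (b in seq_len(n_b)) {
        br <- stats::runif(1, 0, 0.22); ba <- stats::runif(1, 0, 2 * pi)
        bx <- cx + br * s * cos(ba); by <- cx + br * s * sin(ba)
        brad <- stats::runif(1, 0.07, 0.12)
        bd <- sqrt((xs - bx)^2 + (ys - by)^2) / s
        w <- exp(-(bd / brad)^2)
        val <- val * (1 - 0.9 * w) + 0.26 * (0.9 * w)
        alpha <- pmax(alpha, pmin(w * 1.4, 0.9))
      }
      # vegetation overgrowth speckle across the footprint
      veg <- r < 0.45 & hash01(xs, ys, seed + 9) > 0.62
      val[veg] <- 0.44
      alpha[veg] <- pmax(alpha[veg], 0.5)
    }
    base <- 0.55 + 0.03 * (hash01(xs, ys, seed + 13) - 0.5)
    out <- base * (1 - alpha) + val * alpha
    attr(out, "mask") <- alpha
    attr(out, "ring_mask") <- ring_mask
    out
  })
}

#' Ring-contrast detector statistic of a patch
#'
#' Mean intensity outside the canonical annulus band minus the mean on the
#' band; large positive values indicate an intact dark enclosure ring.
#'
#' @param patch Matrix from [render_settlement()] (or any square patch; the
#'   canonical band at radius 0.30-0.40 of the side length is used).
#' @return Numeric statistic.
#' @export
ring_contrast <- function(patch) {
  ring <- attr(patch, "ring_mask")
  if (is.null(ring)) {
    s <- nrow(patch); cx <- (s + 1) / 2
    xs <- matrix(rep(seq_len(s), each = s), s, s)
    ys <- matrix(rep(seq_len(s), times = s), s, s)
    r <- sqrt((xs - cx)^2 + (ys - cx)^2) / s
    ring <- r >= 0.30 & r <= 0.40
  }
  mean(patch[!ring]) - mean(patch[ring])
}

# ---- placement -------------------------------------------------------------

# Truncated-normal sampler on [lower, upper] by batched rejection.
sample_truncnorm <- function(n, mu, sigma, lower = 0, upper = Inf) {
  mass <- stats::pnorm(upper, mu, sigma) - stats::pnorm(lower, mu, sigma)
  if (mass < 1e-8)
    stopf("truncation window [%g, %g] has negligible mass under N(%g, %g^2)",
          lower, upper, mu, sigma)
  out <- numeric(0)
  while (length(out) < n) {
    draw <- stats::rnorm(ceiling((n - length(out)) / mass) + 8, mu, sigma)
    out <- c(out, draw[draw >= lower & draw <= upper])
  }
  out[seq_len(n)]
}

# Chebyshev separation check against already-placed points.
is_free <- function(x, y, px, py, min_sep) {
  if (length(px) == 0L) return(TRUE)
  all(pmax(abs(px - x), abs(py - y)) >= min_sep)
}

#' Generate a synthetic scene
#'
#' Lays out the road and waterway networks, then places active settlements,
#' inactive settlements, and stratified negative points by rejection
#' sampling against the realized polylines: each point proposes target
#' nearest-road and nearest-water distances drawn from its class's
#' truncated normal and is placed so those distances are realized exactly
#' (and re-verified against the polyline geometry), subject to region
#' bounds and a minimum Chebyshev separation. Near-settlement negatives
#' are instead placed uniformly within 1,000 m of a random active
#' settlement, inheriting whatever infrastructure distances result.
#'
#' @param config A [scene_config()].
#' @return A `scene_bundle` with the infrastructure sets, the settlement
#'   table (positions, strata, target and realized distances, per-point
#'   render seeds), and the labeled tile manifest.
#' @export
generate_scene <- function(config) {
  if (!inherits(config, "scene_config")) stopf("`config` must be a scene_config")
  w <- config$region_width_m; h <- config$region_height_m
  res <- config$resolution_m_per_px
  margin <- config$tile_size_m / 2
  spacing_r <- w / config$n_roads
  spacing_w <- h / config$n_waters
  roads_x <- (seq_len(config$n_roads) - 0.5) * spacing_r
  waters_y <- (seq_len(config$n_waters) - 0.5) * spacing_w
  d_max_road <- spacing_r / 2
  d_max_water <- spacing_w / 2
  roads <- infrastructure_set(
    lapply(roads_x, function(x) cbind(c(x, x, x), c(0, h / 2, h))), "road")
  waters <- infrastructure_set(
    lapply(waters_y, function(y) cbind(c(0, w / 2, w), c(y, y, y))), "water")

  rp <- config$road_distance_params; wp <- config$water_distance_params
  diam_px <- config$settlement_diameter_m / res
  patch_px <- max(32L, as.integer(round(diam_px * 1.8)))

  categories <- c(rep("active_settlement", config$n_active),
                  rep("inactive_settlement", config$n_inactive),
                  rep("near_settlement", config$negative_strata[["near_settlement"]]),
                  rep("random_national", config$negative_strata[["random_national"]]),
                  rep("random_continental", config$negative_strata[["random_continental"]]))
  n_total <- length(categories)
  if (n_total == 0L) stopf("nothing to place: all counts are zero")

  # all (road, water, side) combinations a distance pair can realize
  combos <- expand.grid(ri = seq_along(roads_x), wi = seq_along(waters_y),
                        sx = c(-1, 1), sy = c(-1, 1))

  with_seed(config$seed, {
    px <- numeric(0); py <- numeric(0)
    tdr <- numeric(0); tdw <- numeric(0)
    max_redraws <- 60L
    for (i in seq_len(n_total)) {
      cat_i <- categories[i]
      placed <- FALSE
      # the target distances are drawn once and kept while positions are
      # searched; they are redrawn only when no free position realizes
      # them, so the realized distance law is not density-biased
      for (attempt in seq_len(max_redraws)) {
        if (cat_i == "near_settlement") {
          n_act <- sum(categories[seq_len(i - 1)] == "active_settlement")
          if (n_act == 0L) stopf("near_settlement stratum requires n_active > 0")
          for (k in seq_len(30L)) {
            j <- sample.int(n_act, 1)
            x <- px[j] + stats::runif(1, -1000, 1000)
            y <- py[j] + stats::runif(1, -1000, 1000)
            if (x < margin || x > w - margin || y < margin || y > h - margin) next
            if (!is_free(x, y, px, py, config$min_separation_m)) next
            placed <- TRUE; dr <- NA_real_; dw <- NA_real_
            break
          }
        } else {
          pos <- cat_i == "active_settlement"
          dr <- sample_truncnorm(1, rp[[if (pos) "mu1" else "mu0"]],
                                 rp[[if (pos) "sigma1" else "sigma0"]],
                                 0, d_max_road)
          dw <- sample_truncnorm(1, wp[[if (pos) "mu1" else "mu0"]],
                                 wp[[if (pos) "sigma1" else "sigma0"]],
                                 0, d_max_water)
          for (ci in sample.int(nrow(combos))) {
            x <- roads_x[combos$ri[ci]] + combos$sx[ci] * dr
            y <- waters_y[combos$wi[ci]] + combos$sy[ci] * dw
            if (x < margin || x > w - margin || y < margin || y > h - margin) next
            if (!is_free(x, y, px, py, config$min_separation_m)) next
            placed <- TRUE
            break
          }
        }
        if (placed) {
          px <- c(px, x); py <- c(py, y)
          tdr <- c(tdr, dr); tdw <- c(tdw, dw)
          break
        }
      }
      if (!placed)
        stopf(paste0("placement failure: could not place %s point %d without ",
                     "overlap; the region is too small for the requested counts"),
              cat_i, i)
    }

    pts <- cbind(px, py)
    settlements <- tibble::tibble(
      id = seq_len(n_total),
      tile_id = sprintf("t%05d", seq_len(n_total)),
      x_m = px, y_m = py,
      stratum = categories,
      label = as.integer(categories == "active_settlement"),
      target_d_road = tdr, target_d_water = tdw,
      d_road_m = nearest_distance_many(pts, roads),
      d_water_m = nearest_distance_many(pts, waters),
      has_footprint = categories %in% c("active_settlement", "inactive_settlement"),
      patch_px = patch_px,
      render_seed = (config$seed + 7919 * seq_len(n_total)) %% 2147483647L,
      palette = ifelse(categories == "random_continental",
                       1L + (seq_len(n_total) %% 3L), 0L)
    )

    manifest <- settlements[, c("tile_id", "x_m", "y_m", "label", "stratum")]

    structure(
      list(config = config,
           roads = roads, waters = waters,
           roads_x = roads_x, waters_y = waters_y,
           settlements = settlements,
           manifest = manifest,
           patch_cache = new.env(parent = emptyenv()),
           tile_cache = new.env(parent = emptyenv())),
      class = "scene_bundle")
  })
}

#' @export
print.scene_bundle <- function(x, ...) {
  cat(sprintf(
    "<scene_bundle> %g x %g m @ %g m/px; %d roads, %d waters; %d points (%d active)\n",
    x$config$region_width_m, x$config$region_height_m,
    x$config$resolution_m_per_px, length(x$roads_x), length(x$waters_y),
    nrow(x$settlements), sum(x$settlements$label)))
  invisible(x)
}

# ---- window rendering ------------------------------------------------------

settlement_patch <- function(bundle, i) {
  key <- as.character(i)
  cached <- bundle$patch_cache[[key]]
  if (!is.null(cached)) return(cached)
  s <- bundle$settlements
  p <- render_settlement(s$stratum[i] == "active_settlement",
                         s$patch_px[i], s$render_seed[i])
  bundle$patch_cache[[key]] <- p
  p
}

#' Render a window of the scene raster
#'
#' Deterministic in the scene seed and absolute pixel coordinates; windows
#' rendered separately agree exactly with the corresponding sub-blocks of
#' [render_raster()].
#'
#' @param bundle A `scene_bundle`.
#' @param x0_px,y0_px Top-left corner of the window in absolute raster
#'   pixels (0-based).
#' @param w_px,h_px Window size in pixels.
#' @return Numeric `h_px` x `w_px` matrix in `[0, 1]`.
#' @export
render_window <- function(bundle, x0_px, y0_px, w_px, h_px) {
  cfg <- bundle$config
  res <- cfg$resolution_m_per_px
  seed <- cfg$seed
  # absolute pixel index grids (0-based)
  PX <- matrix(rep(x0_px + seq_len(w_px) - 1L, each = h_px), h_px, w_px)
  PY <- matrix(rep(y0_px + seq_len(h_px) - 1L, times = w_px), h_px, w_px)
  out <- render_background(PX, PY, seed, palette = 0L)
  # distinct texture palettes around continental-stratum points
  cont <- which(bundle$settlements$stratum == "random_continental")
  if (length(cont)) {
    Xm <- (PX + 0.5) * res; Ym <- (PY + 0.5) * res
    zone_r <- 1.5 * cfg$tile_size_m
    for (i in cont) {
      sx <- bundle$settlements$x_m[i]; sy <- bundle$settlements$y_m[i]
      if (sx < Xm[1, 1] - zone_r || sx > Xm[1, w_px] + zone_r ||
          sy < Ym[1, 1] - zone_r || sy > Ym[h_px, 1] + zone_r) next
      mask <- (Xm - sx)^2 + (Ym - sy)^2 < zone_r^2
      if (!any(mask)) next
      alt <- render_background(PX, PY, seed, palette = bundle$settlements$palette[i])
      out[mask] <- alt[mask]
    }
  }
  # infrastructure: waterways (dark), then roads (bright dirt tracks)
  Xm_col <- (x0_px + seq_len(w_px) - 0.5) * res
  Ym_row <- (y0_px + seq_len(h_px) - 0.5) * res
  for (wy in bundle$waters_y) {
    rows <- which(abs(Ym_row - wy) < 5)
    if (length(rows)) out[rows, ] <- 0.20 +
        0.03 * (hash01(PX[rows, , drop = FALSE], PY[rows, , drop = FALSE], seed + 71) - 0.5)
  }
  for (rx in bundle$roads_x) {
    cols <- which(abs(Xm_col - rx) < 2.5)
    if (length(cols)) out[, cols] <- 0.78 +
        0.04 * (hash01(PX[, cols, drop = FALSE], PY[, cols, drop = FALSE], seed + 87) - 0.5)
  }
  # settlements with an imagery footprint
  foot <- which(bundle$settlements$has_footprint)
  for (i in foot) {
    st <- bundle$settlements[i, ]
    half <- st$patch_px / 2
    # patch top-left in absolute pixels
    sx0 <- round(st$x_m / res) - floor(half)
    sy0 <- round(st$y_m / res) - floor(half)
    if (sx0 + st$patch_px <= x0_px || sx0 >= x0_px + w_px ||
        sy0 + st$patch_px <= y0_px || sy0 >= y0_px + h_px) next
    patch <- settlement_patch(bundle, i)
    alpha <- attr(patch, "mask")
    # overlap in absolute pixels
    ox0 <- max(sx0, x0_px); ox1 <- min(sx0 + st$patch_px, x0_px + w_px) - 1L
    oy0 <- max(sy0, y0_px); oy1 <- min(sy0 + st$patch_px, y0_px + h_px) - 1L
    wr <- (oy0:oy1) - y0_px + 1L; wc <- (ox0:ox1) - x0_px + 1L
    pr <- (oy0:oy1) - sy0 + 1L; pc <- (ox0:ox1) - sx0 + 1L
    a <- alpha[pr, pc, drop = FALSE]
    out[wr, wc] <- out[wr, wc] * (1 - a) + patch[pr, pc, drop = FALSE] * a
  }
  clamp(out, 0, 1)
}

#' Render a tile centered on a point
#'
#' @param bundle A `scene_bundle`.
#' @param x_m,y_m Tile center in meters.
#' @param tile_size_m Tile footprint (defaults to the scene's tile size).
#' @return An `image_tile`.
#' @export
render_tile_at <- function(bundle, x_m, y_m, tile_size_m = NULL) {
  cfg <- bundle$config
  if (is.null(tile_size_m)) tile_size_m <- cfg$tile_size_m
  res <- cfg$resolution_m_per_px
  size_px <- as.integer(round(tile_size_m / res))
  x0 <- round(x_m / res) - size_px %/% 2L
  y0 <- round(y_m / res) - size_px %/% 2L
  key <- sprintf("%d_%d_%d", x0, y0, size_px)
  px <- bundle$tile_cache[[key]]
  if (is.null(px)) {
    px <- render_window(bundle, x0, y0, size_px, size_px)
    bundle$tile_cache[[key]] <- px
  }
  new_image_tile(px, c(x_m, y_m), source_resolution = res)
}

#' Materialize the full scene raster
#'
#' Intended for small scenes (e.g. TIFF export, visual inspection); refuses
#' rasters above `max_px` pixels because large scenes are meant to be
#' rendered window-by-window.
#'
#' @param bundle A `scene_bundle`.
#' @param max_px Maximum pixel count (default 4e7).
#' @return Numeric matrix.
#' @export
render_raster <- function(bundle, max_px = 4e7) {
  cfg <- bundle$config
  res <- cfg$resolution_m_per_px
  w_px <- as.integer(round(cfg$region_width_m / res))
  h_px <- as.integer(round(cfg$region_height_m / res))
  if (as.numeric(w_px) * h_px > max_px)
    stopf("raster would be %d x %d px; render windows instead or raise max_px",
          h_px, w_px)
  render_window(bundle, 0L, 0L, w_px, h_px)
}

# ---- labeled dataset construction ------------------------------------------

# Largest-remainder apportionment of m items into fractions f (sums to m).
largest_remainder <- function(m, f) {
  q <- m * f
  base <- floor(q)
  rem <- q - base
  leftover <- m - sum(base)
  if (leftover > 0) {
    add <- order(rem, decreasing = TRUE)[seq_len(leftover)]
    base[add] <- base[add] + 1
  }
  as.integer(base)
}

#' Assign train/validation/test splits to a scene manifest
#'
#' Splits are stratified: within every stratum the tiles are shuffled
#' (seeded) and apportioned by the largest-remainder method, so stratum
#' proportions are preserved to within one tile and the split totals are
#' exact. Tile windows of distinct points never overlap (the generator
#' enforces a Chebyshev separation of at least the tile size), so no image
#' content leaks between splits.
#'
#' @param bundle A `scene_bundle` (or a manifest tibble with `tile_id` and
#'   `stratum` columns).
#' @param split_fractions Named positive fractions summing to 1 (default
#'   `c(train = 0.7, validation = 0.15, test = 0.15)`).
#' @param seed Integer seed for the within-stratum shuffle.
#' @return The manifest tibble with a `split` column; attribute
#'   `split_checksum` identifies the exact assignment.
#' @export
make_labeled_dataset <- function(bundle,
                                 split_fractions = c(train = 0.7,
                                                     validation = 0.15,
                                                     test = 0.15),
                                 seed = 0) {
  manifest <- if (inherits(bundle, "scene_bundle")) bundle$manifest else bundle
  if (is.null(manifest) || nrow(manifest) == 0L) stopf("empty scene bundle")
  if (any(split_fractions <= 0)) stopf("split fractions must be positive")
  if (abs(sum(split_fractions) - 1) > 1e-8) stopf("split fractions must sum to 1")
  split_names <- names(split_fractions)
  if (is.null(split_names)) stopf("split fractions must be named")
  manifest$split <- NA_character_
  with_seed(seed, {
    for (st in unique(manifest$stratum)) {
      idx <- which(manifest$stratum == st)
      idx <- idx[sample.int(length(idx))]
      counts <- largest_remainder(length(idx), split_fractions)
      assign_to <- rep(split_names, counts)
      manifest$split[idx] <- assign_to
    }
  })
  attr(manifest, "split_checksum") <-
    text_checksum(paste(manifest$tile_id, manifest$split))
  manifest
}

#' Render the tiles of a manifest
#' @param bundle A `scene_bundle`.
#' @param manifest Manifest tibble (rows define which tiles to render).
#' @param tile_size_m Tile footprint (defaults to the scene's tile size).
#' @return Named list of `image_tile` objects keyed by `tile_id`.
#' @export
load_tiles <- function(bundle, manifest, tile_size_m = NULL) {
  out <- lapply(seq_len(nrow(manifest)), function(i)
    render_tile_at(bundle, manifest$x_m[i], manifest$y_m[i], tile_size_m))
  names(out) <- manifest$tile_id
  out
}

#' Write a labeled dataset to disk
#'
#' Tiles as PNG, the manifest as CSV with columns `(tile_id, path, x_m,
#' y_m, label, stratum, split)`, the configuration as YAML, and the
#' infrastructure as GeoJSON.
#'
#' @param bundle A `scene_bundle`.
#' @param manifest Split manifest from [make_labeled_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(bundle, manifest, dir) {
  dir.create(file.path(dir, "tiles"), recursive = TRUE, showWarnings = FALSE)
  paths <- character(nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    tile <- render_tile_at(bundle, manifest$x_m[i], manifest$y_m[i])
    paths[i] <- file.path("tiles", paste0(manifest$tile_id[i], ".png"))
    png::writePNG(tile$pixels, file.path(dir, paths[i]))
  }
  out <- manifest
  out$path <- paths
  cols <- c("tile_id", "path", "x_m", "y_m", "label", "stratum",
            intersect("split", names(out)))
  utils::write.csv(out[, cols], file.path(dir, "manifest.csv"), row.names = FALSE)
  cfg <- bundle$config
  yaml::write_yaml(unclass(cfg), file.path(dir, "scene_config.yaml"))
  write_infrastructure_geojson(bundle$roads, file.path(dir, "roads.geojson"))
  write_infrastructure_geojson(bundle$waters, file.path(dir, "waters.geojson"))
  invisible(dir)
}
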