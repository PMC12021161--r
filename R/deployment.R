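# Region-scale deployment: scanning every tile of a grid with a calibrated
# threshold, merging adjacent positive tiles into detections, reporting the
# manual-review reduction, and the packaged experiment runners (resolution
# ablation, low-data ablation).

#' Scan a region tile by tile
#'
#' Scores every tile of the grid with the model and flags tiles whose score
#' exceeds the calibrated threshold `alpha` (rule: `score > alpha`). Scans
#' are resumable: progress is checkpointed every `checkpoint_every` tiles
#' to a CSV, and a rerun pointing at the same checkpoint continues where it
#' left off with identical results.
#'
#' @param model A `settlement_classifier`.
#' @param scene A `scene_bundle` (tiles rendered on demand) or a raster
#'   matrix (tiles extracted directly).
#' @param grid A [build_tile_grid()] grid covering the region.
#' @param alpha Decision threshold, typically from [calibrate_threshold()]
#'   on a labeled validation pool.
#' @param gda_models Named list of [fit_gda()] models; required when the
#'   model fuses auxiliary features (tile-center distances are computed
#'   against the scene's infrastructure).
#' @param aux_mode `"gda"` or `"raw_distance"`.
#' @param checkpoint_path Optional CSV path for resumable scanning.
#' @param checkpoint_every Tiles between checkpoint writes (default 1000).
#' @param batch_size Tiles per forward pass.
#' @return Tibble `(tile_id, col, row, x_m, y_m, score, flagged)` with
#'   attributes `alpha` and `total_tiles`.
#' @export
scan_region <- function(model, scene, grid, alpha, gda_models = NULL,
                        aux_mode = "gda", checkpoint_path = NULL,
                        checkpoint_every = 1000L, batch_size = 64L) {
  fused <- model$fusion$strategy != "none"
  if (fused && is.null(gda_models))
    stopf("model fuses auxiliary features: supply `gda_models` before scanning")
  centers <- tile_centers(grid)
  n <- nrow(centers)
  aux <- NULL
  if (fused) {
    if (!inherits(scene, "scene_bundle"))
      stopf("aux-fused scanning needs a scene_bundle (for infrastructure geometry)")
    recs <- compute_distance_features(centers, scene$roads, scene$waters)
    aux <- build_aux_matrix(recs, gda_models, aux_mode)
    if (ncol(aux) != model$fusion$aux_dim)
      stopf("aux feature dimension (%d) does not match the model (%d)",
            ncol(aux), model$fusion$aux_dim)
  }
  scores <- rep(NA_real_, n)
  start <- 1L
  if (!is.null(checkpoint_path) && file.exists(checkpoint_path)) {
    done <- utils::read.csv(checkpoint_path)
    m <- min(nrow(done), n)
    scores[seq_len(m)] <- done$score[seq_len(m)]
    start <- m + 1L
  }
  size_px <- as.integer(round(grid$tile_size_m / grid$resolution_m_per_px))
  i <- start
  while (i <= n) {
    j <- min(i + batch_size - 1L, n)
    tiles <- lapply(i:j, function(t) {
      if (inherits(scene, "scene_bundle")) {
        render_window(scene,
                      (centers$col[t] - 1L) * size_px,
                      (centers$row[t] - 1L) * size_px,
                      size_px, size_px)
      } else {
        extract_tile(scene, grid, centers$col[t], centers$row[t])$pixels
      }
    })
    a <- if (is.null(aux)) NULL else aux[i:j, , drop = FALSE]
    scores[i:j] <- predict_proba(model, tiles, aux = a,
                                 batch_size = batch_size)
    if (!is.null(checkpoint_path) &&
        (j %% checkpoint_every < batch_size || j == n)) {
      utils::write.csv(
        data.frame(tile_id = centers$tile_id[seq_len(j)],
                   score = scores[seq_len(j)]),
        checkpoint_path, row.names = FALSE)
    }
    i <- j + 1L
  }
  out <- centers
  out$score <- scores
  out$flagged <- scores > alpha
  attr(out, "alpha") <- alpha
  attr(out, "total_tiles") <- n
  out
}

#' Merge adjacent flagged tiles into detections
#'
#' Flagged tiles are grouped into connected components under
#' 8-connectivity (tiles touching along an edge or a corner belong to the
#' same candidate settlement, so a settlement straddling a tile corner is
#' not split). Each component becomes one detection whose centroid is the
#' area centroid of the spatial union of its tiles — for disjoint
#' equal-area square tiles this equals the mean of the member tile
#' centers, including L-shaped components.
#'
#' @param scan Tibble from [scan_region()] (or any tibble with `tile_id`,
#'   `col`, `row`, `x_m`, `y_m`, `score`, `flagged`).
#' @param grid The [build_tile_grid()] used for the scan.
#' @return A `detection_set` tibble `(detection_id, centroid_x, centroid_y,
#'   n_tiles, max_score, tile_ids)` with attributes `total_tiles_scanned`,
#'   `n_flagged_tiles`, `alpha`.
#' @export
merge_detections <- function(scan, grid) {
  flagged <- scan[which(scan$flagged), , drop = FALSE]
  total <- attr(scan, "total_tiles")
  if (is.null(total)) total <- nrow(scan)
  nf <- nrow(flagged)
  empty <- tibble::tibble(detection_id = integer(), centroid_x = numeric(),
                          centroid_y = numeric(), n_tiles = integer(),
                          max_score = numeric(), tile_ids = list())
  if (nf == 0L) {
    out <- empty
  } else {
    key <- paste(flagged$col, flagged$row)
    lookup <- new.env(parent = emptyenv())
    for (i in seq_len(nf)) assign(key[i], i, envir = lookup)
    comp <- integer(nf)
    cur <- 0L
    for (i in seq_len(nf)) {
      if (comp[i] != 0L) next
      cur <- cur + 1L
      queue <- i
      comp[i] <- cur
      while (length(queue)) {
        t <- queue[1]; queue <- queue[-1]
        for (dc in -1:1) for (dr in -1:1) {
          if (dc == 0L && dr == 0L) next
          nb <- get0(paste(flagged$col[t] + dc, flagged$row[t] + dr),
                     envir = lookup)
          if (!is.null(nb) && comp[nb] == 0L) {
            comp[nb] <- cur
            queue <- c(queue, nb)
          }
        }
      }
    }
    rows <- lapply(seq_len(cur), function(cid) {
      m <- flagged[comp == cid, , drop = FALSE]
      tibble::tibble(detection_id = cid,
                     centroid_x = mean(m$x_m), centroid_y = mean(m$y_m),
                     n_tiles = nrow(m), max_score = max(m$score),
                     tile_ids = list(m$tile_id))
    })
    out <- do.call(rbind, rows)
  }
  attr(out, "total_tiles_scanned") <- total
  attr(out, "n_flagged_tiles") <- nf
  attr(out, "alpha") <- attr(scan, "alpha")
  class(out) <- c("detection_set", class(out))
  out
}

#' Manual-review reduction report
#'
#' The fold reduction is the ratio of tiles scanned to merged candidates
#' requiring manual review — the quantity that makes region-scale manual
#' follow-up feasible.
#'
#' @param total_tiles Number of tiles scanned.
#' @param detections A `detection_set`, or a candidate count.
#' @return A `reduction_report` list: `total_candidates`, `n_for_review`,
#'   `fold_reduction` (NA with `undefined = TRUE` when there are no
#'   detections).
#' @examples
#' reduction_report(300000, 1100)$fold_reduction  # ~272.7
#' @export
reduction_report <- function(total_tiles, detections) {
  n_rev <- if (inherits(detections, "detection_set") ||
               is.data.frame(detections)) nrow(detections) else as.numeric(detections)
  structure(
    list(total_candidates = as.numeric(total_tiles),
         n_for_review = as.numeric(n_rev),
         fold_reduction = if (n_rev > 0) total_tiles / n_rev else NA_real_,
         undefined = n_rev == 0),
    class = "reduction_report")
}

#' @export
print.reduction_report <- function(x, ...) {
  cat(sprintf("<reduction_report> %s tiles -> %s for review (%s-fold reduction)\n",
              format(x$total_candidates, big.mark = ","),
              format(x$n_for_review, big.mark = ","),
              if (x$undefined) "undefined" else sprintf("%.1f", x$fold_reduction)))
  invisible(x)
}

#' Export detections for manual review
#'
#' Writes a GeoJSON FeatureCollection of centroid points (with score and
#' member-tile count) and a CSV worklist ordered by descending score.
#'
#' @param detections A `detection_set`.
#' @param geojson_path Output GeoJSON path.
#' @param csv_path Output CSV path.
#' @return Invisibly, a list of the two paths.
#' @export
export_detections <- function(detections, geojson_path, csv_path) {
  feats <- lapply(seq_len(nrow(detections)), function(i) {
    list(type = "Feature",
         properties = list(detection_id = detections$detection_id[i],
                           score = detections$max_score[i],
                           n_tiles = detections$n_tiles[i]),
         geometry = list(type = "Point",
                         coordinates = c(detections$centroid_x[i],
                                         detections$centroid_y[i])))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       geojson_path, auto_unbox = TRUE, digits = NA)
  ord <- order(detections$max_score, decreasing = TRUE)
  wl <- detections[ord, c("detection_id", "centroid_x", "centroid_y",
                          "n_tiles", "max_score")]
  utils::write.csv(as.data.frame(wl), csv_path, row.names = FALSE)
  invisible(list(geojson = geojson_path, csv = csv_path))
}

#' Read exported detections back from GeoJSON
#' @param path Path written by [export_detections()].
#' @return Tibble `(detection_id, centroid_x, centroid_y, n_tiles,
#'   max_score)`.
#' @export
read_detections_geojson <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  rows <- lapply(j$features, function(f)
    tibble::tibble(detection_id = f$properties$detection_id,
                   centroid_x = f$geometry$coordinates[[1]],
                   centroid_y = f$geometry$coordinates[[2]],
                   n_tiles = f$properties$n_tiles,
                   max_score = f$properties$score))
  if (length(rows) == 0L)
    return(tibble::tibble(detection_id = integer(), centroid_x = numeric(),
                          centroid_y = numeric(), n_tiles = integer(),
                          max_score = numeric()))
  do.call(rbind, rows)
}

# ---- experiment runners ----------------------------------------------------

# Assemble one split of a dataset as tiles + labels (+ centers for aux).
assemble_split <- function(bundle, manifest, split) {
  m <- manifest[manifest$split == split, , drop = FALSE]
  list(manifest = m,
       tiles = load_tiles(bundle, m),
       labels = m$label)
}

degrade_tiles <- function(tiles, target_resolution) {
  lapply(tiles, function(t) degrade_resolution(t, target_resolution))
}

#' Spatial-resolution ablation
#'
#' Trains and evaluates one model per target resolution on identically
#' split data with identical seeds: tiles of every split are degraded to
#' the target resolution (downsample + upsample back), a fresh model is
#' trained, and test-split metrics are recorded. Every row carries the same
#' data-split checksum, so metric differences isolate the resolution
#' effect.
#'
#' @param bundle A `scene_bundle`.
#' @param manifest Split manifest from [make_labeled_dataset()].
#' @param resolutions Target resolutions (m/pixel), each at least the
#'   scene's native resolution.
#' @param config A [training_config()].
#' @param encoder_spec Encoder name for [build_model()].
#' @return Tibble `(resolution, auprc, precision_at_recall, best_f1,
#'   selected_epoch, split_checksum)`.
#' @export
run_resolution_ablation <- function(bundle, manifest, resolutions,
                                    config = training_config(),
                                    encoder_spec = "small_cnn") {
  native <- bundle$config$resolution_m_per_px
  if (any(resolutions < native))
    stopf("all target resolutions must be >= the native %g m/px", native)
  tr <- assemble_split(bundle, manifest, "train")
  va <- assemble_split(bundle, manifest, "validation")
  te <- assemble_split(bundle, manifest, "test")
  checksum <- attr(manifest, "split_checksum")
  rows <- lapply(resolutions, function(res) {
    dtr <- degrade_tiles(tr$tiles, res)
    dva <- degrade_tiles(va$tiles, res)
    dte <- degrade_tiles(te$tiles, res)
    model <- build_model(encoder_spec, "none", 0L, seed = config$seed)
    fit <- train(model, dtr, tr$labels, dva, va$labels, config)
    scores <- predict_proba(fit$model, dte)
    rep <- metrics_report(scores, te$labels, config$target_recall)
    tibble::tibble(resolution = res, auprc = rep$auprc,
                   precision_at_recall = rep$precision_at_recall,
                   best_f1 = rep$best_f1,
                   selected_epoch = attr(fit$history, "selected_epoch"),
                   split_checksum = checksum)
  })
  do.call(rbind, rows)
}

#' Low-data ablation with GDA fusion strategies
#'
#' For each positive-count and auxiliary-data class, active-settlement
#' training examples are subsampled with a seed that depends only on the
#' count (so every strategy sees the identical subsample — a paired
#' design) while negatives are held constant. Fused cells hold out a
#' stratified GDA fitting subset from their training pool (excluded from
#' classifier training); the baseline uses the full pool. Metrics are
#' computed on the untouched test split.
#'
#' @param bundle A `scene_bundle`.
#' @param manifest Split manifest from [make_labeled_dataset()].
#' @param counts Positive-example counts to test (e.g. `c(25, 50, 75, 100)`).
#' @param strategies Auxiliary data classes: subset of
#'   `c("none", "water", "road", "water_road")`.
#' @param fusion `"aux1"`, `"aux2"` or `"aux12"` for the fused cells.
#' @param config A [training_config()].
#' @param encoder_spec Encoder name.
#' @param gda_fraction Fraction of the training pool held out to fit GDA.
#' @return Tibble with one row per (count, strategy): metrics plus the ids
#'   of the subsampled positives (as a checksum for the paired design).
#' @export
run_low_data_ablation <- function(bundle, manifest, counts,
                                  strategies = c("none", "water", "road",
                                                 "water_road"),
                                  fusion = "aux2",
                                  config = training_config(),
                                  encoder_spec = "small_cnn",
                                  gda_fraction = 0.2) {
  strategies <- match.arg(strategies, several.ok = TRUE)
  tr <- assemble_split(bundle, manifest, "train")
  va <- assemble_split(bundle, manifest, "validation")
  te <- assemble_split(bundle, manifest, "test")
  pos_idx <- which(tr$labels == 1)
  neg_idx <- which(tr$labels == 0)
  dist_all <- compute_distance_features(bundle$manifest, bundle$roads,
                                        bundle$waters)
  rows <- list()
  for (count in counts) {
    if (count > length(pos_idx))
      stopf("count %d exceeds the %d available training positives",
            count, length(pos_idx))
    sub_pos <- with_seed(config$seed + count,
                         sort(sample(pos_idx, count)))
    pool <- c(sub_pos, neg_idx)
    pool_ids <- tr$manifest$tile_id[pool]
    pos_checksum <- text_checksum(tr$manifest$tile_id[sub_pos])
    for (strat in strategies) {
      kinds <- switch(strat, none = character(),
                      water = "water", road = "road",
                      water_road = c("water", "road"))
      if (strat == "none") {
        model <- build_model(encoder_spec, "none", 0L, seed = config$seed)
        fit <- train(model, tr$tiles[pool], tr$labels[pool],
                     va$tiles, va$labels, config)
        scores <- predict_proba(fit$model, te$tiles)
      } else {
        hold <- gda_holdout_split(tr$labels[pool], gda_fraction,
                                  seed = config$seed)
        fit_ids <- pool[hold$fit]
        cls_ids <- pool[hold$train]
        rec_of <- function(ids) dist_all[match(tr$manifest$tile_id[ids],
                                               dist_all$tile_id), ]
        fit_rec <- rec_of(fit_ids)
        models <- list()
        for (k in kinds) {
          col <- paste0("d_", k, "_m")
          models[[k]] <- fit_gda(fit_rec[[col]], tr$labels[fit_ids], k)
        }
        aux_tr <- build_aux_matrix(rec_of(cls_ids), models)
        rec_va <- dist_all[match(va$manifest$tile_id, dist_all$tile_id), ]
        rec_te <- dist_all[match(te$manifest$tile_id, dist_all$tile_id), ]
        aux_va <- build_aux_matrix(rec_va, models)
        aux_te <- build_aux_matrix(rec_te, models)
        model <- build_model(encoder_spec, fusion, ncol(aux_tr),
                             seed = config$seed)
        fit <- train(model, tr$tiles[cls_ids], tr$labels[cls_ids],
                     va$tiles, va$labels, config,
                     train_aux = aux_tr, val_aux = aux_va)
        scores <- predict_proba(fit$model, te$tiles, aux = aux_te)
      }
      rep <- metrics_report(scores, te$labels, config$target_recall)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        count = count, strategy = strat, fusion = if (strat == "none") "none" else fusion,
        auprc = rep$auprc, precision_at_recall = rep$precision_at_recall,
        best_f1 = rep$best_f1, positives_checksum = pos_checksum)
    }
  }
  do.call(rbind, rows)
}
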