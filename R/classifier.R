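# The tile classifier h_theta = f_phi . E_psi: a CNN encoder mapping a tile
# to a d-dimensional embedding, a dense head mapping the embedding (plus
# optional auxiliary infrastructure features) to a probability, and the
# training loop (unweighted binary cross entropy, Adam, per-epoch AUPRC /
# precision-at-recall monitoring with best-epoch checkpointing).

# ---- encoder registry ------------------------------------------------------

.encoders <- new.env(parent = emptyenv())

#' Register an encoder architecture
#'
#' The registry makes the encoder pluggable: any constructor returning a
#' spec with fields `input_size`, `in_channels`, `channels` (per conv
#' block), `kernel`, `stride` can be registered and used by name. The
#' packaged desk-scale encoders are compact CNNs sized to train on one CPU;
#' larger backbones can be registered by the user without touching the
#' training machinery.
#'
#' @param name Encoder name.
#' @param constructor Function `(…) -> encoder spec list`.
#' @return `name`, invisibly.
#' @export
register_encoder <- function(name, constructor) {
  assign(name, constructor, envir = .encoders)
  invisible(name)
}

#' List registered encoder names
#' @return Character vector.
#' @export
list_encoders <- function() sort(ls(.encoders))

default_encoders <- function() {
  register_encoder("small_cnn", function(input_size = 64L, in_channels = 1L,
                                         channels = c(8L, 16L, 32L, 32L)) {
    list(name = "small_cnn", input_size = as.integer(input_size),
         in_channels = as.integer(in_channels),
         channels = as.integer(channels), kernel = 3L, stride = 2L)
  })
  register_encoder("tiny_cnn", function(input_size = 32L, in_channels = 1L,
                                        channels = c(6L, 12L)) {
    list(name = "tiny_cnn", input_size = as.integer(input_size),
         in_channels = as.integer(in_channels),
         channels = as.integer(channels), kernel = 3L, stride = 2L)
  })
}

# ---- loss ------------------------------------------------------------------

#' Unweighted binary cross-entropy loss
#'
#' Mean over the batch of `-[y log h + (1 - y) log(1 - h)]`; probabilities
#' are clamped away from 0/1 before taking logs.
#'
#' @param probabilities Predicted probabilities in `(0, 1)`.
#' @param labels Binary labels of equal length.
#' @return Scalar loss.
#' @examples
#' bce_loss(0.5, 1)  # log(2)
#' @export
bce_loss <- function(probabilities, labels) {
  if (length(probabilities) != length(labels))
    stopf("probabilities and labels differ in length")
  if (!all(labels %in% c(0, 1))) stopf("labels must be binary (0/1)")
  h <- clamp(probabilities, 1e-12, 1 - 1e-12)
  -mean(labels * log(h) + (1 - labels) * log(1 - h))
}

# ---- model construction ----------------------------------------------------

#' Build a tile classifier
#'
#' @param encoder_spec Name of a registered encoder (default `"small_cnn"`,
#'   a 4-block CNN on 64 x 64 inputs) or a spec list from a registered
#'   constructor.
#' @param fusion_strategy `"none"`, `"aux1"`, `"aux2"` or `"aux12"`; see
#'   [fusion_spec()].
#' @param aux_dim Auxiliary feature dimension (0 for `"none"`).
#' @param seed Integer seed for weight initialization; identical spec and
#'   seed give identical initial weights.
#' @param encoder_args Arguments passed to the encoder constructor.
#' @return A `settlement_classifier`.
#' @export
build_model <- function(encoder_spec = "small_cnn",
                        fusion_strategy = c("none", "aux1", "aux2", "aux12"),
                        aux_dim = 0L, seed = 0,
                        encoder_args = list()) {
  fusion_strategy <- match.arg(fusion_strategy)
  if (is.character(encoder_spec)) {
    ctor <- get0(encoder_spec, envir = .encoders)
    if (is.null(ctor)) stopf("unknown encoder '%s'; see list_encoders()", encoder_spec)
    enc <- do.call(ctor, encoder_args)
  } else enc <- encoder_spec

  caches <- list()
  in_h <- enc$input_size; in_w <- enc$input_size; c_in <- enc$in_channels
  for (l in seq_along(enc$channels)) {
    caches[[l]] <- conv_cache(in_h, in_w, c_in, enc$channels[l],
                              enc$kernel, enc$stride)
    in_h <- caches[[l]]$out_h; in_w <- caches[[l]]$out_w
    c_in <- enc$channels[l]
  }
  embed_dim <- enc$channels[length(enc$channels)]
  fus <- fusion_spec(fusion_strategy, embed_dim, aux_dim)

  params <- with_seed(seed, {
    p <- list()
    for (l in seq_along(caches)) {
      ch <- caches[[l]]
      p[[paste0("conv", l, "_W")]] <-
        matrix(stats::rnorm(ch$c_out * ch$k2c, 0, sqrt(2 / ch$k2c)),
               ch$c_out, ch$k2c)
      p[[paste0("conv", l, "_b")]] <- matrix(0, ch$c_out, 1)
    }
    m <- fus$head_input_dim
    p$head_W <- matrix(stats::rnorm(m, 0, sqrt(1 / m)), 1, m)
    p$head_b <- matrix(0, 1, 1)
    if (!is.null(fus$combiner_input_dim)) {
      # start at the identity on the image logit so fusion begins at the
      # baseline operating point and learns the aux contribution
      p$comb_W <- matrix(c(1, rep(0, fus$aux_dim)), 1, fus$combiner_input_dim)
      p$comb_b <- matrix(0, 1, 1)
    }
    p
  })

  n_params <- sum(vapply(params, length, 1L))
  structure(
    list(encoder = enc, fusion = fus, caches = caches, params = params,
         n_params = n_params, seed = as.integer(seed),
         provenance = character()),
    class = "settlement_classifier")
}

#' @export
print.settlement_classifier <- function(x, ...) {
  cat(sprintf(
    "<settlement_classifier> encoder=%s (%d px, %d blocks, d=%d), fusion=%s (k=%d), %d parameters\n",
    x$encoder$name, x$encoder$input_size, length(x$encoder$channels),
    x$fusion$embed_dim, x$fusion$strategy, x$fusion$aux_dim, x$n_params))
  if (length(x$provenance))
    cat("  provenance:", paste(x$provenance, collapse = " -> "), "\n")
  invisible(x)
}

# ---- input preparation -----------------------------------------------------

#' Prepare tiles as a model input matrix
#'
#' Tiles are resized (area-averaged) to the encoder input size and
#' flattened; pixel values are expected already normalized to `[0, 1]`.
#'
#' @param model A `settlement_classifier`.
#' @param tiles List of `image_tile` objects or plain pixel matrices.
#' @return Numeric matrix `(input_size^2 * channels) x n_tiles`.
#' @export
prepare_inputs <- function(model, tiles) {
  sz <- model$encoder$input_size
  cols <- lapply(tiles, function(t) {
    m <- if (inherits(t, "image_tile")) t$pixels else t
    if (!is.matrix(m)) stopf("tiles must be matrices or image_tile objects")
    if (nrow(m) != sz || ncol(m) != sz)
      m <- resize_image(m, sz, sz)
    as.vector(m)  # column-major = channel-fastest layout with C = 1
  })
  matrix(unlist(cols), ncol = length(cols))
}

# Forward pass to probabilities. X prepared; aux (k x B) or NULL.
model_forward <- function(model, X, aux = NULL, keep = FALSE) {
  fus <- model$fusion
  B <- ncol(X)
  if (fus$strategy != "none") {
    if (is.null(aux))
      stopf("model uses fusion strategy '%s' but no auxiliary features were supplied",
            fus$strategy)
    aux <- matrix(aux, nrow = fus$aux_dim, ncol = B)
  } else if (!is.null(aux)) {
    stopf("baseline model (fusion 'none') takes no auxiliary features")
  }
  ef <- encoder_forward(model$params, model$caches, X, keep = keep)
  F_in <- if (fus$strategy %in% c("aux2", "aux12")) rbind(ef$Z, aux) else ef$Z
  logit0 <- model$params$head_W %*% F_in +
    model$params$head_b[1, 1]
  if (!is.null(fus$combiner_input_dim)) {
    G <- rbind(logit0, aux)
    logit <- model$params$comb_W %*% G + model$params$comb_b[1, 1]
  } else {
    G <- NULL
    logit <- logit0
  }
  probs <- stats::plogis(as.vector(logit))
  list(probs = probs, Z = ef$Z, acts = ef$acts, F_in = F_in,
       logit0 = logit0, G = G)
}

#' Predict active-settlement probabilities for tiles
#'
#' Inference is deterministic given fixed weights, and scores are
#' independent of how tiles are batched.
#'
#' @param model A `settlement_classifier`.
#' @param tiles List of tiles or a prepared input matrix.
#' @param aux Auxiliary feature matrix (tiles x k) when the model fuses
#'   auxiliary features; an error otherwise.
#' @param batch_size Tiles per forward pass.
#' @return Numeric vector of probabilities in `(0, 1)`.
#' @export
predict_proba <- function(model, tiles, aux = NULL, batch_size = 64L) {
  X <- if (is.matrix(tiles)) tiles else prepare_inputs(model, tiles)
  n <- ncol(X)
  if (!is.null(aux)) {
    aux <- as.matrix(aux)
    if (nrow(aux) != n && ncol(aux) == n) aux <- t(aux)
    if (nrow(aux) != n)
      stopf("aux has %d rows but there are %d tiles", nrow(aux), n)
  }
  out <- numeric(n)
  for (b0 in seq(1L, n, by = batch_size)) {
    b1 <- min(b0 + batch_size - 1L, n)
    a <- if (is.null(aux)) NULL else t(aux[b0:b1, , drop = FALSE])
    out[b0:b1] <- model_forward(model, X[, b0:b1, drop = FALSE], a)$probs
  }
  out
}

# ---- training --------------------------------------------------------------

#' Training configuration
#'
#' Defaults follow the training recipe the method was developed with: Adam,
#' batch size 16, learning rate 0.001, up to 40 epochs, with per-epoch
#' validation AUPRC and precision at 0.95 recall monitored and the best
#' epoch (by the configured selection metric) checkpointed. There is no
#' early stopping and no class weighting (the objective is unweighted).
#'
#' @param batch_size Minibatch size (default 16).
#' @param learning_rate Adam learning rate (default 0.001).
#' @param max_epochs Maximum epochs (default 40).
#' @param optimizer Only `"adam"` is implemented.
#' @param seed Seed for shuffling (training is fully reproducible).
#' @param selection_metric `"auprc"` or `"precision_at_recall"`.
#' @param target_recall Recall target for the monitored precision metric.
#' @return A `training_config` list.
#' @export
training_config <- function(batch_size = 16L, learning_rate = 0.001,
                            max_epochs = 40L, optimizer = "adam",
                            seed = 0L,
                            selection_metric = c("auprc", "precision_at_recall"),
                            target_recall = 0.95) {
  selection_metric <- match.arg(selection_metric)
  check_number(batch_size, "batch_size", positive = TRUE)
  check_number(learning_rate, "learning_rate", positive = TRUE)
  check_number(max_epochs, "max_epochs", min = 0)
  if (optimizer != "adam") stopf("only the adam optimizer is implemented")
  structure(list(batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs), optimizer = optimizer,
                 seed = as.integer(seed), selection_metric = selection_metric,
                 target_recall = target_recall),
            class = "training_config")
}

#' Select the best epoch from a training history
#'
#' @param history Tibble with per-epoch `val_auprc` and
#'   `val_precision_at_recall` columns.
#' @param metric `"auprc"` or `"precision_at_recall"`.
#' @return The 1-based epoch index maximizing the metric (first maximum on
#'   ties), so selection is reproducible from a saved history.
#' @export
select_epoch <- function(history, metric = c("auprc", "precision_at_recall")) {
  metric <- match.arg(metric)
  col <- if (metric == "auprc") "val_auprc" else "val_precision_at_recall"
  which.max(history[[col]])
}

# One optimization pass + per-epoch monitoring. Internal core shared by
# train() and fine_tune().
run_training <- function(model, train_x, train_y, val_x, val_y, config,
                         train_aux = NULL, val_aux = NULL, run_label = "train") {
  if (model$fusion$strategy != "none" &&
      (is.null(train_aux) || is.null(val_aux)))
    stopf("fusion strategy '%s' requires aux features for every tile",
          model$fusion$strategy)
  X <- if (is.matrix(train_x)) train_x else prepare_inputs(model, train_x)
  Xv <- if (is.matrix(val_x)) val_x else prepare_inputs(model, val_x)
  n <- ncol(X)
  if (length(train_y) != n) stopf("train labels do not match tiles")
  if (!is.null(train_aux)) {
    train_aux <- as.matrix(train_aux)
    if (nrow(train_aux) != n) stopf("train aux does not match tiles")
  }
  params <- model$params
  state <- adam_init(params)
  hist <- list()
  best_metric <- -Inf; best_params <- params; best_epoch <- 0L
  metric_col <- config$selection_metric
  set.seed(config$seed)
  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample.int(n)
    epoch_loss <- 0; n_batches <- 0L
    for (b0 in seq(1L, n, by = config$batch_size)) {
      b1 <- min(b0 + config$batch_size - 1L, n)
      sel <- ord[b0:b1]
      Xb <- X[, sel, drop = FALSE]
      yb <- train_y[sel]
      ab <- if (is.null(train_aux)) NULL else t(train_aux[sel, , drop = FALSE])
      model$params <- params
      fw <- model_forward(model, Xb, ab, keep = TRUE)
      loss <- bce_loss(fw$probs, yb)
      if (!is.finite(loss))
        stopf("non-finite loss at epoch %d; aborting (inspect learning rate/inputs)", epoch)
      epoch_loss <- epoch_loss + loss; n_batches <- n_batches + 1L
      grads <- backward_pass(model, fw, Xb, yb, ab)
      upd <- adam_step(params, grads, state, config$learning_rate)
      params <- upd$params; state <- upd$state
    }
    model$params <- params
    val_scores <- predict_proba(model, Xv, aux = val_aux)
    vm <- metrics_report(val_scores, val_y, config$target_recall)
    row <- tibble::tibble(
      epoch = epoch,
      train_loss = epoch_loss / n_batches,
      val_auprc = vm$auprc,
      val_precision_at_recall = vm$precision_at_recall)
    hist[[epoch]] <- row
    cur <- if (metric_col == "auprc") vm$auprc else vm$precision_at_recall
    if (cur > best_metric) {
      best_metric <- cur; best_params <- params; best_epoch <- epoch
    }
  }
  history <- if (length(hist)) do.call(rbind, hist) else
    tibble::tibble(epoch = integer(), train_loss = numeric(),
                   val_auprc = numeric(), val_precision_at_recall = numeric())
  attr(history, "selected_epoch") <- best_epoch
  attr(history, "selection_metric") <- metric_col
  if (best_epoch > 0L) model$params <- best_params
  model$provenance <- c(model$provenance,
                        sprintf("%s-seed%d-ep%d", run_label, config$seed,
                                config$max_epochs))
  list(model = model, history = history)
}

# Gradients of the mean BCE loss w.r.t. all parameters.
backward_pass <- function(model, fw, Xb, yb, ab) {
  fus <- model$fusion
  B <- length(yb)
  dlogit <- matrix(fw$probs - yb, 1, B) / B
  grads <- list()
  if (!is.null(fus$combiner_input_dim)) {
    grads$comb_W <- dlogit %*% t(fw$G)
    grads$comb_b <- matrix(sum(dlogit), 1, 1)
    dG <- t(model$params$comb_W) %*% dlogit
    dlogit0 <- dG[1, , drop = FALSE]
  } else {
    dlogit0 <- dlogit
  }
  grads$head_W <- dlogit0 %*% t(fw$F_in)
  grads$head_b <- matrix(sum(dlogit0), 1, 1)
  dF <- t(model$params$head_W) %*% dlogit0
  d <- fus$embed_dim
  dZ <- dF[seq_len(d), , drop = FALSE]
  c(grads, encoder_backward(model$params, model$caches, dZ, fw$acts, B))
}

#' Train a tile classifier
#'
#' Minimizes the unweighted BCE objective with Adam; at the end of each
#' epoch the validation AUPRC and precision at the target recall are
#' recorded, and the weights of the epoch maximizing the configured
#' selection metric are returned. All randomness is seeded, so identical
#' configurations reproduce identical histories.
#'
#' @param model A `settlement_classifier` from [build_model()].
#' @param train_tiles,val_tiles Lists of tiles (or prepared input
#'   matrices); train and validation sets must be disjoint.
#' @param train_labels,val_labels Binary label vectors.
#' @param config A [training_config()].
#' @param train_aux,val_aux Aux feature matrices (tiles x k); required when
#'   the model fuses auxiliary features.
#' @return List with `model` (best-epoch weights) and `history` (tibble
#'   with attribute `selected_epoch`).
#' @export
train <- function(model, train_tiles, train_labels, val_tiles, val_labels,
                  config = training_config(), train_aux = NULL, val_aux = NULL) {
  run_training(model, train_tiles, train_labels, val_tiles, val_labels,
               config, train_aux, val_aux, run_label = "train")
}

#' Fine-tune a pretrained classifier on a new dataset
#'
#' Training resumes from the supplied model's weights; the run is appended
#' to the model's provenance so pretrain and fine-tune runs are both
#' recorded. With `max_epochs = 0` the model is returned unchanged.
#'
#' @inheritParams train
#' @return List with `model` and `history`.
#' @export
fine_tune <- function(model, train_tiles, train_labels, val_tiles, val_labels,
                      config = training_config(), train_aux = NULL,
                      val_aux = NULL) {
  if (config$max_epochs == 0L) {
    model$provenance <- c(model$provenance,
                          sprintf("finetune-seed%d-ep0", config$seed))
    return(list(model = model,
                history = tibble::tibble(epoch = integer(),
                                         train_loss = numeric(),
                                         val_auprc = numeric(),
                                         val_precision_at_recall = numeric())))
  }
  run_training(model, train_tiles, train_labels, val_tiles, val_labels,
               config, train_aux, val_aux, run_label = "finetune")
}

# ---- checkpointing ---------------------------------------------------------

#' Save a model checkpoint (weights as CSV-free plain JSON + sidecar)
#'
#' Weights and the architecture/fusion description are written to a single
#' JSON file so checkpoints are plain text and portable.
#'
#' @param model A `settlement_classifier`.
#' @param path Output `.json` path.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path) {
  obj <- list(
    encoder = model$encoder,
    fusion = unclass(model$fusion),
    seed = model$seed,
    provenance = model$provenance,
    params = lapply(model$params, function(p)
      list(dim = dim(p), values = as.vector(p))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a model checkpoint
#' @param path Path written by [save_checkpoint()].
#' @return A `settlement_classifier`.
#' @export
load_checkpoint <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  enc <- obj$encoder
  enc$channels <- as.integer(enc$channels)
  model <- build_model(encoder_spec = enc,
                       fusion_strategy = obj$fusion$strategy,
                       aux_dim = obj$fusion$aux_dim, seed = obj$seed)
  stored <- obj$params
  for (nm in names(stored)) {
    if (is.null(model$params[[nm]]))
      stopf("checkpoint parameter '%s' does not fit the architecture", nm)
    d_new <- dim(model$params[[nm]])
    d_old <- as.integer(stored[[nm]]$dim)
    if (!identical(d_new, d_old))
      stopf("shape mismatch for '%s': checkpoint %s vs model %s",
            nm, paste(d_old, collapse = "x"), paste(d_new, collapse = "x"))
    model$params[[nm]] <- matrix(stored[[nm]]$values, d_old[1], d_old[2])
  }
  model$provenance <- as.character(obj$provenance)
  model
}

#' Write a training history to CSV
#' @param history History tibble from [train()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_history_csv <- function(history, path) {
  utils::write.csv(history, path, row.names = FALSE)
  invisible(path)
}
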