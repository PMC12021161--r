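# Class-conditional Gaussian models of infrastructure distance and their
# fusion into the tile classifier.
#
# The generative model: the active-settlement label y ~ Bernoulli(xi), and
# the distance D to the nearest road (or waterway) is conditionally normal,
# D | y = 0 ~ N(mu0, sigma0^2) and D | y = 1 ~ N(mu1, sigma1^2). Parameters
# are maximum-likelihood estimates, whose asymptotic efficiency is the
# reason the approach holds up with few labeled positives. Bayes' rule turns
# a distance into P(y = 1 | d), and the pair of class densities plus the
# posterior are used as auxiliary features for the image classifier.
#
# Distances are nonnegative in reality but are modeled with untruncated
# normals, exactly as in the generative formulation above; the approximation
# is mild whenever mu_c is a few sigma_c above zero.

VAR_FLOOR <- 1.0  # (1 m)^2; the MLE is degenerate at zero variance

#' Fit a class-conditional Gaussian distance model
#'
#' Maximum-likelihood estimation: class means are sample means, class
#' variances are the MLE (divide by n_c, floored at (1 m)^2), and the
#' prevalence `xi` is the fraction of label-1 samples in the fitting set.
#'
#' @param distances Numeric vector of nearest-infrastructure distances (m).
#' @param labels Binary vector (1 = active settlement) of equal length.
#' @param infra_kind `"road"` or `"water"`.
#' @return A `gda_model` with fields `xi`, `mu0`, `mu1`, `var0`, `var1`,
#'   `infra_kind`, `n0`, `n1` plus the distance range of the fitting set
#'   (used by the raw-distance ablation mode).
#' @examples
#' m <- fit_gda(c(0, 2, 10, 14), c(1, 1, 0, 0), "road")
#' posterior_probability(m, 5)
#' @export
fit_gda <- function(distances, labels, infra_kind = c("road", "water")) {
  infra_kind <- match.arg(infra_kind)
  if (length(distances) != length(labels)) stopf("distances and labels differ in length")
  if (!all(labels %in% c(0, 1))) stopf("labels must be binary (0/1)")
  if (!all(is.finite(distances)) || any(distances < 0))
    stopf("distances must be finite and >= 0")
  d1 <- distances[labels == 1]
  d0 <- distances[labels == 0]
  if (length(d1) == 0L || length(d0) == 0L)
    stopf("both classes must be present to fit a GDA model")
  if (length(d1) < 2L || length(d0) < 2L)
    stopf("need >= 2 samples per class (got %d positive, %d negative)",
          length(d1), length(d0))
  mle_var <- function(x) max(mean((x - mean(x))^2), VAR_FLOOR)
  structure(
    list(xi = length(d1) / length(distances),
         mu0 = mean(d0), mu1 = mean(d1),
         var0 = mle_var(d0), var1 = mle_var(d1),
         infra_kind = infra_kind,
         n0 = length(d0), n1 = length(d1),
         d_min = min(distances), d_max = max(distances)),
    class = "gda_model")
}

#' @export
print.gda_model <- function(x, ...) {
  cat(sprintf(
    "<gda_model:%s> xi=%.3f  active: N(%.1f, %.1f^2) n=%d  other: N(%.1f, %.1f^2) n=%d\n",
    x$infra_kind, x$xi, x$mu1, sqrt(x$var1), x$n1, x$mu0, sqrt(x$var0), x$n0))
  invisible(x)
}

#' Posterior probability of an active settlement given a distance
#'
#' Bayes' rule with the two fitted normal densities and the Bernoulli prior,
#' evaluated through log-density differences for numerical stability:
#' `P(y=1|d) = p(d|1) xi / (p(d|0)(1-xi) + p(d|1) xi)`.
#'
#' @param model A fitted [fit_gda()] model.
#' @param d Distance(s) in meters (vectorized).
#' @return Posterior probabilities in `[0, 1]`.
#' @export
posterior_probability <- function(model, d) {
  if (!inherits(model, "gda_model")) stopf("`model` must be a gda_model")
  llr <- stats::dnorm(d, model$mu1, sqrt(model$var1), log = TRUE) -
         stats::dnorm(d, model$mu0, sqrt(model$var0), log = TRUE)
  stats::plogis(stats::qlogis(model$xi) + llr)
}

#' Hold out a stratified subset for GDA fitting
#'
#' The GDA model is fit on a label-stratified subset of the training pool
#' which is then excluded from classifier training, so the auxiliary
#' features seen by the classifier are never computed on the data that
#' produced them.
#'
#' @param labels Binary label vector for the training pool.
#' @param fraction Fraction (default 0.2) withheld for GDA fitting.
#' @param seed Integer seed.
#' @return List with integer index vectors `fit` (GDA fitting subset) and
#'   `train` (remainder, for the classifier).
#' @export
gda_holdout_split <- function(labels, fraction = 0.2, seed = 0) {
  if (fraction <= 0 || fraction >= 1) stopf("`fraction` must be in (0, 1)")
  idx1 <- which(labels == 1); idx0 <- which(labels == 0)
  n1 <- max(2L, as.integer(round(length(idx1) * fraction)))
  n0 <- max(2L, as.integer(round(length(idx0) * fraction)))
  if (n1 >= length(idx1) || n0 >= length(idx0))
    stopf("training pool too small to hold out a GDA fitting subset")
  fit <- with_seed(seed, c(sample(idx1, n1), sample(idx0, n0)))
  list(fit = sort(fit), train = setdiff(seq_along(labels), sort(fit)))
}

#' Auxiliary feature vector for one distance record
#'
#' In `"gda"` mode each requested infrastructure kind contributes three
#' features in fixed order: the class-0 density `p(d|y=0)`, the class-1
#' density `p(d|y=1)`, and the posterior `P(y=1|d)`. Densities are fed in
#' unit-peak form (scaled by their `sigma * sqrt(2*pi)`, i.e.
#' `exp(-(d - mu)^2 / (2 sigma^2))`, a fixed monotone rescale to `[0, 1]`)
#' so all auxiliary inputs share the probability scale the classifier head
#' conditions well on. In `"raw_distance"` mode (the ablation without GDA
#' preprocessing) each kind contributes a single min-max-normalized
#' distance instead. Kinds appear in the order of `names(models)`.
#'
#' @param models Named list of [fit_gda()] models (e.g.
#'   `list(water = ..., road = ...)`).
#' @param record One-row data frame / list with `d_road_m` and/or
#'   `d_water_m` as required by `models`.
#' @param mode `"gda"` or `"raw_distance"`.
#' @return Named numeric feature vector (length `3 * n_kinds` or `n_kinds`).
#' @export
build_aux_features <- function(models, record, mode = c("gda", "raw_distance")) {
  mode <- match.arg(mode)
  if (length(models) == 0L) stopf("no GDA models supplied")
  kinds <- names(models)
  if (is.null(kinds) || any(!nzchar(kinds)))
    stopf("`models` must be a named list (names give the feature order)")
  out <- c()
  for (k in kinds) {
    m <- models[[k]]
    if (!inherits(m, "gda_model"))
      stopf("missing or invalid GDA model for kind '%s'", k)
    col <- paste0("d_", m$infra_kind, "_m")
    d <- record[[col]]
    if (is.null(d) || !is.finite(d))
      stopf("record lacks a finite distance column '%s'", col)
    if (mode == "gda") {
      v <- c(exp(-(d - m$mu0)^2 / (2 * m$var0)),
             exp(-(d - m$mu1)^2 / (2 * m$var1)),
             posterior_probability(m, d))
      names(v) <- paste0(k, c("_p0", "_p1", "_posterior"))
    } else {
      rng <- m$d_max - m$d_min
      v <- if (rng > 0) clamp((d - m$d_min) / rng, 0, 1) else 0
      names(v) <- paste0(k, "_norm_distance")
    }
    out <- c(out, v)
  }
  out
}

#' Auxiliary feature matrix for many distance records
#' @param models Named list of [fit_gda()] models.
#' @param records Tibble from [compute_distance_features()].
#' @param mode `"gda"` or `"raw_distance"`.
#' @return Numeric matrix, one row per record, columns as in
#'   [build_aux_features()].
#' @export
build_aux_matrix <- function(records, models, mode = c("gda", "raw_distance")) {
  mode <- match.arg(mode)
  rows <- lapply(seq_len(nrow(records)), function(i)
    build_aux_features(models, records[i, , drop = FALSE], mode))
  out <- do.call(rbind, rows)
  rownames(out) <- records$tile_id
  out
}

#' Fusion wiring specification
#'
#' Declares how auxiliary features enter the classifier. `aux2` concatenates
#' the aux vector (length `k`) to the global-average-pooled embedding (head
#' input dimension `d + k`); `aux1` concatenates it to the pre-sigmoid class
#' logit, which a small learned linear combiner maps back to a scalar logit
#' (concatenation + combiner rather than arithmetic addition: the aux
#' entries are densities/probabilities, not logits, so adding them to a
#' logit would be scale-incoherent); `aux12` applies both simultaneously;
#' `none` is the pass-through baseline.
#'
#' @param strategy One of `"none"`, `"aux1"`, `"aux2"`, `"aux12"`.
#' @param embed_dim Embedding dimension `d` of the encoder.
#' @param aux_dim Auxiliary feature dimension `k` (0 for `"none"`).
#' @return A `fusion_spec` list with `head_input_dim` and
#'   `combiner_input_dim` (NULL when no combiner is used).
#' @export
fusion_spec <- function(strategy = c("none", "aux1", "aux2", "aux12"),
                        embed_dim, aux_dim = 0L) {
  strategy <- match.arg(strategy)
  check_number(embed_dim, "embed_dim", positive = TRUE)
  check_number(aux_dim, "aux_dim", min = 0)
  if (strategy == "none" && aux_dim != 0L)
    stopf("strategy 'none' takes no auxiliary features (aux_dim must be 0)")
  if (strategy != "none" && aux_dim < 1L)
    stopf("fusion strategy '%s' requires aux_dim >= 1", strategy)
  structure(
    list(strategy = strategy,
         embed_dim = as.integer(embed_dim),
         aux_dim = as.integer(aux_dim),
         head_input_dim = as.integer(embed_dim +
                                       if (strategy %in% c("aux2", "aux12")) aux_dim else 0L),
         combiner_input_dim = if (strategy %in% c("aux1", "aux12"))
           as.integer(1L + aux_dim) else NULL),
    class = "fusion_spec")
}

# ---- serialization ---------------------------------------------------------

#' Write a GDA model to JSON
#' @param model A `gda_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gda_json <- function(model, path) {
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a GDA model from JSON
#' @param path Path written by [write_gda_json()].
#' @return A `gda_model`.
#' @export
read_gda_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(j, class = "gda_model")
}
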