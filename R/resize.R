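# Deterministic image resampling used throughout the pipeline.
#
# Downsampling uses exact area averaging (each output pixel is the mean of
# the input area it covers), which models the footprint averaging of a
# coarser sensor. Upsampling uses bilinear interpolation. Both are expressed
# as small weight-matrix products so results are reproducible and easy to
# reason about.

# Row-weight matrix for area-averaging n_in pixels into n_out pixels.
# W[i, j] = |overlap of output cell i with input pixel j| / cell width.
area_weights <- function(n_in, n_out) {
  s <- n_in / n_out
  lo <- (seq_len(n_out) - 1) * s
  hi <- seq_len(n_out) * s
  W <- matrix(0, n_out, n_in)
  for (i in seq_len(n_out)) {
    j0 <- floor(lo[i]) + 1
    j1 <- min(ceiling(hi[i]), n_in)
    j <- j0:j1
    ov <- pmin(hi[i], j) - pmax(lo[i], j - 1)
    W[i, j] <- pmax(ov, 0) / s
  }
  W
}

# Row-weight matrix for bilinear sampling (pixel-center aligned, edges clamped).
bilinear_weights <- function(n_in, n_out) {
  pos <- (seq_len(n_out) - 0.5) * n_in / n_out  # in input-pixel units
  x <- pos - 0.5                                 # input pixel j has center j - 0.5
  j0 <- clamp(floor(x), 0, n_in - 1)
  j1 <- clamp(j0 + 1, 0, n_in - 1)
  t <- clamp(x - j0, 0, 1)
  W <- matrix(0, n_out, n_in)
  idx <- seq_len(n_out)
  W[cbind(idx, j0 + 1)] <- W[cbind(idx, j0 + 1)] + (1 - t)
  W[cbind(idx, j1 + 1)] <- W[cbind(idx, j1 + 1)] + t
  W
}

resize_matrix <- function(img, out_h, out_w, method = c("area", "bilinear")) {
  method <- match.arg(method)
  wfun <- if (method == "area") area_weights else bilinear_weights
  Wr <- wfun(nrow(img), out_h)
  Wc <- wfun(ncol(img), out_w)
  Wr %*% img %*% t(Wc)
}

#' Resize an image array
#'
#' Area-averaging is used for reduction, bilinear interpolation for
#' enlargement (selected automatically unless `method` is given). Works on
#' matrices (single band) and H x W x C arrays.
#'
#' @param img Numeric matrix or 3-d array with values in `[0, 1]`.
#' @param out_h,out_w Output dimensions in pixels.
#' @param method `"area"`, `"bilinear"`, or `"auto"` (default).
#' @return Resized matrix or array.
#' @export
resize_image <- function(img, out_h, out_w, method = c("auto", "area", "bilinear")) {
  method <- match.arg(method)
  if (method == "auto")
    method <- if (out_h <= dim(img)[1]) "area" else "bilinear"
  if (is.matrix(img)) return(resize_matrix(img, out_h, out_w, method))
  if (length(dim(img)) == 3L) {
    out <- array(0, c(out_h, out_w, dim(img)[3]))
    for (c in seq_len(dim(img)[3]))
      out[, , c] <- resize_matrix(img[, , c], out_h, out_w, method)
    return(out)
  }
  stopf("`img` must be a matrix or an H x W x C array")
}
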