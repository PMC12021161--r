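# Internal helpers shared across modules.

#' Run an expression with a temporary RNG seed
#'
#' Saves and restores the global RNG state so that seeded helpers do not
#' perturb the caller's random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# round-half-up to nearest integer (base round() is banker's rounding)
round_half_up <- function(x) floor(x + 0.5)

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_number <- function(x, name, positive = FALSE, min = NULL) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("`%s` must be a single finite number", name)
  if (positive && x <= 0) stopf("`%s` must be > 0", name)
  if (!is.null(min) && x < min) stopf("`%s` must be >= %s", name, min)
  invisible(x)
}

# Cheap deterministic checksum for plain-text content (no binary deps):
# polynomial rolling hash over the UTF-8 bytes, modulo 2^31 - 1.
text_checksum <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\x1f"))
  m <- 2147483647
  h <- 17
  for (b in bytes) h <- (h * 257 + b) %% m  # 257 * 2^31 < 2^53: exact in doubles
  as.integer(h)
}
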