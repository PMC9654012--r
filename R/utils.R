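# Internal helpers shared across modules.

usnlm_abort <- function(message, class, ...) {
  abort(message, class = c(paste0("usnlm_error_", class), "usnlm_error"), ...)
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

#' Reflect an index vector into `1:n`
#'
#' Symmetric ("mirror with edge repeated") reflection, the boundary rule used
#' by every window operation in the package: index 0 maps to 1, index -1 to 2,
#' index n+1 to n, and so on.
#'
#' @param idx integer vector of (possibly out-of-range) indices.
#' @param n axis length.
#' @return integer vector of the same length, all values in `1:n`.
#' @keywords internal
#' @noRd
reflect_index <- function(idx, n) {
  if (n == 1L) {
    return(rep(1L, length(idx)))
  }
  period <- 2L * n
  k <- (as.integer(idx) - 1L) %% period
  ifelse(k >= n, period - k, k + 1L)
}

# Pad a matrix by `p` pixels on every side using reflected (symmetric) copies.
pad_reflect <- function(x, p) {
  ri <- reflect_index(seq.int(1L - p, nrow(x) + p), nrow(x))
  ci <- reflect_index(seq.int(1L - p, ncol(x) + p), ncol(x))
  x[ri, ci, drop = FALSE]
}

# Sliding-window sum / mean over a (2r+1)^2 window with reflected padding,
# via a summed-area table.  O(n) regardless of r.
box_sum <- function(x, r) {
  n <- nrow(x)
  m <- ncol(x)
  w <- 2L * r + 1L
  p <- pad_reflect(x, r)
  s <- rbind(0, apply(p, 2L, cumsum))
  s <- cbind(0, t(apply(s, 1L, cumsum)))
  s[(1:n) + w, (1:m) + w, drop = FALSE] -
    s[1:n, (1:m) + w, drop = FALSE] -
    s[(1:n) + w, 1:m, drop = FALSE] +
    s[1:n, 1:m, drop = FALSE]
}

box_mean <- function(x, r) box_sum(x, r) / (2 * r + 1)^2

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_fixed_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a per-stage seed from a master seed
#'
#' Mixes a master seed with a stage name so that each stochastic stage of a
#' pipeline gets its own reproducible stream and can be rerun in isolation.
#' The result is always a positive integer below 2^31 - 1.
#'
#' @param seed master seed (integer).
#' @param stage stage name (string).
#' @return integer seed.
#' @export
#' @examples
#' stage_seed(7, "speckle")
stage_seed <- function(seed, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  codes <- utf8ToInt(stage)
  h <- sum(as.double(codes) * seq_along(codes) * 131)
  as.integer((abs(as.double(seed)) * 48271 + h) %% 2147483646) + 1L
}
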