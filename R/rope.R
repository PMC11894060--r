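# Rotary positional encoding.

#' Apply rotary positional encoding to a vector
#'
#' Rotates consecutive dimension pairs (1,2), (3,4), ... of `vec` by
#' angle `position * theta^(-2*(i-1)/d)` for pair `i`. Rotation preserves
#' the norm, position 0 is the identity, and inner products of rotated
#' query/key vectors depend only on the relative position offset, which
#' is what makes the encoding compatible with causal attention.
#'
#' @param vec Numeric vector of even length.
#' @param position Non-negative integer position.
#' @param theta Base of the geometric frequency progression (default
#'   10000).
#' @return Rotated vector, same length as `vec`.
#' @examples
#' apply_rotary(c(1, 0), position = 0)
#' @export
apply_rotary <- function(vec, position, theta = 10000) {
  d <- length(vec)
  if (d %% 2L != 0L) stop("rotary encoding needs an even dimension")
  freqs <- theta^(-(2 * (seq_len(d / 2) - 1)) / d)
  ang <- position * freqs
  co <- rep(cos(ang), each = 2)
  si <- rep(sin(ang), each = 2)
  vec * co + rotate_half(vec) * si
}

# pairwise (x1, x2) -> (-x2, x1), vector or row-matrix layout
rotate_half <- function(x) {
  if (is.matrix(x)) {
    out <- x
    even <- seq(2, ncol(x), by = 2)
    odd <- even - 1L
    out[, odd] <- -x[, even]
    out[, even] <- x[, odd]
    out
  } else {
    out <- x
    even <- seq(2, length(x), by = 2)
    odd <- even - 1L
    out[odd] <- -x[even]
    out[even] <- x[odd]
    out
  }
}

# cos/sin tables for a vector of 0-based positions (rows) across one
# head dimension dh; returns list(co, si) of n x dh matrices.
rope_tables <- function(positions, dh, theta) {
  freqs <- theta^(-(2 * (seq_len(dh / 2) - 1)) / dh)
  ang <- outer(positions, freqs) # n x dh/2
  idx <- rep(seq_len(dh / 2), each = 2)
  list(co = cos(ang)[, idx, drop = FALSE],
       si = sin(ang)[, idx, drop = FALSE])
}

rope_rows <- function(x, tab) x * tab$co + rotate_half(x) * tab$si
rope_rows_bwd <- function(g, tab) g * tab$co - rotate_half(g) * tab$si
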