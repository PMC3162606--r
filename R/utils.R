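#' Wrap angles to (-pi, pi]
#'
#' @param x numeric vector of angles in radians.
#' @return angles wrapped to the principal interval.
#' @keywords internal
#' @noRd
wrap_pi <- function(x) atan2(sin(x), cos(x))

#' Circular mean of angles
#'
#' Resultant-vector (circular) mean.  For tightly clustered angles this
#' coincides with the arithmetic mean to high accuracy.
#'
#' @param x angles in radians.
#' @param na.rm drop missing values.
#' @return mean angle in (-pi, pi], or NA if no finite values.
#' @export
circ_mean <- function(x, na.rm = TRUE) {
  if (na.rm) x <- x[is.finite(x)]
  if (!length(x)) return(NA_real_)
  atan2(mean(sin(x)), mean(cos(x)))
}

# Sliding box sum over a matrix (window w x w, w odd), computed with
# cumulative sums.  Returns the (H-w+1) x (W-w+1) matrix of full-window
# sums; used by the spatial detrending.
box_sum <- function(M, w) {
  H <- nrow(M); W <- ncol(M)
  stopifnot(w %% 2 == 1, H >= w, W >= w)
  cs <- apply(M, 2, cumsum)
  rows <- cs[w:H, , drop = FALSE] -
    rbind(0, cs[seq_len(H - w), , drop = FALSE])
  cs2 <- t(apply(rows, 1, cumsum))
  if (nrow(rows) == 1L) cs2 <- matrix(cs2, nrow = 1L)  # apply() drops dims
  cs2[, w:W, drop = FALSE] -
    cbind(0, cs2[, seq_len(W - w), drop = FALSE])
}

# Derive a stream of independent sub-seeds from one base seed, without
# perturbing the caller's RNG state more than once.
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1, n >= 1)
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
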