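#' Round half away from zero
#'
#' Deterministic rounding used everywhere a continuous size or coordinate is
#' converted to an integer (output shapes, point mapping, 0-255 intensity
#' scaling). `round()` in R rounds half to even, which is platform-stable but
#' surprises users expecting 0.5 -> 1; all user-visible rounding in this
#' package rounds halves away from zero instead.
#'
#' @param x numeric vector.
#' @return integer-valued numeric vector.
#' @export
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

stop_invalid <- function(...) {
  stop(structure(class = c("epievents_invalid_input", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_format <- function(...) {
  stop(structure(class = c("epievents_format_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Separable Gaussian smoothing of a (t, y, x) array
#'
#' Used to regularise probability maps before watershed seeding. Sigma can
#' differ between the temporal and the two spatial axes. Borders are handled
#' by kernel renormalisation (no intensity bleed from outside the array).
#'
#' @param a 3D numeric array ordered (t, y, x).
#' @param sigma_t,sigma_xy standard deviations in frames / pixels; 0 skips
#'   smoothing along that axis.
#' @return smoothed array of the same shape.
#' @keywords internal
gauss_smooth3 <- function(a, sigma_t = 1, sigma_xy = 2) {
  smooth_axis <- function(a, axis, sigma) {
    if (sigma <= 0) return(a)
    r <- max(1L, ceiling(3 * sigma))
    k <- exp(-((-r):r)^2 / (2 * sigma^2))
    d <- dim(a)
    n <- d[axis]
    # fold the axis of interest into rows of a matrix
    perm <- c(axis, setdiff(1:3, axis))
    m <- aperm(a, perm)
    dim(m) <- c(n, prod(d[perm[2:3]]))
    out <- matrix(0, n, ncol(m))
    wsum <- numeric(n)
    for (j in (-r):r) {
      src <- pmin(pmax(seq_len(n) + j, 1L), n)
      keep <- (seq_len(n) + j >= 1L) & (seq_len(n) + j <= n)
      w <- k[j + r + 1]
      out[keep, ] <- out[keep, ] + w * m[src[keep], , drop = FALSE]
      wsum[keep] <- wsum[keep] + w
    }
    out <- out / wsum
    dim(out) <- d[perm]
    aperm(out, order(perm))
  }
  a <- smooth_axis(a, 1L, sigma_t)
  a <- smooth_axis(a, 2L, sigma_xy)
  smooth_axis(a, 3L, sigma_xy)
}
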