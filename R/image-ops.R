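# Low-level raster helpers shared by the simulator, augmentation and the
# classifier front end. Images are numeric arrays dim = c(H, W, 3) with
# intensities in [0, 1]; coordinates are row-major, origin top-left, 0-based
# at the API surface (1-based internally, as usual in R).

#' Circular scope mask
#'
#' Boolean mask of the centred fetoscope disc: `TRUE` inside the scope's
#' field of view, `FALSE` in the black corners.
#'
#' @param n Image side length in pixels.
#' @param radius_frac Disc radius as a fraction of the image half-width,
#'   in (0, 1].
#' @return An `n x n` logical matrix.
#' @export
disc_mask <- function(n, radius_frac = 0.95) {
  stopifnot(n >= 1, radius_frac > 0, radius_frac <= 1)
  c0 <- (n + 1) / 2
  r <- radius_frac * n / 2
  dx <- matrix(rep(seq_len(n) - c0, each = n), n, n)   # column offsets
  dy <- matrix(rep(seq_len(n) - c0, times = n), n, n)  # row offsets
  dx * dx + dy * dy <= r * r
}

# Bilinear sampling plan at fractional source coordinates (ys, xs),
# 1-based, shared across channels. Reads outside the image return 0 via a
# one-pixel zero border: coordinates are clamped onto the border, so any
# out-of-range neighbour lands on a zero.
.bilinear_plan <- function(ys, xs, n) {
  y0 <- floor(ys); x0 <- floor(xs)
  fy <- ys - y0;   fx <- xs - x0
  np <- n + 2
  li <- function(yy, xx) {
    pmin(pmax(xx, 0), n + 1) * np + pmin(pmax(yy, 0), n + 1) + 1
  }
  list(
    n = n, np = np,
    i00 = li(y0, x0), i01 = li(y0, x0 + 1),
    i10 = li(y0 + 1, x0), i11 = li(y0 + 1, x0 + 1),
    w00 = (1 - fy) * (1 - fx), w01 = (1 - fy) * fx,
    w10 = fy * (1 - fx), w11 = fy * fx
  )
}

.bilinear_apply <- function(ch, plan) {
  P <- matrix(0, plan$np, plan$np)
  P[2:(plan$n + 1), 2:(plan$n + 1)] <- ch
  P[plan$i00] * plan$w00 + P[plan$i01] * plan$w01 +
    P[plan$i10] * plan$w10 + P[plan$i11] * plan$w11
}

# Resample a square H x W x 3 array onto an n_out grid (bilinear,
# align-corners-false convention: output pixel centre i maps to source
# coordinate (i - 0.5) * n_in / n_out + 0.5). Identity when sizes match.
.resize_array <- function(px, n_out) {
  n_in <- dim(px)[1]
  if (n_out == n_in) return(px)
  ctr <- (seq_len(n_out) - 0.5) * n_in / n_out + 0.5
  src <- pmin(pmax(ctr, 1), n_in)  # clamp so constants stay constant
  ys <- rep(src, times = n_out)
  xs <- rep(src, each = n_out)
  plan <- .bilinear_plan(ys, xs, n_in)
  out <- array(0, dim = c(n_out, n_out, 3))
  for (c in 1:3) {
    out[, , c] <- matrix(.bilinear_apply(px[, , c], plan), n_out, n_out)
  }
  out
}

# Rotate a square H x W x 3 array by `angle_deg` counter-clockwise about the
# image centre, bilinear interpolation, black fill. Exact for quarter turns
# (the inverse map lands on integer coordinates).
.rotate_array <- function(px, angle_deg) {
  n <- dim(px)[1]
  th <- angle_deg * pi / 180
  ct <- cos(th); st <- sin(th)
  c0 <- (n + 1) / 2
  # target grid offsets (x right, y down); inverse rotation to source coords
  xt <- rep(seq_len(n) - c0, each = n)
  yt <- rep(seq_len(n) - c0, times = n)
  xs <- ct * xt - st * yt + c0
  ys <- st * xt + ct * yt + c0
  # snap near-integer coordinates so quarter turns are bitwise exact
  rx <- round(xs); sn <- abs(xs - rx) < 1e-9; xs[sn] <- rx[sn]
  ry <- round(ys); sn <- abs(ys - ry) < 1e-9; ys[sn] <- ry[sn]
  plan <- .bilinear_plan(ys, xs, n)
  out <- array(0, dim = dim(px))
  for (c in 1:3) {
    out[, , c] <- matrix(.bilinear_apply(px[, , c], plan), n, n)
  }
  out
}

# Separable Gaussian blur with zero padding; no-op for sigma ~ 0.
.blur_array <- function(px, sigma) {
  if (sigma < 1e-3) return(px)
  k <- max(1L, ceiling(3 * sigma))
  w <- exp(-((-k:k)^2) / (2 * sigma^2))
  w <- w / sum(w)
  n <- dim(px)[1]
  blur_mat <- function(m) {
    acc_r <- matrix(0, n, n)
    for (i in seq_along(w)) {      # vertical pass, zero padded
      o <- i - k - 1L
      src <- seq_len(n) + o
      ok <- src >= 1 & src <= n
      acc_r[ok, ] <- acc_r[ok, ] + w[i] * m[src[ok], ]
    }
    acc <- matrix(0, n, n)
    for (i in seq_along(w)) {      # horizontal pass
      o <- i - k - 1L
      src <- seq_len(n) + o
      ok <- src >= 1 & src <= n
      acc[, ok] <- acc[, ok] + w[i] * acc_r[, src[ok]]
    }
    acc
  }
  out <- px
  for (c in 1:3) out[, , c] <- blur_mat(px[, , c])
  out
}

# Snap intensities to the 8-bit grid k/255 so a PNG round trip is lossless.
.quantize8 <- function(px) {
  round(pmin(pmax(px, 0), 1) * 255) / 255
}
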