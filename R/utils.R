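# Shared numerical helpers: phase arithmetic, interpolation, small filters.

#' Wrap angles to (-pi, pi]
#' @param x angles in radians.
#' @return wrapped angles.
#' @keywords internal
#' @noRd
wrap_phase <- function(x) {
  w <- (x + pi) %% (2 * pi) - pi
  # %% maps exact +pi to -pi; keep the (-pi, pi] convention
  w[w == -pi] <- pi
  w
}

#' Bilinear x2 up-sampling of a matrix
#'
#' Output pixel (i, j) takes the value of the input at fractional coordinate
#' ((i - 1) / 2, (j - 1) / 2) (0-based), clamped to the grid, so even output
#' indices coincide with input pixels and odd ones are midpoints. Works for
#' numeric and complex matrices (complex parts interpolated separately).
#' @keywords internal
#' @noRd
interp2x <- function(m) {
  if (is.complex(m)) {
    return(interp2x(Re(m)) + (0 + 1i) * interp2x(Im(m)))
  }
  nr <- nrow(m); nc <- ncol(m)
  ri <- (seq_len(2L * nr) - 1) / 2      # 0-based input row coordinate
  ci <- (seq_len(2L * nc) - 1) / 2
  r0 <- pmin(floor(ri), nr - 1L); r1 <- pmin(r0 + 1L, nr - 1L); fr <- ri - r0
  c0 <- pmin(floor(ci), nc - 1L); c1 <- pmin(c0 + 1L, nc - 1L); fc <- ci - c0
  fr[ri >= nr - 1L] <- 0; fc[ci >= nc - 1L] <- 0   # clamp at the far edge
  a <- m[r0 + 1L, c0 + 1L, drop = FALSE]
  b <- m[r1 + 1L, c0 + 1L, drop = FALSE]
  d <- m[r0 + 1L, c1 + 1L, drop = FALSE]
  e <- m[r1 + 1L, c1 + 1L, drop = FALSE]
  wr <- matrix(fr, length(ri), length(ci))
  wc <- matrix(fc, length(ri), length(ci), byrow = TRUE)
  (1 - wr) * (1 - wc) * a + wr * (1 - wc) * b + (1 - wr) * wc * d + wr * wc * e
}

#' NA-aware 3x3 median filter
#'
#' Median over the 3x3 neighbourhood, ignoring NA entries and pixels outside
#' the image. A pixel that is NA stays NA (filtering never invents values).
#' @keywords internal
#' @noRd
median_filter3 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  stack <- array(NA_real_, c(nr, nc, 9L))
  k <- 0L
  for (dr in -1:1) for (dc in -1:1) {
    k <- k + 1L
    rs <- seq_len(nr) + dr; cs <- seq_len(nc) + dc
    ok_r <- rs >= 1L & rs <= nr; ok_c <- cs >= 1L & cs <= nc
    stack[ok_r, ok_c, k] <- m[rs[ok_r], cs[ok_c]]
  }
  out <- apply(stack, c(1, 2), function(v) {
    v <- v[!is.na(v)]
    if (length(v)) median(v) else NA_real_
  })
  out[is.na(m)] <- NA_real_
  out
}

#' Shift a matrix by integer offsets, padding with NA
#'
#' `shift_image(m, dr, dc)[i, j] == m[i - dr, j - dc]` where defined.
#' @keywords internal
#' @noRd
shift_image <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(m[1][NA], nr, nc)
  src_r <- seq_len(nr) - dr; src_c <- seq_len(nc) - dc
  ok_r <- src_r >= 1L & src_r <= nr; ok_c <- src_c >= 1L & src_c <= nc
  out[ok_r, ok_c] <- m[src_r[ok_r], src_c[ok_c]]
  out
}

#' Normalized edge-to-center distance inside a binary mask
#'
#' Distance of each in-mask pixel to the nearest background pixel (Euclidean
#' distance transform), rescaled so the outermost in-mask pixels map to 0 and
#' the innermost to 1.
#' @param mask logical or 0/1 matrix.
#' @return numeric matrix with NA outside the mask; attribute `"degenerate"`
#'   is TRUE when the mask has no interior depth (all pixels at one level).
#' @keywords internal
#' @noRd
edge_distance_norm <- function(mask) {
  mask <- mask != 0
  d <- EBImage::distmap(matrix(as.numeric(mask), nrow(mask), ncol(mask)))
  d <- as.matrix(d)
  d[!mask] <- NA_real_
  rng <- range(d, na.rm = TRUE)
  degen <- !is.finite(rng[1]) || rng[2] <= rng[1]
  out <- if (degen) d * 0 else (d - rng[1]) / (rng[2] - rng[1])
  attr(out, "degenerate") <- degen
  out
}

#' Shape moments of a binary mask
#'
#' Eccentricity from the eigenvalues of the pixel-coordinate covariance
#' matrix (0 for a disk, ->1 for a line) and a boundary-face perimeter
#' estimate used for compactness = perimeter^2 / (4 pi area).
#' @keywords internal
#' @noRd
mask_shape <- function(mask) {
  mask <- mask != 0
  idx <- which(mask, arr.ind = TRUE)
  n <- nrow(idx)
  if (n == 0L) {
    return(list(area = 0L, eccentricity = NA_real_, compactness = NA_real_,
                centroid = c(NA_real_, NA_real_)))
  }
  mu <- colMeans(idx)
  if (n == 1L) {
    ecc <- 0
  } else {
    xc <- idx[, 1] - mu[1]; yc <- idx[, 2] - mu[2]
    # add the 1/12 variance of a unit pixel so single-row masks stay finite
    cxx <- mean(xc^2) + 1 / 12; cyy <- mean(yc^2) + 1 / 12; cxy <- mean(xc * yc)
    tr <- cxx + cyy; det <- cxx * cyy - cxy^2
    disc <- sqrt(max(tr^2 / 4 - det, 0))
    l1 <- tr / 2 + disc; l2 <- tr / 2 - disc
    ecc <- sqrt(max(1 - l2 / max(l1, .Machine$double.eps), 0))
  }
  # perimeter: count exposed 4-neighbour faces
  padded <- matrix(FALSE, nrow(mask) + 2L, ncol(mask) + 2L)
  padded[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] <- mask
  per <- 0L
  for (off in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
    nb <- shift_image(padded, off[1], off[2]); nb[is.na(nb)] <- FALSE
    per <- per + sum(padded & !nb)
  }
  list(area = n, eccentricity = ecc,
       compactness = per^2 / (4 * pi * n),
       centroid = mu)
}

#' Coefficient of variation in percent
#' @keywords internal
#' @noRd
cv_percent <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2L || mean(x) == 0) return(NA_real_)
  100 * sd(x) / mean(x)
}

# run expr with a private RNG stream, restoring the caller's state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(expr)
}
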