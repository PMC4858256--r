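# Internal 2-D image primitives used by the vesselness filter, segmentation
# smoothing and disc-margin fitting. Hand-rolled because the installed R
# stack carries no raster image-processing package; all operate on plain
# numeric matrices indexed [x, y].

# Replicate-pad a matrix by `k` pixels on every side.
pad_replicate <- function(m, k) {
  if (k == 0L) return(m)
  ri <- c(rep(1L, k), seq_len(nrow(m)), rep(nrow(m), k))
  ci <- c(rep(1L, k), seq_len(ncol(m)), rep(ncol(m), k))
  m[ri, ci, drop = FALSE]
}

gaussian_kernel <- function(sigma) {
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

# Separable convolution with replicate boundary handling. The same kernel is
# applied along both axes so the operator commutes with 90-degree rotation,
# which the vesselness symmetry property relies on.
gaussian_blur <- function(m, sigma) {
  k <- gaussian_kernel(sigma)
  r <- (length(k) - 1L) %/% 2L
  conv_rows <- function(mm) {
    # convolve along the first (x) axis by accumulating shifted slabs
    p <- pad_replicate(mm, r)[, (r + 1L):(r + ncol(mm)), drop = FALSE]
    out <- matrix(0, nrow(mm), ncol(mm))
    for (j in seq_along(k)) {
      out <- out + k[j] * p[(j):(j + nrow(mm) - 1L), , drop = FALSE]
    }
    out
  }
  t(conv_rows(t(conv_rows(m))))
}

# Second derivatives by symmetric finite differences (replicate padding).
hessian_2d <- function(m) {
  n1 <- nrow(m); n2 <- ncol(m)
  p <- pad_replicate(m, 1L)
  ctr <- p[2:(n1 + 1), 2:(n2 + 1), drop = FALSE]
  xm <- p[1:n1, 2:(n2 + 1), drop = FALSE]
  xp <- p[3:(n1 + 2), 2:(n2 + 1), drop = FALSE]
  ym <- p[2:(n1 + 1), 1:n2, drop = FALSE]
  yp <- p[2:(n1 + 1), 3:(n2 + 2), drop = FALSE]
  list(
    xx = xp - 2 * ctr + xm,
    yy = yp - 2 * ctr + ym,
    xy = (p[3:(n1 + 2), 3:(n2 + 2)] + p[1:n1, 1:n2] -
            p[3:(n1 + 2), 1:n2] - p[1:n1, 3:(n2 + 2)]) / 4
  )
}

# 3x3 median filter (replicate boundary), used to regularize layer surfaces.
median_filter_3x3 <- function(m) {
  p <- pad_replicate(m, 1L)
  n1 <- nrow(m); n2 <- ncol(m)
  stack <- vapply(
    list(c(0, 0), c(1, 0), c(2, 0), c(0, 1), c(1, 1), c(2, 1),
         c(0, 2), c(1, 2), c(2, 2)),
    function(o) as.vector(p[(1 + o[1]):(n1 + o[1]), (1 + o[2]):(n2 + o[2])]),
    numeric(n1 * n2)
  )
  matrix(apply(stack, 1L, median, na.rm = TRUE), n1, n2)
}

# Otsu threshold on a numeric vector: maximizes between-class variance over
# a fixed histogram. Returns NA for (near-)constant input.
otsu_threshold <- function(x, nbins = 256L) {
  x <- x[is.finite(x)]
  rng <- range(x)
  if (diff(rng) <= .Machine$double.eps * max(1, abs(rng[2]))) return(NA_real_)
  br <- seq(rng[1], rng[2], length.out = nbins + 1L)
  h <- tabulate(findInterval(x, br, rightmost.closed = TRUE), nbins)
  mids <- (br[-1] + br[-length(br)]) / 2
  w <- cumsum(h)
  mu <- cumsum(h * mids)
  tot <- w[nbins]; mu_t <- mu[nbins]
  w0 <- w[-nbins]; w1 <- tot - w0
  valid <- w0 > 0 & w1 > 0
  bcv <- rep(-Inf, nbins - 1L)
  bcv[valid] <- (mu_t * w0[valid] - tot * mu[-nbins][valid])^2 /
    (w0[valid] * w1[valid])
  # ties (flat between-class-variance plateaus) resolve to the plateau middle
  top <- which(bcv >= max(bcv) * (1 - 1e-12))
  br[-c(1L, nbins + 1L)][top[ceiling(length(top) / 2)]]
}

# Direct least-squares ellipse fit (Fitzgibbon-style, via the generalized
# eigenproblem on the conic coefficients). Points are (x, y); returns center,
# semi-axes and orientation, or NULL when the fit degenerates.
fit_ellipse <- function(x, y) {
  if (length(x) < 6L) return(NULL)
  mx <- mean(x); my <- mean(y)
  sx <- max(sd(x), 1e-9); sy <- max(sd(y), 1e-9)
  xs <- (x - mx) / sx; ys <- (y - my) / sy
  D <- cbind(xs^2, xs * ys, ys^2, xs, ys, 1)
  S <- crossprod(D)
  C <- matrix(0, 6, 6)
  C[1, 3] <- 2; C[3, 1] <- 2; C[2, 2] <- -1
  Si <- tryCatch(solve(S, C), error = function(e) NULL)
  if (is.null(Si)) return(NULL)
  eg <- eigen(Si)
  # pick the eigenvector satisfying the ellipse constraint 4AC - B^2 > 0
  ok <- which(vapply(seq_len(6), function(j) {
    v <- Re(eg$vectors[, j])
    isTRUE(4 * v[1] * v[3] - v[2]^2 > 1e-12)
  }, logical(1)))
  if (!length(ok)) return(NULL)
  a <- Re(eg$vectors[, ok[1]])
  # undo normalization: conic in original coordinates
  A <- a[1] / sx^2
  B <- a[2] / (sx * sy)
  Cc <- a[3] / sy^2
  Dd <- a[4] / sx - 2 * a[1] * mx / sx^2 - a[2] * my / (sx * sy)
  Ee <- a[5] / sy - 2 * a[3] * my / sy^2 - a[2] * mx / (sx * sy)
  Ff <- a[6] + a[1] * mx^2 / sx^2 + a[3] * my^2 / sy^2 +
    a[2] * mx * my / (sx * sy) - a[4] * mx / sx - a[5] * my / sy
  den <- B^2 - 4 * A * Cc
  if (den >= 0) return(NULL)
  xc <- (2 * Cc * Dd - B * Ee) / den
  yc <- (2 * A * Ee - B * Dd) / den
  theta <- 0.5 * atan2(B, A - Cc)
  # semi-axes from the conic evaluated at the center
  num <- 2 * (A * xc^2 + Cc * yc^2 + B * xc * yc + Dd * xc + Ee * yc + Ff)
  disc <- sqrt((A - Cc)^2 + B^2)
  ax1 <- sqrt(abs(num * (A + Cc + disc)) ) / sqrt(abs(den))
  ax2 <- sqrt(abs(num * (A + Cc - disc)) ) / sqrt(abs(den))
  list(xc = xc, yc = yc, a = max(ax1, ax2), b = min(ax1, ax2), theta = theta)
}

rasterize_ellipse <- function(e, nx, ny) {
  xg <- matrix(seq_len(nx), nx, ny)
  yg <- matrix(seq_len(ny), nx, ny, byrow = TRUE)
  dx <- xg - e$xc; dy <- yg - e$yc
  ct <- cos(e$theta); st <- sin(e$theta)
  u <- (dx * ct + dy * st) / e$a
  v <- (-dx * st + dy * ct) / e$b
  u^2 + v^2 <= 1
}

# Even-odd (crossing number) point-in-polygon rasterizer for manual disc
# contours. `poly` is a data frame / matrix with columns x, y.
rasterize_polygon <- function(poly, nx, ny) {
  px <- poly[[1]]; py <- poly[[2]]
  n <- length(px)
  mask <- matrix(FALSE, nx, ny)
  for (yy in seq_len(ny)) {
    # x-coordinates where polygon edges cross the horizontal line y = yy
    xs <- c()
    for (i in seq_len(n)) {
      j <- if (i == n) 1L else i + 1L
      y1 <- py[i]; y2 <- py[j]
      if ((y1 <= yy) != (y2 <= yy)) {
        xs <- c(xs, px[i] + (yy - y1) / (y2 - y1) * (px[j] - px[i]))
      }
    }
    if (length(xs) >= 2L) {
      xs <- sort(xs)
      for (k in seq(1L, length(xs) - 1L, by = 2L)) {
        lo <- ceiling(xs[k]); hi <- floor(xs[k + 1L])
        if (hi >= lo) mask[max(1L, lo):min(nx, hi), yy] <- TRUE
      }
    }
  }
  mask
}
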