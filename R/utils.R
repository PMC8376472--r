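# Internal array utilities shared across modules. All axes are 1-based.

epi_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "epi_error")))
}

epi_warn <- function(msg, class) {
  warning(warningCondition(msg, class = c(class, "epi_warning")))
}

robust_max <- function(x) {
  stats::quantile(abs(x[is.finite(x)]), 0.99, names = FALSE)
}

#' @noRd
# Permute an array so that `axis` becomes dimension 1; returns the permuted
# array plus the permutation needed to undo it.
perm_to_front <- function(arr, axis) {
  perm <- c(axis, setdiff(seq_along(dim(arr)), axis))
  list(arr = aperm(arr, perm), inverse = order(perm))
}

perm_back <- function(arr, inverse) aperm(arr, inverse)

# Spatial derivative along `axis` in voxel units: central differences in the
# interior, one-sided at the two boundary slices.
axis_deriv <- function(arr, axis) {
  p <- perm_to_front(arr, axis)
  a <- p$arr
  d <- dim(a)
  n <- d[1]
  if (n < 2L) epi_stop("need at least 2 voxels along the derivative axis",
                       "epi_argument_error")
  m <- matrix(a, nrow = n)
  out <- matrix(0, nrow = n, ncol = ncol(m))
  if (n > 2L) out[2:(n - 1L), ] <- (m[3:n, ] - m[1:(n - 2L), ]) / 2
  out[1L, ] <- m[2L, ] - m[1L, ]
  out[n, ] <- m[n, ] - m[n - 1L, ]
  dim(out) <- d
  perm_back(out, p$inverse)
}

# Linear interpolation with edge clamp of the columns of `m` (n x k) at
# fractional row positions `pos` (n x k), vectorized over all columns.
sample_columns_linear <- function(m, pos) {
  n <- nrow(m)
  k <- ncol(m)
  pos <- pmin(pmax(pos, 1), n)
  i0 <- pmin(floor(pos), n - 1L)
  fr <- pos - i0
  col <- rep(seq_len(k) - 1L, each = n) * n
  lo <- m[i0 + col]
  hi <- m[i0 + 1L + col]
  out <- lo * (1 - fr) + hi * fr
  dim(out) <- dim(pos)
  out
}

# Given per-column strictly increasing sample positions t (n x k) and sample
# values y (n x k), evaluate the piecewise-linear interpolant of the points
# (t[i,], y[i,]) at the integer grid 1..n, clamping outside the range.  This
# is exactly "invert the monotone 1-D map, then sample linearly".
invert_columns_linear <- function(t, y) {
  n <- nrow(t)
  k <- ncol(t)
  u <- matrix(rep(seq_len(n), k), nrow = n)
  i <- pmin(pmax(round(u - (t - u)), 1L), n - 1L)
  col <- rep(seq_len(k) - 1L, each = n) * n
  maxstep <- ceiling(max(abs(t - u))) + 2L
  for (s in seq_len(maxstep)) {
    up <- t[i + 1L + col] <= u & i < n - 1L
    dn <- t[i + col] > u & i > 1L
    if (!any(up) && !any(dn)) break
    i <- i + up - dn
  }
  t0 <- t[i + col]
  t1 <- t[i + 1L + col]
  fr <- pmin(pmax((u - t0) / pmax(t1 - t0, 1e-12), 0), 1)
  out <- y[i + col] * (1 - fr) + y[i + 1L + col] * fr
  dim(out) <- c(n, k)
  out
}

# Shift an array along an axis with replicate (edge-clamp) padding.
shift_replicate <- function(arr, axis, by) {
  if (by == 0L) return(arr)
  d <- dim(arr)
  n <- d[axis]
  idx <- pmin(pmax(seq_len(n) - by, 1L), n)
  sel <- rep(list(quote(expr = )), length(d))
  sel[[axis]] <- idx
  do.call(`[`, c(list(arr), sel, list(drop = FALSE)))
}

# Adjoint-consistent discrete regularizer: R(b) = sum over axes of squared
# forward differences; reg_grad returns d R / d b (the Neumann Laplacian
# A'A b), so that the Gauss-Newton normal equations match the objective.
reg_value <- function(b) {
  v <- 0
  for (ax in seq_along(dim(b))) {
    p <- perm_to_front(b, ax)$arr
    n <- dim(p)[1]
    if (n < 2L) next
    m <- matrix(p, nrow = n)
    v <- v + sum((m[2:n, ] - m[1:(n - 1L), ])^2)
  }
  v
}

reg_grad <- function(b) {
  out <- array(0, dim(b))
  for (ax in seq_along(dim(b))) {
    p <- perm_to_front(b, ax)
    a <- p$arr
    n <- dim(a)[1]
    if (n < 2L) next
    m <- matrix(a, nrow = n)
    dmat <- m[2:n, , drop = FALSE] - m[1:(n - 1L), , drop = FALSE]
    g <- matrix(0, nrow = n, ncol = ncol(m))
    g[1:(n - 1L), ] <- g[1:(n - 1L), ] - dmat
    g[2:n, ] <- g[2:n, ] + dmat
    dim(g) <- dim(a)
    out <- out + perm_back(g, p$inverse)
  }
  2 * out
}

# Matrix-free conjugate gradient for s.p.d. operators on arrays.
cg_solve <- function(apply_A, rhs, max_iter = 40L, tol = 1e-6) {
  x <- array(0, dim(rhs))
  r <- rhs
  p <- r
  rs <- sum(r * r)
  rs0 <- rs
  if (rs0 == 0) return(x)
  for (it in seq_len(max_iter)) {
    Ap <- apply_A(p)
    alpha <- rs / sum(p * Ap)
    if (!is.finite(alpha)) break
    x <- x + alpha * p
    r <- r - alpha * Ap
    rs_new <- sum(r * r)
    if (rs_new / rs0 < tol^2) break
    p <- r + (rs_new / rs) * p
    rs <- rs_new
  }
  x
}

# Block-mean downsampling by a factor of 2 along every axis (replicate-pad
# odd dimensions).
downsample2 <- function(arr) {
  d <- dim(arr)
  for (ax in seq_along(d)) {
    if (dim(arr)[ax] %% 2L == 1L) {
      last <- shift_replicate(arr, ax, -(dim(arr)[ax] - 1L))
      sel <- rep(list(quote(expr = )), length(d))
      sel[[ax]] <- dim(arr)[ax]
      edge <- do.call(`[`, c(list(arr), sel, list(drop = FALSE)))
      arr <- abind_axis(arr, edge, ax)
    }
  }
  d <- dim(arr)
  p <- arr
  for (ax in seq_along(d)) {
    pf <- perm_to_front(p, ax)
    a <- pf$arr
    n <- dim(a)[1]
    m <- matrix(a, nrow = n)
    m2 <- (m[seq(1L, n, 2L), , drop = FALSE] + m[seq(2L, n, 2L), , drop = FALSE]) / 2
    dm <- dim(a)
    dm[1] <- n %/% 2L
    dim(m2) <- dm
    p <- perm_back(m2, pf$inverse)
  }
  p
}

abind_axis <- function(a, b, axis) {
  pa <- perm_to_front(a, axis)
  pb <- perm_to_front(b, axis)
  ma <- matrix(pa$arr, nrow = dim(pa$arr)[1])
  mb <- matrix(pb$arr, nrow = dim(pb$arr)[1])
  m <- rbind(ma, mb)
  dm <- dim(pa$arr)
  dm[1] <- dm[1] + dim(pb$arr)[1]
  dim(m) <- dm
  perm_back(m, pa$inverse)
}

# Trilinear resampling of a 3-D array onto a new grid size, with
# cell-centred alignment (matches block downsampling).
resample_trilinear <- function(arr, new_dim) {
  d <- dim(arr)
  coords <- lapply(1:3, function(ax) {
    sc <- d[ax] / new_dim[ax]
    (seq_len(new_dim[ax]) - 0.5) * sc + 0.5
  })
  gx <- coords[[1]]; gy <- coords[[2]]; gz <- coords[[3]]
  cx <- pmin(pmax(gx, 1), d[1]); cy <- pmin(pmax(gy, 1), d[2])
  cz <- pmin(pmax(gz, 1), d[3])
  x0 <- pmin(floor(cx), d[1] - 1L); y0 <- pmin(floor(cy), d[2] - 1L)
  z0 <- pmin(floor(cz), d[3] - 1L)
  fx <- cx - x0; fy <- cy - y0; fz <- cz - z0
  X0 <- array(x0, new_dim); FX <- array(fx, new_dim)
  Y0 <- array(rep(y0, each = new_dim[1]), new_dim)
  FY <- array(rep(fy, each = new_dim[1]), new_dim)
  Z0 <- array(rep(z0, each = new_dim[1] * new_dim[2]), new_dim)
  FZ <- array(rep(fz, each = new_dim[1] * new_dim[2]), new_dim)
  idx <- function(x, y, z) x + (y - 1L) * d[1] + (z - 1L) * d[1] * d[2]
  out <- arr[idx(X0, Y0, Z0)] * (1 - FX) * (1 - FY) * (1 - FZ) +
    arr[idx(X0 + 1L, Y0, Z0)] * FX * (1 - FY) * (1 - FZ) +
    arr[idx(X0, Y0 + 1L, Z0)] * (1 - FX) * FY * (1 - FZ) +
    arr[idx(X0 + 1L, Y0 + 1L, Z0)] * FX * FY * (1 - FZ) +
    arr[idx(X0, Y0, Z0 + 1L)] * (1 - FX) * (1 - FY) * FZ +
    arr[idx(X0 + 1L, Y0, Z0 + 1L)] * FX * (1 - FY) * FZ +
    arr[idx(X0, Y0 + 1L, Z0 + 1L)] * (1 - FX) * FY * FZ +
    arr[idx(X0 + 1L, Y0 + 1L, Z0 + 1L)] * FX * FY * FZ
  array(out, new_dim)
}

# 6-neighbour binary dilation via shifts.
dilate6 <- function(mask) {
  out <- mask
  for (ax in 1:3) {
    out <- out | shift_replicate(mask, ax, 1L) | shift_replicate(mask, ax, -1L)
  }
  out
}

erode6 <- function(mask) {
  out <- mask
  for (ax in 1:3) {
    out <- out & shift_replicate(mask, ax, 1L) & shift_replicate(mask, ax, -1L)
  }
  out
}

# Largest 6-connected component, by seeded binary propagation from the
# strongest remaining voxel until all voxels are labelled.
largest_component <- function(mask) {
  remaining <- mask
  best <- NULL
  best_n <- 0L
  while (any(remaining)) {
    seed <- array(FALSE, dim(mask))
    seed[which(remaining)[1]] <- TRUE
    repeat {
      grown <- dilate6(seed) & remaining
      if (sum(grown) == sum(seed)) break
      seed <- grown
    }
    n <- sum(seed)
    if (n > best_n) {
      best <- seed
      best_n <- n
    }
    remaining <- remaining & !seed
  }
  if (is.null(best)) mask else best
}

binary_closing <- function(mask) erode6(dilate6(mask))

`%||%` <- function(a, b) if (is.null(a)) b else a

# Separable Gaussian smoothing with replicate padding.
gaussian_smooth3 <- function(arr, sigma) {
  if (sigma <= 0) return(arr)
  half <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-half):half)^2 / (2 * sigma^2))
  k <- k / sum(k)
  out <- arr
  for (ax in 1:3) {
    acc <- array(0, dim(out))
    for (j in seq_along(k)) {
      acc <- acc + k[j] * shift_replicate(out, ax, j - half - 1L)
    }
    out <- acc
  }
  out
}
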