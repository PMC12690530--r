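# Low-level 3D array operations used by the morphometry module. Written on
# plain arrays so the whole pipeline stays dependency-light and exactly
# reproducible; all are separable or frontier-based and vectorized per step.

# Shift a 3D array by `by` voxels along `axis`. Vacated positions take
# `pad`; with pad = NULL the border is edge-replicated.
shift3 <- function(a, axis, by, pad = NULL) {
  d <- dim(a)
  n <- d[axis]
  src <- seq_len(n) - by
  clamped <- pmin(pmax(src, 1L), n)
  out <- switch(axis,
                a[clamped, , , drop = FALSE],
                a[, clamped, , drop = FALSE],
                a[, , clamped, drop = FALSE])
  if (!is.null(pad)) {
    bad <- which(src < 1L | src > n)
    if (length(bad) > 0) {
      switch(axis,
             out[bad, , ] <- pad,
             out[, bad, ] <- pad,
             out[, , bad] <- pad)
    }
  }
  out
}

# Separable convolution with a symmetric 1D kernel along every axis,
# edge-replicated borders.
convolve_separable <- function(a, kernel1d) {
  h <- (length(kernel1d) - 1L) / 2L
  offsets <- seq(-h, h)
  for (axis in 1:3) {
    acc <- a * 0
    for (j in seq_along(offsets)) {
      acc <- acc + kernel1d[j] * shift3(a, axis, offsets[j])
    }
    a <- acc
  }
  a
}

# Binary dilation/erosion with a cube structuring element of the given odd
# width (separable: per-axis running OR/AND). Outside the array is FALSE.
binary_dilate <- function(mask, width = 3L) {
  h <- (width - 1L) %/% 2L
  for (axis in 1:3) {
    acc <- mask
    for (by in setdiff(seq(-h, h), 0L)) {
      acc <- acc | shift3(mask, axis, by, pad = FALSE)
    }
    mask <- acc
  }
  mask
}

binary_erode <- function(mask, width = 3L) {
  h <- (width - 1L) %/% 2L
  for (axis in 1:3) {
    acc <- mask
    for (by in setdiff(seq(-h, h), 0L)) {
      acc <- acc & shift3(mask, axis, by, pad = FALSE)
    }
    mask <- acc
  }
  mask
}

binary_close <- function(mask, width = 3L) binary_erode(binary_dilate(mask, width), width)
binary_open <- function(mask, width = 3L) binary_dilate(binary_erode(mask, width), width)

# Largest 6-connected component of a binary 3D mask, by frontier growth
# (iterated 6-neighbour dilation restricted to the mask).
largest_component <- function(mask) {
  remaining <- mask
  best <- NULL
  best_size <- -1
  grow_neighbours <- function(m) {
    out <- m
    for (axis in 1:3) {
      out <- out | shift3(m, axis, 1L, pad = FALSE) |
        shift3(m, axis, -1L, pad = FALSE)
    }
    out
  }
  while (any(remaining)) {
    seed_idx <- which(remaining)[1]
    comp <- array(FALSE, dim(mask))
    comp[seed_idx] <- TRUE
    repeat {
      grown <- grow_neighbours(comp) & remaining
      if (sum(grown) == sum(comp)) break
      comp <- grown
    }
    size <- sum(comp)
    if (size > best_size) {
      best <- comp
      best_size <- size
    }
    remaining <- remaining & !comp
  }
  if (is.null(best)) mask else best
}

# Otsu's threshold on the values inside a mask: maximize between-class
# variance over a 256-bin histogram; returns the bin-edge threshold.
otsu_threshold <- function(values, n_bins = 256L) {
  values <- values[is.finite(values)]
  if (length(values) == 0) stop_ivd("No values to threshold.", "bad_threshold")
  rng <- range(values)
  if (rng[1] == rng[2]) return(rng[1])
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  counts <- tabulate(findInterval(values, edges, rightmost.closed = TRUE),
                     nbins = n_bins)
  p <- counts / sum(counts)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  w0 <- cumsum(p)
  mu0 <- cumsum(p * mids)
  mu_t <- mu0[n_bins]
  w1 <- 1 - w0
  between <- (mu_t * w0 - mu0)^2 / (w0 * w1)
  between[!is.finite(between)] <- -Inf
  k <- which.max(between)
  edges[k + 1L]
}

# Signed distance from every pixel centre of an nr x nc grid to a closed
# polygon given as (row, col) vertices: negative inside (even-odd rule),
# positive outside, zero on the boundary.
polygon_sdf <- function(vertices, nr, nc) {
  stopifnot(is.matrix(vertices), ncol(vertices) == 2, nrow(vertices) >= 3)
  py <- rep(seq_len(nr), times = nc)   # pixel row coords
  px <- rep(seq_len(nc), each = nr)    # pixel col coords
  m <- nrow(vertices)
  nxt <- c(2:m, 1L)
  dist2 <- rep(Inf, nr * nc)
  inside <- rep(FALSE, nr * nc)
  for (s in seq_len(m)) {
    ay <- vertices[s, 1]; ax <- vertices[s, 2]
    by <- vertices[nxt[s], 1]; bx <- vertices[nxt[s], 2]
    ey <- by - ay; ex <- bx - ax
    len2 <- ey^2 + ex^2
    t <- if (len2 == 0) 0 else pmin(pmax(((py - ay) * ey + (px - ax) * ex) / len2, 0), 1)
    dy <- py - (ay + t * ey); dx <- px - (ax + t * ex)
    dist2 <- pmin(dist2, dy^2 + dx^2)
    # even-odd crossing test on the horizontal ray to +x
    crosses <- ((ay > py) != (by > py)) &
      (px < (bx - ax) * (py - ay) / (by - ay) + ax)
    inside <- xor(inside, crosses)
  }
  sdf <- sqrt(dist2)
  sdf[inside] <- -sdf[inside]
  matrix(sdf, nr, nc)
}
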