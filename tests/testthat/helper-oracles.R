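# Independent oracles and fixture builders used across the suite.

# Random rim geometry: bands of a smoothed Gaussian field. Arbitrary
# topology on purpose — the distance oracle must hold on any geometry.
random_rim <- function(shape, seed, voxel_size = c(1, 1, 1)) {
  set.seed(seed)
  u <- array(rnorm(prod(shape)), dim = shape)
  # small separable Gaussian blur so the bands are connected-ish
  k <- dnorm(-2:2, sd = 1.2)
  k <- k / sum(k)
  for (axis in 1:3) {
    if (shape[axis] == 1) next
    out <- array(0, dim = shape)
    for (o in -2:2) {
      off <- c(0L, 0L, 0L)
      off[axis] <- o
      idx <- lapply(1:3, function(a) {
        i <- seq_len(shape[a]) - off[a]
        i[i < 1 | i > shape[a]] <- NA
        i
      })
      sh <- u[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
      sh[is.na(sh)] <- 0
      dim(sh) <- shape
      out <- out + k[o + 3] * sh
    }
    u <- out
  }
  q <- quantile(u, c(0.30, 0.42, 0.62, 0.74))
  codes <- array(0L, dim = shape)
  codes[u >= q[1] & u < q[2]] <- 1L
  codes[u >= q[2] & u < q[3]] <- 3L
  codes[u >= q[3] & u < q[4]] <- 2L
  voxel_grid(codes, voxel_size = voxel_size)
}

# Shortest-path distances on the weighted 26-connected lattice via igraph
# (Dijkstra), fully independent of the package's growing code. Returns a
# vector of distances (Inf if unreachable) over all voxels; only voxels
# whose code is in `allowed` participate, sources are code == source_code.
dijkstra_oracle <- function(rim, source_code, allowed) {
  codes <- rim$data
  dims <- dim(codes)
  vs <- rim$voxel_size
  n <- prod(dims)
  node_ok <- as.vector(codes %in% allowed)
  idx <- array(seq_len(n), dim = dims)

  from <- integer(0); to <- integer(0); w <- numeric(0)
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offs <- offs[!(offs$dx == 0 & offs$dy == 0 & offs$dz == 0), ]
  # half the offsets suffice for an undirected graph
  offs <- offs[offs$dz > 0 | (offs$dz == 0 & offs$dy > 0) |
                 (offs$dz == 0 & offs$dy == 0 & offs$dx > 0), ]
  for (r in seq_len(nrow(offs))) {
    o <- c(offs$dx[r], offs$dy[r], offs$dz[r])
    sx <- seq_len(dims[1] - abs(o[1]))
    sy <- seq_len(dims[2] - abs(o[2]))
    sz <- seq_len(dims[3] - abs(o[3]))
    if (!length(sx) || !length(sy) || !length(sz)) next
    a <- idx[sx + max(0, -o[1]), sy + max(0, -o[2]), sz + max(0, -o[3]),
             drop = FALSE]
    b <- idx[sx + max(0, o[1]), sy + max(0, o[2]), sz + max(0, o[3]),
             drop = FALSE]
    keep <- node_ok[a] & node_ok[b]
    from <- c(from, a[keep])
    to <- c(to, b[keep])
    w <- c(w, rep(sqrt(sum((o * vs)^2)), sum(keep)))
  }
  sources <- which(as.vector(codes == source_code))
  dist <- rep(Inf, n)
  if (!length(sources)) return(dist)
  nodes <- which(node_ok)
  relab <- match(seq_len(n), nodes)  # lattice index -> graph vertex
  g <- igraph::make_empty_graph(n = length(nodes), directed = FALSE)
  g <- igraph::add_edges(g, rbind(relab[from], relab[to]))
  igraph::E(g)$weight <- w
  # supersource with zero-weight spokes to every source voxel
  g <- igraph::add_vertices(g, 1)
  ss <- length(nodes) + 1L
  g <- igraph::add_edges(g, rbind(ss, relab[sources]))
  igraph::E(g)$weight[igraph::ecount(g) - seq_along(sources) + 1L] <- 0
  d <- igraph::distances(g, v = ss, algorithm = "dijkstra")[1, ]
  dist[nodes] <- d[seq_along(nodes)]
  dist
}

# Literal O(window^2) smoothing oracles: plain double loops over voxels
# and window members, written without reference to the package kernels.
bf_layer_smooth <- function(data3d, layers, voxdim, fwhm, trunc = 3) {
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  rad <- trunc * sigma
  dims <- dim(data3d)
  out <- data3d
  rr <- ceiling(rad / voxdim)
  for (z in seq_len(dims[3])) for (y in seq_len(dims[2]))
    for (x in seq_len(dims[1])) {
      lv <- layers[x, y, z]
      if (lv <= 0) next
      acc <- 0; wsum <- 0
      for (zz in max(1, z - rr[3]):min(dims[3], z + rr[3]))
        for (yy in max(1, y - rr[2]):min(dims[2], y + rr[2]))
          for (xx in max(1, x - rr[1]):min(dims[1], x + rr[1])) {
            if (layers[xx, yy, zz] != lv) next
            d2 <- sum((((c(xx, yy, zz) - c(x, y, z))) * voxdim)^2)
            if (d2 > rad^2) next
            w <- exp(-d2 / (2 * sigma^2))
            acc <- acc + w * data3d[xx, yy, zz]
            wsum <- wsum + w
          }
      out[x, y, z] <- acc / wsum
    }
  out
}

bf_grad_smooth <- function(data3d, grad, voxdim, fwhm, selectivity,
                           trunc = 3) {
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  rad <- trunc * sigma
  dims <- dim(data3d)
  out <- data3d
  rr <- ceiling(rad / voxdim)
  if (dims[3] == 1) rr[3] <- 0
  for (z in seq_len(dims[3])) for (y in seq_len(dims[2]))
    for (x in seq_len(dims[1])) {
      xs <- max(1, x - rr[1]):min(dims[1], x + rr[1])
      ys <- max(1, y - rr[2]):min(dims[2], y + rr[2])
      zs <- max(1, z - rr[3]):min(dims[3], z + rr[3])
      win <- grad[xs, ys, zs]
      m <- mean(win)
      sdw <- sqrt(mean((win - m)^2))
      acc <- 0; wsum <- 0
      for (zz in zs) for (yy in ys) for (xx in xs) {
        d2 <- sum((((c(xx, yy, zz) - c(x, y, z))) * voxdim)^2)
        if (d2 > rad^2) next
        w <- exp(-d2 / (2 * sigma^2))
        if (sdw > 0) {
          di <- grad[xx, yy, zz] - grad[x, y, z]
          w <- w * exp(-di^2 / (2 * (selectivity * sdw)^2))
        }
        acc <- acc + w * data3d[xx, yy, zz]
        wsum <- wsum + w
      }
      out[x, y, z] <- acc / wsum
    }
  out
}
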