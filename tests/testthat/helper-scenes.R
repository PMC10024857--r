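# shared fixtures: small scene configurations and independent oracles

small_scene_config <- function(seed = 1, ...) {
  args <- list(field_um = 224, n_cells = 24, n_plaques = 2, n_tangles = 2,
               n_other_nuclei = 20, n_astrocytes = 4, n_vessels = 1,
               n_process_fragments = 8, n_diffuse_speckles = 10, seed = seed)
  do.call(scene_config, utils::modifyList(args, list(...)))
}

# independent forward mixing: densities + stain basis -> OD array
forward_mix_od <- function(dens_list, basis) {
  d <- dim(dens_list[[1]])
  od <- array(0, c(d[1], d[2], 3))
  for (k in 1:3)
    for (j in seq_along(dens_list))
      od[, , k] <- od[, , k] + dens_list[[j]] * basis[k, j]
  od
}

# brute-force 4-connected flood fill labelling of a binary matrix
flood_fill_label <- function(bin) {
  ny <- nrow(bin); nx <- ncol(bin)
  lab <- matrix(0L, ny, nx)
  cur <- 0L
  for (j in seq_len(nx)) for (i in seq_len(ny)) {
    if (bin[i, j] && lab[i, j] == 0L) {
      cur <- cur + 1L
      queue <- list(c(i, j)); lab[i, j] <- cur
      while (length(queue)) {
        p <- queue[[1]]; queue <- queue[-1]
        for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
          q <- p + d
          if (q[1] >= 1 && q[1] <= ny && q[2] >= 1 && q[2] <= nx &&
              bin[q[1], q[2]] && lab[q[1], q[2]] == 0L) {
            lab[q[1], q[2]] <- cur
            queue[[length(queue) + 1L]] <- q
          }
        }
      }
    }
  }
  lab
}

# analytic scene of Gaussian blobs, rendered at arbitrary (sub-pixel)
# positions without any resampling call
render_blob_image <- function(cx, cy, n = 128, sigma = 3) {
  xs <- matrix(rep(0:(n - 1), each = n), n, n)
  ys <- matrix(rep(0:(n - 1), n), n, n)
  m <- matrix(0, n, n)
  for (i in seq_along(cx))
    m <- m + exp(-((xs - cx[i])^2 + (ys - cy[i])^2) / (2 * sigma^2))
  m
}

# distance from a point to a polygon boundary by dense sampling of its
# edges (independent of the package's segment geometry)
brute_boundary_distance <- function(p, poly, step = 0.01) {
  m <- nrow(poly)
  dmin <- Inf
  for (s in seq_len(m)) {
    a <- poly[s, ]; b <- poly[if (s == m) 1L else s + 1L, ]
    L <- sqrt(sum((b - a)^2))
    ts <- seq(0, 1, by = if (L > 0) step / max(L, step) else 1)
    pts <- cbind(a[1] + ts * (b[1] - a[1]), a[2] + ts * (b[2] - a[2]))
    dmin <- min(dmin, sqrt((pts[, 1] - p[1])^2 + (pts[, 2] - p[2])^2))
  }
  dmin
}

all_marker_combos <- function(markers) {
  grid <- expand.grid(rep(list(c(FALSE, TRUE)), length(markers)))
  names(grid) <- markers
  grid
}
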