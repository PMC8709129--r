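## shared fixtures: small meshes are rebuilt per test from code

tpl_small <- function(resolution = 4L, n_chordae = 16L)
  build_template(mv_default_parameters(), resolution = resolution,
                 n_chordae = n_chordae)

random_rotation <- function(seed = 1L) {
  set.seed(seed)
  Q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

## independent Dijkstra on the mesh edge graph (no igraph), used as the
## geodesic oracle against measure_parameters()
dijkstra_geodesic <- function(mesh, from, to) {
  f <- mesh$faces
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  e <- unique(t(apply(e, 1, sort)))
  w <- sqrt(rowSums((mesh$vertices[e[, 1], , drop = FALSE] -
                     mesh$vertices[e[, 2], , drop = FALSE])^2))
  n <- nrow(mesh$vertices)
  adj <- vector("list", n)
  for (k in seq_len(nrow(e))) {
    adj[[e[k, 1]]] <- rbind(adj[[e[k, 1]]], c(e[k, 2], w[k]))
    adj[[e[k, 2]]] <- rbind(adj[[e[k, 2]]], c(e[k, 1], w[k]))
  }
  dist <- rep(Inf, n); dist[from] <- 0
  visited <- rep(FALSE, n)
  repeat {
    u <- which.min(ifelse(visited, Inf, dist))
    if (visited[u] || is.infinite(dist[u])) break
    if (u == to) return(dist[u])
    visited[u] <- TRUE
    for (k in seq_len(NROW(adj[[u]]))) {
      v <- adj[[u]][k, 1]; alt <- dist[u] + adj[[u]][k, 2]
      if (alt < dist[v]) dist[v] <- alt
    }
  }
  dist[to]
}

## shoelace area of an ordered 2-D polygon (test-side oracle)
shoelace <- function(p) {
  i2 <- c(2:nrow(p), 1)
  abs(sum(p[, 1] * p[i2, 2] - p[i2, 1] * p[, 2])) / 2
}
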