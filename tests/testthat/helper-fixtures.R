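# Shared fixtures, built in code at test time.

# small but well-conditioned multi-shell protocol
small_protocol <- function() multishell_protocol(n_dirs = c(16L, 16L, 16L),
                                                 n_b0 = 3L)

# planar white/pial sheets: an n x n grid at z = 0 and z = h
planar_sheets <- function(n = 5L, spacing = 1, h = 2) {
  g <- expand.grid(x = (seq_len(n) - 1) * spacing,
                   y = (seq_len(n) - 1) * spacing)
  white <- cbind(g$x, g$y, 0)
  pial <- cbind(g$x, g$y, h)
  idx <- matrix(seq_len(n * n), n, n)
  tri <- NULL
  for (i in seq_len(n - 1)) for (j in seq_len(n - 1)) {
    tri <- rbind(tri,
                 c(idx[i, j], idx[i + 1, j], idx[i, j + 1]),
                 c(idx[i + 1, j], idx[i + 1, j + 1], idx[i, j + 1]))
  }
  surface_pair(white, pial, tri)
}

# rotation matrix about a random axis (seeded by caller)
random_rotation <- function() {
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
  th <- runif(1, 0, 2 * pi)
  K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
}

# brute-force connected components by BFS (oracle for largest_component)
bfs_components <- function(mask, triangles) {
  n <- length(mask)
  nb <- vector("list", n)
  for (r in seq_len(nrow(triangles))) {
    t3 <- triangles[r, ]
    for (a in 1:3) for (b in 1:3) if (a != b)
      nb[[t3[a]]] <- c(nb[[t3[a]]], t3[b])
  }
  lab <- integer(n); cur <- 0L
  for (s in which(mask)) {
    if (lab[s] > 0L) next
    cur <- cur + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      if (lab[v] > 0L) next
      lab[v] <- cur
      queue <- c(queue, Filter(function(u) mask[u] && lab[u] == 0L,
                               unique(nb[[v]])))
    }
  }
  lab
}

# brute-force Benjamini-Hochberg step-up rejection set (oracle for fdr_bh)
bh_bruteforce <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ks <- which(p[o] <= (seq_len(m) / m) * q)
  rej <- rep(FALSE, m)
  if (length(ks)) rej[o[seq_len(max(ks))]] <- TRUE
  rej
}
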