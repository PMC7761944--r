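# Fixture meshes built in code, plus independent brute-force oracles used to
# cross-check the package's geometry kernels.

makeCubeMesh <- function(a = 1, origin = c(0, 0, 0)) {
  v <- as.matrix(expand.grid(c(0, a), c(0, a), c(0, a)))
  v <- sweep(v, 2, origin, "+")
  f <- rbind(c(1, 3, 4), c(1, 4, 2),   # z = 0 (down)
             c(5, 6, 8), c(5, 8, 7),   # z = a (up)
             c(1, 2, 6), c(1, 6, 5),   # y = 0
             c(3, 7, 8), c(3, 8, 4),   # y = a
             c(1, 5, 7), c(1, 7, 3),   # x = 0
             c(2, 4, 8), c(2, 8, 6))   # x = a
  TriangleMesh(v, f)
}

makeBoxMesh <- function(dims = c(1, 1, 1), origin = c(0, 0, 0)) {
  m <- makeCubeMesh(1, c(0, 0, 0))
  v <- sweep(meshVertices(m), 2, dims, "*")
  TriangleMesh(sweep(v, 2, origin, "+"), meshFaces(m))
}

# open cylinder (no caps), axis +z
makeOpenCylinder <- function(r = 1, h = 2, nTheta = 24, nz = 5) {
  th <- seq(0, 2 * pi, length.out = nTheta + 1)[-(nTheta + 1)]
  zs <- seq(0, h, length.out = nz)
  v <- do.call(rbind, lapply(zs, function(z) cbind(r * cos(th), r * sin(th), z)))
  f <- list()
  for (k in seq_len(nz - 1)) {
    i0 <- (k - 1) * nTheta + seq_len(nTheta)
    i1 <- k * nTheta + seq_len(nTheta)
    j2 <- c(2:nTheta, 1)
    f[[k]] <- rbind(cbind(i0, i0[j2], i1[j2]), cbind(i0, i1[j2], i1))
  }
  TriangleMesh(v, do.call(rbind, f))
}

# icosphere by midpoint subdivision, radius r
makeIcosphere <- function(subdiv = 3, r = 1) {
  t <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, t, 0), c(1, t, 0), c(-1, -t, 0), c(1, -t, 0),
             c(0, -1, t), c(0, 1, t), c(0, -1, -t), c(0, 1, -t),
             c(t, 0, -1), c(t, 0, 1), c(-t, 0, -1), c(-t, 0, 1))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdiv)) {
    mid <- new.env()
    nv <- nrow(v)
    getMid <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      hit <- mid[[key]]
      if (!is.null(hit)) return(hit)
      v <<- rbind(v, (v[i, ] + v[j, ]) / 2)
      nv <<- nv + 1
      mid[[key]] <- nv
      nv
    }
    nf <- matrix(0L, 0, 3)
    for (k in seq_len(nrow(f))) {
      a <- f[k, 1]; b <- f[k, 2]; c3 <- f[k, 3]
      ab <- getMid(a, b); bc <- getMid(b, c3); ca <- getMid(c3, a)
      nf <- rbind(nf, c(a, ab, ca), c(b, bc, ab), c(c3, ca, bc), c(ab, bc, ca))
    }
    f <- nf
  }
  v <- v / sqrt(rowSums(v^2)) * r
  TriangleMesh(v, f)
}

# --- independent closest-point oracle -------------------------------------
# candidates: the three vertices, the clamped projection on each edge
# segment, and the in-plane projection when its barycentrics are all
# positive. Deliberately a different algorithm from the package kernel.
oracleClosestOnTriangle <- function(p, a, b, c) {
  cands <- list(a, b, c)
  for (e in list(list(a, b), list(b, c), list(c, a))) {
    d <- e[[2]] - e[[1]]
    t <- sum((p - e[[1]]) * d) / sum(d * d)
    t <- max(0, min(1, t))
    cands[[length(cands) + 1]] <- e[[1]] + t * d
  }
  n <- c((b - a)[2] * (c - a)[3] - (b - a)[3] * (c - a)[2],
         (b - a)[3] * (c - a)[1] - (b - a)[1] * (c - a)[3],
         (b - a)[1] * (c - a)[2] - (b - a)[2] * (c - a)[1])
  if (sum(n^2) > 0) {
    q <- p - sum((p - a) * n) / sum(n^2) * n
    M <- cbind(b - a, c - a)
    uv <- tryCatch(qr.solve(M, q - a), error = function(e) NULL)
    if (!is.null(uv) && all(uv > -1e-12) && sum(uv) < 1 + 1e-12)
      cands[[length(cands) + 1]] <- q
  }
  d2 <- vapply(cands, function(x) sum((p - x)^2), numeric(1))
  cands[[which.min(d2)]]
}

oracleClosestOnMesh <- function(p, mesh) {
  v <- meshVertices(mesh)
  f <- meshFaces(mesh)
  best <- NULL
  bestD <- Inf
  for (k in seq_len(nrow(f))) {
    q <- oracleClosestOnTriangle(p, v[f[k, 1], ], v[f[k, 2], ], v[f[k, 3], ])
    d <- sqrt(sum((p - q)^2))
    if (d < bestD) { bestD <- d; best <- q }
  }
  list(point = best, distance = bestD)
}

# brute-force boundary edge scan: edges with exactly one incident face
oracleBoundaryEdgeCount <- function(mesh) {
  f <- meshFaces(mesh)
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  sum(table(key) == 1)
}

# exact Wilcoxon signed-rank p (two-sided) by enumerating all sign patterns
oracleSignedRankP <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  obs <- sum(r[d > 0])
  stats <- vapply(seq_len(2^n) - 1, function(mask) {
    sum(r[bitwAnd(mask, 2^(seq_len(n) - 1)) > 0])
  }, numeric(1))
  mu <- n * (n + 1) / 4
  mean(abs(stats - mu) >= abs(obs - mu) - 1e-12)
}

# exact Mann-Whitney p (two-sided) by enumerating all group assignments
oracleRankSumP <- function(x, y) {
  pooled <- c(x, y)
  n <- length(x)
  r <- rank(pooled)
  obs <- sum(r[seq_len(n)])
  combs <- combn(length(pooled), n)
  stats <- apply(combs, 2, function(idx) sum(r[idx]))
  mu <- n * (length(pooled) + 1) / 2
  mean(abs(stats - mu) >= abs(obs - mu) - 1e-12)
}

# small shared fixtures for pipeline tests (built once per test run)
tinyCase <- local({
  cache <- new.env()
  function(id = "tiny", toothType = "incisor", loss = 1,
           pattern = "symmetric", seed = 3L, noise = NULL,
           retainer = retainerSpec(), resolution = 1600L) {
    key <- paste(id, toothType, loss, pattern, seed, is.null(noise),
                 is.null(retainer), resolution)
    if (is.null(cache[[key]]))
      cache[[key]] <- makeWearCase(id, toothType, loss, pattern,
                                   crowding = FALSE, seed = seed,
                                   resolution = resolution, noise = noise,
                                   retainer = retainer)
    cache[[key]]
  }
})
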