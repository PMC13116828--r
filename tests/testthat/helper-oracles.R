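# Independent brute-force oracles and fixture builders. These deliberately
# use different algorithms/code paths from the package implementation.

# exhaustive containing-cell search: test every face's z-band and longitude
# interval instead of the package's closed-form index arithmetic
bf_face_of_direction <- function(dirs, sphere) {
  dirs <- rbind(dirs)
  nb <- sphere$n_bands; nl <- sphere$n_lon
  dz <- 2 / nb; dlon <- 2 * pi / nl
  f <- seq_len(sphere$n_faces)
  b <- (f - 1) %/% nl + 1
  l <- (f - 1) %% nl + 1
  zhi <- 1 - (b - 1) * dz; zlo <- 1 - b * dz
  lamlo <- (l - 1) * dlon; lamhi <- l * dlon
  out <- integer(nrow(dirs))
  for (i in seq_len(nrow(dirs))) {
    v <- dirs[i, ] / sqrt(sum(dirs[i, ]^2))
    lam <- atan2(v[2], v[1]) %% (2 * pi)
    okz <- (v[3] > zlo & v[3] <= zhi) | (b == nb & v[3] >= zlo - 1e-12)
    okl <- (lam >= lamlo & lam < lamhi) | (l == nl & lam >= lamlo)
    hit <- which(okz & okl)
    out[i] <- hit[1]
  }
  out
}

# flood-fill connected components over the face grid metric
bf_components <- function(faces, sphere, link_radius) {
  k <- length(faces)
  nl <- sphere$n_lon
  band <- (faces - 1) %/% nl + 1
  lon <- (faces - 1) %% nl + 1
  gdist <- function(i, j) {
    dl <- abs(lon[i] - lon[j])
    abs(band[i] - band[j]) + min(dl, nl - dl)
  }
  comp <- rep(NA_integer_, k)
  cur <- 0L
  for (s in seq_len(k)) {
    if (!is.na(comp[s])) next
    cur <- cur + 1L
    queue <- s; comp[s] <- cur
    while (length(queue)) {
      i <- queue[1]; queue <- queue[-1]
      for (j in seq_len(k)) {
        if (is.na(comp[j]) && gdist(i, j) <= link_radius) {
          comp[j] <- cur; queue <- c(queue, j)
        }
      }
    }
  }
  comp
}

# per-point activation gradient, one explicit pass per point (the package
# builds a full dist matrix instead)
bf_gradient <- function(points, radius, min_dist) {
  n <- nrow(points)
  X <- as.matrix(points[, c("x", "y", "z")])
  lat <- points$lat
  gr <- numeric(n)
  for (i in seq_len(n)) {
    d <- sqrt((X[, 1] - X[i, 1])^2 + (X[, 2] - X[i, 2])^2 +
              (X[, 3] - X[i, 3])^2)
    ok <- d <= radius & d >= min_dist & seq_len(n) != i
    gr[i] <- if (any(ok)) max(abs(lat[ok] - lat[i]) / d[ok]) else 0
  }
  gr
}

# O(n^2) concordant-pair AUC with half ties
bf_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  if (!length(pos) || !length(neg)) return(NA_real_)
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

random_export <- function(n = 100, seed = 1, radius = 35) {
  set.seed(seed)
  g <- matrix(rnorm(3 * n), n, 3)
  g <- g / sqrt(rowSums(g^2)) * radius * runif(n, 0.9, 1.1)
  eam_export(data.frame(
    x = g[, 1], y = g[, 2], z = g[, 3],
    alpha = runif(n, 0, 360), beta = runif(n, 0, 360), gamma = runif(n, 0, 360),
    uni_v = runif(n, 2, 12), bip_v = runif(n, 0.1, 5),
    lat = runif(n, -60, 40), imp = runif(n, 80, 140)),
    patient_id = sprintf("rand-%d", seed))
}

random_rotation <- function(seed) {
  set.seed(seed)
  qr_d <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qr_d)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

apply_rigid <- function(export, Q, shift = c(0, 0, 0), scale = 1) {
  pts <- export$points
  X <- as.matrix(pts[, c("x", "y", "z")]) %*% t(Q) * scale
  pts$x <- X[, 1] + shift[1]; pts$y <- X[, 2] + shift[2]; pts$z <- X[, 3] + shift[3]
  eam_export(pts, patient_id = export$patient_id, metadata = export$metadata)
}

# shared small sphere for tests that don't need the full tessellation
small_sphere <- function() build_sphere(12L, 12L)
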