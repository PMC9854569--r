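# Independent oracles used across the suite.  These deliberately avoid
# the package's own computational paths: brute force, direct formula
# evaluation, or literal simulation.

# Random star polygon (test-side construction, not generate_cell()).
random_polygon <- function(n_rays = 32, center = c(20, 20),
                           rmin = 3, rmax = 15, score = NULL) {
  if (is.null(score)) score <- runif(1)
  star_polygon(center, runif(n_rays, rmin, rmax), score = score)
}

# Vertices by direct trigonometric evaluation.
oracle_vertices <- function(p) {
  th <- 2 * pi * (seq_len(p$n_rays) - 1) / p$n_rays
  cbind(p$center[1] + p$distances * sin(th),
        p$center[2] + p$distances * cos(th))
}

# Area by fine rasterization over the bounding box.
oracle_area_raster <- function(p, step = 0.05) {
  v <- oracle_vertices(p)
  rs <- seq(min(v[, 1]), max(v[, 1]), by = step)
  cs <- seq(min(v[, 2]), max(v[, 2]), by = step)
  count <- 0L
  for (r in rs) {
    # even-odd crossing test per row, vectorized over columns
    xs <- c()
    n <- nrow(v)
    for (a in seq_len(n)) {
      b <- if (a == 1) n else a - 1
      if ((v[b, 1] > r) != (v[a, 1] > r)) {
        xs <- c(xs, v[b, 2] + (r - v[b, 1]) * (v[a, 2] - v[b, 2]) /
                  (v[a, 1] - v[b, 1]))
      }
    }
    if (length(xs) == 0) next
    xs <- sort(xs)
    inside <- colSums(outer(xs, cs, ">")) %% 2 == 1
    count <- count + sum(inside)
  }
  count * step^2
}

# IoU via the package's independent raster backend at a fine grid.
oracle_iou_raster <- function(a, b, grid = 0.02) {
  polygon_iou(a, b, method = "raster", grid = grid)
}

# Exhaustive O(N^2) Euclidean distance transform (border = background).
oracle_edt <- function(labels) {
  H <- nrow(labels); W <- ncol(labels)
  bg <- which(labels == 0, arr.ind = TRUE)
  out <- matrix(0, H, W)
  for (i in seq_len(H)) {
    for (j in seq_len(W)) {
      if (labels[i, j] == 0) next
      dborder <- min(i, j, H + 1 - i, W + 1 - j)
      dbg <- if (nrow(bg) > 0)
        sqrt(min((bg[, 1] - i)^2 + (bg[, 2] - j)^2)) else Inf
      out[i, j] <- min(dborder, dbg)
    }
  }
  out
}

# Sub-pixel ray march at a very fine step, independent of the C++ path.
oracle_ray_distance <- function(labels, i, j, dir_rc, step = 0.01) {
  H <- nrow(labels); W <- ncol(labels)
  id <- labels[i + 1, j + 1]
  t <- step
  repeat {
    r <- round(i + t * dir_rc[1]); c <- round(j + t * dir_rc[2])
    if (r < 0 || r >= H || c < 0 || c >= W) return(t)
    if (labels[r + 1, c + 1] != id) return(t)
    t <- t + step
    if (t > sqrt(H^2 + W^2) + 2) return(t)
  }
}

# Literal line-by-line simulation of the adaptive suppression
# pseudocode, using polygon_iou() directly on the polygon objects.
oracle_pa_nms <- function(polygons, scores, densities, Nt) {
  B <- polygons; S <- scores; D <- densities
  F_idx <- integer(0)
  idx <- seq_along(B)
  while (length(B) > 0) {
    m <- which.max(S)
    M <- B[[m]]
    NM <- max(Nt, D[m])
    F_idx <- c(F_idx, idx[m])
    B <- B[-m]; S <- S[-m]; D <- D[-m]; idx <- idx[-m]
    if (length(B) > 0) {
      drop <- vapply(B, function(p) polygon_iou(M, p) >= NM, TRUE)
      B <- B[!drop]; S <- S[!drop]; D <- D[!drop]; idx <- idx[!drop]
    }
  }
  F_idx
}

# Exhaustive maximum one-to-one matching: maximum number of pred/gt
# pairs with IoU >= tau, by recursion over predictions.
oracle_max_matching <- function(iou, tau) {
  np <- nrow(iou); ng <- ncol(iou)
  if (np == 0 || ng == 0) return(0L)
  best <- 0L
  rec <- function(p, used, count) {
    if (count + (np - p + 1) <= best) return()
    if (p > np) { best <<- max(best, count); return() }
    rec(p + 1, used, count)  # leave prediction p unmatched
    for (g in seq_len(ng)) {
      if (!used[g] && iou[p, g] >= tau) {
        used[g] <- TRUE
        rec(p + 1, used, count + 1L)
        used[g] <- FALSE
      }
    }
  }
  rec(1L, rep(FALSE, ng), 0L)
  best
}

# Tiny deterministic dataset for training smoke tests.
tiny_dataset <- function(n, size = 48, seed = 99) {
  cfg <- generator_config(image_size = c(size, size),
                          cells_per_image = c(2, 4),
                          radius_range = c(5, 9), seed = seed)
  generate_dataset(n, cfg, n_rays = 8)$pairs
}
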