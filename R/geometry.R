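#' Star-convex polygon
#'
#' A star-convex polygon is described by a continuous center point, `n_rays`
#' non-negative radial distances along fixed equiangular directions, and an
#' optional confidence score.  Vertex `k` lies at
#' `center + distances[k] * ray_directions(n_rays)[k, ]`; connecting the
#' vertices in ray order yields a simple polygon that is star-shaped about
#' its center.
#'
#' @param center numeric length-2, `(row, col)` in 0-based continuous pixel
#'   coordinates.
#' @param distances numeric vector of `n_rays` non-negative radial
#'   distances in pixels.
#' @param score confidence in `[0, 1]`.
#' @return An object of class `star_polygon`.
#' @examples
#' p <- star_polygon(c(10, 10), rep(5, 32))
#' polygon_area(p)
#' @export
star_polygon <- function(center, distances, score = 1) {
  stopifnot(length(center) == 2, is.numeric(distances))
  if (length(distances) < 3)
    stop("a star polygon needs at least 3 rays")
  if (any(distances < 0)) stop("radial distances must be non-negative")
  if (score < 0 || score > 1) stop("score must lie in [0, 1]")
  structure(list(center = as.numeric(center),
                 distances = as.numeric(distances),
                 n_rays = length(distances),
                 score = as.numeric(score)),
            class = "star_polygon")
}

#' @export
print.star_polygon <- function(x, ...) {
  cat(sprintf("star_polygon: center (%.2f, %.2f), %d rays, score %.3f\n",
              x$center[1], x$center[2], x$n_rays, x$score))
  cat(sprintf("  radial distances: %.2f-%.2f px (mean %.2f)\n",
              min(x$distances), max(x$distances), mean(x$distances)))
  invisible(x)
}

#' Equiangular ray directions
#'
#' Unit vectors of the `n_rays` radial directions, in `(row, col)` order.
#' Direction `k` (0-based) has angle `theta_k = 2*pi*k/n_rays` measured
#' from the +col axis, with +row at `pi/2`.
#'
#' @param n_rays number of directions, at least 3.
#' @return `n_rays x 2` matrix of unit `(row, col)` vectors.
#' @export
ray_directions <- function(n_rays) {
  if (!is.numeric(n_rays) || n_rays < 3)
    stop("n_rays must be an integer >= 3")
  theta <- 2 * pi * (seq_len(n_rays) - 1) / n_rays
  cbind(row = sin(theta), col = cos(theta))
}

#' Polygon vertices
#'
#' @param p a [star_polygon()].
#' @return `n_rays x 2` matrix of `(row, col)` vertex coordinates, in ray
#'   order.
#' @export
polygon_vertices <- function(p) {
  stopifnot(inherits(p, "star_polygon"))
  dirs <- ray_directions(p$n_rays)
  sweep(dirs * p$distances, 2, p$center, "+")
}

#' Polygon area (shoelace)
#'
#' @inheritParams polygon_vertices
#' @return non-negative area in square pixels; 0 for a degenerate polygon.
#' @export
polygon_area <- function(p) {
  cpp_polygon_area(polygon_vertices(p))
}

#' Polygon intersection-over-union
#'
#' IoU of two star-convex polygons.  The default backend computes the
#' intersection area exactly by decomposing one polygon into its triangle
#' fan and clipping the other against each (convex) triangle; the
#' `"raster"` backend supersamples the union bounding box and serves as an
#' independent cross-check.  The IoU of two degenerate (zero-area)
#' polygons is 0 by definition.
#'
#' @param a,b [star_polygon()] objects.
#' @param method `"clip"` (exact, default) or `"raster"`.
#' @param grid sampling step in pixels for the raster backend.
#' @return IoU in `[0, 1]`.
#' @export
polygon_iou <- function(a, b, method = c("clip", "raster"), grid = 0.1) {
  method <- match.arg(method)
  va <- polygon_vertices(a)
  vb <- polygon_vertices(b)
  if (method == "clip") {
    cpp_clip_iou(va, vb, a$center[1], a$center[2], b$center[1], b$center[2])
  } else {
    if (cpp_polygon_area(va) <= 0 && cpp_polygon_area(vb) <= 0) return(0)
    cpp_raster_iou(va, vb, grid)
  }
}

#' Rasterize a polygon into a binary mask
#'
#' A pixel is set iff its center lies inside the polygon (even-odd rule);
#' parts of the polygon outside the image are dropped.
#'
#' @inheritParams polygon_vertices
#' @param shape integer `(H, W)`.
#' @return `H x W` integer matrix of 0/1.
#' @export
rasterize_polygon <- function(p, shape) {
  stopifnot(length(shape) == 2, all(shape > 0))
  cpp_rasterize(polygon_vertices(p), as.integer(shape[1]),
                as.integer(shape[2]))
}

#' Read and write polygon sets as CSV
#'
#' One polygon per row: `center_row, center_col, score, d_0 .. d_{n-1}`.
#'
#' @param polys list of [star_polygon()] objects.
#' @param path output file.
#' @export
write_polygons_csv <- function(polys, path) {
  if (length(polys) == 0) {
    write.csv(data.frame(center_row = numeric(0), center_col = numeric(0),
                         score = numeric(0)), path, row.names = FALSE)
    return(invisible(path))
  }
  n <- polys[[1]]$n_rays
  df <- do.call(rbind, lapply(polys, function(p) {
    stopifnot(p$n_rays == n)
    c(p$center, p$score, p$distances)
  }))
  df <- as.data.frame(df)
  names(df) <- c("center_row", "center_col", "score",
                 paste0("d_", seq_len(n) - 1))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_polygons_csv
#' @export
read_polygons_csv <- function(path) {
  df <- read.csv(path)
  dcols <- grep("^d_", names(df))
  lapply(seq_len(nrow(df)), function(i) {
    star_polygon(c(df$center_row[i], df$center_col[i]),
                 as.numeric(df[i, dcols]), score = df$score[i])
  })
}

#' Export a polygon as a GeoJSON-style vertex list
#'
#' @inheritParams polygon_vertices
#' @return a list with `type`, `coordinates` (closed ring, `(col, row)`
#'   order as GeoJSON x/y) and `score`.
#' @export
polygon_geojson <- function(p) {
  v <- polygon_vertices(p)
  ring <- cbind(v[, 2], v[, 1])
  ring <- rbind(ring, ring[1, ])
  list(type = "Polygon", coordinates = list(ring), score = p$score)
}
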