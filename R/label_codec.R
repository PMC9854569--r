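#' Fill interior holes in an instance label map
#'
#' Background regions that are not connected to the image border through
#' background (4-connectivity) are assigned the instance id that encloses
#' them.  Instance pixels are never changed.
#'
#' @param labels integer matrix; 0 is background, positive ids are
#'   instances.
#' @return label map of the same shape with holes filled.
#' @export
fill_holes <- function(labels) {
  stopifnot(is.matrix(labels), all(labels >= 0))
  cpp_fill_holes(.as_int_matrix(labels))
}

.as_int_matrix <- function(m) {
  if (!is.integer(m)) storage.mode(m) <- "integer"
  m
}

#' Object probability map
#'
#' For every foreground pixel, the Euclidean distance to the nearest
#' background pixel (the image border counts as background), normalized by
#' the maximum distance within its own instance so that every cell attains
#' probability 1 at its core.  Background pixels are 0.
#'
#' @param labels integer label map with holes already filled.
#' @param per_instance normalize per instance (default) or by the global
#'   maximum distance.
#' @return numeric matrix in `[0, 1]`.
#' @export
object_probability_map <- function(labels, per_instance = TRUE) {
  labels <- .as_int_matrix(labels)
  edt <- cpp_edt(labels)
  prob <- matrix(0, nrow(labels), ncol(labels))
  fg <- labels > 0
  if (!any(fg)) return(prob)
  if (per_instance) {
    mx <- tapply(edt[fg], labels[fg], max)
    prob[fg] <- edt[fg] / mx[as.character(labels[fg])]
  } else {
    prob[fg] <- edt[fg] / max(edt[fg])
  }
  prob
}

#' Radial distance maps
#'
#' For each foreground pixel and each of the `n_rays` equiangular
#' directions, the star-convex distance from the pixel to the boundary of
#' its instance: the ray is marched in unit steps and stops at the first
#' sampled position whose nearest pixel does not carry the same id (or
#' falls outside the image); the final step is refined at `refine`
#' resolution.  Background pixels are all-zero.
#'
#' @inheritParams object_probability_map
#' @param n_rays number of radial directions (default 32).
#' @param refine sub-pixel refinement step for the boundary crossing.
#' @return `H x W x n_rays` array of distances in pixels.
#' @export
radial_distance_maps <- function(labels, n_rays = 32, refine = 0.01) {
  labels <- .as_int_matrix(labels)
  if (n_rays < 3) stop("n_rays must be >= 3")
  cpp_radial_dist(labels, ray_directions(n_rays), refine)
}

#' Encode an instance label map into network targets
#'
#' Composition of [fill_holes()], [object_probability_map()] and
#' [radial_distance_maps()]: the training representation of one image.
#'
#' @inheritParams radial_distance_maps
#' @return list with `prob` (`H x W`), `dist` (`H x W x n_rays`) and the
#'   hole-filled `labels`.
#' @export
encode_targets <- function(labels, n_rays = 32) {
  filled <- fill_holes(labels)
  list(prob = object_probability_map(filled),
       dist = radial_distance_maps(filled, n_rays),
       labels = filled)
}

#' Decode the star polygon stored at one pixel
#'
#' Reads the `n_rays` distances of pixel `(row, col)` (0-based) from a
#' distance stack and returns the corresponding polygon, scored by the
#' probability map when given.
#'
#' @param dist `H x W x n_rays` distance stack.
#' @param row,col 0-based pixel coordinates.
#' @param prob optional probability map supplying the score.
#' @return a [star_polygon()].
#' @export
decode_pixel_polygon <- function(dist, row, col, prob = NULL) {
  d <- dist[row + 1, col + 1, ]
  s <- if (is.null(prob)) 1 else prob[row + 1, col + 1]
  star_polygon(c(row, col), pmax(d, 0), score = min(max(s, 0), 1))
}

#' Round-trip an encoded instance back to a mask
#'
#' Decodes the polygon at the instance's maximum-probability pixel and
#' rasterizes it; used to quantify how much of an instance the star-convex
#' representation can recover.
#'
#' @param enc result of [encode_targets()].
#' @param id instance id.
#' @return list with the recovered `mask` and its IoU against the
#'   instance mask.
#' @export
roundtrip_instance <- function(enc, id) {
  inst <- enc$labels == id
  if (!any(inst)) stop("no pixels with id ", id)
  p <- enc$prob
  p[!inst] <- -1
  px <- arrayInd(which.max(p), dim(p))
  poly <- decode_pixel_polygon(enc$dist, px[1] - 1, px[2] - 1, enc$prob)
  mask <- rasterize_polygon(poly, dim(enc$labels))
  inter <- sum(mask == 1 & inst)
  un <- sum(mask == 1 | inst)
  list(mask = mask, polygon = poly,
       iou = if (un > 0) inter / un else 0)
}
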