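#' Synthetic adherent-cell generator configuration
#'
#' Parameters of the synthetic dataset: single-channel grayscale images
#' containing a handful of adherent but never overlapping circular-like
#' cells with matching instance label maps.  Defaults emulate the
#' geometry of the reference cell dataset: 256x256 images with 3--9
#' cells per image of varied shape and size.
#'
#' @param image_size integer `(H, W)`.
#' @param cells_per_image integer range `(min, max)` of cells per image.
#' @param radius_range base cell radius range in pixels.
#' @param irregularity amplitude of the low-frequency radial perturbation
#'   (0 gives circles).
#' @param adhesion allow (and encourage) tangent contact between cells.
#' @param adhesion_prob probability that a new cell is placed adjacent to
#'   an existing one.
#' @param background background gray level in `[0, 1]`.
#' @param cell_intensity range of per-cell base gray levels.
#' @param noise_sd additive Gaussian noise standard deviation.
#' @param seed RNG seed used by [generate_dataset()].
#' @return object of class `generator_config`.
#' @export
generator_config <- function(image_size = c(256, 256),
                             cells_per_image = c(3, 9),
                             radius_range = c(12, 40),
                             irregularity = 0.25,
                             adhesion = TRUE, adhesion_prob = 0.6,
                             background = 0.15,
                             cell_intensity = c(0.55, 0.85),
                             noise_sd = 0.05, seed = 1) {
  stopifnot(length(image_size) == 2, all(image_size > 0),
            cells_per_image[1] >= 1,
            cells_per_image[2] >= cells_per_image[1],
            all(radius_range > 0), irregularity >= 0)
  structure(list(image_size = as.integer(image_size),
                 cells_per_image = as.integer(cells_per_image),
                 radius_range = radius_range,
                 irregularity = irregularity,
                 adhesion = isTRUE(adhesion),
                 adhesion_prob = adhesion_prob,
                 background = background,
                 cell_intensity = cell_intensity,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "generator_config")
}

#' Generate one random cell shape
#'
#' A star-convex polygon with a random center inside the image (margin
#' one radius), base radius drawn from `radius_range`, and distances
#' `r * (1 + irregularity * p(theta))` where `p` is a smooth periodic
#' perturbation (random low-order harmonics, normalized to `[-1, 1]`).
#' Consumes the current RNG stream.
#'
#' @param config a [generator_config()].
#' @param n_rays polygon resolution.
#' @param center optional fixed `(row, col)` center.
#' @return a [star_polygon()].
#' @export
generate_cell <- function(config = generator_config(), n_rays = 32,
                          center = NULL) {
  H <- config$image_size[1]; W <- config$image_size[2]
  r0 <- runif(1, config$radius_range[1], config$radius_range[2])
  rmax <- r0 * (1 + config$irregularity)
  if (is.null(center)) {
    mr <- min(rmax, (H - 1) / 2); mc <- min(rmax, (W - 1) / 2)
    center <- c(runif(1, mr, H - 1 - mr), runif(1, mc, W - 1 - mc))
  }
  theta <- 2 * pi * (seq_len(n_rays) - 1) / n_rays
  p <- rep(0, n_rays)
  for (k in 2:4) p <- p + runif(1) * cos(k * theta + runif(1, 0, 2 * pi))
  mx <- max(abs(p))
  if (mx > 0) p <- p / mx
  star_polygon(center, r0 * (1 + config$irregularity * p))
}

.mask_touches <- function(mask, labels) {
  # any pixel of mask 8-adjacent to (or on) a labelled pixel?
  idx <- which(mask == 1, arr.ind = TRUE)
  if (nrow(idx) == 0) return(FALSE)
  H <- nrow(labels); W <- ncol(labels)
  for (di in -1:1) for (dj in -1:1) {
    r <- idx[, 1] + di; c <- idx[, 2] + dj
    ok <- r >= 1 & r <= H & c >= 1 & c <= W
    if (any(labels[cbind(r[ok], c[ok])] > 0)) return(TRUE)
  }
  FALSE
}

#' Generate one synthetic image with its instance label map
#'
#' Cells are placed by rejection sampling: a candidate polygon is
#' rasterized and accepted only if its mask shares no pixel with the
#' cells already placed (tangent contact is allowed).  Under adhesion,
#' later cells are preferentially proposed tangent to an existing cell.
#' Cells are rendered with a center-bright interior gradient on a darker
#' background, plus Gaussian noise.  Consumes the current RNG stream;
#' see [generate_dataset()] for seeded generation.
#'
#' @param config a [generator_config()].
#' @param n_rays polygon resolution of the generated shapes.
#' @param max_tries placement attempts per cell before giving up (the
#'   image then simply contains fewer cells, never an overlap).
#' @return list with `image` (matrix in `[0, 1]`), `labels` (integer
#'   matrix) and `polygons` (the generating shapes).
#' @export
generate_image <- function(config = generator_config(), n_rays = 32,
                           max_tries = 50) {
  H <- config$image_size[1]; W <- config$image_size[2]
  n_cells <- sample(config$cells_per_image[1]:config$cells_per_image[2], 1)
  labels <- matrix(0L, H, W)
  polys <- list()
  for (k in seq_len(n_cells)) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      adhere <- config$adhesion && length(polys) > 0 &&
        runif(1) < config$adhesion_prob
      if (adhere) {
        anchor <- polys[[sample(length(polys), 1)]]
        r0 <- runif(1, config$radius_range[1], config$radius_range[2])
        phi <- runif(1, 0, 2 * pi)
        gap <- runif(1, 0.97, 1.04)
        d <- (mean(anchor$distances) + r0) * gap
        ctr <- anchor$center + d * c(sin(phi), cos(phi))
        rmax <- r0 * (1 + config$irregularity)
        if (ctr[1] < rmax || ctr[1] > H - 1 - rmax ||
            ctr[2] < rmax || ctr[2] > W - 1 - rmax) next
        cand <- generate_cell(modifyList(config, list(
          radius_range = c(r0, r0))), n_rays, center = ctr)
      } else {
        cand <- generate_cell(config, n_rays)
      }
      mask <- rasterize_polygon(cand, c(H, W))
      if (any(labels[mask == 1] > 0)) next
      if (sum(mask) < 9) next
      labels[mask == 1] <- k
      polys[[length(polys) + 1]] <- cand
      placed <- TRUE
      break
    }
  }
  # relabel 1..K in case some cells failed to place
  ids <- setdiff(sort(unique(as.vector(labels))), 0)
  relab <- matrix(0L, H, W)
  for (i in seq_along(ids)) relab[labels == ids[i]] <- i
  labels <- relab
  # render: per-cell base intensity, center-bright interior gradient
  img <- matrix(config$background, H, W)
  if (length(ids) > 0) {
    pm <- object_probability_map(labels)
    base <- runif(length(ids), config$cell_intensity[1],
                  config$cell_intensity[2])
    fg <- labels > 0
    img[fg] <- base[labels[fg]] * (0.7 + 0.3 * pm[fg])
  }
  img <- img + rnorm(H * W, sd = config$noise_sd)
  img <- pmin(pmax(img, 0), 1)
  list(image = img, labels = labels, polygons = polys)
}

#' Generate a seeded dataset
#'
#' Generates `n_images` image/label pairs, fully reproducible from
#' `config$seed`.  When `out_dir` is given, images and label maps are
#' written as TIFF (`img_0001.tif`, `lab_0001.tif`, ...) together with a
#' `manifest.csv` (filename, n_cells, seed).
#'
#' @param n_images number of images.
#' @param config a [generator_config()].
#' @param out_dir optional output directory.
#' @param n_rays polygon resolution of the generated shapes.
#' @return invisibly, a list with `pairs` (in-memory dataset) and
#'   `manifest` (data frame).
#' @export
generate_dataset <- function(n_images, config = generator_config(),
                             out_dir = NULL, n_rays = 32) {
  set.seed(config$seed)
  pairs <- vector("list", n_images)
  manifest <- data.frame(filename = character(0), n_cells = integer(0),
                         seed = integer(0))
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  for (i in seq_len(n_images)) {
    g <- generate_image(config, n_rays)
    pairs[[i]] <- g[c("image", "labels")]
    fn <- sprintf("img_%04d.tif", i)
    if (!is.null(out_dir)) {
      write_image_tiff(g$image, file.path(out_dir, fn))
      write_label_tiff(g$labels, file.path(out_dir, sprintf("lab_%04d.tif", i)))
    }
    manifest <- rbind(manifest,
                      data.frame(filename = fn, n_cells = max(g$labels),
                                 seed = config$seed))
  }
  if (!is.null(out_dir))
    write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  invisible(list(pairs = pairs, manifest = manifest))
}

#' Does an image contain at least one touching cell pair?
#'
#' Two cells touch when some pixel of one is 8-adjacent to a pixel of
#' the other (masks never share pixels by construction).
#'
#' @param labels instance label map.
#' @return logical.
#' @export
has_touching_pair <- function(labels) {
  ids <- setdiff(sort(unique(as.vector(labels))), 0)
  if (length(ids) < 2) return(FALSE)
  for (id in ids) {
    if (.mask_touches(matrix(as.integer(labels == id), nrow(labels)),
                      ifelse(labels == id, 0L, labels)))
      return(TRUE)
  }
  FALSE
}
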