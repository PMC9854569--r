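#' Proposal set
#'
#' Parallel lists of candidate star polygons (`B`), their detection
#' scores (`S`) and detection densities (`D`), as consumed by [pa_nms()].
#'
#' @param polygons list of [star_polygon()] objects.
#' @param scores numeric scores in `[0, 1]`; defaults to the polygons'
#'   own scores.
#' @param densities numeric densities in `[0, 1]`, or `NULL` if not yet
#'   computed.
#' @return object of class `proposal_set`.
#' @export
proposal_set <- function(polygons, scores = NULL, densities = NULL) {
  if (is.null(scores)) scores <- vapply(polygons, `[[`, 0, "score")
  stopifnot(length(polygons) == length(scores))
  if (!is.null(densities)) stopifnot(length(densities) == length(polygons))
  structure(list(polygons = polygons, scores = as.numeric(scores),
                 densities = densities),
            class = "proposal_set")
}

#' @export
print.proposal_set <- function(x, ...) {
  cat(sprintf("proposal_set: %d polygons%s\n", length(x$polygons),
              if (is.null(x$densities)) "" else " (with densities)"))
  invisible(x)
}

#' @export
length.proposal_set <- function(x) length(x$polygons)

.proposal_geometry <- function(ps) {
  n <- length(ps$polygons)
  if (n == 0) return(list(centers = matrix(0, 0, 2), dists = NULL))
  m <- ps$polygons[[1]]$n_rays
  centers <- t(vapply(ps$polygons, `[[`, numeric(2), "center"))
  dists <- t(vapply(ps$polygons, `[[`, numeric(m), "distances"))
  list(centers = centers, dists = dists, dirs = ray_directions(m))
}

#' Extract polygon proposals from network predictions
#'
#' Every pixel whose predicted object probability reaches
#' `prob_threshold` becomes one star polygon centered at that pixel, with
#' that pixel's predicted radial distances and the probability as score.
#' Proposals are sorted by score (descending) and truncated to `top_k`.
#'
#' @param prob `H x W` probability map.
#' @param dist `H x W x n_rays` distance stack.
#' @param prob_threshold proposal threshold (default 0.3).
#' @param top_k keep at most this many proposals (default 5000).
#' @return a [proposal_set()] (densities not yet computed).
#' @export
extract_proposals <- function(prob, dist, prob_threshold = 0.3,
                              top_k = 5000) {
  stopifnot(all(dim(prob) == dim(dist)[1:2]))
  sel <- which(prob >= prob_threshold)
  if (length(sel) == 0) return(proposal_set(list()))
  ord <- sel[order(prob[sel], decreasing = TRUE)]
  ord <- ord[seq_len(min(length(ord), top_k))]
  idx <- arrayInd(ord, dim(prob))
  m <- dim(dist)[3]
  dmat <- matrix(dist, ncol = m)[ord, , drop = FALSE]
  polys <- lapply(seq_along(ord), function(i)
    star_polygon(c(idx[i, 1] - 1, idx[i, 2] - 1), pmax(dmat[i, ], 0),
                 score = min(max(prob[ord[i]], 0), 1)))
  proposal_set(polys)
}

#' Detection densities of a proposal set
#'
#' The density of a detection is how crowded the scene is around it:
#' the maximum polygon IoU it attains against *other objects* near it.
#' Because thousands of thresholded pixel proposals describe the same
#' handful of objects, the object set is first estimated with a standard
#' greedy NMS pre-pass at `Nt`; the density of proposal `i` is then its
#' maximum IoU against the estimated objects, excluding the object that
#' `i` itself represents (its best-matching one).  A singleton proposal
#' has density 0.  Pairs whose bounding circles cannot intersect are
#' skipped as provably zero.
#'
#' Defining the density instead as the maximum IoU against all other
#' raw proposals saturates near 1 inside every proposal cluster, which
#' raises every adaptive threshold to ~1 and disables suppression
#' entirely; see the methods vignette.
#'
#' @param ps a [proposal_set()].
#' @param Nt IoU threshold of the object-estimation pre-pass (use the
#'   same value as the final suppression).
#' @return the proposal set with `densities` filled in.
#' @export
proposal_density <- function(ps, Nt = 0.4) {
  stopifnot(inherits(ps, "proposal_set"))
  n <- length(ps$polygons)
  if (n == 0) { ps$densities <- numeric(0); return(ps) }
  if (n == 1) { ps$densities <- 0; return(ps) }
  g <- .proposal_geometry(ps)
  M <- cpp_iou_matrix(g$centers, g$dists, g$dirs)
  kept <- .greedy_nms_idx(ps$scores, M, Nt)
  dens <- numeric(n)
  for (i in seq_len(n)) {
    ious <- M[i, kept]
    if (i %in% kept) {
      ious <- ious[kept != i]        # own object is i itself
    } else if (length(ious) > 0) {
      ious <- ious[-which.max(ious)] # drop the best-matching object
    }
    dens[i] <- if (length(ious) > 0) max(ious) else 0
  }
  ps$densities <- dens
  attr(ps, "iou_matrix") <- M
  ps
}

# Standard greedy NMS on a precomputed IoU matrix; returns kept indices
# in pop order (score descending, ties by lower index).
.greedy_nms_idx <- function(scores, M, Nt) {
  n <- length(scores)
  alive <- rep(TRUE, n)
  keep <- integer(0)
  while (any(alive)) {
    cand <- which(alive)
    m <- cand[which.max(scores[cand])]
    keep <- c(keep, m)
    alive[m] <- FALSE
    alive[alive & M[m, ] >= Nt] <- FALSE
  }
  keep
}

#' Polygon-based adaptive non-maximum suppression
#'
#' Greedy suppression with a per-detection adaptive threshold: the
#' highest-scoring proposal `M` is moved to the kept list, its threshold
#' is `N_M = max(Nt, d_M)` (its density), and every remaining proposal
#' whose polygon IoU with `M` is `>= N_M` is removed together with its
#' score.  When all densities are at most `Nt` this reduces exactly to
#' standard greedy NMS at threshold `Nt`.  Score ties are broken by the
#' lower proposal index.
#'
#' @param ps a [proposal_set()]; densities are computed on the fly when
#'   missing.
#' @param Nt initial IoU threshold in `(0, 1)` (default 0.4).
#' @return the kept [proposal_set()] (with densities), in kept order.
#' @export
pa_nms <- function(ps, Nt = 0.4) {
  stopifnot(inherits(ps, "proposal_set"))
  if (Nt <= 0 || Nt >= 1) stop("Nt must lie in (0, 1)")
  if (is.null(ps$densities)) ps <- proposal_density(ps, Nt)
  n <- length(ps$polygons)
  if (n == 0) return(ps)
  M <- attr(ps, "iou_matrix")
  if (is.null(M)) {
    g <- .proposal_geometry(ps)
    M <- cpp_iou_matrix(g$centers, g$dists, g$dirs)
  }
  alive <- rep(TRUE, n)
  keep <- integer(0)
  scores <- ps$scores
  while (any(alive)) {
    cand <- which(alive)
    m <- cand[which.max(scores[cand])]  # which.max takes the first tie
    keep <- c(keep, m)
    alive[m] <- FALSE
    nm <- max(Nt, ps$densities[m])
    alive[alive & M[m, ] >= nm] <- FALSE  # row m: polygon_iou(M, p)
  }
  out <- proposal_set(ps$polygons[keep], scores[keep], ps$densities[keep])
  attr(out, "kept_index") <- keep
  out
}

#' Segment an image end to end
#'
#' Forward pass, proposal extraction, density computation, adaptive NMS,
#' and rasterization of the kept polygons into an instance label map.
#' Kept polygons are drawn in descending score order and earlier polygons
#' win contested pixels; ids are assigned 1..K by rank.
#'
#' @param params trained `spc_params`.
#' @param image numeric image matrix.
#' @param prob_threshold proposal threshold (default 0.3).
#' @param top_k proposal cap before density computation.
#' @param Nt adaptive NMS base threshold (default 0.4).
#' @param use_pa_nms when `FALSE`, run standard NMS (densities forced to
#'   0); the ablation switch.
#' @param equalize apply histogram equalization before the forward pass
#'   (must match training).
#' @return list with `labels` (integer map) and `proposals` (the kept
#'   [proposal_set()]).
#' @export
segment_image <- function(params, image, prob_threshold = 0.3, top_k = 5000,
                          Nt = 0.4, use_pa_nms = TRUE, equalize = TRUE) {
  if (equalize) image <- equalize_histogram(image)
  fw <- spc_forward(image, params)
  ps <- extract_proposals(fw$prob, fw$dist, prob_threshold, top_k)
  if (length(ps) > 0) {
    ps <- proposal_density(ps, Nt)
    if (!use_pa_nms) ps$densities <- rep(0, length(ps))
    kept <- pa_nms(ps, Nt)
  } else {
    kept <- ps
  }
  labels <- matrix(0L, nrow(image), ncol(image))
  if (length(kept) > 0) {
    ord <- order(kept$scores, decreasing = TRUE)
    for (r in seq_along(ord)) {
      mask <- rasterize_polygon(kept$polygons[[ord[r]]], dim(labels))
      paint <- mask == 1 & labels == 0L
      labels[paint] <- r
    }
  }
  list(labels = labels, proposals = kept, prob = fw$prob)
}
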