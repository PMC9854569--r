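#' Pixel-level confusion between two label maps
#'
#' Both maps are binarized (any positive id is foreground).  Rates:
#' `TPp = TP / (TP + FN)` (recall over ground-truth foreground) and
#' `FPp = FP / (TN + FP)` (false positives over ground-truth background).
#'
#' @param pred,gt integer label maps of the same shape.
#' @return list with counts `tp`, `fp`, `fn`, `tn` and rates `tpp`,
#'   `fpp`.
#' @export
pixel_confusion <- function(pred, gt) {
  if (!all(dim(pred) == dim(gt))) stop("pixel_confusion: shape mismatch")
  p <- pred > 0; g <- gt > 0
  tp <- sum(p & g); fp <- sum(p & !g); fn <- sum(!p & g); tn <- sum(!p & !g)
  list(tp = tp, fp = fp, fn = fn, tn = tn,
       tpp = if (tp + fn > 0) tp / (tp + fn) else 0,
       fpp = if (tn + fp > 0) fp / (tn + fp) else 0)
}

#' Dice coefficient
#'
#' `DC = 2*TP / (2*TP + FN + FP)` on the binarized maps; 1 when both are
#' empty.
#'
#' @inheritParams pixel_confusion
#' @return scalar in `[0, 1]`.
#' @export
dice <- function(pred, gt) {
  cm <- pixel_confusion(pred, gt)
  den <- 2 * cm$tp + cm$fn + cm$fp
  if (den == 0) 1 else 2 * cm$tp / den
}

.instance_iou_table <- function(pred, gt) {
  pids <- setdiff(sort(unique(as.vector(pred))), 0)
  gids <- setdiff(sort(unique(as.vector(gt))), 0)
  if (length(pids) == 0 || length(gids) == 0)
    return(list(pids = pids, gids = gids,
                iou = matrix(0, length(pids), length(gids))))
  psz <- tabulate(match(pred[pred > 0], pids), length(pids))
  gsz <- tabulate(match(gt[gt > 0], gids), length(gids))
  both <- pred > 0 & gt > 0
  ov <- table(factor(pred[both], levels = pids),
              factor(gt[both], levels = gids))
  inter <- matrix(as.numeric(ov), length(pids), length(gids))
  un <- outer(psz, gsz, "+") - inter
  iou <- ifelse(un > 0, inter / un, 0)
  list(pids = pids, gids = gids, iou = iou)
}

#' Match predicted and ground-truth instances
#'
#' Pairwise mask IoU between every predicted and ground-truth instance;
#' pairs are accepted greedily in descending IoU, one-to-one, while
#' `IoU >= tau`.
#'
#' @inheritParams pixel_confusion
#' @param tau IoU acceptance threshold (default 0.7).
#' @return list with `matches` (data frame: pred id, gt id, iou), counts
#'   `tp`, `fp`, `fn`, and the unmatched id vectors.
#' @export
match_instances <- function(pred, gt, tau = 0.7) {
  tb <- .instance_iou_table(pred, gt)
  iou <- tb$iou
  matches <- data.frame(pred = integer(0), gt = integer(0), iou = numeric(0))
  if (length(tb$pids) && length(tb$gids)) {
    repeat {
      best <- which.max(iou)
      if (length(best) == 0 || iou[best] < tau) break
      ij <- arrayInd(best, dim(iou))
      matches <- rbind(matches, data.frame(pred = tb$pids[ij[1]],
                                           gt = tb$gids[ij[2]],
                                           iou = iou[best]))
      iou[ij[1], ] <- -1
      iou[, ij[2]] <- -1
    }
  }
  tp <- nrow(matches)
  list(matches = matches, tp = tp,
       fp = length(tb$pids) - tp, fn = length(tb$gids) - tp,
       unmatched_pred = setdiff(tb$pids, matches$pred),
       unmatched_gt = setdiff(tb$gids, matches$gt),
       tau = tau)
}

#' Object-level average precision
#'
#' `AP = TP / (TP + FP + FN)` from an instance matching.
#'
#' @param matching result of [match_instances()].
#' @return scalar in `[0, 1]`; 1 when there are no instances at all.
#' @export
average_precision <- function(matching) {
  den <- matching$tp + matching$fp + matching$fn
  if (den == 0) 1 else matching$tp / den
}

#' Object-level false negative rate
#'
#' Fraction of ground-truth instances left unmatched at `tau`.
#'
#' @inheritParams average_precision
#' @return scalar in `[0, 1]`; 0 when there is no ground truth.
#' @export
object_fn_rate <- function(matching) {
  ngt <- matching$tp + matching$fn
  if (ngt == 0) 0 else matching$fn / ngt
}

#' Full metrics report for one prediction/ground-truth pair
#'
#' Pixel metrics (Dice, TPp, FPp) and object metrics (FN rate, AP at
#' `tau`).
#'
#' @inheritParams pixel_confusion
#' @param tau object matching IoU threshold (default 0.7).
#' @return object of class `metrics_report`: a named list with `DC`,
#'   `TPp`, `FPp`, `FN`, `AP` and `tau`.
#' @export
evaluate_pair <- function(pred, gt, tau = 0.7) {
  cm <- pixel_confusion(pred, gt)
  m <- match_instances(pred, gt, tau)
  structure(list(DC = dice(pred, gt), TPp = cm$tpp, FPp = cm$fpp,
                 FN = object_fn_rate(m), AP = average_precision(m),
                 tau = tau),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("DC %.2f%%  TPp %.2f%%  FPp %.2f%%  FN %.2f%%  AP %.2f%% (tau=%.2f)\n",
              100 * x$DC, 100 * x$TPp, 100 * x$FPp, 100 * x$FN, 100 * x$AP,
              x$tau))
  invisible(x)
}

#' Average metrics over a list of prediction/ground-truth pairs
#'
#' Metrics are computed per image and averaged (per-image averaging).
#'
#' @param preds,gts lists of label maps.
#' @param tau object matching IoU threshold.
#' @return `metrics_report` of the means.
#' @export
evaluate_dataset <- function(preds, gts, tau = 0.7) {
  stopifnot(length(preds) == length(gts), length(preds) > 0)
  reps <- mapply(evaluate_pair, preds, gts, MoreArgs = list(tau = tau),
                 SIMPLIFY = FALSE)
  out <- lapply(c(DC = "DC", TPp = "TPp", FPp = "FPp", FN = "FN", AP = "AP"),
                function(f) mean(vapply(reps, `[[`, 0, f)))
  structure(c(out, list(tau = tau)), class = "metrics_report")
}
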