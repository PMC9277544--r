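# Evaluation metrics. All operate on a single image: `pred` a numeric H x W
# matrix in [0, 1] (continuous or binary), `gt` a binary H x W matrix.
# evaluateSegmentation() aggregates over image sets with the "m" prefix
# convention (mean over test images).
#
# Degenerate frames are scored explicitly: when prediction and ground truth
# are both empty the similarity metrics are 1 (perfect agreement on "no
# polyp"), and an empty ground truth with a non-empty prediction scores 0
# on the weighted F-measure.

as_mask_matrix <- function(x, what = "gt", binary = TRUE) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  x <- as.matrix(x)
  if (binary && !all(x %in% c(0, 1)))
    stop("input error: ", what, " must be binary (0/1)", call. = FALSE)
  x
}

check_same_shape <- function(pred, gt) {
  if (!identical(dim(pred), dim(gt)))
    stop("input error: prediction and ground truth shapes differ", call. = FALSE)
}

#' Dice similarity coefficient of two binary masks
#' @param predBin binary prediction mask (H x W matrix or vector).
#' @param gt binary ground-truth mask, same shape.
#' @return \eqn{2|P \cap G|/(|P|+|G|)} in [0, 1]; 1 when both masks are empty.
#' @export
diceCoef <- function(predBin, gt) {
  p <- as_mask_matrix(predBin, "predBin")
  g <- as_mask_matrix(gt)
  check_same_shape(p, g)
  s <- sum(p) + sum(g)
  if (s == 0) return(1)
  2 * sum(p * g) / s
}

#' Intersection over union (Jaccard index) of two binary masks
#' @inheritParams diceCoef
#' @return \eqn{|P \cap G|/|P \cup G|} in [0, 1]; 1 when both masks are empty.
#' @export
iouCoef <- function(predBin, gt) {
  p <- as_mask_matrix(predBin, "predBin")
  g <- as_mask_matrix(gt)
  check_same_shape(p, g)
  inter <- sum(p * g)
  uni <- sum(p) + sum(g) - inter
  if (uni == 0) return(1)
  inter / uni
}

#' Mean absolute error between a probability map and a binary mask
#' @param pred probability map in [0, 1].
#' @param gt binary ground-truth mask, same shape.
#' @return mean of |pred - gt| over all pixels, in [0, 1].
#' @export
maeScore <- function(pred, gt) {
  p <- as_mask_matrix(pred, "pred", binary = FALSE)
  g <- as_mask_matrix(gt)
  check_same_shape(p, g)
  mean(abs(p - g))
}

# 7x7 Gaussian kernel (sigma 5), zero-padded filtering
gauss7 <- local({
  g <- outer(-3:3, -3:3, function(i, j) exp(-(i^2 + j^2) / (2 * 25)))
  g / sum(g)
})

filter2_zero <- function(x, k) {
  H <- nrow(x); W <- ncol(x)
  r <- (nrow(k) - 1L) %/% 2L
  out <- matrix(0, H, W)
  for (di in -r:r) for (dj in -r:r) {
    kk <- k[di + r + 1L, dj + r + 1L]
    if (kk == 0) next
    si <- max(1, 1 - di):min(H, H - di)
    sj <- max(1, 1 - dj):min(W, W - dj)
    out[si, sj] <- out[si, sj] + kk * x[si + di, sj + dj]
  }
  out
}

#' Weighted F-measure
#'
#' The dependency-weighted precision/recall harmonic mean: absolute errors
#' are propagated to their nearest foreground pixel, smoothed with a 7x7
#' Gaussian (sigma 5), and down-weighted in the background with distance
#' from the object before precision and recall are formed.
#'
#' @param pred probability map in [0, 1].
#' @param gt binary ground-truth mask, same shape.
#' @param beta2 beta squared balancing precision and recall (default 1).
#' @return score in [0, 1]; 1 for a perfect prediction. An empty ground
#'   truth scores 1 if the prediction is also empty, else 0.
#' @export
weightedFmeasure <- function(pred, gt, beta2 = 1) {
  p <- as_mask_matrix(pred, "pred", binary = FALSE)
  g <- as_mask_matrix(gt)
  check_same_shape(p, g)
  eps <- .Machine$double.eps
  if (sum(g) == 0) return(if (sum(p) == 0) 1 else 0)
  fg <- g > 0.5
  nf <- cpp_nearest_fg(g)
  E <- abs(p - g)
  Et <- E
  Et[!fg] <- E[nf$idx[!fg] + 1L]          # error at the nearest foreground pixel
  EA <- filter2_zero(Et, gauss7)
  minEA <- E
  sel <- fg & (EA < E)
  minEA[sel] <- EA[sel]
  B <- matrix(1, nrow(g), ncol(g))
  B[!fg] <- 2 - exp(log(0.5) / 5 * nf$dist[!fg])
  Ew <- minEA * B
  TPw <- sum(g) - sum(Ew[fg])
  FPw <- sum(Ew[!fg])
  Rw <- 1 - mean(Ew[fg])
  Pw <- TPw / (eps + TPw + FPw)
  (1 + beta2) * Rw * Pw / (eps + Rw + beta2 * Pw)
}

# object-aware component: similarity of the (masked) prediction to a
# uniform unit response inside the region
s_object_score <- function(x) {
  if (length(x) == 0) return(0)
  m <- mean(x)
  s <- if (length(x) > 1) sd(x) else 0
  2 * m / (m * m + 1 + s + .Machine$double.eps)
}

ssim_region <- function(p, g) {
  n <- length(p)
  if (n <= 1) return(as.numeric(mean(p) == mean(g)))
  mx <- mean(p); my <- mean(g)
  vx <- sum((p - mx)^2) / (n - 1)
  vy <- sum((g - my)^2) / (n - 1)
  vxy <- sum((p - mx) * (g - my)) / (n - 1)
  a <- 4 * mx * my * vxy
  b <- (mx^2 + my^2) * (vx + vy)
  if (a != 0) a / (b + .Machine$double.eps)
  else if (b == 0) 1
  else 0
}

#' Structure measure (S-measure)
#'
#' Blends an object-aware component (mean/spread similarity of the
#' prediction inside the foreground and of its complement inside the
#' background) with a region-aware component (SSIM-style similarity over
#' the four quadrants cut at the ground-truth centroid, area-weighted).
#'
#' @param pred probability map in [0, 1].
#' @param gt binary ground-truth mask, same shape.
#' @param alpha mixing weight of the object component (default 0.5).
#' @return score in [0, 1].
#' @export
sMeasure <- function(pred, gt, alpha = 0.5) {
  p <- as_mask_matrix(pred, "pred", binary = FALSE)
  g <- as_mask_matrix(gt)
  check_same_shape(p, g)
  y <- mean(g)
  if (y == 0) return(max(0, 1 - mean(p)))
  if (y == 1) return(max(0, mean(p)))
  fg <- g > 0.5
  so <- y * s_object_score(p[fg]) + (1 - y) * s_object_score(1 - p[!fg])
  # region component: quadrants at the foreground centroid
  H <- nrow(g); W <- ncol(g)
  rows <- row(g)[fg]; cols <- col(g)[fg]
  ci <- round(mean(rows)); cj <- round(mean(cols))
  ci <- min(max(ci, 1L), H); cj <- min(max(cj, 1L), W)
  blocks <- list(
    list(1:ci, 1:cj), list(1:ci, if (cj < W) (cj + 1L):W else integer(0)),
    list(if (ci < H) (ci + 1L):H else integer(0), 1:cj),
    list(if (ci < H) (ci + 1L):H else integer(0),
         if (cj < W) (cj + 1L):W else integer(0)))
  sr <- 0
  for (b in blocks) {
    if (length(b[[1]]) == 0 || length(b[[2]]) == 0) next
    pw <- p[b[[1]], b[[2]]]
    gw <- g[b[[1]], b[[2]]]
    wgt <- length(gw) / (H * W)
    sr <- sr + wgt * ssim_region(as.vector(pw), as.vector(gw))
  }
  max(0, alpha * so + (1 - alpha) * sr)
}

e_measure_single <- function(predBin, g) {
  n <- length(g)
  if (sum(g) == 0) {
    enhanced <- 1 - predBin
  } else if (sum(g) == n) {
    enhanced <- predBin
  } else {
    phiFM <- predBin - mean(predBin)
    phiGT <- g - mean(g)
    align <- 2 * phiFM * phiGT / (phiFM^2 + phiGT^2 + .Machine$double.eps)
    enhanced <- (align + 1)^2 / 4
  }
  # the n-1 normalization can nudge a perfect frame above 1; cap at 1
  min(1, sum(enhanced) / (n - 1 + .Machine$double.eps))
}

#' Enhanced-alignment measure (E-measure)
#'
#' Binarizes the prediction (strictly above threshold) at `nThresholds`
#' equally spaced thresholds k/n, k = 0..n-1 (0.5 is on the grid for even
#' n), scores the alignment of the centered prediction and ground truth at
#' each, and returns the mean and maximum over thresholds. The strict
#' comparison makes a binary prediction reproduce itself at every
#' threshold, so a perfect binary prediction scores exactly 1.
#'
#' @param pred probability map in [0, 1].
#' @param gt binary ground-truth mask, same shape.
#' @param nThresholds number of thresholds (default 256).
#' @return list with elements `mean` and `max`, both in [0, 1].
#' @export
eMeasure <- function(pred, gt, nThresholds = 256L) {
  p <- as_mask_matrix(pred, "pred", binary = FALSE)
  g <- as_mask_matrix(gt)
  check_same_shape(p, g)
  ths <- (seq_len(nThresholds) - 1) / nThresholds
  scores <- vapply(ths, function(th)
    e_measure_single((p > th) * 1, g), numeric(1))
  list(mean = mean(scores), max = max(scores))
}

#' E-measure at a single binarization threshold
#' @inheritParams eMeasure
#' @param threshold binarization threshold.
#' @return scalar in [0, 1].
#' @export
eMeasureAt <- function(pred, gt, threshold = 0.5) {
  p <- as_mask_matrix(pred, "pred", binary = FALSE)
  g <- as_mask_matrix(gt)
  check_same_shape(p, g)
  e_measure_single((p > threshold) * 1, g)
}

as_image_list <- function(x, what) {
  if (is.list(x)) return(lapply(x, as_mask_matrix, what = what, binary = FALSE))
  if (is.array(x) && length(dim(x)) == 4L)
    return(lapply(seq_len(dim(x)[1]), function(n) x[n, 1, , ]))
  if (is.matrix(x)) return(list(x))
  stop("input error: expected a list of matrices or an (N, 1, H, W) array",
       call. = FALSE)
}

#' Evaluate predictions against ground truth over an image set
#'
#' Computes the seven-statistic report: per-image Dice and IoU of the
#' binarized prediction, weighted F-measure, S-measure, mean/max E-measure,
#' and MAE of the continuous map, averaged over images.
#'
#' @param preds list of probability matrices, or an (N, 1, H, W) array.
#' @param gts matching binary ground-truth masks.
#' @param cfg a [MetricConfig-class] (defaults: binarize at 0.5, beta^2 = 1,
#'   alpha = 0.5, 256 E-measure thresholds).
#' @return a [MetricReport-class].
#' @export
evaluateSegmentation <- function(preds, gts, cfg = metricConfig()) {
  stopifnot(is(cfg, "MetricConfig"))
  pl <- as_image_list(preds, "preds")
  gl <- as_image_list(gts, "gts")
  if (length(pl) != length(gl))
    stop("input error: ", length(pl), " predictions vs ", length(gl),
         " ground truths", call. = FALSE)
  rows <- lapply(seq_along(pl), function(i) {
    p <- pl[[i]]
    g <- as_mask_matrix(gl[[i]])
    pb <- (p >= cfg@binThreshold) * 1
    e <- eMeasure(p, g, cfg@eThresholds)
    data.frame(
      dice = diceCoef(pb, g), iou = iouCoef(pb, g),
      wfb = weightedFmeasure(p, g, cfg@fbwBeta2),
      s = sMeasure(p, g, cfg@sAlpha),
      meanE = e$mean, maxE = e$max, mae = maeScore(p, g))
  })
  per <- do.call(rbind, rows)
  new("MetricReport",
      mDice = mean(per$dice), mIoU = mean(per$iou), wFb = mean(per$wfb),
      sAlpha = mean(per$s), meanE = mean(per$meanE), maxE = mean(per$maxE),
      mae = mean(per$mae), perImage = per)
}

#' Serialize a metric report to JSON
#' @param report a [MetricReport-class].
#' @param path file to write; the JSON carries the seven summary fields plus
#'   the per-image arrays.
#' @return the path, invisibly.
#' @export
writeMetricReport <- function(report, path) {
  stopifnot(is(report, "MetricReport"))
  obj <- list(mDice = report@mDice, mIoU = report@mIoU, wFb = report@wFb,
              sAlpha = report@sAlpha, meanE = report@meanE, maxE = report@maxE,
              mae = report@mae, perImage = report@perImage)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
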