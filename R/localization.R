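# Gradient class activation mapping and classifier-facing operations.

#' Compute a gradient class activation map
#'
#' Weighted sum of a convolution layer's feature maps, with per-channel
#' weights equal to the spatial mean of the corresponding output gradients
#' (the global-average-pooled gradient), rectified at 0 and min-max rescaled
#' to \[0, 1\]. A raw map that is identically <= 0 yields the all-zero map;
#' a constant positive raw map yields the all-ones map (the whole frame is
#' equally class-discriminative).
#'
#' @param features H x W x K array (or list of K matrices) of feature maps
#'   A^k from the tapped layer.
#' @param gradients array/list of the same shape: gradients of the target
#'   score with respect to each A^k.
#' @param sourceLayer layer name recorded on the result.
#' @return an \linkS4class{ActivationMap}.
#' @examples
#' A <- array(c(1, 0, 0, 1, 0, 2, 2, 0), c(2, 2, 2))
#' G <- array(c(rep(1, 4), rep(0.5, 4)), c(2, 2, 2))
#' grid(gradCAM(A, G))   # constant positive raw map -> all ones
#' @export
gradCAM <- function(features, gradients, sourceLayer = "block5_conv4") {
  toArr <- function(x) {
    if (is.list(x)) x <- simplify2array(x)
    if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
    x
  }
  A <- toArr(features); G <- toArr(gradients)
  if (!identical(dim(A), dim(G)))
    stop("feature and gradient stacks must have identical dimensions")
  if (any(dim(A) == 0L)) stop("stacks must be non-empty")
  K <- dim(A)[3]
  alpha <- apply(G, 3, mean)                     # GAP of the gradients
  raw <- matrix(0, dim(A)[1], dim(A)[2])
  for (k in seq_len(K)) raw <- raw + alpha[k] * A[, , k]
  raw <- pmax(raw, 0)                            # rectification
  mx <- max(raw); mn <- min(raw)
  g <- if (mx <= 0) raw * 0
       else if (mx - mn < 1e-12) raw * 0 + 1     # constant positive map
       else (raw - mn) / (mx - mn)
  new("ActivationMap", grid = g, sourceLayer = sourceLayer)
}

#' Bilinearly upsample an activation map
#'
#' Align-corners bilinear interpolation from the layer's resolution to the
#' image resolution. Values stay within the source range (convexity), so a
#' valid \[0, 1\] map remains valid. Downscaling is rejected.
#'
#' @param map an \linkS4class{ActivationMap}.
#' @param target integer (H, W) of the output, each >= the map size.
#' @return an upsampled \linkS4class{ActivationMap}.
#' @export
upsampleMap <- function(map, target) {
  src <- map@grid
  H <- nrow(src); W <- ncol(src)
  th <- as.integer(target[1]); tw <- as.integer(target[2])
  if (th < H || tw < W) stop("upsampleMap cannot downscale (target smaller than map)")
  out <- bilinearResize(src, th, tw)
  new("ActivationMap", grid = pmin(pmax(out, 0), 1), sourceLayer = map@sourceLayer)
}

# align-corners bilinear resize of a matrix
bilinearResize <- function(src, th, tw) {
  H <- nrow(src); W <- ncol(src)
  ry <- if (th == 1L || H == 1L) rep(1, th) else 1 + (seq_len(th) - 1) * (H - 1) / (th - 1)
  rx <- if (tw == 1L || W == 1L) rep(1, tw) else 1 + (seq_len(tw) - 1) * (W - 1) / (tw - 1)
  y0 <- pmin(floor(ry), H - 1); y0[H == 1] <- 1
  x0 <- pmin(floor(rx), W - 1); x0[W == 1] <- 1
  if (H == 1L) { y0 <- rep(1, th); fy <- rep(0, th) } else fy <- ry - y0
  if (W == 1L) { x0 <- rep(1, tw); fx <- rep(0, tw) } else fx <- rx - x0
  y1 <- pmin(y0 + 1, H); x1 <- pmin(x0 + 1, W)
  (1 - fy) %o% (1 - fx) * src[y0, x0, drop = FALSE] +
    (1 - fy) %o% fx * src[y0, x1, drop = FALSE] +
    fy %o% (1 - fx) * src[y1, x0, drop = FALSE] +
    fy %o% fx * src[y1, x1, drop = FALSE]
}

#' Blend the localization heatmap over the input image
#'
#' Colorizes the activation map with a jet-style colormap and forms the
#' per-pixel convex combination \code{(1 - alpha) * image + alpha * heat};
#' \code{alpha = 0} returns the original image exactly. The map is
#' upsampled first when it is smaller than the image.
#'
#' @param image a \linkS4class{LesionImage}.
#' @param map an \linkS4class{ActivationMap} no larger than the image.
#' @param alpha blend weight in \[0, 1\] (default 0.4).
#' @return a \linkS4class{LesionImage} holding the blended raster.
#' @export
superimpose <- function(image, map, alpha = 0.4) {
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")
  d <- dim(image@raster)
  if (!all(dim(map@grid) == d[1:2])) {
    if (any(dim(map@grid) > d[1:2]))
      stop("activation map is larger than the image; sizes must agree after upsampling")
    map <- upsampleMap(map, d[1:2])
  }
  heat <- array(jetColors(as.vector(map@grid)), c(d[1], d[2], 3))
  blended <- (1 - alpha) * image@raster + alpha * heat
  new("LesionImage", raster = pmin(pmax(blended, 0), 1),
      lesionMask = image@lesionMask, source = paste0(image@source, "+cam"))
}

#' Classify a lesion image through a model adapter
#'
#' Returns the adapter's malignancy probability plus the binary label at
#' the sigmoid convention threshold 0.5. A tie at exactly 0.5 is labelled
#' "Malignant" (sensitivity is favored in a cancer screen).
#'
#' @param image a \linkS4class{LesionImage}.
#' @param adapter a \linkS4class{ModelAdapter}.
#' @return list with elements \code{probability} and \code{label}.
#' @export
classifyLesion <- function(image, adapter) {
  p <- tryCatch(adapter@predictFun(image),
                error = function(e) stop("model adapter failed during predict: ",
                                         conditionMessage(e)))
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1)
    stop("adapter predict must return a single probability in [0, 1]")
  list(probability = p, label = if (p >= 0.5) "Malignant" else "Benign")
}

#' Confusion-matrix evaluation metrics
#'
#' Standard binary metrics from confusion counts: accuracy, precision,
#' recall, the F1 score (harmonic mean of precision and recall) and the
#' Matthews correlation coefficient
#' \eqn{(tp \cdot tn - fp \cdot fn) / \sqrt{(tp+fp)(tp+fn)(tn+fp)(tn+fn)}}.
#' A metric whose denominator vanishes is returned as \code{NA} (flagged
#' missing), never as an error.
#'
#' @param tp,fp,tn,fn non-negative confusion counts.
#' @return named numeric vector
#'   \code{c(accuracy, precision, recall, f1, mcc)}.
#' @examples
#' evaluateBinary(10, 0, 10, 0)    # perfect classifier
#' @export
evaluateBinary <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0)) stop("confusion counts must be non-negative")
  tot <- sum(counts)
  safe <- function(num, den) if (den > 0) num / den else NA_real_
  accuracy <- safe(tp + tn, tot)
  precision <- safe(tp, tp + fp)
  recall <- safe(tp, tp + fn)
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else NA_real_
  mden <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (mden > 0) (tp * tn - fp * fn) / sqrt(mden) else NA_real_
  c(accuracy = accuracy, precision = precision, recall = recall,
    f1 = f1, mcc = mcc)
}

#' F1 score from precision and recall
#'
#' Harmonic mean \code{2 p r / (p + r)}; the consistency check on reported
#' precision/recall pairs.
#'
#' @param precision,recall values in \[0, 1\].
#' @return the F1 score.
#' @examples
#' f1Score(0.84, 0.86)
#' @export
f1Score <- function(precision, recall) {
  if (precision + recall == 0) return(NA_real_)
  2 * precision * recall / (precision + recall)
}
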