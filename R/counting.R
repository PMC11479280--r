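#' Drop low-confidence block predictions
#'
#' Keeps predictions whose corn probability is at least the threshold
#' (inclusive: exactly 0.90 survives the default filter).  Order is
#' preserved.
#'
#' @param preds data frame with columns `x0, y0, x1, y1, probability`.
#' @param threshold minimum probability retained.
#' @return the filtered data frame.
#' @export
filter_by_probability <- function(preds, threshold = 0.90) {
  preds[preds$probability >= threshold, , drop = FALSE]
}

#' Intersection over union of two rectangles
#'
#' @param a,b rectangles: [cs_rect()]s, named vectors or one-row data
#'   frames with `x0, y0, x1, y1`.
#' @return IoU in `[0, 1]`; 0 for disjoint rectangles.  Errors on a
#'   zero-area rectangle.
#' @export
iou <- function(a, b) {
  g <- function(r, f) if (is.data.frame(r)) r[[f]][1] else r[[f]]
  ax0 <- g(a, "x0"); ay0 <- g(a, "y0"); ax1 <- g(a, "x1"); ay1 <- g(a, "y1")
  bx0 <- g(b, "x0"); by0 <- g(b, "y0"); bx1 <- g(b, "x1"); by1 <- g(b, "y1")
  area_a <- (ax1 - ax0) * (ay1 - ay0)
  area_b <- (bx1 - bx0) * (by1 - by0)
  if (area_a <= 0 || area_b <= 0) stop("zero-area rectangle in iou()")
  iw <- min(ax1, bx1) - max(ax0, bx0)
  ih <- min(ay1, by1) - max(ay0, by0)
  if (iw <= 0 || ih <= 0) return(0)
  inter <- iw * ih
  inter / (area_a + area_b - inter)
}

expand_rects <- function(preds, frac) {
  w <- (preds$x1 - preds$x0) * frac / 2
  h <- (preds$y1 - preds$y0) * frac / 2
  data.frame(x0 = preds$x0 - w, y0 = preds$y0 - h,
             x1 = preds$x1 + w, y1 = preds$y1 + h)
}

#' Suppress duplicate block detections with expanded-rectangle IoU
#'
#' Adjacent blocks often cover portions of the same plant, so each
#' prediction rectangle is first expanded by `expand_frac` of its side
#' lengths (centred) to make adjacency a measurable overlap, then greedy
#' non-maximum suppression runs: predictions are visited in order of
#' decreasing probability (ties: smaller `y0`, then smaller `x0`); the
#' head is kept and any remaining prediction whose expanded-rectangle IoU
#' with an already-kept one *exceeds* `iou_threshold` is dropped.  With
#' `expand_frac = 0` and non-overlapping tiles the pass is a no-op.
#'
#' @param preds data frame with `x0, y0, x1, y1, probability`.
#' @param expand_frac fractional expansion of each side.
#' @param iou_threshold suppression threshold on expanded-rect IoU.
#' @return the kept rows of `preds` (original, unexpanded rectangles).
#' @export
dedup_predictions <- function(preds, expand_frac = 0.25, iou_threshold = 0.1) {
  if (!nrow(preds)) return(preds)
  ex <- expand_rects(preds, expand_frac)
  ord <- order(-preds$probability, preds$y0, preds$x0)
  kept <- integer(0)
  for (i in ord) {
    clash <- FALSE
    for (k in kept) {
      if (iou(ex[i, ], ex[k, ]) > iou_threshold) { clash <- TRUE; break }
    }
    if (!clash) kept <- c(kept, i)
  }
  preds[sort(kept), , drop = FALSE]
}

#' Count stands inside a region
#'
#' Counts kept predictions whose rectangle centre lies in the region
#' (half-open on the high edges: a centre exactly on `x1`/`y1` is out).
#'
#' @param preds deduplicated prediction data frame.
#' @param region a [cs_rect()].
#' @return integer stand count.
#' @export
count_region <- function(preds, region) {
  if (!nrow(preds)) return(0L)
  cx <- (preds$x0 + preds$x1) / 2
  cy <- (preds$y0 + preds$y1) / 2
  sum(cx >= region[["x0"]] & cx < region[["x1"]] &
      cy >= region[["y0"]] & cy < region[["y1"]])
}

#' Block-level confusion counts
#'
#' Compares aligned predicted and true block labels: TP = both corn,
#' FP = predicted corn only, FN = truth corn only, TN = neither.
#'
#' @param predicted,truth character vectors of `"corn"`/`"non_corn"`,
#'   aligned block-for-block.
#' @return named integer vector `c(tp, fp, fn, tn)`.
#' @export
confusion_counts <- function(predicted, truth) {
  if (length(predicted) != length(truth))
    stop("predicted and truth label vectors differ in length")
  pc <- predicted == "corn"; tc <- truth == "corn"
  c(tp = sum(pc & tc), fp = sum(pc & !tc),
    fn = sum(!pc & tc), tn = sum(!pc & !tc))
}

#' Precision, recall and F1 from confusion counts
#'
#' `P = TP / (TP + FP)`, `R = TP / (TP + FN)`, `F1 = 2PR / (P + R)`.
#' A zero denominator yields 0 with a warning.
#'
#' @param counts named vector from [confusion_counts()] (needs `tp`, `fp`,
#'   `fn`).
#' @return named numeric `c(precision, recall, f1)`.
#' @export
precision_recall_f1 <- function(counts) {
  tp <- counts[["tp"]]; fp <- counts[["fp"]]; fn <- counts[["fn"]]
  safe <- function(num, den, what) {
    if (den == 0) { warning("zero denominator in ", what, "; returning 0"); 0 }
    else num / den
  }
  p <- safe(tp, tp + fp, "precision")
  r <- safe(tp, tp + fn, "recall")
  f1 <- if (p + r == 0) { warning("zero denominator in F1; returning 0"); 0 }
        else 2 * p * r / (p + r)
  c(precision = p, recall = r, f1 = f1)
}

#' Root-mean-square error of estimated counts
#'
#' `sqrt(sum((x_i - p_i)^2) / n)` over regions, where `x` are the manual
#' (ground-truth) counts and `p` the estimated counts.
#'
#' @param x,p equal-length numeric vectors (manual and estimated counts).
#' @return the RMSE.
#' @export
rmse <- function(x, p) {
  if (length(x) != length(p) || length(x) == 0)
    stop("rmse needs two equal-length non-empty vectors")
  sqrt(sum((x - p)^2) / length(x))
}

#' Coefficient of determination of estimated counts
#'
#' `1 - sum((x_i - p_i)^2) / sum((x_i - mean(x))^2)`.  Undefined (an
#' error) when the manual counts are constant.
#'
#' @param x,p equal-length numeric vectors (manual and estimated counts),
#'   `n >= 2`.
#' @return the R-squared value (can be negative for a poor estimator).
#' @export
r_squared <- function(x, p) {
  if (length(x) != length(p) || length(x) < 2)
    stop("r_squared needs two equal-length vectors with n >= 2")
  tss <- sum((x - mean(x))^2)
  if (tss == 0) stop("undefined R-squared: manual counts are constant")
  1 - sum((x - p)^2) / tss
}

#' Per-version and per-model count-accuracy summary
#'
#' Takes a stand-count table with one ground-truth row and one row per
#' model version (wide format, one column per test region), computes
#' R-squared and RMSE per version against the ground truth, and averages
#' them per model.  Values are kept at full precision; round only when
#' printing.
#'
#' @param counts data frame with columns `model`, `version`, then one
#'   numeric column per test region; the ground-truth row has
#'   `model == "ground_truth"`.
#' @return list with `versions` (`model, version, r2, rmse`) and `models`
#'   (`model, mean_r2, mean_rmse, min_rmse`).
#' @export
model_comparison_table <- function(counts) {
  meta <- c("model", "version")
  regions <- setdiff(names(counts), meta)
  gt_row <- counts$model == "ground_truth"
  if (sum(gt_row) != 1) stop("need exactly one ground_truth row")
  x <- as.numeric(counts[gt_row, regions])
  est <- counts[!gt_row, , drop = FALSE]
  if (!nrow(est)) stop("no model version rows")
  versions <- do.call(rbind, lapply(seq_len(nrow(est)), function(i) {
    p <- as.numeric(est[i, regions])
    data.frame(model = est$model[i], version = est$version[i],
               r2 = r_squared(x, p), rmse = rmse(x, p))
  }))
  models <- do.call(rbind, lapply(split(versions, versions$model), function(v) {
    data.frame(model = v$model[1], mean_r2 = mean(v$r2),
               mean_rmse = mean(v$rmse), min_rmse = min(v$rmse))
  }))
  rownames(models) <- NULL
  list(versions = versions, models = models)
}

#' Published stand-count benchmark table
#'
#' Loads the packaged stand-count benchmark: manually counted ("ground
#' truth") corn stands in five test regions of a 1.5-acre Ohio corn field,
#' and the counts estimated by five trained versions each of four deep
#' learning classifiers (InceptionV3, VGG16, VGG19, ViT).  Used as a fixed
#' input for metric arithmetic.
#'
#' @return data frame in the wide format expected by
#'   [model_comparison_table()].
#' @export
stand_count_table <- function() {
  read.csv(system.file("extdata", "stand_counts_benchmark.csv",
                       package = "cornstand"), stringsAsFactors = FALSE)
}

#' Count stands in a field with a trained classifier
#'
#' End-to-end counting: rotate the field to the rows-horizontal frame
#' (estimating the orientation from its vegetation mask), tile it into
#' blocks, score every block with the classifier, drop predictions below
#' the probability threshold, and suppress duplicates with expanded-IoU
#' non-maximum suppression.  No row information is used at test time; the
#' classifier alone decides which blocks hold corn.
#'
#' @param raster a [cs_raster()], original frame.
#' @param model a fitted classifier ([fit_baseline()]).
#' @param spec a [block_spec()] (tiling geometry).
#' @param prob_threshold probability filter (inclusive).
#' @param expand_frac,iou_threshold duplicate-suppression settings, see
#'   [dedup_predictions()].
#' @param thr a [green_thresholds()] for orientation estimation.
#' @return list of class `stand_count`: `predictions` (kept blocks with
#'   probabilities, rotated-frame metres), `theta_deg`, `count` (total
#'   kept), `raster_rot`.
#' @export
count_stands <- function(raster, model, spec = block_spec(),
                         prob_threshold = 0.90, expand_frac = 0.25,
                         iou_threshold = 0.1, thr = green_thresholds()) {
  m <- green_mask(raster, thr)
  theta <- estimate_row_orientation(m)
  ## nearest, as in annotate_field(): no colour blending at block edges
  rrot <- rotate_raster(raster, theta, interp = "nearest")
  d <- dim(rrot$pixels)
  extent <- cs_rect(0, 0, d[2] * raster$gsd, d[1] * raster$gsd)
  blocks <- tile_blocks(extent, spec)
  blocks$label <- "unknown"
  chips <- extract_chips(rrot, blocks)
  blocks$probability <- predict_proba(model, chips)
  preds <- filter_by_probability(blocks, prob_threshold)
  kept <- dedup_predictions(preds, expand_frac, iou_threshold)
  structure(list(predictions = kept, theta_deg = theta,
                 count = nrow(kept), raster_rot = rrot),
            class = "stand_count")
}

#' @export
print.stand_count <- function(x, ...) {
  cat(sprintf("<stand_count> %d stands (rotation %.2f deg)\n",
              x$count, x$theta_deg))
  invisible(x)
}
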