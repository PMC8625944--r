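# Segmentation-accuracy metrics against labeled ground truth.
#
# Ground truth is a list of per-cell masks.  Because touching cells may
# overlap, a single label map cannot represent them; each cell is its own
# mask.  Masks may be full logical matrices or compact index vectors
# (integer linear indices with a `dim` attribute), which is how the
# synthetic generator stores them.

truth_indices <- function(mask, dims = NULL) {
  if (is.logical(mask) && is.matrix(mask)) {
    structure(which(mask), dim_full = dim(mask))
  } else if (is.numeric(mask)) {
    structure(as.integer(mask), dim_full = attr(mask, "dim_full"))
  } else {
    stop("ground-truth masks must be logical matrices or index vectors",
         call. = FALSE)
  }
}

#' Per-image agreement between predicted regions and ground-truth cells
#'
#' For each annotated cell j, a binary indicator B_j records whether some
#' predicted region matches it; the per-image score is
#' \deqn{\epsilon_i = \frac{\sum_j B_j}{N} \times 100\%.}
#' Matching is greedy one-to-one by descending IoU (ties broken by the
#' smaller predicted label, then the smaller truth index), so a predicted
#' region that merges two cells can satisfy at most one of them. Two
#' criteria are available: `"iou"` accepts a pair whose intersection over
#' union reaches `iou_threshold`; `"exact"` demands pixel-identical masks.
#'
#' @param pred Integer label matrix from the segmentation.
#' @param truth List of ground-truth cell masks (logical matrices or index
#'   vectors), length `N >= 1`.
#' @param criterion `"iou"` (default) or `"exact"`.
#' @param iou_threshold IoU acceptance level for the `"iou"` criterion.
#' @return An object of class `match_report`: `epsilon` (the agreement
#'   percentage), `error` (`100 - epsilon`), the per-cell `matched`
#'   indicator, and the matched predicted label per truth cell (0 = none).
#' @export
mask_agreement <- function(pred, truth, criterion = c("iou", "exact"),
                           iou_threshold = 0.5) {
  assert_labels(pred)
  criterion <- match.arg(criterion)
  if (!is.list(truth) || length(truth) == 0) {
    stop("`truth` must be a non-empty list of cell masks", call. = FALSE)
  }
  n_truth <- length(truth)
  pred <- as_int_matrix(pred)
  mx <- max(pred)
  pred_sizes <- if (mx > 0) tabulate(pred[pred > 0L], nbins = mx) else integer(0)

  cand <- list()
  for (j in seq_len(n_truth)) {
    ti <- truth_indices(truth[[j]])
    nt <- length(ti)
    if (nt == 0) next
    under <- pred[ti]
    under <- under[under > 0L]
    if (length(under) == 0) next
    tab <- table(under)
    for (k in seq_along(tab)) {
      l <- as.integer(names(tab)[k])
      inter <- as.integer(tab[k])
      union <- nt + pred_sizes[l] - inter
      iou <- inter / union
      exact <- inter == nt && pred_sizes[l] == nt
      cand[[length(cand) + 1]] <-
        data.frame(truth = j, label = l, iou = iou, exact = exact)
    }
  }
  matched <- logical(n_truth)
  matched_label <- integer(n_truth)
  if (length(cand) > 0) {
    cand <- do.call(rbind, cand)
    cand <- cand[order(-cand$iou, cand$label, cand$truth), , drop = FALSE]
    used <- logical(mx)
    for (i in seq_len(nrow(cand))) {
      j <- cand$truth[i]; l <- cand$label[i]
      if (matched[j] || used[l]) next
      ok <- if (criterion == "exact") cand$exact[i]
            else cand$iou[i] >= iou_threshold
      if (ok) {
        matched[j] <- TRUE
        matched_label[j] <- l
        used[l] <- TRUE
      }
    }
  }
  eps <- 100 * sum(matched) / n_truth
  structure(list(epsilon = eps, error = 100 - eps, matched = matched,
                 matched_label = matched_label, n_truth = n_truth,
                 n_pred = sum(pred_sizes > 0), criterion = criterion,
                 iou_threshold = iou_threshold),
            class = "match_report")
}

#' @export
print.match_report <- function(x, ...) {
  cat(sprintf("agreement %.1f%% (%d/%d cells matched, criterion %s)\n",
              x$epsilon, sum(x$matched), x$n_truth, x$criterion))
  invisible(x)
}

#' Mean absolute error between cell counts
#'
#' @param pred_counts,true_counts Equal-length integer vectors of per-image
#'   cell counts.
#' @return Mean of `|pred - true|`.
#' @export
count_mae <- function(pred_counts, true_counts) {
  if (length(pred_counts) != length(true_counts) ||
      length(pred_counts) == 0) {
    stop("count vectors must be non-empty and of equal length",
         call. = FALSE)
  }
  mean(abs(pred_counts - true_counts))
}

#' Summarize agreement over a suite of images
#'
#' Sample mean and sample standard deviation (n - 1 denominator) of the
#' per-image agreement, reported both as agreement and as its complement
#' `error = 100 - agreement`.
#'
#' @param reports List of [mask_agreement()] reports (at least 2).
#' @return List with `mean_agreement`, `sd_agreement`, `mean_error`,
#'   `sd_error` and the per-image `epsilon` vector.
#' @export
suite_summary <- function(reports) {
  if (!is.list(reports) || length(reports) < 2) {
    stop("need at least 2 reports to summarize", call. = FALSE)
  }
  eps <- vapply(reports, function(r) r$epsilon, numeric(1))
  list(mean_agreement = mean(eps), sd_agreement = stats::sd(eps),
       mean_error = 100 - mean(eps), sd_error = stats::sd(eps),
       epsilon = eps)
}
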