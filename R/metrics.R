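# Overlap metrics between a predicted and a ground-truth tumor pixel set.
# All four are undefined on empty denominators and then return NA (never a
# silent 0 or 1): empty-vs-empty comparisons would otherwise corrupt
# dataset averages.

pixel_counts <- function(pred, truth) {
  pred <- as.matrix(pred)
  truth <- as.matrix(truth)
  if (!identical(dim(pred), dim(truth))) {
    stop("prediction and truth shapes differ", call. = FALSE)
  }
  p <- pred > 0
  g <- truth > 0
  list(vs = sum(p), vg = sum(g), inter = sum(p & g), union = sum(p | g))
}

#' Dice coefficient
#'
#' `2 |Vs intersect Vg| / (|Vs| + |Vg|)` for predicted pixel set `Vs` and
#' ground-truth set `Vg`. Undefined (NA) when both sets are empty.
#'
#' @param pred,truth binary matrices of one common shape.
#' @return A scalar in `[0, 1]`, or `NA` when undefined.
#' @export
dice <- function(pred, truth) {
  n <- pixel_counts(pred, truth)
  if (n$vs + n$vg == 0) return(NA_real_)
  2 * n$inter / (n$vs + n$vg)
}

#' Jaccard coefficient (IoU)
#'
#' `|Vs intersect Vg| / |Vs union Vg|`; undefined (NA) on an empty union.
#' Related to Dice by `J = D / (2 - D)`.
#'
#' @inheritParams dice
#' @return A scalar in `[0, 1]`, or `NA` when undefined.
#' @export
jaccard <- function(pred, truth) {
  n <- pixel_counts(pred, truth)
  if (n$union == 0) return(NA_real_)
  n$inter / n$union
}

#' Pixel precision
#'
#' `|Vs intersect Vg| / |Vs|`; undefined (NA) when nothing was predicted.
#'
#' @inheritParams dice
#' @return A scalar in `[0, 1]`, or `NA` when undefined.
#' @export
precision <- function(pred, truth) {
  n <- pixel_counts(pred, truth)
  if (n$vs == 0) return(NA_real_)
  n$inter / n$vs
}

#' Pixel recall
#'
#' `|Vs intersect Vg| / |Vg|`; undefined (NA) when the truth is empty.
#'
#' @inheritParams dice
#' @return A scalar in `[0, 1]`, or `NA` when undefined.
#' @export
recall <- function(pred, truth) {
  n <- pixel_counts(pred, truth)
  if (n$vg == 0) return(NA_real_)
  n$inter / n$vg
}

#' Evaluate predictions against ground truth
#'
#' Computes Dice, Jaccard, precision and recall per sample and aggregates
#' them. The default policy averages over samples with non-empty ground
#' truth (where recall is defined); slices where the model predicts tumor
#' on a truly tumor-free slice are reported separately as
#' `false_positive_slices`. `policy = "pooled"` instead pools pixel counts
#' over all samples and computes one set of metrics.
#'
#' @param predictions,truths lists of binary matrices of equal length.
#' @param ids optional sample identifiers.
#' @param policy `"tumor_slices"` (default) or `"pooled"`.
#' @return A `metrics_report`: per-sample data frame, aggregate means,
#'   the policy used, and the false-positive-slice count.
#' @export
evaluate <- function(predictions, truths, ids = NULL,
                     policy = c("tumor_slices", "pooled")) {
  policy <- match.arg(policy)
  if (length(predictions) != length(truths)) {
    stop("prediction/truth length mismatch", call. = FALSE)
  }
  n <- length(predictions)
  if (is.null(ids)) ids <- sprintf("sample%04d", seq_len(n))
  per <- data.frame(id = ids,
                    dice = NA_real_, jaccard = NA_real_,
                    precision = NA_real_, recall = NA_real_,
                    has_truth = FALSE, stringsAsFactors = FALSE)
  fp_slices <- 0L
  tot <- list(vs = 0, vg = 0, inter = 0, union = 0)
  for (i in seq_len(n)) {
    cnt <- pixel_counts(predictions[[i]], truths[[i]])
    tot <- Map(`+`, tot, cnt)
    per$has_truth[i] <- cnt$vg > 0
    if (cnt$vg == 0 && cnt$vs > 0) fp_slices <- fp_slices + 1L
    per$dice[i] <- if (cnt$vs + cnt$vg > 0) 2 * cnt$inter / (cnt$vs + cnt$vg) else NA_real_
    per$jaccard[i] <- if (cnt$union > 0) cnt$inter / cnt$union else NA_real_
    per$precision[i] <- if (cnt$vs > 0) cnt$inter / cnt$vs else NA_real_
    per$recall[i] <- if (cnt$vg > 0) cnt$inter / cnt$vg else NA_real_
  }
  if (policy == "tumor_slices") {
    inc <- per$has_truth
    agg <- c(dice = mean(per$dice[inc]),
             jaccard = mean(per$jaccard[inc]),
             precision = mean(per$precision[inc], na.rm = TRUE),
             recall = mean(per$recall[inc]))
  } else {
    agg <- c(dice = if (tot$vs + tot$vg > 0) 2 * tot$inter / (tot$vs + tot$vg) else NA_real_,
             jaccard = if (tot$union > 0) tot$inter / tot$union else NA_real_,
             precision = if (tot$vs > 0) tot$inter / tot$vs else NA_real_,
             recall = if (tot$vg > 0) tot$inter / tot$vg else NA_real_)
  }
  structure(list(per_sample = per, aggregate = agg, policy = policy,
                 false_positive_slices = fp_slices),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> %d samples, policy = %s\n",
              nrow(x$per_sample), x$policy))
  cat(sprintf("  dice %.4f  jaccard %.4f  precision %.4f  recall %.4f\n",
              x$aggregate["dice"], x$aggregate["jaccard"],
              x$aggregate["precision"], x$aggregate["recall"]))
  cat(sprintf("  false-positive slices: %d\n", x$false_positive_slices))
  invisible(x)
}

#' Write a metrics report to CSV and JSON
#'
#' @param report a `metrics_report`.
#' @param stem output path stem; writes `<stem>.csv` and `<stem>.json`.
#' @return The two paths, invisibly.
#' @export
write_metrics_report <- function(report, stem) {
  csv <- paste0(stem, ".csv")
  js <- paste0(stem, ".json")
  write.csv(report$per_sample, csv, row.names = FALSE)
  jsonlite::write_json(
    list(aggregate = as.list(report$aggregate), policy = report$policy,
         false_positive_slices = report$false_positive_slices),
    js, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(c(csv, js))
}
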