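## Diagnostic-performance statistics: ROC/AUC with DeLong confidence
## intervals and paired tests, Tsukuba-BI-RADS score fusion, blind-test
## perceptual scoring, and depth-stratified evaluation.

as_binary_labels <- function(labels) {
  if (is.character(labels) || is.factor(labels)) {
    labels <- as.integer(as.character(labels) == "malignant")
  }
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) {
    stop("labels must be 0/1 or 'benign'/'malignant'")
  }
  labels
}

#' AUC with a DeLong 95% confidence interval
#'
#' Mann-Whitney AUC (ties counted one half) for the convention that higher
#' scores predict the positive class, with the confidence interval from the
#' DeLong variance estimator.
#'
#' @param scores Numeric scores.
#' @param labels 0/1 vector (or `"benign"`/`"malignant"`); 1 = positive.
#' @param conf_level Confidence level (default 0.95).
#' @return An object of class `veus_roc`: list with `auc`, `ci_low`,
#'   `ci_high`, `n_pos`, `n_neg`.
#' @export
auc_ci <- function(scores, labels, conf_level = 0.95) {
  labels <- as_binary_labels(labels)
  if (length(scores) != length(labels)) stop("scores and labels differ in length")
  if (length(unique(labels)) < 2L) {
    stop("both classes must be present to compute an AUC")
  }
  r <- pROC::roc(labels, scores, levels = c(0, 1), direction = "<", quiet = TRUE)
  ## pROC warns that a degenerate AUC of 1 gives a 1-1 interval; that is the
  ## expected behaviour here, not a problem to surface per call
  ci <- suppressWarnings(pROC::ci.auc(r, conf.level = conf_level, method = "delong"))
  structure(list(auc = as.numeric(pROC::auc(r)),
                 ci_low = max(0, ci[1]), ci_high = min(1, ci[3]),
                 n_pos = sum(labels == 1L), n_neg = sum(labels == 0L)),
            class = "veus_roc")
}

#' @export
print.veus_roc <- function(x, ...) {
  cat(sprintf("<veus_roc> AUC %.3f (95%% CI %.3f-%.3f), %d pos / %d neg\n",
              x$auc, x$ci_low, x$ci_high, x$n_pos, x$n_neg))
  invisible(x)
}

#' DeLong test for two correlated AUCs
#'
#' Two-sided test of equality of the AUCs of two score sets computed on the
#' same cases (structural-components formulation, midranks for ties).
#'
#' @param scores_a,scores_b Paired score vectors on identical cases.
#' @param labels 0/1 (or `"benign"`/`"malignant"`) labels.
#' @return Two-sided p-value.
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  labels <- as_binary_labels(labels)
  if (length(scores_a) != length(scores_b) || length(scores_a) != length(labels)) {
    stop("scores_a, scores_b and labels must have identical length")
  }
  ra <- pROC::roc(labels, scores_a, levels = c(0, 1), direction = "<", quiet = TRUE)
  rb <- pROC::roc(labels, scores_b, levels = c(0, 1), direction = "<", quiet = TRUE)
  if (isTRUE(all.equal(scores_a, scores_b))) return(1)
  as.numeric(pROC::roc.test(ra, rb, method = "delong", paired = TRUE)$p.value)
}

#' Combine a Tsukuba elasticity score with a BI-RADS category
#'
#' Moves the BI-RADS category one step down the ordered scale
#' `2 < 3 < 4a < 4b < 4c < 5` for Tsukuba scores 1-3, one step up for
#' scores 4-5, clipping at both ends. Vectorized.
#'
#' @param birads Character vector of categories in
#'   `c("2","3","4a","4b","4c","5")`.
#' @param tsukuba Integer vector of Tsukuba scores on `[1, 5]`.
#' @return Character vector of adjusted categories.
#' @export
combine_tsukuba_birads <- function(birads, tsukuba) {
  lv <- birads_levels()
  idx <- match(as.character(birads), lv)
  if (anyNA(idx)) {
    stop("invalid BI-RADS category: ",
         paste(unique(birads[is.na(idx)]), collapse = ", "))
  }
  tsukuba <- as.integer(tsukuba)
  if (anyNA(tsukuba) || any(tsukuba < 1L | tsukuba > 5L)) {
    stop("Tsukuba scores must be integers on [1, 5]")
  }
  step <- ifelse(tsukuba <= 3L, -1L, 1L)
  lv[clamp(idx + step, 1L, length(lv))]
}

#' Numeric coding of BI-RADS categories for ROC analysis
#'
#' Maps the ordered scale `2, 3, 4a, 4b, 4c, 5` to integers `0..5`,
#' preserving order.
#'
#' @param birads Character vector of categories.
#' @return Integer vector.
#' @export
birads_ordinal <- function(birads) {
  idx <- match(as.character(birads), birads_levels())
  if (anyNA(idx)) stop("invalid BI-RADS category")
  idx - 1L
}

#' Perceptual score of a blind real-vs-virtual evaluation
#'
#' Each trial scores 0 when the observer correctly picks the real image and
#' 1 otherwise; the perceptual score is the mean. 0.5 means the virtual
#' images are indistinguishable from real ones; 0 means always detectable.
#'
#' @param picked_real_correctly Logical vector, one element per trial (also
#'   accepts a data frame of reader records with that column).
#' @return Mean score on `[0, 1]`.
#' @export
perceptual_score <- function(picked_real_correctly) {
  if (is.data.frame(picked_real_correctly)) {
    picked_real_correctly <- picked_real_correctly$picked_real_correctly
  }
  if (length(picked_real_correctly) == 0L) stop("no blind-evaluation records")
  mean(1 - as.numeric(as.logical(picked_real_correctly)))
}

#' Simulate a chance-level blind-test reader
#'
#' Simulates `n` independent trials in which the reader picks one of the two
#' displayed images uniformly at random, and scores each trial with the
#' blind-evaluation rule. Consumes the current RNG stream.
#'
#' @param n Number of trials.
#' @return Logical vector of length `n`: whether the real image was picked.
#' @export
simulate_chance_reader <- function(n) stats::runif(n) < 0.5

#' Depth-stratified AUC table
#'
#' Computes [auc_ci()] within lesion-depth bins. Bins missing one of the
#' two classes are reported as undefined rather than dropped.
#'
#' @param scores Numeric scores (e.g. strain ratios).
#' @param labels 0/1 or `"benign"`/`"malignant"` labels.
#' @param depth_mm Lesion depth per case, mm.
#' @param bin_edges Increasing numeric vector of interior bin edges; the
#'   default follows the conventional depth strata <10, 10-14.9, 15-20,
#'   >20 mm.
#' @return A data frame with one row per bin: `bin`, `n`, `n_pos`, `n_neg`,
#'   `auc`, `ci_low`, `ci_high`, `defined`.
#' @export
depth_stratified_auc <- function(scores, labels, depth_mm,
                                 bin_edges = c(10, 15, 20)) {
  if (is.unsorted(bin_edges, strictly = TRUE)) {
    stop("bin_edges must be strictly increasing")
  }
  labels <- as_binary_labels(labels)
  edges <- c(-Inf, bin_edges, Inf)
  bin <- cut(depth_mm, edges, right = FALSE)
  out <- lapply(levels(bin), function(b) {
    i <- which(bin == b)
    n_pos <- sum(labels[i] == 1L); n_neg <- sum(labels[i] == 0L)
    if (n_pos > 0L && n_neg > 0L) {
      r <- auc_ci(scores[i], labels[i])
      data.frame(bin = b, n = length(i), n_pos = n_pos, n_neg = n_neg,
                 auc = r$auc, ci_low = r$ci_low, ci_high = r$ci_high,
                 defined = TRUE)
    } else {
      data.frame(bin = b, n = length(i), n_pos = n_pos, n_neg = n_neg,
                 auc = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                 defined = FALSE)
    }
  })
  do.call(rbind, out)
}

#' Read blind-evaluation reader records
#'
#' CSV columns: `case_id`, `birads`, `tsukuba_real`, `tsukuba_virtual`,
#' `picked_real_correctly`, `reader_tier`.
#'
#' @param path CSV file path.
#' @return Data frame of reader records.
#' @export
read_reader_records <- function(path) {
  df <- utils::read.csv(path, colClasses = c(birads = "character"))
  needed <- c("case_id", "birads", "tsukuba_real", "tsukuba_virtual",
              "picked_real_correctly", "reader_tier")
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    stop("reader records missing columns: ", paste(missing, collapse = ", "))
  }
  df$picked_real_correctly <- as.logical(df$picked_real_correctly)
  df
}
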