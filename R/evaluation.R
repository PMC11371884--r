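## Stratified cross-validation, confusion-matrix accounting, the six
## derived classification metrics, and ROC/AUC.
## Positive class everywhere: incorrectly seated condyle.

#' Stratified k-fold assignment
#'
#' Within each class, a seeded shuffle is dealt round-robin to the k folds,
#' so per-fold class counts differ from perfect stratification by at most
#' one and every joint appears in exactly one validation fold.
#'
#' @param labels named vector (names = joint ids) of binary labels.
#' @param k number of folds (default 5).
#' @param rng_seed shuffle seed.
#' @return A `fold_split`: list with `assignments` (named integer vector,
#'   joint id -> fold in 1..k) and `k`.
#' @export
stratified_kfold <- function(labels, k = 5L, rng_seed = 0L) {
  k <- as.integer(k)
  if (k < 2L) stop("'k' must be >= 2")
  y <- encode_labels(labels)
  ids <- names(labels)
  if (is.null(ids)) ids <- as.character(seq_along(labels))
  if (anyDuplicated(ids)) stop("duplicate joint ids")
  for (cls in unique(y)) {
    if (sum(y == cls) < k)
      stop("class with ", sum(y == cls), " members cannot fill k = ", k,
           " folds")
  }
  assignments <- integer(length(y))
  names(assignments) <- ids
  for (cls in sort(unique(y))) {
    members <- which(y == cls)
    shuffled <- with_seed(derive_seed(rng_seed, "fold", cls),
                          sample(members))
    assignments[shuffled] <- rep_len(seq_len(k), length(shuffled))
  }
  structure(list(assignments = assignments, k = k), class = "fold_split")
}

#' Confusion matrix with positive = incorrectly seated
#'
#' @param y_true,y_pred equal-length binary label vectors (0/1, logical or
#'   `"correct"`/`"incorrect"`).
#' @return A `confusion_matrix`: list with `TP`, `FP`, `TN`, `FN`.
#' @export
confusion <- function(y_true, y_pred) {
  yt <- encode_labels(y_true)
  yp <- encode_labels(y_pred)
  if (length(yt) != length(yp))
    stop("length mismatch: ", length(yt), " true vs ", length(yp),
         " predicted")
  structure(list(TP = sum(yt == 1 & yp == 1),
                 FP = sum(yt == 0 & yp == 1),
                 TN = sum(yt == 0 & yp == 0),
                 FN = sum(yt == 1 & yp == 0)),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("confusion_matrix (positive = incorrectly seated):\n"))
  cat(sprintf("  TP %d  FN %d\n  FP %d  TN %d\n", x$TP, x$FN, x$FP, x$TN))
  invisible(x)
}

#' Sum confusion matrices (e.g. pooling over folds)
#' @param ... `confusion_matrix` objects.
#' @export
pool_confusion <- function(...) {
  cms <- list(...)
  if (length(cms) == 1L && is.list(cms[[1]]) &&
      !inherits(cms[[1]], "confusion_matrix")) cms <- cms[[1]]
  out <- list(TP = 0L, FP = 0L, TN = 0L, FN = 0L)
  for (cm in cms) for (nm in names(out)) out[[nm]] <- out[[nm]] + cm[[nm]]
  structure(out, class = "confusion_matrix")
}

#' The six classification metrics from a confusion matrix
#'
#' accuracy = (TP+TN)/(TP+TN+FP+FN); precision (PPV) = TP/(TP+FP);
#' NPV = TN/(TN+FN); F1 (Dice) = 2TP/(2TP+FP+FN); sensitivity (recall) =
#' TP/(TP+FN); specificity = TN/(TN+FP).  A metric whose denominator is
#' zero is reported as `NA` (undefined), never as 0.
#'
#' @param cm a [confusion] matrix.
#' @return list with `accuracy`, `precision_ppv`, `npv`, `f1`,
#'   `sensitivity`, `specificity`.
#' @export
compute_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  safe_div <- function(num, den) if (den == 0) NA_real_ else num / den
  with(cm, list(
    accuracy = safe_div(TP + TN, TP + TN + FP + FN),
    precision_ppv = safe_div(TP, TP + FP),
    npv = safe_div(TN, TN + FN),
    f1 = safe_div(2 * TP, 2 * TP + FP + FN),
    sensitivity = safe_div(TP, TP + FN),
    specificity = safe_div(TN, TN + FP)))
}

#' ROC AUC by the Mann-Whitney rank formulation
#'
#' Tie-safe: uses midranks.  Equals the probability that a random positive
#' (incorrectly seated) joint receives a higher confidence than a random
#' negative one, with ties counting one half.
#'
#' @param confidences numeric scores, higher = more likely positive.
#' @param labels binary labels aligned with `confidences`.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(confidences, labels) {
  y <- encode_labels(labels)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0L || n0 == 0L)
    stop("both classes must be present to compute AUC")
  r <- rank(confidences)            # midranks for ties
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve points (FPR, TPR) at every distinct threshold
#'
#' @inheritParams roc_auc
#' @return data.frame with `threshold`, `fpr`, `tpr`, ordered for
#'   trapezoidal integration.
#' @export
roc_curve <- function(confidences, labels) {
  y <- encode_labels(labels)
  ord <- order(confidences, decreasing = TRUE)
  ys <- y[ord]; cs <- confidences[ord]
  # collapse tied thresholds
  keep <- c(diff(cs) != 0, TRUE)
  tpr <- cumsum(ys) / sum(ys)
  fpr <- cumsum(1 - ys) / sum(1 - ys)
  data.frame(threshold = c(Inf, cs[keep]),
             fpr = c(0, fpr[keep]),
             tpr = c(0, tpr[keep]))
}

#' Trapezoidal AUC from the ROC curve (cross-check of [roc_auc])
#' @inheritParams roc_auc
#' @export
roc_auc_trapezoid <- function(confidences, labels) {
  rc <- roc_curve(confidences, labels)
  sum(diff(rc$fpr) * (head(rc$tpr, -1) + tail(rc$tpr, -1)) / 2)
}

#' Round half-up to a number of decimals
#'
#' Used when comparing computed metrics with values printed at 2 decimals
#' (R's `round` is round-half-even).
#'
#' @param x numeric; @param digits decimals.
#' @export
round_half_up <- function(x, digits = 2) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' Recover the integer confusion matrix behind printed sensitivity and
#' specificity
#'
#' Brute-force search over all `TP` in `0..n_pos` and `TN` in `0..n_neg`
#' for matrices whose sensitivity and specificity round (half-up, 2 dp) to
#' the printed values; succeeds only when the candidate is unique.
#'
#' @param sens_2dp,spec_2dp printed sensitivity and specificity (2 dp).
#' @param n_pos,n_neg class totals.
#' @return The unique [confusion] matrix.
#' @export
recover_confusion_matrix <- function(sens_2dp, spec_2dp, n_pos, n_neg) {
  stopifnot(n_pos > 0, n_neg > 0)
  tp_ok <- which(round_half_up((0:n_pos) / n_pos) == sens_2dp) - 1L
  tn_ok <- which(round_half_up((0:n_neg) / n_neg) == spec_2dp) - 1L
  cand <- expand.grid(TP = tp_ok, TN = tn_ok)
  if (nrow(cand) == 0L)
    stop("no integer confusion matrix matches sensitivity ", sens_2dp,
         " and specificity ", spec_2dp, " at n_pos = ", n_pos,
         ", n_neg = ", n_neg)
  if (nrow(cand) > 1L)
    stop("ambiguous: ", nrow(cand), " candidate matrices match (TP in {",
         paste(unique(cand$TP), collapse = ", "), "}, TN in {",
         paste(unique(cand$TN), collapse = ", "), "})")
  structure(list(TP = cand$TP[1], FP = n_neg - cand$TN[1],
                 TN = cand$TN[1], FN = n_pos - cand$TP[1]),
            class = "confusion_matrix")
}
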