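## Multi-reader label fusion by majority rule.
##
## Throughout the package the POSITIVE class is the incorrectly seated
## condyle, so sensitivity measures detection of seating problems.

#' Fuse reader votes into a final seating label by majority rule
#'
#' @param votes logical vector, one vote per reader; `TRUE` marks the joint
#'   as incorrectly seated.  The reader count must be odd (ties undefined).
#' @return list with `final_label` (`"correct"` or `"incorrect"`),
#'   `unanimous`, and `n_incorrect_votes`.
#' @export
majority_label <- function(votes) {
  votes <- as.logical(votes)
  if (!length(votes) || anyNA(votes)) stop("votes must be non-missing logicals")
  if (length(votes) %% 2 == 0)
    stop("even reader count (", length(votes),
         "): majority undefined without a tie rule")
  n_inc <- sum(votes)
  list(final_label = if (n_inc > length(votes) / 2) "incorrect" else "correct",
       unanimous = n_inc == 0L || n_inc == length(votes),
       n_incorrect_votes = n_inc)
}

#' Build annotation records from a votes table
#'
#' @param votes_df data.frame with column `joint_id` and one 0/1 column per
#'   reader (any columns matching `reader_`), or a logical/0-1 matrix.
#' @return data.frame with `joint_id`, `n_incorrect_votes`, `final_label`,
#'   `unanimous`.
#' @export
fuse_annotations <- function(votes_df) {
  reader_cols <- grep("^reader", names(votes_df), value = TRUE)
  if (!length(reader_cols)) stop("no reader_* vote columns found")
  fused <- lapply(seq_len(nrow(votes_df)), function(i) {
    v <- as.logical(as.numeric(votes_df[i, reader_cols]))
    majority_label(v)
  })
  data.frame(joint_id = votes_df$joint_id,
             n_incorrect_votes = vapply(fused, `[[`, integer(1),
                                        "n_incorrect_votes"),
             final_label = vapply(fused, `[[`, character(1), "final_label"),
             unanimous = vapply(fused, `[[`, logical(1), "unanimous"),
             stringsAsFactors = FALSE)
}

#' Histogram of incorrect-seating votes over joints
#'
#' Counts joints by how many readers marked them incorrectly seated
#' (0..n_readers), the summary a reading panel reports before fusion.
#'
#' @param n_incorrect_votes integer vector, per-joint count of incorrect
#'   votes.
#' @param n_readers total reader count (default 5).
#' @return named integer vector of length `n_readers + 1`, names `"0"` ..
#'   `"n_readers"`; sums to the number of joints.
#' @export
vote_histogram <- function(n_incorrect_votes, n_readers = 5L) {
  n_incorrect_votes <- as.integer(n_incorrect_votes)
  if (length(n_incorrect_votes) &&
      (min(n_incorrect_votes) < 0L || max(n_incorrect_votes) > n_readers))
    stop("vote counts outside 0..", n_readers)
  tab <- tabulate(n_incorrect_votes + 1L, nbins = n_readers + 1L)
  names(tab) <- as.character(0:n_readers)
  tab
}

#' Fusion summary of a vote histogram
#'
#' Applies the majority rule and unanimity counting to a histogram of
#' incorrect votes.
#'
#' @param histogram named vector as returned by [vote_histogram] (names are
#'   incorrect-vote counts).
#' @param n_readers reader count (odd; default 5).
#' @return list with `n_correct`, `n_incorrect` (majority-rule totals),
#'   `n_unanimous`, `n_majority_needed`, `n_total`.
#' @export
histogram_summary <- function(histogram, n_readers = 5L) {
  if (n_readers %% 2 == 0) stop("even reader count: majority undefined")
  k <- as.integer(names(histogram))
  if (anyNA(k)) k <- seq_along(histogram) - 1L
  inc <- k > n_readers / 2
  unan <- k == 0L | k == n_readers
  list(n_correct = sum(histogram[!inc]),
       n_incorrect = sum(histogram[inc]),
       n_unanimous = sum(histogram[unan]),
       n_majority_needed = sum(histogram[!unan]),
       n_total = sum(histogram))
}
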