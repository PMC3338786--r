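#' Score an assignment set against the truth
#'
#' Computes, per rank, the three benchmark metrics: recovery (proportion of
#' queries correctly classified), erroneous recovery (proportion incorrectly
#' classified), and coverage (proportion classified at all, correct or not),
#' so recovery + erroneous = coverage. The denominator at each rank is the
#' number of queries whose truth names that rank; queries with truth-side
#' gaps are excluded there.
#'
#' @param x An \code{assignment_set}.
#' @param truth Lineage matrix of true lineages with rownames (or a parallel
#'   \code{ids} vector) keyed by query id; every query must have a truth.
#' @param ids Optional character vector pairing \code{truth} rows with query
#'   ids (defaults to \code{rownames(truth)}).
#' @param ranks Ranks to evaluate (default all seven).
#' @return Data frame: \code{rank}, \code{n}, \code{correct},
#'   \code{incorrect}, \code{unclassified}, \code{recovery},
#'   \code{erroneous}, \code{coverage}.
#' @export
evaluate_assignments <- function(x, truth, ids = rownames(truth),
                                 ranks = tax_ranks()) {
  stopifnot(inherits(x, "assignment_set"), all(ranks %in% tax_ranks()))
  hit <- match(x$query_id, ids)
  if (anyNA(hit)) {
    stop("no truth lineage for query(s): ",
         paste(x$query_id[is.na(hit)], collapse = ", "))
  }
  tr <- truth[hit, , drop = FALSE]
  out <- lapply(ranks, function(r) {
    denom <- which(!is.na(tr[, r]))
    pred <- x$lineage[denom, r]
    correct <- sum(!is.na(pred) & pred == tr[denom, r])
    incorrect <- sum(!is.na(pred) & pred != tr[denom, r])
    unclassified <- sum(is.na(pred))
    n <- length(denom)
    data.frame(rank = r, n = n, correct = correct, incorrect = incorrect,
               unclassified = unclassified,
               recovery = if (n > 0) correct / n else NA_real_,
               erroneous = if (n > 0) incorrect / n else NA_real_,
               coverage = if (n > 0) (correct + incorrect) / n else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Mean and standard error over grouped summaries
#'
#' Aggregates replicate evaluation summaries (e.g. one per primer) into the
#' mean and standard error of the mean (sd / sqrt(n)) per group cell. Cells
#' with a single replicate get the mean only, with \code{sem} set to
#' \code{NA} and flagged.
#'
#' @param data Data frame of stacked summaries.
#' @param value Name of the value column to aggregate.
#' @param by Character vector of grouping column names.
#' @return Data frame with the grouping columns plus \code{mean},
#'   \code{sem}, \code{n_rep}, and \code{sem_defined}.
#' @export
aggregate_sem <- function(data, value, by) {
  stopifnot(value %in% names(data), all(by %in% names(data)))
  key <- interaction(data[by], drop = TRUE, lex.order = TRUE)
  rows <- split(seq_len(nrow(data)), key)
  out <- lapply(rows, function(idx) {
    v <- data[[value]][idx]
    cell <- data[idx[[1]], by, drop = FALSE]
    cell$mean <- mean(v)
    cell$sem <- if (length(v) >= 2) stats::sd(v) / sqrt(length(v)) else
      NA_real_
    cell$n_rep <- length(v)
    cell$sem_defined <- length(v) >= 2
    cell
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Track recovery degradation under increasing error
#'
#' Restricts attention to the queries correctly classified at zero error and
#' follows their change in recovery as the simulated per-base error rate
#' grows: \code{delta(r)} = (fraction of the tracked queries still correct
#' at rate r) - 1, so \code{delta(0) = 0} and deltas cannot be positive.
#'
#' @param assignments Named list of \code{assignment_set}s, one per error
#'   rate; names are the rates, and a rate-0 entry must be present. Query
#'   ids must encode the same underlying reads across rates via
#'   \code{parent_ids}.
#' @param parent_ids Named list (same names) of the per-query parent/read
#'   keys used to match queries across rates.
#' @param truth,ids Truth lineages as in [evaluate_assignments()], keyed by
#'   parent id.
#' @param rank Rank at which correctness is tracked (default genus).
#' @return Data frame: \code{rate}, \code{n_tracked}, \code{still_correct},
#'   \code{delta}.
#' @export
track_error_degradation <- function(assignments, parent_ids, truth,
                                    ids = rownames(truth), rank = "genus") {
  stopifnot("0" %in% names(assignments))
  correct_keys <- function(label) {
    a <- assignments[[label]]
    keys <- parent_ids[[label]]
    tr <- truth[match(keys, ids), rank]
    keys[!is.na(a$lineage[, rank]) & !is.na(tr) & a$lineage[, rank] == tr]
  }
  tracked <- correct_keys("0")
  if (length(tracked) == 0) stop("no query is correct at zero error")
  out <- lapply(names(assignments), function(label) {
    still <- sum(tracked %in% correct_keys(label))
    data.frame(rate = as.numeric(label), n_tracked = length(tracked),
               still_correct = still,
               delta = still / length(tracked) - 1,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res[order(res$rate), ]
}
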