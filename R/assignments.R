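#' Assignment sets
#'
#' All three classifiers return an \code{assignment_set}: per-query taxon
#' calls with one name per rank (a contiguous prefix from kingdom down) and,
#' where the method provides one, a per-rank confidence in \[0, 1\].
#'
#' @param query_id Character vector of query ids.
#' @param lineage Lineage matrix (one row per query; all-NA rows mean
#'   unclassified).
#' @param confidence Optional numeric matrix (same shape) of per-rank
#'   confidences; \code{NA} where the method provides none.
#' @param query_len Optional integer vector of query lengths in bp.
#' @param method Label of the producing classifier.
#' @return An object of class \code{assignment_set}.
#' @export
assignment_set <- function(query_id, lineage, confidence = NULL,
                           query_len = NA_integer_, method = NA_character_) {
  n <- length(query_id)
  stopifnot(nrow(lineage) == n)
  if (is.null(confidence)) {
    confidence <- matrix(NA_real_, n, 7, dimnames = list(NULL, tax_ranks()))
  }
  stopifnot(nrow(confidence) == n)
  validate_lineage(lineage)
  structure(list(query_id = query_id, lineage = lineage,
                 confidence = confidence,
                 query_len = rep_len(query_len, n), method = method),
            class = "assignment_set")
}

#' @export
length.assignment_set <- function(x) length(x$query_id)

#' @export
print.assignment_set <- function(x, ...) {
  named <- colSums(!is.na(x$lineage))
  cat("<assignment_set> ", length(x$query_id), " queries",
      if (!is.na(x$method)) paste0(" [", x$method, "]"), "\n", sep = "")
  cat("classified per rank: ",
      paste(paste0(substr(tax_ranks(), 1, 1), "=", named), collapse = " "),
      "\n", sep = "")
  invisible(x)
}

#' Long-format view of an assignment set
#'
#' One row per named rank per query: \code{query_id}, \code{rank},
#' \code{taxon}, \code{confidence} - the TSV shape shared by all
#' classifiers.
#'
#' @param x An \code{assignment_set}.
#' @param ... Unused.
#' @return A data frame.
#' @export
as.data.frame.assignment_set <- function(x, ...) {
  rows <- which(!is.na(x$lineage), arr.ind = TRUE)
  rows <- rows[order(rows[, 1], rows[, 2]), , drop = FALSE]
  data.frame(query_id = x$query_id[rows[, 1]],
             rank = tax_ranks()[rows[, 2]],
             taxon = x$lineage[rows],
             confidence = x$confidence[rows],
             stringsAsFactors = FALSE)
}

# empty (all-unclassified) assignment rows
blank_assignments <- function(n) {
  matrix(NA_character_, n, 7, dimnames = list(NULL, tax_ranks()))
}
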