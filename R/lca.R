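#' LCA consensus parameters
#'
#' Parameters of the MEGAN-style lowest-common-ancestor consensus used to
#' parse scored hit lists: \code{min_support} (reads per reported taxon),
#' \code{min_score} (hits below it are discarded; the recommended values are
#' 50 for 50 bp fragments and 100 for longer queries), \code{top_percent}
#' (hits within this percentage of the best retained score are kept), and
#' \code{winscore} (when positive and reached by any hit, only hits at or
#' above it are kept, overriding the top-percent filter).
#'
#' @param min_support Minimum reads per taxon (default 1, i.e. disabled).
#' @param min_score Minimum hit score (default 100).
#' @param top_percent Top-percent window (default 1.0).
#' @param winscore Win-score floor (default 0, disabled).
#' @return A list of class \code{lca_params}.
#' @export
lca_params <- function(min_support = 1, min_score = 100, top_percent = 1.0,
                       winscore = 0) {
  stopifnot(min_support >= 1, top_percent >= 0, top_percent <= 100)
  structure(list(min_support = min_support, min_score = min_score,
                 top_percent = top_percent, winscore = winscore),
            class = "lca_params")
}

#' Recommended minimum score for a read length
#'
#' @param L Read length in bp.
#' @return 50 for reads shorter than 100 bp, else 100.
#' @export
default_min_score <- function(L) if (L < 100) 50 else 100

#' Optimal local alignment of two sequences
#'
#' Affine-gap Smith-Waterman with blastn-like default scoring (match +2,
#' mismatch -3, gap open 5, gap extend 2; a gap of length k costs
#' open + k * extend). The raw alignment score stands in for a search
#' engine's bit score throughout the package.
#'
#' @param query,subject DNA sequences (character).
#' @param match,mismatch,gap_open,gap_ext Scoring parameters.
#' @return One-row data frame: \code{score}, \code{identity} (percent over
#'   the aligned span), \code{matches}, \code{align_length},
#'   \code{qstart}, \code{qend}, \code{sstart}, \code{send}.
#' @export
local_align <- function(query, subject, match = 2, mismatch = -3,
                        gap_open = 5, gap_ext = 2) {
  stopifnot(nchar(query) >= 1, nchar(subject) >= 1)
  h <- sw_align_cpp(toupper(query), toupper(subject), match, mismatch,
                    gap_open, gap_ext)
  h$identity <- ifelse(h$align_length > 0, 100 * h$matches / h$align_length, 0)
  h
}

#' Search a reference database by local alignment
#'
#' Aligns the query against every record and returns scored hits, sorted by
#' score descending (ties by subject id), with zero-score subjects dropped.
#' \code{exclude_id} removes one subject from the results, emulating a
#' leave-one-out search in which the query's own accession is absent.
#'
#' @param query Query sequence.
#' @param db A \code{ref_db}.
#' @param min_score Drop hits below this score (default 0: keep all).
#' @param exclude_id Optional subject id to exclude.
#' @return Data frame of hits: \code{subject}, \code{score},
#'   \code{identity}, plus alignment spans.
#' @export
search_db <- function(query, db, min_score = 0, exclude_id = NULL) {
  h <- local_align(query, db$seq)
  h$subject <- db$id
  h <- h[h$score > 0 & h$score >= min_score, , drop = FALSE]
  if (!is.null(exclude_id)) h <- h[h$subject != exclude_id, , drop = FALSE]
  h <- h[order(-h$score, h$subject), , drop = FALSE]
  rownames(h) <- NULL
  h[, c("subject", "score", "identity", "matches", "align_length",
        "qstart", "qend", "sstart", "send")]
}

#' LCA consensus assignment from a hit list
#'
#' Retains hits with score >= \code{min_score}; if \code{winscore} > 0 and
#' any hit reaches it, only those hits are retained; then keeps hits within
#' \code{top_percent} of the best retained score
#' (score >= best x (1 - top_percent/100)); the assignment is the lowest
#' common ancestor of the retained subjects' lineages. No retained hits
#' means unclassified (an all-NA lineage).
#'
#' @param hits Hit data frame ([search_db()] shape: \code{subject},
#'   \code{score}).
#' @param params An [lca_params()].
#' @param db The \code{ref_db} providing subject lineages; every subject
#'   must be present.
#' @return A 1-row lineage matrix.
#' @export
lca_assign <- function(hits, params, db) {
  keep <- hits[hits$score >= params$min_score, , drop = FALSE]
  if (params$winscore > 0 && any(keep$score >= params$winscore)) {
    keep <- keep[keep$score >= params$winscore, , drop = FALSE]
  }
  if (nrow(keep) == 0) {
    return(matrix(NA_character_, 1, 7, dimnames = list(NULL, tax_ranks())))
  }
  best <- max(keep$score)
  keep <- keep[keep$score >= best * (1 - params$top_percent / 100), ,
               drop = FALSE]
  rows <- match(keep$subject, db$id)
  if (anyNA(rows)) {
    stop("subject(s) missing from reference db: ",
         paste(keep$subject[is.na(rows)], collapse = ", "))
  }
  lineage_lca(db$lineage[rows, , drop = FALSE])
}

#' Classify reads by similarity search + LCA consensus
#'
#' The full similarity + LCA pipeline: each read is aligned against the
#' reference database once, and assignments are derived per scenario - a
#' complete search keeps the read's parent record as a valid subject, a
#' leave-one-out search removes it.
#'
#' @param reads Read data frame (\code{read_id}, \code{parent_id},
#'   \code{seq}).
#' @param db A \code{ref_db}.
#' @param params An [lca_params()]; default uses the recommended minimum
#'   score for the reads' length.
#' @param scenario \code{"leave_one_out"} or \code{"complete"}; several may
#'   be given.
#' @param hits Optional precomputed hit lists (named by \code{read_id}) to
#'   reuse searches across classifiers.
#' @param orient Normalize read orientation against the database first
#'   ([orient_reads()]); set \code{FALSE} when the reads are already on the
#'   reference strand.
#' @return An \code{assignment_set} (single scenario), or a named list of
#'   them.
#' @export
classify_lca <- function(reads, db, params = NULL,
                         scenario = "leave_one_out", hits = NULL,
                         orient = TRUE) {
  stopifnot(all(scenario %in% c("leave_one_out", "complete")))
  if (orient && is.null(hits)) reads <- orient_reads(reads, db)
  if (is.null(params)) {
    params <- lca_params(min_score = default_min_score(
      min(nchar(reads$seq))))
  }
  n <- nrow(reads)
  out <- lapply(scenario, function(s) blank_assignments(n))
  names(out) <- scenario
  for (i in seq_len(n)) {
    hi <- if (!is.null(hits)) hits[[reads$read_id[[i]]]] else {
      search_db(reads$seq[[i]], db)
    }
    for (s in scenario) {
      h <- if (s == "leave_one_out") {
        hi[hi$subject != reads$parent_id[[i]], , drop = FALSE]
      } else hi
      out[[s]][i, ] <- lca_assign(h, params, db)
    }
  }
  sets <- lapply(scenario, function(s) {
    assignment_set(reads$read_id, out[[s]], query_len = nchar(reads$seq),
                   method = paste0("lca_", s))
  })
  names(sets) <- scenario
  if (length(sets) == 1) sets[[1]] else sets
}

#' Enforce minimum support on an assignment set
#'
#' Taxa receiving fewer than \code{min_support} reads have those reads moved
#' to the nearest ancestor whose subtree (reads assigned at or below it)
#' meets the support; \code{min_support = 1} is the identity.
#'
#' @param x An \code{assignment_set}.
#' @param min_support Minimum reads per reported taxon.
#' @return The adjusted \code{assignment_set}.
#' @export
apply_min_support <- function(x, min_support = 1) {
  stopifnot(min_support >= 1)
  if (min_support == 1) return(x)
  # subtree support of a prefix = number of reads whose original assignment
  # starts with that prefix
  orig <- x$lineage
  prefix_key <- function(lin, d) {
    apply(lin[, seq_len(d), drop = FALSE], 1, paste, collapse = ";")
  }
  for (i in seq_along(x$query_id)) {
    depth <- sum(!is.na(x$lineage[i, ]))
    while (depth > 0) {
      key <- paste(orig[i, seq_len(depth)], collapse = ";")
      support <- sum(prefix_key(orig, depth) == key, na.rm = FALSE)
      if (!is.na(support) && support >= min_support) break
      x$lineage[i, depth] <- NA_character_
      x$confidence[i, depth] <- NA_real_
      depth <- depth - 1L
    }
  }
  x
}

#' Re-parse naive Bayes assignments through the LCA stage
#'
#' Treats each query's per-rank calls as pseudo-hits whose score is the
#' confidence on a 0-100 scale, discards ranks scoring below
#' \code{min_score}, truncates the lineage at the deepest surviving rank,
#' and reconciles the result against the reference taxonomy: a lineage that
#' disagrees with the taxonomy at some rank collapses to the deepest shared
#' ancestor.
#'
#' @param x An \code{assignment_set} with confidences (e.g. from
#'   [predict.nbc()]).
#' @param taxonomy Reference [build_taxonomy()] to reconcile against.
#' @param params An [lca_params()]; the recommended import settings are
#'   \code{min_support = 1}, \code{min_score = 50}, \code{top_percent = 100}.
#' @return An \code{assignment_set} without confidences.
#' @export
import_nbc_assignments <- function(x, taxonomy,
                                   params = lca_params(min_score = 50,
                                                       top_percent = 100)) {
  stopifnot(inherits(x, "assignment_set"))
  lin <- blank_assignments(length(x$query_id))
  for (i in seq_along(x$query_id)) {
    named <- which(!is.na(x$lineage[i, ]))
    keep <- named[!is.na(x$confidence[i, named]) &
                    100 * x$confidence[i, named] >= params$min_score]
    if (length(keep) == 0) next
    cand <- x$lineage[i, , drop = FALSE]
    deepest <- max(keep)
    if (deepest < 7L) cand[1, (deepest + 1L):7L] <- NA_character_
    node <- lineage_node(taxonomy, cand)
    lin[i, ] <- node_lineage(taxonomy, node)
  }
  out <- assignment_set(x$query_id, lin, query_len = x$query_len,
                        method = "nbc_lca")
  apply_min_support(out, params$min_support)
}

#' Read a 12-column tabular hit file
#'
#' Accepts the standard tabular search-report convention (query, subject,
#' percent identity, alignment length, mismatches, gap opens, qstart, qend,
#' sstart, send, evalue, bitscore); the bitscore column is used as the hit
#' score.
#'
#' @param path Path to a tab-separated hit file without header.
#' @return Data frame of hits with columns \code{query}, \code{subject},
#'   \code{identity}, \code{align_length}, \code{score}, and the coordinate
#'   columns.
#' @export
read_hit_table <- function(path) {
  cols <- c("query", "subject", "identity", "align_length", "mismatches",
            "gap_opens", "qstart", "qend", "sstart", "send", "evalue",
            "bitscore")
  h <- utils::read.delim(path, header = FALSE, col.names = cols,
                         stringsAsFactors = FALSE)
  h$score <- h$bitscore
  h
}
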