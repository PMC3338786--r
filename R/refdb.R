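#' Reference database of annotated sequences
#'
#' A \code{ref_db} is an ordered collection of reference records: a unique id,
#' an IUPAC DNA sequence, and a taxonomic lineage. It is the unit every other
#' stage of the benchmark consumes: classifier training sets, similarity-search
#' subjects, and the source of simulated reads.
#'
#' @param id Character vector of unique record ids.
#' @param seq Character vector of IUPAC DNA sequences.
#' @param lineage Lineage matrix ([parse_lineage()] layout) with one row per
#'   record.
#' @return An object of class \code{ref_db}.
#' @export
ref_db <- function(id, seq, lineage) {
  lineage <- if (is.character(lineage) && !is.matrix(lineage)) {
    parse_lineage(lineage)
  } else {
    as_lineage_matrix_n(lineage, length(id))
  }
  stopifnot(length(id) == length(seq), nrow(lineage) == length(id))
  if (anyDuplicated(id)) {
    stop("duplicate record id(s): ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  seq <- toupper(seq)
  if (any(nchar(seq) < 1)) stop("empty sequence(s)")
  bad <- grepl("[^ACGTRYSWKMBDHVN]", seq)
  if (any(bad)) {
    stop("non-IUPAC symbols in record(s): ", paste(id[bad], collapse = ", "))
  }
  validate_lineage(lineage)
  structure(list(id = id, seq = seq, lineage = lineage), class = "ref_db")
}

as_lineage_matrix_n <- function(lineage, n) {
  if (is.matrix(lineage)) return(lineage)
  m <- as_lineage_matrix(lineage)
  m[rep(1, n), , drop = FALSE]
}

#' @export
print.ref_db <- function(x, ...) {
  cat("<ref_db> ", length(x$id), " records, mean length ",
      round(mean(nchar(x$seq))), " bp\n", sep = "")
  named <- colSums(!is.na(x$lineage))
  cat("records named per rank: ",
      paste(paste0(substr(tax_ranks(), 1, 1), "=", named), collapse = " "),
      "\n", sep = "")
  invisible(x)
}

#' @export
length.ref_db <- function(x) length(x$id)

#' Subset a reference database by record index
#'
#' @param db A \code{ref_db}.
#' @param idx Integer or logical index over records.
#' @return A \code{ref_db} with the selected records, in order.
#' @export
db_subset <- function(db, idx) {
  structure(list(id = db$id[idx], seq = db$seq[idx],
                 lineage = db$lineage[idx, , drop = FALSE]),
            class = "ref_db")
}

#' Taxonomy induced by a reference database
#'
#' @param db A \code{ref_db}.
#' @return A [build_taxonomy()] object over the records' lineages.
#' @export
db_taxonomy <- function(db) build_taxonomy(db$lineage)

#' Read a reference database from FASTA
#'
#' The default annotation dialect carries the lineage in the FASTA description
#' after the id, as a rank-prefixed string
#' (\code{>id k__Fungi;p__...;...}). Alternatively, a two-column tab-separated
#' sidecar (id, lineage string) may provide the lineages.
#'
#' @param fasta_path Path to a FASTA file (wrapped or single-line).
#' @param lineage_path Optional path to a two-column TSV sidecar; when given,
#'   FASTA descriptions are ignored.
#' @return A \code{ref_db}.
#' @export
read_refdb <- function(fasta_path, lineage_path = NULL) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  headers <- names(seqs)
  ids <- sub("\\s.*$", "", headers)
  if (anyDuplicated(ids)) {
    stop("duplicate record id(s) in ", fasta_path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (is.null(lineage_path)) {
    desc <- sub("^\\S+\\s*", "", headers)
    if (any(!nzchar(desc))) {
      stop("record(s) without lineage annotation: ",
           paste(ids[!nzchar(desc)], collapse = ", "))
    }
    lin <- parse_lineage(desc)
  } else {
    side <- utils::read.delim(lineage_path, header = FALSE,
                              col.names = c("id", "lineage"),
                              stringsAsFactors = FALSE)
    hit <- match(ids, side$id)
    if (anyNA(hit)) {
      stop("no sidecar lineage for record(s): ",
           paste(ids[is.na(hit)], collapse = ", "))
    }
    lin <- parse_lineage(side$lineage[hit])
  }
  ref_db(ids, unname(as.character(seqs)), lin)
}

#' Write a reference database as single-line FASTA
#'
#' Lineages are emitted in the FASTA description using the rank-prefixed
#' dialect, so [read_refdb()] round-trips losslessly.
#'
#' @param db A \code{ref_db}.
#' @param fasta_path Output path.
#' @return \code{fasta_path}, invisibly.
#' @export
write_refdb <- function(db, fasta_path) {
  lines <- character(2L * length(db$id))
  lines[c(TRUE, FALSE)] <- paste0(">", db$id, " ", format_lineage(db$lineage))
  lines[c(FALSE, TRUE)] <- db$seq
  writeLines(lines, fasta_path)
  invisible(fasta_path)
}

#' Filter a reference database
#'
#' Applies the dataset-assembly filters: minimum sequence length, species-level
#' identification, and redundancy removal. The dedupe key is the exact
#' (sequence, species) pair, so identically sequenced sister species are both
#' retained; the first of each duplicate group survives.
#'
#' @param db A \code{ref_db}.
#' @param min_len Minimum sequence length in bp (default 100).
#' @param require_species Drop records lacking a species name (default TRUE).
#' @param dedupe Drop later duplicates of identical (sequence, species) pairs
#'   (default TRUE).
#' @return A filtered \code{ref_db} (possibly empty). Idempotent.
#' @export
filter_refdb <- function(db, min_len = 100, require_species = TRUE,
                         dedupe = TRUE) {
  stopifnot(min_len >= 1)
  keep <- nchar(db$seq) >= min_len
  if (require_species) keep <- keep & !is.na(db$lineage[, "species"])
  out <- db_subset(db, keep)
  if (dedupe && length(out$id) > 0) {
    key <- paste(out$seq, out$lineage[, "species"], sep = "\r")
    out <- db_subset(out, !duplicated(key))
  }
  out
}

#' Leave-one-out view of a database
#'
#' Returns the database minus exactly one record, emulating a search against
#' an incomplete reference set in which the query's own accession is absent.
#'
#' @param db A \code{ref_db}.
#' @param query_id Id of the record to exclude; must be present.
#' @return A \code{ref_db} of size n - 1. The input is unmodified.
#' @export
leave_one_out <- function(db, query_id) {
  i <- match(query_id, db$id)
  if (is.na(i)) stop("unknown record id: ", query_id)
  db_subset(db, -i)
}
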