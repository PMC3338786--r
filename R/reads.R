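#' LSU rDNA primer reference table
#'
#' Twelve primers commonly used to amplify the 5' region of the nuclear
#' large-subunit ribosomal RNA gene, with their published 1-based coordinates
#' on the Saccharomyces cerevisiae 25S gene. Descending coordinate ranges
#' denote reverse primers: the printed range runs 5' to 3' of the primer
#' itself, so the primer matches the reverse complement of that span.
#'
#' @return Data frame with columns \code{name}, \code{seq} (5' to 3' IUPAC),
#'   \code{orientation}, \code{ref_start}, \code{ref_end}.
#' @export
#' @examples
#' lsu_primers()
lsu_primers <- function() {
  p <- rbind(
    c("LR0R",      "ACCCGCTGAACTTAAGC",        26,   42),
    c("LR1",       "AGCATATCAATAAGCGGAGGA",    40,   60),
    c("NL-1",      "GCATATCAATAAGCGGAGGAAAAG", 41,   64),
    c("LR3R",      "GTCTTGAAACACGGACC",        639,  655),
    c("NL-4",      "GGTCCGTGTTTCAAGACGG",      655,  637),
    c("TW13",      "GGTCCGTGTTTCAAGACG",       655,  638),
    c("LR3",       "GGTCCGTGTTTCAAGAC",        655,  639),
    c("NDL22",     "TGGTCCGTGTTTCAAGACG",      656,  638),
    c("LR16",      "TTCCACCCAAACACTCG",        691,  675),
    c("LR5",       "ATCCTGAGGGAAACTTC",        966,  950),
    c("nLSU1221R", "CTAGATGAACYAACACCTT",      1222, 1204),
    c("LR7",       "TACTACCACCAAGATCT",        1449, 1433))
  out <- data.frame(name = p[, 1], seq = p[, 2],
                    ref_start = as.integer(p[, 3]),
                    ref_end = as.integer(p[, 4]), stringsAsFactors = FALSE)
  out$orientation <- ifelse(out$ref_start <= out$ref_end, "forward", "reverse")
  out[, c("name", "seq", "orientation", "ref_start", "ref_end")]
}

# mismatch profile of a primer (character vector) along a sequence strand
scan_mismatches <- function(seqc, primerc) {
  L <- length(seqc); m <- length(primerc)
  if (L < m) return(integer(0))
  n <- L - m + 1L
  mm <- integer(n)
  for (j in seq_len(m)) {
    set <- IUPAC_SETS[[primerc[[j]]]]
    if (is.null(set)) stop("non-IUPAC primer symbol: ", primerc[[j]])
    mm <- mm + !(seqc[j:(n + j - 1L)] %in% set)
  }
  mm
}

#' Locate a primer binding site
#'
#' Scans both the sequence (forward orientation) and its reverse complement
#' (reverse orientation); a position matches when the target base belongs to
#' the primer symbol's IUPAC set. Returns the best site (fewest mismatches)
#' within the allowance, or \code{NULL}. Ties are broken deterministically:
#' the 5'-most forward-strand site wins, else the 5'-most reverse-strand
#' site; tied searches are flagged via the \code{ambiguous} attribute.
#'
#' @param seq Template sequence (character).
#' @param primer Primer 5' to 3' IUPAC string.
#' @param max_mismatch Mismatch allowance (default 1).
#' @return \code{NULL}, or a list with 1-based inclusive \code{start},
#'   \code{end} on the template's forward coordinates, \code{strand}
#'   (\code{"+"}/\code{"-"}), and \code{mismatches}.
#' @export
find_primer_site <- function(seq, primer, max_mismatch = 1) {
  stopifnot(max_mismatch >= 0)
  seqc <- chars(toupper(seq))
  m <- nchar(primer)
  fwd <- scan_mismatches(seqc, chars(toupper(primer)))
  rev <- scan_mismatches(seqc, chars(revcomp(toupper(primer))))
  strand_hits <- function(mm_vec, strand) {
    hit <- which(mm_vec <= max_mismatch)
    if (length(hit) == 0) return(NULL)
    data.frame(start = hit, mm = mm_vec[hit], strand = strand,
               stringsAsFactors = FALSE)
  }
  cand <- rbind(strand_hits(fwd, "+"), strand_hits(rev, "-"))
  if (is.null(cand) || nrow(cand) == 0) return(NULL)
  best <- cand[cand$mm == min(cand$mm), , drop = FALSE]
  pick <- if (any(best$strand == "+")) {
    b <- best[best$strand == "+", , drop = FALSE]
    b[which.min(b$start), ]
  } else {
    best[which.min(best$start), ]
  }
  structure(list(start = pick$start, end = pick$start + m - 1L,
                 strand = pick$strand, mismatches = pick$mm),
            ambiguous = nrow(best) > 1)
}

#' Clip a fixed-length fragment at a primer site
#'
#' Fragments include the primer-binding span at their 5' end and are read in
#' sequencing direction: forward-strand sites give template positions
#' \code{start..start+L-1}; reverse-strand sites give the reverse complement
#' of \code{end-L+1..end}.
#'
#' @param seq Template sequence.
#' @param site A [find_primer_site()] result.
#' @param L Fragment length in bp.
#' @return \code{NULL} when fewer than \code{L} template bases remain,
#'   otherwise a list with \code{seq} (length exactly \code{L}),
#'   \code{start}, \code{end} (template coordinates), \code{strand}.
#' @export
clip_fragment <- function(seq, site, L) {
  stopifnot(L >= 1)
  n <- nchar(seq)
  if (site$strand == "+") {
    to <- site$start + L - 1L
    if (to > n) return(NULL)
    list(seq = substr(seq, site$start, to),
         start = site$start, end = to, strand = "+")
  } else {
    from <- site$end - L + 1L
    if (from < 1L) return(NULL)
    list(seq = revcomp(substr(seq, from, site$end)),
         start = from, end = site$end, strand = "-")
  }
}

#' Inject independent per-base substitution errors
#'
#' Each position is substituted independently with probability \code{r}; a
#' substituted base is drawn uniformly from the three alternatives, so an
#' "error" never silently restores the original base.
#'
#' @param seq Input sequence (A/C/G/T).
#' @param r Per-base error rate in \[0, 1\].
#' @param seed Optional integer seed; when \code{NULL} the current RNG stream
#'   is consumed.
#' @return List with \code{seq} (mutated) and \code{n_errors}.
#' @export
inject_errors <- function(seq, r, seed = NULL) {
  stopifnot(r >= 0, r <= 1)
  run <- function() {
    v <- chars(seq)
    hit <- which(stats::runif(length(v)) < r)
    for (i in hit) {
      alt <- setdiff(BASES, v[[i]])
      v[[i]] <- alt[[sample.int(length(alt), 1)]]
    }
    list(seq = paste(v, collapse = ""), n_errors = length(hit))
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Orient reads to the reference strand
#'
#' Sequencing reads from reverse primers arrive reverse-complemented
#' relative to the reference strand. Like any strand-aware search or
#' classification tool, the classifiers here normalize orientation first:
#' a read is flipped when its reverse complement shares more k-mers with
#' the reference database than the read itself does.
#'
#' @param reads Read data frame with a \code{seq} column (e.g. from
#'   [build_mock_communities()]), or a character vector.
#' @param db The \code{ref_db} the reads will be classified against.
#' @param k Word size for the orientation vote (default 11).
#' @return The reads with \code{seq} in reference orientation and a logical
#'   \code{flipped} column recording which were reverse-complemented.
#' @export
orient_reads <- function(reads, db, k = 11) {
  if (is.character(reads)) {
    reads <- data.frame(read_id = paste0("q", seq_along(reads)),
                        seq = reads, stringsAsFactors = FALSE)
  }
  words <- unique(unlist(lapply(db$seq, distinct_words, k = k)))
  flipped <- logical(nrow(reads))
  for (i in seq_len(nrow(reads))) {
    fwd <- sum(distinct_words(reads$seq[[i]], k) %in% words)
    rc <- revcomp(reads$seq[[i]])
    rev <- sum(distinct_words(rc, k) %in% words)
    if (rev > fwd) {
      reads$seq[[i]] <- rc
      flipped[[i]] <- TRUE
    }
  }
  reads$flipped <- flipped
  reads
}

#' Assemble equal-size mock communities
#'
#' Restricts the database to parents on which every primer yields a valid
#' clip of length \code{L}, then emits one read per retained parent for every
#' (primer, error rate) combination. Communities for different primers (and
#' rates) therefore share identical parent-id sets and sizes. Error injection
#' uses an independent seeded stream per (primer, rate) community.
#'
#' @param db A \code{ref_db}.
#' @param primers Primer data frame (\code{name}, \code{seq}); defaults to
#'   the four benchmark primers.
#' @param L Read length (default 200).
#' @param rates Per-base error rates; must include 0.
#' @param max_mismatch Primer-site mismatch allowance.
#' @param seed Root seed for the error streams.
#' @return Data frame of reads: \code{read_id}, \code{parent_id},
#'   \code{primer}, \code{rate}, \code{seq}, \code{n_errors}, \code{strand},
#'   \code{start}, \code{end}.
#' @export
build_mock_communities <- function(db, primers = default_sim_primers(),
                                   L = 200,
                                   rates = c(0, 1e-4, 1e-3, 1e-2, 0.1),
                                   max_mismatch = 1, seed = 1) {
  stopifnot(nrow(primers) >= 1, 0 %in% rates)
  clips <- list()
  ok <- rep(TRUE, length(db$id))
  for (i in seq_along(db$id)) {
    for (p in seq_len(nrow(primers))) {
      site <- find_primer_site(db$seq[[i]], primers$seq[[p]], max_mismatch)
      clip <- if (is.null(site)) NULL else clip_fragment(db$seq[[i]], site, L)
      if (is.null(clip)) { ok[[i]] <- FALSE; break }
      clips[[paste(db$id[[i]], primers$name[[p]], sep = "\r")]] <- clip
    }
  }
  parents <- db$id[ok]
  if (length(parents) == 0) stop("no parent passes all primers at L = ", L)
  out <- list()
  for (p in primers$name) {
    base <- clips[paste(parents, p, sep = "\r")]
    for (r in rates) {
      reads <- with_seed(derive_seed(seed, paste("errors", p, r)), {
        lapply(base, function(cl) {
          if (r == 0) list(seq = cl$seq, n_errors = 0L)
          else inject_errors(cl$seq, r)
        })
      })
      out[[paste(p, r)]] <- data.frame(
        read_id = paste(parents, p, r, sep = "|"),
        parent_id = parents, primer = p, rate = r,
        seq = vapply(reads, `[[`, character(1), "seq"),
        n_errors = vapply(reads, function(x) as.integer(x$n_errors),
                          integer(1)),
        strand = vapply(base, `[[`, character(1), "strand"),
        start = vapply(base, function(x) as.integer(x$start), integer(1)),
        end = vapply(base, function(x) as.integer(x$end), integer(1)),
        stringsAsFactors = FALSE, row.names = NULL)
    }
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
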