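# shared fixtures and independent oracles

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

# a small hand-written database: 2 phyla, 3 genera, 6 species
toy_lineages <- c(
  "k__Fungi;p__Asco;c__Sordario;o__Hypo;f__Nectria;g__Fusarium;s__Fusarium alpha",
  "k__Fungi;p__Asco;c__Sordario;o__Hypo;f__Nectria;g__Fusarium;s__Fusarium beta",
  "k__Fungi;p__Asco;c__Sordario;o__Hypo;f__Nectria;g__Neonectria;s__Neonectria gamma",
  "k__Fungi;p__Asco;c__Sordario;o__Hypo;f__Nectria;g__Neonectria;s__Neonectria delta",
  "k__Fungi;p__Basidio;c__Agarico;o__Agaricales;f__Amanitaceae;g__Amanita;s__Amanita epsilon",
  "k__Fungi;p__Basidio;c__Agarico;o__Agaricales;f__Amanitaceae;g__Amanita;s__Amanita zeta")

toy_db <- function(seqs = NULL, n = 6, len = 60, seed = 11) {
  if (is.null(seqs)) {
    seqs <- with_test_seed(seed, vapply(seq_len(n), function(i) rand_seq(len),
                                        character(1)))
  }
  ref_db(paste0("rec", seq_along(seqs)), seqs,
         toy_lineages[seq_along(seqs)])
}

with_test_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

# independent naive Bayes oracle: per-genus log score for a query computed
# by direct enumeration over the training sequences
nbc_oracle_scores <- function(db, query, k = 8) {
  kmers <- function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    w <- substring(s, 1:(n - k + 1), k:n)
    unique(w[!grepl("[^ACGT]", w)])
  }
  rec_words <- lapply(db$seq, kmers)
  N <- length(db$seq)
  genera <- unique(db$lineage[, "genus"])
  q <- kmers(query)
  vapply(genera, function(g) {
    members <- which(db$lineage[, "genus"] == g)
    M <- length(members)
    sum(vapply(q, function(w) {
      n_w <- sum(vapply(rec_words, function(ws) w %in% ws, logical(1)))
      P_i <- (n_w + 0.5) / (N + 1)
      m_w <- sum(vapply(rec_words[members], function(ws) w %in% ws,
                        logical(1)))
      log((m_w + P_i) / (M + 1))
    }, numeric(1)))
  }, numeric(1))
}

# independent sliding-window primer scan: every position, both strands,
# IUPAC set membership
primer_scan_oracle <- function(seq, primer, max_mismatch) {
  sets <- list(A = "A", C = "C", G = "G", T = "T",
               R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
               W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
               B = c("C", "G", "T"), D = c("A", "G", "T"),
               H = c("A", "C", "T"), V = c("A", "C", "G"),
               N = c("A", "C", "G", "T"))
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  sv <- strsplit(seq, "")[[1]]
  hits <- list()
  for (strand in c("+", "-")) {
    pv <- strsplit(primer, "")[[1]]
    if (strand == "-") pv <- rev(vapply(pv, function(ch) {
      names(sets)[vapply(names(sets), function(s2) {
        setequal(comp[sets[[s2]]], sets[[ch]])
      }, logical(1))][1]
    }, character(1)))
    m <- length(pv)
    for (i in seq_len(nchar(seq) - m + 1)) {
      mm <- sum(vapply(seq_len(m), function(j) {
        !(sv[i + j - 1] %in% sets[[pv[j]]])
      }, logical(1)))
      if (mm <= max_mismatch) {
        hits[[length(hits) + 1]] <- list(start = i, end = i + m - 1,
                                         strand = strand, mm = mm)
      }
    }
  }
  hits
}

# Biostrings full-DP local alignment score (independent oracle)
biostrings_local_score <- function(x, y, match = 2, mismatch = -3,
                                   gap_open = 5, gap_ext = 2) {
  Biostrings::pairwiseAlignment(
    x, y, type = "local",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match, mismatch, baseOnly = TRUE),
    gapOpening = gap_open, gapExtension = gap_ext, scoreOnly = TRUE)
}

scaffold_path <- function() {
  system.file("extdata", "scerevisiae_25s_synthetic_scaffold.fasta",
              package = "lsubench")
}

read_scaffold <- function() {
  as.character(Biostrings::readDNAStringSet(scaffold_path()))[[1]]
}
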