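#' Train a naive Bayesian k-mer classifier
#'
#' RDP-style composition classifier. Training counts, over the N reference
#' sequences, how many contain each k-mer word (duplicate words within one
#' sequence count once), and per genus how many of its M member sequences
#' contain the word. The corpus prior for word \eqn{w_i} is
#' \eqn{P_i = (n(w_i) + 0.5) / (N + 1)} and the genus conditional is
#' \eqn{(m(w_i) + P_i) / (M + 1)}; a query's score for a genus is the sum of
#' log conditionals over the query's distinct words. Words containing
#' non-ACGT symbols are skipped. Placement is always to a genus; higher ranks
#' derive from the winning genus' lineage.
#'
#' @param db A \code{ref_db}; every record must have a genus name.
#' @param k Word size in bp (default 8).
#' @return An object of class \code{nbc}, usable with [predict.nbc()].
#' @export
nbc <- function(db, k = 8) {
  if (length(db$id) == 0) stop("cannot train on an empty database")
  if (anyNA(db$lineage[, "genus"])) {
    stop("all training records must have a genus name")
  }
  rec_words_chr <- lapply(db$seq, function(s) distinct_words(s, k))
  words <- sort(unique(unlist(rec_words_chr)))
  rec_words <- lapply(rec_words_chr, match, words)
  n_w <- tabulate(unlist(rec_words), nbins = length(words))
  N <- length(db$id)
  prior <- (n_w + 0.5) / (N + 1)
  genus_key <- apply(db$lineage[, 1:6, drop = FALSE], 1, paste,
                     collapse = ";")
  genus_f <- factor(genus_key, levels = unique(genus_key))
  genus_lineage <- db$lineage[!duplicated(genus_key), , drop = FALSE]
  # the genus is the unit of placement: assignments never claim species
  genus_lineage[, "species"] <- NA_character_
  m <- Matrix::sparseMatrix(
    i = unlist(rec_words),
    j = rep(as.integer(genus_f), lengths(rec_words)),
    x = 1, dims = c(length(words), nlevels(genus_f)))
  structure(list(k = k, words = words, n_w = n_w, prior = prior, m = m,
                 M = as.integer(table(genus_f)), N = N,
                 genus = db$lineage[!duplicated(genus_key), "genus"],
                 genus_lineage = genus_lineage,
                 record_id = db$id, record_words = rec_words,
                 record_genus = as.integer(genus_f)),
            class = "nbc")
}

distinct_words <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  w <- substring(seq, 1:(n - k + 1), k:n)
  unique(w[grepl("^[ACGT]+$", w)])
}

#' @export
print.nbc <- function(x, ...) {
  cat("<nbc> naive Bayesian classifier: k = ", x$k, ", ",
      x$N, " training sequences, ", length(x$genus), " genera, ",
      length(x$words), " distinct words\n", sep = "")
  invisible(x)
}

#' Classify sequences with a naive Bayesian classifier
#'
#' The full-word-set winning genus names the lineage; B bootstrap replicates
#' each draw \code{ceiling(W/8)} of the query's W distinct words with
#' replacement and re-pick a winner, and the confidence at a rank is the
#' fraction of replicates whose winner agrees with the named lineage there.
#' Ties for the winning genus are broken uniformly at random from the seeded
#' stream.
#'
#' With \code{leave_one_out = TRUE} each query is scored against the model
#' with its own parent record's contribution removed (training counts are
#' downdated exactly), emulating classification against an incomplete
#' reference set.
#'
#' @param object An [nbc()] model.
#' @param reads Data frame with columns \code{read_id}, \code{seq} and (for
#'   leave-one-out) \code{parent_id}; or a character vector of sequences.
#' @param B Bootstrap replicates (default 100).
#' @param threshold \code{"none"}, or \code{"auto"} to apply the recommended
#'   length-dependent confidence cutoffs after classification (see
#'   [apply_confidence_threshold()]).
#' @param leave_one_out Downdate the model per query's parent record.
#' @param seed Integer seed for bootstrap and tie-breaking.
#' @param ... Unused.
#' @return An \code{assignment_set} with per-rank confidences.
#' @export
predict.nbc <- function(object, reads, B = 100,
                        threshold = c("none", "auto"),
                        leave_one_out = FALSE, seed = 1, ...) {
  threshold <- match.arg(threshold)
  if (is.character(reads)) {
    reads <- data.frame(read_id = paste0("q", seq_along(reads)),
                        seq = reads, stringsAsFactors = FALSE)
  }
  if (leave_one_out && is.null(reads$parent_id)) {
    stop("leave_one_out classification needs reads$parent_id")
  }
  n <- nrow(reads)
  lin <- blank_assignments(n)
  conf <- matrix(NA_real_, n, 7, dimnames = list(NULL, tax_ranks()))
  with_seed(seed, {
    for (i in seq_len(n)) {
      res <- nbc_classify_one(object, reads$seq[[i]], B,
                              exclude = if (leave_one_out)
                                reads$parent_id[[i]] else NULL)
      if (is.null(res)) next
      lin[i, ] <- res$lineage
      conf[i, ] <- res$confidence
    }
  })
  out <- assignment_set(reads$read_id, lin, conf,
                        query_len = nchar(reads$seq), method = "nbc")
  if (threshold == "auto") apply_confidence_threshold(out) else out
}

# classify one query; returns NULL when no valid word exists
nbc_classify_one <- function(model, seq, B, exclude = NULL) {
  qwords <- distinct_words(toupper(seq), model$k)
  W <- length(qwords)
  if (W == 0) return(NULL)
  idx <- match(qwords, model$words)
  seen <- !is.na(idx)
  n_w <- ifelse(seen, model$n_w[idx], 0)
  mm <- matrix(0, W, length(model$genus))
  if (any(seen)) mm[seen, ] <- as.matrix(model$m[idx[seen], , drop = FALSE])
  M <- model$M
  N <- model$N
  keep_genus <- rep(TRUE, length(M))
  if (!is.null(exclude)) {
    r <- match(exclude, model$record_id)
    if (!is.na(r)) {
      has <- idx[seen] %in% model$record_words[[r]]
      n_w[seen] <- n_w[seen] - has
      g <- model$record_genus[[r]]
      mm[seen, g] <- mm[seen, g] - has
      M[g] <- M[g] - 1L
      N <- N - 1L
      if (M[g] == 0L) keep_genus[g] <- FALSE
    }
  }
  prior <- (n_w + 0.5) / (N + 1)
  logc <- log(mm + prior) -
    matrix(log(M + 1), W, length(M), byrow = TRUE)
  logc <- logc[, keep_genus, drop = FALSE]
  genus_rows <- which(keep_genus)
  if (length(genus_rows) == 0) return(NULL)
  full <- colSums(logc)
  winner <- pick_max(full)
  named <- model$genus_lineage[genus_rows[winner], , drop = FALSE]
  nb <- ceiling(W / 8)
  S <- Matrix::sparseMatrix(i = rep(seq_len(B), each = nb),
                            j = sample.int(W, nb * B, replace = TRUE),
                            x = 1, dims = c(B, W))
  bscores <- as.matrix(S %*% logc)
  bwin <- max.col(bscores, ties.method = "random")
  conf <- rep(NA_real_, 7)
  names(conf) <- tax_ranks()
  for (d in which(!is.na(named[1, ]))) {
    conf[d] <- mean(model$genus_lineage[genus_rows[bwin], d] == named[1, d],
                    na.rm = FALSE)
  }
  list(lineage = named[1, ], confidence = conf)
}

pick_max <- function(x) {
  best <- which(x == max(x))
  if (length(best) == 1) best else best[[sample.int(length(best), 1)]]
}

#' Apply length-dependent confidence thresholds
#'
#' The recommended cutoffs: 50% confidence for queries shorter than 250 bp,
#' 80% for longer queries. Ranks whose confidence falls below the cutoff are
#' cleared, and the result ends at the deepest surviving rank.
#'
#' @param x An \code{assignment_set} with confidences and query lengths.
#' @return The thresholded \code{assignment_set}.
#' @export
apply_confidence_threshold <- function(x) {
  stopifnot(inherits(x, "assignment_set"))
  for (i in seq_along(x$query_id)) {
    t <- if (!is.na(x$query_len[[i]]) && x$query_len[[i]] < 250) 0.5 else 0.8
    named <- which(!is.na(x$lineage[i, ]))
    surviving <- named[!is.na(x$confidence[i, named]) &
                         x$confidence[i, named] >= t]
    deepest <- if (length(surviving)) max(surviving) else 0L
    if (deepest < 7L) {
      x$lineage[i, (deepest + 1L):7L] <- NA_character_
      x$confidence[i, (deepest + 1L):7L] <- NA_real_
    }
  }
  x
}
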