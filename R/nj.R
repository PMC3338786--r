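#' Default homolog diversity quotas
#'
#' Homolog compilation targets at least one phylum, two classes, three
#' orders, five families, and ten genera, taking at most one record per
#' species.
#'
#' @return Named integer vector of per-rank quotas.
#' @export
homolog_quotas <- function() {
  c(phylum = 1L, class = 2L, order = 3L, family = 5L, genus = 10L)
}

#' Select homologs for phylogenetic placement
#'
#' Candidates are reference records whose local-alignment identity with the
#' query is at least \code{min_identity}. Records are added greedily in
#' descending identity order (ties by id), skipping species already
#' represented, until every diversity quota is met or the candidates are
#' exhausted.
#'
#' @param hits Hit data frame ([search_db()] shape with \code{identity}).
#' @param db The \code{ref_db} the hits refer to.
#' @param min_identity Identity threshold as a fraction (default 0.90).
#' @param quotas Named vector of rank quotas ([homolog_quotas()]).
#' @return Character vector of selected record ids (possibly empty).
#' @export
select_homologs <- function(hits, db, min_identity = 0.90,
                            quotas = homolog_quotas()) {
  stopifnot(all(names(quotas) %in% tax_ranks()))
  cand <- hits[hits$identity >= 100 * min_identity, , drop = FALSE]
  if (nrow(cand) == 0) return(character(0))
  cand <- cand[order(-cand$identity, cand$subject), , drop = FALSE]
  chosen <- character(0)
  seen_species <- character(0)
  tally <- function(ids) {
    rows <- match(ids, db$id)
    vapply(names(quotas), function(r) {
      length(unique(stats::na.omit(db$lineage[rows, r])))
    }, integer(1))
  }
  for (i in seq_len(nrow(cand))) {
    row <- match(cand$subject[[i]], db$id)
    sp <- db$lineage[row, "species"]
    if (!is.na(sp) && sp %in% seen_species) next
    chosen <- c(chosen, cand$subject[[i]])
    if (!is.na(sp)) seen_species <- c(seen_species, sp)
    if (all(tally(chosen) >= quotas)) break
  }
  chosen
}

#' Neighbor-joining tree from a distance matrix
#'
#' Thin validating wrapper around the standard neighbor-joining
#' reconstruction.
#'
#' @param d Symmetric distance matrix with zero diagonal and at least 3
#'   labelled taxa.
#' @return An unrooted \code{phylo} tree.
#' @export
build_nj_tree <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 3) stop("neighbor joining needs at least 3 taxa")
  if (!isSymmetric(unname(d)) || any(diag(d) != 0)) {
    stop("distance matrix must be symmetric with a zero diagonal")
  }
  if (is.null(rownames(d))) stop("distance matrix must be labelled")
  ape::nj(stats::as.dist(d))
}

# leaves (tip labels) descending from an internal node of a rooted tree
clade_tips <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(tree$tip.label[[node]])
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  unlist(lapply(kids, clade_tips, tree = tree))
}

# query-anchored pseudo-alignment: align each homolog to the query (query
# global, subject local) and record the homolog base over every query
# position; returns a character matrix (homologs + query) x query length.
# When a homolog's local-alignment span is gapless, the column mapping is a
# fixed offset and is applied directly; otherwise the full pairwise
# alignment is computed.
anchor_alignment <- function(query, homolog_seqs, homolog_ids,
                             spans = NULL) {
  qlen <- nchar(query)
  out <- matrix("-", nrow = length(homolog_seqs) + 1L, ncol = qlen,
                dimnames = list(c("query", homolog_ids), NULL))
  out["query", ] <- chars(query)
  todo <- seq_along(homolog_seqs)
  if (!is.null(spans)) {
    for (i in todo) {
      sp <- spans[match(homolog_ids[[i]], spans$subject), ]
      if (nrow(sp) == 0 || is.na(sp$qstart)) next
      gapless <- (sp$qend - sp$qstart == sp$send - sp$sstart) &&
        (sp$align_length == sp$qend - sp$qstart + 1)
      if (!gapless) next
      offset <- sp$sstart - sp$qstart
      pos <- seq_len(qlen)
      sidx <- pos + offset
      ok <- sidx >= 1 & sidx <= nchar(homolog_seqs[[i]])
      sv <- chars(homolog_seqs[[i]])
      out[i + 1L, pos[ok]] <- sv[sidx[ok]]
      todo <- setdiff(todo, i)
    }
  }
  if (length(todo)) {
    aln <- Biostrings::pairwiseAlignment(
      pattern = Biostrings::DNAStringSet(rep(query, length(todo))),
      subject = Biostrings::DNAStringSet(homolog_seqs[todo]),
      type = "global-local",
      substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
        match = 1, mismatch = -1, baseOnly = FALSE),
      gapOpening = 10, gapExtension = 1)
    pat <- as.character(Biostrings::alignedPattern(aln))
    sub <- as.character(Biostrings::alignedSubject(aln))
    for (k in seq_along(todo)) {
      p <- chars(pat[[k]])
      s <- chars(sub[[k]])
      out[todo[[k]] + 1L, ] <- s[p != "-"]
    }
  }
  out
}

# per-pair column profiles of an alignment matrix: which columns are
# comparable (no gap in either row) and which of those mismatch; p-distances
# over any column resample are then two rowSums calls
pair_profiles <- function(msa) {
  n <- nrow(msa)
  ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  gap <- msa == "-"
  comp <- !(gap[ij[, 1], , drop = FALSE] | gap[ij[, 2], , drop = FALSE])
  mis <- comp & (msa[ij[, 1], , drop = FALSE] != msa[ij[, 2], , drop = FALSE])
  list(ij = ij, comp = comp, mis = mis, n = n, labels = rownames(msa))
}

pdist_from_profiles <- function(prof, cols) {
  num <- rowSums(prof$mis[, cols, drop = FALSE])
  den <- rowSums(prof$comp[, cols, drop = FALSE])
  v <- ifelse(den == 0, 0, num / den)
  d <- matrix(0, prof$n, prof$n, dimnames = list(prof$labels, prof$labels))
  d[prof$ij] <- v
  d[prof$ij[, c(2, 1), drop = FALSE]] <- v
  d
}

#' Phylogeny-based rank assignment of one query
#'
#' Distance-based placement: p-distances are computed from pairwise global
#' alignments of the homologs against the query, a neighbor-joining tree is
#' built, rooted at the non-query leaf most distant from the query (ties by
#' id), and the assignment is the lineage LCA of the query's smallest
#' enclosing non-trivial clade. B bootstrap replicates resample alignment
#' columns and repeat the procedure; the support at a rank is the fraction
#' of replicates agreeing with the full-data assignment there. An optional
#' support cutoff (the conventional default is 0.95) clears unsupported
#' ranks.
#'
#' @param query Query sequence.
#' @param homologs A \code{ref_db} of selected homologs (>= 3 records).
#' @param B Bootstrap replicates (default 100).
#' @param support_cutoff Optional support threshold in \[0, 1\];
#'   \code{NULL} disables filtering.
#' @param seed Integer seed.
#' @param spans Optional precomputed local-alignment spans ([search_db()]
#'   hit rows for the homologs) reused to anchor the alignment.
#' @return List with \code{lineage} (1-row matrix), \code{support} (per-rank
#'   numeric), and \code{tree} (the full-data rooted \code{phylo}), or
#'   \code{NULL} with a warning for degenerate inputs.
#' @export
assign_from_tree <- function(query, homologs, B = 100,
                             support_cutoff = NULL, seed = 1,
                             spans = NULL) {
  nh <- length(homologs$id)
  if (nh < 3) {
    warning("fewer than 3 homologs; query unclassifiable")
    return(NULL)
  }
  msa <- anchor_alignment(query, homologs$seq, homologs$id, spans = spans)
  qlen <- ncol(msa)
  prof <- pair_profiles(msa)
  full_d <- pdist_from_profiles(prof, seq_len(qlen))
  if (all(full_d == 0)) {
    warning("all pairwise distances are zero; placement is undefined")
    return(NULL)
  }
  place <- function(d) {
    tree <- tryCatch(build_nj_tree(d), error = function(e) NULL)
    if (is.null(tree)) return(NULL)
    dq <- d["query", homologs$id]
    out_id <- homologs$id[order(-dq, homologs$id)][[1]]
    tree <- ape::root(tree, outgroup = out_id, resolve.root = TRUE)
    qtip <- match("query", tree$tip.label)
    parent <- tree$edge[tree$edge[, 2] == qtip, 1]
    tips <- setdiff(clade_tips(tree, parent), "query")
    if (length(tips) == 0) return(NULL)
    list(lineage = lineage_lca(
      homologs$lineage[match(tips, homologs$id), , drop = FALSE]),
      tree = tree)
  }
  full <- place(full_d)
  if (is.null(full) || all(is.na(full$lineage))) {
    return(list(lineage = blank_assignments(1)[1, ],
                support = rep(NA_real_, 7), tree = NULL))
  }
  support <- rep(NA_real_, 7)
  names(support) <- tax_ranks()
  named <- which(!is.na(full$lineage[1, ]))
  agree <- matrix(0, B, length(named))
  with_seed(seed, {
    for (b in seq_len(B)) {
      cols <- sample.int(qlen, qlen, replace = TRUE)
      rep_res <- place(pdist_from_profiles(prof, cols))
      if (is.null(rep_res)) next
      agree[b, ] <- !is.na(rep_res$lineage[1, named]) &
        rep_res$lineage[1, named] == full$lineage[1, named]
    }
  })
  support[named] <- colMeans(agree)
  lineage <- full$lineage[1, ]
  if (!is.null(support_cutoff)) {
    surviving <- named[support[named] >= support_cutoff]
    deepest <- if (length(surviving)) max(surviving) else 0L
    if (deepest < 7L) {
      lineage[(deepest + 1L):7L] <- NA_character_
      support[(deepest + 1L):7L] <- NA_real_
    }
  }
  list(lineage = lineage, support = support, tree = full$tree)
}

#' Classify reads by neighbor-joining placement
#'
#' The full phylogeny-based pipeline: per read, candidate homologs are drawn
#' from a similarity search (>= 90% identity by default) under diversity
#' quotas, and the read is placed by [assign_from_tree()]. In the
#' leave-one-out scenario the read's parent record is excluded from the
#' candidates.
#'
#' @param reads Read data frame (\code{read_id}, \code{parent_id},
#'   \code{seq}).
#' @param db A \code{ref_db}.
#' @param B Bootstrap replicates per read.
#' @param min_identity Homolog identity threshold (fraction).
#' @param quotas Homolog diversity quotas.
#' @param support_cutoff Optional bootstrap support cutoff (e.g. 0.95).
#' @param scenario \code{"leave_one_out"} or \code{"complete"}.
#' @param seed Root seed (a child stream per read).
#' @param hits Optional precomputed hit lists (named by \code{read_id}) to
#'   reuse searches across classifiers; implies the reads are already
#'   oriented.
#' @param orient Normalize read orientation against the database first
#'   ([orient_reads()]).
#' @return An \code{assignment_set} with bootstrap supports as confidences.
#' @export
classify_nj <- function(reads, db, B = 100, min_identity = 0.90,
                        quotas = homolog_quotas(), support_cutoff = NULL,
                        scenario = "leave_one_out", seed = 1, hits = NULL,
                        orient = TRUE) {
  scenario <- match.arg(scenario, c("leave_one_out", "complete"))
  if (orient && is.null(hits)) reads <- orient_reads(reads, db)
  n <- nrow(reads)
  lin <- blank_assignments(n)
  conf <- matrix(NA_real_, n, 7, dimnames = list(NULL, tax_ranks()))
  for (i in seq_len(n)) {
    h <- if (!is.null(hits)) hits[[reads$read_id[[i]]]] else {
      search_db(reads$seq[[i]], db)
    }
    if (scenario == "leave_one_out") {
      h <- h[h$subject != reads$parent_id[[i]], , drop = FALSE]
    }
    ids <- select_homologs(h, db, min_identity, quotas)
    if (length(ids) < 3) next
    res <- suppressWarnings(assign_from_tree(
      reads$seq[[i]], db_subset(db, match(ids, db$id)), B = B,
      support_cutoff = support_cutoff,
      seed = derive_seed(seed, paste("nj", reads$read_id[[i]])),
      spans = h))
    if (is.null(res)) next
    lin[i, ] <- res$lineage
    conf[i, ] <- res$support
  }
  assignment_set(reads$read_id, lin, conf, query_len = nchar(reads$seq),
                 method = paste0("nj_", scenario))
}

#' Enforce a bootstrap support cutoff on an assignment set
#'
#' Clears ranks whose bootstrap support falls below the cutoff; the result
#' ends at the deepest surviving rank. Applying the cutoff can only remove
#' names, so recovery and coverage never increase.
#'
#' @param x An \code{assignment_set} whose confidences are bootstrap
#'   supports.
#' @param cutoff Support threshold in \[0, 1\] (default 0.95).
#' @return The filtered \code{assignment_set}.
#' @export
apply_support_cutoff <- function(x, cutoff = 0.95) {
  stopifnot(inherits(x, "assignment_set"))
  for (i in seq_along(x$query_id)) {
    named <- which(!is.na(x$lineage[i, ]))
    surviving <- named[!is.na(x$confidence[i, named]) &
                         x$confidence[i, named] >= cutoff]
    deepest <- if (length(surviving)) max(surviving) else 0L
    if (deepest < 7L) {
      x$lineage[i, (deepest + 1L):7L] <- NA_character_
      x$confidence[i, (deepest + 1L):7L] <- NA_real_
    }
  }
  x
}
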