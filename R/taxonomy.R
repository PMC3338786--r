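#' @useDynLib lsubench, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Taxonomic ranks
#'
#' The fixed seven-rank backbone used throughout the package, ordered from the
#' most inclusive (kingdom) to the most specific (species). Intermediate ranks
#' (subphylum, suborder, ...) are not modelled.
#'
#' @return Character vector of the seven ranks in order.
#' @export
#' @examples
#' tax_ranks()
tax_ranks <- function() {
  c("kingdom", "phylum", "class", "order", "family", "genus", "species")
}

rank_prefixes <- c(kingdom = "k", phylum = "p", class = "c", order = "o",
                   family = "f", genus = "g", species = "s")

#' Position of a rank in the backbone
#'
#' @param rank Rank name (one of \code{tax_ranks()}).
#' @return Integer depth, 1 (kingdom) to 7 (species).
#' @export
rank_depth <- function(rank) {
  i <- match(rank, tax_ranks())
  if (anyNA(i)) stop("unknown rank: ", paste(rank[is.na(i)], collapse = ", "))
  i
}

#' Parse a rank-prefixed lineage string
#'
#' Lineages are serialized as semicolon-delimited, rank-prefixed fields
#' (\code{k__Fungi;p__...;...;s__...}). Any suffix of ranks may be absent or
#' empty, meaning the record is unidentified below some level.
#'
#' @param x Character vector of lineage strings.
#' @return A character matrix with one row per input and one column per rank;
#'   absent ranks are \code{NA}.
#' @export
#' @examples
#' parse_lineage("k__Fungi;p__Ascomycota;c__;o__")
parse_lineage <- function(x) {
  ranks <- tax_ranks()
  out <- matrix(NA_character_, nrow = length(x), ncol = 7,
                dimnames = list(NULL, ranks))
  for (i in seq_along(x)) {
    fields <- strsplit(x[[i]], ";", fixed = TRUE)[[1]]
    fields <- trimws(fields)
    fields <- fields[nzchar(fields)]
    for (f in fields) {
      if (!grepl("^[kpcofgs]__", f)) {
        stop("malformed lineage field '", f, "' in '", x[[i]], "'")
      }
      pre <- substr(f, 1, 1)
      rank <- names(rank_prefixes)[match(pre, rank_prefixes)]
      name <- gsub("\\s+", " ", trimws(substr(f, 4, nchar(f))))
      if (nzchar(name)) out[i, rank] <- name
    }
  }
  validate_lineage(out)
  out
}

#' Serialize lineages to rank-prefixed strings
#'
#' @param lineage Character matrix as produced by [parse_lineage()], or a
#'   single named character vector.
#' @return Character vector of lineage strings; absent ranks are emitted as
#'   empty fields so parsing is lossless.
#' @export
format_lineage <- function(lineage) {
  lineage <- as_lineage_matrix(lineage)
  apply(lineage, 1, function(row) {
    paste0(rank_prefixes, "__", ifelse(is.na(row), "", row), collapse = ";")
  })
}

as_lineage_matrix <- function(lineage) {
  if (is.matrix(lineage)) {
    stopifnot(identical(colnames(lineage), tax_ranks()))
    return(lineage)
  }
  m <- matrix(NA_character_, 1, 7, dimnames = list(NULL, tax_ranks()))
  m[1, names(lineage)] <- unname(lineage)
  m
}

validate_lineage <- function(m) {
  present <- !is.na(m)
  # contiguous prefix: no named rank may follow an unnamed one
  bad <- apply(present, 1, function(p) {
    if (!any(p)) return(FALSE)
    last <- max(which(p))
    !all(p[seq_len(last)])
  })
  if (any(bad)) {
    stop("lineage names must form a contiguous prefix from kingdom down; ",
         "offending row(s): ", paste(which(bad), collapse = ", "))
  }
  invisible(m)
}

#' Build a taxonomy tree from lineages
#'
#' Constructs the rooted tree induced by a set of lineages: one node per
#' distinct (name, rank, parent) triple, a synthetic root (id 0) above
#' kingdom.
#'
#' @param lineage Character matrix of lineages ([parse_lineage()] layout).
#' @return An object of class \code{taxonomy}: a data frame with columns
#'   \code{id}, \code{name}, \code{rank}, \code{parent}.
#' @export
build_taxonomy <- function(lineage) {
  lineage <- as_lineage_matrix(lineage)
  validate_lineage(lineage)
  nodes <- data.frame(id = integer(), name = character(), rank = character(),
                      parent = integer(), stringsAsFactors = FALSE)
  key2id <- new.env(parent = emptyenv())
  next_id <- 1L
  for (i in seq_len(nrow(lineage))) {
    parent <- 0L
    for (d in 1:7) {
      nm <- lineage[i, d]
      if (is.na(nm)) break
      key <- paste(parent, d, nm, sep = "\r")
      id <- key2id[[key]]
      if (is.null(id)) {
        id <- next_id
        key2id[[key]] <- id
        nodes[nrow(nodes) + 1L, ] <- list(id, nm, tax_ranks()[d], parent)
        next_id <- next_id + 1L
      }
      parent <- id
    }
  }
  structure(nodes, class = c("taxonomy", "data.frame"))
}

#' @export
print.taxonomy <- function(x, ...) {
  cat("<taxonomy> ", nrow(x), " nodes, ",
      sum(x$rank == "species"), " species\n", sep = "")
  tab <- table(factor(x$rank, levels = tax_ranks()))
  print(tab)
  invisible(x)
}

#' Root-to-node path of a taxonomy node
#'
#' @param taxonomy A [build_taxonomy()] object.
#' @param id Node id.
#' @return Integer vector of node ids from the root's first child down to
#'   \code{id} (the root, id 0, is implicit and excluded).
#' @export
taxon_path <- function(taxonomy, id) {
  path <- integer()
  cur <- id
  while (!is.na(cur) && cur != 0L) {
    path <- c(cur, path)
    row <- match(cur, taxonomy$id)
    if (is.na(row)) stop("node ", cur, " not in taxonomy")
    cur <- taxonomy$parent[row]
  }
  path
}

#' Lowest common ancestor of taxonomy nodes
#'
#' Returns the deepest node lying on every root-to-node path of the input
#' set. With a single node this is the node itself; for nodes sharing only
#' the root the result is the root (id 0).
#'
#' @param taxonomy A [build_taxonomy()] object.
#' @param ids Non-empty integer vector of node ids.
#' @return The id of the LCA node (0 for the root).
#' @export
lowest_common_ancestor <- function(taxonomy, ids) {
  if (length(ids) == 0) stop("lowest_common_ancestor: empty node set")
  ids <- unique(ids)
  paths <- lapply(ids, function(id) taxon_path(taxonomy, id))
  shortest <- min(lengths(paths))
  lca <- 0L
  for (d in seq_len(shortest)) {
    step <- vapply(paths, `[[`, integer(1), d)
    if (all(step == step[[1]])) lca <- step[[1]] else break
  }
  lca
}

#' Lineage of a taxonomy node
#'
#' @param taxonomy A [build_taxonomy()] object.
#' @param id Node id (0 gives an all-\code{NA} lineage).
#' @return A 1-row lineage matrix.
#' @export
node_lineage <- function(taxonomy, id) {
  out <- matrix(NA_character_, 1, 7, dimnames = list(NULL, tax_ranks()))
  if (id == 0L) return(out)
  for (nid in taxon_path(taxonomy, id)) {
    row <- match(nid, taxonomy$id)
    out[1, taxonomy$rank[row]] <- taxonomy$name[row]
  }
  out
}

#' Find the taxonomy node matching a lineage's deepest shared prefix
#'
#' Walks the lineage down the taxonomy and returns the deepest node whose
#' (name, rank, parent) chain exists in the tree; lineages disagreeing with
#' the tree at some rank collapse to the last shared ancestor.
#'
#' @param taxonomy A [build_taxonomy()] object.
#' @param lineage A 1-row lineage matrix or named character vector.
#' @return Node id (0 if even the kingdom is absent from the tree).
#' @export
lineage_node <- function(taxonomy, lineage) {
  lineage <- as_lineage_matrix(lineage)
  parent <- 0L
  for (d in 1:7) {
    nm <- lineage[1, d]
    if (is.na(nm)) break
    row <- which(taxonomy$parent == parent &
                 taxonomy$rank == tax_ranks()[d] &
                 taxonomy$name == nm)
    if (length(row) == 0) break
    parent <- taxonomy$id[row[[1]]]
  }
  parent
}

#' Common-prefix LCA of lineages
#'
#' Name-based lowest common ancestor: the deepest contiguous rank prefix on
#' which all lineages agree. Equivalent to [lowest_common_ancestor()] on the
#' induced taxonomy, but operates directly on lineage matrices.
#'
#' @param lineage Character matrix of lineages (rows are taxa).
#' @return A 1-row lineage matrix of the shared prefix.
#' @export
lineage_lca <- function(lineage) {
  lineage <- as_lineage_matrix(lineage)
  out <- matrix(NA_character_, 1, 7, dimnames = list(NULL, tax_ranks()))
  for (d in 1:7) {
    vals <- lineage[, d]
    if (anyNA(vals) || length(unique(vals)) != 1L) break
    out[1, d] <- vals[[1]]
  }
  out
}

#' Compare a predicted lineage with the truth at one rank
#'
#' @param predicted,truth 1-row lineage matrices or named character vectors.
#' @param rank Rank at which to compare; the truth must name it.
#' @return One of \code{"correct"}, \code{"incorrect"}, \code{"unclassified"}.
#'   \code{correct} iff the predicted name equals the true name at the rank,
#'   \code{unclassified} iff the prediction has no name there.
#' @export
compare_at_rank <- function(predicted, truth, rank) {
  predicted <- as_lineage_matrix(predicted)
  truth <- as_lineage_matrix(truth)
  stopifnot(rank %in% tax_ranks())
  t <- truth[1, rank]
  if (is.na(t)) stop("truth lineage has no name at rank ", rank)
  p <- predicted[1, rank]
  if (is.na(p)) return("unclassified")
  if (identical(p, t)) "correct" else "incorrect"
}
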