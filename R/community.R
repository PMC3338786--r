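#' Summarize assignments as a rank-level community profile
#'
#' Each read assigned at or below the chosen rank counts toward its
#' rank-level ancestor; reads assigned above the rank (or unclassified) are
#' tallied as unplaced so totals reconcile.
#'
#' @param x An \code{assignment_set}.
#' @param rank Summary rank (default \code{"order"}).
#' @param label Dataset label.
#' @return An object of class \code{community_profile}: \code{label},
#'   \code{rank}, named integer \code{counts}, integer \code{unplaced}.
#' @export
profile_assignments <- function(x, rank = "order", label = x$method) {
  stopifnot(inherits(x, "assignment_set"), rank %in% tax_ranks())
  taxa <- x$lineage[, rank]
  counts <- table(taxa[!is.na(taxa)])
  structure(list(label = label, rank = rank,
                 counts = stats::setNames(as.integer(counts), names(counts)),
                 unplaced = sum(is.na(taxa))),
            class = "community_profile")
}

#' @export
print.community_profile <- function(x, ...) {
  cat("<community_profile> ", x$label, " @ ", x$rank, ": ",
      sum(x$counts), " placed in ", length(x$counts), " taxa, ",
      x$unplaced, " unplaced\n", sep = "")
  invisible(x)
}

#' Normalize community profiles to a common size
#'
#' Rescales every profile's placed counts to the minimum placed total across
#' profiles, using largest-remainder rounding so integer totals are
#' preserved exactly and the within-profile rank order of taxa is unchanged.
#'
#' @param profiles List of \code{community_profile}s at the same rank.
#' @return List of rescaled profiles.
#' @export
normalize_profiles <- function(profiles) {
  stopifnot(length(profiles) >= 1)
  totals <- vapply(profiles, function(p) sum(p$counts), numeric(1))
  if (any(totals == 0)) {
    stop("cannot normalize a profile with zero placed reads: ",
         paste(vapply(profiles[totals == 0], `[[`, "", "label"),
               collapse = ", "))
  }
  target <- min(totals)
  lapply(profiles, function(p) {
    raw <- p$counts * target / sum(p$counts)
    base <- floor(raw)
    short <- as.integer(round(target - sum(base)))
    if (short > 0) {
      frac <- raw - base
      give <- order(-frac, -p$counts, names(p$counts))[seq_len(short)]
      base[give] <- base[give] + 1
    }
    p$counts <- stats::setNames(as.integer(base), names(p$counts))
    p
  })
}

#' Bray-Curtis dissimilarity between two profiles
#'
#' \eqn{\sum_t |p_t - q_t| / \sum_t (p_t + q_t)} over the union of taxa.
#'
#' @param p,q \code{community_profile}s at the same rank.
#' @return Distance in \[0, 1\].
#' @export
bray_curtis <- function(p, q) {
  stopifnot(identical(p$rank, q$rank))
  taxa <- union(names(p$counts), names(q$counts))
  if (length(taxa) == 0) stop("both profiles are empty")
  a <- p$counts[taxa]; a[is.na(a)] <- 0
  b <- q$counts[taxa]; b[is.na(b)] <- 0
  sum(abs(a - b)) / sum(a + b)
}

#' Simplified taxonomy-based UniFrac distance
#'
#' Unweighted, presence/absence UniFrac on the taxonomy tree with unit edge
#' lengths: the edge set is the union of root-to-taxon path edges over taxa
#' present in either profile, and the distance is the fraction of those
#' edges that lie only on paths of taxa unique to one profile (i.e. not on
#' any shared taxon's path).
#'
#' @param p,q \code{community_profile}s at the same rank.
#' @param taxonomy A [build_taxonomy()] covering the profiles' taxa.
#' @return Distance in \[0, 1\].
#' @export
simple_unifrac <- function(p, q, taxonomy) {
  stopifnot(identical(p$rank, q$rank))
  present <- function(pr) names(pr$counts)[pr$counts > 0]
  pa <- present(p); qa <- present(q)
  if (length(pa) + length(qa) == 0) stop("both profiles are empty")
  path_edges <- function(taxa) {
    unique(unlist(lapply(taxa, function(nm) {
      row <- which(taxonomy$rank == p$rank & taxonomy$name == nm)
      if (length(row) == 0) stop("taxon not in taxonomy: ", nm)
      taxon_path(taxonomy, taxonomy$id[row[[1]]])
    })))
  }
  all_edges <- path_edges(union(pa, qa))
  shared <- intersect(pa, qa)
  shared_edges <- if (length(shared)) path_edges(shared) else integer(0)
  length(setdiff(all_edges, shared_edges)) / length(all_edges)
}

#' Distance matrix over community profiles
#'
#' @param profiles List of \code{community_profile}s.
#' @param method \code{"bray_curtis"} or \code{"unifrac"}.
#' @param taxonomy Required for \code{"unifrac"}.
#' @return Symmetric labelled distance matrix.
#' @export
community_distances <- function(profiles, method = c("bray_curtis",
                                                     "unifrac"),
                                taxonomy = NULL) {
  method <- match.arg(method)
  n <- length(profiles)
  labels <- vapply(profiles, `[[`, "", "label")
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- if (method == "bray_curtis") {
        bray_curtis(profiles[[i]], profiles[[j]])
      } else {
        simple_unifrac(profiles[[i]], profiles[[j]], taxonomy)
      }
    }
  }
  d
}

#' Non-metric multidimensional scaling
#'
#' Kruskal stress-1 NMDS: iterative improvement with monotone regression,
#' run from a classical-scaling start plus seeded random restarts; the best
#' (lowest-stress) solution is returned with centered coordinates. Zero
#' distances between distinct items are clamped to a tiny positive value so
#' the monotone regression is well defined.
#'
#' @param d Symmetric distance matrix (>= 3 items for a meaningful
#'   ordination; 2 items embed exactly).
#' @param dims Embedding dimensions (default 2).
#' @param restarts Number of ordination starts (default 10: one classical,
#'   nine random).
#' @param seed Integer seed for the random starts.
#' @param maxit Improvement-iteration cap per start.
#' @return List with \code{points} (items x dims, centered) and
#'   \code{stress} (Kruskal stress-1, as a fraction).
#' @export
nmds <- function(d, dims = 2, restarts = 10, seed = 1, maxit = 500) {
  d <- as.matrix(d)
  if (!isSymmetric(unname(d))) stop("distance matrix must be symmetric")
  n <- nrow(d)
  if (n == 2) {
    pts <- matrix(0, 2, dims, dimnames = list(rownames(d), NULL))
    pts[, 1] <- c(-d[1, 2] / 2, d[1, 2] / 2)
    return(list(points = pts, stress = 0))
  }
  eps <- 1e-9 * max(d)
  dd <- d
  dd[dd == 0] <- eps
  diag(dd) <- 0
  dist_obj <- stats::as.dist(dd)
  run_one <- function(init) {
    fit <- tryCatch(
      MASS::isoMDS(dist_obj, y = init, k = dims, maxit = maxit,
                   trace = FALSE, tol = 1e-8),
      error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    list(points = fit$points, stress = fit$stress / 100)
  }
  init <- suppressWarnings(stats::cmdscale(dist_obj, k = dims))
  # cmdscale may return fewer columns or non-finite values for degenerate
  # inputs; pad and sanitize
  if (ncol(init) < dims) init <- cbind(init, matrix(0, n, dims - ncol(init)))
  init[!is.finite(init)] <- 0
  if (all(init == 0)) init <- matrix(seq_len(n * dims) * 1e-6, n, dims)
  starts <- list(init)
  with_seed(seed, {
    for (r in seq_len(max(0, restarts - 1))) {
      starts[[r + 1]] <- matrix(stats::rnorm(n * dims), n, dims)
    }
    fits <- Filter(Negate(is.null), lapply(starts, run_one))
  })
  if (length(fits) == 0) stop("all NMDS starts failed")
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "stress"))]]
  pts <- scale(best$points, center = TRUE, scale = FALSE)
  attr(pts, "scaled:center") <- NULL
  rownames(pts) <- rownames(d)
  list(points = pts, stress = best$stress)
}

#' Pool community profiles
#'
#' Taxon-wise sum of counts across profiles at the same rank; the label
#' records the contributors.
#'
#' @param profiles Non-empty list of \code{community_profile}s.
#' @param label Optional label for the pooled profile.
#' @return A \code{community_profile}.
#' @export
pool_profiles <- function(profiles, label = NULL) {
  if (length(profiles) == 0) stop("nothing to pool")
  rank <- profiles[[1]]$rank
  stopifnot(all(vapply(profiles, `[[`, "", "rank") == rank))
  taxa <- unique(unlist(lapply(profiles, function(p) names(p$counts))))
  counts <- stats::setNames(integer(length(taxa)), taxa)
  for (p in profiles) counts[names(p$counts)] <-
      counts[names(p$counts)] + p$counts
  if (is.null(label)) {
    label <- paste0("pool(", paste(vapply(profiles, `[[`, "", "label"),
                                   collapse = "+"), ")")
  }
  structure(list(label = label, rank = rank, counts = counts,
                 unplaced = sum(vapply(profiles, `[[`, integer(1),
                                       "unplaced"))),
            class = "community_profile")
}
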