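#' Benchmark run configuration
#'
#' Bundles the experiment grid: the synthetic-database configuration, read
#' lengths, per-base error rates (applied at one read length), classifiers,
#' and the root seed from which every stage derives its own stream.
#'
#' @param sim A [sim_config()] describing the reference database.
#' @param lengths Read lengths for the length grid (bp).
#' @param error_rates Per-base error rates for the error grid; must include
#'   0.
#' @param error_length Read length used for the error grid (bp).
#' @param methods Classifiers to run: subset of \code{"lca"}, \code{"nbc"},
#'   \code{"nj"}.
#' @param B Bootstrap replicates for NBC and NJ.
#' @param n_parents Number of parent sequences per mock community (default
#'   33, the equal community size used throughout): parents on which every
#'   primer site is detectable are subsampled once, and the same parent set
#'   feeds every primer, length, and error rate, so communities stay equal
#'   sized and comparable.
#' @param summary_rank Rank for community profiles (default order).
#' @param normalize Normalize profile sizes before community distances.
#' @param seed Root seed; recorded in the run manifest.
#' @return A list of class \code{benchmark_config}.
#' @export
benchmark_config <- function(sim = sim_config(),
                             lengths = c(50, 100, 200, 400),
                             error_rates = c(0, 1e-4, 1e-3, 1e-2, 0.1),
                             error_length = 200,
                             methods = c("lca", "nbc", "nj"),
                             B = 100, n_parents = 33,
                             summary_rank = "order",
                             normalize = TRUE, seed = 1) {
  stopifnot(length(methods) >= 1, all(methods %in% c("lca", "nbc", "nj")),
            length(lengths) >= 1, 0 %in% error_rates, n_parents >= 1)
  structure(list(sim = sim, lengths = lengths, error_rates = error_rates,
                 error_length = error_length, methods = methods, B = B,
                 n_parents = n_parents, summary_rank = summary_rank,
                 normalize = normalize, seed = seed),
            class = "benchmark_config")
}

# subset an assignment set by query index
aset_subset <- function(aset, idx) {
  assignment_set(aset$query_id[idx], aset$lineage[idx, , drop = FALSE],
                 aset$confidence[idx, , drop = FALSE],
                 aset$query_len[idx], aset$method)
}

# evaluate one assignment set per primer and stack the long summary;
# the truth of a read is its parent record's lineage
eval_by_primer <- function(aset, reads, db, method, scenario, L, rate) {
  stopifnot(identical(aset$query_id, reads$read_id))
  truth <- db$lineage[match(reads$parent_id, db$id), , drop = FALSE]
  out <- lapply(unique(reads$primer), function(p) {
    idx <- which(reads$primer == p)
    s <- evaluate_assignments(aset_subset(aset, idx),
                              truth[idx, , drop = FALSE],
                              ids = reads$read_id[idx])
    s$method <- method; s$scenario <- scenario
    s$L <- L; s$rate <- rate; s$primer <- p
    s
  })
  do.call(rbind, out)
}

#' Run the full classification benchmark
#'
#' Executes the pipeline end to end on a synthetic reference database:
#' generate references, simulate primer-anchored reads, classify with the
#' configured methods, and score recovery / erroneous recovery / coverage
#' per rank, per primer, per read length, in complete and leave-one-out
#' search scenarios. Optionally follows with the error grid (recovery
#' degradation under increasing per-base error) and community comparison
#' (order-rank profiles, Bray-Curtis and simplified UniFrac distances,
#' NMDS).
#'
#' All randomness derives from \code{config$seed}; rerunning with the same
#' configuration reproduces every output exactly.
#'
#' @param config A [benchmark_config()].
#' @param stages Which stages to run, in addition to database generation:
#'   any of \code{"length_grid"}, \code{"error_grid"}, \code{"community"}
#'   (community requires the error grid).
#' @param out_dir Optional directory; when given, metric tables are written
#'   as TSV together with a run manifest.
#' @return A list with the database, taxonomy, per-stage assignment sets and
#'   metric tables (see the package vignette for a walk-through).
#' @export
run_benchmark <- function(config = benchmark_config(),
                          stages = c("length_grid", "error_grid",
                                     "community"),
                          out_dir = NULL) {
  stopifnot(inherits(config, "benchmark_config"))
  seed <- config$seed
  taxonomy <- generate_taxonomy(config$sim)
  db <- generate_references(taxonomy, config$sim,
                            seed = derive_seed(seed, "refs"))
  truth <- db$lineage
  rownames(truth) <- NULL
  model <- if ("nbc" %in% config$methods) nbc(db) else NULL
  primers <- config$sim$primers
  # community parents: records on which every primer site is detectable and
  # the longest fragment fits; one seeded subsample shared by every stage
  max_L <- max(config$lengths, config$error_length)
  ok <- vapply(seq_along(db$id), function(i) {
    all(vapply(seq_len(nrow(primers)), function(p) {
      site <- find_primer_site(db$seq[[i]], primers$seq[[p]])
      !is.null(site) && !is.null(clip_fragment(db$seq[[i]], site, max_L))
    }, logical(1)))
  }, logical(1))
  pool <- db$id[ok]
  if (length(pool) == 0) stop("no record carries every primer site")
  parents <- with_seed(derive_seed(seed, "parents"), {
    sort(sample(pool, min(config$n_parents, length(pool))))
  })
  sub_db <- db_subset(db, match(parents, db$id))
  res <- list(config = config, taxonomy = taxonomy, db = db,
              model = model, parents = parents)

  if ("length_grid" %in% stages) {
    grid <- list(); asets <- list()
    for (L in config$lengths) {
      reads <- build_mock_communities(
        sub_db, primers, L = L, rates = 0,
        seed = derive_seed(seed, paste("reads", L)))
      reads <- orient_reads(reads, db)
      hits <- lapply(seq_len(nrow(reads)), function(i) {
        search_db(reads$seq[[i]], db)
      })
      names(hits) <- reads$read_id
      if ("lca" %in% config$methods) {
        params <- lca_params(min_score = default_min_score(L))
        both <- classify_lca(reads, db, params,
                             scenario = c("leave_one_out", "complete"),
                             hits = hits)
        for (s in names(both)) {
          asets[[paste("lca", s, L)]] <- both[[s]]
          grid[[paste("lca", s, L)]] <-
            eval_by_primer(both[[s]], reads, db,
                           method = "lca", scenario = s, L = L, rate = 0)
        }
      }
      if ("nbc" %in% config$methods) {
        for (s in c("leave_one_out", "complete")) {
          a <- predict(model, reads, B = config$B, threshold = "none",
                       leave_one_out = (s == "leave_one_out"),
                       seed = derive_seed(seed, paste("nbc", s, L)))
          asets[[paste("nbc", s, L)]] <- a
          grid[[paste("nbc", s, L)]] <-
            eval_by_primer(a, reads, db, "nbc", s, L, 0)
          cut <- apply_confidence_threshold(a)
          asets[[paste("nbc_cut", s, L)]] <- cut
          grid[[paste("nbc_cut", s, L)]] <-
            eval_by_primer(cut, reads, db, "nbc_cut", s, L, 0)
        }
      }
      if ("nj" %in% config$methods) {
        scenarios <- if (L == config$error_length) {
          c("leave_one_out", "complete")
        } else "leave_one_out"
        for (s in scenarios) {
          a <- classify_nj(reads, db, B = config$B, scenario = s,
                           seed = derive_seed(seed, paste("nj", s, L)),
                           hits = hits)
          asets[[paste("nj", s, L)]] <- a
          grid[[paste("nj", s, L)]] <-
            eval_by_primer(a, reads, db, "nj", s, L, 0)
          cut <- apply_support_cutoff(a, 0.95)
          asets[[paste("nj_cut", s, L)]] <- cut
          grid[[paste("nj_cut", s, L)]] <-
            eval_by_primer(cut, reads, db, "nj_cut", s, L, 0)
        }
      }
      res$length_reads[[as.character(L)]] <- reads
    }
    res$length_grid <- do.call(rbind, grid)
    rownames(res$length_grid) <- NULL
    res$length_assignments <- asets
  }

  if ("error_grid" %in% stages) {
    reads <- build_mock_communities(
      sub_db, primers, L = config$error_length, rates = config$error_rates,
      seed = derive_seed(seed, "error_reads"))
    reads <- orient_reads(reads, db)
    res$error_reads <- reads
    err_sets <- list()
    for (r in unique(reads$rate)) {
      sub <- reads[reads$rate == r, , drop = FALSE]
      if ("lca" %in% config$methods) {
        params <- lca_params(
          min_score = default_min_score(config$error_length))
        err_sets[[paste("lca", r)]] <-
          classify_lca(sub, db, params, scenario = "leave_one_out",
                       orient = FALSE)
      }
      if ("nbc" %in% config$methods) {
        # run "as is": complete training, recommended threshold applied
        err_sets[[paste("nbc", r)]] <-
          predict(model, sub, B = config$B, threshold = "auto",
                  leave_one_out = FALSE,
                  seed = derive_seed(seed, paste("nbc_err", r)))
      }
    }
    res$error_assignments <- err_sets
    tracking <- list()
    for (m in intersect(config$methods, c("lca", "nbc"))) {
      for (p in primers$name) {
        sets <- list(); keys <- list()
        for (r in unique(reads$rate)) {
          sub_idx <- which(reads$rate == r)
          a <- err_sets[[paste(m, r)]]
          pk <- reads$primer[sub_idx][match(a$query_id,
                                            reads$read_id[sub_idx])]
          sel <- which(pk == p)
          sets[[as.character(r)]] <- assignment_set(
            a$query_id[sel], a$lineage[sel, , drop = FALSE],
            a$confidence[sel, , drop = FALSE], a$query_len[sel], a$method)
          keys[[as.character(r)]] <-
            reads$parent_id[sub_idx][match(a$query_id[sel],
                                           reads$read_id[sub_idx])]
        }
        tr <- tryCatch(
          track_error_degradation(sets, keys, db$lineage, ids = db$id,
                                  rank = "genus"),
          error = function(e) NULL)  # no correct baseline for this primer
        if (!is.null(tr)) {
          tr$method <- m; tr$primer <- p
          tracking[[paste(m, p)]] <- tr
        }
      }
    }
    res$error_tracking <- do.call(rbind, tracking)
    rownames(res$error_tracking) <- NULL
  }

  if ("community" %in% stages) {
    stopifnot(!is.null(res$error_assignments))
    reads <- res$error_reads
    profiles <- list()
    for (m in intersect(config$methods, c("lca", "nbc"))) {
      for (r in unique(reads$rate)) {
        a <- res$error_assignments[[paste(m, r)]]
        if (m == "nbc") a <- import_nbc_assignments(a, taxonomy)
        sub_idx <- which(reads$rate == r)
        for (p in primers$name) {
          pk <- reads$primer[sub_idx][match(a$query_id,
                                            reads$read_id[sub_idx])]
          sel <- which(pk == p)
          profiles[[paste(m, p, r)]] <- profile_assignments(
            aset_subset(a, sel), config$summary_rank,
            label = paste(m, p, r, sep = "|"))
        }
      }
    }
    # the reference set: full-length parents against the complete database
    parent_reads <- data.frame(read_id = sub_db$id,
                               parent_id = sub_db$id,
                               seq = sub_db$seq,
                               stringsAsFactors = FALSE)
    parent_aset <- classify_lca(parent_reads, db,
                                lca_params(min_score = 100),
                                scenario = "complete", orient = FALSE)
    res$parent_assignments <- parent_aset
    res$parent_eval <- evaluate_assignments(parent_aset, db$lineage,
                                            ids = db$id)
    for (m in intersect(config$methods, c("lca", "nbc"))) {
      profiles[[paste(m, "reference")]] <- profile_assignments(
        parent_aset, config$summary_rank,
        label = paste(m, "reference", sep = "|"))
      pooled <- pool_profiles(
        profiles[paste(m, primers$name, 0)],
        label = paste(m, "pooled", 0, sep = "|"))
      profiles[[paste(m, "pooled")]] <- pooled
    }
    res$profiles <- profiles
    res$community <- list()
    for (m in intersect(config$methods, c("lca", "nbc"))) {
      keep <- grep(paste0("^", m, " "), names(profiles), value = TRUE)
      prof <- profiles[keep]
      placed <- vapply(prof, function(p) sum(p$counts), numeric(1))
      if (any(placed == 0)) prof <- prof[placed > 0]  # nothing to compare
      if (length(prof) < 3) next
      if (config$normalize) prof <- normalize_profiles(prof)
      for (metric in c("bray_curtis", "unifrac")) {
        d <- community_distances(prof, metric, taxonomy)
        ord <- tryCatch(
          nmds(d, dims = 2, restarts = 10,
               seed = derive_seed(seed, paste("nmds", m, metric))),
          error = function(e) NULL)  # degenerate distances
        res$community[[paste(m, metric)]] <-
          list(distances = d, nmds = ord)
      }
    }
  }

  if (!is.null(out_dir)) write_benchmark(res, out_dir)
  res
}

# write metric tables + a plain-text run manifest
write_benchmark <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(x, name) {
    utils::write.table(x, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (!is.null(res$length_grid)) tsv(res$length_grid, "length_grid.tsv")
  if (!is.null(res$error_tracking)) {
    tsv(res$error_tracking, "error_tracking.tsv")
  }
  if (!is.null(res$community)) {
    for (nm in names(res$community)) {
      d <- res$community[[nm]]$distances
      tsv(data.frame(label = rownames(d), d, check.names = FALSE),
          paste0("distances_", gsub(" ", "_", nm), ".tsv"))
      pts <- res$community[[nm]]$nmds$points
      tsv(data.frame(label = rownames(pts), axis1 = pts[, 1],
                     axis2 = pts[, 2],
                     stress = res$community[[nm]]$nmds$stress),
          paste0("nmds_", gsub(" ", "_", nm), ".tsv"))
    }
  }
  cfg <- res$config
  manifest <- c(
    paste0("seed\t", cfg$seed),
    paste0("lengths\t", paste(cfg$lengths, collapse = ",")),
    paste0("error_rates\t", paste(cfg$error_rates, collapse = ",")),
    paste0("error_length\t", cfg$error_length),
    paste0("methods\t", paste(cfg$methods, collapse = ",")),
    paste0("B\t", cfg$B),
    paste0("n_parents\t", cfg$n_parents),
    paste0("summary_rank\t", cfg$summary_rank),
    paste0("normalize\t", cfg$normalize),
    paste0("species\t", prod(cfg$sim$counts)),
    paste0("package_version\t",
           as.character(utils::packageVersion("lsubench"))))
  writeLines(manifest, file.path(out_dir, "manifest.tsv"))
  invisible(out_dir)
}
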