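small_cfg <- function(...) {
  sim_config(counts = c(phyla = 2, classes = 1, orders = 2, families = 1,
                        genera = 2, species = 2), ...)
}

test_that("balanced taxonomy has the configured shape", {
  cfg1 <- sim_config(counts = c(phyla = 1, classes = 1, orders = 1,
                                families = 1, genera = 1, species = 1))
  tax1 <- generate_taxonomy(cfg1)
  expect_equal(nrow(tax1), 7)  # a single root-to-species path

  cfg <- small_cfg()
  tax <- generate_taxonomy(cfg)
  expect_equal(sum(tax$rank == "species"), prod(cfg$counts))
  expect_equal(sum(tax$rank == "genus"), prod(cfg$counts[1:5]))
  expect_error(sim_config(counts = c(phyla = 0, classes = 1, orders = 1,
                                     families = 1, genera = 1, species = 1)),
               ">= 1")
})

test_that("reference generation is deterministic and seed-sensitive", {
  cfg <- small_cfg()
  tax <- generate_taxonomy(cfg)
  db1 <- generate_references(tax, cfg, seed = 7)
  db2 <- generate_references(tax, cfg, seed = 7)
  db3 <- generate_references(tax, cfg, seed = 8)
  expect_identical(db1$seq, db2$seq)
  expect_false(identical(db1$seq, db3$seq))
  # byte-identical FASTA under the same seed
  p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
  write_refdb(db1, p1); write_refdb(db2, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("zero branch multipliers freeze the root sequence", {
  cfg <- small_cfg(multipliers = c(kingdom = 0, phylum = 0, class = 0,
                                   order = 0, family = 0, genus = 0,
                                   species = 0),
                   record_multiplier = 0)
  tax <- generate_taxonomy(cfg)
  db <- generate_references(tax, cfg, seed = 3)
  expect_equal(length(unique(db$seq)), 1)
})

test_that("primer sites survive evolution in nearly all records", {
  cfg <- sim_config()
  db <- generate_references(generate_taxonomy(cfg), cfg, seed = 5)
  pr <- default_sim_primers()
  for (i in seq_len(nrow(pr))) {
    found <- vapply(db$seq, function(s) {
      !is.null(find_primer_site(s, pr$seq[i], max_mismatch = 1))
    }, logical(1))
    expect_gte(mean(found), 0.95)
  }
})

test_that("sequence divergence tracks taxonomic rank", {
  cfg <- sim_config()
  db <- generate_references(generate_taxonomy(cfg), cfg, seed = 9)
  pdist <- function(a, b) {
    mean(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }
  genus <- db$lineage[, "genus"]; phylum <- db$lineage[, "phylum"]
  within_genus <- c(); between_phyla <- c()
  with_test_seed(2, {
    for (g in unique(genus)) {
      idx <- which(genus == g)
      within_genus <- c(within_genus, pdist(db$seq[idx[1]], db$seq[idx[2]]))
    }
    for (rep in 1:20) {
      i <- sample(which(phylum == "P1"), 1)
      j <- sample(which(phylum == "P2"), 1)
      between_phyla <- c(between_phyla, pdist(db$seq[i], db$seq[j]))
    }
  })
  # identity within a genus exceeds identity between phyla
  expect_lt(mean(within_genus), mean(between_phyla))
})

test_that("neighbor joining on per-species distances recovers the tree", {
  skip_if_not_installed("phangorn")
  cfg <- sim_config(counts = c(phyla = 2, classes = 1, orders = 1,
                               families = 2, genera = 1, species = 2))
  tax <- generate_taxonomy(cfg)
  # generating topology: ((s,s),(s,s)) x 2 phyla
  truth <- ape::read.tree(text = paste0(
    "(((S1.1.1.1.1.1,S1.1.1.1.1.2),(S1.1.1.2.1.1,S1.1.1.2.1.2)),",
    "((S2.1.1.1.1.1,S2.1.1.1.1.2),(S2.1.1.2.1.1,S2.1.1.2.1.2)));"))
  hits <- 0
  for (seed in 1:10) {
    db <- generate_references(tax, cfg, seed = seed)
    n <- length(db$id)
    d <- matrix(0, n, n, dimnames = list(db$lineage[, "species"],
                                         db$lineage[, "species"]))
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- mean(strsplit(db$seq[i], "")[[1]] !=
                                   strsplit(db$seq[j], "")[[1]])
    }
    tree <- build_nj_tree(d)
    if (phangorn::RF.dist(ape::unroot(tree), ape::unroot(truth)) == 0) {
      hits <- hits + 1
    }
  }
  expect_gte(hits / 10, 0.9)
})

test_that("annotation degradation truncates at or above genus", {
  cfg <- small_cfg()
  db <- generate_references(generate_taxonomy(cfg), cfg, seed = 4)
  expect_identical(degrade_annotations(db, 0, seed = 1)$lineage, db$lineage)
  all_cut <- degrade_annotations(db, 1, seed = 1)
  expect_true(all(is.na(all_cut$lineage[, "species"])))
  # expected degraded count ~ Binomial(n, fraction)
  n <- length(db$id); frac <- 0.5
  hits <- vapply(1:50, function(s) {
    d <- degrade_annotations(db, frac, seed = s)
    sum(is.na(d$lineage[, "species"]))
  }, numeric(1))
  se <- sqrt(n * frac * (1 - frac))
  expect_lt(abs(mean(hits) - n * frac), 3 * se / sqrt(50))
})
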