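test_that("homolog selection honours the identity floor and quotas", {
  db <- toy_db(n = 6, len = 80)
  hits <- data.frame(subject = db$id,
                     identity = c(99, 97, 95, 93, 91, 85))
  sel <- select_homologs(hits, db, min_identity = 0.90,
                         quotas = c(genus = 2))
  expect_false("rec6" %in% sel)  # 85% < 90% floor
  # quota of 2 genera met after the first cross-genus candidate
  expect_equal(sel, c("rec1", "rec2", "rec3"))
  # database smaller than the quotas: all eligible records taken
  sel_all <- select_homologs(hits, db, min_identity = 0.90,
                             quotas = homolog_quotas())
  expect_setequal(sel_all, db$id[1:5])
  # one individual per species
  dup <- db
  dup$lineage[2, "species"] <- dup$lineage[1, "species"]
  sel_dup <- select_homologs(hits, dup, min_identity = 0.90,
                             quotas = homolog_quotas())
  expect_false("rec2" %in% sel_dup)
})

test_that("neighbor joining reproduces additive trees exactly", {
  skip_if_not_installed("phangorn")
  with_test_seed(61, {
    for (n in c(4, 6, 8)) {
      truth <- ape::rtree(n)
      truth$edge.length <- truth$edge.length + 0.05
      d <- ape::cophenetic.phylo(truth)
      tree <- build_nj_tree(d)
      expect_equal(phangorn::RF.dist(ape::unroot(tree),
                                     ape::unroot(truth)), 0)
      # path lengths are reproduced for additive input
      d2 <- ape::cophenetic.phylo(tree)[rownames(d), colnames(d)]
      expect_equal(d2, d, tolerance = 1e-8)
    }
  })
})

test_that("three taxa give the closed-form star", {
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tree <- build_nj_tree(d)
  expect_equal(ape::Ntip(tree), 3)
  # branch lengths: la = (dab + dac - dbc)/2 etc.
  bl <- setNames(tree$edge.length[match(1:3, tree$edge[, 2])],
                 tree$tip.label)
  expect_equal(unname(bl[c("a", "b", "c")]), c(1, 2, 3))
  expect_error(build_nj_tree(d[1:2, 1:2]), "at least 3")
  expect_error(build_nj_tree(matrix(1, 3, 3)), "symmetric|diagonal")
})

test_that("ultrametric distances reproduce single-linkage groupings", {
  labs <- letters[1:5]
  d <- matrix(8, 5, 5, dimnames = list(labs, labs))
  d[1:2, 1:2] <- 2; d[3:4, 3:4] <- 2; d[5, 3:4] <- 4; d[3:4, 5] <- 4
  diag(d) <- 0
  tree <- ape::root(build_nj_tree(d), outgroup = "a", resolve.root = TRUE)
  hc <- stats::hclust(stats::as.dist(d), method = "single")
  groups <- stats::cutree(hc, k = 2)
  # the {c,d,e} single-linkage cluster is a clade in the NJ tree
  cde <- names(groups)[groups == groups[["c"]]]
  anc <- ape::getMRCA(tree, cde)
  tips <- ape::extract.clade(tree, anc)$tip.label
  expect_setequal(tips, cde)
})

test_that("placement assigns the clade of clean homolog neighborhoods", {
  # query nearly identical to genus Fusarium, far from the rest
  base <- rand_seq(120)
  mutate_at <- function(s, at) {
    v <- strsplit(s, "")[[1]]
    v[at] <- vapply(v[at], function(b) setdiff(c("A", "C", "G", "T"), b)[1],
                    character(1))
    paste(v, collapse = "")
  }
  with_test_seed(62, {
    far <- vapply(1:4, function(i) mutate_at(base, sample(120, 45)),
                  character(1))
  })
  seqs <- c(mutate_at(base, 3), mutate_at(base, 7), far)
  db <- toy_db(seqs = seqs)
  res <- assign_from_tree(base, db, B = 50, seed = 3)
  expect_equal(unname(res$lineage[["genus"]]), "Fusarium")
  expect_equal(unname(res$support[["genus"]]), 1)
  expect_true(all(diff(res$support[!is.na(res$support)]) <= 0 + 1e-9))
})

test_that("support cutoffs only remove names", {
  lin <- parse_lineage(toy_lineages[c(1, 1)])
  conf <- rbind(c(1, 1, 1, 1, 0.97, 0.93, 0.5),
                c(1, 1, 1, 1, 1, 1, 1))
  colnames(conf) <- tax_ranks()
  a <- assignment_set(c("q1", "q2"), lin, conf)
  out <- apply_support_cutoff(a, 0.95)
  expect_true(is.na(out$lineage[1, "genus"]))
  expect_equal(unname(out$lineage[1, "family"]), "Nectria")
  expect_equal(out$lineage[2, ], a$lineage[2, ])
  # fewer names than before, never more
  expect_lte(sum(!is.na(out$lineage)), sum(!is.na(a$lineage)))
})

test_that("degenerate homolog sets are unclassifiable", {
  db <- toy_db(seqs = rep(strrep("ACGT", 30), 6))
  expect_warning(res <- assign_from_tree(strrep("ACGT", 30), db, B = 5,
                                         seed = 1),
                 "zero")
  expect_null(res)
  expect_warning(res2 <- assign_from_tree("ACGTACGTAC",
                                          toy_db(n = 2, len = 20), B = 5,
                                          seed = 1),
                 "fewer than 3")
  expect_null(res2)
})
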