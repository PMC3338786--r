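test_that("local alignment scores match simple closed forms", {
  x <- rand_seq(100)
  self <- local_align(x, x)
  expect_equal(self$score, 200)  # 100 matches at +2
  expect_equal(self$identity, 100)
  none <- local_align(strrep("A", 30), strrep("C", 30))
  expect_equal(none$score, 0)
})

test_that("local alignment equals the full-DP oracle on random 30-mers", {
  with_test_seed(51, {
    for (rep in 1:25) {
      x <- rand_seq(30)
      y <- rand_seq(30)
      expect_equal(local_align(x, y)$score,
                   as.numeric(biostrings_local_score(x, y)))
    }
    # and with gaps forced by an internal deletion
    for (rep in 1:10) {
      x <- rand_seq(60)
      y <- paste0(substr(x, 1, 25), substr(x, 31, 60))
      expect_equal(local_align(x, y)$score,
                   as.numeric(biostrings_local_score(x, y)))
    }
  })
})

test_that("database search ranks hits and honours exclusion", {
  with_test_seed(52, {
    db <- toy_db(n = 6, len = 80)
  })
  q <- db$seq[3]
  hits <- search_db(q, db)
  expect_equal(hits$subject[1], "rec3")  # self is the top hit
  expect_equal(hits$score[1], 160)
  loo <- search_db(q, db, exclude_id = "rec3")
  expect_false("rec3" %in% loo$subject)
  expect_true(all(diff(loo$score) <= 0))
  none <- search_db(q, db, min_score = 1e6)
  expect_equal(nrow(none), 0)
})

test_that("LCA assignment collapses retained hits by manual tree walk", {
  db <- toy_db(n = 6, len = 80)
  params <- lca_params(min_score = 50, top_percent = 10)
  one <- data.frame(subject = "rec1", score = 100)
  expect_equal(unname(lca_assign(one, params, db)[1, "species"]),
               "Fusarium alpha")
  # two species of one genus within the top window -> genus
  two <- data.frame(subject = c("rec1", "rec2"), score = c(100, 95))
  lin <- lca_assign(two, params, db)
  expect_equal(unname(lin[1, "genus"]), "Fusarium")
  expect_true(is.na(lin[1, "species"]))
  # the second hit outside the 10% window is ignored
  far <- data.frame(subject = c("rec1", "rec2"), score = c(100, 85))
  expect_equal(unname(lca_assign(far, params, db)[1, "species"]),
               "Fusarium alpha")
  # cross-phylum hits collapse to kingdom
  wide <- data.frame(subject = c("rec1", "rec5"), score = c(100, 100))
  lin <- lca_assign(wide, params, db)
  expect_equal(unname(lin[1, "kingdom"]), "Fungi")
  expect_true(all(is.na(lin[1, 2:7])))
  # below the minimum score -> unclassified
  low <- data.frame(subject = "rec1", score = 45)
  expect_true(all(is.na(lca_assign(low, lca_params(min_score = 50), db))))
  # winscore, when reached, overrides the top-percent prefilter
  ws <- lca_params(min_score = 50, top_percent = 100, winscore = 98)
  expect_equal(unname(lca_assign(two, ws, db)[1, "species"]),
               "Fusarium alpha")
})

test_that("the assignment is an ancestor of every retained subject", {
  with_test_seed(53, {
    db <- toy_db(n = 6, len = 80)
    for (rep in 1:10) {
      k <- sample(2:5, 1)
      hits <- data.frame(subject = sample(db$id, k),
                         score = sample(60:100, k))
      lin <- lca_assign(hits, lca_params(min_score = 50,
                                         top_percent = 100), db)
      named <- which(!is.na(lin[1, ]))
      for (s in hits$subject) {
        truth <- db$lineage[match(s, db$id), ]
        expect_equal(lin[1, named], truth[named])
      }
    }
  })
})

test_that("widening top_percent never deepens the assignment", {
  with_test_seed(54, {
    db <- toy_db(n = 6, len = 80)
    hits <- data.frame(subject = db$id, score = c(100, 97, 93, 88, 70, 60))
    depth_prev <- 8
    for (tp in c(1, 5, 10, 30, 100)) {
      lin <- lca_assign(hits, lca_params(min_score = 50, top_percent = tp),
                        db)
      depth <- sum(!is.na(lin[1, ]))
      expect_lte(depth, depth_prev)
      depth_prev <- depth
    }
  })
})

test_that("minimum support moves unsupported reads to ancestors", {
  lin <- parse_lineage(toy_lineages[c(1, 3, 4)])
  a <- assignment_set(c("q1", "q2", "q3"), lin)
  expect_identical(apply_min_support(a, 1)$lineage, a$lineage)
  # Fusarium holds 1 read (below support 2); family Nectria holds all 3
  out <- apply_min_support(a, 2)
  expect_true(is.na(out$lineage[1, "genus"]))
  expect_equal(unname(out$lineage[1, "family"]), "Nectria")
  expect_equal(unname(out$lineage[2, "genus"]), "Neonectria")
  # single-taxon sets are stable for any support <= n
  same <- assignment_set(c("a", "b", "c"),
                         parse_lineage(toy_lineages[c(1, 1, 1)]))
  expect_identical(apply_min_support(same, 3)$lineage, same$lineage)
})

test_that("NBC imports filter by confidence then reconcile with taxonomy", {
  tax <- build_taxonomy(parse_lineage(toy_lineages))
  lin <- parse_lineage(toy_lineages[c(1, 1, 1)])
  lin[, "species"] <- NA
  conf <- rbind(c(1, 1, 1, 1, 0.95, 0.90, NA),
                c(1, 1, 1, 0.8, 0.70, 0.40, NA),
                c(1, 1, 1, 1, 0.95, 0.90, NA))
  colnames(conf) <- tax_ranks()
  # third query claims a family unknown to the reference taxonomy
  lin[3, "family"] <- "Ghostaceae"
  a <- assignment_set(c("hi", "mid", "alien"), lin, conf)
  out <- import_nbc_assignments(a, tax)
  expect_equal(unname(out$lineage[1, "genus"]), "Fusarium")  # 90 >= 50 kept
  expect_true(is.na(out$lineage[2, "genus"]))  # 40 < 50 dropped
  expect_equal(unname(out$lineage[2, "family"]), "Nectria")  # 70 kept
  # disagreement at family collapses to the shared order
  expect_true(is.na(out$lineage[3, "family"]))
  expect_equal(unname(out$lineage[3, "order"]), "Hypo")
})

test_that("tabular hit files parse with bitscore as the score", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(paste(c("q1\trec1\t98.5\t200\t3\t0\t1\t200\t26\t225\t1e-50\t350",
                     "q1\trec2\t92.0\t200\t16\t0\t1\t200\t26\t225\t1e-30\t250"),
                   collapse = "\n"), path)
  h <- read_hit_table(path)
  expect_equal(nrow(h), 2)
  expect_equal(h$score, c(350, 250))
  db <- toy_db(n = 6, len = 80)
  lin <- lca_assign(h, lca_params(min_score = 100, top_percent = 50), db)
  expect_equal(unname(lin[1, "genus"]), "Fusarium")
})
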