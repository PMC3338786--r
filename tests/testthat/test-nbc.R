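test_that("training counts words once per sequence and skips non-ACGT", {
  db <- ref_db("a", "AAAAAAAAA", toy_lineages[1])
  m <- nbc(db)
  expect_equal(m$words, "AAAAAAAA")  # one distinct word from a 9 bp read
  expect_equal(m$n_w, 1L)
  expect_equal(m$N, 1)

  dbn <- ref_db("b", "AAAANAAAA", toy_lineages[1])
  mn <- nbc(dbn)
  expect_equal(length(mn$words), 0)  # every 8-mer crosses the N

  expect_error(nbc(ref_db("c", "ACGTACGTACGT",
                          "k__Fungi;p__Asco;c__S;o__H;f__N")),
               "genus")
})

test_that("priors and genus conditionals match direct enumeration", {
  with_test_seed(41, {
    db <- toy_db(n = 4, len = 20)
  })
  m <- nbc(db)
  # word prior: P_i = (n(w) + 0.5) / (N + 1)
  for (w in sample(m$words, 5)) {
    n_w <- sum(vapply(db$seq, function(s) {
      grepl(w, s, fixed = TRUE)
    }, logical(1)))
    expect_equal(m$prior[match(w, m$words)], (n_w + 0.5) / (4 + 1))
  }
  # full classification score equals the brute-force Bayes oracle
  query <- substr(db$seq[1], 3, 18)
  oracle <- nbc_oracle_scores(db, query)
  res <- predict(m, query, B = 10, seed = 1)
  expect_equal(unname(res$lineage[1, "genus"]),
               names(which.max(oracle)))
})

test_that("winner matches the brute-force oracle across random queries", {
  with_test_seed(42, {
    db <- toy_db(n = 6, len = 40)
    m <- nbc(db)
    for (rep in 1:10) {
      query <- rand_seq(25)
      oracle <- nbc_oracle_scores(db, query)
      best <- names(oracle)[oracle == max(oracle)]
      res <- predict(m, query, B = 5, seed = rep)
      expect_true(unname(res$lineage[1, "genus"]) %in% best)
    }
  })
})

test_that("an exact unique-word query gets full confidence at every rank", {
  seqs <- c(strrep("AC", 15), strrep("GT", 15), strrep("AG", 15),
            strrep("CT", 15), strrep("TA", 15), strrep("GA", 15))
  db <- toy_db(seqs = seqs)
  m <- nbc(db)
  res <- predict(m, seqs[1], B = 50, seed = 1)
  expect_equal(unname(res$lineage[1, "genus"]), "Fusarium")
  named <- !is.na(res$lineage[1, ])
  expect_true(all(res$confidence[1, named] == 1))
  # genus is the placement unit: no species claim
  expect_true(is.na(res$lineage[1, "species"]))
})

test_that("sub-word queries are unclassified", {
  db <- toy_db(n = 2, len = 30)
  m <- nbc(db)
  res <- predict(m, "ACGTA", B = 10, seed = 1)
  expect_true(all(is.na(res$lineage[1, ])))
})

test_that("winner is invariant to query duplication", {
  with_test_seed(43, {
    db <- toy_db(n = 6, len = 40)
    m <- nbc(db)
    q <- rand_seq(30)
  })
  r1 <- predict(m, q, B = 5, seed = 9)
  r2 <- predict(m, paste0(q, q), B = 5, seed = 9)
  expect_equal(r1$lineage[1, "genus"], r2$lineage[1, "genus"])
})

test_that("length-dependent confidence thresholds clear weak ranks", {
  lin <- parse_lineage(toy_lineages[c(1, 1, 1)])
  lin[, "species"] <- NA
  conf <- rbind(c(1, 1, 1, 1, 0.9, 0.62, NA),
                c(1, 1, 1, 1, 0.90, 0.62, NA),
                c(1, 1, 1, 1, 1, 1, NA))
  colnames(conf) <- tax_ranks()
  a <- assignment_set(c("q200", "q400", "qhi"), lin, conf,
                      query_len = c(200, 400, 400))
  out <- apply_confidence_threshold(a)
  # 200 bp query: 50% cutoff keeps the 0.62 genus
  expect_equal(unname(out$lineage[1, "genus"]), "Fusarium")
  # 400 bp query: 80% cutoff clears genus, reports to family
  expect_true(is.na(out$lineage[2, "genus"]))
  expect_equal(unname(out$lineage[2, "family"]), "Nectria")
  # full-confidence assignment unchanged
  expect_equal(out$lineage[3, ], a$lineage[3, ])
})

test_that("leave-one-out downdating equals retraining without the record", {
  with_test_seed(44, {
    db <- toy_db(n = 6, len = 50)
  })
  m_full <- nbc(db)
  q <- substr(db$seq[2], 5, 40)
  loo_pred <- predict(m_full, data.frame(read_id = "q", parent_id = "rec2",
                                         seq = q), B = 25,
                      leave_one_out = TRUE, seed = 2)
  m_drop <- nbc(leave_one_out(db, "rec2"))
  re_pred <- predict(m_drop, q, B = 25, seed = 2)
  expect_equal(loo_pred$lineage[1, ], re_pred$lineage[1, ])
  expect_equal(loo_pred$confidence[1, ], re_pred$confidence[1, ])
})
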