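test_that("primer table carries published coordinates and orientations", {
  p <- lsu_primers()
  expect_equal(nrow(p), 12)
  expect_setequal(p$orientation, c("forward", "reverse"))
  lr0r <- p[p$name == "LR0R", ]
  expect_equal(c(lr0r$ref_start, lr0r$ref_end), c(26, 42))
  lr3 <- p[p$name == "LR3", ]
  expect_equal(lr3$orientation, "reverse")
  expect_gt(lr3$ref_start, lr3$ref_end)  # printed 5'->3' of the primer
})

test_that("primer site finding handles both strands and degeneracies", {
  seq <- paste0("ACCCGCTGAACTTAAGC", rand_seq(40))
  site <- find_primer_site(seq, "ACCCGCTGAACTTAAGC")
  expect_equal(site[c("start", "end", "strand", "mismatches")],
               list(start = 1L, end = 17L, strand = "+", mismatches = 0L))

  # reverse-strand occurrence found as the primer's reverse complement
  with_test_seed(21, {
    primer <- rand_seq(17)
    host <- paste0(rand_seq(30), revcomp(primer), rand_seq(30))
  })
  site <- find_primer_site(host, primer)
  expect_equal(site$strand, "-")
  expect_equal(c(site$start, site$end), c(31, 47))

  # IUPAC degeneracy in the primer matches every concrete base in its set
  deg <- find_primer_site("CAGGTC", "ARRT")
  expect_equal(deg$mismatches, 0L)
  expect_equal(deg$start, 2L)

  # two mismatches exceed an allowance of one
  with_test_seed(22, {
    primer <- rand_seq(17)
    broken <- primer
    substr(broken, 3, 3) <- setdiff(c("A", "C", "G", "T"),
                                    substr(primer, 3, 3))[1]
    substr(broken, 9, 9) <- setdiff(c("A", "C", "G", "T"),
                                    substr(primer, 9, 9))[1]
    host <- paste0(rand_seq(25), broken, rand_seq(25))
  })
  expect_null(find_primer_site(host, primer, max_mismatch = 1))
  expect_equal(find_primer_site(host, primer, max_mismatch = 2)$mismatches,
               2L)
})

test_that("site finder agrees with an exhaustive two-strand scan", {
  with_test_seed(31, {
    for (rep in 1:15) {
      seq <- rand_seq(120)
      primer <- rand_seq(12)
      # plant an occurrence half the time to make hits likely
      if (rep %% 2 == 0) {
        at <- sample(1:(120 - 12), 1)
        planted <- if (rep %% 4 == 0) revcomp(primer) else primer
        substr(seq, at, at + 11) <- planted
      }
      oracle <- primer_scan_oracle(seq, primer, max_mismatch = 1)
      site <- find_primer_site(seq, primer, max_mismatch = 1)
      if (length(oracle) == 0) {
        expect_null(site)
      } else {
        best_mm <- min(vapply(oracle, `[[`, numeric(1), "mm"))
        expect_equal(site$mismatches, best_mm)
        match_found <- any(vapply(oracle, function(h) {
          h$start == site$start && h$strand == site$strand &&
            h$mm == site$mismatches
        }, logical(1)))
        expect_true(match_found)
      }
    }
  })
})

test_that("fragments are clipped in sequencing direction, primer included", {
  seq <- rand_seq(200)
  fwd <- list(start = 26L, end = 42L, strand = "+")
  frag <- clip_fragment(seq, fwd, 50)
  expect_equal(frag$seq, substr(seq, 26, 75))
  expect_equal(c(frag$start, frag$end), c(26, 75))
  expect_null(clip_fragment(seq, fwd, 200))  # runs off the template

  rev <- list(start = 100L, end = 116L, strand = "-")
  frag <- clip_fragment(seq, rev, 60)
  expect_equal(frag$seq, revcomp(substr(seq, 57, 116)))
  expect_equal(nchar(frag$seq), 60)
  expect_null(clip_fragment(seq, list(start = 1L, end = 30L, strand = "-"),
                            40))
})

test_that("error injection is Bernoulli per base with forced substitution", {
  s <- rand_seq(500)
  r0 <- inject_errors(s, 0, seed = 1)
  expect_equal(r0$seq, s)
  expect_equal(r0$n_errors, 0L)

  r1 <- inject_errors(s, 1, seed = 1)
  expect_equal(r1$n_errors, 500L)
  expect_true(all(strsplit(r1$seq, "")[[1]] != strsplit(s, "")[[1]]))

  counts <- vapply(1:100, function(seed) {
    inject_errors(strrep("A", 1000), 0.1, seed = seed)$n_errors
  }, numeric(1))
  se <- sqrt(1000 * 0.1 * 0.9)
  expect_lt(abs(mean(counts) - 100), 3 * se / sqrt(100))
})

test_that("mock communities are equal sized with shared parents", {
  cfg <- sim_config(counts = c(phyla = 2, classes = 1, orders = 1,
                               families = 2, genera = 2, species = 2))
  db <- generate_references(generate_taxonomy(cfg), cfg, seed = 6)
  reads <- build_mock_communities(db, L = 150, rates = c(0, 0.01), seed = 3)
  by_comm <- split(reads$parent_id, paste(reads$primer, reads$rate))
  sizes <- lengths(by_comm)
  expect_true(all(sizes == sizes[[1]]))
  ref_set <- sort(unique(by_comm[[1]]))
  for (s in by_comm) expect_equal(sort(unique(s)), ref_set)

  # rate-0 reads are exact (possibly reverse-complemented) substrings
  r0 <- reads[reads$rate == 0, ]
  for (i in seq_len(nrow(r0))) {
    parent <- db$seq[db$id == r0$parent_id[i]]
    probe <- if (r0$strand[i] == "-") revcomp(r0$seq[i]) else r0$seq[i]
    expect_true(grepl(probe, parent, fixed = TRUE))
  }

  # a parent lacking one primer site is excluded everywhere
  db2 <- db
  bad <- db2$id[1]
  db2$seq[1] <- rand_seq(3396)
  reads2 <- build_mock_communities(db2, L = 150, rates = 0, seed = 3)
  expect_false(bad %in% reads2$parent_id)
})
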