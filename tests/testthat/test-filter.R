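test_that("class-code exclusion drops =, e, p, c and keeps the rest", {
  tx <- make_tx(c("a", "b", "c", "d"), c("u", "=", "i", "c"))
  r <- filter_class_codes(tx)
  expect_equal(r$retained$transcript_id, c("a", "c"))
  expect_setequal(r$report$removed$id, c("b", "d"))
  expect_equal(r$report$n_out, 2)
  # empty exclusion set is the identity
  r0 <- filter_class_codes(tx, excluded = character(0))
  expect_equal(r0$retained$transcript_id, tx$transcript_id)
  # all excluded
  tx2 <- make_tx(c("x", "y"), "=")
  r2 <- filter_class_codes(tx2)
  expect_equal(nrow(r2$retained), 0)
  expect_equal(r2$report$removed$reason, rep("class_code", 2))
})

test_that("structure filter enforces inclusive 2-exon / 200-bp boundaries", {
  tx <- make_tx(c("one_exon", "short", "boundary", "ok"),
                "u",
                n_exons = c(1, 2, 2, 3),
                lengths = c(500, 199, 200, 1000))
  r <- filter_structure(tx)
  expect_setequal(r$retained$transcript_id, c("boundary", "ok"))
  rem <- r$report$removed
  expect_equal(rem$reason[rem$id == "one_exon"], "exon_count")
  expect_equal(rem$reason[rem$id == "short"], "length")
})

test_that("expression filter keeps >=10 reads in >=5 samples, inclusive", {
  m <- rbind(
    boundary = c(10, 10, 10, 10, 10, 0, 0, 0, 0, 0, 0),
    all_nine = rep(9, 11),
    high = rep(50, 11))
  colnames(m) <- paste0("s", 1:11)
  design <- setNames(rep(c("pigmented", "unpigmented"), c(5, 6)),
                     colnames(m))
  cm <- count_matrix(m, design)
  r <- filter_expression(cm)
  expect_setequal(r$retained, c("boundary", "high"))
  expect_equal(r$report$removed$id, "all_nine")
  # min_samples = 0 retains everything
  expect_equal(length(filter_expression(cm, min_samples = 0)$retained), 3)
})

test_that("known-lncRNA matching agrees with the local-alignment oracle", {
  set.seed(23)
  db <- setNames(vapply(1:5, function(i) rand_dna(sample(600:1500, 1)),
                        ""), paste0("K", 1:5))
  dblen <- sum(nchar(db))
  # identical copy: perfect identity and coverage
  r <- match_known(db[["K2"]], db)
  expect_equal(r$identity, 1.0)
  expect_equal(r$coverage, 1.0)
  expect_equal(r$verdict, "known")
  # no shared 11-mer: novel
  r0 <- match_known(strrep("AC", 150), db)
  expect_equal(r0$verdict, "novel")
  expect_error(match_known("", db), "empty query")
  # 1000-bp copies with 50 vs 150 substitutions: verdicts bracket the
  # 90 percent identity gate and match the quadratic-time oracle
  base <- rand_dna(1000)
  db2 <- c(db, REF = base)
  q50 <- mutate_seq(base, 50)
  q150 <- mutate_seq(base, 150)
  r50 <- match_known(q50, db2)
  r150 <- match_known(q150, db2)
  expect_equal(r50$verdict, "known")
  expect_gt(r50$identity, 0.90)
  expect_equal(r150$verdict, "novel")
  o50 <- sw_oracle_verdict(q50, base, sum(nchar(db2)))
  o150 <- sw_oracle_verdict(q150, base, sum(nchar(db2)))
  expect_equal(r50$verdict == "known", o50$pass)
  expect_equal(r150$verdict == "known", o150$pass)
  expect_lt(abs(r50$identity - o50$identity), 0.02)
})

test_that("verdicts agree with the oracle across random pair panels", {
  set.seed(31)
  for (i in 1:30) {
    n <- sample(300:2000, 1)
    subject <- rand_dna(n)
    query <- if (i %% 3 == 0) mutate_seq(subject, round(n * 0.05))
             else if (i %% 3 == 1) mutate_seq(subject, round(n * 0.2))
             else rand_dna(n)
    r <- match_known(query, c(S = subject))
    o <- sw_oracle_verdict(query, subject, nchar(subject))
    expect_equal(r$verdict == "known", o$pass,
                 label = paste("pair", i, "verdict"))
  }
})

test_that("the cascade conserves every transcript and is order-faithful", {
  sim <- get_sim()
  casc <- run_cascade(sim$tx, sim$counts, sim$known_db)
  n_removed <- sum(vapply(casc$reports[c("class_code", "structure",
                                         "expression")],
                          function(r) nrow(r$removed), numeric(1)))
  expect_equal(n_removed + nrow(casc$novel_candidates) +
                 nrow(casc$known_lnc), nrow(sim$tx))
  all_ids <- unname(c(casc$novel_candidates$transcript_id,
                      casc$known_lnc$transcript_id,
                      unlist(lapply(casc$reports[c("class_code", "structure",
                                                   "expression")],
                                    function(r) r$removed$id))))
  expect_equal(sort(all_ids), sort(sim$tx$transcript_id))
  # planted database copies end in the known bin
  copies <- names(sim$truth$known_copy)
  survived <- intersect(copies, c(casc$novel_candidates$transcript_id,
                                  casc$known_lnc$transcript_id))
  expect_true(all(survived %in% casc$known_lnc$transcript_id))
  expect_gt(length(survived), 0)
  # permuting the input order never changes the output sets
  set.seed(77)
  perm <- sample(nrow(sim$tx))
  tx_p <- transcripts(as.data.frame(sim$tx[perm, ]))
  casc_p <- run_cascade(tx_p, sim$counts, sim$known_db)
  expect_setequal(casc_p$novel_candidates$transcript_id,
                  casc$novel_candidates$transcript_id)
  expect_setequal(casc_p$known_lnc$transcript_id,
                  casc$known_lnc$transcript_id)
})

test_that("an empty cascade input yields empty outputs and zero reports", {
  tx <- make_tx(character(0), character(0))
  m <- matrix(integer(0), nrow = 0, ncol = 3,
              dimnames = list(NULL, paste0("s", 1:3)))
  cm <- count_matrix(m, setNames(c("pigmented", "pigmented", "unpigmented"),
                                 paste0("s", 1:3)),
                     lib_sizes = setNames(rep(1e6, 3), paste0("s", 1:3)))
  casc <- run_cascade(tx, cm, c(K = "ACGTACGTACGTACGT"))
  expect_equal(nrow(casc$novel_candidates), 0)
  expect_equal(nrow(casc$known_lnc), 0)
  expect_equal(length(casc$reports), 4)
  expect_true(all(vapply(casc$reports, function(r) r$n_in, numeric(1)) == 0))
})
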