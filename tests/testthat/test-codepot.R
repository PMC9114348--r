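test_that("longest ORF handles canonical and degenerate inputs", {
  o <- longest_orf("ATGAAATAG")
  expect_equal(o$length, 9L)
  expect_equal(o$coverage, 1.0)
  expect_equal(o$integrity, 1L)
  expect_equal(longest_orf("CCCCCC")$length, 0L)
  # open ORF: no in-frame stop counts to the last complete codon
  o2 <- longest_orf("ATGAAAAAAA") # 10 nt, 3 complete codons from ATG
  expect_equal(o2$length, 9L)
  expect_equal(o2$integrity, -1L)
})

test_that("longest ORF equals the exhaustive start/stop-pair oracle", {
  set.seed(5)
  for (i in 1:120) {
    s <- rand_dna(300)
    got <- longest_orf(s)
    ora <- orf_oracle(s)
    expect_equal(got$length, ora$length, label = paste("length", i))
    if (ora$length > 0) {
      expect_equal(got$start, ora$start, label = paste("start", i))
      expect_equal(got$integrity, ora$integrity,
                   label = paste("integrity", i))
    }
  }
})

test_that("Fickett score matches a hand-evaluated lookup and is invariant", {
  # A homopolymer: A gets position value 100/101 -> last bin, content 1.0 ->
  # first bin; C, G, T get zero counts -> last bins. Summing the frozen
  # table entries by hand gives 0.3458.
  expect_equal(fickett_score(strrep("A", 300)), 0.3458, tolerance = 1e-9)
  set.seed(9)
  s <- rand_dna(240)
  expect_identical(fickett_score(s), fickett_score(tolower(s)))
  expect_identical(fickett_score(s), fickett_score(chartr("T", "U", s)))
  # score bounds implied by the lookup tables
  lo <- sum(vapply(c("A","C","G","T"), function(b)
    min(lnckit:::fickett_position_prob[[b]]) *
      lnckit:::fickett_position_weight[[b]] +
      min(lnckit:::fickett_content_prob[[b]]) *
      lnckit:::fickett_content_weight[[b]], numeric(1)))
  hi <- sum(vapply(c("A","C","G","T"), function(b)
    max(lnckit:::fickett_position_prob[[b]]) *
      lnckit:::fickett_position_weight[[b]] +
      max(lnckit:::fickett_content_prob[[b]]) *
      lnckit:::fickett_content_weight[[b]], numeric(1)))
  for (i in 1:25) {
    v <- fickett_score(rand_dna(sample(50:500, 1)))
    expect_gte(v, lo)
    expect_lte(v, hi)
  }
})

test_that("hexamer ratio reproduces hand computations", {
  hexes <- paste0(rep(c("ATGATG"), 3))
  # toy tables: in-frame hexamers of ATGATGATGATG are all "ATGATG"
  fc <- c(ATGATG = 0.1)
  fn <- c(ATGATG = 0.01)
  expect_equal(hexamer_ratio("ATGATGATGATG", fc, fn), log(10))
  # identical tables give 0 for any sequence
  set.seed(3)
  s <- rand_dna(120)
  tbl <- build_hexamer_table(c(s, rand_dna(90)))
  expect_equal(hexamer_ratio(s, tbl, tbl), 0)
  # shorter than one hexamer
  expect_equal(hexamer_ratio("ACGTA", fc, fn), 0)
})

test_that("logistic channel training is deterministic and calibrated", {
  set.seed(11)
  # linearly separable toy set
  x <- cbind(f1 = c(rnorm(40, -2), rnorm(40, 2)), f2 = rnorm(80))
  y <- rep(c(0, 1), each = 40)
  ch <- train_channel(x, y)
  expect_equal(mean((predict_channel(ch, x) > 0.5) == (y == 1)), 1.0)
  # duplicating every row leaves the fit unchanged
  ch2 <- train_channel(rbind(x, x), c(y, y))
  expect_equal(ch$coef, ch2$coef, tolerance = 1e-6)
  # permuted labels carry no signal
  yp <- sample(y)
  chp <- train_channel(x[1:40, ], yp[1:40])
  acc <- mean((predict_channel(chp, x[41:80, ]) > 0.5) == (yp[41:80] == 1))
  expect_gt(acc, 0.25)
  expect_lt(acc, 0.75)
  expect_error(train_channel(x, rep(1, 80)), "single class")
})

test_that("cutoff selection maximizes Youden J with smallest-tie rule", {
  sc <- c(0.7, 0.8, 0.9, 0.1, 0.2, 0.3)
  lb <- c(1, 1, 1, 0, 0, 0)
  r <- select_cutoff(sc, lb, folds = 1)
  expect_equal(r$cutoff, 0.3)
  expect_equal(r$folds$j, 1)
  # interleaved scores cannot reach J = 1 and stay within the score range
  set.seed(2)
  sc2 <- runif(60)
  lb2 <- rbinom(60, 1, 0.5)
  r2 <- select_cutoff(sc2, lb2, folds = 5, seed = 4)
  expect_lt(max(r2$folds$j), 1)
  expect_gte(r2$cutoff, min(sc2))
  expect_lte(r2$cutoff, max(sc2))
  # same seed, same folds, same cutoff
  expect_equal(select_cutoff(sc2, lb2, folds = 5, seed = 4)$cutoff,
               r2$cutoff)
  expect_equal(nrow(select_cutoff(rep(c(.1, .9), 50), rep(0:1, 50),
                                  folds = 10, seed = 1)$folds), 10)
})

test_that("consensus gates use strict and inclusive boundaries correctly", {
  expect_equal(consensus_verdict(0.4, 0.30, -1.0, cpat_cutoff = 0.36),
               "noncoding")
  # the first gate is strict <
  expect_equal(consensus_verdict(0.5, 0.30, -1.0, cpat_cutoff = 0.36),
               "coding_potential")
  # the second gate is <=
  expect_equal(consensus_verdict(0.4, 0.36, -1.0, cpat_cutoff = 0.36),
               "noncoding")
  # the k-mer gate is strict <
  expect_equal(consensus_verdict(0.4, 0.30, 0.0, cpat_cutoff = 0.36),
               "coding_potential")
})

test_that("consensus classification separates synthetic classes", {
  gen <- generate_transcriptome(120, 120, seed = 301)
  lab <- gen$truth$coding_labels[gen$tx$transcript_id]
  seqs <- setNames(gen$tx$sequence, gen$tx$transcript_id)
  model <- train_codepot(seqs[lab == "coding"], seqs[lab == "noncoding"],
                         folds = 10, seed = 301)
  gen2 <- generate_transcriptome(80, 80, seed = 302)
  lab2 <- gen2$truth$coding_labels[gen2$tx$transcript_id]
  seqs2 <- setNames(gen2$tx$sequence, gen2$tx$transcript_id)
  cl <- classify_consensus(seqs2, model)
  sens <- mean(cl$verdict[lab2 == "noncoding"] == "noncoding")
  spec <- mean(cl$verdict[lab2 == "coding"] == "coding_potential")
  expect_gte(sens, 0.9)
  expect_gte(spec, 0.9)
  # pure function of (sequence, model)
  cl2 <- classify_consensus(seqs2[1:5], model)
  expect_equal(cl2, cl[1:5, ], ignore_attr = TRUE)
})
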