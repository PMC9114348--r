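test_that("the transcriptome generator is deterministic and calibrated", {
  g1 <- generate_transcriptome(80, 80, seed = 51)
  g2 <- generate_transcriptome(80, 80, seed = 51)
  expect_identical(g1, g2)
  f1 <- tempfile(fileext = ".fa"); f2 <- tempfile(fileext = ".fa")
  write_fasta(setNames(g1$tx$sequence, g1$tx$transcript_id), f1)
  write_fasta(setNames(g2$tx$sequence, g2$tx$transcript_id), f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  # no noncoding transcripts requested -> none labeled
  g0 <- generate_transcriptome(10, 0, seed = 52)
  expect_false(any(g0$truth$coding_labels == "noncoding"))
  expect_error(generate_transcriptome(5, 5, seed = 1,
                                      params = within(sim_params(),
                                                      coding_len_mean <- -5)),
               "positive")
})

test_that("class means follow the study's feature orderings", {
  g <- generate_transcriptome(400, 400, seed = 53)
  lab <- g$truth$coding_labels[g$tx$transcript_id]
  gc <- gc_content(g$tx$sequence)
  expect_gt(mean(gc[lab == "coding"]) - mean(gc[lab == "noncoding"]), 0.02)
  expect_gt(mean(g$tx$n_exons[lab == "coding"]),
            mean(g$tx$n_exons[lab == "noncoding"]))
  expect_gt(mean(g$tx$length[lab == "coding"]),
            mean(g$tx$length[lab == "noncoding"]))
})

test_that("NB counts approach the Poisson limit as dispersion vanishes", {
  params <- sim_params()
  params$lib_size_sd_log <- 0
  feats <- data.frame(feature_id = "F1", class = "coding", length = 1000,
                      stringsAsFactors = FALSE)
  r <- generate_counts(feats, n_de = 0, seed = 55,
                       design = c(pigmented = 5000, unpigmented = 5000),
                       dispersion = 1e-8, params = params,
                       base_fpkm = c(F1 = 25))
  x <- as.numeric(r$counts$counts)
  expect_equal(length(x), 10000)
  expect_lt(abs(var(x) / mean(x) - 1), 0.05)
})

test_that("null features have group mean ratios centered on one", {
  feats <- data.frame(feature_id = paste0("F", 1:400),
                      class = rep(c("coding", "noncoding"), 200),
                      length = 1500, stringsAsFactors = FALSE)
  r <- generate_counts(feats, n_de = 0, seed = 57)
  cm <- r$counts
  gp <- cm$group == "pigmented"
  ratio <- rowMeans(cm$counts[, gp]) / pmax(rowMeans(cm$counts[, !gp]), 0.5)
  expect_lt(abs(median(log2(ratio))), 0.15)
  expect_true(all(r$truth$status == "null"))
  # noncoding features sit lower than coding ones
  expect_gt(median(rowMeans(cm$counts)[feats$class == "coding"]),
            median(rowMeans(cm$counts)[feats$class == "noncoding"]))
  # determinism and the n_de guard
  r2 <- generate_counts(feats, n_de = 0, seed = 57)
  expect_identical(r$counts$counts, r2$counts$counts)
  expect_error(generate_counts(feats, n_de = 1000, seed = 1), "n_de")
})

test_that("cis planting respects windows, decoys, and correlations", {
  sim <- get_sim()
  cp <- sim$truth$cis_pairs
  expect_true(all(cp$distance[cp$planted] <= 3e5))
  expect_true(all(cp$distance[!cp$planted] > 3e5))
  expect_equal(sum(cp$planted), sum(!cp$planted))
  # recorded loci really are that far apart
  loci <- sim$truth$loci
  for (k in seq_len(nrow(cp))) {
    li <- loci[loci$transcript_id == cp$lnc_id[k], ]
    gi <- loci[loci$transcript_id == cp$gene_id[k], ]
    expect_equal(li$chrom, gi$chrom)
    gap <- max(0, gi$start - li$end, li$start - gi$end)
    expect_equal(gap, cp$distance[k])
  }
  # planted pairs correlate strongly in expression
  expr <- fpkm_matrix(sim$counts, setNames(sim$tx$length,
                                           sim$tx$transcript_id))
  rs <- vapply(which(cp$planted), function(k)
    abs(cor(log10(expr[cp$lnc_id[k], ] + 1e-3),
            log10(expr[cp$gene_id[k], ] + 1e-3))), numeric(1))
  expect_gte(mean(rs), 0.6)
  expect_error(plant_cis_pairs(sim, 2, window = 0, seed = 1), "window")
})

test_that("trans planting splices an exact reverse-complement segment", {
  sim <- get_sim()
  tp <- sim$truth$trans_pairs
  seqs <- setNames(sim$tx$sequence, sim$tx$transcript_id)
  for (k in seq_len(nrow(tp))) {
    seg <- substr(seqs[[tp$gene_id[k]]], tp$seg_start_mrna[k],
                  tp$seg_start_mrna[k] + tp$seg_len[k] - 1)
    ins <- substr(seqs[[tp$lnc_id[k]]], tp$seg_start_lnc[k],
                  tp$seg_start_lnc[k] + tp$seg_len[k] - 1)
    expect_identical(ins, revcomp_chr(seg))
  }
  # same seed edits identically; oversized segments are rejected
  s2a <- plant_trans_pairs(sim, 2, seg_len = 25, seed = 61)
  s2b <- plant_trans_pairs(sim, 2, seg_len = 25, seed = 61)
  expect_identical(s2a$tx$sequence, s2b$tx$sequence)
  expect_error(plant_trans_pairs(sim, 1, seg_len = 10^6, seed = 62),
               "seg_len")
})

test_that("qPCR simulation plants exact shifts when noiseless", {
  truth <- list(de_status = data.frame(feature_id = "G", status = "up",
                                       lfc = 2, stringsAsFactors = FALSE))
  q <- generate_qpcr(truth, "G", noise_sd = 0, tech_sd = 0, seed = 63)
  r <- qpcr_analysis(q)
  expect_equal(r$ddct, -2, tolerance = 1e-12)
  expect_equal(r$log2fc, 2, tolerance = 1e-12)
  # duplicates are present
  expect_equal(nrow(q), 2 * 11)
  # empty panel / empty design
  expect_equal(nrow(generate_qpcr(truth, character(0), seed = 1)), 0)
  expect_equal(nrow(generate_qpcr(truth, "G",
                                  n_per_group = c(pigmented = 0,
                                                  unpigmented = 0),
                                  seed = 1)), 0)
})
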