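test_that("cis candidate distances use inclusive windows and span gaps", {
  lnc <- list(chrom = "chr1", start = 500000L, end = 510000L)
  gl <- data.frame(
    gene_id = c("before", "after_far", "overlap", "boundary", "beyond",
                "other_chrom"),
    chrom = c("chr1", "chr1", "chr1", "chr1", "chr1", "chr2"),
    start = c(240000L, 900000L, 505000L, 810000L, 810001L, 500000L),
    end = c(250000L, 950000L, 520000L, 815000L, 815001L, 510000L),
    stringsAsFactors = FALSE)
  cand <- cis_candidates(lnc, gl, window = 3e5)
  expect_setequal(cand$gene_id, c("before", "overlap", "boundary"))
  expect_equal(cand$distance[cand$gene_id == "before"], 250000)
  expect_equal(cand$distance[cand$gene_id == "overlap"], 0)
  expect_equal(cand$distance[cand$gene_id == "boundary"], 300000)
})

test_that("Pearson gate matches closed forms and permutation estimates", {
  expect_equal(pearson_cor(c(1, 2, 3), c(2, 4, 6))$r, 1.0)
  expect_equal(pearson_cor(c(1, 2, 3), c(-1, -2, -3))$r, -1.0)
  expect_true(is.na(pearson_cor(rep(1, 5), rnorm(5))$r))
  set.seed(21)
  x <- rnorm(11); y <- 0.5 * x + rnorm(11)
  got <- pearson_cor(x, y)
  obs <- abs(cor(x, y))
  B <- 1e5
  xs <- scale(x)[, 1]; ys <- scale(y)[, 1]
  perm <- replicate(B, abs(mean(xs * sample(ys)) * 11 / 10))
  p_perm <- mean(perm >= obs - 1e-12)
  expect_lt(abs(got$p - p_perm), 0.01)
})

test_that("ndg matches constructions and the exhaustive-offset oracle", {
  expect_equal(ndg(strrep("A", 30), strrep("A", 30))$ndg, 0)
  # exact 20-nt reverse complement planted in a pure-AT context
  mr <- paste0(strrep("A", 40), "ATTATAATTTAAATATTTAT", strrep("A", 40))
  seg <- substr(mr, 41, 60)
  lnc <- paste0(strrep("T", 30), revcomp_chr(seg), strrep("T", 30))
  r <- ndg(lnc, mr)
  expect_lte(r$dg, -40)
  expect_lte(r$ndg, -40 / min(nchar(lnc), nchar(mr)))
  expect_error(ndg("", "ACGT"), "empty")
  set.seed(25)
  for (i in 1:25) {
    a <- rand_dna(sample(10:50, 1))
    b <- rand_dna(sample(10:50, 1))
    mr_run <- sample(c(1, 4), 1)
    expect_equal(ndg(a, b, min_run = mr_run)$ndg,
                 ndg_oracle(a, b, min_run = mr_run),
                 label = paste("pair", i))
  }
})

test_that("ndg is symmetric and monotone in the complementary segment", {
  set.seed(27)
  for (i in 1:10) {
    a <- rand_dna(sample(20:60, 1))
    b <- rand_dna(sample(20:60, 1))
    expect_equal(ndg(a, b)$dg, ndg(b, a)$dg)
  }
  # extending a planted complement never increases the minimum energy
  host <- rand_dna(80)
  target <- rand_dna(80)
  prev <- 0
  for (len in c(8, 12, 16, 20)) {
    seg <- substr(target, 10, 10 + len - 1)
    probe <- paste0(substr(host, 1, 30), revcomp_chr(seg),
                    substr(host, 31 + len, 80))
    cur <- ndg(probe, target)$dg
    expect_lte(cur, prev)
    prev <- cur
  }
})

test_that("planted pairs hybridize more strongly than background", {
  sim <- get_sim()
  seqs <- setNames(sim$tx$sequence, sim$tx$transcript_id)
  tp <- sim$truth$trans_pairs
  planted <- vapply(seq_len(nrow(tp)), function(k)
    ndg(seqs[[tp$lnc_id[k]]], seqs[[tp$gene_id[k]]], min_run = 15)$dg,
    numeric(1))
  set.seed(29)
  coding <- names(sim$truth$coding_labels)[
    sim$truth$coding_labels == "coding"]
  noncod <- setdiff(names(sim$truth$coding_labels)[
    sim$truth$coding_labels == "noncoding"], tp$lnc_id)
  bg <- vapply(1:20, function(k)
    ndg(seqs[[sample(noncod, 1)]], seqs[[sample(coding, 1)]],
        min_run = 15)$dg, numeric(1))
  expect_lt(median(planted), median(bg))
})

test_that("target linking recovers planted pairs and respects the window", {
  sim <- get_sim()
  tr <- sim$truth
  expr <- fpkm_matrix(sim$counts, setNames(sim$tx$length,
                                           sim$tx$transcript_id))
  loci <- data.frame(gene_id = tr$loci$gene_id,
                     transcript_id = tr$loci$transcript_id,
                     chrom = tr$loci$chrom, start = tr$loci$start,
                     end = tr$loci$end, stringsAsFactors = FALSE)
  cis_pairs <- tr$cis_pairs
  de_lnc <- unique(cis_pairs$lnc_id)
  de_genes <- unique(cis_pairs$gene_id)
  links <- link_targets(de_lnc, de_genes, expr, loci, "cis")
  # hard guarantee: no link beyond the window
  expect_true(all(links$distance <= 3e5))
  planted <- cis_pairs[cis_pairs$planted, ]
  hit <- vapply(seq_len(nrow(planted)), function(k)
    any(links$passed & links$lnc_id == planted$lnc_id[k] &
          links$gene_id == planted$gene_id[k]), logical(1))
  expect_gte(mean(hit), 0.8)
  # decoys sit beyond the window and never link
  decoys <- cis_pairs[!cis_pairs$planted, ]
  dhit <- vapply(seq_len(nrow(decoys)), function(k)
    any(links$lnc_id == decoys$lnc_id[k] &
          links$gene_id == decoys$gene_id[k]), logical(1))
  expect_equal(sum(dhit), 0)
  # every emitted link satisfies its own gate invariants
  ok <- links$passed
  expect_true(all(abs(links$r[ok]) >= 0.60 & links$r_p[ok] <= 0.05))
})

test_that("trans linking passes planted pairs and rejects decoy pairs", {
  sim <- get_sim()
  tr <- sim$truth
  seqs <- setNames(sim$tx$sequence, sim$tx$transcript_id)
  expr <- fpkm_matrix(sim$counts, setNames(sim$tx$length,
                                           sim$tx$transcript_id))
  tp <- tr$trans_pairs
  links <- link_targets(unique(tp$lnc_id), unique(tp$gene_id), expr,
                        mode = "trans", seqs = seqs)
  hit <- vapply(seq_len(nrow(tp)), function(k)
    any(links$passed & links$lnc_id == tp$lnc_id[k] &
          links$gene_id == tp$gene_id[k]), logical(1))
  expect_gte(mean(hit), 0.8)
  expect_true(all(links$ndg[links$passed] <= -0.08))
  # decoys: shuffling the lncRNA sequence destroys the planted helix, so
  # under the discriminative duplex gate (a perfect run of >= 20 pairs,
  # energy at most -0.012 per nt of the shorter sequence) the same pairs
  # stop linking even though their expression stays correlated, while the
  # planted sequences keep linking
  set.seed(33)
  shuf <- vapply(tp$lnc_id, function(l)
    paste(sample(strsplit(seqs[[l]], "")[[1]]), collapse = ""), "")
  names(shuf) <- paste0("shuf_", tp$lnc_id)
  expr2 <- rbind(expr, expr[tp$lnc_id, , drop = FALSE])
  rownames(expr2) <- c(rownames(expr), names(shuf))
  pair_gate <- function(lncs) {
    vapply(seq_along(lncs), function(k) {
      lk <- link_targets(lncs[k], tp$gene_id[k], expr2, mode = "trans",
                         seqs = c(seqs, shuf), min_run = 20,
                         ndg_threshold = -0.012)
      sum(lk$passed)
    }, numeric(1))
  }
  expect_equal(sum(pair_gate(names(shuf))), 0)
  expect_gte(mean(pair_gate(tp$lnc_id) > 0), 0.8)
})
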