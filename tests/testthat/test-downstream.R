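test_that("hypergeometric enrichment reproduces the combinatorial sum", {
  pop <- paste0("g", 1:20)
  set1 <- list(set_id = "S1", name = "s", members = pop[1:5])
  study <- c(pop[1:4], pop[10])
  r <- hypergeom_enrich(study, pop, list(set1))
  # N=20, K=5, n=5, k=4: (C(5,4)C(15,1) + C(5,5)C(15,0)) / C(20,5)
  expect_equal(r$p, 76 / 15504, tolerance = 1e-12)
  expect_equal(r$fold_enrichment, (4 / 5) / (5 / 20))
  # k = 0 gives an upper-tail p of 1
  r0 <- hypergeom_enrich(pop[10:12], pop,
                         list(list(set_id = "S", name = "s",
                                   members = pop[1:5])))
  expect_equal(r0$p, 1.0)
  expect_error(hypergeom_enrich(c("zz"), pop, list(set1)), "subset")
})

test_that("hypergeometric p equals one-sided Fisher for all small tables", {
  for (N in c(8, 12, 15)) {
    pop <- paste0("g", seq_len(N))
    for (K in c(2, 4, N %/% 2)) {
      for (n in c(3, N %/% 2)) {
        for (k in 0:min(n, K)) {
          study <- c(pop[seq_len(k)], pop[K + seq_len(n - k)])
          sets <- list(list(set_id = "S", name = "s",
                            members = pop[seq_len(K)]))
          p_mine <- hypergeom_enrich(study, pop, sets)$p
          tab <- matrix(c(k, K - k, n - k, N - K - (n - k)), 2)
          p_fisher <- fisher.test(tab, alternative = "greater")$p.value
          expect_equal(p_mine, p_fisher, tolerance = 1e-9,
                       label = sprintf("N=%d K=%d n=%d k=%d", N, K, n, k))
        }
      }
    }
  }
})

test_that("gene sets are intersected with the population and BH-adjusted", {
  pop <- paste0("g", 1:50)
  sets <- list(
    list(set_id = "A", name = "a", members = c(pop[1:10], "not_in_pop")),
    list(set_id = "B", name = "b", members = pop[11:30]),
    list(set_id = "EMPTY", name = "e", members = "absent_gene"))
  r <- hypergeom_enrich(pop[1:8], pop, sets)
  expect_setequal(r$set_id, c("A", "B")) # empty intersection skipped
  expect_equal(r$K[r$set_id == "A"], 10) # foreign member dropped
  expect_equal(r$padj, bh_adjust(r$p)[order(r$p)][order(order(r$p))],
               tolerance = 1e-12)
})

test_that("delta-delta-Ct arithmetic and identities are exact", {
  mk <- function(dct_p, dct_u) {
    data.frame(
      sample_id = c(paste0("p", seq_along(dct_p)),
                    paste0("u", seq_along(dct_u))),
      group = rep(c("pigmented", "unpigmented"),
                  c(length(dct_p), length(dct_u))),
      gene_id = "G1",
      ct_target = 20 + c(dct_p, dct_u),
      ct_housekeeping = 20, stringsAsFactors = FALSE)
  }
  r <- qpcr_analysis(mk(c(5, 5, 5), c(7, 7, 7)))
  expect_equal(r$ddct, -2)
  expect_equal(r$log2fc, 2)
  expect_equal(r$log2fc, log2(2^-r$ddct)) # the defining identity
  # identical groups: no effect, p near 1
  r0 <- qpcr_analysis(mk(c(5.1, 5.3, 5.2), c(5.1, 5.3, 5.2)))
  expect_equal(r0$log2fc, 0)
  expect_gt(r0$t_p, 0.95)
  expect_error(qpcr_analysis(mk(5, c(7, 7))), "at least 2")
  expect_error(qpcr_analysis({
    m <- mk(c(5, 5), c(7, 7)); m$ct_target[1] <- -1; m
  }), "finite")
})

test_that("duplicates are averaged before the per-sample delta-Ct", {
  m <- data.frame(
    sample_id = rep(c("p1", "p2", "u1", "u2"), each = 2),
    group = rep(c("pigmented", "pigmented", "unpigmented", "unpigmented"),
                each = 2),
    gene_id = "G1",
    ct_target = c(24, 26, 25, 25, 27, 29, 28, 28), # duplicate means 25, 28
    ct_housekeeping = 20, stringsAsFactors = FALSE)
  r <- qpcr_analysis(m)
  expect_equal(r$ddct, -3)
  expect_equal(r$log2fc, 3)
})

test_that("the qPCR estimator recovers planted effects and is unbiased", {
  truth <- list(de_status = data.frame(feature_id = "GENE", status = "up",
                                       lfc = 2, stringsAsFactors = FALSE))
  errs <- vapply(1:200, function(i) {
    q <- generate_qpcr(truth, "GENE", noise_sd = 0.25, tech_sd = 0.05,
                       seed = 1000 + i)
    qpcr_analysis(q)$log2fc - 2
  }, numeric(1))
  expect_gte(mean(abs(errs) <= 0.5), 0.95)
  expect_lt(abs(mean(errs)), 0.05)
})

test_that("concordance flags sign agreement per validated gene", {
  de <- c(G1 = 2.0, G2 = 2.0, G3 = -1.2)
  qp <- c(G1 = 1.7, G2 = -0.3, G3 = -0.9)
  r <- concordance_report(de, qp)
  expect_equal(r$agree, c(TRUE, FALSE, TRUE))
  expect_equal(r$gene_id, c("G1", "G2", "G3"))
})
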