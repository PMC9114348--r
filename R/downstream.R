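# Downstream statistics: hypergeometric over-representation of target genes
# in user-supplied gene sets, delta-delta-Ct qPCR summaries, and the
# RNA-seq/qPCR concordance report.

#' Hypergeometric gene-set enrichment
#'
#' One-sided upper-tail test of over-representation of the study genes in
#' each set (equivalent to one-sided Fisher's exact on the 2x2 table), BH
#' adjustment across sets. Sets are intersected with the population; empty
#' intersections are skipped.
#'
#' @param study character vector of study gene ids (subset of `population`).
#' @param population character vector: the testing universe (all genes that
#'   entered DE testing).
#' @param gene_sets list of gene sets ([read_gmt()] layout).
#' @param two_sided also compute a two-sided p (off by default; the
#'   enrichment question is one-sided).
#' @return data.frame: `set_id`, `name`, `k`, `n`, `K`, `N`, `p`, `padj`,
#'   `fold_enrichment`.
#' @export
hypergeom_enrich <- function(study, population, gene_sets,
                             two_sided = FALSE) {
  study <- unique(study)
  population <- unique(population)
  if (!all(study %in% population))
    stop("study genes must be a subset of the population")
  N <- length(population)
  n <- length(study)
  rows <- lapply(gene_sets, function(s) {
    members <- intersect(s$members, population)
    K <- length(members)
    if (K == 0) return(NULL)
    k <- length(intersect(study, members))
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    row <- data.frame(set_id = s$set_id, name = s$name, k = k, n = n, K = K,
                      N = N, p = p,
                      fold_enrichment = (k / n) / (K / N),
                      stringsAsFactors = FALSE)
    if (two_sided) {
      tab <- matrix(c(k, K - k, n - k, N - K - (n - k)), 2)
      row$p_two_sided <- stats::fisher.test(tab)$p.value
    }
    row
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) {
    return(data.frame(set_id = character(), name = character(),
                      k = integer(), n = integer(), K = integer(),
                      N = integer(), p = numeric(), padj = numeric(),
                      fold_enrichment = numeric(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out$padj <- bh_adjust(out$p)
  out[order(out$p), , drop = FALSE]
}

#' Delta-delta-Ct qPCR analysis
#'
#' Duplicates are averaged per sample; `delta Ct = Ct_target -
#' Ct_housekeeping`; `ddCt = mean(dCt pigmented) - mean(dCt reference)`;
#' `log2FC = -ddCt`. Group difference tested by Welch's t on the per-sample
#' delta-Ct values; the fold-change range comes from `ddCt +- SE`.
#'
#' @param measures data.frame with `sample_id`, `group`, `gene_id`,
#'   `ct_target`, `ct_housekeeping`.
#' @param reference_group baseline group (default `unpigmented`).
#' @return data.frame per gene: `gene_id`, `ddct`, `log2fc`, `se`,
#'   `log2fc_lo`, `log2fc_hi`, `t_p`, `n_pigmented`, `n_reference`.
#' @export
qpcr_analysis <- function(measures, reference_group = "unpigmented") {
  if (nrow(measures) == 0) {
    return(data.frame(gene_id = character(), ddct = numeric(),
                      log2fc = numeric(), se = numeric(),
                      log2fc_lo = numeric(), log2fc_hi = numeric(),
                      t_p = numeric(), n_pigmented = integer(),
                      n_reference = integer(), stringsAsFactors = FALSE))
  }
  if (any(!is.finite(measures$ct_target)) ||
      any(!is.finite(measures$ct_housekeeping)) ||
      any(measures$ct_target <= 0) || any(measures$ct_housekeeping <= 0))
    stop("Ct values must be finite and > 0")
  rows <- lapply(split(measures, measures$gene_id), function(mg) {
    agg <- stats::aggregate(cbind(ct_target, ct_housekeeping) ~
                              sample_id + group, data = mg, FUN = mean)
    agg$dct <- agg$ct_target - agg$ct_housekeeping
    is_ref <- agg$group == reference_group
    if (sum(is_ref) < 2 || sum(!is_ref) < 2)
      stop("each group needs at least 2 samples for gene ",
           mg$gene_id[1])
    d_t <- agg$dct[!is_ref]
    d_r <- agg$dct[is_ref]
    ddct <- mean(d_t) - mean(d_r)
    se <- sqrt(var(d_t) / length(d_t) + var(d_r) / length(d_r))
    t_p <- if (se == 0) as.numeric(abs(ddct) < 1e-12)
           else t.test(d_t, d_r)$p.value
    data.frame(gene_id = mg$gene_id[1], ddct = ddct, log2fc = -ddct,
               se = se, log2fc_lo = -(ddct + se), log2fc_hi = -(ddct - se),
               t_p = t_p, n_pigmented = length(d_t),
               n_reference = length(d_r), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' RNA-seq vs qPCR concordance report
#'
#' Joins the two log2 fold changes per validated gene and flags sign
#' agreement.
#'
#' @param de_log2fc named numeric vector of RNA-seq log2 fold changes.
#' @param qpcr_log2fc named numeric vector (or [qpcr_analysis()] output).
#' @return data.frame: `gene_id`, `rnaseq_log2fc`, `qpcr_log2fc`, `agree`.
#' @export
concordance_report <- function(de_log2fc, qpcr_log2fc) {
  if (is.data.frame(qpcr_log2fc))
    qpcr_log2fc <- setNames(qpcr_log2fc$log2fc, qpcr_log2fc$gene_id)
  genes <- intersect(names(de_log2fc), names(qpcr_log2fc))
  data.frame(gene_id = genes,
             rnaseq_log2fc = unname(de_log2fc[genes]),
             qpcr_log2fc = unname(qpcr_log2fc[genes]),
             agree = sign(de_log2fc[genes]) == sign(qpcr_log2fc[genes]),
             stringsAsFactors = FALSE, row.names = NULL)
}
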