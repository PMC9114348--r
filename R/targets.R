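# Cis/trans target prediction for DE lncRNAs: cis candidates are
# protein-coding loci within a genomic window (default +-300 kb, inclusive);
# trans candidates pass a hybridization-energy gate (ndG); both are then
# gated on expression correlation (Pearson |r| >= 0.60, p <= 0.05,
# computed on log10(FPKM + 1e-3)).

#' Cis candidate genes around a lncRNA locus
#'
#' Distance is the minimal endpoint gap between the two genomic spans on the
#' same chromosome (overlap = 0); candidates satisfy `distance <= window`
#' (inclusive). Strand is ignored.
#'
#' @param lnc_locus one-row data.frame/list with `chrom`, `start`, `end`.
#' @param gene_loci data.frame of loci with `gene_id`, `chrom`, `start`,
#'   `end`.
#' @param window window size in bp.
#' @return data.frame `gene_id`, `distance`.
#' @export
cis_candidates <- function(lnc_locus, gene_loci, window = 3e5) {
  same <- gene_loci$chrom == lnc_locus$chrom
  g <- gene_loci[same, , drop = FALSE]
  d <- pmax(0, pmax(g$start - lnc_locus$end, lnc_locus$start - g$end))
  keep <- d <= window
  data.frame(gene_id = g$gene_id[keep], distance = d[keep],
             stringsAsFactors = FALSE)
}

#' Pearson correlation with t-based p-value
#'
#' Two-sided p from `t = r sqrt((n-2)/(1-r^2))` on `n - 2` df
#' (`stats::cor.test`). Zero-variance input is flagged undefined.
#'
#' @param x,y numeric vectors (length >= 3).
#' @return list with `r` and `p` (both `NA` when undefined).
#' @export
pearson_cor <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (sd(x) == 0 || sd(y) == 0) return(list(r = NA_real_, p = NA_real_))
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Normalized lncRNA-mRNA hybridization energy (ndG)
#'
#' Ungapped antiparallel scan over every alignment offset; each offset's
#' energy sums Watson-Crick/GU pair energies over maximal runs of at least
#' `min_run` consecutive pairs (shorter runs contribute 0). `ndg` is the
#' minimum offset energy divided by the shorter sequence length; it is
#' always `<= 0` and symmetric in its arguments.
#'
#' @param lnc_seq,mrna_seq sequences (non-empty).
#' @param pair_energy energies `c(GC = -3, AU = -2, GU = -1)`.
#' @param min_run minimum pairing run (1 disables the run filter).
#' @return list with `ndg`, `dg` (unnormalized minimum) and `offset`.
#' @export
ndg <- function(lnc_seq, mrna_seq, pair_energy = c(GC = -3, AU = -2,
                                                   GU = -1), min_run = 4) {
  if (nchar(lnc_seq) == 0 || nchar(mrna_seq) == 0)
    stop("empty sequence")
  r <- hybrid_scan_cpp(encode_bases(lnc_seq), encode_bases(mrna_seq),
                       as.numeric(pair_energy[c("GC", "AU", "GU")]),
                       as.integer(min_run))
  list(ndg = r$dg / min(nchar(lnc_seq), nchar(mrna_seq)), dg = r$dg,
       offset = r$offset)
}

#' Link DE lncRNAs to DE target genes
#'
#' `cis` mode: [cis_candidates()] within `window`, then the correlation
#' gate. `trans` mode: `ndg <= ndg_threshold`, then the correlation gate.
#' Links are sorted by `|r|` (descending). The lncRNA set is expected to be
#' the strict DE set and the gene set the relaxed DE set.
#'
#' @param de_lnc character vector of DE lncRNA ids.
#' @param de_genes character vector of DE protein-coding gene ids.
#' @param expr FPKM matrix (features x samples).
#' @param loci loci data.frame (`transcript_id` or `gene_id` keyed;
#'   `chrom`, `start`, `end`) — required for cis.
#' @param mode `"cis"` or `"trans"`.
#' @param seqs named sequences — required for trans.
#' @param window cis window (bp).
#' @param ndg_threshold trans energy gate (scaled units; more negative
#'   passes).
#' @param min_run trans pairing-run filter.
#' @param r_min,p_max correlation gate (`|r| >= r_min`, `p <= p_max`).
#' @return data.frame of TargetLink rows: `lnc_id`, `gene_id`, `mode`,
#'   `distance`, `ndg`, `r`, `r_p`, `passed`.
#' @export
link_targets <- function(de_lnc, de_genes, expr, loci = NULL,
                         mode = c("cis", "trans"), seqs = NULL,
                         window = 3e5, ndg_threshold = -0.08, min_run = 4,
                         r_min = 0.60, p_max = 0.05) {
  mode <- match.arg(mode)
  out <- list()
  le <- function(id) log10(expr[id, ] + 1e-3)
  for (lnc in de_lnc) {
    if (mode == "cis") {
      li <- loci[match(lnc, loci$transcript_id), ]
      cand <- cis_candidates(li, loci[loci$transcript_id %in% de_genes |
                                        loci$gene_id %in% de_genes, ,
                                      drop = FALSE], window)
      cand$id <- loci$transcript_id[match(cand$gene_id, loci$gene_id)]
    } else {
      cand <- data.frame(id = de_genes, stringsAsFactors = FALSE)
      cand$ndg <- vapply(de_genes, function(g)
        ndg(seqs[[lnc]], seqs[[g]], min_run = min_run)$ndg, numeric(1))
      cand <- cand[cand$ndg <= ndg_threshold, , drop = FALSE]
    }
    if (nrow(cand) == 0) next
    for (k in seq_len(nrow(cand))) {
      gid <- cand$id[k]
      if (identical(gid, lnc)) next
      if (!gid %in% rownames(expr) || !lnc %in% rownames(expr)) next
      pc <- pearson_cor(le(lnc), le(gid))
      passed <- !is.na(pc$r) && abs(pc$r) >= r_min && pc$p <= p_max
      out[[length(out) + 1]] <- data.frame(
        lnc_id = lnc, gene_id = gid, mode = mode,
        distance = if (mode == "cis") cand$distance[k] else NA_real_,
        ndg = if (mode == "trans") cand$ndg[k] else NA_real_,
        r = pc$r %||% NA_real_, r_p = pc$p %||% NA_real_, passed = passed,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) {
    return(data.frame(lnc_id = character(), gene_id = character(),
                      mode = character(), distance = numeric(),
                      ndg = numeric(), r = numeric(), r_p = numeric(),
                      passed = logical(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res[order(-abs(res$r)), , drop = FALSE]
}
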