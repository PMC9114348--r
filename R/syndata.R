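# Synthetic transcriptomes, count matrices, qPCR tables and gene sets with
# planted ground truth. The generator emulates the structure of the eyelid
# RNA-seq study: coding transcripts carry a long ORF drawn from a biased codon
# model (hexamer signal), noncoding transcripts are stop-seeded and ORF-poor
# with lower GC, fewer exons, shorter length and lower expression; counts are
# negative binomial for a 5 pigmented vs 6 unpigmented design with planted
# log2 fold changes; cis pairs sit within a genomic window with correlated
# expression; trans pairs carry a spliced-in reverse-complement segment.

#' Default generator parameters
#'
#' Class-specific means follow the feature tendencies reported for novel
#' lncRNAs, known lncRNAs and protein-coding transcripts (GC 46.9 / 47 / 52
#' percent, lengths 2532 / 2199 / 3056 nt, exon counts 3.8 / 2.9 / 12.3,
#' log10-FPKM 0.34 / 0.21 / 0.98).
#'
#' @return named list of generator parameters.
#' @export
sim_params <- function() {
  list(
    coding_gc = 0.52, noncoding_gc = 0.469, known_gc = 0.47,
    coding_len_mean = 3056, noncoding_len_mean = 2532, known_len_mean = 2199,
    len_cv = 0.35, min_len = 250,
    coding_exons_mean = 12.3, noncoding_exons_mean = 3.8,
    known_exons_mean = 2.9,
    orf_fraction = 0.5, codon_tilt = 0.35, stop_spacing = 24,
    coding_log10fpkm = 0.98, noncoding_log10fpkm = 0.34,
    known_log10fpkm = 0.21, log10fpkm_sd = 0.45,
    lib_size_mean = 2e7, lib_size_sd_log = 0.12,
    dispersion = 0.1,
    loci_per_chrom = 50, gap_min = 1e3, gap_max = 5e5,
    intron_min = 100, intron_max = 4000,
    class_code_freq = c(j = 0.515, o = 0.145, i = 0.123, u = 0.165,
                        x = 0.052)
  )
}

# Fixed synthetic codon-usage table: 61 sense codons, weights tilted toward
# GC-rich codons (drives coding GC above noncoding) with a deterministic
# per-codon jitter that creates codon-to-codon (hence hexamer) bias.
codon_table <- function(tilt = 0.35) {
  b <- c("T", "C", "A", "G")
  codons <- as.vector(outer(outer(b, b, paste0), b, paste0))
  codons <- setdiff(codons, c("TAA", "TAG", "TGA"))
  gc <- vapply(strsplit(codons, ""), function(x) sum(x %in% c("G", "C")),
               numeric(1))
  jit <- 0.5 + ((seq_along(codons) * 37L) %% 11L) / 11
  w <- exp(tilt * gc) * jit
  setNames(w / sum(w), codons)
}

rand_seq <- function(n, gc, alphabet = c("A", "C", "G", "T")) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(alphabet, n, replace = TRUE, prob = p), collapse = "")
}

# Split `total` into k parts, each >= min_part, with random proportions.
split_lengths <- function(total, k, min_part = 1L) {
  if (k == 1) return(total)
  w <- stats::rexp(k) + 0.2
  l <- floor(w / sum(w) * (total - k * min_part)) + min_part
  l[1] <- l[1] + (total - sum(l))
  l
}

make_coding_seq <- function(len, params, ctab) {
  orf_codons <- max(10L, round(len * params$orf_fraction / 3))
  orf_len <- orf_codons * 3L
  if (orf_len > len - 6L) {
    orf_codons <- max(4L, (len - 6L) %/% 3L)
    orf_len <- orf_codons * 3L
  }
  # expected ORF GC under the codon table, used to balance UTR GC so that the
  # whole transcript hits the class target
  gc_codon <- vapply(strsplit(names(ctab), ""), function(x)
    sum(x %in% c("G", "C")), numeric(1))
  orf_gc <- sum(ctab * gc_codon) / 3
  utr_len <- len - orf_len
  utr_gc <- if (utr_len > 0)
    min(0.8, max(0.2, (params$coding_gc * len - orf_gc * orf_len) / utr_len))
  else 0.5
  body <- paste(sample(names(ctab), orf_codons - 2L, replace = TRUE,
                       prob = ctab), collapse = "")
  orf <- paste0("ATG", body, sample(c("TAA", "TAG", "TGA"), 1))
  u5 <- utr_len %/% 2
  u3 <- utr_len - u5
  paste0(if (u5 > 0) rand_seq(u5, utr_gc) else "",
         orf,
         if (u3 > 0) rand_seq(u3, utr_gc) else "")
}

make_noncoding_seq <- function(len, gc, spacing) {
  # stop-codon seeding keeps ORFs short; background GC is raised to
  # compensate for the AT-rich stops so the overall GC hits the target
  stop_frac <- 3 / spacing
  bg_gc <- min(0.8, max(0.1, (gc - stop_frac * 2 / 9) / (1 - stop_frac)))
  s <- rand_seq(len, bg_gc)
  if (len >= 6) {
    pos <- seq.int(sample.int(min(spacing, len - 2L), 1), len - 2L,
                   by = spacing)
    stops <- sample(c("TAA", "TAG", "TGA"), length(pos), replace = TRUE)
    for (k in seq_along(pos)) {
      substr(s, pos[k], pos[k] + 2L) <- stops[k]
    }
  }
  s
}

draw_lengths <- function(n, mean_len, cv, min_len) {
  s2 <- log(1 + cv^2)
  l <- round(stats::rlnorm(n, log(mean_len) - s2 / 2, sqrt(s2)))
  pmax(as.integer(l), as.integer(min_len))
}

# Lay transcripts out on synthetic chromosomes (loci_per_chrom per
# chromosome, log-uniform intergenic gaps) and derive exon structures.
layout_loci <- function(n_exons, lengths, params) {
  n <- length(lengths)
  chrom <- paste0("chr", (seq_len(n) - 1) %/% params$loci_per_chrom + 1)
  start <- integer(n)
  exons <- vector("list", n)
  cursor <- 1e4
  cur_chrom <- ""
  for (i in seq_len(n)) {
    if (chrom[i] != cur_chrom) {
      cursor <- 1e4
      cur_chrom <- chrom[i]
    }
    ex_len <- split_lengths(lengths[i], n_exons[i], min_part = 20L)
    introns <- if (n_exons[i] > 1)
      round(stats::runif(n_exons[i] - 1, params$intron_min,
                         params$intron_max))
    else integer(0)
    st <- cursor + cumsum(c(0, ex_len[-n_exons[i]] + introns))
    exons[[i]] <- cbind(start = as.integer(st),
                        end = as.integer(st + ex_len))
    start[i] <- cursor
    span <- sum(ex_len) + sum(introns)
    gap <- round(exp(stats::runif(1, log(params$gap_min),
                                  log(params$gap_max))))
    cursor <- cursor + span + gap
  }
  list(chrom = chrom, exons = exons)
}

#' Generate a synthetic transcriptome with planted coding labels
#'
#' @param n_coding,n_noncoding number of protein-coding and noncoding
#'   transcripts (>= 0).
#' @param seed integer RNG seed; the same seed reproduces the output exactly.
#' @param params generator parameters from [sim_params()].
#' @param noncoding_kind `"novel"` or `"known"`; selects the noncoding
#'   length/exon/GC regime.
#' @return list with `tx` (a [transcripts()] table with sequences; coding
#'   transcripts carry class code `"="`, noncoding candidates cuffcompare-like
#'   codes) and `truth` (planted labels, loci and the generator config).
#' @export
generate_transcriptome <- function(n_coding, n_noncoding, seed,
                                   params = sim_params(),
                                   noncoding_kind = "novel") {
  stopifnot(n_coding >= 0, n_noncoding >= 0)
  if (params$coding_len_mean <= 0 || params$noncoding_len_mean <= 0)
    stop("lengths must be positive")
  set.seed(seed)
  ctab <- codon_table(params$codon_tilt)
  nc_len_mean <- if (noncoding_kind == "known") params$known_len_mean
                 else params$noncoding_len_mean
  nc_gc <- if (noncoding_kind == "known") params$known_gc
           else params$noncoding_gc
  nc_ex_mean <- if (noncoding_kind == "known") params$known_exons_mean
                else params$noncoding_exons_mean
  n <- n_coding + n_noncoding
  label <- rep(c("coding", "noncoding"), c(n_coding, n_noncoding))
  lengths <- c(draw_lengths(n_coding, params$coding_len_mean, params$len_cv,
                            params$min_len),
               draw_lengths(n_noncoding, nc_len_mean, params$len_cv,
                            params$min_len))
  n_exons <- as.integer(2L + stats::rpois(n, pmax(
    ifelse(label == "coding", params$coding_exons_mean, nc_ex_mean) - 2,
    0.01)))
  seqs <- character(n)
  for (i in seq_len(n)) {
    seqs[i] <- if (label[i] == "coding")
      make_coding_seq(lengths[i], params, ctab)
    else make_noncoding_seq(lengths[i], nc_gc, params$stop_spacing)
  }
  ord <- sample.int(n)  # interleave classes along the genome
  lay <- layout_loci(n_exons[ord], lengths[ord], params)
  chrom <- character(n); exons <- vector("list", n)
  chrom[ord] <- lay$chrom
  exons[ord] <- lay$exons
  strand <- sample(c("+", "-"), n, replace = TRUE)
  ccf <- params$class_code_freq
  class_code <- ifelse(label == "coding", "=",
                       sample(names(ccf), n, replace = TRUE, prob = ccf))
  ids <- sprintf("TX%05d", seq_len(n))
  tx <- transcripts(data.frame(
    transcript_id = ids,
    gene_id = sprintf("G%05d", seq_len(n)),
    chrom = chrom, strand = strand, class_code = class_code,
    exons = I(exons), sequence = seqs,
    source = ifelse(label == "coding", "annotated_coding", "candidate"),
    stringsAsFactors = FALSE))
  loci <- data.frame(
    gene_id = tx$gene_id, transcript_id = ids, chrom = chrom,
    strand = strand,
    start = vapply(exons, function(e) e[1, 1], integer(1)),
    end = vapply(exons, function(e) e[nrow(e), 2], integer(1)),
    biotype = ifelse(label == "coding", "coding", "lncRNA"),
    stringsAsFactors = FALSE)
  truth <- list(coding_labels = setNames(label, ids), loci = loci,
                de_status = NULL, cis_pairs = NULL, trans_pairs = NULL,
                config = list(op = "generate_transcriptome", seed = seed,
                              n_coding = n_coding, n_noncoding = n_noncoding,
                              params = params))
  list(tx = tx, truth = truth)
}

#' Generate NB counts with planted differential expression
#'
#' Counts are negative binomial with `Var = mu + dispersion * mu^2`;
#' per-feature base means derive from class-specific log-normal FPKM levels
#' (noncoding lower than coding) and per-sample library sizes. Planted DE
#' features split their fold change symmetrically across the two groups so
#' the group mean ratio is `2^lfc` (pigmented over unpigmented).
#'
#' @param features data.frame with `feature_id`, `class`
#'   (`coding`/`noncoding`), `length`.
#' @param n_de number of DE features to plant (`<=` number of features).
#' @param seed RNG seed.
#' @param design named integer vector `c(pigmented = 5, unpigmented = 6)`.
#' @param lfc_range absolute log2-fold-change range for planted effects.
#' @param dispersion NB dispersion alpha (> 0).
#' @param params generator parameters.
#' @param base_fpkm optional named vector forcing specific features' FPKM.
#' @return list with `counts` ([count_matrix()]) and `truth` de_status table.
#' @export
generate_counts <- function(features, n_de, seed,
                            design = c(pigmented = 5, unpigmented = 6),
                            lfc_range = c(1.5, 4), dispersion = 0.1,
                            params = sim_params(), base_fpkm = NULL) {
  stopifnot(dispersion > 0)
  n <- nrow(features)
  if (n_de > n) stop("n_de exceeds the number of features")
  set.seed(seed)
  groups <- rep(names(design), design)
  samples <- paste0(substr(groups, 1, 1), unlist(lapply(design, seq_len)))
  lib <- round(exp(stats::rnorm(length(samples), log(params$lib_size_mean),
                                params$lib_size_sd_log)))
  mu_fpkm <- ifelse(features$class == "coding", params$coding_log10fpkm,
                    params$noncoding_log10fpkm)
  fpkm <- 10^stats::rnorm(n, mu_fpkm, params$log10fpkm_sd)
  if (!is.null(base_fpkm)) {
    hit <- match(names(base_fpkm), features$feature_id)
    fpkm[hit[!is.na(hit)]] <- base_fpkm[!is.na(hit)]
  }
  lfc <- numeric(n)
  if (n_de > 0) {
    de_idx <- sample.int(n, n_de)
    lfc[de_idx] <- sample(c(-1, 1), n_de, replace = TRUE) *
      stats::runif(n_de, lfc_range[1], lfc_range[2])
  }
  base_mu <- fpkm * features$length / 1000 # per million mapped reads
  shift <- ifelse(groups == "pigmented", 0.5, -0.5)
  mu <- outer(base_mu, lib / 1e6) * 2^(lfc %o% shift)
  cnt <- matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion),
                nrow = n,
                dimnames = list(features$feature_id, samples))
  de_status <- data.frame(
    feature_id = features$feature_id,
    status = ifelse(lfc > 0, "up", ifelse(lfc < 0, "down", "null")),
    lfc = lfc, stringsAsFactors = FALSE)
  cm <- count_matrix(cnt, setNames(groups, samples),
                     lib_sizes = setNames(lib, samples))
  list(counts = cm, truth = de_status)
}

# Shared-latent-factor count regeneration used by the cis/trans planting.
# A planted pair is DE in the same direction, so much of its expression
# correlation already comes from the shared group effect; a common
# group-centered log-normal factor adds within-group co-variation, with its
# scale tau solved from the log-scale variance decomposition so the expected
# Pearson r across all samples is ~rho (larger tau would inflate the
# apparent dispersion and erode the planted fold change's testability).
replant_pair_counts <- function(cm, ids, lfcs, rho, dispersion, lengths,
                                fpkm = 5) {
  groups <- cm$group
  lib <- cm$lib_sizes
  shift <- ifelse(groups == "pigmented", 0.5, -0.5)
  mu_bar <- fpkm * lengths / 1000 * mean(lib) / 1e6
  sig2 <- 1 / pmax(mu_bar, 1) + dispersion     # per-feature NB log variance
  vshift <- var(shift) * log(2)^2               # group-indicator variance
  v1 <- vshift * lfcs[1]^2; v2 <- vshift * lfcs[2]^2
  cg <- vshift * abs(lfcs[1] * lfcs[2])
  vz_of <- function(tau) tau^2 * (1 - 1 / mean(table(groups)))
  r_of <- function(tau) (cg + vz_of(tau)) /
    sqrt((v1 + vz_of(tau) + sig2[1]) * (v2 + vz_of(tau) + sig2[2]))
  tau <- if (r_of(0) >= rho) 0.15 else
    stats::uniroot(function(t) r_of(t) - rho, c(0, 5))$root
  z <- stats::rnorm(length(groups))
  # group-center the latent factor so it induces within-group correlation
  # without perturbing the planted group-mean fold change
  z <- z - stats::ave(z, groups)
  f <- exp(tau * z - tau^2 / 2)
  for (k in seq_along(ids)) {
    mu <- fpkm * lengths[k] / 1000 * lib / 1e6 * 2^(lfcs[k] * shift) * f
    cm$counts[ids[k], ] <- stats::rnbinom(length(mu), mu = mu,
                                          size = 1 / dispersion)
  }
  cm
}

#' Plant cis lncRNA-gene pairs within a genomic window
#'
#' Each planted pair relocates a coding gene to within `window` bp of a
#' noncoding (lncRNA) locus, plants same-sign DE on both members and
#' regenerates their counts with a shared latent log-normal factor so their
#' expression correlates (target Pearson ~ `rho`). An equal number of decoy
#' pairs is planted identically but at a distance beyond the window.
#'
#' @param sim study bundle (list with `tx`, `counts`, `truth`) as built by
#'   [simulate_study()].
#' @param n_pairs number of positive pairs (an equal number of decoys is
#'   added).
#' @param window window size in bp (> 0).
#' @param rho target expression correlation.
#' @param seed RNG seed.
#' @return updated bundle; `truth$cis_pairs` gains rows with `planted`
#'   `TRUE`/`FALSE` (decoy) and the realized genomic distance.
#' @export
plant_cis_pairs <- function(sim, n_pairs, window = 3e5, rho = 0.9, seed) {
  if (window <= 0) stop("window must be > 0 to plant cis pairs")
  set.seed(seed)
  truth <- sim$truth
  used <- unique(c(truth$cis_pairs$lnc_id, truth$cis_pairs$gene_id,
                   truth$trans_pairs$lnc_id, truth$trans_pairs$gene_id))
  lnc_pool <- setdiff(names(truth$coding_labels)[
    truth$coding_labels == "noncoding"], used)
  gene_pool <- setdiff(names(truth$coding_labels)[
    truth$coding_labels == "coding"], used)
  if (length(lnc_pool) < 2 * n_pairs || length(gene_pool) < 2 * n_pairs)
    stop("not enough unused features to plant cis pairs")
  lncs <- sample(lnc_pool, 2 * n_pairs)
  genes <- sample(gene_pool, 2 * n_pairs)
  planted <- rep(c(TRUE, FALSE), each = n_pairs)
  rows <- vector("list", 2 * n_pairs)
  disp <- truth$config$params$dispersion %||% 0.1
  for (k in seq_len(2 * n_pairs)) {
    li <- match(lncs[k], truth$loci$transcript_id)
    gi <- match(genes[k], truth$loci$transcript_id)
    d <- if (planted[k]) round(stats::runif(1, 1e3, window))
         else round(window + stats::runif(1, 5e4, 2e5))
    new_start <- truth$loci$end[li] + d
    delta <- new_start - truth$loci$start[gi]
    ti <- match(genes[k], sim$tx$transcript_id)
    sim$tx$exons[[ti]] <- sim$tx$exons[[ti]] + as.integer(delta)
    sim$tx$chrom[ti] <- truth$loci$chrom[li]
    truth$loci$chrom[gi] <- truth$loci$chrom[li]
    truth$loci$start[gi] <- truth$loci$start[gi] + delta
    truth$loci$end[gi] <- truth$loci$end[gi] + delta
    sgn <- sample(c(-1, 1), 1)
    lfc_l <- sgn * stats::runif(1, 2, 3.5)
    lfc_g <- sgn * stats::runif(1, 1.5, 3)
    lens <- c(sim$tx$length[match(lncs[k], sim$tx$transcript_id)],
              sim$tx$length[ti])
    sim$counts <- replant_pair_counts(sim$counts, c(lncs[k], genes[k]),
                                      c(lfc_l, lfc_g), rho, disp, lens)
    truth$de_status$status[truth$de_status$feature_id == lncs[k]] <-
      if (sgn > 0) "up" else "down"
    truth$de_status$lfc[truth$de_status$feature_id == lncs[k]] <- lfc_l
    truth$de_status$status[truth$de_status$feature_id == genes[k]] <-
      if (sgn > 0) "up" else "down"
    truth$de_status$lfc[truth$de_status$feature_id == genes[k]] <- lfc_g
    rows[[k]] <- data.frame(lnc_id = lncs[k], gene_id = genes[k],
                            distance = d, planted = planted[k],
                            stringsAsFactors = FALSE)
  }
  truth$cis_pairs <- rbind(truth$cis_pairs, do.call(rbind, rows))
  sim$truth <- truth
  sim
}

#' Plant trans lncRNA-gene pairs by sequence complementarity
#'
#' Splices the reverse complement of a GC-rich `seg_len`-nt segment of the
#' target mRNA into the lncRNA (length preserved) and plants same-sign DE
#' plus correlated counts as in [plant_cis_pairs()].
#'
#' @inheritParams plant_cis_pairs
#' @param seg_len complementary segment length (must not exceed the lncRNA
#'   length).
#' @return updated bundle with edited sequences and `truth$trans_pairs`.
#' @export
plant_trans_pairs <- function(sim, n_pairs, seg_len = 20, rho = 0.9, seed) {
  set.seed(seed)
  truth <- sim$truth
  used <- unique(c(truth$cis_pairs$lnc_id, truth$cis_pairs$gene_id,
                   truth$trans_pairs$lnc_id, truth$trans_pairs$gene_id))
  lnc_pool <- setdiff(names(truth$coding_labels)[
    truth$coding_labels == "noncoding"], used)
  gene_pool <- setdiff(names(truth$coding_labels)[
    truth$coding_labels == "coding"], used)
  if (length(lnc_pool) < n_pairs || length(gene_pool) < n_pairs)
    stop("not enough unused features to plant trans pairs")
  lncs <- sample(lnc_pool, n_pairs)
  genes <- sample(gene_pool, n_pairs)
  rows <- vector("list", n_pairs)
  disp <- truth$config$params$dispersion %||% 0.1
  for (k in seq_len(n_pairs)) {
    li <- match(lncs[k], sim$tx$transcript_id)
    gi <- match(genes[k], sim$tx$transcript_id)
    lseq <- sim$tx$sequence[li]
    gseq <- sim$tx$sequence[gi]
    if (seg_len > nchar(lseq))
      stop("seg_len exceeds the lncRNA length for ", lncs[k])
    # pick a thermodynamically strong (GC-rich) donor segment from the mRNA
    cand <- sample.int(nchar(gseq) - seg_len + 1, min(60, nchar(gseq) -
                                                        seg_len + 1))
    gcs <- vapply(cand, function(p) {
      s <- substr(gseq, p, p + seg_len - 1)
      sum(strsplit(s, "")[[1]] %in% c("G", "C"))
    }, numeric(1))
    p0 <- cand[which.max(gcs)]
    seg <- substr(gseq, p0, p0 + seg_len - 1)
    ins <- sample.int(nchar(lseq) - seg_len + 1, 1)
    substr(lseq, ins, ins + seg_len - 1) <- revcomp(seg)
    sim$tx$sequence[li] <- lseq
    sgn <- sample(c(-1, 1), 1)
    lfc_l <- sgn * stats::runif(1, 2, 3.5)
    lfc_g <- sgn * stats::runif(1, 1.5, 3)
    sim$counts <- replant_pair_counts(sim$counts, c(lncs[k], genes[k]),
                                      c(lfc_l, lfc_g), rho, disp,
                                      c(nchar(lseq), nchar(gseq)))
    truth$de_status$status[truth$de_status$feature_id == lncs[k]] <-
      if (sgn > 0) "up" else "down"
    truth$de_status$lfc[truth$de_status$feature_id == lncs[k]] <- lfc_l
    truth$de_status$status[truth$de_status$feature_id == genes[k]] <-
      if (sgn > 0) "up" else "down"
    truth$de_status$lfc[truth$de_status$feature_id == genes[k]] <- lfc_g
    rows[[k]] <- data.frame(lnc_id = lncs[k], gene_id = genes[k],
                            seg_start_mrna = p0, seg_start_lnc = ins,
                            seg_len = seg_len, stringsAsFactors = FALSE)
  }
  truth$trans_pairs <- rbind(truth$trans_pairs, do.call(rbind, rows))
  sim$truth <- truth
  sim
}

#' Generate a synthetic qPCR Ct table
#'
#' Ct values are simulated as housekeeping Ct plus a per-sample delta-Ct whose
#' pigmented-group shift equals minus the planted log2 fold change; every
#' sample is emitted in duplicate.
#'
#' @param truth truth object carrying `de_status` (planted log2FC per
#'   feature).
#' @param genes feature ids to assay.
#' @param n_per_group named vector `c(pigmented = , unpigmented = )`.
#' @param noise_sd biological delta-Ct noise (cycles).
#' @param tech_sd technical duplicate noise (cycles).
#' @param seed RNG seed.
#' @return data.frame with `sample_id`, `group`, `gene_id`, `ct_target`,
#'   `ct_housekeeping`.
#' @export
generate_qpcr <- function(truth, genes,
                          n_per_group = c(pigmented = 5, unpigmented = 6),
                          noise_sd = 0.25, tech_sd = 0.05, seed = 1) {
  set.seed(seed)
  groups <- rep(names(n_per_group), n_per_group)
  samples <- if (length(groups) == 0) character(0)
             else paste0("q", substr(groups, 1, 1),
                         unlist(lapply(n_per_group, seq_len)))
  if (length(samples) == 0 || length(genes) == 0) {
    return(data.frame(sample_id = character(), group = character(),
                      gene_id = character(), ct_target = numeric(),
                      ct_housekeeping = numeric(), stringsAsFactors = FALSE))
  }
  lfc <- setNames(truth$de_status$lfc, truth$de_status$feature_id)[genes]
  lfc[is.na(lfc)] <- 0
  rows <- list()
  hk <- stats::rnorm(length(samples), 18, 0.4)
  for (g in seq_along(genes)) {
    base <- stats::runif(1, 4, 8)
    dct <- base - lfc[g] * (groups == "pigmented") +
      stats::rnorm(length(samples), 0, noise_sd)
    for (dup in 1:2) {
      rows[[length(rows) + 1]] <- data.frame(
        sample_id = samples, group = groups, gene_id = genes[g],
        ct_target = hk + dct + stats::rnorm(length(samples), 0, tech_sd),
        ct_housekeeping = hk, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate a complete synthetic study with planted truth
#'
#' Builds a transcriptome (annotated coding transcripts plus noncoding
#' candidates), a known-lncRNA reference database with mutated copies among
#' the candidates, an NB count matrix for the 5-vs-6 design, planted cis and
#' trans target pairs, a qPCR table for a validation panel and gene sets
#' containing the planted trans targets.
#'
#' @param seed integer seed controlling every random choice.
#' @param n_coding,n_noncoding transcriptome size per class.
#' @param n_known_db known-lncRNA database size.
#' @param n_known_copies candidates that are mutated copies of database
#'   entries (~2 percent substitutions).
#' @param n_de DE features planted at large (before pair planting).
#' @param n_cis,n_trans planted positive cis / trans pairs.
#' @param n_qpcr validation panel size (half lncRNAs, half coding).
#' @param params generator parameters.
#' @return list with `tx`, `counts`, `known_db`, `qpcr`, `gene_sets`,
#'   `truth`.
#' @export
simulate_study <- function(seed, n_coding = 250, n_noncoding = 250,
                           n_known_db = 60, n_known_copies = 20, n_de = 60,
                           n_cis = 6, n_trans = 6, n_qpcr = 6,
                           params = sim_params()) {
  gen <- generate_transcriptome(n_coding, n_noncoding, seed, params)
  tx <- gen$tx
  truth <- gen$truth
  # known-lncRNA database + mutated copies among the candidates
  kn <- generate_transcriptome(0, n_known_db, seed + 1, params,
                               noncoding_kind = "known")
  known_db <- setNames(kn$tx$sequence, sprintf("KLNC%04d", seq_len(n_known_db)))
  set.seed(seed + 2)
  copy_of <- if (n_known_copies > 0) sample(names(known_db), n_known_copies)
             else character(0)
  cp <- generate_transcriptome(0, n_known_copies, seed + 3, params,
                               noncoding_kind = "known")
  cp_tx <- cp$tx
  for (k in seq_len(n_known_copies)) {
    s <- known_db[[copy_of[k]]]
    n_sub <- max(1L, round(nchar(s) * 0.02))
    pos <- sample.int(nchar(s), n_sub)
    for (p in pos) {
      cur <- substr(s, p, p)
      substr(s, p, p) <- sample(setdiff(c("A", "C", "G", "T"), cur), 1)
    }
    # rebuild exon structure to match the copied sequence length
    ex <- cp_tx$exons[[k]]
    lens <- split_lengths(nchar(s), nrow(ex), min_part = 20L)
    st <- ex[1, 1] + cumsum(c(0, lens[-length(lens)] + 500L))
    cp_tx$exons[[k]] <- cbind(start = as.integer(st),
                              end = as.integer(st + lens))
    cp_tx$sequence[k] <- s
  }
  cp_tx$transcript_id <- sprintf("TXK%04d", seq_len(n_known_copies))
  cp_tx$gene_id <- sprintf("GK%04d", seq_len(n_known_copies))
  cp_tx$chrom <- vapply(seq_len(n_known_copies), function(k)
    paste0("chrK", k %/% 20 + 1), "")
  cp_tx <- transcripts(as.data.frame(cp_tx))
  tx <- transcripts(rbind(as.data.frame(tx), as.data.frame(cp_tx)))
  truth$coding_labels <- c(truth$coding_labels,
                           setNames(rep("noncoding", n_known_copies),
                                    cp_tx$transcript_id))
  truth$known_copy <- setNames(copy_of, cp_tx$transcript_id)
  if (n_known_copies > 0) {
    truth$loci <- rbind(truth$loci, data.frame(
      gene_id = cp_tx$gene_id, transcript_id = cp_tx$transcript_id,
      chrom = cp_tx$chrom, strand = cp_tx$strand,
      start = vapply(cp_tx$exons, function(e) e[1, 1], integer(1)),
      end = vapply(cp_tx$exons, function(e) e[nrow(e), 2], integer(1)),
      biotype = "lncRNA", stringsAsFactors = FALSE))
  }
  # counts; known copies get a floor FPKM so they survive the expression
  # filter and the cascade recovery is about matching, not abundance
  feats <- data.frame(
    feature_id = tx$transcript_id,
    class = unname(truth$coding_labels[tx$transcript_id]),
    length = tx$length, stringsAsFactors = FALSE)
  gc_res <- generate_counts(feats, n_de, seed + 4, dispersion =
                              params$dispersion, params = params,
                            base_fpkm = setNames(rep(6, n_known_copies),
                                                 cp_tx$transcript_id))
  sim <- list(tx = tx, counts = gc_res$counts, known_db = known_db,
              truth = truth)
  sim$truth$de_status <- gc_res$truth
  sim$truth$config$study <- list(seed = seed, n_de = n_de, n_cis = n_cis,
                                 n_trans = n_trans)
  if (n_cis > 0) sim <- plant_cis_pairs(sim, n_cis, seed = seed + 5)
  if (n_trans > 0) sim <- plant_trans_pairs(sim, n_trans, seed = seed + 6)
  # qPCR panel: planted DE lncRNAs and coding genes
  de <- sim$truth$de_status
  lab <- sim$truth$coding_labels[de$feature_id]
  panel <- c(head(de$feature_id[de$status != "null" & lab == "noncoding"],
                  ceiling(n_qpcr / 2)),
             head(de$feature_id[de$status != "null" & lab == "coding"],
                  floor(n_qpcr / 2)))
  sim$qpcr <- generate_qpcr(sim$truth, panel, seed = seed + 7)
  sim$truth$qpcr_panel <- panel
  # gene sets over coding genes: one set collecting the planted trans
  # targets (plus padding) and random sets
  set.seed(seed + 8)
  coding_ids <- names(sim$truth$coding_labels)[
    sim$truth$coding_labels == "coding"]
  planted_set <- unique(c(sim$truth$trans_pairs$gene_id,
                          sample(coding_ids, 5)))
  rand_sets <- lapply(1:15, function(i)
    list(set_id = sprintf("SET_RAND%02d", i),
         name = "random background set",
         members = sample(coding_ids, sample(10:40, 1))))
  sim$gene_sets <- c(list(list(set_id = "SET_PIGMENT",
                               name = "planted pigmentation-like set",
                               members = planted_set)), rand_sets)
  sim
}
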