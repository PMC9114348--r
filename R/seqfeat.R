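# Sequence characterization: GC content, FPKM expression, minimum folding
# energy (ME) under a simple additive pair-energy model, the per-100-nt
# normalized folding energy (MEN), and rank-based class comparisons.

#' GC content
#'
#' `(G + C) / (A + C + G + T)`; `N` is excluded from the denominator. An
#' empty or all-N sequence returns `NA`.
#'
#' @param seqs character vector of sequences.
#' @return numeric fractions in `[0, 1]` (or `NA`).
#' @export
gc_content <- function(seqs) {
  ss <- Biostrings::DNAStringSet(chartr("U", "T", toupper(seqs)))
  f <- Biostrings::letterFrequency(ss, letters = c("A", "C", "G", "T"))
  den <- rowSums(f)
  out <- (f[, "G"] + f[, "C"]) / den
  out[den == 0] <- NA_real_
  unname(out)
}

#' FPKM expression matrix
#'
#' `fpkm = count / (length/1000) / (library_size/1e6)`.
#'
#' @param cm [count_matrix()] object.
#' @param lengths named vector of feature lengths (nt).
#' @return numeric matrix of FPKM values (same shape as the counts).
#' @export
fpkm_matrix <- function(cm, lengths) {
  lengths <- lengths[rownames(cm$counts)]
  if (any(is.na(lengths))) stop("missing lengths for some features")
  t(t(cm$counts / (lengths / 1000)) / (cm$lib_sizes / 1e6))
}

#' Minimum folding energy of a transcript
#'
#' Dynamic program over nested (pseudoknot-free) structures with additive
#' pair energies and a minimum hairpin loop of `min_loop` unpaired bases.
#' `N` never pairs. Ties resolve toward fewer pairs with a deterministic
#' traceback.
#'
#' @param seq ACGTUN sequence (treated as RNA).
#' @param energies pair energies `c(GC = -3, AU = -2, GU = -1)`.
#' @param min_loop minimum hairpin loop length.
#' @return list with `me` (energy, `<= 0`), `structure` (dot-bracket) and
#'   `n_pairs`.
#' @export
fold_me <- function(seq, energies = c(GC = -3, AU = -2, GU = -1),
                    min_loop = 3) {
  if (nchar(seq) < 1) stop("sequence must have length >= 1")
  r <- nussinov_fold_cpp(encode_bases(seq), as.integer(min_loop),
                         as.numeric(energies[c("GC", "AU", "GU")]))
  list(me = r$energy, structure = r$structure, n_pairs = r$n_pairs)
}

#' Normalized folding energy (per 100 nt)
#'
#' `MEN = ME / length * 100`.
#'
#' @param me minimum folding energy.
#' @param length sequence length (nt).
#' @return numeric.
#' @export
men <- function(me, length) {
  me / length * 100
}

#' Wilcoxon rank-sum test
#'
#' Exact p by enumeration of all group assignments when `n_x + n_y <= 12`
#' (ties handled by mid-ranks over the observed data); otherwise the normal
#' approximation with tie and continuity corrections.
#'
#' @param x,y numeric samples.
#' @param alternative `two.sided`, `less` or `greater` (x versus y).
#' @return list with `statistic` (U for x) and `p`.
#' @export
wilcoxon_rank_sum <- function(x, y, alternative = "two.sided") {
  m <- length(x); n <- length(y)
  stopifnot(m > 0, n > 0)
  pooled <- c(x, y)
  rk <- rank(pooled)
  W <- sum(rk[seq_len(m)])
  U <- W - m * (m + 1) / 2
  EW <- m * (m + n + 1) / 2
  if (m + n <= 12) {
    idx <- combn(m + n, m)
    Ws <- colSums(matrix(rk[idx], nrow = m))
    p <- switch(alternative,
                two.sided = mean(abs(Ws - EW) >= abs(W - EW) - 1e-9),
                less = mean(Ws <= W + 1e-9),
                greater = mean(Ws >= W - 1e-9))
  } else {
    ties <- table(rk)
    nt <- m + n
    varW <- m * n / 12 * (nt + 1 - sum(ties^3 - ties) / (nt * (nt - 1)))
    if (varW <= 0) return(list(statistic = U, p = 1))
    dev <- W - EW
    cc <- 0.5
    p <- switch(alternative,
                two.sided = 2 * pnorm((abs(dev) - cc) / sqrt(varW),
                                      lower.tail = FALSE),
                less = pnorm((dev + cc) / sqrt(varW)),
                greater = pnorm((dev - cc) / sqrt(varW),
                                lower.tail = FALSE))
    p <- min(1, p)
  }
  list(statistic = U, p = p)
}

#' Assemble the per-transcript feature table
#'
#' Computes GC, length, exon number, mean FPKM (log10 with pseudocount for
#' display) and, optionally, folding energy (ME) and MEN for a subsample of
#' transcripts (folding is cubic in length, so the energy columns are filled
#' for `me_subsample` transcripts per class by default).
#'
#' @param tx [transcripts()] table with sequences.
#' @param cm [count_matrix()] or `NULL`.
#' @param class named vector transcript -> class label (`novel_lnc`,
#'   `known_lnc`, `coding` or similar).
#' @param me_subsample folding subsample size per class (0 = skip folding,
#'   `Inf` = fold everything).
#' @param me_max_len transcripts longer than this are folded on a central
#'   window of this length and MEN is the windowed energy density (folding
#'   is cubic in length).
#' @param seed subsample seed.
#' @return data.frame: `id`, `class`, `gc`, `length`, `exons`, `fpkm`,
#'   `log10_fpkm`, `me` (energy of the folded span), `me_len` (folded span
#'   length), `men`.
#' @export
feature_table <- function(tx, cm = NULL, class = NULL, me_subsample = 15,
                          me_max_len = 1000, seed = 1) {
  ids <- tx$transcript_id
  ft <- data.frame(
    id = ids,
    class = if (is.null(class)) tx$source else unname(class[ids]),
    gc = gc_content(tx$sequence),
    length = tx$length,
    exons = tx$n_exons,
    stringsAsFactors = FALSE)
  if (!is.null(cm)) {
    sub <- count_matrix(cm$counts[ids, , drop = FALSE], cm$group,
                        cm$lib_sizes)
    fp <- fpkm_matrix(sub, setNames(tx$length, ids))
    ft$fpkm <- rowMeans(fp)[ids]
    ft$log10_fpkm <- log10(ft$fpkm + 1e-3)
  } else {
    ft$fpkm <- NA_real_
    ft$log10_fpkm <- NA_real_
  }
  ft$me <- NA_real_
  ft$me_len <- NA_integer_
  ft$men <- NA_real_
  if (me_subsample > 0) {
    set.seed(seed)
    pick <- unlist(lapply(split(seq_len(nrow(ft)), ft$class), function(ii)
      if (length(ii) <= me_subsample) ii
      else sample(ii, me_subsample)))
    for (i in pick) {
      s <- tx$sequence[i]
      if (nchar(s) > me_max_len) {
        off <- (nchar(s) - me_max_len) %/% 2
        s <- substr(s, off + 1, off + me_max_len)
      }
      ft$me[i] <- fold_me(s)$me
      ft$me_len[i] <- nchar(s)
      ft$men[i] <- men(ft$me[i], ft$me_len[i])
    }
  }
  ft
}

# Compact letter display: classes share a letter iff their pairwise p
# exceeds the threshold. Maximal cliques of the "not significantly
# different" graph get letters (brute force over subsets; class counts are
# small).
letter_groups <- function(classes, pmat, p_threshold) {
  k <- length(classes)
  if (k == 1) return(setNames("a", classes))
  similar <- pmat > p_threshold | is.na(pmat)
  diag(similar) <- TRUE
  cliques <- list()
  for (bits in seq_len(2^k - 1)) {
    mem <- which(bitwAnd(bits, 2^(seq_len(k) - 1)) > 0)
    if (all(similar[mem, mem])) cliques[[length(cliques) + 1]] <- mem
  }
  sizes <- vapply(cliques, length, integer(1))
  maximal <- cliques[vapply(seq_along(cliques), function(i)
    !any(vapply(cliques, function(cj)
      length(cj) > sizes[i] && all(cliques[[i]] %in% cj), logical(1))),
    logical(1))]
  letters_used <- letters[seq_along(maximal)]
  out <- vapply(seq_len(k), function(i)
    paste(letters_used[vapply(maximal, function(cl) i %in% cl, logical(1))],
          collapse = ""), "")
  setNames(out, classes)
}

#' Class-wise feature summary with rank tests
#'
#' Produces a Table-1-style summary: mean and standard error per class for
#' each metric, pairwise Wilcoxon rank-sum p-values, and letter groups
#' (classes sharing a letter are not significantly different at
#' `p_threshold`).
#'
#' @param ft [feature_table()] output.
#' @param metrics columns to summarize.
#' @param p_threshold letter-group significance threshold (default 0.01).
#' @return list with `summary` (per class x metric: mean, se, n, letters)
#'   and `pairwise` (per metric pairwise p-values).
#' @export
compare_classes <- function(ft, metrics = c("gc", "length", "men", "exons",
                                            "log10_fpkm"),
                            p_threshold = 0.01) {
  classes <- unique(ft$class)
  sum_rows <- list()
  pair_rows <- list()
  for (mcol in metrics) {
    vals <- split(ft[[mcol]][!is.na(ft[[mcol]])],
                  ft$class[!is.na(ft[[mcol]])])
    vals <- vals[names(vals) %in% classes & lengths(vals) > 0]
    cls <- names(vals)
    pmat <- matrix(NA_real_, length(cls), length(cls),
                   dimnames = list(cls, cls))
    if (length(cls) > 1) {
      for (a in seq_along(cls)) for (b in seq_along(cls)) {
        if (a < b) {
          p <- wilcoxon_rank_sum(vals[[a]], vals[[b]])$p
          pmat[a, b] <- pmat[b, a] <- p
          pair_rows[[length(pair_rows) + 1]] <- data.frame(
            metric = mcol, class_a = cls[a], class_b = cls[b], p = p,
            stringsAsFactors = FALSE)
        }
      }
    }
    lg <- letter_groups(cls, pmat, p_threshold)
    for (cl in cls) {
      v <- vals[[cl]]
      sum_rows[[length(sum_rows) + 1]] <- data.frame(
        metric = mcol, class = cl, mean = mean(v),
        se = sd(v) / sqrt(length(v)), n = length(v), letters = lg[[cl]],
        stringsAsFactors = FALSE)
    }
  }
  list(summary = do.call(rbind, sum_rows),
       pairwise = if (length(pair_rows) > 0) do.call(rbind, pair_rows)
                  else NULL)
}
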