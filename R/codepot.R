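# Three-channel coding-potential assessment. Channel one mirrors a
# logistic-regression coding-probability score on ORF + Fickett + hexamer
# features with a cross-validated cutoff; channel two uses ORF/Fickett
# features with a fixed 0.5 probability cutoff; channel three is a
# regularized linear score on the full 1..5-mer spectrum whose sign carries
# the decision (positive = coding). A transcript is called noncoding only
# when all three channels agree.

# Fickett TESTCODE lookup tables: positional-asymmetry and composition
# parameters map through per-base probability bins combined with the
# published weights.
fickett_position_prob <- list(
  A = c(0.94, 0.68, 0.84, 0.93, 0.58, 0.68, 0.45, 0.34, 0.20, 0.22),
  C = c(0.80, 0.70, 0.70, 0.81, 0.66, 0.48, 0.51, 0.33, 0.30, 0.23),
  G = c(0.90, 0.88, 0.74, 0.64, 0.53, 0.48, 0.27, 0.16, 0.08, 0.08),
  T = c(0.97, 0.97, 0.91, 0.68, 0.69, 0.44, 0.54, 0.20, 0.09, 0.09))
fickett_position_weight <- c(A = 0.26, C = 0.18, G = 0.31, T = 0.33)
fickett_position_para <- c(1.9, 1.8, 1.7, 1.6, 1.5, 1.4, 1.3, 1.2, 1.1, 0.0)
fickett_content_prob <- list(
  A = c(0.28, 0.49, 0.44, 0.55, 0.62, 0.49, 0.67, 0.65, 0.81, 0.21),
  C = c(0.82, 0.64, 0.51, 0.64, 0.59, 0.59, 0.43, 0.44, 0.39, 0.31),
  G = c(0.40, 0.54, 0.47, 0.64, 0.64, 0.73, 0.41, 0.41, 0.33, 0.29),
  T = c(0.28, 0.24, 0.39, 0.40, 0.55, 0.75, 0.56, 0.69, 0.51, 0.58))
fickett_content_weight <- c(A = 0.11, C = 0.12, G = 0.15, T = 0.14)
fickett_content_para <- c(0.33, 0.31, 0.29, 0.27, 0.25, 0.23, 0.21, 0.19,
                          0.17, 0.0)

#' Longest open reading frame
#'
#' Scans the three forward frames. An ORF runs from `ATG` to the first
#' in-frame stop (inclusive, integrity +1); an `ATG` without a downstream
#' in-frame stop counts to the last complete codon with integrity -1. The
#' longest span wins; ties go to the leftmost start.
#'
#' @param seq ACGTN sequence (T or U).
#' @return list with `start` (1-based, NA if no ORF), `length` (nt),
#'   `coverage` (length over sequence length) and `integrity` (+1/-1).
#' @export
longest_orf <- function(seq) {
  s <- chartr("U", "T", toupper(seq))
  n <- nchar(s)
  best <- list(start = NA_integer_, length = 0L, coverage = 0,
               integrity = -1L)
  if (n < 3) return(best)
  stops <- c("TAA", "TAG", "TGA")
  for (f in 0:2) {
    ncod <- (n - f) %/% 3
    if (ncod < 1) next
    cpos <- f + 3 * (seq_len(ncod) - 1) + 1
    codons <- substring(s, cpos, cpos + 2)
    atg <- which(codons == "ATG")
    stp <- which(codons %in% stops)
    for (a in atg) {
      nxt <- stp[stp >= a]
      if (length(nxt) > 0) {
        len <- (nxt[1] - a + 1) * 3L
        integ <- 1L
      } else {
        len <- (ncod - a + 1) * 3L
        integ <- -1L
      }
      st <- cpos[a]
      if (len > best$length ||
          (len == best$length && !is.na(best$start) && st < best$start)) {
        best <- list(start = st, length = len, coverage = len / n,
                     integrity = integ)
      }
    }
  }
  best
}

#' Fickett TESTCODE score
#'
#' Position-asymmetry (max over min+1 of the three codon-position counts) and
#' composition of each base are mapped through lookup tables and combined
#' with fixed weights. `N` bases are ignored. Case and U/T encoding do not
#' affect the score.
#'
#' @param seq sequence.
#' @return numeric score (higher = more coding-like).
#' @export
fickett_score <- function(seq) {
  s <- chartr("U", "T", toupper(seq))
  ch <- strsplit(s, "")[[1]]
  keep <- ch %in% c("A", "C", "G", "T")
  n <- sum(keep)
  if (n == 0) return(0)
  score <- 0
  phase <- (seq_along(ch) - 1) %% 3
  for (b in c("A", "C", "G", "T")) {
    cnt <- vapply(0:2, function(p) sum(ch == b & phase == p), numeric(1))
    posval <- max(cnt) / (min(cnt) + 1)
    pbin <- which(posval >= fickett_position_para)[1]
    score <- score + fickett_position_prob[[b]][pbin] *
      fickett_position_weight[[b]]
    contval <- sum(cnt) / n
    cbin <- which(contval >= fickett_content_para)[1]
    score <- score + fickett_content_prob[[b]][cbin] *
      fickett_content_weight[[b]]
  }
  score
}

#' Build an in-frame hexamer frequency table
#'
#' Counts hexamers stepping by 3 from the longest-ORF start (frame 1 when no
#' ORF exists) across a training set and normalizes to frequencies.
#'
#' @param seqs character vector of sequences.
#' @return named numeric vector of hexamer frequencies (sums to 1).
#' @export
build_hexamer_table <- function(seqs) {
  counts <- new.env(parent = emptyenv())
  total <- 0
  for (s in seqs) {
    s <- chartr("U", "T", toupper(s))
    st <- longest_orf(s)$start
    if (is.na(st)) st <- 1L
    pos <- seq.int(st, nchar(s) - 5L, by = 3L)
    if (length(pos) == 0 || pos[1] > nchar(s) - 5L) next
    hx <- substring(s, pos, pos + 5L)
    hx <- hx[!grepl("N", hx, fixed = TRUE)]
    for (h in hx) {
      counts[[h]] <- (counts[[h]] %||% 0) + 1
      total <- total + 1
    }
  }
  if (total == 0) return(setNames(numeric(0), character(0)))
  ks <- ls(counts)
  setNames(vapply(ks, function(k) counts[[k]] / total, numeric(1)), ks)
}

#' Hexamer usage log-likelihood ratio
#'
#' Mean over in-frame hexamers (frame of the longest ORF, step 3) of
#' `log(f_coding / f_noncoding)` with pseudo-frequency 1e-8 for unseen
#' hexamers; sequences shorter than 6 nt score 0.
#'
#' @param seq sequence.
#' @param coding_freq,noncoding_freq hexamer frequency tables
#'   ([build_hexamer_table()]).
#' @return mean log-likelihood ratio.
#' @export
hexamer_ratio <- function(seq, coding_freq, noncoding_freq) {
  s <- chartr("U", "T", toupper(seq))
  if (nchar(s) < 6) return(0)
  st <- longest_orf(s)$start
  if (is.na(st)) st <- 1L
  if (st > nchar(s) - 5L) st <- 1L
  pos <- seq.int(st, nchar(s) - 5L, by = 3L)
  hx <- substring(s, pos, pos + 5L)
  hx <- hx[!grepl("N", hx, fixed = TRUE)]
  if (length(hx) == 0) return(0)
  eps <- 1e-8
  fc <- coding_freq[hx]
  fn <- noncoding_freq[hx]
  fc[is.na(fc) | fc == 0] <- eps
  fn[is.na(fn) | fn == 0] <- eps
  mean(log(fc / fn))
}

#' Normalized k-mer spectrum (k = 1..kmax)
#'
#' @param seq sequence.
#' @param kmax maximum k (default 5 -> 1364 features).
#' @return named numeric vector; frequencies sum to 1 within each k.
#' @export
kmer_spectrum <- function(seq, kmax = 5) {
  d <- Biostrings::DNAString(chartr("U", "T", toupper(seq)))
  unlist(lapply(seq_len(kmax), function(k) {
    f <- Biostrings::oligonucleotideFrequency(d, width = k)
    tot <- sum(f)
    if (tot > 0) f / tot else f
  }))
}

#' Feature vector(s) for coding-potential channels
#'
#' @param seqs named character vector of sequences.
#' @param coding_freq,noncoding_freq hexamer tables (may be `NULL`, in which
#'   case `hexamer` is 0).
#' @return data.frame with `orf_length`, `orf_coverage`, `orf_integrity`,
#'   `fickett`, `hexamer` per sequence.
#' @export
codepot_features <- function(seqs, coding_freq = NULL, noncoding_freq = NULL) {
  rows <- lapply(seqs, function(s) {
    o <- longest_orf(s)
    data.frame(orf_length = o$length, orf_coverage = o$coverage,
               orf_integrity = o$integrity, fickett = fickett_score(s),
               hexamer = if (is.null(coding_freq)) 0
                         else hexamer_ratio(s, coding_freq, noncoding_freq))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- names(seqs)
  out
}

#' Train an L2-regularized logistic channel by IRLS
#'
#' Minimizes the mean negative log-likelihood plus `l2/2 * ||beta||^2`
#' (intercept unpenalized). The mean-scaled objective makes the fit invariant
#' to duplicating every row. Deterministic given its inputs.
#'
#' @param x numeric feature matrix.
#' @param y 0/1 (or logical) labels; both classes must be present.
#' @param l2 ridge penalty.
#' @param max_iter,tol IRLS controls.
#' @return channel object (list with coefficients and scaling info).
#' @export
train_channel <- function(x, y, l2 = 1e-3, max_iter = 100, tol = 1e-10) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  if (length(unique(y)) < 2) stop("labels contain a single class")
  n <- nrow(x)
  ctr <- colMeans(x)
  scl <- sqrt(colMeans(x^2) - ctr^2) # population sd: duplication-invariant
  scl[scl == 0 | !is.finite(scl)] <- 1
  xs <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  p <- ncol(xs)
  beta <- numeric(p + 1) # intercept first
  X <- cbind(1, xs)
  pen <- diag(c(0, rep(l2, p)), p + 1)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- pmin(pmax(drop(X %*% beta), -30), 30)
    mu <- 1 / (1 + exp(-eta))
    w <- pmax(mu * (1 - mu), 1e-10)
    g <- drop(crossprod(X, y - mu)) / n - pen %*% beta
    H <- crossprod(X * w, X) / n + pen
    step <- solve(H, g)
    beta <- beta + drop(step)
    if (max(abs(step)) < tol) {
      converged <- TRUE
      break
    }
  }
  structure(list(coef = beta, center = ctr, scale = scl,
                 features = colnames(x), converged = converged, iter = it),
            class = "lnc_channel")
}

#' Predict coding probability from a logistic channel
#' @param channel object from [train_channel()].
#' @param x feature matrix (same columns).
#' @return numeric probabilities.
#' @export
predict_channel <- function(channel, x) {
  x <- as.matrix(x)[, channel$features, drop = FALSE]
  xs <- sweep(sweep(x, 2, channel$center), 2, channel$scale, "/")
  eta <- pmin(pmax(drop(cbind(1, xs) %*% channel$coef), -30), 30)
  1 / (1 + exp(-eta))
}

# Ridge-regression linear channel on +-1 labels (the k-mer channel): a
# single deterministic solve with class-balanced weights and standardized
# features, so the zero crossing of the score separates the classes
# regardless of training-set imbalance; positive scores mark coding.
train_linear_channel <- function(x, y01, l2 = 1e-2) {
  x <- as.matrix(x)
  y <- ifelse(as.numeric(y01) > 0.5, 1, -1)
  w <- ifelse(y > 0, 0.5 / sum(y > 0), 0.5 / sum(y < 0))
  ctr <- drop(w %*% x)
  scl <- sqrt(drop(w %*% sweep(x, 2, ctr)^2))
  scl[scl == 0 | !is.finite(scl)] <- 1
  xs <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  A <- crossprod(xs * w, xs) + diag(l2, ncol(xs))
  b <- drop(crossprod(xs * w, y))
  structure(list(coef = solve(A, b), center = ctr, scale = scl,
                 features = colnames(x)), class = "lnc_linear_channel")
}

predict_linear_channel <- function(channel, x) {
  x <- as.matrix(x)[, channel$features, drop = FALSE]
  xs <- sweep(sweep(x, 2, channel$center), 2, channel$scale, "/")
  drop(xs %*% channel$coef)
}

#' Select a score cutoff by k-fold cross-validated Youden J
#'
#' Within each fold the candidate cutoffs are the fold's unique scores; the
#' cutoff maximizing sensitivity + specificity (calling coding when
#' `score > cutoff`) is chosen, smallest first on ties. The final cutoff is
#' the mean over folds.
#'
#' @param scores numeric scores (higher = more coding-like).
#' @param labels coding labels (logical/0-1).
#' @param folds number of folds (1 = use all data once).
#' @param seed RNG seed for the fold split.
#' @return list with `cutoff` and per-fold `folds` data.frame (cutoff,
#'   sensitivity, specificity, j).
#' @export
select_cutoff <- function(scores, labels, folds = 10, seed = 1) {
  labels <- as.logical(labels > 0 | labels == TRUE)
  n <- length(scores)
  set.seed(seed)
  fold_id <- if (folds <= 1) rep(1L, n) else sample(rep(seq_len(folds),
                                                        length.out = n))
  per_fold <- lapply(seq_len(max(fold_id)), function(f) {
    s <- scores[fold_id == f]
    l <- labels[fold_id == f]
    cand <- sort(unique(s))
    stats_at <- vapply(cand, function(c) {
      sens <- if (any(l)) mean(s[l] > c) else NA_real_
      spec <- if (any(!l)) mean(s[!l] <= c) else NA_real_
      c(sens, spec)
    }, numeric(2))
    j <- stats_at[1, ] + stats_at[2, ] - 1
    best <- which(j == max(j, na.rm = TRUE))[1] # sorted: smallest tie wins
    data.frame(fold = f, cutoff = cand[best], sensitivity = stats_at[1, best],
               specificity = stats_at[2, best], j = j[best])
  })
  per_fold <- do.call(rbind, per_fold)
  list(cutoff = mean(per_fold$cutoff), folds = per_fold)
}

#' Train the three-channel coding-potential model
#'
#' Builds hexamer tables from the training sequences, fits the logistic
#' ORF/Fickett channel (fixed 0.5 cutoff), the logistic ORF/Fickett/hexamer
#' channel (cutoff from [select_cutoff()], 10-fold CV) and the linear k-mer
#' channel (sign cutoff 0).
#'
#' @param coding_seqs,noncoding_seqs training sequences.
#' @param folds CV folds for the cutoff.
#' @param seed RNG seed (folds only; the rest is deterministic).
#' @param l2 logistic ridge penalty.
#' @param kmer_l2 linear-channel ridge penalty.
#' @return `coding_potential_model` list.
#' @export
train_codepot <- function(coding_seqs, noncoding_seqs, folds = 10, seed = 1,
                          l2 = 1e-3, kmer_l2 = 1e-2) {
  if (length(coding_seqs) < 2 || length(noncoding_seqs) < 2)
    stop("need at least two sequences per class")
  hex_c <- build_hexamer_table(coding_seqs)
  hex_n <- build_hexamer_table(noncoding_seqs)
  seqs <- c(coding_seqs, noncoding_seqs)
  y <- rep(c(1, 0), c(length(coding_seqs), length(noncoding_seqs)))
  ft <- codepot_features(seqs, hex_c, hex_n)
  ft$log_orf_length <- log1p(ft$orf_length)
  cpc2 <- train_channel(ft[, c("fickett", "log_orf_length", "orf_coverage",
                               "orf_integrity")], y, l2 = l2)
  cpat <- train_channel(ft[, c("log_orf_length", "orf_coverage", "fickett",
                               "hexamer")], y, l2 = l2)
  km <- t(vapply(seqs, kmer_spectrum, numeric(sum(4^(1:5)))))
  plek <- train_linear_channel(km, y, l2 = kmer_l2)
  cpat_scores <- predict_channel(cpat, ft)
  cut <- select_cutoff(cpat_scores, y, folds = folds, seed = seed)
  structure(list(
    hexamer_coding = hex_c, hexamer_noncoding = hex_n,
    cpc2 = cpc2, cpat = cpat, plek = plek,
    cpat_cutoff = cut$cutoff, cpc2_cutoff = 0.5, plek_cutoff = 0,
    metadata = list(n_coding = length(coding_seqs),
                    n_noncoding = length(noncoding_seqs),
                    folds = folds, seed = seed, cv = cut$folds)),
    class = "coding_potential_model")
}

#' @export
print.coding_potential_model <- function(x, ...) {
  cat("coding-potential model:", x$metadata$n_coding, "coding /",
      x$metadata$n_noncoding, "noncoding training sequences;",
      x$metadata$folds, "folds; cutoff", signif(x$cpat_cutoff, 3), "\n")
  invisible(x)
}

#' Score the three channels for a set of sequences
#'
#' @param seqs named character vector.
#' @param model [train_codepot()] model.
#' @return data.frame with `cpc2` (probability), `cpat` (probability),
#'   `plek` (signed score).
#' @export
score_channels <- function(seqs, model) {
  ft <- codepot_features(seqs, model$hexamer_coding, model$hexamer_noncoding)
  ft$log_orf_length <- log1p(ft$orf_length)
  km <- t(vapply(seqs, kmer_spectrum,
                 numeric(length(model$plek$features))))
  data.frame(id = names(seqs),
             cpc2 = predict_channel(model$cpc2, ft),
             cpat = predict_channel(model$cpat, ft),
             plek = predict_linear_channel(model$plek, km),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Consensus verdict from the three channel scores
#'
#' `noncoding` iff the first channel probability is strictly below
#' `cpc2_cutoff`, the second is at or below `cpat_cutoff` (`<=`), and the
#' k-mer score is strictly below `plek_cutoff`.
#'
#' @param cpc2,cpat,plek channel scores (vectors recycle).
#' @param cpat_cutoff probability cutoff for the second channel.
#' @param cpc2_cutoff,plek_cutoff fixed gates.
#' @return character vector, `"noncoding"` or `"coding_potential"`.
#' @export
consensus_verdict <- function(cpc2, cpat, plek, cpat_cutoff = 0.36,
                              cpc2_cutoff = 0.5, plek_cutoff = 0) {
  ifelse(cpc2 < cpc2_cutoff & cpat <= cpat_cutoff & plek < plek_cutoff,
         "noncoding", "coding_potential")
}

#' Consensus coding-potential classification
#'
#' A transcript is `noncoding` iff channel one is strictly below 0.5, channel
#' two is at or below the model cutoff (`<=`), and the k-mer score is
#' strictly below 0; otherwise it retains `coding_potential`.
#'
#' @param seqs named character vector.
#' @param model [train_codepot()] model.
#' @param cpat_cutoff override for the trained cutoff (e.g. a published
#'   value such as 0.36).
#' @return data.frame with per-channel scores and `verdict`.
#' @export
classify_consensus <- function(seqs, model, cpat_cutoff = NULL) {
  sc <- score_channels(seqs, model)
  sc$verdict <- consensus_verdict(sc$cpc2, sc$cpat, sc$plek,
                                  cpat_cutoff = cpat_cutoff %||%
                                    model$cpat_cutoff,
                                  cpc2_cutoff = model$cpc2_cutoff,
                                  plek_cutoff = model$plek_cutoff)
  sc
}
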