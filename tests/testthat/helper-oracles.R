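# Independent oracles used across the suite. Each reimplements the quantity
# it checks by a different route than the package (quadratic-time alignment,
# memo-free recursion, explicit double loops), so agreement is evidence and
# not tautology.

rand_dna <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
        collapse = "")
}

mutate_seq <- function(s, n_sub) {
  pos <- sample(nchar(s), n_sub)
  for (p in pos) {
    substr(s, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                      substr(s, p, p)), 1)
  }
  s
}

# Full quadratic-time local alignment via Biostrings, same scoring scheme as
# the package aligner (match +1, mismatch -2, gap of length L costs 3 + L).
sw_oracle <- function(query, subject) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                  baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(query, subject, type = "local",
                                       substitutionMatrix = mat,
                                       gapOpening = 3, gapExtension = 1)
  cols <- Biostrings::nchar(aln)
  qr <- Biostrings::pattern(aln)
  list(score = Biostrings::score(aln),
       identity = Biostrings::nmatch(aln) / max(cols, 1),
       coverage = (Biostrings::end(qr) - Biostrings::start(qr) + 1) /
         nchar(query))
}

sw_oracle_verdict <- function(query, subject, db_len,
                              min_identity = 0.90, min_coverage = 0.90,
                              max_evalue = 1e-6) {
  pass <- FALSE
  best_id <- 0
  for (q in c(query, as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(query))))) {
    r <- sw_oracle(q, subject)
    ev <- 0.1 * nchar(query) * db_len * exp(-r$score)
    if (r$identity > best_id) best_id <- r$identity
    if (r$identity >= min_identity && r$coverage >= min_coverage &&
        ev <= max_evalue) pass <- TRUE
  }
  list(pass = pass, identity = best_id)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Minimum folding energy by memo-free recursion over the first-position
# decomposition (i unpaired, or i paired with some j), independent of the
# package's last-position DP.
fold_oracle <- function(seq, energies = c(GC = -3, AU = -2, GU = -1),
                        min_loop = 3) {
  s <- strsplit(chartr("U", "T", toupper(seq)), "")[[1]]
  pe <- function(x, y) {
    k <- paste0(x, y)
    switch(k, GC = , CG = energies[["GC"]], AT = , TA = energies[["AU"]],
           GT = , TG = energies[["GU"]], NA_real_)
  }
  rec <- function(i, j) {
    if (j - i < min_loop + 1) return(0)
    best <- rec(i + 1, j)
    for (k in (i + min_loop + 1):j) {
      e <- pe(s[i], s[k])
      if (is.na(e)) next
      inner <- if (k - i >= 2) rec(i + 1, k - 1) else 0
      rest <- if (k < j) rec(k + 1, j) else 0
      cand <- e + inner + rest
      if (cand < best) best <- cand
    }
    best
  }
  if (length(s) < 2) return(0)
  rec(1, length(s))
}

# Hybridization scan oracle: explicit loop over all anti-diagonals of the
# (lnc, mrna) pairing grid.
ndg_oracle <- function(a, b, energies = c(GC = -3, AU = -2, GU = -1),
                       min_run = 4) {
  av <- strsplit(chartr("U", "T", toupper(a)), "")[[1]]
  bv <- strsplit(chartr("U", "T", toupper(b)), "")[[1]]
  pe <- function(x, y) {
    k <- paste0(x, y)
    switch(k, GC = , CG = energies[["GC"]], AT = , TA = energies[["AU"]],
           GT = , TG = energies[["GU"]], NA_real_)
  }
  n <- length(av); m <- length(bv)
  best <- 0
  for (s in seq_len(n + m - 1)) { # anti-diagonal: i + j = s + 1
    total <- 0; run <- 0; runlen <- 0
    for (i in max(1, s + 1 - m):min(n, s)) {
      j <- s + 1 - i
      e <- pe(av[i], bv[j])
      if (!is.na(e)) {
        run <- run + e; runlen <- runlen + 1
      } else {
        if (runlen >= min_run) total <- total + run
        run <- 0; runlen <- 0
      }
    }
    if (runlen >= min_run) total <- total + run
    if (total < best) best <- total
  }
  best / min(n, m)
}

# Textbook BH step-up by explicit double loop.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  padj <- numeric(m)
  for (k in seq_len(m)) {
    vals <- numeric(0)
    for (j in k:m) vals <- c(vals, m / j * p[ord[j]])
    padj[ord[k]] <- min(1, min(vals))
  }
  padj
}

# Exhaustive longest-ORF scan over all (ATG, stop) codon pairs in all
# forward frames.
orf_oracle <- function(seq) {
  s <- chartr("U", "T", toupper(seq))
  n <- nchar(s)
  best <- list(start = NA_integer_, length = 0L, integrity = -1L)
  for (st in seq_len(max(n - 2, 0))) {
    if (substr(s, st, st + 2) != "ATG") next
    len <- NA
    integ <- NA
    p <- st
    while (p + 2 <= n) {
      cod <- substr(s, p, p + 2)
      if (p > st && cod %in% c("TAA", "TAG", "TGA")) {
        len <- p + 2 - st + 1
        integ <- 1L
        break
      }
      p <- p + 3
    }
    if (is.na(len)) {
      len <- (((n - st + 1) %/% 3)) * 3
      integ <- -1L
    }
    if (len > best$length) best <- list(start = st, length = len,
                                        integrity = integ)
  }
  best
}

# A small cached synthetic study shared by the heavier tests.
.sim_cache <- new.env(parent = emptyenv())
get_sim <- function() {
  if (is.null(.sim_cache$sim)) {
    .sim_cache$sim <- simulate_study(seed = 401, n_coding = 150,
                                     n_noncoding = 150, n_known_db = 40,
                                     n_known_copies = 12, n_de = 40,
                                     n_cis = 5, n_trans = 5)
  }
  .sim_cache$sim
}

# Minimal transcript-table constructor for filter tests.
make_tx <- function(ids, class_codes, n_exons = 2, lengths = 300,
                    chrom = "chr1") {
  n <- length(ids)
  if (n == 0) {
    return(transcripts(data.frame(
      transcript_id = character(), gene_id = character(),
      chrom = character(), strand = character(), class_code = character(),
      exons = I(list()), stringsAsFactors = FALSE)))
  }
  n_exons <- rep_len(n_exons, n)
  lengths <- rep_len(lengths, n)
  exons <- lapply(seq_len(n), function(i) {
    k <- n_exons[i]
    per <- diff(round(seq(0, lengths[i], length.out = k + 1)))
    st <- cumsum(c(0, head(per, -1) + 100))
    cbind(start = as.integer(st), end = as.integer(st + per))
  })
  transcripts(data.frame(
    transcript_id = ids, gene_id = paste0("g_", ids),
    chrom = rep_len(chrom, n), strand = rep_len("+", n),
    class_code = rep_len(class_codes, n),
    exons = I(exons), stringsAsFactors = FALSE))
}

revcomp_chr <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}
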