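# Known-lncRNA matching: a reproducible seed-and-extend local aligner.
# Shared exact k-mers between query and database vote for subject diagonals;
# subjects with enough seeds get a banded affine-gap Smith-Waterman
# extension (match +1, mismatch -2, gap open -3, gap extend -1; a gap of
# length L costs 3 + L). E-values use the Karlin-Altschul form
# E = K*m*n*exp(-lambda*S) with fixed (K = 0.1, lambda = 1.0), an
# approximation adequate for thresholding, not a BLAST statistic.

kmer_positions <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(list(kmers = character(0), pos = integer(0)))
  pos <- seq_len(n - k + 1)
  list(kmers = substring(seq, pos, pos + k - 1), pos = pos)
}

#' Build a k-mer index over a sequence database
#'
#' @param db named character vector of sequences.
#' @param k k-mer size.
#' @return index object reused by [match_known()] across queries.
#' @export
build_db_index <- function(db, k = 11) {
  subj <- integer(0); pos <- integer(0); kmers <- character(0)
  for (i in seq_along(db)) {
    kp <- kmer_positions(db[[i]], k)
    subj <- c(subj, rep(i, length(kp$pos)))
    pos <- c(pos, kp$pos)
    kmers <- c(kmers, kp$kmers)
  }
  list(map = split(seq_along(kmers), kmers), subject = subj, pos = pos,
       ids = names(db), k = k, db = db,
       encoded = lapply(db, encode_bases), total_len = sum(nchar(db)))
}

# Best banded local alignment of an encoded query against one encoded
# subject, trying the most seed-supported diagonals.
extend_on_subject <- function(qe, se, qpos, spos, band = 24,
                              max_diagonals = 3) {
  diag_tab <- sort(table(qpos - spos), decreasing = TRUE)
  diags <- as.integer(names(diag_tab))[seq_len(min(max_diagonals,
                                                   length(diag_tab)))]
  diags <- diags[!duplicated(diags %/% band)]
  best <- NULL
  for (d in diags) {
    r <- banded_sw_cpp(qe, se, d, band, 1, -2, 3, 1)
    if (is.null(best) || r$score > best$score) best <- r
  }
  best
}

#' Match a candidate transcript against a known-lncRNA database
#'
#' Seed-and-extend local alignment of the query (both strands) against the
#' database. A query is a `known` lncRNA iff some subject alignment reaches
#' `min_identity` (matches over alignment columns), `min_coverage` (aligned
#' query span over query length) and `max_evalue` simultaneously. Subjects
#' sharing fewer than `min_seeds` exact k-mers with the query are not
#' extended (they cannot approach the identity/coverage gates).
#'
#' @param query sequence (ACGTN, non-empty).
#' @param known_db named character vector of database sequences.
#' @param min_identity,min_coverage,max_evalue verdict thresholds.
#' @param k seed k-mer size (>= 4).
#' @param band half-width of the banded extension.
#' @param min_seeds minimum shared k-mers before extension.
#' @param db_index optional prebuilt [build_db_index()] (must match `k`).
#' @return one-row data.frame: `query_id` (`NA`; see [match_known_many()]),
#'   `subject_id`, `identity`, `coverage`, `evalue`, `score`, `strand`,
#'   `verdict`.
#' @export
match_known <- function(query, known_db, min_identity = 0.90,
                        min_coverage = 0.90, max_evalue = 1e-6, k = 11,
                        band = 24, min_seeds = 15, db_index = NULL) {
  if (is.na(query) || nchar(query) == 0) stop("empty query sequence")
  if (k < 4) stop("seed size k must be >= 4")
  if (is.null(db_index)) db_index <- build_db_index(known_db, k)
  m <- nchar(query)
  best <- data.frame(query_id = NA_character_, subject_id = NA_character_,
                     identity = 0, coverage = 0, evalue = Inf, score = 0,
                     strand = "+", verdict = "novel",
                     stringsAsFactors = FALSE)
  best_pass <- NULL
  for (strand in c("+", "-")) {
    q <- if (strand == "+") query else revcomp(query)
    qk <- kmer_positions(q, k)
    if (length(qk$kmers) == 0) next
    hits <- db_index$map[qk$kmers]
    nh <- lengths(hits)
    nh[is.na(names(hits))] <- 0L
    if (sum(nh) == 0) next
    flat <- unlist(hits[nh > 0], use.names = FALSE)
    qpos_all <- rep(qk$pos, nh)
    subj <- db_index$subject[flat]
    qe <- encode_bases(q)
    for (si in unique(subj)) {
      sel <- subj == si
      if (sum(sel) < min_seeds) next
      r <- extend_on_subject(qe, db_index$encoded[[si]], qpos_all[sel],
                             db_index$pos[flat[sel]], band = band)
      if (is.null(r) || r$score <= 0) next
      identity <- r$matches / max(r$columns, 1)
      coverage <- (r$qend - r$qstart + 1) / m
      evalue <- 0.1 * m * db_index$total_len * exp(-1.0 * r$score)
      pass <- identity >= min_identity && coverage >= min_coverage &&
        evalue <= max_evalue
      row <- data.frame(query_id = NA_character_,
                        subject_id = db_index$ids[si],
                        identity = identity, coverage = coverage,
                        evalue = evalue, score = r$score, strand = strand,
                        verdict = if (pass) "known" else "novel",
                        stringsAsFactors = FALSE)
      if (pass && (is.null(best_pass) || identity > best_pass$identity))
        best_pass <- row
      if (r$score > best$score) best <- row
    }
  }
  if (!is.null(best_pass)) best_pass else best
}

#' Match many queries against a known-lncRNA database
#'
#' Builds the database index once and reuses it across queries.
#'
#' @param queries named character vector of query sequences.
#' @param known_db named character vector of database sequences.
#' @param k seed k-mer size.
#' @param ... passed to [match_known()].
#' @return data.frame, one row per query ([match_known()] columns).
#' @export
match_known_many <- function(queries, known_db, k = 11, ...) {
  if (length(queries) == 0) {
    return(data.frame(query_id = character(), subject_id = character(),
                      identity = numeric(), coverage = numeric(),
                      evalue = numeric(), score = numeric(),
                      strand = character(), verdict = character(),
                      stringsAsFactors = FALSE))
  }
  idx <- build_db_index(known_db, k)
  rows <- lapply(names(queries), function(id) {
    r <- match_known(queries[[id]], known_db, k = k, db_index = idx, ...)
    r$query_id <- id
    r
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
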