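# The lncRNA identification cascade: class-code exclusion, structural
# filters (>= 2 exons, >= 200 bp), the expression threshold (>= 10 reads in
# >= 5 replicates) and known-lncRNA database matching.

filter_report <- function(stage, n_in, removed_ids, reasons) {
  list(stage = stage, n_in = n_in, n_out = n_in - length(removed_ids),
       removed = data.frame(id = removed_ids, reason = reasons,
                            stringsAsFactors = FALSE))
}

#' Filter transcripts by cuffcompare class code
#'
#' Removes transcripts whose class code marks them as matching the reference
#' annotation (`=`), exonic overlap (`e`), pseudogene-like (`p`) or contained
#' (`c`); unknown codes are retained.
#'
#' @param tx [transcripts()] table.
#' @param excluded class codes to drop.
#' @return list with `retained` (transcripts) and `report`.
#' @export
filter_class_codes <- function(tx, excluded = c("=", "e", "p", "c")) {
  drop <- tx$class_code %in% excluded
  list(retained = tx[!drop, , drop = FALSE],
       report = filter_report("class_code", nrow(tx),
                              tx$transcript_id[drop],
                              rep("class_code", sum(drop))))
}

#' Filter transcripts by exon count and length
#'
#' Boundary inclusive: a 200-bp transcript with 2 exons is kept.
#'
#' @param tx [transcripts()] table.
#' @param min_exons,min_length inclusive minima.
#' @return list with `retained` and `report`.
#' @export
filter_structure <- function(tx, min_exons = 2, min_length = 200) {
  bad_ex <- tx$n_exons < min_exons
  bad_len <- !bad_ex & tx$length < min_length
  drop <- bad_ex | bad_len
  reasons <- ifelse(bad_ex[drop], "exon_count", "length")
  list(retained = tx[!drop, , drop = FALSE],
       report = filter_report("structure", nrow(tx),
                              tx$transcript_id[drop], reasons))
}

#' Filter features by the expression threshold
#'
#' Keeps a feature iff at least `min_samples` samples have at least
#' `min_reads` mapped reads (both boundaries inclusive).
#'
#' @param counts [count_matrix()] object.
#' @param min_reads,min_samples thresholds.
#' @param ids optional subset of feature ids to assess (default: all rows).
#' @return list with `retained` (ids) and `report`.
#' @export
filter_expression <- function(counts, min_reads = 10, min_samples = 5,
                              ids = NULL) {
  m <- counts$counts
  if (!is.null(ids)) {
    miss <- setdiff(ids, rownames(m))
    if (length(miss) > 0)
      stop("features absent from counts: ", paste(head(miss), collapse = ", "))
    m <- m[ids, , drop = FALSE]
  }
  ok <- rowSums(m >= min_reads) >= min_samples
  list(retained = rownames(m)[ok],
       report = filter_report("expression", nrow(m), rownames(m)[!ok],
                              rep("expression", sum(!ok))))
}

#' Run the full identification cascade
#'
#' Stages apply in order: class-code exclusion, structure, expression,
#' known-database matching. Every input transcript ends in exactly one bin:
#' a removal reason in one report, `known_lnc`, or `novel_candidates`.
#'
#' @param tx [transcripts()] table with sequences.
#' @param counts [count_matrix()] covering the transcripts.
#' @param known_db named character vector of known lncRNA sequences.
#' @param min_identity,min_coverage,max_evalue known-match thresholds.
#' @param ... passed to the stage filters.
#' @return list with `novel_candidates`, `known_lnc` (transcripts tables),
#'   `matches` (per-candidate [match_known()] results) and `reports`.
#' @export
run_cascade <- function(tx, counts, known_db, min_identity = 0.90,
                        min_coverage = 0.90, max_evalue = 1e-6, ...) {
  s1 <- filter_class_codes(tx)
  s2 <- filter_structure(s1$retained)
  s3 <- filter_expression(counts, ids = s2$retained$transcript_id)
  surv <- s2$retained[s2$retained$transcript_id %in% s3$retained, ,
                      drop = FALSE]
  if (nrow(surv) > 0 && any(is.na(surv$sequence)))
    stop("cascade requires sequences for all surviving transcripts")
  matches <- match_known_many(setNames(surv$sequence, surv$transcript_id),
                              known_db, min_identity = min_identity,
                              min_coverage = min_coverage,
                              max_evalue = max_evalue)
  is_known <- matches$verdict == "known"
  rep4 <- filter_report("known_match", nrow(surv),
                        surv$transcript_id[is_known],
                        rep("known_lnc", sum(is_known)))
  rep4$n_out <- nrow(surv) # nothing is lost at this stage, only re-binned
  list(novel_candidates = surv[!is_known, , drop = FALSE],
       known_lnc = surv[is_known, , drop = FALSE],
       matches = matches,
       reports = list(class_code = s1$report, structure = s2$report,
                      expression = s3$report, known_match = rep4))
}
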