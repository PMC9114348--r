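# End-to-end orchestration: filter cascade -> coding potential -> features
# -> differential expression -> cis/trans targets -> enrichment -> qPCR,
# with a reproducibility manifest. Re-running with the same inputs and seed
# reproduces byte-identical tables.

#' Assemble a pipeline configuration
#'
#' File-based inputs for [run_all()]. Every threshold default is the
#' published value of the corresponding stage (class codes `=epc`; >= 2
#' exons; >= 200 bp; >= 10 reads in >= 5 samples; identity/coverage >= 0.90
#' and e-value <= 1e-6; consensus gates 0.5 / trained cutoff / 0; strict DE
#' padj <= 0.05 and |log2FC| >= 1.5; relaxed DE p <= 0.01 and |log2FC| >= 1;
#' cis window 300 kb; ndG gate -0.08; Pearson |r| >= 0.60, p <= 0.05).
#'
#' @param gtf,fasta,counts,known_db input paths (GTF, FASTA, TSV count
#'   matrix, known-lncRNA FASTA).
#' @param design named vector sample -> group.
#' @param gmt optional GMT path for enrichment.
#' @param qpcr optional qPCR Ct TSV path (`sample_id`, `group`, `gene_id`,
#'   `ct_target`, `ct_housekeeping`).
#' @param outdir output directory.
#' @param seed integer seed for every stochastic stage.
#' @param thresholds named list overriding defaults (see above).
#' @return `lnc_config` list.
#' @export
run_config <- function(gtf, fasta, counts, known_db, design, gmt = NULL,
                       qpcr = NULL, outdir = "lnckit_out", seed = 1,
                       thresholds = list()) {
  def <- list(excluded_class_codes = c("=", "e", "p", "c"),
              min_exons = 2, min_length = 200,
              min_reads = 10, min_samples = 5,
              min_identity = 0.90, min_coverage = 0.90, max_evalue = 1e-6,
              codepot_folds = 10, use_trained_cutoff = FALSE,
              published_cpat_cutoff = 0.36,
              window = 3e5, ndg_threshold = -0.08, ndg_min_run = 4,
              r_min = 0.60, r_p_max = 0.05,
              me_subsample = 15)
  def[names(thresholds)] <- thresholds
  structure(list(gtf = gtf, fasta = fasta, counts = counts,
                 known_db = known_db, design = design, gmt = gmt,
                 qpcr = qpcr, outdir = outdir, seed = seed,
                 thresholds = def),
            class = "lnc_config")
}

#' Write a simulated study to disk in the pipeline's input formats
#'
#' @param sim [simulate_study()] bundle.
#' @param dir output directory.
#' @return named list of written paths (plus `design`).
#' @export
write_study <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(gtf = file.path(dir, "transcripts.gtf"),
                fasta = file.path(dir, "transcripts.fa"),
                counts = file.path(dir, "counts.tsv"),
                known_db = file.path(dir, "known_lnc.fa"),
                gmt = file.path(dir, "gene_sets.gmt"),
                qpcr = file.path(dir, "qpcr.tsv"),
                truth = file.path(dir, "truth.json"))
  write_gtf(sim$tx, paths$gtf)
  write_fasta(setNames(sim$tx$sequence, sim$tx$transcript_id), paths$fasta)
  write_counts(sim$counts, paths$counts)
  write_fasta(sim$known_db, paths$known_db)
  write_gmt(sim$gene_sets, paths$gmt)
  write.table(sim$qpcr, paths$qpcr, sep = "\t", quote = FALSE,
              row.names = FALSE)
  truth <- sim$truth
  truth$config <- NULL
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA)
  paths$design <- sim$counts$group
  paths
}

#' Run the full analysis end-to-end
#'
#' Stages execute in the pipeline's canonical order: identification cascade,
#' coding-potential consensus (channels trained on the annotated coding
#' transcripts vs the known-lncRNA database), sequence features, NB
#' differential expression (strict calls for lncRNAs, relaxed calls for
#' coding target candidates), cis and trans target linking, optional
#' enrichment and qPCR validation. All stage tables plus `manifest.json`
#' (config, seed, stage counts, output checksums) are written to
#' `config$outdir`.
#'
#' @param config [run_config()] object.
#' @return invisible list with the in-memory stage results.
#' @export
run_all <- function(config) {
  for (f in c("gtf", "fasta", "counts", "known_db"))
    if (!file.exists(config[[f]])) stop("missing input: ", config[[f]])
  th <- config$thresholds
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  tx <- read_gtf(config$gtf)
  seqs <- read_fasta(config$fasta)
  tx$sequence <- unname(seqs[tx$transcript_id])
  # reference-matching transcripts ("=") are the annotated coding set; they
  # double as the coding-potential training class
  tx$source <- ifelse(tx$class_code == "=", "annotated_coding", "candidate")
  tx <- transcripts(as.data.frame(tx))
  cm <- read_counts(config$counts, config$design)
  known_db <- read_fasta(config$known_db)
  log_stage <- function(...) message("[lnckit] ", ...)

  casc <- run_cascade(tx, cm, known_db, min_identity = th$min_identity,
                      min_coverage = th$min_coverage,
                      max_evalue = th$max_evalue)
  log_stage("cascade: ", nrow(tx), " transcripts -> ",
            nrow(casc$novel_candidates), " candidates + ",
            nrow(casc$known_lnc), " known lncRNAs")
  rep_df <- do.call(rbind, lapply(casc$reports, function(r)
    data.frame(stage = r$stage, n_in = r$n_in, n_out = r$n_out,
               n_removed = nrow(r$removed), stringsAsFactors = FALSE)))
  write_results(rep_df, file.path(config$outdir, "filter_report.tsv"))
  removed_df <- do.call(rbind, lapply(casc$reports, function(r) {
    if (nrow(r$removed) == 0) return(NULL)
    cbind(stage = r$stage, r$removed)
  }))
  if (!is.null(removed_df))
    write_results(removed_df, file.path(config$outdir, "filter_removed.tsv"))
  write_results(casc$matches, file.path(config$outdir, "known_lnc.tsv"))

  coding_train <- setNames(
    tx$sequence[tx$source == "annotated_coding"],
    tx$transcript_id[tx$source == "annotated_coding"])
  model <- train_codepot(coding_train, known_db,
                         folds = th$codepot_folds, seed = config$seed)
  cand_seqs <- setNames(casc$novel_candidates$sequence,
                        casc$novel_candidates$transcript_id)
  cons <- classify_consensus(
    cand_seqs, model,
    cpat_cutoff = if (th$use_trained_cutoff) NULL
                  else th$published_cpat_cutoff)
  write_results(cons, file.path(config$outdir, "coding_potential.tsv"))
  novel_lnc_ids <- cons$id[cons$verdict == "noncoding"]
  log_stage("coding potential: ", length(novel_lnc_ids),
            " putative lncRNAs of ", nrow(cons), " candidates (cutoff ",
            signif(model$cpat_cutoff, 3), ")")

  class_map <- setNames(rep("other", nrow(tx)), tx$transcript_id)
  class_map[tx$source == "annotated_coding"] <- "coding"
  class_map[casc$known_lnc$transcript_id] <- "known_lnc"
  class_map[novel_lnc_ids] <- "novel_lnc"
  ft_tx <- tx[class_map[tx$transcript_id] %in%
                c("coding", "known_lnc", "novel_lnc"), , drop = FALSE]
  ft <- feature_table(ft_tx, cm, class = class_map,
                      me_subsample = th$me_subsample, seed = config$seed)
  write_results(ft, file.path(config$outdir, "features.tsv"))
  cmp <- compare_classes(ft)
  write_results(cmp$summary, file.path(config$outdir, "feature_summary.tsv"))

  expressed <- filter_expression(cm, th$min_reads, th$min_samples)$retained
  cm_expr <- count_matrix(cm$counts[expressed, , drop = FALSE], cm$group,
                          cm$lib_sizes)
  de <- nb_wald_test(cm_expr)
  write_results(de, file.path(config$outdir, "de_results.tsv"))
  lnc_ids <- c(novel_lnc_ids, casc$known_lnc$transcript_id)
  de_lnc <- call_de(de[de$feature_id %in% lnc_ids, ], "strict")
  de_genes <- call_de(de[class_map[de$feature_id] == "coding", ], "relaxed")
  log_stage("DE: ", length(de_lnc$all), " lncRNAs (strict), ",
            length(de_genes$all), " coding genes (relaxed)")

  expr <- fpkm_matrix(cm, setNames(tx$length, tx$transcript_id))
  loci <- data.frame(
    gene_id = tx$gene_id, transcript_id = tx$transcript_id,
    chrom = tx$chrom,
    start = vapply(tx$exons, function(e) e[1, 1], integer(1)),
    end = vapply(tx$exons, function(e) e[nrow(e), 2], integer(1)),
    stringsAsFactors = FALSE)
  all_seqs <- setNames(tx$sequence, tx$transcript_id)
  cis <- link_targets(de_lnc$all, de_genes$all, expr, loci, "cis",
                      window = th$window, r_min = th$r_min,
                      p_max = th$r_p_max)
  trans <- link_targets(de_lnc$all, de_genes$all, expr, loci, "trans",
                        seqs = all_seqs, ndg_threshold = th$ndg_threshold,
                        min_run = th$ndg_min_run, r_min = th$r_min,
                        p_max = th$r_p_max)
  write_results(cis, file.path(config$outdir, "targets_cis.tsv"))
  write_results(trans, file.path(config$outdir, "targets_trans.tsv"))
  log_stage("targets: ", sum(cis$passed), " cis, ", sum(trans$passed),
            " trans links")

  enrich <- NULL
  if (!is.null(config$gmt) && file.exists(config$gmt)) {
    sets <- read_gmt(config$gmt)
    targets <- unique(c(cis$gene_id[cis$passed], trans$gene_id[trans$passed]))
    universe <- de$feature_id[class_map[de$feature_id] == "coding"]
    enrich <- hypergeom_enrich(intersect(targets, universe), universe, sets)
    write_results(enrich, file.path(config$outdir, "enrichment.tsv"))
  }

  qpcr <- NULL
  concord <- NULL
  if (!is.null(config$qpcr) && file.exists(config$qpcr)) {
    qt <- read.delim(config$qpcr, stringsAsFactors = FALSE)
    qpcr <- qpcr_analysis(qt)
    write_results(qpcr, file.path(config$outdir, "qpcr_summary.tsv"))
    concord <- concordance_report(setNames(de$log2fc, de$feature_id), qpcr)
    write_results(concord, file.path(config$outdir, "qpcr_concordance.tsv"))
  } else {
    log_stage("qPCR stage skipped (no table provided)")
  }

  tables <- list.files(config$outdir, pattern = "\\.tsv$")
  manifest <- list(
    package = "lnckit",
    version = as.character(utils::packageVersion("lnckit")),
    seed = config$seed,
    thresholds = th,
    inputs = config[c("gtf", "fasta", "counts", "known_db", "gmt", "qpcr")],
    qpcr_stage = if (is.null(qpcr)) "skipped" else "run",
    stage_counts = list(
      input_transcripts = nrow(tx),
      candidates = nrow(casc$novel_candidates),
      known_lnc = nrow(casc$known_lnc),
      putative_novel_lnc = length(novel_lnc_ids),
      de_lnc_strict = length(de_lnc$all),
      de_genes_relaxed = length(de_genes$all),
      cis_links = sum(cis$passed),
      trans_links = sum(trans$passed)),
    outputs = as.list(tools::md5sum(file.path(config$outdir, tables))))
  names(manifest$outputs) <- tables
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(list(cascade = casc, model = model, consensus = cons,
                 features = ft, summary = cmp, de = de, de_lnc = de_lnc,
                 de_genes = de_genes, cis = cis, trans = trans,
                 enrichment = enrich, qpcr = qpcr, concordance = concord,
                 manifest = manifest))
}
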