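# Domain containers and readers/writers for the formats the pipeline touches:
# GTF transcript models (cuffcompare-style class codes), FASTA sequences, TSV
# count matrices, GMT gene sets and TSV result tables.
#
# Internal coordinates are 0-based half-open; GTF I/O converts at the boundary
# (GTF is 1-based inclusive). Sequences are stored sense-strand.

#' Construct a transcript table
#'
#' A transcript table is a `data.frame` (class `lnc_transcripts`) with one row
#' per transcript and columns `transcript_id`, `gene_id`, `chrom`, `strand`
#' (`+`/`-`), `class_code` (single cuffcompare character), `exons` (list
#' column; each element a two-column integer matrix of 0-based half-open
#' `start`/`end` intervals, sorted and non-overlapping), `length` (sum of exon
#' widths), `n_exons`, `sequence` (sense-strand `ACGTN` string or `NA`) and
#' `source` (`annotated_coding`, `known_lnc` or `candidate`).
#'
#' @param df data.frame with the columns above (`length`/`n_exons` are
#'   recomputed from `exons`).
#' @return validated `lnc_transcripts` data.frame.
#' @export
transcripts <- function(df) {
  stopifnot(is.data.frame(df))
  need <- c("transcript_id", "gene_id", "chrom", "strand", "class_code",
            "exons")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) stop("missing columns: ", paste(miss, collapse = ", "))
  if (!all(df$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  if (anyDuplicated(df$transcript_id)) stop("duplicate transcript ids")
  df$exons <- lapply(df$exons, function(e) {
    e <- matrix(as.integer(e), ncol = 2,
                dimnames = list(NULL, c("start", "end")))
    e <- e[order(e[, 1]), , drop = FALSE]
    if (any(e[, 2] <= e[, 1])) stop("empty or inverted exon interval")
    if (nrow(e) > 1 && any(e[-1, 1] < e[-nrow(e), 2]))
      stop("overlapping exons within one transcript")
    e
  })
  df$length <- vapply(df$exons, function(e) sum(e[, 2] - e[, 1]), integer(1))
  df$n_exons <- vapply(df$exons, nrow, integer(1))
  if (is.null(df$sequence)) df$sequence <- rep(NA_character_, nrow(df))
  if (is.null(df$source)) df$source <- rep("candidate", nrow(df))
  has_seq <- !is.na(df$sequence)
  if (any(nchar(df$sequence[has_seq]) != df$length[has_seq]))
    stop("sequence length must equal the sum of exon lengths")
  class(df) <- c("lnc_transcripts", "data.frame")
  df
}

#' Read transcript models from a GTF file
#'
#' Exon rows are grouped per transcript and 1-based inclusive GTF coordinates
#' are converted to internal 0-based half-open intervals. Transcripts without
#' a `class_code` attribute receive class code `"u"` (intergenic).
#'
#' @param path GTF file path.
#' @return [transcripts()] table (no sequences).
#' @export
read_gtf <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  if (!any(keep)) {
    return(transcripts(data.frame(
      transcript_id = character(), gene_id = character(),
      chrom = character(), strand = character(), class_code = character(),
      exons = I(list()), stringsAsFactors = FALSE)))
  }
  for (ln in which(keep)) {
    f <- strsplit(lines[ln], "\t", fixed = TRUE)[[1]]
    if (length(f) < 9)
      stop("malformed GTF record (fewer than 9 fields) at line ", ln)
    if (!grepl("transcript_id \"[^\"]+\"", f[9]))
      stop("malformed attribute string (no transcript_id) at line ", ln)
  }
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  md <- S4Vectors::mcols(gr)
  tid <- as.character(md$transcript_id)
  gid <- as.character(md$gene_id)
  cc <- if ("class_code" %in% names(md)) as.character(md$class_code)
        else rep(NA_character_, length(gr))
  ord <- order(tid, GenomicRanges::start(gr))
  gr <- gr[ord]; tid <- tid[ord]; gid <- gid[ord]; cc <- cc[ord]
  idx <- split(seq_along(gr), tid)
  rows <- lapply(idx, function(ii) {
    chrom <- unique(as.character(GenomicRanges::seqnames(gr[ii])))
    if (length(chrom) != 1)
      stop("transcript ", tid[ii[1]], " has exons on multiple chromosomes")
    strand <- unique(as.character(BiocGenerics::strand(gr[ii])))
    if (length(strand) != 1 || !strand %in% c("+", "-"))
      stop("transcript ", tid[ii[1]], " lacks a single +/- strand")
    code <- unique(cc[ii]); code <- code[!is.na(code)]
    list(transcript_id = tid[ii[1]], gene_id = gid[ii[1]], chrom = chrom,
         strand = strand,
         class_code = if (length(code) >= 1) code[1] else "u",
         exons = cbind(start = GenomicRanges::start(gr[ii]) - 1L,
                       end = GenomicRanges::end(gr[ii])))
  })
  transcripts(data.frame(
    transcript_id = vapply(rows, `[[`, "", "transcript_id"),
    gene_id = vapply(rows, `[[`, "", "gene_id"),
    chrom = vapply(rows, `[[`, "", "chrom"),
    strand = vapply(rows, `[[`, "", "strand"),
    class_code = vapply(rows, `[[`, "", "class_code"),
    exons = I(unname(lapply(rows, `[[`, "exons"))),
    stringsAsFactors = FALSE, row.names = NULL))
}

#' Write transcript models to a GTF file
#'
#' Inverse of [read_gtf()]: internal 0-based half-open exons become 1-based
#' inclusive GTF rows carrying `transcript_id`, `gene_id` and `class_code`
#' attributes.
#'
#' @param tx [transcripts()] table.
#' @param path output path.
#' @export
write_gtf <- function(tx, path) {
  if (nrow(tx) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  n_ex <- vapply(tx$exons, nrow, integer(1))
  gr <- GenomicRanges::GRanges(
    seqnames = rep(tx$chrom, n_ex),
    ranges = IRanges::IRanges(
      start = unlist(lapply(tx$exons, function(e) e[, 1])) + 1L,
      end = unlist(lapply(tx$exons, function(e) e[, 2]))),
    strand = rep(tx$strand, n_ex))
  S4Vectors::mcols(gr)$source <- "lnckit"
  S4Vectors::mcols(gr)$type <- "exon"
  S4Vectors::mcols(gr)$transcript_id <- rep(tx$transcript_id, n_ex)
  S4Vectors::mcols(gr)$gene_id <- rep(tx$gene_id, n_ex)
  S4Vectors::mcols(gr)$class_code <- rep(tx$class_code, n_ex)
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Construct a count matrix with its two-group design
#'
#' @param counts non-negative integer matrix, features x samples.
#' @param group named character vector mapping every sample (column) to
#'   `"pigmented"` or `"unpigmented"`.
#' @param lib_sizes optional per-sample totals of mapped reads (> 0); default
#'   column sums.
#' @return `lnc_counts` object (list with `counts`, `group`, `lib_sizes`).
#' @export
count_matrix <- function(counts, group, lib_sizes = NULL) {
  counts <- as.matrix(counts)
  if ((nrow(counts) > 0 && is.null(rownames(counts))) ||
      is.null(colnames(counts)))
    stop("counts must have feature rownames and sample colnames")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  storage.mode(counts) <- "integer"
  miss <- setdiff(colnames(counts), names(group))
  if (length(miss) > 0)
    stop("samples missing from design: ", paste(miss, collapse = ", "))
  group <- group[colnames(counts)]
  if (!all(group %in% c("pigmented", "unpigmented")))
    stop("groups must be 'pigmented' or 'unpigmented'")
  if (is.null(lib_sizes)) lib_sizes <- colSums(counts)
  lib_sizes <- lib_sizes[colnames(counts)] %||% lib_sizes
  if (any(lib_sizes <= 0)) stop("library sizes must be > 0")
  structure(list(counts = counts, group = group,
                 lib_sizes = setNames(as.numeric(lib_sizes),
                                      colnames(counts))),
            class = "lnc_counts")
}

#' @export
print.lnc_counts <- function(x, ...) {
  cat("count matrix:", nrow(x$counts), "features x", ncol(x$counts),
      "samples (", sum(x$group == "pigmented"), "pigmented /",
      sum(x$group == "unpigmented"), "unpigmented )\n")
  invisible(x)
}

#' Read a count matrix from TSV
#'
#' First column is the feature id; remaining columns are integer counts.
#'
#' @param path TSV path.
#' @param design named vector sample -> group (`pigmented`/`unpigmented`).
#' @param lib_sizes optional per-sample library sizes.
#' @return [count_matrix()] object.
#' @export
read_counts <- function(path, design, lib_sizes = NULL) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("count columns must be numeric")
  if (any(m < 0)) stop("negative count entry")
  if (any(m != round(m))) stop("non-integer count entry")
  rownames(m) <- ids
  count_matrix(m, design, lib_sizes)
}

#' Write a count matrix to TSV
#' @param cm [count_matrix()] object.
#' @param path output path.
#' @export
write_counts <- function(cm, path) {
  df <- data.frame(feature_id = rownames(cm$counts), cm$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read FASTA sequences
#'
#' Sequences are uppercased and `U` is normalized to `T`; only `ACGTN` symbols
#' are accepted. Duplicate ids are an error.
#'
#' @param path FASTA path.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids)) stop("duplicate FASTA ids: ",
                               paste(unique(ids[duplicated(ids)]),
                                     collapse = ", "))
  seqs <- chartr("U", "T", toupper(as.character(ss)))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) stop("non-ACGTN symbols in FASTA records: ",
                     paste(ids[bad], collapse = ", "))
  setNames(seqs, ids)
}

#' Write FASTA sequences
#' @param seqs named character vector.
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path, width = 70)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Each line is `set_id <TAB> description <TAB> member1 <TAB> member2 ...`.
#'
#' @param path GMT path.
#' @return list of gene sets, each a list with `set_id`, `name`, `members`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stop("GMT line ", i, " has fewer than 3 fields")
    members <- unique(f[-(1:2)])
    list(set_id = f[1], name = f[2], members = members)
  })
  ids <- vapply(sets, `[[`, "", "set_id")
  if (anyDuplicated(ids)) stop("duplicate gene-set ids in GMT")
  sets
}

#' Write gene sets to a GMT file
#' @param sets list of gene sets as returned by [read_gmt()].
#' @param path output path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(sets, function(s)
    paste(c(s$set_id, s$name, s$members), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Write a result table to TSV
#' @param table data.frame.
#' @param path output path.
#' @export
write_results <- function(table, path) {
  table <- as.data.frame(table)
  listcols <- vapply(table, is.list, logical(1))
  table <- table[, !listcols, drop = FALSE]
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
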