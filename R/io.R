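# Readers and writers for the plain-text interchange formats: BED12 gene
# models, BED6 TE intervals, tab-delimited CpG call tables (1-based
# positions), TSV expression matrices and per-gene tables. BED files are
# 0-based half-open on disk and converted to 1-based GRanges on read.

#' Write gene models as BED12
#'
#' One BED12 line per transcript (single-block), `name` holding
#' `gene_id|tx_id`.
#'
#' @param transcripts `GRanges` with `gene_id`/`tx_id` metadata.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gene_models_bed12 <- function(transcripts, path) {
  mc <- S4Vectors::mcols(transcripts)
  start0 <- GenomicRanges::start(transcripts) - 1L
  end0 <- GenomicRanges::end(transcripts)
  d <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(transcripts)),
    start = start0, end = end0,
    name = paste0(mc$gene_id, "|", mc$tx_id),
    score = 0L,
    strand = as.character(GenomicRanges::strand(transcripts)),
    thickStart = start0, thickEnd = end0, itemRgb = 0L,
    blockCount = 1L, blockSizes = paste0(end0 - start0, ","),
    blockStarts = "0,",
    stringsAsFactors = FALSE
  )
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read gene models (BED12 or tab-delimited RefSeq-like)
#'
#' BED12 input (12 columns, no header) must carry `gene_id|tx_id` in the
#' name field. Tab-delimited input must have a header with columns
#' `chrom`, `strand`, `txStart`, `txEnd`, `gene_id`, `tx_id`
#' (`txStart`/`txEnd` 0-based half-open).
#'
#' @param path input file.
#' @return `GRanges` of transcripts with `gene_id`/`tx_id` metadata.
#' @export
read_gene_models <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\\btxStart\\b", first)) {
    d <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
    gr <- GenomicRanges::GRanges(
      d$chrom, IRanges::IRanges(d$txStart + 1L, d$txEnd), d$strand)
    S4Vectors::mcols(gr)$gene_id <- d$gene_id
    S4Vectors::mcols(gr)$tx_id <- d$tx_id
    return(gr)
  }
  d <- read.table(path, header = FALSE, sep = "\t",
                  stringsAsFactors = FALSE)
  if (ncol(d) < 12L) stop("expected BED12 or a header with txStart/txEnd",
                          call. = FALSE)
  ids <- strsplit(d[[4]], "|", fixed = TRUE)
  gr <- GenomicRanges::GRanges(
    d[[1]], IRanges::IRanges(d[[2]] + 1L, d[[3]]), d[[6]])
  S4Vectors::mcols(gr)$gene_id <- vapply(ids, `[`, "", 1L)
  S4Vectors::mcols(gr)$tx_id <- vapply(ids, `[`, "", 2L)
  gr
}

#' Write intervals as BED6
#' @param gr `GRanges`.
#' @param path output file.
#' @param name feature name column (recycled).
#' @return `path`, invisibly.
#' @export
write_bed6 <- function(gr, path, name = "TE") {
  d <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    name = rep_len(name, length(gr)),
    score = 0L,
    strand = ".",
    stringsAsFactors = FALSE
  )
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a BED file (first 3-6 columns) into a GRanges
#' @param path BED file (0-based half-open).
#' @return `GRanges`.
#' @export
read_bed6 <- function(path) {
  d <- read.table(path, header = FALSE, sep = "\t",
                  stringsAsFactors = FALSE)
  if (nrow(d) == 0L) return(GenomicRanges::GRanges())
  strand <- if (ncol(d) >= 6L) ifelse(d[[6]] %in% c("+", "-"), d[[6]], "*")
            else "*"
  GenomicRanges::GRanges(d[[1]], IRanges::IRanges(d[[2]] + 1L, d[[3]]),
                         strand)
}

#' Write a CpG call table
#'
#' Tab-delimited with header: `chrom`, `pos` (1-based), `strand`,
#' `c_reads`, `t_reads`.
#'
#' @param calls data.frame of calls.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_cpg_calls <- function(calls, path) {
  write.table(calls[c("chrom", "pos", "strand", "c_reads", "t_reads")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a CpG call table (see [write_cpg_calls()] for the dialect)
#' @param path input file.
#' @return data.frame of calls.
#' @export
read_cpg_calls <- function(path) {
  d <- read.table(path, header = TRUE, sep = "\t",
                  stringsAsFactors = FALSE)
  req <- c("chrom", "pos", "strand", "c_reads", "t_reads")
  if (!all(req %in% names(d))) {
    stop("CpG call file needs columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  d
}

#' Write / read a genes-by-arrays matrix as TSV
#' @param mat numeric matrix with gene rownames and array colnames.
#' @param path file path.
#' @return `path` (writer) or the matrix (reader).
#' @export
write_matrix_tsv <- function(mat, path) {
  d <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE,
                  stringsAsFactors = FALSE)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  d <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                  stringsAsFactors = FALSE)
  mat <- as.matrix(d[, -1, drop = FALSE])
  rownames(mat) <- d[[1]]
  mat
}

#' Write / read a plain per-gene TSV table
#' @param d data.frame.
#' @param path file path.
#' @return `path` (writer) or the data.frame (reader).
#' @export
write_table_tsv <- function(d, path) {
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_table_tsv
#' @export
read_table_tsv <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
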