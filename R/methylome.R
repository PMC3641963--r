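#' Per-site fractional methylation
#'
#' The fractional methylation of a cytosine is the number of methylated
#' ('C') reads divided by the total number of reads
#' (`c / (c + t)`). Sites whose total coverage falls below `min_coverage`
#' (or with zero reads) get `NA` — they are dropped from aggregation, not
#' treated as errors.
#'
#' @param c_reads,t_reads non-negative integer vectors of 'C' and 'T' read
#'   counts.
#' @param min_coverage minimum total reads for a site to be usable
#'   (default 1).
#' @return numeric vector of fractions in `[0, 1]`, `NA` where coverage is
#'   insufficient.
#' @export
#' @examples
#' fractional_methylation(c(3, 0, 0), c(1, 5, 0))  # 0.75, 0, NA
fractional_methylation <- function(c_reads, t_reads, min_coverage = 1L) {
  if (any(c_reads < 0, na.rm = TRUE) || any(t_reads < 0, na.rm = TRUE)) {
    stop("read counts must be non-negative", call. = FALSE)
  }
  total <- c_reads + t_reads
  out <- ifelse(total >= max(1L, min_coverage), c_reads / total, NA_real_)
  as.numeric(out)
}

#' Select the longest transcript per gene
#'
#' When a gene has alternative transcripts, its transcription unit is taken
#' to be the longest transcript. Equal lengths are broken deterministically
#' by the lexicographically smallest transcript id.
#'
#' @param transcripts `GRanges` with metadata columns `gene_id` and `tx_id`.
#' @return `GRanges` with one range per gene (the gene body), ordered by
#'   `gene_id`.
#' @export
select_longest_transcript <- function(transcripts) {
  stopifnot(is(transcripts, "GRanges"))
  mc <- S4Vectors::mcols(transcripts)
  if (is.null(mc$gene_id) || is.null(mc$tx_id)) {
    stop("'transcripts' needs 'gene_id' and 'tx_id' metadata columns",
         call. = FALSE)
  }
  if (length(transcripts) == 0L) {
    stop("empty transcript set", call. = FALSE)
  }
  ord <- order(mc$gene_id, -GenomicRanges::width(transcripts), mc$tx_id)
  x <- transcripts[ord]
  x[!duplicated(S4Vectors::mcols(x)$gene_id)]
}

#' Promoter window around the transcription start site
#'
#' The promoter is the region spanning 1,500 bp upstream and 500 bp
#' downstream of the TSS (strand-aware: for minus-strand genes the TSS is
#' the higher-coordinate transcript end). Windows are clipped at the
#' chromosome start.
#'
#' @param models `GRanges` of gene bodies (one per gene) with known strand.
#' @param upstream,downstream window extent in bases.
#' @return `GRanges` of promoter windows, same order and metadata as
#'   `models`.
#' @export
promoter_interval <- function(models, upstream = 1500L, downstream = 500L) {
  stopifnot(is(models, "GRanges"))
  if (any(as.character(GenomicRanges::strand(models)) == "*")) {
    stop("strand must be '+' or '-' for every gene model", call. = FALSE)
  }
  p <- GenomicRanges::promoters(models, upstream = upstream,
                                downstream = downstream)
  # clip at chromosome start (position 1)
  GenomicRanges::start(p) <- pmax(1L, GenomicRanges::start(p))
  p
}

#' Partition a gene body into TE and non-TE parts
#'
#' Overlapping TE records are merged first; the body is then split into the
#' portion covered by TEs and the remainder. The two parts partition the
#' body base set exactly.
#'
#' @param body `GRanges` of one gene body (may hold several intervals).
#' @param tes `GRanges` of TE intervals on the same chromosome.
#' @return list with `non_te` and `te` `GRanges`.
#' @export
mask_te <- function(body, tes) {
  stopifnot(is(body, "GRanges"), is(tes, "GRanges"))
  if (any(GenomicRanges::width(body) < 1L) ||
      any(GenomicRanges::width(tes) < 1L)) {
    stop("malformed interval: start must precede end", call. = FALSE)
  }
  tes <- GenomicRanges::reduce(tes)
  te_part <- GenomicRanges::intersect(body, tes, ignore.strand = TRUE)
  non_te <- GenomicRanges::setdiff(body, tes, ignore.strand = TRUE)
  list(non_te = non_te, te = te_part)
}

#' Aggregate per-site fractional methylation over features
#'
#' The methylation of a feature is the unweighted arithmetic mean of the
#' per-site fractional values of all covered CpGs falling inside it; the
#' number of contributing sites is reported alongside. Features with no
#' covered site get `NA`.
#'
#' @param calls CpG call data.frame (`chrom`, `pos`, `strand`, `c_reads`,
#'   `t_reads`).
#' @param features `GRanges` with a `feature_id` (or `gene_id`) metadata
#'   column; several intervals may share one id.
#' @param min_coverage minimum site coverage (see
#'   [fractional_methylation()]).
#' @return data.frame: `feature_id`, `meth` (mean fraction or `NA`),
#'   `n_sites`.
#' @export
aggregate_feature <- function(calls, features, min_coverage = 1L) {
  stopifnot(is(features, "GRanges"))
  mc <- S4Vectors::mcols(features)
  fid <- if (!is.null(mc$feature_id)) mc$feature_id else mc$gene_id
  if (is.null(fid)) {
    stop("'features' needs a 'feature_id' or 'gene_id' metadata column",
         call. = FALSE)
  }
  sites <- cpg_granges(calls, min_coverage = min_coverage)
  ov <- GenomicRanges::findOverlaps(sites, features, ignore.strand = TRUE)
  frac <- S4Vectors::mcols(sites)$frac[S4Vectors::queryHits(ov)]
  grp <- fid[S4Vectors::subjectHits(ov)]
  ids <- unique(fid)
  if (length(grp)) {
    sums <- tapply(frac, factor(grp, levels = ids), sum)
    ns <- tapply(frac, factor(grp, levels = ids), length)
  } else {
    sums <- setNames(rep(NA_real_, length(ids)), ids)
    ns <- setNames(rep(0L, length(ids)), ids)
  }
  ns[is.na(ns)] <- 0L
  data.frame(
    feature_id = ids,
    meth = as.numeric(ifelse(ns > 0, sums / ns, NA_real_)),
    n_sites = as.integer(ns),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

# Covered CpG calls as a GRanges with a per-site fractional value.
cpg_granges <- function(calls, min_coverage = 1L) {
  req <- c("chrom", "pos", "strand", "c_reads", "t_reads")
  if (!all(req %in% names(calls))) {
    stop("calls need columns: ", paste(req, collapse = ", "), call. = FALSE)
  }
  frac <- fractional_methylation(calls$c_reads, calls$t_reads, min_coverage)
  keep <- !is.na(frac)
  gr <- GenomicRanges::GRanges(
    seqnames = calls$chrom[keep],
    ranges = IRanges::IRanges(start = calls$pos[keep], width = 1L),
    strand = calls$strand[keep]
  )
  S4Vectors::mcols(gr)$frac <- frac[keep]
  gr
}

#' Per-gene feature methylation from CpG calls
#'
#' The full methylome summarisation: selects the longest transcript of each
#' gene as its transcription unit, masks merged TE intervals out of gene
#' bodies, builds strand-aware promoter windows (not TE-masked), and
#' averages per-site fractional methylation within each feature. CpGs on
#' either strand are treated as independent sites.
#'
#' @param calls CpG call data.frame (`chrom`, `pos`, `strand`, `c_reads`,
#'   `t_reads`; 1-based positions).
#' @param transcripts `GRanges` of transcripts with `gene_id`/`tx_id`
#'   metadata.
#' @param tes `GRanges` of TE intervals (merged internally).
#' @param min_coverage minimum reads for a site to contribute.
#' @return data.frame with one row per gene: `gene_id`, `body_meth`
#'   (non-TE body), `body_n`, `te_meth` (TE portion of the body), `te_n`,
#'   `promoter_meth`, `promoter_n`.
#' @export
feature_methylation <- function(calls, transcripts, tes, min_coverage = 1L) {
  models <- select_longest_transcript(transcripts)
  ids <- S4Vectors::mcols(models)$gene_id
  proms <- promoter_interval(models)
  tes <- GenomicRanges::reduce(tes)
  sites <- cpg_granges(calls, min_coverage = min_coverage)
  in_te <- IRanges::overlapsAny(sites, tes, ignore.strand = TRUE)

  agg <- function(sub_sites, regions) {
    ov <- GenomicRanges::findOverlaps(sub_sites, regions,
                                      ignore.strand = TRUE)
    frac <- S4Vectors::mcols(sub_sites)$frac[S4Vectors::queryHits(ov)]
    grp <- factor(ids[S4Vectors::subjectHits(ov)], levels = ids)
    sums <- tapply(frac, grp, sum)
    ns <- tapply(frac, grp, length)
    ns[is.na(ns)] <- 0L
    list(meth = as.numeric(ifelse(ns > 0, sums / ns, NA_real_)),
         n = as.integer(ns))
  }

  body <- agg(sites[!in_te], models)
  te <- agg(sites[in_te], models)
  prom <- agg(sites, proms)

  data.frame(
    gene_id = ids,
    body_meth = body$meth, body_n = body$n,
    te_meth = te$meth, te_n = te$n,
    promoter_meth = prom$meth, promoter_n = prom$n,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}
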