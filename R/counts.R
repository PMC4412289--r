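# Containers and I/O for gene-level count matrices and per-SNP allele counts,
# plus the SNP-quality and gene-informativeness rules applied before any
# allelic test.

# quality-flag vocabulary for per-SNP allele records; any flagged SNP is
# removed wholesale before aggregation
.FLAGS <- c("third_allele", "repeat_region", "near_indel",
            "exon_intron_junction", "non_monoallelic_parent")

#' Quality-flag vocabulary for SNP allele records
#'
#' @return Character vector of the recognised per-SNP quality flags.
#' @export
snp_flag_vocabulary <- function() .FLAGS

#' Construct a gene x sample count matrix with sample metadata
#'
#' @param counts Integer matrix, genes in rows (rownames = gene ids), samples
#'   in columns (colnames = sample ids).
#' @param samples Data frame with columns `sample`, `group` (strain or F1
#'   cross), `condition` (`"control"` or `"TM"`) and `replicate`; one row per
#'   column of `counts`.
#' @param norm_factors Optional per-sample normalization factors (default 1).
#' @return An object of class `gene_counts`.
#' @export
gene_counts <- function(counts, samples, norm_factors = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have gene rownames and sample colnames")
  if (anyDuplicated(rownames(counts)))
    stop("schema error: duplicate gene id in counts")
  if (any(is.na(counts)) || any(counts < 0))
    stop("schema error: counts must be non-negative")
  if (any(counts != round(counts)))
    stop("schema error: counts must be integers")
  required <- c("sample", "group", "condition", "replicate")
  if (!all(required %in% names(samples)))
    stop("sample metadata needs columns: ", paste(required, collapse = ", "))
  missing <- setdiff(colnames(counts), samples$sample)
  if (length(missing))
    stop("schema error: samples without metadata: ",
         paste(missing, collapse = ", "))
  if (!all(samples$condition %in% c("control", "TM")))
    stop("condition must be 'control' or 'TM'")
  samples <- samples[match(colnames(counts), samples$sample), , drop = FALSE]
  rownames(samples) <- NULL
  if (is.null(norm_factors)) norm_factors <- rep(1, ncol(counts))
  if (length(norm_factors) != ncol(counts) || any(norm_factors <= 0))
    stop("norm_factors must be positive, one per sample")
  structure(list(counts = counts, samples = samples,
                 norm_factors = as.numeric(norm_factors)),
            class = "gene_counts")
}

#' @export
print.gene_counts <- function(x, ...) {
  cat(sprintf("gene_counts: %d genes x %d samples (%d groups, conditions: %s)\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$samples$group)),
              paste(unique(x$samples$condition), collapse = "/")))
  invisible(x)
}

.write_tsv <- function(df, path, comments = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (cm in comments) writeLines(paste0("# ", cm), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

.provenance <- function(extra = character()) {
  c(sprintf("stressdiv %s",
            as.character(utils::packageVersion("stressdiv"))), extra)
}

# accept non-negative decimals (averaged maternal/paternal alignments) by
# flooring, with a warning
.floor_counts <- function(x, what) {
  if (any(x < 0, na.rm = TRUE)) stop("schema error: negative ", what)
  if (any(x != floor(x), na.rm = TRUE)) {
    warning("non-integer ", what, " floored (averaged-alignment input)")
    x <- floor(x)
  }
  x
}

#' Write / read a gene x sample count matrix with its sample metadata
#'
#' The counts file is TSV with `#` comment headers, a `gene` column and one
#' column per sample; metadata is a TSV with columns sample/group/condition/
#' replicate.
#'
#' @param x A `gene_counts` object.
#' @param path,metadata_path File paths for counts and sample metadata.
#' @param comments Extra provenance comment lines for the file header.
#' @return `write_counts` returns `path` invisibly; `read_counts` returns a
#'   validated `gene_counts` object.
#' @export
write_counts <- function(x, path, metadata_path, comments = character()) {
  stopifnot(inherits(x, "gene_counts"))
  df <- data.frame(gene = rownames(x$counts), x$counts,
                   check.names = FALSE, row.names = NULL)
  .write_tsv(df, path, .provenance(comments))
  .write_tsv(x$samples, metadata_path, .provenance(comments))
  invisible(path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path, metadata_path) {
  tab <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (names(tab)[1L] != "gene") stop("schema error: first column must be 'gene'")
  meta <- utils::read.delim(metadata_path, comment.char = "#",
                            stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("schema error: non-numeric counts")
  m <- .floor_counts(m, "counts")
  rownames(m) <- tab$gene
  gene_counts(m, meta)
}

#' Write / read per-SNP allele-count records
#'
#' One row per gene x SNP x sample with maternal (reference) and paternal
#' counts; `flags` holds semicolon-separated quality-flag tokens (empty when
#' clean). On read, sample metadata is joined so each record carries its
#' cross, condition and replicate.
#'
#' @param records Data frame of SNP allele records.
#' @param path File path.
#' @param metadata Sample metadata data frame (as in [gene_counts()]).
#' @param comments Extra provenance comment lines.
#' @export
write_snp_records <- function(records, path, comments = character()) {
  cols <- c("gene", "snp_id", "position", "sample",
            "maternal_count", "paternal_count", "flags")
  stopifnot(all(cols %in% names(records)))
  .write_tsv(records[cols], path, .provenance(comments))
  invisible(path)
}

#' @rdname write_snp_records
#' @export
read_snp_records <- function(path, metadata) {
  rec <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE)
  cols <- c("gene", "snp_id", "position", "sample",
            "maternal_count", "paternal_count", "flags")
  if (!all(cols %in% names(rec)))
    stop("schema error: SNP record file needs columns: ",
         paste(cols, collapse = ", "))
  rec$flags[is.na(rec$flags)] <- ""
  rec$maternal_count <- .floor_counts(rec$maternal_count, "allele counts")
  rec$paternal_count <- .floor_counts(rec$paternal_count, "allele counts")
  if (any(rec$position < 1)) stop("schema error: positions are 1-based")
  toks <- unique(unlist(strsplit(rec$flags[rec$flags != ""], ";", fixed = TRUE)))
  if (length(setdiff(toks, .FLAGS)))
    stop("schema error: unknown quality flag(s): ",
         paste(setdiff(toks, .FLAGS), collapse = ", "))
  missing <- setdiff(unique(rec$sample), metadata$sample)
  if (length(missing))
    stop("schema error: samples without metadata: ",
         paste(missing, collapse = ", "))
  i <- match(rec$sample, metadata$sample)
  rec$cross <- metadata$group[i]
  rec$condition <- metadata$condition[i]
  rec$replicate <- metadata$replicate[i]
  rec
}

#' Filter SNP allele records on coverage and quality flags
#'
#' Removes (i) every record whose per-sample coverage (maternal + paternal) is
#' below 4 reads, and (ii) every record of any SNP that carries a quality flag
#' in any sample (flag filtering is per SNP, coverage filtering per record).
#' Idempotent; an empty result is allowed.
#'
#' @param records SNP allele records (see [read_snp_records()]).
#' @param min_coverage Per-record coverage floor (default 4).
#' @return The surviving records.
#' @export
filter_snps <- function(records, min_coverage = 4) {
  if (nrow(records) == 0L) return(records)
  key <- paste(records$gene, records$snp_id, sep = "\r")
  flagged <- unique(key[records$flags != ""])
  keep <- !(key %in% flagged) &
    (records$maternal_count + records$paternal_count) >= min_coverage
  records[keep, , drop = FALSE]
}

#' Aggregate filtered SNP records to per-gene allele totals
#'
#' Sums maternal and paternal counts over surviving SNPs per gene, cross and
#' condition, pooling replicates by default; `n_snps` counts the distinct
#' surviving SNPs contributing to the total.
#'
#' @param records Filtered SNP allele records (with `cross`, `condition`,
#'   `replicate` columns).
#' @param pool_replicates Pool replicates within a condition (default TRUE,
#'   the analysis mode); if FALSE one row per replicate is returned.
#' @return Data frame with columns gene, cross, condition (and replicate when
#'   not pooling), maternal_total, paternal_total, n_snps.
#' @export
aggregate_gene_allele_counts <- function(records, pool_replicates = TRUE) {
  need <- c("gene", "cross", "condition", "snp_id",
            "maternal_count", "paternal_count")
  stopifnot(all(need %in% names(records)))
  byvars <- c("gene", "cross", "condition",
              if (!pool_replicates) "replicate")
  if (nrow(records) == 0L) {
    out <- stats::setNames(
      as.data.frame(matrix(nrow = 0, ncol = length(byvars) + 3L)),
      c(byvars, "maternal_total", "paternal_total", "n_snps"))
    return(out)
  }
  key <- do.call(paste, c(records[byvars], sep = "\r"))
  mat <- rowsum(records$maternal_count, key)
  pat <- rowsum(records$paternal_count, key)
  nsnp <- vapply(split(records$snp_id, key),
                 function(s) length(unique(s)), integer(1))
  keys <- rownames(mat)
  parts <- do.call(rbind, strsplit(keys, "\r", fixed = TRUE))
  out <- stats::setNames(as.data.frame(parts, stringsAsFactors = FALSE), byvars)
  out$maternal_total <- as.integer(mat[, 1L])
  out$paternal_total <- as.integer(pat[, 1L])
  out$n_snps <- as.integer(nsnp[keys])
  if (!pool_replicates) out$replicate <- as.integer(out$replicate)
  rownames(out) <- NULL
  out[order(out$gene, out$cross, out$condition), , drop = FALSE]
}

#' Informative genes for allelic analysis
#'
#' A gene is informative when it has at least two surviving discriminating
#' SNPs and pooled allelic coverage above the purpose-specific floor (strictly
#' greater than 20 reads for cis/trans analysis, 50 for ASE analysis) in every
#' condition present in the table.
#'
#' @param gac Aggregated allele counts (replicates pooled) for one cross.
#' @param purpose `"cistrans"` or `"ase"`.
#' @return Character vector of informative gene ids.
#' @export
informative_genes <- function(gac, purpose = c("cistrans", "ase")) {
  purpose <- match.arg(purpose)
  floor_cov <- if (purpose == "cistrans") 20 else 50
  if (nrow(gac) == 0L) return(character(0))
  ok <- gac$n_snps >= 2 &
    (gac$maternal_total + gac$paternal_total) > floor_cov
  conditions <- unique(gac$condition)
  per_gene <- rowsum(as.integer(ok), gac$gene)
  n_cond <- rowsum(rep(1L, nrow(gac)), gac$gene)
  # a gene must qualify in every analyzed condition
  genes <- rownames(per_gene)[per_gene[, 1L] == length(conditions) &
                                n_cond[, 1L] == length(conditions)]
  sort(genes)
}
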