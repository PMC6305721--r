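#' Contig-level RPKM from mapped-read counts
#'
#' Reads Per Kilobase per Million mapped reads:
#' `RPKM(c, s) = count(c, s) / ((length_bp(c) / 1000) * (total(s) / 1e6))`.
#' By default `total(s)` is the number of reads mapped to the contig
#' database in sample `s` (the column sum); an externally measured
#' per-sample total (e.g. library size) can be supplied instead.
#'
#' @param contigs a `contig_table` as produced by [generate_contig_data()]
#'   or read from TSV: columns `contig_id`, `length_bp`, `taxon`, then one
#'   count column per sample.
#' @param sample_totals optional named numeric vector of per-sample read
#'   totals overriding the column sums.
#' @return numeric matrix contigs x samples of RPKM values.
#' @examples
#' ct <- data.frame(contig_id = "c1", length_bp = 2000L, taxon = "vA",
#'                  s1 = 100L)
#' compute_rpkm(ct, sample_totals = c(s1 = 1e6))  # 50
#' @export
compute_rpkm <- function(contigs, sample_totals = NULL) {
  counts <- contig_counts(contigs)
  if (any(counts < 0)) stop("negative read counts")
  if (any(contigs$length_bp < 1)) stop("contig lengths must be >= 1 bp")
  totals <- if (is.null(sample_totals)) colSums(counts)
            else sample_totals[colnames(counts)]
  if (anyNA(totals)) stop("sample_totals missing for some samples")
  zero <- totals == 0
  if (any(zero))
    stop("zero total mapped reads in sample(s): ",
         paste(colnames(counts)[zero], collapse = ", "))
  sweep(counts / (contigs$length_bp / 1000), 2, totals / 1e6, "/")
}

#' Taxon-level relative abundance from contig RPKM
#'
#' For each taxon the arithmetic mean RPKM over its contigs is taken, then
#' each sample's taxon vector is closed to relative abundances summing to
#' one. Samples whose taxon vector is entirely zero are flagged via the
#' `zero_samples` attribute of the result and should be excluded from
#' distance-based stages.
#'
#' @param rpkm contig x sample RPKM matrix from [compute_rpkm()].
#' @param taxon character vector mapping each contig (row) to its taxon.
#' @param kind taxon kind tag for the resulting table.
#' @return an [abundance_table()] (taxa x samples).
#' @export
taxon_relative_abundance <- function(rpkm, taxon, kind = "virus") {
  if (length(taxon) != nrow(rpkm))
    stop("need exactly one taxon annotation per contig")
  if (anyNA(taxon) || any(!nzchar(taxon)))
    stop("contigs with unknown taxon mapping")
  sums <- rowsum(rpkm, group = taxon)
  means <- sums / as.vector(table(taxon)[rownames(sums)])
  abundance_table(means[order(rownames(means)), , drop = FALSE],
                  kind = kind, renormalize = TRUE)
}

#' Read a contig table from TSV
#'
#' Expects header `contig_id  length_bp  taxon  <sample ids...>` with
#' integer non-negative counts.
#' @param path file path.
#' @return a `data.frame` of class `contig_table`.
#' @export
read_contig_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("contig_id", "length_bp", "taxon")
  if (!all(need %in% colnames(df)[1:3]))
    stop("malformed contig TSV: expected columns ", paste(need, collapse = ", "))
  if (anyDuplicated(df$contig_id)) stop("duplicate contig ids in ", path)
  class(df) <- c("contig_table", "data.frame")
  df
}

#' @param contigs the table to serialize.
#' @rdname read_contig_table
#' @export
write_contig_table <- function(contigs, path) {
  utils::write.table(contigs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
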