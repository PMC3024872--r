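#' Compute RPKM
#'
#' Reads Per Kilobase of exon model per Million mapped reads:
#' `1e9 * mapped_reads / (total_mapped_reads * exon_model_length_nt)`.
#' Vectorised over its arguments.
#'
#' @param mapped_reads Reads mapped to the gene's exon model (>= 0).
#' @param exon_model_length_nt Exon model length in nucleotides (> 0).
#' @param total_mapped_reads Total mapped reads in the library (> 0).
#' @return Numeric RPKM values.
#' @examples
#' compute_rpkm(1000, 2000, 1e7)  # 50
#' @export
compute_rpkm <- function(mapped_reads, exon_model_length_nt,
                         total_mapped_reads) {
  if (any(exon_model_length_nt <= 0)) stop("exon model length must be > 0")
  if (any(total_mapped_reads <= 0)) stop("total mapped reads must be > 0")
  if (any(mapped_reads < 0)) stop("mapped reads must be >= 0")
  1e9 * mapped_reads / (total_mapped_reads * exon_model_length_nt)
}

#' Read an expression table and attach MS detection status
#'
#' The expression TSV must have header columns `gene_id`,
#' `exon_model_length_nt`, `mapped_reads`, `total_mapped_reads` (RPKM is
#' recomputed from these); the optional detection TSV has `gene_id`,
#' `spectral_count`. Genes absent from the detection table get spectral
#' count 0 and `detected_by_ms = FALSE`.
#'
#' @param expr_path Expression TSV path.
#' @param detect_path Optional detection TSV path.
#' @return A data frame of expression records.
#' @export
read_expression_table <- function(expr_path, detect_path = NULL) {
  d <- read.delim(expr_path, stringsAsFactors = FALSE)
  need <- c("gene_id", "exon_model_length_nt", "mapped_reads",
            "total_mapped_reads")
  if (!all(need %in% names(d))) {
    stop("expression table must have columns: ", paste(need, collapse = ", "))
  }
  d$rpkm <- compute_rpkm(d$mapped_reads, d$exon_model_length_nt,
                         d$total_mapped_reads)
  d$spectral_count <- 0L
  if (!is.null(detect_path)) {
    det <- read.delim(detect_path, stringsAsFactors = FALSE)
    m <- match(d$gene_id, det$gene_id)
    d$spectral_count <- ifelse(is.na(m), 0L, det$spectral_count[m])
  }
  d$detected_by_ms <- d$spectral_count >= 1L
  d
}

#' MS detection fraction by transcript-abundance bin
#'
#' Genes are binned by `log10(rpkm)` on a grid of width `bin_width_log10`;
#' genes with zero RPKM are collected in a dedicated bin (reported with
#' `NA` bounds). Empty bins are omitted.
#'
#' @param records Data frame with columns `rpkm` and `detected_by_ms`.
#' @param bin_width_log10 Bin width on the log10 scale (default 0.5).
#' @return Data frame with columns `bin_lo`, `bin_hi` (log10 RPKM bounds,
#'   `NA` for the zero bin), `n_genes`, `n_detected`, `fraction`, ordered by
#'   abundance with the zero bin first.
#' @export
detection_fraction_by_bin <- function(records, bin_width_log10 = 0.5) {
  stopifnot(all(c("rpkm", "detected_by_ms") %in% names(records)),
            bin_width_log10 > 0)
  zero <- records$rpkm == 0
  pos <- records[!zero, , drop = FALSE]
  if (!nrow(pos)) stop("no records with rpkm > 0")
  b <- floor(log10(pos$rpkm) / bin_width_log10)
  tab <- do.call(rbind, lapply(sort(unique(b)), function(bb) {
    sel <- b == bb
    data.frame(bin_lo = bb * bin_width_log10,
               bin_hi = (bb + 1) * bin_width_log10,
               n_genes = sum(sel),
               n_detected = sum(pos$detected_by_ms[sel]))
  }))
  if (any(zero)) {
    tab <- rbind(data.frame(bin_lo = NA_real_, bin_hi = NA_real_,
                            n_genes = sum(zero),
                            n_detected = sum(records$detected_by_ms[zero])),
                 tab)
  }
  tab$fraction <- tab$n_detected / tab$n_genes
  rownames(tab) <- NULL
  tab
}

#' Correlation between transcript abundance and spectral counts
#'
#' Correlation between `log10(rpkm)` and `log10(spectral_count)` over
#' MS-detected genes (spectral count >= 1). Spectral counts are a label-free
#' proxy for protein abundance, so this quantifies mRNA-protein abundance
#' concordance.
#'
#' @param records Data frame with columns `rpkm` and `spectral_count`.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return Correlation coefficient, or `NA` with a warning if either
#'   log-transformed vector is constant.
#' @export
abundance_correlation <- function(records, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  det <- records[records$spectral_count >= 1L, , drop = FALSE]
  if (any(det$rpkm <= 0)) {
    warning(sum(det$rpkm <= 0), " detected gene(s) with rpkm = 0 dropped")
    det <- det[det$rpkm > 0, , drop = FALSE]
  }
  if (nrow(det) < 3L) stop("need at least 3 detected records")
  x <- log10(det$rpkm)
  y <- log10(det$spectral_count)
  if (sd(x) == 0 || sd(y) == 0) {
    warning("constant vector; correlation undefined")
    return(NA_real_)
  }
  cor(x, y, method = method)
}
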