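#' Read a genome FASTA
#'
#' Loads a nucleotide FASTA into a [Biostrings::DNAStringSet]. Sequences are
#' uppercased, `U` is mapped to `T`, and the alphabet is restricted to
#' `A/C/G/T/N`. Record names are truncated at the first whitespace.
#'
#' @param path Path to a FASTA file.
#' @return A named [Biostrings::DNAStringSet], one entry per chromosome.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1", "ACGTACGT"), fa)
#' read_genome_fasta(fa)
#' @export
read_genome_fasta <- function(path) {
  if (!file.exists(path)) stop("genome FASTA not found: ", path)
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0L) stop("empty FASTA file: ", path)
  nms <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(nms)) {
    stop("duplicate sequence names in genome FASTA: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  }
  x <- chartr("U", "T", toupper(as.character(seqs)))
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) {
    stop("non-ACGTN characters in sequence(s): ",
         paste(nms[bad], collapse = ", "))
  }
  out <- Biostrings::DNAStringSet(x)
  names(out) <- nms
  out
}

# build a jx_gene_models object from an exon table with 0-based half-open
# coordinates; introns are derived per transcript and pooled (unique) per gene
.gene_models_from_exons <- function(exons, genome = NULL) {
  stopifnot(all(c("gene_id", "transcript_id", "chrom", "strand",
                  "start", "end") %in% names(exons)))
  exons$start <- as.integer(exons$start)
  exons$end <- as.integer(exons$end)
  if (any(exons$end <= exons$start)) stop("exon with non-positive width")
  if (!all(exons$strand %in% c("+", "-"))) stop("exon strand must be + or -")
  if (!is.null(genome)) {
    lens <- setNames(Biostrings::width(genome), names(genome))
    if (!all(exons$chrom %in% names(lens))) {
      stop("exon on chromosome absent from genome: ",
           paste(setdiff(unique(exons$chrom), names(lens)), collapse = ", "))
    }
    if (any(exons$start < 0L | exons$end > lens[exons$chrom])) {
      stop("exon outside chromosome bounds")
    }
  }
  # sort exons within transcript, warn if input order was not positional
  ord <- order(exons$transcript_id, exons$start, exons$end)
  by_tx_in <- split(exons$start, exons$transcript_id)
  if (any(vapply(by_tx_in, is.unsorted, logical(1)))) {
    warning("exons were not sorted by start within transcript; sorting")
  }
  exons <- exons[ord, , drop = FALSE]
  rownames(exons) <- NULL

  introns <- do.call(rbind, lapply(split(exons, exons$transcript_id), function(e) {
    n <- nrow(e)
    if (n < 2L) return(NULL)
    if (any(e$start[-1L] < e$end[-n])) {
      warning("overlapping exons within transcript ", e$transcript_id[1L])
    }
    data.frame(gene_id = e$gene_id[1L], chrom = e$chrom[1L],
               strand = e$strand[1L], start = e$end[-n], end = e$start[-1L],
               stringsAsFactors = FALSE)
  }))
  if (is.null(introns)) {
    introns <- data.frame(gene_id = character(), chrom = character(),
                          strand = character(), start = integer(),
                          end = integer(), stringsAsFactors = FALSE)
  } else {
    introns <- unique(introns)
    introns <- introns[order(introns$gene_id, introns$start), , drop = FALSE]
    rownames(introns) <- NULL
  }
  genes <- do.call(rbind, lapply(split(exons, exons$gene_id), function(e) {
    data.frame(gene_id = e$gene_id[1L], chrom = e$chrom[1L],
               strand = e$strand[1L], start = min(e$start), end = max(e$end),
               stringsAsFactors = FALSE)
  }))
  rownames(genes) <- NULL
  structure(list(exons = exons, introns = introns, genes = genes),
            class = "jx_gene_models")
}

#' Read gene models from GTF or BED12
#'
#' Exon intervals are converted to the internal 0-based half-open convention
#' (GTF is 1-based inclusive on input). Introns are derived per transcript
#' from consecutive exon pairs and pooled, unique, per gene. For BED12 input
#' the record `name` is used as both gene and transcript identifier.
#'
#' @param path Path to the annotation file.
#' @param format `"gtf"` or `"bed12"`.
#' @param genome Optional genome ([read_genome_fasta()]); when supplied, exons
#'   outside chromosome bounds raise an error.
#' @return A `jx_gene_models` object: list with data frames `exons`,
#'   `introns` (pooled per gene) and `genes` (spans).
#' @export
read_gene_models <- function(path, format = c("gtf", "bed12"), genome = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("gene model file not found: ", path)
  if (format == "gtf") {
    gr <- rtracklayer::import(path, format = "gtf")
    gr <- gr[gr$type == "exon"]
    if (length(gr) == 0L) stop("no exon records in ", path)
    md <- S4Vectors::mcols(gr)
    tx <- if ("transcript_id" %in% names(md)) md$transcript_id else md$gene_id
    exons <- data.frame(
      gene_id = as.character(md$gene_id),
      transcript_id = as.character(tx),
      chrom = as.character(GenomicRanges::seqnames(gr)),
      strand = as.character(GenomicRanges::strand(gr)),
      start = GenomicRanges::start(gr) - 1L,
      end = GenomicRanges::end(gr),
      stringsAsFactors = FALSE)
  } else {
    gr <- rtracklayer::import(path, format = "bed")
    if (length(gr) == 0L) stop("no records in ", path)
    if (is.null(gr$blocks)) {
      blocks <- IRanges::IRangesList(lapply(GenomicRanges::width(gr),
                                            function(w) IRanges::IRanges(1L, w)))
    } else {
      blocks <- gr$blocks
    }
    nb <- S4Vectors::elementNROWS(blocks)
    flat <- unlist(blocks, use.names = FALSE)
    tx_start0 <- rep(GenomicRanges::start(gr) - 1L, nb)
    exons <- data.frame(
      gene_id = rep(as.character(gr$name), nb),
      transcript_id = rep(as.character(gr$name), nb),
      chrom = rep(as.character(GenomicRanges::seqnames(gr)), nb),
      strand = rep(as.character(GenomicRanges::strand(gr)), nb),
      start = tx_start0 + IRanges::start(flat) - 1L,
      end = tx_start0 + IRanges::end(flat),
      stringsAsFactors = FALSE)
  }
  .gene_models_from_exons(exons, genome = genome)
}

#' Write gene models to GTF
#'
#' Emits one `exon` feature line per exon, converting internal 0-based
#' half-open coordinates back to 1-based inclusive GTF. Re-reading the file
#' with [read_gene_models()] reproduces identical exon and intron sets.
#'
#' @param models A `jx_gene_models` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_models_gtf <- function(models, path) {
  stopifnot(inherits(models, "jx_gene_models"))
  e <- models$exons
  lines <- sprintf(
    "%s\tjxpepdb\texon\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s\";",
    e$chrom, e$start + 1L, e$end, e$strand, e$gene_id, e$transcript_id)
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.jx_gene_models <- function(x, ...) {
  cat("Gene models:", nrow(x$genes), "genes,", nrow(x$exons), "exons,",
      nrow(x$introns), "annotated introns (pooled per gene)\n")
  invisible(x)
}

#' Read splice junctions (BED6-style intron intervals)
#'
#' Expects a tab-separated file with columns chrom, intron start, intron end,
#' name, read count, strand (no header). Coordinates are 0-based half-open on
#' the *intron*: `start` is the first intronic base and `end` the first base
#' of the downstream exon. Records with `end <= start` are rejected with a
#' warning, records with read count < 1 are dropped, duplicates (same
#' chrom/strand/intron) are merged with summed read counts, and unstranded
#' records (`.`) are duplicated onto both strands with a warning.
#'
#' @param path Path to the junction file.
#' @return A `jx_junctions` data frame with columns `junction_id`, `chrom`,
#'   `strand`, `start`, `end`, `read_count`, `status` (`"unclassified"`) and
#'   `gene_id` (`NA`).
#' @export
read_junctions <- function(path) {
  if (!file.exists(path)) stop("junction file not found: ", path)
  d <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                  comment.char = "#")
  if (ncol(d) < 6L) stop("junction file must have 6 tab-separated columns")
  d <- d[, 1:6]
  names(d) <- c("chrom", "start", "end", "junction_id", "read_count", "strand")
  d$start <- as.integer(d$start); d$end <- as.integer(d$end)
  d$read_count <- as.integer(d$read_count)
  bad <- d$end <= d$start
  if (any(bad)) {
    warning(sum(bad), " junction record(s) with end <= start rejected")
    d <- d[!bad, , drop = FALSE]
  }
  d <- d[d$read_count >= 1L, , drop = FALSE]
  uns <- d$strand == "."
  if (any(uns)) {
    warning(sum(uns), " unstranded junction(s) duplicated onto both strands")
    dup <- d[uns, , drop = FALSE]
    d$strand[uns] <- "+"
    dup$strand <- "-"
    d <- rbind(d, dup)
  }
  if (!all(d$strand %in% c("+", "-"))) stop("junction strand must be +, - or .")
  key <- paste(d$chrom, d$strand, d$start, d$end)
  agg <- rowsum(d$read_count, key, reorder = FALSE)
  first <- !duplicated(key)
  out <- d[first, c("junction_id", "chrom", "strand", "start", "end"),
           drop = FALSE]
  out$read_count <- as.integer(agg[match(key[first], rownames(agg)), 1L])
  out$status <- "unclassified"
  out$gene_id <- NA_character_
  rownames(out) <- NULL
  class(out) <- c("jx_junctions", "data.frame")
  out
}

#' Write splice junctions to a BED6-style file
#'
#' Inverse of [read_junctions()]: chrom, intron start, intron end, junction
#' id, read count, strand.
#'
#' @param junctions A `jx_junctions` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_junctions_bed <- function(junctions, path) {
  write.table(junctions[, c("chrom", "start", "end", "junction_id",
                            "read_count", "strand")],
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Classify junctions as known or novel against gene models
#'
#' A junction is `known` iff its intron interval exactly matches an annotated
#' intron of a gene model on the same chromosome and strand (both boundaries;
#' one-sided matches are novel). Gene assignment: for known junctions, the
#' gene owning the matched intron; otherwise the gene whose exon set flanks
#' the intron on both sides (an exon ending at the intron start and an exon
#' starting at the intron end); otherwise the gene whose span contains the
#' intron (smallest span on ties); otherwise `"unassigned"`.
#'
#' @param junctions A `jx_junctions` data frame.
#' @param models A `jx_gene_models` object.
#' @return The input with `status` and `gene_id` filled in.
#' @export
classify_junctions <- function(junctions, models) {
  stopifnot(inherits(models, "jx_gene_models"))
  j <- junctions
  ik <- with(models$introns, paste(chrom, strand, start, end))
  jk <- paste(j$chrom, j$strand, j$start, j$end)
  hit <- match(jk, ik)
  j$status <- ifelse(is.na(hit), "novel", "known")
  j$gene_id <- models$introns$gene_id[hit]

  todo <- which(is.na(j$gene_id))
  if (length(todo)) {
    e <- models$exons
    donor_key <- paste(e$chrom, e$strand, e$end)     # exon ending here
    accept_key <- paste(e$chrom, e$strand, e$start)  # exon starting here
    g <- models$genes
    for (i in todo) {
      dk <- paste(j$chrom[i], j$strand[i], j$start[i])
      ak <- paste(j$chrom[i], j$strand[i], j$end[i])
      cand <- intersect(unique(e$gene_id[donor_key == dk]),
                        unique(e$gene_id[accept_key == ak]))
      if (length(cand)) {
        j$gene_id[i] <- cand[1L]
        next
      }
      cont <- g$chrom == j$chrom[i] & g$strand == j$strand[i] &
        g$start <= j$start[i] & g$end >= j$end[i]
      if (any(cont)) {
        gc <- g[cont, , drop = FALSE]
        j$gene_id[i] <- gc$gene_id[which.min(gc$end - gc$start)]
      } else {
        j$gene_id[i] <- "unassigned"
      }
    }
  }
  j
}
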