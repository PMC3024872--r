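#' In-silico tryptic digestion
#'
#' Cleaves C-terminal to K or R, suppressed when the next residue is P (the
#' rule used by common search engines; disable with `kp_rule = FALSE`).
#' Returns every fully tryptic peptide with up to `max_missed` missed
#' cleavages, with 0-based half-open coordinates in the parent sequence.
#'
#' @param sequence Amino-acid string without `*`.
#' @param max_missed Maximum number of missed cleavages (default 1).
#' @param kp_rule Suppress cleavage before proline (default `TRUE`).
#' @return Data frame with columns `sequence`, `start`, `end`,
#'   `missed_cleavages`, ordered by start then missed cleavages.
#' @examples
#' tryptic_digest("MKAAAAAR", max_missed = 1)
#' @export
tryptic_digest <- function(sequence, max_missed = 1L, kp_rule = TRUE) {
  if (max_missed < 0L) stop("max_missed must be >= 0")
  if (!nzchar(sequence)) stop("empty sequence")
  if (grepl("*", sequence, fixed = TRUE)) stop("sequence contains '*'")
  ch <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  n <- length(ch)
  sites <- which(ch %in% c("K", "R"))
  sites <- sites[sites < n]
  if (kp_rule) sites <- sites[ch[sites + 1L] != "P"]
  bounds <- c(0L, sites, n)
  nfrag <- length(bounds) - 1L
  out <- list()
  for (mc in 0:min(max_missed, nfrag - 1L)) {
    i <- seq_len(nfrag - mc)
    s <- bounds[i]
    e <- bounds[i + mc + 1L]
    out[[mc + 1L]] <- data.frame(
      sequence = substring(sequence, s + 1L, e),
      start = s, end = e, missed_cleavages = mc,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res <- res[order(res$start, res$missed_cleavages), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Junction-spanning tryptic peptides of a database entry
#'
#' Subset of the tryptic digest of `entry$aa_sequence` whose interval places
#' at least one residue on each side of the junction boundary
#' (`start < boundary_aa < end`).
#'
#' @param entry One row of a `jx_junction_db` (or a list with `aa_sequence`
#'   and `boundary_aa`).
#' @param max_missed Maximum missed cleavages.
#' @param kp_rule Passed to [tryptic_digest()].
#' @return Data frame as from [tryptic_digest()], possibly empty.
#' @export
junction_spanning_peptides <- function(entry, max_missed = 1L,
                                       kp_rule = TRUE) {
  entry <- as.list(entry)
  b <- entry$boundary_aa
  peps <- tryptic_digest(entry$aa_sequence, max_missed = max_missed,
                         kp_rule = kp_rule)
  out <- peps[peps$start < b & peps$end > b, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Is a junction identifiable by MS-compatible tryptic peptides?
#'
#' A junction counts as identifiable iff any of its database entries (any
#' reading frame) yields a junction-spanning tryptic peptide with length in
#' `[min_len, max_len]` (inclusive; 6-30 aa is the range most compatible
#' with MS/MS sequencing) and at most `max_missed` missed cleavages.
#'
#' @param entries `jx_junction_db` rows for one junction (zero rows allowed).
#' @param min_len,max_len Inclusive peptide length bounds.
#' @param max_missed Maximum missed cleavages.
#' @param kp_rule Passed to [tryptic_digest()].
#' @return Logical scalar.
#' @export
is_identifiable <- function(entries, min_len = 6L, max_len = 30L,
                            max_missed = 1L, kp_rule = TRUE) {
  if (is.null(entries) || nrow(entries) == 0L) return(FALSE)
  for (i in seq_len(nrow(entries))) {
    sp <- junction_spanning_peptides(entries[i, ], max_missed = max_missed,
                                     kp_rule = kp_rule)
    len <- nchar(sp$sequence)
    if (any(len >= min_len & len <= max_len)) return(TRUE)
  }
  FALSE
}

#' Per-junction identifiability over a whole database
#'
#' Evaluates [is_identifiable()] for every junction id appearing in the
#' database, honouring deduplicated entries: an entry counts for every
#' junction listed in its `all_junction_ids` metadata (falling back to
#' `junction_id` when absent).
#'
#' @param db A `jx_junction_db` data frame.
#' @param junction_ids Junction ids to evaluate (default: all in `db`).
#' @inheritParams is_identifiable
#' @return Named logical vector over `junction_ids`; junctions with no
#'   database entry are `FALSE`.
#' @export
identifiable_junctions <- function(db, junction_ids = NULL, min_len = 6L,
                                   max_len = 30L, max_missed = 1L,
                                   kp_rule = TRUE) {
  prov <- db$all_junction_ids
  if (is.null(prov) || all(is.na(prov))) prov <- db$junction_id
  ids_per_entry <- strsplit(prov, ",", fixed = TRUE)
  if (is.null(junction_ids)) {
    junction_ids <- unique(unlist(ids_per_entry))
  }
  res <- setNames(logical(length(junction_ids)), junction_ids)
  if (nrow(db) == 0L) return(res)
  entry_ok <- vapply(seq_len(nrow(db)), function(i) {
    is_identifiable(db[i, ], min_len = min_len, max_len = max_len,
                    max_missed = max_missed, kp_rule = kp_rule)
  }, logical(1))
  hit <- unique(unlist(ids_per_entry[entry_ok]))
  res[names(res) %in% hit] <- TRUE
  res
}

#' Per-gene junction identifiability statistics
#'
#' The Table-1-style analysis: distinct junctions per gene (deduplicated by
#' intron coordinates), how many are identifiable by junction-straddling
#' tryptic peptides at 0 and at 1 allowed missed cleavage, and known/novel
#' tallies. Averages are unweighted means over genes (each gene counts once);
#' genes with zero junctions contribute 0 to the numerator and 1 to the
#' denominator when listed in `all_genes`. Junctions with gene
#' `"unassigned"` are excluded from per-gene averages.
#'
#' @param junctions Classified `jx_junctions` (with `gene_id`, `status`).
#' @param db `jx_junction_db` built from the same junctions.
#' @param gene_subset Optional character vector of gene ids (e.g. a
#'   mitochondrial gene list); a separate summary is computed over it.
#' @param all_genes Optional character vector of every gene in the
#'   annotation, so that junction-free genes enter the averages.
#' @param min_len,max_len Peptide length screen (inclusive).
#' @param kp_rule Passed to [tryptic_digest()].
#' @return A `jx_gene_stats` list: `per_gene` data frame (`gene_id`,
#'   `n_junctions`, `n_identifiable_mc0`, `n_identifiable_mc1`,
#'   `n_known_junctions`, `n_novel_junctions`), `summary`, and
#'   `subset_summary` (or `NULL`).
#' @export
per_gene_stats <- function(junctions, db, gene_subset = NULL,
                           all_genes = NULL, min_len = 6L, max_len = 30L,
                           kp_rule = TRUE) {
  j <- junctions[!is.na(junctions$gene_id) &
                   junctions$gene_id != "unassigned", , drop = FALSE]
  # distinct junctions per gene: dedupe by intron coordinates
  key <- paste(j$gene_id, j$chrom, j$strand, j$start, j$end)
  j <- j[!duplicated(key), , drop = FALSE]
  id0 <- identifiable_junctions(db, junction_ids = j$junction_id,
                                min_len = min_len, max_len = max_len,
                                max_missed = 0L, kp_rule = kp_rule)
  id1 <- identifiable_junctions(db, junction_ids = j$junction_id,
                                min_len = min_len, max_len = max_len,
                                max_missed = 1L, kp_rule = kp_rule)
  genes <- unique(c(j$gene_id, all_genes))
  per_gene <- do.call(rbind, lapply(genes, function(g) {
    sel <- j$gene_id == g
    data.frame(gene_id = g,
               n_junctions = sum(sel),
               n_identifiable_mc0 = sum(id0[j$junction_id[sel]]),
               n_identifiable_mc1 = sum(id1[j$junction_id[sel]]),
               n_known_junctions = sum(sel & j$status == "known"),
               n_novel_junctions = sum(sel & j$status == "novel"),
               stringsAsFactors = FALSE)
  }))
  if (is.null(per_gene)) {
    warning("no genes with assigned junctions")
    per_gene <- data.frame(gene_id = character(), n_junctions = integer(),
                           n_identifiable_mc0 = integer(),
                           n_identifiable_mc1 = integer(),
                           n_known_junctions = integer(),
                           n_novel_junctions = integer())
  }
  rownames(per_gene) <- NULL
  summarise <- function(pg) {
    if (nrow(pg) == 0L) {
      warning("empty gene set; averages reported as 0")
      return(list(n_genes = 0L, avg_junctions_per_gene = 0,
                  avg_identifiable_mc0 = 0, avg_identifiable_mc1 = 0,
                  identifiable_fraction_mc0 = 0,
                  identifiable_fraction_mc1 = 0,
                  known_fraction = 0, novel_fraction = 0))
    }
    nj <- sum(pg$n_junctions)
    list(n_genes = nrow(pg),
         avg_junctions_per_gene = mean(pg$n_junctions),
         avg_identifiable_mc0 = mean(pg$n_identifiable_mc0),
         avg_identifiable_mc1 = mean(pg$n_identifiable_mc1),
         identifiable_fraction_mc0 = if (nj) sum(pg$n_identifiable_mc0) / nj else 0,
         identifiable_fraction_mc1 = if (nj) sum(pg$n_identifiable_mc1) / nj else 0,
         known_fraction = if (nj) sum(pg$n_known_junctions) / nj else 0,
         novel_fraction = if (nj) sum(pg$n_novel_junctions) / nj else 0)
  }
  out <- list(per_gene = per_gene, summary = summarise(per_gene),
              subset_summary = NULL,
              params = list(min_len = min_len, max_len = max_len))
  if (!is.null(gene_subset)) {
    out$subset_summary <- summarise(
      per_gene[per_gene$gene_id %in% gene_subset, , drop = FALSE])
  }
  class(out) <- "jx_gene_stats"
  out
}

#' @export
print.jx_gene_stats <- function(x, ...) {
  s <- x$summary
  cat("Junction identifiability over", s$n_genes, "genes\n")
  cat(sprintf("  avg junctions/gene:            %.2f\n",
              s$avg_junctions_per_gene))
  cat(sprintf("  avg identifiable/gene (mc0):   %.2f\n",
              s$avg_identifiable_mc0))
  cat(sprintf("  avg identifiable/gene (mc<=1): %.2f\n",
              s$avg_identifiable_mc1))
  cat(sprintf("  identifiable fraction (mc0):   %.3f\n",
              s$identifiable_fraction_mc0))
  cat(sprintf("  known : novel junction split:  %.2f : %.2f\n",
              s$known_fraction, s$novel_fraction))
  if (!is.null(x$subset_summary)) {
    ss <- x$subset_summary
    cat(sprintf("  gene subset (%d genes): %.2f junctions/gene, %.2f (%.2f) identifiable mc0 (mc<=1)\n",
                ss$n_genes, ss$avg_junctions_per_gene,
                ss$avg_identifiable_mc0, ss$avg_identifiable_mc1))
  }
  invisible(x)
}

#' Expected novel-peptide yield
#'
#' The back-of-envelope product used to anticipate how many junction
#' peptides a search should find: number of genes, junctions per gene, the
#' fraction of junctions in the class of interest (e.g. ~20% novel), and the
#' fraction identifiable by MS-compatible tryptic peptides (~5%).
#'
#' @param n_genes Number of genes.
#' @param junctions_per_gene Average junctions per gene.
#' @param class_fraction Fraction of junctions in the class of interest
#'   (in `[0, 1]`).
#' @param identifiable_fraction Fraction identifiable by tryptic peptides
#'   (in `[0, 1]`).
#' @return List with `expected` (unrounded product) and `rounded`.
#' @examples
#' expected_yield(700, 5, 0.20, 0.05)  # ~35 expected novel peptides
#' @export
expected_yield <- function(n_genes, junctions_per_gene, class_fraction,
                           identifiable_fraction) {
  stopifnot(n_genes >= 0, junctions_per_gene >= 0,
            class_fraction >= 0, class_fraction <= 1,
            identifiable_fraction >= 0, identifiable_fraction <= 1)
  v <- n_genes * junctions_per_gene * class_fraction * identifiable_fraction
  list(expected = v, rounded = round(v))
}
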