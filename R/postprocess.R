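#' Construct a protein database object
#'
#' @param accession Character vector of unique accessions.
#' @param sequence Amino-acid sequences.
#' @param origin One of `"reference"`, `"junction"`, `"decoy"` per entry.
#' @return A `jx_protein_db` data frame.
#' @export
protein_db <- function(accession, sequence,
                       origin = rep("reference", length(accession))) {
  stopifnot(length(accession) == length(sequence),
            length(origin) == length(accession))
  if (anyDuplicated(accession)) stop("duplicate accessions")
  if (!all(origin %in% c("reference", "junction", "decoy"))) {
    stop("origin must be reference, junction or decoy")
  }
  out <- data.frame(accession = as.character(accession),
                    sequence = toupper(as.character(sequence)),
                    origin = origin, stringsAsFactors = FALSE)
  class(out) <- c("jx_protein_db", "data.frame")
  out
}

#' Read a protein FASTA into a `jx_protein_db`
#'
#' @param path FASTA path.
#' @param origin Origin label for all entries (default `"reference"`); pass
#'   `"auto"` to derive from accession prefixes (`DECOY_` = decoy,
#'   `JXN|` = junction, else reference).
#' @return A `jx_protein_db` data frame.
#' @export
read_protein_fasta <- function(path, origin = "reference") {
  aa <- Biostrings::readAAStringSet(path)
  acc <- sub("\\s.*$", "", names(aa))
  if (identical(origin, "auto")) {
    origin <- ifelse(startsWith(acc, "DECOY_"), "decoy",
                     ifelse(startsWith(acc, "JXN|"), "junction", "reference"))
  } else {
    origin <- rep(origin, length(acc))
  }
  protein_db(acc, as.character(aa), origin)
}

#' Write a `jx_protein_db` to FASTA
#'
#' @param db A `jx_protein_db`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_protein_fasta <- function(db, path) {
  aa <- Biostrings::AAStringSet(db$sequence)
  names(aa) <- db$accession
  Biostrings::writeXStringSet(aa, path, width = 60L)
  invisible(path)
}

#' Append reversed decoys to a protein database
#'
#' One decoy per target entry: the sequence fully reversed and the accession
#' prefixed `DECOY_`, so the output holds exactly twice the input count and
#' the decoy length distribution equals the target one.
#'
#' @param db A `jx_protein_db` without decoys.
#' @param prefix Decoy accession prefix.
#' @return A `jx_protein_db` with targets followed by decoys.
#' @export
generate_decoys <- function(db, prefix = "DECOY_") {
  if (any(db$origin == "decoy")) stop("database already contains decoys")
  dec_acc <- paste0(prefix, db$accession)
  if (any(dec_acc %in% db$accession)) {
    stop("decoy accession collides with an existing accession")
  }
  pal <- db$sequence == .str_rev(db$sequence)
  if (any(pal)) {
    message(sum(pal), " palindromic target(s): decoy equals target sequence")
  }
  dec <- protein_db(dec_acc, .str_rev(db$sequence),
                    rep("decoy", nrow(db)))
  out <- rbind(db, dec)
  class(out) <- c("jx_protein_db", "data.frame")
  out
}

#' Assemble the combined target+decoy search database
#'
#' Concatenates the reference proteome with translated junction entries
#' (accessions `JXN|<entry_id>`), then generates reversed decoys over the
#' union, mirroring the combined-search scheme in which translated mRNA
#' sequences are appended to a standard protein database before an equal
#' number of reverse sequences is added. Junction entries whose accession
#' collides with a reference accession are suffixed `_jxn` with a warning;
#' junction sequences identical to a reference sequence are retained
#' (novelty is resolved at the peptide level, not the entry level).
#'
#' @param reference A `jx_protein_db` of reference proteins.
#' @param junction_entries A `jx_junction_db` (or a `jx_protein_db` with
#'   origin `"junction"`).
#' @return A `jx_protein_db` with `2 * (n_reference + n_junction)` entries.
#' @export
assemble_combined_db <- function(reference, junction_entries) {
  if (inherits(junction_entries, "jx_junction_db")) {
    jdb <- protein_db(paste0("JXN|", junction_entries$entry_id,
                             recycle0 = TRUE),
                      junction_entries$aa_sequence,
                      rep("junction", nrow(junction_entries)))
  } else {
    jdb <- junction_entries
  }
  clash <- jdb$accession %in% reference$accession
  if (any(clash)) {
    warning(sum(clash), " junction accession(s) collide with reference; ",
            "suffixed '_jxn'")
    jdb$accession[clash] <- paste0(jdb$accession[clash], "_jxn")
  }
  combined <- rbind(reference, jdb)
  class(combined) <- c("jx_protein_db", "data.frame")
  generate_decoys(combined)
}

# classify accession lists: is_decoy iff all matched accessions are decoys;
# novelty 'known' if any non-decoy reference match (precedence over novel)
.classify_psm_accessions <- function(acc_list) {
  is_dec <- vapply(acc_list, function(a) all(startsWith(a, "DECOY_")),
                   logical(1))
  novelty <- vapply(acc_list, function(a) {
    tgt <- a[!startsWith(a, "DECOY_")]
    if (!length(tgt)) return("decoy")
    if (any(!startsWith(tgt, "JXN|"))) "known" else "novel_candidate"
  }, character(1))
  list(is_decoy = is_dec, novelty = novelty)
}

#' Read a peptide-spectrum-match table
#'
#' Expects a TSV with header columns `spectrum_id`, `peptide`,
#' `probability`, `proteins` (semicolon-separated accessions) and an
#' optional `quality` column (precomputed spectrum quality score). Peptides
#' are uppercased and bracketed modification mass annotations (`[...]`) are
#' stripped. `is_decoy` is true iff every matched accession carries the
#' `DECOY_` prefix; novelty is `known` if any reference accession matches
#' (precedence over novel), `novel_candidate` if only junction (`JXN|`)
#' accessions match. Rows with probability outside `[0, 1]` are rejected
#' with a warning, as are rows naming accessions absent from `db` when a
#' database is supplied.
#'
#' @param path TSV path.
#' @param db Optional `jx_protein_db` used to validate accessions.
#' @return A `jx_psms` data frame with columns `spectrum_id`, `peptide`,
#'   `probability`, `proteins`, `is_decoy`, `novelty`, `quality`.
#' @export
read_psm_table <- function(path, db = NULL) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("spectrum_id", "peptide", "probability", "proteins")
  if (!all(need %in% names(d))) {
    stop("PSM table must have columns: ", paste(need, collapse = ", "))
  }
  d$probability <- as.numeric(d$probability)
  bad <- is.na(d$probability) | d$probability < 0 | d$probability > 1
  if (any(bad)) {
    warning(sum(bad), " PSM row(s) with probability outside [0,1] rejected")
    d <- d[!bad, , drop = FALSE]
  }
  d$peptide <- toupper(gsub("\\[[^][]*\\]", "", d$peptide))
  acc_list <- strsplit(d$proteins, ";", fixed = TRUE)
  if (!is.null(db)) {
    known_acc <- db$accession
    ok <- vapply(acc_list, function(a) all(a %in% known_acc), logical(1))
    if (!all(ok)) {
      warning(sum(!ok), " PSM row(s) naming unknown accessions rejected")
      d <- d[ok, , drop = FALSE]
      acc_list <- acc_list[ok]
    }
  }
  cls <- .classify_psm_accessions(acc_list)
  out <- data.frame(spectrum_id = d$spectrum_id, peptide = d$peptide,
                    probability = d$probability, proteins = d$proteins,
                    is_decoy = cls$is_decoy, novelty = cls$novelty,
                    quality = if ("quality" %in% names(d))
                      as.numeric(d$quality) else NA_real_,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("jx_psms", "data.frame")
  out
}

#' Write a PSM table
#'
#' @param psms A `jx_psms` (or compatible) data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_psm_table <- function(psms, path) {
  cols <- intersect(c("spectrum_id", "peptide", "probability", "proteins",
                      "quality"), names(psms))
  write.table(psms[, cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Filter PSMs on a precomputed spectrum-quality score
#'
#' Keeps PSMs whose `quality` column is at least `min_quality` (PSMs with no
#' quality value are kept). Quality is consumed as given, never recomputed
#' from spectra.
#'
#' @param psms A `jx_psms` data frame.
#' @param min_quality Minimum quality score (default 1).
#' @return Filtered `jx_psms`.
#' @export
filter_quality <- function(psms, min_quality = 1) {
  keep <- is.na(psms$quality) | psms$quality >= min_quality
  psms[keep, , drop = FALSE]
}

#' Estimate the target-decoy FDR curve
#'
#' At each distinct score threshold `t` (descending),
#' `fdr(t) = N_decoy(score >= t) / max(1, N_target(score >= t))`; q-values
#' are the running minimum of `fdr` from the most permissive threshold up,
#' so they are monotone non-decreasing as the threshold decreases.
#'
#' @param psms A `jx_psms` data frame (uses `probability` as the score,
#'   higher is better, and `is_decoy`).
#' @return A `jx_fdr_curve` list with `thresholds` (descending), `n_target`,
#'   `n_decoy`, `fdr`, `q`.
#' @export
estimate_fdr_curve <- function(psms) {
  if (!nrow(psms)) stop("no PSMs")
  if (!any(!psms$is_decoy)) stop("all-decoy input: no target PSMs")
  ord <- order(psms$probability, decreasing = TRUE)
  s <- psms$probability[ord]
  dec <- psms$is_decoy[ord]
  ct <- cumsum(!dec)
  cd <- cumsum(dec)
  last <- !duplicated(s, fromLast = TRUE)  # last row of each tied score
  thresholds <- s[last]
  n_target <- ct[last]
  n_decoy <- cd[last]
  fdr <- n_decoy / pmax(1L, n_target)
  q <- rev(cummin(rev(fdr)))
  structure(list(thresholds = thresholds, n_target = n_target,
                 n_decoy = n_decoy, fdr = fdr, q = q),
            class = "jx_fdr_curve")
}

#' @export
print.jx_fdr_curve <- function(x, ...) {
  cat("Target-decoy FDR curve:", length(x$thresholds),
      "distinct score thresholds\n")
  cat(sprintf("  targets: %d, decoys: %d (at the most permissive threshold)\n",
              max(x$n_target), max(x$n_decoy)))
  for (a in c(0.01, 0.02, 0.05)) {
    thr <- suppressWarnings(threshold_at_fdr(x, a))
    if (!is.na(thr)) {
      i <- match(TRUE, x$thresholds <= thr)
      cat(sprintf("  q <= %.2f at score >= %.4f (%d targets)\n",
                  a, thr, x$n_target[i]))
    }
  }
  invisible(x)
}

#' @export
plot.jx_fdr_curve <- function(x, ...) {
  plot(x$thresholds, x$q, type = "s", xlab = "score threshold",
       ylab = "q-value", xlim = rev(range(x$thresholds)), ...)
  graphics::lines(x$thresholds, x$fdr, type = "s", col = "grey60")
  graphics::abline(h = 0.02, lty = 2)
  invisible(x)
}

#' Score threshold achieving a target FDR
#'
#' Returns the lowest (most permissive) score threshold whose q-value is at
#' most `target_fdr`, or `NA` if the target is unattainable.
#'
#' @param curve A `jx_fdr_curve`.
#' @param target_fdr Target FDR (default 0.02).
#' @return Numeric score threshold, or `NA_real_` with a warning.
#' @export
threshold_at_fdr <- function(curve, target_fdr = 0.02) {
  if (target_fdr <= 0) stop("target_fdr must be > 0")
  ok <- curve$q <= target_fdr
  if (!any(ok)) {
    warning("target FDR unattainable at any threshold")
    return(NA_real_)
  }
  min(curve$thresholds[ok])
}

#' Filter PSMs at a global FDR
#'
#' Convenience wrapper: estimates the FDR curve over all PSMs, finds the
#' threshold at `target_fdr`, and returns the passing target PSMs.
#'
#' @param psms A `jx_psms` data frame.
#' @param target_fdr Target FDR.
#' @return List with `threshold`, `curve` and `psms` (passing targets).
#' @export
fdr_filter <- function(psms, target_fdr = 0.02) {
  curve <- estimate_fdr_curve(psms)
  thr <- threshold_at_fdr(curve, target_fdr)
  pass <- if (is.na(thr)) psms[0, , drop = FALSE] else
    psms[!psms$is_decoy & psms$probability >= thr, , drop = FALSE]
  list(threshold = thr, curve = curve, psms = pass)
}

#' Class-specific FDR filtering for novel-candidate PSMs
#'
#' The error rate among novel-candidate peptides is typically much higher
#' than the global one, so the FDR curve is recomputed using only PSMs whose
#' peptides map exclusively to junction entries (targets with novelty
#' `novel_candidate`) or exclusively to junction decoys, and a stricter
#' subset-specific threshold is derived.
#'
#' @param psms A `jx_psms` data frame (full set, targets and decoys).
#' @param target_fdr Target subset FDR (default 0.02).
#' @param junction_decoy_prefix Accession prefix identifying junction
#'   decoys.
#' @return List with `threshold` (subset-specific score threshold, `NA` when
#'   undefined), `curve` (subset `jx_fdr_curve` or `NULL`) and `psms`
#'   (passing novel-candidate PSMs; empty when none reach the target).
#' @export
subset_fdr_filter <- function(psms, target_fdr = 0.02,
                              junction_decoy_prefix = "DECOY_JXN|") {
  acc_list <- strsplit(psms$proteins, ";", fixed = TRUE)
  dec_jxn <- psms$is_decoy &
    vapply(acc_list, function(a) all(startsWith(a, junction_decoy_prefix)),
           logical(1))
  sub <- psms[psms$novelty == "novel_candidate" | dec_jxn, , drop = FALSE]
  if (!any(!sub$is_decoy)) {
    warning("no novel-candidate target PSMs in subset")
    return(list(threshold = NA_real_, curve = NULL,
                psms = psms[0, , drop = FALSE]))
  }
  if (!any(sub$is_decoy)) {
    warning("novel subset contains no junction-decoy PSMs; ",
            "subset threshold undefined")
    return(list(threshold = NA_real_, curve = NULL,
                psms = psms[0, , drop = FALSE]))
  }
  curve <- estimate_fdr_curve(sub)
  thr <- suppressWarnings(threshold_at_fdr(curve, target_fdr))
  pass <- if (is.na(thr)) psms[0, , drop = FALSE] else
    sub[!sub$is_decoy & sub$probability >= thr, , drop = FALSE]
  list(threshold = thr, curve = curve, psms = pass)
}

# encode reference sequences for the sliding Hamming scan; separator 0 marks
# sequence boundaries so windows never straddle two proteins
.ref_codes <- function(seqs, il_equivalent = TRUE) {
  s <- toupper(seqs)
  if (il_equivalent) s <- chartr("I", "L", s)
  codes <- utf8ToInt(paste(s, collapse = "\1"))
  lens <- nchar(s)
  idx <- unlist(lapply(seq_along(s), function(i) c(rep(i, lens[i]), 0L)))
  idx <- idx[-length(idx)]
  list(codes = codes, idx = idx)
}

.min_mismatch_scan <- function(peptide, ref, il_equivalent = TRUE) {
  p <- toupper(peptide)
  if (il_equivalent) p <- chartr("I", "L", p)
  pc <- utf8ToInt(p)
  k <- length(pc)
  M <- length(ref$codes) - k + 1L
  if (M < 1L) return(k)
  mism <- integer(M)
  base <- seq_len(M)
  for (d in 0:(k - 1L)) {
    mism <- mism + (ref$codes[base + d] != pc[d + 1L])
  }
  valid <- ref$idx[base] != 0L & ref$idx[base] == ref$idx[base + k - 1L]
  if (!any(valid)) return(k)
  min(mism[valid])
}

#' Minimum mismatch distance of a peptide to a reference proteome
#'
#' Exhaustive scan: the minimum Hamming distance between the peptide and any
#' equal-length substring of any reference sequence, with isoleucine and
#' leucine treated as identical by default (they are isobaric and
#' indistinguishable by standard MS/MS). This replaces a heuristic BLAST
#' screen with an exact, reproducible computation; gapped homology is out of
#' scope. Returns the peptide length when the reference is empty or holds no
#' window of sufficient length.
#'
#' @param peptide Amino-acid string (length >= 1).
#' @param reference A `jx_protein_db` or character vector of sequences.
#' @param il_equivalent Treat I and L as identical (default `TRUE`).
#' @return Integer minimum mismatch count.
#' @export
min_mismatch_distance <- function(peptide, reference, il_equivalent = TRUE) {
  stopifnot(nchar(peptide) >= 1L)
  seqs <- if (is.data.frame(reference)) reference$sequence else reference
  if (!length(seqs)) return(nchar(peptide))
  .min_mismatch_scan(peptide, .ref_codes(seqs, il_equivalent), il_equivalent)
}

#' Homology filter for candidate novel peptides
#'
#' Removes candidate novel peptides lying too close in sequence to the known
#' proteome: a PSM is retained iff [min_mismatch_distance()] of its peptide
#' to the reference is at least `min_mismatches` (peptides with fewer than 3
#' mismatches to a known sequence are removed by default). With
#' `min_mismatches = 0` this is the identity.
#'
#' @param novel_psms `jx_psms` rows, all with novelty `novel_candidate`.
#' @param reference A `jx_protein_db` or character vector of reference
#'   sequences.
#' @param min_mismatches Minimum mismatch distance to retain (default 3).
#' @param il_equivalent Treat I and L as identical.
#' @return The retained PSMs with an added `min_mismatch` column.
#' @export
homology_filter <- function(novel_psms, reference, min_mismatches = 3L,
                            il_equivalent = TRUE) {
  if (!all(novel_psms$novelty == "novel_candidate")) {
    stop("homology_filter expects novel-candidate PSMs only")
  }
  seqs <- if (is.data.frame(reference)) reference$sequence else reference
  if (!nrow(novel_psms)) {
    novel_psms$min_mismatch <- integer(0)
    return(novel_psms)
  }
  if (length(seqs)) {
    ref <- .ref_codes(seqs, il_equivalent)
    u <- unique(novel_psms$peptide)
    d <- vapply(u, function(p) .min_mismatch_scan(p, ref, il_equivalent),
                integer(1))
    novel_psms$min_mismatch <- d[novel_psms$peptide]
  } else {
    novel_psms$min_mismatch <- nchar(novel_psms$peptide)
  }
  novel_psms[novel_psms$min_mismatch >= min_mismatches, , drop = FALSE]
}
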