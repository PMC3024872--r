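# Independent brute-force oracles. These deliberately avoid the package's
# own algorithms: digestion by substring enumeration, translation by a
# hand-written codon table, mismatch distance by a double loop.

# every substring with tryptic termini and at most max_missed internal sites
oracle_digest <- function(sequence, max_missed, kp_rule = TRUE) {
  ch <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  n <- length(ch)
  is_site <- function(p) {           # cleavage after 1-based position p
    p >= 1 && p < n && ch[p] %in% c("K", "R") &&
      (!kp_rule || ch[p + 1L] != "P")
  }
  out <- list()
  for (i in 1:n) {
    for (j in i:n) {
      nterm_ok <- (i == 1L) || is_site(i - 1L)
      cterm_ok <- (j == n) || is_site(j)
      if (!nterm_ok || !cterm_ok) next
      internal <- if (j > i) sum(vapply(i:(j - 1L), is_site, logical(1))) else 0L
      if (internal > max_missed) next
      out[[length(out) + 1L]] <- data.frame(
        sequence = paste(ch[i:j], collapse = ""),
        start = i - 1L, end = j, missed_cleavages = internal,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(res$start, res$missed_cleavages), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# hand-written standard genetic code
oracle_codon_table <- local({
  bases <- c("T", "C", "A", "G")
  aas <- strsplit(paste0(
    "FFLLSSSSYY**CC*W",   # TTT TTC TTA TTG TCT ... TGG
    "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR",
    "VVVVAAAADDEEGGGG"), "")[[1L]]
  codons <- character(64)
  k <- 0L
  for (b1 in bases) for (b2 in bases) for (b3 in bases) {
    k <- k + 1L
    codons[k] <- paste0(b1, b2, b3)
  }
  stats::setNames(aas, codons)
})

oracle_translate <- function(nt, offset = 0L) {
  nt <- toupper(nt)
  n <- (nchar(nt) - offset) %/% 3L
  if (n < 1L) return("")
  aa <- character(n)
  for (i in seq_len(n)) {
    codon <- substr(nt, offset + 3L * (i - 1L) + 1L, offset + 3L * i)
    aa[i] <- if (grepl("N", codon)) "X" else oracle_codon_table[[codon]]
  }
  paste(aa, collapse = "")
}

oracle_revcomp <- function(nt) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", toupper(nt)), "")[[1L]]),
        collapse = "")
}

# naive double-loop minimum Hamming distance
oracle_min_mismatch <- function(peptide, seqs, il_equivalent = TRUE) {
  p <- toupper(peptide)
  if (il_equivalent) {
    p <- chartr("I", "L", p)
    seqs <- chartr("I", "L", toupper(seqs))
  } else {
    seqs <- toupper(seqs)
  }
  k <- nchar(p)
  pc <- strsplit(p, "")[[1L]]
  best <- k
  for (s in seqs) {
    n <- nchar(s)
    if (n < k) next
    sc <- strsplit(s, "")[[1L]]
    for (i in 1:(n - k + 1L)) {
      d <- sum(sc[i:(i + k - 1L)] != pc)
      if (d < best) best <- d
    }
  }
  best
}

random_peptide <- function(len) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]], len, TRUE),
        collapse = "")
}

random_protein_seqs <- function(n, len_range = c(30L, 120L)) {
  vapply(sample(seq(len_range[1L], len_range[2L]), n, TRUE),
         random_peptide, character(1))
}

write_tmp <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
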