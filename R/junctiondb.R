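#' Extract the spliced nucleotide window around a junction
#'
#' Takes `flank_nt` bases immediately upstream of the intron start and
#' `flank_nt` bases from the intron end onward, concatenated with the intron
#' removed. With gene models (and a gene assignment on the junction), flanks
#' are clipped at the boundaries of the flanking exons; with
#' `genomic_flanks = TRUE`, or when no exon covers the boundary, they are
#' clipped at chromosome bounds only. Junctions for which either available
#' flank is shorter than `flank_nt` are filtered (returns `NULL`).
#' Minus-strand windows are reverse-complemented so the sequence reads 5' to
#' 3' in transcript orientation, and the boundary offset is remapped.
#'
#' @param junction A single junction: one row of a `jx_junctions` data frame
#'   (or a list with `junction_id`, `chrom`, `strand`, `start`, `end`, and
#'   optionally `gene_id`, `status`).
#' @param genome A [Biostrings::DNAStringSet] from [read_genome_fasta()].
#' @param models Optional `jx_gene_models` used for exon-boundary clipping.
#' @param flank_nt Flank length per side in nucleotides; the default 75
#'   corresponds to 25 codons per exon side.
#' @param genomic_flanks If `TRUE`, ignore exon boundaries and clip at
#'   chromosome bounds only.
#' @return A `jx_window` list with `junction_id`, `nt_sequence`,
#'   `boundary_nt` (0-based offset of the first nucleotide contributed by the
#'   transcript-downstream exon), `flank_nt`, `strand`, `status`; or `NULL`
#'   if the junction is filtered.
#' @export
extract_junction_window <- function(junction, genome, models = NULL,
                                    flank_nt = 75L, genomic_flanks = FALSE) {
  junction <- as.list(junction)
  chrom <- junction$chrom
  if (!chrom %in% names(genome)) {
    stop("junction chromosome absent from genome: ", chrom)
  }
  s <- as.integer(junction$start)
  e <- as.integer(junction$end)
  chrlen <- length(genome[[chrom]])
  up_avail <- s
  down_avail <- chrlen - e
  gene <- junction$gene_id
  if (!genomic_flanks && !is.null(models) && !is.null(gene) &&
      !is.na(gene) && gene != "unassigned") {
    ex <- models$exons
    ex <- ex[ex$gene_id == gene & ex$chrom == chrom &
               ex$strand == junction$strand, , drop = FALSE]
    up_ex <- ex[ex$start <= s - 1L & ex$end >= s, , drop = FALSE]
    if (nrow(up_ex)) up_avail <- min(s - max(up_ex$start), up_avail)
    down_ex <- ex[ex$start <= e & ex$end > e, , drop = FALSE]
    if (nrow(down_ex)) {
      down_avail <- min(max(down_ex$end) - e, down_avail)
    }
  }
  if (up_avail < flank_nt || down_avail < flank_nt) return(NULL)
  left <- Biostrings::subseq(genome[[chrom]], s - flank_nt + 1L, s)
  right <- Biostrings::subseq(genome[[chrom]], e + 1L, e + flank_nt)
  win <- Biostrings::xscat(left, right)
  boundary <- flank_nt
  if (junction$strand == "-") {
    win <- Biostrings::reverseComplement(win)
    boundary <- length(win) - boundary
  }
  structure(list(junction_id = junction$junction_id,
                 nt_sequence = as.character(win),
                 boundary_nt = as.integer(boundary),
                 flank_nt = as.integer(flank_nt),
                 strand = junction$strand,
                 status = if (is.null(junction$status)) "unclassified"
                          else junction$status),
            class = "jx_window")
}

# boundary residue in one frame: index of the first residue whose codon
# overlaps nucleotide position `bnt` (0-based) or later, at frame offset f
.frame_boundary_aa <- function(bnt, f, n_aa) {
  b <- as.integer(ceiling((bnt - f - 2) / 3))
  min(max(b, 0L), n_aa)
}

#' Six-frame translation of a junction window
#'
#' Frames `+0/+1/+2` translate the window at offsets 0/1/2; frames
#' `-0/-1/-2` translate the reverse complement at the same offsets. Trailing
#' partial codons are dropped, stop codons are rendered `*`, and codons
#' containing `N` are rendered `X`. For each frame the junction boundary is
#' mapped to the index of the first residue whose codon overlaps the
#' boundary nucleotide or later, in that frame's reading sense.
#'
#' @param window A `jx_window` from [extract_junction_window()], or any list
#'   with `nt_sequence` and `boundary_nt`.
#' @return Data frame with columns `frame`, `aa` (translation, may contain
#'   `*` and `X`) and `boundary_aa`.
#' @export
six_frame_translate <- function(window) {
  nt <- window$nt_sequence
  bnt <- window$boundary_nt
  L <- nchar(nt)
  if (L < 3L) stop("window shorter than 3 nt")
  fwd <- Biostrings::DNAString(nt)
  rev <- Biostrings::reverseComplement(fwd)
  frames <- c("+0", "+1", "+2", "-0", "-1", "-2")
  aa <- character(6)
  baa <- integer(6)
  for (i in seq_along(frames)) {
    f <- as.integer(substr(frames[i], 2, 2))
    s <- if (startsWith(frames[i], "+")) fwd else rev
    b <- if (startsWith(frames[i], "+")) bnt else L - bnt
    n <- (L - f) %/% 3L
    if (n < 1L) {
      aa[i] <- ""
      baa[i] <- 0L
      next
    }
    sub <- Biostrings::subseq(s, f + 1L, f + 3L * n)
    aa[i] <- as.character(Biostrings::translate(sub, if.fuzzy.codon = "X",
                                                no.init.codon = TRUE))
    baa[i] <- .frame_boundary_aa(b, f, n)
  }
  data.frame(frame = frames, aa = aa, boundary_aa = baa,
             stringsAsFactors = FALSE)
}

#' Extract junction-spanning ORFs from six-frame translations
#'
#' ORFs are maximal stop-free segments (split at `*`); no initiator
#' methionine is required since windows are internal transcript fragments. A
#' segment is kept iff it is at least `min_orf_len` residues long and spans
#' the junction (at least one residue wholly upstream of the boundary and at
#' least one residue at or past it). Segments whose junction-straddling
#' residue is `X` (an `N`-containing codon at the boundary) are discarded.
#'
#' @param translations Data frame from [six_frame_translate()].
#' @param min_orf_len Minimum ORF length in residues (default 30).
#' @param junction_id,source_status Provenance carried into the output.
#' @return Data frame with columns `junction_id`, `frame`, `aa_sequence`,
#'   `boundary_aa` (relative to segment start; `0 < boundary_aa < length`)
#'   and `source_status`. Zero rows if nothing qualifies.
#' @export
extract_spanning_orfs <- function(translations, min_orf_len = 30L,
                                  junction_id = NA_character_,
                                  source_status = NA_character_) {
  out <- list()
  for (i in seq_len(nrow(translations))) {
    aa <- translations$aa[i]
    b <- translations$boundary_aa[i]
    if (!nzchar(aa)) next
    m <- gregexpr("[^*]+", aa)[[1L]]
    if (m[1L] == -1L) next
    segs <- attr(m, "match.length")
    for (k in seq_along(m)) {
      s0 <- m[k] - 1L            # 0-based segment start in the frame
      e0 <- s0 + segs[k]
      if (!(s0 < b && e0 > b)) next
      if (substr(aa, b + 1L, b + 1L) == "X") next
      if (segs[k] < min_orf_len) next
      out[[length(out) + 1L]] <- data.frame(
        junction_id = junction_id,
        frame = translations$frame[i],
        aa_sequence = substr(aa, m[k], m[k] + segs[k] - 1L),
        boundary_aa = b - s0,
        source_status = source_status,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(junction_id = character(), frame = character(),
                      aa_sequence = character(), boundary_aa = integer(),
                      source_status = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Build a translated junction-peptide database
#'
#' Composes [extract_junction_window()], [six_frame_translate()] and
#' [extract_spanning_orfs()] over a junction table and deduplicates entries
#' on exact amino-acid sequence (first-seen provenance kept; all contributing
#' junction ids recorded in `all_junction_ids`). Entry ids are assigned in
#' first-seen order, so identical input yields byte-identical output.
#'
#' @param junctions `jx_junctions` data frame, ideally after
#'   [classify_junctions()] (the `status` column is carried into entries).
#' @param genome Genome from [read_genome_fasta()].
#' @param models Optional `jx_gene_models` for exon-boundary clipping.
#' @param flank_nt,min_orf_len,genomic_flanks See
#'   [extract_junction_window()] and [extract_spanning_orfs()].
#' @param verbose Log summary counts with [message()].
#' @return A `jx_junction_db` data frame with columns `entry_id`,
#'   `junction_id`, `frame`, `aa_sequence`, `boundary_aa`, `source_status`,
#'   `all_junction_ids`; attribute `counts` holds the stage tallies.
#' @export
build_junction_database <- function(junctions, genome, models = NULL,
                                    flank_nt = 75L, min_orf_len = 30L,
                                    genomic_flanks = FALSE, verbose = TRUE) {
  pieces <- vector("list", nrow(junctions))
  n_windows <- 0L
  for (i in seq_len(nrow(junctions))) {
    w <- extract_junction_window(junctions[i, ], genome, models,
                                 flank_nt = flank_nt,
                                 genomic_flanks = genomic_flanks)
    if (is.null(w)) next
    n_windows <- n_windows + 1L
    tr <- six_frame_translate(w)
    pieces[[i]] <- extract_spanning_orfs(tr, min_orf_len = min_orf_len,
                                         junction_id = w$junction_id,
                                         source_status = w$status)
  }
  entries <- do.call(rbind, pieces)
  if (is.null(entries) || nrow(entries) == 0L) {
    entries <- data.frame(entry_id = character(), junction_id = character(),
                          frame = character(), aa_sequence = character(),
                          boundary_aa = integer(), source_status = character(),
                          all_junction_ids = character(),
                          stringsAsFactors = FALSE)
    class(entries) <- c("jx_junction_db", "data.frame")
    attr(entries, "counts") <- c(junctions_in = nrow(junctions),
                                 windows_kept = n_windows, orfs = 0L,
                                 entries = 0L)
    return(entries)
  }
  n_orfs <- nrow(entries)
  all_ids <- vapply(split(entries$junction_id, entries$aa_sequence),
                    function(x) paste(unique(x), collapse = ","), character(1))
  keep <- !duplicated(entries$aa_sequence)
  entries <- entries[keep, , drop = FALSE]
  entries$all_junction_ids <- unname(all_ids[entries$aa_sequence])
  entries$entry_id <- sprintf("JP%06d", seq_len(nrow(entries)))
  entries <- entries[, c("entry_id", "junction_id", "frame", "aa_sequence",
                         "boundary_aa", "source_status", "all_junction_ids")]
  rownames(entries) <- NULL
  class(entries) <- c("jx_junction_db", "data.frame")
  attr(entries, "counts") <- c(junctions_in = nrow(junctions),
                               windows_kept = n_windows, orfs = n_orfs,
                               entries = nrow(entries))
  if (verbose) {
    message("junction database: ", nrow(junctions), " junctions in, ",
            n_windows, " windows kept, ", n_orfs, " spanning ORFs, ",
            nrow(entries), " unique entries")
  }
  entries
}

#' Write a junction database to protein FASTA
#'
#' Headers follow the grammar
#' `>JXN|<entry_id>|<junction_id>|frame=<f>|baa=<boundary_aa>`; sequences are
#' wrapped at 60 columns and records sorted by entry id.
#'
#' @param entries A `jx_junction_db` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_database_fasta <- function(entries, path) {
  if (anyDuplicated(entries$entry_id)) stop("duplicate entry_id")
  entries <- entries[order(entries$entry_id), , drop = FALSE]
  aa <- Biostrings::AAStringSet(entries$aa_sequence)
  names(aa) <- sprintf("JXN|%s|%s|frame=%s|baa=%d", entries$entry_id,
                       entries$junction_id, entries$frame,
                       entries$boundary_aa)
  Biostrings::writeXStringSet(aa, path, width = 60L)
  invisible(path)
}

#' Read a junction database written by [write_database_fasta()]
#'
#' @param path FASTA path.
#' @return A `jx_junction_db` data frame (without provenance merge metadata,
#'   which is not stored in headers).
#' @export
read_database_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  parts <- strsplit(names(aa), "|", fixed = TRUE)
  bad <- vapply(parts, function(p) length(p) != 5L || p[1L] != "JXN",
                logical(1))
  if (any(bad)) stop("malformed junction database header(s)")
  out <- data.frame(
    entry_id = vapply(parts, `[`, character(1), 2L),
    junction_id = vapply(parts, `[`, character(1), 3L),
    frame = sub("^frame=", "", vapply(parts, `[`, character(1), 4L)),
    aa_sequence = as.character(aa),
    boundary_aa = as.integer(sub("^baa=", "",
                                 vapply(parts, `[`, character(1), 5L))),
    source_status = NA_character_,
    all_junction_ids = NA_character_,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("jx_junction_db", "data.frame")
  out
}

# mirror a dataset: reverse-complement every chromosome, flip coordinates
# (p -> L - p) and strands. The junction-database amino-acid content must be
# invariant under this transform; used by the validation suite.
mirror_dataset <- function(genome, models = NULL, junctions = NULL) {
  lens <- setNames(Biostrings::width(genome), names(genome))
  g2 <- Biostrings::reverseComplement(genome)
  names(g2) <- names(genome)
  flip <- function(d) {
    L <- lens[d$chrom]
    s <- L - d$end
    e <- L - d$start
    d$start <- as.integer(s)
    d$end <- as.integer(e)
    d$strand <- ifelse(d$strand == "+", "-", "+")
    d
  }
  m2 <- NULL
  if (!is.null(models)) {
    e2 <- flip(models$exons)
    e2 <- e2[order(e2$transcript_id, e2$start), , drop = FALSE]
    m2 <- .gene_models_from_exons(e2)
  }
  j2 <- NULL
  if (!is.null(junctions)) {
    j2 <- flip(junctions)
    rownames(j2) <- NULL
  }
  list(genome = g2, models = m2, junctions = j2)
}
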