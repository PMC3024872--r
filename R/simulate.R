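#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generators. The defaults encode
#' the study conditions the pipeline is validated against: ~20% of emitted
#' junctions novel, ~5% of junctions identifiable by junction-straddling
#' tryptic peptides, a novel-candidate PSM subset whose naive false-positive
#' rate at the global threshold is ~0.38, and an mRNA-protein abundance
#' correlation of 0.53 on the log10 scale. Identical seed and configuration
#' give byte-identical outputs.
#'
#' @param seed Integer random seed.
#' @param n_genes Number of simulated genes.
#' @param exons_per_gene Integer range `c(min, max)` of exons per gene
#'   (>= 4, so every gene can host an exon-skip or alternative-acceptor
#'   event).
#' @param exon_len,intron_len Length ranges in nt. Exons must be at least
#'   `2 * flank_nt + 9` nt so engineered flank regions never collide.
#' @param n_chroms Number of synthetic chromosomes.
#' @param novel_junction_fraction Target fraction of emitted junctions that
#'   are novel (default 0.20).
#' @param target_identifiable_fraction Probability that a junction is
#'   engineered to be identifiable by a 6-30 aa spanning tryptic peptide
#'   (default 0.05).
#' @param flank_nt Exon flank per side used by the database builder.
#' @param n_ref_proteins,ref_protein_len Reference proteome size and length
#'   range.
#' @param n_psms Number of simulated PSMs (default 10000).
#' @param incorrect_psm_fraction Fraction of PSMs that are incorrect
#'   (spectrum matched to the wrong peptide); incorrect matches split evenly
#'   between targets and decoys.
#' @param novel_correct_fraction Fraction of *correct* PSMs whose peptide is
#'   a genuine junction-exclusive (novel) peptide.
#' @param subset_fp_rate Calibrated naive false-positive rate of the
#'   novel-candidate subset at the global FDR threshold (default 0.38).
#' @param fdr_target Global FDR the calibration anticipates (default 0.02).
#' @param correct_score_shape,incorrect_score_shape Beta shape parameters of
#'   the posterior-probability-like score mixture (defaults Beta(8,1) and
#'   Beta(1,8)).
#' @param n_expr_genes Cohort size for the expression generator.
#' @param log10_rpkm_mean,log10_rpkm_sd Log-normal RPKM parameters.
#' @param zero_rpkm_fraction Fraction of genes with zero RPKM (never
#'   detected).
#' @param detection_logistic Named vector `c(midpoint, slope)`: detection
#'   probability is `plogis(slope * (log10(rpkm) - midpoint))`.
#' @param target_abundance_correlation Target Pearson correlation between
#'   log10 RPKM and log10 spectral count over detected genes (default 0.53).
#' @param total_mapped_reads Library size used for RPKM arithmetic.
#' @param spectral_count_log10_intercept Intercept of the log-linear
#'   spectral-count model.
#' @return A `jx_sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 80L,
                       exons_per_gene = c(5L, 7L),
                       exon_len = c(180L, 260L),
                       intron_len = c(200L, 600L),
                       n_chroms = 2L,
                       novel_junction_fraction = 0.20,
                       target_identifiable_fraction = 0.05,
                       flank_nt = 75L,
                       n_ref_proteins = 150L,
                       ref_protein_len = c(120L, 300L),
                       n_psms = 10000L,
                       incorrect_psm_fraction = 0.30,
                       novel_correct_fraction = 0.02,
                       subset_fp_rate = 0.38,
                       fdr_target = 0.02,
                       correct_score_shape = c(8, 1),
                       incorrect_score_shape = c(1, 8),
                       n_expr_genes = 2000L,
                       log10_rpkm_mean = 1.0,
                       log10_rpkm_sd = 1.0,
                       zero_rpkm_fraction = 0.05,
                       detection_logistic = c(midpoint = 0.5, slope = 1.5),
                       target_abundance_correlation = 0.53,
                       total_mapped_reads = 2e7,
                       spectral_count_log10_intercept = 2.0) {
  cfg <- as.list(environment())
  fr <- c("novel_junction_fraction", "target_identifiable_fraction",
          "incorrect_psm_fraction", "novel_correct_fraction",
          "subset_fp_rate", "zero_rpkm_fraction")
  for (f in fr) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stop(f, " must be in [0, 1]")
  }
  if (abs(cfg$target_abundance_correlation) >= 1 ||
      cfg$target_abundance_correlation <= 0) {
    stop("target_abundance_correlation must be in (0, 1)")
  }
  for (r in c("exons_per_gene", "exon_len", "intron_len",
              "ref_protein_len")) {
    if (length(cfg[[r]]) != 2L || any(cfg[[r]] < 1L) ||
        cfg[[r]][2L] < cfg[[r]][1L]) {
      stop(r, " must be a positive c(min, max) range")
    }
  }
  if (cfg$exon_len[1L] < 3L) stop("exons shorter than 3 nt are infeasible")
  if (cfg$exons_per_gene[1L] < 4L) {
    stop("need at least 4 exons per gene to host novel splice events")
  }
  if (cfg$exon_len[1L] < 2L * cfg$flank_nt + 9L) {
    stop("minimum exon length must be at least 2*flank_nt + 9 nt ",
         "so engineered flank regions cannot collide")
  }
  class(cfg) <- "jx_sim_config"
  cfg
}

#' @export
print.jx_sim_config <- function(x, ...) {
  cat("Simulation config (seed", x$seed, "):", x$n_genes, "genes,",
      x$n_psms, "PSMs,", x$n_expr_genes, "expression genes\n")
  cat(sprintf("  novel junction fraction %.2f, identifiable fraction %.2f\n",
              x$novel_junction_fraction, x$target_identifiable_fraction))
  cat(sprintf("  incorrect PSM fraction %.2f, subset FP rate %.2f, target r %.2f\n",
              x$incorrect_psm_fraction, x$subset_fp_rate,
              x$target_abundance_correlation))
  invisible(x)
}

# codons free of stop/K/R/P in-frame: A G L S T V D E F M
.safe_codons <- c("GCT", "GGT", "CTG", "TCT", "ACT", "GTT", "GAT", "GAA",
                  "TTT", "ATG")
# 12-nt self-reverse-complementary cassette with a stop codon in every
# reading phase on both strands
.stop_cassette <- "TTAATTAATTAA"
.ALTACC_SHIFT <- 9L

.rand_nt <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

# transcript-oriented engineered flanks (flank_nt nt each side).
# identifiable: frame +0 of the window is stop-free with K at residue 20 and
# R at residue 30, giving a 10-aa spanning tryptic peptide at zero missed
# cleavages. non-identifiable: stop cassettes 20-32 nt from the boundary on
# both sides put a stop within ~11 residues of the junction in all six
# frames, so no stop-free spanning stretch can reach 30 residues.
.engineer_flanks <- function(identifiable, flank_nt = 75L) {
  stopifnot(flank_nt %% 3L == 0L, flank_nt >= 75L)
  nc <- flank_nt %/% 3L
  if (identifiable) {
    up <- paste0(paste(sample(.safe_codons, nc - 6L, TRUE), collapse = ""),
                 "AAA",
                 paste(sample(.safe_codons, 5L, TRUE), collapse = ""))
    down <- paste0(paste(sample(.safe_codons, 4L, TRUE), collapse = ""),
                   "CGT",
                   paste(sample(.safe_codons, nc - 5L, TRUE), collapse = ""))
  } else {
    up <- paste0(.rand_nt(flank_nt - 32L), .stop_cassette, .rand_nt(20L))
    down <- paste0(.rand_nt(20L), .stop_cassette, .rand_nt(flank_nt - 32L))
  }
  list(up = up, down = down)
}

.chars <- function(s) strsplit(s, "", fixed = TRUE)[[1L]]

.revcomp_chr <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# deterministic joint planner for genome, gene models and junctions.
# identifiability must be planted in the genome sequence, so structure,
# junction plan and sequence are drawn in one pass from cfg$seed; the public
# generators expose slices of the same plan.
.sim_plan <- function(cfg) {
  stopifnot(inherits(cfg, "jx_sim_config"))
  set.seed(cfg$seed)
  rint <- function(r, n = 1L) {
    if (r[1L] == r[2L]) rep(r[1L], n) else
      sample(seq(r[1L], r[2L]), n, replace = TRUE)
  }
  # per-gene probability of hosting one novel event so that the expected
  # novel fraction of emitted junctions matches the config (a hosting gene
  # trades one or two annotated introns for a single novel junction)
  K <- mean(seq(cfg$exons_per_gene[1L], cfg$exons_per_gene[2L])) - 1
  p_novel <- min(1, cfg$novel_junction_fraction * K /
                   (1 + 0.5 * cfg$novel_junction_fraction))

  chroms <- sprintf("chrS%d", seq_len(cfg$n_chroms))
  cursor <- setNames(rep(0L, cfg$n_chroms), chroms)
  exons <- list(); junctions <- list(); plant <- list()
  jn <- 0L
  for (g in seq_len(cfg$n_genes)) {
    gid <- sprintf("G%04d", g)
    chrom <- chroms[((g - 1L) %% cfg$n_chroms) + 1L]
    strand <- if (g %% 2L) "+" else "-"
    k_ex <- rint(cfg$exons_per_gene)
    ex_len <- rint(cfg$exon_len, k_ex)
    in_len <- rint(cfg$intron_len, k_ex - 1L)
    gap <- rint(c(150L, 400L))
    pos <- cursor[[chrom]] + gap
    ex_start <- integer(k_ex); ex_end <- integer(k_ex)
    for (i in seq_len(k_ex)) {
      ex_start[i] <- pos
      ex_end[i] <- pos + ex_len[i]
      pos <- ex_end[i] + if (i < k_ex) in_len[i] else 0L
    }
    cursor[[chrom]] <- pos
    exons[[g]] <- data.frame(gene_id = gid,
                             transcript_id = paste0(gid, ".t1"),
                             chrom = chrom, strand = strand,
                             start = ex_start, end = ex_end,
                             stringsAsFactors = FALSE)
    n_int <- k_ex - 1L
    int_s <- ex_end[-k_ex]; int_e <- ex_start[-1L]
    host <- n_int >= 3L && runif(1L) < p_novel
    type <- if (host) sample(c("skip", "altacc"), 1L) else "none"
    if (type == "skip") {
      known_idx <- seq_len(n_int - 2L)
      nov <- c(int_s[n_int - 1L], int_e[n_int])
    } else if (type == "altacc") {
      known_idx <- c(seq_len(n_int - 2L), n_int)
      nov <- c(int_s[n_int - 1L], int_e[n_int - 1L] + .ALTACC_SHIFT)
    } else {
      known_idx <- seq_len(n_int)
      nov <- NULL
    }
    add_j <- function(s, e, status, jtype) {
      jn <<- jn + 1L
      ident <- runif(1L) < cfg$target_identifiable_fraction
      rc <- if (status == "known") rnbinom(1L, mu = 50, size = 5) + 1L else
        rnbinom(1L, mu = 8, size = 3) + 1L
      junctions[[jn]] <<- data.frame(
        junction_id = sprintf("J%05d", jn), chrom = chrom, strand = strand,
        start = s, end = e, read_count = as.integer(rc), status = status,
        gene_id = gid, type = jtype, identifiable = ident,
        stringsAsFactors = FALSE)
      fl <- .engineer_flanks(ident, cfg$flank_nt)
      plant[[jn]] <<- list(chrom = chrom, strand = strand, s = s, e = e,
                           up = fl$up, down = fl$down)
    }
    for (i in known_idx) add_j(int_s[i], int_e[i], "known", "annotated")
    if (!is.null(nov)) add_j(nov[1L], nov[2L], "novel", type)
  }
  exons <- do.call(rbind, exons)
  truth <- do.call(rbind, junctions)
  rownames(truth) <- NULL

  # random genome, then engineered flank regions written over exon sequence
  chrom_len <- cursor + 200L
  seqs <- lapply(chrom_len, function(L) sample(c("A", "C", "G", "T"), L,
                                               replace = TRUE))
  fl <- cfg$flank_nt
  for (p in plant) {
    up_idx <- (p$s - fl + 1L):p$s          # 1-based genomic, left of intron
    down_idx <- (p$e + 1L):(p$e + fl)      # right of intron end
    if (p$strand == "+") {
      seqs[[p$chrom]][up_idx] <- .chars(p$up)
      seqs[[p$chrom]][down_idx] <- .chars(p$down)
    } else {
      seqs[[p$chrom]][down_idx] <- .chars(.revcomp_chr(p$up))
      seqs[[p$chrom]][up_idx] <- .chars(.revcomp_chr(p$down))
    }
  }
  genome <- Biostrings::DNAStringSet(vapply(seqs, paste, character(1),
                                            collapse = ""))
  names(genome) <- chroms
  models <- .gene_models_from_exons(exons, genome = genome)
  list(genome = genome, models = models, truth = truth)
}

#' Simulate a genome and gene models
#'
#' Multi-exon genes on both strands of synthetic chromosomes. The exon
#' sequence around every planned splice site is engineered so that each
#' junction's tryptic identifiability is known by construction (see
#' [sim_junctions()]); identical seed and config give identical output.
#'
#' @param cfg A [sim_config()] object.
#' @return List with `genome` (a [Biostrings::DNAStringSet]) and `models`
#'   (a `jx_gene_models`).
#' @export
sim_genome_models <- function(cfg) {
  plan <- .sim_plan(cfg)
  plan[c("genome", "models")]
}

#' Simulate splice junctions with planted ground truth
#'
#' Known junctions are annotated introns of the simulated genes; novel
#' junctions arise by exon skipping or alternative-acceptor shifts, at an
#' overall novel fraction matching `cfg$novel_junction_fraction`. Each
#' junction carries a planted identifiability flag realised by engineering
#' K/R placement (identifiable: an in-frame 10-residue spanning tryptic
#' peptide) or all-frame stop cassettes (non-identifiable: no stop-free
#' spanning stretch can reach 30 residues) in its exon flanks.
#'
#' @param cfg A [sim_config()] object.
#' @param models Optional `jx_gene_models` from [sim_genome_models()] with
#'   the same config; checked for consistency when supplied.
#' @return List with `junctions` (an unclassified `jx_junctions` data
#'   frame) and `truth` (junction id, status, gene, event type,
#'   identifiability flag, read count).
#' @export
sim_junctions <- function(cfg, models = NULL) {
  plan <- .sim_plan(cfg)
  if (!is.null(models) &&
      !identical(models$exons, plan$models$exons)) {
    stop("supplied models do not match this configuration/seed")
  }
  truth <- plan$truth
  j <- truth[, c("junction_id", "chrom", "strand", "start", "end",
                 "read_count")]
  j$status <- "unclassified"
  j$gene_id <- NA_character_
  rownames(j) <- NULL
  class(j) <- c("jx_junctions", "data.frame")
  list(junctions = j,
       truth = truth[, c("junction_id", "status", "gene_id", "type",
                         "identifiable", "read_count")])
}

#' Simulate a reference proteome
#'
#' Random protein sequences over the 20-residue alphabet (uniform), so
#' tryptic sites are abundant. Accessions are `REF%04d`; the output is a
#' synthetic stand-in for a curated proteome such as IPI.
#'
#' @param cfg A [sim_config()] object.
#' @return A `jx_protein_db` with origin `"reference"`.
#' @export
sim_reference_proteome <- function(cfg) {
  stopifnot(inherits(cfg, "jx_sim_config"))
  set.seed(cfg$seed + 101L)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]
  lens <- sample(seq(cfg$ref_protein_len[1L], cfg$ref_protein_len[2L]),
                 cfg$n_ref_proteins, replace = TRUE)
  seqs <- vapply(lens, function(L) paste(sample(aa, L, TRUE), collapse = ""),
                 character(1))
  protein_db(sprintf("REF%04d", seq_len(cfg$n_ref_proteins)), seqs)
}

# all tryptic peptides (mc <= 1) of MS-compatible length from a sequence set
.peptide_pool <- function(seqs, min_len = 6L, max_len = 30L) {
  unique(unlist(lapply(seqs, function(s) {
    d <- tryptic_digest(s, max_missed = 1L)
    n <- nchar(d$sequence)
    d$sequence[n >= min_len & n <= max_len]
  })))
}

.in_cat <- function(peps, cat) {
  if (!nzchar(cat)) return(rep(FALSE, length(peps)))
  vapply(peps, function(p) grepl(p, cat, fixed = TRUE), logical(1))
}

#' Simulate peptide-spectrum matches with truth labels
#'
#' Correct PSMs draw peptides from target entries with Beta(8,1) scores;
#' incorrect PSMs draw uniformly from the stated class with Beta(1,8)
#' scores and split evenly between targets and decoys, so the decoy count
#' above a threshold estimates the incorrect-target count. The
#' novel-candidate class is enriched for incorrect matches (equally on
#' junction targets and junction decoys) so that its naive false-positive
#' rate at the anticipated global threshold matches `cfg$subset_fp_rate`;
#' the enrichment is solved from the Beta score survivals, not tuned.
#'
#' @param cfg A [sim_config()] object.
#' @param combined_db A combined target+decoy `jx_protein_db` from
#'   [assemble_combined_db()] (reference + junction entries + decoys).
#' @return List with `psms` (a `jx_psms` data frame), `truth` (spectrum id,
#'   `"correct"`/`"incorrect"`, intended class) and `calibration` (the
#'   anticipated global threshold and incorrect-allocation counts).
#' @export
sim_psms <- function(cfg, combined_db) {
  stopifnot(inherits(cfg, "jx_sim_config"))
  if (!any(combined_db$origin == "decoy")) {
    stop("combined_db must contain decoys")
  }
  set.seed(cfg$seed + 202L)
  db <- combined_db
  grp <- ifelse(db$origin == "decoy",
                ifelse(startsWith(db$accession, "DECOY_JXN|"),
                       "jxn_d", "ref_d"),
                ifelse(db$origin == "junction", "jxn_t", "ref_t"))
  cat_of <- function(g) paste(db$sequence[grp == g], collapse = "\1")
  cats <- sapply(c("ref_t", "jxn_t", "ref_d", "jxn_d"), cat_of)
  pool <- lapply(c(ref_t = "ref_t", jxn_t = "jxn_t", ref_d = "ref_d",
                   jxn_d = "jxn_d"),
                 function(g) .peptide_pool(db$sequence[grp == g]))
  if (!length(pool$jxn_t)) {
    stop("no junction target peptides; database has no junction entries")
  }
  # junction-exclusive (novel) peptides and junction-decoy-exclusive decoys
  novel_pool <- pool$jxn_t[!.in_cat(pool$jxn_t, cats["ref_t"])]
  jxn_d_pool <- pool$jxn_d[!.in_cat(pool$jxn_d, cats["ref_t"]) &
                             !.in_cat(pool$jxn_d, cats["jxn_t"]) &
                             !.in_cat(pool$jxn_d, cats["ref_d"])]
  ref_d_pool <- pool$ref_d[!.in_cat(pool$ref_d, cats["ref_t"]) &
                             !.in_cat(pool$ref_d, cats["jxn_t"])]
  if (!length(novel_pool)) stop("no junction-exclusive peptides in database")
  if (!length(jxn_d_pool)) stop("no junction-decoy-exclusive peptides")

  N <- cfg$n_psms
  I <- round(N * cfg$incorrect_psm_fraction)
  C <- N - I
  n_nc <- round(C * cfg$novel_correct_fraction)
  n_kc <- C - n_nc
  cs <- cfg$correct_score_shape; is_ <- cfg$incorrect_score_shape
  S_cor <- function(t) 1 - stats::pbeta(t, cs[1L], cs[2L])
  S_inc <- function(t) 1 - stats::pbeta(t, is_[1L], is_[2L])
  I_dec <- I %/% 2L
  I_tgt <- I - I_dec
  # anticipated global threshold from the expected mixture, then the
  # junction-incorrect allocation that realises the target subset FP rate
  f_exp <- function(t) (I_dec * S_inc(t)) /
    (C * S_cor(t) + I_tgt * S_inc(t))
  tstar <- uniroot(function(t) f_exp(t) - cfg$fdr_target,
                   c(1e-4, 1 - 1e-4))$root
  r <- cfg$subset_fp_rate
  n_ij <- round(n_nc * S_cor(tstar) * r / ((1 - r) * S_inc(tstar)))
  if (n_ij > I_tgt - 50L) {
    warning("subset enrichment capped by the incorrect-PSM budget")
    n_ij <- max(0L, I_tgt - 50L)
  }
  n_ir_t <- I_tgt - n_ij
  n_ij_d <- min(n_ij, I_dec)
  n_ir_d <- I_dec - n_ij_d

  samp <- function(p, n) if (n > 0L) sample(p, n, replace = TRUE) else
    character(0)
  pep <- c(samp(pool$ref_t, n_kc), samp(novel_pool, n_nc),
           samp(novel_pool, n_ij), samp(pool$ref_t, n_ir_t),
           samp(jxn_d_pool, n_ij_d), samp(ref_d_pool, n_ir_d))
  truth <- c(rep("correct", n_kc + n_nc), rep("incorrect", I))
  cls <- c(rep("known_correct", n_kc), rep("novel_correct", n_nc),
           rep("novel_incorrect", n_ij), rep("known_incorrect", n_ir_t),
           rep("jxn_decoy", n_ij_d), rep("ref_decoy", n_ir_d))
  score <- c(rbeta(n_kc + n_nc, cs[1L], cs[2L]),
             rbeta(I, is_[1L], is_[2L]))

  u <- unique(pep)
  prot <- vapply(u, function(p) {
    paste(db$accession[grepl(p, db$sequence, fixed = TRUE)], collapse = ";")
  }, character(1))
  ord <- sample(length(pep))
  psms <- data.frame(spectrum_id = sprintf("sp%06d", seq_along(pep)),
                     peptide = pep[ord], probability = score[ord],
                     proteins = unname(prot[pep[ord]]),
                     quality = round(runif(length(pep), 0.5, 3), 2),
                     stringsAsFactors = FALSE)
  cl <- .classify_psm_accessions(strsplit(psms$proteins, ";", fixed = TRUE))
  psms$is_decoy <- cl$is_decoy
  psms$novelty <- cl$novelty
  psms <- psms[, c("spectrum_id", "peptide", "probability", "proteins",
                   "is_decoy", "novelty", "quality")]
  class(psms) <- c("jx_psms", "data.frame")
  list(psms = psms,
       truth = data.frame(spectrum_id = psms$spectrum_id,
                          truth = truth[ord], class = cls[ord],
                          stringsAsFactors = FALSE),
       calibration = list(anticipated_threshold = tstar,
                          n_incorrect_junction_target = n_ij,
                          n_incorrect_junction_decoy = n_ij_d))
}

#' Simulate gene expression coupled to MS detection
#'
#' Log-normal RPKM (with a zero-RPKM class that is never detected),
#' detection sampled from a logistic in log10 RPKM, and spectral counts
#' log-linear in RPKM with Gaussian noise whose standard deviation is solved
#' from the realised spread of detected log10 RPKM so that the Pearson
#' correlation targets `cfg$target_abundance_correlation`. Read counts are
#' integers and RPKM is recomputed from them, so the RPKM invariant holds
#' exactly.
#'
#' @param cfg A [sim_config()] object.
#' @param gene_ids Optional gene ids (default `EG%05d` over
#'   `cfg$n_expr_genes`).
#' @return Data frame with columns `gene_id`, `exon_model_length_nt`,
#'   `mapped_reads`, `total_mapped_reads`, `rpkm`, `detected_by_ms`,
#'   `spectral_count`.
#' @export
sim_expression <- function(cfg, gene_ids = NULL) {
  stopifnot(inherits(cfg, "jx_sim_config"))
  set.seed(cfg$seed + 303L)
  n <- if (is.null(gene_ids)) cfg$n_expr_genes else length(gene_ids)
  ids <- if (is.null(gene_ids)) sprintf("EG%05d", seq_len(n)) else gene_ids
  zero <- runif(n) < cfg$zero_rpkm_fraction
  len <- sample(800:3000, n, replace = TRUE)
  x <- rnorm(n, cfg$log10_rpkm_mean, cfg$log10_rpkm_sd)
  reads <- ifelse(zero, 0L,
                  pmax(1, round(10^x * len * cfg$total_mapped_reads / 1e9)))
  rpkm <- compute_rpkm(reads, len, cfg$total_mapped_reads)
  lp <- cfg$detection_logistic
  pdet <- ifelse(rpkm > 0,
                 plogis(lp[["slope"]] * (log10(pmax(rpkm, 1e-12)) -
                                           lp[["midpoint"]])), 0)
  det <- runif(n) < pdet
  sc <- numeric(n)
  if (any(det)) {
    xd <- log10(rpkm[det])
    rho <- cfg$target_abundance_correlation
    sde <- sd(xd) * sqrt(1 / rho^2 - 1)
    y <- cfg$spectral_count_log10_intercept + xd + rnorm(sum(det), 0, sde)
    sc[det] <- pmax(1, round(10^pmin(y, 7)))
  }
  data.frame(gene_id = ids, exon_model_length_nt = len,
             mapped_reads = as.integer(round(reads)),
             total_mapped_reads = cfg$total_mapped_reads, rpkm = rpkm,
             detected_by_ms = det, spectral_count = sc,
             stringsAsFactors = FALSE)
}

#' Write a complete simulated dataset to disk
#'
#' Runs every generator plus the downstream pipeline stages and writes
#' standard-format files: genome FASTA, gene-model GTF, junction BED,
#' reference and combined-database FASTA, PSM and truth TSVs, and
#' expression/detection TSVs.
#'
#' @param cfg A [sim_config()] object.
#' @param outdir Output directory (created if missing).
#' @return Named list of file paths, invisibly.
#' @export
sim_write_all <- function(cfg, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(outdir, f)
  gm <- sim_genome_models(cfg)
  sj <- sim_junctions(cfg)
  Biostrings::writeXStringSet(gm$genome, p("genome.fa"), width = 60L)
  write_gene_models_gtf(gm$models, p("models.gtf"))
  write_junctions_bed(sj$junctions, p("junctions.bed"))
  write.table(sj$truth, p("truth_junctions.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  cj <- classify_junctions(sj$junctions, gm$models)
  db <- build_junction_database(cj, gm$genome, gm$models,
                                flank_nt = cfg$flank_nt, verbose = FALSE)
  write_database_fasta(db, p("junction_db.fa"))
  ref <- sim_reference_proteome(cfg)
  write_protein_fasta(ref, p("reference.fa"))
  combined <- assemble_combined_db(ref, db)
  write_protein_fasta(combined, p("combined_db.fa"))
  sp <- sim_psms(cfg, combined)
  write_psm_table(sp$psms, p("psms.tsv"))
  write.table(sp$truth, p("truth_psms.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  ex <- sim_expression(cfg)
  write.table(ex[, c("gene_id", "exon_model_length_nt", "mapped_reads",
                     "total_mapped_reads")],
              p("expression.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(ex[ex$detected_by_ms, c("gene_id", "spectral_count")],
              p("detection.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(list(genome = p("genome.fa"), models = p("models.gtf"),
                 junctions = p("junctions.bed"),
                 truth_junctions = p("truth_junctions.tsv"),
                 junction_db = p("junction_db.fa"),
                 reference = p("reference.fa"),
                 combined_db = p("combined_db.fa"), psms = p("psms.tsv"),
                 truth_psms = p("truth_psms.tsv"),
                 expression = p("expression.tsv"),
                 detection = p("detection.tsv")))
}
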