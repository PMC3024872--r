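test_that("decoy generation reverses sequences and doubles the database", {
  db <- protein_db(c("P1", "P2"), c("PEPTIDER", "MKAW"))
  d <- generate_decoys(db)
  expect_equal(nrow(d), 4L)
  expect_equal(d$sequence[d$accession == "DECOY_P1"], "REDITPEP")
  expect_equal(sort(nchar(d$sequence[d$origin == "decoy"])),
               sort(nchar(db$sequence)))
  expect_error(generate_decoys(d), "already contains decoys")
  clash <- protein_db(c("P1", "DECOY_P1"), c("AAA", "CCC"))
  expect_error(generate_decoys(clash), "collides")
  # palindromic target: decoy equals the target but is kept
  expect_message(pal <- generate_decoys(protein_db("P", "AGA")),
                 "palindromic")
  expect_equal(pal$sequence, c("AGA", "AGA"))
})

test_that("combined database assembly counts and collision policy", {
  ref <- protein_db(paste0("R", 1:10), random_protein_seqs(10))
  jdb <- data.frame(entry_id = sprintf("JP%06d", 1:5),
                    junction_id = paste0("j", 1:5), frame = "+0",
                    aa_sequence = random_protein_seqs(5),
                    boundary_aa = 10L, source_status = "novel",
                    all_junction_ids = paste0("j", 1:5),
                    stringsAsFactors = FALSE)
  class(jdb) <- c("jx_junction_db", "data.frame")
  comb <- assemble_combined_db(ref, jdb)
  expect_equal(nrow(comb), 30L)
  expect_equal(sum(comb$origin == "decoy"), 15L)
  expect_true(all(startsWith(comb$accession[comb$origin == "junction"],
                             "JXN|")))
  # written FASTA is parseable by a standard reader
  f <- tempfile(fileext = ".fa")
  write_protein_fasta(comb, f)
  aa <- Biostrings::readAAStringSet(f)
  expect_equal(length(aa), 30L)
  expect_equal(as.character(aa[["JXN|JP000001"]]), jdb$aa_sequence[1])
  # junction sequence identical to a reference sequence is retained
  jdb2 <- jdb
  jdb2$aa_sequence[1] <- ref$sequence[1]
  expect_equal(nrow(assemble_combined_db(ref, jdb2)), 30L)
})

test_that("PSM tables classify decoy and novelty status from accessions", {
  f <- write_tmp(c(
    "spectrum_id\tpeptide\tprobability\tproteins\tquality",
    "s1\tPEPTIDEK\t0.99\tDECOY_R1\t2.0",
    "s2\tAW[147]CK\t0.95\tJXN|JP000001\t1.5",
    "s3\tMMMK\t0.80\tJXN|JP000002;R2\t0.5",
    "s4\tQQQK\t1.50\tR1\t2.0",
    "s5\tLLLK\t0.70\tDECOY_R1;R1\t2.0"), ".tsv")
  expect_warning(p <- read_psm_table(f), "probability")
  expect_equal(nrow(p), 4L)
  expect_true(p$is_decoy[p$spectrum_id == "s1"])
  expect_equal(p$novelty[p$spectrum_id == "s1"], "decoy")
  # modification annotation stripped
  expect_equal(p$peptide[p$spectrum_id == "s2"], "AWCK")
  expect_equal(p$novelty[p$spectrum_id == "s2"], "novel_candidate")
  # known takes precedence over novel when both match
  expect_equal(p$novelty[p$spectrum_id == "s3"], "known")
  # a target accession among decoys makes the PSM a target
  expect_false(p$is_decoy[p$spectrum_id == "s5"])
  # unknown accessions are rejected when a database is given
  db <- protein_db("R1", "AAAA")
  expect_warning(p2 <- read_psm_table(f, db = generate_decoys(db)),
                 "unknown")
  expect_equal(p2$spectrum_id, c("s1", "s5"))
})

test_that("quality filtering keeps PSMs at or above the cutoff", {
  s <- default_sim_psms()
  kept <- filter_quality(s$psms, min_quality = 1)
  expect_true(all(kept$quality >= 1))
  expect_lt(nrow(kept), nrow(s$psms))
})

test_that("FDR curve implements N_decoy / N_target with monotone q", {
  mk <- function(score, dec) {
    d <- data.frame(spectrum_id = paste0("s", seq_along(score)),
                    peptide = "PEPK", probability = score,
                    proteins = ifelse(dec, "DECOY_R1", "R1"),
                    is_decoy = dec, novelty = ifelse(dec, "decoy", "known"),
                    quality = NA_real_, stringsAsFactors = FALSE)
    class(d) <- c("jx_psms", "data.frame")
    d
  }
  # 98 targets and 2 decoys above the lowest threshold
  p <- mk(seq(0.99, 0.01, length.out = 100),
          c(rep(FALSE, 50), TRUE, rep(FALSE, 48), TRUE))
  cv <- estimate_fdr_curve(p)
  i <- length(cv$thresholds)
  expect_equal(cv$n_target[i], 98L)
  expect_equal(cv$n_decoy[i], 2L)
  expect_equal(cv$fdr[i], 2 / 98, tolerance = 1e-12)
  # zero decoys above the top threshold -> fdr 0
  expect_equal(cv$fdr[1], 0)
  expect_true(all(diff(cv$q) >= 0))
  expect_true(all(diff(cv$n_target) >= 0) && all(diff(cv$n_decoy) >= 0))
  expect_error(estimate_fdr_curve(mk(0.9, TRUE)), "all-decoy")
})

test_that("threshold selection is the most permissive q <= target", {
  p <- data.frame(probability = c(0.95, 0.9, 0.8, 0.5, 0.4),
                  is_decoy = c(FALSE, FALSE, FALSE, TRUE, FALSE))
  cv <- estimate_fdr_curve(p)
  # q: 0, 0, 0, 1/3, 1/4 -> monotonized from below: 0,0,0,1/4,1/4
  expect_equal(threshold_at_fdr(cv, 0.30), 0.4)
  expect_equal(threshold_at_fdr(cv, 0.10), 0.8)
  expect_equal(threshold_at_fdr(cv, 1.0), 0.4)
  expect_error(threshold_at_fdr(cv, 0))
  # monotonicity: stricter target never lowers the threshold
  alphas <- c(0.5, 0.2, 0.1, 0.05)
  thr <- vapply(alphas, function(a)
    suppressWarnings(threshold_at_fdr(cv, a)), numeric(1))
  expect_true(all(diff(thr[!is.na(thr)]) >= 0))
})

test_that("passing sets never contain more decoys than alpha allows", {
  s <- default_sim_psms()
  cv <- estimate_fdr_curve(s$psms)
  for (a in c(0.01, 0.02, 0.05)) {
    thr <- threshold_at_fdr(cv, a)
    nd <- sum(s$psms$is_decoy & s$psms$probability >= thr)
    nt <- sum(!s$psms$is_decoy & s$psms$probability >= thr)
    expect_lte(nd / max(1, nt), a)
  }
})

test_that("subset FDR threshold is stricter than the global one", {
  s <- default_sim_psms()
  g <- fdr_filter(s$psms, 0.02)
  sub <- subset_fdr_filter(s$psms, 0.02)
  expect_gt(sub$threshold, g$threshold)
  expect_true(all(sub$psms$novelty == "novel_candidate"))
  expect_true(all(sub$psms$probability >= sub$threshold))
  # degenerate case: subset identical to the full set gives the global
  # threshold
  all_novel <- s$psms
  all_novel$novelty[!all_novel$is_decoy] <- "novel_candidate"
  all_novel$proteins <- ifelse(all_novel$is_decoy, "DECOY_JXN|X", "JXN|X")
  cl <- jxpepdb:::.classify_psm_accessions(
    strsplit(all_novel$proteins, ";", fixed = TRUE))
  all_novel$is_decoy <- cl$is_decoy
  all_novel$novelty <- cl$novelty
  expect_equal(subset_fdr_filter(all_novel, 0.02)$threshold,
               fdr_filter(all_novel, 0.02)$threshold)
  # unattainable target (all decoys outscore all targets): empty passing
  # set, not an error
  few <- all_novel[1:20, ]
  few$is_decoy[1:10] <- TRUE
  few$novelty[1:10] <- "decoy"
  few$proteins[1:10] <- "DECOY_JXN|X"
  few$probability <- c(seq(0.90, 0.99, length.out = 10),
                       seq(0.10, 0.50, length.out = 10))
  res <- subset_fdr_filter(few, 0.001)
  expect_equal(nrow(res$psms), 0L)
})

test_that("subset filter warns when the subset has no decoys", {
  p <- data.frame(spectrum_id = "s1", peptide = "AAAK", probability = 0.99,
                  proteins = "JXN|JP1", is_decoy = FALSE,
                  novelty = "novel_candidate", quality = NA_real_,
                  stringsAsFactors = FALSE)
  class(p) <- c("jx_psms", "data.frame")
  expect_warning(res <- subset_fdr_filter(p), "no junction-decoy")
  expect_true(is.na(res$threshold))
})

test_that("mismatch distance matches the naive oracle", {
  ref <- protein_db(paste0("R", 1:8), random_protein_seqs(8, c(20L, 60L)))
  # verbatim presence -> 0
  pep <- substr(ref$sequence[3], 5, 14)
  expect_equal(min_mismatch_distance(pep, ref), 0L)
  # empty reference -> peptide length
  expect_equal(min_mismatch_distance("PEPTIDE", character(0)), 7L)
  # reference shorter than the peptide -> peptide length
  expect_equal(min_mismatch_distance("PEPTIDEPEPTIDE", "AW"), 14L)
  set.seed(31)
  for (rep in 1:40) {
    p <- random_peptide(sample(6:15, 1))
    for (il in c(TRUE, FALSE)) {
      expect_equal(min_mismatch_distance(p, ref, il_equivalent = il),
                   oracle_min_mismatch(p, ref$sequence, il_equivalent = il),
                   info = paste(p, il))
    }
  }
})

test_that("I/L equivalence makes isobaric peptides indistinguishable", {
  ref <- "AAAILVKAAA"
  expect_equal(min_mismatch_distance("ILVK", ref), 0L)
  expect_equal(min_mismatch_distance("LIVK", ref), 0L)
  expect_equal(min_mismatch_distance("LIVK", ref, il_equivalent = FALSE), 2L)
})

test_that("homology filter removes peptides within 3 mismatches", {
  ref <- protein_db("R1", "GGGGWWWWGGGGHHHH")
  mk <- function(peps) {
    d <- data.frame(spectrum_id = paste0("s", seq_along(peps)),
                    peptide = peps, probability = 0.99,
                    proteins = "JXN|JP1", is_decoy = FALSE,
                    novelty = "novel_candidate", quality = NA_real_,
                    stringsAsFactors = FALSE)
    class(d) <- c("jx_psms", "data.frame")
    d
  }
  # distances to "WWWWGGGG": 0, 2, 3 mismatches
  psms <- mk(c("WWWWGGGG", "WWAWGGGA", "WAAWGGGA"))
  kept <- homology_filter(psms, ref, min_mismatches = 3)
  expect_equal(kept$peptide, "WAAWGGGA")
  expect_equal(kept$min_mismatch, 3L)
  # min_mismatches = 0 is the identity
  kept0 <- homology_filter(psms, ref, min_mismatches = 0)
  expect_equal(kept0$peptide, psms$peptide)
  # I <-> L substitutions alone leave distance 0, so the peptide is removed
  ref2 <- protein_db("R1", "AAAAIIIIKAAA")
  psmIL <- mk("AALLLIK")
  expect_equal(nrow(homology_filter(psmIL, ref2, 1)), 0L)
  # ... but counts as real mismatches when I/L equivalence is off
  expect_equal(nrow(homology_filter(psmIL, ref2, 3,
                                    il_equivalent = FALSE)), 1L)
  expect_error(homology_filter(default_sim_psms()$psms[1:3, ], ref))
})
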