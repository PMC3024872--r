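test_that("junction windows splice full flanks with the boundary at flank_nt", {
  td <- tiny_dataset()
  j <- classify_junctions(td$junctions, td$models)
  w <- extract_junction_window(j[1, ], td$genome, td$models)
  expect_equal(nchar(w$nt_sequence), 150L)
  expect_equal(w$boundary_nt, 75L)
  # window is upstream-exon tail + downstream-exon head, intron removed
  chrom <- as.character(td$genome[[1]])
  expect_equal(w$nt_sequence,
               paste0(substr(chrom, 26, 100), substr(chrom, 151, 225)))
})

test_that("junctions with short exon flanks are filtered", {
  td <- tiny_dataset()
  j <- classify_junctions(td$junctions, td$models)
  # upstream exon has 100 nt; demand more than available
  expect_null(extract_junction_window(j[1, ], td$genome, td$models,
                                      flank_nt = 120L))
  # exon-boundary clipping: a 40 nt upstream exon cannot give a 75 nt flank
  m2 <- td$models
  m2$exons$start[1] <- 60L
  m2 <- jxpepdb:::.gene_models_from_exons(m2$exons)
  expect_null(extract_junction_window(j[1, ], td$genome, m2))
  # without models the same junction is clipped at chromosome bounds only
  expect_false(is.null(extract_junction_window(j[1, ], td$genome, m2,
                                               genomic_flanks = TRUE)))
})

test_that("minus-strand windows are the reverse complement of the plus
           construction with a remapped boundary", {
  td <- tiny_dataset()
  jp <- classify_junctions(td$junctions, td$models)
  jm <- jp
  jm$strand <- "-"
  wp <- extract_junction_window(jp[1, ], td$genome, NULL)
  wm <- extract_junction_window(jm[1, ], td$genome, NULL)
  expect_equal(wm$nt_sequence, oracle_revcomp(wp$nt_sequence))
  expect_equal(wm$boundary_nt, 150L - wp$boundary_nt)
})

test_that("six-frame translation matches a hand-coded codon table", {
  w <- list(nt_sequence = "ATGAAA", boundary_nt = 3L)
  tr <- six_frame_translate(w)
  expect_equal(tr$aa[tr$frame == "+0"], "MK")
  expect_equal(tr$aa[tr$frame == "-0"], "FH")  # revcomp TTTCAT

  set.seed(11)
  for (rep in 1:20) {
    nt <- paste(sample(c("A", "C", "G", "T", "N"), 150,
                       prob = c(.24, .24, .24, .24, .04), replace = TRUE),
                collapse = "")
    tr <- six_frame_translate(list(nt_sequence = nt, boundary_nt = 75L))
    for (f in 0:2) {
      expect_equal(tr$aa[tr$frame == paste0("+", f)],
                   oracle_translate(nt, f))
      expect_equal(tr$aa[tr$frame == paste0("-", f)],
                   oracle_translate(oracle_revcomp(nt), f))
    }
  }
})

test_that("frame boundary maps to the first codon using downstream bases", {
  # boundary at nt 75: frame +0 codon 25 covers nts 75-77
  tr <- six_frame_translate(list(nt_sequence = strrep("ACG", 50),
                                 boundary_nt = 75L))
  expect_equal(tr$boundary_aa[tr$frame == "+0"], 25L)
  # frame +1 codon 24 covers nts 73-75, overlapping the boundary nucleotide
  expect_equal(tr$boundary_aa[tr$frame == "+1"], 24L)
  # frame +2 codon 24 covers nts 74-76, also straddling
  expect_equal(tr$boundary_aa[tr$frame == "+2"], 24L)
})

test_that("spanning-ORF extraction applies length, stop and boundary rules", {
  mk <- function(aa, b) data.frame(frame = "+0", aa = aa, boundary_aa = b,
                                   stringsAsFactors = FALSE)
  # 50-aa stop-free frame, boundary 25 -> one entry with boundary 25
  o <- extract_spanning_orfs(mk(strrep("A", 50), 25L), junction_id = "j")
  expect_equal(nrow(o), 1L)
  expect_equal(o$boundary_aa, 25L)
  # stop at residue 10 (0-based), boundary 25 -> segment [11,50) of 39 aa
  aa <- paste0(strrep("A", 10), "*", strrep("C", 39))
  o <- extract_spanning_orfs(mk(aa, 25L))
  expect_equal(nrow(o), 1L)
  expect_equal(nchar(o$aa_sequence), 39L)
  expect_equal(o$boundary_aa, 14L)
  # below the minimum ORF length: nothing
  expect_equal(nrow(extract_spanning_orfs(mk(aa, 25L), min_orf_len = 40L)),
               0L)
  # segment not spanning the boundary: nothing
  expect_equal(nrow(extract_spanning_orfs(mk(strrep("A", 50), 0L))), 0L)
  expect_equal(nrow(extract_spanning_orfs(mk(strrep("A", 50), 50L))), 0L)
  # X at the junction-straddling codon discards the segment
  aa_x <- paste0(strrep("A", 25), "X", strrep("A", 24))
  expect_equal(nrow(extract_spanning_orfs(mk(aa_x, 25L))), 0L)
})

test_that("windows with stops near the boundary in all frames give no ORFs", {
  # the simulator's non-identifiable construction is exactly this case
  set.seed(5)
  cass <- "TTAATTAATTAA"
  rnt <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                           collapse = "")
  for (rep in 1:10) {
    nt <- paste0(rnt(43), cass, rnt(20), rnt(20), cass, rnt(43))
    tr <- six_frame_translate(list(nt_sequence = nt, boundary_nt = 75L))
    expect_equal(nrow(extract_spanning_orfs(tr)), 0L)
  }
})

test_that("database build matches a hand-enumerated tiny fixture", {
  td <- tiny_dataset()
  j <- classify_junctions(td$junctions, td$models)
  db <- build_junction_database(j, td$genome, td$models, verbose = FALSE)
  # the engineered +0 frame is stop-free over all 50 codons and must be
  # present; boundary residue 25
  eng <- db[db$frame == "+0", ]
  expect_equal(nrow(eng), 1L)
  expect_equal(nchar(eng$aa_sequence), 50L)
  expect_equal(eng$boundary_aa, 25L)
  expect_true(all(db$boundary_aa > 0 & db$boundary_aa < nchar(db$aa_sequence)))
  expect_false(any(grepl("*", db$aa_sequence, fixed = TRUE)))
  # determinism: same input, identical FASTA bytes
  f1 <- tempfile(fileext = ".fa"); f2 <- tempfile(fileext = ".fa")
  write_database_fasta(db, f1)
  db2 <- build_junction_database(j, td$genome, td$models, verbose = FALSE)
  write_database_fasta(db2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("empty junction sets give an empty database", {
  td <- tiny_dataset()
  db <- build_junction_database(td$junctions[0, ], td$genome, td$models,
                                verbose = FALSE)
  expect_equal(nrow(db), 0L)
})

test_that("lowering min_orf_len never decreases the entry count", {
  s <- default_sim()
  sub <- s$classified[1:40, ]
  n_entries <- vapply(c(45L, 30L, 15L), function(mo) {
    nrow(build_junction_database(sub, s$genome, s$models, min_orf_len = mo,
                                 verbose = FALSE))
  }, integer(1))
  expect_true(all(diff(n_entries) >= 0))
})

test_that("database FASTA round-trips exactly", {
  s <- default_sim()
  f <- tempfile(fileext = ".fa")
  write_database_fasta(s$db, f)
  back <- read_database_fasta(f)
  ord <- order(s$db$entry_id)
  expect_equal(back$entry_id, s$db$entry_id[ord])
  expect_equal(back$aa_sequence, s$db$aa_sequence[ord])
  expect_equal(back$boundary_aa, s$db$boundary_aa[ord])
  expect_equal(back$frame, s$db$frame[ord])
  # and the written file is plain FASTA for any standard reader
  aa <- Biostrings::readAAStringSet(f)
  expect_equal(length(aa), nrow(s$db))
  # duplicate entry ids are refused
  dup <- rbind(s$db[1, ], s$db[1, ])
  expect_error(write_database_fasta(dup, tempfile()), "duplicate")
})

test_that("the database is invariant under genome mirroring", {
  s <- default_sim()
  sub <- s$classified[seq(1, nrow(s$classified), by = 6), ]
  db1 <- build_junction_database(sub, s$genome, s$models, verbose = FALSE)
  mir <- jxpepdb:::mirror_dataset(s$genome, s$models, sub)
  db2 <- build_junction_database(mir$junctions, mir$genome, mir$models,
                                 verbose = FALSE)
  expect_setequal(db1$aa_sequence, db2$aa_sequence)
})
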