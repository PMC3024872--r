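# One shared simulated dataset per test run (the junction database build is
# the slow step); computed lazily and reused across test files.
.jx_test_cache <- new.env(parent = emptyenv())

default_sim <- function() {
  if (is.null(.jx_test_cache$sim)) {
    cfg <- sim_config()
    gm <- sim_genome_models(cfg)
    sj <- sim_junctions(cfg)
    classified <- classify_junctions(sj$junctions, gm$models)
    db <- build_junction_database(classified, gm$genome, gm$models,
                                  verbose = FALSE)
    ref <- sim_reference_proteome(cfg)
    combined <- assemble_combined_db(ref, db)
    .jx_test_cache$sim <- list(cfg = cfg, genome = gm$genome,
                               models = gm$models,
                               junctions = sj$junctions, truth = sj$truth,
                               classified = classified, db = db, ref = ref,
                               combined = combined)
  }
  .jx_test_cache$sim
}

default_sim_psms <- function() {
  if (is.null(.jx_test_cache$psms)) {
    s <- default_sim()
    .jx_test_cache$psms <- sim_psms(s$cfg, s$combined)
  }
  .jx_test_cache$psms
}

# a tiny single-gene dataset on the plus strand for hand-checkable cases:
# two exons of 100 nt around a 50 nt intron, in-frame stop-free flanks with
# K at residue 20 and R at residue 30 of the +0 window frame
tiny_dataset <- function() {
  set.seed(7)
  exon1 <- paste(sample(c("A", "C", "G", "T"), 100, TRUE), collapse = "")
  exon2 <- paste(sample(c("A", "C", "G", "T"), 100, TRUE), collapse = "")
  safe <- c("GCT", "GGT", "CTG", "TCT", "ACT", "GTT", "GAT", "GAA")
  up75 <- paste0(paste(sample(safe, 19, TRUE), collapse = ""), "AAA",
                 paste(sample(safe, 5, TRUE), collapse = ""))
  dn75 <- paste0(paste(sample(safe, 4, TRUE), collapse = ""), "CGT",
                 paste(sample(safe, 20, TRUE), collapse = ""))
  substr(exon1, 26, 100) <- up75
  substr(exon2, 1, 75) <- dn75
  intron <- paste(sample(c("A", "C", "G", "T"), 50, TRUE), collapse = "")
  chrom <- paste0(exon1, intron, exon2)
  genome <- Biostrings::DNAStringSet(c(chr1 = chrom))
  exons <- data.frame(gene_id = "g1", transcript_id = "g1.t1",
                      chrom = "chr1", strand = "+",
                      start = c(0L, 150L), end = c(100L, 250L),
                      stringsAsFactors = FALSE)
  models <- jxpepdb:::.gene_models_from_exons(exons, genome = genome)
  j <- data.frame(junction_id = "j1", chrom = "chr1", strand = "+",
                  start = 100L, end = 150L, read_count = 5L,
                  status = "unclassified", gene_id = NA_character_,
                  stringsAsFactors = FALSE)
  class(j) <- c("jx_junctions", "data.frame")
  list(genome = genome, models = models, junctions = j)
}
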