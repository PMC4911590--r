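test_that("a fixed seed gives byte-identical fixture files", {
  cfg <- family_config(n_members = 8, n_decoys_kinase_only = 2,
                       n_decoys_naf_only = 2, n_chromosomes = 4,
                       tandem_clusters = data.frame(chromosome = 1,
                                                    size = 2,
                                                    max_gap_bp = 50000),
                       segmental_pairs = 1,
                       intron_counts = c(0, 0, 1, 2, 9, 11, 13, 14),
                       seed = 42)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  f1 <- generate_family(cfg, d1)
  f2 <- generate_family(cfg, d2)
  for (nm in names(f1$paths)) {
    expect_identical(readLines(f1$paths[[nm]]),
                     readLines(f2$paths[[nm]]),
                     info = nm)
  }
  # expression generator too
  e1 <- generate_expression(expression_config(seed = 7),
                            f1$truth$members, dir = file.path(d1, "e"))
  e2 <- generate_expression(expression_config(seed = 7),
                            f2$truth$members, dir = file.path(d2, "e"))
  for (nm in names(e1$paths))
    expect_identical(readLines(e1$paths[[nm]]),
                     readLines(e2$paths[[nm]]), info = nm)
})

test_that("planted intron counts and clades drive the catalog downstream", {
  counts <- c(rep(0, 4), rep(1, 2), rep(9, 2), rep(11, 2))
  fam <- generate_family(
    family_config(n_members = 10, n_decoys_kinase_only = 0,
                  n_decoys_naf_only = 0, n_chromosomes = 3,
                  tandem_clusters = data.frame(chromosome = integer(),
                                               size = integer(),
                                               max_gap_bp = integer()),
                  segmental_pairs = 0, intron_counts = counts,
                  seed = 3),
    withr::local_tempdir())
  clade <- classify_intron_clade(fam$catalog$exon_count - 1L)
  expect_equal(sum(clade == "intron_poor"), 6L)
  expect_equal(sum(clade == "intron_rich"), 4L)
  expect_equal(unname(unlist(fam$truth$intron_counts)), counts)
})

test_that("zero motif mutation gives every member the maximum PSSM score", {
  fam <- generate_family(
    family_config(n_members = 4, n_decoys_kinase_only = 0,
                  n_decoys_naf_only = 0, n_chromosomes = 2,
                  tandem_clusters = data.frame(chromosome = integer(),
                                               size = integer(),
                                               max_gap_bp = integer()),
                  segmental_pairs = 0, intron_counts = rep(0, 4),
                  motif_mutation_rate = 0, seed = 8),
    withr::local_tempdir())
  pssms <- default_pssms()
  prot <- read_protein_fasta(fam$paths$fasta)
  for (m in fam$truth$members) {
    hits <- scan_motifs(prot[[m]], pssms, id = m)
    expect_equal(sort(hits$bit_score),
                 sort(unname(vapply(pssms, `[[`, numeric(1),
                                    "max_score"))))
  }
})

test_that("decoys carry exactly one planted domain", {
  fam <- small_family(seed = 4)
  prot <- read_protein_fasta(fam$paths$fasta)
  hits <- scan_proteins(prot)
  for (d in fam$truth$decoys_kinase_only)
    expect_equal(hits$domain_label[hits$protein_id == d], "Pkinase")
  for (d in fam$truth$decoys_naf_only)
    expect_equal(hits$domain_label[hits$protein_id == d], "NAF")
})

test_that("impossible layouts and invalid configs are rejected", {
  expect_error(family_config(n_members = 1), "n_members")
  expect_error(family_config(n_members = 4, intron_counts = c(0, 1)),
               "length")
  expect_error(family_config(
    n_members = 4,
    tandem_clusters = data.frame(chromosome = 30, size = 2,
                                 max_gap_bp = 5e4)),
    "nonexistent chromosome")
  expect_error(family_config(
    n_members = 4,
    tandem_clusters = data.frame(chromosome = 1, size = 2,
                                 max_gap_bp = 2e5)),
    "100 kb")
  expect_error(family_config(
    n_members = 4, intron_counts = rep(0, 4),
    tandem_clusters = data.frame(chromosome = 1, size = 6,
                                 max_gap_bp = 5e4)),
    "more members")
  expect_error(expression_config(ct_noise_sd = -1), "ct_noise_sd")
  expect_error(expression_config(n_bio_reps = 1), "n_bio_reps")
  pl <- data.frame(gene = "RefS20e", tissue = "leaf", timepoint = 4,
                   log2fc = 2)
  expect_error(expression_config(planted_log2fc = pl), "reference gene")
})

test_that("default generator mirrors the published family design", {
  cfg <- family_config()
  expect_equal(cfg$n_members, 52L)
  expect_equal(sum(cfg$intron_counts < 3), 35L)
  expect_equal(sum(cfg$intron_counts > 8), 17L)
  expect_equal(nrow(cfg$tandem_clusters), 6L)
  pat <- expression_config()$stage_pattern
  expect_equal(unname(pat["both_up"] + pat["up_down"]), 20)    # stage 1 up
  expect_equal(unname(pat["both_down"] + pat["down_up"]), 28)  # stage 1 down
})
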