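test_that("generation is deterministic in the seed", {
  d1 <- generate_dataset(sim_config(seed = 61))
  d2 <- generate_dataset(sim_config(seed = 61))
  d3 <- generate_dataset(sim_config(seed = 62))
  expect_identical(d1$reference, d2$reference)
  expect_identical(d1$ests, d2$ests)
  expect_identical(d1$manifest, d2$manifest)
  expect_false(identical(d1$ests, d3$ests))
})

test_that("reference simulation honours species counts and planted duplicates", {
  cfg <- sim_config(seed = 63, n_duplicate_pairs = 3L)
  ds <- generate_dataset(cfg)
  tab <- table(ds$reference$species)
  expect_equal(as.integer(tab[cfg$species_spec$code]), cfg$species_spec$n)
  # duplicates collapse in the non-redundant view
  ref <- parse_mature_fasta(paste0(">", ds$reference$id, "\n",
                                   ds$reference$sequence, collapse = "\n"))
  expect_equal(nrow(ref$records) - nrow(ref$nr), 3L)
})

test_that("hairpin construction arithmetic and arm side hold", {
  set.seed(64)
  mat <- random_rna(21)
  hp5 <- build_hairpin(mat, 0, 8, "5p")
  expect_equal(hp5$PL, 2 * 21 + 8 + 26)
  expect_equal(hp5$mature_span, c(14, 34))      # after the 13-nt flank
  hp3 <- build_hairpin(mat, 0, 8, "3p")
  expect_equal(hp3$mature_span[2], hp3$PL - 13) # mature ends before 3' flank
  expect_error(build_hairpin(mat, 0, 2, "5p"))  # loop below the minimum
})

test_that("designed duplex mismatches are realized by the folding engine", {
  set.seed(65)
  ok <- 0L
  for (i in 1:40) {
    mat <- random_rna(sample(20:22, 1), gc = 0.5)
    nm <- sample(0:2, 1)
    hp <- build_hairpin(mat, nm, 8, sample(c("5p", "3p"), 1))
    if (identical(hp$realized_nm, as.integer(nm))) ok <- ok + 1L
  }
  expect_gte(ok / 40, 0.95)
})

test_that("planted target sites chain through scanning and profiling", {
  set.seed(66)
  mat <- random_rna(21)
  ref <- parse_mature_fasta(c(">aaa-miR300", mat))
  pt0 <- plant_target(mat, integer(0))
  pt11 <- plant_target(mat, 11L)
  pt4 <- plant_target(mat, c(2, 8, 15, 20))
  ests <- data.frame(id = c("perfect", "pos11", "four"),
                     sequence = c(pt0$sequence, pt11$sequence, pt4$sequence),
                     stringsAsFactors = FALSE)
  hits <- scan_homology(ref, ests, 3)
  expect_setequal(hits$est_id, c("perfect", "pos11"))  # 4 mm: not found
  h0 <- hits[hits$est_id == "perfect", ]
  expect_equal(h0$mismatches, 0L)
  h11 <- hits[hits$est_id == "pos11", ]
  prof <- site_profile(h11, mat, pt11$sequence)
  expect_true(prof$cleavage_site_mismatch)
})

test_that("written datasets round-trip through files and validate", {
  ds <- generate_dataset(sim_config(seed = 67))
  dir <- withr::local_tempdir()
  paths <- write_dataset(ds, dir)
  expect_true(all(file.exists(paths)))
  expect_true(validate_manifest(ds))
  seqs <- mirEST:::read_fasta_chr(paths[["ests"]])
  expect_equal(length(seqs), nrow(ds$ests))
  memb <- read_cluster_table(paths[["clusters"]])
  expect_setequal(memb$cluster_id, ds$clusters$cluster_id)
  man <- jsonlite::read_json(paths[["manifest"]])
  expect_equal(length(man$targets), length(ds$manifest$targets))
})

test_that("null simulation tail rate stays within Monte Carlo bounds and pmfs normalize", {
  set.seed(68)
  counts <- c(a = 200L, b = 150L, c = 100L, d = 50L)
  sim <- null_enrichment_sim(counts, K = 100, reps = 200)
  expect_lte(sim$rate, sim$alpha + 3 * sim$mc_se)
  pm <- vapply(0:100, function(k)
    representation_stat(200, 500, k, 100)$p_value, numeric(1))
  expect_equal(sum(pm), 1, tolerance = 1e-12)
})
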