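test_that("variant calling applies the two-copy support rule", {
  set.seed(51)
  tpl <- mirEST:::random_seq(100, 0.5)
  mk <- function(pos, base, n_alt, n_tot) {
    seqs <- rep(tpl, n_tot)
    for (i in seq_len(n_alt)) substr(seqs[i], pos, pos) <- base
    setNames(seqs, paste0("m", seq_len(n_tot)))
  }
  ref_base <- substr(tpl, 50, 50)
  alt_base <- setdiff(c("A", "C", "G", "T"), ref_base)[1]
  regions <- data.frame(start = 40L, end = 60L, kind = "target_site")
  # 2 alt copies in 5 -> candidate_true
  aln <- assemble_cluster(mk(50, alt_base, 2, 5), "cl")
  calls <- call_variants(aln, regions)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$consensus_pos, 49L)
  expect_equal(calls$ref, ref_base)
  expect_equal(calls$alt, alt_base)
  expect_equal(calls$vtype, "SNP")
  expect_equal(calls$support_class, "candidate_true")
  # 1 alt copy -> low_support
  calls1 <- call_variants(assemble_cluster(mk(50, alt_base, 1, 5)), regions)
  expect_equal(calls1$support_class, "low_support")
  # allele-count conservation at the called column
  expect_equal(calls$ref_count + sum(as.integer(
    strsplit(calls$alt_counts, ",")[[1]])), calls$depth)
  # columns outside regions are not called
  off <- data.frame(start = 0L, end = 10L, kind = "target_site")
  expect_equal(nrow(call_variants(aln, off)), 0L)
})

test_that("a planted deletion carried by two members is called as an indel", {
  set.seed(52)
  tpl <- mirEST:::random_seq(90, 0.5)
  del <- paste0(substr(tpl, 1, 44), substr(tpl, 47, 90))  # drop 45-46
  mems <- setNames(c(rep(tpl, 4), del, del), paste0("m", 1:6))
  aln <- assemble_cluster(mems, "cl")
  calls <- call_variants(aln, data.frame(start = 30L, end = 60L,
                                         kind = "target_site"))
  idx <- calls$vtype == "indel"
  expect_equal(sum(idx), 2L)
  expect_true(all(calls$support_class[idx] == "candidate_true"))
  expect_setequal(calls$consensus_pos[idx], c(44L, 45L))
  expect_true(all(calls$alt[idx] == "-"))
})

test_that("miRNA-coordinate mapping flags critical and cleavage positions", {
  span <- c(20L, 40L)   # 20-nt target site
  m12 <- map_to_mirna_position(span[2] - 12L, span, "antisense")
  expect_equal(m12$position, 12L)
  expect_true(m12$critical)
  expect_false(m12$cleavage_site)
  m10 <- map_to_mirna_position(span[2] - 10L, span, "antisense")
  expect_true(m10$cleavage_site)
  m15 <- map_to_mirna_position(span[2] - 15L, span, "antisense")
  expect_false(m15$critical)
  # direct mapping for mature regions
  s <- map_to_mirna_position(24L, span, "sense")
  expect_equal(s$position, 5L)
  expect_true(s$critical)
  expect_error(map_to_mirna_position(40L, span, "antisense"), "outside")
})

test_that("ddG is exactly antisymmetric and zero for identical alleles", {
  set.seed(53)
  mat <- random_rna(21, gc = 0.5)
  hp <- build_hairpin(mat, 0, 8, "5p")
  est <- mirEST:::rna_to_dna(hp$sequence)
  cand <- extract_candidate(est, make_hit(hp$mature_span[1] - 1L,
                                          hp$mature_span[2]))
  pos <- hp$mature_span[1] + 10L
  ref <- substr(cand$sequence, pos, pos)
  alt <- setdiff(c("A", "C", "G", "U"), ref)[1]
  fwd <- precursor_variant_impact(cand, pos, ref, alt)
  rev <- precursor_variant_impact(cand, pos, alt, ref)
  expect_identical(fwd$ddG, -rev$ddG)
  expect_equal(fwd$dG_ref, rev$dG_alt)
  same <- precursor_variant_impact(cand, pos, ref, ref)
  expect_identical(same$ddG, 0)
})

test_that("a stem-breaking substitution destabilizes a small hairpin", {
  # toy hairpin checked against the exhaustive oracle for both alleles
  seq <- "GGCGCGAAACGCGCC"        # strong stem, 15 nt
  f_ref <- brute_force_mfe(seq)
  alt_seq <- seq
  substr(alt_seq, 2, 2) <- "A"    # break a GC pair in the stem
  f_alt <- brute_force_mfe(alt_seq)
  ddg_oracle <- f_alt$dG - f_ref$dG
  expect_gt(ddg_oracle, 0)
  # engine agrees with the oracle on both alleles
  expect_equal(fold_rna(seq)$dG, f_ref$dG, tolerance = 1e-9)
  expect_equal(fold_rna(alt_seq)$dG, f_alt$dG, tolerance = 1e-9)
})

test_that("seeded recovery: planted variants called with expected class, no phantoms", {
  cfg <- sim_config(seed = 54, error_rate = 0)
  ds <- generate_dataset(cfg)
  res <- run_pipeline(ds$reference, ds$ests, ds$clusters)
  v <- res$variants
  planted <- ds$manifest$variants
  for (pv in planted) {
    row <- v[v$cluster_id == pv$cluster_id &
               v$consensus_pos == pv$template_pos, ]
    expect_equal(nrow(row), 1L, label = pv$cluster_id)
    expect_equal(row$support_class, pv$expected_class)
    expect_equal(row$alt, pv$alt)
    expect_equal(row$mirna_position, pv$mirna_position)
  }
  # zero unplanted calls at zero noise
  planted_keys <- vapply(planted, function(p)
    paste(p$cluster_id, p$template_pos), character(1))
  got_keys <- paste(v$cluster_id, v$consensus_pos)
  expect_setequal(got_keys, planted_keys)
})
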