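test_that("cluster annotations classify by keyword rule", {
  expect_equal(classify_cluster("protein coding (SBP domain)"),
               "protein_coding")
  expect_equal(classify_cluster("transcribed locus"), "transcribed")
  expect_equal(classify_cluster(""), "unknown")
  expect_equal(classify_cluster(NA_character_), "unknown")
  expect_equal(classify_cluster("serine/threonine kinase"), "protein_coding")
})

test_that("site profiling maps miRNA positions onto the antisense site", {
  # hand-enumerated 6-nt example: mature ACGGUU, perfect site = revcomp
  mature <- "ACGGUU"
  site <- mirEST:::revcomp_dna(mirEST:::rna_to_dna(mature))  # AACCGT
  est <- paste0("TTTT", site, "GGGG")
  hit <- make_hit(4, 10, "antisense")
  prof <- site_profile(hit, mature, est)
  expect_equal(prof$per_position, rep("match", 6))
  expect_false(prof$critical_mismatch)
  expect_false(prof$cleavage_site_mismatch)
  # mutate the EST base opposite miRNA position 3 (coordinate end - 3 = 7)
  est2 <- est
  old <- substr(est2, 8, 8)
  substr(est2, 8, 8) <- setdiff(c("A", "C", "G", "T"),
                                c(old, mirEST:::COMP_DNA[[mirEST:::rna_to_dna(substr(mature, 3, 3))]]))[1]
  prof2 <- site_profile(hit, mature, est2)
  expect_equal(which(prof2$per_position == "mismatch"), 3L)
  expect_true(prof2$critical_mismatch)
  expect_false(prof2$cleavage_site_mismatch)
})

test_that("a mismatch opposite position 11 raises the cleavage-site flag", {
  set.seed(41)
  mature <- random_rna(20)
  pt <- plant_target(mature, 11, est_length = 120)
  hit <- make_hit(pt$start, pt$end, "antisense")
  prof <- site_profile(hit, mature, pt$sequence)
  expect_equal(which(prof$per_position == "mismatch"), 11L)
  expect_true(prof$cleavage_site_mismatch)
  expect_true(prof$critical_mismatch)
  expect_error(site_profile(make_hit(0, 20, "sense"), mature, pt$sequence),
               "not a target-type hit")
})

test_that("position mapping is a bijection over the site span", {
  span <- c(37L, 57L)   # 20-nt site
  for (pos in 1:20) {
    coord <- span[2] - pos
    m <- map_to_mirna_position(coord, span, "antisense")
    expect_equal(m$position, pos)
  }
  # round trip: consensus -> miRNA -> consensus
  coords <- span[1]:(span[2] - 1L)
  back <- vapply(coords, function(cc)
    span[2] - map_to_mirna_position(cc, span, "antisense")$position,
    numeric(1))
  expect_equal(back, as.numeric(coords))
})

test_that("reverse-complement round trip yields an all-match profile", {
  set.seed(42)
  for (i in 1:10) {
    mature <- random_rna(sample(18:24, 1))
    pt <- plant_target(mature, integer(0), est_length = 150)
    prof <- site_profile(make_hit(pt$start, pt$end, "antisense"),
                         mature, pt$sequence)
    expect_true(all(prof$per_position == "match"))
  }
})

test_that("target summaries count distinct clusters and label multi-family sites", {
  clusters <- data.frame(
    cluster_id = c("c1", "c2", "c3", "c4", "c5"),
    category = c("protein_coding", "protein_coding", "protein_coding",
                 "transcribed", "protein_coding"),
    stringsAsFactors = FALSE)
  hits <- rbind(
    make_hit(0, 20, "antisense", "c1", "c1", "mA1", "1128"),
    make_hit(5, 25, "antisense", "c1", "c1", "mB1", "1133"),
    make_hit(0, 20, "antisense", "c2", "c2", "mA1", "1128"),
    make_hit(0, 20, "antisense", "c2", "c2", "mA2", "1128"),  # same family twice
    make_hit(0, 20, "antisense", "c3", "c3", "mB1", "1133"),
    make_hit(0, 20, "antisense", "c4", "c4", "mA1", "1128"),  # not protein-coding
    make_hit(0, 20, "sense", "c5", "c5", "mA1", "1128"))      # sense: excluded
  s <- summarize_targets(hits, clusters)
  fc <- setNames(s$family_counts$n_target_clusters, s$family_counts$family)
  expect_equal(fc[["1128"]], 2L)   # c1, c2 (c4 transcribed, c5 sense)
  expect_equal(fc[["1133"]], 2L)   # c1, c3
  expect_equal(s$multi_family_sites$label, "1128+1133")
  expect_equal(s$multi_family_sites$est_id, "c1")
})

test_that("category tally maps terms and pools the rest as unannotated", {
  ann <- c("MYB family transcription factor", "serine/threonine kinase",
           "dehydrin family protein", NA)
  map <- c("transcription factor" = "transcription regulation",
           "kinase" = "signalling")
  tal <- category_tally(ann, map)
  expect_equal(tal$n[tal$category == "transcription regulation"], 1L)
  expect_equal(tal$n[tal$category == "signalling"], 1L)
  expect_equal(tal$n[tal$category == "unannotated"], 2L)
  expect_equal(sum(tal$n), 4L)
  empty <- category_tally(ann, character(0))
  expect_equal(empty$category, "unannotated")
  expect_equal(empty$n, 4L)
})
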