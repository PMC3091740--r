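test_that("count_mismatches treats U as T and N as mismatch", {
  expect_equal(count_mismatches("UGACAG", "TGACAG"), 0L)
  expect_equal(count_mismatches("UGACAG", "TGACAC"), 1L)
  expect_equal(count_mismatches("UGACAG", "TGNCAG"), 1L)
  expect_error(count_mismatches("UGACAG", "TGACA"), "length")
})

test_that("planted sense and antisense sites are found with exact coordinates", {
  set.seed(101)
  mat <- random_rna(21)
  ref <- parse_mature_fasta(c(">aaa-miR200", mat))
  bg <- mirEST:::random_seq(120, 0.45)
  est_sense <- paste0(substr(bg, 1, 40), mirEST:::rna_to_dna(mat),
                      substr(bg, 62, 120))
  # antisense with 2 planted substitutions opposite miRNA positions 5 and 11
  pt <- plant_target(mat, c(5, 11), est_length = 150)
  ests <- data.frame(id = c("s1", "a1"),
                     sequence = c(est_sense, pt$sequence),
                     stringsAsFactors = FALSE)
  hits <- scan_homology(ref, ests, max_mm = 3)
  s <- hits[hits$est_id == "s1", ]
  expect_equal(nrow(s), 1L)
  expect_equal(s$start, 40L)
  expect_equal(s$orientation, "sense")
  expect_equal(s$mismatches, 0L)
  a <- hits[hits$est_id == "a1", ]
  expect_equal(nrow(a), 1L)
  expect_equal(a$orientation, "antisense")
  expect_equal(c(a$start, a$end), c(pt$start, pt$end))
  expect_equal(a$mismatch_positions, "5,11")
})

test_that("sites beyond the mismatch cap are not reported", {
  set.seed(102)
  mat <- random_rna(20)
  ref <- parse_mature_fasta(c(">aaa-miR201", mat))
  pt <- plant_target(mat, c(3, 8, 13, 17), est_length = 120)
  hits <- scan_homology(ref, data.frame(id = "e", sequence = pt$sequence),
                        max_mm = 3)
  expect_equal(nrow(hits[hits$mismatches == 4, ]), 0L)
  expect_equal(nrow(hits), 0L)
})

test_that("scanner equals the naive quadratic oracle on random cases", {
  set.seed(103)
  for (case in 1:20) {
    mat <- random_rna(sample(16:22, 1))
    ref <- parse_mature_fasta(c(">aaa-miR1", mat))
    ests <- data.frame(
      id = paste0("e", 1:3),
      sequence = replicate(3, mirEST:::random_seq(sample(60:200, 1), 0.5)),
      stringsAsFactors = FALSE)
    # high cap so random matches occur
    mm_cap <- sample(c(3L, 6L, 8L), 1)
    got <- scan_homology(ref, ests, mm_cap)
    want <- naive_scan(ref, ests, mm_cap)
    cols <- c("mirna_nr_id", "est_id", "start", "end", "orientation",
              "mismatches", "mismatch_positions")
    if (is.null(want)) expect_equal(nrow(got), 0L)
    else expect_equal(got[, cols], want[, cols])
  }
})

test_that("reverse-complementing an EST swaps orientations and maps coordinates", {
  set.seed(104)
  mat <- random_rna(20)
  ref <- parse_mature_fasta(c(">aaa-miR1", mat))
  est <- mirEST:::random_seq(150, 0.5)
  est <- paste0(substr(est, 1, 50), mirEST:::rna_to_dna(mat),
                substr(est, 71, 150))
  L <- nchar(est)
  fw <- scan_homology(ref, data.frame(id = "e", sequence = est), 3)
  rv <- scan_homology(ref, data.frame(id = "e",
                                      sequence = mirEST:::revcomp_dna(est)), 3)
  expect_equal(nrow(fw), nrow(rv))
  fw <- fw[order(fw$start), ]; rv <- rv[order(-rv$end), ]
  expect_equal(rv$start, L - fw$end)
  expect_equal(rv$end, L - fw$start)
  expect_equal(rv$mismatches, fw$mismatches)
  expect_setequal(paste(fw$orientation, rv$orientation),
                  c("sense antisense"))
})

test_that("matched counts expand over the redundant set and count records once", {
  seqs <- c("UGACAGAAGAGAGUGAGCAC", "UGACAGAAGAGAGUGAGCAC",
            "AAGGCCUUAAGGCCUUAAGG")
  ref <- parse_mature_fasta(c(">aaa-miR1", seqs[1], ">bbb-miR2", seqs[2],
                              ">aaa-miR3", seqs[3]))
  # many ESTs all hitting only the shared sequence
  ests <- data.frame(id = paste0("e", 1:5),
                     sequence = replicate(5, paste0(
                       mirEST:::random_seq(20, .5),
                       mirEST:::rna_to_dna(seqs[1]),
                       mirEST:::random_seq(20, .5))),
                     stringsAsFactors = FALSE)
  hits <- scan_homology(ref, ests, 0)
  counts <- matched_redundant_set(hits, ref)
  expect_equal(counts[["aaa"]], 1L)   # miR1 matched (once), miR3 not
  expect_equal(counts[["bbb"]], 1L)   # duplicate re-expanded
})

test_that("multi-hit ESTs are flagged by family relationship", {
  hits <- rbind(make_hit(0, 20, est_id = "multi", family = "156",
                         mirna_nr_id = "m1"),
                make_hit(50, 70, est_id = "multi", family = "172",
                         mirna_nr_id = "m2"),
                make_hit(0, 20, est_id = "samefam", family = "1436",
                         mirna_nr_id = "m3"),
                make_hit(40, 60, est_id = "samefam", family = "1436",
                         mirna_nr_id = "m4"),
                make_hit(0, 20, est_id = "single", family = "156",
                         mirna_nr_id = "m1"))
  rep <- multi_hit_report(hits)
  expect_setequal(rep$est_id, c("multi", "samefam"))
  expect_true(rep$multi_family[rep$est_id == "multi"])
  expect_false(rep$same_family_multi_site[rep$est_id == "multi"])
  expect_true(rep$same_family_multi_site[rep$est_id == "samefam"])
})
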