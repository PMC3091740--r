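test_that("star_and_nm reads a hand-constructed duplex correctly", {
  # 8-bp duplex, 4-nt loop: mature = positions 1-8, star = 13-20
  db <- "((((((((....))))))))"
  d <- star_and_nm(db, c(1, 8))
  expect_equal(d$star_span, c(13, 20))
  expect_equal(d$NM, 0)
  expect_equal(nrow(d$bulges), 0)
  # single unpaired mature position (1x1 internal loop: one bulge per arm)
  db2 <- "(((.((((....)))).)))"
  d2 <- star_and_nm(db2, c(1, 8))
  expect_equal(d2$NM, 1)
  expect_setequal(d2$bulges$arm, c("mature", "star"))
  expect_true(all(d2$bulges$size == 1))
  # star-arm bulge of 2: mature 1-4 pairs 11-12 and 15-16, 13-14 bulged
  db3 <- "((((......))..))"
  d3 <- star_and_nm(db3, c(1, 4))
  expect_equal(d3$star_span, c(11, 16))
  expect_equal(d3$NM, 0)
  expect_equal(d3$bulges$arm, "star")
  expect_equal(d3$bulges$size, 2)
  expect_error(star_and_nm("....................", c(1, 8)), "no duplex")
})

test_that("generator-built hairpins are recovered with designed geometry", {
  set.seed(31)
  mat <- random_rna(21, gc = 0.5)
  hp <- build_hairpin(mat, nm_star = 0, loop_len = 8, arm = "5p")
  expect_equal(hp$PL, 2 * 21 + 8 + 26)   # no bulges: 2 ML + loop + 2 flanks
  expect_equal(hp$realized_nm, 0L)
  pad <- 25
  est <- paste0(mirEST:::random_seq(pad, .45),
                mirEST:::rna_to_dna(hp$sequence),
                mirEST:::random_seq(pad, .45))
  hit <- make_hit(pad + hp$mature_span[1] - 1L, pad + hp$mature_span[2])
  cand <- extract_candidate(est, hit)
  expect_s3_class(cand, "precursor_candidate")
  expect_equal(cand$NM, 0L)
  expect_equal(cand$ML, 21L)
  expect_equal(cand$arm, "5'")
  expect_lte(cand$PL, hp$PL + 2 * 13)    # flanks never exceed 13 nt/side
  expect_gte(cand$PL, 2 * 21 + 8)
})

test_that("boundary hits clamp the flank instead of failing", {
  set.seed(32)
  mat <- random_rna(20, gc = 0.5)
  hp <- build_hairpin(mat, 0, 8, "5p", flank = 13)
  # hairpin starts 5 nt from the sequence start
  est <- paste0(mirEST:::random_seq(5, .45), mirEST:::rna_to_dna(hp$sequence))
  hit <- make_hit(5 + hp$mature_span[1] - 1L, 5 + hp$mature_span[2])
  cand <- extract_candidate(est, hit)
  expect_s3_class(cand, "precursor_candidate")
  expect_lte(cand$PL, nchar(est))
})

test_that("a mature planted in unstructured sequence is rejected", {
  mat <- "ACGUACGUACGUACGUACGU"
  est <- paste0(strrep("AT", 30), mirEST:::rna_to_dna(mat), strrep("AT", 30))
  hit <- make_hit(60, 80)
  cand <- extract_candidate(est, hit)
  expect_s3_class(cand, "precursor_rejection")
})

test_that("antisense hits are refused for precursor extraction", {
  expect_error(extract_candidate("ACGT", make_hit(0, 2, "antisense")),
               "sense")
})

test_that("validation enforces strict MFEI and duplex limits", {
  set.seed(33)
  mat <- random_rna(21, gc = 0.5)
  hp <- build_hairpin(mat, 0, 8, "5p")
  est <- mirEST:::rna_to_dna(hp$sequence)
  hit <- make_hit(hp$mature_span[1] - 1L, hp$mature_span[2])
  cand <- extract_candidate(est, hit)
  ok <- validate_candidate(cand)
  expect_true(ok$accepted)
  # boundary: MFEI exactly at the threshold is rejected (strict inequality)
  boundary <- cand; boundary$MFEI <- 0.85
  expect_false(validate_candidate(boundary)$accepted)
  expect_match(validate_candidate(boundary)$reject_reasons, "MFEI")
  just_over <- cand; just_over$MFEI <- 0.8500001
  expect_true(validate_candidate(just_over)$accepted)
  # NM over the cap
  nm5 <- cand; nm5$NM <- 5L
  expect_match(validate_candidate(nm5)$reject_reasons, "star mismatches")
  # bulge count/size rules
  bulgy <- cand
  bulgy$bulges <- data.frame(arm = c("mature", "star", "star"),
                             offset = c(3L, 5L, 9L), size = c(1L, 1L, 1L))
  expect_match(validate_candidate(bulgy)$reject_reasons, "too many bulges")
  big <- cand
  big$bulges <- data.frame(arm = "star", offset = 4L, size = 4L)
  expect_match(validate_candidate(big)$reject_reasons, "larger than")
})

test_that("family assignment by precursor alignment finds the source hairpin", {
  set.seed(34)
  lib <- setNames(vapply(1:4, function(i) random_rna(90, 0.5), character(1)),
                  paste0("MIR", 1:4))
  # candidate = library hairpin 3 with 5 substitutions
  cand_seq <- strsplit(lib[[3]], "")[[1]]
  pos <- sample(90, 5)
  for (p in pos) cand_seq[p] <- setdiff(c("A", "C", "G", "U"), cand_seq[p])[1]
  hit <- assign_family_by_precursor(paste(cand_seq, collapse = ""), lib)
  expect_equal(hit$id, "MIR3")
  # identical sequence scores 2 * length at 100% identity
  self <- assign_family_by_precursor(lib[[1]], lib[1])
  expect_equal(self$score, 2 * 90)
  expect_equal(self$identity, 100)
  expect_null(assign_family_by_precursor(lib[[1]], character(0)))
})

test_that("mature length reporting covers the expected range", {
  set.seed(35)
  cands <- lapply(c(20, 21, 21, 22), function(L) {
    structure(list(ML = L), class = "precursor_candidate")
  })
  rep <- mature_length_report(cands)
  expect_equal(rep$ML, 18:26)
  expect_equal(rep$n[rep$ML == 21], 2)
  expect_equal(sum(rep$n), 4)
})
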