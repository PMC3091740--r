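test_that("representation statistic reproduces the published barley survey values", {
  # printed count pairs with M = 1929 initial, K = 497 matched records
  sc <- species_counts()
  M <- sum(sc$initial); K <- sum(sc$matched)
  expect_equal(M, 1929L)
  expect_equal(K, 497L)
  printed <- c("Triticum aestivum" = 2.0e-4,
               "Chlamydomonas reinhardtii" = 6.3e-8,
               "Physcomitrella patens" = 1.7e-6,
               "Zea mays" = 1.1e-5,
               "Saccharum officinarum" = 2.3e-3,
               "Arabidopsis thaliana" = 0.019,
               "Gossypium herbecium" = 0.773)
  for (sp in names(printed)) {
    row <- sc[sc$species == sp, ]
    st <- representation_stat(row$initial, M, row$matched, K)
    expect_equal(signif(st$p_value, 2), signif(printed[[sp]], 2),
                 tolerance = 1e-9, label = sp)
  }
  # the closed-form zero-match case
  expect_equal(representation_stat(1, 1929, 0, 497)$p_value,
               (1 - 1 / 1929)^497)
})

test_that("directions follow the observed vs expected share", {
  expect_equal(representation_stat(32, 1929, 20, 497)$direction, "over")
  expect_equal(representation_stat(281, 1929, 39, 497)$direction, "under")
  expect_equal(representation_stat(10, 100, 5, 50)$direction, "none")
})

test_that("point mass matches an independent log-gamma evaluation", {
  set.seed(42)
  for (i in 1:50) {
    M <- sample(100:5000, 1); K <- sample(50:min(M, 1000), 1)
    m <- sample(1:M, 1); k <- sample(0:K, 1)
    expect_equal(representation_stat(m, M, k, K)$p_value,
                 loggamma_pmf(m, M, k, K), tolerance = 1e-12)
  }
})

test_that("pmf normalizes and stays finite at large K", {
  q <- 32 / 1929
  total <- sum(vapply(0:497, function(k)
    representation_stat(32, 1929, k, 497)$p_value, numeric(1)))
  expect_equal(total, 1, tolerance = 1e-12)
  total10 <- sum(vapply(0:10, function(k)
    representation_stat(3, 10, k, 10)$p_value, numeric(1)))
  expect_equal(total10, 1, tolerance = 1e-12)
  big <- representation_stat(1e5, 1e6, 1e5, 1e6)$p_value
  expect_true(is.finite(big) && big > 0)
})

test_that("percentages round half away from zero to one decimal", {
  expect_equal(percent(20, 497), 4.0)
  expect_equal(percent(48, 497), 9.7)
  expect_equal(percent(0, 497), 0.0)
  expect_equal(percent(1, 1929), 0.1)   # 0.0518 -> 0.1
  sc <- species_counts()
  expect_equal(percent(sc$initial, sum(sc$initial)),
               c(10.7, 21.5, 4.1, 2.0, 1.7, 14.6, 12.3, 4.4, 3.3, 7.3, 2.3,
                 0.7, 2.4, 1.6, 3.7, 5.1, 0.4, 1.0, 0.8, 0.1, 0.1, 0.1,
                 0.1, 0.1))
})

test_that("full survey table reproduces every printed p-value at 2 significant digits", {
  v <- verify_species_table(species_counts())
  printed <- c("0.019", "0.038", "0.046", "0.068", "2.0e-04", "1.7e-06",
               "0.021", "6.3e-08", "0.058", "0.012", "0.01", "0.18",
               "0.068", "0.065", "0.014", "1.1e-05", "0.27", "0.061",
               "0.0023", "0.77", "0.77", "0.77", "0.6", "0.079")
  expect_equal(signif(v$table$p_value, 2), as.numeric(printed))
})

test_that("threshold sweep membership and nesting", {
  v <- verify_species_table(species_counts())
  sw <- v$sweep
  strict <- sw[["0.001"]]
  expect_setequal(strict$over, c("Triticum aestivum", "Zea mays"))
  expect_setequal(strict$under,
                  c("Physcomitrella patens", "Chlamydomonas reinhardtii"))
  # nested subsets across thresholds
  ths <- names(sw)
  for (i in seq_along(sw)[-1]) {
    expect_true(all(sw[[i]]$over %in% sw[[i - 1]]$over))
    expect_true(all(sw[[i]]$under %in% sw[[i - 1]]$under))
  }
  all_listed <- threshold_sweep(v$table, 1.0)[[1]]
  expect_equal(length(all_listed$over) + length(all_listed$under) +
                 sum(v$table$direction == "none"), nrow(v$table))
})

test_that("degenerate and invalid inputs are handled", {
  st <- representation_stat(10, 10, 5, 5)
  expect_equal(st$p_value, 1)
  expect_equal(st$direction, "none")
  expect_error(representation_stat(0, 100, 3, 50), "absent")
  expect_error(build_enrichment_table(c(a = 5L), c(b = 1L)), "not in initial")
  expect_warning(build_enrichment_table(c(a = 5L, b = 5L), c(a = 6L)),
                 "exceeds")
})

test_that("tail mode is calibrated under a null matched-set simulation", {
  set.seed(77)
  sc <- species_counts()
  sim <- null_enrichment_sim(setNames(sc$initial, sc$species), K = 497,
                             reps = 400, alpha = 0.05)
  expect_lte(sim$rate, sim$alpha + 3 * sim$mc_se)
})
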