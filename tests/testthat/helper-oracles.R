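# Independent oracles used across test files.

# naive quadratic scanner: loops over every window of every EST on both
# strands, counting mismatches character by character
naive_scan <- function(ref, ests, max_mm = 3L) {
  out <- list()
  for (r in seq_len(nrow(ref$nr))) {
    mat <- mirEST:::rna_to_dna(ref$nr$sequence[r])
    L <- nchar(mat)
    rc <- mirEST:::revcomp_dna(mat)
    for (e in seq_len(nrow(ests))) {
      s <- toupper(ests$sequence[e])
      if (nchar(s) < L) next
      for (st in 1:(nchar(s) - L + 1L)) {
        win <- substr(s, st, st + L - 1L)
        wv <- strsplit(win, "")[[1]]
        for (ori in c("sense", "antisense")) {
          pv <- strsplit(if (ori == "sense") mat else rc, "")[[1]]
          d <- which(wv != pv)
          if (length(d) <= max_mm) {
            mp <- if (ori == "antisense") sort(L - d + 1L) else d
            out[[length(out) + 1L]] <- data.frame(
              mirna_nr_id = ref$nr$id[r], est_id = ests$id[e],
              start = st - 1L, end = st - 1L + L, orientation = ori,
              mismatches = length(d),
              mismatch_positions = paste(mp, collapse = ","),
              stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res)) return(res)
  res <- res[order(res$est_id, res$start, res$orientation, res$mirna_nr_id), ]
  rownames(res) <- NULL
  res
}

# log-gamma evaluation of the binomial pmf, independent of lchoose
loggamma_pmf <- function(m, M, k, K) {
  q <- m / M
  lg <- lgamma(K + 1) - lgamma(k + 1) - lgamma(K - k + 1)
  exp(lg + k * log(q) + (K - k) * log1p(-q))
}

# pure-R enumeration of all nested structures as partner lists (tiny n only);
# used to cross-check the C++ brute-force oracle itself
enum_structures_r <- function(seq, minh = 3L) {
  v <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(v)
  can <- function(i, j) mirEST:::pair_code(v[i], v[j]) > 0 && j - i - 1 >= minh
  gen <- function(i, j) {
    if (j - i + 1 < minh + 2) return(list(list()))
    res <- gen(i + 1, j)
    for (k in (i + minh + 1):j) {
      if (k > n || k > j) break
      if (can(i, k)) {
        for (a in gen(i + 1, k - 1)) for (b in gen(k + 1, j))
          res[[length(res) + 1L]] <- c(list(c(i, k)), a, b)
      }
    }
    res
  }
  gen(1L, n)
}

r_enum_mfe <- function(seq, model = energy_model()) {
  best <- 0; n <- nchar(seq)
  best_db <- strrep(".", n)
  for (s in enum_structures_r(seq)) {
    if (!length(s)) next
    partner <- integer(n)
    for (p in s) { partner[p[1]] <- p[2]; partner[p[2]] <- p[1] }
    db <- mirEST:::partner_to_dotbracket(partner)
    e <- structure_energy(seq, db, model)
    if (e < best - 1e-12) { best <- e; best_db <- db }
  }
  list(dG = best, structure = best_db)
}

random_rna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# barley survey species counts shipped with the package
species_counts <- function() {
  read.delim(system.file("extdata", "barley_species_counts.tsv",
                         package = "mirEST"), stringsAsFactors = FALSE)
}

make_hit <- function(start, end, orientation = "sense", est_id = "e",
                     cluster_id = "c", mirna_nr_id = "m", family = "f",
                     mismatches = 0L, mismatch_positions = "") {
  data.frame(mirna_nr_id = mirna_nr_id, family = family, est_id = est_id,
             cluster_id = cluster_id, start = start, end = end,
             orientation = orientation, mismatches = mismatches,
             mismatch_positions = mismatch_positions, stringsAsFactors = FALSE)
}
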