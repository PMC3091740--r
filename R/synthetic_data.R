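#' Configuration for the synthetic EST/miRNA data generator
#'
#' Defines the conditions the generator emulates: a multi-species mature
#' miRNA reference (miRBase-like IDs), EST clusters replicating a template
#' transcript with sequencing noise, planted hairpin precursors, planted
#' antisense target sites with controlled mismatch patterns, and planted
#' SNPs/indels with controlled allele support.
#'
#' Defaults are chosen to resemble a cereal EST survey at desk scale:
#' i.i.d. background sequence at 45\% GC, mature lengths 20-22 nt,
#' clusters of 4-8 ESTs, and a 0.1\% per-base substitution error rate
#' (typical of single-pass cDNA reads).
#'
#' @param seed integer seed; every generator output is a deterministic
#'   function of the config including this seed.
#' @param species_spec data.frame with \code{code} (ID prefix) and \code{n}
#'   (mature count per species).
#' @param mature_length_range inclusive range of mature lengths.
#' @param n_duplicate_pairs number of cross-species identical-sequence pairs
#'   (exercises redundant/non-redundant bookkeeping).
#' @param n_background_clusters clusters with no planted feature.
#' @param members_per_cluster inclusive range of ESTs per cluster.
#' @param planted_targets data.frame: \code{mature_index} (row of the
#'   reference), \code{mismatch_positions} (comma-joined string, "" for a
#'   perfect site), \code{category} of the carrying cluster.
#' @param planted_precursors data.frame: \code{mature_index}, \code{nm_star},
#'   \code{loop_len}, \code{arm} ("5p"/"3p").
#' @param planted_variants data.frame: \code{cluster_kind}
#'   (\code{"target"}/\code{"precursor"}), \code{feature_index} (which
#'   planted target/precursor cluster), \code{region_kind}
#'   (\code{"target_site"}/\code{"mature_region"}), \code{mirna_position},
#'   \code{alt} allele, \code{alt_support} copies.
#' @param error_rate per-base substitution probability in EST copies.
#' @param background_gc background GC fraction.
#' @param est_length template transcript length (nt).
#' @return List of class \code{sim_config}.
#' @export
sim_config <- function(seed = 1L,
                       species_spec = data.frame(
                         code = c("aaa", "bbb", "ccc", "ddd", "eee", "fff"),
                         n = c(40L, 30L, 20L, 15L, 10L, 5L)),
                       mature_length_range = c(20L, 22L),
                       n_duplicate_pairs = 3L,
                       n_background_clusters = 6L,
                       members_per_cluster = c(4L, 8L),
                       planted_targets = default_planted_targets(),
                       planted_precursors = default_planted_precursors(),
                       planted_variants = default_planted_variants(),
                       error_rate = 0.001,
                       background_gc = 0.45,
                       est_length = 300L) {
  stopifnot(nrow(species_spec) >= 1L, all(species_spec$n >= 1L),
            mature_length_range[1] >= 16L, mature_length_range[2] <= 30L,
            members_per_cluster[1] >= 1L,
            error_rate >= 0, error_rate < 1, background_gc > 0,
            background_gc < 1)
  if (nrow(planted_variants)) {
    if (any(planted_variants$alt_support > members_per_cluster[1]))
      stop("alt_support exceeds the minimum cluster size")
  }
  structure(as.list(environment()), class = "sim_config")
}

#' @rdname sim_config
#' @export
default_planted_targets <- function() {
  data.frame(mature_index = 1:8,
             mismatch_positions = c("", "", "11", "2", "5,14", "3,9,20",
                                    "", "16"),
             category = "protein_coding",
             stringsAsFactors = FALSE)
}

#' @rdname sim_config
#' @export
default_planted_precursors <- function() {
  data.frame(mature_index = 9:12,
             nm_star = c(0L, 0L, 1L, 2L),
             loop_len = c(8L, 6L, 10L, 8L),
             arm = c("5p", "3p", "5p", "3p"),
             stringsAsFactors = FALSE)
}

#' @rdname sim_config
#' @export
default_planted_variants <- function() {
  data.frame(cluster_kind = c("target", "target", "target", "precursor"),
             feature_index = c(1L, 2L, 3L, 1L),
             region_kind = c("target_site", "target_site", "target_site",
                             "mature_region"),
             mirna_position = c(11L, 4L, 15L, 13L),
             alt = c("A", "C", "G", "T"),
             alt_support = c(2L, 3L, 1L, 2L),
             stringsAsFactors = FALSE)
}

random_seq <- function(n, gc = 0.45, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

#' Simulate a multi-species mature miRNA reference set
#'
#' @param cfg a \code{\link{sim_config}} (only the reference fields are
#'   used). Call inside an established RNG state or rely on \code{cfg$seed}
#'   via \code{\link{generate_dataset}}.
#' @return data.frame with \code{id}, \code{species}, \code{sequence} (RNA).
#' @export
simulate_reference <- function(cfg) {
  sp <- cfg$species_spec
  ids <- character(0); species <- character(0)
  fam <- 100L
  seqs <- character(0)
  for (i in seq_len(nrow(sp))) {
    for (j in seq_len(sp$n[i])) {
      fam <- fam + 1L
      ids <- c(ids, sprintf("%s-miR%d", sp$code[i], fam))
      species <- c(species, sp$code[i])
      L <- sample(cfg$mature_length_range[1]:cfg$mature_length_range[2], 1L)
      seqs <- c(seqs, chartr("T", "U", random_seq(L, cfg$background_gc)))
    }
  }
  # cross-species duplicates: copy sequence of record i into a record of the
  # next species over
  if (cfg$n_duplicate_pairs > 0L && nrow(sp) > 1L) {
    for (d in seq_len(cfg$n_duplicate_pairs)) {
      from <- which(species == sp$code[1L])[d]
      to <- which(species == sp$code[2L])[d]
      if (!is.na(from) && !is.na(to)) seqs[to] <- seqs[from]
    }
  }
  data.frame(id = ids, species = species, sequence = seqs,
             stringsAsFactors = FALSE)
}

#' Construct a hairpin precursor around a mature sequence
#'
#' Builds the passenger (miRNA*) as the reverse complement of the mature
#' with \code{nm_star} planted non-complementary positions, joins the two
#' arms with a low-complementarity loop and adds \code{flank}-nt
#' pri-extensions, then folds the construct with the baseline engine. If the
#' realized duplex deviates from the design, flanks and loop are resampled
#' up to \code{max_tries} times; the realized mismatch count is recorded
#' either way (the folding engine, not the generator, is the arbiter of the
#' realized structure).
#'
#' @param mature mature RNA sequence.
#' @param nm_star designed non-complementary duplex positions.
#' @param loop_len loop length (>= 3).
#' @param arm \code{"5p"} (mature before loop) or \code{"3p"}.
#' @param flank pri-extension length on each side.
#' @param gc GC fraction of the flanks.
#' @param model an \code{\link{energy_model}}.
#' @param max_tries resampling attempts.
#' @return List: \code{sequence} (RNA), \code{structure}, \code{mature_span}
#'   (1-based inclusive), \code{designed_nm}, \code{realized_nm},
#'   \code{arm}, \code{loop_len}, \code{PL}.
#' @export
build_hairpin <- function(mature, nm_star = 0L, loop_len = 8L, arm = "5p",
                          flank = 13L, gc = 0.45, model = energy_model(),
                          max_tries = 50L) {
  stopifnot(loop_len >= 3L, arm %in% c("5p", "3p"))
  mature <- toupper(dna_to_rna(mature))
  L <- nchar(mature)
  mvec <- strsplit(mature, "", fixed = TRUE)[[1]]
  best <- NULL
  for (try in seq_len(max_tries)) {
    star <- strsplit(revcomp_rna(mature), "", fixed = TRUE)[[1]]
    if (nm_star > 0L) {
      # interior mature positions whose star partner is mutated
      mm_mat_pos <- sort(sample(3:(L - 2L), nm_star))
      for (i in mm_mat_pos) {
        sp <- L - i + 1L          # star index pairing mature position i
        old <- star[sp]
        star[sp] <- sample(setdiff(c("A", "C", "G", "U"), old), 1L)
      }
    }
    star <- paste(star, collapse = "")
    loop <- chartr("T", "U", random_seq(loop_len, gc = 0.25,
                                        alphabet = c("A", "C", "G", "T")))
    f5 <- chartr("T", "U", random_seq(flank, gc))
    f3 <- chartr("T", "U", random_seq(flank, gc))
    if (arm == "5p") {
      seqs <- paste0(f5, mature, loop, star, f3)
      mspan <- c(flank + 1L, flank + L)
    } else {
      seqs <- paste0(f5, star, loop, mature, f3)
      mspan <- c(flank + nchar(star) + loop_len + 1L,
                 flank + nchar(star) + loop_len + L)
    }
    f <- fold_rna(seqs, model)
    d <- tryCatch(star_and_nm(f$structure, mspan), error = function(e) NULL)
    realized <- if (is.null(d)) NA_integer_ else d$NM
    ok <- !is.null(d) &&
      !(d$star_span[1] <= mspan[2] && d$star_span[2] >= mspan[1]) &&
      identical(realized, as.integer(nm_star))
    cand <- list(sequence = seqs, structure = f$structure,
                 mature_span = mspan, designed_nm = as.integer(nm_star),
                 realized_nm = realized, arm = arm, loop_len = loop_len,
                 PL = nchar(seqs))
    if (ok) return(cand)
    if (is.null(best) || (!is.na(realized) && is.na(best$realized_nm)))
      best <- cand
  }
  if (is.null(best)) stop("hairpin construction failed after ", max_tries,
                          " attempts")
  best
}

#' Plant an antisense miRNA target site in background sequence
#'
#' Inserts the reverse complement of the mature (with substitutions planted
#' opposite the requested miRNA positions) at a random offset in an i.i.d.
#' background sequence.
#'
#' @param mature mature RNA sequence.
#' @param mismatch_positions integer vector of miRNA positions (1-based from
#'   the 5' end) to mismatch.
#' @param est_length total EST length.
#' @param gc background GC fraction.
#' @return List: \code{sequence} (DNA), \code{start}, \code{end} (0-based
#'   half-open site span), \code{mismatch_positions}.
#' @export
plant_target <- function(mature, mismatch_positions = integer(0),
                         est_length = 300L, gc = 0.45) {
  mature <- toupper(dna_to_rna(mature))
  L <- nchar(mature)
  stopifnot(est_length >= L + 20L,
            all(mismatch_positions >= 1), all(mismatch_positions <= L))
  site <- strsplit(revcomp_dna(rna_to_dna(mature)), "", fixed = TRUE)[[1]]
  for (i in mismatch_positions) {
    w <- L - i + 1L               # site index opposite miRNA position i
    site[w] <- sample(setdiff(c("A", "C", "G", "T"), site[w]), 1L)
  }
  site <- paste(site, collapse = "")
  start0 <- sample(10:(est_length - L - 10L), 1L)
  bg <- random_seq(est_length, gc)
  seqs <- paste0(substr(bg, 1L, start0), site,
                 substr(bg, start0 + L + 1L, est_length))
  list(sequence = seqs, start = start0, end = start0 + L,
       mismatch_positions = sort(as.integer(mismatch_positions)))
}

#' Generate a full synthetic dataset with ground truth
#'
#' Produces the mature reference, EST clusters (target, precursor and
#' background), the cluster-membership table and a ground-truth manifest
#' recording every planted feature with its coordinates and the verdict the
#' pipeline is expected to reach. All outputs are a deterministic function
#' of the config (including its seed).
#'
#' @param cfg a \code{\link{sim_config}}.
#' @return List of class \code{sim_dataset}: \code{reference} (data.frame),
#'   \code{ests} (data.frame id, sequence, cluster_id), \code{clusters}
#'   (data.frame cluster_id, annotation, category), \code{manifest} (list).
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  reference <- simulate_reference(cfg)
  n_feat_clusters <- nrow(cfg$planted_targets) + nrow(cfg$planted_precursors)
  manifest <- list(seed = cfg$seed, targets = list(), precursors = list(),
                   variants = list())
  ests <- list(); clusters <- list(); templates <- list()
  feature_meta <- list()
  cl_n <- 0L
  add_cluster <- function(kind, template, annotation, category, extra) {
    cl_n <<- cl_n + 1L
    cid <- sprintf("Sim.%04d", cl_n)
    clusters[[cl_n]] <<- data.frame(cluster_id = cid, annotation = annotation,
                                    category = category,
                                    stringsAsFactors = FALSE)
    templates[[cid]] <<- template
    feature_meta[[cl_n]] <<- c(list(kind = kind, cluster_id = cid), extra)
    cid
  }
  ann_pool <- c("protein coding (ZF domain)", "serine/threonine kinase",
                "MYB family transcription factor", "ubiquitin family protein",
                "NAC domain containing protein", "protein coding")
  # target clusters
  for (i in seq_len(nrow(cfg$planted_targets))) {
    tg <- cfg$planted_targets[i, ]
    mat <- reference$sequence[tg$mature_index]
    mm <- if (nzchar(tg$mismatch_positions))
      as.integer(strsplit(tg$mismatch_positions, ",")[[1]]) else integer(0)
    pt <- plant_target(mat, mm, cfg$est_length, cfg$background_gc)
    ann <- if (tg$category == "protein_coding")
      ann_pool[(i - 1L) %% length(ann_pool) + 1L] else "transcribed locus"
    cid <- add_cluster("target", pt$sequence, ann, tg$category,
                       list(mature_id = reference$id[tg$mature_index],
                            site_start = pt$start, site_end = pt$end,
                            mismatch_positions = pt$mismatch_positions))
    manifest$targets[[length(manifest$targets) + 1L]] <- list(
      cluster_id = cid, mature_id = reference$id[tg$mature_index],
      start = pt$start, end = pt$end,
      n_mismatch = length(pt$mismatch_positions),
      mismatch_positions = pt$mismatch_positions,
      category = tg$category)
  }
  # precursor clusters: hairpin embedded mid-transcript
  for (i in seq_len(nrow(cfg$planted_precursors))) {
    pp <- cfg$planted_precursors[i, ]
    mat <- reference$sequence[pp$mature_index]
    hp <- build_hairpin(mat, pp$nm_star, pp$loop_len, pp$arm,
                        gc = cfg$background_gc)
    pad <- max(20L, (cfg$est_length - hp$PL) %/% 2L)
    left <- random_seq(pad, cfg$background_gc)
    right <- random_seq(pad, cfg$background_gc)
    template <- paste0(left, rna_to_dna(hp$sequence), right)
    mstart0 <- pad + hp$mature_span[1] - 1L   # 0-based on template
    cid <- add_cluster("precursor", template, "transcribed locus",
                       "transcribed",
                       list(mature_id = reference$id[pp$mature_index],
                            mature_start = mstart0,
                            mature_end = mstart0 + nchar(mat),
                            hairpin_start = pad,
                            hairpin_end = pad + hp$PL))
    manifest$precursors[[length(manifest$precursors) + 1L]] <- list(
      cluster_id = cid, mature_id = reference$id[pp$mature_index],
      designed_nm = hp$designed_nm, realized_nm = hp$realized_nm,
      arm = pp$arm, loop_len = pp$loop_len, PL = hp$PL,
      mature_start = mstart0, mature_end = mstart0 + nchar(mat),
      structure = hp$structure)
  }
  for (i in seq_len(cfg$n_background_clusters))
    add_cluster("background", random_seq(cfg$est_length, cfg$background_gc),
                NA_character_, "unknown", list())
  clusters <- do.call(rbind, clusters)
  # expand clusters into noisy member ESTs, then inject planted variants
  mutate_seq <- function(s, eps) {
    if (eps <= 0) return(s)
    v <- strsplit(s, "", fixed = TRUE)[[1]]
    hitpos <- which(runif(length(v)) < eps)
    for (p in hitpos) v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1L)
    paste(v, collapse = "")
  }
  # clusters carrying a planted variant need the alternative allele to stay
  # in the minority: draw at least 2*alt_support + 1 members there
  min_members <- setNames(rep(cfg$members_per_cluster[1], nrow(clusters)),
                          clusters$cluster_id)
  if (nrow(cfg$planted_variants)) {
    for (i in seq_len(nrow(cfg$planted_variants))) {
      pv <- cfg$planted_variants[i, ]
      meta_idx <- which(vapply(feature_meta, function(x)
        x$kind == (if (pv$cluster_kind == "target") "target" else "precursor"),
        logical(1)))[pv$feature_index]
      cid <- feature_meta[[meta_idx]]$cluster_id
      min_members[cid] <- max(min_members[cid], 2L * pv$alt_support + 1L)
    }
    if (any(min_members > cfg$members_per_cluster[2]))
      stop("members_per_cluster too small for the requested alt_support")
  }
  member_map <- list()
  est_n <- 0L
  for (ci in seq_len(nrow(clusters))) {
    cid <- clusters$cluster_id[ci]
    nm <- sample(min_members[[cid]]:cfg$members_per_cluster[2], 1L)
    ids <- sprintf("%s.est%02d", cid, seq_len(nm))
    member_map[[cid]] <- ids
    for (id in ids) {
      est_n <- est_n + 1L
      ests[[est_n]] <- data.frame(
        id = id, sequence = mutate_seq(templates[[cid]], cfg$error_rate),
        cluster_id = cid, stringsAsFactors = FALSE)
    }
  }
  ests <- do.call(rbind, ests)
  # planted variants: overwrite the template base in alt_support members
  if (nrow(cfg$planted_variants)) for (i in seq_len(nrow(cfg$planted_variants))) {
    pv <- cfg$planted_variants[i, ]
    meta_idx <- which(vapply(feature_meta, function(x)
      x$kind == (if (pv$cluster_kind == "target") "target" else "precursor"),
      logical(1)))[pv$feature_index]
    meta <- feature_meta[[meta_idx]]
    cid <- meta$cluster_id
    tpos0 <- if (pv$region_kind == "target_site")
      meta$site_end - pv$mirna_position            # 0-based template coord
    else meta$mature_start + pv$mirna_position - 1L
    ref_base <- substr(templates[[cid]], tpos0 + 1L, tpos0 + 1L)
    alt <- toupper(pv$alt)
    if (alt == ref_base)
      alt <- setdiff(c("A", "C", "G", "T"), ref_base)[1L]
    carriers <- member_map[[cid]][seq_len(pv$alt_support)]
    for (id in carriers) {
      r <- which(ests$id == id)
      substr(ests$sequence[r], tpos0 + 1L, tpos0 + 1L) <- alt
    }
    manifest$variants[[length(manifest$variants) + 1L]] <- list(
      cluster_id = cid, region_kind = pv$region_kind,
      mirna_position = pv$mirna_position, template_pos = tpos0,
      ref = ref_base, alt = alt, alt_support = pv$alt_support,
      expected_class = if (pv$alt_support >= 2L) "candidate_true"
                       else "low_support")
  }
  structure(list(reference = reference, ests = ests, clusters = clusters,
                 manifest = manifest, config = cfg),
            class = "sim_dataset")
}

#' Write a generated dataset to disk
#'
#' Emits reference FASTA, EST FASTA, cluster-membership TSV and the manifest
#' as JSON.
#'
#' @param dataset a \code{\link{generate_dataset}} result.
#' @param dir output directory (created if needed).
#' @return Named character vector of the written paths.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "sim_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(reference = file.path(dir, "reference.fasta"),
             ests = file.path(dir, "ests.fasta"),
             clusters = file.path(dir, "clusters.tsv"),
             manifest = file.path(dir, "manifest.json"))
  write_fasta_chr(setNames(dataset$reference$sequence, dataset$reference$id),
                  paths["reference"])
  write_fasta_chr(setNames(dataset$ests$sequence, dataset$ests$id),
                  paths["ests"])
  memb <- merge(dataset$ests[, c("id", "cluster_id")], dataset$clusters,
                by = "cluster_id")[, c("id", "cluster_id", "annotation",
                                       "category")]
  names(memb)[1] <- "est_id"
  write.table(memb[order(memb$est_id), ], paths["clusters"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(dataset$manifest, paths["manifest"], auto_unbox = TRUE,
                       digits = NA)
  paths
}

#' Validate a manifest against the emitted sequences
#'
#' Re-reads every planted-feature coordinate from the dataset and checks it
#' is consistent with the sequences: target sites must show exactly the
#' designed mismatch pattern against the mature, precursor mature spans must
#' contain the mature sequence.
#'
#' @param dataset a \code{\link{generate_dataset}} result.
#' @return TRUE (invisibly) or an error describing the inconsistency.
#' @export
validate_manifest <- function(dataset) {
  ref <- setNames(dataset$reference$sequence, dataset$reference$id)
  templates <- list()
  for (tg in dataset$manifest$targets) {
    est1 <- dataset$ests[dataset$ests$cluster_id == tg$cluster_id, ][1L, ]
    mat <- ref[[tg$mature_id]]
    win <- substr(est1$sequence, tg$start + 1L, tg$end)
    mm <- count_mismatches(mat, revcomp_dna(win))
    if (mm < tg$n_mismatch)
      stop("manifest mismatch count too high for ", tg$cluster_id)
  }
  for (pc in dataset$manifest$precursors) {
    est1 <- dataset$ests[dataset$ests$cluster_id == pc$cluster_id, ][1L, ]
    mat <- ref[[pc$mature_id]]
    win <- substr(est1$sequence, pc$mature_start + 1L, pc$mature_end)
    if (dataset$config$error_rate == 0 &&
        !identical(dna_to_rna(win), mat))
      stop("mature span mismatch for ", pc$cluster_id)
  }
  invisible(TRUE)
}

#' Null simulation for the species representation statistic
#'
#' Draws matched sets of size K uniformly (without replacement) from the
#' initial redundant set and records the tail-mode p-value of every species
#' in every draw, yielding the empirical rate at which tail p-values fall
#' below a nominal level under the null.
#'
#' @param initial_counts named integer vector: species -> initial count.
#' @param K matched-set size.
#' @param reps number of draws (>= 100).
#' @param alpha nominal level.
#' @return List: \code{rate} (empirical fraction of tail p-values <= alpha,
#'   pooled over species and draws), \code{alpha}, \code{mc_se}, \code{reps},
#'   \code{p_values} (matrix reps x species).
#' @export
null_enrichment_sim <- function(initial_counts, K, reps = 1000L,
                                alpha = 0.05) {
  stopifnot(reps >= 100L, K <= sum(initial_counts))
  species <- rep(names(initial_counts), initial_counts)
  M <- length(species)
  pv <- matrix(NA_real_, reps, length(initial_counts),
               dimnames = list(NULL, names(initial_counts)))
  for (r in seq_len(reps)) {
    drawn <- sample(species, K)
    kt <- table(factor(drawn, levels = names(initial_counts)))
    for (s in seq_along(initial_counts)) {
      pv[r, s] <- representation_stat(initial_counts[[s]], M, kt[[s]], K,
                                      mode = "tail")$p_value
    }
  }
  rate <- mean(pv <= alpha)
  list(rate = rate, alpha = alpha,
       mc_se = sqrt(alpha * (1 - alpha) / (reps * length(initial_counts))),
       reps = reps, p_values = pv)
}
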