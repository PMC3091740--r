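#' Pipeline configuration
#'
#' One place for every tunable threshold, with the screen's standard
#' defaults: fewer than 4 mismatches for the homology scan, representation
#' thresholds 0.05/0.01/0.005/0.001, MFEI > 0.85, at most 4 unpaired mature
#' positions in the duplex, 13-nt pri-extension flanks, and two independent
#' copies for a candidate-true polymorphism.
#'
#' @param max_mm homology scan mismatch cap.
#' @param thresholds representation p-value thresholds.
#' @param stat_mode \code{"point_mass"} or \code{"tail"}.
#' @param mfei_min strict MFEI acceptance threshold.
#' @param max_star_mm,max_bulges,max_bulge_size duplex screening limits.
#' @param flank pri-extension length (nt per side).
#' @param fold_window folding context around a hit (nt per side).
#' @param min_support copies required for a candidate-true variant.
#' @param seed RNG seed recorded with outputs.
#' @return List of class \code{pipeline_config}.
#' @export
pipeline_config <- function(max_mm = 3L,
                            thresholds = c(0.05, 0.01, 0.005, 0.001),
                            stat_mode = "point_mass",
                            mfei_min = 0.85, max_star_mm = 4L,
                            max_bulges = 2L, max_bulge_size = 3L,
                            flank = 13L, fold_window = 250L,
                            min_support = 2L, seed = 1L) {
  stopifnot(all(thresholds > 0), all(thresholds <= 1), max_mm >= 0,
            mfei_min > 0, flank >= 0, fold_window > 0, min_support >= 1)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full discovery pipeline
#'
#' Orchestrates the stages over an in-memory dataset (or file paths):
#' cluster assembly, homology scan of the mature reference against ESTs
#' (for species representation) and against cluster consensi (for
#' precursor/target/variant analysis), species enrichment with threshold
#' sweep, precursor extraction + validation on sense hits of transcribed
#' clusters, target profiling on antisense hits of protein-coding clusters,
#' and variant calling over miRNA-relevant consensus regions.
#'
#' @param reference a \code{reference_set}, a data.frame (id, sequence), or
#'   a FASTA path.
#' @param ests data.frame (id, sequence, cluster_id) or EST FASTA path.
#' @param clusters data.frame (cluster_id, annotation, category) or
#'   cluster-membership TSV path (est_id, cluster_id, annotation, category).
#' @param config a \code{\link{pipeline_config}}.
#' @param out_dir if given, the output tables are written there as TSV.
#' @return List of class \code{pipeline_result} with \code{hits},
#'   \code{consensus_hits}, \code{enrichment}, \code{sweep},
#'   \code{precursors} (data.frame), \code{precursor_candidates} (objects),
#'   \code{targets}, \code{target_summary}, \code{variants},
#'   \code{alignments}, \code{multi_hits}.
#' @export
run_pipeline <- function(reference, ests, clusters,
                         config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  ref <- if (inherits(reference, "reference_set")) reference
  else if (is.data.frame(reference))
    parse_mature_fasta(paste0(">", reference$id, "\n", reference$sequence,
                              collapse = "\n"))
  else parse_mature_fasta(reference)
  if (is.character(ests)) {
    seqs <- read_fasta_chr(ests)
    ests <- data.frame(id = names(seqs), sequence = unname(seqs),
                       stringsAsFactors = FALSE)
  }
  if (is.character(clusters)) {
    memb <- read_cluster_table(clusters)
    if (is.null(ests$cluster_id))
      ests <- merge(ests, memb[, c("est_id", "cluster_id")],
                    by.x = "id", by.y = "est_id", all.x = TRUE)
    clusters <- unique(memb[, c("cluster_id", "annotation", "category")])
  }
  if (is.null(clusters$category) || all(is.na(clusters$category)))
    clusters$category <- vapply(clusters$annotation, classify_cluster,
                                character(1))
  # --- assemble
  alignments <- list()
  for (cid in unique(clusters$cluster_id)) {
    mem <- ests[!is.na(ests$cluster_id) & ests$cluster_id == cid, ]
    if (!nrow(mem)) next
    alignments[[cid]] <- assemble_cluster(mem[, c("id", "sequence")], cid)
  }
  consensi <- data.frame(
    id = names(alignments),
    sequence = vapply(alignments, `[[`, character(1), "consensus"),
    cluster_id = names(alignments), stringsAsFactors = FALSE)
  # --- scan
  hits <- scan_homology(ref, ests, config$max_mm)
  chits <- scan_homology(ref, consensi, config$max_mm)
  multi <- multi_hit_report(hits)
  # --- enrichment
  init <- table(ref$records$species[!is.na(ref$records$species)])
  initial_counts <- setNames(as.integer(init), names(init))
  matched_counts <- matched_redundant_set(hits, ref)
  enrichment <- if (length(matched_counts))
    build_enrichment_table(initial_counts, matched_counts,
                           mode = config$stat_mode) else NULL
  sweep <- if (!is.null(enrichment))
    threshold_sweep(enrichment, config$thresholds) else NULL
  # --- precursors (sense hits on transcribed clusters)
  cat_of <- setNames(clusters$category, clusters$cluster_id)
  mat_of <- setNames(ref$nr$sequence, ref$nr$id)
  prec_objects <- list(); prec_rows <- list()
  ph <- chits[chits$orientation == "sense" &
                cat_of[chits$cluster_id] %in% "transcribed", , drop = FALSE]
  for (r in seq_len(nrow(ph))) {
    hit <- ph[r, ]
    cand <- extract_candidate(alignments[[hit$cluster_id]]$consensus, hit,
                              config$fold_window, config$flank)
    if (inherits(cand, "precursor_rejection")) {
      prec_rows[[length(prec_rows) + 1L]] <- data.frame(
        source_id = hit$cluster_id, mirna_id = hit$mirna_nr_id,
        family = hit$family, dG = NA_real_, gc_pct = NA_real_,
        MFEI = NA_real_, NM = NA_integer_, ML = NA_integer_,
        PL = NA_integer_, arm = NA_character_, accepted = FALSE,
        reject_reasons = cand$reason, stringsAsFactors = FALSE)
      next
    }
    cand <- validate_candidate(cand, config$mfei_min, config$max_star_mm,
                               config$max_bulges, config$max_bulge_size)
    cand$source_id <- hit$cluster_id
    prec_objects[[length(prec_objects) + 1L]] <- cand
    prec_rows[[length(prec_rows) + 1L]] <- data.frame(
      source_id = hit$cluster_id, mirna_id = hit$mirna_nr_id,
      family = hit$family, dG = cand$dG, gc_pct = cand$gc_pct,
      MFEI = cand$MFEI, NM = cand$NM, ML = cand$ML, PL = cand$PL,
      arm = cand$arm, accepted = cand$accepted,
      reject_reasons = paste(cand$reject_reasons, collapse = "; "),
      stringsAsFactors = FALSE)
  }
  precursors <- if (length(prec_rows)) do.call(rbind, prec_rows) else
    data.frame(source_id = character(), mirna_id = character(),
               family = character(), dG = numeric(), gc_pct = numeric(),
               MFEI = numeric(), NM = integer(), ML = integer(),
               PL = integer(), arm = character(), accepted = logical(),
               reject_reasons = character(), stringsAsFactors = FALSE)
  # --- targets (antisense hits on protein-coding clusters)
  th <- chits[chits$orientation == "antisense" &
                cat_of[chits$cluster_id] %in% "protein_coding", ,
              drop = FALSE]
  target_rows <- list()
  for (r in seq_len(nrow(th))) {
    hit <- th[r, ]
    prof <- site_profile(hit, mat_of[[hit$mirna_nr_id]],
                         alignments[[hit$cluster_id]]$consensus)
    target_rows[[length(target_rows) + 1L]] <- data.frame(
      cluster_id = hit$cluster_id, mirna_id = hit$mirna_nr_id,
      family = hit$family, start = hit$start, end = hit$end,
      n_mismatch = hit$mismatches,
      mismatch_positions = hit$mismatch_positions,
      critical_mismatch = prof$critical_mismatch,
      cleavage_site_mismatch = prof$cleavage_site_mismatch,
      stringsAsFactors = FALSE)
  }
  targets <- if (length(target_rows)) do.call(rbind, target_rows) else
    data.frame(cluster_id = character(), mirna_id = character(),
               family = character(), start = integer(), end = integer(),
               n_mismatch = integer(), mismatch_positions = character(),
               critical_mismatch = logical(),
               cleavage_site_mismatch = logical(), stringsAsFactors = FALSE)
  target_summary <- summarize_targets(chits, clusters)
  # --- variants over miRNA-relevant consensus regions
  var_rows <- list()
  for (cid in names(alignments)) {
    hc <- chits[chits$cluster_id == cid, , drop = FALSE]
    if (!nrow(hc)) next
    regions <- data.frame(
      start = hc$start, end = hc$end,
      kind = ifelse(hc$orientation == "antisense", "target_site",
                    "mature_region"), stringsAsFactors = FALSE)
    calls <- call_variants(alignments[[cid]], regions, config$min_support)
    if (!nrow(calls)) next
    calls$mirna_position <- NA_integer_
    calls$critical <- NA
    for (i in seq_len(nrow(calls))) {
      reg <- which(hc$start <= calls$consensus_pos[i] &
                     hc$end > calls$consensus_pos[i])[1L]
      if (is.na(reg)) next
      mp <- map_to_mirna_position(
        calls$consensus_pos[i], c(hc$start[reg], hc$end[reg]),
        if (hc$orientation[reg] == "antisense") "antisense" else "sense")
      calls$mirna_position[i] <- mp$position
      calls$critical[i] <- mp$critical
    }
    var_rows[[length(var_rows) + 1L]] <- calls
  }
  variants <- if (length(var_rows)) do.call(rbind, var_rows) else
    call_variants(structure(list(columns = data.frame(), cluster_id = NA,
                                 symbols = matrix(nrow = 0, ncol = 0)),
                            class = "cluster_alignment"),
                  data.frame(start = integer(), end = integer(),
                             kind = character()))
  res <- structure(list(hits = hits, consensus_hits = chits,
                        enrichment = enrichment, sweep = sweep,
                        precursors = precursors,
                        precursor_candidates = prec_objects,
                        targets = targets, target_summary = target_summary,
                        variants = variants, multi_hits = multi,
                        alignments = alignments, config = config),
                   class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_tables(res, out_dir)
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf(paste0(
    "pipeline_result: %d EST hits, %d clusters assembled, %d precursor\n",
    "candidates (%d accepted), %d target sites, %d variant calls\n"),
    nrow(x$hits), length(x$alignments), nrow(x$precursors),
    sum(x$precursors$accepted), nrow(x$targets), nrow(x$variants)))
  invisible(x)
}

#' Write pipeline outputs as TSV tables
#'
#' Emits hits.tsv, enrichment.tsv, sweep.tsv, precursors.tsv, targets.tsv
#' and variants.tsv with fixed numeric formatting, so identical inputs give
#' byte-identical outputs.
#'
#' @param res a \code{pipeline_result}.
#' @param dir output directory.
#' @return The directory, invisibly.
#' @export
write_pipeline_tables <- function(res, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wt <- function(d, f) write.table(d, file.path(dir, f), sep = "\t",
                                   quote = FALSE, row.names = FALSE)
  wt(res$hits, "hits.tsv")
  if (!is.null(res$enrichment)) {
    enr <- res$enrichment
    enr$p_value <- format_pvalue(enr$p_value)
    wt(enr, "enrichment.tsv")
    sw <- do.call(rbind, lapply(res$sweep, function(lev) data.frame(
      threshold = format(lev$threshold, trim = TRUE),
      over = paste(lev$over, collapse = ","),
      under = paste(lev$under, collapse = ","), stringsAsFactors = FALSE)))
    wt(sw, "sweep.tsv")
  }
  prec <- res$precursors
  prec$dG <- ifelse(is.na(prec$dG), "", sprintf("%.1f", prec$dG))
  prec$MFEI <- ifelse(is.na(prec$MFEI), "", sprintf("%.2f", prec$MFEI))
  prec$gc_pct <- ifelse(is.na(prec$gc_pct), "", sprintf("%.1f", prec$gc_pct))
  wt(prec, "precursors.tsv")
  wt(res$targets, "targets.tsv")
  wt(res$variants, "variants.tsv")
  invisible(dir)
}

#' Recompute a species representation table from printed counts
#'
#' Takes a table of per-species initial and matched counts (for example the
#' counts column pairs of a published representation table), recomputes the
#' percentage columns, the representation statistic and the threshold
#' sweep, and returns them for comparison with the printed values.
#'
#' @param counts data.frame with columns \code{species}, \code{initial},
#'   \code{matched}, or the path to such a TSV. The bundled
#'   \code{system.file("extdata", "barley_species_counts.tsv", package =
#'   "mirEST")} carries the barley EST survey counts.
#' @param thresholds sweep thresholds.
#' @param mode statistic mode.
#' @return List with \code{table} (enrichment data.frame with formatted
#'   p-values in \code{p_printed}) and \code{sweep}.
#' @export
verify_species_table <- function(counts,
                                 thresholds = c(0.05, 0.01, 0.005, 0.001),
                                 mode = "point_mass") {
  if (is.character(counts)) counts <- read.delim(counts,
                                                 stringsAsFactors = FALSE)
  stopifnot(all(c("species", "initial", "matched") %in% names(counts)))
  tab <- build_enrichment_table(
    setNames(counts$initial, counts$species),
    setNames(counts$matched, counts$species), mode = mode)
  tab$p_printed <- format_pvalue(tab$p_value)
  list(table = tab, sweep = threshold_sweep(tab, thresholds))
}
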