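#' Classify a cluster annotation into a functional category
#'
#' Keyword rule: annotations carrying protein/product descriptors are
#' \code{protein_coding} (target candidates); annotations describing
#' transcribed loci without protein evidence are \code{transcribed}
#' (precursor candidates); everything else is \code{unknown}.
#'
#' @param annotation free-text cluster annotation.
#' @param protein_terms,transcribed_terms keyword sets (regular expressions,
#'   case-insensitive) defining the two informative categories.
#' @return One of \code{"protein_coding"}, \code{"transcribed"},
#'   \code{"unknown"}.
#' @examples
#' classify_cluster("protein coding (SBP domain)")  # protein_coding
#' @export
classify_cluster <- function(annotation,
                             protein_terms = c("protein", "coding", "domain",
                                               "factor", "kinase", "binding",
                                               "enzyme", "superfamily"),
                             transcribed_terms = c("transcribed")) {
  if (is.na(annotation) || !nzchar(trimws(annotation))) return("unknown")
  hit <- function(terms) any(vapply(terms, function(t)
    grepl(t, annotation, ignore.case = TRUE), logical(1)))
  if (hit(protein_terms)) "protein_coding"
  else if (hit(transcribed_terms)) "transcribed"
  else "unknown"
}

#' Profile an antisense target site position-by-position
#'
#' Maps each miRNA position (1-based from the mature 5' end) onto the EST
#' and records whether the EST base is the Watson-Crick complement of the
#' miRNA base (U equivalent to T; GU wobble is NOT counted as a match in
#' target profiling). Under antisense orientation, miRNA position i sits at
#' EST forward-strand coordinate \code{end - i} (0-based). Flags mark any
#' mismatch at the functionally critical positions 2-12 and at the cleavage
#' positions 10/11.
#'
#' @param hit one-row antisense hit from \code{\link{scan_homology}}.
#' @param mature mature RNA sequence of the matching miRNA.
#' @param est_seq the EST (or consensus) sequence the hit lies on.
#' @return List of class \code{target_site}: \code{cluster_id},
#'   \code{families}, \code{site_span} (0-based half-open),
#'   \code{per_position} (character vector over miRNA positions, values
#'   \code{"match"}/\code{"mismatch"}), \code{critical_mismatch},
#'   \code{cleavage_site_mismatch}.
#' @export
site_profile <- function(hit, mature, est_seq) {
  stopifnot(nrow(hit) == 1L)
  if (hit$orientation != "antisense")
    stop("not a target-type hit: orientation is ", hit$orientation)
  mat <- strsplit(toupper(dna_to_rna(mature)), "", fixed = TRUE)[[1]]
  L <- length(mat)
  stopifnot(hit$end - hit$start == L)
  est <- strsplit(toupper(rna_to_dna(est_seq)), "", fixed = TRUE)[[1]]
  status <- character(L)
  for (i in seq_len(L)) {
    coord <- hit$end - i           # 0-based EST coordinate of miRNA pos i
    est_base <- est[coord + 1L]
    expected <- unname(COMP_DNA[rna_to_dna(mat[i])])
    status[i] <- if (identical(est_base, expected)) "match" else "mismatch"
  }
  mm_pos <- which(status == "mismatch")
  structure(list(cluster_id = hit$cluster_id,
                 families = unique(hit$family),
                 site_span = c(hit$start, hit$end),
                 per_position = status,
                 mismatch_positions = mm_pos,
                 critical_mismatch = any(mm_pos >= 2L & mm_pos <= 12L),
                 cleavage_site_mismatch = any(mm_pos %in% c(10L, 11L))),
            class = "target_site")
}

#' Summarize target clusters per miRNA family
#'
#' Keeps antisense hits on protein-coding clusters, counts distinct target
#' clusters per family, and reports sites where hits of two or more families
#' overlap as combined multi-miRNA sites (labels like \code{"1128+1133"}).
#'
#' @param hits data.frame from \code{\link{scan_homology}}.
#' @param clusters data.frame with \code{cluster_id} and \code{category}
#'   (from \code{\link{read_cluster_table}} / \code{\link{classify_cluster}}).
#' @return List with \code{family_counts} (data.frame family,
#'   n_target_clusters), \code{targets} (per family, the cluster IDs) and
#'   \code{multi_family_sites} (data.frame est_id, label, start, end).
#' @export
summarize_targets <- function(hits, clusters) {
  cl <- unique(clusters[, c("cluster_id", "category")])
  h <- merge(hits, cl, by = "cluster_id", all.x = TRUE)
  h <- h[h$orientation == "antisense" &
           !is.na(h$category) & h$category == "protein_coding", , drop = FALSE]
  if (!nrow(h))
    return(list(family_counts = data.frame(family = character(),
                                           n_target_clusters = integer()),
                targets = list(),
                multi_family_sites = data.frame(est_id = character(),
                                                label = character(),
                                                start = integer(),
                                                end = integer())))
  targets <- lapply(split(h$cluster_id, h$family), function(x) sort(unique(x)))
  family_counts <- data.frame(family = names(targets),
                              n_target_clusters = lengths(targets),
                              row.names = NULL, stringsAsFactors = FALSE)
  # overlapping sites of different families on one EST
  multi <- list()
  for (e in unique(h$est_id)) {
    he <- h[h$est_id == e, , drop = FALSE]
    if (length(unique(he$family)) < 2L) next
    ir <- IRanges::IRanges(start = he$start + 1L, end = he$end)
    ov <- IRanges::findOverlaps(ir, ir)
    grp <- IRanges::reduce(ir)
    memb <- IRanges::findOverlaps(ir, grp)
    for (g in unique(S4Vectors::subjectHits(memb))) {
      rows <- S4Vectors::queryHits(memb)[S4Vectors::subjectHits(memb) == g]
      fams <- sort(unique(he$family[rows]))
      if (length(fams) > 1L)
        multi[[length(multi) + 1L]] <- data.frame(
          est_id = e, label = paste(fams, collapse = "+"),
          start = min(he$start[rows]), end = max(he$end[rows]),
          stringsAsFactors = FALSE)
    }
  }
  multi_family_sites <- if (length(multi)) do.call(rbind, multi) else
    data.frame(est_id = character(), label = character(),
               start = integer(), end = integer())
  list(family_counts = family_counts, targets = targets,
       multi_family_sites = multi_family_sites)
}

#' Tally target clusters into user-supplied functional categories
#'
#' A plain keyword tally standing in for ontology-based slimming: each
#' annotation is matched against a term -> category map; annotations
#' matching no term are counted as \code{"unannotated"}.
#'
#' @param annotations character vector of cluster annotations.
#' @param category_map named character vector: term (fixed substring,
#'   case-insensitive) -> category.
#' @return data.frame with \code{category}, \code{n}, \code{pct} (one
#'   decimal, of all annotations).
#' @export
category_tally <- function(annotations, category_map = character(0)) {
  cats <- vapply(annotations, function(a) {
    if (!is.na(a) && length(category_map)) {
      hit <- vapply(names(category_map), function(t)
        grepl(t, a, ignore.case = TRUE, fixed = FALSE), logical(1))
      if (any(hit)) return(unname(category_map[which(hit)[1L]]))
    }
    "unannotated"
  }, character(1))
  tab <- table(cats)
  data.frame(category = names(tab), n = as.integer(tab),
             pct = percent(as.integer(tab), length(annotations)),
             row.names = NULL, stringsAsFactors = FALSE)
}
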