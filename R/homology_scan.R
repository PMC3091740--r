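#' Count mismatches between a mature miRNA and an equal-length window
#'
#' Positional comparison with U treated as T; any \code{N} in the window
#' counts as a mismatch.
#'
#' @param mature RNA sequence (character scalar).
#' @param window DNA window of the same length.
#' @return Integer mismatch count.
#' @examples
#' count_mismatches("UGACAG", "TGACAG")  # 0
#' @export
count_mismatches <- function(mature, window) {
  m <- strsplit(toupper(rna_to_dna(mature)), "", fixed = TRUE)[[1]]
  w <- strsplit(toupper(window), "", fixed = TRUE)[[1]]
  if (length(m) != length(w)) stop("mature and window lengths differ")
  sum(m != w)
}

#' Scan a reference set against ESTs for mismatch-limited matches
#'
#' Deterministic replacement for a BLASTn homology search: every full-length
#' ungapped window of every EST is compared against every non-redundant
#' mature sequence, on the forward strand (sense: the EST carries the miRNA
#' sequence itself) and on the reverse complement (antisense: the EST carries
#' a target-type site). Windows with at most \code{max_mm} mismatches are
#' reported. Coordinates are 0-based half-open on the EST forward strand;
#' mismatch positions are 1-based from the mature 5' end in both
#' orientations.
#'
#' @param ref a \code{\link{parse_mature_fasta}} reference set.
#' @param ests data.frame with columns \code{id}, \code{sequence} and
#'   optionally \code{cluster_id} (DNA, upper-case or mixed).
#' @param max_mm maximum number of mismatches (default 3, i.e. fewer than 4).
#' @return data.frame of hits with columns \code{mirna_nr_id}, \code{family},
#'   \code{est_id}, \code{cluster_id}, \code{start}, \code{end},
#'   \code{orientation} (\code{"sense"}/\code{"antisense"}),
#'   \code{mismatches}, \code{mismatch_positions} (comma-joined, "" if none),
#'   ordered by (est_id, start, orientation).
#' @export
scan_homology <- function(ref, ests, max_mm = 3L) {
  stopifnot(inherits(ref, "reference_set"), max_mm >= 0L)
  empty <- data.frame(mirna_nr_id = character(), family = character(),
                      est_id = character(), cluster_id = character(),
                      start = integer(), end = integer(),
                      orientation = character(), mismatches = integer(),
                      mismatch_positions = character(),
                      stringsAsFactors = FALSE)
  if (!nrow(ests) || !nrow(ref$nr)) return(empty)
  if (is.null(ests$cluster_id)) ests$cluster_id <- NA_character_
  subj <- Biostrings::DNAStringSet(toupper(ests$sequence))
  names(subj) <- ests$id
  fam <- setNames(ref$records$family, ref$records$id)
  out <- vector("list", 2L * nrow(ref$nr))
  slot <- 0L
  for (r in seq_len(nrow(ref$nr))) {
    mat_rna <- ref$nr$sequence[r]
    pat <- Biostrings::DNAString(rna_to_dna(mat_rna))
    L <- length(pat)
    for (ori in c("sense", "antisense")) {
      p <- if (ori == "sense") pat else Biostrings::reverseComplement(pat)
      pchr <- strsplit(as.character(p), "", fixed = TRUE)[[1]]
      mm <- Biostrings::vmatchPattern(p, subj, max.mismatch = max_mm,
                                      fixed = TRUE)
      ne <- lengths(mm)
      if (!sum(ne)) next
      hits_i <- rep(seq_along(subj), ne)
      starts <- unlist(Biostrings::startIndex(mm), use.names = FALSE)
      keep <- starts >= 1L &
        (starts + L - 1L) <= nchar(ests$sequence)[hits_i]
      hits_i <- hits_i[keep]; starts <- starts[keep]
      if (!length(starts)) next
      win <- substring(ests$sequence[hits_i], starts, starts + L - 1L)
      mmpos <- lapply(seq_along(win), function(q) {
        w <- strsplit(toupper(win[q]), "", fixed = TRUE)[[1]]
        d <- which(w != pchr)
        if (ori == "antisense") sort(L - d + 1L) else d
      })
      slot <- slot + 1L
      out[[slot]] <- data.frame(
        mirna_nr_id = ref$nr$id[r],
        family = unname(fam[ref$nr$id[r]]),
        est_id = ests$id[hits_i],
        cluster_id = ests$cluster_id[hits_i],
        start = starts - 1L,
        end = starts - 1L + L,
        orientation = ori,
        mismatches = lengths(mmpos),
        mismatch_positions = vapply(mmpos, paste, character(1), collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  if (!slot) return(empty)
  hits <- do.call(rbind, out[seq_len(slot)])
  hits <- hits[hits$mismatches <= max_mm, , drop = FALSE]
  hits <- hits[order(hits$est_id, hits$start, hits$orientation,
                     hits$mirna_nr_id), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Per-species matched counts over the redundant reference set
#'
#' A redundant mature record counts as matched when its sequence's
#' non-redundant representative has at least one hit, regardless of how many
#' ESTs it matches; identical sequences removed during deduplication are
#' re-included here so per-species counts reflect the full redundant set.
#' Records without a parseable species code are ignored.
#'
#' @param hits data.frame from \code{\link{scan_homology}}.
#' @param ref the reference set the hits were produced from.
#' @return Named integer vector: species code -> number of matched redundant
#'   records.
#' @export
matched_redundant_set <- function(hits, ref) {
  stopifnot(inherits(ref, "reference_set"))
  rep_seq <- setNames(ref$nr$sequence, ref$nr$id)
  matched_seqs <- unique(unname(rep_seq[unique(hits$mirna_nr_id)]))
  matched_ids <- unlist(ref$nr_map[matched_seqs], use.names = FALSE)
  rec <- ref$records[ref$records$id %in% matched_ids &
                       !is.na(ref$records$species), , drop = FALSE]
  tab <- table(rec$species)
  setNames(as.integer(tab), names(tab))
}

#' Report ESTs carrying more than one miRNA site
#'
#' Flags ESTs with multiple hits, distinguishing several sites of one family
#' (near-identical family members) from sites of different families
#' (candidate multi-miRNA control).
#'
#' @param hits data.frame from \code{\link{scan_homology}}.
#' @return data.frame with one row per EST having > 1 hit: \code{est_id},
#'   \code{n_hits}, \code{families} (comma-joined), \code{multi_family},
#'   \code{same_family_multi_site}.
#' @export
multi_hit_report <- function(hits) {
  if (!nrow(hits)) return(data.frame(est_id = character(),
                                     n_hits = integer(),
                                     families = character(),
                                     multi_family = logical(),
                                     same_family_multi_site = logical()))
  sp <- split(hits, hits$est_id)
  sp <- sp[vapply(sp, nrow, integer(1)) > 1L]
  out <- lapply(sp, function(h) {
    fams <- h$family
    data.frame(est_id = h$est_id[1L],
               n_hits = nrow(h),
               families = paste(sort(unique(fams)), collapse = ","),
               multi_family = length(unique(fams)) > 1L,
               same_family_multi_site = any(table(fams) > 1L),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  if (is.null(res)) res <- data.frame()
  res
}
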