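#' Locate the miRNA* and duplex irregularities in a folded precursor
#'
#' Given a secondary structure and the mature span, finds the passenger
#' (miRNA*) span as the minimal interval covering all partners of mature
#' positions, counts the mature positions left unpaired in the duplex
#' (\code{NM}), and extracts bulges: maximal runs of unpaired positions
#' interior to the duplex, labelled by the arm carrying them.
#'
#' @param db dot-bracket structure.
#' @param mature_span integer c(start, end), 1-based inclusive positions of
#'   the mature on the folded sequence.
#' @return List with \code{star_span} (1-based inclusive), \code{NM},
#'   and \code{bulges} (data.frame \code{arm} in mature/star, \code{offset}
#'   1-based within the arm span, \code{size}).
#' @export
star_and_nm <- function(db, mature_span) {
  partner <- dotbracket_to_partner(db)
  stopifnot(mature_span[1] >= 1, mature_span[2] <= length(partner),
            mature_span[1] <= mature_span[2])
  mpos <- mature_span[1]:mature_span[2]
  partners <- partner[mpos]
  if (!any(partners != 0L)) stop("no duplex: no mature position is paired")
  # partition partners by side; the arm with most partners is the star arm,
  # and stray pairings to the other side or within the mature itself are
  # treated as unpaired (robustness against isolated long-range pairs)
  left <- partners != 0L & partners < mature_span[1]
  right <- partners != 0L & partners > mature_span[2]
  paired <- if (sum(left) >= sum(right)) left else right
  if (!any(paired))
    stop("no duplex: mature positions pair only within the mature span")
  star_span <- c(min(partners[paired]), max(partners[paired]))
  nm <- sum(!paired)
  runs_in <- function(flags, arm, base_offset) {
    r <- rle(flags)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    sel <- r$values
    if (!any(sel)) return(NULL)
    data.frame(arm = arm, offset = starts[sel] + base_offset,
               size = r$lengths[sel], stringsAsFactors = FALSE)
  }
  # interior of the mature arm: between first and last paired mature position
  fp <- which(paired)[1L]; lp <- which(paired)[length(which(paired))]
  bl <- list()
  if (lp - fp > 1L)
    bl$mature <- runs_in(!paired[(fp + 1L):(lp - 1L)], "mature", fp)
  spos <- star_span[1]:star_span[2]
  sp_unpaired <- partner[spos] == 0L
  if (length(spos) > 2L)
    bl$star <- runs_in(sp_unpaired[2:(length(spos) - 1L)], "star", 1L)
  bulges <- do.call(rbind, bl)
  if (is.null(bulges))
    bulges <- data.frame(arm = character(), offset = integer(),
                         size = integer(), stringsAsFactors = FALSE)
  rownames(bulges) <- NULL
  list(star_span = star_span, NM = nm, bulges = bulges)
}

#' Extract and fold a candidate pre-miRNA around a sense hit
#'
#' Folds a window around the hit, locates the hairpin duplex (mature +
#' passenger on the opposite arm), trims the precursor to the duplex ends
#' extended by the pri-extension flank (13 nt by default on each side,
#' clamped to the available sequence), and re-folds the trimmed region to
#' populate the candidate record.
#'
#' @param consensus DNA (or RNA) sequence the hit lies on.
#' @param hit one-row data.frame from \code{\link{scan_homology}} with
#'   \code{orientation == "sense"}.
#' @param fold_window nt of context folded on each side of the hit.
#' @param flank pri-extension length beyond each duplex end.
#' @param model an \code{\link{energy_model}}.
#' @return An object of class \code{precursor_candidate} (fields
#'   \code{sequence}, \code{structure}, \code{dG}, \code{gc_pct},
#'   \code{MFEI}, \code{NM}, \code{ML}, \code{PL}, \code{arm},
#'   \code{mature_span}, \code{star_span}, \code{bulges},
#'   \code{source_id}, \code{source_offset}, \code{accepted},
#'   \code{reject_reasons}) or of class \code{precursor_rejection} with a
#'   \code{reason} (\code{"no hairpin"} when no mature position pairs,
#'   \code{"no opposite arm"} when the passenger overlaps the mature side).
#' @export
extract_candidate <- function(consensus, hit, fold_window = 250L,
                              flank = 13L, model = energy_model()) {
  stopifnot(nrow(hit) == 1L)
  if (hit$orientation != "sense")
    stop("precursor candidates are extracted around sense hits")
  n <- nchar(consensus)
  w0 <- max(0L, hit$start - fold_window)
  w1 <- min(n, hit$end + fold_window)
  wseq <- dna_to_rna(toupper(substr(consensus, w0 + 1L, w1)))
  f <- fold_rna(wseq, model)
  ms <- hit$start - w0 + 1L
  me <- hit$end - w0
  duplex <- tryCatch(star_and_nm(f$structure, c(ms, me)),
                     error = function(e) NULL)
  reject <- function(reason)
    structure(list(source_id = hit$est_id, reason = reason),
              class = "precursor_rejection")
  if (is.null(duplex)) return(reject("no hairpin"))
  if (duplex$star_span[1] <= me && duplex$star_span[2] >= ms)
    return(reject("no opposite arm"))
  lo <- max(1L, min(ms, duplex$star_span[1]) - flank)
  hi <- min(nchar(wseq), max(me, duplex$star_span[2]) + flank)
  pseq <- substr(wseq, lo, hi)
  pf <- fold_rna(pseq, model)
  pms <- c(ms - lo + 1L, me - lo + 1L)
  pd <- tryCatch(star_and_nm(pf$structure, pms), error = function(e) NULL)
  if (is.null(pd)) return(reject("no hairpin"))
  if (pd$star_span[1] <= pms[2] && pd$star_span[2] >= pms[1])
    return(reject("no opposite arm"))
  gc <- gc_percent(pseq)
  structure(list(
    source_id = hit$est_id,
    sequence = pseq,
    structure = pf$structure,
    dG = pf$dG,
    gc_pct = gc,
    MFEI = mfei(pf$dG, nchar(pseq), gc),
    NM = pd$NM,
    ML = me - ms + 1L,
    PL = nchar(pseq),
    arm = if (pms[1] < pd$star_span[1]) "5'" else "3'",
    mature_span = pms,
    star_span = pd$star_span,
    bulges = pd$bulges,
    source_offset = w0 + lo - 1L,
    mirna_nr_id = hit$mirna_nr_id,
    family = hit$family,
    accepted = NA,
    reject_reasons = character(0)),
    class = "precursor_candidate")
}

#' @export
print.precursor_candidate <- function(x, ...) {
  cat(sprintf(
    "precursor_candidate [%s]: PL=%d ML=%d NM=%d arm=%s dG=%.1f MFEI=%.2f\n",
    x$source_id, x$PL, x$ML, x$NM, x$arm, x$dG, x$MFEI))
  invisible(x)
}

#' Screen a precursor candidate on hairpin-quality criteria
#'
#' A candidate is accepted when its MFEI is strictly greater than
#' \code{mfei_min}, at most \code{max_star_mm} mature positions are unpaired
#' in the miRNA/miRNA* duplex, and the duplex carries few and small bulges
#' (at most \code{max_bulges} of at most \code{max_bulge_size} nt).
#'
#' @param candidate a \code{precursor_candidate}.
#' @param mfei_min MFEI threshold (strict, default 0.85).
#' @param max_star_mm maximum unpaired mature positions (default 4).
#' @param max_bulges,max_bulge_size bulge count/size limits (default 2 and 3).
#' @return The candidate with \code{accepted} and \code{reject_reasons} set.
#' @export
validate_candidate <- function(candidate, mfei_min = 0.85, max_star_mm = 4L,
                               max_bulges = 2L, max_bulge_size = 3L) {
  stopifnot(inherits(candidate, "precursor_candidate"))
  reasons <- character(0)
  if (is.na(candidate$MFEI) || candidate$MFEI <= mfei_min)
    reasons <- c(reasons, sprintf("MFEI not greater than %g", mfei_min))
  if (candidate$NM > max_star_mm)
    reasons <- c(reasons, sprintf("star mismatches > %d", max_star_mm))
  if (nrow(candidate$bulges) > max_bulges)
    reasons <- c(reasons, "too many bulges")
  if (nrow(candidate$bulges) && any(candidate$bulges$size > max_bulge_size))
    reasons <- c(reasons, sprintf("bulge larger than %d nt", max_bulge_size))
  candidate$accepted <- length(reasons) == 0L
  candidate$reject_reasons <- reasons
  candidate
}

#' Best match of a candidate against a library of known hairpins
#'
#' Local alignment (match +2, mismatch -3, gap of length L costs 3 + 2L,
#' i.e. -5 to open and -2 to extend) of the candidate sequence against each
#' library hairpin; the top raw score wins.
#'
#' @param candidate a \code{precursor_candidate} or an RNA/DNA string.
#' @param hairpins named character vector of hairpin sequences (or path to a
#'   FASTA).
#' @return One-row data.frame (\code{id}, \code{score}, \code{identity}), or
#'   \code{NULL} for an empty library.
#' @export
assign_family_by_precursor <- function(candidate, hairpins) {
  qseq <- if (inherits(candidate, "precursor_candidate"))
    candidate$sequence else candidate
  if (is.character(hairpins) && length(hairpins) == 1L &&
      (file.exists(hairpins) || grepl(">", hairpins)))
    hairpins <- read_fasta_chr(hairpins)
  if (!length(hairpins)) return(NULL)
  q <- Biostrings::DNAString(toupper(rna_to_dna(qseq)))
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3)
  best <- NULL
  for (i in seq_along(hairpins)) {
    s <- Biostrings::DNAString(toupper(rna_to_dna(hairpins[[i]])))
    aln <- Biostrings::pairwiseAlignment(q, s, type = "local",
                                         substitutionMatrix = submat,
                                         gapOpening = 3, gapExtension = 2)
    row <- data.frame(id = names(hairpins)[i],
                      score = Biostrings::score(aln),
                      identity = Biostrings::pid(aln),
                      stringsAsFactors = FALSE)
    if (is.null(best) || row$score > best$score) best <- row
  }
  best
}

#' Tabulate mature lengths across candidates
#'
#' @param candidates list of \code{precursor_candidate} objects.
#' @return data.frame with \code{ML} and \code{n}, covering 18-26 nt.
#' @export
mature_length_report <- function(candidates) {
  ml <- as.integer(vapply(candidates, function(x) as.numeric(x$ML),
                          numeric(1)))
  lens <- 18:26
  data.frame(ML = lens, n = vapply(lens, function(l) sum(ml == l), integer(1)))
}
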