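#' Call SNPs/indels from a cluster alignment within given regions
#'
#' Scans alignment columns overlapping the supplied consensus regions and
#' emits a call wherever two or more alleles (bases or gap) are observed.
#' The reference allele is the most frequent symbol (bases beat gap on ties,
#' then alphabetical order); calls whose strongest alternative allele is
#' carried by at least \code{min_support} members are classed
#' \code{candidate_true}, singletons \code{low_support} — encoding the
#' "two or more independent copies" heuristic for separating real
#' polymorphisms from sequencing errors. Insertion columns (absent from the
#' consensus) are anchored to the preceding consensus coordinate with an
#' insertion ordinal.
#'
#' @param aln a \code{\link{assemble_cluster}} alignment.
#' @param regions data.frame with 0-based half-open \code{start}, \code{end}
#'   on the consensus and a \code{kind} label (e.g. \code{"target_site"},
#'   \code{"mature_region"}, \code{"precursor_other"}).
#' @param min_support alternative-allele copies needed for
#'   \code{candidate_true} (default 2).
#' @param report_all also report columns outside the regions (context
#'   \code{"outside"}).
#' @return data.frame with one row per call: \code{cluster_id},
#'   \code{column} (row in \code{aln$columns}), \code{consensus_pos}
#'   (0-based; for insertions the preceding coordinate),
#'   \code{insertion_ordinal}, \code{ref}, \code{alt}, \code{ref_count},
#'   \code{alt_count} (strongest alternative; all alternatives in
#'   \code{alt} comma-joined with counts in \code{alt_counts}),
#'   \code{depth}, \code{vtype}, \code{support_class}, \code{context}.
#' @export
call_variants <- function(aln, regions, min_support = 2L,
                          report_all = FALSE) {
  stopifnot(inherits(aln, "cluster_alignment"))
  cols <- aln$columns
  # anchor consensus coordinate per column: own for base columns, the
  # nearest preceding base column's for insertion columns
  anchor <- cols$consensus_pos
  last <- NA_integer_
  for (i in seq_len(nrow(cols))) {
    if (!is.na(cols$consensus_pos[i])) last <- cols$consensus_pos[i]
    if (is.na(anchor[i])) anchor[i] <- last
  }
  context <- rep(if (report_all) "outside" else NA_character_, nrow(cols))
  if (nrow(regions)) for (r in seq_len(nrow(regions))) {
    sel <- !is.na(anchor) & anchor >= regions$start[r] & anchor < regions$end[r]
    context[sel] <- regions$kind[r]
  }
  keep <- !is.na(context)
  out <- list()
  sym_names <- c("A", "C", "G", "T", "gap")
  for (i in which(keep)) {
    counts <- setNames(as.integer(cols[i, sym_names]), sym_names)
    obs <- counts[counts > 0L]
    if (length(obs) < 2L) next
    lab <- names(obs)
    lab[lab == "gap"] <- "-"
    ord <- order(-obs, lab == "-", lab)   # count desc, bases beat gap, A<C<G<T
    lab <- lab[ord]; cnt <- as.integer(obs[ord])
    ref <- lab[1L]
    alts <- lab[-1L]; acnt <- cnt[-1L]
    out[[length(out) + 1L]] <- data.frame(
      cluster_id = aln$cluster_id,
      column = i,
      consensus_pos = anchor[i],
      insertion_ordinal = cols$ins[i],
      ref = ref,
      alt = paste(alts, collapse = ","),
      ref_count = cnt[1L],
      alt_count = acnt[1L],
      alt_counts = paste(acnt, collapse = ","),
      depth = cols$depth[i],
      vtype = if (ref == "-" || any(alts == "-")) "indel" else "SNP",
      support_class = if (acnt[1L] >= min_support) "candidate_true"
                      else "low_support",
      context = context[i],
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(cluster_id = character(), column = integer(),
                      consensus_pos = integer(), insertion_ordinal = integer(),
                      ref = character(), alt = character(),
                      ref_count = integer(), alt_count = integer(),
                      alt_counts = character(), depth = integer(),
                      vtype = character(), support_class = character(),
                      context = character(), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Map a consensus coordinate into miRNA coordinates
#'
#' For target sites (antisense orientation) miRNA position i lies at
#' consensus coordinate \code{end - i}; for mature regions (sense) the
#' mapping is direct. Positions 2-12 are flagged critical; 10/11 carry the
#' cleavage annotation.
#'
#' @param consensus_pos 0-based consensus coordinate of the variant.
#' @param span integer c(start, end), 0-based half-open span of the site or
#'   mature region on the consensus.
#' @param orientation \code{"antisense"} (target site) or \code{"sense"}
#'   (mature region).
#' @return List: \code{position} (1-based from the mature 5' end),
#'   \code{critical}, \code{cleavage_site}.
#' @export
map_to_mirna_position <- function(consensus_pos, span,
                                  orientation = c("antisense", "sense")) {
  orientation <- match.arg(orientation)
  if (consensus_pos < span[1] || consensus_pos >= span[2])
    stop("variant at ", consensus_pos, " lies outside the span [",
         span[1], ",", span[2], ")")
  pos <- if (orientation == "antisense") span[2] - consensus_pos
         else consensus_pos - span[1] + 1L
  list(position = as.integer(pos),
       critical = pos >= 2L && pos <= 12L,
       cleavage_site = pos %in% c(10L, 11L))
}

#' Folding impact of a precursor variant
#'
#' Substitutes each of two alleles into the precursor sequence, folds both
#' versions, and reports the free-energy difference
#' \code{ddG = dG_alt - dG_ref} (positive = the alternative allele
#' destabilises the hairpin) together with both MFEI values. Swapping the
#' allele labels flips the sign of ddG exactly. For indels the mature span
#' is shifted accordingly; if the alternative version no longer folds into
#' a mature/passenger duplex the impact is flagged \code{structure_lost}.
#'
#' @param candidate a \code{precursor_candidate}.
#' @param pos 1-based position of the variant on the precursor sequence.
#' @param ref,alt the two alleles (single bases, or \code{"-"} for a gap
#'   side of an indel; multi-base strings allowed).
#' @param model an \code{\link{energy_model}}.
#' @return List of class \code{variant_impact}: \code{dG_ref},
#'   \code{dG_alt}, \code{ddG}, \code{MFEI_ref}, \code{MFEI_alt},
#'   \code{structure_ref}, \code{structure_alt}, \code{structure_lost}.
#' @export
precursor_variant_impact <- function(candidate, pos, ref, alt,
                                     model = energy_model()) {
  stopifnot(inherits(candidate, "precursor_candidate"),
            pos >= 1, pos <= candidate$PL)
  apply_allele <- function(allele) {
    s <- candidate$sequence
    before <- substr(s, 1L, pos - 1L)
    after <- substr(s, pos + 1L, nchar(s))
    cur <- substr(s, pos, pos)
    if (allele == "-") paste0(before, after)
    else if (ref == "-" && allele != ref)
      # insertion: allele inserted after the anchor position
      paste0(before, cur, dna_to_rna(toupper(allele)), after)
    else paste0(before, dna_to_rna(toupper(allele)), after)
  }
  seq_ref <- if (ref == "-") candidate$sequence else apply_allele(ref)
  seq_alt <- apply_allele(alt)
  f_ref <- fold_rna(seq_ref, model)
  f_alt <- fold_rna(seq_alt, model)
  shift <- nchar(seq_alt) - nchar(seq_ref)
  mspan <- candidate$mature_span
  mspan_alt <- mspan
  if (shift != 0L && pos < mspan[1]) mspan_alt <- mspan + shift
  lost <- FALSE
  d_alt <- tryCatch(star_and_nm(f_alt$structure,
                                pmax(pmin(mspan_alt, nchar(seq_alt)), 1L)),
                    error = function(e) NULL)
  if (is.null(d_alt) ||
      (d_alt$star_span[1] <= mspan_alt[2] && d_alt$star_span[2] >= mspan_alt[1]))
    lost <- TRUE
  gc_ref <- gc_percent(seq_ref); gc_alt <- gc_percent(seq_alt)
  structure(list(
    dG_ref = f_ref$dG, dG_alt = f_alt$dG,
    ddG = f_alt$dG - f_ref$dG,
    MFEI_ref = mfei(f_ref$dG, nchar(seq_ref), gc_ref),
    MFEI_alt = mfei(f_alt$dG, nchar(seq_alt), gc_alt),
    structure_ref = f_ref$structure, structure_alt = f_alt$structure,
    structure_lost = lost),
    class = "variant_impact")
}

#' @export
print.variant_impact <- function(x, ...) {
  cat(sprintf("variant_impact: dG %.2f -> %.2f (ddG %+.2f)%s\n",
              x$dG_ref, x$dG_alt, x$ddG,
              if (x$structure_lost) " [structure lost]" else ""))
  invisible(x)
}
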