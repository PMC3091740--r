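#' Read a cluster-membership table
#'
#' @param path TSV with columns \code{est_id}, \code{cluster_id},
#'   \code{annotation}, \code{category} (the last two optional).
#' @return data.frame with those columns (missing ones filled with
#'   \code{NA}/"unknown").
#' @export
read_cluster_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("est_id", "cluster_id") %in% names(tab)))
    stop("cluster table needs est_id and cluster_id columns")
  if (is.null(tab$annotation)) tab$annotation <- NA_character_
  if (is.null(tab$category)) tab$category <- "unknown"
  tab
}

#' Assemble the ESTs of a cluster into a column-indexed alignment
#'
#' Star alignment standing in for a chromatogram-aware assembler: the longest
#' member is the backbone and every other member is aligned to it with an
#' end-gap-free pairwise alignment (match +1, mismatch -1, gap -2, end gaps
#' free). Alignment columns are merged across members; the consensus takes
#' the most frequent base per column, with ties broken by the
#' lexicographically smallest base (flagged low-confidence), and gap-majority
#' columns dropped from the consensus but retained for indel calling.
#' Members aligning at below \code{min_identity} percent identity over their
#' aligned span are excluded with a warning (guards against chimeric
#' clusters).
#'
#' @param members data.frame with columns \code{id} and \code{sequence}
#'   (DNA), or a named character vector.
#' @param cluster_id optional label carried through to outputs.
#' @param min_identity minimum percent identity to the backbone (default 60).
#' @return Object of class \code{cluster_alignment}: list with
#'   \describe{
#'     \item{columns}{data.frame, one row per alignment column: backbone
#'       position \code{pos}, insertion ordinal \code{ins} (0 = backbone
#'       column), symbol counts \code{A,C,G,T,gap,other}, \code{depth},
#'       0-based \code{consensus_pos} (\code{NA} for dropped columns) and
#'       \code{low_confidence};}
#'     \item{symbols}{character matrix members x columns (\code{NA} where a
#'       member does not cover a column);}
#'     \item{consensus}{consensus DNA string;}
#'     \item{members, excluded}{member IDs used / dropped.}
#'   }
#' @export
assemble_cluster <- function(members, cluster_id = NA_character_,
                             min_identity = 60) {
  if (is.character(members))
    members <- data.frame(id = names(members), sequence = unname(members),
                          stringsAsFactors = FALSE)
  stopifnot(nrow(members) >= 1L, !anyDuplicated(members$id))
  members$sequence <- toupper(members$sequence)
  bi <- which.max(nchar(members$sequence))
  backbone <- members$sequence[bi]
  nb <- nchar(backbone)
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  # per-member alignment footprint: list of (pos, ins, symbol) plus span
  parsed <- list()
  excluded <- character(0)
  for (i in seq_len(nrow(members))) {
    id <- members$id[i]
    if (i == bi) {
      parsed[[id]] <- list(df = data.frame(pos = seq_len(nb), ins = 0L,
                                           symbol = strsplit(backbone, "")[[1]],
                                           stringsAsFactors = FALSE),
                           span = c(1L, nb))
      next
    }
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(members$sequence[i]),
      Biostrings::DNAString(backbone),
      type = "overlap", substitutionMatrix = submat,
      gapOpening = 0, gapExtension = 2)
    # identity over the full member length (not the local aligned span),
    # so short spurious alignments of chimeric members do not slip through
    ident <- 100 * Biostrings::nmatch(aln) / nchar(members$sequence[i])
    if (ident < min_identity) {
      warning(sprintf("member %s aligns at %.1f%% identity; excluded",
                      id, ident))
      excluded <- c(excluded, id)
      next
    }
    pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
    sa <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
    s0 <- Biostrings::start(Biostrings::subject(aln)) - 1L
    pos <- integer(length(pa)); ins <- integer(length(pa))
    s <- s0; o <- 0L
    for (cix in seq_along(pa)) {
      if (sa[cix] != "-") { s <- s + 1L; o <- 0L; pos[cix] <- s; ins[cix] <- 0L }
      else { o <- o + 1L; pos[cix] <- s; ins[cix] <- o }
    }
    parsed[[id]] <- list(df = data.frame(pos = pos, ins = ins, symbol = pa,
                                         stringsAsFactors = FALSE),
                         span = c(s0 + 1L,
                                  Biostrings::end(Biostrings::subject(aln))))
  }
  if (!length(parsed)) stop("no members left after identity filtering")
  used <- names(parsed)
  # column universe: (pos, ins) over all members
  allcols <- unique(do.call(rbind, lapply(parsed, function(p)
    p$df[, c("pos", "ins")])))
  allcols <- allcols[order(allcols$pos, allcols$ins), , drop = FALSE]
  key <- paste(allcols$pos, allcols$ins)
  ncol_aln <- nrow(allcols)
  symbols <- matrix(NA_character_, nrow = length(used), ncol = ncol_aln,
                    dimnames = list(used, key))
  for (id in used) {
    p <- parsed[[id]]
    mkey <- paste(p$df$pos, p$df$ins)
    symbols[id, mkey] <- p$df$symbol
    # implicit gaps at insertion columns inside the member's span
    span_cols <- allcols$pos >= p$span[1L] & allcols$pos <= p$span[2L] &
      !(key %in% mkey) &
      !(allcols$pos == p$span[2L] & allcols$ins > 0L)  # ins after span end
    symbols[id, span_cols] <- "-"
  }
  cnt <- function(sym) colSums(symbols == sym, na.rm = TRUE)
  columns <- data.frame(pos = allcols$pos, ins = allcols$ins,
                        A = cnt("A"), C = cnt("C"), G = cnt("G"), T = cnt("T"),
                        gap = cnt("-"), row.names = NULL)
  columns$other <- colSums(!is.na(symbols)) -
    with(columns, A + C + G + T + gap)
  columns$depth <- colSums(!is.na(symbols))
  base_counts <- as.matrix(columns[, c("A", "C", "G", "T")])
  best <- apply(base_counts, 1L, max)
  cons_base <- colnames(base_counts)[apply(base_counts, 1L, which.max)]
  tie <- rowSums(base_counts == best) > 1L & best > 0L
  keep <- best >= columns$gap & best > 0L
  columns$low_confidence <- tie
  columns$consensus_pos <- NA_integer_
  columns$consensus_pos[keep] <- seq_len(sum(keep)) - 1L
  consensus <- paste(cons_base[keep], collapse = "")
  structure(list(cluster_id = cluster_id, columns = columns,
                 symbols = symbols, consensus = consensus,
                 backbone = members$id[bi], members = used,
                 excluded = excluded),
            class = "cluster_alignment")
}

#' @export
print.cluster_alignment <- function(x, ...) {
  cat(sprintf("cluster_alignment %s: %d members, %d columns, consensus %d nt\n",
              x$cluster_id, length(x$members), nrow(x$columns),
              nchar(x$consensus)))
  invisible(x)
}

#' Extract a consensus substring
#'
#' @param aln a \code{cluster_alignment}.
#' @param start,end 0-based half-open range on the consensus.
#' @return DNA string.
#' @export
consensus_region <- function(aln, start, end) {
  stopifnot(inherits(aln, "cluster_alignment"),
            start >= 0, end >= start, end <= nchar(aln$consensus))
  substr(aln$consensus, start + 1L, end)
}
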