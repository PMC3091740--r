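#' Fold an RNA sequence to its minimum-free-energy nested structure
#'
#' Computes the minimum-free-energy secondary structure (no pseudoknots) of a
#' short RNA under the bundled nearest-neighbour model (see
#' \code{\link{energy_model}}) by dynamic programming, with a deterministic
#' traceback. The returned free energy is always <= 0 (the open chain scores
#' 0 and is always admissible).
#'
#' @param seq RNA sequence (character scalar over A, C, G, U; T is accepted
#'   and converted to U).
#' @param model an \code{\link{energy_model}}.
#' @return A list of class \code{fold_result} with elements \code{structure}
#'   (dot-bracket string), \code{dG} (kcal/mol), \code{partner} (1-based
#'   partner index per position, 0 = unpaired) and \code{engine}.
#' @examples
#' fold_rna("GGGGGAAACCCCC")
#' @export
fold_rna <- function(seq, model = energy_model()) {
  seq <- normalize_rna(seq)
  n <- nchar(seq)
  if (n < 10) stop("too short to fold (need >= 10 nt)")
  if (n > 1000) stop("sequence longer than 1000 nt not supported")
  codes <- encode_rna(seq)
  pen <- precompute_penalties(model, n)
  res <- .fold_cpp(codes, model$stack, pen$hairpin, pen$bulge, pen$internal,
                   model$ml_close, model$ml_branch, model$ml_unpaired,
                   model$min_hairpin, model$max_internal)
  db <- partner_to_dotbracket(res$partner)
  structure(list(structure = db, dG = res$dG, partner = res$partner,
                 sequence = seq, engine = "mirEST-nnstack-0.1"),
            class = "fold_result")
}

#' @export
print.fold_result <- function(x, ...) {
  cat(x$sequence, "\n", x$structure, "\n",
      sprintf("dG = %.2f kcal/mol [%s]\n", x$dG, x$engine), sep = "")
  invisible(x)
}

normalize_rna <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L, !is.na(seq))
  chartr("Tt", "Uu", toupper(seq))
}

#' Convert between partner vectors and dot-bracket strings
#'
#' @param partner integer vector, 1-based partner index per position
#'   (0 = unpaired).
#' @return Dot-bracket string.
#' @keywords internal
partner_to_dotbracket <- function(partner) {
  out <- rep(".", length(partner))
  out[partner > seq_along(partner)] <- "("
  out[partner != 0 & partner < seq_along(partner)] <- ")"
  paste(out, collapse = "")
}

#' @rdname partner_to_dotbracket
#' @param db dot-bracket string.
#' @keywords internal
dotbracket_to_partner <- function(db) {
  v <- strsplit(db, "", fixed = TRUE)[[1]]
  if (!all(v %in% c(".", "(", ")"))) stop("invalid dot-bracket symbols")
  partner <- integer(length(v))
  stack <- integer(0)
  for (i in seq_along(v)) {
    if (v[i] == "(") stack <- c(stack, i)
    else if (v[i] == ")") {
      if (!length(stack)) stop("unbalanced dot-bracket structure")
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      partner[i] <- j; partner[j] <- i
    }
  }
  if (length(stack)) stop("unbalanced dot-bracket structure")
  partner
}

#' Score a given secondary structure under the energy model
#'
#' Independent re-scorer for an explicit structure: decomposes the structure
#' into hairpin, stacked-pair, bulge/internal and multiloop elements and sums
#' their energies. \code{structure_energy(seq, fold_rna(seq)$structure)}
#' equals \code{fold_rna(seq)$dG}; the implementation is deliberately separate
#' from the dynamic programme so the two can check each other.
#'
#' @param seq RNA sequence.
#' @param db dot-bracket structure of the same length.
#' @param model an \code{\link{energy_model}}.
#' @return Free energy in kcal/mol.
#' @export
structure_energy <- function(seq, db, model = energy_model()) {
  seq <- normalize_rna(seq)
  v <- strsplit(seq, "", fixed = TRUE)[[1]]
  if (!all(v %in% c("A", "C", "G", "U")))
    stop("non-RNA symbols in sequence")
  if (nchar(db) != length(v)) stop("structure/sequence length mismatch")
  partner <- dotbracket_to_partner(db)
  op <- which(partner > seq_along(partner))
  for (i in op) {
    j <- partner[i]
    if (pair_code(v[i], v[j]) == 0L)
      stop(sprintf("non-complementary pair at (%d,%d): %s-%s", i, j, v[i], v[j]))
  }
  total <- 0
  for (i in op) {
    j <- partner[i]
    # top-level children of the loop closed by (i, j)
    children <- list()
    unpaired <- 0L
    k <- i + 1L
    while (k < j) {
      if (partner[k] > k) {
        children[[length(children) + 1L]] <- c(k, partner[k])
        k <- partner[k] + 1L
      } else if (partner[k] == 0L) {
        unpaired <- unpaired + 1L
        k <- k + 1L
      } else stop("crossing pairs (pseudoknot) are not supported")
    }
    nc <- length(children)
    if (nc == 0L) {
      l <- j - i - 1L
      if (l < model$min_hairpin)
        stop(sprintf("hairpin loop shorter than %d at pair (%d,%d)",
                     model$min_hairpin, i, j))
      total <- total + hairpin_penalty(model, l)
    } else if (nc == 1L) {
      k <- children[[1L]][1L]; l <- children[[1L]][2L]
      s1 <- k - i - 1L; s2 <- j - l - 1L
      if (s1 == 0L && s2 == 0L) {
        total <- total + model$stack[pair_code(v[i], v[j]),
                                     pair_code(v[k], v[l])]
      } else if (s1 == 0L || s2 == 0L) {
        total <- total + bulge_penalty(model, s1 + s2)
      } else {
        total <- total + internal_penalty(model, s1 + s2)
      }
    } else {
      total <- total + model$ml_close + model$ml_branch * (nc + 1L) +
        model$ml_unpaired * unpaired
    }
  }
  total
}

#' GC content of a sequence
#'
#' @param seq RNA or DNA sequence (character scalar).
#' @return Percentage of G+C bases, 0-100.
#' @examples gc_percent("GCAU")
#' @export
gc_percent <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L, nchar(seq) > 0L)
  v <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  100 * sum(v %in% c("G", "C")) / length(v)
}

#' Adjusted MFE and minimal folding free energy index
#'
#' \code{amfe} is the length-adjusted minimum free energy,
#' \code{|dG| * 100 / length}; \code{mfei} is AMFE divided by the GC
#' percentage. Both use the positive sign convention, so hairpin-like
#' sequences score high and the classical plant pre-miRNA screen keeps
#' candidates with MFEI strictly greater than 0.85.
#'
#' @param dG folding free energy (kcal/mol, <= 0).
#' @param length sequence length (nt).
#' @param gc_pct GC percentage (0-100).
#' @return \code{amfe}: numeric; \code{mfei}: numeric, \code{NA} when
#'   \code{gc_pct} is 0 (index undefined).
#' @examples
#' mfei(-50, 100, 50)  # 1.0
#' @export
mfei <- function(dG, length, gc_pct) {
  stopifnot(length > 0)
  if (gc_pct == 0) return(NA_real_)
  amfe(dG, length) / gc_pct
}

#' @rdname mfei
#' @export
amfe <- function(dG, length) {
  stopifnot(length > 0)
  abs(dG) * 100 / length
}

#' Brute-force minimum-free-energy search (validation oracle)
#'
#' Exhaustively enumerates every nested structure of a short RNA and scores
#' each complete structure by loop decomposition, independently of the
#' dynamic programme in \code{\link{fold_rna}}. Exponential in sequence
#' length; intended for cross-validating the folding engine on sequences of
#' roughly 10-30 nt.
#'
#' @inheritParams fold_rna
#' @return List with \code{dG}, \code{structure} (dot-bracket) and
#'   \code{n_structures} (number of structures enumerated).
#' @export
brute_force_mfe <- function(seq, model = energy_model()) {
  seq <- normalize_rna(seq)
  n <- nchar(seq)
  if (n > 32) stop("brute-force enumeration is limited to 32 nt")
  codes <- encode_rna(seq)
  pen <- precompute_penalties(model, n)
  res <- .enum_mfe_cpp(codes, model$stack, pen$hairpin, pen$bulge,
                       pen$internal, model$ml_close, model$ml_branch,
                       model$ml_unpaired, model$min_hairpin)
  list(dG = res$dG, structure = partner_to_dotbracket(res$partner),
       n_structures = res$n_structures)
}
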