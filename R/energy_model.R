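#' Nearest-neighbour RNA energy model
#'
#' Parameters of the simplified nearest-neighbour model used by the bundled
#' folding engine: stacking energies for adjacent canonical/wobble base pairs,
#' length-dependent penalties for hairpin, bulge and internal loops, and a
#' linear multiloop model. Stacking energies are negative (stabilising),
#' loop penalties positive (destabilising), all in kcal/mol.
#'
#' The model is deliberately small and fully documented so that minimum free
#' energies are exactly reproducible; it is not a substitute for a full
#' Turner parameter set, and absolute free energies from it should only be
#' compared with each other (e.g. between allele variants of one precursor),
#' never with values from other programs.
#'
#' @param stack 6x6 numeric matrix of stacking energies; rows index the outer
#'   pair and columns the inner pair, in the order AU, UA, GC, CG, GU, UG.
#' @param hairpin_base,hairpin_slope hairpin-loop penalty: tabulated for loop
#'   lengths 3-5, then \code{hairpin_base + hairpin_slope * log(l/5)}.
#' @param bulge_base,bulge_slope bulge penalty \code{bulge_base +
#'   bulge_slope * log(s)} for a bulge of s unpaired bases.
#' @param internal_base,internal_slope internal-loop penalty
#'   \code{internal_base + internal_slope * log(s/2)} for s total unpaired
#'   bases (s >= 2).
#' @param ml_close,ml_branch,ml_unpaired multiloop closing penalty, per-branch
#'   penalty (the closing pair counts as a branch) and per-unpaired-base
#'   penalty.
#' @param min_hairpin minimum hairpin loop length (nt).
#' @param max_internal maximum total unpaired length of a bulge/internal loop
#'   considered by the dynamic programme.
#' @return An object of class \code{energy_model}.
#' @export
energy_model <- function(stack = default_stack_matrix(),
                         hairpin_base = 5.7, hairpin_slope = 1.08,
                         bulge_base = 3.8, bulge_slope = 1.08,
                         internal_base = 1.7, internal_slope = 1.08,
                         ml_close = 3.4, ml_branch = 0.4, ml_unpaired = 0.1,
                         min_hairpin = 3L, max_internal = 30L) {
  stopifnot(is.matrix(stack), dim(stack) == c(6L, 6L), all(stack < 0),
            hairpin_base > 0, bulge_base > 0, internal_base > 0,
            ml_close >= 0, ml_branch >= 0, ml_unpaired >= 0,
            min_hairpin >= 3L, max_internal >= 4L)
  structure(list(stack = stack,
                 hairpin_base = hairpin_base, hairpin_slope = hairpin_slope,
                 bulge_base = bulge_base, bulge_slope = bulge_slope,
                 internal_base = internal_base, internal_slope = internal_slope,
                 ml_close = ml_close, ml_branch = ml_branch,
                 ml_unpaired = ml_unpaired,
                 min_hairpin = as.integer(min_hairpin),
                 max_internal = as.integer(max_internal)),
            class = "energy_model")
}

#' @rdname energy_model
#' @export
default_stack_matrix <- function() {
  p <- c("AU", "UA", "GC", "CG", "GU", "UG")
  m <- matrix(c(
    # inner:  AU    UA    GC    CG    GU    UG
    -0.9, -1.1, -2.1, -2.2, -0.6, -1.4,  # outer AU
    -1.3, -0.9, -2.4, -2.1, -1.0, -1.3,  # outer UA
    -2.1, -2.2, -3.3, -3.4, -1.5, -2.5,  # outer GC
    -2.4, -2.1, -3.0, -3.3, -1.4, -2.1,  # outer CG
    -1.3, -1.4, -2.5, -2.1, -0.5, -0.4,  # outer GU
    -1.0, -0.6, -1.5, -1.4, -0.3, -0.5), # outer UG
    nrow = 6, byrow = TRUE, dimnames = list(p, p))
  m
}

## penalty functions; scalar l/s, vectorised over integer input
hairpin_penalty <- function(model, l) {
  ifelse(l < model$min_hairpin, Inf,
         ifelse(l == 3, model$hairpin_base - 0.3,
         ifelse(l == 4, model$hairpin_base - 0.1,
         ifelse(l == 5, model$hairpin_base,
                model$hairpin_base + model$hairpin_slope * log(l / 5)))))
}

bulge_penalty <- function(model, s) {
  ifelse(s < 1, Inf, model$bulge_base + model$bulge_slope * log(s))
}

internal_penalty <- function(model, s) {
  ifelse(s < 2, Inf, model$internal_base + model$internal_slope * log(s / 2))
}

## pair coding shared by the R scorer and the C++ dynamic programme:
## 0 = not pairable, 1 AU, 2 UA, 3 GC, 4 CG, 5 GU, 6 UG
pair_code <- function(a, b) {
  key <- paste0(a, b)
  code <- c(AU = 1L, UA = 2L, GC = 3L, CG = 4L, GU = 5L, UG = 6L)[key]
  ifelse(is.na(code), 0L, unname(code))
}

## base coding for the C++ engine: A=1, C=2, G=3, U=4
encode_rna <- function(seq) {
  v <- strsplit(seq, "", fixed = TRUE)[[1]]
  code <- c(A = 1L, C = 2L, G = 3L, U = 4L)[v]
  if (anyNA(code))
    stop("non-RNA symbols in sequence: ",
         paste(unique(v[is.na(code)]), collapse = ", "))
  unname(code)
}

## precompute penalty lookup vectors (index = loop size) for a sequence of
## length n; used by both the C++ DP (passed in) and kept consistent with
## the R scorer because both call the same penalty functions
precompute_penalties <- function(model, n) {
  sizes <- seq_len(max(n, 4L))
  list(hairpin = hairpin_penalty(model, sizes),
       bulge = bulge_penalty(model, sizes),
       internal = internal_penalty(model, sizes))
}
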