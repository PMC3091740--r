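#' Parse a mature miRNA reference FASTA into a reference set
#'
#' Reads a miRBase-style mature miRNA FASTA (IDs such as \code{tae-miR1137})
#' and builds the bookkeeping needed downstream: the full redundant record
#' table, the non-redundant sequence map, and one representative record per
#' distinct sequence. Identity is case- and T/U-insensitive, since mature
#' sets mix DNA- and RNA-alphabet conventions and deduplication is at the
#' sequence level. Species is read from the ID prefix (letters before the
#' first hyphen); records whose IDs cannot be parsed are kept for scanning
#' but carry \code{NA} species/family and are excluded from enrichment.
#'
#' @param x path to a FASTA file, or FASTA text (single string or character
#'   vector of lines).
#' @return An object of class \code{reference_set}: a list with
#'   \describe{
#'     \item{records}{data.frame (id, species, family, sequence) of all
#'       redundant records, sequences normalized to upper-case RNA;}
#'     \item{nr_map}{named list mapping each distinct sequence to the member
#'       record IDs carrying it;}
#'     \item{nr}{data.frame (id, sequence) of one representative (first seen)
#'       per distinct sequence.}
#'   }
#' @examples
#' ref <- parse_mature_fasta(c(">aaa-miR1", "UGACAGAAGAGAGUGAGCAC",
#'                             ">bbb-miR2", "ugacagaagagagugagcac"))
#' nrow(ref$records)    # 2 redundant records
#' length(ref$nr_map)   # 1 distinct sequence
#' @export
parse_mature_fasta <- function(x) {
  seqs <- read_fasta_chr(x)
  if (!length(seqs)) stop("empty reference")
  norm <- toupper(dna_to_rna(seqs))
  bad <- vapply(norm, function(s)
    !grepl("^[ACGUN]+$", s) || nchar(s) == 0L, logical(1))
  if (any(bad))
    stop("invalid characters in reference record(s): ",
         paste(names(seqs)[bad], collapse = ", "))
  ids <- names(seqs)
  if (anyDuplicated(ids))
    stop("duplicated record IDs in reference: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  records <- data.frame(
    id = ids,
    species = vapply(ids, species_of, character(1)),
    family = vapply(ids, function(i)
      tryCatch(family_of(i), error = function(e) NA_character_),
      character(1)),
    sequence = unname(norm),
    stringsAsFactors = FALSE, row.names = NULL)
  nr_map <- split(records$id, records$sequence)
  first_idx <- !duplicated(records$sequence)
  nr <- data.frame(id = records$id[first_idx],
                   sequence = records$sequence[first_idx],
                   stringsAsFactors = FALSE)
  structure(list(records = records, nr_map = nr_map, nr = nr),
            class = "reference_set")
}

#' @export
print.reference_set <- function(x, ...) {
  cat(sprintf(
    "reference_set: %d mature records, %d non-redundant sequences, %d families\n",
    nrow(x$records), nrow(x$nr),
    length(unique(stats::na.omit(x$records$family)))))
  invisible(x)
}

#' Extract the family token from a miRNA identifier
#'
#' The family is the digit run following the \code{miR}/\code{MIR} token;
#' letter and ordinal suffixes (\code{a}, \code{d}, \code{-5p}) are stripped.
#'
#' @param id miRNA identifier, e.g. \code{"ath-miR156a"}.
#' @return Family token as a character string, e.g. \code{"156"}.
#' @examples
#' family_of("ath-miR156a")  # "156"
#' @export
family_of <- function(id) {
  stopifnot(is.character(id), length(id) == 1L)
  m <- regmatches(id, regexec("[mM][iI][rR][-_]?([0-9]+)", id))[[1]]
  if (length(m) < 2L) stop("unparseable ID: ", id)
  m[2L]
}

#' Species prefix of a miRBase-style identifier
#'
#' @param id miRNA identifier.
#' @return The 2-4 letter species code before the first hyphen, or \code{NA}
#'   if the ID does not follow the convention.
#' @export
species_of <- function(id) {
  m <- regmatches(id, regexec("^([A-Za-z]{2,4})-", id))[[1]]
  if (length(m) < 2L) NA_character_ else tolower(m[2L])
}

#' Write a reference set as TSV
#'
#' @param ref a \code{reference_set}.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_reference_tsv <- function(ref, path) {
  stopifnot(inherits(ref, "reference_set"))
  write.table(ref$records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
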