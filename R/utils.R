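## small sequence utilities shared across modules

COMP_DNA <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
COMP_RNA <- c(A = "U", C = "G", G = "C", U = "A", N = "N")

revcomp_dna <- function(seq) {
  v <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  paste(rev(unname(COMP_DNA[v])), collapse = "")
}

revcomp_rna <- function(seq) {
  v <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  paste(rev(unname(COMP_RNA[v])), collapse = "")
}

rna_to_dna <- function(seq) chartr("Uu", "Tt", seq)
dna_to_rna <- function(seq) chartr("Tt", "Uu", seq)

## parse FASTA given either a file path or raw text lines
read_fasta_chr <- function(x) {
  lines <- if (length(x) == 1L && !grepl("[\n>]", x) && file.exists(x))
    readLines(x) else unlist(strsplit(x, "\n", fixed = TRUE))
  lines <- lines[nzchar(lines)]
  hdr <- grepl("^>", lines)
  if (!any(hdr)) stop("no FASTA headers found")
  idx <- cumsum(hdr)
  ids <- sub("^>\\s*", "", lines[hdr])
  ids <- sub("\\s.*$", "", ids)
  seqs <- vapply(split(lines[!hdr], idx[!hdr]),
                 paste, character(1), collapse = "")
  out <- character(length(ids))
  names(out) <- ids
  present <- as.integer(names(seqs))
  out[present] <- unname(seqs)
  out
}

write_fasta_chr <- function(seqs, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}
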