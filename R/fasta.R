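#' Read a DNA FASTA file into a named assembly
#'
#' Contigs are returned as a [Biostrings::DNAStringSet] with sequences
#' upper-cased on ingestion. Gzip-compressed files are read transparently.
#'
#' @param path path to a (possibly gzipped) FASTA file.
#' @return a `DNAStringSet`, one element per contig, names = FASTA ids.
#' @export
read_dna_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  validate_fasta_records(x, path)
  names(x) <- sub("\\s.*$", "", names(x))
  validate_fasta_ids(x, path)
  Biostrings::DNAStringSet(toupper(as.character(x)))
}

#' Read a protein FASTA file
#'
#' @param path path to a (possibly gzipped) FASTA file of polypeptides.
#' @return an `AAStringSet`, upper-cased; `*` (stop) and `X` are permitted.
#' @export
read_aa_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  validate_fasta_records(x, path)
  names(x) <- sub("\\s.*$", "", names(x))
  validate_fasta_ids(x, path)
  Biostrings::AAStringSet(toupper(as.character(x)))
}

validate_fasta_records <- function(x, path) {
  if (length(x) == 0L)
    stop("no FASTA records in ", path)
  if (any(Biostrings::width(x) == 0L))
    stop("empty FASTA record in ", path, ": ",
         paste(names(x)[Biostrings::width(x) == 0L], collapse = ", "))
  invisible(x)
}

validate_fasta_ids <- function(x, path) {
  dup <- unique(names(x)[duplicated(names(x))])
  if (length(dup))
    stop("duplicate FASTA id(s) in ", path, ": ", paste(dup, collapse = ", "))
  invisible(x)
}

#' Write sequences to FASTA
#'
#' Round-trips with [read_dna_fasta()] / [read_aa_fasta()]: ids and sequences
#' are preserved exactly.
#'
#' @param x a named `DNAStringSet`/`AAStringSet` or named character vector.
#' @param path output path.
#' @param type `"dna"` or `"aa"`; only used when `x` is a character vector.
#' @export
write_fasta <- function(x, path, type = c("dna", "aa")) {
  if (is.character(x)) {
    type <- match.arg(type)
    x <- if (type == "dna") Biostrings::DNAStringSet(x)
         else Biostrings::AAStringSet(x)
  }
  if (is.null(names(x)) || any(names(x) == ""))
    stop("all sequences must be named")
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
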