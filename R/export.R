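#' Export annotated loci to GFF3 or TSV
#'
#' GFF3 output is 1-based inclusive, feature type
#' `endogenous_viral_element`, with `ID` (the CVe id when assigned),
#' `gene`, `group`, `status` and `intact` attributes; reserved characters
#' in attribute values are percent-escaped. The writer emits no timestamp,
#' so reruns are byte-identical. TSV output mirrors the internal table and
#' round-trips through [read_loci_tsv()].
#'
#' @param loci annotated locus table ([annotate_loci()]).
#' @param path output file path.
#' @param format `"gff3"` or `"tsv"`.
#' @return the path, invisibly.
#' @export
export_loci <- function(loci, path, format = c("gff3", "tsv")) {
  if (length(format) == 1 && !format %in% c("gff3", "tsv"))
    stop("unknown format: ", format)
  format <- match.arg(format)
  if (format == "tsv") {
    write_tsv_exact(loci_flat(loci), path)
    return(invisible(path))
  }
  lines <- "##gff-version 3"
  if (nrow(loci)) {
    attrs <- vapply(seq_len(nrow(loci)), function(i) {
      a <- c(
        if (!is.na(loci$cve_id[i])) paste0("ID=", gff3_escape(loci$cve_id[i])),
        paste0("species=", gff3_escape(loci$species[i])),
        paste0("gene=", gff3_escape(loci$assigned_gene[i])),
        paste0("group=", gff3_escape(loci$assigned_group[i])),
        paste0("status=", gff3_escape(loci$status[i])),
        paste0("intact=", tolower(as.character(loci$intact[i]))))
      paste(a, collapse = ";")
    }, "")
    lines <- c(lines, sprintf(
      "%s\tcircofossil\tendogenous_viral_element\t%d\t%d\t%s\t%s\t.\t%s",
      loci$contig, loci$nt_start + 1L, loci$nt_end,
      format(loci$score, trim = TRUE), loci$strand, attrs))
  }
  writeLines(lines, path)
  invisible(path)
}

# GFF3 column-9 escaping (RFC 3986 subset required by the format).
gff3_escape <- function(x) {
  x <- gsub("%", "%25", x, fixed = TRUE)
  x <- gsub(";", "%3B", x, fixed = TRUE)
  x <- gsub("=", "%3D", x, fixed = TRUE)
  x <- gsub("&", "%26", x, fixed = TRUE)
  x <- gsub(",", "%2C", x, fixed = TRUE)
  x <- gsub("\t", "%09", x, fixed = TRUE)
  x
}

loci_flat <- function(loci) {
  keep <- c("species", "contig", "nt_start", "nt_end", "strand",
            "n_fragments", "frames", "score", "assigned_gene",
            "assigned_group", "flank5", "flank3", "status", "intact",
            "cve_id", "ortholog_group")
  loci[, intersect(keep, names(loci)), drop = FALSE]
}

#' Read a locus TSV written by [export_loci()]
#'
#' @param path TSV path.
#' @return the locus table (without the `fragments` list-column).
#' @export
read_loci_tsv <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' Write / read a CVe id registry
#'
#' The registry records assigned ids with their genomic span so later runs
#' reassign identical ids ([assign_cve_ids()]).
#'
#' @param loci locus table with `cve_id` assigned.
#' @param path TSV path.
#' @return for the writer, the path invisibly; for the reader, a data.frame
#'   with columns `cve_id`, `species`, `contig`, `nt_start`, `nt_end`.
#' @export
write_cve_registry <- function(loci, path) {
  reg <- loci[!is.na(loci$cve_id),
              c("cve_id", "species", "contig", "nt_start", "nt_end")]
  write_tsv_exact(reg, path)
  invisible(path)
}

#' @rdname write_cve_registry
#' @export
read_cve_registry <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
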