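#' Translate a contig in all six reading frames
#'
#' Uses the standard genetic code; any codon containing an ambiguity
#' character (e.g. `N`) translates to `X`, stop codons to `*`. The trailing
#' 1-2 nucleotides that do not complete a codon are dropped. Reverse frames
#' translate the reverse complement.
#'
#' @param contig a DNA string (character or `DNAString`) of length >= 3.
#' @return a list of six elements named `"+1"`..`"-3"`, each with fields
#'   `frame` (integer in \{+1,+2,+3,-1,-2,-3\}), `peptide` (character) and
#'   `contig_length`.
#' @seealso [frame_span_to_nt()] for mapping peptide spans back to
#'   forward-strand nucleotide coordinates.
#' @export
translate_six_frames <- function(contig) {
  chr <- toupper(as.character(contig))
  s <- Biostrings::DNAString(chr)
  L <- length(s)
  if (L < 3) stop("contig shorter than one codon (length ", L, ")")
  rc <- Biostrings::reverseComplement(s)
  # ambiguity-free sequences can take the fast translation path
  fuzzy <- grepl("[^ACGT]", chr)
  tr <- function(x) {
    if (fuzzy)
      as.character(Biostrings::translate(x, if.fuzzy.codon = "X",
                                         no.init.codon = TRUE))
    else as.character(Biostrings::translate(x, no.init.codon = TRUE))
  }
  out <- vector("list", 6)
  k <- 0
  for (fr in 1:3) {
    for (str in c(1L, -1L)) {
      src <- if (str > 0) s else rc
      nc <- (L - (fr - 1L)) %/% 3L
      pep <- if (nc == 0L) "" else
        tr(Biostrings::subseq(src, start = fr, width = 3L * nc))
      k <- k + 1
      out[[k]] <- list(frame = str * fr, peptide = pep, contig_length = L)
    }
  }
  names(out) <- vapply(out, function(x) sprintf("%+d", x$frame), "")
  out[order(match(names(out), c("+1", "+2", "+3", "-1", "-2", "-3")))]
}

#' Map a peptide span in a reading frame to forward-strand nucleotides
#'
#' @param frame integer in \{+1,+2,+3,-1,-2,-3\}.
#' @param p_start,p_end 0-based half-open span on the frame's peptide.
#' @param contig_length contig length in nucleotides.
#' @return integer vector `c(nt_start, nt_end)`, 0-based half-open on the
#'   forward strand. Every peptide position covers exactly 3 nucleotides.
#' @export
frame_span_to_nt <- function(frame, p_start, p_end, contig_length) {
  off <- abs(frame) - 1L
  if (frame > 0) {
    c(off + 3L * p_start, off + 3L * p_end)
  } else {
    c(contig_length - off - 3L * p_end, contig_length - off - 3L * p_start)
  }
}

#' Search one contig for a polypeptide probe in all six frames
#'
#' The probe is aligned locally against each frame translation; matches with
#' score >= `scheme$min_score` are reported. Multiple matches per frame are
#' found by iterated masking: the best local alignment is recorded, the
#' matched target span removed, and the flanking segments re-searched, so
#' reported matches never overlap within a frame. Ties in score are resolved
#' towards the smaller start coordinate, then `+` before `-` strand.
#'
#' @param contig DNA string (character or `DNAString`).
#' @param probe polypeptide string.
#' @param scheme a [scoring_scheme()].
#' @param contig_id,probe_id ids recorded in the output.
#' @return a data.frame of hits: `contig_id`, `nt_start`, `nt_end` (0-based
#'   half-open, forward strand), `strand`, `frame`, `score`, `probe_id`,
#'   `matched_peptide` (the contiguous target span of the frame translation).
#' @export
search_translated_contig <- function(contig, probe, scheme = scoring_scheme(),
                                     contig_id = "contig", probe_id = "probe") {
  search_frames(translate_six_frames(contig), probe, scheme, contig_id,
                probe_id)
}

# Inner search over precomputed frame translations (lets the assembly
# screen translate each contig once, not once per probe).
search_frames <- function(frames, probe, scheme, contig_id, probe_id) {
  L <- frames[[1]]$contig_length
  rows <- list()
  for (f in frames) {
    if (nchar(f$peptide) == 0) next
    segs <- sw_segments(probe, f$peptide, scheme)
    for (sg in segs) {
      nt <- frame_span_to_nt(f$frame, sg$t_start, sg$t_end, L)
      rows[[length(rows) + 1]] <- data.frame(
        contig_id = contig_id, nt_start = nt[1], nt_end = nt[2],
        strand = if (f$frame > 0) "+" else "-", frame = f$frame,
        score = sg$score, probe_id = probe_id,
        matched_peptide = substr(f$peptide, sg$t_start + 1, sg$t_end),
        stringsAsFactors = FALSE)
    }
  }
  hits <- if (length(rows)) do.call(rbind, rows) else empty_hits()
  sort_hits(hits)
}

# Iterated masking within one target peptide: report the best local
# alignment, then recurse on the unsearched left/right target segments.
sw_segments <- function(probe, target, scheme, offset = 0L) {
  if (nchar(target) == 0) return(list())
  r <- .sw_endpoints_cpp(aa_encode(probe, scheme), aa_encode(target, scheme),
                         scheme$matrix, scheme$gap_open, scheme$gap_extend)
  if (r$score < scheme$min_score) return(list())
  hit <- list(score = r$score,
              t_start = offset + r$t_start, t_end = offset + r$t_end)
  left <- sw_segments(probe, substr(target, 1, r$t_start), scheme, offset)
  right <- sw_segments(probe, substr(target, r$t_end + 1, nchar(target)),
                       scheme, offset + r$t_end)
  c(list(hit), left, right)
}

empty_hits <- function() {
  data.frame(contig_id = character(), nt_start = integer(),
             nt_end = integer(), strand = character(), frame = integer(),
             score = numeric(), probe_id = character(),
             matched_peptide = character(), stringsAsFactors = FALSE)
}

# Deterministic hit order: by contig, then start, then score (desc), then
# '+' before '-'.
sort_hits <- function(hits) {
  if (!nrow(hits)) return(hits)
  o <- order(hits$contig_id, hits$nt_start, -hits$score,
             match(hits$strand, c("+", "-")))
  hits <- hits[o, , drop = FALSE]
  rownames(hits) <- NULL
  hits
}
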