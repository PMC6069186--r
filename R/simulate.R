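#' Simulate a host genome assembly
#'
#' Contigs are i.i.d. nucleotide sequence at the requested GC content;
#' lengths are normal around `mean_length` (sd = `length_sd`, floored at
#' 100 nt). Pure function of its arguments and `seed`.
#'
#' @param n_contigs number of contigs.
#' @param mean_length mean contig length (nt).
#' @param gc_content GC proportion in [0,1].
#' @param seed integer seed.
#' @param length_sd sd of contig length (default 10% of the mean; 0 gives
#'   fixed-length contigs).
#' @param prefix contig id prefix.
#' @return named character vector of contig sequences.
#' @export
simulate_host_genome <- function(n_contigs, mean_length, gc_content, seed,
                                 length_sd = 0.1 * mean_length,
                                 prefix = "contig") {
  stopifnot(n_contigs > 0, mean_length > 0, gc_content >= 0, gc_content <= 1)
  with_seed(seed, {
    lens <- pmax(100L, as.integer(round(rnorm(n_contigs, mean_length,
                                              length_sd))))
    p <- c(A = (1 - gc_content) / 2, C = gc_content / 2,
           G = gc_content / 2, T = (1 - gc_content) / 2)
    seqs <- vapply(lens, function(L)
      paste(sample(names(p), L, replace = TRUE, prob = p), collapse = ""),
      "")
    setNames(seqs, sprintf("%s_%d", prefix, seq_len(n_contigs)))
  })
}

#' Evolve a polypeptide by point substitution
#'
#' Exactly `round(proportion * length)` positions are replaced by a
#' different residue drawn uniformly from the 20 amino acids.
#'
#' @param peptide source polypeptide string.
#' @param proportion substituted fraction in [0,1].
#' @param seed integer seed.
#' @return the evolved polypeptide string.
#' @export
evolve_peptide <- function(peptide, proportion, seed) {
  stopifnot(proportion >= 0, proportion <= 1)
  with_seed(seed, {
    aa <- strsplit(peptide, "")[[1]]
    n <- round(proportion * length(aa))
    if (n > 0) {
      pos <- sample(length(aa), n)
      aa[pos] <- vapply(aa[pos], function(a)
        sample(setdiff(AA20, a), 1), "", USE.NAMES = FALSE)
    }
    paste(aa, collapse = "")
  })
}

#' Specify a coding-decay model for planted elements
#'
#' Describes the germline degradation applied to a planted viral insertion:
#' non-synonymous codon substitutions, premature in-frame stop codons, and
#' frameshifting indels (length not divisible by 3). Counts are
#' deterministic — `round(aa_substitution_rate * n_codons)` substitutions,
#' `round(stop_rate)` stops, `round(frameshift_rate)` frameshifts — so
#' truth tables are exactly controllable; positions are random under the
#' model's seed.
#'
#' @param aa_substitution_rate proportion of codons substituted
#'   non-synonymously (0-1).
#' @param stop_rate expected premature stops per element.
#' @param frameshift_rate expected frameshifting indels per element.
#' @param seed integer seed for mutation placement.
#' @return a `decay_model` list.
#' @export
decay_model <- function(aa_substitution_rate = 0, stop_rate = 0,
                        frameshift_rate = 0, seed = 1) {
  stopifnot(aa_substitution_rate >= 0, aa_substitution_rate <= 1,
            stop_rate >= 0, frameshift_rate >= 0)
  structure(list(aa_substitution_rate = aa_substitution_rate,
                 stop_rate = stop_rate, frameshift_rate = frameshift_rate,
                 seed = seed),
            class = "decay_model")
}

codons_for <- function(aa) {
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc == aa]
}

# Back-translate a peptide with uniform codon choice (call inside with_seed).
back_translate_codons <- function(peptide) {
  aa <- strsplit(peptide, "")[[1]]
  vapply(aa, function(a) {
    cods <- codons_for(a)
    cods[sample.int(length(cods), 1)]
  }, "", USE.NAMES = FALSE)
}

#' Plant a decayed viral element into a contig
#'
#' The element is a back-translation of `source_peptide` (uniform codon
#' choice), degraded per the [decay_model()]: substituted codons are
#' recoded to a different (non-stop) residue; premature stops replace
#' interior codons; frameshifts insert or delete 1-2 nt. Stops and
#' frameshifts are placed in the interior 25-75% of the element so the
#' flanking homology stays detectable, and when frameshifts are applied
#' their total length is kept indivisible by 3 (so the realized span
#' betrays the shift). Reverse-strand insertions store the reverse
#' complement. Truth fields are computed from the *realized* sequence and
#' flanks, not from the requested rates.
#'
#' @param contig host contig (character string).
#' @param source_peptide the viral polypeptide the element derives from.
#' @param decay a [decay_model()].
#' @param position 0-based insertion point into the contig.
#' @param strand `"+"` or `"-"`.
#' @param contig_id,species,source_ref_id ids recorded in the truth row.
#' @return list with `contig` (modified sequence) and `record`, a one-row
#'   truth data.frame: `species`, `contig_id`, `nt_start`, `nt_end`,
#'   `strand`, `source_ref_id`, `n_subs`, `n_stops`, `n_shifts`, `flank5`,
#'   `flank3`, `true_status`, `true_intact`, `element_class`.
#' @export
insert_eve <- function(contig, source_peptide, decay = decay_model(),
                       position, strand = "+", contig_id = "contig",
                       species = "species", source_ref_id = "ref") {
  L0 <- nchar(contig)
  npep <- nchar(source_peptide)
  if (3 * npep > L0) stop("element (", 3 * npep, " nt) longer than contig")
  if (position < 0 || position > L0) stop("position outside contig")
  el <- with_seed(decay$seed, {
    cods <- back_translate_codons(source_peptide)
    n_cod <- length(cods)
    n_subs <- round(decay$aa_substitution_rate * n_cod)
    n_stops <- round(decay$stop_rate)
    n_shifts <- round(decay$frameshift_rate)
    interior <- seq(max(2L, ceiling(0.25 * n_cod)),
                    min(n_cod - 1L, floor(0.75 * n_cod)))
    stop_pos <- if (n_stops > 0) sample(interior, n_stops) else integer(0)
    sub_pool <- setdiff(seq_len(n_cod), stop_pos)
    sub_pos <- if (n_subs > 0) sample(sub_pool, min(n_subs, length(sub_pool)))
               else integer(0)
    aa <- strsplit(source_peptide, "")[[1]]
    for (p in sub_pos) {
      new_aa <- sample(setdiff(AA20, aa[p]), 1)
      cods[p] <- sample(codons_for(new_aa), 1)
    }
    for (p in stop_pos)
      cods[p] <- sample(c("TAA", "TAG", "TGA"), 1)
    seq <- paste(cods, collapse = "")
    shift_total <- 0L
    if (n_shifts > 0) {
      lens <- sample(1:2, n_shifts, replace = TRUE)
      if (sum(lens) %% 3 == 0) lens[n_shifts] <- 3L - lens[n_shifts]
      lo <- ceiling(0.25 * nchar(seq)); hi <- floor(0.75 * nchar(seq))
      for (k in seq_len(n_shifts)) {
        at <- sample(lo:hi, 1)
        if (runif(1) < 0.5) {  # insertion
          ins <- paste(sample(c("A", "C", "G", "T"), lens[k], replace = TRUE),
                       collapse = "")
          seq <- paste0(substr(seq, 1, at), ins,
                        substr(seq, at + 1, nchar(seq)))
        } else {               # deletion
          seq <- paste0(substr(seq, 1, at),
                        substr(seq, at + lens[k] + 1, nchar(seq)))
        }
      }
      shift_total <- n_shifts
    }
    list(seq = seq, n_subs = length(sub_pos), n_stops = n_stops,
         n_shifts = shift_total)
  })
  element <- el$seq
  if (strand == "-")
    element <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(element)))
  newc <- paste0(substr(contig, 1, position), element,
                 substr(contig, position + 1, L0))
  span <- nchar(element)
  flank5 <- position
  flank3 <- L0 - position
  record <- data.frame(
    species = species, contig_id = contig_id,
    nt_start = position, nt_end = position + span, strand = strand,
    source_ref_id = source_ref_id,
    n_subs = el$n_subs, n_stops = el$n_stops, n_shifts = el$n_shifts,
    flank5 = flank5, flank3 = flank3,
    true_status = if (min(flank5, flank3) > 3000) "confirmed_cve"
                  else "unconfirmed",
    true_intact = span >= 200 && el$n_stops == 0 && el$n_shifts == 0,
    element_class = "viral", stringsAsFactors = FALSE)
  list(contig = newc, record = record)
}

#' Re-derive truth labels from the emitted sequences
#'
#' Internal-consistency check of a truth table: status is recomputed from
#' the recorded span and the contig length, intactness from the realized
#' span and an in-frame translation of the planted region. Every row must
#' agree with the recorded `true_status` / `true_intact`.
#'
#' @param truth truth table ([insert_eve()] records).
#' @param assemblies named list (by species) of named contig vectors.
#' @return logical vector per row: does the re-derivation agree?
#' @export
validate_truth_table <- function(truth, assemblies) {
  vapply(seq_len(nrow(truth)), function(i) {
    r <- truth[i, ]
    contig <- as_named_character(assemblies[[r$species]])[[r$contig_id]]
    L <- nchar(contig)
    status <- if (min(r$nt_start, L - r$nt_end) > 3000) "confirmed_cve"
              else "unconfirmed"
    span <- r$nt_end - r$nt_start
    intact <- FALSE
    if (span >= 200 && span %% 3 == 0) {
      region <- Biostrings::DNAString(substr(contig, r$nt_start + 1, r$nt_end))
      if (r$strand == "-") region <- Biostrings::reverseComplement(region)
      pep <- as.character(Biostrings::translate(region, if.fuzzy.codon = "X",
                                                no.init.codon = TRUE))
      intact <- !grepl("*", substr(pep, 1, nchar(pep) - 1), fixed = TRUE)
    }
    identical(status, r$true_status) && identical(intact, r$true_intact)
  }, NA)
}
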