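#' Merge classified hits on one contig into loci
#'
#' Same-strand hits whose nucleotide gap is at most `max_gap` are chained
#' into a single locus (a putative integration that the screen recovered as
#' several fragments, e.g. across frameshifts). Different strands never
#' merge. Merging is idempotent. The locus inherits gene/group from its
#' highest-scoring fragment when the hits carry classifications.
#'
#' @param hits data.frame of hits on a single contig (columns as produced by
#'   [run_paired_screen()] or [search_translated_contig()]).
#' @param max_gap maximum nucleotide gap between consecutive fragments.
#' @return data.frame of loci with columns `contig`, `nt_start`, `nt_end`,
#'   `strand`, `n_fragments`, `frames` (comma-joined), `score` (best
#'   fragment), `assigned_gene`, `assigned_group` (NA if hits unclassified)
#'   and a list-column `fragments` holding the member hit rows.
#' @export
merge_hits_to_loci <- function(hits, max_gap = 100) {
  stopifnot(max_gap >= 0)
  cid_col <- if ("contig" %in% names(hits)) "contig" else "contig_id"
  start_col <- if ("start" %in% names(hits)) "start" else "nt_start"
  end_col <- if ("end" %in% names(hits)) "end" else "nt_end"
  if (nrow(hits) && length(unique(hits[[cid_col]])) > 1)
    stop("merge_hits_to_loci expects hits from a single contig")
  out <- list()
  for (str in c("+", "-")) {
    h <- hits[hits$strand == str, , drop = FALSE]
    if (!nrow(h)) next
    h <- h[order(h[[start_col]], h[[end_col]]), , drop = FALSE]
    grp <- cumsum(c(1, (h[[start_col]][-1] -
                          cummax(h[[end_col]])[-nrow(h)]) > max_gap))
    for (g in unique(grp)) {
      fr <- h[grp == g, , drop = FALSE]
      best <- which.max(fr$score)
      out[[length(out) + 1]] <- data.frame(
        contig = fr[[cid_col]][1],
        nt_start = min(fr[[start_col]]), nt_end = max(fr[[end_col]]),
        strand = str, n_fragments = nrow(fr),
        frames = paste(sort(unique(fr$frame)), collapse = ","),
        score = max(fr$score),
        assigned_gene = if ("assigned_gene" %in% names(fr))
          fr$assigned_gene[best] else NA_character_,
        assigned_group = if ("assigned_group" %in% names(fr))
          fr$assigned_group[best] else NA_character_,
        stringsAsFactors = FALSE)
      out[[length(out)]]$fragments <- I(list(fr))
    }
  }
  if (!length(out)) return(empty_loci())
  loci <- do.call(rbind, out)
  loci <- loci[order(loci$nt_start, loci$nt_end,
                     match(loci$strand, c("+", "-"))), , drop = FALSE]
  rownames(loci) <- NULL
  loci
}

empty_loci <- function() {
  data.frame(contig = character(), nt_start = integer(), nt_end = integer(),
             strand = character(), n_fragments = integer(),
             frames = character(), score = numeric(),
             assigned_gene = character(), assigned_group = character(),
             stringsAsFactors = FALSE)
}

#' Call CVe status of a locus from its flanks
#'
#' A locus is a confirmed endogenous element (`confirmed_cve`) only when it
#' is flanked on *both* sides by more than `flank_threshold` nucleotides of
#' non-locus genomic sequence on its contig (strict inequality); otherwise
#' it is `unconfirmed` and annotated as potentially derived from
#' contaminating virus. Long flanks are the evidence that the match sits
#' inside host genomic DNA rather than on a short viral contig.
#'
#' @param nt_start,nt_end 0-based half-open locus span.
#' @param contig_length contig length in nucleotides.
#' @param flank_threshold nucleotides of flank required (default 3000,
#'   i.e. the ">3 kb" rule).
#' @return `"confirmed_cve"` or `"unconfirmed"`.
#' @export
call_status <- function(nt_start, nt_end, contig_length,
                        flank_threshold = 3000) {
  if (nt_start < 0 || nt_end > contig_length || nt_start >= nt_end)
    stop("locus [", nt_start, ",", nt_end, ") outside contig of length ",
         contig_length)
  flank5 <- nt_start
  flank3 <- contig_length - nt_end
  if (min(flank5, flank3) > flank_threshold) "confirmed_cve" else "unconfirmed"
}

#' Call coding intactness of a locus
#'
#' A locus is intact when protein-coding potential is maintained across the
#' whole detected region of viral homology: the span is at least `min_len`
#' nucleotides, all fragments lie in one reading frame (no frameshift: the
#' span must also be a whole number of codons), and translating the full
#' span in that frame yields no internal stop codon (a stop at the terminal
#' codon is tolerated).
#'
#' @param locus one locus row from [merge_hits_to_loci()] (or any list with
#'   `nt_start`, `nt_end`, `strand`, `frames`).
#' @param contig the contig DNA (character or `DNAString`).
#' @param min_len minimum span in nucleotides (default 200).
#' @return logical.
#' @export
call_intactness <- function(locus, contig, min_len = 200) {
  span <- locus$nt_end - locus$nt_start
  if (span < min_len) return(FALSE)
  frames <- strsplit(as.character(locus$frames), ",")[[1]]
  if (length(frames) != 1) return(FALSE)
  if (span %% 3 != 0) return(FALSE)
  s <- Biostrings::DNAString(toupper(as.character(contig)))
  region <- Biostrings::subseq(s, start = locus$nt_start + 1, end = locus$nt_end)
  if (locus$strand == "-") region <- Biostrings::reverseComplement(region)
  pep <- as.character(Biostrings::translate(region, if.fuzzy.codon = "X",
                                            no.init.codon = TRUE))
  internal <- substr(pep, 1, nchar(pep) - 1)
  !grepl("*", internal, fixed = TRUE)
}

#' Annotate a screen results table into loci
#'
#' Driver over [merge_hits_to_loci()], [call_status()] and
#' [call_intactness()]: per species and contig, classified hits are merged,
#' flanks measured against the contig, and status / intactness called.
#'
#' @param results screen results ([run_paired_screen()]).
#' @param assemblies named list (by species) of named assemblies
#'   (`DNAStringSet` or character vectors).
#' @param max_gap fragment-merging gap ([merge_hits_to_loci()]).
#' @param flank_threshold see [call_status()].
#' @param min_intact_len see [call_intactness()].
#' @return locus table: `species`, `contig`, `nt_start`, `nt_end`, `strand`,
#'   `n_fragments`, `frames`, `score`, `assigned_gene`, `assigned_group`,
#'   `flank5`, `flank3`, `status`, `intact`, `cve_id` (NA until
#'   [assign_cve_ids()]), plus the `fragments` list-column.
#' @export
annotate_loci <- function(results, assemblies, max_gap = 100,
                          flank_threshold = 3000, min_intact_len = 200) {
  out <- list()
  for (sp in unique(results$species)) {
    rsp <- results[results$species == sp, , drop = FALSE]
    asm <- assemblies[[sp]]
    if (is.null(asm)) stop("no assembly supplied for species ", sp)
    asm <- as_named_character(asm)
    for (cid in unique(rsp$contig)) {
      loci <- merge_hits_to_loci(rsp[rsp$contig == cid, , drop = FALSE],
                                 max_gap = max_gap)
      if (!nrow(loci)) next
      L <- nchar(asm[[cid]])
      loci$species <- sp
      loci$flank5 <- loci$nt_start
      loci$flank3 <- L - loci$nt_end
      loci$status <- vapply(seq_len(nrow(loci)), function(i)
        call_status(loci$nt_start[i], loci$nt_end[i], L, flank_threshold), "")
      loci$intact <- vapply(seq_len(nrow(loci)), function(i)
        call_intactness(loci[i, ], asm[[cid]], min_intact_len), NA)
      out[[length(out) + 1]] <- loci
    }
  }
  if (!length(out)) {
    e <- empty_loci(); e$species <- character(); e$flank5 <- integer()
    e$flank3 <- integer(); e$status <- character(); e$intact <- logical()
    e$cve_id <- character()
    return(e)
  }
  loci <- do.call(rbind, out)
  loci$cve_id <- NA_character_
  o <- order(loci$species, loci$contig, loci$nt_start)
  loci <- loci[o, , drop = FALSE]
  rownames(loci) <- NULL
  loci
}
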