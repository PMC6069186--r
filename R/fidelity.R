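#' Rule fidelity of status/intactness calls on a planted boundary grid
#'
#' Runs the screen-and-annotate pipeline over a [simulate_boundary_grid()]
#' dataset — each grid contig is screened with the probe matching its
#' planted element's peptide — and compares the detected locus's status and
#' intactness calls against the truth table, row by row. A planted element
#' is matched to the detected locus overlapping its span.
#'
#' @param ds a [simulate_boundary_grid()] dataset.
#' @param scheme a [scoring_scheme()].
#' @return data.frame per planted element: truth fields plus
#'   `detected_start`, `detected_end`, `called_status`, `called_intact`,
#'   `status_agrees`, `intact_agrees`.
#' @export
grid_rule_agreement <- function(ds, scheme = scoring_scheme()) {
  asm <- ds$assemblies[[1]]
  sp <- names(ds$assemblies)[1]
  out <- list()
  for (i in seq_len(nrow(ds$truth))) {
    tr <- ds$truth[i, ]
    probe_id <- sprintf("probe_len%d", ds$grid[[i]]$len)
    hits <- search_translated_contig(asm[[tr$contig_id]],
                                     ds$probes[[probe_id]], scheme,
                                     contig_id = tr$contig_id,
                                     probe_id = probe_id)
    loci <- merge_hits_to_loci(hits)
    row <- tr
    row$detected_start <- NA_integer_; row$detected_end <- NA_integer_
    row$called_status <- NA_character_; row$called_intact <- NA
    if (nrow(loci)) {
      ov <- which(loci$nt_start < tr$nt_end & loci$nt_end > tr$nt_start)
      if (length(ov)) {
        lo <- loci[ov[which.max(loci$score[ov])], ]
        L <- nchar(asm[[tr$contig_id]])
        row$detected_start <- lo$nt_start
        row$detected_end <- lo$nt_end
        row$called_status <- call_status(lo$nt_start, lo$nt_end, L)
        row$called_intact <- call_intactness(lo, asm[[tr$contig_id]])
      }
    }
    row$status_agrees <- identical(row$called_status, tr$true_status)
    row$intact_agrees <- identical(row$called_intact, tr$true_intact)
    out[[i]] <- row
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Screen recall and group-assignment accuracy against a truth table
#'
#' Matches classified screen hits to planted (non-distractor) elements by
#' overlap and reports, per element, whether it was recovered and whether
#' the best-scoring overlapping hit's assigned group matches the planted
#' source reference's group.
#'
#' @param results classified screen results ([run_paired_screen()]).
#' @param truth truth table from the simulator.
#' @param library reference library (maps `source_ref_id` to its group).
#' @return data.frame per viral planted element: `species`, `contig_id`,
#'   `recovered`, `true_group`, `assigned_group`, `group_correct`.
#' @export
screen_recovery <- function(results, truth, library) {
  tv <- truth[truth$element_class == "viral", , drop = FALSE]
  rows <- lapply(seq_len(nrow(tv)), function(i) {
    tr <- tv[i, ]
    ov <- results$species == tr$species & results$contig == tr$contig_id &
      results$start < tr$nt_end & results$end > tr$nt_start
    true_group <- library$group[library$id == tr$source_ref_id]
    if (!length(true_group)) true_group <- NA_character_
    if (any(ov)) {
      r <- results[ov, , drop = FALSE]
      best <- r[which.max(r$score), ]
      data.frame(species = tr$species, contig_id = tr$contig_id,
                 recovered = TRUE, true_group = true_group,
                 assigned_group = best$assigned_group,
                 group_correct = identical(best$assigned_group, true_group),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(species = tr$species, contig_id = tr$contig_id,
                 recovered = FALSE, true_group = true_group,
                 assigned_group = NA_character_, group_correct = FALSE,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
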