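#' Read a reference polypeptide library
#'
#' The library pairs a protein FASTA with a metadata table carrying, per
#' reference, its gene (`rep`/`cap`), group (`Circovirus`/`Cyclovirus`/
#' `CRESS`), host association and evidence tier (`cve`/`isolate`/
#' `metagenomic`).
#'
#' @param fasta_path protein FASTA of reference polypeptides.
#' @param meta_path TSV with columns `id`, `gene`, `group`,
#'   `host_association`, `evidence_tier`.
#' @return a data.frame with one row per reference and a `peptide` column.
#' @export
read_reference_library <- function(fasta_path, meta_path) {
  seqs <- read_aa_fasta(fasta_path)
  meta <- read.delim(meta_path, stringsAsFactors = FALSE)
  need <- c("id", "gene", "group", "host_association", "evidence_tier")
  miss <- setdiff(need, names(meta))
  if (length(miss)) stop("reference metadata lacks column(s): ",
                         paste(miss, collapse = ", "))
  absent <- setdiff(meta$id, names(seqs))
  if (length(absent)) stop("metadata id(s) without sequence: ",
                           paste(absent, collapse = ", "))
  bad <- setdiff(meta$evidence_tier, c("cve", "isolate", "metagenomic"))
  if (length(bad)) stop("unknown evidence tier(s): ", paste(bad, collapse = ", "))
  meta$peptide <- as.character(seqs[meta$id])
  meta
}

#' Step 1 of the paired screen: search an assembly with polypeptide probes
#'
#' Runs [search_translated_contig()] for every (contig, probe) pair and
#' pools the hits. Hits from different probes over the same region are all
#' retained; de-duplication happens later at locus merging.
#'
#' @param assembly named `DNAStringSet` (or named character vector) of contigs.
#' @param probes named `AAStringSet` (or named character vector) of probe
#'   polypeptides, e.g. circovirus Rep and Cap sequences.
#' @param scheme a [scoring_scheme()].
#' @return hit data.frame as in [search_translated_contig()], sorted by
#'   (contig, start, score desc).
#' @export
screen_assembly <- function(assembly, probes, scheme = scoring_scheme()) {
  if (length(assembly) == 0) stop("empty assembly")
  if (length(probes) == 0) stop("empty probe set")
  assembly <- as_named_character(assembly)
  probes <- as_named_character(probes)
  if (is.null(names(assembly)) || is.null(names(probes)))
    stop("assembly contigs and probes must be named")
  out <- list()
  for (cid in names(assembly)) {
    frames <- translate_six_frames(assembly[[cid]])
    for (pid in names(probes)) {
      h <- search_frames(frames, probes[[pid]], scheme,
                         contig_id = cid, probe_id = pid)
      if (nrow(h)) out[[length(out) + 1]] <- h
    }
  }
  hits <- if (length(out)) do.call(rbind, out) else empty_hits()
  sort_hits(hits)
}

#' Step 2 of the paired screen: classify an extracted peptide
#'
#' The extracted peptide is aligned against every library entry; the
#' highest-scoring reference assigns gene and group. Score ties are broken
#' by lexicographic reference id. `runner_up_score` is the best score among
#' references whose *group* differs from the winner's (0 if none), i.e. a
#' cross-group classification margin.
#'
#' @param peptide extracted polypeptide string.
#' @param library data.frame from [read_reference_library()].
#' @param scheme a [scoring_scheme()].
#' @return one-row data.frame: `best_ref_id`, `assigned_gene`,
#'   `assigned_group`, `score`, `runner_up_score`.
#' @export
classify_peptide <- function(peptide, library, scheme = scoring_scheme()) {
  if (is.null(library) || nrow(library) == 0) stop("empty reference library")
  sc <- vapply(library$peptide, function(ref)
    local_align_score(peptide, ref, scheme), numeric(1), USE.NAMES = FALSE)
  o <- order(-sc, library$id)
  best <- o[1]
  other <- library$group != library$group[best]
  runner <- if (any(other)) max(sc[other]) else 0
  data.frame(best_ref_id = library$id[best],
             assigned_gene = library$gene[best],
             assigned_group = library$group[best],
             score = sc[best], runner_up_score = runner,
             stringsAsFactors = FALSE)
}

#' Run the full two-step screen over several species
#'
#' For each species the assembly is screened with all probes (step 1), each
#' hit's matched peptide is classified against the reference library
#' (step 2), and the classified hits are appended to a single results table.
#' The run is deterministic in its inputs; an unreadable assembly is logged
#' and skipped without aborting the other species.
#'
#' @param manifest data.frame with columns `species`, `path` (assembly
#'   FASTA) and `species_code` (short code used in CVe ids). Alternatively
#'   `assemblies` may be supplied directly.
#' @param probes named `AAStringSet`/character vector of probes.
#' @param library reference library data.frame
#'   ([read_reference_library()]).
#' @param scheme a [scoring_scheme()].
#' @param out_dir if non-NULL, `screen_results.tsv` and `screen_log.txt`
#'   are written there.
#' @param assemblies optional named list of assemblies (named character
#'   vectors / `DNAStringSet`), keyed by species; overrides `manifest$path`.
#' @return the results data.frame, one row per classified hit, with columns
#'   `species`, `contig`, `start`, `end`, `strand`, `frame`, `score`,
#'   `probe_id`, `best_ref`, `assigned_gene`, `assigned_group`. Attribute
#'   `"log"` carries the per-species log lines; attribute `"errors"` any
#'   per-species failures.
#' @export
run_paired_screen <- function(manifest, probes, library,
                              scheme = scoring_scheme(), out_dir = NULL,
                              assemblies = NULL) {
  if (length(probes) == 0) stop("empty probe set")
  species <- manifest$species
  res <- list(); log <- character(); errs <- character()
  for (i in seq_along(species)) {
    sp <- species[i]
    tab <- tryCatch({
      asm <- if (!is.null(assemblies)) assemblies[[sp]]
             else read_dna_fasta(manifest$path[i])
      hits <- screen_assembly(asm, probes, scheme)
      if (nrow(hits)) {
        cls <- do.call(rbind, lapply(hits$matched_peptide, classify_peptide,
                                     library = library, scheme = scheme))
        data.frame(species = sp, contig = hits$contig_id,
                   start = hits$nt_start, end = hits$nt_end,
                   strand = hits$strand, frame = hits$frame,
                   score = hits$score, probe_id = hits$probe_id,
                   best_ref = cls$best_ref_id,
                   assigned_gene = cls$assigned_gene,
                   assigned_group = cls$assigned_group,
                   matched_peptide = hits$matched_peptide,
                   stringsAsFactors = FALSE)
      } else NULL
    }, error = function(e) e)
    if (inherits(tab, "error")) {
      errs <- c(errs, sprintf("%s\t%s", sp, conditionMessage(tab)))
      log <- c(log, sprintf("%s\tERROR\t%s", sp, conditionMessage(tab)))
    } else {
      n <- if (is.null(tab)) 0L else nrow(tab)
      log <- c(log, sprintf("%s\thits\t%d", sp, n))
      if (n) res[[length(res) + 1]] <- tab
    }
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(species = character(), contig = character(), start = integer(),
               end = integer(), strand = character(), frame = integer(),
               score = numeric(), probe_id = character(),
               best_ref = character(), assigned_gene = character(),
               assigned_group = character(), matched_peptide = character(),
               stringsAsFactors = FALSE)
  o <- order(out$species, out$contig, out$start, -out$score)
  out <- out[o, , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_tsv_exact(out, file.path(out_dir, "screen_results.tsv"))
    writeLines(log, file.path(out_dir, "screen_log.txt"))
  }
  attr(out, "log") <- log
  attr(out, "errors") <- errs
  out
}

# Coerce DNAStringSet/AAStringSet or character to a named character vector.
as_named_character <- function(x) {
  if (is.character(x)) return(x)
  setNames(as.character(x), names(x))
}

# Deterministic TSV writer (fixed quoting/NA conventions so reruns are
# byte-identical).
write_tsv_exact <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}
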