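#' Group confirmed loci into cross-species ortholog groups
#'
#' Orthology between insertions in different species is established from
#' shared flanking host sequence: two loci are called orthologous when they
#' carry the same gene and group assignment *and* a flank-vs-flank
#' nucleotide alignment on the same side reaches `min_flank_identity` over a
#' `flank_window`-nucleotide window. Groups are the connected components of
#' this relation; loci without enough flank (or without a partner) become
#' singletons.
#'
#' Identity is `nmatch / flank_window` of a global affine alignment
#' (match 1, mismatch -2, gap open 10, gap extend 2); under these penalties
#' unrelated flanks score well below the 0.7 default while orthologous
#' flanks at a few percent divergence score close to 1.
#'
#' @param loci annotated locus table ([annotate_loci()]); typically only
#'   confirmed loci are passed.
#' @param assemblies named list (by species) of named assemblies.
#' @param flank_window nucleotides of flank compared (default 500).
#' @param min_flank_identity identity threshold in (0,1] (default 0.7).
#' @return the locus table with an integer `ortholog_group` column; groups
#'   are numbered deterministically by (group, species, contig, start) of
#'   their first member.
#' @export
group_orthologs <- function(loci, assemblies, flank_window = 500,
                            min_flank_identity = 0.7) {
  n <- nrow(loci)
  loci$ortholog_group <- integer(n)
  if (n == 0) return(loci)
  fl5 <- fl3 <- character(n)
  for (i in seq_len(n)) {
    asm <- as_named_character(assemblies[[loci$species[i]]])
    s <- asm[[loci$contig[i]]]
    st <- loci$nt_start[i]; en <- loci$nt_end[i]
    fl5[i] <- if (st >= flank_window)
      substr(s, st - flank_window + 1, st) else ""
    fl3[i] <- if (nchar(s) - en >= flank_window)
      substr(s, en + 1, en + flank_window) else ""
  }
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  if (n > 1) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      if (loci$species[i] == loci$species[j]) next
      if (!identical(loci$assigned_gene[i], loci$assigned_gene[j])) next
      if (!identical(loci$assigned_group[i], loci$assigned_group[j])) next
      linked <-
        (nchar(fl5[i]) > 0 && nchar(fl5[j]) > 0 &&
           flank_identity(fl5[i], fl5[j], flank_window) >= min_flank_identity) ||
        (nchar(fl3[i]) > 0 && nchar(fl3[j]) > 0 &&
           flank_identity(fl3[i], fl3[j], flank_window) >= min_flank_identity)
      if (linked) parent[find(j)] <- find(i)
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  # deterministic numbering by first member under canonical locus order
  o <- order(loci$assigned_group, loci$species, loci$contig, loci$nt_start)
  ids <- setNames(seq_along(unique(comp[o])), unique(comp[o]))
  loci$ortholog_group <- as.integer(ids[as.character(comp)])
  loci
}

# Fraction of identically aligned bases over the window length, from a
# global affine nucleotide alignment.
flank_identity <- function(a, b, window) {
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -2, baseOnly = FALSE),
    gapOpening = 10, gapExtension = 2)
  Biostrings::nmatch(pa) / window
}

#' Assign stable CVe identifiers
#'
#' Ids follow the convention `CVe-<GroupName>.<n>-<SpeciesCode>`: the fixed
#' classifier `CVe`, the taxonomic group of the element plus a numeric id
#' unique to the insertion, and a short species code. Orthologous copies in
#' different species share the numeric id and differ only in the species
#' code. Numbers for new insertions continue from the maximum already used
#' within the group name in `registry`; loci present in the registry (same
#' species, contig and span) keep their registered id, so reruns are stable.
#'
#' @param loci locus table with an `ortholog_group` column
#'   ([group_orthologs()]).
#' @param species_codes named character vector, species -> short code.
#' @param registry optional data.frame of previously assigned ids with
#'   columns `cve_id`, `species`, `contig`, `nt_start`, `nt_end`.
#' @return the locus table with `cve_id` filled in.
#' @export
assign_cve_ids <- function(loci, species_codes, registry = NULL) {
  if (!nrow(loci)) { loci$cve_id <- character(0); return(loci) }
  miss <- setdiff(unique(loci$species), names(species_codes))
  if (length(miss)) stop("no species code for: ", paste(miss, collapse = ", "))
  next_num <- new.env()
  reg_key <- character(0)
  if (!is.null(registry) && nrow(registry)) {
    parts <- regmatches(registry$cve_id,
                        regexec("^CVe-([^.]+)\\.([0-9]+)-", registry$cve_id))
    for (p in parts) {
      if (length(p) == 3) {
        g <- p[2]; k <- as.integer(p[3])
        cur <- mget(g, envir = next_num, ifnotfound = 0L)[[1]]
        assign(g, max(cur, k), envir = next_num)
      }
    }
    reg_key <- setNames(registry$cve_id,
                        paste(registry$species, registry$contig,
                              registry$nt_start, registry$nt_end))
  }
  loci$cve_id <- NA_character_
  # deterministic group order: by (group name, first member's species code,
  # contig, start)
  ord <- order(loci$assigned_group, species_codes[loci$species],
               loci$contig, loci$nt_start)
  group_num <- list()
  for (i in ord) {
    key <- paste(loci$species[i], loci$contig[i], loci$nt_start[i],
                 loci$nt_end[i])
    gname <- loci$assigned_group[i]
    og <- as.character(loci$ortholog_group[i])
    if (key %in% names(reg_key)) {
      loci$cve_id[i] <- reg_key[[key]]
      m <- regmatches(loci$cve_id[i],
                      regexec("^CVe-([^.]+)\\.([0-9]+)-", loci$cve_id[i]))[[1]]
      if (length(m) == 3 && is.null(group_num[[og]]))
        group_num[[og]] <- as.integer(m[3])
      next
    }
    if (is.null(group_num[[og]])) {
      cur <- mget(gname, envir = next_num, ifnotfound = 0L)[[1]]
      group_num[[og]] <- cur + 1L
      assign(gname, cur + 1L, envir = next_num)
    }
    loci$cve_id[i] <- sprintf("CVe-%s.%d-%s", gname, group_num[[og]],
                              species_codes[[loci$species[i]]])
  }
  dup <- loci$cve_id[duplicated(loci$cve_id)]
  if (length(dup)) stop("CVe id collision: ", paste(unique(dup), collapse = ", "))
  loci
}
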