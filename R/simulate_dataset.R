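#' Default configuration for a simulated screening dataset
#'
#' The defaults define the study conditions emulated by the simulator: a
#' handful of modest assemblies (real screens cover hundreds of genomes;
#' the simulator keeps the same structure at desk scale), Rep-derived
#' elements of 100 codons planted with generous (>3 kb) flanks, one
#' unrelated distractor insertion per species, 42% GC hosts, and a
#' three-group Rep/Cap reference family whose groups sit at ~25-35%
#' amino-acid divergence (circovirus-like depths).
#'
#' @param ... overrides for any default field.
#' @return a config list.
#' @export
screen_config <- function(...) {
  cfg <- list(
    n_species = 3,
    plants_per_species = 2,
    distractors_per_species = 1,
    contig_length = 9000,
    gc = 0.42,
    element_len_aa = 100,
    flank_min = 3500,
    decay = list(decay_model()),   # recycled over plants
    ref_len_aa = 300,
    cap_len_aa = 250,
    groups = c("Circovirus", "Cyclovirus", "CRESS"),
    refs_per_group = 3,
    group_divergence = c(0.25, 0.25, 0.35),
    within_group_divergence = 0.08,
    probe_divergence = 0.05)
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

# Seeded reference family: a rep ancestor radiated into groups, plus a
# smaller cap family. Returns probes (named vector) and a library df.
build_reference_family <- function(cfg, seed) {
  with_seed(seed, {
    rep_base <- paste(sample(AA20, cfg$ref_len_aa, replace = TRUE),
                      collapse = "")
    cap_base <- paste(sample(AA20, cfg$cap_len_aa, replace = TRUE),
                      collapse = "")
    sub_seeds <- sample.int(.Machine$integer.max, 200)
    k <- 0
    nxt <- function() { k <<- k + 1; sub_seeds[k] }
    refs <- list(); probes <- character()
    hosts <- c("mammal", "bird", "fish", "insect", "unknown")
    tiers <- c("isolate", "metagenomic", "cve")
    ri <- 0
    for (gi in seq_along(cfg$groups)) {
      g <- cfg$groups[gi]
      gbase <- evolve_peptide(rep_base, cfg$group_divergence[gi], nxt())
      for (j in seq_len(cfg$refs_per_group)) {
        ri <- ri + 1
        refs[[length(refs) + 1]] <- data.frame(
          id = sprintf("rep_%s_%d", g, j),
          gene = "rep", group = g,
          host_association = hosts[(ri - 1) %% length(hosts) + 1],
          evidence_tier = tiers[(ri - 1) %% length(tiers) + 1],
          peptide = evolve_peptide(gbase, cfg$within_group_divergence, nxt()),
          stringsAsFactors = FALSE)
      }
      probes[sprintf("probe_rep_%s", g)] <-
        evolve_peptide(gbase, cfg$probe_divergence, nxt())
      cbase <- evolve_peptide(cap_base, cfg$group_divergence[gi], nxt())
      ri <- ri + 1
      refs[[length(refs) + 1]] <- data.frame(
        id = sprintf("cap_%s_1", g), gene = "cap", group = g,
        host_association = hosts[(ri - 1) %% length(hosts) + 1],
        evidence_tier = tiers[(ri - 1) %% length(tiers) + 1],
        peptide = evolve_peptide(cbase, cfg$within_group_divergence, nxt()),
        stringsAsFactors = FALSE)
    }
    probes["probe_cap"] <- evolve_peptide(cap_base, cfg$probe_divergence,
                                          nxt())
    list(probes = probes, library = do.call(rbind, refs))
  })
}

#' Simulate a complete screening dataset with truth table
#'
#' Generates host assemblies with planted, decayed Rep-derived elements
#' (one per contig, flanks sampled above `flank_min`), unrelated distractor
#' insertions, a probe set and reference library, and the truth table
#' enumerating every planted element. Fully deterministic in
#' (config, seed). With `out_dir` set, everything needed to rerun the
#' screen from disk is written there (per-species FASTA, `manifest.tsv`,
#' `probes.faa`, `reflib.faa` + `reflib.tsv`, `truth.tsv`).
#'
#' @param config a [screen_config()].
#' @param seed integer master seed.
#' @param out_dir optional output directory.
#' @return list: `assemblies` (named list of named contig vectors),
#'   `manifest` (species, path, species_code), `probes`, `library`,
#'   `truth`, `species_codes`.
#' @export
simulate_screen_dataset <- function(config = screen_config(), seed = 1,
                                    out_dir = NULL) {
  cfg <- config
  fam_seed <- with_seed(seed, sample.int(.Machine$integer.max, 1))
  fam <- build_reference_family(cfg, fam_seed)
  rep_refs <- fam$library[fam$library$gene == "rep", , drop = FALSE]
  species <- sprintf("species_%s", LETTERS[seq_len(cfg$n_species)])
  codes <- setNames(sprintf("Sp%s", LETTERS[seq_len(cfg$n_species)]), species)
  n_draws <- cfg$n_species *
    (3 * (cfg$plants_per_species + cfg$distractors_per_species) + 4)
  seeds <- with_seed(seed + 1, sample.int(.Machine$integer.max, n_draws))
  si <- 0
  nxt <- function() { si <<- si + 1; seeds[si] }
  assemblies <- list(); truth <- list()
  plant_i <- 0
  for (sp in species) {
    n_contigs <- cfg$plants_per_species + cfg$distractors_per_species + 1
    asm <- simulate_host_genome(n_contigs, cfg$contig_length, cfg$gc,
                                seed = nxt(), length_sd = 0,
                                prefix = paste0(codes[[sp]], "_ctg"))
    for (p in seq_len(cfg$plants_per_species)) {
      plant_i <- plant_i + 1
      ref <- rep_refs[(plant_i - 1) %% nrow(rep_refs) + 1, ]
      pep <- substr(ref$peptide, 1, cfg$element_len_aa)
      dk <- cfg$decay[[(plant_i - 1) %% length(cfg$decay) + 1]]
      dk$seed <- nxt()
      cid <- names(asm)[p]
      L <- nchar(asm[[cid]])
      pos <- with_seed(nxt(),
                       sample(cfg$flank_min:(L - cfg$flank_min), 1))
      strand <- with_seed(nxt(), sample(c("+", "-"), 1))
      ins <- insert_eve(asm[[cid]], pep, dk, pos, strand, contig_id = cid,
                        species = sp, source_ref_id = ref$id)
      asm[[cid]] <- ins$contig
      truth[[length(truth) + 1]] <- ins$record
    }
    for (d in seq_len(cfg$distractors_per_species)) {
      dpep <- with_seed(nxt(),
                        paste(sample(AA20, cfg$element_len_aa,
                                     replace = TRUE), collapse = ""))
      cid <- names(asm)[cfg$plants_per_species + d]
      L <- nchar(asm[[cid]])
      pos <- with_seed(nxt(),
                       sample(cfg$flank_min:(L - cfg$flank_min), 1))
      ins <- insert_eve(asm[[cid]], dpep, decay_model(seed = nxt()), pos,
                        "+", contig_id = cid, species = sp,
                        source_ref_id = sprintf("distractor_%s_%d", sp, d))
      ins$record$element_class <- "distractor"
      asm[[cid]] <- ins$contig
      truth[[length(truth) + 1]] <- ins$record
    }
    assemblies[[sp]] <- asm
  }
  truth <- do.call(rbind, truth)
  manifest <- data.frame(species = species, path = NA_character_,
                         species_code = unname(codes),
                         stringsAsFactors = FALSE)
  out <- list(assemblies = assemblies, manifest = manifest,
              probes = fam$probes, library = fam$library, truth = truth,
              species_codes = codes)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (sp in species) {
      f <- file.path(out_dir, paste0(sp, ".fasta"))
      write_fasta(assemblies[[sp]], f, type = "dna")
      manifest$path[manifest$species == sp] <- f
    }
    # manifest on disk uses paths relative to its own directory, so the
    # written dataset is byte-identical wherever it lands
    rel <- manifest; rel$path <- basename(rel$path)
    write_tsv_exact(rel, file.path(out_dir, "manifest.tsv"))
    write_fasta(fam$probes, file.path(out_dir, "probes.faa"), type = "aa")
    write_fasta(setNames(fam$library$peptide, fam$library$id),
                file.path(out_dir, "reflib.faa"), type = "aa")
    write_tsv_exact(fam$library[, c("id", "gene", "group",
                                    "host_association", "evidence_tier")],
                    file.path(out_dir, "reflib.tsv"))
    write_tsv_exact(truth, file.path(out_dir, "truth.tsv"))
    out$manifest <- manifest
  }
  out
}

#' Simulate the boundary decay grid for rule-fidelity checks
#'
#' Builds one planted element per grid cell, crossing the decision
#' boundaries of the status and intactness rules: 5' flanks of
#' 2999/3000/3001 nt (paired with a deep 3' flank, and mirrored), element
#' spans of 66 and 67 codons (198/201 nt, straddling the 200-nt intactness
#' cutoff), and 0 or 1 premature stops / frameshifts, all at zero
#' substitution so planted and detected boundaries coincide exactly. Each
#' element is screened with a probe of exactly its own peptide, so the
#' query is exhausted at both element ends and alignments cannot extend
#' into the flanks.
#'
#' @param seed integer seed.
#' @return list like [simulate_screen_dataset()] (single species
#'   `species_G`), plus `grid` describing each cell.
#' @export
simulate_boundary_grid <- function(seed = 1) {
  fam <- build_reference_family(screen_config(), with_seed(seed,
    sample.int(.Machine$integer.max, 1)))
  probe <- fam$probes[["probe_rep_Circovirus"]]
  cells <- list(
    list(flank5 = 2999, flank3 = 5000, len = 100, stops = 0, shifts = 0),
    list(flank5 = 3000, flank3 = 5000, len = 100, stops = 0, shifts = 0),
    list(flank5 = 3001, flank3 = 5000, len = 100, stops = 0, shifts = 0),
    list(flank5 = 5000, flank3 = 2999, len = 100, stops = 0, shifts = 0),
    list(flank5 = 5000, flank3 = 3000, len = 100, stops = 0, shifts = 0),
    list(flank5 = 5000, flank3 = 3001, len = 100, stops = 0, shifts = 0),
    list(flank5 = 4000, flank3 = 4000, len = 66, stops = 0, shifts = 0),
    list(flank5 = 4000, flank3 = 4000, len = 67, stops = 0, shifts = 0),
    list(flank5 = 4000, flank3 = 4000, len = 100, stops = 1, shifts = 0),
    list(flank5 = 4000, flank3 = 4000, len = 100, stops = 0, shifts = 1),
    list(flank5 = 2999, flank3 = 2999, len = 100, stops = 1, shifts = 0),
    list(flank5 = 3500, flank3 = 3500, len = 100, stops = 1, shifts = 1))
  seeds <- with_seed(seed + 1, sample.int(.Machine$integer.max,
                                          3 * length(cells)))
  lens <- unique(vapply(cells, `[[`, numeric(1), "len"))
  probes <- setNames(vapply(lens, function(l) substr(probe, 1, l), ""),
                     sprintf("probe_len%d", lens))
  asm <- character(); truth <- list()
  for (i in seq_along(cells)) {
    cl <- cells[[i]]
    cid <- sprintf("grid_ctg_%d", i)
    bg <- simulate_host_genome(1, cl$flank5 + cl$flank3, 0.42,
                               seed = seeds[3 * i - 2], length_sd = 0,
                               prefix = "bg")
    strand <- if (i %% 2 == 0) "-" else "+"
    dk <- decay_model(stop_rate = cl$stops, frameshift_rate = cl$shifts,
                      seed = seeds[3 * i - 1])
    ins <- insert_eve(unname(bg[1]), probes[[sprintf("probe_len%d", cl$len)]],
                      dk, position = cl$flank5, strand = strand,
                      contig_id = cid, species = "species_G",
                      source_ref_id = "probe_rep_Circovirus")
    asm[cid] <- ins$contig
    truth[[i]] <- ins$record
  }
  list(assemblies = list(species_G = asm),
       manifest = data.frame(species = "species_G", path = NA,
                             species_code = "SpG"),
       probes = probes,
       library = fam$library, truth = do.call(rbind, truth),
       species_codes = c(species_G = "SpG"),
       grid = cells)
}
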