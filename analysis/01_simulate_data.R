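#!/usr/bin/env Rscript
# Step 1: generate the synthetic study inputs.
#
# Two screening datasets stand in for the WGS assemblies a real screen
# would download: a clean one (no decay; used to measure raw recall) and a
# decayed one (15% amino-acid substitution plus stop/frameshift lesions;
# used for classification accuracy and intactness calls). A set of
# host-labelled Rep phylogenies with planted host switches and metagenomic
# contaminants feeds the host-association analyses.

suppressPackageStartupMessages(library(circofossil))

out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

message("simulating clean screening dataset (3 species, 2 plants each) ...")
clean <- simulate_screen_dataset(screen_config(plants_per_species = 2),
                                 seed = 101,
                                 out_dir = file.path(out, "clean"))

message("simulating decayed screening dataset (3 species, 4 plants each) ...")
decay_grid <- list(decay_model(),
                   decay_model(aa_substitution_rate = 0.15),
                   decay_model(aa_substitution_rate = 0.1, stop_rate = 1),
                   decay_model(frameshift_rate = 1))
decayed <- simulate_screen_dataset(
  screen_config(plants_per_species = 4, decay = decay_grid),
  seed = 102, out_dir = file.path(out, "decayed"))

message("simulating host-labelled Rep tree with contaminants ...")
s <- simulate_labeled_tree(50, k = 2, contamination_rate = 0.2, seed = 103)
write_annotated_tree(s$atree, file.path(out, "rep_tree.nwk"),
                     file.path(out, "rep_tree_annotations.tsv"))
writeLines(c(sprintf("planted_transitions\t%d", s$planted_transition_count),
             sprintf("contaminants\t%s", paste(s$contaminants,
                                               collapse = ","))),
           file.path(out, "rep_tree_truth.tsv"))

n_el <- sum(decayed$truth$element_class == "viral")
message(sprintf("done: %d + %d planted elements, tree with %d tips (%d contaminants)",
                sum(clean$truth$element_class == "viral"), n_el,
                length(s$atree$tree$tip.label), length(s$contaminants)))
message("truth tables under ", out)
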