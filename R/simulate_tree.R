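#' Simulate a host-labelled phylogeny with planted switches and contaminants
#'
#' Generates a random rooted binary backbone (`ape::rtree`), assigns host
#' groups by planting `k` label switches on randomly chosen edges (every
#' backbone tip is anchored: tier `cve` or `isolate`), then grafts
#' metagenomic duplicate tips next to sampled backbone tips:
#' *contaminants*, whose host label is replaced by a group from a different
#' backbone tip's label (emulating, e.g., an arthropod virus sequenced
#' from a vertebrate sample), and *clean* metagenomic tips, which keep
#' their neighbour's label. Internal nodes receive bootstrap supports
#' drawn uniformly from 85-100 so anchored-clade ascent is exercised.
#'
#' @param n_tips backbone tips.
#' @param host_groups character vector of host-group labels (>= 2 for any
#'   switching or contamination).
#' @param k number of planted host switches (`k <= n_tips - 1`).
#' @param contamination_rate fraction of backbone tips duplicated as
#'   mislabelled metagenomic tips.
#' @param clean_meta_rate fraction duplicated as correctly labelled
#'   metagenomic tips (default: same as `contamination_rate`).
#' @param seed integer seed.
#' @return list: `atree` (an `annotated_tree`), `newick`,
#'   `planted_transition_count`, `contaminants` (tip ids),
#'   `clean_metagenomic` (tip ids).
#' @export
simulate_labeled_tree <- function(n_tips, host_groups = c("arthropod",
                                                          "vertebrate"),
                                  k = 0, contamination_rate = 0,
                                  clean_meta_rate = contamination_rate,
                                  seed = 1) {
  stopifnot(n_tips >= 3, k >= 0, k <= n_tips - 1,
            contamination_rate >= 0, clean_meta_rate >= 0)
  if ((k > 0 || contamination_rate > 0) && length(host_groups) < 2)
    stop("need >= 2 host groups to plant switches or contaminants")
  with_seed(seed, {
    tree <- ape::rtree(n_tips)
    tree$tip.label <- sprintf("t%02d", seq_len(n_tips))
    nn <- n_tips + tree$Nnode
    state <- character(nn)
    root <- n_tips + 1L
    state[root] <- host_groups[1]
    switch_edges <- if (k > 0) sample(nrow(tree$edge), k) else integer(0)
    cw <- ape::reorder.phylo(tree, "cladewise")  # parents before children
    for (e in seq_len(nrow(cw$edge))) {
      p <- cw$edge[e, 1]; ch <- cw$edge[e, 2]
      state[ch] <- if (e %in% switch_edges)
        sample(setdiff(host_groups, state[p]), 1) else state[p]
    }
    labels <- setNames(state[seq_len(n_tips)], tree$tip.label)
    tiers <- setNames(sample(c("cve", "isolate"), n_tips, replace = TRUE),
                      tree$tip.label)
    n_cont <- round(contamination_rate * n_tips)
    n_clean <- round(clean_meta_rate * n_tips)
    picked <- sample(tree$tip.label, n_cont + n_clean)
    cont_of <- picked[seq_len(n_cont)]
    clean_of <- picked[n_cont + seq_len(n_clean)]
    graft <- function(tree, host_tip, new_label) {
      ei <- which(tree$edge[, 2] == which(tree$tip.label == host_tip))
      phytools::bind.tip(tree, new_label,
                         edge.length = tree$edge.length[ei] / 2,
                         where = which(tree$tip.label == host_tip),
                         position = tree$edge.length[ei] / 2)
    }
    contaminants <- clean_meta <- character(0)
    for (tp in cont_of) {
      nm <- paste0(tp, "_meta")
      tree <- graft(tree, tp, nm)
      labels[nm] <- sample(setdiff(host_groups, labels[[tp]]), 1)
      tiers[nm] <- "metagenomic"
      contaminants <- c(contaminants, nm)
    }
    for (tp in clean_of) {
      nm <- paste0(tp, "_meta")
      tree <- graft(tree, tp, nm)
      labels[nm] <- labels[[tp]]
      tiers[nm] <- "metagenomic"
      clean_meta <- c(clean_meta, nm)
    }
    tree$node.label <- as.character(round(runif(tree$Nnode, 85, 100)))
    annot <- data.frame(taxon = tree$tip.label,
                        host_group = unname(labels[tree$tip.label]),
                        evidence_tier = unname(tiers[tree$tip.label]),
                        stringsAsFactors = FALSE)
    list(atree = annotated_tree(tree, annot),
         newick = ape::write.tree(tree),
         planted_transition_count = k,
         contaminants = contaminants,
         clean_metagenomic = clean_meta)
  })
}
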