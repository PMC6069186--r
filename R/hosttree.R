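#' Read a host-annotated phylogeny
#'
#' Pairs a rooted newick tree (internal node labels interpreted as bootstrap
#' support in [0,100], where present) with a tip annotation table carrying
#' each taxon's host group and evidence tier. Tiers distinguish *anchored*
#' taxa — endogenous elements in sequenced germlines (`cve`) and isolated
#' viruses (`isolate`), whose host is established beyond sequencing — from
#' `metagenomic` taxa whose host label reflects only the sampled material.
#'
#' @param newick_path newick file; polytomies are preserved.
#' @param annotation_path TSV with columns `taxon`, `host_group`,
#'   `evidence_tier`.
#' @return an `annotated_tree`: list with `tree` (ape `phylo`), `annot`
#'   (data.frame aligned to `tree$tip.label`) and `support` (numeric per
#'   internal node, NA where absent).
#' @export
read_annotated_tree <- function(newick_path, annotation_path) {
  tree <- ape::read.tree(newick_path)
  if (is.null(tree)) stop("malformed newick in ", newick_path)
  annot <- read.delim(annotation_path, stringsAsFactors = FALSE)
  annotated_tree(tree, annot)
}

#' @rdname read_annotated_tree
#' @param tree an ape `phylo` object (rooted; node labels = support).
#' @param annot annotation data.frame as above.
#' @export
annotated_tree <- function(tree, annot) {
  need <- c("taxon", "host_group", "evidence_tier")
  miss <- setdiff(need, names(annot))
  if (length(miss)) stop("annotation lacks column(s): ",
                         paste(miss, collapse = ", "))
  absent <- setdiff(tree$tip.label, annot$taxon)
  if (length(absent))
    stop("tip(s) missing from annotation: ", paste(absent, collapse = ", "))
  bad <- setdiff(annot$evidence_tier, c("cve", "isolate", "metagenomic"))
  if (length(bad)) stop("unknown evidence tier(s): ", paste(bad, collapse = ", "))
  annot <- annot[match(tree$tip.label, annot$taxon), , drop = FALSE]
  rownames(annot) <- NULL
  support <- rep(NA_real_, tree$Nnode)
  if (!is.null(tree$node.label)) {
    sup <- suppressWarnings(as.numeric(tree$node.label))
    support[!is.na(sup)] <- sup[!is.na(sup)]
  }
  structure(list(tree = tree, annot = annot, support = support),
            class = "annotated_tree")
}

#' Write an annotated tree back to newick + TSV
#'
#' @param atree an `annotated_tree`.
#' @param newick_path,annotation_path output paths.
#' @export
write_annotated_tree <- function(atree, newick_path, annotation_path) {
  ape::write.tree(atree$tree, newick_path)
  write_tsv_exact(atree$annot, annotation_path)
  invisible(newick_path)
}

anchored_tips <- function(atree) {
  atree$tree$tip.label[atree$annot$evidence_tier != "metagenomic"]
}

#' Minimum host-switch count by parsimony
#'
#' Computes the minimum number of host-group changes required on the tree
#' (unordered states, unit cost) by dynamic programming over node state
#' costs — the Sankoff recursion, which equals the Fitch count on binary
#' trees and remains exact on multifurcations. This formalizes reading a
#' host-colored phylogeny for transmission events: a count of 1 or more
#' among, say, vertebrate- and invertebrate-associated clades means at
#' least that many cross-host transfers are implied by the tree.
#'
#' @param atree an `annotated_tree`.
#' @param tip_filter `"all"` or `"anchored_only"` (metagenomic tips pruned
#'   before counting).
#' @return list with `min_transitions`, `node_states` (per-node set of
#'   states attaining the minimum, tips included) and `n_tips`.
#' @export
fitch_min_transitions <- function(atree, tip_filter = c("all", "anchored_only")) {
  tip_filter <- match.arg(tip_filter)
  tree <- atree$tree
  labels <- setNames(atree$annot$host_group, atree$annot$taxon)
  if (tip_filter == "anchored_only") {
    keep <- anchored_tips(atree)
    if (length(keep) < 2) stop("fewer than 2 tips after filtering")
    if (length(keep) < length(tree$tip.label))
      tree <- ape::keep.tip(tree, keep)
  }
  ntip <- length(tree$tip.label)
  if (ntip < 2) stop("fewer than 2 tips after filtering")
  states <- sort(unique(unname(labels[tree$tip.label])))
  S <- length(states)
  nnode <- ntip + tree$Nnode
  cost <- matrix(Inf, nnode, S)
  for (i in seq_len(ntip))
    cost[i, match(labels[[tree$tip.label[i]]], states)] <- 0
  po <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(po$edge))) {
    child <- po$edge[e, 2]; parent <- po$edge[e, 1]
    # min over child states of (child cost + unit change penalty)
    inc <- vapply(seq_len(S), function(s)
      min(cost[child, ] + (seq_len(S) != s)), numeric(1))
    if (all(!is.finite(cost[parent, ]))) cost[parent, ] <- 0
    cost[parent, ] <- cost[parent, ] + inc
  }
  root <- ntip + 1L
  mt <- min(cost[root, ])
  node_states <- lapply(seq_len(nnode), function(i)
    states[cost[i, ] == min(cost[i, ])])
  list(min_transitions = as.integer(mt), node_states = node_states,
       n_tips = ntip, states = states)
}

#' Host-label inflation attributable to metagenomic taxa
#'
#' The difference between the parsimony host-switch count on the full tree
#' and the count after pruning metagenomic tips. Pruning can never raise
#' the minimum, so the statistic is non-negative; large values mean the
#' sequencing-only host labels drive most of the implied host switching —
#' the signature expected if metagenomic labels frequently reflect
#' contamination (e.g. arthropod viruses in vertebrate samples) rather
#' than true host range.
#'
#' @param atree an `annotated_tree` with at least 2 anchored tips.
#' @return non-negative integer.
#' @export
host_label_inflation <- function(atree) {
  all_t <- fitch_min_transitions(atree, "all")$min_transitions
  anch <- fitch_min_transitions(atree, "anchored_only")$min_transitions
  all_t - anch
}

#' Flag metagenomic tips whose host label conflicts with their clade
#'
#' For each metagenomic tip, ascend to the smallest ancestral clade with
#' bootstrap support above `support_threshold` that contains at least one
#' anchored tip. The clade's consensus host is the majority higher rank
#' (via `rank_map`, e.g. class or phylum) among its anchored tips; a tie
#' gives `"ambiguous"` and no flag. The tip conflicts when its own label's
#' rank differs from the consensus — the pattern expected of a contaminant
#' (say, a "bat"-labelled sequence nested among arthropod endogenous
#' elements). Tips with no qualifying ancestor are reported `"unanchored"`.
#'
#' @param atree an `annotated_tree`.
#' @param rank_map named character vector, host_group -> higher rank; must
#'   cover every host_group present.
#' @param support_threshold clades qualify when support > this (default 70).
#' @return data.frame, one row per metagenomic tip: `taxon`, `host_group`,
#'   `tip_rank`, `clade_node`, `clade_support`, `n_anchored`,
#'   `consensus_rank`, `conflict`, `anchoring` (`"anchored"`/`"unanchored"`).
#' @export
anchored_conflicts <- function(atree, rank_map, support_threshold = 70) {
  tree <- atree$tree
  miss <- setdiff(unique(atree$annot$host_group), names(rank_map))
  if (length(miss)) stop("rank_map lacks host group(s): ",
                         paste(miss, collapse = ", "))
  ntip <- length(tree$tip.label)
  parent <- integer(ntip + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  clade_tips <- clade_tip_sets(tree)
  anchored <- atree$annot$evidence_tier != "metagenomic"
  meta_idx <- which(!anchored)
  rows <- lapply(meta_idx, function(i) {
    node <- parent[i]
    while (node != 0) {
      sup <- atree$support[node - ntip]
      tips <- clade_tips[[node - ntip]]
      anch <- tips[anchored[tips]]
      if (!is.na(sup) && sup > support_threshold && length(anch) > 0) {
        ranks <- rank_map[atree$annot$host_group[anch]]
        tab <- sort(table(ranks), decreasing = TRUE)
        consensus <- if (length(tab) > 1 && tab[1] == tab[2]) "ambiguous"
                     else names(tab)[1]
        tip_rank <- unname(rank_map[[atree$annot$host_group[i]]])
        return(data.frame(
          taxon = tree$tip.label[i],
          host_group = atree$annot$host_group[i], tip_rank = tip_rank,
          clade_node = node, clade_support = sup,
          n_anchored = length(anch), consensus_rank = consensus,
          conflict = consensus != "ambiguous" && tip_rank != consensus,
          anchoring = "anchored", stringsAsFactors = FALSE))
      }
      node <- if (node == ntip + 1L) 0L else parent[node]
    }
    data.frame(taxon = tree$tip.label[i],
               host_group = atree$annot$host_group[i],
               tip_rank = unname(rank_map[[atree$annot$host_group[i]]]),
               clade_node = NA_integer_, clade_support = NA_real_,
               n_anchored = 0L, consensus_rank = NA_character_,
               conflict = FALSE, anchoring = "unanchored",
               stringsAsFactors = FALSE)
  })
  if (!length(rows))
    return(data.frame(taxon = character(), host_group = character(),
                      tip_rank = character(), clade_node = integer(),
                      clade_support = numeric(), n_anchored = integer(),
                      consensus_rank = character(), conflict = logical(),
                      anchoring = character(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# tip indices under each internal node (index = node - ntip)
clade_tip_sets <- function(tree) {
  ntip <- length(tree$tip.label)
  sets <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) sets[[i]] <- i
  po <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(po$edge)))
    sets[[po$edge[e, 1]]] <- c(sets[[po$edge[e, 1]]], sets[[po$edge[e, 2]]])
  lapply((ntip + 1):(ntip + tree$Nnode), function(i) sort(sets[[i]]))
}

#' Minimum-age constraints from shared orthologous insertions
#'
#' An endogenous element shared orthologously by several species must
#' predate their divergence, so the most recent common ancestor of the
#' carrying tips is at least as old as the hosts' split. Each ortholog
#' group therefore places `min_age = max` pairwise host divergence on its
#' MRCA, and constraints propagate rootward (an ancestor is at least as
#' old as any descendant).
#'
#' @param atree an `annotated_tree`.
#' @param ortholog_tips named list: ortholog group label -> character
#'   vector of member tip taxa (>= 2 required; singletons are skipped with
#'   a warning).
#' @param divergence data.frame with columns `species_a`, `species_b`,
#'   `mya` covering every needed pair (order-insensitive).
#' @return data.frame sorted by node: `node`, `min_age` (million years),
#'   `source` (label of the constraint that set the age).
#' @export
min_age_constraints <- function(atree, ortholog_tips, divergence) {
  tree <- atree$tree
  ntip <- length(tree$tip.label)
  parent <- integer(ntip + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  lookup <- function(a, b) {
    hit <- (divergence$species_a == a & divergence$species_b == b) |
           (divergence$species_a == b & divergence$species_b == a)
    if (!any(hit)) stop("no divergence time for pair: ", a, " / ", b)
    divergence$mya[which(hit)[1]]
  }
  age <- rep(0, ntip + tree$Nnode)
  src <- rep(NA_character_, ntip + tree$Nnode)
  for (g in names(ortholog_tips)) {
    tips <- intersect(ortholog_tips[[g]], tree$tip.label)
    if (length(tips) < 2) {
      warning("ortholog group ", g, " has fewer than 2 tips in tree; skipped")
      next
    }
    prs <- utils::combn(tips, 2)
    ages <- vapply(seq_len(ncol(prs)), function(k)
      lookup(prs[1, k], prs[2, k]), numeric(1))
    node <- ape::getMRCA(tree, tips)
    a <- max(ages)
    if (a <= 0) stop("non-positive divergence time for group ", g)
    if (a > age[node]) { age[node] <- a; src[node] <- g }
    # propagate rootward
    n <- node
    while (n != ntip + 1L) {
      n <- parent[n]
      if (a > age[n]) { age[n] <- a; src[n] <- g }
    }
  }
  keep <- which(age > 0)
  out <- data.frame(node = keep, min_age = age[keep], source = src[keep],
                    stringsAsFactors = FALSE)
  out[order(out$node), , drop = FALSE]
}
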