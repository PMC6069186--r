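write_tree_fixture <- function(newick, annot) {
  nf <- withr::local_tempfile(fileext = ".nwk", .local_envir = parent.frame())
  af <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(newick, nf)
  write.table(annot, af, sep = "\t", quote = FALSE, row.names = FALSE)
  list(newick = nf, annot = af)
}

test_that("annotated trees parse, validate, and round-trip", {
  annot <- data.frame(taxon = c("A", "B", "C"),
                      host_group = c("arthropod", "arthropod", "vertebrate"),
                      evidence_tier = c("cve", "isolate", "metagenomic"))
  fx <- write_tree_fixture("((A:1,B:1)90:1,C:2);", annot)
  at <- read_annotated_tree(fx$newick, fx$annot)
  expect_equal(length(at$tree$tip.label), 3)
  expect_equal(at$annot$host_group[match("C", at$annot$taxon)], "vertebrate")
  expect_true(90 %in% at$support)
  # missing tip errors by name
  fx2 <- write_tree_fixture("((A:1,B:1):1,D:2);", annot)
  expect_error(read_annotated_tree(fx2$newick, fx2$annot), "D")
  # round trip preserves topology and labels
  out <- write_tree_fixture("placeholder;", annot)  # placeholder paths
  write_annotated_tree(at, out$newick, out$annot)
  back <- read_annotated_tree(out$newick, out$annot)
  expect_true(ape::all.equal.phylo(at$tree, back$tree))
  expect_identical(back$annot, at$annot)
})

test_that("parsimony count is zero for uniform labels and one for one clade", {
  uni <- annotated_tree(ape::read.tree(text = "((A,B),(C,D));"),
                        data.frame(taxon = LETTERS[1:4], host_group = "x",
                                   evidence_tier = "cve"))
  expect_equal(fitch_min_transitions(uni)$min_transitions, 0L)
  two <- annotated_tree(ape::read.tree(text = "((A,B),(C,D));"),
                        data.frame(taxon = LETTERS[1:4],
                                   host_group = c("x", "x", "y", "y"),
                                   evidence_tier = "cve"))
  expect_equal(fitch_min_transitions(two)$min_transitions, 1L)
})

test_that("parsimony count equals exhaustive enumeration on random trees", {
  set.seed(301)
  for (i in 1:60) {
    at <- random_annotated_tree(sample(4:8, 1), sample(2:3, 1))
    tip_states <- setNames(at$annot$host_group, at$annot$taxon)
    expect_equal(fitch_min_transitions(at)$min_transitions,
                 bf_min_transitions(at$tree, tip_states),
                 info = ape::write.tree(at$tree))
  }
})

test_that("parsimony count matches phangorn on binary trees", {
  skip_if_not_installed("phangorn")
  set.seed(302)
  for (i in 1:20) {
    tr <- ape::rtree(sample(5:12, 1))
    labs <- sample(c("a", "b", "c"), length(tr$tip.label), TRUE)
    at <- annotated_tree(tr, data.frame(taxon = tr$tip.label,
                                        host_group = labs,
                                        evidence_tier = "cve"))
    pd <- phangorn::phyDat(setNames(as.list(labs), tr$tip.label),
                           type = "USER", levels = c("a", "b", "c"))
    expect_equal(fitch_min_transitions(at)$min_transitions,
                 as.integer(phangorn::parsimony(tr, pd)))
  }
})

test_that("host-label inflation is the metagenomic excess and never negative", {
  # no metagenomic tips: inflation must be 0
  s0 <- simulate_labeled_tree(15, k = 2, contamination_rate = 0,
                              clean_meta_rate = 0, seed = 41)
  expect_equal(host_label_inflation(s0$atree), 0L)
  # anchored tips all one group, contaminants interleaved: anchored term 0
  s1 <- simulate_labeled_tree(10, k = 0, contamination_rate = 0.5,
                              clean_meta_rate = 0, seed = 42)
  infl <- host_label_inflation(s1$atree)
  all_t <- fitch_min_transitions(s1$atree, "all")$min_transitions
  expect_equal(fitch_min_transitions(s1$atree,
                                     "anchored_only")$min_transitions, 0L)
  expect_equal(infl, all_t)
  expect_gte(infl, 1L)
  # pruning tips can never raise the minimum
  set.seed(43)
  for (i in 1:25) {
    s <- simulate_labeled_tree(sample(8:20, 1), k = sample(0:3, 1),
                               contamination_rate = runif(1, 0, 0.3),
                               seed = 4300 + i)
    expect_gte(host_label_inflation(s$atree), 0L)
  }
})

test_that("metagenomic labels conflicting with anchored clades are flagged", {
  # a "bat"-labelled metagenomic tip nested in a well-supported clade of
  # arthropod CVe
  tr <- ape::read.tree(text = "(((A1:1,M1:1)95:1,(A2:1,A3:1)88:1)92:2,(V1:1,V2:1)90:2);")
  annot <- data.frame(
    taxon = c("A1", "M1", "A2", "A3", "V1", "V2"),
    host_group = c("insect", "bat", "insect", "mite", "bird", "bat"),
    evidence_tier = c("cve", "metagenomic", "cve", "cve", "isolate", "cve"))
  at <- annotated_tree(tr, annot)
  rank_map <- c(insect = "arthropod", mite = "arthropod",
                bat = "vertebrate", bird = "vertebrate")
  cr <- anchored_conflicts(at, rank_map)
  expect_equal(nrow(cr), 1)
  expect_true(cr$conflict[cr$taxon == "M1"])
  expect_equal(cr$consensus_rank[1], "arthropod")
  # a vertebrate metagenomic tip inside a vertebrate clade is clean
  annot2 <- annot
  annot2$host_group[annot2$taxon == "M1"] <- "bat"
  annot2$evidence_tier <- c("cve", "cve", "cve", "cve", "isolate",
                            "metagenomic")
  cr2 <- anchored_conflicts(annotated_tree(tr, annot2), rank_map)
  expect_false(any(cr2$conflict))
})

test_that("low-support clades are skipped during ascent", {
  # immediate parent support 60: consensus must come from the deeper
  # 92-support clade, which is arthropod-majority
  tr <- ape::read.tree(text = "(((A1:1,M1:1)60:1,(A2:1,A3:1)88:1)92:2,(V1:1,V2:1)90:2);")
  annot <- data.frame(
    taxon = c("A1", "M1", "A2", "A3", "V1", "V2"),
    host_group = c("insect", "bat", "insect", "mite", "bird", "bat"),
    evidence_tier = c("cve", "metagenomic", "cve", "cve", "isolate", "cve"))
  rank_map <- c(insect = "arthropod", mite = "arthropod",
                bat = "vertebrate", bird = "vertebrate")
  cr <- anchored_conflicts(annotated_tree(tr, annot), rank_map)
  expect_equal(cr$clade_support[1], 92)
  expect_true(cr$conflict[1])
  # no supported ancestor at all: unanchored, never flagged
  tr2 <- ape::read.tree(text = "(((A1:1,M1:1):1,A2:1):2,V1:2);")
  annot3 <- annot[annot$taxon %in% c("A1", "M1", "A2", "V1"), ]
  cr3 <- anchored_conflicts(annotated_tree(tr2, annot3), rank_map)
  expect_equal(cr3$anchoring[1], "unanchored")
  expect_false(any(cr3$conflict))
})

test_that("planted contaminants are detected at high recall and low false flags", {
  set.seed(305)
  recalls <- fps <- numeric(0)
  for (i in 1:20) {
    s <- simulate_labeled_tree(50, k = 2, contamination_rate = 0.2,
                               seed = 5000 + i)
    cr <- anchored_conflicts(s$atree,
                             c(arthropod = "arthropod",
                               vertebrate = "vertebrate"))
    recalls <- c(recalls, mean(s$contaminants %in%
                                 cr$taxon[cr$conflict]))
    fps <- c(fps, mean(s$clean_metagenomic %in% cr$taxon[cr$conflict]))
  }
  expect_gte(mean(recalls), 0.9)
  expect_lt(mean(fps), 0.05)
})

test_that("ortholog calibrations set MRCA ages and propagate to the root", {
  tr <- ape::read.tree(text = "(((P1:1,P2:1):1,S1:2):1,(S2:1,S3:1):2);")
  at <- annotated_tree(tr, data.frame(taxon = c("P1", "P2", "S1", "S2", "S3"),
                                      host_group = "bird",
                                      evidence_tier = "cve"))
  div <- data.frame(species_a = c("P1", "S2"), species_b = c("P2", "S3"),
                    mya = c(38, 72))
  ac <- min_age_constraints(at, list(passerine = c("P1", "P2"),
                                     snake = c("S2", "S3")), div)
  ntip <- 5
  mrca_p <- ape::getMRCA(tr, c("P1", "P2"))
  mrca_s <- ape::getMRCA(tr, c("S2", "S3"))
  root <- ntip + 1
  expect_equal(ac$min_age[ac$node == mrca_p], 38)
  expect_equal(ac$min_age[ac$node == mrca_s], 72)
  expect_equal(ac$min_age[ac$node == root], 72)   # deep constraint wins
  # singleton group warns and is skipped; missing pair errors by name
  expect_warning(min_age_constraints(at, list(solo = "P1"), div), "solo")
  expect_error(min_age_constraints(at, list(bad = c("P1", "S1")), div),
               "P1 / S1")
})

test_that("propagated ages are monotone along every root-to-tip path", {
  set.seed(306)
  for (i in 1:10) {
    n <- sample(6:12, 1)
    tr <- ape::rtree(n)
    at <- annotated_tree(tr, data.frame(taxon = tr$tip.label,
                                        host_group = "g",
                                        evidence_tier = "cve"))
    k <- sample(2:4, 1)
    groups <- lapply(seq_len(k), function(j)
      sample(tr$tip.label, sample(2:3, 1)))
    names(groups) <- paste0("og", seq_len(k))
    pairs <- t(utils::combn(tr$tip.label, 2))
    div <- data.frame(species_a = pairs[, 1], species_b = pairs[, 2],
                      mya = sample(10:100, nrow(pairs), TRUE))
    ac <- min_age_constraints(at, groups, div)
    ages <- setNames(rep(0, n + tr$Nnode), seq_len(n + tr$Nnode))
    ages[as.character(ac$node)] <- ac$min_age
    parent <- integer(n + tr$Nnode)
    parent[tr$edge[, 2]] <- tr$edge[, 1]
    for (nd in (n + 2):(n + tr$Nnode))   # every non-root internal node
      expect_gte(ages[as.character(parent[nd])], ages[as.character(nd)])
  }
})
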