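# Independent oracles, written against the definitions rather than the
# package implementation.

AA20_TEST <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F",
               "P","S","T","W","Y","V")

random_peptide <- function(n) paste(sample(AA20_TEST, n, TRUE), collapse = "")
random_dna <- function(n) paste(sample(c("A","C","G","T"), n, TRUE), collapse = "")

# --- local alignment oracle -------------------------------------------------
# Best local alignment score by explicit enumeration of alignment-ending
# states at every cell: ending in a substitution (M), a gap in the target
# (U, query residue unmatched) or a gap in the query (L). An alignment may
# start at any cell (the max with 0) and end at any cell; a gap of length
# g costs gap_open + g * gap_extend.
bf_local_score <- function(q, t, mat, gap_open, gap_extend) {
  qa <- strsplit(q, "")[[1]]; ta <- strsplit(t, "")[[1]]
  m <- length(qa); n <- length(ta)
  M <- U <- L <- matrix(-Inf, m + 1, n + 1)
  best <- 0
  for (i in seq_len(m)) for (j in seq_len(n)) {
    prev <- max(0, M[i, j], U[i, j], L[i, j])
    M[i + 1, j + 1] <- prev + mat[qa[i], ta[j]]
    U[i + 1, j + 1] <- max(M[i, j + 1] - gap_open - gap_extend,
                           U[i, j + 1] - gap_extend)
    L[i + 1, j + 1] <- max(M[i + 1, j] - gap_open - gap_extend,
                           L[i + 1, j] - gap_extend)
    best <- max(best, M[i + 1, j + 1], U[i + 1, j + 1], L[i + 1, j + 1])
  }
  best
}

# --- translation oracle -----------------------------------------------------
# Hand-written standard codon table (independent of any library lookup).
CODON_TABLE <- c(
  TTT="F",TTC="F",TTA="L",TTG="L",CTT="L",CTC="L",CTA="L",CTG="L",
  ATT="I",ATC="I",ATA="I",ATG="M",GTT="V",GTC="V",GTA="V",GTG="V",
  TCT="S",TCC="S",TCA="S",TCG="S",CCT="P",CCC="P",CCA="P",CCG="P",
  ACT="T",ACC="T",ACA="T",ACG="T",GCT="A",GCC="A",GCA="A",GCG="A",
  TAT="Y",TAC="Y",TAA="*",TAG="*",CAT="H",CAC="H",CAA="Q",CAG="Q",
  AAT="N",AAC="N",AAA="K",AAG="K",GAT="D",GAC="D",GAA="E",GAG="E",
  TGT="C",TGC="C",TGA="*",TGG="W",CGT="R",CGC="R",CGA="R",CGG="R",
  AGT="S",AGC="S",AGA="R",AGG="R",GGT="G",GGC="G",GGA="G",GGG="G")

oracle_revcomp <- function(seq) {
  comp <- c(A="T",C="G",G="C",T="A",N="N")
  paste(rev(comp[strsplit(seq, "")[[1]]]), collapse = "")
}

# codon-by-codon lookup; codons with any non-ACGT character give 'X'
oracle_translate_frame <- function(seq, frame) {
  s <- if (frame > 0) seq else oracle_revcomp(seq)
  off <- abs(frame) - 1
  s <- substr(s, off + 1, nchar(s))
  n_codons <- nchar(s) %/% 3
  if (n_codons == 0) return("")
  paste(vapply(seq_len(n_codons), function(k) {
    cod <- substr(s, 3 * k - 2, 3 * k)
    if (grepl("[^ACGT]", cod)) "X" else CODON_TABLE[[cod]]
  }, ""), collapse = "")
}

# --- parsimony oracle -------------------------------------------------------
# Exhaustive minimization over all internal-node labelings.
bf_min_transitions <- function(tree, tip_states) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  states <- sort(unique(unname(tip_states)))
  assign_all <- expand.grid(rep(list(states), nnode),
                            stringsAsFactors = FALSE)
  full <- character(ntip + nnode)
  full[seq_len(ntip)] <- tip_states[tree$tip.label]
  best <- Inf
  for (r in seq_len(nrow(assign_all))) {
    full[(ntip + 1):(ntip + nnode)] <- unlist(assign_all[r, ],
                                              use.names = FALSE)
    chg <- sum(full[tree$edge[, 1]] != full[tree$edge[, 2]])
    best <- min(best, chg)
  }
  as.integer(best)
}

# random tree with optional polytomies; tips get <= n_labels states
random_annotated_tree <- function(n_tips, n_labels, p_collapse = 0.3) {
  tr <- ape::rtree(n_tips)
  if (n_tips > 3 && runif(1) < 0.6) {
    internal <- which(tr$edge[, 2] > n_tips)
    drop <- internal[runif(length(internal)) < p_collapse]
    if (length(drop)) {
      tr$edge.length[drop] <- 0
      tr <- ape::di2multi(tr, tol = 1e-8)
    }
  }
  labs <- paste0("h", seq_len(n_labels))
  annot <- data.frame(taxon = tr$tip.label,
                      host_group = sample(labs, length(tr$tip.label), TRUE),
                      evidence_tier = "cve", stringsAsFactors = FALSE)
  annotated_tree(tr, annot)
}

# point-mutate DNA at a given per-base rate (test fixture helper)
mutate_dna <- function(seq, rate) {
  b <- strsplit(seq, "")[[1]]
  hit <- which(runif(length(b)) < rate)
  for (i in hit) b[i] <- sample(setdiff(c("A","C","G","T"), b[i]), 1)
  paste(b, collapse = "")
}
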