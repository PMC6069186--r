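---
title: "Detecting and interpreting endogenous circoviral elements: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and interpreting endogenous circoviral elements: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circofossil)
```

## The problem

Circoviruses are ~2 kb circular ssDNA viruses with two genes, *rep*
(replication-associated protein) and *cap* (capsid), transcribed
bidirectionally. Fragments of these genomes occasionally integrate into
host germlines and become endogenous circoviral elements (CVe) —
heritable genomic fossils. Two inferences hang on them. First, a CVe
embedded deep inside host chromosomal sequence proves the host lineage
was infected, in a way a viral read in a sequencing library never can
(libraries are easily contaminated). Second, an insertion shared
orthologously by several species must predate their divergence, turning
host phylogenies and divergence times into minimum ages for viral
lineages. `circofossil` implements the complete chain: screen assemblies
for Rep/Cap homology, annotate and classify the loci, and analyze host
associations on a Rep phylogeny.

## The screen

### Translated search

Each contig is translated in six frames under the standard genetic code
(`translate_six_frames()`); codons containing ambiguity characters
translate to `X`, and incomplete trailing codons are dropped. Probe
polypeptides are aligned against every frame translation with exact
affine-gap local alignment (Smith–Waterman with Gotoh's recurrences,
implemented in C++). A gap of length $L$ costs
$\mathrm{open} + L\cdot\mathrm{extend}$.

Exact alignment, rather than a heuristic seeded search, is a deliberate
choice: at desk scale (megabases, not the hundreds of gigabases of a
full WGS survey) exactness is affordable, removes all heuristic
nondeterminism, and makes the scorer testable against a brute-force
oracle. The cost is speed on truly genome-scale inputs, which is out of
scope here.

Multiple matches per frame are found by iterated masking: the optimal
local alignment is reported, its target span removed, and the flanking
segments re-searched until the score drops below threshold, so reported
matches never overlap within a frame. Score ties resolve toward the
smaller start coordinate, then `+` before `-` strand. All coordinates
are 0-based half-open on the forward strand internally; only exporters
convert to 1-based.

### Scoring parameters

* **Matrix**: BLOSUM62 over the 20 residues plus `X` and `*`. Every
  score involving `X` is fixed at −1: an unknown residue neither rewards
  nor severely punishes, so N-rich regions can neither generate nor
  anchor hits. `*` keeps its strongly negative BLOSUM row, which
  naturally fragments alignments at stop codons.
* **Gaps**: open 11, extend 1 — the standard protein defaults.
* **Reporting threshold** (`min_score`, default 80, raw score): a raw
  score rather than an E-value; Karlin–Altschul statistics are
  deliberately not implemented (a documented limitation — raw scores are
  not comparable across very different probe lengths). The default was
  calibrated on the empirical null: the maximum local score of a 300-aa
  probe against six-frame translations of 2 Mb of i.i.d. random DNA
  ranged 42–67 per 100 kb genome (more than half the 100-kb replicates
  exceeded 50), so a cutoff of 80 keeps the expected false-hit rate well
  under one per 10 Mb per probe while sitting far below the scores of
  genuine planted elements (a 66-codon exact match already scores ≈330).

### Classification

Matched peptides (the hit span only, no padding) are classified against
a reference library of Rep and Cap polypeptides annotated with gene,
group and host metadata: the best-scoring reference assigns gene and
group, ties breaking toward the lexicographically smaller id. The
reported `runner_up_score` is the best score among references of a
*different* group — a cross-group margin, more informative as a
classification confidence than the overall second-best (which is
usually a same-group homolog).

## Locus annotation

* **Merging** (`max_gap` = 100 nt): same-strand hits within 100 nt merge
  into one locus, reuniting fragments split by frameshifts or local
  decay. Merging is idempotent; strands never mix.
* **CVe status**: confirmed only when *both* flanks exceed 3,000 nt of
  non-locus contig sequence, strict inequality. The both-sides reading
  is the conservative interpretation for claiming germline integration —
  a match at a contig edge could be an assembly artifact of co-purified
  virus; everything not confirmed is annotated as potentially derived
  from contaminating virus rather than discarded.
* **Intactness**: protein-coding potential across the whole detected
  region — span ≥ 200 nt (raw span, gaps included), all fragments in one
  reading frame with the span a whole number of codons, and no internal
  stop in the spanning translation (a terminal stop is tolerated, since
  a complete ORF legitimately ends in one). Frame agreement between
  fragments is checked arithmetically (frames modulo 3) rather than by
  re-aligning with a frameshift-aware model: simpler, exact, and
  faithful to the fragment structure the screen produces.
* **Identifiers**: `CVe-<Group>.<n>-<SpeciesCode>`. Orthologous copies
  share `n`; new numbers continue from the registry maximum within the
  group name, allocated in a canonical order (group, species code,
  contig, start) so ids are invariant to input file order. Species codes
  come from the input manifest rather than being derived from binomials,
  avoiding collision heuristics.
* **Orthology**: two confirmed loci in different species are orthologs
  when gene and group agree and a same-side flank-vs-flank global
  alignment reaches 70% identity over a 500-nt window (identity =
  matched bases / window, match 1, mismatch −2, gap 10/2). Random flanks
  score far below 0.7 under these penalties while a few percent of
  neutral divergence leaves orthologous flanks near 1. Groups are
  connected components; both parameters are configurable.

## Host-association analysis

Input is a rooted Rep phylogeny (newick, support values as internal node
labels) with per-tip host group and evidence tier. The tier separates
*anchored* taxa — CVe in sequenced germlines and isolated viruses, whose
host is established beyond sequencing — from *metagenomic* taxa whose
label only names the sampled material.

* **Minimum host switches** (`fitch_min_transitions()`): the
  parsimony minimum number of host-group changes, computed by the
  unit-cost Sankoff recursion
  $c_v(s) = \sum_{u \in \mathrm{children}(v)} \min_t\,[c_u(t) + \mathbf{1}(s \ne t)]$.
  On binary trees this equals the classic Fitch count; we use the
  Sankoff form because it remains *exact* on multifurcations, where
  iterative pairwise set-intersection generalizations of Fitch can
  undercount (a star tree with tip states A,A,B,B needs 2 changes, but
  pairwise intersection reports 1). Exactness is what lets the
  implementation be verified against exhaustive enumeration of all
  internal labelings on small trees. Parsimony (unordered, equal costs)
  was chosen over model-based ancestral reconstruction as the
  assumption-light formalization of reading a host-colored tree.
* **Host-label inflation**: count on all tips minus count on anchored
  tips only. Pruning can never increase a parsimony minimum, so the
  statistic is non-negative, and it is 0 when metagenomic labels are
  phylogenetically unsurprising. Large values quantify how much of the
  apparent host switching is carried entirely by sequencing-only labels
  — the pattern expected if metagenomic host assignments frequently
  reflect contamination (e.g. arthropod viruses in vertebrate samples).
* **Conflict detection** (`anchored_conflicts()`): for each metagenomic
  tip, ascend to the smallest ancestor with bootstrap support above 70
  (the conventional threshold for treating a clade as resolved) that
  contains anchored tips; the consensus is the majority higher rank
  (via a caller-supplied rank map, by default at the arthropod /
  vertebrate level — the level at which contamination claims are made)
  among those anchored tips, ties giving "ambiguous" and no flag. A tip
  whose own rank contradicts the consensus is flagged. Tips with no
  supported, anchored ancestor are reported "unanchored" rather than
  guessed at.
* **Minimum ages** (`min_age_constraints()`): each ortholog group puts
  `min_age = max` pairwise host divergence on the MRCA of its carrying
  tips, and ages propagate rootward so every ancestor is at least as old
  as any constrained descendant. Singleton groups are skipped with a
  warning (one species dates nothing); a missing divergence entry is an
  error naming the pair. Only *minimum* ages are produced — branch
  lengths are never converted to time, and trees are consumed as given,
  never inferred.

## The simulator

The generator exists to make every claim above testable against planted
truth.

* **Host genomes**: i.i.d. nucleotide sequence at 42% GC (a typical
  animal genome-wide value), contig lengths fixed or normally varying.
  No repeats, isochores or codon-usage structure — deliberately, since
  the screen's guarantees should not depend on background realism, and
  the null calibration above covers composition effects on scores.
* **Reference family**: a 300-aa Rep ancestor radiated into three
  groups at 25–35% amino-acid divergence with 3 references each ~8%
  within-group, plus a smaller Cap family; probes sit ~5% from each
  group base. These depths give clearly separated groups while keeping
  cross-group alignment scores non-trivial.
* **Planted elements**: uniform-codon back-translations of reference
  peptides (100 codons by default), inserted with controlled flanks and
  strand. Decay is applied at the nucleotide level after back-
  translation, so truth labels always describe the realized sequence:
  substitutions recode whole codons non-synonymously,
  `round(stop_rate)` premature stops and `round(frameshift_rate)`
  1–2-nt indels are placed in the interior 25–75% of the element.
  Deterministic counts (rather than Poisson draws) make boundary cases
  exactly constructible; interior placement keeps both flanking
  homology segments individually detectable, so a frameshifted element
  is recovered as two fragments rather than silently truncated; and
  when several indels are applied their total length is forced off a
  multiple of 3, so the realized span always betrays the shift. Each
  dataset also plants unrelated random-peptide distractors to exercise
  classification specificity, and every plant is recorded in a truth
  table whose labels a validator re-derives from the FASTA alone.
* **Boundary grid** (`simulate_boundary_grid()`): one element per
  decision boundary — flanks 2999/3000/3001 nt on either side, spans of
  66/67 codons (198/201 nt) straddling the 200-nt intactness cutoff, and
  0/1 stops and frameshifts — all at zero substitution and screened with
  a probe equal to the planted peptide, so the aligner cannot extend
  past the planted ends and detected boundaries are exact. (Planted
  spans are codon multiples by construction; the literal 199/200-nt
  length boundary is additionally exercised directly on the intactness
  rule in the unit tests.)
* **Labelled trees**: random binary backbones with `k` host switches
  planted on random edges, every backbone tip anchored; metagenomic
  duplicates grafted as sisters of sampled tips, either *contaminants*
  (label replaced by a different group) or *clean* (label kept). Clean
  metagenomic tips are not part of the real screen's data model; they
  exist so the conflict detector's false-flag rate is measurable.
  Internal supports are drawn from 85–100, so clade ascent is exercised
  without the support threshold dominating the results (threshold
  behavior has its own fixtures).

## What passing tests do and do not show

The simulator's homogeneous background means the quoted recall and
accuracy describe the method's behavior under its own stated model —
detectable homology, honest flanks — not performance on real assemblies,
where repeats, low-complexity regions, assembly chimeras and much deeper
divergence all bite. In particular, recall of 100% at zero decay is a
correctness statement (nothing plantable is missed), not a sensitivity
claim for 100-My-old fossils; and the contamination detector's 90%+
recall presumes well-supported backbones and truly anchored neighbors.
The per-species counting consistency checks are the desk-scale analogue
of a real screen's per-species status/intactness summary, nothing more.

## Numerical and scale choices

Problem sizes throughout (3–5 species, 8–12 kb contigs, 100–300-aa
probes, 50-tip trees, 100–200 simulation replicates) were chosen so the
full test suite and the acceptance script each complete in minutes on a
single core while still crossing every decision boundary the rules
define; all are configurable upward. Determinism is absolute: every
generator is a pure function of (configuration, seed), a private RNG
stream protects the caller's state, outputs carry no timestamps, and the
GFF3/TSV writers are byte-stable across reruns — which is why the GFF3
writer is in-package (available exporters stamp a date line).

## Known limitations

* Raw-score reporting threshold; no E-values, so thresholds need
  re-calibration if probe lengths change radically.
* No frameshift-aware alignment: heavily shattered elements are
  recovered as fragment sets, and locus boundaries are the union of
  detected fragments, not a reconstructed ancestral ORF.
* Orthology rests on flank identity within a fixed window; ancient
  orthologs whose flanks have diverged past ~30% identity, or loci near
  contig edges, fall back to singletons.
* Host-switch counts are parsimony minima on the given rooted topology;
  alternative rootings or reconciliation-style event models are the
  caller's responsibility.
* Insertion dating uses host divergence only; no molecular-clock dating
  of individual insertions is attempted.
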