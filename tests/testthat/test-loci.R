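fake_hits <- function(starts, ends, strand = "+", frame = 1, score = 100,
                      contig = "c1") {
  data.frame(contig_id = contig, nt_start = starts, nt_end = ends,
             strand = strand, frame = frame, score = score,
             probe_id = "p", matched_peptide = "M",
             stringsAsFactors = FALSE)
}

test_that("hits merge across small gaps and split across large ones", {
  h <- fake_hits(c(100, 450), c(400, 700))
  one <- merge_hits_to_loci(h, max_gap = 100)
  expect_equal(nrow(one), 1)
  expect_equal(one$nt_start, 100); expect_equal(one$nt_end, 700)
  expect_equal(one$n_fragments, 2)
  two <- merge_hits_to_loci(h, max_gap = 40)
  expect_equal(nrow(two), 2)
})

test_that("opposite strands never merge and merging is idempotent", {
  h <- rbind(fake_hits(100, 400, strand = "+"),
             fake_hits(420, 700, strand = "-", frame = -1))
  loci <- merge_hits_to_loci(h, max_gap = 100)
  expect_equal(nrow(loci), 2)
  set.seed(12)
  for (i in 1:20) {
    n <- sample(1:8, 1)
    starts <- sort(sample(0:5000, n))
    ends <- starts + sample(90:600, n, replace = TRUE)
    h <- fake_hits(starts, ends,
                   strand = sample(c("+", "-"), n, replace = TRUE),
                   score = sample(80:500, n, replace = TRUE))
    m1 <- merge_hits_to_loci(h, max_gap = 100)
    # re-merge the merged loci (as hits) and expect no change
    again <- data.frame(contig_id = m1$contig, nt_start = m1$nt_start,
                        nt_end = m1$nt_end, strand = m1$strand,
                        frame = ifelse(m1$strand == "+", 1, -1),
                        score = m1$score, probe_id = "p",
                        matched_peptide = "M", stringsAsFactors = FALSE)
    m2 <- merge_hits_to_loci(again, max_gap = 100)
    expect_equal(m2$nt_start, m1$nt_start)
    expect_equal(m2$nt_end, m1$nt_end)
    expect_equal(m2$strand, m1$strand)
  }
})

test_that("status requires more than the flank threshold on both sides", {
  expect_equal(call_status(3500, 4000, 11500), "confirmed_cve")
  expect_equal(call_status(3000, 5000, 10000), "unconfirmed")  # exactly 3000
  expect_equal(call_status(0, 1500, 1500), "unconfirmed")      # whole contig
  expect_equal(call_status(3001, 6001, 9002), "confirmed_cve")
  expect_error(call_status(100, 1700, 1500), "outside")
})

test_that("growing both flanks never demotes a confirmed locus", {
  set.seed(21)
  for (i in 1:50) {
    f5 <- sample(0:6000, 1); f3 <- sample(0:6000, 1)
    span <- sample(200:900, 1)
    s1 <- call_status(f5, f5 + span, f5 + span + f3)
    extra <- sample(0:3000, 1)
    s2 <- call_status(f5 + extra, f5 + extra + span,
                      f5 + extra + span + f3 + extra)
    if (s1 == "confirmed_cve") expect_equal(s2, "confirmed_cve")
  }
})

test_that("intactness needs 200 nt, one frame, and no internal stop", {
  set.seed(22)
  pep <- random_peptide(120)            # no stops
  codons <- 3 * nchar(pep)
  contig <- paste0(random_dna(500),
                   insert_eve(random_dna(codons + 10), pep,
                              decay_model(seed = 2), 0, "+")$contig)
  # the element occupies [500, 500+360)
  mk <- function(start, end, frames = "1", strand = "+")
    list(nt_start = start, nt_end = end, frames = frames, strand = strand)
  expect_false(call_intactness(mk(500, 699), contig))   # 199 nt: too short
  expect_false(call_intactness(mk(500, 698), contig))   # 198 nt in frame
  expect_true(call_intactness(mk(500, 701), contig))    # 201 nt
  expect_true(call_intactness(mk(500, 860), contig))    # full span
  expect_false(call_intactness(mk(500, 860, frames = "1,2"), contig))
  # plant an internal stop and expect the call to flip
  stopped <- paste0(substr(contig, 1, 650), "TAA", substr(contig, 654,
                                                          nchar(contig)))
  # keep frame: positions 651-653 replaced in-frame ((650-500) %% 3 == 0)
  expect_false(call_intactness(mk(500, 860), stopped))
})

test_that("a frameshifting insertion flips intactness end to end", {
  set.seed(23)
  pep <- random_peptide(110)
  bg <- random_dna(8200)
  clean <- insert_eve(bg, pep, decay_model(seed = 5), 4000, "+")
  shifted <- insert_eve(bg, pep, decay_model(frameshift_rate = 1, seed = 5),
                        4000, "+")
  expect_true(clean$record$true_intact)
  expect_false(shifted$record$true_intact)
  sch <- scoring_scheme()
  for (case in list(clean, shifted)) {
    h <- search_translated_contig(case$contig, pep, sch, contig_id = "c1")
    loci <- merge_hits_to_loci(h)
    expect_equal(nrow(loci), 1)
    expect_equal(call_intactness(loci[1, ], case$contig),
                 case$record$true_intact)
  }
})

test_that("orthologous insertions group by shared flanks; unrelated do not", {
  set.seed(24)
  pep <- random_peptide(100)
  ancestor <- insert_eve(random_dna(8000), pep, decay_model(seed = 7),
                         4000, "+")$contig
  spA <- mutate_dna(ancestor, 0.05)
  spB <- mutate_dna(ancestor, 0.05)
  # same element also dropped at an unrelated position in an unrelated genome
  spC <- insert_eve(random_dna(8000), pep, decay_model(seed = 7),
                    2500, "+")$contig
  loci <- data.frame(
    species = c("A", "B", "C"), contig = "c1",
    nt_start = c(4000, 4000, 2500), nt_end = c(4300, 4300, 2800),
    strand = "+", assigned_gene = "rep", assigned_group = "Circovirus",
    stringsAsFactors = FALSE)
  asm <- list(A = c(c1 = spA), B = c(c1 = spB), C = c(c1 = spC))
  g <- group_orthologs(loci, asm)
  expect_equal(g$ortholog_group[1], g$ortholog_group[2])
  expect_false(g$ortholog_group[3] == g$ortholog_group[1])
  # a single species yields only singletons
  g1 <- group_orthologs(loci[1, , drop = FALSE], asm)
  expect_equal(g1$ortholog_group, 1L)
})

test_that("CVe ids follow the convention and are stable under reruns", {
  loci <- data.frame(
    species = c("spA", "spB", "spC"), contig = c("c1", "c2", "c3"),
    nt_start = c(100, 200, 300), nt_end = c(400, 500, 600), strand = "+",
    assigned_gene = "rep",
    assigned_group = c("Cyclovirus", "Cyclovirus", "Cyclovirus"),
    ortholog_group = c(1L, 1L, 2L), stringsAsFactors = FALSE)
  codes <- c(spA = "PGra", spB = "QBet", spC = "RGam")
  out <- assign_cve_ids(loci, codes)
  expect_equal(out$cve_id[1], "CVe-Cyclovirus.1-PGra")
  expect_equal(out$cve_id[2], "CVe-Cyclovirus.1-QBet")  # shared number
  expect_equal(out$cve_id[3], "CVe-Cyclovirus.2-RGam")
  # ids are invariant to input row order
  shuffled <- loci[c(3, 1, 2), ]
  out2 <- assign_cve_ids(shuffled, codes)
  expect_setequal(out2$cve_id, out$cve_id)
  # re-running against the produced registry reassigns identical ids
  reg <- data.frame(cve_id = out$cve_id, species = out$species,
                    contig = out$contig, nt_start = out$nt_start,
                    nt_end = out$nt_end, stringsAsFactors = FALSE)
  out3 <- assign_cve_ids(loci, codes, registry = reg)
  expect_identical(out3$cve_id, out$cve_id)
  # new locus continues numbering after the registry maximum
  extra <- loci[3, ]; extra$contig <- "c9"; extra$nt_start <- 900
  extra$nt_end <- 1200; extra$ortholog_group <- 3L
  out4 <- assign_cve_ids(rbind(loci, extra), codes, registry = reg)
  expect_equal(out4$cve_id[4], "CVe-Cyclovirus.3-RGam")
})

test_that("GFF3 export uses 1-based inclusive coordinates and escapes attributes", {
  loci <- data.frame(
    species = "spA", contig = "c1", nt_start = 100, nt_end = 700,
    strand = "+", n_fragments = 1L, frames = "1", score = 250,
    assigned_gene = "rep", assigned_group = "Circo;virus", flank5 = 100,
    flank3 = 300, status = "confirmed_cve", intact = TRUE,
    cve_id = "CVe-Circovirus.1-SpA", stringsAsFactors = FALSE)
  f <- withr::local_tempfile(fileext = ".gff3")
  export_loci(loci, f, format = "gff3")
  lines <- readLines(f)
  expect_equal(lines[1], "##gff-version 3")
  cols <- strsplit(lines[2], "\t")[[1]]
  expect_equal(length(cols), 9)
  expect_equal(cols[4], "101")
  expect_equal(cols[5], "700")
  expect_equal(cols[3], "endogenous_viral_element")
  expect_match(cols[9], "Circo%3Bvirus")
  expect_error(export_loci(loci, f, format = "bed"), "format|arg")
})

test_that("GFF3 output for random loci passes an independent parser", {
  skip_if_not_installed("rtracklayer")
  set.seed(25)
  n <- 50
  loci <- data.frame(
    species = sample(c("spA", "spB"), n, TRUE),
    contig = sprintf("ctg%d", sample(1:5, n, TRUE)),
    nt_start = sample(0:5000, n), strand = sample(c("+", "-"), n, TRUE),
    n_fragments = 1L, frames = "1", score = sample(80:900, n),
    assigned_gene = "rep",
    assigned_group = sample(c("Circovirus", "CRESS"), n, TRUE),
    flank5 = 0, flank3 = 0,
    status = sample(c("confirmed_cve", "unconfirmed"), n, TRUE),
    intact = sample(c(TRUE, FALSE), n, TRUE), stringsAsFactors = FALSE)
  loci$nt_end <- loci$nt_start + sample(200:900, n)
  loci$cve_id <- sprintf("CVe-%s.%d-Sp%d", loci$assigned_group, 1:n,
                         sample(1:3, n, TRUE))
  f <- withr::local_tempfile(fileext = ".gff3")
  export_loci(loci, f, format = "gff3")
  gr <- rtracklayer::import(f)
  expect_equal(length(gr), n)
  expect_equal(GenomicRanges::start(gr), loci$nt_start + 1L)
  expect_equal(GenomicRanges::end(gr), loci$nt_end)
  expect_equal(as.character(gr$type),
               rep("endogenous_viral_element", n))
  expect_equal(gr$ID, loci$cve_id)
})

test_that("locus TSV round-trips", {
  loci <- data.frame(
    species = c("spA", "spB"), contig = c("c1", "c2"),
    nt_start = c(100L, 50L), nt_end = c(700L, 450L), strand = c("+", "-"),
    n_fragments = c(1L, 2L), frames = c("1", "-2,-3"), score = c(250, 130),
    assigned_gene = "rep", assigned_group = "Circovirus",
    flank5 = c(100L, 50L), flank3 = c(300L, 20L),
    status = c("confirmed_cve", "unconfirmed"), intact = c(TRUE, FALSE),
    cve_id = c("CVe-Circovirus.1-SpA", NA), stringsAsFactors = FALSE)
  f <- withr::local_tempfile(fileext = ".tsv")
  export_loci(loci, f, format = "tsv")
  back <- read_loci_tsv(f)
  expect_equal(back$nt_start, loci$nt_start)
  expect_equal(back$nt_end, loci$nt_end)
  expect_equal(back$status, loci$status)
  expect_equal(back$intact, loci$intact)
  expect_equal(back$frames, loci$frames)
})
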