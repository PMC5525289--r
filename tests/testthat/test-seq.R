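test_that("domain architecture is derived from the RXL rule and fixed-length tails", {
  seq <- paste0(strrep("M", 15), strrep("A", 27), "RRL",
                paste0(strrep("NQ", 170), "C"), strrep("I", 20),
                strrep("K", 20))
  expect_equal(nchar(seq), 426)
  ann <- annotate_architecture(seq)
  expect_equal(ann$domains$start, c(1L, 16L, 46L, 387L, 407L))
  expect_equal(ann$domains$end, c(15L, 45L, 386L, 406L, 426L))
  # domains partition the sequence
  expect_equal(ann$domains$start[-1], ann$domains$end[-5] + 1L)
  expect_error(annotate_architecture(strrep("A", 50)), "too short")
  # non-canonical closing tripeptide warns but does not fail
  seq2 <- paste0(strrep("M", 15), strrep("A", 28), "KL",
                 strrep("NQ", 170), "C", strrep("I", 20), strrep("K", 20))
  expect_warning(annotate_architecture(seq2, sp_end = 15), "RRL")
})

test_that("the bundled synthetic silicanin reproduces the published statistics", {
  fa <- system.file("extdata", "sin1_B8CBQ8_synthetic.fasta",
                    package = "silitrace")
  seqs <- read_protein(fa)
  seq <- seqs[[1]]
  expect_equal(nchar(seq), 426)
  ann <- annotate_architecture(seq)
  expect_equal(ann$domains$end - ann$domains$start + 1L,
               c(15L, 30L, 341L, 20L, 20L))
  lum <- composition_stats(seq, c(25, 383))
  expect_equal(lum$counts[["C"]], 18L)
  expect_equal(lum$acidic_percent, 14)
  expect_equal(find_motif(seq), 276L)
  expect_gt(nrow(nq_clusters(seq)), 0)
  pI <- isoelectric_point(seq, c(25, 383))
  expect_lt(pI, 5)
})

test_that("NQ clusters are maximal merged windows above the fraction threshold", {
  cl <- nq_clusters("NQNQNQNQNQ", window = 10)
  expect_equal(cl, data.frame(start = 1L, end = 10L))
  expect_equal(nrow(nq_clusters(strrep("A", 40))), 0)
  # planted clusters in an NQ-free background are recovered without
  # spurious calls
  bg_letters <- c("A", "S", "T", "G", "V")
  for (s in 1:20) {
    set.seed(s)
    bg <- sample(bg_letters, 200, replace = TRUE)
    bg[51:60] <- strsplit("NNQQNQNNQQ", "")[[1]]
    bg[121:130] <- strsplit("QQNNQNQQNN", "")[[1]]
    cl <- nq_clusters(paste0(bg, collapse = ""))
    expect_equal(nrow(cl), 2)
    expect_true(cl$start[1] <= 51 && cl$end[1] >= 60)
    expect_true(cl$start[2] <= 121 && cl$end[2] >= 130)
    # clusters cannot extend further than one window beyond the plants
    expect_true(cl$start[1] > 51 - 10 && cl$end[1] < 60 + 10)
  }
})

test_that("motif search is exact, 1-based and overlap-aware", {
  expect_equal(find_motif("AAGGQKFALAA"), 3L)
  expect_equal(find_motif("AAAAGGQK"), integer(0))
  expect_equal(find_motif("AAAA", motif = "AAA"), c(1L, 2L))
})

test_that("composition statistics count residues exactly", {
  cs <- composition_stats("DDEEGGGG")
  expect_equal(cs$acidic_fraction, 0.5)
  expect_equal(cs$acidic_percent, 50)
  expect_equal(composition_stats("CCCC")$counts[["C"]], 4L)
  expect_error(composition_stats("ACDE", c(2, 9)), "interval")
})

test_that("the isoelectric point is a zero of the net-charge function", {
  # two-group closed form: glycine peptide with only the termini ionizable
  pka <- pka_table_default()
  expect_equal(isoelectric_point("GGGGG"),
               (pka[["Nterm"]] + pka[["Cterm"]]) / 2, tolerance = 1e-3)
  expect_lt(isoelectric_point("DDDDDDDDDD"), 5)
  set.seed(23)
  for (i in 1:50) {
    pep <- random_peptide(sample(5:40, 1))
    pI <- isoelectric_point(pep)
    expect_lt(abs(protein_net_charge(pep, pI)), 0.01)
  }
})

test_that("global identity matches the brute-force alignment oracle", {
  expect_equal(pairwise_identity("MKVLNQERT", "MKVLNQERT")$percent_identity,
               100)
  expect_equal(pairwise_identity("ACDE", "ACDF")$percent_identity, 75)
  submat <- getFromNamespace(".blosum62", "silitrace")()
  set.seed(41)
  for (i in 1:200) {
    a <- random_peptide(sample(3:30, 1))
    b <- random_peptide(sample(3:30, 1))
    got <- pairwise_identity(a, b)
    want <- oracle_align(a, b, submat, 11, 1)
    expect_equal(got$score, want$score)
    expect_equal(got$identities, want$identities)
    expect_equal(got$columns, want$columns)
    expect_equal(got$percent_identity, want$percent_identity)
  }
})

test_that("identity is symmetric and cross-checks against Biostrings scores", {
  data(BLOSUM62, package = "Biostrings", envir = environment())
  set.seed(59)
  for (i in 1:25) {
    a <- random_peptide(sample(5:40, 1))
    b <- random_peptide(sample(5:40, 1))
    got_ab <- pairwise_identity(a, b)
    got_ba <- pairwise_identity(b, a)
    expect_equal(got_ab$percent_identity, got_ba$percent_identity)
    aln <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                         substitutionMatrix = BLOSUM62,
                                         gapOpening = 11, gapExtension = 1)
    expect_equal(got_ab$score, Biostrings::score(aln))
  }
})

test_that("homolog screening keeps hits strictly below the E-value threshold", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_blast_tab(tmp, list(
    blast_row("Thalassiosira_pseudonana|c1", 1e-60),
    blast_row("Thalassiosira_pseudonana|c2", 1e-55),
    blast_row("Cyclotella_cryptica|c9", 1e-40)))
  res <- screen_homologs(tmp)
  expect_equal(res$n_hits, 2)
  expect_equal(res$n_species, 1)   # both kept hits share one species tag
  # empty input
  tmp2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(character(0), tmp2)
  expect_equal(screen_homologs(tmp2)$n_hits, 0)
  # malformed rows are skipped with a warning, the rest still parse
  tmp3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(paste(blast_row("Navicula_sp|c3", 1e-70), collapse = "\t"),
               "broken\trow"), tmp3)
  expect_warning(res3 <- screen_homologs(tmp3), "malformed")
  expect_equal(res3$n_hits, 1)
  # boundary: exactly at the threshold is excluded
  df <- data.frame(sseqid = c("A|x", "B|y"), evalue = c(1e-50, 0.9e-50))
  expect_equal(screen_homologs(df)$n_hits, 1)
})
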