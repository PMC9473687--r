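test_that("translation annotates residues with the exon(s) their codon touches", {
  m <- build_exon_model("ATGGCTAAATAG",
                        data.frame(index = 1:2, start = c(1, 7), end = c(6, 12)))
  expect_equal(m$protein, "MAK")
  expect_equal(m$residue_exons, list(1L, 1L, 2L))
  expect_equal(m$cds_end, 12L)

  # codon GCT spans nts 4-6 across the 4|5 junction
  m2 <- build_exon_model("ATGGCTAAATAG",
                         data.frame(index = 1:2, start = c(1, 5), end = c(4, 12)))
  expect_equal(m2$residue_exons[[2]], c(1L, 2L))

  # stop codon terminates translation; trailing sequence ignored
  m3 <- build_exon_model("ATGTAGGGGCCC",
                         data.frame(index = 1, start = 1, end = 12))
  expect_equal(m3$protein, "M")
})

test_that("boundary tiling violations and bad CDS offsets are structural errors", {
  expect_error(
    build_exon_model("ATGGCTAAATAG",
                     data.frame(index = 1:2, start = c(1, 8), end = c(6, 12))),
    "gap or overlap")
  expect_error(
    build_exon_model("ATGGCTAAATAG",
                     data.frame(index = 1:2, start = c(1, 6), end = c(6, 12))),
    "gap or overlap")
  expect_error(
    build_exon_model("ATGGCTAAATAG",
                     data.frame(index = 1, start = 1, end = 12), cds_start = 99),
    "cds_start")
  expect_error(
    build_exon_model("TAGGCTAAATAG",
                     data.frame(index = 1, start = 1, end = 12)),
    "stop")
})

test_that("renumbering maps transcript exons onto the genomic scheme", {
  m <- build_exon_model("ATGCCC",
                        data.frame(index = 1:2, start = c(1, 4), end = c(3, 6)))
  r <- renumber_exons(m, genomic_exon_seqs = c("ATG", "AAA", "CCC"))
  expect_equal(r$exons$genomic_number, c(1L, 3L))
  # residue annotations follow the renumbering
  expect_equal(r$residue_exons[[2]], 3L)

  # identity mapping table leaves numbering unchanged
  r2 <- renumber_exons(m, mapping = data.frame(index = 1:2,
                                               genomic_number = 1:2))
  expect_equal(r2$exons$genomic_number, m$exons$genomic_number)

  # unmatched and ambiguous exact matches are errors
  expect_error(renumber_exons(m, genomic_exon_seqs = c("ATG", "GGG")),
               "no exact genomic match")
  expect_error(renumber_exons(m, genomic_exon_seqs = c("ATG", "CCC", "CCC")),
               "ambiguous")
  expect_warning(
    rp <- renumber_exons(m, genomic_exon_seqs = c("ATG", "GGG"),
                         allow_partial = TRUE),
    "no exact genomic match")
  expect_true(is.na(rp$exons$genomic_number[2]))
})

test_that("exact-sequence renumbering is idempotent", {
  m <- build_exon_model("ATGCCCAAA",
                        data.frame(index = 1:3, start = c(1, 4, 7),
                                   end = c(3, 6, 9)))
  glist <- c("TTT", "ATG", "GGG", "CCC", "AAA")
  r1 <- renumber_exons(m, genomic_exon_seqs = glist)
  r2 <- renumber_exons(r1, genomic_exon_seqs = glist)
  expect_identical(r1$exons$genomic_number, r2$exons$genomic_number)
  expect_identical(r1$residue_exons, r2$residue_exons)
})

test_that("tryptic digestion follows the K/R-not-before-P rule", {
  bounds <- function(n) data.frame(index = 1, start = 1, end = n)
  prot_to_model <- function(p) {
    codon_of <- vapply(strsplit(p, "")[[1]], function(a) {
      names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE == a][1]
    }, character(1))
    nt <- paste(codon_of, collapse = "")
    build_exon_model(nt, bounds(nchar(nt)))
  }
  m <- prot_to_model("MAKRPGK")
  expect_equal(digest_tryptic(m, 0)$sequence, c("MAK", "RPGK"))

  # no K/R at all: the whole protein is one peptide
  m2 <- prot_to_model("MAGGHIL")
  expect_equal(digest_tryptic(m2, 0)$sequence, "MAGGHIL")

  # one missed cleavage enumerates adjacent fragment concatenations
  m3 <- prot_to_model("MAKRGK")
  d <- digest_tryptic(m3, 1)
  expect_setequal(d$sequence, c("MAK", "R", "GK", "MAKR", "RGK"))
  expect_true(all(c("MAKR", "RGK", "MAK", "GK") %in% d$sequence))
})

test_that("digestion round-trips random transcripts and peptides carry exon sets", {
  set.seed(42)
  for (i in 1:20) {
    tr <- random_transcript(n_res = sample(20:80, 1),
                            n_exons = sample(2:6, 1))
    m <- build_exon_model(tr$seq, tr$boundaries)
    expect_equal(m$protein, tr$protein)
    d <- digest_tryptic(m, 0)
    expect_equal(paste(d$sequence, collapse = ""), tr$protein)
    # coverage: residues jointly touch every CDS-overlapping exon
    expect_setequal(unique(unlist(d$exon_set)),
                    unique(unlist(m$residue_exons)))
  }
})

test_that("peptide mapping agrees with a brute-force substring scan", {
  tr <- random_transcript(n_res = 50, n_exons = 3, seed = 7)
  m <- build_exon_model(tr$seq, tr$boundaries)
  for (start in c(1, 10, 31)) {
    pep <- substring(m$protein, start, start + 5)
    mp <- map_peptide_to_exons(pep, m)
    expect_equal(mp$loci, oracle_find_all(pep, m$protein))
    expect_equal(mp$exon_set,
                 sort(unique(unlist(m$residue_exons[mp$start_res:mp$end_res]))))
  }
  expect_error(map_peptide_to_exons("WWWWWWWW", m), "not found")
})

test_that("repeated peptides report all loci and the union exon set", {
  # protein = ABCK | fill | ABCK with the two copies in different exons
  p1 <- "MAGK"; fill <- "DEFGHIK"
  prot <- paste0(p1, fill, p1)
  codon_of <- vapply(strsplit(prot, "")[[1]], function(a) {
    names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE == a][1]
  }, character(1))
  nt <- paste(codon_of, collapse = "")
  n <- nchar(nt)
  m <- build_exon_model(nt, data.frame(index = 1:2, start = c(1, 13),
                                       end = c(12, n)))
  mp <- map_peptide_to_exons("MAGK", m)
  expect_equal(mp$n_loci, 2L)
  expect_equal(mp$exon_set, c(1L, 2L))
  d <- digest_tryptic(m, 0)
  expect_equal(d$n_loci[d$sequence == "MAGK"], c(2L, 2L))
})

test_that("exon models survive a JSON round trip", {
  tr <- random_transcript(n_res = 30, n_exons = 3, seed = 9)
  m <- build_exon_model(tr$seq, tr$boundaries)
  path <- withr::local_tempfile(fileext = ".json")
  write_exon_model(m, path)
  m2 <- read_exon_model(path)
  expect_equal(m2$protein, m$protein)
  expect_equal(m2$residue_exons, m$residue_exons)
  expect_equal(m2$exons$genomic_number, m$exons$genomic_number)
})
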