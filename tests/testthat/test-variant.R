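refSeq <- function(n) paste(rep("A", n), collapse = "")

test_that("diploid decoding follows the IUPAC ambiguity convention", {
  g <- genotypeColumn(c("A", "R", "G", "N"))
  expect_identical(g$alleles[1, ], c("A", "A"))
  expect_identical(g$alleles[2, ], c("A", "G"))
  expect_identical(g$alleles[3, ], c("G", "G"))
  expect_true(all(is.na(g$alleles[4, ])))
  expect_false(g$multiAllelic)
  multi <- genotypeColumn(c(rep("A", 5), rep("G", 2), "C"))
  expect_true(multi$multiAllelic)
  expect_error(genotypeColumn(c("A", "B")), class = "formatError")
})

test_that("alignment reading validates shape, symbols and headers", {
  seqs <- c("S1|P1" = "ACGT", "S2|P1" = "ACGA", "S3|P2" = "RCGT")
  aln <- readAlignment(seqs)
  expect_length(aln, 3)
  expect_identical(S4Vectors::metadata(aln)$locality,
                   c("P1", "P1", "P2"))
  expect_error(readAlignment(c("S1|P1" = "ACGT", "S2|P1" = "ACG")),
               class = "formatError")
  bad <- c("S1|P1" = "ABGT", "S2|P1" = "ACGT")
  expect_error(readAlignment(bad), class = "formatError")
  expect_error(readAlignment(bad), "S1\\|P1")
  expect_error(readAlignment(c("S1" = "ACGT")), class = "formatError")
})

test_that("the carrier rule calls a SNP only when >3 specimens carry it", {
  # 10 specimens; make the variant present in exactly k specimens
  mkAln <- function(k, het = FALSE) {
    mat <- matrix("A", nrow = 10, ncol = 5)
    mat[seq_len(k), 3] <- if (het) "R" else "G"
    alnFromMatrix(mat, rep(c("P1", "P2"), each = 5))
  }
  ann <- fragmentAnnotation(2, 3, 0, refSeq(5))
  expect_identical(nrow(callSnps(mkAln(3), ann)$snps), 0L)
  expect_identical(nrow(callSnps(mkAln(4), ann)$snps), 1L)
  # heterozygotes count as carrying specimens
  expect_identical(nrow(callSnps(mkAln(4, het = TRUE), ann)$snps), 1L)
  expect_identical(nrow(callSnps(mkAln(3, het = TRUE), ann)$snps), 0L)
  called <- callSnps(mkAln(5), ann)$snps
  expect_identical(called$carriers, 5L)
  expect_identical(called$ref, "A")
  expect_identical(called$alt, "G")
  # monomorphic alignment
  expect_identical(nrow(callSnps(mkAln(0), ann)$snps), 0L)
})

test_that("multi-allelic columns are excluded with a warning", {
  mat <- matrix("A", nrow = 10, ncol = 4)
  mat[1:4, 2] <- "G"
  mat[5:8, 2] <- "C"
  aln <- alnFromMatrix(mat, rep("P1", 10))
  expect_warning(calls <- callSnps(aln, fragmentAnnotation(4, 0, 0,
                                                           refSeq(4))),
                 "multi-allelic")
  expect_identical(nrow(calls$snps), 0L)
})

test_that("calling is invariant to specimen order and sequence case", {
  set.seed(5)
  mat <- matrix(sample(c("A", "G", "R"), 80, replace = TRUE,
                       prob = c(0.6, 0.25, 0.15)), nrow = 16)
  locs <- rep(c("P1", "P2"), each = 8)
  ann <- fragmentAnnotation(2, 3, 0, refSeq(5))
  a1 <- callSnps(alnFromMatrix(mat, locs), ann)
  perm <- sample(16)
  a2 <- callSnps(alnFromMatrix(mat[perm, ], locs[perm]), ann)
  expect_identical(a1$snps, a2$snps)
  lower <- alnFromMatrix(matrix(tolower(mat), nrow = 16), locs)
  expect_identical(callSnps(lower, ann)$snps, a1$snps)
})

test_that("region labels count back from the intron/exon boundary", {
  ann <- fragmentAnnotation(829, 849, 0, refSeq(1678))
  expect_identical(classifyRegion(671, ann)$positionLabel, -158L)
  expect_identical(classifyRegion(828, ann)$positionLabel, -1L)
  expect_identical(classifyRegion(829, ann)$positionLabel, 1L)
  expect_identical(classifyRegion(671, ann)$region, "INTRONIC")
  all <- classifyRegion(0:1677, ann)
  expect_identical(sum(all$region == "INTRONIC"), 829L)
  expect_false(anyDuplicated(all$positionLabel) > 0)
  byRegion <- split(all$positionLabel, all$region)
  expect_true(all(vapply(byRegion, function(v) all(diff(v) > 0),
                         logical(1))))
  expect_error(classifyRegion(1678, ann), class = "inputError")
})

test_that("coding effect translates ref and alt codons correctly", {
  ann <- fragmentAnnotation(0, 9, 0, "GGAATGAAA")
  expect_identical(codingEffect(2, "G", ann), "SYNONYMOUS")   # GGA>GGG
  expect_identical(codingEffect(5, "A", ann), "NONSYNONYMOUS") # ATG>ATA
  # frame offset shifts the codon grid
  ann1 <- fragmentAnnotation(0, 9, 1, "GGAATGAAA")
  expect_warning(expect_identical(codingEffect(0, "C", ann1),
                                  NA_character_))
  # codon containing N
  annN <- fragmentAnnotation(0, 6, 0, "GGNATG")
  expect_warning(expect_identical(codingEffect(2, "G", annN),
                                  NA_character_))
  expect_error(codingEffect(2, "G", fragmentAnnotation(5, 4, 0,
                                                       refSeq(9))),
               class = "inputError")
})

test_that("coding effect agrees with an independent translation oracle", {
  skip_if_not_installed("seqinr")
  set.seed(31)
  bases <- c("A", "C", "G", "T")
  for (i in 1:100) {
    codon <- sample(bases, 3, replace = TRUE)
    pos <- sample(0:2, 1)
    alt <- sample(setdiff(bases, codon[pos + 1]), 1)
    ann <- fragmentAnnotation(0, 3, 0, paste(codon, collapse = ""))
    got <- codingEffect(pos, alt, ann)
    mut <- codon
    mut[pos + 1] <- alt
    same <- identical(
      seqinr::translate(tolower(codon)),
      seqinr::translate(tolower(mut)))
    expect_identical(got, if (same) "SYNONYMOUS" else "NONSYNONYMOUS")
  }
})

test_that("population allele frequencies aggregate diploid dosages", {
  # P1: A/A, A/G, A/G, G/G -> alt G frequency 0.5
  # P2: all A/A -> 0 ; P3: R, R, A, A -> 0.25
  mat <- matrix("A", nrow = 12, ncol = 6)
  mat[2, 2] <- "R"; mat[3, 2] <- "R"; mat[4, 2] <- "G"
  mat[9, 2] <- "R"; mat[10, 2] <- "R"
  locs <- rep(c("P1", "P2", "P3"), each = 4)
  ann <- fragmentAnnotation(3, 3, 0, refSeq(6))
  calls <- callSnps(alnFromMatrix(mat, locs), ann)
  localities <- data.frame(id = c("P1", "P2", "P3"),
                           latitude = c(45, 50, 55),
                           longitude = 0, altitude = 100,
                           lineage = "WEST")
  set <- snpFrequencySet(calls, localities)
  f <- alleleFrequencies(set)
  expect_equal(unname(f["P1", 1]), 0.5)
  expect_equal(unname(f["P2", 1]), 0)
  expect_equal(unname(f["P3", 1]), 0.25)
  expect_true(all(f >= 0 & f <= 1, na.rm = TRUE))
  # per-population alt counts sum to the global allele count
  alt <- SummarizedExperiment::assay(set, "altCount")
  expect_equal(sum(alt), sum(calls$dosage, na.rm = TRUE))
  expect_error(snpFrequencySet(calls, localities[1:2, ]),
               class = "inputError")
})

test_that("missing genotypes drop out of numerator and denominator", {
  mat <- matrix("A", nrow = 8, ncol = 4)
  mat[1:5, 2] <- "G"
  mat[6, 2] <- "N"
  calls <- callSnps(alnFromMatrix(mat, rep("P1", 8)),
                    fragmentAnnotation(2, 2, 0, refSeq(4)))
  localities <- data.frame(id = "P1", latitude = 45, longitude = 0,
                           altitude = 0, lineage = "WEST")
  set <- snpFrequencySet(calls, localities)
  expect_equal(unname(alleleFrequencies(set)[1, 1]), 10 / 14)
  expect_equal(unname(sampleSizes(set)[1, 1]), 7)
})
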