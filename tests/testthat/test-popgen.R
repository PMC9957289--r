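mkSet <- function(freq, n, lineage = NULL) {
  # build a SnpFrequencySet directly from a pop x locus frequency
  # matrix and diploid sample sizes (same shape or scalar)
  pops <- rownames(freq)
  if (is.null(pops)) pops <- paste0("P", seq_len(nrow(freq)))
  L <- ncol(freq)
  nMat <- matrix(n, nrow(freq), L)
  alt <- t(round(freq * 2 * nMat))
  tot <- t(2 * nMat)
  f <- alt / tot
  dimnames(alt) <- dimnames(tot) <- dimnames(f) <-
    list(paste0("L", seq_len(L)), pops)
  if (is.null(lineage)) lineage <- rep("WEST", length(pops))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(altCount = alt, totalCount = tot, freq = f),
    rowData = S4Vectors::DataFrame(
      positionLabel = seq_len(L), region = rep("INTRONIC", L),
      carriers = rep(10L, L), row.names = paste0("L", seq_len(L))),
    colData = S4Vectors::DataFrame(lineage = lineage,
                                   row.names = pops))
  new("SnpFrequencySet", se)
}

test_that("G_ST is zero for identical populations and one at fixation", {
  expect_identical(neiGst(c(0.3, 0.7), c(0.3, 0.7), 10, 10), 0)
  expect_gt(neiGst(0, 1, 500, 500), 0.99)
  # both monomorphic and identical -> 0 by convention
  expect_identical(neiGst(c(0, 1), c(0, 1), 10, 10), 0)
  expect_error(neiGst(NA_real_, NA_real_, 10, 10), class = "inputError")
})

test_that("G_ST matches the symbol-by-symbol oracle", {
  expect_equal(neiGst(0.2, 0.8, 10, 10), oracleGst(0.2, 0.8, 10, 10),
               tolerance = 1e-12)
  set.seed(41)
  for (i in 1:25) {
    L <- sample(3:8, 1)
    pA <- runif(L)
    pB <- runif(L)
    nA <- sample(4:30, L, replace = TRUE)
    nB <- sample(4:30, L, replace = TRUE)
    got <- neiGst(pA, pB, nA, nB)
    expect_equal(got, oracleGst(pA, pB, nA, nB), tolerance = 1e-12)
    expect_identical(got, neiGst(pB, pA, nB, nA))  # symmetry
    expect_true(got >= 0 && got <= 1)
    # a locus monomorphic in both populations changes nothing
    expect_equal(neiGst(c(pA, 0), c(pB, 0), c(nA, 10), c(nB, 10)), got)
  }
})

test_that("the F_ST matrix is symmetric, bounded and relabeling-invariant", {
  set.seed(43)
  freq <- matrix(runif(5 * 8), 5, 8,
                 dimnames = list(paste0("P", 1:5), NULL))
  set <- mkSet(freq, n = 12)
  m <- fstMatrix(set)
  expect_identical(m, t(m))
  expect_true(all(diag(m) == 0))
  expect_true(all(m >= 0 & m <= 1))
  perm <- c(3, 1, 5, 2, 4)
  mp <- fstMatrix(mkSet(freq[perm, ], n = 12))
  expect_equal(mp, m[perm, perm])
  # identical populations -> zero matrix
  z <- fstMatrix(mkSet(rbind(Q1 = freq[1, ], Q2 = freq[1, ]), n = 12))
  expect_equal(unname(z), matrix(0, 2, 2))
})

test_that("F_ST block summaries separate lineages", {
  freq <- rbind(P1 = c(0.05, 0.1), P2 = c(0.1, 0.05),
                P3 = c(0.9, 0.95), P4 = c(0.95, 0.9))
  set <- mkSet(freq, n = 20, lineage = c("WEST", "WEST", "EAST", "EAST"))
  m <- fstMatrix(set)
  s <- fstSummary(m, c("WEST", "WEST", "EAST", "EAST"))
  expect_setequal(s$block, c("overall", "within-WEST", "within-EAST",
                             "between-lineages"))
  between <- s$mean[s$block == "between-lineages"]
  within <- s$mean[grepl("within", s$block)]
  expect_true(all(between > within))
  expect_identical(s$nPairs[s$block == "overall"], 6L)
})

test_that("composite LD r2 matches hand-computed correlations", {
  expect_equal(compositeLdR2(c(0, 1, 2, 2, 0), c(0, 1, 2, 2, 0)), 1)
  expect_equal(compositeLdR2(c(0, 2, 0, 2), c(0, 0, 2, 2)), 0)
  hand <- cor(c(0, 1, 2, 2, 0), c(0, 1, 1, 2, 0))^2
  expect_equal(compositeLdR2(c(0, 1, 2, 2, 0), c(0, 1, 1, 2, 0)), hand)
  expect_true(is.na(compositeLdR2(c(1, 1, 1), c(0, 1, 2))))
  # pairwise deletion of missing specimens
  expect_equal(compositeLdR2(c(0, 1, 2, NA), c(0, 1, 2, 0)), 1)
})

test_that("composite r2 equals D^2/(p q p q) on phased-equivalent data", {
  # homozygous-only specimens: dosages 0/2 are two identical haplotypes,
  # so the composite measure must equal the haplotype-based r2
  set.seed(47)
  for (i in 1:20) {
    n <- 40
    hapI <- rbinom(n, 1, 0.5)
    hapJ <- ifelse(runif(n) < 0.7, hapI, rbinom(n, 1, 0.5))
    if (var(hapI) == 0 || var(hapJ) == 0) next
    pI <- mean(hapI); pJ <- mean(hapJ)
    D <- mean(hapI * hapJ) - pI * pJ
    r2hap <- D^2 / (pI * (1 - pI) * pJ * (1 - pJ))
    expect_equal(compositeLdR2(2 * hapI, 2 * hapJ), r2hap,
                 tolerance = 1e-12)
  }
})

test_that("the LD matrix over called SNPs is symmetric with unit diagonal", {
  set.seed(49)
  mat <- matrix(sample(c("A", "G", "R"), 200, replace = TRUE,
                       prob = c(0.5, 0.3, 0.2)), nrow = 20)
  calls <- suppressWarnings(
    callSnps(alnFromMatrix(mat, rep(c("P1", "P2"), each = 10)),
             fragmentAnnotation(5, 5, 0,
                                paste(rep("A", 10), collapse = ""))))
  locs <- data.frame(id = c("P1", "P2"), latitude = c(45, 50),
                     longitude = 0, altitude = 0, lineage = "WEST")
  ld <- ldMatrix(snpFrequencySet(calls, locs))
  expect_identical(ld, t(ld))
  expect_true(all(diag(ld) == 1))
  expect_true(all(ld >= 0 & ld <= 1, na.rm = TRUE))
})

test_that("neighbor joining recovers a 4-taxon additive tree exactly", {
  # tree ((A:2,B:3):1,(C:4,D:5)) -> additive distances
  d <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  a <- 2; b <- 3; cc <- 4; dd <- 5; m <- 1
  d["A", "B"] <- d["B", "A"] <- a + b
  d["A", "C"] <- d["C", "A"] <- a + m + cc
  d["A", "D"] <- d["D", "A"] <- a + m + dd
  d["B", "C"] <- d["C", "B"] <- b + m + cc
  d["B", "D"] <- d["D", "B"] <- b + m + dd
  d["C", "D"] <- d["D", "C"] <- cc + dd
  tr <- njTree(d)
  # oracle: the four-point condition picks the AB|CD split
  sums <- c(AB.CD = d["A", "B"] + d["C", "D"],
            AC.BD = d["A", "C"] + d["B", "D"],
            AD.BC = d["A", "D"] + d["B", "C"])
  expect_identical(names(which.min(sums)), "AB.CD")
  # additive matrix -> patristic distances reproduce the input exactly
  coph <- ape::cophenetic.phylo(tr)[rownames(d), colnames(d)]
  expect_equal(coph, d, tolerance = 1e-12)
  expect_setequal(tr$tip.label, LETTERS[1:4])
})

test_that("neighbor joining handles degenerate input and relabeling", {
  z <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tz <- suppressMessages(njTree(z))
  expect_true(all(tz$edge.length == 0))
  expect_error(njTree(matrix(0, 2, 2, dimnames = list(c("A", "B"),
                                                      c("A", "B")))),
               class = "inputError")
  set.seed(53)
  pts <- matrix(runif(12), 6, 2)
  d <- as.matrix(dist(pts))
  dimnames(d) <- list(paste0("P", 1:6), paste0("P", 1:6))
  t1 <- njTree(d)
  perm <- sample(6)
  t2 <- njTree(d[perm, perm])
  splits <- function(tr) {
    pp <- ape::prop.part(tr)
    labs <- attr(pp, "labels")
    sort(vapply(pp, function(s) paste(sort(labs[s]), collapse = ","),
                character(1)))
  }
  expect_identical(splits(ape::unroot(t1)), splits(ape::unroot(t2)))
})

test_that("population trees carry all populations and valid Newick", {
  set.seed(59)
  freq <- matrix(runif(4 * 6), 4, 6,
                 dimnames = list(paste0("P", 1:4), NULL))
  set <- mkSet(freq, n = 15)
  for (distance in c("fst", "da")) {
    pt <- populationTree(set, distance)
    expect_setequal(pt$tree$tip.label, paste0("P", 1:4))
    reread <- ape::read.tree(text = pt$newick)
    expect_setequal(reread$tip.label, paste0("P", 1:4))
    expect_true(all(pt$tree$edge.length >= 0))
  }
})
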