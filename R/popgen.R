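#' Multilocus Nei G_ST between two populations
#'
#' Unbiased Nei/Chesser-style G_ST for biallelic loci, with small-sample
#' correction. Per locus, with alternative-allele frequencies `pA`, `pB`
#' and diploid sample sizes `nA`, `nB`:
#' within-population heterozygosity
#' `H_S = mean_i (2 n_i / (2 n_i - 1)) * 2 p_i q_i`;
#' total heterozygosity from the unweighted mean frequency
#' `H_T = (2 nh / (2 nh - 1)) * 2 pbar qbar`, where `nh` is the harmonic
#' mean of `nA` and `nB` (so identical populations of equal size give
#' exactly 0). The multilocus value is
#' `(sum H_T - sum H_S) / sum H_T` over loci polymorphic in the union of
#' the two populations; negative estimates are clamped to 0.
#'
#' @param pA,pB numeric vectors of alt-allele frequencies per locus.
#' @param nA,nB diploid sample sizes per locus (scalar or vector).
#' @return G_ST in \[0, 1\]. Two populations monomorphic and identical at
#'   every shared locus return 0 by convention.
#' @examples
#' neiGst(0.2, 0.8, 10, 10)
#' @export
neiGst <- function(pA, pB, nA, nB) {
  k <- length(pA)
  nA <- rep_len(nA, k)
  nB <- rep_len(nB, k)
  ok <- is.finite(pA) & is.finite(pB) & nA >= 1 & nB >= 1
  if (!any(ok))
    .pcError("no shared genotyped loci between the two populations",
             "inputError")
  pA <- pA[ok]; pB <- pB[ok]; nA <- nA[ok]; nB <- nB[ok]
  pbar <- (pA + pB) / 2
  poly <- pbar > 0 & pbar < 1   # polymorphic in the union of the pair
  if (!any(poly)) return(0)
  pA <- pA[poly]; pB <- pB[poly]; nA <- nA[poly]; nB <- nB[poly]
  pbar <- pbar[poly]
  hS <- ((2 * nA / (2 * nA - 1)) * 2 * pA * (1 - pA) +
         (2 * nB / (2 * nB - 1)) * 2 * pB * (1 - pB)) / 2
  nh <- 2 / (1 / nA + 1 / nB)
  hT <- (2 * nh / (2 * nh - 1)) * 2 * pbar * (1 - pbar)
  gst <- (sum(hT) - sum(hS)) / sum(hT)
  min(max(gst, 0), 1)
}

#' Pairwise multilocus G_ST from a SnpFrequencySet
#'
#' @param x a [SnpFrequencySet-class].
#' @param popA,popB population (locality) ids.
#' @return Multilocus G_ST for the pair (see [neiGst()]).
#' @export
pairwiseFst <- function(x, popA, popB) {
  stopifnot(is(x, "SnpFrequencySet"))
  f <- assay(x, "freq")
  n <- assay(x, "totalCount") / 2
  if (!all(c(popA, popB) %in% colnames(f)))
    .pcError("unknown population id", "inputError")
  neiGst(f[, popA], f[, popB], n[, popA], n[, popB])
}

#' Full pairwise multilocus F_ST matrix
#'
#' Symmetric population-by-population matrix of multilocus Nei G_ST
#' values, with zero diagonal.
#'
#' @param x a [SnpFrequencySet-class] with at least 2 populations.
#' @return Symmetric numeric matrix with population ids as dimnames.
#' @seealso [fstSummary()] for block summaries, [populationTree()] for a
#'   neighbor-joining tree on this matrix.
#' @export
fstMatrix <- function(x) {
  stopifnot(is(x, "SnpFrequencySet"))
  pops <- colnames(x)
  if (length(pops) < 2L)
    .pcError("need at least 2 populations", "inputError")
  m <- matrix(0, length(pops), length(pops),
              dimnames = list(pops, pops))
  for (i in seq_along(pops)[-1])
    for (j in seq_len(i - 1)) {
      v <- pairwiseFst(x, pops[i], pops[j])
      m[i, j] <- m[j, i] <- v
    }
  m
}

#' Lineage-block summaries of a pairwise F_ST matrix
#'
#' Min/max/mean of the pairwise values overall, within each lineage, and
#' between lineages.
#'
#' @param fst symmetric matrix from [fstMatrix()].
#' @param lineage character vector of lineage labels, one per
#'   population, in matrix order (e.g. "WEST"/"EAST").
#' @return data.frame with columns `block, nPairs, min, mean, max`.
#' @export
fstSummary <- function(fst, lineage) {
  stopifnot(nrow(fst) == length(lineage))
  pairs <- which(lower.tri(fst), arr.ind = TRUE)
  v <- fst[pairs]
  la <- lineage[pairs[, 1]]
  lb <- lineage[pairs[, 2]]
  block <- ifelse(la == lb, paste0("within-", la), "between-lineages")
  blocks <- c("overall", sort(unique(block)))
  out <- lapply(blocks, function(b) {
    sel <- if (b == "overall") rep(TRUE, length(v)) else block == b
    data.frame(block = b, nPairs = sum(sel), min = min(v[sel]),
               mean = mean(v[sel]), max = max(v[sel]))
  })
  do.call(rbind, out)
}

#' Composite linkage-disequilibrium r-squared
#'
#' Squared Pearson correlation of per-specimen alternative-allele
#' dosages (0/1/2) at two sites -- the composite, phase-free LD measure
#' appropriate for unphased Sanger-consensus genotypes. Specimens
#' missing either genotype are dropped pairwise.
#'
#' @param dosageI,dosageJ numeric dosage vectors over the same
#'   specimens.
#' @return r-squared in \[0, 1\], or NA when fewer than two complete
#'   specimens remain or either site is monomorphic among them.
#' @examples
#' compositeLdR2(c(0, 1, 2, 2, 0), c(0, 1, 1, 2, 0))
#' @export
compositeLdR2 <- function(dosageI, dosageJ) {
  ok <- !is.na(dosageI) & !is.na(dosageJ)
  if (sum(ok) < 2L) return(NA_real_)
  x <- dosageI[ok]; y <- dosageJ[ok]
  if (var(x) == 0 || var(y) == 0) return(NA_real_)
  cor(x, y)^2
}

#' Pairwise LD matrix over all called SNPs
#'
#' @param x a [SnpFrequencySet-class] (uses the per-specimen dosage
#'   matrix stored at calling time).
#' @return Symmetric matrix of composite r-squared values with unit
#'   diagonal, SNP position labels as dimnames.
#' @export
ldMatrix <- function(x) {
  stopifnot(is(x, "SnpFrequencySet"))
  d <- metadata(x)$dosage
  if (is.null(d))
    .pcError("no dosage matrix stored; build the set via callSnps()",
             "inputError")
  k <- nrow(d)
  m <- matrix(1, k, k, dimnames = list(rownames(d), rownames(d)))
  if (k >= 2L)
    for (i in 2:k)
      for (j in 1:(i - 1))
        m[i, j] <- m[j, i] <- compositeLdR2(d[i, ], d[j, ])
  m
}

#' Nei's D_A genetic distance between two populations
#'
#' `D_A = 1 - (1/L) * sum_l sum_alleles sqrt(x_l y_l)` over shared
#' genotyped biallelic loci; an alternative tree distance to F_ST.
#'
#' @inheritParams pairwiseFst
#' @return D_A in \[0, 1\].
#' @export
neiDa <- function(x, popA, popB) {
  stopifnot(is(x, "SnpFrequencySet"))
  f <- assay(x, "freq")
  pA <- f[, popA]; pB <- f[, popB]
  ok <- is.finite(pA) & is.finite(pB)
  if (!any(ok))
    .pcError("no shared genotyped loci", "inputError")
  pA <- pA[ok]; pB <- pB[ok]
  1 - mean(sqrt(pA * pB) + sqrt((1 - pA) * (1 - pB)))
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining (via \pkg{ape}) with negative branch
#' lengths clamped to zero (a message notes how many were clamped).
#'
#' @param d symmetric distance matrix (>= 3 labelled tips) or `dist`.
#' @return An \pkg{ape} `phylo` tree.
#' @export
njTree <- function(d) {
  m <- as.matrix(d)
  if (nrow(m) < 3L)
    .pcError("neighbor joining needs at least 3 populations",
             "inputError")
  if (max(abs(m - t(m))) > 1e-12)
    .pcError("distance matrix must be symmetric", "inputError")
  tr <- ape::nj(as.dist(m))
  neg <- tr$edge.length < 0
  if (any(neg)) {
    message(sum(neg), " negative branch length(s) clamped to 0")
    tr$edge.length[neg] <- 0
  }
  tr
}

#' Neighbor-joining population tree from SNP frequencies
#'
#' Builds the pairwise distance matrix (multilocus F_ST by default,
#' Nei's D_A optionally) and returns the neighbor-joining tree plus its
#' Newick string.
#'
#' @param x a [SnpFrequencySet-class].
#' @param distance "fst" (default) or "da".
#' @return list with `tree` (`phylo`), `newick` (string) and `dist`
#'   (the matrix used).
#' @export
populationTree <- function(x, distance = c("fst", "da")) {
  distance <- match.arg(distance)
  pops <- colnames(x)
  m <- matrix(0, length(pops), length(pops),
              dimnames = list(pops, pops))
  fun <- if (distance == "fst") pairwiseFst else neiDa
  for (i in seq_along(pops)[-1])
    for (j in seq_len(i - 1))
      m[i, j] <- m[j, i] <- fun(x, pops[i], pops[j])
  tr <- njTree(m)
  list(tree = tr, newick = ape::write.tree(tr), dist = m)
}

#' @importFrom stats as.dist
NULL
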