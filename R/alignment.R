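# IUPAC two-allele ambiguity codes used for Sanger-consensus heterozygotes
IUPAC_HET <- list(
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
  W = c("A", "T"), K = c("G", "T"), M = c("A", "C")
)
ALLOWED_SYMBOLS <- c("A", "C", "G", "T", "N", names(IUPAC_HET))

#' Read a multi-specimen consensus alignment
#'
#' Reads an aligned FASTA of per-specimen consensus sequences. Headers
#' must be `specimen_id|locality_id`. Sequences must be equal length and
#' use only A/C/G/T, N (missing), or the IUPAC two-allele ambiguity
#' codes R/Y/S/W/K/M encoding heterozygous diploid positions. Case is
#' ignored.
#'
#' @param path path to the FASTA file, or a named character vector /
#'   `DNAStringSet` already in memory (names as above).
#' @return A `DNAStringSet` with `specimen` and `locality` in its
#'   `metadata()`.
#' @export
readAlignment <- function(path) {
  seqs <- if (is(path, "DNAStringSet")) {
    path
  } else if (is.character(path) && length(path) == 1L && file.exists(path)) {
    readDNAStringSet(path)
  } else if (is.character(path) && !is.null(names(path))) {
    DNAStringSet(toupper(path))
  } else {
    .pcError("alignment must be a FASTA path or named sequences",
             "formatError")
  }
  if (length(seqs) == 0L)
    .pcError("alignment contains no sequences", "formatError")
  w <- width(seqs)
  if (length(unique(w)) != 1L)
    .pcError(sprintf(
      "ragged alignment: sequence lengths %s",
      paste(sort(unique(w)), collapse = ", ")), "formatError")
  mat <- toupper(as.matrix(seqs))
  bad <- which(!mat %in% ALLOWED_SYMBOLS)
  if (length(bad)) {
    r <- ((bad[1] - 1) %% nrow(mat)) + 1
    co <- ((bad[1] - 1) %/% nrow(mat)) + 1
    .pcError(sprintf(
      "invalid symbol '%s' in specimen '%s' at column %d (0-based %d)",
      mat[bad[1]], names(seqs)[r], co, co - 1), "formatError")
  }
  ids <- strsplit(names(seqs), "|", fixed = TRUE)
  if (any(lengths(ids) != 2L))
    .pcError("FASTA headers must be 'specimen_id|locality_id'",
             "formatError")
  out <- DNAStringSet(apply(mat, 1, paste, collapse = ""))
  names(out) <- names(seqs)
  metadata(out) <- list(
    specimen = vapply(ids, `[`, "", 1L),
    locality = vapply(ids, `[`, "", 2L)
  )
  out
}

#' Decode one alignment column into diploid genotypes
#'
#' Maps consensus symbols of a single column to per-specimen diploid
#' genotypes: a plain base X becomes the homozygote (X, X), an IUPAC
#' ambiguity code its two constituent bases, and N a missing genotype.
#' Columns with more than two segregating bases are flagged
#' multi-allelic.
#'
#' @param symbols character vector of one column's symbols (one per
#'   specimen).
#' @return list with `alleles` (n x 2 character matrix, NA rows for
#'   missing), `segregating` (sorted unique bases present), and
#'   `multiAllelic` (logical).
#' @examples
#' genotypeColumn(c("A", "R", "G", "N"))
#' @export
genotypeColumn <- function(symbols) {
  symbols <- toupper(symbols)
  bad <- setdiff(unique(symbols), ALLOWED_SYMBOLS)
  if (length(bad))
    .pcError(paste("invalid symbol(s):", paste(bad, collapse = ", ")),
             "formatError")
  n <- length(symbols)
  alleles <- matrix(NA_character_, n, 2)
  plain <- symbols %in% c("A", "C", "G", "T")
  alleles[plain, 1] <- alleles[plain, 2] <- symbols[plain]
  for (code in names(IUPAC_HET)) {
    hit <- symbols == code
    if (any(hit)) {
      alleles[hit, 1] <- IUPAC_HET[[code]][1]
      alleles[hit, 2] <- IUPAC_HET[[code]][2]
    }
  }
  seg <- sort(unique(as.vector(alleles[!is.na(alleles)])))
  list(alleles = alleles, segregating = seg,
       multiAllelic = length(seg) > 2L)
}

# IUPAC code for an unordered pair of distinct bases
.hetCode <- function(a, b) {
  pair <- paste(sort(c(a, b)), collapse = "")
  codes <- c(AG = "R", CT = "Y", CG = "S", AT = "W", GT = "K", AC = "M")
  unname(codes[pair])
}
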