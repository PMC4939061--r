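#' Two-locus genotype tables for a SNP pair
#'
#' Cross-tabulates the two-SNP genotype combinations of the affected and
#' the unaffected sibs. Families missing any of the four genotypes (two
#' sibs x two SNPs) are excluded pair-wise, so each SNP pair uses the
#' maximal set of complete families. Rows index the genotype at
#' \code{snp1}, columns the genotype at \code{snp2} (1 = minor homozygote,
#' 2 = het, 3 = major homozygote). By construction the unaffected table is
#' the total (both-sib) table minus the affected table.
#'
#' @param cohort a [DspCohort-class].
#' @param snp1,snp2 SNP ids or column indices; must differ.
#' @return List with \code{affected} and \code{unaffected} 3x3 integer
#'   matrices and \code{kUsed}, the number of retained families
#'   (\code{kUsed = 0} marks the pair non-testable).
#' @export
buildGenotypeTables <- function(cohort, snp1, snp2) {
  i <- .resolveSnp(cohort, snp1)
  j <- .resolveSnp(cohort, snp2)
  if (i == j) stop("snp1 and snp2 must differ")
  g1a <- cohort@aff[, i]; g2a <- cohort@aff[, j]
  g1u <- cohort@unaff[, i]; g2u <- cohort@unaff[, j]
  ok <- !(is.na(g1a) | is.na(g2a) | is.na(g1u) | is.na(g2u))
  dn <- list(snp1 = c("mm", "mM", "MM"), snp2 = c("mm", "mM", "MM"))
  aff <- matrix(tabulate(.cellIndex(g1a[ok], g2a[ok]), 9L), 3L, 3L,
                dimnames = dn)
  una <- matrix(tabulate(.cellIndex(g1u[ok], g2u[ok]), 9L), 3L, 3L,
                dimnames = dn)
  list(affected = aff, unaffected = una, kUsed = sum(ok))
}

.resolveSnp <- function(cohort, snp) {
  if (is.character(snp)) {
    i <- match(snp, cohort@map$snp)
    if (is.na(i)) stop("unknown SNP id: ", snp)
    i
  } else as.integer(snp)
}

#' Collapse a 3x3 genotype table to the 2x2 weighted allele table
#'
#' Phase-unknown allele-count collapsing: a homozygote-homozygote cell
#' contributes 4 identical allele pairs, a homozygote-heterozygote cell 2,
#' and the double heterozygote contributes 1 to every cell. The result is
#' the named vector (a, b, c, d) with a = minor1 & minor2, b = major1 &
#' minor2, c = minor1 & major2, d = major1 & major2; the allelic odds
#' ratio is \code{a*d/(b*c)}. The total \code{a+b+c+d} is always 4 times
#' the genotype-table total.
#'
#' @param tab3x3 3x3 count matrix (rows = SNP1 genotype, cols = SNP2
#'   genotype, index 1 = minor homozygote).
#' @return Named numeric vector \code{c(a, b, c, d)}.
#' @seealso [oddsRatio()]
#' @export
collapseAlleleTable <- function(tab3x3) {
  stopifnot(all(dim(tab3x3) == c(3L, 3L)), all(tab3x3 >= 0))
  out <- as.vector(.W %*% as.vector(tab3x3))
  names(out) <- c("a", "b", "c", "d")
  out
}
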