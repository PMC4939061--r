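#' Allelic odds ratio of a collapsed 2x2 table
#'
#' Returns \code{a*d/(b*c)}. Any zero cell makes the odds ratio
#' non-testable and \code{NA} is returned (no continuity correction by
#' default; see the \code{haldane} argument of [gdsp()]).
#'
#' @param tab2x2 named numeric vector (a, b, c, d) from
#'   [collapseAlleleTable()].
#' @return The odds ratio, or \code{NA_real_} if any cell is zero.
#' @export
oddsRatio <- function(tab2x2) {
  stopifnot(length(tab2x2) == 4L)
  if (any(tab2x2 == 0)) return(NA_real_)
  (tab2x2[[1L]] * tab2x2[[4L]]) / (tab2x2[[2L]] * tab2x2[[3L]])
}

#' Null covariance of the affected-table cell counts
#'
#' Under the within-family label-exchange null, conditional on the two
#' genotype configurations seen in family s (cells \code{u[s]} for the sib
#' currently labelled affected and \code{v[s]} for the unaffected sib),
#' the affected label lands on either sib with probability 1/2 (a draw of
#' 1 of 2 without replacement, i.e. the 2-sib multivariate hypergeometric
#' law). A family with \code{u[s] == v[s]} contributes nothing; otherwise
#' it contributes \code{(e_u - e_v)(e_u - e_v)'/4}, with \code{e_x} the
#' 9-vector indicator of cell x. The total covariance is the sum over
#' families.
#'
#' @param u,v integer vectors (same length) of 3x3 cell indices in 1..9
#'   (column-major, \code{g1 + 3*(g2-1)}) for the affected and unaffected
#'   sib of each family.
#' @return 9x9 covariance matrix of the affected-table cell counts.
#' @seealso [familyCellConfig()], [permutationOracle()]
#' @export
nullCellCovariance <- function(u, v) {
  stopifnot(length(u) == length(v), all(c(u, v) %in% 1:9))
  M <- matrix(0, 9L, 9L)
  idx <- cbind(u, v)
  for (r in seq_len(nrow(idx))) M[idx[r, 1L], idx[r, 2L]] <-
      M[idx[r, 1L], idx[r, 2L]] + 1
  0.25 * (diag(rowSums(M)) + diag(colSums(M)) - M - t(M))
}

#' Per-family cell configuration for a SNP pair
#'
#' Maps each complete family to its pair of 3x3 cell indices: \code{u} for
#' the affected sib's two-locus genotype, \code{v} for the unaffected
#' sib's. Families with any missing genotype at the pair are dropped.
#'
#' @inheritParams buildGenotypeTables
#' @return List with integer vectors \code{u}, \code{v} and \code{kUsed}.
#' @export
familyCellConfig <- function(cohort, snp1, snp2) {
  i <- .resolveSnp(cohort, snp1); j <- .resolveSnp(cohort, snp2)
  if (i == j) stop("snp1 and snp2 must differ")
  g1a <- cohort@aff[, i]; g2a <- cohort@aff[, j]
  g1u <- cohort@unaff[, i]; g2u <- cohort@unaff[, j]
  ok <- !(is.na(g1a) | is.na(g2a) | is.na(g1u) | is.na(g2u))
  list(u = .cellIndex(g1a[ok], g2a[ok]),
       v = .cellIndex(g1u[ok], g2u[ok]),
       kUsed = sum(ok))
}

#' Delta-method variance of the case log odds ratio
#'
#' log OR_case = log a - log b - log c + log d with (a, b, c, d) linear in
#' the nine affected-table cell counts via the collapsing weights W. The
#' delta gradient \code{g = W' (1/a, -1/b, -1/c, 1/d)} is evaluated at the
#' null expectation of the case cells -- the midpoint of the affected and
#' unaffected collapsed tables, since under the label-exchange null each
#' family's contribution lands in either table with probability 1/2. The
#' variance is \code{g' Sigma g} with Sigma the within-family covariance
#' of [nullCellCovariance()], which reduces to
#' \code{sum((g[u] - g[v])^2) / 4} over families. Evaluating at the
#' midpoint makes the variance symmetric in the two sib classes, so
#' Var(log OR_case) = Var(log OR_control) holds exactly and swapping all
#' affection labels negates the statistic exactly.
#'
#' @param affected3x3 observed 3x3 affected-sib genotype table
#'   (consistent with \code{u}).
#' @param u,v family cell configurations as in [nullCellCovariance()].
#' @return The variance, or \code{NA_real_} with attribute \code{status}
#'   ("ZERO_CELL" if a collapsed affected cell is zero, "DEGENERATE" if
#'   every family is genotype-concordant so the variance is zero).
#' @export
varLogOrCase <- function(affected3x3, u, v) {
  ab <- collapseAlleleTable(affected3x3)
  if (any(ab == 0)) return(structure(NA_real_, status = "ZERO_CELL"))
  abU <- as.vector(.W %*% tabulate(v, 9L)) * sum(affected3x3) / length(u)
  mid <- (ab + abU) / 2
  r <- c(1 / mid[[1L]], -1 / mid[[2L]], -1 / mid[[3L]], 1 / mid[[4L]])
  w <- as.vector(crossprod(.W, r))
  v0 <- 0.25 * sum((w[u] - w[v])^2)
  if (v0 <= 0) return(structure(NA_real_, status = "DEGENERATE"))
  v0
}

# Core statistic from raw code vectors; used by gdsp(), runScan() and the
# simulation experiments. Returns a plain list for speed.
.pairStat <- function(g1a, g2a, g1u, g2u, haldane = FALSE) {
  ok <- !(is.na(g1a) | is.na(g2a) | is.na(g1u) | is.na(g2u))
  k <- sum(ok)
  na <- list(kUsed = k, logOrCase = NA_real_, logOrCtrl = NA_real_,
             varLogOrCase = NA_real_, gDsp = NA_real_, pValue = NA_real_)
  if (k == 0L) { na$status <- "NO_DATA"; return(na) }
  u <- .cellIndex(g1a[ok], g2a[ok])
  v <- .cellIndex(g1u[ok], g2u[ok])
  cc <- as.vector(.W %*% tabulate(u, 9L))
  uc <- as.vector(.W %*% tabulate(v, 9L))
  if (haldane) { cc <- cc + 0.5; uc <- uc + 0.5 }
  if (any(cc == 0) || any(uc == 0)) { na$status <- "ZERO_CELL"; return(na) }
  lorC <- log(cc[1L]) - log(cc[2L]) - log(cc[3L]) + log(cc[4L])
  lorU <- log(uc[1L]) - log(uc[2L]) - log(uc[3L]) + log(uc[4L])
  mid <- (cc + uc) / 2          # null expectation of the case cells
  r <- c(1 / mid[1L], -1 / mid[2L], -1 / mid[3L], 1 / mid[4L])
  w <- as.vector(crossprod(.W, r))
  vr <- 0.25 * sum((w[u] - w[v])^2)
  na$logOrCase <- lorC; na$logOrCtrl <- lorU
  if (vr <= 0) { na$status <- "DEGENERATE"; return(na) }
  g <- (lorC - lorU) / sqrt(4 * vr)
  list(kUsed = k, logOrCase = lorC, logOrCtrl = lorU, varLogOrCase = vr,
       gDsp = g, pValue = 2 * pnorm(-abs(g)), status = "OK")
}

#' The GCORE-sib interaction statistic for one SNP pair
#'
#' Contrasts the allelic log odds ratio between two SNPs in affected sibs
#' against the same quantity in unaffected sibs:
#' \deqn{G = \frac{\log OR_{case} - \log OR_{control}}
#'                {\sqrt{4\,Var(\log OR_{case})}}}
#' The factor 4 in the denominator follows from the label-exchange null,
#' under which Var(log OR_case) = Var(log OR_control) and their covariance
#' equals minus that variance, so the difference has variance 4 Var.
#' G is referred to the standard normal; the p-value is two-sided.
#'
#' A pair is non-testable when any of the eight collapsed allele-table
#' cells is zero (\code{status = "ZERO_CELL"}; set \code{haldane = TRUE}
#' to add 0.5 to every collapsed cell for exploratory use) or when every
#' retained family is genotype-concordant at both SNPs, which makes the
#' null variance zero (\code{status = "DEGENERATE"}). Genotype-concordant
#' families are retained in the counts (they inform the odds ratios) but
#' contribute nothing to the variance.
#'
#' @inheritParams buildGenotypeTables
#' @param haldane logical; add 0.5 to every collapsed allele-table cell.
#' @return An [InteractionResult-class].
#' @examples
#' d <- simDesign(nDsp = 200, seed = 7)
#' co <- simulateDspCohort(d)
#' gdsp(co, "SNP1", "SNP2")
#' @export
gdsp <- function(cohort, snp1, snp2, haldane = FALSE) {
  i <- .resolveSnp(cohort, snp1); j <- .resolveSnp(cohort, snp2)
  if (i == j) stop("snp1 and snp2 must differ")
  st <- .pairStat(cohort@aff[, i], cohort@aff[, j],
                  cohort@unaff[, i], cohort@unaff[, j], haldane = haldane)
  new("InteractionResult",
      snp1 = cohort@map$snp[i], snp2 = cohort@map$snp[j],
      kUsed = as.integer(st$kUsed),
      logOrCase = st$logOrCase, logOrCtrl = st$logOrCtrl,
      varLogOrCase = st$varLogOrCase, gDsp = st$gDsp,
      pValue = st$pValue, status = st$status)
}
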