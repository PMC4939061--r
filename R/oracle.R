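#' Within-family permutation oracle for one SNP pair
#'
#' Enumerates (or samples) the label-exchange null: within each family the
#' affected/unaffected labels are swapped or not, all \code{2^k}
#' assignments equally likely. For each assignment the collapsed allele
#' tables and both log odds ratios are recomputed. Serves as the
#' independent reference for the closed-form variance of [gdsp()].
#'
#' Two sets of moments are reported. \emph{Raw} moments are those of the
#' actual log odds ratios, computed over the assignments in which all
#' eight collapsed cells are positive (the log OR is undefined
#' otherwise). \emph{Linearized} moments are those of the first-order
#' (delta) expansions \code{g'n} of both log ORs around the null
#' expectation of the cell counts (the midpoint of the two collapsed
#' tables), the same gradient for both classes; they are computed over
#' all assignments and satisfy the identities
#' \code{Var(case) = Var(control)}, \code{Cov = -Var} and
#' \code{Var(diff) = 4 Var(case)} exactly, because the control counts are
#' the fixed totals minus the case counts. The raw moments obey the same
#' identities only approximately, to the accuracy of the delta expansion.
#'
#' @inheritParams buildGenotypeTables
#' @param mode "exhaustive" (all \code{2^k} assignments; refused for
#'   k > 20) or "monte_carlo".
#' @param nPerm number of sampled assignments for Monte Carlo mode.
#' @param seed RNG seed for Monte Carlo mode.
#' @return A list: \code{kUsed}, \code{nAssign}, \code{nValid};
#'   \code{observedDiff}; raw moments \code{meanCase}, \code{meanCtrl},
#'   \code{varCase}, \code{varCtrl}, \code{cov}, \code{varDiff};
#'   linearized moments \code{linVarCase}, \code{linVarCtrl},
#'   \code{linCov}, \code{linVarDiff}; and \code{pEmpirical}, the
#'   proportion of valid assignments with |diff| at least the observed
#'   |diff|.
#' @export
permutationOracle <- function(cohort, snp1, snp2,
                              mode = c("exhaustive", "monte_carlo"),
                              nPerm = 10000L, seed = 1L) {
  mode <- match.arg(mode)
  cfg <- familyCellConfig(cohort, snp1, snp2)
  k <- cfg$kUsed
  if (k == 0L) stop("no complete families for this SNP pair")
  if (mode == "exhaustive") {
    if (k > 20L) stop("exhaustive enumeration refused for k > 20 (k = ",
                      k, "); use monte_carlo")
    B <- 2L^k
    bits <- vapply(seq_len(k),
                   function(s) bitwAnd(0:(B - 1L), bitwShiftL(1L, s - 1L)) > 0L,
                   logical(B))
  } else {
    set.seed(seed)
    B <- as.integer(nPerm)
    bits <- matrix(runif(B * k) < 0.5, B, k)
  }
  storage.mode(bits) <- "double"

  cu <- .W[, cfg$u, drop = FALSE]            # 4 x k case-cell weights
  cv <- .W[, cfg$v, drop = FALSE]
  base <- rowSums(cu)                        # observed case cells (a,b,c,d)
  tot <- rowSums(cu) + rowSums(cv)
  delta <- cv - cu
  caseCells <- base + delta %*% t(bits)      # 4 x B
  ctrlCells <- tot - caseCells

  valid <- colSums(caseCells > 0) == 4L & colSums(ctrlCells > 0) == 4L
  if (!any(valid)) stop("no assignment yields positive collapsed cells")
  lorOf <- function(m) log(m[1L, ]) - log(m[2L, ]) - log(m[3L, ]) + log(m[4L, ])
  lorCase <- lorOf(caseCells[, valid, drop = FALSE])
  lorCtrl <- lorOf(ctrlCells[, valid, drop = FALSE])

  # population moments (equal weight over assignments)
  mom <- function(x, y) mean((x - mean(x)) * (y - mean(y)))
  varCase <- mom(lorCase, lorCase)
  varCtrl <- mom(lorCtrl, lorCtrl)
  covCC <- mom(lorCase, lorCtrl)
  varDiff <- mom(lorCase - lorCtrl, lorCase - lorCtrl)

  if (any(base == 0) || any(tot - base == 0))
    stop("observed tables have a zero collapsed cell; pair not testable")
  obsDiff <- unname(
    (log(base[1L]) - log(base[2L]) - log(base[3L]) + log(base[4L])) -
    (log(tot[1L] - base[1L]) - log(tot[2L] - base[2L]) -
     log(tot[3L] - base[3L]) + log(tot[4L] - base[4L])))

  mid <- tot / 2
  r <- c(1 / mid[1L], -1 / mid[2L], -1 / mid[3L], 1 / mid[4L])
  linCase <- as.vector(r %*% caseCells)      # over ALL assignments
  linCtrl <- as.vector(r %*% ctrlCells)
  linVarCase <- mom(linCase, linCase)
  linVarCtrl <- mom(linCtrl, linCtrl)
  linCov <- mom(linCase, linCtrl)
  linVarDiff <- mom(linCase - linCtrl, linCase - linCtrl)

  pEmp <- mean(abs(lorCase - lorCtrl) >= abs(obsDiff) - 1e-12)

  list(kUsed = k, nAssign = B, nValid = sum(valid),
       observedDiff = obsDiff,
       meanCase = mean(lorCase), meanCtrl = mean(lorCtrl),
       varCase = varCase, varCtrl = varCtrl, cov = covCC,
       varDiff = varDiff,
       linVarCase = linVarCase, linVarCtrl = linVarCtrl,
       linCov = linCov, linVarDiff = linVarDiff,
       pEmpirical = pEmp)
}
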