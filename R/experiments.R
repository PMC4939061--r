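# Shared replicate engine: simulate `nReps` cohorts from `design` and test
# the single disease-SNP pair in each. Per-replicate seeds are drawn once
# from the experiment seed, so each cohort has its own reproducible stream.
.runReplicates <- function(design, nReps, seed) {
  set.seed(seed)
  repSeeds <- sample.int(.Machine$integer.max - 1L, nReps)
  p <- g <- rep(NA_real_, nReps)
  status <- character(nReps)
  for (i in seq_len(nReps)) {
    set.seed(repSeeds[i])
    cd <- .simulateDspCodes(design@nDsp, design@hap, design@pen,
                            design@linked)
    st <- .pairStat(cd$g1a, cd$g2a, cd$g1u, cd$g2u)
    status[i] <- st$status
    if (identical(st$status, "OK")) { p[i] <- st$pValue; g[i] <- st$gDsp }
  }
  list(p = p, g = g, status = status)
}

.normalizeDesigns <- function(designs) {
  if (is(designs, "SimDesign")) designs <- list(designs)
  if (!is.list(designs) || !all(vapply(designs, is, TRUE, "SimDesign")))
    stop("designs must be a SimDesign or a list of SimDesign objects")
  if (is.null(names(designs)) || any(!nzchar(names(designs))))
    names(designs) <- paste0("design", seq_along(designs))
  designs
}

.rateRow <- function(label, alpha, pvals, status) {
  testable <- which(status == "OK")
  nT <- length(testable)
  x <- sum(pvals[testable] < alpha)
  ci <- if (nT > 0) binom.test(x, nT)$conf.int else c(NA_real_, NA_real_)
  data.frame(scenario = label, alpha = alpha, nReps = length(status),
             nTestable = nT, nNotTestable = length(status) - nT,
             rate = if (nT > 0) x / nT else NA_real_,
             ciLower = ci[1L], ciUpper = ci[2L],
             excludesNominal = ci[1L] > alpha | ci[2L] < alpha,
             stringsAsFactors = FALSE)
}

#' Empirical type I error of the interaction test
#'
#' For each null design (interaction effect lambda3 must be 0), simulates
#' \code{nReps} replicate cohorts, tests the disease-SNP pair in each, and
#' reports the empirical rejection rate at each significance level with a
#' 95\% exact binomial confidence interval. Non-testable replicates are
#' counted separately; rates are rejections over testable replicates.
#'
#' @param designs a [SimDesign-class] or (optionally named) list of them;
#'   all with \code{lambda3 = 0}.
#' @param nReps replicates per design (default 5000).
#' @param alphas significance levels (default 0.05 and 0.01).
#' @param seed experiment seed; replicate seeds are derived from it.
#' @param keepStats if TRUE, attach the per-design Z statistics and
#'   p-values as the \code{"stats"} attribute.
#' @return data.frame with one row per design x alpha: \code{scenario},
#'   \code{alpha}, \code{nReps}, \code{nTestable}, \code{nNotTestable},
#'   \code{rate}, \code{ciLower}, \code{ciUpper},
#'   \code{excludesNominal}.
#' @seealso [powerExperiment()]
#' @export
type1Experiment <- function(designs, nReps = 5000L,
                            alphas = c(0.05, 0.01), seed = 1L,
                            keepStats = FALSE) {
  designs <- .normalizeDesigns(designs)
  if (any(vapply(designs, function(d) d@pen@lambda3, 0) != 0))
    stop("type I error designs must have lambda3 = 0")
  set.seed(seed)
  dSeeds <- sample.int(.Machine$integer.max - 1L, length(designs))
  rows <- list(); stats <- list()
  for (di in seq_along(designs)) {
    rep <- .runReplicates(designs[[di]], nReps, dSeeds[di])
    lab <- names(designs)[di]
    stats[[lab]] <- rep
    for (a in alphas)
      rows[[length(rows) + 1L]] <- .rateRow(lab, a, rep$p, rep$status)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (keepStats) attr(out, "stats") <- stats
  out
}

#' Empirical power of the interaction test
#'
#' As [type1Experiment()] but for designs with a nonzero interaction
#' effect (lambda3 != 0), at a single significance level. When several
#' designs share all parameters except the number of families, a
#' monotonicity diagnostic is attached (\code{"monotonicity"} attribute):
#' power should be non-decreasing in the number of families, flagged as a
#' violation only when a decrease is backed by disjoint confidence
#' intervals.
#'
#' @inheritParams type1Experiment
#' @param alpha significance level (default 0.05).
#' @param nReps replicates per design (default 1000).
#' @return data.frame as in [type1Experiment()].
#' @export
powerExperiment <- function(designs, nReps = 1000L, alpha = 0.05,
                            seed = 1L, keepStats = FALSE) {
  designs <- .normalizeDesigns(designs)
  if (any(vapply(designs, function(d) d@pen@lambda3, 0) == 0))
    stop("power designs must have lambda3 != 0")
  out <- NULL
  set.seed(seed)
  dSeeds <- sample.int(.Machine$integer.max - 1L, length(designs))
  rows <- list(); stats <- list()
  for (di in seq_along(designs)) {
    rep <- .runReplicates(designs[[di]], nReps, dSeeds[di])
    lab <- names(designs)[di]
    stats[[lab]] <- rep
    rows[[length(rows) + 1L]] <- .rateRow(lab, alpha, rep$p, rep$status)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "monotonicity") <- .powerMonotonicity(designs, out)
  if (keepStats) attr(out, "stats") <- stats
  out
}

# Group designs identical up to nDsp; within each group check that power
# does not decrease with nDsp beyond CI overlap.
.powerMonotonicity <- function(designs, report) {
  keyOf <- function(d) paste(d@hap@maf1, d@hap@maf2, d@hap@r2,
                             d@pen@model, d@pen@lambda1, d@pen@lambda2,
                             d@pen@lambda3, d@prevalence, sep = "|")
  keys <- vapply(designs, keyOf, "")
  nf <- vapply(designs, function(d) d@nDsp, 1L)
  cmp <- list()
  for (k in unique(keys[duplicated(keys)])) {
    idx <- which(keys == k)
    idx <- idx[order(nf[idx])]
    for (s in seq_len(length(idx) - 1L)) {
      lo <- report[report$scenario == names(designs)[idx[s]], ]
      hi <- report[report$scenario == names(designs)[idx[s + 1L]], ]
      cmp[[length(cmp) + 1L]] <- data.frame(
        smaller = lo$scenario, larger = hi$scenario,
        rateSmaller = lo$rate, rateLarger = hi$rate,
        violation = hi$rate < lo$rate & hi$ciUpper < lo$ciLower,
        stringsAsFactors = FALSE)
    }
  }
  if (length(cmp)) do.call(rbind, cmp) else
    data.frame(smaller = character(0), larger = character(0),
               rateSmaller = numeric(0), rateLarger = numeric(0),
               violation = logical(0))
}
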