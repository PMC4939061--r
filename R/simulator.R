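#' Two-SNP haplotype frequencies from MAFs and r2
#'
#' Builds the four haplotype frequencies for two biallelic SNPs with the
#' given minor allele frequencies and squared allelic correlation, using
#' the positive-D convention: \code{D = sqrt(r2 * p1 q1 p2 q2)},
#' \code{h_AB = p1 p2 + D}, \code{h_Ab = p1 q2 - D}, \code{h_aB = q1 p2 -
#' D}, \code{h_ab = q1 q2 + D} (uppercase = minor allele). The requested
#' r2 must not exceed the Lewontin bound implied by the MAFs; at the
#' boundary a haplotype frequency hits zero, which is rejected unless
#' \code{allowBoundary = TRUE}.
#'
#' @param maf1,maf2 minor allele frequencies in (0, 0.5].
#' @param r2 squared allelic correlation in [0, 1].
#' @param allowBoundary accept zero haplotype frequencies at the bound.
#' @return A [TwoSnpHaplotypeModel-class].
#' @export
haplotypeFreqs <- function(maf1, maf2, r2 = 0, allowBoundary = FALSE) {
  stopifnot(maf1 > 0, maf1 <= 0.5, maf2 > 0, maf2 <= 0.5,
            r2 >= 0, r2 <= 1)
  q1 <- 1 - maf1; q2 <- 1 - maf2
  denom <- maf1 * q1 * maf2 * q2
  D <- sqrt(r2 * denom)
  Dmax <- min(maf1 * q2, q1 * maf2)
  r2max <- Dmax^2 / denom
  if (D > Dmax + 1e-12)
    stop(sprintf(
      "r2 = %g infeasible for MAFs (%g, %g); maximum feasible r2 = %g",
      r2, maf1, maf2, r2max))
  h <- c(AB = maf1 * maf2 + D, Ab = maf1 * q2 - D,
         aB = q1 * maf2 - D, ab = q1 * q2 + D)
  h[abs(h) < 1e-15] <- 0
  if (any(h == 0) && !allowBoundary)
    stop("a haplotype frequency is exactly zero at this r2; ",
         "set allowBoundary = TRUE to accept the boundary model")
  new("TwoSnpHaplotypeModel", maf1 = maf1, maf2 = maf2, r2 = r2, freqs = h)
}

# Joint distribution of minor-allele counts (0..2 at each SNP) for a
# genotype formed by the random union of two haplotypes from `hap` (HWE).
# Returns a 3x3 matrix, rows = count at SNP1, cols = count at SNP2.
.genotypeDist <- function(hap) {
  h <- hap@freqs
  hm1 <- c(1L, 1L, 0L, 0L)   # minor-allele indicator at SNP1 per haplotype
  hm2 <- c(1L, 0L, 1L, 0L)
  P <- outer(h, h)
  m1 <- outer(hm1, hm1, "+"); m2 <- outer(hm2, hm2, "+")
  pg <- matrix(0, 3L, 3L)
  for (i in 1:4) for (j in 1:4)
    pg[m1[i, j] + 1L, m2[i, j] + 1L] <-
      pg[m1[i, j] + 1L, m2[i, j] + 1L] + P[i, j]
  pg
}

# Genotype coding X for the penetrance model, from minor-allele count m.
.codeX <- function(m, model) {
  switch(model,
         additive = m,
         dominant = as.numeric(m >= 1),
         recessive = as.numeric(m == 2))
}

#' Calibrate the penetrance intercept to a target prevalence
#'
#' Solves \code{E[P(affected | X)] = prevalence} for \code{rho}, with the
#' expectation over the two-locus genotype distribution implied by random
#' union of gametes (HWE) under the haplotype model. The logistic is
#' strictly increasing in rho, so monotone root-finding converges to
#' within 1e-10 of the target.
#'
#' @param lambda1,lambda2,lambda3 effect sizes on the log-odds scale.
#' @param model "additive", "dominant" or "recessive".
#' @param hap a [TwoSnpHaplotypeModel-class].
#' @param prevalence target population prevalence in (0, 1).
#' @return The calibrated \code{rho}.
#' @export
calibrateRho <- function(lambda1, lambda2, lambda3, model, hap, prevalence) {
  stopifnot(prevalence > 0, prevalence < 1)
  pg <- .genotypeDist(hap)
  X1 <- .codeX(0:2, model); X2 <- .codeX(0:2, model)
  eta0 <- outer(lambda1 * X1, lambda2 * X2, "+") +
    lambda3 * outer(X1, X2)
  f <- function(rho) sum(pg * plogis(rho + eta0)) - prevalence
  rho <- uniroot(f, c(-80, 80), tol = 1e-13)$root
  if (abs(f(rho)) > 1e-10)
    stop("prevalence calibration did not converge")
  rho
}

#' Build a simulation design
#'
#' Convenience constructor: derives the haplotype model from MAFs and r2,
#' calibrates the penetrance intercept to the target prevalence, and
#' fixes the transmission mode (intact shared-haplotype transmission when
#' the SNPs are in LD, independent transmission otherwise, reflecting two
#' unlinked genes).
#'
#' @param nDsp number of discordant sib pairs to ascertain.
#' @param maf1,maf2 minor allele frequencies.
#' @param r2 squared allelic correlation between the two SNPs.
#' @param model disease model for the genotype coding.
#' @param lambda1,lambda2 main effect sizes (log-odds scale).
#' @param lambda3 interaction effect size (log-odds scale).
#' @param prevalence target population prevalence.
#' @param seed default RNG seed for [simulateDspCohort()].
#' @param linked logical; transmit the two SNPs on one haplotype
#'   (defaults to \code{r2 > 0}).
#' @return A [SimDesign-class].
#' @export
simDesign <- function(nDsp, maf1 = 0.2, maf2 = 0.2, r2 = 0,
                      model = c("additive", "dominant", "recessive"),
                      lambda1 = 0, lambda2 = 0, lambda3 = 0,
                      prevalence = 0.05, seed = 1L, linked = r2 > 0) {
  model <- match.arg(model)
  hap <- haplotypeFreqs(maf1, maf2, r2)
  rho <- calibrateRho(lambda1, lambda2, lambda3, model, hap, prevalence)
  pen <- new("PenetranceModel", rho = rho, lambda1 = lambda1,
             lambda2 = lambda2, lambda3 = lambda3, model = model)
  new("SimDesign", nDsp = as.integer(nDsp), hap = hap, pen = pen,
      prevalence = prevalence, linked = linked, seed = as.integer(seed))
}

# Draw n haplotypes (categories 1=AB, 2=Ab, 3=aB, 4=ab) from cumulative
# frequencies `cum` (length 3).
.drawHap <- function(n, cum) findInterval(runif(n), cum) + 1L

# Simulate one batch of B nuclear families with two offspring; returns
# genotype codes (1/2/3) of the affected and unaffected sib at both SNPs
# for the discordant families only. Codes: 3 - minor allele count.
.simBatch <- function(B, cum, pen, linked) {
  f1 <- .drawHap(B, cum); f2 <- .drawHap(B, cum)
  m1 <- .drawHap(B, cum); m2 <- .drawHap(B, cum)
  hA1 <- function(h) as.integer(h <= 2L)        # minor at SNP1 on haplotype
  hA2 <- function(h) as.integer(h %% 2L == 1L)  # minor at SNP2 on haplotype

  childCounts <- function() {
    if (linked) {
      hf <- ifelse(runif(B) < 0.5, f1, f2)
      hm <- ifelse(runif(B) < 0.5, m1, m2)
      list(c1 = hA1(hf) + hA1(hm), c2 = hA2(hf) + hA2(hm))
    } else {
      af <- ifelse(runif(B) < 0.5, hA1(f1), hA1(f2))
      am <- ifelse(runif(B) < 0.5, hA1(m1), hA1(m2))
      bf <- ifelse(runif(B) < 0.5, hA2(f1), hA2(f2))
      bm <- ifelse(runif(B) < 0.5, hA2(m1), hA2(m2))
      list(c1 = af + am, c2 = bf + bm)
    }
  }
  kid1 <- childCounts(); kid2 <- childCounts()

  affProb <- function(kid) {
    X1 <- .codeX(kid$c1, pen@model); X2 <- .codeX(kid$c2, pen@model)
    plogis(pen@rho + pen@lambda1 * X1 + pen@lambda2 * X2 +
             pen@lambda3 * X1 * X2)
  }
  aff1 <- runif(B) < affProb(kid1)
  aff2 <- runif(B) < affProb(kid2)
  disc <- xor(aff1, aff2)
  if (!any(disc)) return(NULL)
  firstAff <- aff1[disc]
  pick <- function(x1, x2, takeFirst) ifelse(takeFirst, x1, x2)
  list(
    g1a = 3L - pick(kid1$c1[disc], kid2$c1[disc], firstAff),
    g2a = 3L - pick(kid1$c2[disc], kid2$c2[disc], firstAff),
    g1u = 3L - pick(kid1$c1[disc], kid2$c1[disc], !firstAff),
    g2u = 3L - pick(kid1$c2[disc], kid2$c2[disc], !firstAff))
}

# Rejection-sample families until nDsp discordant sib pairs are collected.
.simulateDspCodes <- function(nDsp, hap, pen, linked) {
  cum <- cumsum(hap@freqs)[1:3]
  got <- 0L; tried <- 0
  acc <- list(g1a = integer(0), g2a = integer(0),
              g1u = integer(0), g2u = integer(0))
  pEst <- 0.1
  repeat {
    B <- as.integer(ceiling((nDsp - got) / max(pEst, 1e-3) * 1.15) + 64L)
    batch <- .simBatch(B, cum, pen, linked)
    tried <- tried + B
    if (!is.null(batch)) {
      for (nm in names(acc)) acc[[nm]] <- c(acc[[nm]], batch[[nm]])
      got <- length(acc$g1a)
    }
    if (got >= nDsp) break
    if (tried >= 2e6 && got / tried < 1e-5)
      stop(sprintf(
        "discordant-pair acceptance rate %.2g below 1e-5 after %d families; check the design",
        got / tried, tried))
    pEst <- max(got / tried, 1e-4)
  }
  lapply(acc, function(x) x[seq_len(nDsp)])
}

#' Simulate a discordant-sib-pair cohort
#'
#' Draws nuclear families with two parents (two haplotypes each from the
#' design's haplotype model) and two offspring, each offspring receiving
#' one gamete per parent. In unlinked mode (the default when r2 = 0, the
#' two disease SNPs sitting in unlinked genes) transmission at the two
#' SNPs is independent; in linked mode the haplotype is transmitted
#' intact. Each offspring is affected independently with the logistic
#' penetrance probability; a family is ascertained iff exactly one sib is
#' affected (rejection sampling), the affected sib listed first. Fully
#' reproducible for a given seed. Aborts with a diagnostic if the
#' discordant-pair acceptance rate falls below 1e-5.
#'
#' @param design a [SimDesign-class].
#' @param seed RNG seed; defaults to the design's seed.
#' @return A [DspCohort-class] with SNPs "SNP1" and "SNP2" (minor allele
#'   "A", major "G"), on chromosomes "1" and "2" in unlinked mode or both
#'   on "1" in linked mode.
#' @export
simulateDspCohort <- function(design, seed = NULL) {
  set.seed(if (is.null(seed)) design@seed else seed)
  cd <- .simulateDspCodes(design@nDsp, design@hap, design@pen,
                          design@linked)
  chrom <- if (design@linked) c("1", "1") else c("1", "2")
  map <- data.frame(chrom = chrom, snp = c("SNP1", "SNP2"),
                    pos = c(1000L, 2000L), minor = "A", major = "G",
                    stringsAsFactors = FALSE)
  DspCohort(cbind(cd$g1a, cd$g2a), cbind(cd$g1u, cd$g2u), map)
}

#' Simulate founder genotypes from a haplotype model
#'
#' Draws \code{n} unrelated individuals as random unions of two
#' haplotypes; used to check marginal MAF and Hardy-Weinberg behaviour of
#' the generator.
#'
#' @param hap a [TwoSnpHaplotypeModel-class].
#' @param n number of individuals.
#' @param seed RNG seed.
#' @return Integer matrix n x 2 of minor-allele counts (0, 1, 2) at the
#'   two SNPs.
#' @export
simulateFounderGenotypes <- function(hap, n, seed = 1L) {
  set.seed(seed)
  cum <- cumsum(hap@freqs)[1:3]
  h1 <- .drawHap(n, cum); h2 <- .drawHap(n, cum)
  cbind(snp1 = as.integer(h1 <= 2L) + as.integer(h2 <= 2L),
        snp2 = as.integer(h1 %% 2L == 1L) + as.integer(h2 %% 2L == 1L))
}
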