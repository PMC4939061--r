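#' Discordant sib pair cohort
#'
#' Holds genotype codes for the affected and the unaffected sib of each
#' discordant sib pair (DSP), one pair per nuclear family, plus the marker
#' map. Genotypes are coded 1 = homozygous for the minor allele, 2 =
#' heterozygous, 3 = homozygous for the major allele, \code{NA} = missing.
#'
#' @slot aff integer matrix, k families x p SNPs: affected-sib codes.
#' @slot unaff integer matrix, same shape: unaffected-sib codes.
#' @slot map data.frame with one row per SNP: columns \code{chrom},
#'   \code{snp}, \code{pos}, \code{minor}, \code{major}.
#' @slot family character vector of family identifiers, length k.
#'
#' @seealso [extractDsps()], [simulateDspCohort()], [gdsp()], [runScan()]
#' @exportClass DspCohort
setClass("DspCohort",
  representation(aff = "matrix", unaff = "matrix",
                 map = "data.frame", family = "character"))

setValidity("DspCohort", function(object) {
  a <- object@aff; u <- object@unaff
  msg <- character(0)
  if (!all(dim(a) == dim(u)))
    msg <- c(msg, "affected and unaffected matrices must have equal dims")
  if (nrow(a) < 1L)
    msg <- c(msg, "cohort must contain at least one discordant sib pair")
  if (length(object@family) != nrow(a))
    msg <- c(msg, "family ids must match the number of sib pairs")
  if (nrow(object@map) != ncol(a))
    msg <- c(msg, "marker map rows must match the number of SNPs")
  need <- c("chrom", "snp", "pos", "minor", "major")
  if (!all(need %in% names(object@map)))
    msg <- c(msg, paste("map must have columns:", paste(need, collapse = ", ")))
  codes <- c(a, u)
  if (!all(is.na(codes) | codes %in% 1:3))
    msg <- c(msg, "genotype codes must be 1, 2, 3 or NA")
  if (anyDuplicated(object@map$snp))
    msg <- c(msg, "SNP ids must be unique")
  if (length(msg)) msg else TRUE
})

#' Construct a DspCohort
#'
#' @param aff,unaff integer matrices of genotype codes (rows = families,
#'   columns = SNPs); see [DspCohort-class].
#' @param map marker map data.frame (\code{chrom}, \code{snp}, \code{pos},
#'   \code{minor}, \code{major}).
#' @param family family identifiers; defaults to \code{"F1"..."Fk"}.
#' @return A [DspCohort-class] object.
#' @export
DspCohort <- function(aff, unaff, map, family = NULL) {
  aff <- as.matrix(aff); unaff <- as.matrix(unaff)
  storage.mode(aff) <- "integer"; storage.mode(unaff) <- "integer"
  if (is.null(family)) family <- paste0("F", seq_len(nrow(aff)))
  map <- as.data.frame(map, stringsAsFactors = FALSE)
  colnames(aff) <- colnames(unaff) <- map$snp
  new("DspCohort", aff = aff, unaff = unaff, map = map,
      family = as.character(family))
}

#' @describeIn DspCohort-class number of discordant sib pairs
#' @param x,object a \code{DspCohort}
#' @export
nDsp <- function(x) nrow(x@aff)

#' @describeIn DspCohort-class SNP identifiers in map order
#' @export
snpIds <- function(x) x@map$snp

#' @describeIn DspCohort-class the marker map data.frame
#' @export
markerInfo <- function(x) x@map

#' @describeIn DspCohort-class affected-sib genotype code matrix
#' @export
affGenotypes <- function(x) x@aff

#' @describeIn DspCohort-class unaffected-sib genotype code matrix
#' @export
unaffGenotypes <- function(x) x@unaff

#' @describeIn DspCohort-class minor allele frequency per SNP, computed
#'   from the sibs in the cohort (the analysis units), ignoring missing
#'   genotypes. Code 1 carries two minor alleles, code 2 one, code 3 none.
#' @export
sibMaf <- function(x) {
  g <- rbind(x@aff, x@unaff)
  cnt <- 3L - g                            # minor-allele count per genotype
  colMeans(cnt, na.rm = TRUE) / 2
}

setMethod("show", "DspCohort", function(object) {
  cat("DspCohort:", nDsp(object), "discordant sib pairs,",
      ncol(object@aff), "SNPs\n")
  m <- object@map
  n <- min(5L, nrow(m))
  cat("  SNPs:", paste(m$snp[seq_len(n)], collapse = ", "),
      if (nrow(m) > n) "..." else "", "\n")
  cat("  sib MAF:", paste(sprintf("%.3f", sibMaf(object)[seq_len(n)]),
                          collapse = ", "),
      if (nrow(m) > n) "..." else "", "\n")
})

#' Two-SNP haplotype frequency model
#'
#' Haplotype frequencies for two biallelic SNPs parameterized by the two
#' minor allele frequencies and the squared allelic correlation r2
#' (positive-D convention). Frequencies are ordered AB, Ab, aB, ab with
#' uppercase denoting the minor allele.
#'
#' @slot maf1,maf2 minor allele frequencies in (0, 0.5].
#' @slot r2 squared allelic correlation in [0, 1].
#' @slot freqs named numeric vector (AB, Ab, aB, ab) summing to 1.
#' @seealso [haplotypeFreqs()]
#' @exportClass TwoSnpHaplotypeModel
setClass("TwoSnpHaplotypeModel",
  representation(maf1 = "numeric", maf2 = "numeric",
                 r2 = "numeric", freqs = "numeric"))

setValidity("TwoSnpHaplotypeModel", function(object) {
  h <- object@freqs
  msg <- character(0)
  if (length(h) != 4L || is.null(names(h)) ||
      !identical(names(h), c("AB", "Ab", "aB", "ab")))
    msg <- c(msg, "freqs must be named AB, Ab, aB, ab")
  if (any(h < -1e-12)) msg <- c(msg, "haplotype frequencies must be >= 0")
  if (abs(sum(h) - 1) > 1e-9) msg <- c(msg, "frequencies must sum to 1")
  if (abs(h[["AB"]] + h[["Ab"]] - object@maf1) > 1e-12)
    msg <- c(msg, "implied MAF at SNP1 does not match maf1")
  if (abs(h[["AB"]] + h[["aB"]] - object@maf2) > 1e-12)
    msg <- c(msg, "implied MAF at SNP2 does not match maf2")
  if (length(msg)) msg else TRUE
})

setMethod("show", "TwoSnpHaplotypeModel", function(object) {
  cat(sprintf("TwoSnpHaplotypeModel: MAF %.3g / %.3g, r2 = %.3g\n",
              object@maf1, object@maf2, object@r2))
  print(round(object@freqs, 6))
})

#' Logistic penetrance model
#'
#' Disease risk P(affected | X) = plogis(rho + l1*X1 + l2*X2 + l3*X1*X2),
#' where X1, X2 code the genotypes at the two disease SNPs under an
#' additive (minor-allele count 0/1/2), dominant (any minor allele) or
#' recessive (two minor alleles) model. \code{rho} sets the population
#' prevalence; \code{lambda1}, \code{lambda2} are main effects and
#' \code{lambda3} the interaction effect on the log-odds scale.
#'
#' @slot rho numeric intercept (log-odds scale).
#' @slot lambda1,lambda2,lambda3 numeric effect sizes.
#' @slot model one of "additive", "dominant", "recessive".
#' @seealso [calibrateRho()], [simDesign()]
#' @exportClass PenetranceModel
setClass("PenetranceModel",
  representation(rho = "numeric", lambda1 = "numeric", lambda2 = "numeric",
                 lambda3 = "numeric", model = "character"))

setValidity("PenetranceModel", function(object) {
  if (!object@model %in% c("additive", "dominant", "recessive"))
    return("model must be additive, dominant or recessive")
  TRUE
})

setMethod("show", "PenetranceModel", function(object) {
  cat(sprintf(
    "PenetranceModel (%s): rho = %.4f, lambda = (%.4f, %.4f, %.4f)\n",
    object@model, object@rho, object@lambda1, object@lambda2,
    object@lambda3))
})

#' Simulation design for a DSP cohort
#'
#' Bundles the number of discordant sib pairs to ascertain, the two-SNP
#' haplotype model, the calibrated penetrance model, the target prevalence,
#' the transmission mode (linked = both SNPs on one haplotype, transmitted
#' intact; unlinked = independent transmission), and the seed.
#'
#' @slot nDsp integer >= 1.
#' @slot hap a [TwoSnpHaplotypeModel-class].
#' @slot pen a [PenetranceModel-class] with calibrated rho.
#' @slot prevalence target population prevalence in (0, 1).
#' @slot linked logical transmission mode.
#' @slot seed integer default seed.
#' @seealso [simDesign()], [simulateDspCohort()]
#' @exportClass SimDesign
setClass("SimDesign",
  representation(nDsp = "integer", hap = "TwoSnpHaplotypeModel",
                 pen = "PenetranceModel", prevalence = "numeric",
                 linked = "logical", seed = "integer"))

setValidity("SimDesign", function(object) {
  msg <- character(0)
  if (object@nDsp < 1L) msg <- c(msg, "nDsp must be >= 1")
  if (object@prevalence <= 0 || object@prevalence >= 1)
    msg <- c(msg, "prevalence must be in (0, 1)")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SimDesign", function(object) {
  cat(sprintf("SimDesign: %d DSPs, prevalence %.3g, %s transmission\n",
              object@nDsp, object@prevalence,
              if (object@linked) "linked" else "unlinked"))
  show(object@hap); show(object@pen)
})

#' Interaction test result for one SNP pair
#'
#' @slot snp1,snp2 SNP identifiers.
#' @slot kUsed number of families with complete genotypes at both SNPs.
#' @slot logOrCase,logOrCtrl log odds ratios in affected / unaffected sibs.
#' @slot varLogOrCase variance of the case log odds ratio under the
#'   within-family label-exchange null.
#' @slot gDsp the Z statistic (difference of log ORs over
#'   \code{sqrt(4 * varLogOrCase)}).
#' @slot pValue two-sided standard-normal p-value.
#' @slot status "OK" or a non-testability reason ("ZERO_CELL",
#'   "DEGENERATE", "NO_DATA").
#' @seealso [gdsp()]
#' @exportClass InteractionResult
setClass("InteractionResult",
  representation(snp1 = "character", snp2 = "character", kUsed = "integer",
                 logOrCase = "numeric", logOrCtrl = "numeric",
                 varLogOrCase = "numeric", gDsp = "numeric",
                 pValue = "numeric", status = "character"))

setMethod("show", "InteractionResult", function(object) {
  cat(sprintf("InteractionResult %s x %s (k = %d): %s\n",
              object@snp1, object@snp2, object@kUsed, object@status))
  if (identical(object@status, "OK"))
    cat(sprintf(
      "  log OR case %.4f, control %.4f; var %.5g; G = %.4f, p = %.4g\n",
      object@logOrCase, object@logOrCtrl, object@varLogOrCase,
      object@gDsp, object@pValue))
})
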