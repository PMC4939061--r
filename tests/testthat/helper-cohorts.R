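# Shared fixture builders (all data generated in code).

.testMap <- function(p = 2L, chrom = NULL) {
  data.frame(chrom = if (is.null(chrom)) as.character(seq_len(p)) else chrom,
             snp = paste0("s", seq_len(p)),
             pos = 1000L * seq_len(p),
             minor = "A", major = "G", stringsAsFactors = FALSE)
}

# Cohort from explicit genotype-code vectors at two SNPs.
makeCohort <- function(aff1, aff2, un1, un2, chrom = c("1", "2")) {
  DspCohort(cbind(aff1, aff2), cbind(un1, un2),
            .testMap(2L, chrom = chrom))
}

# Random k-family, p-SNP cohort with iid genotype codes.
randomCohort <- function(k, p = 2L, seed = 1L, probs = c(0.2, 0.35, 0.45)) {
  set.seed(seed)
  DspCohort(matrix(sample(1:3, k * p, TRUE, probs), k, p),
            matrix(sample(1:3, k * p, TRUE, probs), k, p),
            .testMap(p))
}

# Independent brute-force covariance of the affected-table cell counts
# over all 2^k within-family label swaps (population divisor).
enumCellCov <- function(u, v) {
  k <- length(u)
  B <- 2L^k
  X <- matrix(0, B, 9L)
  for (b in 0:(B - 1L)) {
    bits <- bitwAnd(b, bitwShiftL(1L, 0:(k - 1L))) > 0L
    X[b + 1L, ] <- tabulate(ifelse(bits, v, u), 9L)
  }
  Xc <- sweep(X, 2L, colMeans(X))
  crossprod(Xc) / B
}

# Write a PED/MAP fixture from a character matrix of rows (samples x
# fields) and a map data.frame; returns the two paths.
writePedMapFiles <- function(pedLines, mapLines, gz = FALSE) {
  ped <- tempfile(fileext = if (gz) ".ped.gz" else ".ped")
  map <- tempfile(fileext = if (gz) ".map.gz" else ".map")
  wl <- function(lines, path) {
    con <- if (gz) gzfile(path, "wt") else file(path, "wt")
    writeLines(lines, con); close(con)
  }
  wl(pedLines, ped); wl(mapLines, map)
  c(ped = ped, map = map)
}
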