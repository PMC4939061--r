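#' Enumerate SNP pairs for a scan
#'
#' Produces the ordered pair stream (matrix of column indices, first
#' member before the second in map order, deterministic order) for one of
#' four modes: all pairs; between-gene pairs (both SNPs genic with
#' disjoint gene sets, so same-gene pairs are excluded); all cross pairs
#' between two chromosomes (within-chromosome pairs when \code{c1 == c2});
#' or an explicit pair list of SNP ids.
#'
#' @param map marker map data.frame ([markerInfo()]).
#' @param mode one of "all", "between_genes", "chrom_pair", "pair_list".
#' @param geneSets named list from [assignSnpsToGenes()] (between_genes).
#' @param chrPair length-2 character vector of chromosomes (chrom_pair).
#' @param pairList 2-column matrix or data.frame of SNP ids (pair_list).
#' @return Integer matrix with columns \code{i}, \code{j} (map indices,
#'   i < j); zero rows (with a warning) if nothing qualifies.
#' @export
enumeratePairs <- function(map,
                           mode = c("all", "between_genes", "chrom_pair",
                                    "pair_list"),
                           geneSets = NULL, chrPair = NULL,
                           pairList = NULL) {
  mode <- match.arg(mode)
  p <- nrow(map)
  allPairs <- function(idx) {
    m <- length(idx)
    if (m < 2L) return(cbind(i = integer(0), j = integer(0)))
    i <- rep.int(seq_len(m - 1L), times = (m - 1L):1L)
    j <- sequence((m - 1L):1L) + i
    cbind(i = idx[i], j = idx[j])
  }
  pairs <- switch(mode,
    all = allPairs(seq_len(p)),
    between_genes = {
      if (is.null(geneSets))
        stop("between_genes mode requires geneSets")
      genic <- which(lengths(geneSets[map$snp]) > 0L)
      cand <- allPairs(genic)
      if (nrow(cand)) {
        keep <- vapply(seq_len(nrow(cand)), function(r) {
          length(intersect(geneSets[[map$snp[cand[r, 1L]]]],
                           geneSets[[map$snp[cand[r, 2L]]]])) == 0L
        }, logical(1L))
        cand[keep, , drop = FALSE]
      } else cand
    },
    chrom_pair = {
      if (is.null(chrPair) || length(chrPair) != 2L)
        stop("chrom_pair mode requires chrPair = c(c1, c2)")
      c1 <- as.character(chrPair[1L]); c2 <- as.character(chrPair[2L])
      if (c1 == c2) {
        allPairs(which(map$chrom == c1))
      } else {
        i1 <- which(map$chrom == c1); i2 <- which(map$chrom == c2)
        g <- expand.grid(a = i1, b = i2)
        m <- cbind(i = pmin(g$a, g$b), j = pmax(g$a, g$b))
        m <- m[order(m[, 1L], m[, 2L]), , drop = FALSE]
        m
      }
    },
    pair_list = {
      pl <- as.matrix(pairList)
      i <- match(pl[, 1L], map$snp); j <- match(pl[, 2L], map$snp)
      if (anyNA(i) || anyNA(j))
        stop("pair_list contains unknown SNP ids")
      cbind(i = pmin(i, j), j = pmax(i, j))
    })
  if (nrow(pairs) == 0L) warning("empty SNP pair stream")
  storage.mode(pairs) <- "integer"
  dimnames(pairs) <- list(NULL, c("i", "j"))
  pairs
}

#' Genome-wide pairwise interaction scan
#'
#' Scores every enumerated SNP pair with [gdsp()]. SNPs whose sib minor
#' allele frequency is below \code{mafMin}, or which are monomorphic among
#' the sibs, are skipped together with all their pairs; the skipped pairs
#' and reasons are attached as the \code{"skipped"} attribute, so that
#' \code{nrow(result) + nrow(skipped)} equals the enumerated pair count
#' (when \code{reportThreshold = 1}). The pair stream is partitioned into
#' \code{workers} contiguous chunks scored in parallel and merged back in
#' enumeration order, so the output is identical for any worker count.
#'
#' @param cohort a [DspCohort-class].
#' @param pairs pair matrix from [enumeratePairs()]; default all pairs.
#' @param mafMin minimum sib MAF (default 0.01).
#' @param workers number of parallel workers (forked; default 1).
#' @param haldane passed to the statistic (see [gdsp()]).
#' @param reportThreshold report only rows with p <= threshold
#'   (non-testable rows are always kept); default 1 reports everything.
#' @return data.frame with columns CHR1, SNP1, CHR2, SNP2, K_USED,
#'   LOG_OR_CASE, LOG_OR_CTRL, VAR, G_DSP, P, STATUS; attributes
#'   \code{skipped} (data.frame SNP1, SNP2, REASON) and
#'   \code{nEnumerated}.
#' @seealso [writeScanResults()]
#' @export
runScan <- function(cohort, pairs = NULL, mafMin = 0.01, workers = 1L,
                    haldane = FALSE, reportThreshold = 1) {
  map <- cohort@map
  if (is.null(pairs)) pairs <- enumeratePairs(map)
  nEnum <- nrow(pairs)
  maf <- sibMaf(cohort)
  badSnp <- is.na(maf) | maf < mafMin | maf == 0
  bad <- badSnp[pairs[, 1L]] | badSnp[pairs[, 2L]]
  skipped <- data.frame(SNP1 = map$snp[pairs[bad, 1L]],
                        SNP2 = map$snp[pairs[bad, 2L]],
                        REASON = rep("MAF_FILTER", sum(bad)),
                        stringsAsFactors = FALSE)
  pairs <- pairs[!bad, , drop = FALSE]

  scoreChunk <- function(rows) {
    n <- length(rows)
    out <- data.frame(
      CHR1 = character(n), SNP1 = character(n), CHR2 = character(n),
      SNP2 = character(n), K_USED = integer(n), LOG_OR_CASE = numeric(n),
      LOG_OR_CTRL = numeric(n), VAR = numeric(n), G_DSP = numeric(n),
      P = numeric(n), STATUS = character(n), stringsAsFactors = FALSE)
    for (r in seq_len(n)) {
      i <- pairs[rows[r], 1L]; j <- pairs[rows[r], 2L]
      st <- .pairStat(cohort@aff[, i], cohort@aff[, j],
                      cohort@unaff[, i], cohort@unaff[, j],
                      haldane = haldane)
      out[r, ] <- list(map$chrom[i], map$snp[i], map$chrom[j], map$snp[j],
                       st$kUsed, st$logOrCase, st$logOrCtrl,
                       st$varLogOrCase, st$gDsp, st$pValue, st$status)
    }
    out
  }

  n <- nrow(pairs)
  if (n == 0L) {
    res <- scoreChunk(integer(0))
  } else {
    workers <- max(1L, as.integer(workers))
    chunkId <- ceiling(seq_len(n) / ceiling(n / workers))
    chunks <- split(seq_len(n), factor(chunkId, levels = unique(chunkId)))
    parts <- if (workers > 1L)
      parallel::mclapply(chunks, scoreChunk, mc.cores = workers)
    else lapply(chunks, scoreChunk)
    res <- do.call(rbind, parts)
    rownames(res) <- NULL
  }
  keep <- is.na(res$P) | res$P <= reportThreshold
  res <- res[keep, , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "skipped") <- skipped
  attr(res, "nEnumerated") <- nEnum
  res
}

#' Write scan results as TSV
#'
#' Fixed column order, header line, tab-separated; identical inputs give
#' byte-identical files.
#'
#' @param results data.frame from [runScan()].
#' @param path output file path.
#' @return Invisibly, \code{path}.
#' @export
writeScanResults <- function(results, path) {
  write.table(results, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE)
  invisible(path)
}
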