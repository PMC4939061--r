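#' Read PLINK text PED/MAP pedigree genotype data
#'
#' Parses whitespace-delimited PED (6 leading columns, then two allele
#' columns per SNP) and MAP (chromosome, SNP id, genetic distance,
#' base-pair position) files. Plain or gzip-compressed files are accepted.
#' Per SNP, the minor allele is the less frequent allele among all
#' individuals in the file (founders and sibs); ties are broken toward the
#' lexicographically smaller allele symbol. Genotypes are coded 1 =
#' minor/minor, 2 = heterozygous, 3 = major/major; any "0" allele makes the
#' genotype missing (\code{NA}).
#'
#' @param pedFile,mapFile paths to the PED and MAP files.
#' @return A list with components \code{samples} (data.frame: \code{fam},
#'   \code{id}, \code{father}, \code{mother}, \code{sex},
#'   \code{phenotype}), \code{genotypes} (integer matrix, individuals x
#'   SNPs), and \code{map} (data.frame: \code{chrom}, \code{snp},
#'   \code{pos}, \code{minor}, \code{major}).
#' @seealso [extractDsps()], [writePedMap()]
#' @export
readPedMap <- function(pedFile, mapFile) {
  map <- .readDelimLines(mapFile)
  bad <- which(lengths(map) != 4L)
  if (length(bad))
    stop("MAP parse error at line ", bad[1L], ": expected 4 fields, found ",
         length(map[[bad[1L]]]))
  map <- data.frame(
    chrom = vapply(map, `[`, "", 1L),
    snp   = vapply(map, `[`, "", 2L),
    pos   = as.integer(vapply(map, `[`, "", 4L)),
    stringsAsFactors = FALSE)
  if (anyNA(map$pos) || any(map$pos < 0))
    stop("MAP positions must be non-negative integers")
  if (anyDuplicated(map$snp))
    stop("duplicated SNP ids in MAP: ",
         map$snp[anyDuplicated(map$snp)])
  p <- nrow(map)

  ped <- .readDelimLines(pedFile)
  want <- 6L + 2L * p
  bad <- which(lengths(ped) != want)
  if (length(bad))
    stop("PED parse error at line ", bad[1L], ": expected ", want,
         " fields (6 + 2 x ", p, " SNPs), found ", length(ped[[bad[1L]]]))
  n <- length(ped)
  if (n == 0L) stop("PED file is empty")
  pedm <- matrix(unlist(ped, use.names = FALSE), nrow = n, byrow = TRUE)
  samples <- data.frame(
    fam = pedm[, 1L], id = pedm[, 2L], father = pedm[, 3L],
    mother = pedm[, 4L], sex = as.integer(pedm[, 5L]),
    phenotype = as.integer(pedm[, 6L]), stringsAsFactors = FALSE)
  if (!all(samples$phenotype %in% c(-9L, 0L, 1L, 2L)))
    stop("phenotype must be 2 (affected), 1 (unaffected), 0 or -9 (missing)")

  a1 <- pedm[, 6L + 2L * seq_len(p) - 1L, drop = FALSE]
  a2 <- pedm[, 6L + 2L * seq_len(p), drop = FALSE]
  geno <- matrix(NA_integer_, n, p,
                 dimnames = list(samples$id, map$snp))
  minor <- major <- character(p)
  for (s in seq_len(p)) {
    al <- c(a1[, s], a2[, s])
    obs <- al[al != "0"]
    syms <- sort(unique(obs))
    if (length(syms) > 2L)
      stop("SNP ", map$snp[s], " has more than two alleles: ",
           paste(syms, collapse = ", "))
    if (length(syms) == 0L) {
      minor[s] <- NA_character_; major[s] <- NA_character_
      next
    }
    if (length(syms) == 1L) {
      # monomorphic: the single observed allele is the major allele
      minor[s] <- NA_character_; major[s] <- syms
      cnt1 <- 0L
    } else {
      tab <- c(sum(obs == syms[1L]), sum(obs == syms[2L]))
      # less frequent allele is minor; tie -> lexicographically smaller
      minor[s] <- if (tab[1L] <= tab[2L]) syms[1L] else syms[2L]
      major[s] <- setdiff(syms, minor[s])
    }
    miss <- a1[, s] == "0" | a2[, s] == "0"
    cntMinor <- (a1[, s] == minor[s]) + (a2[, s] == minor[s])
    if (length(syms) == 1L) cntMinor <- rep(0L, n)
    g <- 3L - as.integer(cntMinor)
    g[miss] <- NA_integer_
    geno[, s] <- g
  }
  map$minor <- minor
  map$major <- major
  list(samples = samples, genotypes = geno, map = map)
}

# readLines with transparent gzip handling, split on whitespace
.readDelimLines <- function(path) {
  con <- file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  strsplit(trimws(lines), "[ \t]+")
}

#' Extract one discordant sib pair per nuclear family
#'
#' Sibs are non-founders (both parent ids nonzero); a nuclear family is a
#' set of full sibs sharing the same (family id, father id, mother id).
#' Half-sibs form separate sibships. For each nuclear family containing at
#' least one affected (phenotype 2) and one unaffected (phenotype 1) sib,
#' the first affected and the first unaffected sib in file order form the
#' pair; other families contribute nothing, and parents never enter the
#' cohort.
#'
#' @param pedData the list returned by [readPedMap()].
#' @return A [DspCohort-class].
#' @export
extractDsps <- function(pedData) {
  s <- pedData$samples
  isSib <- s$father != "0" & s$mother != "0"
  key <- paste(s$fam, s$father, s$mother, sep = "\r")
  affIdx <- unaffIdx <- integer(0)
  famIds <- character(0)
  for (k in unique(key[isSib])) {
    rows <- which(isSib & key == k)
    a <- rows[s$phenotype[rows] == 2L]
    u <- rows[s$phenotype[rows] == 1L]
    if (length(a) >= 1L && length(u) >= 1L) {
      affIdx <- c(affIdx, a[1L])
      unaffIdx <- c(unaffIdx, u[1L])
      famIds <- c(famIds, s$fam[a[1L]])
    }
  }
  if (length(affIdx) == 0L)
    stop("no discordant sib pairs found in the pedigree")
  DspCohort(pedData$genotypes[affIdx, , drop = FALSE],
            pedData$genotypes[unaffIdx, , drop = FALSE],
            pedData$map, famIds)
}

#' Write a DSP cohort as PLINK text PED/MAP
#'
#' Each family is written as two sib rows (affected first, phenotype 2;
#' unaffected second, phenotype 1) with synthetic nonzero parent ids, so
#' that [readPedMap()] + [extractDsps()] round-trips the cohort. Genotype
#' codes are expanded with the map's minor/major allele symbols; missing
#' genotypes become "0 0".
#'
#' @param cohort a [DspCohort-class].
#' @param prefix output path prefix; writes \code{prefix.ped} and
#'   \code{prefix.map}.
#' @return Invisibly, the two file paths.
#' @export
writePedMap <- function(cohort, prefix) {
  map <- cohort@map
  minor <- ifelse(is.na(map$minor), "A", map$minor)
  major <- ifelse(is.na(map$major), "G", map$major)
  code2al <- function(g) {
    # 2 x p allele symbols for one individual's code vector
    a1 <- ifelse(is.na(g), "0", ifelse(g == 1L, minor, ifelse(g == 2L, minor, major)))
    a2 <- ifelse(is.na(g), "0", ifelse(g == 1L, minor, major))
    as.vector(rbind(a1, a2))
  }
  k <- nDsp(cohort)
  lines <- character(2L * k)
  for (i in seq_len(k)) {
    fam <- cohort@family[i]
    fa <- paste0(fam, "_fa"); mo <- paste0(fam, "_mo")
    lines[2L * i - 1L] <- paste(c(fam, paste0(fam, "_aff"), fa, mo, 0L, 2L,
                                  code2al(cohort@aff[i, ])), collapse = " ")
    lines[2L * i] <- paste(c(fam, paste0(fam, "_una"), fa, mo, 0L, 1L,
                             code2al(cohort@unaff[i, ])), collapse = " ")
  }
  pedPath <- paste0(prefix, ".ped"); mapPath <- paste0(prefix, ".map")
  writeLines(lines, pedPath)
  writeLines(paste(map$chrom, map$snp, 0L, map$pos), mapPath)
  invisible(c(pedPath, mapPath))
}

#' Read gene annotation intervals
#'
#' Tab-delimited intervals with columns chromosome, start, end, gene name.
#' By default coordinates are 1-based inclusive; \code{format = "bed"}
#' treats them as 0-based half-open (BED) and converts. Chromosome names
#' are kept verbatim. Plain or gzip-compressed files are accepted.
#'
#' @param path annotation file path.
#' @param format "onebased" (default) or "bed".
#' @return A [GenomicRanges::GRanges] with a \code{name} metadata column.
#' @seealso [assignSnpsToGenes()]
#' @export
readGeneIntervals <- function(path, format = c("onebased", "bed")) {
  format <- match.arg(format)
  con <- file(path, "rt")
  on.exit(close(con))
  df <- read.table(con, sep = "\t", header = FALSE,
                   colClasses = c("character", "integer", "integer",
                                  "character"),
                   col.names = c("chrom", "start", "end", "name"))
  if (format == "bed") df$start <- df$start + 1L
  if (any(df$start > df$end))
    stop("interval with start > end at row ", which(df$start > df$end)[1L])
  GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end),
                         name = df$name)
}

#' Assign SNPs to the genes containing them
#'
#' A SNP belongs to every gene whose interval (1-based inclusive) contains
#' its position; intergenic SNPs get an empty gene set.
#'
#' @param map marker map data.frame (from [readPedMap()] or
#'   [markerInfo()]).
#' @param genes GRanges from [readGeneIntervals()].
#' @return Named list (by SNP id) of character vectors of gene names.
#' @export
assignSnpsToGenes <- function(map, genes) {
  snpGr <- GenomicRanges::GRanges(map$chrom,
                                  IRanges::IRanges(map$pos, map$pos))
  hits <- GenomicRanges::findOverlaps(snpGr, genes)
  sets <- rep(list(character(0)), nrow(map))
  names(sets) <- map$snp
  if (length(hits)) {
    sp <- split(S4Vectors::mcols(genes)$name[S4Vectors::subjectHits(hits)],
                S4Vectors::queryHits(hits))
    for (q in names(sp)) sets[[as.integer(q)]] <- sort(unique(sp[[q]]))
  }
  sets
}
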