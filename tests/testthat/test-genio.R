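mapLines2 <- c("1 s1 0 100", "2 s2 0 200")

test_that("PED genotypes are coded against the sample minor allele", {
  # s1: allele A appears 3 times, G 5 times -> A minor
  # s2: C and T appear 4 times each -> tie, C (lexicographic) minor
  ped <- c(
    "F1 p1 0 0 1 1  A G  C C",
    "F1 p2 0 0 2 1  G G  T T",
    "F1 k1 p1 p2 1 2  A A  C T",
    "F1 k2 p1 p2 2 1  G G  C T")
  f <- writePedMapFiles(ped, mapLines2)
  pd <- readPedMap(f["ped"], f["map"])
  expect_identical(pd$map$minor, c("A", "C"))
  expect_identical(pd$map$major, c("G", "T"))
  expect_identical(unname(pd$genotypes[, "s1"]), c(2L, 3L, 1L, 3L))
  expect_identical(unname(pd$genotypes[, "s2"]), c(1L, 3L, 2L, 2L))
})

test_that("missing alleles and malformed lines are handled", {
  ped <- c(
    "F1 k1 p1 p2 1 2  0 0  C C",
    "F1 k2 p1 p2 1 1  A G  C 0")
  f <- writePedMapFiles(ped, mapLines2)
  pd <- readPedMap(f["ped"], f["map"])
  expect_true(is.na(pd$genotypes[1L, "s1"]))
  expect_true(is.na(pd$genotypes[2L, "s2"]))
  expect_false(anyNA(pd$genotypes[2L, "s1"]))

  bad <- writePedMapFiles(c("F1 k1 p1 p2 1 2  A G", ped[2L]), mapLines2)
  expect_error(readPedMap(bad["ped"], bad["map"]), "line 1")
  badMap <- writePedMapFiles(ped, c("1 s1 0", "2 s2 0 200"))
  expect_error(readPedMap(badMap["ped"], badMap["map"]), "line 1")
})

test_that("gzip-compressed PED/MAP files are read transparently", {
  ped <- c("F1 k1 p1 p2 1 2  A A  C C", "F1 k2 p1 p2 1 1  G G  T T")
  f <- writePedMapFiles(ped, mapLines2, gz = TRUE)
  pd <- readPedMap(f["ped"], f["map"])
  expect_identical(dim(pd$genotypes), c(2L, 2L))
  expect_identical(pd$map$snp, c("s1", "s2"))
})

test_that("extractDsps takes one first-in-file pair per nuclear family", {
  ped <- c(
    # F1: two affected then two unaffected sibs -> pair (a1, u1)
    "F1 a1 p1 p2 1 2  A A  C C",
    "F1 a2 p1 p2 1 2  A G  T T",
    "F1 u1 p1 p2 2 1  G G  T T",
    "F1 u2 p1 p2 2 1  G G  C T",
    # F2: concordant affected sibs -> dropped
    "F2 b1 q1 q2 1 2  A G  C T",
    "F2 b2 q1 q2 1 2  A G  C T",
    # F3: parents present (founders), one discordant pair
    "F3 r1 0 0 1 1  A G  C T",
    "F3 r2 0 0 2 2  A G  C T",
    "F3 c1 r1 r2 1 2  A A  T T",
    "F3 c2 r1 r2 1 1  G G  C C",
    # F4: half sibs (different mothers) -> two sibships, no pair in either
    "F4 d1 s1 s2 1 2  A G  C T",
    "F4 d2 s1 s3 1 1  A G  C T")
  f <- writePedMapFiles(ped, mapLines2)
  pd <- readPedMap(f["ped"], f["map"])
  co <- extractDsps(pd)
  expect_s4_class(co, "DspCohort")
  expect_identical(nDsp(co), 2L)
  expect_identical(co@family, c("F1", "F3"))
  # F1 affected = a1 (A A -> code 1 at s1); unaffected = u1 (G G -> 3)
  expect_identical(unname(affGenotypes(co)[1L, ]), c(1L, 1L))
  expect_identical(unname(unaffGenotypes(co)[1L, ]), c(3L, 3L))
  # affected parent r2 in F3 never enters the cohort
  expect_identical(nDsp(co), 2L)

  none <- writePedMapFiles(ped[5:8], mapLines2)
  expect_error(extractDsps(readPedMap(none["ped"], none["map"])),
               "no discordant sib pairs")
})

test_that("writePedMap round-trips genotype codes through the reader", {
  co <- randomCohort(25L, p = 3L, seed = 42L)
  prefix <- tempfile()
  writePedMap(co, prefix)
  co2 <- extractDsps(readPedMap(paste0(prefix, ".ped"),
                                paste0(prefix, ".map")))
  expect_identical(unname(affGenotypes(co2)), unname(affGenotypes(co)))
  expect_identical(unname(unaffGenotypes(co2)), unname(unaffGenotypes(co)))
  expect_identical(markerInfo(co2)$snp, markerInfo(co)$snp)
})

test_that("SNP-to-gene assignment respects 1-based inclusive bounds", {
  gfile <- tempfile(fileext = ".txt")
  writeLines(c("1\t50\t150\tGENE_A", "1\t140\t300\tGENE_B",
               "2\t10\t20\tGENE_C"), gfile)
  genes <- readGeneIntervals(gfile)
  map <- data.frame(chrom = c("1", "1", "1", "2"),
                    snp = c("in1", "edge", "out", "none"),
                    pos = c(100L, 150L, 301L, 25L),
                    minor = "A", major = "G", stringsAsFactors = FALSE)
  sets <- assignSnpsToGenes(map, genes)
  expect_identical(sets$in1, "GENE_A")
  expect_identical(sets$edge, c("GENE_A", "GENE_B"))  # inclusive end, 2 genes
  expect_identical(sets$out, character(0))
  expect_identical(sets$none, character(0))

  # BED dialect: 0-based half-open [49, 150) == 1-based [50, 150]
  bfile <- tempfile(fileext = ".bed")
  writeLines("1\t49\t150\tGENE_A", bfile)
  bed <- readGeneIntervals(bfile, format = "bed")
  setsB <- assignSnpsToGenes(map[1:2, ], bed)
  expect_identical(setsB$in1, "GENE_A")
  expect_identical(setsB$edge, "GENE_A")
})
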