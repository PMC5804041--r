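# readers, writers and phenotype summaries

test_that("count tables read back what was written and validate input", {
  tf <- writeTempTsv(c("feature_id\ts1\ts2", "g1\t0\t5", "g2\t3\t1"))
  cm <- readCounts(tf, layer = "mRNA")
  expect_identical(unname(counts(cm)), matrix(c(0, 3, 5, 1), 2))
  expect_identical(featureIds(cm), c("g1", "g2"))
  expect_identical(sampleIds(cm), c("s1", "s2"))
  expect_identical(layer(cm), "mRNA")

  # write -> read -> write round-trips byte-identically
  out1 <- tempfile(); out2 <- tempfile()
  writeCounts(cm, out1)
  writeCounts(readCounts(out1, layer = "mRNA"), out2)
  expect_identical(readLines(out1), readLines(out2))

  dup <- writeTempTsv(c("feature_id\ts1", "g1\t1", "g1\t2"))
  expect_error(readCounts(dup, "mRNA"), "g1")
  bad <- writeTempTsv(c("feature_id\ts1\ts2", "g1\t1\t-2"))
  expect_error(readCounts(bad, "mRNA"), "g1.*s2")
  frac <- writeTempTsv(c("feature_id\ts1", "g1\t1.5"))
  expect_error(readCounts(frac, "mRNA"), "g1")
})

test_that("CountMatrix validity rejects malformed input", {
  m <- matrix(1:4, 2, dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_s4_class(CountMatrix(m, "miRNA"), "CountMatrix")
  m2 <- m; m2[1] <- -1
  expect_error(CountMatrix(m2, "miRNA"), "non-negative")
})

test_that("phenotype reader types columns and enforces the group labels", {
  ph <- readPhenotypes(phenotypesPath())
  expect_identical(nrow(ph), 30L)
  expect_identical(as.vector(table(ph$group)), c(15L, 15L))
  expect_type(ph$imf_percent, "double")

  expect_error(readPhenotypes(writeTempTsv("sample_id\tgroup")),
               "no samples")
  expect_error(
    readPhenotypes(writeTempTsv(c("sample_id\timf_percent", "s1\t1"))),
    "group")
  expect_error(
    readPhenotypes(writeTempTsv(
      c("sample_id\tgroup\timf_percent", "s1\tH\t2.0", "s2\tM\t1.0"))),
    "M")
  expect_error(
    readPhenotypes(writeTempTsv(
      c("sample_id\tgroup\timf_percent", "s1\tH\ttwo"))),
    "imf_percent.*row 1")

  out <- tempfile()
  writePhenotypes(ph, out)
  expect_identical(readPhenotypes(out), ph)
})

test_that("per-group summaries reproduce the printed phenotype means", {
  ph <- readPhenotypes(phenotypesPath())
  ulp <- function(x, printed, digits)
    expect_lte(abs(round(x, digits) - printed), 10^(-digits) + 1e-12)

  s <- summarizePhenotypes(ph, "imf_percent")
  ulp(s$mean[s$group == "H"], 4.306, 3)
  ulp(s$mean[s$group == "L"], 1.508, 3)
  s <- summarizePhenotypes(ph, "gebv")
  ulp(s$mean[s$group == "H"], 0.592, 3)
  ulp(s$mean[s$group == "L"], -0.432, 3)
  s <- summarizePhenotypes(ph, "mapped_reads")
  ulp(s$mean[s$group == "H"], 735255.28, 2)
  ulp(s$mean[s$group == "L"], 756385.08, 2)
})

test_that("summaries are permutation-invariant, affine-linear, and handle n = 1", {
  ph <- readPhenotypes(phenotypesPath())
  set.seed(1)
  perm <- ph[sample.int(nrow(ph)), ]
  expect_equal(summarizePhenotypes(perm, "gebv")$mean,
               summarizePhenotypes(ph, "gebv")$mean)
  ph2 <- ph; ph2$gebv <- 3 * ph$gebv + 1
  expect_equal(summarizePhenotypes(ph2, "gebv")$mean,
               3 * summarizePhenotypes(ph, "gebv")$mean + 1)

  single <- data.frame(sample_id = c("a", "b"), group = c("H", "L"),
                       y = c(2.5, 1))
  s <- summarizePhenotypes(single, "y")
  expect_equal(s$mean, c(2.5, 1))
  expect_equal(s$sd, c(0, 0))
  expect_true(all(s$sd_flag))
})

test_that("the Welch comparison matches the reported contrast and its conventions", {
  ph <- readPhenotypes(phenotypesPath())
  cg <- compareGroups(ph, "gebv")
  expect_lte(cg$p.value, 2.2e-16)

  # swapping the group labels negates t, p unchanged
  ph2 <- ph; ph2$group <- ifelse(ph$group == "H", "L", "H")
  cg2 <- compareGroups(ph2, "gebv")
  expect_equal(cg2$statistic, -cg$statistic)
  expect_equal(cg2$p.value, cg$p.value)

  same <- data.frame(sample_id = letters[1:4], group = c("H", "H", "L", "L"),
                     y = c(1, 1, 1, 1))
  cs <- compareGroups(same, "y")
  expect_identical(cs$statistic, 0)
  expect_identical(cs$p.value, 1)
})

test_that("Welch p agrees with a permutation null for Gaussian data", {
  set.seed(11)
  y <- rnorm(30)
  grp <- rep(c("H", "L"), each = 15)
  ph <- data.frame(sample_id = sprintf("s%02d", 1:30), group = grp, y = y)
  obs <- compareGroups(ph, "y")

  welch <- function(a, b) {
    (mean(a) - mean(b)) / sqrt(var(a) / length(a) + var(b) / length(b))
  }
  nPerm <- 4000L
  t0 <- abs(welch(y[grp == "H"], y[grp == "L"]))
  perm <- replicate(nPerm, {
    g <- sample(grp)
    abs(welch(y[g == "H"], y[g == "L"]))
  })
  pPerm <- (1 + sum(perm >= t0)) / (nPerm + 1)
  mcSd <- sqrt(pPerm * (1 - pPerm) / nPerm)
  expect_lt(abs(obs$p.value - pPerm), 4 * mcSd + 0.01)
})

test_that("annotation readers aggregate GMT and TSV pairs identically", {
  gmt <- writeTempTsv(c("GO:0006006\tglucose metabolic process\tg1\tg2",
                        "GO:0000001\tother\tg3"))
  a1 <- readAnnotation(gmt, format = "gmt")
  expect_identical(sort(a1[["GO:0006006"]]), c("g1", "g2"))
  expect_identical(attr(a1, "descriptions")[["GO:0006006"]],
                   "glucose metabolic process")

  tsv <- writeTempTsv(c("GO:0006006\tg1", "GO:0006006\tg2",
                        "GO:0000001\tg3"))
  a2 <- readAnnotation(tsv, format = "tsv")
  expect_identical(lapply(a1, sort)[names(a2)], lapply(a2, sort))

  out <- tempfile(fileext = ".gmt")
  writeAnnotation(a1, out)
  expect_identical(readAnnotation(out, "gmt")[names(a1)], a1[names(a1)])

  expect_warning(readAnnotation(writeTempTsv(c("\tx\tg1", "t\td\tg1")),
                                "gmt"), "empty term")
})

test_that("FASTA reading uppercases, concatenates, validates and round-trips", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">u1 some description", "acgt", ">u2", "AAA", "CCC"), fa)
  ss <- readSequenceSet(fa)
  expect_identical(ss, c(u1 = "ACGT", u2 = "AAACCC"))

  out <- tempfile(fileext = ".fa")
  writeSequenceSet(ss, out)
  expect_identical(readSequenceSet(out), ss)

  writeLines(c(">a", "ACGT", ">a", "CCCC"), fa)
  expect_error(readSequenceSet(fa), "duplicate")
  writeLines(c(">a", "ACXT"), fa)
  expect_error(readSequenceSet(fa), "a")
})
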