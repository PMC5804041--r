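# the synthetic paired-count generator and its planted truth

test_that("the generator is deterministic and produces valid containers", {
  cfg <- smallConfig(seed = 4L)
  d1 <- generateDataset(cfg)
  d2 <- generateDataset(cfg)
  expect_identical(counts(d1$mrna), counts(d2$mrna))
  expect_identical(counts(d1$mirna), counts(d2$mirna))
  expect_identical(d1$phenotypes, d2$phenotypes)
  expect_identical(trueModules(d1$truth), trueModules(d2$truth))

  expect_true(all(counts(d1$mrna) >= 0))
  expect_true(all(counts(d1$mrna) == round(counts(d1$mrna))))
  expect_identical(layer(d1$mirna), "miRNA")
  expect_error(generateDataset(
    simConfig(modules = data.frame(name = "A", layer = "mRNA", size = 10L,
                                   loading = 0.7, factor = "A"),
              regulatorSpec = list(feature = "mir_0001",
                                   targetModule = "nope",
                                   loadingH = 1, loadingL = 0),
              hubSpec = list(),
              traitSpec = list(driverModule = "A", slope = 1,
                               noiseSd = 0.4, baseline = 3))),
    "unknown module")
})

test_that("planted log2 fold changes are recovered empirically at large n", {
  # 10 features with log2FC = 1.0 at n = 50 per group, dispersion 0.05
  cfg <- simConfig(
    nPerGroup = 50L, nGenes = 20L, nMirnas = 30L,
    modules = emptyModuleSpec(),
    deSpec = data.frame(feature = sprintf("mir_%04d", 1:10),
                        log2fc = rep(1.0, 10)),
    regulatorSpec = list(), hubSpec = list(), traitSpec = list(),
    dispersion = 0.05, seed = 21L)
  ds <- generateDataset(cfg)
  # normalize by the generator's own library factors (mapped_reads is
  # proportional to the drawn factor); the estimator's behaviour under
  # many DE features is a separate concern of the DE stage
  lib <- ds$phenotypes$mapped_reads / mean(ds$phenotypes$mapped_reads)
  norm <- sweep(counts(ds$mirna), 2, lib, `/`)
  grp <- ds$phenotypes$group
  lfc <- log2(rowMeans(norm[1:10, grp == "L"]) /
                rowMeans(norm[1:10, grp == "H"]))
  expect_lt(abs(mean(lfc) - 1.0), 0.15)
})

test_that("zero loadings give uncorrelated features, and correlation grows with loading", {
  base <- function(loading, seed) {
    mods <- if (loading > 0)
      data.frame(name = "A", layer = "mRNA", size = 30L,
                 loading = loading, factor = "A")
    else emptyModuleSpec()
    # module is a minority of the features so the median-of-ratios
    # normalization is anchored on the unstructured background
    cfg <- simConfig(nPerGroup = 50L, nGenes = 200L, nMirnas = 2L,
                     modules = mods,
                     deSpec = data.frame(feature = character(),
                                         log2fc = numeric()),
                     regulatorSpec = list(), hubSpec = list(),
                     traitSpec = list(), seed = seed)
    ds <- generateDataset(cfg)
    ex <- exprValues(normalizeCounts(ds$mrna))
    r <- cor(t(ex[1:30, ]))
    mean(r[upper.tri(r)])
  }
  expect_lt(abs(base(0, 31L)), 0.05)
  r02 <- base(0.2, 32L); r05 <- base(0.5, 32L); r08 <- base(0.8, 32L)
  expect_true(r02 < r05 && r05 < r08)
  expect_gt(r08, 0.4)
})

test_that("regulator wiring difference matches the configured sign", {
  cfg <- smallConfig(seed = 6L)
  ds <- generateDataset(cfg)
  ph <- ds$phenotypes
  ex <- exprValues(normalizeCounts(ds$mirna))
  tm <- trueModules(ds$truth)
  members <- intersect(names(tm)[tm == "d"], rownames(ex))
  reg <- trueRegulator(ds$truth)
  rH <- mean(cor(ex[reg, ph$group == "H"],
                 t(ex[members, ph$group == "H"])))
  rL <- mean(cor(ex[reg, ph$group == "L"],
                 t(ex[members, ph$group == "L"])))
  # loadingH > loadingL in the config, so wiring must drop from H to L
  expect_gt(rH, 0.5)
  expect_lt(rL, -0.5)
})

test_that("library sizes scale the counts as drawn", {
  # without planted structure the column sums track the library factor
  ds <- generateDataset(nullConfig(8L, nGenes = 1000L))
  expect_gt(cor(colSums(counts(ds$mrna)), ds$phenotypes$mapped_reads), 0.9)
})

test_that("truth tables round-trip and reflect the planted design", {
  ds <- generateDataset(smallConfig(seed = 9L))
  outdir <- file.path(tempdir(), "truth-rt")
  truthTables(ds$truth, outdir)

  mods <- read.delim(file.path(outdir, "truth_modules.tsv"))
  expect_identical(nrow(mods), length(trueModules(ds$truth)))
  expect_identical(setNames(mods$module, mods$feature),
                   trueModules(ds$truth))

  de <- read.delim(file.path(outdir, "truth_de.tsv"))
  expect_equal(de, trueDe(ds$truth))

  reg <- read.delim(file.path(outdir, "truth_regulator.tsv"))
  expect_identical(reg$feature, trueRegulator(ds$truth))

  # empty DE spec still writes a header-only file
  dn <- generateDataset(nullConfig(2L, nGenes = 20L))
  outdir2 <- file.path(tempdir(), "truth-empty")
  truthTables(dn$truth, outdir2)
  deEmpty <- read.delim(file.path(outdir2, "truth_de.tsv"))
  expect_identical(nrow(deEmpty), 0L)
  expect_identical(names(deEmpty), c("feature", "log2fc"))
})
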