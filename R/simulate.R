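#' @importFrom stats rnorm rnbinom runif setNames
NULL

.defaultModules <- function() {
  data.frame(
    name    = c("M1", "M2", "M3", "M4", "MX", "MT",
                "m1", "m2", "mx", "mDE"),
    layer   = c(rep("mRNA", 6), rep("miRNA", 4)),
    size    = c(100L, 80L, 60L, 50L, 60L, 40L, 20L, 15L, 10L, 12L),
    loading = c(0.7, 0.7, 0.7, 0.7, 0.75, 2.5, 0.7, 0.7, -0.9, 0.9),
    factor  = c("M1", "M2", "M3", "M4", "X", "MT", "m1", "m2", "X", "mDE"),
    stringsAsFactors = FALSE
  )
}

#' Build a synthetic-dataset configuration
#'
#' The defaults emulate the study design the package targets: 15 + 15
#' samples in a High/Low group contrast, 2,000 genes and 150 miRNAs with
#' negative-binomial counts (Var = mu + alpha mu^2, alpha = 0.1), lognormal
#' library-size variation, block-correlated latent-factor modules on both
#' layers, one cross-layer module pair sharing a latent factor with
#' opposite-sign loadings (MX vs mx), six planted differentially expressed
#' miRNAs with |log2FC| between 1.30 and 1.71, one miRNA regulator wired to
#' the DE module in the High group only, one gene hub wired to a tight gene
#' module in the Low group only, and an IMF-like trait driven by module M1's
#' latent factor.
#'
#' @param nPerGroup Samples per group (default 15).
#' @param nGenes,nMirnas Features per layer (defaults 2000 and 150).
#' @param modules data.frame(name, layer, size, loading, factor); modules
#'   listing the same factor share one latent factor.
#' @param deSpec data.frame(feature, log2fc), Low-minus-High orientation;
#'   \code{NULL} plants the default six DE miRNAs inside module mDE.
#' @param regulatorSpec list(feature, targetModule, loadingH, loadingL) or
#'   empty list for none; \code{NULL} gives the default regulator.
#' @param hubSpec list(feature, targetModule, loadingH, loadingL) or empty
#'   list; \code{NULL} gives the default Low-group hub.
#' @param traitSpec list(driverModule, slope, noiseSd, baseline).
#' @param dispersion Global NB dispersion alpha.
#' @param libsizeLognormalSd sd of log library-size factors.
#' @param baseLog2Range Range of baseline log2 mean expression.
#' @param seed Integer seed.
#' @return A validated \linkS4class{SimConfig}.
#' @export
simConfig <- function(nPerGroup = 15L, nGenes = 2000L, nMirnas = 150L,
                      modules = .defaultModules(), deSpec = NULL,
                      regulatorSpec = NULL, hubSpec = NULL,
                      traitSpec = list(driverModule = "M1", slope = 0.9,
                                       noiseSd = 0.45, baseline = 3),
                      dispersion = 0.1, libsizeLognormalSd = 0.3,
                      baseLog2Range = c(5, 9), seed = 1L) {
  gid <- function(i) sprintf("gene_%04d", i)
  mid <- function(i) sprintf("mir_%04d", i)
  if (is.null(deSpec)) {
    # six coherently upregulated miRNAs inside the co-regulated module
    # (co-module miRNAs shift together) plus four weaker mixed-sign DE
    # miRNAs among the unstructured features
    if ("mDE" %in% modules$name) {
      first <- .moduleMemberIds(modules, "mDE", nGenes, nMirnas)[1:6]
      lone <- sprintf("mir_%04d", seq.int(nMirnas - 3L, nMirnas))
      deSpec <- data.frame(
        feature = c(first, lone),
        log2fc = c(1.67, 1.45, 1.55, 1.71, 1.30, 1.60,
                   -0.45, 0.50, -0.60, 0.40),
        stringsAsFactors = FALSE)
    } else {
      deSpec <- data.frame(feature = character(), log2fc = numeric())
    }
  }
  nModMirna <- sum(modules$size[modules$layer == "miRNA"])
  nModGene <- sum(modules$size[modules$layer == "mRNA"])
  if (nModGene + 1L > nGenes || nModMirna + 1L > nMirnas)
    stop("module sizes exceed the number of features in a layer")
  if (is.null(regulatorSpec)) {
    # sign-reversing wiring: positively coupled to the DE module in High,
    # negatively in Low (differential wiring with a sign flip)
    regulatorSpec <- if ("mDE" %in% modules$name)
      list(feature = mid(nModMirna + 1L), targetModule = "mDE",
           loadingH = 2.0, loadingL = -2.0)
    else list()
  }
  if (is.null(hubSpec)) {
    hubSpec <- if ("MT" %in% modules$name)
      list(feature = gid(nModGene + 1L), targetModule = "MT",
           loadingH = 0, loadingL = 2.5)
    else list()
  }
  new("SimConfig", nPerGroup = as.integer(nPerGroup),
      nGenes = as.integer(nGenes), nMirnas = as.integer(nMirnas),
      modules = modules, deSpec = deSpec, regulatorSpec = regulatorSpec,
      hubSpec = hubSpec, traitSpec = traitSpec, dispersion = dispersion,
      libsizeLognormalSd = libsizeLognormalSd, baseLog2Range = baseLog2Range,
      seed = as.integer(seed))
}

# ids of the members of one module under the deterministic layout:
# modules fill each layer's feature ids in the order listed in `modules`.
.moduleMemberIds <- function(modules, name, nGenes, nMirnas) {
  row <- modules[modules$name == name, ]
  if (nrow(row) != 1L) stop("unknown module '", name, "'")
  same <- modules[modules$layer == row$layer, ]
  offset <- cumsum(c(0L, same$size))[which(same$name == name)]
  idx <- seq.int(offset + 1L, offset + row$size)
  if (row$layer == "mRNA") sprintf("gene_%04d", idx) else
    sprintf("mir_%04d", idx)
}

#' Generate a paired synthetic miRNA/mRNA dataset with planted truth
#'
#' Counts are drawn as NB(mean = s_j * 2^(mu_i + loading * F_mj + de_i *
#' g_j), alpha) where F_m are per-module standard-normal latent factors
#' shared across a module's members (the cross-layer pair shares one factor
#' with opposite-sign loadings), de_i is the planted log2FC applied as
#' +/- log2fc/2 (Low minus High orientation) and s_j the lognormal library
#' size factor. The trait is baseline + slope * F_driver + Gaussian noise;
#' GEBV is derived from the group contrast and the trait with added noise.
#' Fully reproducible from the config seed.
#'
#' @param config A \linkS4class{SimConfig}.
#' @return list(mrna = CountMatrix, mirna = CountMatrix, phenotypes =
#'   data.frame, truth = SyntheticTruth).
#' @examples
#' ds <- generateDataset(simConfig(nGenes = 50, nMirnas = 20,
#'   modules = data.frame(name = "A", layer = "mRNA", size = 10,
#'                        loading = 0.8, factor = "A"),
#'   deSpec = data.frame(feature = "mir_0001", log2fc = 1),
#'   regulatorSpec = list(), hubSpec = list(),
#'   traitSpec = list(driverModule = "A", slope = 0.9, noiseSd = 0.45,
#'                    baseline = 3)))
#' ds$mrna
#' @export
generateDataset <- function(config) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  set.seed(config@seed)
  nS <- 2L * config@nPerGroup
  group <- rep(c("H", "L"), each = config@nPerGroup)
  sampleIds <- sprintf("%s%02d", group, c(seq_len(config@nPerGroup),
                                          seq_len(config@nPerGroup)))
  geneIds <- sprintf("gene_%04d", seq_len(config@nGenes))
  mirIds <- sprintf("mir_%04d", seq_len(config@nMirnas))

  # latent factors, one per distinct factor label
  facNames <- unique(config@modules$factor)
  FF <- matrix(rnorm(length(facNames) * nS), length(facNames), nS,
               dimnames = list(facNames, sampleIds))

  # per-feature module membership (layout of .moduleMemberIds)
  truthMod <- c(setNames(rep("background", config@nGenes), geneIds),
                setNames(rep("background", config@nMirnas), mirIds))
  loading <- setNames(numeric(length(truthMod)), names(truthMod))
  facOf <- setNames(rep(NA_character_, length(truthMod)), names(truthMod))
  for (i in seq_len(nrow(config@modules))) {
    mm <- config@modules[i, ]
    ids <- .moduleMemberIds(config@modules, mm$name, config@nGenes,
                            config@nMirnas)
    truthMod[ids] <- mm$name
    loading[ids] <- mm$loading
    facOf[ids] <- mm$factor
  }

  baseMu <- setNames(runif(length(truthMod), config@baseLog2Range[1L],
                           config@baseLog2Range[2L]), names(truthMod))
  libFac <- setNames(exp(rnorm(nS, 0, config@libsizeLognormalSd)), sampleIds)

  log2mu <- matrix(baseMu, length(truthMod), nS,
                   dimnames = list(names(truthMod), sampleIds))
  hasFac <- !is.na(facOf)
  log2mu[hasFac, ] <- log2mu[hasFac, ] +
    loading[hasFac] * FF[facOf[hasFac], , drop = FALSE]

  if (nrow(config@deSpec)) {
    unknown <- setdiff(config@deSpec$feature, names(truthMod))
    if (length(unknown))
      stop("deSpec references unknown feature(s): ",
           paste(unknown, collapse = ", "))
    shift <- ifelse(group == "L", 0.5, -0.5)
    for (i in seq_len(nrow(config@deSpec))) {
      f <- config@deSpec$feature[i]
      log2mu[f, ] <- log2mu[f, ] + shift * config@deSpec$log2fc[i]
    }
  }
  # group-dependent wiring for the regulator and the hub
  for (sp in list(config@regulatorSpec, config@hubSpec)) {
    if (!length(sp)) next
    fac <- config@modules$factor[config@modules$name == sp$targetModule]
    lam <- ifelse(group == "H", sp$loadingH, sp$loadingL)
    log2mu[sp$feature, ] <- baseMu[sp$feature] + lam * FF[fac, ]
  }

  mean_ <- sweep(2^log2mu, 2L, libFac, `*`)
  countsAll <- matrix(
    rnbinom(length(mean_), mu = as.vector(mean_),
            size = 1 / config@dispersion),
    nrow(mean_), ncol(mean_), dimnames = dimnames(mean_))
  storage.mode(countsAll) <- "double"

  # trait and phenotype table (no driver module: pure noise trait)
  ts <- config@traitSpec
  if (length(ts) && !is.null(ts$driverModule)) {
    drvFac <- config@modules$factor[config@modules$name == ts$driverModule]
    imf <- ts$baseline + ts$slope * FF[drvFac, ] + rnorm(nS, 0, ts$noiseSd)
    driver <- ts$driverModule
    coefs <- c(baseline = ts$baseline, slope = ts$slope,
               noiseSd = ts$noiseSd)
  } else {
    ts <- list(baseline = 3, noiseSd = 0.45)
    imf <- ts$baseline + rnorm(nS, 0, ts$noiseSd)
    driver <- NA_character_
    coefs <- c(baseline = ts$baseline, slope = 0, noiseSd = ts$noiseSd)
  }
  imf <- pmax(imf, 0.01)
  gebv <- ifelse(group == "H", 0.59, -0.43) +
    0.15 * (imf - ts$baseline) + rnorm(nS, 0, 0.08)
  pheno <- data.frame(
    sample_id = sampleIds,
    imf_percent = imf,
    gebv = gebv,
    group = group,
    age_days = round(rnorm(nS, 760, 25)),
    contemporary_group = rep_len(c("cg1", "cg2", "cg3"), nS),
    mapped_reads = round(7.5e5 * libFac, 2),
    stringsAsFactors = FALSE
  )
  rownames(pheno) <- NULL

  truth <- new("SyntheticTruth",
    modules = truthMod, de = config@deSpec,
    regulator = if (length(config@regulatorSpec))
      config@regulatorSpec$feature else NA_character_,
    hub = if (length(config@hubSpec)) config@hubSpec$feature
      else NA_character_,
    traitDriver = driver,
    traitCoef = coefs,
    seed = config@seed)

  list(
    mrna = CountMatrix(countsAll[geneIds, , drop = FALSE], layer = "mRNA"),
    mirna = CountMatrix(countsAll[mirIds, , drop = FALSE], layer = "miRNA"),
    phenotypes = pheno,
    truth = truth
  )
}

#' Write planted-truth tables as TSV
#'
#' Writes \code{truth_modules.tsv} (feature, module),
#' \code{truth_de.tsv} (feature, log2fc), \code{truth_regulator.tsv},
#' \code{truth_hub.tsv} and \code{truth_trait.tsv} into a directory.
#'
#' @param truth A \linkS4class{SyntheticTruth}.
#' @param outdir Output directory (created if absent).
#' @return Character vector of the files written, invisibly.
#' @export
truthTables <- function(truth, outdir) {
  stopifnot(is(truth, "SyntheticTruth"))
  if (!dir.exists(outdir))
    dir.create(outdir, recursive = TRUE)
  paths <- file.path(outdir, c("truth_modules.tsv", "truth_de.tsv",
                               "truth_regulator.tsv", "truth_hub.tsv",
                               "truth_trait.tsv"))
  write.table(data.frame(feature = names(truth@modules),
                         module = unname(truth@modules)),
              paths[1L], sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(truth@de[, c("feature", "log2fc"), drop = FALSE], paths[2L],
              sep = "\t", quote = FALSE, row.names = FALSE)
  reg <- truth@regulator
  write.table(data.frame(feature = reg[!is.na(reg)]), paths[3L], sep = "\t",
              quote = FALSE, row.names = FALSE)
  hub <- truth@hub
  write.table(data.frame(feature = hub[!is.na(hub)]), paths[4L], sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(data.frame(driver_module = truth@traitDriver,
                         baseline = truth@traitCoef[["baseline"]],
                         slope = truth@traitCoef[["slope"]],
                         noise_sd = truth@traitCoef[["noiseSd"]],
                         seed = truth@seed),
              paths[5L], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}
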