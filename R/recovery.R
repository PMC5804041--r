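#' Planted-truth recovery evaluation on one synthetic dataset
#'
#' Generates a dataset from the config and measures whether each planted
#' construct is recovered by the pipeline's own methods:
#' \itemize{
#'   \item \code{regulatorTop}: the differentially wired regulator attains
#'     the largest |RIF1 z-score| among all candidate features, using the
#'     planted DE set as the DE features;
#'   \item \code{hubMinDh}: the planted group-specific hub attains the
#'     minimum differential hubbing score on the variance-capped PCIT
#'     network;
#'   \item \code{ariMrna}, \code{ariMirna}: adjusted Rand index between
#'     planted and detected module labels, restricted to features planted
#'     in modules (background features are excluded - "grey" is
#'     unassigned, not a module);
#'   \item \code{traitDriverTop}: the detected mRNA module with the
#'     largest |module-trait correlation| contains the majority of the
#'     planted driver module's members;
#'   \item \code{crossPairRetained}: some retained miRNA-mRNA module pair
#'     (r <= rCut, p < pCut) consists of modules containing the majority
#'     of the planted anti-correlated pair's members.
#' }
#' Module detection runs on the full sample set: the planted modules are
#' not condition-specific, so recovery is evaluated where the information
#' is (the per-group split in the pipeline probes condition-specific
#' wiring instead).
#'
#' @param config A \linkS4class{SimConfig} (seed included).
#' @param pcitTop Variance cap for the PCIT/DH stage (default 500).
#' @param edgeThreshold DH edge filter (default 0.9).
#' @param rCut,pCut Cross-layer retention thresholds (defaults -0.4, 0.05).
#' @return Named list with the elements described above.
#' @export
evaluateRecovery <- function(config, pcitTop = 500L, edgeThreshold = 0.9,
                             rCut = -0.4, pCut = 0.05) {
  if (!requireNamespace("mclust", quietly = TRUE))
    stop("evaluateRecovery needs the 'mclust' package for the ARI")
  ds <- generateDataset(config)
  ph <- ds$phenotypes
  truth <- ds$truth
  exprG <- normalizeCounts(ds$mrna)
  exprM <- normalizeCounts(ds$mirna)
  grpH <- ph$sample_id[ph$group == "H"]
  grpL <- ph$sample_id[ph$group == "L"]

  # regulator by |RIF1_z| against the planted DE set
  gm <- groupMeans(list(exprG, exprM), ph)
  rs <- regulatorScores(
    list(exprValues(exprG)[, grpH], exprValues(exprM)[, grpH]),
    list(exprValues(exprG)[, grpL], exprValues(exprM)[, grpL]),
    gm, trueDe(truth)$feature)
  sc <- rs$scores
  regulatorTop <- !is.na(trueRegulator(truth)) &&
    sc$regulator[which.max(abs(sc$rif1_z))] == trueRegulator(truth)

  # hub by minimum DH on the variance-capped PCIT network
  keep <- topVarianceFeatures(list(exprG, exprM), top = pcitTop)
  stk <- rbind(exprValues(exprG), exprValues(exprM))[keep, , drop = FALSE]
  netH <- pcit(correlationNetwork(stk, samples = grpH, group = "H"))
  netL <- pcit(correlationNetwork(stk, samples = grpL, group = "L"))
  dh <- dhScores(netH, netL, edgeThreshold = edgeThreshold)
  hubMinDh <- !is.na(trueHub(truth)) && trueHub(truth) %in% dh$feature &&
    dh$dh[dh$feature == trueHub(truth)] == min(dh$dh)

  # module recovery per layer, planted features only
  tm <- trueModules(truth)
  msG <- coexpressionModules(exprG, minSize = 30L)
  msM <- coexpressionModules(exprM, minSize = 5L)
  ariOf <- function(ms, ids) {
    planted <- ids[tm[ids] != "background"]
    if (!length(planted)) return(NA_real_)
    mclust::adjustedRandIndex(tm[planted], moduleLabels(ms)[planted])
  }
  ariMrna <- ariOf(msG, featureIds(ds$mrna))
  ariMirna <- ariOf(msM, featureIds(ds$mirna))

  majorityModule <- function(ms, members) {
    # detected module holding the majority of the given planted members
    labs <- moduleLabels(ms)[members]
    tab <- sort(table(labs), decreasing = TRUE)
    if (!length(tab) || tab[1L] <= length(members) / 2) return(NA_character_)
    names(tab)[1L]
  }

  mt <- moduleTraitCorrelation(msG, ph)
  drv <- trueTraitDriver(truth)
  traitDriverTop <- FALSE
  if (!is.na(drv) && nrow(mt)) {
    best <- mt$module[which.max(abs(mt$r))]
    drvMod <- majorityModule(msG, names(tm)[tm == drv])
    traitDriverTop <- !is.na(drvMod) && best == drvMod
  }

  crossPairRetained <- FALSE
  pairMods <- config@modules[duplicated(config@modules$factor) |
                               duplicated(config@modules$factor,
                                          fromLast = TRUE), ]
  if (nrow(pairMods) >= 2L && nrow(eigengenes(msM)) &&
      nrow(eigengenes(msG))) {
    mmc <- moduleModuleCorrelation(msM, msG, rCut = rCut, pCut = pCut)
    kept <- mmc[mmc$retained, , drop = FALSE]
    miName <- pairMods$name[pairMods$layer == "miRNA"][1L]
    mrName <- pairMods$name[pairMods$layer == "mRNA"][1L]
    miMod <- majorityModule(msM, names(tm)[tm == miName])
    mrMod <- majorityModule(msG, names(tm)[tm == mrName])
    crossPairRetained <- !is.na(miMod) && !is.na(mrMod) &&
      any(kept$mirnaModule == miMod & kept$mrnaModule == mrMod)
  }

  list(regulatorTop = regulatorTop, hubMinDh = hubMinDh,
       ariMrna = ariMrna, ariMirna = ariMirna,
       traitDriverTop = traitDriverTop,
       crossPairRetained = crossPairRetained)
}
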