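#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#' @importFrom S4Vectors metadata metadata<-
NULL

#' CountMatrix: raw counts for one expression layer
#'
#' A \linkS4class{SummarizedExperiment} holding a single \code{"counts"}
#' assay of non-negative integer counts (features in rows, samples in
#' columns) for one molecular layer, either \code{"mRNA"} or \code{"miRNA"}.
#'
#' @slot layer Character scalar, \code{"mRNA"} or \code{"miRNA"}.
#' @seealso \code{\link{readCounts}}, \code{\link{counts}}
#' @export
setClass("CountMatrix",
  contains = "SummarizedExperiment",
  slots = c(layer = "character")
)

setValidity("CountMatrix", function(object) {
  msg <- character()
  if (length(object@layer) != 1L || !object@layer %in% c("mRNA", "miRNA"))
    msg <- c(msg, "layer must be one of 'mRNA', 'miRNA'")
  if (!"counts" %in% names(assays(object)))
    msg <- c(msg, "a 'counts' assay is required")
  else {
    v <- assay(object, "counts")
    if (any(!is.finite(v)))
      msg <- c(msg, "counts must be finite")
    else {
      if (any(v < 0)) msg <- c(msg, "counts must be non-negative")
      if (any(v != round(v))) msg <- c(msg, "counts must be integers")
    }
    if (is.null(rownames(v)) || anyDuplicated(rownames(v)))
      msg <- c(msg, "feature ids must be present and unique")
    if (is.null(colnames(v)) || anyDuplicated(colnames(v)))
      msg <- c(msg, "sample ids must be present and unique")
  }
  if (length(msg)) msg else TRUE
})

#' ExpressionMatrix: log-scale normalized expression
#'
#' A \linkS4class{SummarizedExperiment} with a single \code{"logexpr"}
#' assay of \code{log2(count / sizeFactor + pseudocount)} values, carrying
#' the size factors and pseudocount that produced it.
#'
#' @slot layer Character scalar, \code{"mRNA"} or \code{"miRNA"}.
#' @slot sizeFactors Named positive numeric, one per sample.
#' @slot pseudocount Positive numeric scalar.
#' @seealso \code{\link{normalizeCounts}}
#' @export
setClass("ExpressionMatrix",
  contains = "SummarizedExperiment",
  slots = c(layer = "character", sizeFactors = "numeric",
            pseudocount = "numeric")
)

setValidity("ExpressionMatrix", function(object) {
  msg <- character()
  if (!"logexpr" %in% names(assays(object)))
    msg <- c(msg, "a 'logexpr' assay is required")
  else if (any(!is.finite(assay(object, "logexpr"))))
    msg <- c(msg, "expression values must be finite")
  if (any(object@sizeFactors <= 0)) msg <- c(msg, "size factors must be > 0")
  if (length(object@sizeFactors) != ncol(object))
    msg <- c(msg, "one size factor per sample is required")
  if (length(object@pseudocount) != 1L || object@pseudocount <= 0)
    msg <- c(msg, "pseudocount must be a positive scalar")
  if (length(msg)) msg else TRUE
})

#' CorrelationNetwork: per-group co-expression network
#'
#' Pairwise Pearson correlations of log-normalized expression across the
#' samples of one phenotype group, with two-sided p-values from the
#' t transform on n - 2 degrees of freedom, and (once \code{\link{pcit}} has
#' been applied) a logical mask of retained associations.
#'
#' @slot group Character scalar group label (e.g. "H" or "L").
#' @slot r Symmetric correlation matrix, unit diagonal.
#' @slot p Symmetric matrix of two-sided p-values.
#' @slot mask Logical symmetric matrix of PCIT-retained edges (may be empty
#'   before \code{\link{pcit}} is run).
#' @slot nSamples Integer number of samples the correlations were computed on.
#' @export
setClass("CorrelationNetwork",
  slots = c(group = "character", r = "matrix", p = "matrix",
            mask = "matrix", nSamples = "integer")
)

setValidity("CorrelationNetwork", function(object) {
  msg <- character()
  r <- object@r
  if (nrow(r) != ncol(r)) msg <- c(msg, "correlation matrix must be square")
  if (is.null(rownames(r)) || !identical(rownames(r), colnames(r)))
    msg <- c(msg, "correlation matrix must carry matching dimnames")
  if (length(r) && max(abs(r)) > 1 + 1e-8)
    msg <- c(msg, "correlations must lie in [-1, 1]")
  if (length(r) && max(abs(diag(r) - 1)) > 1e-8)
    msg <- c(msg, "correlation diagonal must be 1")
  if (length(object@mask) && !identical(dim(object@mask), dim(r)))
    msg <- c(msg, "mask dimensions must match the correlation matrix")
  if (length(msg)) msg else TRUE
})

#' ModuleSet: co-expression module assignment and eigengenes
#'
#' The result of signed co-expression module detection on one layer:
#' feature-to-module colour labels ("grey" = unassigned), module eigengenes
#' (first principal component profiles across samples), the share of module
#' variance each eigengene explains, and per-feature module membership.
#'
#' @slot labels Named character vector, feature id -> module colour.
#' @slot eigengenes Numeric matrix, modules x samples.
#' @slot varExplained Named numeric, proportion of (standardized) module
#'   variance captured by each eigengene.
#' @slot membership Numeric matrix, features x modules, of correlations
#'   between each feature and each module eigengene.
#' @slot minSize Integer, minimum module size used.
#' @slot mergeHeight Numeric, eigengene-dissimilarity merge threshold used.
#' @slot cutHeight Numeric, static tree-cut height used.
#' @export
setClass("ModuleSet",
  slots = c(labels = "character", eigengenes = "matrix",
            varExplained = "numeric", membership = "matrix",
            minSize = "integer", mergeHeight = "numeric",
            cutHeight = "numeric")
)

setValidity("ModuleSet", function(object) {
  msg <- character()
  if (is.null(names(object@labels)))
    msg <- c(msg, "labels must be named by feature id")
  mods <- setdiff(unique(object@labels), "grey")
  if (length(mods) && nrow(object@eigengenes) &&
      !all(mods %in% rownames(object@eigengenes)))
    msg <- c(msg, "every non-grey module needs an eigengene row")
  tab <- table(object@labels[object@labels != "grey"])
  if (length(tab) && length(object@minSize) && any(tab < object@minSize))
    msg <- c(msg, "non-grey modules below the minimum size")
  if (length(msg)) msg else TRUE
})

#' SimConfig: synthetic paired-dataset configuration
#'
#' Describes a two-group paired miRNA/mRNA count simulation: negative-
#' binomial counts with lognormal library sizes, block-correlated latent-
#' factor modules (one cross-layer anti-correlated pair sharing a factor),
#' planted differentially expressed features, one differentially wired
#' regulator, one group-specific hub, and a trait driven by one module's
#' latent factor. Build with \code{\link{simConfig}}.
#'
#' @slot nPerGroup Samples per group.
#' @slot nGenes,nMirnas Features per layer.
#' @slot modules data.frame with columns name, layer, size, loading, factor.
#' @slot deSpec data.frame with columns feature, log2fc (Low minus High).
#' @slot regulatorSpec list(feature, targetModule, loadingH, loadingL).
#' @slot hubSpec list(feature, targetModule, loadingH, loadingL).
#' @slot traitSpec list(driverModule, slope, noiseSd, baseline).
#' @slot dispersion Global NB dispersion alpha (Var = mu + alpha mu^2).
#' @slot libsizeLognormalSd sd of the log-normal library-size factors.
#' @slot baseLog2Range Range of baseline log2 mean expression.
#' @slot seed Integer seed for the single pseudo-random stream.
#' @export
setClass("SimConfig",
  slots = c(nPerGroup = "integer", nGenes = "integer", nMirnas = "integer",
            modules = "data.frame", deSpec = "data.frame",
            regulatorSpec = "list", hubSpec = "list", traitSpec = "list",
            dispersion = "numeric", libsizeLognormalSd = "numeric",
            baseLog2Range = "numeric", seed = "integer")
)

setValidity("SimConfig", function(object) {
  msg <- character()
  if (object@nPerGroup < 2L) msg <- c(msg, "need at least 2 samples per group")
  m <- object@modules
  if (nrow(m)) {
    if (any(m$size < 2)) msg <- c(msg, "module sizes must be >= 2")
    if (!all(m$layer %in% c("mRNA", "miRNA")))
      msg <- c(msg, "module layer must be mRNA or miRNA")
    if (anyDuplicated(m$name)) msg <- c(msg, "module names must be unique")
  }
  if (object@dispersion <= 0) msg <- c(msg, "dispersion must be > 0")
  if (object@libsizeLognormalSd < 0)
    msg <- c(msg, "libsizeLognormalSd must be >= 0")
  for (fld in c("regulatorSpec", "hubSpec")) {
    sp <- slot(object, fld)
    if (length(sp) && !sp$targetModule %in% m$name)
      msg <- c(msg, sprintf("%s references unknown module '%s'", fld,
                            sp$targetModule))
  }
  if (length(object@traitSpec) &&
      !is.null(object@traitSpec$driverModule) &&
      !object@traitSpec$driverModule %in% m$name)
    msg <- c(msg, "traitSpec references an unknown module")
  if (length(msg)) msg else TRUE
})

#' SyntheticTruth: planted ground truth of a simulated dataset
#'
#' @slot modules Named character vector feature -> planted module
#'   ("background" for unstructured features).
#' @slot de data.frame(feature, log2fc) of planted effects.
#' @slot regulator Feature id of the differentially wired regulator
#'   (NA if none planted).
#' @slot hub Feature id of the group-specific hub (NA if none planted).
#' @slot traitDriver Name of the module whose factor drives the trait.
#' @slot traitCoef Named numeric: baseline, slope and noise sd of the trait
#'   model.
#' @slot seed Integer seed the dataset was generated from.
#' @export
setClass("SyntheticTruth",
  slots = c(modules = "character", de = "data.frame", regulator = "character",
            hub = "character", traitDriver = "character",
            traitCoef = "numeric", seed = "integer")
)

setValidity("SyntheticTruth", function(object) {
  msg <- character()
  ids <- names(object@modules)
  if (is.null(ids)) msg <- c(msg, "module truth must be named by feature id")
  if (nrow(object@de) && !all(object@de$feature %in% ids))
    msg <- c(msg, "DE truth references unknown features")
  for (fld in c("regulator", "hub")) {
    v <- slot(object, fld)
    if (length(v) == 1L && !is.na(v) && !v %in% ids)
      msg <- c(msg, sprintf("%s references an unknown feature", fld))
  }
  if (length(msg)) msg else TRUE
})
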