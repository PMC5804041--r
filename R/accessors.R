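#' @importFrom BiocGenerics counts
NULL

#' Access the raw counts of a CountMatrix
#'
#' @param object A \linkS4class{CountMatrix}.
#' @return Integer matrix, features x samples.
#' @export
setMethod("counts", "CountMatrix", function(object) {
  assay(object, "counts")
})

#' Layer of an expression container
#'
#' @param object A \linkS4class{CountMatrix} or \linkS4class{ExpressionMatrix}.
#' @return \code{"mRNA"} or \code{"miRNA"}.
#' @export
setGeneric("layer", function(object) standardGeneric("layer"))

#' @rdname layer
#' @export
setMethod("layer", "CountMatrix", function(object) object@layer)

#' @rdname layer
#' @export
setMethod("layer", "ExpressionMatrix", function(object) object@layer)

#' Feature identifiers
#' @param object A package container with feature rows.
#' @return Character vector of feature ids.
#' @export
setGeneric("featureIds", function(object) standardGeneric("featureIds"))

#' @rdname featureIds
#' @export
setMethod("featureIds", "SummarizedExperiment", function(object)
  rownames(object))

#' @rdname featureIds
#' @export
setMethod("featureIds", "CorrelationNetwork", function(object)
  rownames(object@r))

#' Sample identifiers
#' @param object A package container with sample columns.
#' @return Character vector of sample ids.
#' @export
setGeneric("sampleIds", function(object) standardGeneric("sampleIds"))

#' @rdname sampleIds
#' @export
setMethod("sampleIds", "SummarizedExperiment", function(object)
  colnames(object))

#' Log-normalized expression values
#' @param object An \linkS4class{ExpressionMatrix}.
#' @return Numeric matrix of log2(count / sizeFactor + pseudocount).
#' @export
setGeneric("exprValues", function(object) standardGeneric("exprValues"))

#' @rdname exprValues
#' @export
setMethod("exprValues", "ExpressionMatrix", function(object)
  assay(object, "logexpr"))

#' Size factors used for normalization
#' @param object An \linkS4class{ExpressionMatrix}.
#' @return Named numeric vector of per-sample size factors.
#' @export
setGeneric("sizeFactorsUsed", function(object)
  standardGeneric("sizeFactorsUsed"))

#' @rdname sizeFactorsUsed
#' @export
setMethod("sizeFactorsUsed", "ExpressionMatrix", function(object)
  object@sizeFactors)

#' Correlation, p-value and PCIT mask of a network
#' @param object A \linkS4class{CorrelationNetwork}.
#' @return Matrix (correlations, p-values) or logical matrix (mask; NULL if
#'   \code{\link{pcit}} has not been applied).
#' @export
setGeneric("networkCorrelations", function(object)
  standardGeneric("networkCorrelations"))

#' @rdname networkCorrelations
#' @export
setMethod("networkCorrelations", "CorrelationNetwork", function(object)
  object@r)

#' @rdname networkCorrelations
#' @export
setGeneric("networkPvalues", function(object)
  standardGeneric("networkPvalues"))

#' @rdname networkCorrelations
#' @export
setMethod("networkPvalues", "CorrelationNetwork", function(object) object@p)

#' @rdname networkCorrelations
#' @export
setGeneric("pcitMask", function(object) standardGeneric("pcitMask"))

#' @rdname networkCorrelations
#' @export
setMethod("pcitMask", "CorrelationNetwork", function(object) {
  if (length(object@mask)) object@mask else NULL
})

#' Module labels of a ModuleSet
#' @param object A \linkS4class{ModuleSet}.
#' @return Named character vector, feature id -> module colour.
#' @export
setGeneric("moduleLabels", function(object) standardGeneric("moduleLabels"))

#' @rdname moduleLabels
#' @export
setMethod("moduleLabels", "ModuleSet", function(object) object@labels)

#' Module eigengenes
#' @param object A \linkS4class{ModuleSet}.
#' @return Numeric matrix, modules x samples.
#' @export
setGeneric("eigengenes", function(object) standardGeneric("eigengenes"))

#' @rdname eigengenes
#' @export
setMethod("eigengenes", "ModuleSet", function(object) object@eigengenes)

#' Variance explained by each module eigengene
#' @param object A \linkS4class{ModuleSet}.
#' @return Named numeric vector of proportions.
#' @export
setGeneric("varianceExplained", function(object)
  standardGeneric("varianceExplained"))

#' @rdname varianceExplained
#' @export
setMethod("varianceExplained", "ModuleSet", function(object)
  object@varExplained)

#' Module membership matrix
#' @param object A \linkS4class{ModuleSet}.
#' @return Numeric matrix, features x modules, of feature-eigengene
#'   correlations.
#' @export
setGeneric("membership", function(object) standardGeneric("membership"))

#' @rdname membership
#' @export
setMethod("membership", "ModuleSet", function(object) object@membership)

#' Planted truth accessors
#' @param object A \linkS4class{SyntheticTruth}.
#' @return The planted module map, DE table, regulator id, hub id or trait
#'   driver module, respectively.
#' @export
setGeneric("trueModules", function(object) standardGeneric("trueModules"))

#' @rdname trueModules
#' @export
setMethod("trueModules", "SyntheticTruth", function(object) object@modules)

#' @rdname trueModules
#' @export
setGeneric("trueDe", function(object) standardGeneric("trueDe"))

#' @rdname trueModules
#' @export
setMethod("trueDe", "SyntheticTruth", function(object) object@de)

#' @rdname trueModules
#' @export
setGeneric("trueRegulator", function(object) standardGeneric("trueRegulator"))

#' @rdname trueModules
#' @export
setMethod("trueRegulator", "SyntheticTruth", function(object)
  object@regulator)

#' @rdname trueModules
#' @export
setGeneric("trueHub", function(object) standardGeneric("trueHub"))

#' @rdname trueModules
#' @export
setMethod("trueHub", "SyntheticTruth", function(object) object@hub)

#' @rdname trueModules
#' @export
setGeneric("trueTraitDriver", function(object)
  standardGeneric("trueTraitDriver"))

#' @rdname trueModules
#' @export
setMethod("trueTraitDriver", "SyntheticTruth", function(object)
  object@traitDriver)

setMethod("show", "CountMatrix", function(object) {
  cat(sprintf("CountMatrix (%s): %d features x %d samples\n",
              object@layer, nrow(object), ncol(object)))
})

setMethod("show", "ExpressionMatrix", function(object) {
  cat(sprintf(
    "ExpressionMatrix (%s): %d features x %d samples, pseudocount %g\n",
    object@layer, nrow(object), ncol(object), object@pseudocount))
})

setMethod("show", "CorrelationNetwork", function(object) {
  cat(sprintf("CorrelationNetwork (group %s): %d features, %d samples%s\n",
              object@group, nrow(object@r), object@nSamples,
              if (length(object@mask))
                sprintf(", %d PCIT-retained edges",
                        sum(object@mask[upper.tri(object@mask)]))
              else ", PCIT not applied"))
})

setMethod("show", "ModuleSet", function(object) {
  mods <- setdiff(rownames(object@eigengenes), "grey")
  cat(sprintf("ModuleSet: %d features in %d modules (+%d grey)\n",
              length(object@labels), length(mods),
              sum(object@labels == "grey")))
})

setMethod("show", "SimConfig", function(object) {
  cat(sprintf(
    "SimConfig: %d+%d samples, %d genes, %d miRNAs, %d planted modules\n",
    object@nPerGroup, object@nPerGroup, object@nGenes, object@nMirnas,
    nrow(object@modules)))
})

setMethod("show", "SyntheticTruth", function(object) {
  cat(sprintf(
    "SyntheticTruth: %d features, %d DE, regulator %s, hub %s, driver %s\n",
    length(object@modules), nrow(object@de), object@regulator, object@hub,
    object@traitDriver))
})
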