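#' Per-group means of log-normalized expression
#'
#' For each feature: the mean log2-normalized expression in the High and
#' Low groups, their average abundance a = (muH + muL) / 2 and the
#' differential expression d = muH - muL (High minus Low).
#'
#' @param expr An \linkS4class{ExpressionMatrix}, matrix, or list of either
#'   (layers stacked by row).
#' @param pheno Phenotype data.frame with \code{sample_id} and \code{group}.
#' @return data.frame(feature, muH, muL, abundance, diff).
#' @export
groupMeans <- function(expr, pheno) {
  asMat <- function(e) if (is(e, "ExpressionMatrix")) exprValues(e) else e
  m <- if (is.list(expr) && !is(expr, "ExpressionMatrix"))
    do.call(rbind, lapply(expr, asMat)) else asMat(expr)
  idx <- match(colnames(m), pheno$sample_id)
  if (anyNA(idx)) stop("phenotype table is missing sample(s)")
  grp <- pheno$group[idx]
  muH <- rowMeans(m[, grp == "H", drop = FALSE])
  muL <- rowMeans(m[, grp == "L", drop = FALSE])
  data.frame(feature = rownames(m), muH = muH, muL = muL,
             abundance = (muH + muL) / 2, diff = muH - muL,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Phenotypic impact factor
#'
#' PIF_j = abundance_j * diff_j: average abundance times differential
#' expression, weighting a feature's contribution to the group contrast.
#'
#' @param gm Result of \code{\link{groupMeans}}.
#' @return Named numeric vector of PIF scores.
#' @export
pifScores <- function(gm) {
  setNames(gm$abundance * gm$diff, gm$feature)
}

#' Regulatory impact factor 1 (differential wiring)
#'
#' RIF1_i = (1/n_de) * sum_j PIF_j * (r_H[i, j] - r_L[i, j])^2 over the DE
#' features j: a PIF-weighted squared change in co-expression between
#' conditions.
#'
#' @param regulators Character vector of candidate regulator ids.
#' @param deFeatures Character vector of DE feature ids (nonempty).
#' @param corrH,corrL Correlation matrices (or
#'   \linkS4class{CorrelationNetwork}s) covering regulators and DE
#'   features, per group.
#' @param pif Named PIF vector covering the DE features.
#' @return Named numeric vector of raw RIF1 scores.
#' @export
rif1Scores <- function(regulators, deFeatures, corrH, corrL, pif) {
  if (!length(deFeatures)) stop("RIF undefined without DE features")
  rH <- if (is(corrH, "CorrelationNetwork")) corrH@r else corrH
  rL <- if (is(corrL, "CorrelationNetwork")) corrL@r else corrL
  .checkRifIds(regulators, deFeatures, rH, rL)
  if (anyNA(pif[deFeatures])) stop("PIF missing for some DE features")
  dw <- (rH[regulators, deFeatures, drop = FALSE] -
           rL[regulators, deFeatures, drop = FALSE])^2
  drop(dw %*% pif[deFeatures]) / length(deFeatures)
}

#' Regulatory impact factor 2 (predicted ability)
#'
#' RIF2_i = (1/n_de) * sum_j [(muH_j r_H[i, j])^2 - (muL_j r_L[i, j])^2]:
#' the change, between conditions, in the regulator's squared ability to
#' predict the DE features' abundance.
#'
#' @param regulators,deFeatures,corrH,corrL As in \code{\link{rif1Scores}}.
#' @param gm Result of \code{\link{groupMeans}} covering the DE features.
#' @return Named numeric vector of raw RIF2 scores.
#' @export
rif2Scores <- function(regulators, deFeatures, corrH, corrL, gm) {
  if (!length(deFeatures)) stop("RIF undefined without DE features")
  rH <- if (is(corrH, "CorrelationNetwork")) corrH@r else corrH
  rL <- if (is(corrL, "CorrelationNetwork")) corrL@r else corrL
  .checkRifIds(regulators, deFeatures, rH, rL)
  mu <- gm[match(deFeatures, gm$feature), ]
  if (anyNA(mu$feature)) stop("group means missing for some DE features")
  eH <- sweep(rH[regulators, deFeatures, drop = FALSE], 2L, mu$muH, `*`)^2
  eL <- sweep(rL[regulators, deFeatures, drop = FALSE], 2L, mu$muL, `*`)^2
  rowSums(eH - eL) / length(deFeatures)
}

.checkRifIds <- function(regulators, deFeatures, rH, rL) {
  for (r in list(rH, rL)) {
    miss <- setdiff(c(regulators, deFeatures), rownames(r))
    if (length(miss))
      stop("correlation matrix is missing feature(s): ",
           paste(utils::head(miss, 5L), collapse = ", "))
  }
  invisible(TRUE)
}

#' Combined PIF/RIF regulator scoring
#'
#' Computes PIF for all features and raw plus standardized (mean 0, sd 1
#' over scored regulators) RIF1 and RIF2 for the candidate regulators.
#'
#' @param exprH,exprL Expression matrices (or lists of layers) restricted
#'   to each group's samples, used for the per-group correlations.
#' @param gm Result of \code{\link{groupMeans}} on the full sample set.
#' @param deFeatures Character vector of DE feature ids.
#' @param regulators Candidate regulator ids; default all features.
#' @return list(pif = named vector over all features, scores = data.frame(
#'   regulator, rif1, rif2, rif1_z, rif2_z)).
#' @export
regulatorScores <- function(exprH, exprL, gm, deFeatures,
                            regulators = NULL) {
  netH <- correlationNetwork(exprH, group = "H")
  netL <- correlationNetwork(exprL, group = "L")
  common <- intersect(featureIds(netH), featureIds(netL))
  if (is.null(regulators)) regulators <- common
  deFeatures <- intersect(deFeatures, common)
  pif <- pifScores(gm)
  r1 <- rif1Scores(regulators, deFeatures, netH, netL, pif)
  r2 <- rif2Scores(regulators, deFeatures, netH, netL, gm)
  zs <- function(x) if (sd(x) > 0) (x - mean(x)) / sd(x) else x * 0
  list(pif = pif,
       scores = data.frame(regulator = regulators, rif1 = unname(r1),
                           rif2 = unname(r2), rif1_z = unname(zs(r1)),
                           rif2_z = unname(zs(r2)),
                           stringsAsFactors = FALSE))
}

#' Rank features by a score
#'
#' Deterministic top-k most positive and most negative scores, ties broken
#' by lexicographic feature id.
#'
#' @param scores Named numeric vector.
#' @param k List length (default 10).
#' @return list(positive, negative) of data.frame(feature, score).
#' @export
rankRegulators <- function(scores, k = 10L) {
  stopifnot(!is.null(names(scores)))
  k <- min(k, length(scores))
  tab <- data.frame(feature = names(scores), score = unname(scores),
                    stringsAsFactors = FALSE)
  pos <- tab[order(-tab$score, tab$feature), ][seq_len(k), ]
  neg <- tab[order(tab$score, tab$feature), ][seq_len(k), ]
  rownames(pos) <- rownames(neg) <- NULL
  list(positive = pos, negative = neg)
}
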