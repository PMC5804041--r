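#' @importFrom stats median model.matrix pt p.adjust sd var cor
#' @useDynLib mirCoNet, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

#' Median-of-ratios size factors
#'
#' Per-sample size factors by the median-of-ratios method: each sample's
#' factor is the median, over features with positive counts in every
#' sample, of the ratio of the sample's count to the feature's geometric
#' mean. Factors are rescaled to geometric mean 1.
#'
#' @param object A \linkS4class{CountMatrix} or count matrix.
#' @return Named positive numeric vector, one factor per sample.
#' @examples
#' cm <- CountMatrix(matrix(c(2, 6, 4, 12), 2,
#'   dimnames = list(c("g1", "g2"), c("s1", "s2"))), layer = "mRNA")
#' medianRatioSizeFactors(cm)
#' @export
medianRatioSizeFactors <- function(object) {
  v <- if (is(object, "CountMatrix")) counts(object) else object
  allPos <- rowSums(v > 0) == ncol(v)
  if (!any(allPos))
    stop("no feature has positive counts in all samples; ",
         "size factors are undefined (consider a pseudo-reference fallback)")
  vv <- v[allPos, , drop = FALSE]
  geo <- exp(rowMeans(log(vv)))
  sf <- apply(vv / geo, 2L, median)
  sf <- sf / exp(mean(log(sf)))
  sf
}

#' Log2 normalization of counts
#'
#' \code{log2(count / sizeFactor + pseudocount)} per cell.
#'
#' @param object A \linkS4class{CountMatrix}.
#' @param sizeFactors Per-sample positive factors; default computed with
#'   \code{\link{medianRatioSizeFactors}}.
#' @param pseudocount Positive pseudocount (default 1).
#' @return An \linkS4class{ExpressionMatrix}.
#' @export
normalizeCounts <- function(object, sizeFactors = NULL, pseudocount = 1) {
  stopifnot(is(object, "CountMatrix"))
  if (is.null(sizeFactors)) sizeFactors <- medianRatioSizeFactors(object)
  if (any(sizeFactors <= 0)) stop("size factors must be positive")
  if (length(sizeFactors) != ncol(object))
    stop("one size factor per sample is required")
  v <- counts(object)
  lv <- log2(sweep(v, 2L, sizeFactors, `/`) + pseudocount)
  se <- SummarizedExperiment(assays = list(logexpr = lv))
  new("ExpressionMatrix", se, layer = object@layer,
      sizeFactors = setNames(as.numeric(sizeFactors), colnames(v)),
      pseudocount = pseudocount)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up BH adjustment (wraps \code{\link[stats]{p.adjust}}), with input
#' validation.
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @return Adjusted q-values, same order as \code{p}.
#' @export
bhAdjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Negative-binomial differential expression test
#'
#' Per-feature NB log-linear model \code{count ~ group + covariates} with
#' a log size-factor offset, fit by iteratively reweighted least squares
#' with a method-of-moments dispersion, and a Wald test on the group
#' coefficient (t reference with residual degrees of freedom). The group
#' factor is coded so the coefficient is Low minus High: negative log2 fold
#' changes mean lower expression in the Low group. This is a deliberately
#' simple DE stage: no dispersion shrinkage across features, no independent
#' filtering, no outlier replacement.
#'
#' @param object A \linkS4class{CountMatrix}.
#' @param pheno Phenotype data.frame with \code{sample_id}, \code{group}
#'   and any covariate columns, in any sample order.
#' @param covariates Character vector of phenotype columns to adjust for
#'   (categorical columns enter as one-hot fixed effects).
#' @param sizeFactors Optional per-sample size factors; default
#'   median-of-ratios.
#' @param fdr FDR level for the DE flag (default 0.10).
#' @return data.frame(feature, baseMeanLow, baseMeanHigh, log2FoldChange,
#'   pvalue, qvalue, de, status). Status is \code{"ok"},
#'   \code{"untestable"} (all-zero or constant feature; p = 1, lfc = 0) or
#'   \code{"not_converged"} (p = 1).
#' @export
deTest <- function(object, pheno, covariates = character(),
                   sizeFactors = NULL, fdr = 0.10) {
  stopifnot(is(object, "CountMatrix"))
  if (!all(c("sample_id", "group") %in% names(pheno)))
    stop("phenotypes need sample_id and group columns")
  idx <- match(colnames(object), pheno$sample_id)
  if (anyNA(idx)) stop("phenotype table is missing sample(s): ",
                       paste(colnames(object)[is.na(idx)], collapse = ", "))
  ph <- pheno[idx, , drop = FALSE]
  if (length(unique(ph$group)) != 2L) stop("two groups are required")
  miss <- setdiff(covariates, names(ph))
  if (length(miss))
    stop("missing covariate column(s): ", paste(miss, collapse = ", "))

  v <- counts(object)
  if (is.null(sizeFactors)) sizeFactors <- medianRatioSizeFactors(object)
  off <- log(sizeFactors)

  # reference level High, so the group coefficient is Low minus High
  df <- data.frame(group = factor(ph$group, levels = c("H", "L")))
  for (cv in covariates) {
    col <- ph[[cv]]
    if (is.character(col)) {
      col <- factor(col)
      confounded <- table(ph$group, col)
      if (any(colSums(confounded > 0) < 2L))
        warning(sprintf(
          "covariate '%s' has level(s) present in only one group", cv))
    }
    df[[cv]] <- col
  }
  X <- model.matrix(~ ., data = df)
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank-deficient")
  coefIdx <- which(colnames(X) == "groupL")

  constant <- apply(v, 1L, function(y) all(y == y[1L]))
  fit <- .nb_wald_cpp(v, X, off, coefIdx - 1L)

  stat <- fit$estimate / (fit$se * sqrt(fit$phi))
  dfRes <- ncol(v) - ncol(X)
  pval <- 2 * pt(-abs(stat), df = dfRes)
  lfc <- fit$estimate / log(2)

  status <- rep("ok", nrow(v))
  status[fit$status == 1L] <- "not_converged"
  status[fit$status == 2L | constant] <- "untestable"
  bad <- status != "ok"
  pval[bad] <- 1
  lfc[status == "untestable"] <- 0
  pval[!is.finite(pval)] <- 1

  norm <- sweep(v, 2L, sizeFactors, `/`)
  isL <- ph$group == "L"
  out <- data.frame(
    feature = rownames(v),
    baseMeanLow = rowMeans(norm[, isL, drop = FALSE]),
    baseMeanHigh = rowMeans(norm[, !isL, drop = FALSE]),
    log2FoldChange = lfc,
    dispersion = fit$alpha,
    pvalue = pval,
    stringsAsFactors = FALSE
  )
  out$qvalue <- bhAdjust(out$pvalue)
  out$de <- out$qvalue <= fdr & !bad
  out$status <- status
  rownames(out) <- NULL
  out
}

#' Write a DE result table as TSV
#'
#' @param de Result of \code{\link{deTest}}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
writeDeTable <- function(de, path) {
  write.table(de, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
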