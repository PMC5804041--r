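#' @importFrom stats hclust cutree as.dist quantile lm coef
NULL

# WGCNA-style colour palette; colours are assigned by decreasing module
# size for familiarity only and carry no semantics.
.moduleColors <- c(
  "turquoise", "blue", "brown", "yellow", "green", "red", "black", "pink",
  "magenta", "purple", "greenyellow", "tan", "salmon", "cyan",
  "midnightblue", "lightcyan", "grey60", "lightgreen", "lightyellow",
  "royalblue", "darkred", "darkgreen", "darkturquoise", "darkgrey",
  "orange", "darkorange", "white", "skyblue", "saddlebrown", "steelblue",
  "paleturquoise", "violet", "darkolivegreen", "darkmagenta")

.colorName <- function(i) {
  if (i <= length(.moduleColors)) .moduleColors[i]
  else sprintf("module%03d", i)
}

#' Signed adjacency from expression or correlations
#'
#' Signed similarity s = (1 + cor) / 2 raised to the soft-threshold power
#' beta: a = s^beta, values in [0, 1], diagonal 1.
#'
#' @param x An \linkS4class{ExpressionMatrix}, expression matrix
#'   (features x samples) or a precomputed correlation matrix (detected by
#'   symmetry with unit diagonal).
#' @param beta Positive soft-threshold power.
#' @return Adjacency matrix in [0, 1].
#' @export
signedAdjacency <- function(x, beta) {
  stopifnot(beta > 0)
  r <- .asCorrelation(x)
  ((1 + r) / 2)^beta
}

.asCorrelation <- function(x) {
  m <- if (is(x, "ExpressionMatrix")) exprValues(x) else x
  stopifnot(is.matrix(m))
  isCor <- nrow(m) == ncol(m) && all(abs(diag(m) - 1) < 1e-12) &&
    max(abs(m)) <= 1 + 1e-12 && isTRUE(all.equal(m, t(m),
                                                 tolerance = 1e-12))
  if (isCor) return(m)
  r <- cor(t(m))
  r[r > 1] <- 1; r[r < -1] <- -1
  r
}

#' Soft-threshold selection by scale-free fit
#'
#' For each candidate power beta the signed adjacency is formed and the
#' connectivity k_i = sum_j a_ij (j != i) computed; features are binned
#' into \code{nBins} equal-occupancy connectivity bins and the signed R^2
#' of the regression of log10 p(k) on log10 mean(k) is taken (negated when
#' the slope is positive). The selected beta is the lowest candidate whose
#' signed R^2 exceeds \code{r2Cut}; if none qualifies, the beta maximizing
#' R^2 is chosen with a warning.
#'
#' @param expr An \linkS4class{ExpressionMatrix} or expression matrix.
#' @param candidates Candidate powers (default 1:20).
#' @param r2Cut Scale-free fit threshold (default 0.90).
#' @param nBins Connectivity bins for the fit (default 10).
#' @return list(table = data.frame(beta, r2, meanK), beta, rule =
#'   "auto" | "max_r2").
#' @export
pickSoftThreshold <- function(expr, candidates = 1:20, r2Cut = 0.90,
                              nBins = 10L) {
  r <- .asCorrelation(expr)
  if (all(abs(r - 1) < 1e-12)) {
    warning("degenerate similarity (all correlations 1); fit is undefined")
    return(list(table = data.frame(beta = candidates, r2 = NA_real_,
                                   meanK = nrow(r) - 1),
                beta = candidates[1L], rule = "degenerate"))
  }
  s <- (1 + r) / 2
  diag(s) <- 0
  rows <- lapply(candidates, function(beta) {
    k <- rowSums(s^beta)
    data.frame(beta = beta, r2 = .scaleFreeR2(k, nBins), meanK = mean(k))
  })
  tab <- do.call(rbind, rows)
  ok <- which(!is.na(tab$r2) & tab$r2 > r2Cut)
  if (length(ok)) {
    list(table = tab, beta = tab$beta[ok[1L]], rule = "auto")
  } else {
    warning(sprintf(
      "no candidate power reached scale-free R^2 > %.2f; using the max",
      r2Cut))
    list(table = tab, beta = tab$beta[which.max(tab$r2)], rule = "max_r2")
  }
}

# signed scale-free fit: log10 density(k) ~ log10 kbar over 10 equal-
# occupancy bins (frequency density = bin share / bin width, so the
# quantile binning estimates p(k) rather than the constant bin share)
.scaleFreeR2 <- function(k, nBins = 10L) {
  if (var(k) == 0) return(NA_real_)
  br <- unique(quantile(k, probs = seq(0, 1, length.out = nBins + 1L)))
  if (length(br) < 4L) return(NA_real_)
  bin <- cut(k, breaks = br, include.lowest = TRUE)
  share <- tabulate(bin, nbins = nlevels(bin)) / length(k)
  width <- diff(br)
  pk <- share / width
  kbar <- tapply(k, bin, mean)
  keep <- pk > 0 & is.finite(kbar) & kbar > 0
  if (sum(keep) < 3L) return(NA_real_)
  fit <- lm(log10(pk[keep]) ~ log10(kbar[keep]))
  r2 <- summary(fit)$r.squared
  if (coef(fit)[2L] > 0) -r2 else r2
}

#' Topological overlap matrix
#'
#' TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij) with the
#' diagonal set to 1; the clustering distance is 1 - TOM.
#'
#' @param adjacency Adjacency matrix in [0, 1] (diagonal ignored).
#' @return TOM similarity matrix in [0, 1].
#' @seealso \code{\link{tomReference}}
#' @export
tomSimilarity <- function(adjacency) {
  a <- adjacency
  stopifnot(nrow(a) == ncol(a))
  diag(a) <- 0
  k <- rowSums(a)
  num <- a %*% a + a
  den <- outer(k, k, pmin) + 1 - a
  tom <- num / den
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adjacency)
  tom
}

#' Reference TOM (scalar triple loop)
#'
#' Plain-loop implementation of the topological overlap formula, used as
#' the oracle for \code{\link{tomSimilarity}} on small inputs.
#'
#' @param adjacency Adjacency matrix in [0, 1].
#' @return TOM similarity matrix.
#' @export
tomReference <- function(adjacency) {
  a <- adjacency
  diag(a) <- 0
  n <- nrow(a)
  tom <- diag(1, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      l <- 0
      for (u in seq_len(n)) l <- l + a[i, u] * a[u, j]
      ki <- sum(a[i, ]); kj <- sum(a[j, ])
      tom[i, j] <- (l + a[i, j]) / (min(ki, kj) + 1 - a[i, j])
    }
  }
  dimnames(tom) <- dimnames(adjacency)
  tom
}

#' Module eigengenes
#'
#' Per module: member features are standardized (mean 0, sd 1 across
#' samples), and the first right singular vector of the standardized
#' submatrix is the eigengene, its sign fixed so the mean correlation with
#' the member features is positive. Zero-variance members are dropped with
#' a warning. Variance explained is the top singular value's share of the
#' total squared singular values.
#'
#' @param expr An \linkS4class{ExpressionMatrix} or matrix
#'   (features x samples).
#' @param labels Named character vector, feature -> module; "grey" is
#'   skipped.
#' @return list(eigengenes = modules x samples matrix, varExplained =
#'   named numeric).
#' @export
moduleEigengenes <- function(expr, labels) {
  m <- if (is(expr, "ExpressionMatrix")) exprValues(expr) else expr
  mods <- setdiff(sort(unique(labels)), "grey")
  me <- matrix(NA_real_, length(mods), ncol(m),
               dimnames = list(mods, colnames(m)))
  ve <- setNames(numeric(length(mods)), mods)
  for (mod in mods) {
    members <- names(labels)[labels == mod]
    x <- m[members, , drop = FALSE]
    sds <- apply(x, 1L, sd)
    if (any(sds == 0)) {
      warning(sprintf("dropping %d zero-variance feature(s) from '%s'",
                      sum(sds == 0), mod))
      x <- x[sds > 0, , drop = FALSE]
      sds <- sds[sds > 0]
    }
    if (nrow(x) < 2L) stop("module '", mod, "' has < 2 usable features")
    xs <- (x - rowMeans(x)) / sds
    sv <- svd(xs, nu = 0, nv = 1)
    v <- sv$v[, 1L]
    if (mean(cor(v, t(x))) < 0) v <- -v
    me[mod, ] <- v
    ve[mod] <- sv$d[1L]^2 / sum(sv$d^2)
  }
  list(eigengenes = me, varExplained = ve)
}

#' Module membership
#'
#' MM[f, m] = correlation across samples between feature f's expression
#' and module m's eigengene.
#'
#' @param expr An \linkS4class{ExpressionMatrix} or matrix.
#' @param me Eigengene matrix (modules x samples) or the list returned by
#'   \code{\link{moduleEigengenes}}.
#' @return Numeric matrix, features x modules.
#' @export
moduleMembership <- function(expr, me) {
  m <- if (is(expr, "ExpressionMatrix")) exprValues(expr) else expr
  if (is.list(me)) me <- me$eigengenes
  ok <- apply(m, 1L, sd) > 0
  mm <- matrix(0, nrow(m), nrow(me), dimnames = list(rownames(m),
                                                     rownames(me)))
  if (any(ok)) mm[ok, ] <- cor(t(m[ok, , drop = FALSE]), t(me))
  mm
}

#' Hub feature of each module
#'
#' The member with the highest module membership for its own module;
#' deterministic with lexicographic tie-break.
#'
#' @param mm Module membership matrix (\code{\link{moduleMembership}}).
#' @param labels Named character feature -> module vector.
#' @return Named character vector, module -> hub feature id.
#' @export
moduleHubs <- function(mm, labels) {
  mods <- setdiff(sort(unique(labels)), "grey")
  vapply(setNames(mods, mods), function(mod) {
    members <- sort(names(labels)[labels == mod])
    v <- mm[members, mod]
    members[which.max(v)]  # which.max takes the first = lexicographic tie
  }, character(1))
}

#' Detect signed co-expression modules
#'
#' Average-linkage hierarchical clustering of the TOM dissimilarity, a
#' static cut (default at the 0.85 quantile of the dendrogram merge
#' heights, below the band where unstructured features coalesce),
#' greying of clusters below the minimum size, eigengene
#' computation, and iterative merging of module pairs whose eigengene
#' dissimilarity 1 - cor is below \code{mergeHeight} until none remain.
#' Final modules are renamed by decreasing size along a fixed colour
#' palette.
#'
#' @param diss TOM dissimilarity matrix (1 - TOM).
#' @param expr An \linkS4class{ExpressionMatrix} or matrix over the same
#'   features, used for eigengenes.
#' @param minSize Minimum module size (30 for mRNA, 5 for miRNA layers in
#'   the package defaults).
#' @param mergeHeight Eigengene-dissimilarity merge threshold
#'   (default 0.25).
#' @param cutHeight Static cut height; default the 0.85 quantile of merge
#'   heights.
#' @return A \linkS4class{ModuleSet}.
#' @export
detectModules <- function(diss, expr, minSize, mergeHeight = 0.25,
                          cutHeight = NULL) {
  stopifnot(nrow(diss) == ncol(diss))
  ids <- rownames(diss)
  if (is.null(ids)) stop("dissimilarity matrix must carry feature ids")
  if (nrow(diss) < minSize) {
    warning("fewer features than the minimum module size; all grey")
    labels <- setNames(rep("grey", nrow(diss)), ids)
    return(new("ModuleSet", labels = labels,
               eigengenes = matrix(numeric(0), 0, 0),
               varExplained = numeric(0),
               membership = matrix(numeric(0), 0, 0),
               minSize = as.integer(minSize), mergeHeight = mergeHeight,
               cutHeight = NA_real_))
  }
  hc <- hclust(as.dist(diss), method = "average")
  if (is.null(cutHeight)) cutHeight <- quantile(hc$height, 0.85)
  cl <- cutree(hc, h = cutHeight)
  tab <- table(cl)
  labels <- setNames(rep("grey", length(ids)), ids)
  big <- names(tab)[tab >= minSize]
  for (i in seq_along(big)) labels[cl == as.integer(big[i])] <-
    paste0("raw", i)

  m <- if (is(expr, "ExpressionMatrix")) exprValues(expr) else expr
  m <- m[ids, , drop = FALSE]

  # iterative eigengene merge
  repeat {
    mods <- setdiff(unique(labels), "grey")
    if (length(mods) < 2L) break
    eg <- moduleEigengenes(m, labels)
    d <- 1 - cor(t(eg$eigengenes))
    diag(d) <- Inf
    if (min(d) >= mergeHeight) break
    pair <- which(d == min(d), arr.ind = TRUE)[1L, ]
    a <- rownames(d)[pair[1L]]; b <- colnames(d)[pair[2L]]
    into <- if (sum(labels == a) >= sum(labels == b)) a else b
    from <- if (into == a) b else a
    labels[labels == from] <- into
  }

  # rename by decreasing size, lexicographic tie-break on old label
  mods <- setdiff(unique(labels), "grey")
  if (length(mods)) {
    sizes <- vapply(mods, function(mod) sum(labels == mod), numeric(1))
    ord <- mods[order(-sizes, mods)]
    newName <- setNames(vapply(seq_along(ord), .colorName, character(1)),
                        ord)
    labels[labels != "grey"] <- newName[labels[labels != "grey"]]
    eg <- moduleEigengenes(m, labels)
    mm <- moduleMembership(m, eg)
  } else {
    eg <- list(eigengenes = matrix(numeric(0), 0, ncol(m),
                                   dimnames = list(NULL, colnames(m))),
               varExplained = numeric(0))
    mm <- matrix(numeric(0), nrow(m), 0,
                 dimnames = list(rownames(m), NULL))
  }
  new("ModuleSet", labels = labels, eigengenes = eg$eigengenes,
      varExplained = eg$varExplained, membership = mm,
      minSize = as.integer(minSize), mergeHeight = mergeHeight,
      cutHeight = unname(cutHeight))
}

#' One-call module detection from expression
#'
#' Convenience wrapper: soft-threshold selection (or a fixed override),
#' signed adjacency, TOM, and \code{\link{detectModules}}.
#'
#' @param expr An \linkS4class{ExpressionMatrix} or matrix
#'   (features x samples).
#' @param minSize Minimum module size.
#' @param beta Fixed soft-threshold power; NULL selects by scale-free fit.
#' @param mergeHeight,cutHeight Passed to \code{\link{detectModules}}.
#' @param r2Cut Scale-free fit threshold for automatic beta selection.
#' @return A \linkS4class{ModuleSet}; the power used is attached as
#'   attribute \code{"beta"}.
#' @export
coexpressionModules <- function(expr, minSize, beta = NULL,
                                mergeHeight = 0.25, cutHeight = NULL,
                                r2Cut = 0.90) {
  r <- .asCorrelation(expr)
  if (is.null(beta)) beta <- pickSoftThreshold(r, r2Cut = r2Cut)$beta
  adj <- signedAdjacency(r, beta)
  tom <- tomSimilarity(adj)
  ms <- detectModules(1 - tom, expr, minSize = minSize,
                      mergeHeight = mergeHeight, cutHeight = cutHeight)
  attr(ms, "beta") <- beta
  ms
}

#' Write module assignment and membership as TSV
#'
#' @param ms A \linkS4class{ModuleSet}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
writeModuleTable <- function(ms, path) {
  mm <- membership(ms)
  tab <- data.frame(feature = names(moduleLabels(ms)),
                    module = unname(moduleLabels(ms)),
                    stringsAsFactors = FALSE)
  if (ncol(mm)) {
    mmTab <- as.data.frame(mm[tab$feature, , drop = FALSE])
    names(mmTab) <- paste0("MM.", colnames(mm))
    tab <- cbind(tab, mmTab)
  }
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write eigengenes as TSV
#'
#' @param ms A \linkS4class{ModuleSet}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
writeEigengeneTable <- function(ms, path) {
  eg <- eigengenes(ms)
  tab <- data.frame(module = rownames(eg), eg, check.names = FALSE,
                    stringsAsFactors = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
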