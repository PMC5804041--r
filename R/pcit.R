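#' Per-group co-expression network
#'
#' Pearson correlations of log-normalized expression across the samples of
#' one group, with two-sided p-values from the t transform on n - 2 degrees
#' of freedom. Constant features are dropped with a warning listing their
#' ids. Multiple expression layers (e.g. mRNA and miRNA) can be combined by
#' passing a list.
#'
#' @param expr An \linkS4class{ExpressionMatrix}, a numeric matrix
#'   (features x samples), or a list of either to stack by row.
#' @param samples Character vector of sample ids (or logical/integer index)
#'   selecting the group's samples; default all columns.
#' @param group Group label stored on the network (default "all").
#' @return A \linkS4class{CorrelationNetwork}.
#' @export
correlationNetwork <- function(expr, samples = NULL, group = "all") {
  asMat <- function(e) if (is(e, "ExpressionMatrix")) exprValues(e) else e
  m <- if (is.list(expr) && !is(expr, "ExpressionMatrix"))
    do.call(rbind, lapply(expr, asMat)) else asMat(expr)
  if (anyDuplicated(rownames(m)))
    stop("duplicate feature ids across layers")
  if (!is.null(samples)) m <- m[, samples, drop = FALSE]
  n <- ncol(m)
  if (n < 3L) stop("at least 3 samples are required")
  const <- apply(m, 1L, function(x) var(x) == 0)
  if (any(const)) {
    warning("dropping constant feature(s): ",
            paste(rownames(m)[const], collapse = ", "))
    m <- m[!const, , drop = FALSE]
  }
  r <- cor(t(m))
  r[r > 1] <- 1; r[r < -1] <- -1
  tt <- abs(r) * sqrt((n - 2) / pmax(1 - r * r, .Machine$double.eps))
  p <- 2 * pt(tt, df = n - 2, lower.tail = FALSE)
  diag(p) <- 0
  new("CorrelationNetwork", group = as.character(group), r = r, p = p,
      mask = matrix(logical(0), 0, 0), nSamples = as.integer(n))
}

#' PCIT association filter
#'
#' For every feature trio (x, y, z) the three first-order partial
#' correlations r_xy.z = (r_xy - r_xz r_yz) / sqrt((1 - r_xz^2)(1 -
#' r_yz^2)) (and cyclic) are computed and a trio tolerance
#' eps = mean of the signed partial/direct ratios is formed; the pair
#' (x, y) is eliminated if some z satisfies |r_xy| < |eps r_xz| and
#' |r_xy| < |eps r_yz|. An association is retained if no trio eliminates
#' it. Trios where a ratio is undefined (|r| numerically 0) or a partial-
#' correlation denominator underflows (|r| >= 1 - 1e-12) are skipped; the
#' count of skipped trios is attached as attribute \code{"skipped"}. With
#' fewer than 3 features every off-diagonal pair is retained by convention.
#'
#' @param x A \linkS4class{CorrelationNetwork} or a symmetric correlation
#'   matrix.
#' @return For a matrix, the logical retention mask (symmetric, diagonal
#'   FALSE). For a network, the network with its \code{mask} slot filled.
#' @seealso \code{\link{pcitReference}} for the plain-R reference loop.
#' @export
pcit <- function(x) {
  if (is(x, "CorrelationNetwork")) {
    mask <- pcit(x@r)
    x@mask <- mask
    validObject(x)
    return(x)
  }
  stopifnot(is.matrix(x), nrow(x) == ncol(x))
  mask <- .pcit_mask_cpp(x)
  skipped <- attr(mask, "skipped")
  attr(mask, "skipped") <- NULL
  if (!is.null(skipped) && skipped > 0)
    message(sprintf("pcit: %d trio(s) skipped (degenerate correlations)",
                    as.integer(skipped)))
  dimnames(mask) <- dimnames(x)
  mask
}

#' Reference PCIT implementation (explicit O(n^3) loop)
#'
#' A deliberately plain triple loop over feature trios implementing the
#' same elimination rule and skip rules as \code{\link{pcit}}. It is the
#' definition of record against which the compiled implementation is
#' checked, and is not meant for large inputs.
#'
#' @param r Symmetric correlation matrix.
#' @return Logical retention mask, as \code{\link{pcit}}.
#' @export
pcitReference <- function(r) {
  stopifnot(is.matrix(r), nrow(r) == ncol(r))
  n <- nrow(r)
  keep <- matrix(TRUE, n, n, dimnames = dimnames(r))
  diag(keep) <- FALSE
  if (n < 3L) return(keep)
  elim <- matrix(FALSE, n, n)
  lo <- 1e-12; hi <- 1 - 1e-12
  for (x in 1:(n - 2)) {
    for (y in (x + 1):(n - 1)) {
      for (z in (y + 1):n) {
        rxy <- r[x, y]; rxz <- r[x, z]; ryz <- r[y, z]
        axy <- abs(rxy); axz <- abs(rxz); ayz <- abs(ryz)
        if (axy < lo || axz < lo || ayz < lo ||
            axy > hi || axz > hi || ayz > hi) next
        rxy_z <- (rxy - rxz * ryz) / sqrt((1 - rxz * rxz) * (1 - ryz * ryz))
        rxz_y <- (rxz - rxy * ryz) / sqrt((1 - rxy * rxy) * (1 - ryz * ryz))
        ryz_x <- (ryz - rxy * rxz) / sqrt((1 - rxy * rxy) * (1 - rxz * rxz))
        eps <- (rxy_z / rxy + rxz_y / rxz + ryz_x / ryz) / 3
        aeps <- abs(eps)
        if (axy < aeps * axz && axy < aeps * ayz) elim[x, y] <- TRUE
        if (axz < aeps * axy && axz < aeps * ayz) elim[x, z] <- TRUE
        if (ayz < aeps * axy && ayz < aeps * axz) elim[y, z] <- TRUE
      }
    }
  }
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      keep[i, j] <- keep[j, i] <- !elim[i, j]
    }
  }
  keep
}

#' Differential hubbing between two group networks
#'
#' A connection in group g is a pair that is PCIT-retained in g and has
#' |r_g| above \code{edgeThreshold}. DH = conn_H - conn_L per feature:
#' negative DH means more connections in the Low group.
#'
#' @param netH,netL \linkS4class{CorrelationNetwork}s for the High and Low
#'   groups with PCIT masks (see \code{\link{pcit}}), over identical
#'   feature lists.
#' @param edgeThreshold Absolute-correlation edge filter (default 0.9).
#' @return data.frame(feature, connH, connL, dh), in network feature order.
#' @export
dhScores <- function(netH, netL, edgeThreshold = 0.9) {
  stopifnot(is(netH, "CorrelationNetwork"), is(netL, "CorrelationNetwork"))
  if (!identical(featureIds(netH), featureIds(netL)))
    stop("the two networks must share the same feature list")
  if (is.null(pcitMask(netH)) || is.null(pcitMask(netL)))
    stop("run pcit() on both networks first")
  connOf <- function(net) {
    e <- pcitMask(net) & abs(net@r) > edgeThreshold
    diag(e) <- FALSE
    rowSums(e)
  }
  connH <- connOf(netH); connL <- connOf(netL)
  data.frame(feature = featureIds(netH), connH = as.integer(connH),
             connL = as.integer(connL), dh = as.integer(connH - connL),
             stringsAsFactors = FALSE)
}

#' Top differentially hubbed features
#'
#' The k most positive and k most negative DH features, ties broken by
#' lexicographic feature id.
#'
#' @param dh Result of \code{\link{dhScores}}.
#' @param k List length (default 10; truncated to the number of features).
#' @return list(positive, negative) of data.frames ordered by decreasing
#'   (resp. increasing) DH.
#' @export
topDh <- function(dh, k = 10L) {
  k <- min(k, nrow(dh))
  pos <- dh[order(-dh$dh, dh$feature), , drop = FALSE][seq_len(k), ]
  neg <- dh[order(dh$dh, dh$feature), , drop = FALSE][seq_len(k), ]
  rownames(pos) <- rownames(neg) <- NULL
  list(positive = pos, negative = neg)
}

#' Neighbors of hub features in a filtered network
#'
#' Features connected to each hub by a PCIT-retained edge with |r| above
#' the threshold, with the signed correlation recorded per edge.
#'
#' @param net A \linkS4class{CorrelationNetwork} with a PCIT mask.
#' @param hubs Character vector of hub feature ids.
#' @param corrThreshold Absolute-correlation filter (default 0.9).
#' @return list(neighbors = named list of feature id vectors, edges =
#'   data.frame(hub, feature, r, sign)).
#' @export
hubNeighbors <- function(net, hubs, corrThreshold = 0.9) {
  stopifnot(is(net, "CorrelationNetwork"))
  if (is.null(pcitMask(net))) stop("run pcit() on the network first")
  unknown <- setdiff(hubs, featureIds(net))
  if (length(unknown))
    stop("unknown hub id(s): ", paste(unknown, collapse = ", "))
  e <- pcitMask(net) & abs(net@r) > corrThreshold
  diag(e) <- FALSE
  nb <- lapply(setNames(hubs, hubs), function(h)
    featureIds(net)[e[h, ]])
  edges <- do.call(rbind, lapply(hubs, function(h) {
    nn <- nb[[h]]
    if (!length(nn)) return(NULL)
    data.frame(hub = h, feature = nn, r = net@r[h, nn],
               sign = ifelse(net@r[h, nn] >= 0, "positive", "negative"),
               stringsAsFactors = FALSE)
  }))
  if (is.null(edges))
    edges <- data.frame(hub = character(), feature = character(),
                        r = numeric(), sign = character())
  rownames(edges) <- NULL
  list(neighbors = nb, edges = edges)
}

#' Write a network edge list as TSV
#'
#' One row per unordered feature pair with its correlation, group label and
#' PCIT retention flag, restricted to pairs with |r| above a floor to keep
#' files tractable.
#'
#' @param net A \linkS4class{CorrelationNetwork} (PCIT applied or not).
#' @param path Output file path.
#' @param minAbsR Only write pairs with |r| >= this floor (default 0.5).
#' @return \code{path}, invisibly.
#' @export
writeEdgeList <- function(net, path, minAbsR = 0.5) {
  r <- net@r
  ut <- upper.tri(r)
  sel <- which(ut & abs(r) >= minAbsR, arr.ind = TRUE)
  mask <- pcitMask(net)
  tab <- data.frame(
    feature_a = rownames(r)[sel[, 1L]],
    feature_b = colnames(r)[sel[, 2L]],
    r = r[sel],
    group = net@group,
    retained = if (is.null(mask)) NA else mask[sel],
    stringsAsFactors = FALSE
  )
  tab <- tab[order(tab$feature_a, tab$feature_b), , drop = FALSE]
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Variance-based feature pre-filter
#'
#' Keeps the top features by variance across samples. PCIT is cubic in the
#' feature count, so network stages default to a desk-scale cap; pass the
#' full feature list to disable.
#'
#' @param expr An \linkS4class{ExpressionMatrix} or matrix, or a list of
#'   them to rank jointly on the stacked feature set.
#' @param top Number of features to keep (default 500).
#' @return Character vector of retained feature ids.
#' @export
topVarianceFeatures <- function(expr, top = 500L) {
  asMat <- function(e) if (is(e, "ExpressionMatrix")) exprValues(e) else e
  m <- if (is.list(expr) && !is(expr, "ExpressionMatrix"))
    do.call(rbind, lapply(expr, asMat)) else asMat(expr)
  v <- apply(m, 1L, var)
  top <- min(top, nrow(m))
  names(sort(v, decreasing = TRUE))[seq_len(top)]
}
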