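#' @importFrom igraph graph_from_data_frame
NULL

# two-sided p for a Pearson correlation via the t transform, n - 2 df
.corPvalue <- function(r, n) {
  tt <- abs(r) * sqrt((n - 2) / pmax(1 - r * r, .Machine$double.eps))
  2 * pt(tt, df = n - 2, lower.tail = FALSE)
}

#' Cross-layer module-module correlation
#'
#' Pearson correlation between every miRNA module eigengene and every mRNA
#' module eigengene over the shared samples; a pair is retained when
#' r <= rCut (a negative correlation at least that strong) and p < pCut.
#'
#' @param meMirna,meMrna Eigengene matrices (modules x samples) or
#'   \linkS4class{ModuleSet}s, over identical samples.
#' @param rCut Correlation threshold (default -0.4).
#' @param pCut P-value threshold (default 0.05).
#' @return data.frame(mirnaModule, mrnaModule, r, p, retained), ordered by
#'   miRNA then mRNA module.
#' @export
moduleModuleCorrelation <- function(meMirna, meMrna, rCut = -0.4,
                                    pCut = 0.05) {
  a <- if (is(meMirna, "ModuleSet")) eigengenes(meMirna) else meMirna
  b <- if (is(meMrna, "ModuleSet")) eigengenes(meMrna) else meMrna
  if (!identical(colnames(a), colnames(b)))
    stop("eigengene matrices must cover identical samples")
  n <- ncol(a)
  r <- cor(t(a), t(b))
  p <- .corPvalue(r, n)
  out <- expand.grid(mirnaModule = rownames(a), mrnaModule = rownames(b),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- out[order(out$mirnaModule, out$mrnaModule), , drop = FALSE]
  out$r <- r[cbind(out$mirnaModule, out$mrnaModule)]
  out$p <- p[cbind(out$mirnaModule, out$mrnaModule)]
  out$retained <- out$r <= rCut & out$p < pCut
  rownames(out) <- NULL
  out
}

#' Module-trait correlation
#'
#' Pearson correlation of each module eigengene with a numeric trait
#' column, two-sided p from the t transform; modules with p < pCut are
#' retained. The p-values are deliberately unadjusted - the stage is
#' exploratory.
#'
#' @param me Eigengene matrix (modules x samples) or a
#'   \linkS4class{ModuleSet}.
#' @param pheno Phenotype data.frame with \code{sample_id} and the trait.
#' @param trait Name of the numeric trait column (e.g. "imf_percent").
#' @param pCut P-value threshold (default 0.1).
#' @return data.frame(module, trait, r, p, retained).
#' @export
moduleTraitCorrelation <- function(me, pheno, trait = "imf_percent",
                                   pCut = 0.1) {
  eg <- if (is(me, "ModuleSet")) eigengenes(me) else me
  if (ncol(eg) < 3L) stop("at least 3 samples are required")
  idx <- match(colnames(eg), pheno$sample_id)
  if (anyNA(idx)) stop("phenotype table is missing sample(s)")
  x <- pheno[[trait]][idx]
  if (!is.numeric(x)) stop("trait column must be numeric")
  if (var(x) == 0) stop("trait is constant")
  r <- drop(cor(t(eg), x))
  p <- .corPvalue(r, ncol(eg))
  out <- data.frame(module = rownames(eg), trait = trait, r = r, p = p,
                    retained = p < pCut, row.names = NULL,
                    stringsAsFactors = FALSE)
  out[order(out$module), , drop = FALSE]
}

#' Hub-miRNA / GO-term bipartite network
#'
#' For each retained miRNA-mRNA module pair, links the hub miRNAs of the
#' miRNA module to the enriched terms of the partner mRNA module, giving a
#' bipartite graph with typed nodes ("miRNA-hub", "term").
#'
#' @param pairs Retained rows of \code{\link{moduleModuleCorrelation}}.
#' @param hubs Named list: miRNA module -> character vector of hub miRNA
#'   ids.
#' @param enrichment Named list: mRNA module -> character vector of
#'   enriched term ids.
#' @return An \pkg{igraph} graph (possibly empty) with vertex attribute
#'   \code{type} and edge attribute \code{pair} recording the module pair.
#' @export
bipartiteNetwork <- function(pairs, hubs, enrichment) {
  edges <- do.call(rbind, lapply(seq_len(NROW(pairs)), function(i) {
    mi <- pairs$mirnaModule[i]; mr <- pairs$mrnaModule[i]
    h <- hubs[[mi]]; tm <- enrichment[[mr]]
    if (!length(h) || !length(tm)) return(NULL)
    expand.grid(from = h, to = tm, pair = paste(mi, mr, sep = "~"),
                KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  }))
  if (is.null(edges) || !nrow(edges)) {
    return(igraph::make_empty_graph(directed = FALSE))
  }
  g <- graph_from_data_frame(edges, directed = FALSE)
  igraph::V(g)$type <- ifelse(igraph::V(g)$name %in% unlist(hubs),
                              "miRNA-hub", "term")
  g
}

#' Write a bipartite (or any) igraph network as GraphML
#'
#' @param graph An \pkg{igraph} graph.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
writeGraphml <- function(graph, path) {
  igraph::write_graph(graph, path, format = "graphml")
  invisible(path)
}
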