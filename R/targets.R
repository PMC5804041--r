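#' Canonical seed-match miRNA target prediction
#'
#' Scans 3'UTR sequences (sense strand, DNA alphabet; U is converted to T
#' on both sides) for the canonical seed site types of each miRNA:
#' \itemize{
#'   \item 7mer-m8: reverse complement of miRNA positions 2-8;
#'   \item 8mer: the 7mer-m8 site followed by A;
#'   \item 7mer-A1: reverse complement of positions 2-7 followed by A.
#' }
#' All (including overlapping) occurrences are reported with 0-based start
#' coordinates on the UTR. miRNAs shorter than 8 nt are skipped with a
#' warning. The target map lists, per miRNA, the UTR ids with at least one
#' site, optionally intersected with an expressed-gene filter.
#'
#' @param mirnas Named character vector of miRNA sequences (5'->3').
#' @param utrs Named character vector of 3'UTR sequences (mRNA sense).
#' @param expressed Optional character vector restricting the target map to
#'   expressed genes.
#' @return list(sites = data.frame(mirna, utr, start, type), targets =
#'   named list miRNA -> character vector of target ids).
#' @examples
#' predictTargets(c(let7a = "UGAGGUAGUAGGUUGUAUAGUU"),
#'                c(u1 = "GGCTACCTCAGG"))
#' @export
predictTargets <- function(mirnas, utrs, expressed = NULL) {
  stopifnot(!is.null(names(mirnas)))
  mirnas <- chartr("Uu", "Tt", toupper(mirnas))
  utrs <- chartr("Uu", "Tt", toupper(utrs))
  short <- nchar(mirnas) < 8L
  if (any(short)) {
    warning("skipping miRNA(s) shorter than 8 nt: ",
            paste(names(mirnas)[short], collapse = ", "))
    mirnas <- mirnas[!short]
  }
  utrSet <- Biostrings::DNAStringSet(utrs)
  rc <- function(s) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(s)))
  rows <- list()
  for (mi in names(mirnas)) {
    seed28 <- substr(mirnas[[mi]], 2L, 8L)
    seed27 <- substr(mirnas[[mi]], 2L, 7L)
    patterns <- c(`7mer-m8` = rc(seed28),
                  `8mer` = paste0(rc(seed28), "A"),
                  `7mer-A1` = paste0(rc(seed27), "A"))
    for (ty in names(patterns)) {
      hits <- Biostrings::vmatchPattern(patterns[[ty]], utrSet)
      starts <- Biostrings::startIndex(hits)
      for (ui in which(lengths(starts) > 0)) {
        rows[[length(rows) + 1L]] <- data.frame(
          mirna = mi, utr = names(utrs)[ui],
          start = starts[[ui]] - 1L, type = ty,
          stringsAsFactors = FALSE)
      }
    }
  }
  sites <- if (length(rows)) do.call(rbind, rows) else
    data.frame(mirna = character(), utr = character(), start = integer(),
               type = character(), stringsAsFactors = FALSE)
  sites <- sites[order(sites$mirna, sites$utr, sites$start, sites$type), ,
                 drop = FALSE]
  rownames(sites) <- NULL
  targets <- lapply(setNames(names(mirnas), names(mirnas)), function(mi) {
    tg <- sort(unique(sites$utr[sites$mirna == mi]))
    if (!is.null(expressed)) tg <- intersect(tg, expressed)
    tg
  })
  list(sites = sites, targets = targets)
}

#' Hypergeometric gene-set enrichment
#'
#' Upper-tail hypergeometric test P[X >= k] per annotation term for a
#' selection drawn from a universe, with Benjamini-Hochberg adjustment
#' across the tested terms and an enrichment flag at the given FDR. Terms
#' are tested only when 1 <= K <= N - 1 and the overlap k >= 1; untested
#' terms can be reported with p = 1.
#'
#' @param selection Character vector of selected feature ids (must be a
#'   subset of the universe).
#' @param universe Character vector of universe feature ids.
#' @param annotation Named list of term member vectors
#'   (\code{\link{readAnnotation}}); members are intersected with the
#'   universe.
#' @param fdr FDR level for the enrichment flag (default 0.10).
#' @param reportUntested Include untested terms with p = 1 (default FALSE).
#' @return data.frame(term, k, K, n, N, p, q, enriched), ordered by p then
#'   term.
#' @export
enrichSets <- function(selection, universe, annotation, fdr = 0.10,
                       reportUntested = FALSE) {
  universe <- unique(universe)
  selection <- unique(selection)
  extra <- setdiff(selection, universe)
  if (length(extra))
    stop("selection not contained in universe: ",
         paste(utils::head(extra, 5L), collapse = ", "))
  N <- length(universe); n <- length(selection)
  tab <- do.call(rbind, lapply(names(annotation), function(term) {
    members <- intersect(annotation[[term]], universe)
    K <- length(members)
    k <- length(intersect(members, selection))
    data.frame(term = term, k = k, K = K, n = n, N = N,
               stringsAsFactors = FALSE)
  }))
  if (is.null(tab))
    return(data.frame(term = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(), p = numeric(),
                      q = numeric(), enriched = logical()))
  testable <- tab$K >= 1L & tab$K <= N - 1L & tab$k >= 1L
  tab$p <- NA_real_
  tab$p[testable] <- stats::phyper(tab$k[testable] - 1L, tab$K[testable],
                                   N - tab$K[testable], n,
                                   lower.tail = FALSE)
  tab$q <- NA_real_
  tab$q[testable] <- bhAdjust(tab$p[testable])
  tab$enriched <- !is.na(tab$q) & tab$q <= fdr
  if (!reportUntested) {
    tab <- tab[testable, , drop = FALSE]
  } else {
    tab$p[!testable] <- 1
    tab$q[!testable] <- 1
  }
  tab <- tab[order(tab$p, tab$term), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Enrichment of a miRNA module via its hub targets
#'
#' The selection is the union of the hub miRNAs' target genes intersected
#' with the universe, then tested with \code{\link{enrichSets}}. Hubs with
#' no targets give an empty selection and an empty result with a warning.
#'
#' @param hubMirnas Character vector of hub miRNA ids.
#' @param targetMap Named list miRNA -> targets
#'   (\code{\link{predictTargets}}).
#' @param universe,annotation,fdr As in \code{\link{enrichSets}}.
#' @return data.frame as \code{\link{enrichSets}} (empty when no targets).
#' @export
enrichMirnaModule <- function(hubMirnas, targetMap, universe, annotation,
                              fdr = 0.10) {
  selection <- intersect(
    unique(unlist(targetMap[intersect(hubMirnas, names(targetMap))])),
    universe)
  if (!length(selection)) {
    warning("hub miRNA(s) have no targets in the universe; empty result")
    return(enrichSets(character(), universe, annotation, fdr)[0L, ])
  }
  enrichSets(selection, universe, annotation, fdr)
}
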