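#' @importFrom utils read.delim write.table packageVersion
NULL

# Canonical table dialect used throughout: tab-separated, header row, feature
# ids in the first column, "\n" line endings, deterministic column order.
# Comma auto-sniffing is deliberately not attempted.

#' Read a feature x sample count table
#'
#' Reads a tab-separated count table (first column feature ids, header row of
#' sample ids, integer cells) into a \linkS4class{CountMatrix}. Row and
#' column order are preserved.
#'
#' @param path Path to a TSV file.
#' @param layer \code{"mRNA"} or \code{"miRNA"}.
#' @return A validated \linkS4class{CountMatrix}.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("feature_id\ts1\ts2", "g1\t0\t5", "g2\t3\t1"), tf)
#' cm <- readCounts(tf, layer = "mRNA")
#' counts(cm)
#' @export
readCounts <- function(path, layer = c("mRNA", "miRNA")) {
  layer <- match.arg(layer)
  tab <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    colClasses = "character", stringsAsFactors = FALSE)
  if (ncol(tab) < 2L)
    stop("count table must have a feature-id column and at least one sample")
  ids <- tab[[1L]]
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate feature id(s): ", paste(unique(dup), collapse = ", "))
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals)))
  bad <- which(is.na(num) | num < 0 | num != round(num), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf(
      "non-integer or negative count at row '%s', column '%s'",
      ids[bad[1L, 1L]], colnames(vals)[bad[1L, 2L]]))
  }
  storage.mode(num) <- "double"
  dimnames(num) <- list(ids, colnames(vals))
  CountMatrix(num, layer = layer)
}

#' Construct a CountMatrix from a matrix
#'
#' @param values Non-negative integer matrix with unique row (feature) and
#'   column (sample) names.
#' @param layer \code{"mRNA"} or \code{"miRNA"}.
#' @return A validated \linkS4class{CountMatrix}.
#' @export
CountMatrix <- function(values, layer = c("mRNA", "miRNA")) {
  layer <- match.arg(layer)
  se <- SummarizedExperiment(assays = list(counts = values))
  new("CountMatrix", se, layer = layer)
}

#' Write a CountMatrix as canonical TSV
#'
#' @param object A \linkS4class{CountMatrix}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
writeCounts <- function(object, path) {
  stopifnot(is(object, "CountMatrix"))
  v <- counts(object)
  tab <- data.frame(feature_id = rownames(v),
                    format(v, scientific = FALSE, trim = TRUE),
                    check.names = FALSE, stringsAsFactors = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
              eol = "\n")
  invisible(path)
}

#' Read a per-sample phenotype table
#'
#' Reads a tab-separated phenotype table. Required columns: \code{sample_id}
#' and \code{group} (values \code{H} or \code{L}). Recognized numeric
#' columns (\code{imf_percent}, \code{gebv}, \code{age_days},
#' \code{mapped_reads}) are typed and checked; \code{contemporary_group}
#' is kept categorical.
#'
#' @param path Path to a TSV file.
#' @return A data.frame with one row per sample.
#' @export
readPhenotypes <- function(path) {
  tab <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    colClasses = "character", stringsAsFactors = FALSE)
  if (nrow(tab) == 0L) stop("no samples in phenotype table")
  req <- c("sample_id", "group")
  miss <- setdiff(req, names(tab))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(tab$sample_id))
    stop("duplicate sample id(s) in phenotype table")
  bad <- setdiff(unique(tab$group), c("H", "L"))
  if (length(bad))
    stop("unknown group label(s): ", paste(bad, collapse = ", "))
  for (col in intersect(c("imf_percent", "gebv", "age_days", "mapped_reads"),
                        names(tab))) {
    num <- suppressWarnings(as.numeric(tab[[col]]))
    if (anyNA(num)) {
      stop(sprintf("non-numeric value in column '%s' at row %d", col,
                   which(is.na(num))[1L]))
    }
    tab[[col]] <- num
  }
  rownames(tab) <- NULL
  tab
}

#' Write a phenotype table as canonical TSV
#'
#' @param pheno A phenotype data.frame (see \code{\link{readPhenotypes}}).
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
writePhenotypes <- function(pheno, path) {
  write.table(pheno, path, sep = "\t", quote = FALSE, row.names = FALSE,
              eol = "\n")
  invisible(path)
}

#' Per-group summary of a numeric phenotype column
#'
#' Arithmetic mean, standard deviation and sample count per group, reported
#' at full precision alongside the value rounded (half-even) to a chosen
#' number of digits.
#'
#' @param pheno Phenotype data.frame with a \code{group} column.
#' @param column Name of the numeric column to summarize.
#' @param digits Digits for the rounded report (default 3).
#' @return data.frame(group, n, mean, sd, mean_rounded, sd_flag); for
#'   single-sample groups sd is reported as 0 with \code{sd_flag = TRUE}.
#' @export
summarizePhenotypes <- function(pheno, column, digits = 3L) {
  if (!column %in% names(pheno)) stop("no column '", column, "'")
  x <- pheno[[column]]
  if (!is.numeric(x)) stop("column '", column, "' is not numeric")
  groups <- sort(unique(pheno$group))
  out <- lapply(groups, function(g) {
    v <- x[pheno$group == g]
    if (length(v) == 0L) stop("group '", g, "' has no samples")
    s <- if (length(v) > 1L) stats::sd(v) else 0
    data.frame(group = g, n = length(v), mean = mean(v), sd = s,
               mean_rounded = round(mean(v), digits),
               sd_flag = length(v) == 1L, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Welch two-sample comparison of a phenotype column between groups
#'
#' Two-sided Welch t-test (unequal variances) of the column between the two
#' phenotype groups. If both groups are constant with equal means, t = 0 and
#' p = 1 by convention.
#'
#' @param pheno Phenotype data.frame with a \code{group} column (two levels,
#'   each n >= 2).
#' @param column Name of the numeric column to compare.
#' @return list(statistic, p.value, df, means) with \code{statistic}
#'   oriented as first group level minus second.
#' @export
compareGroups <- function(pheno, column) {
  if (!column %in% names(pheno)) stop("no column '", column, "'")
  groups <- sort(unique(pheno$group))
  if (length(groups) != 2L) stop("exactly two groups are required")
  xs <- split(pheno[[column]], factor(pheno$group, levels = groups))
  if (any(lengths(xs) < 2L)) stop("each group needs n >= 2")
  v1 <- stats::var(xs[[1L]]); v2 <- stats::var(xs[[2L]])
  means <- vapply(xs, mean, numeric(1))
  if (v1 == 0 && v2 == 0) {
    if (means[1L] == means[2L])
      return(list(statistic = 0, p.value = 1, df = NA_real_, means = means))
    return(list(statistic = sign(means[1L] - means[2L]) * Inf, p.value = 0,
                df = NA_real_, means = means))
  }
  tt <- stats::t.test(xs[[1L]], xs[[2L]], var.equal = FALSE)
  list(statistic = unname(tt$statistic), p.value = tt$p.value,
       df = unname(tt$parameter), means = means)
}

#' Read a gene-set annotation (GMT or two-column TSV)
#'
#' GMT lines are \code{term<TAB>description<TAB>member...}; the two-column
#' dialect is \code{term<TAB>member} pairs (aggregated per term, description
#' empty). Lines with an empty term are skipped with a warning.
#'
#' @param path Path to the annotation file.
#' @param format \code{"gmt"} or \code{"tsv"}.
#' @return A named list of unique member character vectors, with a
#'   \code{"descriptions"} attribute (named character).
#' @export
readAnnotation <- function(path, format = c("gmt", "tsv")) {
  format <- match.arg(format)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list(); descs <- character()
  if (format == "gmt") {
    for (ln in lines) {
      parts <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
      if (length(parts) < 1L || !nzchar(parts[1L])) {
        warning("skipping annotation line with empty term")
        next
      }
      term <- parts[1L]
      members <- unique(parts[-(1:2)])
      members <- members[nzchar(members)]
      sets[[term]] <- unique(c(sets[[term]], members))
      descs[term] <- if (length(parts) >= 2L) parts[2L] else ""
    }
  } else {
    for (ln in lines) {
      parts <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
      if (length(parts) < 2L || !nzchar(parts[1L])) {
        warning("skipping annotation line with empty term")
        next
      }
      sets[[parts[1L]]] <- unique(c(sets[[parts[1L]]], parts[2L]))
      descs[parts[1L]] <- ""
    }
  }
  empty <- !lengths(sets)
  if (any(empty)) {
    warning("dropping empty term(s): ",
            paste(names(sets)[empty], collapse = ", "))
    sets <- sets[!empty]; descs <- descs[names(sets)]
  }
  attr(sets, "descriptions") <- descs
  sets
}

#' Write a gene-set annotation as GMT
#'
#' @param annotation Named list of member vectors as returned by
#'   \code{\link{readAnnotation}}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
writeAnnotation <- function(annotation, path) {
  descs <- attr(annotation, "descriptions")
  lines <- vapply(names(annotation), function(term) {
    d <- if (!is.null(descs) && term %in% names(descs)) descs[[term]] else ""
    paste(c(term, d, annotation[[term]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a nucleotide FASTA file
#'
#' Reads a FASTA file of nucleotide sequences (alphabet A, C, G, T, U, N;
#' case-insensitive). Record ids are the header up to the first whitespace;
#' sequences are uppercased and multi-line records concatenated.
#'
#' @param path Path to the FASTA file.
#' @return Named character vector of uppercase sequences.
#' @export
readSequenceSet <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids))
    stop("duplicate FASTA id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- toupper(as.character(ss))
  names(seqs) <- ids
  bad <- grepl("[^ACGTUN]", seqs)
  if (any(bad))
    stop("illegal characters in record(s): ",
         paste(ids[bad], collapse = ", "))
  if (any(!nzchar(seqs)))
    stop("empty sequence in record(s): ",
         paste(ids[!nzchar(seqs)], collapse = ", "))
  seqs
}

#' Write sequences as FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output file path.
#' @param width Line width for wrapping (default 60).
#' @return \code{path}, invisibly.
#' @export
writeSequenceSet <- function(seqs, path, width = 60L) {
  ss <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}
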