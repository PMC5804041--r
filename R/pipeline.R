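#' @importFrom stats phyper
NULL

# FNV-1a string hash, used only to stamp outputs with a config fingerprint
.hashString <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    low <- bitwXor(h %% 256, b %% 256)  # xor touches the low byte only
    h <- h - (h %% 256) + low
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

.provenance <- function(seed, confHash) {
  sprintf("# mirCoNet %s; seed=%d; config=%s",
          as.character(packageVersion("mirCoNet")), seed, confHash)
}

.writeStageTsv <- function(tab, path, header) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.readStageTsv <- function(path) {
  read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
             check.names = FALSE, stringsAsFactors = FALSE)
}

# deterministic synthetic sequences for the targeting stage: random 22-nt
# miRNAs, 300-nt gene UTRs, and for each miRNA an implanted 8mer site in a
# fixed-size random subset of gene UTRs (synthetic plumbing, not biology)
.syntheticSequences <- function(geneIds, mirIds, targetsPerMirna = 25L) {
  bases <- c("A", "C", "G", "T")
  randSeq <- function(n) paste(sample(bases, n, replace = TRUE),
                               collapse = "")
  mirnas <- vapply(mirIds, function(i) randSeq(22L), character(1))
  utrs <- vapply(geneIds, function(i) randSeq(300L), character(1))
  rc <- function(s) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(s)))
  for (mi in mirIds) {
    site <- paste0(rc(substr(mirnas[[mi]], 2L, 8L)), "A")
    tg <- sample(geneIds, min(targetsPerMirna, length(geneIds)))
    for (g in tg) {
      pos <- sample(seq_len(300L - 8L), 1L)
      substr(utrs[[g]], pos, pos + 7L) <- site
    }
  }
  list(mirnas = mirnas, utrs = utrs)
}

# annotation synthesized from the planted truth: one term per planted mRNA
# module plus random filler terms over the gene universe
.syntheticAnnotation <- function(truth, geneIds, nRandom = 20L,
                                 randomSize = 30L) {
  mods <- trueModules(truth)
  genes <- intersect(names(mods), geneIds)
  sets <- list()
  for (mod in setdiff(unique(mods[genes]), "background")) {
    sets[[paste0("SET_", mod)]] <- genes[mods[genes] == mod]
  }
  for (i in seq_len(nRandom)) {
    sets[[sprintf("SET_rand%02d", i)]] <-
      sample(geneIds, min(randomSize, length(geneIds)))
  }
  attr(sets, "descriptions") <-
    setNames(rep("synthetic gene set", length(sets)), names(sets))
  sets
}

#' Run the integrative co-expression pipeline end-to-end
#'
#' Executes simulate, summarize, DE, PCIT/DH, PIF/RIF, module detection,
#' integration, targeting and enrichment on a synthetic dataset, writing
#' deterministic TSV outputs (every file carries a provenance header with
#' package version, seed and config hash) plus a report. Identical config
#' and seed give byte-identical outputs. Stage failures raise an error
#' naming the stage; earlier outputs are preserved.
#'
#' @param outDir Output directory (created; must be writable).
#' @param config A \linkS4class{SimConfig} (its seed drives all
#'   randomness).
#' @param stages Character vector of stages to run, a subset of
#'   \code{c("simulate", "summarize", "de", "pcit", "rif", "modules",
#'   "integrate", "targets", "enrich", "report")}. Omitted stages are
#'   logged and their dependents skipped.
#' @param deFdr DE flag FDR (default 0.10).
#' @param edgeThreshold |r| filter for DH connections (default 0.9).
#' @param pcitTop Variance cap on the PCIT feature list (default 500);
#'   \code{Inf} disables the cap.
#' @param minSizeMrna,minSizeMirna Minimum module sizes (defaults 30, 5).
#' @param mergeHeight Module eigengene merge height (default 0.25).
#' @param pairRCut,pairPCut Module-pair retention thresholds (defaults
#'   -0.4, 0.05).
#' @param traitPCut Module-trait retention threshold (default 0.1).
#' @param trait Trait column for module-trait correlation (default
#'   "imf_percent").
#' @return Invisibly, the output directory.
#' @export
runPipeline <- function(outDir, config = simConfig(),
                        stages = c("simulate", "summarize", "de", "pcit",
                                   "rif", "modules", "integrate",
                                   "targets", "enrich", "report"),
                        deFdr = 0.10, edgeThreshold = 0.9, pcitTop = 500L,
                        minSizeMrna = 30L, minSizeMirna = 5L,
                        mergeHeight = 0.25, pairRCut = -0.4,
                        pairPCut = 0.05, traitPCut = 0.1,
                        trait = "imf_percent") {
  stopifnot(is(config, "SimConfig"))
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  confHash <- .hashString(c(
    deparse(config@modules), deparse(config@deSpec),
    deparse(config@regulatorSpec), deparse(config@hubSpec),
    deparse(config@traitSpec),
    sprintf("%d %d %d %g %g %d", config@nPerGroup, config@nGenes,
            config@nMirnas, config@dispersion, config@libsizeLognormalSd,
            config@seed),
    sprintf("%g %g %g %d %d %g %g %g %g %s", deFdr, edgeThreshold,
            as.numeric(pcitTop), minSizeMrna, minSizeMirna, mergeHeight,
            pairRCut, pairPCut, traitPCut, trait)))
  hdr <- .provenance(config@seed, confHash)
  log_ <- function(fmt, ...) message(sprintf(paste0("[mirCoNet] ", fmt),
                                             ...))
  log_("run start; seed=%d; deFdr=%g; edgeThreshold=%g; pcitTop=%s",
       config@seed, deFdr, edgeThreshold, format(pcitTop))
  log_("thresholds: minSize=%d/%d mergeHeight=%g pair(r<=%g,p<%g) trait(p<%g)",
       minSizeMrna, minSizeMirna, mergeHeight, pairRCut, pairPCut,
       traitPCut)
  stage <- function(name, expr) {
    if (!name %in% stages) {
      log_("stage %s: skipped (toggled off)", name)
      return(NULL)
    }
    log_("stage %s: start", name)
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  ds <- stage("simulate", {
    d <- generateDataset(config)
    writeCounts(d$mrna, file.path(outDir, "counts_mrna.tsv"))
    writeCounts(d$mirna, file.path(outDir, "counts_mirna.tsv"))
    .writeStageTsv(d$phenotypes, file.path(outDir, "phenotypes.tsv"), hdr)
    truthTables(d$truth, file.path(outDir, "truth"))
    d
  })
  if (is.null(ds)) stop("the simulate stage is required for this run")
  pheno <- ds$phenotypes

  stage("summarize", {
    tabs <- lapply(c("imf_percent", "gebv", "mapped_reads"), function(col)
      cbind(column = col, summarizePhenotypes(pheno, col)))
    .writeStageTsv(do.call(rbind, tabs),
                   file.path(outDir, "phenotype_summary.tsv"), hdr)
  })

  exprMrna <- normalizeCounts(ds$mrna)
  exprMirna <- normalizeCounts(ds$mirna)

  de <- stage("de", {
    d <- deTest(ds$mirna, pheno,
                covariates = c("age_days", "contemporary_group"),
                fdr = deFdr)
    .writeStageTsv(d[order(d$qvalue, d$feature), ],
                   file.path(outDir, "de_mirna.tsv"), hdr)
    d
  })

  grpH <- pheno$sample_id[pheno$group == "H"]
  grpL <- pheno$sample_id[pheno$group == "L"]

  pcitRes <- stage("pcit", {
    keep <- topVarianceFeatures(list(exprMrna, exprMirna),
                                top = if (is.finite(pcitTop)) pcitTop
                                      else (nrow(exprMrna) +
                                            nrow(exprMirna)))
    stacked <- rbind(exprValues(exprMrna), exprValues(exprMirna))
    stacked <- stacked[keep, , drop = FALSE]
    netH <- pcit(correlationNetwork(stacked, samples = grpH, group = "H"))
    netL <- pcit(correlationNetwork(stacked, samples = grpL, group = "L"))
    dh <- dhScores(netH, netL, edgeThreshold = edgeThreshold)
    .writeStageTsv(dh, file.path(outDir, "dh_table.tsv"), hdr)
    top <- topDh(dh, 10L)
    .writeStageTsv(rbind(cbind(direction = "positive", top$positive),
                         cbind(direction = "negative", top$negative)),
                   file.path(outDir, "dh_top.tsv"), hdr)
    writeEdgeList(netH, file.path(outDir, "edges_H.tsv"), minAbsR = 0.8)
    writeEdgeList(netL, file.path(outDir, "edges_L.tsv"), minAbsR = 0.8)
    list(netH = netH, netL = netL, dh = dh, top = top, keep = keep)
  })

  stage("rif", {
    deFeatures <- if (is.null(de)) character() else de$feature[de$de]
    if (is.null(de)) {
      log_("stage rif: skipped (needs the de stage)")
      NULL
    } else if (!length(deFeatures)) {
      log_("stage rif: no DE features at FDR %g; table not written", deFdr)
      NULL
    } else {
      gm <- groupMeans(list(exprMrna, exprMirna), pheno)
      rs <- regulatorScores(
        lapply(list(exprMrna, exprMirna), function(e)
          exprValues(e)[, grpH, drop = FALSE]),
        lapply(list(exprMrna, exprMirna), function(e)
          exprValues(e)[, grpL, drop = FALSE]),
        gm, deFeatures)
      pifTab <- data.frame(feature = names(rs$pif), pif = unname(rs$pif))
      .writeStageTsv(pifTab[order(-abs(pifTab$pif)), ],
                     file.path(outDir, "pif_table.tsv"), hdr)
      .writeStageTsv(rs$scores[order(-abs(rs$scores$rif1_z)), ],
                     file.path(outDir, "rif_table.tsv"), hdr)
      rs
    }
  })

  mods <- stage("modules", {
    out <- list()
    for (g in c("H", "L")) {
      ss <- if (g == "H") grpH else grpL
      for (ly in c("mrna", "mirna")) {
        ex <- if (ly == "mrna") exprMrna else exprMirna
        ms <- coexpressionModules(
          exprValues(ex)[, ss, drop = FALSE],
          minSize = if (ly == "mrna") minSizeMrna else minSizeMirna,
          mergeHeight = mergeHeight)
        writeModuleTable(ms, file.path(outDir,
                                       sprintf("modules_%s_%s.tsv", ly, g)))
        writeEigengeneTable(ms, file.path(outDir,
                                          sprintf("eigengenes_%s_%s.tsv",
                                                  ly, g)))
        out[[paste(ly, g, sep = "_")]] <- ms
      }
    }
    out
  })

  integ <- stage("integrate", {
    if (is.null(mods)) {
      log_("stage integrate: skipped (needs the modules stage)")
      NULL
    } else {
    pairRows <- list(); traitRows <- list()
    for (g in c("H", "L")) {
      pr <- moduleModuleCorrelation(mods[[paste0("mirna_", g)]],
                                    mods[[paste0("mrna_", g)]],
                                    rCut = pairRCut, pCut = pairPCut)
      pairRows[[g]] <- cbind(group = g, pr)
      for (ly in c("mrna", "mirna")) {
        tr <- moduleTraitCorrelation(mods[[paste(ly, g, sep = "_")]],
                                     pheno, trait = trait, pCut = traitPCut)
        traitRows[[paste(ly, g)]] <- cbind(group = g, layer = ly, tr)
      }
    }
    pairs <- do.call(rbind, pairRows)
    traits <- do.call(rbind, traitRows)
    .writeStageTsv(pairs, file.path(outDir, "module_pairs.tsv"), hdr)
    .writeStageTsv(traits, file.path(outDir, "module_trait.tsv"), hdr)
    list(pairs = pairs, traits = traits)
    }
  })

  tg <- stage("targets", {
    set.seed(config@seed + 1L)
    seqs <- .syntheticSequences(featureIds(ds$mrna), featureIds(ds$mirna))
    writeSequenceSet(seqs$mirnas,
                     file.path(outDir, "synthetic_mirnas.fasta"))
    writeSequenceSet(seqs$utrs, file.path(outDir, "synthetic_utrs.fasta"))
    pt <- predictTargets(seqs$mirnas, seqs$utrs)
    .writeStageTsv(pt$sites, file.path(outDir, "target_sites.tsv"), hdr)
    pairsTab <- do.call(rbind, lapply(names(pt$targets), function(mi)
      if (length(pt$targets[[mi]]))
        data.frame(mirna = mi, gene = pt$targets[[mi]]) else NULL))
    .writeStageTsv(pairsTab, file.path(outDir, "target_map.tsv"), hdr)
    pt
  })

  stage("enrich", {
    set.seed(config@seed + 2L)
    universe <- featureIds(ds$mrna)
    anno <- .syntheticAnnotation(ds$truth, universe)
    writeAnnotation(anno, file.path(outDir, "synthetic_annotation.gmt"))
    enrRows <- list()
    if (!is.null(pcitRes)) {
      negHubs <- pcitRes$top$negative$feature
      nb <- hubNeighbors(pcitRes$netL, negHubs,
                         corrThreshold = edgeThreshold)
      sel <- intersect(unique(unlist(nb$neighbors)), universe)
      if (length(sel))
        enrRows[["dh_negative"]] <-
          cbind(selection = "dh_negative_neighbors",
                enrichSets(sel, universe, anno, fdr = deFdr))
    }
    if (!is.null(mods) && !is.null(tg)) {
      for (g in c("H", "L")) {
        ms <- mods[[paste0("mirna_", g)]]
        if (!length(varianceExplained(ms))) next
        hubs <- moduleHubs(membership(ms), moduleLabels(ms))
        for (mod in names(hubs)) {
          res <- tryCatch(
            enrichMirnaModule(hubs[[mod]], tg$targets, universe, anno,
                              fdr = deFdr),
            warning = function(w) NULL)
          if (!is.null(res) && nrow(res))
            enrRows[[paste("mirna", g, mod)]] <-
              cbind(selection = sprintf("mirna_module_%s_%s", g, mod),
                    res)
        }
      }
    } else {
      log_("stage enrich: miRNA-module enrichment skipped (needs %s)",
           if (is.null(tg)) "the targets stage" else "the modules stage")
    }
    enr <- do.call(rbind, enrRows)
    if (!is.null(enr))
      .writeStageTsv(enr, file.path(outDir, "enrichment.tsv"), hdr)
    # bipartite hub-term networks from retained pairs
    if (!is.null(integ) && !is.null(mods) && !is.null(tg)) {
      for (g in c("H", "L")) {
        pr <- integ$pairs[integ$pairs$group == g & integ$pairs$retained, ]
        ms <- mods[[paste0("mirna_", g)]]
        if (!length(varianceExplained(ms))) next
        hubs <- as.list(moduleHubs(membership(ms), moduleLabels(ms)))
        terms <- lapply(
          setNames(unique(pr$mrnaModule), unique(pr$mrnaModule)),
          function(mod) {
            labs <- moduleLabels(mods[[paste0("mrna_", g)]])
            sel <- intersect(names(labs)[labs == mod], universe)
            if (!length(sel)) return(character())
            e <- enrichSets(sel, universe, anno, fdr = deFdr)
            e$term[e$enriched]
          })
        graph <- bipartiteNetwork(pr, hubs, terms)
        writeGraphml(graph, file.path(outDir,
                                      sprintf("bipartite_%s.graphml", g)))
      }
    }
    invisible(NULL)
  })

  stage("report", pipelineReport(outDir))
  log_("run complete: %s", outDir)
  invisible(outDir)
}

#' Assemble a run report
#'
#' Builds \code{report.md} in the output directory from the stage tables:
#' phenotype summaries, DE miRNAs, top differential hubbing, top PIF/RIF
#' scores, modules correlated with the trait, and retained cross-layer
#' module pairs. Sections whose stage output is missing are marked
#' "not run".
#'
#' @param outDir A pipeline output directory.
#' @return The report path, invisibly.
#' @export
pipelineReport <- function(outDir) {
  lines <- c("# mirCoNet pipeline report", "")
  section <- function(title, file, render) {
    path <- file.path(outDir, file)
    lines <<- c(lines, paste("##", title), "")
    if (!file.exists(path)) {
      lines <<- c(lines, "not run", "")
      return(invisible(NULL))
    }
    tab <- .readStageTsv(path)
    lines <<- c(lines, render(tab), "")
  }
  fmtTable <- function(tab, n = 10L) {
    tab <- utils::head(tab, n)
    num <- vapply(tab, is.numeric, logical(1))
    tab[num] <- lapply(tab[num], function(x) signif(x, 4))
    c(paste(names(tab), collapse = " | "),
      paste(rep("---", ncol(tab)), collapse = " | "),
      apply(tab, 1L, paste, collapse = " | "))
  }
  section("Phenotype summaries", "phenotype_summary.tsv", fmtTable)
  section("Differentially expressed miRNAs", "de_mirna.tsv", function(tab)
    fmtTable(tab[tab$de == "TRUE" | tab$de == TRUE, , drop = FALSE], 20L))
  section("Top differential hubbing", "dh_top.tsv",
          function(tab) fmtTable(tab, 20L))
  section("Top regulators (PIF / RIF)", "rif_table.tsv", fmtTable)
  section("Modules correlated with the trait", "module_trait.tsv",
    function(tab)
      fmtTable(tab[tab$retained == "TRUE" | tab$retained == TRUE, ,
                   drop = FALSE], 20L))
  section("Retained miRNA-mRNA module pairs", "module_pairs.tsv",
    function(tab) {
      kept <- tab[tab$retained == "TRUE" | tab$retained == TRUE, ,
                  drop = FALSE]
      if (!nrow(kept)) "0 retained pairs" else fmtTable(kept, 20L)
    })
  section("Enrichment", "enrichment.tsv", function(tab) fmtTable(tab, 15L))
  path <- file.path(outDir, "report.md")
  writeLines(lines, path)
  invisible(path)
}
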