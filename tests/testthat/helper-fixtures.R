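# shared fixtures, built in code

phenotypesPath <- function() {
  system.file("extdata", "imf_gebv_phenotypes.tsv", package = "mirCoNet")
}

emptyModuleSpec <- function() {
  data.frame(name = character(), layer = character(), size = integer(),
             loading = numeric(), factor = character(),
             stringsAsFactors = FALSE)
}

# a fully null configuration: no modules, no DE, no regulator/hub, noise trait
nullConfig <- function(seed, nGenes = 300L, nMirnas = 2L, nPerGroup = 15L) {
  simConfig(nPerGroup = nPerGroup, nGenes = nGenes, nMirnas = nMirnas,
            modules = emptyModuleSpec(),
            deSpec = data.frame(feature = character(), log2fc = numeric()),
            regulatorSpec = list(), hubSpec = list(), traitSpec = list(),
            seed = seed)
}

# a down-scaled analogue of the default design for fast end-to-end tests
# (fewer features; the 15 + 15 sample design is kept - DE power on
# module-correlated miRNAs depends on it)
smallConfig <- function(seed, nPerGroup = 15L) {
  mods <- data.frame(
    name = c("A", "B", "X", "T", "a", "x", "d"),
    layer = c("mRNA", "mRNA", "mRNA", "mRNA", "miRNA", "miRNA", "miRNA"),
    size = c(40L, 35L, 30L, 15L, 8L, 6L, 6L),
    loading = c(0.7, 0.7, 0.75, 2.5, 0.7, -0.9, 0.9),
    factor = c("A", "B", "X", "T", "a", "X", "d"),
    stringsAsFactors = FALSE)
  simConfig(
    nPerGroup = nPerGroup, nGenes = 300L, nMirnas = 50L, modules = mods,
    deSpec = data.frame(feature = sprintf("mir_%04d", 15:20),
                        log2fc = c(1.6, 1.4, 1.5, 1.7, 1.3, 1.6)),
    regulatorSpec = list(feature = "mir_0021", targetModule = "d",
                         loadingH = 2, loadingL = -2),
    hubSpec = list(feature = "gene_0121", targetModule = "T",
                   loadingH = 0, loadingL = 2.5),
    traitSpec = list(driverModule = "A", slope = 0.9, noiseSd = 0.45,
                     baseline = 3),
    seed = seed)
}

# random correlation matrix from a random data matrix (always a valid
# correlation matrix, arbitrary structure)
randomCorrelation <- function(n, samples = 30L) {
  m <- matrix(rnorm(n * samples), n, samples)
  r <- cor(t(m))
  dimnames(r) <- list(sprintf("f%02d", seq_len(n)),
                      sprintf("f%02d", seq_len(n)))
  r
}

writeTempTsv <- function(lines) {
  tf <- tempfile(fileext = ".tsv")
  writeLines(lines, tf)
  tf
}
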