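# signed co-expression modules: soft threshold, TOM, detection, eigengenes

test_that("signed adjacency lies in [0,1] and decreases with the power", {
  set.seed(61)
  r <- randomCorrelation(10)
  a2 <- signedAdjacency(r, 2); a6 <- signedAdjacency(r, 6)
  expect_true(all(a2 >= 0 & a2 <= 1))
  off <- upper.tri(r) & (1 + r) / 2 < 1
  expect_true(all(a6[off] <= a2[off]))
})

test_that("soft-threshold selection flags degenerate similarity and fits the target", {
  ones <- matrix(1, 5, 5, dimnames = list(letters[1:5], letters[1:5]))
  expect_warning(st <- pickSoftThreshold(ones), "degenerate")
  expect_identical(st$rule, "degenerate")

  # generated modular data: the auto rule reaches the scale-free target
  # and the reported fit matches an independent re-implementation of the
  # binned fit
  ds <- generateDataset(simConfig(seed = 67L))
  m <- exprValues(normalizeCounts(ds$mrna))
  st <- pickSoftThreshold(m)
  expect_identical(st$rule, "auto")
  sel <- st$table[st$table$beta == st$beta, ]
  expect_gt(sel$r2, 0.90)

  refFit <- function(k) {
    br <- unique(quantile(k, probs = seq(0, 1, length.out = 11)))
    bin <- cut(k, breaks = br, include.lowest = TRUE)
    pk <- (tabulate(bin, nlevels(bin)) / length(k)) / diff(br)
    kb <- tapply(k, bin, mean)
    use <- pk > 0
    fit <- lm(log10(pk[use]) ~ log10(kb[use]))
    r2 <- summary(fit)$r.squared
    if (coef(fit)[2] > 0) -r2 else r2
  }
  s <- (1 + cor(t(m))) / 2; diag(s) <- 0
  k <- rowSums(s^st$beta)
  expect_equal(sel$r2, refFit(k), tolerance = 1e-12)
})

test_that("TOM matches its closed form, bounds and the scalar oracle", {
  zero <- matrix(0, 4, 4)
  expect_equal(tomSimilarity(zero), diag(1, 4))

  ones <- matrix(1, 5, 5)
  t1 <- tomSimilarity(ones)
  expect_equal(t1, matrix(1, 5, 5))

  set.seed(71)
  for (rep in 1:3) {
    a <- matrix(runif(25), 5, 5); a <- (a + t(a)) / 2; diag(a) <- 1
    expect_equal(tomSimilarity(a), tomReference(a), tolerance = 1e-12)
  }
  a <- matrix(runif(900), 30, 30); a <- (a + t(a)) / 2; diag(a) <- 1
  tom <- tomSimilarity(a)
  expect_equal(tom, tomReference(a), tolerance = 1e-12)
  expect_true(all(tom >= 0 & tom <= 1 + 1e-12))
  perm <- sample.int(30)
  expect_equal(tomSimilarity(a[perm, perm]), tom[perm, perm],
               tolerance = 1e-12)
})

test_that("eigengenes follow the SVD definition, sign rule and scaling invariance", {
  set.seed(73)
  f <- rnorm(20)
  m <- rbind(a = f, b = f, c = f) + 0  # identical profiles
  colnames(m) <- sprintf("s%02d", 1:20)
  labels <- c(a = "mod", b = "mod", c = "mod")
  eg <- moduleEigengenes(m, labels)
  expect_equal(abs(cor(eg$eigengenes["mod", ], f)), 1, tolerance = 1e-12)
  expect_gt(cor(eg$eigengenes["mod", ], m["a", ]), 0)  # sign rule
  expect_equal(unname(eg$varExplained["mod"]), 1, tolerance = 1e-12)

  # flipping all members flips the ME, sign rule keeps mean MM positive
  egFlip <- moduleEigengenes(-m, labels)
  expect_gt(cor(egFlip$eigengenes["mod", ], -m["a", ]), 0)

  # scaling a member leaves the ME invariant (features are standardized)
  m2 <- rbind(a = f + rnorm(20, 0, .2), b = f + rnorm(20, 0, .2),
              c = f + rnorm(20, 0, .2))
  colnames(m2) <- colnames(m)
  eg2 <- moduleEigengenes(m2, labels)
  m3 <- m2; m3["a", ] <- 100 * m3["a", ]
  eg3 <- moduleEigengenes(m3, labels)
  expect_equal(eg2$eigengenes, eg3$eigengenes, tolerance = 1e-10)

  # variance explained equals the top singular share of the full SVD
  xs <- t(scale(t(m2)))
  d <- svd(xs)$d
  expect_equal(unname(eg2$varExplained["mod"]), d[1]^2 / sum(d^2),
               tolerance = 1e-10)

  mz <- rbind(m2, z = rep(1, 20))
  expect_warning(moduleEigengenes(mz, c(labels, z = "mod")),
                 "zero-variance")
})

test_that("module membership and hub calls follow their definitions", {
  set.seed(79)
  f <- rnorm(30)
  m <- rbind(a = 0.95 * f + rnorm(30, 0, sqrt(1 - 0.95^2)),
             b = 0.7 * f + rnorm(30, 0, sqrt(1 - 0.49)),
             c = 0.7 * f + rnorm(30, 0, sqrt(1 - 0.49)),
             d = f, e = f)
  colnames(m) <- sprintf("s%02d", 1:30)
  labels <- c(a = "mod", b = "mod", c = "mod", d = "mod", e = "mod")
  eg <- moduleEigengenes(m, labels)
  mm <- moduleMembership(m, eg)
  expect_true(all(mm >= -1 & mm <= 1))
  # identical profiles d and e: both MM near 1; hub tie broken to 'd'
  mEq <- m; mEq["a", ] <- f; mEq["b", ] <- f; mEq["c", ] <- f
  egEq <- moduleEigengenes(mEq, labels)
  mmEq <- moduleMembership(mEq, egEq)
  expect_equal(unname(mmEq[, "mod"]), rep(1, 5), tolerance = 1e-12)
  expect_identical(unname(moduleHubs(mmEq, labels)), "a")

  orth <- rbind(m, o = rnorm(30))
  mmO <- moduleMembership(orth, eg)
  expect_lt(abs(mmO["o", "mod"]), 0.5)
})

test_that("module detection separates blocks, greys singletons and honours sizes", {
  set.seed(83)
  n <- 24
  f1 <- rnorm(n); f2 <- rnorm(n)
  block <- function(f, size, nm)
    matrix(0.9, size, 1) %*% rbind(f) +
      matrix(rnorm(size * n, 0, 0.4), size, n,
             dimnames = list(sprintf("%s%02d", nm, seq_len(size)), NULL))
  m <- rbind(block(f1, 10, "a"), block(f2, 10, "b"),
             matrix(rnorm(3 * n), 3, n,
                    dimnames = list(c("s1", "s2", "s3"), NULL)))
  colnames(m) <- sprintf("smp%02d", seq_len(n))
  tom <- tomSimilarity(signedAdjacency(m, 6))
  ms <- detectModules(1 - tom, m, minSize = 5)
  labs <- moduleLabels(ms)
  expect_identical(length(unique(labs[paste0("a", sprintf("%02d", 1:10))])),
                   1L)
  expect_identical(length(unique(labs[paste0("b", sprintf("%02d", 1:10))])),
                   1L)
  expect_identical(unname(labs[c("s1", "s2", "s3")]), rep("grey", 3))
  expect_identical(sort(unique(labs)), c("blue", "grey", "turquoise"))

  # two modules driven by one factor merge at height 0.25
  m2 <- rbind(block(f1, 8, "p"), block(f1, 8, "q"))
  colnames(m2) <- colnames(m)
  tom2 <- tomSimilarity(signedAdjacency(m2, 6))
  ms2 <- detectModules(1 - tom2, m2, minSize = 5, mergeHeight = 0.25)
  expect_identical(length(setdiff(unique(moduleLabels(ms2)), "grey")), 1L)

  expect_warning(ms3 <- detectModules(1 - tom[1:3, 1:3], m[1:3, ],
                                      minSize = 5),
                 "all grey")
  expect_true(all(moduleLabels(ms3) == "grey"))
})

test_that("planted modules are recovered with high ARI on generated data", {
  skip_if_not_installed("mclust")
  aris <- sapply(1:3, function(s) {
    ds <- generateDataset(smallConfig(seed = 90L + s))
    ex <- normalizeCounts(ds$mrna)
    ms <- coexpressionModules(ex, minSize = 15L)
    tm <- trueModules(ds$truth)[featureIds(ds$mrna)]
    planted <- names(tm)[tm != "background"]
    mclust::adjustedRandIndex(tm[planted], moduleLabels(ms)[planted])
  })
  expect_gte(mean(aris), 0.8)
})
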