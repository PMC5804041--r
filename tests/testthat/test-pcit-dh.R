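# correlation networks, the PCIT filter and differential hubbing

test_that("correlation networks carry exact correlations and drop constants", {
  m <- rbind(f1 = c(1, 0, -1), f2 = c(0, 1, 0), f3 = c(2, 1, 0),
             f4 = c(5, 5, 5))
  colnames(m) <- c("s1", "s2", "s3")
  expect_warning(net <- correlationNetwork(m, group = "H"), "f4")
  r <- networkCorrelations(net)
  expect_equal(diag(r), c(f1 = 1, f2 = 1, f3 = 1))
  expect_equal(r["f1", "f2"], 0)           # orthogonal after centering
  expect_equal(r["f1", "f3"], 1)
  expect_error(correlationNetwork(m[, 1:2]), "3 samples")
})

test_that("correlation p-values agree with a permutation null", {
  set.seed(23)
  n <- 15
  x <- rnorm(n)
  y <- 0.5 * x + rnorm(n, 0, sqrt(1 - 0.25))
  m <- rbind(x = x, y = y)
  colnames(m) <- sprintf("s%02d", 1:n)
  net <- correlationNetwork(m)
  pObs <- networkPvalues(net)["x", "y"]
  r0 <- abs(cor(x, y))
  perm <- replicate(10000, abs(cor(x, sample(y))))
  pPerm <- (1 + sum(perm >= r0)) / 10001
  expect_lt(abs(pObs - pPerm), 4 * sqrt(pPerm * (1 - pPerm) / 10000) + 0.01)
})

test_that("pcit follows its conventions on tiny inputs", {
  r2 <- matrix(c(1, .5, .5, 1), 2,
               dimnames = list(c("a", "b"), c("a", "b")))
  mask <- pcit(r2)
  expect_identical(unname(mask), matrix(c(FALSE, TRUE, TRUE, FALSE), 2))
})

test_that("compiled PCIT equals the reference loop on random instances", {
  set.seed(31)
  for (i in 1:12) {
    n <- sample(4:30, 1)
    r <- randomCorrelation(n)
    expect_identical(pcit(r), pcitReference(r))
  }
})

test_that("pcit is equivariant under feature permutation", {
  set.seed(37)
  r <- randomCorrelation(12)
  mask <- pcit(r)
  perm <- sample.int(12)
  expect_identical(pcit(r[perm, perm]), mask[perm, perm])
})

test_that("pcit keeps the direct association and preferentially drops the spurious one", {
  set.seed(41)
  hits <- replicate(100, {
    n <- 200
    x <- rnorm(n)
    z <- x + rnorm(n, 0, 0.3)   # z is a noisy copy of x
    y <- rnorm(n)               # y independent of both
    r <- cor(cbind(x = x, y = y, z = z))
    mask <- pcit(r)
    c(xz = mask["x", "z"], xy = mask["x", "y"])
  })
  # the genuine x-z edge survives essentially always; the noise edge x-y
  # is the only one the trio tolerance ever removes
  expect_gte(mean(hits["xz", ]), 0.95)
  expect_gt(mean(!hits["xy", ]), mean(!hits["xz", ]))
  expect_gt(mean(!hits["xy", ]), 0)
})

test_that("differential hubbing counts retained strong edges per group", {
  set.seed(43)
  m <- matrix(rnorm(8 * 30), 8, 30,
              dimnames = list(sprintf("f%d", 1:8), sprintf("s%d", 1:30)))
  netH <- pcit(correlationNetwork(m[, 1:15], group = "H"))
  netL <- pcit(correlationNetwork(m[, 16:30], group = "L"))
  dh <- dhScores(netH, netL, edgeThreshold = 0.9)

  connOf <- function(net) {
    e <- pcitMask(net) & abs(networkCorrelations(net)) > 0.9
    diag(e) <- FALSE
    rowSums(e)
  }
  expect_identical(dh$connH, as.integer(unname(connOf(netH))))
  expect_identical(dh$dh, dh$connH - dh$connL)
  # each edge is counted at both endpoints
  expect_identical(sum(dh$dh),
                   as.integer(2 * (sum(connOf(netH)) / 2 -
                                   sum(connOf(netL)) / 2)))

  # identical networks give dh = 0
  dh0 <- dhScores(netH, netH)
  expect_true(all(dh0$dh == 0L))

  # raising the threshold never increases a connection count
  dhLoose <- dhScores(netH, netL, edgeThreshold = 0.3)
  expect_true(all(dhLoose$connH >= dh$connH))

  netBad <- pcit(correlationNetwork(m[1:5, 16:30], group = "L"))
  expect_error(dhScores(netH, netBad), "same feature list")
})

test_that("top-DH ranking is deterministic with lexicographic ties", {
  dh <- data.frame(feature = c("b", "a", "c"), connH = c(5L, 0L, 1L),
                   connL = c(0L, 2L, 1L), dh = c(5L, -2L, 0L))
  top <- topDh(dh, k = 1)
  expect_identical(top$positive$feature, "b")
  expect_identical(top$negative$feature, "a")

  ties <- data.frame(feature = c("c", "a", "b"), connH = 0L, connL = 0L,
                     dh = 0L)
  topT <- topDh(ties, k = 2)
  expect_identical(topT$positive$feature, c("a", "b"))
  expect_identical(topT$negative$feature, c("a", "b"))

  full <- topDh(dh, k = 3)
  expect_identical(full$positive$feature, rev(full$negative$feature))
})

test_that("hub neighbours equal direct filtering of the edge list", {
  set.seed(47)
  m <- matrix(rnorm(10 * 20), 10, 20,
              dimnames = list(sprintf("f%02d", 1:10), sprintf("s%d", 1:20)))
  net <- pcit(correlationNetwork(m))
  hn <- hubNeighbors(net, c("f01", "f02"), corrThreshold = 0.2)
  r <- networkCorrelations(net); mask <- pcitMask(net)
  for (h in c("f01", "f02")) {
    direct <- rownames(r)[mask[h, ] & abs(r[h, ]) > 0.2 &
                            rownames(r) != h]
    expect_setequal(hn$neighbors[[h]], direct)
  }
  # threshold 0 returns all retained partners
  hn0 <- hubNeighbors(net, "f01", corrThreshold = 0)
  expect_setequal(hn0$neighbors$f01,
                  rownames(r)[mask["f01", ]])
  # impossible threshold gives the empty set
  hn1 <- hubNeighbors(net, "f01", corrThreshold = 1)
  expect_length(hn1$neighbors$f01, 0)
  expect_error(hubNeighbors(net, "nope"), "unknown hub")
})
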