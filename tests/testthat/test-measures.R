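test_that("B and C match hand-computed values on a p = 2 pair", {
  # x_i = {e1:2, e3:1, e4:1}, x_j = {e1:1, e2:1, e3:1, e4:1}
  gi <- Genome("i", c("L0E1", "L1E3"), c("L0E1", "L1E4"))
  gj <- Genome("j", c("L0E1", "L1E3"), c("L0E2", "L1E4"))
  hm <- designMatrix(list(gi, gj))
  B <- as.matrix(intersectMeasure(hm))
  C <- as.matrix(productMeasure(hm))
  K <- sharedHeterozygosity(hm)
  expect_equal(B["i", "j"], (1 + 0 + 1 + 1) / 4)        # 0.75
  expect_equal(C["i", "j"], (2 * 1 + 1 * 1 + 1 * 1) / 4)  # 1.0
  expect_equal(K["i", "j"], 2 / 4)
  expect_equal(C["i", "j"], 2 * B["i", "j"] - K["i", "j"])
  expect_equal(diag(B), c(i = 1, j = 1))
})

test_that("identical genomes have b = 1 and disjoint genomes b = c = 0", {
  g1 <- randomGenome("a", p = 5L, nAlleles = 2L)
  g2 <- Genome("b", g1@hap1, g1@hap2)
  g3 <- Genome("c", segId(0:4, 8L), segId(0:4, 9L))
  hm <- designMatrix(list(g1, g2, g3))
  B <- as.matrix(intersectMeasure(hm))
  C <- as.matrix(productMeasure(hm))
  expect_equal(B["a", "b"], 1)
  expect_equal(B["a", "c"], 0)
  expect_equal(C["a", "c"], 0)
})

test_that("matrix route equals the brute-force multiset oracle", {
  set.seed(19)
  for (rep in 1:10) {
    genomes <- lapply(1:5, function(i)
      randomGenome(paste0("g", i), p = 6L))
    hm <- designMatrix(genomes)
    oracle <- bruteMeasures(genomes)
    expect_equal(as.matrix(intersectMeasure(hm)), oracle$B)
    expect_equal(as.matrix(productMeasure(hm)), oracle$C)
    expect_equal(sharedHeterozygosity(hm), oracle$K)
    expect_equal(homozygosity(hm), oracle$f)
  }
})

test_that("C = 2B - kappa and c_ii = 1 + f_i hold exactly", {
  set.seed(23)
  genomes <- lapply(1:12, function(i) randomGenome(paste0("g", i), p = 11L))
  hm <- designMatrix(genomes)
  B <- as.matrix(intersectMeasure(hm))
  C <- as.matrix(productMeasure(hm))
  K <- sharedHeterozygosity(hm)
  # the identity is exact on the integer counts (recovered by rounding,
  # since every entry is an integer multiple of 1/2p)
  d <- 2 * 11
  expect_identical(round(C * d), 2 * round(B * d) - round(K * d))
  expect_equal(C, 2 * B - K, tolerance = 1e-15)
  expect_equal(diag(C), 1 + homozygosity(hm), tolerance = 1e-15)
  # kappa_ii counts the heterozygous intervals
  expect_equal(diag(K), rowSums(hmMatrix(hm) == 1L) / (2 * 11))
  expect_true(all(B >= 0 & B <= 1))
  expect_true(all(C >= 0 & C <= 2))
})

test_that("c equals twice the IBS coancestry from allele-pair enumeration", {
  set.seed(31)
  for (rep in 1:50) {
    p <- 7L
    gi <- randomGenome("i", p = p)
    gj <- randomGenome("j", p = p)
    hm <- designMatrix(list(gi, gj))
    C <- as.matrix(productMeasure(hm))
    # brute force over the 4p ordered allele-pair identity indicators
    ind <- 0L
    for (k in seq_len(p))
      for (a in c(gi@hap1[k], gi@hap2[k]))
        for (b in c(gj@hap1[k], gj@hap2[k]))
          ind <- ind + (a == b)
    theta_ij <- ind / (4 * p)
    expect_equal(C["i", "j"], 2 * theta_ij)
    # diagonal: c_ii = 1 + theta_i with theta_i the IBS inbreeding
    theta_i <- mean(gi@hap1 == gi@hap2)
    expect_equal(C["i", "i"], 1 + theta_i)
  }
})

test_that("uniform weights reproduce the unweighted measures exactly", {
  set.seed(37)
  p <- 9L
  genomes <- lapply(1:6, function(i) randomGenome(paste0("g", i), p = p))
  hm <- designMatrix(genomes)
  w <- rep(1 / p, p)
  expect_equal(as.matrix(intersectMeasure(hm, w)),
               as.matrix(intersectMeasure(hm)))
  expect_equal(as.matrix(productMeasure(hm, w)),
               as.matrix(productMeasure(hm)))
  expect_error(intersectMeasure(hm, rep(1 / p, p - 1L)), "weights")
  expect_error(productMeasure(hm, rep(2 / p, p)), "sum to 1")

  # non-uniform weights: oracle by direct summation
  w <- (1:p) / sum(1:p)
  Bw <- as.matrix(intersectMeasure(hm, w))
  X <- hmMatrix(hm)
  ws <- w[hm@level + 1L]
  oracle <- sum(ws * pmin(X[1L, ], X[2L, ])) / 2
  expect_equal(Bw[1L, 2L], oracle)
  expect_equal(diag(Bw), stats::setNames(rep(1, 6), individualIds(hm)))
})

test_that("vanRaden G rows sum to zero and match a double-loop oracle", {
  M <- rbind(c(0, 1), c(2, 1), c(1, 0))
  rownames(M) <- c("u", "v", "w")
  G <- vanRadenG(M)
  expect_true(max(abs(rowSums(as.matrix(G)))) < 1e-12)
  mbar <- colMeans(M)
  num <- outer(1:3, 1:3, Vectorize(function(i, j)
    sum((M[i, ] - mbar) * (M[j, ] - mbar))))
  phat <- mbar / 2
  expect_equal(unname(as.matrix(G)), num / sum(2 * phat * (1 - phat)),
               tolerance = 1e-12)
  Gm <- vanRadenG(M, denominator = "genotype-mean")
  expect_equal(unname(as.matrix(Gm)), num / sum(2 * mbar * (1 - mbar)),
               tolerance = 1e-12)

  set.seed(5)
  M2 <- matrix(sample(0:2, 60L, TRUE), 6L, 10L)
  G2 <- as.matrix(vanRadenG(M2, dropMonomorphic = TRUE))
  expect_true(max(abs(rowSums(G2))) < 1e-10)

  expect_error(vanRadenG(matrix(1, 4L, 3L)), "monomorphic")
  expect_error(vanRadenG(matrix(1, 4L, 3L), dropMonomorphic = TRUE),
               "no polymorphic")
})

test_that("matrix comparison reproduces a regression oracle", {
  set.seed(41)
  ids <- letters[1:5]
  X1 <- randomSpd(5L, ids)
  X2 <- X1 + 0.1 * randomSpd(5L, ids)
  st <- compareMatrices(X1, X2)
  ut <- upper.tri(X1)
  x <- X1[ut]; y <- X2[ut]
  expect_equal(st$msd, mean((x - y)^2))
  fit0 <- stats::lm(y ~ 0 + x)
  fit1 <- stats::lm(y ~ x)
  expect_equal(st$adjR2NoIntercept, summary(fit0)$adj.r.squared)
  expect_equal(st$adjR2WithIntercept, summary(fit1)$adj.r.squared)
  expect_equal(st$slopeNoIntercept, unname(coef(fit0)[1L]))

  same <- compareMatrices(X1, X1)
  expect_equal(same$msd, 0)
  expect_equal(same$adjR2NoIntercept, 1)
  expect_equal(same$adjR2WithIntercept, 1)

  X3 <- 2 * X1
  prop <- compareMatrices(X1, X3)
  expect_equal(prop$adjR2NoIntercept, 1)
  expect_gt(prop$msd, 0)

  expect_error(compareMatrices(X1, randomSpd(4L)), "dimensions")
})

test_that("-log(b) distances embed correctly with classical scaling", {
  b1 <- matrix(1, 2, 2)
  expect_equal(bToDistance(b1), matrix(0, 2, 2))

  b0 <- matrix(c(1, 0, 0, 1), 2)
  expect_message(d0 <- bToDistance(b0), "infinite")
  expect_true(is.infinite(d0[1, 2]))
  expect_error(principalCoordinates(d0, 1L), "finite")

  # three points with known planar coordinates are recovered up to
  # rotation/reflection
  pts <- rbind(c(0, 0), c(3, 0), c(0, 4))
  D <- as.matrix(stats::dist(pts))
  Y <- principalCoordinates(D, k = 2L)
  skip_if_not_installed("vegan")
  pr <- vegan::procrustes(pts, Y, symmetric = FALSE)
  expect_lt(sqrt(sum(pr$residuals^2)), 1e-8)
})
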