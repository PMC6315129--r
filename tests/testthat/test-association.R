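test_that("minor-allele carrier filter applies the boundary correctly", {
  g4 <- c(rep(1, 4), rep(0, 96))              # 4 heterozygote carriers
  g5 <- c(rep(1, 5), rep(0, 95))              # 5 carriers: retained
  mono <- rep(0, 100)                         # monomorphic: removed
  flipped <- 2 - g4                           # same SNP coded on the major allele
  G <- cbind(a = g4, b = g5, c = mono, d = flipped)
  kept <- macFilter(G, minSubjects = 5)
  expect_identical(colnames(kept), "b")

  # allele-count mode: 5 het carriers = 5 alleles, 3 hom carriers = 6
  G2 <- cbind(het5 = c(rep(1, 5), rep(0, 95)),
              hom3 = c(rep(2, 3), rep(0, 97)))
  expect_identical(colnames(macFilter(G2, 6, mode = "allele")), "hom3")
  expect_warning(macFilter(cbind(x = mono), 5), "removed every SNP")
  expect_error(macFilter(cbind(x = c(0, 3)), 5), "codes")
})

test_that("genotype PCs separate populations, are orthogonal and rank-checked", {
  set.seed(17)
  n <- 60; m <- 120
  pops <- rep(0:1, each = n / 2)
  maf <- cbind(runif(m, 0.05, 0.3), runif(m, 0.6, 0.9))
  G <- t(vapply(pops, function(p) rbinom(m, 2, maf[, p + 1]), numeric(m)))
  pcs <- genotypePCs(G, 4)
  # PC1 separates the two populations with no overlap
  expect_true(max(pcs[pops == 0, 1]) < min(pcs[pops == 1, 1]) ||
              min(pcs[pops == 0, 1]) > max(pcs[pops == 1, 1]))
  # orthogonality of score columns
  gram <- crossprod(pcs)
  expect_lt(max(abs(gram[upper.tri(gram)])), 1e-8 * max(diag(gram)))
  # deterministic sign convention
  expect_identical(pcs, genotypePCs(G, 4))

  # rank-3 toy matrix cannot give 4 PCs
  base <- matrix(rbinom(30, 2, 0.5), 10, 3)
  lowRank <- cbind(base, base[, 1], base[, 2], base[, 3])
  expect_error(genotypePCs(lowRank, 4), "rank")
})

test_that("the per-SNP linear model matches brute-force OLS", {
  # exact fit: y = 2 g with no noise
  g <- c(0, 1, 2, 0, 1, 2, 1, 0, 2, 1)
  fit <- linearAssoc(2 * g, g)
  expect_equal(fit$beta, 2, tolerance = 1e-12)
  expect_lt(fit$p.value, 1e-100)

  # random small designs vs normal equations
  set.seed(27)
  for (rep in 1:5) {
    n <- 40
    g <- rbinom(n, 2, 0.3)
    covs <- cbind(age = runif(n, 3, 40), sex = rbinom(n, 1, 0.5),
                  PC1 = rnorm(n))
    y <- 0.3 * g + 0.01 * covs[, 1] + rnorm(n)
    fit <- linearAssoc(y, g, covs)
    X <- cbind(1, g, covs)
    want <- bfOLS(X, y)
    expect_equal(fit$beta, want$beta[2], tolerance = 1e-9)
    expect_equal(fit$se, want$se[2], tolerance = 1e-9)
    expect_equal(fit$p.value, want$p[2], tolerance = 1e-9)
  }

  # missing genotypes drop to complete cases
  g10 <- c(0, 1, 2, 0, 1, 2, 1, 0, 2, 1)
  gm <- g10; gm[1:3] <- NA
  expect_equal(linearAssoc(rnorm(10), gm)$n, 7L, ignore_attr = TRUE)

  # collinear designs are rejected with the offending column named
  expect_error(linearAssoc(rnorm(10), g10, cbind(dup = g10)), "collinear")
})

test_that("type-I error of the linear model under the null is nominal", {
  set.seed(37)
  n <- 300
  y <- rnorm(n)
  covs <- cbind(age = runif(n, 3, 40), sex = rbinom(n, 1, 0.5))
  p <- vapply(1:400, function(i) {
    linearAssoc(y, rbinom(n, 2, runif(1, 0.1, 0.5)), covs)$p.value
  }, numeric(1))
  expect_gt(mean(p < 0.05), 0.02)
  expect_lt(mean(p < 0.05), 0.08)
})

test_that("BH adjustment follows the step-up definition", {
  # hand-derived case: p*m/rank then cumulative min from the bottom
  expect_equal(bhAdjust(c(1e-4, 0.02, 0.03, 0.5)),
               c(4e-4, 0.04, 0.04, 0.5), tolerance = 1e-12)
  expect_equal(bhAdjust(rep(0.05, 10)), rep(0.05, 10))
  set.seed(47)
  for (rep in 1:5) {
    p <- runif(50)^2
    q <- bhAdjust(p)
    expect_equal(q, bfBH(p), tolerance = 1e-12)
    expect_true(all(q >= p))
    # step-up monotonicity: adjusted values non-decreasing in raw rank
    expect_true(all(diff(q[order(p)]) >= -1e-15))
  }
  expect_error(bhAdjust(c(0.5, 0)), "0, 1")
  expect_error(bhAdjust(c(0.5, 1.2)), "0, 1")
})

test_that("covariate tests give Pearson r and Kendall tau with sane behavior", {
  ct <- covariateTests(c(2, 4, 6, 8), c(1, 2, 3, 4), c(0, 1, 0, 1))
  expect_equal(ct$estimate[ct$test == "pearson_age"], 1, tolerance = 1e-12)

  # tau flips sign when the sex coding flips
  set.seed(57)
  y <- rnorm(50); sex <- rbinom(50, 1, 0.5); age <- runif(50, 3, 40)
  t1 <- covariateTests(y, age, sex)
  t2 <- covariateTests(y, age, 1 - sex)
  expect_equal(t1$estimate[2], -t2$estimate[2], tolerance = 1e-12)
  expect_equal(t1$p.value[2], t2$p.value[2], tolerance = 1e-12)

  # null sex association is usually non-significant
  pvals <- vapply(1:60, function(i) {
    covariateTests(rnorm(200), runif(200, 3, 40),
                   rbinom(200, 1, 0.5))$p.value[2]
  }, numeric(1))
  expect_gt(mean(pvals > 0.05), 0.9)

  expect_error(covariateTests(rep(1, 5), 1:5, c(0, 1, 0, 1, 0)), "constant")
  expect_error(covariateTests(1:2, 1:2, c(0, 1)), "at least 3")
})

test_that("the association scan ranks a planted causal SNP first", {
  cfg <- cohortConfig(nSubjects = 250, nSNPs = 300, causalSNP = 42,
                      causalEffect = 0.6, seed = 67)
  coh <- simulateCohort(cfg, makeMeshes = FALSE)
  res <- associationScan(list(amplitude = coh$truth$amplitude),
                         coh$genotypes, age = coh$covariates$age,
                         sex = coh$covariates$sex, snpInfo = coh$snpInfo)
  tab <- manhattanTable(res)
  expect_identical(tab$SNP[1], "snp0042")
  expect_true(all(res$P_FDR >= res$P))
  expect_equal(res$P_FDR, bfBH(res$P), tolerance = 1e-12)
  # effect recovery within 2 SE
  hit <- res[res$SNP == "snp0042", ]
  expect_lt(abs(hit$BETA - 0.6), 2 * hit$SE)
})

test_that("manhattan table applies the two significance thresholds", {
  df <- data.frame(PHENO = "s", SNP = c("a", "b", "c"), CHR = 1:3,
                   POS = 1:3, BETA = 0, SE = 1, T = 0,
                   P = c(6e-8, 4e-8, 2e-3))
  tab <- manhattanTable(df)
  expect_identical(tab$level[tab$SNP == "b"], "significant")
  expect_identical(tab$level[tab$SNP == "a"], "suggestive")
  expect_identical(tab$level[tab$SNP == "c"], "ns")
  expect_identical(tab$SNP, c("b", "a", "c"))
  empty <- manhattanTable(df[0, ])
  expect_identical(nrow(empty), 0L)
})

test_that("genotype and PLINK text readers agree on additive codes", {
  dirp <- withr::local_tempdir()
  G <- cbind(s1 = c(0, 1, 2), s2 = c(2, 2, 0), s3 = c(0, NA, 1))
  rownames(G) <- c("A", "B", "C")
  tsv <- file.path(dirp, "g.tsv")
  writeGenotypesTSV(G, tsv)
  expect_equal(readGenotypesTSV(tsv), G)

  # equivalent .ped/.map (alleles A = minor, G = major for s1)
  writeLines(c("1 A 0 0 1 -9  G G  A G  A A",
               "1 B 0 0 2 -9  A G  A G  0 0",
               "1 C 0 0 1 -9  A A  G G  A G"),
             file.path(dirp, "g.ped"))
  writeLines(c("1 s1 0 100", "1 s2 0 200", "1 s3 0 300"),
             file.path(dirp, "g.map"))
  plink <- readPlinkPedMap(file.path(dirp, "g.ped"),
                           file.path(dirp, "g.map"))
  expect_identical(plink$map$snp, c("s1", "s2", "s3"))
  expect_equal(plink$genotypes[, "s1"], c(A = 0, B = 1, C = 2))
  expect_true(is.na(plink$genotypes["B", "s3"]))
})
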