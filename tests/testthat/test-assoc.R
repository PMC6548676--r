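test_that("QC keeps boundary values and excludes below-threshold variants", {
  # 10 toy variants: v2 fails MAF, v5 fails info, v8 fails both -> 7 survive
  caf <- c(0.10, 0.02, 0.03, 0.25, 0.30, 0.97, 0.50, 0.01, 0.15, 0.40)
  info <- c(0.80, 0.90, 0.50, 0.70, 0.49, 0.60, 1.00, 0.30, 0.51, 0.95)
  g <- toy_genotypes(matrix(1, 4, 10), caf = caf, info = info)
  kept <- qc_filter(g)
  expect_equal(ncol(kept$dosage), 7L)
  expect_true("v003" %in% kept$variants$id)    # MAF exactly 0.03 retained
  expect_true("v007" %in% kept$variants$id)    # info exactly 0.5 retained
  expect_false("v005" %in% kept$variants$id)   # info 0.49 excluded
  excl <- attr(kept, "exclusions")
  expect_setequal(excl$id, c("v002", "v005", "v008"))
  expect_equal(excl$reason[excl$id == "v008"], "low_maf;low_info")
})

test_that("principal components separate planted ancestry clusters and are
           orthogonal", {
  set.seed(701)
  n <- 120; p <- 80
  pop <- rep(0:1, each = n / 2)
  f1 <- runif(p, 0.1, 0.5)
  f2 <- pmin(f1 + 0.3, 0.9)
  D <- t(vapply(seq_len(n), function(i)
    rbinom(p, 2, if (pop[i] == 0) f1 else f2), numeric(p)))
  g <- toy_genotypes(D)
  pcs <- compute_pcs(g, 3)
  expect_gt(min(pcs$PC1[pop == 1]), max(pcs$PC1[pop == 0]))  # no overlap
  cp <- crossprod(as.matrix(pcs))
  expect_lt(max(abs(cp[upper.tri(cp)])), 1e-8)
  expect_equal(ncol(compute_pcs(g, 0)), 0L)
})

test_that("scan coefficients match an independent ML-optimizer oracle", {
  set.seed(702)
  n <- 200
  g <- rbinom(n, 2, 0.3)
  age <- rnorm(n, 75, 6)
  sex <- rbinom(n, 1, 0.5)
  y <- rbinom(n, 1, plogis(-0.3 + 0.4 * g + 0.02 * (age - 75) + 0.1 * sex))
  gm <- toy_genotypes(matrix(as.numeric(g), n, 1))
  rec <- logistic_scan(gm, y, data.frame(age = age, sex = sex))
  # independent oracle: direct Newton-free ML via optim on the deviance
  X <- cbind(1, g, age, sex)
  nll <- function(beta) {
    eta <- X %*% beta
    -sum(y * eta - log1p(exp(eta)))
  }
  gr <- function(beta) -as.numeric(crossprod(X, y - plogis(X %*% beta)))
  opt <- optim(rep(0, 4), nll, gr, method = "BFGS", hessian = TRUE,
               control = list(reltol = 1e-16, maxit = 5000))
  se_or <- sqrt(diag(solve(opt$hessian)))
  expect_equal(rec$beta, opt$par[2], tolerance = 1e-6)
  expect_equal(rec$se, se_or[2], tolerance = 1e-6)
  expect_equal(rec$or, exp(rec$beta), tolerance = 1e-12)
  # dosage independent of outcome -> beta within noise of zero
  g0 <- toy_genotypes(matrix(rbinom(n, 2, 0.4), n, 1))
  rec0 <- logistic_scan(g0, y)
  expect_lt(abs(rec0$beta), 3 * rec0$se)
  expect_error(logistic_scan(gm, rep(1, n)), "constant")
})

test_that("flipping coded/other alleles negates beta and preserves p", {
  set.seed(703)
  n <- 300
  g <- rbinom(n, 2, 0.35)
  y <- rbinom(n, 1, plogis(-0.2 + 0.5 * g))
  gm <- toy_genotypes(matrix(as.numeric(g), n, 1), coded = "A", other = "G")
  gm_fl <- toy_genotypes(matrix(2 - as.numeric(g), n, 1),
                         coded = "G", other = "A")
  r1 <- logistic_scan(gm, y)
  r2 <- logistic_scan(gm_fl, y)
  expect_equal(r2$beta, -r1$beta, tolerance = 1e-10)
  expect_equal(r2$p, r1$p, tolerance = 1e-10)
})

test_that("fixed-effect meta-analysis matches hand computation and metafor", {
  base <- data.frame(variant = "v1", subgroup = "memory", chr = "2",
                     pos = 100, coded = "A", other = "G", caf = 0.3,
                     converged = TRUE, stringsAsFactors = FALSE)
  # hand-computed two-study example
  rec <- rbind(cbind(base, beta = 0.2, se = 0.1, dataset = "d1"),
               cbind(base, beta = 0.4, se = 0.1, dataset = "d2"))
  m <- meta_fixed(rec)
  expect_equal(m$beta, 0.3, tolerance = 1e-12)
  expect_equal(m$Q, 2.0, tolerance = 1e-12)
  expect_equal(m$se, 0.1 / sqrt(2), tolerance = 1e-12)
  expect_equal(m$direction, "++")
  mf <- metafor::rma(yi = c(0.2, 0.4), sei = c(0.1, 0.1), method = "FE")
  expect_equal(m$beta, as.numeric(mf$beta), tolerance = 1e-10)
  expect_equal(m$se, mf$se, tolerance = 1e-10)
  expect_equal(m$Q, mf$QE, tolerance = 1e-10)
  # identical studies: Q = 0, I2 = 0, pooled se = se/sqrt(2)
  rec2 <- rbind(cbind(base, beta = 0.3, se = 0.1, dataset = "d1"),
                cbind(base, beta = 0.3, se = 0.1, dataset = "d2"))
  m2 <- meta_fixed(rec2)
  expect_equal(m2$beta, 0.3, tolerance = 1e-12)
  expect_equal(m2$se, 0.1 / sqrt(2), tolerance = 1e-12)
  expect_equal(m2$Q, 0, tolerance = 1e-12)
  expect_equal(m2$i2, 0)
  # single record passes through with k = 1 and undefined Q
  m1 <- meta_fixed(cbind(base, beta = 0.25, se = 0.12, dataset = "d1"))
  expect_equal(m1$beta, 0.25)
  expect_equal(m1$se, 0.12)
  expect_equal(m1$k, 1L)
  expect_true(is.na(m1$Q))
  # pooled se never exceeds the smallest contributing se; pooled estimate
  # stays inside the convex hull
  set.seed(704)
  rec3 <- do.call(rbind, lapply(1:4, function(i)
    cbind(base, beta = rnorm(1, 0.2, 0.1), se = runif(1, 0.05, 0.2),
          dataset = paste0("d", i))))
  m3 <- meta_fixed(rec3)
  expect_lte(m3$se, min(rec3$se))
  expect_gte(m3$beta, min(rec3$beta))
  expect_lte(m3$beta, max(rec3$beta))
})

test_that("meta-analysis aligns swapped coded alleles by sign flip", {
  base <- data.frame(variant = "v1", subgroup = "memory", chr = "2",
                     pos = 100, converged = TRUE, stringsAsFactors = FALSE)
  rec <- rbind(
    cbind(base, coded = "A", other = "G", caf = 0.3, beta = 0.2, se = 0.1,
          dataset = "d1"),
    cbind(base, coded = "G", other = "A", caf = 0.7, beta = -0.2, se = 0.1,
          dataset = "d2"))
  m <- meta_fixed(rec)
  expect_equal(m$beta, 0.2, tolerance = 1e-12)
  expect_equal(m$Q, 0, tolerance = 1e-12)
  # unresolvable mismatch drops the variant
  rec_bad <- rbind(
    cbind(base, coded = "A", other = "G", caf = 0.3, beta = 0.2, se = 0.1,
          dataset = "d1"),
    cbind(base, coded = "C", other = "T", caf = 0.3, beta = 0.2, se = 0.1,
          dataset = "d2"))
  m_bad <- meta_fixed(rec_bad)
  expect_true(is.null(m_bad) || nrow(m_bad) == 0L)
  expect_equal(attr(m_bad, "dropped"), "v1")
})

test_that("suggestive selection applies strict OR bounds and the region
           exclusion", {
  mk <- function(or, p, chr = "2") data.frame(
    variant = paste0("v", seq_along(or)), subgroup = "memory", chr = chr,
    pos = 1, coded = "A", other = "G", beta = log(or), se = 0.1,
    or = or, z = 0, p = p, Q = 0, het_p = 1, i2 = 0,
    direction = "++++", k = 4L, stringsAsFactors = FALSE)
  # boundary: OR exactly 0.77 is never selected
  s <- select_suggestive(mk(c(0.77, 0.769, 1 / 0.77, 1.31), rep(1e-8, 4)))
  expect_equal(s$selected, c(FALSE, TRUE, FALSE, TRUE))
  # chromosome-19 exclusion beats an extreme OR with a tiny p
  s19 <- select_suggestive(mk(0.4, 1e-12, chr = "19"))
  expect_false(s19$selected)
  expect_true(s19$region_excluded)
  # p threshold is strict
  sp <- select_suggestive(mk(c(2, 2), c(1e-5, 0.99e-5)))
  expect_equal(sp$selected, c(FALSE, TRUE))
})

test_that("comparison against a published reference OR follows the
           reconstructed-SE formula", {
  # record identical to the reference
  id <- compare_to_reference(log(1.2), (log(1.3) - log(1.1)) / (2 * 1.959964),
                             1.2, 1.1, 1.3)
  expect_equal(id$z, 0)
  expect_equal(id$p, 1)
  # arithmetic oracle
  r <- compare_to_reference(log(2), 0.1, 1.0, 0.82, 1.22)
  se_ref <- (log(1.22) - log(0.82)) / (2 * 1.959964)
  z_or <- log(2) / sqrt(0.1^2 + se_ref^2)
  expect_equal(r$z, z_or, tolerance = 1e-12)
  expect_equal(r$p, 2 * pnorm(-abs(z_or)), tolerance = 1e-12)
  # widening the reference CI strictly shrinks |z|
  r_wide <- compare_to_reference(log(2), 0.1, 1.0, 0.7, 1.43)
  expect_lt(abs(r_wide$z), abs(r$z))
  expect_error(compare_to_reference(0.1, 0.1, 1.0, 1.1, 1.3), "bracket")
})
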