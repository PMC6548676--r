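test_that("risk scores are linear dosage-weight sums with allele
           alignment", {
  D <- matrix(c(0, 1, 2), 3, 1)
  g <- toy_genotypes(D, coded = "A", other = "G")
  w <- data.frame(variant = "v001", coded_allele = "A", weight = 0.5,
                  source = "ref", stringsAsFactors = FALSE)
  expect_equal(build_score(g, w)$score, c(0, 0.5, 1.0))
  # zero weights -> zero scores
  w0 <- transform(w, weight = 0)
  expect_equal(build_score(g, w0)$score, c(0, 0, 0))
  # flipping the weight file's coded allele leaves scores unchanged up to
  # the constant 2w offset absorbed consistently for every sample
  set.seed(801)
  D2 <- matrix(rbinom(60, 2, 0.4) * 1.0, 20, 3)
  g2 <- toy_genotypes(D2, coded = c("A", "C", "G"),
                      other = c("G", "T", "A"))
  w2 <- data.frame(variant = c("v001", "v002", "v003"),
                   coded_allele = c("A", "C", "G"),
                   weight = c(0.3, -0.2, 0.1), stringsAsFactors = FALSE)
  w2_fl <- transform(w2, coded_allele = c("G", "T", "A"),
                     weight = -weight)
  s <- build_score(g2, w2)$score
  s_fl <- build_score(g2, w2_fl)$score
  expect_equal(s_fl - s_fl[1], s - s[1], tolerance = 1e-12)
  # linearity in the weight vector
  w2b <- transform(w2, weight = weight * 2)
  expect_equal(build_score(g2, w2b)$score, 2 * s, tolerance = 1e-12)
  # strand-ambiguous variants are dropped
  g3 <- toy_genotypes(D2, coded = c("A", "C", "G"),
                      other = c("T", "G", "A"))
  s3 <- build_score(g3, w2)
  expect_equal(s3$n_variants[1], 1L)
  expect_setequal(attr(s3, "dropped")$variant, c("v001", "v002"))
  # empty intersection errors
  expect_error(build_score(g2, transform(w2, variant = paste0("x", 1:3))),
               "no usable variants")
})

test_that("nested model comparison computes the 5-df LRT and flags
           collinearity", {
  set.seed(802)
  n <- 600
  age <- rnorm(n, 78, 6)
  sex <- rbinom(n, 1, 0.5)
  ref <- rnorm(n)
  S <- matrix(rnorm(n * 5), n, 5,
              dimnames = list(NULL, paste0("sg", 1:5)))
  y <- rbinom(n, 1, plogis(0.5 * ref + 0.4 * S[, 1] - 0.4 * S[, 2]))
  cmp <- fit_nested_models(y, age, sex, ref, S)
  expect_equal(cmp$df, 5L)
  expect_gte(cmp$lr, 0)
  expect_equal(cmp$lr, 2 * (cmp$ll_extended - cmp$ll_base),
               tolerance = 1e-10)
  expect_gte(cmp$pseudo_r2_extended, cmp$pseudo_r2_base)
  expect_false(cmp$collinear)
  # adding exact copies of the reference score is flagged, not fabricated
  S_cop <- matrix(ref, n, 5, dimnames = list(NULL, paste0("c", 1:5)))
  cmp2 <- fit_nested_models(y, age, sex, ref, S_cop)
  expect_true(cmp2$collinear)
  expect_lt(cmp2$df, 5L)
  # all-zero added columns: LR exactly 0
  S0 <- matrix(0, n, 5, dimnames = list(NULL, paste0("z", 1:5)))
  cmp3 <- fit_nested_models(y, age, sex, ref, S0)
  expect_equal(cmp3$lr, 0, tolerance = 1e-8)
})

test_that("AUC equals exhaustive concordant-pair counting and is invariant
           to monotone transforms", {
  set.seed(803)
  y <- rep(c(1, 0), times = c(12, 18))        # 30-sample toy set
  pred <- c(rnorm(12, 1), rnorm(18, 0))
  pred[c(3, 20)] <- pred[c(4, 21)]            # inject ties
  # brute force over all case-control pairs, ties counted 1/2
  cases <- pred[y == 1]; controls <- pred[y == 0]
  brute <- mean(outer(cases, controls,
                      function(a, b) (a > b) + 0.5 * (a == b)))
  expect_equal(auc_mw(pred, y), brute, tolerance = 1e-12)
  expect_equal(auc_mw(exp(2 * pred) + 5, y), brute, tolerance = 1e-12)
  # perfect separation
  expect_equal(auc_mw(y + 0.0, y), 1.0)
  # null predictor at n = 2000: AUC within 3 SE of 0.5
  y2 <- rbinom(2000, 1, 0.5)
  p2 <- rnorm(2000)
  se0 <- sqrt((sum(y2 == 1) + sum(y2 == 0) + 1) /
                (12 * sum(y2 == 1) * sum(y2 == 0)))
  expect_lt(abs(auc_mw(p2, y2) - 0.5), 3 * se0)
})

test_that("DeLong paired comparison matches pROC and is zero for a
           predictor against itself", {
  set.seed(804)
  n <- 300
  y <- rbinom(n, 1, 0.4)
  a <- rnorm(n) + y
  b <- rnorm(n) + 0.5 * y
  rc <- roc_compare(y, a, b)
  pr <- pROC::roc.test(pROC::roc(y, a, quiet = TRUE),
                       pROC::roc(y, b, quiet = TRUE),
                       method = "delong", paired = TRUE)
  expect_equal(rc$auc_a, as.numeric(pROC::auc(pROC::roc(y, a, quiet = TRUE))),
               tolerance = 1e-12)
  expect_equal(rc$chi2, unname(pr$statistic)^2, tolerance = 1e-8)
  expect_equal(rc$p, pr$p.value, tolerance = 1e-8)
  # self-comparison: chi-square exactly 0, p = 1
  rc_self <- roc_compare(y, a, a)
  expect_identical(rc_self$chi2, 0)
  expect_identical(rc_self$p, 1)
  expect_error(roc_compare(rep(1, 10), rnorm(10), rnorm(10)), "both")
})
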