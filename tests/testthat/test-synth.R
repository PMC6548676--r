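test_that("configuration validation names the offending field", {
  expect_error(sim_config(n_categories = 1), "n_categories")
  expect_error(sim_config(anchor_fraction = 1.5), "anchor_fraction")
  expect_error(sim_config(subgroup_prevalence = rep(0.2, 6)),
               "subgroup_prevalence")
  expect_error(sim_config(carrier_base_freq = 0), "carrier_base_freq")
  expect_error(sim_config(n_snps = 3, snp_or_matrix = matrix(1, 2, 6)),
               "snp_or_matrix")
  expect_error(sim_config(maf_range = c(0, 0.5)), "maf_range")
})

test_that("item banks honor the anchor fraction and are deterministic", {
  cfg <- sim_config(n_studies = 3, items_per_domain = 10,
                    anchor_fraction = 0.5, seed = 11)
  bank <- simulate_item_bank(cfg)
  per <- table(bank$study, bank$domain)
  expect_true(all(per == 10))
  # exactly 5 anchors per domain per study, identical across studies
  anch <- bank[bank$anchor, ]
  expect_true(all(table(anch$study, anch$domain) == 5))
  sp <- split(anch[, c("item_id", "a", "b1", "b2", "b3")], anch$study)
  expect_identical(sp[[1]][order(sp[[1]]$item_id), ],
                   sp[[2]][order(sp[[2]]$item_id), ],
                   ignore_attr = TRUE)
  # discriminations positive, thresholds strictly increasing
  expect_true(all(bank$a > 0))
  expect_true(all(bank$b1 < bank$b2 & bank$b2 < bank$b3))
  # anchor_fraction = 1: every item anchored
  bank1 <- simulate_item_bank(sim_config(n_studies = 2, anchor_fraction = 1,
                                         seed = 12))
  expect_true(all(bank1$anchor))
  # same seed -> byte-identical banks
  expect_identical(bank, simulate_item_bank(cfg))
})

test_that("cohort simulation plants the configured subgroup structure", {
  cfg <- sim_config(n_studies = 1, n_cases_per_study = 200,
                    n_controls_per_study = 50,
                    subgroup_prevalence = c(1, 0, 0, 0, 0, 0), seed = 13)
  bank <- simulate_item_bank(cfg)
  co <- simulate_cohort(cfg, bank)
  cases <- co$truth[!is.na(co$truth$subgroup), ]
  expect_true(all(cases$subgroup == "no-domain"))
  expect_equal(nrow(cases), 200L)
  # deficits depress the planted domain relative to the person's level
  cfg2 <- sim_config(n_studies = 1, n_cases_per_study = 300,
                     n_controls_per_study = 0,
                     subgroup_prevalence = c(0, 1, 0, 0, 0, 0),
                     deficit_magnitude = 2, seed = 14)
  co2 <- simulate_cohort(cfg2, simulate_item_bank(cfg2))
  gap <- co2$truth$general - co2$truth$theta_memory
  expect_equal(mean(gap), 2, tolerance = 0.1)
  # determinism
  expect_identical(co$responses, simulate_cohort(cfg, bank)$responses)
})

test_that("control dosages follow Hardy-Weinberg at the configured MAF and
           carrier enrichment behaves as planted", {
  cfg <- sim_config(n_studies = 1, n_cases_per_study = 0,
                    n_controls_per_study = 10000, n_snps = 12,
                    items_per_domain = 1, maf_range = c(0.1, 0.4),
                    carrier_enrichment_or = 1, seed = 15)
  bank <- simulate_item_bank(cfg)
  co <- simulate_cohort(cfg, bank)
  g <- simulate_genotypes(cfg, co$truth)
  freq <- colMeans(g$genotypes$dosage) / 2
  maf <- g$genotypes$variants$caf
  se <- sqrt(maf * (1 - maf) / (2 * 10000))
  expect_true(all(abs(freq - maf) < 3 * se))
  expect_true(all(g$genotypes$variants$info >= 0.6 &
                    g$genotypes$variants$info <= 1))
})

test_that("planted odds ratios are recovered and converge with n", {
  emp_logor <- function(n_cases, seed) {
    orm <- matrix(1, 5, 6); orm[, 2] <- 1.6
    cfg <- sim_config(n_studies = 1, n_cases_per_study = n_cases,
                      n_controls_per_study = n_cases,
                      subgroup_prevalence = c(0, 1, 0, 0, 0, 0),
                      items_per_domain = 1, n_snps = 5,
                      snp_or_matrix = orm, maf_range = c(0.3, 0.4),
                      seed = seed)
    co <- simulate_cohort(cfg, simulate_item_bank(cfg))
    g <- simulate_genotypes(cfg, co$truth)
    case <- !is.na(co$truth$subgroup)
    mean(vapply(1:5, function(j) {
      d <- g$genotypes$dosage[, j]
      f1 <- mean(d[case]) / 2; f0 <- mean(d[!case]) / 2
      log(f1 / (1 - f1)) - log(f0 / (1 - f0))
    }, numeric(1)))
  }
  err_small <- abs(emp_logor(500, 16) - log(1.6))
  err_large <- abs(emp_logor(8000, 16) - log(1.6))
  expect_lt(err_large, err_small)
  expect_lt(err_large, 0.05)
  # null ORs leave subgroup and control frequencies indistinguishable
  cfg0 <- sim_config(n_studies = 1, n_cases_per_study = 3000,
                     n_controls_per_study = 3000, items_per_domain = 1,
                     n_snps = 8, maf_range = c(0.2, 0.4),
                     carrier_enrichment_or = 1, seed = 17)
  co0 <- simulate_cohort(cfg0, simulate_item_bank(cfg0))
  g0 <- simulate_genotypes(cfg0, co0$truth)
  case0 <- !is.na(co0$truth$subgroup)
  for (j in 1:8) {
    d <- g0$genotypes$dosage[, j]
    f1 <- mean(d[case0]) / 2; f0 <- mean(d[!case0]) / 2
    lo <- log(f1 / (1 - f1)) - log(f0 / (1 - f0))
    mcse <- sqrt(1 / (2 * 3000 * f1 * (1 - f1)) +
                   1 / (2 * 3000 * f0 * (1 - f0)))
    expect_lt(abs(lo), 3 * mcse)
  }
  # equal carrier fractions when enrichment OR is 1
  carr <- g0$carrier
  mem <- co0$truth$subgroup == "memory" & !is.na(co0$truth$subgroup)
  p1 <- mean(carr[mem]); p0 <- mean(carr[!mem])
  expect_lt(abs(p1 - p0),
            3 * sqrt(p1 * (1 - p1) / sum(mem) + p0 * (1 - p0) / sum(!mem)))
})
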