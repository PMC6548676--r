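mk_scores <- function(m, e, l, v, pid = "p1", study = "s1") {
  data.frame(person_id = pid, study = study, memory = m, executive = e,
             language = l, visuospatial = v, stringsAsFactors = FALSE)
}

test_that("the 0.80-SD rule matches the enumerated truth table", {
  # flat profile -> no-domain
  expect_equal(as.character(assign_subgroups(mk_scores(0, 0, 0, 0))$label),
               "no-domain")
  # isolated memory: mean -0.2, memory deviation exactly -1.0
  a <- assign_subgroups(mk_scores(-1.2, 0.1, 0.1, 0.2))
  expect_equal(as.character(a$label), "memory")
  expect_equal(a$mean_score, -0.2)
  expect_equal(a$d_memory, -1.0)
  # two deviations exactly at the (inclusive) threshold -> multiple
  b <- assign_subgroups(mk_scores(-1.6, -1.6, 0, 0))
  expect_equal(as.character(b$label), "multiple")
  expect_equal(unname(unlist(b[paste0("d_", c("memory", "executive",
                                              "language",
                                              "visuospatial"))])),
               c(-0.8, -0.8, 0.8, 0.8))
  # single deviations for each remaining domain
  expect_equal(as.character(assign_subgroups(
    mk_scores(0, -2, 0, 0))$label), "executive")
  expect_equal(as.character(assign_subgroups(
    mk_scores(0, 0, -2, 0))$label), "language")
  expect_equal(as.character(assign_subgroups(
    mk_scores(0, 0, 0, -2))$label), "visuospatial")
  # just inside the threshold -> no label
  expect_equal(as.character(assign_subgroups(
    mk_scores(-0.79 * 4 / 3, 0, 0, 0))$label), "no-domain")
})

test_that("assignment is a translation-invariant partition with sum-zero
           deviations", {
  set.seed(601)
  n <- 1000
  sc <- data.frame(person_id = sprintf("p%04d", 1:n), study = "s1",
                   memory = rnorm(n), executive = rnorm(n),
                   language = rnorm(n), visuospatial = rnorm(n))
  a <- assign_subgroups(sc)
  expect_equal(nrow(a), n)                       # partition: one label each
  expect_equal(sum(table(a$label)), n)
  dev <- as.matrix(a[, paste0("d_", c("memory", "executive", "language",
                                      "visuospatial"))])
  expect_true(all(abs(rowSums(dev)) < 1e-12))    # deviations sum to zero
  shift <- sc
  per_person <- rnorm(n) + 3      # same constant across a person's domains
  for (d in c("memory", "executive", "language", "visuospatial"))
    shift[[d]] <- shift[[d]] + per_person
  expect_identical(assign_subgroups(shift)$label, a$label)
  # missing scores excluded with a logged reason
  sc$memory[5] <- NA
  a2 <- assign_subgroups(sc)
  expect_equal(nrow(a2), n - 1L)
  expect_equal(attr(a2, "excluded")$person_id, "p0005")
  expect_error(assign_subgroups(sc, delta = 0), "positive")
})

test_that("threshold sweep is monotone and flags degenerate thresholds", {
  set.seed(602)
  n <- 400
  sc <- data.frame(person_id = sprintf("p%03d", 1:n), study = "s1",
                   memory = rnorm(n), executive = rnorm(n),
                   language = rnorm(n), visuospatial = rnorm(n))
  carrier <- rbinom(n, 1, 0.4)
  sw <- threshold_sweep(sc, deltas = seq(0.5, 1.2, 0.1), carrier = carrier)
  expect_true(all(diff(sw[["p_no-domain"]]) >= 0))   # monotone in delta
  # a threshold beyond every deviation: everyone no-domain, contrast flagged
  sw2 <- threshold_sweep(sc, deltas = 50, carrier = carrier)
  expect_equal(sw2[["p_no-domain"]], 1)
  expect_false(sw2$contrast_defined)
  expect_true(is.na(sw2$enrichment_contrast))
})

test_that("study-by-subgroup heterogeneity test has the right df and a
           Pearson-formula oracle", {
  set.seed(603)
  # 5 studies x 6 subgroups, all cells non-empty -> df = 20
  lab <- factor(rep(subgroup_levels(), times = 5 * c(8, 7, 4, 5, 5, 3)),
                levels = subgroup_levels())
  study <- rep(paste0("st", 1:5), each = length(lab) / 5)
  lab <- sample(lab)
  r <- subgroup_distribution_test(lab, study)
  expect_equal(r$df, 20L)
  # identical proportions across studies -> statistic 0
  lab0 <- rep(rep(subgroup_levels(), times = c(4, 3, 2, 2, 2, 1)), 3)
  study0 <- rep(paste0("st", 1:3), each = 14)
  r0 <- subgroup_distribution_test(lab0, study0)
  expect_equal(r0$statistic, 0, tolerance = 1e-12)
  # 2x2 oracle
  lab2 <- rep(c("memory", "language"), times = c(30, 30))
  study2 <- c(rep("a", 10), rep("b", 20), rep("a", 20), rep("b", 10))
  expect_warning(r2 <- subgroup_distribution_test(lab2, study2),
                 "all-zero")   # four empty subgroup columns dropped
  expect_equal(r2$statistic,
               pearson_oracle(matrix(c(10, 20, 20, 10), 2)),
               tolerance = 1e-12)
})

test_that("carrier contingency drops empty subgroups from the df and
           matches a hand Pearson computation", {
  # a cohort with an empty executive subgroup -> df = 4
  lab <- rep(c("no-domain", "memory", "language", "visuospatial",
               "multiple"), times = c(40, 30, 20, 20, 10))
  set.seed(604)
  carrier <- rbinom(length(lab), 1, ifelse(lab == "memory", 0.65, 0.45))
  r <- apoe_contingency(lab, carrier)$overall
  expect_equal(r$df, 4L)
  expect_equal(r$empty, "executive")
  # equal carrier proportions -> statistic 0
  lab_eq <- rep(c("memory", "language"), each = 20)
  carr_eq <- rep(c(1, 0), 20)
  expect_equal(apoe_contingency(lab_eq, carr_eq)$overall$statistic, 0,
               tolerance = 1e-12)
  # toy two-subgroup table: carriers (10, 10), non-carriers (20, 5)
  lab_toy <- rep(c("memory", "language"), times = c(30, 15))
  carr_toy <- c(rep(1, 10), rep(0, 20), rep(1, 10), rep(0, 5))
  r_toy <- apoe_contingency(lab_toy, carr_toy)$overall
  expect_equal(r_toy$statistic,
               pearson_oracle(matrix(c(10, 20, 10, 5), 2)),
               tolerance = 1e-12)
  expect_equal(r_toy$df, 1L)
})
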