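# Synthetic multi-study generator with planted truth: ordinal item
# responses driven by domain latent traits with partial anchor overlap,
# subgroup structure as domain-specific deficits relative to the person
# mean, a carrier variable enriched in the memory subgroup, and SNP
# dosages with subgroup-specific odds ratios against a shared control pool.

#' Simulation configuration
#'
#' Defaults emulate the multi-study design the package targets: five
#' studies, six subgroups with prevalences close to those observed in the
#' combined cohorts, a memory-enriched carrier allele (base frequency 0.45
#' among non-enriched participants, enrichment odds ratio 2.3), and common
#' imputed SNPs.
#'
#' @param n_cases_per_study,n_controls_per_study per-study sample sizes.
#' @param n_studies number of studies.
#' @param items_per_domain items per cognitive domain per study.
#' @param n_categories ordinal categories per item (>= 2).
#' @param anchor_fraction fraction of each domain's items shared verbatim
#'   (identical parameters) across studies, in `[0, 1]`.
#' @param subgroup_prevalence 6-vector of case subgroup probabilities
#'   (order: [subgroup_levels()]), summing to 1.
#' @param deficit_magnitude latent-trait depression (SD units) applied to
#'   affected domains of cases.
#' @param domain_noise_sd SD of person-by-domain trait noise around the
#'   general level.
#' @param carrier_base_freq carrier probability outside the enriched
#'   subgroup.
#' @param carrier_enrichment_or carrier odds ratio for the memory subgroup.
#' @param n_snps number of simulated SNPs.
#' @param snp_or_matrix `n_snps` x 6 matrix of subgroup-vs-control odds
#'   ratios (default all 1 = null SNPs).
#' @param maf_range,info_range uniform ranges for simulated minor-allele
#'   frequencies and info scores.
#' @param study_mean_shift optional per-study latent mean shifts
#'   (default 0 for the reference study, modest shifts elsewhere).
#' @param seed integer random seed for the run.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_cases_per_study = 600, n_controls_per_study = 600,
                       n_studies = 5, items_per_domain = 10,
                       n_categories = 4, anchor_fraction = 0.5,
                       subgroup_prevalence = c(0.39, 0.28, 0.02, 0.13,
                                               0.12, 0.06),
                       deficit_magnitude = 2.0, domain_noise_sd = 0.3,
                       carrier_base_freq = 0.45,
                       carrier_enrichment_or = 2.3,
                       n_snps = 200, snp_or_matrix = NULL,
                       maf_range = c(0.05, 0.5), info_range = c(0.6, 1.0),
                       study_mean_shift = NULL, seed = 1L) {
  cfg <- list(n_cases_per_study = n_cases_per_study,
              n_controls_per_study = n_controls_per_study,
              n_studies = n_studies, items_per_domain = items_per_domain,
              n_categories = n_categories, anchor_fraction = anchor_fraction,
              subgroup_prevalence = subgroup_prevalence,
              deficit_magnitude = deficit_magnitude,
              domain_noise_sd = domain_noise_sd,
              carrier_base_freq = carrier_base_freq,
              carrier_enrichment_or = carrier_enrichment_or,
              n_snps = n_snps, snp_or_matrix = snp_or_matrix,
              maf_range = maf_range, info_range = info_range,
              study_mean_shift = study_mean_shift, seed = as.integer(seed))
  .chk <- function(cond, field, msg)
    if (!cond) stop("invalid configuration field '", field, "': ", msg)
  .chk(cfg$n_studies >= 1, "n_studies", "need >= 1")
  .chk(cfg$n_categories >= 2, "n_categories", "need >= 2 categories")
  .chk(cfg$anchor_fraction >= 0 && cfg$anchor_fraction <= 1,
       "anchor_fraction", "must lie in [0, 1]")
  .chk(length(cfg$subgroup_prevalence) == 6 &&
         all(cfg$subgroup_prevalence >= 0) &&
         abs(sum(cfg$subgroup_prevalence) - 1) < 1e-12,
       "subgroup_prevalence", "must be 6 non-negative values summing to 1")
  .chk(cfg$deficit_magnitude >= 0, "deficit_magnitude", "must be >= 0")
  .chk(cfg$carrier_base_freq > 0 && cfg$carrier_base_freq < 1,
       "carrier_base_freq", "must lie in (0, 1)")
  .chk(cfg$carrier_enrichment_or > 0, "carrier_enrichment_or",
       "must be > 0")
  .chk(all(cfg$maf_range > 0) && all(cfg$maf_range < 1) &&
         diff(cfg$maf_range) >= 0, "maf_range",
       "must be an interval inside (0, 1)")
  .chk(diff(cfg$info_range) >= 0 && all(cfg$info_range >= 0) &&
         all(cfg$info_range <= 1), "info_range",
       "must be an interval inside [0, 1]")
  if (!is.null(cfg$snp_or_matrix)) {
    cfg$snp_or_matrix <- as.matrix(cfg$snp_or_matrix)
    .chk(nrow(cfg$snp_or_matrix) == cfg$n_snps &&
           ncol(cfg$snp_or_matrix) == 6 && all(cfg$snp_or_matrix > 0),
         "snp_or_matrix", "must be n_snps x 6 with all ORs > 0")
  }
  if (!is.null(cfg$study_mean_shift))
    .chk(length(cfg$study_mean_shift) == cfg$n_studies, "study_mean_shift",
         "length must equal n_studies")
  class(cfg) <- "sim_config"
  cfg
}

.study_names <- function(n) paste0("study", seq_len(n))

#' Simulate per-study item banks with anchor structure
#'
#' Each study's bank has `items_per_domain` items per domain with positive
#' discriminations and strictly increasing thresholds. A deterministic
#' subset of `round(anchor_fraction * items_per_domain)` items per domain is
#' flagged as anchors and carries identical parameters (and ids) in every
#' study; the remaining items are study-specific.
#'
#' @param config a [sim_config()].
#' @return data frame, one row per study x item: `study`, `item_id`,
#'   `domain`, `subdomain`, `anchor`, `a`, `b1..b(K-1)`.
#' @export
simulate_item_bank <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  K <- config$n_categories
  J <- config$items_per_domain
  n_anchor <- round(config$anchor_fraction * J)
  draw_items <- function(n, ids, domain, anchor) {
    if (n == 0L) return(NULL)
    a <- stats::runif(n, 0.9, 2.5)
    bmid <- stats::runif(n, -1.2, 1.2)
    half <- stats::runif(n, 0.4, 1.0)
    blist <- lapply(seq_len(n), function(i)
      bmid[i] + seq(-half[i], half[i], length.out = K - 1L))
    cbind(data.frame(item_id = ids, domain = domain,
                     subdomain = paste0(domain,
                                        c("_sub1", "_sub2")[1 +
                                          (seq_len(n) %% 2L)]),
                     anchor = anchor, a = a, stringsAsFactors = FALSE),
          .pad_b(blist))
  }
  studies <- .study_names(config$n_studies)
  anchor_banks <- list()
  for (d in .domains) {
    anchor_banks[[d]] <- draw_items(
      n_anchor, sprintf("anchor_%s_%02d", d, seq_len(n_anchor)), d, TRUE)
  }
  rows <- list()
  for (s in studies) {
    for (d in .domains) {
      sb <- draw_items(J - n_anchor,
                       sprintf("%s_%s_%02d", s, d,
                               seq_len(max(J - n_anchor, 0L))), d, FALSE)
      part <- rbind(anchor_banks[[d]], sb)
      if (!is.null(part)) {
        part <- cbind(study = s, part, stringsAsFactors = FALSE)
        rows[[paste(s, d)]] <- part
      }
    }
  }
  bank <- do.call(rbind, rows)
  rownames(bank) <- NULL
  bank
}

#' Simulate a multi-study cohort with planted subgroup structure
#'
#' Cases draw a subgroup label from `subgroup_prevalence`; affected domain
#' traits are lowered by `deficit_magnitude` relative to the person's
#' general cognitive level (single-domain subgroups depress one domain,
#' the "multiple" subgroup depresses two randomly chosen domains).
#' Controls' traits carry no deficits. Ordinal responses are drawn from
#' the graded-response category probabilities at the person's domain
#' trait; age and sex are simulated covariates independent of everything
#' else.
#'
#' @param config a [sim_config()].
#' @param bank item bank from [simulate_item_bank()].
#' @return list: `responses` (long data frame `person_id`, `study`,
#'   `item_id`, `domain`, `response`), `covariates` (`person_id`, `study`,
#'   `age`, `sex`, `case`), `truth` (`person_id`, `study`, `subgroup`,
#'   `general`, `theta_<domain>` per domain).
#' @export
simulate_cohort <- function(config, bank) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  studies <- .study_names(config$n_studies)
  shift <- config$study_mean_shift
  if (is.null(shift)) shift <- rep(0, config$n_studies)
  levs <- subgroup_levels()
  resp <- list(); cov <- list(); tru <- list()
  for (si in seq_along(studies)) {
    s <- studies[si]
    n_case <- config$n_cases_per_study
    n_ctrl <- config$n_controls_per_study
    n <- n_case + n_ctrl
    pid <- sprintf("%s_p%04d", s, seq_len(n))
    case <- c(rep(1L, n_case), rep(0L, n_ctrl))
    sg <- rep(NA_character_, n)
    sg[seq_len(n_case)] <- sample(levs, n_case, replace = TRUE,
                                  prob = config$subgroup_prevalence)
    general <- stats::rnorm(n, shift[si], 1)
    theta <- matrix(stats::rnorm(n * 4, 0, config$domain_noise_sd), n, 4,
                    dimnames = list(NULL, .domains)) + general
    for (i in seq_len(n_case)) {
      aff <- switch(sg[i],
                    "no-domain" = character(0),
                    "multiple" = sample(.domains, 2L),
                    sg[i])
      theta[i, aff] <- theta[i, aff] - config$deficit_magnitude
    }
    sb <- bank[bank$study == s, , drop = FALSE]
    blist <- item_thresholds(sb)
    # draw responses item by item: cumulative probabilities vs uniforms
    rr <- matrix(NA_integer_, n, nrow(sb))
    for (j in seq_len(nrow(sb))) {
      th <- theta[, sb$domain[j]]
      cum <- stats::plogis(outer(th, blist[[j]],
                                 function(t, b) sb$a[j] * (t - b)))
      rr[, j] <- rowSums(cum > stats::runif(n))
    }
    resp[[s]] <- data.frame(
      person_id = rep(pid, times = nrow(sb)),
      study = s,
      item_id = rep(sb$item_id, each = n),
      domain = rep(sb$domain, each = n),
      response = as.integer(rr), stringsAsFactors = FALSE)
    cov[[s]] <- data.frame(person_id = pid, study = s,
                           age = round(stats::rnorm(n, 80, 7)),
                           sex = stats::rbinom(n, 1, 0.6),
                           case = case, stringsAsFactors = FALSE)
    tr <- data.frame(person_id = pid, study = s, subgroup = sg,
                     general = general, stringsAsFactors = FALSE)
    tr[paste0("theta_", .domains)] <- as.data.frame(theta)
    tru[[s]] <- tr
  }
  list(responses = do.call(rbind, c(resp, make.row.names = FALSE)),
       covariates = do.call(rbind, c(cov, make.row.names = FALSE)),
       truth = do.call(rbind, c(tru, make.row.names = FALSE)))
}

#' Widen a long response table into a persons x items matrix
#'
#' @param responses long data frame (`person_id`, `item_id`, `response`).
#' @return integer matrix with person rownames and item colnames.
#' @export
responses_to_matrix <- function(responses) {
  pid <- unique(responses$person_id)
  iid <- unique(responses$item_id)
  m <- matrix(NA_integer_, length(pid), length(iid),
              dimnames = list(pid, iid))
  m[cbind(match(responses$person_id, pid),
          match(responses$item_id, iid))] <- responses$response
  m
}

# exponentially tilted HWE dosage distribution: p(g) C(2,g) f^g (1-f)^(2-g)
# exp(beta g) / Z  -- cases carry the planted log-OR beta exactly in
# expectation
.tilted_dosage_probs <- function(f, beta) {
  p <- stats::dbinom(0:2, 2, f) * exp(beta * (0:2))
  p / sum(p)
}

#' Simulate genotypes with planted subgroup odds ratios
#'
#' Controls draw dosages from Hardy-Weinberg binomial(2, MAF); cases in
#' subgroup g draw from the exponentially tilted distribution
#' `p(g) ~ HWE(g) * exp(beta_g * g)`, so the subgroup-vs-control odds
#' ratio equals the configured value in expectation. A carrier variable is
#' generated analogously from `carrier_base_freq` with odds multiplied by
#' `carrier_enrichment_or` in the memory subgroup. Info scores are drawn
#' uniformly from `info_range` and attached as metadata.
#'
#' @param config a [sim_config()].
#' @param truth truth table from [simulate_cohort()] (needs `person_id`,
#'   `subgroup`; `NA` subgroup = control).
#' @return list: `genotypes` (a [genotype_matrix()] over all persons),
#'   `carrier` (named 0/1 vector), `true_betas` (`n_snps` x 6 log-OR
#'   matrix).
#' @export
simulate_genotypes <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 3L)
  n <- nrow(truth)
  levs <- subgroup_levels()
  orm <- config$snp_or_matrix
  if (is.null(orm)) orm <- matrix(1, config$n_snps, 6)
  betas <- log(orm)
  colnames(betas) <- levs
  maf <- stats::runif(config$n_snps, config$maf_range[1],
                      config$maf_range[2])
  info <- stats::runif(config$n_snps, config$info_range[1],
                       config$info_range[2])
  sg_idx <- match(truth$subgroup, levs)           # NA for controls
  D <- matrix(0L, n, config$n_snps)
  for (j in seq_len(config$n_snps)) {
    d <- stats::rbinom(n, 2, maf[j])              # controls: HWE
    for (g in which(betas[j, ] != 0)) {
      sel <- which(!is.na(sg_idx) & sg_idx == g)
      if (length(sel))
        d[sel] <- sample(0:2, length(sel), replace = TRUE,
                         prob = .tilted_dosage_probs(maf[j], betas[j, g]))
    }
    # cases of null subgroups keep the HWE draw (beta = 0 tilt is HWE)
    D[, j] <- d
  }
  rownames(D) <- truth$person_id
  alleles <- c("A", "C", "G", "T")
  coded <- sample(alleles, config$n_snps, replace = TRUE)
  other <- vapply(coded, function(a)
    sample(setdiff(alleles, c(a, chartr("ACGT", "TGCA", a))), 1L), "")
  variants <- data.frame(
    id = sprintf("rs%06d", seq_len(config$n_snps)),
    chr = as.character(1 + (seq_len(config$n_snps) - 1L) %% 22L),
    pos = 1e6 + 1000 * seq_len(config$n_snps),
    coded = coded, other = unname(other), caf = maf, info = info,
    stringsAsFactors = FALSE)
  # carrier: base odds tilted in the memory subgroup
  base_odds <- config$carrier_base_freq / (1 - config$carrier_base_freq)
  odds <- ifelse(!is.na(truth$subgroup) & truth$subgroup == "memory",
                 base_odds * config$carrier_enrichment_or, base_odds)
  carrier <- stats::rbinom(n, 1, odds / (1 + odds))
  names(carrier) <- truth$person_id
  list(genotypes = genotype_matrix(D * 1.0, variants), carrier = carrier,
       true_betas = betas)
}

#' Simulate one full synthetic study set
#'
#' Convenience wrapper chaining [simulate_item_bank()],
#' [simulate_cohort()], and [simulate_genotypes()].
#'
#' @param config a [sim_config()].
#' @return list: `bank`, `responses`, `covariates`, `truth`, `genotypes`,
#'   `carrier`, `true_betas`.
#' @export
simulate_study_set <- function(config) {
  bank <- simulate_item_bank(config)
  cohort <- simulate_cohort(config, bank)
  gen <- simulate_genotypes(config, cohort$truth)
  c(list(bank = bank), cohort, gen)
}
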