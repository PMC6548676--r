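# End-to-end pipeline: simulate (or load) -> calibrate -> score ->
# z-transform -> subgroup -> carrier contingency -> per-subgroup scans ->
# meta-analysis -> suggestive selection -> risk scores -> nested-model and
# ROC evaluation, with a JSON run manifest recording stage row counts and
# output checksums.

#' Validate a pipeline configuration
#'
#' @param config list or path to a YAML file. Recognized fields:
#'   `simulate` (list of [sim_config()] arguments), `reference_study`,
#'   `delta`, `qc` (`maf_min`, `info_min`), `selection` (`p_threshold`,
#'   `or_low`, `or_high`, `excluded_chr`), `n_pcs`, `min_cases`,
#'   `risk` (`subgroup_rule` = "suggestive" or "top", `top_n`,
#'   `reference_p`), `seed`.
#' @return validated config list with defaults filled in.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  def <- list(reference_study = "study1", delta = 0.80,
              qc = list(maf_min = 0.03, info_min = 0.5),
              selection = list(p_threshold = 1e-5, or_low = 0.77,
                               or_high = 1 / 0.77, excluded_chr = "19"),
              n_pcs = 2, min_cases = 30,
              risk = list(subgroup_rule = "suggestive", top_n = 10,
                          reference_p = 1e-3),
              n_quad = 49, seed = 1L)
  for (k in names(def)) {
    if (is.null(config[[k]])) config[[k]] <- def[[k]]
    else if (is.list(def[[k]]))
      for (k2 in names(def[[k]]))
        if (is.null(config[[k]][[k2]])) config[[k]][[k2]] <- def[[k]][[k2]]
  }
  if (!is.numeric(config$delta) || config$delta <= 0)
    stop("invalid configuration field 'delta': threshold must be positive")
  if (config$selection$or_low <= 0 ||
      config$selection$or_high <= config$selection$or_low)
    stop("invalid configuration field 'selection': need 0 < or_low < or_high")
  if (config$qc$maf_min < 0 || config$qc$maf_min > 0.5)
    stop("invalid configuration field 'qc$maf_min': must lie in [0, 0.5]")
  config$seed <- as.integer(config$seed)
  config
}

#' Bundled small example pipeline configuration
#'
#' Two studies of 600 persons each (300 cases + 300 controls) and 200 SNPs,
#' with planted subgroup effects: three memory-subgroup risk SNPs
#' (OR 2.5), three visuospatial protective SNPs (OR 0.4), and two
#' language-subgroup risk SNPs (OR 2.5); the remainder are null. Small
#' enough to run end to end in a few minutes on one CPU.
#'
#' @param seed integer seed for the run.
#' @return configuration list for [run_pipeline()].
#' @export
example_pipeline_config <- function(seed = 1L) {
  orm <- matrix(1, 200, 6)
  colnames(orm) <- subgroup_levels()
  orm[1:3, "memory"] <- 2.5
  orm[4:6, "visuospatial"] <- 0.4
  orm[7:8, "language"] <- 2.5
  list(simulate = list(n_cases_per_study = 300, n_controls_per_study = 300,
                       n_studies = 2, items_per_domain = 10,
                       n_categories = 4, anchor_fraction = 0.5,
                       n_snps = 200, snp_or_matrix = orm,
                       study_mean_shift = c(0, -0.3)),
       reference_study = "study1", min_cases = 15,
       seed = as.integer(seed))
}

.manifest_add <- function(manifest, stage, n_in, n_out, warnings = character(0)) {
  manifest$stages[[length(manifest$stages) + 1L]] <-
    list(stage = stage, n_in = n_in, n_out = n_out,
         warnings = as.character(warnings))
  manifest
}

#' Run the full subgroup-genetics pipeline on one configuration
#'
#' Executes the stage sequence calibrate -> score -> subgroup -> carrier
#' contingency -> scan -> meta -> select -> riskscore -> evaluate on
#' simulated inputs, writing every intermediate artifact as TSV/VCF/JSON
#' under `out_dir` plus a run manifest with per-stage row counts and
#' output checksums. Reruns with the same configuration produce identical
#' manifests.
#'
#' @param config pipeline configuration (list or YAML path); see
#'   [pipeline_config()]. Must contain a `simulate` block.
#' @param out_dir output directory (created if absent).
#' @return the manifest (invisibly also written to
#'   `file.path(out_dir, "manifest.json")`), plus key results in its
#'   `results` element.
#' @export
run_pipeline <- function(config, out_dir) {
  config <- pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package_version =
                     as.character(utils::packageVersion("cogsub")),
                   stages = list(), outputs = list(), results = list())

  # --- simulate ------------------------------------------------------------
  if (is.null(config$simulate))
    stop("config must contain a 'simulate' block")
  simargs <- config$simulate
  simargs$seed <- config$seed
  cfg <- do.call(sim_config, simargs)
  sim <- simulate_study_set(cfg)
  write_item_bank(sim$bank, file.path(out_dir, "item_bank.tsv"))
  write_tsv_file(sim$responses, file.path(out_dir, "responses.tsv"))
  covs <- sim$covariates
  covs$carrier <- sim$carrier[covs$person_id]
  write_tsv_file(covs, file.path(out_dir, "covariates.tsv"))
  write_vcf(sim$genotypes, file.path(out_dir, "genotypes.vcf"))
  write_tsv_file(sim$truth, file.path(out_dir, "truth.tsv"))
  manifest <- .manifest_add(manifest, "simulate", 0,
                            nrow(covs))

  studies <- unique(covs$study)
  ref <- config$reference_study
  if (!ref %in% studies) stop("reference study '", ref, "' not simulated")

  # --- calibrate + score ----------------------------------------------------
  score_rows <- list()
  ref_items_all <- list()
  n_warn <- character(0)
  for (d in .domains) {
    bank_d <- sim$bank[sim$bank$domain == d, ]
    rs <- sim$responses[sim$responses$domain == d &
                          sim$responses$study == ref, ]
    rm_ref <- responses_to_matrix(rs)
    fit_ref <- withCallingHandlers(
      fit_grm(rm_ref, n_quad = config$n_quad,
              items_meta = bank_d[bank_d$study == ref, ]),
      warning = function(w) {
        n_warn <<- c(n_warn, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    ref_items_all[[d]] <- fit_ref$items
    sc <- score_eap(rm_ref, fit_ref$items)
    sc$study <- ref; sc$domain <- d
    score_rows[[paste(ref, d)]] <- sc
    for (s in setdiff(studies, ref)) {
      rs_s <- sim$responses[sim$responses$domain == d &
                              sim$responses$study == s, ]
      rm_s <- responses_to_matrix(rs_s)
      fit_s <- withCallingHandlers(
        calibrate_with_anchors(rm_s, fit_ref$items,
                               n_quad = config$n_quad),
        warning = function(w) {
          n_warn <<- c(n_warn, conditionMessage(w))
          invokeRestart("muffleWarning")
        })
      sc <- score_eap(rm_s, fit_s$items, prior_mean = fit_s$latent_mean,
                      prior_var = fit_s$latent_var)
      sc$study <- s; sc$domain <- d
      score_rows[[paste(s, d)]] <- sc
    }
  }
  scores <- do.call(rbind, c(score_rows, make.row.names = FALSE))
  write_tsv_file(scores[, c("person_id", "study", "domain", "theta", "se",
                            "n_items")],
                 file.path(out_dir, "scores.tsv"))
  manifest <- .manifest_add(manifest, "calibrate_score", nrow(sim$responses),
                            nrow(scores), unique(n_warn))

  # --- z-transform + subgroups ----------------------------------------------
  case_ids <- covs$person_id[covs$case == 1L]
  ref_case_scores <- scores[scores$study == ref &
                              scores$person_id %in% case_ids, ]
  zt <- ztransform_to_reference(scores[scores$person_id %in% case_ids, ],
                                ref_case_scores)
  write_tsv_file(zt, file.path(out_dir, "domain_scores.tsv"))
  asg <- assign_subgroups(zt, delta = config$delta)
  write_tsv_file(asg[, c("person_id", "study", "label", "mean_score",
                         paste0("d_", .domains))],
                 file.path(out_dir, "assignments.tsv"))
  manifest <- .manifest_add(manifest, "subgroup", nrow(zt), nrow(asg))

  dist_test <- subgroup_distribution_test(asg, asg$study)
  carrier <- stats::setNames(covs$carrier, covs$person_id)[asg$person_id]
  apoe <- apoe_contingency(asg, carrier, study = asg$study)
  apoe_tab <- do.call(rbind, lapply(names(apoe), function(s) {
    data.frame(stratum = s, subgroup = subgroup_levels(),
               carriers = apoe[[s]]$carriers, n = apoe[[s]]$n,
               pct = apoe[[s]]$pct,
               chisq = apoe[[s]]$statistic, df = apoe[[s]]$df,
               p = apoe[[s]]$p, stringsAsFactors = FALSE)
  }))
  write_tsv_file(apoe_tab, file.path(out_dir, "apoe_contingency.tsv"))
  manifest <- .manifest_add(manifest, "apoe", nrow(asg), nrow(apoe_tab))
  manifest$results$distribution_chisq <- unname(dist_test$statistic)
  manifest$results$distribution_df <- unname(dist_test$df)
  manifest$results$apoe_overall_chisq <- unname(apoe$overall$statistic)
  manifest$results$apoe_overall_p <- unname(apoe$overall$p)

  # --- scan ------------------------------------------------------------------
  geno <- qc_filter(sim$genotypes, config$qc$maf_min, config$qc$info_min)
  label <- rep(NA_character_, nrow(covs))
  names(label) <- covs$person_id
  label[asg$person_id] <- as.character(asg$label)
  recs <- list()
  for (s in studies) {
    sel <- which(covs$study == s)
    g_s <- geno[sel, ]
    covar <- covs[sel, c("age", "sex")]
    if (config$n_pcs > 0) {
      pcs <- compute_pcs(g_s, config$n_pcs)
      covar <- cbind(covar, pcs)
    }
    recs[[s]] <- scan_subgroups(g_s, label[sel], covar, dataset = s,
                                min_cases = config$min_cases)
  }
  assoc <- do.call(rbind, c(recs, make.row.names = FALSE))
  write_tsv_file(assoc, file.path(out_dir, "associations.tsv"))
  manifest <- .manifest_add(manifest, "scan", ncol(geno$dosage),
                            nrow(assoc))

  # --- meta + select ----------------------------------------------------------
  meta <- meta_fixed(assoc)
  sel <- select_suggestive(meta, config$selection$p_threshold,
                           config$selection$or_low,
                           config$selection$or_high,
                           config$selection$excluded_chr)
  write_tsv_file(sel, file.path(out_dir, "meta.tsv"))
  hits <- sel[sel$selected, , drop = FALSE]
  write_tsv_file(hits, file.path(out_dir, "suggestive_loci.tsv"))
  manifest <- .manifest_add(manifest, "meta_select", nrow(assoc), nrow(sel))
  manifest$results$n_suggestive <- nrow(hits)

  # --- risk scores -------------------------------------------------------------
  # reference weights: overall case-control meta (in-sample; see docs)
  case_lab <- ifelse(covs$case == 1L, "case", "control")
  overall_recs <- do.call(rbind, c(lapply(studies, function(s) {
    sel_s <- which(covs$study == s)
    scan_subgroups(geno[sel_s, ], case_lab[sel_s],
                   covs[sel_s, c("age", "sex")], dataset = s,
                   min_cases = config$min_cases)
  }), make.row.names = FALSE))
  overall_meta <- meta_fixed(overall_recs)
  ref_w <- overall_meta[overall_meta$p < config$risk$reference_p &
                          is.finite(overall_meta$p), ]
  if (nrow(ref_w) == 0L)
    ref_w <- overall_meta[order(overall_meta$p), ][
      seq_len(min(config$risk$top_n, nrow(overall_meta))), ]
  make_weights <- function(m, src) data.frame(
    variant = m$variant, coded_allele = m$coded, weight = m$beta,
    source = src, stringsAsFactors = FALSE)
  weights <- make_weights(ref_w, "reference")
  sg_scanned <- setdiff(unique(assoc$subgroup), NA)
  sg_scores <- list()
  for (g in sg_scanned) {
    mg <- sel[sel$subgroup == g, , drop = FALSE]
    wg <- if (config$risk$subgroup_rule == "suggestive" &&
              any(mg$selected))
      mg[mg$selected, ] else mg[order(mg$p), ][
        seq_len(min(config$risk$top_n, nrow(mg))), ]
    weights <- rbind(weights, make_weights(wg, g))
    sg_scores[[g]] <- build_score(geno, make_weights(wg, g))$score
  }
  write_tsv_file(weights, file.path(out_dir, "weights.tsv"))
  ref_score <- build_score(geno, make_weights(ref_w, "reference"))$score
  score_tab <- data.frame(sample = rownames(geno$dosage),
                          reference = ref_score,
                          as.data.frame(sg_scores, check.names = FALSE))
  write_tsv_file(score_tab, file.path(out_dir, "risk_scores.tsv"))
  manifest <- .manifest_add(manifest, "riskscore", nrow(weights),
                            nrow(score_tab))

  # --- evaluate ---------------------------------------------------------------
  cmp <- fit_nested_models(covs$case, covs$age, covs$sex, ref_score,
                           as.data.frame(sg_scores, check.names = FALSE))
  base_pred <- stats::predict(cmp$base_fit, type = "link")
  sgdf <- as.data.frame(sg_scores)
  names(sgdf) <- make.names(names(sgdf))
  ext_sg <- stats::glm(
    stats::as.formula(paste("y ~ age + sex +",
                            paste(names(sgdf), collapse = " + "))),
    binomial(),
    data = cbind(data.frame(y = covs$case, age = covs$age,
                            sex = covs$sex), sgdf))
  roc <- roc_compare(covs$case, stats::predict(ext_sg, type = "link"),
                     base_pred)
  eval_out <- data.frame(
    metric = c("ll_base", "ll_extended", "lr", "df", "p",
               "pseudo_r2_base", "pseudo_r2_extended",
               "model_chisq_base", "model_chisq_extended",
               "auc_subgroup", "auc_reference", "delong_chi2", "delong_p"),
    value = c(cmp$ll_base, cmp$ll_extended, cmp$lr, cmp$df, cmp$p,
              cmp$pseudo_r2_base, cmp$pseudo_r2_extended,
              cmp$model_chisq_base, cmp$model_chisq_extended,
              roc$auc_a, roc$auc_b, roc$chi2, roc$p))
  write_tsv_file(eval_out, file.path(out_dir, "model_comparison.tsv"))
  manifest <- .manifest_add(manifest, "evaluate", nrow(score_tab),
                            nrow(eval_out))
  manifest$results$lr_stat <- cmp$lr
  manifest$results$lr_df <- cmp$df
  manifest$results$auc_reference <- roc$auc_b
  manifest$results$auc_subgroup <- roc$auc_a

  # --- manifest ----------------------------------------------------------------
  outs <- c("item_bank.tsv", "responses.tsv", "covariates.tsv",
            "genotypes.vcf", "truth.tsv", "scores.tsv",
            "domain_scores.tsv", "assignments.tsv", "apoe_contingency.tsv",
            "associations.tsv", "meta.tsv", "suggestive_loci.tsv",
            "weights.tsv", "risk_scores.tsv", "model_comparison.tsv")
  sums <- tools::md5sum(file.path(out_dir, outs))
  manifest$outputs <- as.list(stats::setNames(unname(sums), outs))
  cfg_file <- tempfile()
  yaml::write_yaml(config, cfg_file)
  manifest$config_hash <- unname(tools::md5sum(cfg_file))
  unlink(cfg_file)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
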