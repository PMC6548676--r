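# End-to-end recovery experiment: generate a cohort with planted subgroup
# structure, run the full measurement chain (calibration -> EAP scoring ->
# z-transform to the reference case sample -> classification), and join
# the resulting labels with the planted truth.

#' Simulate a cohort and classify it through the full measurement chain
#'
#' Runs [simulate_item_bank()] and [simulate_cohort()], fits the reference
#' study's graded-response models per domain, calibrates any further
#' studies onto the reference metric through their anchor items, computes
#' EAP domain scores, z-transforms case scores to the reference study's
#' case sample, and assigns subgroups. The returned table joins assigned
#' labels with planted truth, so classifier recovery can be measured
#' directly.
#'
#' @param config a [sim_config()].
#' @param delta impairment threshold passed to [assign_subgroups()].
#' @param reference_study study defining the metric (default the first).
#' @param n_quad quadrature nodes for calibration.
#' @return list: `assignments` (with `true_subgroup` column), `scores`
#'   (long EAP table), `truth`, `covariates`, `bank`.
#' @export
simulate_and_classify <- function(config, delta = 0.80,
                                  reference_study = NULL, n_quad = 49) {
  bank <- simulate_item_bank(config)
  co <- simulate_cohort(config, bank)
  studies <- unique(co$covariates$study)
  if (is.null(reference_study)) reference_study <- studies[1]
  score_rows <- list()
  for (d in .domains) {
    rs <- co$responses[co$responses$domain == d &
                         co$responses$study == reference_study, ]
    rm_ref <- responses_to_matrix(rs)
    fit_ref <- fit_grm(rm_ref, n_quad = n_quad,
                       items_meta = bank[bank$study == reference_study, ])
    sc <- score_eap(rm_ref, fit_ref$items)
    sc$study <- reference_study
    sc$domain <- d
    score_rows[[paste(reference_study, d)]] <- sc
    for (s in setdiff(studies, reference_study)) {
      rm_s <- responses_to_matrix(
        co$responses[co$responses$domain == d & co$responses$study == s, ])
      fit_s <- calibrate_with_anchors(rm_s, fit_ref$items, n_quad = n_quad)
      sc_s <- score_eap(rm_s, fit_s$items,
                        prior_mean = fit_s$latent_mean,
                        prior_var = fit_s$latent_var)
      sc_s$study <- s
      sc_s$domain <- d
      score_rows[[paste(s, d)]] <- sc_s
    }
  }
  scores <- do.call(rbind, c(score_rows, make.row.names = FALSE))
  case_ids <- co$covariates$person_id[co$covariates$case == 1L]
  ref_cases <- scores[scores$study == reference_study &
                        scores$person_id %in% case_ids, ]
  zt <- ztransform_to_reference(scores[scores$person_id %in% case_ids, ],
                                ref_cases)
  asg <- assign_subgroups(zt, delta = delta)
  asg$true_subgroup <- co$truth$subgroup[match(asg$person_id,
                                               co$truth$person_id)]
  list(assignments = asg, scores = scores, truth = co$truth,
       covariates = co$covariates, bank = bank)
}
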