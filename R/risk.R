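# Weighted allele scores and nested-model evaluation: genetic risk scores
# are per-sample sums of coded-allele dosages weighted by per-variant
# log-ORs; model value is judged by a 5-df likelihood ratio test and a
# paired DeLong comparison of ROC curves.

.ambiguous_pair <- function(a, b) {
  p <- paste0(toupper(a), toupper(b))
  p %in% c("AT", "TA", "CG", "GC")
}

#' Build a weighted allele (genetic risk) score
#'
#' `score_s = sum_j w_j * dose_j(coded allele)` over the variants shared by
#' the weight table and the genotype matrix. When the weight table's coded
#' allele is the genotype matrix's other allele, the dose is flipped
#' (`2 - g`); strand-ambiguous variants (A/T, C/G) are dropped by default
#' since their alignment is unresolvable from allele labels alone.
#'
#' @param genotypes a [genotype_matrix()].
#' @param weights data frame: `variant`, `coded_allele`, `weight` (log-OR
#'   per coded-allele dose), optional `other_allele` and `source`.
#' @param drop_ambiguous drop A/T and C/G variants (default TRUE).
#' @return data frame: `sample`, `source`, `score`, `n_variants`;
#'   attribute `"used_variants"` lists contributing variant ids, and
#'   `"dropped"` the excluded ones with reasons.
#' @export
build_score <- function(genotypes, weights, drop_ambiguous = TRUE) {
  v <- genotypes$variants
  m <- match(weights$variant, v$id)
  present <- !is.na(m)
  dropped <- data.frame(variant = character(0), reason = character(0),
                        stringsAsFactors = FALSE)
  if (any(!present))
    dropped <- rbind(dropped,
                     data.frame(variant = weights$variant[!present],
                                reason = "absent", stringsAsFactors = FALSE))
  w <- weights[present, , drop = FALSE]
  vi <- m[present]
  keep <- rep(TRUE, nrow(w))
  sign_flip <- rep(FALSE, nrow(w))
  for (i in seq_len(nrow(w))) {
    ca <- w$coded_allele[i]
    if (drop_ambiguous && .ambiguous_pair(v$coded[vi[i]], v$other[vi[i]])) {
      keep[i] <- FALSE
      dropped <- rbind(dropped, data.frame(variant = w$variant[i],
                                           reason = "strand_ambiguous",
                                           stringsAsFactors = FALSE))
    } else if (ca == v$coded[vi[i]]) {
      # aligned
    } else if (ca == v$other[vi[i]]) {
      sign_flip[i] <- TRUE
    } else {
      keep[i] <- FALSE
      dropped <- rbind(dropped, data.frame(variant = w$variant[i],
                                           reason = "allele_mismatch",
                                           stringsAsFactors = FALSE))
    }
  }
  w <- w[keep, , drop = FALSE]
  vi <- vi[keep]
  sign_flip <- sign_flip[keep]
  if (nrow(w) == 0L)
    stop("no usable variants shared by weights and genotypes")
  G <- genotypes$dosage[, vi, drop = FALSE]
  if (any(sign_flip))
    G[, sign_flip] <- 2 - G[, sign_flip]
  score <- as.numeric(G %*% w$weight)
  src <- if (!is.null(w$source)) w$source[1L] else "score"
  out <- data.frame(sample = rownames(genotypes$dosage), source = src,
                    score = score, n_variants = nrow(w),
                    stringsAsFactors = FALSE)
  attr(out, "used_variants") <- w$variant
  attr(out, "dropped") <- dropped
  out
}

.mcfadden <- function(ll, ll_null) 1 - ll / ll_null

#' Compare nested risk-score logistic models by likelihood ratio
#'
#' Fits a base model `case ~ age + sex + reference score` and an extended
#' model adding the subgroup scores, and reports the likelihood ratio
#' statistic (df = number of added, non-aliased terms — 5 when all five
#' subgroup scores enter), McFadden pseudo-R-squared for both models
#' (relative to the intercept-only fit), and each model's chi-square
#' against the null.
#'
#' @param outcome 0/1 case status.
#' @param age,sex covariates.
#' @param score_reference reference (e.g. external case-control GWAS)
#'   risk score per sample.
#' @param scores_subgroup matrix or data frame of subgroup risk scores
#'   (one column per subgroup, typically 5).
#' @return object of class `model_comparison`: log-likelihoods, `lr`,
#'   `df`, `p`, pseudo-R-squared values, model chi-squares, and
#'   `collinear` flag (TRUE when added terms were aliased and dropped).
#' @export
fit_nested_models <- function(outcome, age, sex, score_reference,
                              scores_subgroup) {
  y <- as.integer(as.logical(outcome))
  S <- as.matrix(scores_subgroup)
  if (is.null(colnames(S))) colnames(S) <- paste0("sg", seq_len(ncol(S)))
  colnames(S) <- make.names(colnames(S))
  dat <- data.frame(y = y, age = age, sex = sex, ref = score_reference)
  dat <- cbind(dat, as.data.frame(S))
  cc <- stats::complete.cases(dat)
  dat <- dat[cc, , drop = FALSE]
  null_fit <- stats::glm(y ~ 1, binomial(), data = dat)
  base_fit <- stats::glm(y ~ age + sex + ref, binomial(), data = dat)
  ext_fit <- stats::glm(
    stats::as.formula(paste("y ~ age + sex + ref +",
                            paste(colnames(S), collapse = " + "))),
    binomial(), data = dat)
  if (!base_fit$converged) stop("base model did not converge")
  if (!ext_fit$converged) stop("extended model did not converge")
  ll0 <- as.numeric(stats::logLik(null_fit))
  llb <- as.numeric(stats::logLik(base_fit))
  lle <- as.numeric(stats::logLik(ext_fit))
  aliased <- names(which(is.na(stats::coef(ext_fit))))
  df <- ncol(S) - sum(aliased %in% colnames(S))
  lr <- max(2 * (lle - llb), 0)
  structure(list(
    ll_null = ll0, ll_base = llb, ll_extended = lle,
    lr = lr, df = df,
    p = stats::pchisq(lr, df, lower.tail = FALSE),
    pseudo_r2_base = .mcfadden(llb, ll0),
    pseudo_r2_extended = .mcfadden(lle, ll0),
    model_chisq_base = 2 * (llb - ll0),
    model_chisq_extended = 2 * (lle - ll0),
    pseudo_r2_type = "McFadden",
    collinear = length(aliased) > 0,
    aliased = aliased,
    n = nrow(dat),
    base_fit = base_fit, ext_fit = ext_fit), class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("Nested logistic models (n = %d)\n", x$n))
  cat(sprintf("  base:     logLik %.3f, chi-square %.2f, McFadden R2 %.4f\n",
              x$ll_base, x$model_chisq_base, x$pseudo_r2_base))
  cat(sprintf("  extended: logLik %.3f, chi-square %.2f, McFadden R2 %.4f\n",
              x$ll_extended, x$model_chisq_extended, x$pseudo_r2_extended))
  cat(sprintf("  LR = %.3f on %d df, p = %.3g%s\n", x$lr, x$df, x$p,
              if (x$collinear) " [collinear terms dropped]" else ""))
  invisible(x)
}

# midrank placement values (DeLong components)
.placements <- function(pred, y) {
  cases <- pred[y == 1L]
  controls <- pred[y == 0L]
  m <- length(cases); n <- length(controls)
  r_all <- rank(c(cases, controls), ties.method = "average")
  v10 <- (r_all[seq_len(m)] - rank(cases, ties.method = "average")) / n
  v01 <- 1 - (r_all[m + seq_len(n)] -
                rank(controls, ties.method = "average")) / m
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' AUC as the Mann-Whitney statistic
#'
#' Proportion of case-control pairs where the case's predictor exceeds the
#' control's, ties counted one half.
#'
#' @param pred numeric predictor.
#' @param outcome 0/1 outcome; both classes must be present.
#' @return scalar AUC in `[0, 1]`.
#' @export
auc_mw <- function(pred, outcome) {
  y <- as.integer(as.logical(outcome))
  if (length(unique(y)) < 2L) stop("both outcome classes must be present")
  .placements(pred, y)$auc
}

#' Paired comparison of two ROC curves by the DeLong method
#'
#' Computes both AUCs as Mann-Whitney statistics, their DeLong variances
#' and covariance from placement values, and the paired difference test
#' reported as a chi-square with 1 df. Two identical predictors give a
#' zero statistic by convention (the difference and its variance are both
#' exactly zero).
#'
#' @param outcome 0/1 outcome, both classes present.
#' @param predictor_a,predictor_b predictors on the same samples.
#' @return object of class `roc_comparison`: `auc_a`, `auc_b`, 95% CIs,
#'   `chi2` (df = 1), `p`.
#' @export
roc_compare <- function(outcome, predictor_a, predictor_b) {
  y <- as.integer(as.logical(outcome))
  stopifnot(length(predictor_a) == length(y),
            length(predictor_b) == length(y))
  if (length(unique(y)) < 2L) stop("both outcome classes must be present")
  pa <- .placements(predictor_a, y)
  pb <- .placements(predictor_b, y)
  m <- sum(y == 1L); n <- sum(y == 0L)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  S <- s10 / m + s01 / n
  dauc <- pa$auc - pb$auc
  vd <- S[1, 1] + S[2, 2] - 2 * S[1, 2]
  if (abs(dauc) < 1e-12 && vd < 1e-12) {
    chi2 <- 0; p <- 1
  } else {
    chi2 <- dauc^2 / vd
    p <- stats::pchisq(chi2, 1, lower.tail = FALSE)
  }
  ci <- function(auc, var) {
    hw <- stats::qnorm(0.975) * sqrt(max(var, 0))
    c(max(0, auc - hw), min(1, auc + hw))
  }
  structure(list(auc_a = pa$auc, auc_b = pb$auc,
                 ci_a = ci(pa$auc, S[1, 1]), ci_b = ci(pb$auc, S[2, 2]),
                 chi2 = chi2, df = 1L, p = p, var_diff = vd),
            class = "roc_comparison")
}

#' @export
print.roc_comparison <- function(x, ...) {
  cat(sprintf("AUC A = %.4f (%.3f, %.3f); AUC B = %.4f (%.3f, %.3f)\n",
              x$auc_a, x$ci_a[1], x$ci_a[2], x$auc_b, x$ci_b[1],
              x$ci_b[2]))
  cat(sprintf("DeLong paired test: chi-square = %.3f (df = 1), p = %.3g\n",
              x$chi2, x$p))
  invisible(x)
}
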