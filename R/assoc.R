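# Case-subgroup vs shared-control association: additive-dosage logistic
# regression per variant with covariate adjustment, METAL-style
# inverse-variance fixed-effect meta-analysis, and extreme-OR
# suggestive-locus selection.

#' Construct a genotype matrix container
#'
#' @param dosage samples x variants numeric matrix of additive dosages in
#'   `[0, 2]`; rownames are sample ids, colnames variant ids.
#' @param variants data frame, one row per variant: `id`, `chr`, `pos`,
#'   `coded`, `other`, `caf` (coded-allele frequency), `info` (imputation
#'   quality score).
#' @return object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosage, variants) {
  stopifnot(is.matrix(dosage), ncol(dosage) == nrow(variants),
            all(c("id", "chr", "pos", "coded", "other", "caf", "info") %in%
                  names(variants)))
  if (anyDuplicated(variants$id)) stop("duplicate variant ids")
  if (any(dosage < -1e-9 | dosage > 2 + 1e-9, na.rm = TRUE))
    stop("dosages must lie in [0, 2]")
  colnames(dosage) <- variants$id
  structure(list(dosage = dosage, variants = variants,
                 samples = rownames(dosage)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$dosage), "samples x", ncol(x$dosage),
      "variants\n")
  invisible(x)
}

#' @export
`[.genotype_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$dosage))
  if (missing(j)) j <- seq_len(nrow(x$variants))
  genotype_matrix(x$dosage[i, j, drop = FALSE],
                  x$variants[j, , drop = FALSE])
}

#' Variant quality-control filter
#'
#' Excludes variants with minor allele frequency below `maf_min` or
#' imputation info score below `info_min`. The exclusion rules are strict
#' `<`, so variants exactly at a threshold are retained.
#'
#' @param genotypes a [genotype_matrix()].
#' @param maf_min minimum minor allele frequency (default 0.03).
#' @param info_min minimum info score (default 0.5).
#' @return filtered `genotype_matrix`; attribute `"exclusions"` is a data
#'   frame of removed variants with reason codes.
#' @export
qc_filter <- function(genotypes, maf_min = 0.03, info_min = 0.5) {
  v <- genotypes$variants
  maf <- pmin(v$caf, 1 - v$caf)
  low_maf <- maf < maf_min
  low_info <- v$info < info_min
  drop <- low_maf | low_info
  excl <- data.frame(id = v$id[drop],
                     reason = ifelse(low_maf[drop] & low_info[drop],
                                     "low_maf;low_info",
                                     ifelse(low_maf[drop], "low_maf",
                                            "low_info")),
                     stringsAsFactors = FALSE)
  out <- genotypes[, which(!drop)]
  attr(out, "exclusions") <- excl
  out
}

#' Principal components of the standardized dosage matrix
#'
#' Column-standardizes dosages (zero-variance variants dropped) and returns
#' the leading principal component scores, for use as population-structure
#' covariates. Sign convention: the largest-magnitude loading of each
#' component is positive.
#'
#' @param genotypes a [genotype_matrix()].
#' @param k number of components (`k = 0` gives a zero-column frame).
#' @return data frame of `PC1..PCk` scores, rownames = sample ids.
#' @export
compute_pcs <- function(genotypes, k) {
  X <- genotypes$dosage
  if (k == 0L)
    return(as.data.frame(matrix(numeric(0), nrow(X), 0),
                         row.names = rownames(X)))
  sds <- apply(X, 2L, stats::sd)
  X <- X[, sds > 0, drop = FALSE]
  if (nrow(X) < k + 1L || ncol(X) < k)
    stop("need more samples/variants than components")
  Xs <- scale(X)
  pc <- stats::prcomp(Xs, center = FALSE, scale. = FALSE, rank. = k)
  scores <- pc$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i, j] < 0) scores[, j] <- -scores[, j]
  }
  out <- as.data.frame(scores)
  names(out) <- paste0("PC", seq_len(k))
  rownames(out) <- rownames(X)
  out
}

#' Per-variant logistic association scan
#'
#' Fits, for each variant, `outcome ~ dosage + covariates` by logistic
#' regression (IRLS) and reports the Wald test on the dosage coefficient —
#' the standard additive-model scan. Rows with incomplete covariates are
#' dropped (logged); non-converged or separated fits are flagged with `NA`
#' statistics rather than fabricated values.
#'
#' @param genotypes a [genotype_matrix()].
#' @param outcome 0/1 (or logical) case status per sample.
#' @param covariates optional data frame of adjustment covariates (e.g.
#'   age, sex, PCs), aligned with samples.
#' @param dataset,subgroup labels copied into the output records.
#' @return data frame of association records: `variant`, `chr`, `pos`,
#'   `coded`, `other`, `caf`, `info`, `beta`, `se`, `or`, `z`, `p`,
#'   `n_cases`, `n_controls`, `converged`, `dataset`, `subgroup`.
#' @export
logistic_scan <- function(genotypes, outcome, covariates = NULL,
                          dataset = "dataset1", subgroup = NA_character_) {
  y <- as.integer(as.logical(outcome))
  X <- genotypes$dosage
  stopifnot(length(y) == nrow(X))
  keep <- !is.na(y)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    stopifnot(nrow(covariates) == nrow(X))
    keep <- keep & stats::complete.cases(covariates)
  }
  n_dropped <- sum(!keep)
  y <- y[keep]
  X <- X[keep, , drop = FALSE]
  if (length(unique(y)) < 2L)
    stop("outcome is constant: need >= 1 case and >= 1 control")
  cmat <- if (!is.null(covariates) && ncol(covariates) > 0)
    stats::model.matrix(~ ., covariates[keep, , drop = FALSE])[, -1,
                                                               drop = FALSE]
  else NULL
  v <- genotypes$variants
  n1 <- sum(y == 1L)
  n0 <- sum(y == 0L)
  out <- vector("list", ncol(X))
  for (j in seq_len(ncol(X))) {
    g <- X[, j]
    dm <- if (is.null(cmat)) cbind(g = g) else cbind(g = g, cmat)
    fit <- tryCatch(
      suppressWarnings(stats::glm.fit(cbind(1, dm), y,
                                      family = stats::binomial(),
                                      control = stats::glm.control(
                                        epsilon = 1e-12, maxit = 100))),
      error = function(e) NULL)
    beta <- se <- z <- p <- NA_real_
    conv <- FALSE
    if (!is.null(fit) && fit$converged && !any(is.na(fit$coefficients))) {
      # Wald SE from the IRLS weighted cross-product
      W <- fit$weights
      XtWX <- crossprod(cbind(1, dm) * sqrt(W))
      cov <- tryCatch(solve(XtWX), error = function(e) NULL)
      if (!is.null(cov)) {
        beta <- fit$coefficients[2L]
        se <- sqrt(cov[2L, 2L])
        # separation heuristic: runaway coefficient or SE
        if (is.finite(beta) && is.finite(se) && abs(beta) < 15 && se < 10) {
          z <- beta / se
          p <- 2 * stats::pnorm(-abs(z))
          conv <- TRUE
        } else beta <- se <- NA_real_
      }
    }
    out[[j]] <- data.frame(
      variant = v$id[j], chr = v$chr[j], pos = v$pos[j],
      coded = v$coded[j], other = v$other[j], caf = v$caf[j],
      info = v$info[j], beta = beta, se = se, or = exp(beta), z = z, p = p,
      n_cases = n1, n_controls = n0, converged = conv,
      dataset = dataset, subgroup = subgroup, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "n_dropped_rows") <- n_dropped
  res
}

#' Scan every subgroup against the shared control pool
#'
#' Convenience wrapper: for each subgroup with at least `min_cases` cases,
#' runs [logistic_scan()] of that subgroup's cases versus all controls.
#'
#' @param genotypes a [genotype_matrix()].
#' @param label subgroup label per sample (`NA` or `"control"` = control).
#' @param covariates optional covariate data frame.
#' @param dataset dataset label.
#' @param min_cases minimum subgroup size to scan (default 30).
#' @return row-bound association records across subgroups.
#' @export
scan_subgroups <- function(genotypes, label, covariates = NULL,
                           dataset = "dataset1", min_cases = 30L) {
  is_control <- is.na(label) | label == "control"
  res <- list()
  for (g in setdiff(unique(label[!is_control]), NA)) {
    sel <- is_control | label == g
    n_cases <- sum(label == g, na.rm = TRUE)
    if (n_cases < min_cases) next
    res[[g]] <- logistic_scan(
      genotypes[which(sel), ],
      outcome = (label == g)[sel] & !is.na(label[sel]),
      covariates = if (!is.null(covariates))
        covariates[sel, , drop = FALSE],
      dataset = dataset, subgroup = g)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

# Align records of one variant to the first dataset's coded allele.
# Returns records with beta/caf flipped where coded/other are swapped;
# NULL when unresolvable.
.align_alleles <- function(rec) {
  if (is.null(rec$coded) || is.null(rec$other)) return(rec)
  ref_coded <- rec$coded[1L]
  ref_other <- rec$other[1L]
  for (i in seq_len(nrow(rec))[-1]) {
    if (rec$coded[i] == ref_coded && rec$other[i] == ref_other) next
    if (rec$coded[i] == ref_other && rec$other[i] == ref_coded) {
      rec$beta[i] <- -rec$beta[i]
      rec$caf[i] <- 1 - rec$caf[i]
      rec$coded[i] <- ref_coded
      rec$other[i] <- ref_other
    } else return(NULL)
  }
  rec
}

#' Inverse-variance fixed-effect meta-analysis
#'
#' METAL-style pooling of per-dataset association records within each
#' variant x subgroup pair: weights `w_i = 1/se_i^2`, pooled
#' `beta = sum(w b)/sum(w)`, pooled `se = 1/sqrt(sum w)`; Cochran's
#' `Q = sum w (b - pooled)^2` with heterogeneity p from a chi-square on
#' k - 1 df, `I2 = max(0, (Q - (k-1))/Q) * 100`, and a per-dataset sign
#' direction string. Coded alleles are aligned across datasets by flipping
#' the effect sign; unresolvable allele mismatches drop the variant with a
#' log entry.
#'
#' @param records association records from [logistic_scan()] across
#'   datasets (non-converged records are ignored).
#' @return data frame of meta records: `variant`, `subgroup`, `chr`,
#'   `pos`, `beta`, `se`, `or`, `z`, `p`, `Q`, `het_p`, `i2`,
#'   `direction`, `k`; attribute `"dropped"` lists unresolvable variants.
#' @export
meta_fixed <- function(records) {
  if (!is.null(records$converged))
    records <- records[records$converged %in% TRUE, , drop = FALSE]
  records <- records[is.finite(records$beta) & is.finite(records$se) &
                       records$se > 0, , drop = FALSE]
  key <- interaction(records$variant, records$subgroup, drop = TRUE)
  dropped <- character(0)
  rows <- lapply(split(records, key), function(rec) {
    vid <- rec$variant[1L]
    rec <- .align_alleles(rec)
    if (is.null(rec)) {
      dropped <<- c(dropped, vid)
      return(NULL)
    }
    w <- 1 / rec$se^2
    beta <- sum(w * rec$beta) / sum(w)
    se <- 1 / sqrt(sum(w))
    z <- beta / se
    k <- nrow(rec)
    Q <- sum(w * (rec$beta - beta)^2)
    het_p <- if (k > 1L) stats::pchisq(Q, k - 1L, lower.tail = FALSE)
             else NA_real_
    i2 <- if (k > 1L && Q > 0) max(0, (Q - (k - 1L)) / Q) * 100 else 0
    data.frame(variant = rec$variant[1L], subgroup = rec$subgroup[1L],
               chr = rec$chr[1L], pos = rec$pos[1L],
               coded = rec$coded[1L], other = rec$other[1L],
               beta = beta, se = se, or = exp(beta), z = z,
               p = 2 * stats::pnorm(-abs(z)),
               Q = if (k > 1L) Q else NA_real_, het_p = het_p, i2 = i2,
               direction = paste(ifelse(rec$beta >= 0, "+", "-"),
                                 collapse = ""),
               k = k, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(variant = character(0), subgroup = character(0),
                      chr = character(0), pos = numeric(0),
                      coded = character(0), other = character(0),
                      beta = numeric(0), se = numeric(0), or = numeric(0),
                      z = numeric(0), p = numeric(0), Q = numeric(0),
                      het_p = numeric(0), i2 = numeric(0),
                      direction = character(0), k = integer(0),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  out
}

#' Select suggestive loci with extreme odds ratios
#'
#' Flags meta-analysis records with `p < p_threshold` and pooled OR outside
#' `[or_low, or_high]` (strict inequalities), excluding a region dominated
#' by known signals (default: all of chromosome 19, the APOE region). The
#' default OR window is `0.77` to `1/0.77`, the most extreme odds ratio
#' reported outside chromosome 19 by the large reference case-control
#' meta-analysis (IGAP) and its reciprocal. Replication support (all
#' contributing datasets with the same effect direction) is annotated.
#'
#' @param meta meta records from [meta_fixed()].
#' @param p_threshold suggestive p-value threshold (default `1e-5`).
#' @param or_low,or_high OR selection window bounds.
#' @param excluded_chr chromosome(s) excluded from selection.
#' @return `meta` with logical columns `p_pass`, `or_pass`,
#'   `region_excluded`, `selected`, `same_direction`.
#' @export
select_suggestive <- function(meta, p_threshold = 1e-5, or_low = 0.77,
                              or_high = 1 / 0.77, excluded_chr = "19") {
  meta$p_pass <- !is.na(meta$p) & meta$p < p_threshold
  meta$or_pass <- !is.na(meta$or) & (meta$or < or_low | meta$or > or_high)
  meta$region_excluded <- as.character(meta$chr) %in%
    as.character(excluded_chr)
  meta$selected <- meta$p_pass & meta$or_pass & !meta$region_excluded
  nplus <- nchar(gsub("-", "", meta$direction))
  meta$same_direction <- nplus == 0L | nplus == meta$k
  meta
}

#' Compare a subgroup effect with a published reference odds ratio
#'
#' Reconstructs the reference standard error from its confidence interval,
#' `se_ref = (log(ci_high) - log(ci_low)) / (2 * 1.959964)`, and tests the
#' difference of log odds ratios: `z = (beta - log(ref_or)) /
#' sqrt(se^2 + se_ref^2)` with a two-sided normal p-value.
#'
#' @param beta,se subgroup log-OR and its standard error.
#' @param ref_or,ref_ci_low,ref_ci_high published OR and 95% CI bounds.
#' @return list with `z`, `p`, `se_ref`.
#' @export
compare_to_reference <- function(beta, se, ref_or, ref_ci_low,
                                 ref_ci_high) {
  if (ref_ci_low <= 0 || ref_ci_high <= 0)
    stop("reference CI bounds must be positive")
  if (ref_ci_low > ref_or || ref_ci_high < ref_or)
    stop("reference CI does not bracket the reference OR")
  se_ref <- (log(ref_ci_high) - log(ref_ci_low)) / (2 * 1.959964)
  z <- (beta - log(ref_or)) / sqrt(se^2 + se_ref^2)
  list(z = z, p = 2 * stats::pnorm(-abs(z)), se_ref = se_ref)
}
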