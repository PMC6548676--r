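# Six-way cognitively defined subgroup assignment: relative impairment of a
# domain means its co-calibrated score falls at least `delta` SD units below
# the person's own mean across the four domains.

.domains <- c("memory", "executive", "language", "visuospatial")

#' Assign cognitively defined subgroups from domain scores
#'
#' For each person, the mean of the four domain scores is computed and the
#' per-domain deviations from that mean. A domain is substantially
#' relatively impaired when its deviation is `<= -delta` (inclusive).
#' People are labelled by the count of impaired domains: none ->
#' `"no-domain"`, exactly one -> that domain's label, two or more ->
#' `"multiple"` — six potential subgroups.
#'
#' @param scores data frame with `person_id` and the four domain score
#'   columns `memory`, `executive`, `language`, `visuospatial` (reference
#'   SD units); other columns (e.g. `study`) are carried through.
#' @param delta impairment threshold in SD units (> 0); default 0.80.
#' @return data frame: carried-through identifiers, `label` (factor with
#'   the six levels), `mean_score`, `d_memory` .. `d_visuospatial`, and
#'   `delta`. Persons with any missing domain score are excluded; the
#'   excluded rows (with reasons) are in attribute `"excluded"`.
#' @export
assign_subgroups <- function(scores, delta = 0.80) {
  if (!is.numeric(delta) || length(delta) != 1L || !is.finite(delta) ||
      delta <= 0)
    stop("delta must be a single positive number")
  miss <- setdiff(.domains, names(scores))
  if (length(miss))
    stop("missing domain score column(s): ", paste(miss, collapse = ", "))
  sm <- as.matrix(scores[, .domains])
  ok <- apply(sm, 1L, function(r) all(is.finite(r)))
  excluded <- scores[!ok, , drop = FALSE]
  if (nrow(excluded)) excluded$reason <- "incomplete_domain_scores"
  scores <- scores[ok, , drop = FALSE]
  sm <- sm[ok, , drop = FALSE]

  mean_score <- rowMeans(sm)
  dev <- sm - mean_score
  impaired <- dev <= -delta
  n_imp <- rowSums(impaired)
  label <- character(nrow(sm))
  label[n_imp == 0L] <- "no-domain"
  label[n_imp >= 2L] <- "multiple"
  single <- which(n_imp == 1L)
  if (length(single))
    label[single] <- .domains[apply(impaired[single, , drop = FALSE], 1L,
                                    which)]
  out <- scores[, setdiff(names(scores), .domains), drop = FALSE]
  out$label <- factor(label, levels = subgroup_levels())
  out$mean_score <- mean_score
  colnames(dev) <- paste0("d_", .domains)
  out <- cbind(out, as.data.frame(dev))
  out$delta <- delta
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}

#' The six subgroup labels, in canonical order
#' @return character vector of length 6.
#' @export
subgroup_levels <- function() {
  c("no-domain", "memory", "executive", "language", "visuospatial",
    "multiple")
}

#' Sensitivity sweep over the impairment threshold
#'
#' Re-runs subgroup assignment over a grid of thresholds and summarizes,
#' per threshold, the subgroup proportions and the carrier-enrichment
#' contrast (memory-subgroup carrier percentage minus overall carrier
#' percentage). Used to check that carrier enrichment in the memory
#' subgroup is not an artifact of the particular threshold.
#'
#' @param scores as for [assign_subgroups()].
#' @param deltas positive, sorted thresholds; default `seq(0.5, 1.2, 0.1)`.
#' @param carrier logical/0-1 carrier status, aligned with `scores` rows.
#' @return data frame with one row per delta: proportions per subgroup,
#'   `memory_carrier_pct`, `overall_carrier_pct`, `enrichment_contrast`
#'   (NA with `contrast_defined = FALSE` when the memory subgroup is
#'   empty).
#' @export
threshold_sweep <- function(scores, deltas = seq(0.5, 1.2, by = 0.1),
                            carrier) {
  stopifnot(all(deltas > 0), !is.unsorted(deltas))
  carrier <- as.logical(carrier)
  stopifnot(length(carrier) == nrow(scores))
  rows <- lapply(deltas, function(d) {
    asg <- assign_subgroups(scores, delta = d)
    ok <- apply(as.matrix(scores[, .domains]), 1L,
                function(r) all(is.finite(r)))
    carr <- carrier[ok]
    prop <- as.numeric(prop.table(table(asg$label)))
    mem <- asg$label == "memory"
    overall_pct <- 100 * mean(carr)
    mem_pct <- if (any(mem)) 100 * mean(carr[mem]) else NA_real_
    data.frame(delta = d,
               t(stats::setNames(prop, paste0("p_", subgroup_levels()))),
               memory_carrier_pct = mem_pct,
               overall_carrier_pct = overall_pct,
               enrichment_contrast = mem_pct - overall_pct,
               contrast_defined = any(mem), check.names = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Pearson chi-square on a count table after dropping all-zero rows/columns;
# no continuity correction.
.pearson_chisq <- function(tab, warn_drop = TRUE) {
  tab <- as.matrix(tab)
  zr <- rowSums(tab) == 0
  zc <- colSums(tab) == 0
  if (any(zr) || any(zc)) {
    if (warn_drop)
      warning("dropping all-zero row(s)/column(s); df adjusted")
    tab <- tab[!zr, !zc, drop = FALSE]
  }
  if (nrow(tab) < 2L || ncol(tab) < 2L)
    return(list(statistic = NA_real_, df = NA_integer_, p = NA_real_,
                table = tab))
  expd <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - expd)^2 / expd)
  df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
  list(statistic = stat, df = df, p = stats::pchisq(stat, df,
                                                    lower.tail = FALSE),
       table = tab)
}

#' Test heterogeneity of subgroup proportions across studies
#'
#' Pearson chi-square on the study x subgroup count table, with all-zero
#' rows/columns dropped (df adjusted) — e.g. five studies with all six
#' subgroups present give df = 20.
#'
#' @param assignments output of [assign_subgroups()] or a vector of labels.
#' @param study study label per person.
#' @return list of class `contingency_result`: `table`, `row_pct`,
#'   `statistic`, `df`, `p`, `empty`.
#' @export
subgroup_distribution_test <- function(assignments, study) {
  label <- if (is.data.frame(assignments)) assignments$label else assignments
  stopifnot(length(label) == length(study))
  if (length(unique(study)) < 2L) stop("need >= 2 studies")
  tab <- table(study = study, subgroup = factor(label,
                                                levels = subgroup_levels()))
  res <- .pearson_chisq(tab)
  structure(list(table = tab, row_pct = 100 * prop.table(tab, 1L),
                 statistic = res$statistic, df = res$df, p = res$p,
                 empty = colnames(tab)[colSums(tab) == 0]),
            class = "contingency_result")
}

#' Carrier-status contingency analysis by subgroup
#'
#' Per study (and overall), counts and percentages of carriers (e.g. of at
#' least one APOE e4 allele) per subgroup, with a Pearson chi-square across
#' subgroups. Empty subgroups are dropped from the test so the degrees of
#' freedom equal (non-empty subgroups - 1); a study missing one subgroup
#' yields df = 4 rather than 5.
#'
#' @param assignments output of [assign_subgroups()] (needs `label`).
#' @param carrier logical/0-1 carrier status per person.
#' @param study optional study label per person.
#' @param by_study compute per-study results in addition to overall.
#' @return list of `contingency_result` objects, one per stratum plus
#'   `"overall"`; each carries `carriers`, `n`, `pct` per subgroup.
#' @export
apoe_contingency <- function(assignments, carrier, study = NULL,
                             by_study = !is.null(study)) {
  label <- if (is.data.frame(assignments)) assignments$label else assignments
  carrier <- as.integer(as.logical(carrier))
  stopifnot(length(carrier) == length(label))
  one <- function(lab, carr) {
    lab <- factor(lab, levels = subgroup_levels())
    n <- as.integer(table(lab))
    carriers <- as.integer(tapply(carr, lab, sum, default = 0L))
    tab <- rbind(carrier = carriers, noncarrier = n - carriers)
    colnames(tab) <- subgroup_levels()
    nonempty <- n > 0L
    if (sum(nonempty) < 2L) {
      warning("fewer than two non-empty subgroups; test skipped")
      res <- list(statistic = NA_real_, df = NA_integer_, p = NA_real_)
    } else {
      res <- .pearson_chisq(t(tab[, nonempty, drop = FALSE]),
                            warn_drop = FALSE)
    }
    structure(list(table = tab, carriers = carriers, n = n,
                   pct = ifelse(n > 0, 100 * carriers / n, NA_real_),
                   statistic = res$statistic, df = res$df, p = res$p,
                   empty = subgroup_levels()[!nonempty]),
              class = "contingency_result")
  }
  out <- list()
  if (by_study) {
    for (s in unique(study))
      out[[as.character(s)]] <- one(label[study == s], carrier[study == s])
  }
  out$overall <- one(label, carrier)
  out
}

#' @export
print.contingency_result <- function(x, ...) {
  print(x$table)
  if (is.finite(x$statistic))
    cat(sprintf("Pearson chi-square = %.3f, df = %d, p = %.3g\n",
                x$statistic, x$df, x$p))
  else cat("test not computed\n")
  invisible(x)
}
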