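# Fixed-anchor co-calibration: anchor items carry the reference metric into
# each new study; the study's latent mean and variance are estimated freely
# along with its non-anchor item parameters.

#' Calibrate a study onto the reference metric via fixed anchor items
#'
#' Anchor item parameters are held fixed at their reference estimates; all
#' other item parameters plus the study's latent mean and variance are
#' estimated by marginal ML. Scores computed from the resulting parameters
#' (with the estimated latent distribution as prior) are on the reference
#' metric.
#'
#' @param study_responses persons x items integer matrix for one study.
#' @param reference_params item table holding reference estimates; rows with
#'   `anchor == TRUE` (or listed in `anchor_ids`) are the anchors.
#' @param anchor_ids optional explicit anchor item ids; defaults to the
#'   `anchor` flag in `reference_params`.
#' @inheritParams fit_grm
#' @return `grm_fit` with anchors bit-identical to the reference input and
#'   `latent_mean` / `latent_var` estimated for the study.
#' @export
calibrate_with_anchors <- function(study_responses, reference_params,
                                   anchor_ids = NULL, n_quad = 49,
                                   max_iter = 500, tol = 1e-6,
                                   quad_range = c(-6, 6),
                                   min_cat_count = 5L) {
  if (is.null(anchor_ids)) {
    if (is.null(reference_params$anchor))
      stop("no anchor flag in reference parameters and no anchor_ids given")
    anchor_ids <- reference_params$item_id[reference_params$anchor %in% TRUE]
  }
  anchors <- intersect(anchor_ids, colnames(study_responses))
  if (length(anchors) == 0L)
    stop("no anchor items present in study data: metric unidentified")
  miss <- setdiff(anchors, reference_params$item_id)
  if (length(miss))
    stop("reference parameters missing for anchor(s): ",
         paste(miss, collapse = ", "))
  fixed <- reference_params[reference_params$item_id %in% anchors, ,
                            drop = FALSE]
  fit <- fit_grm(study_responses, n_quad = n_quad, max_iter = max_iter,
                 tol = tol, quad_range = quad_range,
                 estimate_latent = TRUE, fixed_items = fixed,
                 items_meta = reference_params, min_cat_count = min_cat_count)
  fit$anchor_ids <- anchors
  fit
}

#' z-transform latent scores to a reference study's metric
#'
#' Every score becomes `(theta - mean_ref) / sd_ref` per domain, where the
#' reference moments are computed from the designated reference score set.
#' The reference set's own transformed scores therefore have mean 0 and
#' SD 1 per domain.
#'
#' @param scores long-format data frame: `person_id`, `study`, `domain`,
#'   `theta` (and optionally `se`).
#' @param reference_scores same format; the reference study's scores
#'   (typically its case sample) defining the metric.
#' @return wide data frame (`person_id`, `study`, one column per domain)
#'   of transformed scores; attribute `"reference_moments"` holds the
#'   per-domain mean/SD used.
#' @export
ztransform_to_reference <- function(scores, reference_scores) {
  stopifnot(all(c("person_id", "study", "domain", "theta") %in%
                  names(scores)),
            all(c("domain", "theta") %in% names(reference_scores)))
  if (nrow(reference_scores) == 0L) stop("reference score set is empty")
  mom <- do.call(rbind, lapply(split(reference_scores$theta,
                                     reference_scores$domain),
                               function(v) {
    v <- v[is.finite(v)]
    c(mean = mean(v), sd = stats::sd(v))
  }))
  if (any(!is.finite(mom[, "sd"]) | mom[, "sd"] <= 0))
    stop("zero or undefined reference SD for domain(s): ",
         paste(rownames(mom)[!(is.finite(mom[, "sd"]) & mom[, "sd"] > 0)],
               collapse = ", "))
  doms <- rownames(mom)
  bad <- setdiff(unique(scores$domain), doms)
  if (length(bad))
    stop("no reference moments for domain(s): ", paste(bad, collapse = ", "))
  z <- (scores$theta - mom[scores$domain, "mean"]) /
    mom[scores$domain, "sd"]
  long <- data.frame(person_id = scores$person_id, study = scores$study,
                     domain = scores$domain, z = z,
                     stringsAsFactors = FALSE)
  wide <- stats::reshape(long, idvar = c("person_id", "study"),
                         timevar = "domain", direction = "wide")
  names(wide) <- sub("^z\\.", "", names(wide))
  rownames(wide) <- NULL
  attr(wide, "reference_moments") <- mom
  wide
}
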