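#' @title Graded-response measurement engine
#' @description Internal helpers plus the exported marginal maximum
#'   likelihood fitter for the logistic graded response model (GRM).
#' @name grm-engine
NULL

# --- item-bank helpers ------------------------------------------------------

.bank_bcols <- function(items) grep("^b[0-9]+$", names(items), value = TRUE)

#' Extract per-item threshold vectors from an item table
#'
#' Item parameter tables store category thresholds in NA-padded columns
#' `b1..bK`; this returns the non-missing thresholds per item, in order.
#'
#' @param items item parameter data frame with columns `a` and `b1..bK`.
#' @return list of numeric threshold vectors (length K-1 per item).
#' @export
item_thresholds <- function(items) {
  bc <- .bank_bcols(items)
  bm <- as.matrix(items[, bc, drop = FALSE])
  lapply(seq_len(nrow(bm)), function(i) {
    v <- as.numeric(bm[i, ])
    v[!is.na(v)]
  })
}

.pad_b <- function(blist, prefix = "b") {
  kmax <- max(vapply(blist, length, 1L))
  m <- matrix(NA_real_, length(blist), kmax,
              dimnames = list(NULL, paste0(prefix, seq_len(kmax))))
  for (i in seq_along(blist)) m[i, seq_along(blist[[i]])] <- blist[[i]]
  as.data.frame(m)
}

#' Graded-response category probabilities
#'
#' Cumulative model: P(X >= k | theta) = logistic(a (theta - b_k) +
#' a_spec * theta_spec); category probabilities by adjacent differences.
#' With `a_spec = 0` this is the unidimensional GRM.
#'
#' @param a discrimination (> 0).
#' @param b strictly increasing numeric vector of K-1 thresholds.
#' @param theta numeric vector of latent trait values.
#' @param a_spec specific-factor loading (bifactor use).
#' @param theta_spec specific trait values, recycled against `theta`.
#' @return K x length(theta) matrix of category probabilities; columns sum
#'   to 1.
#' @export
grm_prob <- function(a, b, theta, a_spec = 0, theta_spec = 0) {
  eta <- outer(-a * b, a * theta + a_spec * theta_spec, `+`)
  cum <- stats::plogis(eta)                     # (K-1) x Q
  p <- rbind(1, cum) - rbind(cum, 0)
  pmax(p, 1e-300)
}

# log category-probability matrix for one item over a node grid
.item_logp <- function(a, b, theta, a_spec = 0, theta_spec = 0) {
  log(grm_prob(a, b, theta, a_spec, theta_spec))
}

# --- response preprocessing -------------------------------------------------

# Collapse categories observed fewer than min_count times into the adjacent
# category (towards lower index, or upward for category 0). Returns list
# (responses, k, collapsed_flag) per item; recodes in place.
.collapse_sparse <- function(x, min_count = 5L) {
  lev <- sort(unique(x[!is.na(x)]))
  if (length(lev) < 2L) {
    return(list(x = x, collapsed = FALSE, k = length(lev)))
  }
  # first recode to contiguous 0..m
  x <- match(x, lev) - 1L
  collapsed <- length(lev) < (max(lev) + 1L)
  repeat {
    tab <- tabulate(x + 1L, nbins = max(x, na.rm = TRUE) + 1L)
    k <- length(tab)
    if (k < 3L || all(tab >= min_count)) break
    j <- which.min(tab)                 # sparsest category (1-based)
    tgt <- if (j == 1L) 2L else j - 1L  # merge into neighbour
    x[x == (j - 1L)] <- tgt - 1L
    x[x > (j - 1L)] <- x[x > (j - 1L)] - 1L
    collapsed <- TRUE
  }
  list(x = x, collapsed = collapsed, k = max(x, na.rm = TRUE) + 1L)
}

.prep_responses <- function(responses, min_cat_count = 5L) {
  stopifnot(is.matrix(responses))
  if (is.null(colnames(responses)))
    colnames(responses) <- paste0("item", seq_len(ncol(responses)))
  dropped <- character(0)
  collapsed <- character(0)
  ks <- integer(ncol(responses))
  for (j in seq_len(ncol(responses))) {
    cs <- .collapse_sparse(responses[, j], min_cat_count)
    responses[, j] <- cs$x
    ks[j] <- cs$k
    if (cs$collapsed) collapsed <- c(collapsed, colnames(responses)[j])
    if (cs$k < 2L) dropped <- c(dropped, colnames(responses)[j])
  }
  if (length(dropped)) {
    warning("dropping item(s) with a single observed category: ",
            paste(dropped, collapse = ", "))
    keep <- !(colnames(responses) %in% dropped)
    responses <- responses[, keep, drop = FALSE]
    ks <- ks[keep]
  }
  list(responses = responses, k = ks, dropped = dropped,
       collapsed = collapsed)
}

# --- quadrature -------------------------------------------------------------

.quad_nodes <- function(n_quad, range = c(-6, 6)) {
  seq(range[1], range[2], length.out = n_quad)
}

.prior_weights <- function(nodes, mean = 0, var = 1) {
  w <- stats::dnorm(nodes, mean, sqrt(var))
  w / sum(w)
}

# person x node log-likelihood matrix (unidimensional)
.loglik_nodes <- function(responses, a, blist, nodes) {
  n <- nrow(responses)
  L <- matrix(0, n, length(nodes))
  for (j in seq_len(ncol(responses))) {
    lp <- .item_logp(a[j], blist[[j]], nodes)
    x <- responses[, j]
    obs <- which(!is.na(x))
    if (length(obs)) L[obs, ] <- L[obs, ] + lp[x[obs] + 1L, , drop = FALSE]
  }
  L
}

.marginal_loglik <- function(L, logw) {
  A <- sweep(L, 2L, logw, `+`)
  m <- apply(A, 1L, max)
  sum(m + log(rowSums(exp(A - m))))
}

.posterior_nodes <- function(L, logw) {
  A <- sweep(L, 2L, logw, `+`)
  m <- apply(A, 1L, max)
  P <- exp(A - m)
  P / rowSums(P)
}

# --- M-step -----------------------------------------------------------------

# maximize sum_k,q r[k,q] log P_k(theta_q) over (a, b); warm start, bounded
.mstep_item <- function(r, nodes, a0, b0) {
  K <- nrow(r)
  par0 <- if (K == 2L) c(log(a0), b0[1]) else
    c(log(a0), b0[1], log(pmax(diff(b0), 1e-3)))
  unpack <- function(par) {
    a <- exp(par[1])
    b <- if (K == 2L) par[2] else par[2] + c(0, cumsum(exp(par[-(1:2)])))
    list(a = a, b = b)
  }
  negq <- function(par) {
    p <- unpack(par)
    -sum(r * log(grm_prob(p$a, p$b, nodes)))
  }
  lower <- c(log(0.01), -12, rep(log(1e-4), K - 2L))
  upper <- c(log(25),    12, rep(log(25),   K - 2L))
  opt <- tryCatch(
    stats::optim(par0, negq, method = "L-BFGS-B", lower = lower,
                 upper = upper, control = list(maxit = 200)),
    error = function(e) NULL)
  f0 <- negq(par0)
  if (is.null(opt) || !is.finite(opt$value) || opt$value > f0) {
    return(list(a = a0, b = b0))
  }
  unpack(opt$par)
}

.init_item <- function(x, k) {
  # cumulative proportions -> logistic quantile start under theta = 0, a = 1
  tab <- tabulate(x[!is.na(x)] + 1L, nbins = k)
  pr <- tab / sum(tab)
  pge <- rev(cumsum(rev(pr)))[-1]             # P(X >= k), k = 1..K-1
  pge <- pmin(pmax(pge, 1e-3), 1 - 1e-3)
  b <- -stats::qlogis(pge)
  for (i in seq_along(b)[-1]) if (b[i] <= b[i - 1]) b[i] <- b[i - 1] + 1e-3
  list(a = 1, b = b)
}

# --- fitter -----------------------------------------------------------------

#' Fit a unidimensional graded response model by marginal ML (EM)
#'
#' Estimates item discriminations and ordered category thresholds under a
#' normal latent trait, by EM with fixed-node quadrature. The latent
#' distribution is standard normal unless `estimate_latent = TRUE`, in which
#' case its mean and variance are estimated (used for anchored calibration).
#' Items with a single observed category are dropped with a warning; sparse
#' categories (< `min_cat_count` observations) are collapsed into an
#' adjacent category.
#'
#' @param responses persons x items integer matrix, categories `0..K-1`,
#'   `NA` allowed (ignorable missingness).
#' @param n_quad number of equally spaced quadrature nodes.
#' @param max_iter maximum EM iterations.
#' @param tol relative log-likelihood convergence threshold.
#' @param quad_range node range on the trait scale.
#' @param prior_mean,prior_var latent prior (fixed unless estimated).
#' @param estimate_latent estimate latent mean/variance (anchored use).
#' @param fixed_items optional item table whose rows (matched by
#'   `item_id`) are held fixed at the given parameters.
#' @param items_meta optional data frame with `item_id`, `domain`,
#'   `subdomain`, `anchor` to carry through to the output.
#' @param min_cat_count collapse threshold for sparse categories.
#' @return object of class `grm_fit`: `items` (parameter table),
#'   `loglik` (final), `trace` (per-iteration log-likelihood),
#'   `converged`, `latent_mean`, `latent_var`, `nodes`, `dropped`,
#'   `collapsed`.
#' @export
fit_grm <- function(responses, n_quad = 49, max_iter = 500, tol = 1e-6,
                    quad_range = c(-6, 6), prior_mean = 0, prior_var = 1,
                    estimate_latent = FALSE, fixed_items = NULL,
                    items_meta = NULL, min_cat_count = 5L) {
  pr <- .prep_responses(responses, min_cat_count)
  resp <- pr$responses
  J <- ncol(resp)
  if (J == 0L) stop("no identifiable items remain")
  ids <- colnames(resp)
  nodes <- .quad_nodes(n_quad, quad_range)

  a <- numeric(J)
  blist <- vector("list", J)
  fixed <- logical(J)
  if (!is.null(fixed_items)) {
    fb <- item_thresholds(fixed_items)
    for (j in seq_len(J)) {
      m <- match(ids[j], fixed_items$item_id)
      if (!is.na(m)) {
        fixed[j] <- TRUE
        a[j] <- fixed_items$a[m]
        blist[[j]] <- fb[[m]]
        kobs <- max(resp[, j], na.rm = TRUE) + 1L
        if (kobs > length(fb[[m]]) + 1L)
          stop("anchor scoring mismatch for item '", ids[j],
               "': ", kobs, " observed categories vs ",
               length(fb[[m]]) + 1L, " in reference parameters")
      }
    }
  }
  for (j in seq_len(J)) {
    if (!fixed[j]) {
      ini <- .init_item(resp[, j], pr$k[j])
      a[j] <- ini$a
      blist[[j]] <- ini$b
    }
  }

  mu <- prior_mean
  sg2 <- prior_var
  trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    logw <- log(.prior_weights(nodes, mu, sg2))
    L <- .loglik_nodes(resp, a, blist, nodes)
    ll <- .marginal_loglik(L, logw)
    trace <- c(trace, ll)
    if (it > 1L &&
        abs(ll - trace[it - 1L]) < tol * (abs(trace[it - 1L]) + 1e-8)) {
      converged <- TRUE
      break
    }
    post <- .posterior_nodes(L, logw)
    for (j in seq_len(J)) {
      if (fixed[j]) next
      x <- resp[, j]
      obs <- which(!is.na(x))
      ind <- matrix(0, pr$k[j], length(obs))
      ind[cbind(x[obs] + 1L, seq_along(obs))] <- 1
      r <- ind %*% post[obs, , drop = FALSE]       # K x Q expected counts
      ms <- .mstep_item(r, nodes, a[j], blist[[j]])
      a[j] <- ms$a
      blist[[j]] <- ms$b
    }
    if (estimate_latent) {
      et <- post %*% nodes
      et2 <- post %*% nodes^2
      mu <- mean(et)
      sg2 <- max(mean(et2) - mu^2, 1e-4)
    }
  }
  if (!converged)
    warning("EM did not converge in ", max_iter, " iterations")

  items <- data.frame(item_id = ids, a = a, stringsAsFactors = FALSE)
  items <- cbind(items, .pad_b(blist))
  if (!is.null(items_meta)) {
    m <- match(items$item_id, items_meta$item_id)
    for (col in intersect(c("domain", "subdomain", "anchor"),
                          names(items_meta)))
      items[[col]] <- items_meta[[col]][m]
  }
  structure(list(items = items, loglik = trace[length(trace)],
                 trace = trace, converged = converged,
                 latent_mean = mu, latent_var = sg2, nodes = nodes,
                 dropped = pr$dropped, collapsed = pr$collapsed),
            class = "grm_fit")
}

#' @export
print.grm_fit <- function(x, ...) {
  cat("Graded response model fit:", nrow(x$items), "items\n")
  cat(sprintf("  log-likelihood %.4f after %d EM iterations (%s)\n",
              x$loglik, length(x$trace),
              if (x$converged) "converged" else "NOT converged"))
  cat(sprintf("  latent mean %.3f, variance %.3f\n",
              x$latent_mean, x$latent_var))
  invisible(x)
}

#' Marginal log-likelihood of response data under given item parameters
#'
#' Evaluates the quadrature marginal log-likelihood at fixed parameters;
#' used for model comparison (e.g. bifactor vs unidimensional nesting).
#' If the item table carries a nonzero `a_spec` column and a `subdomain`
#' column, the bifactor likelihood is evaluated (general factor plus one
#' orthogonal specific factor per subdomain).
#'
#' @inheritParams fit_grm
#' @param items item parameter table (`item_id`, `a`, `b1..`, optionally
#'   `a_spec`, `subdomain`).
#' @return scalar log-likelihood.
#' @export
grm_loglik <- function(responses, items, n_quad = 49, quad_range = c(-6, 6),
                       prior_mean = 0, prior_var = 1) {
  has_spec <- !is.null(items$a_spec) && any(items$a_spec != 0, na.rm = TRUE)
  if (has_spec) {
    return(.bifactor_loglik(responses, items, n_quad, quad_range))
  }
  m <- match(colnames(responses), items$item_id)
  if (anyNA(m)) stop("parameters missing for some items")
  nodes <- .quad_nodes(n_quad, quad_range)
  blist <- item_thresholds(items)[m]
  L <- .loglik_nodes(responses, items$a[m], blist, nodes)
  .marginal_loglik(L, log(.prior_weights(nodes, prior_mean, prior_var)))
}

# --- EAP scoring ------------------------------------------------------------

#' Expected a posteriori (EAP) latent trait scores
#'
#' Posterior mean and SD of the latent trait given each person's responses,
#' by quadrature against a normal prior. Persons answering zero items get
#' `NA` scores with `n_items = 0`, never the prior mean.
#'
#' @param responses persons x items integer matrix (categories `0..K-1`).
#' @param items item parameter table covering every answered item.
#' @param prior_mean,prior_var normal prior for the trait.
#' @param n_quad number of quadrature nodes.
#' @return data frame: `person_id`, `theta`, `se`, `n_items`.
#' @export
score_eap <- function(responses, items, prior_mean = 0, prior_var = 1,
                      n_quad = 101) {
  m <- match(colnames(responses), items$item_id)
  if (anyNA(m))
    stop("parameters missing for item(s): ",
         paste(colnames(responses)[is.na(m)], collapse = ", "))
  sd0 <- sqrt(prior_var)
  nodes <- seq(prior_mean - 6 * sd0, prior_mean + 6 * sd0,
               length.out = n_quad)
  blist <- item_thresholds(items)[m]
  L <- .loglik_nodes(responses, items$a[m], blist, nodes)
  post <- .posterior_nodes(L, log(.prior_weights(nodes, prior_mean,
                                                 prior_var)))
  theta <- as.numeric(post %*% nodes)
  se <- sqrt(pmax(as.numeric(post %*% nodes^2) - theta^2, 0))
  n_items <- rowSums(!is.na(responses))
  theta[n_items == 0L] <- NA_real_
  se[n_items == 0L] <- NA_real_
  pid <- rownames(responses)
  if (is.null(pid)) pid <- as.character(seq_len(nrow(responses)))
  data.frame(person_id = pid, theta = theta, se = se, n_items = n_items,
             stringsAsFactors = FALSE)
}
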