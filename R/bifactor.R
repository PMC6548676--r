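# Bifactor graded-response estimation: one general factor plus orthogonal
# subdomain-specific factors, all standard normal. Because the specific
# factors are mutually independent given the general factor, the marginal
# likelihood factors over subdomains, so integration is a sequence of
# (general x specific) product grids rather than one high-dimensional grid.

# column layout for the product grid: column (qg-1)*Qs + qs
.grid_expand <- function(gnodes, snodes) {
  list(g = rep(gnodes, each = length(snodes)),
       s = rep(snodes, times = length(gnodes)))
}

# per-subdomain person x (Qg*Qs) log-likelihood
.subdom_loglik <- function(resp, jidx, a, a_spec, blist, grid) {
  n <- nrow(resp)
  M <- matrix(0, n, length(grid$g))
  for (j in jidx) {
    lp <- .item_logp(a[j], blist[[j]], grid$g, a_spec[j], grid$s)
    x <- resp[, j]
    obs <- which(!is.na(x))
    if (length(obs)) M[obs, ] <- M[obs, ] + lp[x[obs] + 1L, , drop = FALSE]
  }
  M
}

# log sum over specific nodes within each general-node block
.block_collapse <- function(A, Qg, Qs, logws) {
  A <- sweep(A, 2L, rep(logws, times = Qg), `+`)
  m <- apply(A, 1L, max)
  E <- exp(A - m)
  blk <- matrix(0, Qg * Qs, Qg)
  blk[cbind(seq_len(Qg * Qs), rep(seq_len(Qg), each = Qs))] <- 1
  S <- E %*% blk                          # n x Qg
  list(logmarg = log(S) + m,              # n x Qg, log p(x_s | theta_g)
       cond = E / S[, rep(seq_len(Qg), each = Qs)])  # cond'l over qs given qg
}

#' Fit a bifactor graded response model by marginal ML (EM)
#'
#' One general factor plus an orthogonal specific factor per subdomain, all
#' standard normal. The cumulative logit for item i at category k is
#' `a_i (theta_g - b_ik) + a_spec_i * theta_s`. The general-factor EAP is
#' the domain score. Subdomains with fewer than three items have their
#' specific factor dropped (loading fixed at zero) with a warning.
#'
#' @inheritParams fit_grm
#' @param subdomain_map named character vector or data frame
#'   (`item_id`, `subdomain`) mapping every item to exactly one subdomain.
#' @param n_quad nodes per factor (product grid `n_quad^2` per subdomain).
#' @param fix_spec_zero fix all specific loadings at zero (reduces to the
#'   unidimensional model; used for nesting checks).
#' @return object of class `bifactor_fit`: `items` (with `a_spec` and
#'   `subdomain`), `loglik`, `trace`, `converged`, `scores` (general-factor
#'   EAP and SD per person), `nodes`.
#' @export
fit_bifactor <- function(responses, subdomain_map, n_quad = 21,
                         max_iter = 200, tol = 1e-6, quad_range = c(-6, 6),
                         fix_spec_zero = FALSE, min_cat_count = 5L) {
  pr <- .prep_responses(responses, min_cat_count)
  resp <- pr$responses
  ids <- colnames(resp)
  if (is.data.frame(subdomain_map)) {
    sd_map <- stats::setNames(as.character(subdomain_map$subdomain),
                              subdomain_map$item_id)
  } else sd_map <- subdomain_map
  subdom <- unname(sd_map[ids])
  if (anyNA(subdom)) stop("every item must map to exactly one subdomain")
  if (length(unique(subdom)) < 2L) stop("need >= 2 subdomains")

  J <- ncol(resp)
  nodes <- .quad_nodes(n_quad, quad_range)
  grid <- .grid_expand(nodes, nodes)
  logw <- log(.prior_weights(nodes))

  spec_free <- rep(!fix_spec_zero, J)
  for (s in unique(subdom)) {
    if (sum(subdom == s) < 3L && !fix_spec_zero) {
      warning("subdomain '", s, "' has < 3 items; specific factor dropped")
      spec_free[subdom == s] <- FALSE
    }
  }

  a <- numeric(J); a_spec <- numeric(J); blist <- vector("list", J)
  for (j in seq_len(J)) {
    ini <- .init_item(resp[, j], pr$k[j])
    a[j] <- ini$a
    a_spec[j] <- if (spec_free[j]) 0.5 else 0
    blist[[j]] <- ini$b
  }

  sdoms <- unique(subdom)
  Qg <- Qs <- n_quad
  trace <- numeric(0)
  converged <- FALSE
  post_g <- NULL
  for (it in seq_len(max_iter)) {
    Lg <- matrix(0, nrow(resp), Qg)       # log p(x | theta_g)
    conds <- vector("list", length(sdoms))
    names(conds) <- sdoms
    for (s in sdoms) {
      jidx <- which(subdom == s)
      M <- .subdom_loglik(resp, jidx, a, a_spec, blist, grid)
      bc <- .block_collapse(M, Qg, Qs, logw)
      Lg <- Lg + bc$logmarg
      conds[[s]] <- bc$cond
    }
    ll <- .marginal_loglik(Lg, logw)
    trace <- c(trace, ll)
    if (it > 1L &&
        abs(ll - trace[it - 1L]) < tol * (abs(trace[it - 1L]) + 1e-8)) {
      converged <- TRUE
      post_g <- .posterior_nodes(Lg, logw)
      break
    }
    post_g <- .posterior_nodes(Lg, logw)
    for (s in sdoms) {
      pj <- post_g[, rep(seq_len(Qg), each = Qs)] * conds[[s]]
      for (j in which(subdom == s)) {
        x <- resp[, j]
        obs <- which(!is.na(x))
        ind <- matrix(0, pr$k[j], length(obs))
        ind[cbind(x[obs] + 1L, seq_along(obs))] <- 1
        r <- ind %*% pj[obs, , drop = FALSE]
        ms <- .mstep_bifactor_item(r, grid, a[j], blist[[j]], a_spec[j],
                                   spec_free[j])
        a[j] <- ms$a; blist[[j]] <- ms$b; a_spec[j] <- ms$a_spec
      }
    }
  }
  if (!converged) warning("EM did not converge in ", max_iter, " iterations")

  theta <- as.numeric(post_g %*% nodes)
  se <- sqrt(pmax(as.numeric(post_g %*% nodes^2) - theta^2, 0))
  pid <- rownames(resp)
  if (is.null(pid)) pid <- as.character(seq_len(nrow(resp)))

  items <- data.frame(item_id = ids, subdomain = subdom, a = a,
                      a_spec = a_spec, stringsAsFactors = FALSE)
  items <- cbind(items, .pad_b(blist))
  structure(list(items = items, loglik = trace[length(trace)], trace = trace,
                 converged = converged,
                 scores = data.frame(person_id = pid, theta = theta, se = se,
                                     stringsAsFactors = FALSE),
                 nodes = nodes),
            class = "bifactor_fit")
}

#' @export
print.bifactor_fit <- function(x, ...) {
  cat("Bifactor graded response fit:", nrow(x$items), "items,",
      length(unique(x$items$subdomain)), "subdomains\n")
  cat(sprintf("  log-likelihood %.4f after %d EM iterations (%s)\n",
              x$loglik, length(x$trace),
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

.mstep_bifactor_item <- function(r, grid, a0, b0, s0, spec_free) {
  K <- nrow(r)
  par0 <- c(log(a0), b0[1], if (K > 2) log(pmax(diff(b0), 1e-3)),
            if (spec_free) s0)
  nb <- if (K == 2L) 2L else K
  unpack <- function(par) {
    a <- exp(par[1])
    b <- if (K == 2L) par[2] else par[2] + c(0, cumsum(exp(par[3:nb])))
    asp <- if (spec_free) par[nb + 1L] else 0
    list(a = a, b = b, a_spec = asp)
  }
  negq <- function(par) {
    p <- unpack(par)
    -sum(r * log(grm_prob(p$a, p$b, grid$g, p$a_spec, grid$s)))
  }
  lower <- c(log(0.01), -12, if (K > 2) rep(log(1e-4), K - 2L),
             if (spec_free) -25)
  upper <- c(log(25), 12, if (K > 2) rep(log(25), K - 2L),
             if (spec_free) 25)
  opt <- tryCatch(
    stats::optim(par0, negq, method = "L-BFGS-B", lower = lower,
                 upper = upper, control = list(maxit = 200)),
    error = function(e) NULL)
  if (is.null(opt) || !is.finite(opt$value) || opt$value > negq(par0)) {
    return(list(a = a0, b = b0, a_spec = s0))
  }
  unpack(opt$par)
}

# bifactor marginal log-likelihood at fixed parameters
.bifactor_loglik <- function(responses, items, n_quad = 21,
                             quad_range = c(-6, 6)) {
  m <- match(colnames(responses), items$item_id)
  if (anyNA(m)) stop("parameters missing for some items")
  a <- items$a[m]
  a_spec <- if (is.null(items$a_spec)) rep(0, length(m)) else items$a_spec[m]
  a_spec[is.na(a_spec)] <- 0
  subdom <- items$subdomain[m]
  blist <- item_thresholds(items)[m]
  nodes <- .quad_nodes(n_quad, quad_range)
  grid <- .grid_expand(nodes, nodes)
  logw <- log(.prior_weights(nodes))
  Lg <- matrix(0, nrow(responses), n_quad)
  for (s in unique(subdom)) {
    jidx <- which(subdom == s)
    M <- .subdom_loglik(responses, jidx, a, a_spec, blist, grid)
    Lg <- Lg + .block_collapse(M, n_quad, n_quad, logw)$logmarg
  }
  .marginal_loglik(Lg, logw)
}
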