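# Shared simulation helpers: generate graded-response data with
# well-populated categories (thresholds spread so no category is sparse).

sim_grm_data <- function(n, J, K = 4, seed = 1, mean = 0, sd = 1,
                         a = NULL, b = NULL, a_range = c(1.2, 2.4)) {
  set.seed(seed)
  if (is.null(a)) a <- stats::runif(J, a_range[1], a_range[2])
  if (is.null(b)) {
    bmid <- stats::runif(J, -0.6, 0.6)
    b <- t(vapply(seq_len(J), function(j)
      bmid[j] + seq(-0.9, 0.9, length.out = K - 1), numeric(K - 1)))
  }
  b <- matrix(b, nrow = J)
  theta <- stats::rnorm(n, mean, sd)
  resp <- vapply(seq_len(J), function(j) {
    cum <- stats::plogis(outer(theta, b[j, ], function(t, bb)
      a[j] * (t - bb)))
    as.integer(rowSums(cum > stats::runif(n)))
  }, integer(n))
  colnames(resp) <- sprintf("it%02d", seq_len(J))
  rownames(resp) <- sprintf("p%04d", seq_len(n))
  list(resp = resp, a = a, b = b, theta = theta)
}

# toy genotype matrix with explicit metadata
toy_genotypes <- function(dosage, caf = NULL, info = NULL,
                          coded = NULL, other = NULL, chr = NULL) {
  p <- ncol(dosage)
  if (is.null(rownames(dosage)))
    rownames(dosage) <- sprintf("s%03d", seq_len(nrow(dosage)))
  genotype_matrix(dosage, data.frame(
    id = sprintf("v%03d", seq_len(p)),
    chr = if (is.null(chr)) rep("1", p) else chr,
    pos = seq_len(p) * 1000,
    coded = if (is.null(coded)) rep("A", p) else coded,
    other = if (is.null(other)) rep("G", p) else other,
    caf = if (is.null(caf)) colMeans(dosage) / 2 else caf,
    info = if (is.null(info)) rep(1, p) else info,
    stringsAsFactors = FALSE))
}

# independent Pearson chi-square oracle (no continuity correction)
pearson_oracle <- function(tab) {
  tab <- as.matrix(tab)
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - e)^2 / e)
}
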