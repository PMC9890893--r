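# Independent oracle implementations used to cross-check the package: each
# is written directly from the published definition of the statistic, in a
# deliberately different style from the package code.

# Step-up Benjamini-Hochberg from the definition: q_(i) = min_{j >= i}
# min(1, p_(j) * m / j).
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    j <- which(o == i)          # rank of p[i]
    cand <- sapply(j:m, function(k) min(1, p[o[k]] * m / k))
    q[i] <- min(cand)
  }
  q
}

# Row-scan gene filter: keep gene iff >= min_samples entries >= min_count.
oracle_filter <- function(counts, min_count = 10, min_samples = 4) {
  keep <- logical(nrow(counts))
  for (g in seq_len(nrow(counts))) {
    n_ok <- 0
    for (j in seq_len(ncol(counts))) if (counts[g, j] >= min_count) n_ok <- n_ok + 1
    keep[g] <- n_ok >= min_samples
  }
  counts[keep, , drop = FALSE]
}

# Standardized Euclidean distance between columns u and v of x:
# sqrt(sum_k (x[k,u] - x[k,v])^2 / Var_k) with Var_k the row variance.
oracle_std_euclid <- function(x) {
  V <- apply(x, 1, var)
  n <- ncol(x)
  d <- matrix(0, n, n)
  for (u in seq_len(n)) for (v in seq_len(n)) {
    d[u, v] <- sqrt(sum((x[, u] - x[, v])^2 / V))
  }
  d
}

# TMM normalization factor re-derivation from the published formula:
# doubly-trimmed, precision-weighted mean of gene-wise M values against a
# reference column, factors rescaled to geometric mean one.
oracle_tmm <- function(counts, logratio_trim = 0.30, sum_trim = 0.05) {
  N <- colSums(counts)
  uq <- apply(counts, 2, function(y) quantile(y[y > 0] / sum(y), 0.75))
  ref <- which.min(abs(uq - mean(uq)))
  f <- numeric(ncol(counts))
  for (j in seq_len(ncol(counts))) {
    if (j == ref) { f[j] <- 1; next }
    y <- counts[, j]; r <- counts[, ref]
    ok <- y > 0 & r > 0
    y <- y[ok]; r <- r[ok]
    M <- log2((y / N[j]) / (r / N[ref]))
    A <- 0.5 * log2((y / N[j]) * (r / N[ref]))
    w <- (N[j] - y) / (N[j] * y) + (N[ref] - r) / (N[ref] * r)
    fin <- is.finite(M) & is.finite(A)
    M <- M[fin]; A <- A[fin]; w <- w[fin]
    loM <- quantile(M, logratio_trim); hiM <- quantile(M, 1 - logratio_trim)
    loA <- quantile(A, sum_trim); hiA <- quantile(A, 1 - sum_trim)
    keep <- M >= loM & M <= hiM & A >= loA & A <= hiA
    f[j] <- 2^(sum((M / w)[keep]) / sum((1 / w)[keep]))
  }
  f / exp(mean(log(f)))
}

# Dunn pairwise z statistic recomputed from the definition: difference of
# mean pooled ranks over its tie-corrected standard error.
oracle_dunn_z <- function(groups, i, j) {
  x <- unlist(groups)
  rk <- rank(x)
  sizes <- sapply(groups, length)
  grp <- rep(seq_along(groups), sizes)
  n <- length(x)
  tie_tab <- table(x)
  correction <- sum(tie_tab^3 - tie_tab) / (12 * (n - 1))
  se <- sqrt((n * (n + 1) / 12 - correction) * (1 / sizes[i] + 1 / sizes[j]))
  (mean(rk[grp == i]) - mean(rk[grp == j])) / se
}

# Log-CPM residual matrix used before network construction in tests.
make_residuals <- function(gen) {
  expr <- log2(sweep(gen$counts, 2, colSums(gen$counts) / 2e6, "/") + 1)
  residualize(expr, gen$meta[, c("sex", "strandness", "exonic_rate")])
}

# Star-shaped cells with angularly well-separated arms: the planted skeleton
# (n_arms branches, one junction, sum of arm lengths) is analytic only when
# arms do not merge near the soma.
random_clean_star <- function(center = c(50, 50), min_sep = 1.0) {
  n_arms <- sample(3:5, 1)
  repeat {
    angs <- sort(runif(n_arms, 0, 2 * pi))
    if (min(diff(c(angs, angs[1] + 2 * pi))) >= min_sep) break
  }
  lens <- runif(n_arms, 12, 20)
  list(cell = microglion_star(center, n_arms, lens, angs, soma_diameter_um = 5),
       n_arms = n_arms, total_len = sum(lens))
}

# Non-overlapping random disk scenes: rejection-sample plaque centers until
# every pair of disk edges is separated by more than `min_edge_sep_um`.
random_separated_plaques <- function(n_large, n_small, roi_um = 150,
                                     min_edge_sep_um = 2) {
  d <- c(runif(n_large, 10, 18), runif(n_small, 4, 6))
  k <- length(d)
  repeat {
    x <- runif(k, 12, roi_um - 12); y <- runif(k, 12, roi_um - 12)
    if (k < 2) break
    dist_c <- as.matrix(dist(cbind(x, y)))
    need <- outer(d, d, "+") / 2 + min_edge_sep_um
    diag(dist_c) <- Inf
    if (all(dist_c > need)) break
  }
  data.frame(x_um = x, y_um = y, diameter_um = d)
}
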