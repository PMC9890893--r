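## Post-count RNA-seq analysis: sample QC, gene filtering, TMM
## normalization, gene-wise negative-binomial DE testing with BH-FDR and
## threshold classification, standardized-Euclidean clustering, signed-hybrid
## co-expression modules with eigengenes / membership / trait correlation,
## and permutation Zsummary module preservation.

#' Sample quality-control exclusion
#'
#' Drops samples whose QC covariates fall outside the configured bands:
#' gene-count percentage below \code{min_gene_count_pct} or strandness score
#' outside \code{strandness_band} (a strandness near 0.5 indicates a failed
#' strand-specific library).
#'
#' @param counts gene x sample count matrix.
#' @param meta data.frame with columns \code{sample}, \code{gene_count_pct},
#'   \code{strandness} (rows keyed to the columns of \code{counts}).
#' @param min_gene_count_pct minimum acceptable gene-count percentage.
#' @param strandness_band acceptable strandness interval.
#' @return list: \code{counts}, \code{meta} (retained), \code{excluded}
#'   (data.frame sample/reason).
#' @export
sample_qc <- function(counts, meta, min_gene_count_pct = 50,
                      strandness_band = c(0.7, 1.0)) {
  stopifnot(ncol(counts) == nrow(meta))
  reasons <- character(0); dropped <- character(0)
  for (i in seq_len(nrow(meta))) {
    r <- character(0)
    if (meta$gene_count_pct[i] < min_gene_count_pct) {
      r <- c(r, sprintf("low gene count percentage (%.4g%%)", meta$gene_count_pct[i]))
    }
    if (meta$strandness[i] < strandness_band[1] || meta$strandness[i] > strandness_band[2]) {
      r <- c(r, sprintf("strandness check (%.4g)", meta$strandness[i]))
    }
    if (length(r)) {
      dropped <- c(dropped, meta$sample[i])
      reasons <- c(reasons, paste(r, collapse = " and "))
    }
  }
  keep <- !(meta$sample %in% dropped)
  if (!any(keep)) stop("all samples excluded by QC", call. = FALSE)
  list(counts = counts[, keep, drop = FALSE],
       meta = meta[keep, , drop = FALSE],
       excluded = data.frame(sample = dropped, reason = reasons))
}

#' Expression filter: keep genes with enough well-covered samples
#'
#' A gene is kept iff at least \code{min_samples} samples have at least
#' \code{min_count} counts of it.
#'
#' @param counts gene x sample matrix.
#' @export
filter_genes <- function(counts, min_count = 10, min_samples = 4) {
  keep <- rowSums(counts >= min_count) >= min_samples
  counts[keep, , drop = FALSE]
}

#' TMM between-sample normalization factors
#'
#' Trimmed mean of M-values: doubly-trimmed, precision-weighted mean of
#' gene-wise log ratios against a reference sample, rescaled to geometric
#' mean 1. Computed by \code{edgeR::calcNormFactors}.
#'
#' @param counts gene x sample matrix with nonzero library sizes.
#' @param trim_M,trim_A log-ratio and absolute-intensity trim fractions.
#' @export
tmm_factors <- function(counts, trim_M = 0.30, trim_A = 0.05) {
  if (ncol(counts) < 2) stop("need >= 2 samples", call. = FALSE)
  if (any(colSums(counts) == 0)) stop("zero library size", call. = FALSE)
  f <- edgeR::calcNormFactors(counts, method = "TMM",
                              logratioTrim = trim_M, sumTrim = trim_A)
  names(f) <- colnames(counts)
  f
}

#' Gene-wise negative-binomial differential-expression test
#'
#' A two-group gene-wise test on TMM-normalized counts: per-gene dispersions
#' are estimated by the method of moments from within-group variability,
#' shrunk on the log scale toward a lowess mean-dispersion trend, and a Wald
#' statistic on the log2 fold-change of normalized group means (with a small
#' prior count) is referred to a t distribution with n - 2 degrees of
#' freedom. This is a deliberately simple stand-in for quasi-likelihood
#' machinery, validated by null calibration and planted-effect recovery.
#'
#' @param counts filtered gene x sample matrix.
#' @param factors TMM factors (from \code{\link{tmm_factors}}).
#' @param groups two-level factor over samples; fold-changes are
#'   level2 / level1.
#' @param prior_count prior added to normalized group means.
#' @param shrink weight of the trend in the log-dispersion shrinkage.
#' @return data.frame: gene, base_mean, log2FC, p_value.
#' @export
genewise_de_test <- function(counts, factors, groups, prior_count = 2,
                             shrink = 0.5) {
  groups <- as.factor(groups)
  stopifnot(nlevels(groups) == 2, all(table(groups) >= 2),
            ncol(counts) == length(groups))
  eff_lib <- colSums(counts) * factors
  s <- eff_lib / mean(eff_lib)
  z <- sweep(counts, 2, s, "/")                  # normalized counts
  g2 <- groups == levels(groups)[2]
  n1 <- sum(!g2); n2 <- sum(g2)
  m1 <- rowMeans(z[, !g2, drop = FALSE])
  m2 <- rowMeans(z[, g2, drop = FALSE])
  mbar <- (n1 * m1 + n2 * m2) / (n1 + n2)
  ## pooled within-group variance of normalized counts
  ss <- rowSums((z[, !g2, drop = FALSE] - m1)^2) +
        rowSums((z[, g2, drop = FALSE] - m2)^2)
  v <- ss / (n1 + n2 - 2)
  ## moment dispersion: Var = mu + phi mu^2 on the normalized scale
  phi <- pmax(0, (v - mbar) / mbar^2)
  ## log-scale shrinkage toward the mean-dispersion lowess trend
  eps <- 1e-4
  lphi <- log(phi + eps)
  lmu <- log(mbar + 0.5)
  trend <- lowess(lmu, lphi, f = 0.5)
  ltrend <- approx(trend$x, trend$y, xout = lmu, rule = 2)$y
  phi_star <- pmax(0, exp(shrink * ltrend + (1 - shrink) * lphi) - eps)
  ## Wald statistic on the log2 fold-change of prior-augmented means
  lfc <- log2((m2 + prior_count) / (m1 + prior_count))
  var_mean <- function(m, n) (m + prior_count + phi_star * (m + prior_count)^2) / n
  se2 <- (var_mean(m1, n1) / (m1 + prior_count)^2 +
          var_mean(m2, n2) / (m2 + prior_count)^2) / log(2)^2
  tstat <- lfc / sqrt(se2)
  p <- 2 * pt(-abs(tstat), df = n1 + n2 - 2)
  data.frame(gene = rownames(counts) %||% seq_len(nrow(counts)),
             base_mean = mbar, log2FC = lfc, p_value = p,
             row.names = NULL)
}

#' Benjamini-Hochberg adjusted p values
#'
#' Step-up FDR adjustment (wraps \code{p.adjust(method = "BH")}).
#' @export
bh_adjust <- function(p_values) {
  stopifnot(all(p_values >= 0 & p_values <= 1, na.rm = TRUE))
  p.adjust(p_values, method = "BH")
}

#' Classify genes by DEG thresholds and compute volcano coordinates
#'
#' Status is \code{up} when \code{fdr < fdr_cut} and \code{log2FC >
#' lfc_cut}, \code{down} when \code{fdr < fdr_cut} and \code{log2FC <
#' -lfc_cut}, otherwise \code{ns} (strict inequalities). Volcano coordinates
#' are \code{x = log2FC}, \code{y = -log10(fdr)}.
#'
#' @param de data.frame with \code{log2FC} and \code{fdr} columns.
#' @param fdr_cut,lfc_cut the DEG thresholds (0.05 and 0.25 by convention;
#'   note |log2FC| > 0.25 is |FC| > 2^0.25, about 1.19).
#' @export
classify_deg <- function(de, fdr_cut = 0.05, lfc_cut = 0.25) {
  stopifnot(all(c("log2FC", "fdr") %in% names(de)))
  status <- rep("ns", nrow(de))
  status[de$fdr < fdr_cut & de$log2FC > lfc_cut] <- "up"
  status[de$fdr < fdr_cut & de$log2FC < -lfc_cut] <- "down"
  de$status <- factor(status, levels = c("up", "down", "ns"))
  de$volcano_x <- de$log2FC
  de$volcano_y <- -log10(de$fdr)
  de
}

#' Hierarchical clustering on standardized Euclidean distances
#'
#' Each feature (row) is standardized to zero mean and unit variance, then
#' average-linkage hierarchical clustering is run on Euclidean distances
#' between columns and between rows. Zero-variance features standardize to
#' zeros with a warning. hclust's ordering is deterministic given the
#' distance matrix; ties resolve by original index.
#'
#' @param x numeric matrix (features x samples).
#' @return list: \code{row_order}, \code{col_order}, \code{row_hclust},
#'   \code{col_hclust}, \code{standardized}.
#' @export
hier_cluster <- function(x) {
  if (nrow(x) < 2) stop("need >= 2 rows", call. = FALSE)
  sds <- apply(x, 1, sd)
  if (any(sds == 0)) {
    warning(sprintf("%d zero-variance feature(s) standardized to zeros", sum(sds == 0)))
  }
  xs <- (x - rowMeans(x)) / ifelse(sds == 0, 1, sds)
  xs[sds == 0, ] <- 0
  ch <- hclust(dist(t(xs)), method = "average")
  rh <- hclust(dist(xs), method = "average")
  list(row_order = rh$order, col_order = ch$order,
       row_hclust = rh, col_hclust = ch, standardized = xs)
}

#' Residualize expression against technical/biological covariates
#'
#' Per-gene ordinary least-squares residuals against the covariate design
#' (e.g., sex, strandness, exonic rate), as used before co-expression
#' network construction.
#'
#' @param expr genes x samples matrix (log scale).
#' @param covariates data.frame of per-sample covariates.
#' @return residual matrix, same shape as \code{expr}.
#' @export
residualize <- function(expr, covariates) {
  stopifnot(ncol(expr) == nrow(covariates))
  X <- model.matrix(~ ., data = covariates)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("collinear covariate design: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  t(qr.resid(qx, t(expr)))
}

# Co-expression modules --------------------------------------------------------

## Signed-hybrid adjacency: cor^beta for positive correlations, 0 otherwise.
signed_hybrid_adjacency <- function(expr, beta = 12) {
  r <- cor(t(expr))
  a <- ifelse(r > 0, r^beta, 0)
  diag(a) <- 0
  a
}

## Topological overlap dissimilarity of an adjacency matrix.
tom_dissimilarity <- function(a) {
  L <- a %*% a
  k <- rowSums(a)
  kmin <- outer(k, k, pmin)
  tom <- (L + a) / (kmin + 1 - a)
  diag(tom) <- 1
  1 - tom
}

## First principal component of the scaled member profiles: one value per
## sample, unit norm, sign fixed so the average member-gene correlation with
## it is positive.
module_eigengene <- function(expr_members) {
  xs <- t(scale(t(expr_members)))           # scale each gene profile
  pc <- prcomp(t(xs), center = FALSE, scale. = FALSE)
  me <- pc$x[, 1]
  me <- me / sqrt(sum(me^2))
  mm <- cor(t(expr_members), me)
  if (mean(mm) < 0) me <- -me
  me
}

#' Build signed-hybrid co-expression modules
#'
#' Adjacency \code{cor^beta} for positively correlated gene pairs (0
#' otherwise), topological-overlap dissimilarity, average-linkage tree, and
#' a static height cut chosen to maximize total intramodular adjacency
#' enrichment subject to the minimum module size. Modules whose eigengenes
#' correlate above \code{1 - merge_cut} are merged. Eigengenes (first PC of
#' the scaled member profiles), module memberships (gene-eigengene
#' correlations, with t-test p values) and hub genes (top 10 by MM p value)
#' are attached.
#'
#' @param residuals genes x samples residual expression matrix.
#' @param beta soft-thresholding power (12 by the scale-free criterion).
#' @param min_module_size smallest allowed module (40).
#' @param merge_cut eigengene-dissimilarity merge threshold (0.4, i.e. merge
#'   when ME correlation > 0.6).
#' @param pve_min minimum fraction of member-profile variance the module
#'   eigengene must explain; candidate clusters below it are dissolved
#'   (random 40-gene sets explain about 0.15-0.2 at these sample sizes, real
#'   co-expression modules considerably more).
#' @return object of class \code{module_set}: \code{membership} (named
#'   module label per gene, "unassigned" otherwise), \code{modules} (list
#'   per module: genes, ME, MM, MM_p, hubs), \code{params}.
#' @export
build_modules <- function(residuals, beta = 12, min_module_size = 40,
                          merge_cut = 0.4, pve_min = 0.3) {
  stopifnot(is.matrix(residuals))
  sds <- apply(residuals, 1, sd)
  if (any(sds == 0)) {
    warning(sprintf("%d constant gene(s) excluded from network", sum(sds == 0)))
    residuals <- residuals[sds > 0, , drop = FALSE]
  }
  ng <- nrow(residuals)
  if (ng < min_module_size) stop("fewer genes than min_module_size", call. = FALSE)
  genes <- rownames(residuals) %||% paste0("g", seq_len(ng))
  rownames(residuals) <- genes
  a <- signed_hybrid_adjacency(residuals, beta)
  dtom <- tom_dissimilarity(a)
  tree <- hclust(as.dist(dtom), method = "average")
  mean_adj <- mean(a[upper.tri(a)])

  ## static cut maximizing intramodular adjacency enrichment over eligible
  ## modules; candidate heights span the merge heights
  heights <- unique(quantile(tree$height, probs = seq(0.05, 0.995, length.out = 40)))
  best <- NULL; best_score <- -Inf
  for (h in heights) {
    cl <- cutree(tree, h = h)
    sizes <- table(cl)
    eligible <- as.integer(names(sizes)[sizes >= min_module_size])
    if (length(eligible) == 0) next
    score <- 0
    for (m in eligible) {
      idx <- which(cl == m)
      if (length(idx) == ng) next   # everything in one cluster: no structure
      sub <- a[idx, idx]
      score <- score + length(idx) * (mean(sub[upper.tri(sub)]) - mean_adj)
    }
    if (score > best_score + 1e-12) {
      best_score <- score; best <- cl
    }
  }
  ## eigengene variance-explained: guard against noise clusters
  me_pve <- function(expr_members) {
    xs <- t(scale(t(expr_members)))
    pc <- prcomp(t(xs), center = FALSE, scale. = FALSE)
    pc$sdev[1]^2 / sum(pc$sdev^2)
  }
  membership <- rep("unassigned", ng)
  names(membership) <- genes
  if (!is.null(best)) {
    sizes <- table(best)
    eligible <- names(sizes)[sizes >= min_module_size]
    eligible <- eligible[vapply(eligible, function(m) {
      me_pve(residuals[best == as.integer(m), , drop = FALSE]) >= pve_min
    }, logical(1))]
    ## label modules M1, M2, ... in decreasing size order
    eligible <- eligible[order(-sizes[eligible])]
    for (i in seq_along(eligible)) {
      membership[best == as.integer(eligible[i])] <- paste0("M", i)
    }
  }

  ## merge modules with eigengene correlation > 1 - merge_cut
  compute_mes <- function(membership) {
    mods <- setdiff(unique(membership), "unassigned")
    mes <- lapply(mods, function(m)
      module_eigengene(residuals[membership == m, , drop = FALSE]))
    names(mes) <- mods
    mes
  }
  mes <- compute_mes(membership)
  repeat {
    if (length(mes) < 2) break
    memat <- do.call(cbind, mes)
    cc <- cor(memat)
    diag(cc) <- -Inf
    mx <- which(cc == max(cc), arr.ind = TRUE)[1, ]
    if (cc[mx[1], mx[2]] <= 1 - merge_cut) break
    from <- colnames(memat)[mx[2]]; into <- colnames(memat)[mx[1]]
    membership[membership == from] <- into
    mes <- compute_mes(membership)
  }
  ## relabel merged set by size again
  mods <- setdiff(unique(membership), "unassigned")
  mods <- mods[order(-vapply(mods, function(m) sum(membership == m), 1L))]
  relab <- setNames(paste0("M", seq_along(mods)), mods)
  membership[membership != "unassigned"] <- relab[membership[membership != "unassigned"]]
  mes <- compute_mes(membership)

  nsamp <- ncol(residuals)
  modules <- lapply(names(mes), function(m) {
    me <- mes[[m]]
    mm <- as.numeric(cor(t(residuals), me))
    names(mm) <- genes
    tstat <- mm * sqrt(nsamp - 2) / sqrt(pmax(1e-12, 1 - mm^2))
    mm_p <- 2 * pt(-abs(tstat), df = nsamp - 2)
    members <- names(membership)[membership == m]
    hubs <- members[order(mm_p[members])][seq_len(min(10, length(members)))]
    list(genes = members, ME = me, MM = mm, MM_p = mm_p, hubs = hubs)
  })
  names(modules) <- names(mes)
  structure(list(membership = membership, modules = modules,
                 params = list(beta = beta, min_module_size = min_module_size,
                               merge_cut = merge_cut)),
            class = "module_set")
}

#' @export
print.module_set <- function(x, ...) {
  sizes <- vapply(x$modules, function(m) length(m$genes), 1L)
  cat(sprintf("Co-expression modules: %d module(s) of %d genes (%d unassigned)\n",
              length(sizes), length(x$membership),
              sum(x$membership == "unassigned")))
  if (length(sizes)) {
    for (m in names(sizes)) cat(sprintf("  %s: %d genes\n", m, sizes[m]))
  }
  invisible(x)
}

#' Module-trait correlation and between-group eigengene comparison
#'
#' Pearson correlation of each module eigengene with a numeric trait (the
#' genotype coded 0/1 by convention), with its t-test p value, plus a
#' rank-sum comparison of the eigengene between the two trait groups when
#' the trait is binary.
#'
#' @param module_set a \code{module_set}.
#' @param trait numeric vector over samples (constant traits are an error).
#' @return data.frame per module: correlation, p, and (binary trait)
#'   rank-sum p.
#' @export
module_trait_correlation <- function(module_set, trait) {
  stopifnot(inherits(module_set, "module_set"))
  if (length(unique(trait)) < 2) stop("constant trait", call. = FALSE)
  rows <- lapply(names(module_set$modules), function(m) {
    me <- module_set$modules[[m]]$ME
    r <- cor(me, trait)
    n <- length(me)
    tstat <- r * sqrt(n - 2) / sqrt(pmax(1e-12, 1 - r^2))
    p <- 2 * pt(-abs(tstat), df = n - 2)
    ranksum_p <- NA_real_
    if (length(unique(trait)) == 2) {
      grp <- trait == max(trait)
      ranksum_p <- ranksum(me[!grp], me[grp])$p_value
    }
    data.frame(module = m, correlation = r, p = p, ranksum_p = ranksum_p)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Permutation Zsummary module preservation
#'
#' For each reference module, the preservation of (i) density — the mean
#' signed-hybrid intramodular adjacency in the test data — and (ii)
#' connectivity — the Spearman correlation between the genes' intramodular
#' connectivity in the reference and in the test data — is standardized
#' against a permutation null of random same-size gene sets drawn from the
#' test data. Zsummary is the mean of the two Z scores; > 2 suggests
#' moderate and > 10 strong preservation.
#'
#' @param reference_modules a \code{module_set} fitted on the reference
#'   data.
#' @param reference_residuals,test_residuals genes x samples matrices; gene
#'   universes must overlap.
#' @param n_permutations permutation count (>= 50).
#' @param seed RNG seed for the permutations.
#' @param beta soft power for the test-data adjacency.
#' @return data.frame per module: n_genes (overlapping), Z_density,
#'   Z_connectivity, Zsummary (NA, flagged, for modules with < 3 overlapping
#'   genes).
#' @export
preservation_zsummary <- function(reference_modules, reference_residuals,
                                  test_residuals, n_permutations = 100,
                                  seed = 1, beta = 12) {
  stopifnot(inherits(reference_modules, "module_set"))
  if (n_permutations < 50) stop("need >= 50 permutations", call. = FALSE)
  common <- intersect(rownames(reference_residuals), rownames(test_residuals))
  if (length(common) < 3) stop("gene universes do not overlap", call. = FALSE)
  a_test <- signed_hybrid_adjacency(test_residuals[common, , drop = FALSE], beta)
  a_ref <- signed_hybrid_adjacency(reference_residuals[common, , drop = FALSE], beta)
  rownames(a_test) <- colnames(a_test) <- common
  rownames(a_ref) <- colnames(a_ref) <- common

  set_stats <- function(genes_idx, kref) {
    sub <- a_test[genes_idx, genes_idx]
    dens <- mean(sub[upper.tri(sub)])
    ktest <- rowSums(sub)
    conn <- suppressWarnings(cor(kref, ktest, method = "spearman"))
    c(density = dens, connectivity = if (is.na(conn)) 0 else conn)
  }

  rows <- with_seed(seed, {
    lapply(names(reference_modules$modules), function(m) {
      genes <- intersect(reference_modules$modules[[m]]$genes, common)
      k <- length(genes)
      if (k < 3) {
        return(data.frame(module = m, n_genes = k, Z_density = NA_real_,
                          Z_connectivity = NA_real_, Zsummary = NA_real_,
                          flagged = TRUE))
      }
      idx <- match(genes, common)
      sub_ref <- a_ref[idx, idx]
      kref <- rowSums(sub_ref)
      obs <- set_stats(idx, kref)
      nulls <- replicate(n_permutations, {
        ridx <- sample(length(common), k)
        set_stats(ridx, kref)
      })
      zd <- (obs["density"] - mean(nulls["density", ])) / sd(nulls["density", ])
      zc <- (obs["connectivity"] - mean(nulls["connectivity", ])) / sd(nulls["connectivity", ])
      data.frame(module = m, n_genes = k, Z_density = unname(zd),
                 Z_connectivity = unname(zc), Zsummary = unname((zd + zc) / 2),
                 flagged = FALSE)
    })
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
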