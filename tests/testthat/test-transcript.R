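test_that("sample QC drops samples outside the configured bands with reasons", {
  g <- gen_counts(n_genes = 50, groups = rep(c("A", "B"), each = 3), seed = 1)
  meta <- g$meta
  q0 <- sample_qc(g$counts, meta)
  expect_equal(ncol(q0$counts), 6)
  expect_equal(nrow(q0$excluded), 0)
  meta$gene_count_pct[2] <- 39
  meta$strandness[5] <- 0.5009
  q <- sample_qc(g$counts, meta, min_gene_count_pct = 50)
  expect_equal(ncol(q$counts), 4)
  expect_equal(nrow(q$excluded), ncol(g$counts) - ncol(q$counts))
  expect_match(q$excluded$reason[1], "39")
  expect_match(q$excluded$reason[2], "strandness")
  meta$gene_count_pct[] <- 0
  expect_error(sample_qc(g$counts, meta), "all samples")
})

test_that("gene filter keeps the >= 10 counts in >= 4 samples boundary", {
  m <- rbind(c(rep(10, 4), 0, 0),
             c(rep(10, 3), 9, 0, 0),
             c(rep(1000, 3), 0, 0, 0))
  colnames(m) <- paste0("s", 1:6)
  expect_equal(nrow(filter_genes(m)), 1)
  set.seed(8)
  for (i in 1:10) {
    r <- matrix(rpois(300, 8), 30, 10)
    expect_identical(filter_genes(r), oracle_filter(r))
  }
})

test_that("TMM factors: identity, depth invariance, geometric mean 1", {
  set.seed(4)
  base <- matrix(rnbinom(3000, mu = 60, size = 10), 500, 6)
  same <- cbind(base[, 1], base[, 1], base[, 1])
  colnames(same) <- paste0("s", 1:3)
  expect_true(all(abs(tmm_factors(same) - 1) < 1e-9))
  depth <- cbind(base[, 1], base[, 1] * 2L, base[, 2])
  expect_true(all(abs(tmm_factors(depth) - 1) < 0.02))
  f <- tmm_factors(base)
  expect_equal(exp(mean(log(f))), 1, tolerance = 1e-9)
  expect_error(tmm_factors(base[, 1, drop = FALSE]), ">= 2")
})

test_that("TMM matches an independent re-derivation of the published formula", {
  set.seed(12)
  for (rep in 1:5) {
    m <- matrix(rnbinom(4000, mu = 80, size = 8), 500, 8)
    ## asymmetric planted composition shift in 5% of genes of one sample
    idx <- sample(500, 25)
    m[idx, 1] <- m[idx, 1] * 8L
    colnames(m) <- paste0("s", 1:8)
    f_pkg <- tmm_factors(m)
    f_orc <- oracle_tmm(m)
    expect_true(all(abs(f_pkg / f_orc - 1) < 0.02))
  }
})

test_that("gene-wise NB test is calibrated under the null", {
  ks_p <- vapply(1:20, function(s) {
    g <- gen_counts(n_genes = 400, groups = rep(c("A", "B"), each = 5), seed = s)
    filt <- filter_genes(g$counts)
    de <- genewise_de_test(filt, tmm_factors(filt), g$meta$group)
    suppressWarnings(ks.test(de$p_value, "punif")$p.value)
  }, numeric(1))
  expect_true(all(ks_p > 0.001))
})

test_that("planted log2 fold-changes are recovered", {
  g <- gen_counts(n_genes = 1000, groups = rep(c("A", "B"), each = 5),
                  nb_dispersion = 0.05,
                  de_genes = setNames(rep(2, 50), as.character(1:50)), seed = 5)
  filt <- g$counts     # keep planted indices aligned; all genes expressed
  de <- genewise_de_test(filt, tmm_factors(filt), g$meta$group)
  expect_lt(abs(median(de$log2FC[1:50]) - 2), 0.2)
  de$fdr <- bh_adjust(de$p_value)
  cls <- classify_deg(de)
  expect_gt(sum(cls$status[1:50] == "up"), 40)
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(bh_adjust(c(0.2, 0.2, 0.2)), c(0.2, 0.2, 0.2))
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  set.seed(2)
  for (i in 1:10) {
    p <- runif(sample(5:50, 1))
    expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-12)
  }
})

test_that("DEG classification applies strict FDR and log2FC thresholds", {
  grid <- expand.grid(fdr = c(0.01, 0.049, 0.05, 0.2),
                      log2FC = c(-1, -0.26, -0.25, 0, 0.25, 0.2500001, 1))
  cls <- classify_deg(grid)
  expect_equal(as.character(cls$status),
               ifelse(grid$fdr < 0.05 & grid$log2FC > 0.25, "up",
                      ifelse(grid$fdr < 0.05 & grid$log2FC < -0.25, "down", "ns")))
  ## |log2FC| > 0.25 is |FC| > 2^0.25, consistent with a 1.2-fold rounding
  expect_equal(2^0.25, 1.19, tolerance = 0.01)
  expect_equal(cls$volcano_y, -log10(grid$fdr))
})

test_that("hierarchical clustering uses standardized Euclidean distances", {
  set.seed(6)
  x <- matrix(rnorm(200, sd = rep(c(1, 10), each = 10)), 20, 10)
  h <- hier_cluster(x)
  d_pkg <- as.matrix(dist(t(h$standardized)))
  expect_equal(d_pkg, oracle_std_euclid(x), tolerance = 1e-9,
               ignore_attr = TRUE)
  ## identical samples merge first
  x2 <- cbind(x, x[, 1])
  h2 <- suppressWarnings(hier_cluster(x2))
  expect_equal(h2$col_hclust$height[1], 0, tolerance = 1e-9)
  expect_warning(hier_cluster(rbind(x, 0)), "zero-variance")
  expect_error(hier_cluster(x[1, , drop = FALSE]), ">= 2 rows")
})

test_that("residualization is orthogonal to the covariate design", {
  g <- gen_counts(n_genes = 60, groups = rep(c("A", "B"), each = 6), seed = 3)
  expr <- log2(g$counts + 1)
  covs <- g$meta[, c("sex", "strandness", "exonic_rate")]
  res <- residualize(expr, covs)
  X <- model.matrix(~ ., data = covs)
  expect_lt(max(abs(res %*% X)), 1e-8)
  ## expression exactly linear in a covariate residualizes to ~0
  lin <- matrix(rep(as.numeric(covs$sex == "M"), each = 5) * 3 + 7, 5,
                nrow(covs), byrow = FALSE)
  expect_lt(max(abs(residualize(lin, covs))), 1e-9)
  bad <- covs; bad$dup <- as.numeric(bad$sex == "M")
  expect_error(residualize(expr, bad), "collinear")
})

test_that("a planted co-expression module is recovered and noise yields none", {
  recovery <- vapply(1:10, function(s) {
    g <- gen_counts(n_genes = 300, groups = rep(c("WT", "Hom"), each = 10),
                    module_genes = 1:60, module_loading = 1.5, seed = s)
    ms <- build_modules(make_residuals(g))
    mod_genes <- rownames(g$counts)[1:60]
    if (length(ms$modules) == 0) return(0)
    max(vapply(ms$modules, function(m) mean(mod_genes %in% m$genes), numeric(1)))
  }, numeric(1))
  expect_gte(median(recovery), 0.8)
  n_null <- vapply(1:10, function(s) {
    g <- gen_counts(n_genes = 300, groups = rep(c("WT", "Hom"), each = 10),
                    seed = 100 + s)
    length(build_modules(make_residuals(g))$modules)
  }, numeric(1))
  expect_equal(median(n_null), 0)
})

test_that("modules with correlated eigengenes merge and MEs are extremal", {
  g <- gen_counts(n_genes = 200, groups = rep(c("WT", "Hom"), each = 10),
                  module_genes = 1:80, module_loading = 1.8, seed = 42)
  res <- make_residuals(g)
  ## split the planted module in two: both halves load on the same factor,
  ## so their eigengenes correlate far above 0.6 and must merge
  ms <- build_modules(res, min_module_size = 30)
  sizes <- vapply(ms$modules, function(m) length(m$genes), numeric(1))
  big <- names(sizes)[which.max(sizes)]
  expect_gte(max(vapply(ms$modules, function(m)
    mean(rownames(g$counts)[1:80] %in% m$genes), numeric(1))), 0.8)
  ## |MM| <= 1 and the eigengene maximizes explained variance vs random
  ## unit directions
  me <- ms$modules[[big]]$ME
  expect_lte(max(abs(ms$modules[[big]]$MM)), 1)
  expect_equal(sum(me^2), 1, tolerance = 1e-9)
  memb <- res[ms$modules[[big]]$genes, ]
  xs <- t(scale(t(memb)))
  v_me <- mean((xs %*% me)^2)
  set.seed(1)
  v_rand <- vapply(1:1000, function(i) {
    u <- rnorm(ncol(xs)); u <- u / sqrt(sum(u^2))
    mean((xs %*% u)^2)
  }, numeric(1))
  expect_gte(v_me / max(v_rand), 1)
})

test_that("module-trait correlation flags the genotype-loaded module", {
  hit <- vapply(1:20, function(s) {
    g <- gen_counts(n_genes = 200, groups = rep(c("WT", "Hom"), each = 10),
                    module_genes = 1:60, module_loading = 1.5,
                    module_trait_r2 = 0.5, seed = s)
    ms <- build_modules(make_residuals(g))
    if (length(ms$modules) == 0) return(NA)
    tr <- as.numeric(g$meta$group == "Hom")
    mt <- module_trait_correlation(ms, tr)
    mod_genes <- rownames(g$counts)[1:60]
    best <- which.max(vapply(ms$modules, function(m)
      mean(mod_genes %in% m$genes), numeric(1)))
    mt$ranksum_p[best] < 0.05
  }, logical(1))
  expect_gte(mean(hit, na.rm = TRUE), 0.9)
  g <- gen_counts(n_genes = 100, groups = rep(c("A", "B"), each = 5), seed = 1)
  ms <- build_modules(make_residuals(g), min_module_size = 10, pve_min = 0)
  expect_error(module_trait_correlation(ms, rep(1, 10)), "constant trait")
})

test_that("Zsummary separates preserved from non-preserved modules", {
  gref <- gen_counts(n_genes = 300, groups = rep(c("WT", "Hom"), each = 10),
                     module_genes = 1:60, module_loading = 1.5, seed = 21)
  rref <- make_residuals(gref)
  ms <- build_modules(rref)
  mod_genes <- rownames(gref$counts)[1:60]
  best <- names(which.max(vapply(ms$modules, function(m)
    mean(mod_genes %in% m$genes), numeric(1))))
  ## test data identical to reference: strong preservation
  z_same <- preservation_zsummary(ms, rref, rref, n_permutations = 100, seed = 1)
  expect_gt(z_same$Zsummary[z_same$module == best], 10)
  ## same module planted in an independent replicate: preserved
  gtest <- gen_counts(n_genes = 300, groups = rep(c("WT", "Hom"), each = 10),
                      module_genes = 1:60, module_loading = 1.5, seed = 22)
  z_rep <- preservation_zsummary(ms, rref, make_residuals(gtest),
                                 n_permutations = 100, seed = 1)
  expect_gt(z_rep$Zsummary[z_rep$module == best], 2)
  ## module absent from the test data: not preserved
  g0 <- gen_counts(n_genes = 300, groups = rep(c("WT", "Hom"), each = 10), seed = 23)
  z_null <- preservation_zsummary(ms, rref, make_residuals(g0),
                                  n_permutations = 100, seed = 1)
  expect_lt(z_null$Zsummary[z_null$module == best], 2)
  expect_error(preservation_zsummary(ms, rref, rref, n_permutations = 10), "50")
})
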