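## The study-style statistical decision rule and the tests it dispatches to.
## Sample sizes above 7 get rank-based tests (Kruskal-Wallis with uncorrected
## Dunn pairwise comparisons for 3+ groups, Wilcoxon rank-sum for 2); small
## samples get an unpaired t test, with Welch's correction when an F-test
## flags unequal variances; paired designs get the matched-pairs signed-rank
## test.

#' Choose the comparison test from the study's decision rule
#'
#' @param group_sizes integer vector of per-group sample sizes.
#' @param paired TRUE for matched-pairs designs.
#' @param n_groups number of groups (defaults to \code{length(group_sizes)}).
#' @param variance_f_test_p p value of an F-test of equal variances (used
#'   only on the small-sample branch; may be NA for the large-sample branch).
#' @param alpha_var significance level for the variance F-test.
#' @param large_n sample-size cutoff above which rank tests are used.
#' @return object of class \code{test_plan}: \code{test} in
#'   \code{kruskal_dunn, ranksum, signed_rank, t_unpaired, t_welch} and a
#'   \code{rationale} string.
#' @export
choose_test <- function(group_sizes, paired = FALSE,
                        n_groups = length(group_sizes),
                        variance_f_test_p = NA_real_, alpha_var = 0.05,
                        large_n = 7) {
  if (any(group_sizes < 1)) stop("empty group", call. = FALSE)
  if (paired) {
    test <- "signed_rank"
    rationale <- "paired design: Wilcoxon matched-pairs signed-rank test"
  } else if (max(group_sizes) > large_n || n_groups > 2) {
    if (n_groups > 2) {
      test <- "kruskal_dunn"
      rationale <- sprintf("%d groups (n = %s): Kruskal-Wallis with uncorrected Dunn pairwise tests",
                           n_groups, paste(group_sizes, collapse = ", "))
    } else {
      test <- "ranksum"
      rationale <- sprintf("n = %s > %d: Wilcoxon rank-sum test",
                           paste(group_sizes, collapse = ", "), large_n)
    }
  } else {
    if (is.na(variance_f_test_p)) {
      stop("small-sample branch needs a variance F-test p value", call. = FALSE)
    }
    if (variance_f_test_p >= alpha_var) {
      test <- "t_unpaired"
      rationale <- sprintf("n <= %d, F-test p = %.3g >= %.2f (similar variances): unpaired t test",
                           large_n, variance_f_test_p, alpha_var)
    } else {
      test <- "t_welch"
      rationale <- sprintf("n <= %d, F-test p = %.3g < %.2f (unequal variances): Welch's t test",
                           large_n, variance_f_test_p, alpha_var)
    }
  }
  structure(list(test = test, rationale = rationale, group_sizes = group_sizes),
            class = "test_plan")
}

#' @export
print.test_plan <- function(x, ...) {
  cat("Test plan:", x$test, "\n  ", x$rationale, "\n")
  invisible(x)
}

#' Apply a test plan to grouped data
#'
#' @param plan a \code{test_plan}.
#' @param groups list of numeric vectors (for \code{signed_rank}, a list of
#'   the two paired vectors).
#' @return list with \code{p_value}, \code{statistic}, and for
#'   \code{kruskal_dunn} the pairwise table.
#' @export
apply_test_plan <- function(plan, groups) {
  switch(plan$test,
    kruskal_dunn = {
      r <- kruskal_dunn(groups)
      list(p_value = r$omnibus_p, statistic = r$statistic, pairwise = r$pairwise)
    },
    ranksum = ranksum(groups[[1]], groups[[2]]),
    signed_rank = signed_rank(groups[[1]], groups[[2]]),
    t_unpaired = t_test(groups[[1]], groups[[2]], welch = FALSE),
    t_welch = t_test(groups[[1]], groups[[2]], welch = TRUE),
    stop("unknown test: ", plan$test)
  )
}

#' Kruskal-Wallis omnibus test with uncorrected Dunn pairwise comparisons
#'
#' Omnibus rank statistic with tie correction; pairwise Dunn z statistics on
#' the pooled ranks. Pairwise p values are deliberately NOT adjusted for
#' multiplicity (set \code{adjust = "bonferroni"} to adjust).
#'
#' @param groups list of >= 3 numeric vectors.
#' @param adjust multiplicity adjustment for the pairwise p values
#'   (\code{"none"}, the study's convention, or \code{"bonferroni"}).
#' @return list: \code{omnibus_p}, \code{statistic}, \code{pairwise}
#'   data.frame (group_i, group_j, z, p).
#' @export
kruskal_dunn <- function(groups, adjust = c("none", "bonferroni")) {
  adjust <- match.arg(adjust)
  if (length(groups) < 3) stop("kruskal_dunn needs >= 3 groups", call. = FALSE)
  if (any(vapply(groups, length, 1L) < 2)) stop("each group needs >= 2 values", call. = FALSE)
  x <- unlist(groups)
  g <- factor(rep(seq_along(groups), vapply(groups, length, 1L)))
  if (diff(range(x)) == 0) {
    pw <- t(utils::combn(length(groups), 2))
    pairwise <- data.frame(group_i = pw[, 1], group_j = pw[, 2], z = 0, p = 1)
    return(list(omnibus_p = 1, statistic = 0, pairwise = pairwise))
  }
  kw <- kruskal.test(x, g)
  ## Dunn pairwise z on pooled ranks with tie correction
  r <- rank(x)
  n <- length(x)
  ties <- table(x)
  tie_term <- sum(ties^3 - ties) / (12 * (n - 1))
  mean_r <- tapply(r, g, mean)
  n_g <- tapply(r, g, length)
  pw <- t(utils::combn(length(groups), 2))
  z <- apply(pw, 1, function(ij) {
    i <- ij[1]; j <- ij[2]
    se <- sqrt((n * (n + 1) / 12 - tie_term) * (1 / n_g[i] + 1 / n_g[j]))
    (mean_r[i] - mean_r[j]) / se
  })
  p <- 2 * pnorm(-abs(z))
  if (adjust == "bonferroni") p <- pmin(1, p * nrow(pw))
  list(omnibus_p = kw$p.value, statistic = unname(kw$statistic),
       pairwise = data.frame(group_i = pw[, 1], group_j = pw[, 2],
                             z = as.numeric(z), p = as.numeric(p)))
}

#' Two-sided Wilcoxon rank-sum test
#' @export
ranksum <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) stop("each sample needs >= 2 values", call. = FALSE)
  w <- suppressWarnings(wilcox.test(a, b, exact = NULL, correct = FALSE))
  list(p_value = w$p.value, statistic = unname(w$statistic))
}

#' Two-sided Wilcoxon matched-pairs signed-rank test
#'
#' For 12 or fewer nonzero differences the null is enumerated exactly over
#' all sign patterns of the observed absolute ranks (valid under ties);
#' larger samples use the normal approximation with tie correction.
#' @export
signed_rank <- function(a, b) {
  d <- a - b
  if (length(d) < 1) stop("no pairs", call. = FALSE)
  d <- d[d != 0]
  if (length(d) == 0) {
    warning("all paired differences are zero; p = 1")
    return(list(p_value = 1, statistic = NA_real_))
  }
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r * sign(d))
  if (n <= 12) {
    ## exact enumeration of the 2^n equiprobable sign patterns
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    w_null <- as.numeric(signs %*% r)
    p <- mean(abs(w_null) >= abs(w_obs) - 1e-9)
  } else {
    w <- suppressWarnings(wilcox.test(a, b, paired = TRUE, exact = FALSE,
                                      correct = FALSE))
    return(list(p_value = w$p.value, statistic = unname(w$statistic)))
  }
  list(p_value = p, statistic = w_obs)
}

#' Two-sided unpaired t test (optionally with Welch's correction)
#' @export
t_test <- function(a, b, welch = FALSE) {
  tt <- t.test(a, b, var.equal = !welch)
  list(p_value = tt$p.value, statistic = unname(tt$statistic),
       df = unname(tt$parameter))
}

#' F-test of equal variances
#' @export
f_test_var <- function(a, b) {
  v <- var.test(a, b)
  list(p_value = v$p.value, statistic = unname(v$statistic))
}

#' Compare regression slopes between two groups (one-way ANCOVA)
#'
#' F-test of the group-by-x interaction in the two-line linear model
#' \code{y ~ x * group}; a significant interaction means the slopes differ.
#'
#' @param points_a,points_b data.frames with columns \code{x} and \code{y}.
#' @return list: \code{p_value}, \code{F}, \code{slopes} (per-group fitted
#'   slopes).
#' @export
ancova_slopes <- function(points_a, points_b) {
  for (pts in list(points_a, points_b)) {
    if (nrow(pts) < 3) stop("each group needs >= 3 points", call. = FALSE)
    if (diff(range(pts$x)) == 0) stop("constant x in a group", call. = FALSE)
  }
  dat <- rbind(data.frame(points_a, g = "a"), data.frame(points_b, g = "b"))
  dat$g <- factor(dat$g)
  full <- lm(y ~ x * g, data = dat)
  reduced <- lm(y ~ x + g, data = dat)
  an <- anova(reduced, full)
  slopes <- c(a = unname(coef(full)["x"]),
              b = unname(coef(full)["x"] + coef(full)["x:gb"]))
  Fstat <- an$F[2]; p <- an$`Pr(>F)`[2]
  ## perfectly collinear groups: interaction and residual sums of squares
  ## both vanish and the F ratio is numerical noise
  if (an$`Sum of Sq`[2] < 1e-10 * (sum(dat$y^2) + 1)) {
    Fstat <- 0; p <- 1
  }
  list(p_value = p, F = Fstat, slopes = slopes)
}
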