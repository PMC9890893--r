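## First-order interstitial-fluid elimination kinetics from hourly
## microdialysis fractions: semi-log slope, Ke, half-life.

new_dialysate_series <- function(t_h, conc, animal_id = "a1") {
  if (any(diff(t_h) <= 0)) stop("fraction times must be strictly increasing", call. = FALSE)
  structure(
    list(t_h = t_h, conc = conc, animal_id = animal_id),
    class = "dialysate_series"
  )
}

#' Construct a dialysate series from a fraction table
#'
#' @param t_h fraction times in hours relative to the production-inhibitor
#'   dose at t = 0 (baseline fractions at negative hours).
#' @param conc concentrations (pg/mL).
#' @param animal_id animal identifier.
#' @export
dialysate_series <- function(t_h, conc, animal_id = "a1") {
  new_dialysate_series(t_h, conc, animal_id)
}

#' @export
print.dialysate_series <- function(x, ...) {
  cat(sprintf("Dialysate series [%s]: %d fractions (%d baseline, %d post-dose)\n",
              x$animal_id, length(x$t_h), sum(x$t_h < 0), sum(x$t_h > 0)))
  invisible(x)
}

#' Mean baseline concentration
#'
#' Arithmetic mean of the concentrations of all fractions collected before
#' the inhibitor dose (t < 0).
#' @param series a \code{dialysate_series}.
#' @export
baseline_mean <- function(series) {
  stopifnot(inherits(series, "dialysate_series"))
  base <- series$conc[series$t_h < 0]
  if (length(base) == 0) stop("no baseline fractions (t < 0)", call. = FALSE)
  mean(base)
}

#' Fit first-order elimination kinetics to a post-dose dialysate series
#'
#' Ordinary least squares of log10(concentration) on time over the post-dose
#' fractions (t > 0; the t = 0 fraction, collected while the dose takes
#' effect, is excluded by default). The semi-log slope \code{a} converts to
#' the elimination rate constant as \code{Ke = -a * ln(10)} and the half-life
#' as \code{ln(2) / Ke}. With \code{paper_constants = TRUE} the rounded
#' constants 2.3 and 0.693 that appear in the classic pharmacokinetic
#' shorthand are used instead (\code{Ke = -2.3 a}, \code{T1/2 = 0.693 / Ke}).
#'
#' @param series a \code{dialysate_series}.
#' @param paper_constants use the rounded constants 2.3 / 0.693 instead of
#'   full-precision ln(10) / ln(2).
#' @param include_t0 include a fraction at exactly t = 0 in the fit.
#' @return object of class \code{elimination_fit} with fields
#'   \code{a_log10_per_h}, \code{Ke_per_h}, \code{half_life_h}, \code{r2},
#'   \code{n_points} and the constants used; supports \code{print},
#'   \code{coef}, \code{predict} (concentration at new times) and
#'   \code{residuals} (log10 scale).
#' @export
fit_elimination <- function(series, paper_constants = FALSE, include_t0 = FALSE) {
  stopifnot(inherits(series, "dialysate_series"))
  sel <- if (include_t0) series$t_h >= 0 else series$t_h > 0
  t <- series$t_h[sel]; conc <- series$conc[sel]
  if (length(t) < 2) stop("need >= 2 post-dose fractions to fit", call. = FALSE)
  bad <- which(conc <= 0)
  if (length(bad)) {
    stop(sprintf("nonpositive concentration in post-dose fraction at t = %g h",
                 t[bad[1]]), call. = FALSE)
  }
  ln10 <- if (paper_constants) 2.3 else log(10)
  ln2 <- if (paper_constants) 0.693 else log(2)
  y <- log10(conc)
  fit <- lm(y ~ t)
  a <- unname(coef(fit)[2])
  Ke <- -ln10 * a
  half_life <- if (Ke > 0) ln2 / Ke else NA_real_
  structure(
    list(a_log10_per_h = a,
         intercept_log10 = unname(coef(fit)[1]),
         Ke_per_h = Ke,
         half_life_h = half_life,
         r2 = suppressWarnings(summary(fit)$r.squared),
         n_points = length(t),
         t_h = t, conc = conc,
         paper_constants = paper_constants,
         constants = c(ln10 = ln10, ln2 = ln2),
         animal_id = series$animal_id),
    class = "elimination_fit"
  )
}

#' @export
print.elimination_fit <- function(x, ...) {
  cat(sprintf("First-order elimination fit [%s], %d post-dose fractions\n",
              x$animal_id, x$n_points))
  cat(sprintf("  semi-log slope a = %.4f log10/h, Ke = %.4f /h, T1/2 = %s h, R^2 = %.4f\n",
              x$a_log10_per_h, x$Ke_per_h,
              if (is.na(x$half_life_h)) "undefined (no decay)" else sprintf("%.4f", x$half_life_h),
              x$r2))
  invisible(x)
}

#' @export
coef.elimination_fit <- function(object, ...) {
  c(a_log10_per_h = object$a_log10_per_h, Ke_per_h = object$Ke_per_h,
    half_life_h = object$half_life_h)
}

#' @export
predict.elimination_fit <- function(object, t_h = object$t_h, ...) {
  10^(object$intercept_log10 + object$a_log10_per_h * t_h)
}

#' @export
residuals.elimination_fit <- function(object, ...) {
  log10(object$conc) - (object$intercept_log10 + object$a_log10_per_h * object$t_h)
}

#' Compare half-lives between two groups of fitted animals
#'
#' Per-animal half-lives are normalized to the mean of the reference group
#' (group A); the comparison test is chosen by \code{\link{choose_test}} from
#' the study's decision rule.
#'
#' @param group_fits_a,group_fits_b lists of \code{elimination_fit} (group A
#'   is the reference).
#' @return list: normalized half-lives per group, group means, the
#'   \code{test_plan} and the test result (p value, statistic).
#' @export
compare_half_lives <- function(group_fits_a, group_fits_b) {
  pull <- function(fits, label) {
    hl <- vapply(fits, `[[`, numeric(1), "half_life_h")
    und <- !is.finite(hl)
    if (any(und)) {
      warning(sprintf("%d %s fit(s) with undefined half-life excluded", sum(und), label))
      hl <- hl[!und]
    }
    hl
  }
  a <- pull(group_fits_a, "group A"); b <- pull(group_fits_b, "group B")
  if (length(a) < 2 || length(b) < 2) stop("each group needs >= 2 usable animals", call. = FALSE)
  ref <- mean(a)
  na <- a / ref; nb <- b / ref
  fp <- f_test_var(na, nb)$p_value
  if (is.na(fp)) fp <- 1          # degenerate zero-variance groups
  plan <- choose_test(group_sizes = c(length(na), length(nb)), paired = FALSE,
                      variance_f_test_p = fp)
  res <- if (sd(c(na, nb)) == 0) {
    list(p_value = 1, statistic = NA_real_)   # all values identical
  } else {
    ## noise-free groups can be internally constant; the comparison is then
    ## degenerate and only the normalized means are meaningful
    tryCatch(apply_test_plan(plan, list(na, nb)),
             error = function(e) list(p_value = NA_real_, statistic = NA_real_))
  }
  list(normalized_a = na, normalized_b = nb,
       mean_a = mean(na), mean_b = mean(nb),
       plan = plan, p_value = res$p_value, statistic = res$statistic)
}
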