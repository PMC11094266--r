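# Statistical primitives shared by every pipeline stage. Standard tests are
# delegated to stats/survival; fisher_exact is computed from the hypergeometric
# mass (stats::dhyper) so the pipeline can vectorise thousands of gene tables.

new_pm_test <- function(statistic, p_value, effect_direction, extra = list(),
                        degenerate = FALSE) {
  structure(list(statistic = statistic, p_value = p_value,
                 effect_direction = effect_direction, extra = extra,
                 degenerate = degenerate),
            class = "pm_test")
}

#' @export
print.pm_test <- function(x, ...) {
  cat(sprintf("pm_test: statistic = %.4g, p = %.4g, direction = %+d%s\n",
              x$statistic, x$p_value, x$effect_direction,
              if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

#' Fisher's exact test on a 2x2 table
#'
#' Exact conditional test of association for the table
#' \code{rbind(c(a, b), c(c, d))}. The two-sided p-value sums all tables with
#' the fixed margins whose hypergeometric probability does not exceed the
#' observed table's; `"greater"` is the one-sided enrichment tail (odds ratio
#' greater than one, i.e. the top-left cell at least as large as observed).
#'
#' @param a,b,c,d nonnegative cell counts (row = condition, column = group).
#' @param alternative `"two_sided"` or `"greater"`.
#' @return a `pm_test` with the sample odds ratio in `extra$odds_ratio` and
#'   `effect_direction = sign(ad - bc)`. An all-zero table is degenerate with
#'   p = 1 and direction 0.
#' @export
fisher_exact <- function(a, b, c, d, alternative = c("two_sided", "greater")) {
  alternative <- match.arg(alternative)
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts)))
    pm_stop("cell counts must be nonnegative integers")
  if (sum(counts) == 0)
    return(new_pm_test(0, 1, 0L, list(odds_ratio = NaN), degenerate = TRUE))
  p <- if (alternative == "greater") {
    fisher_p_greater(a, b, c, d)
  } else {
    fisher_p_two_sided(a, b, c, d)
  }
  or <- (a * d) / (b * c)
  new_pm_test(a, min(1, p), sign_int(a * d - b * c),
              list(odds_ratio = or))
}

sign_int <- function(x) as.integer(sign(x))

# One-sided (enrichment) tail, vectorised over tables.
fisher_p_greater <- function(a, b, c, d) {
  pmin(1, phyper(a - 1, a + b, c + d, a + c, lower.tail = FALSE))
}

# Two-sided p: sum of hypergeometric point masses <= observed mass, with the
# same relative tolerance stats::fisher.test uses for ties.
fisher_p_two_sided <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0, k - n); hi <- min(k, m)
  x <- lo:hi
  dens <- dhyper(x, m, n, k)
  obs <- dhyper(a, m, n, k)
  min(1, sum(dens[dens <= obs * (1 + 1e-7)]))
}

#' Two-sample Student's t-test (pooled variance)
#'
#' Equal-variance two-sample t-test with a two-sided p-value. The mean
#' difference `mean(x) - mean(y)` is reported in `extra$mean_difference`.
#' When the pooled variance is zero the test is degenerate: p = 1 and t = 0
#' for equal means, p = 0 with an infinite statistic otherwise.
#'
#' @param x,y numeric vectors, each of length >= 2 (NAs dropped).
#' @return a `pm_test`.
#' @export
student_t <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2)
    pm_stop("each group needs at least 2 non-missing values")
  diff <- mean(x) - mean(y)
  sp2 <- ((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
    (length(x) + length(y) - 2)
  if (sp2 == 0) {
    if (diff == 0)
      return(new_pm_test(0, 1, 0L, list(mean_difference = 0),
                         degenerate = TRUE))
    return(new_pm_test(sign(diff) * Inf, 0, sign_int(diff),
                       list(mean_difference = diff), degenerate = TRUE))
  }
  fit <- t.test(x, y, var.equal = TRUE)
  new_pm_test(unname(fit$statistic), fit$p.value, sign_int(diff),
              list(mean_difference = diff, df = unname(fit$parameter)))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted values in the original order, capped at 1.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    pm_stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Two-group logrank test
#'
#' Chi-square (1 df) logrank comparison of survival between group A and
#' group B. `effect_direction` is the sign of observed minus expected events
#' in group A (positive = group A fares worse). With zero events overall the
#' test is degenerate and p = 1.
#'
#' @param time_a,event_a times (nonnegative) and event indicators for group A.
#' @param time_b,event_b same for group B.
#' @return a `pm_test` with `extra$observed_a` and `extra$expected_a`.
#' @export
logrank_test <- function(time_a, event_a, time_b, event_b) {
  if (!length(time_a) || !length(time_b))
    pm_stop("both groups must be non-empty")
  if (any(c(time_a, time_b) < 0)) pm_stop("times must be nonnegative")
  ev <- c(as.logical(event_a), as.logical(event_b))
  if (!any(ev))
    return(new_pm_test(0, 1, 0L, list(observed_a = 0, expected_a = 0),
                       degenerate = TRUE))
  grp <- factor(rep(c("A", "B"), c(length(time_a), length(time_b))),
                levels = c("A", "B"))
  sd <- tryCatch(survdiff(Surv(c(time_a, time_b), ev) ~ grp),
                 error = function(e) NULL)
  if (is.null(sd))  # zero-variance risk sets (all events inside one group)
    return(new_pm_test(0, 1, 0L, list(observed_a = NA, expected_a = NA),
                       degenerate = TRUE))
  stat <- unname(sd$chisq)
  p <- pchisq(stat, df = 1, lower.tail = FALSE)
  new_pm_test(stat, p, sign_int(sd$obs[1] - sd$exp[1]),
              list(observed_a = unname(sd$obs[1]),
                   expected_a = unname(sd$exp[1])))
}

#' Univariate Cox proportional-hazards fit
#'
#' Fits a single binary covariate by Newton-Raphson on the Breslow partial
#' likelihood (via \pkg{survival}) and reports the log hazard ratio with a
#' Wald 95\% confidence interval. A monotone likelihood (all events at one
#' extreme) is flagged as non-converged with a signed infinite hazard-ratio
#' sentinel.
#'
#' @param times,events survival times and event indicators.
#' @param group binary covariate (logical, 0/1 or two-level factor); the
#'   hazard ratio is for the second level / `TRUE` / 1 versus the other.
#' @return a `pm_test` with statistic = log hazard ratio and `extra`
#'   containing `hr`, `ci_lower`, `ci_upper`, `se`, `converged`.
#' @export
cox_univariate <- function(times, events, group) {
  g <- if (is.factor(group)) as.integer(group) - 1L else as.integer(as.logical(group))
  events <- as.logical(events)
  if (!any(events)) pm_stop("need at least one event")
  if (length(unique(g)) < 2) pm_stop("group covariate must take two values")
  fit <- withCallingHandlers(
    coxph(Surv(times, events) ~ g, ties = "breslow"),
    warning = function(w) invokeRestart("muffleWarning"))
  beta <- unname(fit$coefficients)
  se <- sqrt(unname(fit$var[1, 1]))
  converged <- is.finite(beta) && abs(beta) < 15
  if (!converged) beta_rep <- sign(beta) * Inf else beta_rep <- beta
  p <- 2 * stats::pnorm(-abs(beta / se))
  new_pm_test(beta_rep, p, sign_int(beta),
              list(hr = exp(beta_rep), ci_lower = exp(beta - 1.96 * se),
                   ci_upper = exp(beta + 1.96 * se), se = se,
                   converged = converged),
              degenerate = !converged)
}

#' Median stratification into upper and lower expression groups
#'
#' Values strictly above the median are `"upper"`; values at or below the
#' median are `"lower"` (deterministic tie rule preserving "upper = strictly
#' above median"). Missing values get `NA` labels.
#'
#' @param values numeric vector with at least 4 non-missing values.
#' @return factor of labels `lower`/`upper` along `values`.
#' @export
median_stratify <- function(values) {
  ok <- !is.na(values)
  if (sum(ok) < 4) pm_stop("need at least 4 non-missing values to stratify")
  v <- values[ok]
  if (length(unique(v)) == 1L) pm_stop("degenerate stratification: all values identical")
  med <- median(v)
  lab <- rep(NA_character_, length(values))
  lab[ok] <- ifelse(values[ok] > med, "upper", "lower")
  if (!any(lab == "upper", na.rm = TRUE) || !any(lab == "lower", na.rm = TRUE))
    pm_stop("degenerate stratification: one group empty")
  factor(lab, levels = c("lower", "upper"))
}
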