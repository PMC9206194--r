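#' Bin a continuous covariate into quartiles
#'
#' Cut points are the empirical 25/50/75 percentiles of the non-missing
#' values; a value equal to a cut point goes to the lower bin. Missing values
#' stay `NA` (they are dropped from the relevant univariate analysis, not
#' from the data).
#'
#' @param x Numeric vector.
#' @return List with `labels` (factor `Q1`-`Q4`, `NA` preserved) and
#'   `cut_points` (the three interior percentiles).
#' @examples
#' quartile_bin(1:8)$labels
#' @export
quartile_bin <- function(x) {
  ok <- !is.na(x)
  if (sum(ok) < 4) stop("need at least 4 non-missing values", call. = FALSE)
  cuts <- stats::quantile(x[ok], probs = c(0.25, 0.5, 0.75), names = FALSE,
                          type = 7)
  if (anyDuplicated(cuts) || length(unique(x[ok])) == 1) {
    stop("quartile cut points are not distinct (degenerate distribution)",
         call. = FALSE)
  }
  labels <- cut(x, breaks = c(-Inf, cuts, Inf),
                labels = c("Q1", "Q2", "Q3", "Q4"), right = TRUE)
  list(labels = labels, cut_points = cuts)
}

#' Restrict access records to the lost-vs-maintained comparison
#'
#' The univariate odds-ratio analysis contrasts tracts that lost access with
#' tracts that maintained it; tracts that never had access and tracts that
#' gained access are excluded.
#'
#' @param records Access records with a `category` column.
#' @return The lost/maintained subset.
#' @export
exclude_for_or_analysis <- function(records) {
  out <- dplyr::filter(records, .data$category %in% c("lost", "maintained"))
  if (nrow(out) == 0) {
    stop("no lost or maintained tracts to analyse", call. = FALSE)
  }
  out
}

#' Odds ratio with Wald confidence interval from a 2x2 table
#'
#' Cross-product odds ratio with the standard large-sample Wald interval
#' `exp(log OR +/- z * sqrt(sum of reciprocal cells))`. For a binary
#' predictor this equals the exponentiated coefficient of a univariate
#' logistic regression.
#'
#' @param exposed_cases,exposed_controls,ref_cases,ref_controls Cell counts;
#'   cases are the outcome of interest (e.g. lost access), the reference
#'   level forms the denominator of the odds ratio.
#' @param conf_level Confidence level, default 0.95.
#' @return List with `or`, `ci_low`, `ci_high`, `log_se` and `cells`.
#' @export
odds_ratio_wald <- function(exposed_cases, exposed_controls,
                            ref_cases, ref_controls, conf_level = 0.95) {
  cells <- c(exposed_cases = exposed_cases, exposed_controls = exposed_controls,
             ref_cases = ref_cases, ref_controls = ref_controls)
  if (any(cells <= 0)) {
    stop("all four cells must be positive for a finite Wald interval ",
         "(continuity corrections are out of scope)", call. = FALSE)
  }
  or <- (exposed_cases * ref_controls) / (exposed_controls * ref_cases)
  se <- sqrt(sum(1 / cells))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(or = or,
       ci_low = exp(log(or) - z * se),
       ci_high = exp(log(or) + z * se),
       log_se = se,
       cells = cells)
}

#' Univariate odds of losing vs maintaining access, by predictor level
#'
#' For each non-reference level of a categorical predictor, computes the odds
#' ratio of the outcome relative to the reference level with a 95% Wald
#' interval. Rows with a missing predictor are dropped (per-covariate
#' exclusion). Equivalent to exponentiating the coefficients of a univariate
#' logistic regression of the outcome on the predictor.
#'
#' @param data Data frame (typically the output of
#'   [exclude_for_or_analysis()]).
#' @param outcome Name of a logical/0-1 column, or a logical vector: `TRUE`
#'   marks the event (lost access).
#' @param predictor Name of a factor/character column, or such a vector.
#' @param reference Reference level; default: first factor level.
#' @param conf_level Confidence level, default 0.95.
#' @return Tibble with one row per non-reference level: `predictor`, `level`,
#'   `reference`, `or`, `ci_low`, `ci_high`, and the four cell counts.
#' @export
univariate_or <- function(data, outcome, predictor, reference = NULL,
                          conf_level = 0.95) {
  y <- if (is.character(outcome) && length(outcome) == 1) data[[outcome]] else outcome
  x <- if (is.character(predictor) && length(predictor) == 1) data[[predictor]] else predictor
  pred_name <- if (is.character(predictor) && length(predictor) == 1) predictor else
    deparse(substitute(predictor))
  keep <- !is.na(x) & !is.na(y)
  y <- as.logical(y[keep])
  x <- factor(x[keep])
  if (!is.null(reference)) x <- stats::relevel(x, ref = reference)
  ref <- levels(x)[1]
  others <- levels(x)[-1]
  ref_cases <- sum(y & x == ref)
  ref_controls <- sum(!y & x == ref)
  rows <- lapply(others, function(l) {
    res <- odds_ratio_wald(sum(y & x == l), sum(!y & x == l),
                           ref_cases, ref_controls, conf_level)
    tibble::tibble(
      predictor = pred_name, level = l, reference = ref,
      or = res$or, ci_low = res$ci_low, ci_high = res$ci_high,
      n_cases = sum(y & x == l), n_controls = sum(!y & x == l),
      n_ref_cases = ref_cases, n_ref_controls = ref_controls
    )
  })
  dplyr::bind_rows(rows)
}

#' Segmented regression of an interrupted time series
#'
#' Ordinary least squares with a level-and-slope-change parameterization:
#' `count ~ year + post + post:year`, where `post` indicates years at or
#' after the breakpoint. The reported quantities are the per-segment slopes
#' *b* (pre: the `year` coefficient; post: `year` + interaction) with 95%
#' confidence intervals from the coefficient covariance matrix, using the
#' t distribution on the residual degrees of freedom.
#'
#' @param annual_counts Data frame with `year` and `count` columns.
#' @param breakpoint_year First year of the post-change segment.
#' @param conf_level Confidence level, default 0.95.
#' @return An `its_fit` list: `pre_slope`, `pre_ci`, `post_slope`, `post_ci`,
#'   `breakpoint_year`, `level_change`, and the underlying `lm` fit.
#' @export
segmented_regression <- function(annual_counts, breakpoint_year,
                                 conf_level = 0.95) {
  df <- tibble::as_tibble(annual_counts)
  stopifnot(all(c("year", "count") %in% names(df)))
  df$post <- as.numeric(df$year >= breakpoint_year)
  if (sum(df$post == 0) < 2 || sum(df$post == 1) < 2) {
    stop("need at least 2 observations in each segment", call. = FALSE)
  }
  df$yearc <- df$year - breakpoint_year
  fit <- stats::lm(count ~ yearc + post + post:yearc, data = df)
  b <- stats::coef(fit)
  # a perfectly linear series makes summary.lm warn about a zero-residual
  # fit; the degenerate (zero-width) intervals are still the right answer
  V <- suppressWarnings(stats::vcov(fit))
  # t critical value on the residual df: with few annual points the normal
  # approximation under-covers (e.g. 15 years, 4 parameters -> df 11)
  z <- stats::qt(1 - (1 - conf_level) / 2, df = stats::df.residual(fit))
  pre <- unname(b["yearc"])
  pre_se <- sqrt(V["yearc", "yearc"])
  post <- unname(b["yearc"] + b["yearc:post"])
  post_se <- sqrt(V["yearc", "yearc"] + V["yearc:post", "yearc:post"] +
                    2 * V["yearc", "yearc:post"])
  structure(list(
    pre_slope = pre,
    pre_ci = c(pre - z * pre_se, pre + z * pre_se),
    post_slope = post,
    post_ci = c(post - z * post_se, post + z * post_se),
    level_change = unname(b["post"]),
    breakpoint_year = breakpoint_year,
    fit = fit
  ), class = "its_fit")
}

#' @export
print.its_fit <- function(x, ...) {
  cat(sprintf("Interrupted time series (breakpoint %d)\n", x$breakpoint_year))
  cat(sprintf("  pre-change slope  b = %8.1f (95%% CI %.1f to %.1f)\n",
              x$pre_slope, x$pre_ci[1], x$pre_ci[2]))
  cat(sprintf("  post-change slope b = %8.1f (95%% CI %.1f to %.1f)\n",
              x$post_slope, x$post_ci[1], x$post_ci[2]))
  invisible(x)
}
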