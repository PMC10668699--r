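#' Descriptive statistics for defect scores
#'
#' Per-trait N, mean, standard error, standard deviation (n-1 denominator),
#' mode (most frequent category, ties to the lowest) and the normal 95%
#' confidence interval of the mean. An empty column yields an N = 0 row of
#' `NA`s rather than an error.
#' @param scores data frame of score columns, or a single numeric vector.
#' @param traits columns to summarise (default: all).
#' @return data frame with one row per trait.
#' @export
descriptive_stats <- function(scores, traits = NULL) {
  if (is.atomic(scores)) scores <- data.frame(score = scores)
  if (is.null(traits)) traits <- names(scores)
  one <- function(x) {
    x <- x[!is.na(x)]
    n <- length(x)
    if (n == 0)
      return(data.frame(n = 0L, mean = NA_real_, se = NA_real_, sd = NA_real_,
                        mode = NA_real_, ci_lower = NA_real_, ci_upper = NA_real_))
    tb <- table(x)
    mode <- as.numeric(names(tb)[tb == max(tb)])[1]  # names sorted ascending
    m <- mean(x); s <- stats::sd(x); se <- s / sqrt(n)
    data.frame(n = n, mean = m, se = se, sd = s, mode = mode,
               ci_lower = m - 1.96 * se, ci_upper = m + 1.96 * se)
  }
  out <- do.call(rbind, lapply(traits, function(tr) one(scores[[tr]])))
  cbind(trait = traits, out)
}

#' Category prevalences
#'
#' Percentage share of each score category among non-missing records.
#' @param scores numeric vector.
#' @param categories category set; defaults to the observed range.
#' @return named numeric vector of percentages (sums to 100 up to rounding).
#' @export
prevalence_by_category <- function(scores, categories = NULL) {
  x <- scores[!is.na(scores)]
  if (is.null(categories)) categories <- sort(unique(x))
  if (length(x) == 0) return(stats::setNames(rep(NA_real_, length(categories)),
                                             categories))
  stats::setNames(100 * vapply(categories, function(k) mean(x == k), 0),
                  categories)
}

#' Pairwise co-occurrence of the top category
#'
#' Share of animals, among those scored on both traits, exhibiting the
#' given category (default 2, the most pronounced defect grade) on both.
#' @param scores_i,scores_j score vectors over the same animals.
#' @param category category whose joint occurrence is counted.
#' @return percentage.
#' @export
cooccurrence_cat2 <- function(scores_i, scores_j, category = 2) {
  ok <- !is.na(scores_i) & !is.na(scores_j)
  if (!any(ok)) return(NA_real_)
  100 * mean(scores_i[ok] == category & scores_j[ok] == category)
}

#' Prevalence trends by birth year and inbreeding bin
#'
#' Percentage of affected animals (score > 0) per birth year and per
#' inbreeding-coefficient bin. Default bins follow the published endpoint
#' convention: \[0, 0.0625\], (0.0625, 0.125\], (0.125, 0.25\] and
#' (0.25, 1); the interior boundaries between 0.0625 and 0.25 are a
#' convention of this package (the source bins print only the endpoints)
#' and are recorded in the output.
#' @param scores score vector.
#' @param birth_year integer vector.
#' @param F inbreeding coefficients.
#' @param f_bins bin boundaries for F.
#' @return list with data frames `by_year` and `by_inbreeding` (empty bins
#'   reported as `NA`, not zero).
#' @export
trend_tables <- function(scores, birth_year, F,
                         f_bins = c(0, 0.0625, 0.125, 0.25, 1)) {
  aff <- as.numeric(scores > 0)
  pct <- function(v) if (length(v) == 0 || all(is.na(v))) NA_real_
                     else 100 * mean(v, na.rm = TRUE)
  yrs <- sort(unique(birth_year[!is.na(birth_year)]))
  by_year <- data.frame(
    birth_year = yrs,
    affected_pct = vapply(yrs, function(y) pct(aff[birth_year == y]), 0))
  bins <- cut(F, breaks = f_bins, include.lowest = TRUE, right = TRUE)
  by_f <- data.frame(
    f_bin = levels(bins),
    affected_pct = vapply(levels(bins),
                          function(b) pct(aff[!is.na(bins) & bins == b]), 0))
  list(by_year = by_year, by_inbreeding = by_f, f_bins = f_bins)
}

#' Breed-registration eligibility under the severity rule
#'
#' A horse cannot be registered as a breeder when it has more than 2 very
#' severe defects or more than 4 severe defects (for the limb deviations:
#' category 2 counts as severe for the splay-footed traits and very severe
#' for the pigeon-toed traits).
#' @param very_severe_count,severe_count integer defect counts.
#' @return logical: `TRUE` when eligible. Vectorised.
#' @examples
#' breeder_eligibility(3, 0)  # FALSE
#' breeder_eligibility(2, 4)  # TRUE (boundary)
#' @export
breeder_eligibility <- function(very_severe_count, severe_count) {
  !(very_severe_count > 2 | severe_count > 4)
}

#' Risk-factor screen by multinomial/binary logit
#'
#' Fits a generalized (non-linear) model with a multinomial logit link of
#' the outcome score on categorical effects and linear covariates, and
#' screens each term by a likelihood-ratio test against the model without
#' it. Binary outcomes use [stats::glm()] with a logit link; outcomes with
#' three or more categories use [nnet::multinom()].
#'
#' @param data data frame holding outcome and predictors.
#' @param outcome name of the (ordinal/binary) outcome column.
#' @param effects categorical predictor columns.
#' @param covariates linear covariate columns.
#' @return list with `tests` (term, df, LR statistic, p-value),
#'   `coefficients`, `affected_by_level` (percent with outcome > 0 per
#'   level of each categorical effect) and the fitted model.
#' @export
glz_risk_screen <- function(data, outcome, effects = c("sex", "stud_size"),
                            covariates = c("age", "F")) {
  df <- data[, c(outcome, effects, covariates), drop = FALSE]
  df <- df[stats::complete.cases(df), , drop = FALSE]
  y <- df[[outcome]]
  if (length(unique(y)) < 2) stop("outcome '", outcome, "' is degenerate")
  for (f in effects) df[[f]] <- droplevels(factor(df[[f]]))
  df$.y <- factor(y)
  terms <- c(effects, covariates)
  fml <- stats::reformulate(terms, response = ".y")
  binary <- nlevels(df$.y) == 2

  fit_one <- function(formula) {
    if (binary)
      stats::glm(formula, family = stats::binomial(),
                 data = df, control = stats::glm.control(epsilon = 1e-12))
    else
      nnet::multinom(formula, data = df, trace = FALSE, maxit = 500)
  }
  dev_of <- function(m) if (binary) m$deviance else m$deviance
  full <- fit_one(fml)
  coefs <- if (binary) stats::coef(full) else t(stats::coef(full))
  if (max(abs(unlist(coefs)), na.rm = TRUE) > 15)
    warning("very large coefficients: possible complete separation")

  tests <- do.call(rbind, lapply(terms, function(tm) {
    rest <- setdiff(terms, tm)
    red <- fit_one(stats::reformulate(if (length(rest)) rest else "1",
                                      response = ".y", intercept = TRUE))
    lr <- dev_of(red) - dev_of(full)
    k <- if (tm %in% effects) nlevels(df[[tm]]) - 1L else 1L
    if (!binary) k <- k * (nlevels(df$.y) - 1L)
    data.frame(term = tm, df = k, lr_stat = lr,
               p_value = stats::pchisq(max(lr, 0), k, lower.tail = FALSE))
  }))

  affected <- lapply(stats::setNames(effects, effects), function(f) {
    lev <- levels(df[[f]])
    vapply(lev, function(l)
      100 * mean(as.numeric(as.character(df$.y[df[[f]] == l])) > 0), 0)
  })
  list(tests = tests, coefficients = coefs,
       affected_by_level = affected, model = full)
}
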