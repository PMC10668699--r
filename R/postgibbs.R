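#' Heritability from variance components
#'
#' \eqn{h^2 = \sigma^2_u / (\sigma^2_u + \sigma^2_e)}; for ordinal traits
#' fitted with unit residual variance this is the liability-scale
#' heritability. Vectorised over draws.
#' @param sigma_u,sigma_e additive-genetic and residual variances (> 0).
#' @return value(s) in (0, 1).
#' @examples
#' heritability(246.57, 1140.70)  # ~ 0.18
#' @export
heritability <- function(sigma_u, sigma_e) {
  if (any(sigma_u <= 0) || any(sigma_e <= 0))
    stop("variance components must be positive")
  sigma_u / (sigma_u + sigma_e)
}

#' Genetic correlation from a covariance matrix
#' @param G genetic covariance matrix (positive definite).
#' @param i,j trait indices or names.
#' @return \eqn{G_{ij} / \sqrt{G_{ii} G_{jj}}}.
#' @export
genetic_correlation <- function(G, i, j) {
  if (G[i, i] <= 0 || G[j, j] <= 0)
    stop("zero or negative diagonal in G")
  G[i, j] / sqrt(G[i, i] * G[j, j])
}

#' Highest posterior density interval
#'
#' Shortest interval containing `ceiling(mass * n)` of the sorted draws;
#' ties between equally short windows are broken towards the left.
#' @param chain numeric draws (>= 20).
#' @param mass interval mass in (0, 1).
#' @return named vector `c(lower, upper)`.
#' @export
hpd_interval <- function(chain, mass = 0.95) {
  if (mass <= 0 || mass >= 1) stop("mass must be in (0, 1)")
  n <- length(chain)
  if (n < 20) stop("need at least 20 draws for an HPD interval")
  s <- sort(chain)
  m <- ceiling(mass * n)
  k <- which.min(s[m:n] - s[seq_len(n - m + 1)])
  c(lower = s[k], upper = s[k + m - 1])
}

# Spectral density at frequency zero via an AR fit with AIC order
# selection; the time-series variance of the chain mean is spec0/n.
spectrum0_ar <- function(x) {
  x <- as.numeric(x)
  if (stats::var(x) == 0) return(0)
  ord <- min(length(x) - 1L, floor(10 * log10(length(x))))
  fit <- stats::ar(x, aic = TRUE, order.max = ord)
  fit$var.pred / (1 - sum(fit$ar))^2
}

#' Geweke convergence diagnostic
#'
#' Z statistic comparing the mean of the first `frac1` of the chain with
#' the mean of the last `frac2`, each scaled by its spectral-density
#' estimate of the time-series variance.
#' @param chain numeric draws (>= 100, non-constant).
#' @param frac1,frac2 window fractions (defaults 10% / 50%).
#' @return the Z score.
#' @export
geweke_z <- function(chain, frac1 = 0.1, frac2 = 0.5) {
  n <- length(chain)
  if (n < 100) stop("need at least 100 draws")
  if (stats::var(chain) == 0) stop("constant chain: Geweke Z undefined")
  x1 <- chain[seq_len(floor(frac1 * n))]
  x2 <- chain[seq.int(n - floor(frac2 * n) + 1L, n)]
  v1 <- spectrum0_ar(x1) / length(x1)
  v2 <- spectrum0_ar(x2) / length(x2)
  if (v1 + v2 == 0) stop("zero spectral variance in both windows")
  (mean(x1) - mean(x2)) / sqrt(v1 + v2)
}

#' Batch-means Monte Carlo standard error
#'
#' Time-series standard error of the chain mean using `floor(sqrt(n))`
#' batches. For i.i.d. chains this approaches \eqn{s/\sqrt{n}}; positive
#' autocorrelation inflates it.
#' @param chain numeric draws (>= 100).
#' @return the Monte Carlo standard error (0 for a constant chain).
#' @export
mcse <- function(chain) {
  n <- length(chain)
  if (n < 100) stop("need at least 100 draws")
  bs <- floor(sqrt(n))
  nb <- floor(n / bs)
  bm <- colMeans(matrix(chain[seq_len(nb * bs)], nrow = bs))
  stats::sd(bm) / sqrt(nb)
}

#' Probability of a common sign
#'
#' The posterior mass on the dominant sign of a chain,
#' `max(P(x > 0), P(x < 0))` -- the usual summary printed alongside a
#' genetic correlation to convey whether it differs from zero.
#' @param chain numeric draws.
#' @return value in \[0.5, 1\] (can fall below 0.5 only via mass at zero).
#' @export
sign_probability <- function(chain) {
  max(mean(chain > 0), mean(chain < 0))
}

#' Percentile overlap of two EBV rankings
#'
#' Percentage of animals shared between the top sets (strictly above the
#' `q` quantile by rank) of two breeding-value vectors over the same
#' animals; the denominator is the size of the first vector's top set.
#' Ties are broken by animal id so the set is deterministic.
#' @param ebv_1,ebv_2 named numeric vectors over identical animal sets.
#' @param q quantile defining the top set (default 0.8: top 20%).
#' @return overlap percentage in \[0, 100\].
#' @export
ebv_percentile_overlap <- function(ebv_1, ebv_2, q = 0.8) {
  if (is.null(names(ebv_1)) || is.null(names(ebv_2)))
    stop("EBV vectors must be named by animal id")
  if (!setequal(names(ebv_1), names(ebv_2)) ||
      length(ebv_1) != length(ebv_2))
    stop("the two EBV vectors cover different animal sets")
  n <- length(ebv_1)
  k <- ceiling((1 - q) * n)
  top <- function(e) names(e)[order(-e, names(e))][seq_len(k)]
  t1 <- top(ebv_1); t2 <- top(ebv_2)
  100 * length(intersect(t1, t2)) / length(t1)
}

summ_chain <- function(x, mass = 0.95) {
  const <- stats::var(x) == 0
  hpd <- if (length(x) >= 20) hpd_interval(x, mass) else c(NA_real_, NA_real_)
  data.frame(mean = mean(x), median = stats::median(x), sd = stats::sd(x),
             hpd_lower = hpd[1], hpd_upper = hpd[2],
             geweke_z = if (!const && length(x) >= 100) geweke_z(x) else NA_real_,
             mcse = if (length(x) >= 100) mcse(x) else NA_real_)
}

#' Posterior summary table
#'
#' One row per parameter: genetic and residual variances, covariate/fixed
#' slopes, heritabilities, genetic correlations (with the sign
#' probability), and sampled thresholds. Columns: mean, median, sd, 95% HPD
#' bounds, Geweke Z and batch-means MCSE. Mean/median/HPD are invariant to
#' the order of the draws; Geweke Z and MCSE are order-sensitive
#' time-series diagnostics.
#' @param fit a `hoof_fit`.
#' @param mass HPD mass.
#' @return data frame with identifying columns `parameter`, `trait` and
#'   `p_sign` (non-missing for genetic correlations only).
#' @export
posterior_summary <- function(fit, mass = 0.95) {
  stopifnot(inherits(fit, "hoof_fit"))
  rows <- list()
  add <- function(param, trait, x, p_sign = NA_real_) {
    r <- summ_chain(x, mass)
    r$parameter <- param; r$trait <- trait; r$p_sign <- p_sign
    rows[[length(rows) + 1L]] <<- r
  }
  tn <- fit$trait_names
  for (tr in tn) {
    add("sigma_u", tr, fit$G[, paste0(tr, ":", tr)])
    add("sigma_e", tr, fit$R[, paste0(tr, ":", tr)])
    add("h2", tr, h2_draws(fit, tr))
  }
  if (length(tn) > 1)
    for (i in seq_len(length(tn) - 1))
      for (j in seq.int(i + 1, length(tn))) {
        x <- rg_draws(fit, tn[i], tn[j])
        add("r_g", paste0(tn[i], "-", tn[j]), x, sign_probability(x))
      }
  if (!is.null(fit$b) && ncol(fit$b))
    for (nm in colnames(fit$b))
      add("b", nm, fit$b[, nm])
  if (!is.null(fit$thresholds))
    for (nm in colnames(fit$thresholds)) {
      x <- fit$thresholds[, nm]
      if (stats::var(x) > 0) add("threshold", nm, x)
    }
  out <- do.call(rbind, rows)
  out[, c("parameter", "trait", "mean", "median", "sd",
          "hpd_lower", "hpd_upper", "geweke_z", "mcse", "p_sign")]
}
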