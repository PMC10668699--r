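# Independent oracles and fixture generators used across the suite.

# Random acyclic pedigree: animals are generated in order, parents drawn
# among earlier animals, so the result is cycle-free by construction.
random_pedigree <- function(n, founder_frac = 0.3) {
  id <- paste0("A", seq_len(n))
  sire <- dam <- rep("0", n)
  for (i in seq_len(n)) {
    if (i <= 2 || stats::runif(1) < founder_frac) next
    s <- sample.int(i - 1L, 1L)
    d <- sample.int(i - 1L, 1L)
    if (s == d) next
    sire[i] <- id[s]
    dam[i] <- id[d]
  }
  parse_pedigree(data.frame(id = id, sire = sire, dam = dam))
}

# Monte Carlo gene-dropping estimate of the additive relationship
# a_ij = 2 * kinship(i, j): founders carry unique allele labels, alleles
# drop down the pedigree, and IBD is scored between random alleles.
gene_drop_relationship <- function(ped, i, j, reps = 4000) {
  n <- ped$n
  hits <- 0
  for (r in seq_len(reps)) {
    al <- matrix(0L, n, 2)
    nxt <- 1L
    for (k in seq_len(n)) {
      s <- ped$sire[k]; d <- ped$dam[k]
      al[k, 1] <- if (is.na(s)) { nxt <- nxt + 1L; nxt - 1L } else al[s, sample.int(2L, 1L)]
      al[k, 2] <- if (is.na(d)) { nxt <- nxt + 1L; nxt - 1L } else al[d, sample.int(2L, 1L)]
    }
    # average IBD over the four allele pairings = kinship
    hits <- hits + mean(outer(al[i, ], al[j, ], "=="))
  }
  2 * hits / reps
}

# Conjugate single-trait Gaussian animal-model Gibbs sampler for
# unrelated founders (A = I), used as an independent oracle for the
# Gaussian special case of the threshold sampler. Same inverse-Wishart
# (here scaled inverse-chi-square) priors, flat prior on fixed effects.
conjugate_gibbs_oracle <- function(y, X, nu_g, Sg, nu_r, Sr,
                                   n_iter, burn_in, thin, seed) {
  set.seed(seed)
  n <- length(y)
  p <- ncol(X)
  b <- numeric(p); u <- numeric(n)
  s2u <- Sg / (nu_g - 2); s2e <- Sr / (nu_r - 2)
  keep <- floor((n_iter - burn_in) / thin)
  out <- matrix(NA_real_, keep, 2, dimnames = list(NULL, c("s2u", "s2e")))
  kept <- 0L
  xtx <- colSums(X^2)
  for (it in seq_len(n_iter)) {
    res <- y - X %*% b - u
    for (k in seq_len(p)) {
      res <- res + X[, k] * b[k]
      m <- sum(X[, k] * res) / xtx[k]
      b[k] <- stats::rnorm(1, m, sqrt(s2e / xtx[k]))
      res <- res - X[, k] * b[k]
    }
    prec <- 1 / s2e + 1 / s2u
    m_u <- (res + u) / s2e / prec
    u <- stats::rnorm(n, m_u, sqrt(1 / prec))
    res <- y - X %*% b - u
    s2u <- (Sg + sum(u^2)) / stats::rchisq(1, nu_g + n)
    s2e <- (Sr + sum(res^2)) / stats::rchisq(1, nu_r + n)
    if (it > burn_in && (it - burn_in) %% thin == 0) {
      kept <- kept + 1L
      out[kept, ] <- c(s2u, s2e)
    }
  }
  out
}

# Exhaustive shortest-window HPD search.
hpd_brute <- function(chain, mass = 0.95) {
  s <- sort(chain)
  n <- length(s)
  m <- ceiling(mass * n)
  best <- c(s[1], s[m]); width <- s[m] - s[1]
  for (k in seq_len(n - m + 1)) {
    w <- s[k + m - 1] - s[k]
    if (w < width - 1e-15) { width <- w; best <- c(s[k], s[k + m - 1]) }
  }
  best
}

# Small binary+Gaussian recovery configuration shared by the sampler and
# acceptance tests (the spec of the simulated study: ~2,000 animals over
# five generations, true h2 0.3/0.4, genetic correlation 0.3).
recovery_config <- function() {
  tr <- list(
    sim_trait("DEF", "ordinal", h2 = 0.3, n_categories = 2, freq = c(0.7, 0.3),
              b_sex = 0.3, b_stud = c(0.2, -0.2), b_age = 0.02, b_F = 0.5),
    sim_trait("QT", "gaussian", h2 = 0.4, mean = 10, sd = 1,
              b_sex = 0.3, b_stud = c(0.1, -0.1), b_age = 0.02, b_F = 0.5))
  sim_config(traits = tr, g_cor = matrix(c(1, 0.3, 0.3, 1), 2),
             n_founders = 200, n_generations = 5, n_per_generation = 360)
}
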