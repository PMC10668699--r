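# Small founder-population Gaussian fixture shared by several blocks
gauss_fixture <- function(n = 200, seed = 29) {
  set.seed(seed)
  ped <- parse_pedigree(data.frame(id = paste0("f", 1:n), sire = "0", dam = "0"))
  u <- rnorm(n, 0, 1)
  phen <- data.frame(id = ped$id, y = 2 + u + rnorm(n, 0, 1))
  design <- build_design(phen, ped, list(trait_spec("y", "gaussian")),
                         fixed = character(0), covariates = character(0))
  list(ped = ped, phen = phen, design = design, ainv = a_inverse(ped))
}

test_that("the sampler is bit-reproducible given a seed and stores the right count", {
  fx <- gauss_fixture()
  cfg <- model_config(n_iter = 800, burn_in = 200, thin = 3, seed = 99)
  f1 <- gibbs_run(fx$design, fx$ainv, cfg)
  f2 <- gibbs_run(fx$design, fx$ainv, cfg)
  expect_identical(f1$G, f2$G)
  expect_identical(f1$b, f2$b)
  expect_identical(f1$ebv, f2$ebv)
  expect_equal(f1$n_keep, (800 - 200) %/% 3)
  f3 <- gibbs_run(fx$design, fx$ainv,
                  model_config(n_iter = 800, burn_in = 200, thin = 3, seed = 100))
  expect_false(identical(f1$G, f3$G))
})

test_that("stored draws satisfy the identification contracts", {
  set.seed(31)
  n <- 150
  ped <- parse_pedigree(data.frame(id = paste0("f", 1:n), sire = "0", dam = "0"))
  phen <- data.frame(id = ped$id,
                     o3 = sample(0:2, n, TRUE, prob = c(.5, .3, .2)),
                     qt = rnorm(n))
  d <- build_design(phen, ped,
                    list(trait_spec("o3", "ordinal", 3), trait_spec("qt", "gaussian")),
                    fixed = character(0), covariates = character(0))
  fit <- gibbs_run(d, a_inverse(ped),
                   model_config(n_iter = 1200, burn_in = 200, thin = 2, seed = 5),
                   store_liab = TRUE)
  # ordinal residual variance is exactly 1 in every stored draw
  expect_true(all(fit$R[, "o3:o3"] == 1))
  # thresholds: first fixed at zero, second strictly above it
  expect_true(all(fit$thresholds[, "o3:t1"] == 0))
  expect_true(all(fit$thresholds[, "o3:t2"] > 0))
  # heritability and correlation draws live in their ranges
  expect_true(all(h2_draws(fit, "o3") > 0 & h2_draws(fit, "o3") < 1))
  expect_true(all(abs(rg_draws(fit, "o3", "qt")) <= 1))
  # every stored covariance draw is positive definite
  for (k in sample(fit$n_keep, 25)) {
    G <- matrix(fit$G[k, ], 2)
    expect_gt(min(eigen(G, symmetric = TRUE, only.values = TRUE)$values), 0)
  }
  # final liabilities respect the observed categories and thresholds
  liab <- fit$final_liab[, 1]
  t2 <- fit$final_thr[[1]][2]
  obs <- phen$o3
  expect_true(all(liab[obs == 0] < 0))
  expect_true(all(liab[obs == 1] >= 0 & liab[obs == 1] < t2))
  expect_true(all(liab[obs == 2] >= t2))
})

test_that("with no phenotypes the Gaussian-trait posterior of G matches its prior", {
  set.seed(37)
  ped <- random_pedigree(40, founder_frac = 0.4)
  phen <- data.frame(id = ped$id[1], y = NA_real_)[0, ]
  d <- build_design(data.frame(id = character(), y = numeric()), ped,
                    list(trait_spec("y", "gaussian")),
                    fixed = character(0), covariates = character(0))
  # the G chain with no data mixes slowly (G and u feed each other), so a
  # long, heavily thinned run keeps the Monte Carlo error well below the
  # asserted band; IW_1(7, 0.5) has mean 0.1 and sd 0.0816
  fit <- gibbs_run(d, a_inverse(ped),
                   model_config(n_iter = 320000, burn_in = 20000, thin = 100,
                                seed = 7,
                                prior_df_g = 7, prior_scale_g = 0.5,
                                prior_df_r = 7, prior_scale_r = 0.8))
  expect_gte(fit$n_keep, 2000)
  g <- fit$G[, 1]
  expect_lt(abs(mean(g) - 0.1), 6 * max(mcse(g), 0.0816 / sqrt(fit$n_keep)))
  r <- fit$R[, 1]
  expect_lt(abs(mean(r) - 0.16), 6 * max(mcse(r), 0.1306 / sqrt(fit$n_keep)))
})

test_that("Gaussian special case agrees with an independent conjugate Gibbs oracle", {
  set.seed(41)
  n <- 200
  ped <- parse_pedigree(data.frame(id = paste0("f", 1:n), sire = "0", dam = "0"))
  X <- cbind(1, rnorm(n))
  u <- rnorm(n, 0, 1)
  y <- X %*% c(1, 0.5) + u + rnorm(n, 0, 1)
  phen <- data.frame(id = ped$id, x = X[, 2], y = as.numeric(y))
  d <- build_design(phen, ped, list(trait_spec("y", "gaussian")),
                    fixed = character(0), covariates = "x")
  # identical priors on both routes (scaled inverse-chi-square pieces)
  fit <- gibbs_run(d, a_inverse(ped),
                   model_config(n_iter = 22000, burn_in = 2000, thin = 5, seed = 13,
                                prior_df_g = 4, prior_scale_g = 0.5,
                                prior_df_r = 4, prior_scale_r = 0.5,
                                prior_b_var = 1e8))
  orc <- conjugate_gibbs_oracle(as.numeric(y), cbind(1, scale(X[, 2], scale = FALSE)),
                                nu_g = 4, Sg = 0.5, nu_r = 4, Sr = 0.5,
                                n_iter = 22000, burn_in = 2000, thin = 5, seed = 14)
  for (comp in c("s2u", "s2e")) {
    a <- if (comp == "s2u") fit$G[, 1] else fit$R[, 1]
    b <- orc[, comp]
    tol <- 5 * sqrt(mcse(a)^2 + mcse(b)^2)
    expect_lt(abs(mean(a) - mean(b)), tol)
    expect_equal(sd(a), sd(b), tolerance = 0.25 * sd(b))
  }
})

test_that("an enormous residual variance shrinks breeding values toward zero", {
  fx <- gauss_fixture(n = 120, seed = 43)
  fx$phen$y <- fx$phen$y * 30  # same signal, residual prior dwarfed below
  d <- build_design(fx$phen, fx$ped, list(trait_spec("y", "gaussian")),
                    fixed = character(0), covariates = character(0))
  # tight prior pinning the genetic variance near zero: u must shrink
  fit <- gibbs_run(d, fx$ainv,
                   model_config(n_iter = 2000, burn_in = 500, thin = 3, seed = 3,
                                prior_df_g = 5000, prior_scale_g = 0.01,
                                prior_df_r = 4, prior_scale_r = 1))
  expect_lt(max(abs(fit$ebv)), 0.5)
  expect_lt(mean(fit$G[, 1]), 0.1)
})

test_that("DIC prefers the generating model and penalises complexity sensibly", {
  set.seed(47)
  wins <- 0
  for (rep in 1:6) {
    n <- 350
    ped <- parse_pedigree(data.frame(id = paste0("f", 1:n), sire = "0", dam = "0"))
    sex <- sample(c("male", "female"), n, TRUE)
    # a real sex effect on the liability; no genetic signal needed
    liab <- 0.8 * (sex == "male") + rnorm(n)
    phen <- data.frame(id = ped$id, sex = sex, y = as.integer(liab > 0.4))
    ai <- a_inverse(ped)
    cfg <- model_config(n_iter = 2500, burn_in = 500, thin = 4, seed = 100 + rep)
    d1 <- build_design(phen, ped, list(trait_spec("y", "ordinal", 2)),
                       fixed = "sex", covariates = character(0))
    f1 <- gibbs_run(d1, ai, cfg)
    d0 <- build_design(phen, ped, list(trait_spec("y", "ordinal", 2)),
                       fixed = character(0), covariates = character(0))
    f0 <- gibbs_run(d0, ai, cfg)
    wins <- wins + (compute_dic(f1)$dic < compute_dic(f0)$dic)
  }
  expect_gte(wins, 5)
})

test_that("compute_dic needs draws and returns coherent pieces", {
  fx <- gauss_fixture(n = 80, seed = 53)
  fit <- gibbs_run(fx$design, fx$ainv,
                   model_config(n_iter = 900, burn_in = 300, thin = 2, seed = 1))
  dic <- compute_dic(fit)
  expect_equal(dic$dic, 2 * dic$mean_deviance - dic$plugin_deviance)
  expect_equal(dic$p_d, dic$mean_deviance - dic$plugin_deviance)
  short <- gibbs_run(fx$design, fx$ainv,
                     model_config(n_iter = 300, burn_in = 100, thin = 4, seed = 1))
  expect_error(compute_dic(short), "100")
})

test_that("the joint distribution of the successive-conditional chain matches the prior", {
  # Geweke-style validation: with the data re-simulated from the model each
  # iteration, stored parameter draws must be distributed as the prior.
  set.seed(59)
  trs <- list(sim_trait("B", "ordinal", h2 = .3, n_categories = 2, freq = c(.7, .3)),
              sim_trait("Q", "gaussian", h2 = .4))
  ped <- simulate_pedigree(sim_config(traits = trs, g_cor = matrix(c(1, .3, .3, 1), 2),
                                      n_founders = 10, n_generations = 2,
                                      n_per_generation = 10))
  phen <- data.frame(id = ped$id, B = rbinom(ped$n, 1, .3), Q = rnorm(ped$n))
  d <- build_design(phen, ped,
                    list(trait_spec("B", "ordinal", 2), trait_spec("Q", "gaussian")),
                    fixed = character(0), covariates = character(0),
                    intercept = FALSE)
  fit <- gibbs_run(d, a_inverse(ped),
                   model_config(n_iter = 120000, burn_in = 10000, thin = 10, seed = 33,
                                prior_df_g = 6, prior_scale_g = 0.5,
                                prior_df_r = 6, prior_scale_r = 0.8),
                   sc_mode = TRUE)
  # prior Monte Carlo for the identified functionals
  set.seed(5)
  M <- 60000
  riw2 <- function(df, S) { W <- crossprod(matrix(rnorm(df * 2), df, 2)); solve(W) * S }
  Gp <- t(replicate(M / 4, { G <- riw2(6, 0.5)
    c(G[1, 1], G[2, 2], G[1, 2] / sqrt(G[1, 1] * G[2, 2])) }))
  Om <- 0.8 / rchisq(M, 6)
  Rqq <- Om + rnorm(M, 0, sqrt(Om / 0.8))^2
  checks <- list(
    list(s = fit$G[, "B:B"], p = Gp[, 1], pv = var(Gp[, 1]) / (M / 4)),
    list(s = fit$G[, "Q:Q"], p = Gp[, 2], pv = var(Gp[, 2]) / (M / 4)),
    list(s = rg_draws(fit, "B", "Q"), p = Gp[, 3], pv = var(Gp[, 3]) / (M / 4)),
    list(s = fit$R[, "Q:Q"], p = Rqq, pv = var(Rqq) / M))
  for (ch in checks) {
    z <- (mean(ch$s) - mean(ch$p)) / sqrt(mcse(ch$s)^2 + ch$pv)
    expect_lt(abs(z), 3)
  }
  # binary residual variance is fixed at one by construction
  expect_true(all(fit$R[, "B:B"] == 1))
})

test_that("draws and EBVs round-trip through the plain-text writers", {
  fx <- gauss_fixture(n = 60, seed = 61)
  fit <- gibbs_run(fx$design, fx$ainv,
                   model_config(n_iter = 600, burn_in = 200, thin = 4, seed = 2))
  dir <- tempfile("fitout")
  write_draws(fit, dir)
  draws <- read.csv(file.path(dir, "draws.csv"))
  expect_setequal(unique(draws$parameter), c("G", "R", "b"))
  gcol <- draws[draws$parameter == "G" & draws$trait_i == "y" &
                draws$trait_j == "y", "value"]
  expect_equal(gcol, unname(fit$G[, "y:y"]))
  ebv_back <- read.csv(file.path(dir, "ebv.csv"))
  expect_equal(ebv_back$y, unname(fit$ebv[, "y"]), tolerance = 1e-12)
  unlink(dir, recursive = TRUE)
})
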