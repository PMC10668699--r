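#' Trait definition for the simulator
#'
#' Ground-truth parameters for one simulated trait. Ordinal traits are
#' generated on the liability scale with unit residual variance, so the
#' additive variance implied by a target liability heritability is
#' \eqn{\sigma^2_u = h^2 / (1 - h^2)}; Gaussian traits are generated with
#' total variance `sd^2` split as `h2 * sd^2` genetic and
#' `(1 - h2) * sd^2` residual.
#'
#' @param name trait name.
#' @param kind `"ordinal"` or `"gaussian"`.
#' @param h2 true (liability-scale) heritability in (0, 1).
#' @param n_categories,base ordinal category count and first code.
#' @param freq target category frequencies (sums to 1); when given,
#'   thresholds are calibrated by inverse-CDF quantiles of the realised
#'   liabilities so the simulated prevalences hit the targets.
#' @param thresholds explicit liability thresholds (used when `freq` is
#'   `NULL`; default 0 and unit steps).
#' @param mean,sd Gaussian trait location and total standard deviation.
#' @param b_sex additive liability effect of the male sex (female = 0).
#' @param b_stud effects of medium and large birth studs (small = 0).
#' @param b_age,b_F linear covariate slopes (age in years, inbreeding F).
#' @param missing_rate per-trait probability that a record is missing.
#' @return a `sim_trait` list.
#' @export
sim_trait <- function(name, kind = c("ordinal", "gaussian"), h2 = 0.2,
                      n_categories = 3L, base = 0L, freq = NULL,
                      thresholds = NULL, mean = 0, sd = 1,
                      b_sex = 0, b_stud = c(0, 0), b_age = 0, b_F = 0,
                      missing_rate = 0) {
  kind <- match.arg(kind)
  stopifnot(h2 > 0, h2 < 1, missing_rate >= 0, missing_rate < 1)
  if (!is.null(freq)) {
    stopifnot(abs(sum(freq) - 1) < 1e-6, length(freq) == n_categories)
  }
  structure(list(name = name, kind = kind, h2 = h2,
                 n_categories = as.integer(n_categories), base = as.integer(base),
                 freq = freq, thresholds = thresholds, mean = mean, sd = sd,
                 b_sex = b_sex, b_stud = b_stud, b_age = b_age, b_F = b_F,
                 missing_rate = missing_rate),
            class = "sim_trait")
}

#' Default simulated trait panel
#'
#' Six traits emulating the study system: the four angular hoof deviations
#' as 3-category ordinal traits with the published category prevalences and
#' model-A liability heritabilities, the tendon-diameter score and the
#' proportionality index as Gaussian traits with their published means,
#' standard deviations and heritabilities. Missingness rates reproduce the
#' per-trait record counts relative to the evaluated population (the two
#' Gaussian traits use a nominal 5%). Fixed-effect and covariate values are
#' modest liability-scale choices (documented in the methods vignette):
#' males slightly more affected by the splay-footed defects and less by the
#' pigeon-toed forelimb, small stud effects, small age slopes and positive
#' inbreeding slopes for the defect traits.
#' @return list of [sim_trait()] objects.
#' @export
default_sim_traits <- function() {
  list(
    sim_trait("SFF", "ordinal", h2 = 0.18, freq = c(0.7339, 0.2061, 0.0599) / 0.9999,
              b_sex = 0.25, b_stud = c(-0.02, 0.02), b_age = -0.02, b_F = 0.5,
              missing_rate = 0.186),
    sim_trait("PTF", "ordinal", h2 = 0.20, freq = c(0.7624, 0.0073, 0.2303),
              b_sex = -0.2, b_stud = c(-0.02, 0.02), b_age = 0.02, b_F = 0.3,
              missing_rate = 0.217),
    sim_trait("SFR", "ordinal", h2 = 0.11, freq = c(0.2047, 0.5389, 0.2564),
              b_sex = 0.01, b_stud = c(0.04, 0.06), b_age = -0.005, b_F = 0.4,
              missing_rate = 0.008),
    sim_trait("PTR", "ordinal", h2 = 0.31, freq = c(0.9614, 0.0316, 0.0070),
              b_sex = 0.03, b_stud = c(0.05, -0.05), b_age = 0.005, b_F = 0.3,
              missing_rate = 0.789),
    sim_trait("SDFT", "gaussian", h2 = 0.076, mean = 4.87, sd = 1.083,
              b_sex = 0.1, b_age = 0.02, missing_rate = 0.05),
    sim_trait("PI", "gaussian", h2 = 0.348, mean = 99.80, sd = 2.379,
              b_sex = 0.2, b_age = 0.02, missing_rate = 0.05))
}

#' Default genetic correlation structure
#'
#' Correlations among the default traits taken from the published model-A
#' estimates (hoof-defect pairs, and each defect with the tendon score and
#' proportionality index); pairs without a published estimate are set to 0.
#' @return 6 x 6 correlation matrix.
#' @export
default_g_cor <- function() {
  tn <- c("SFF", "PTF", "SFR", "PTR", "SDFT", "PI")
  C <- diag(6); dimnames(C) <- list(tn, tn)
  set_ <- function(i, j, v) { C[i, j] <<- v; C[j, i] <<- v }
  set_("SFF", "PTR", 0.09); set_("SFF", "SFR", 0.09)
  set_("PTF", "PTR", 0.27); set_("PTF", "SFR", -0.31)
  set_("SFF", "SDFT", -0.081); set_("PTF", "SDFT", 0.283)
  set_("SFR", "SDFT", -0.113); set_("PTR", "SDFT", 0.276)
  set_("SFF", "PI", 0.212); set_("PTF", "PI", -0.034)
  set_("SFR", "PI", 0.124); set_("PTR", "PI", -0.088)
  C
}

#' Simulation configuration
#'
#' @param traits list of [sim_trait()] objects.
#' @param g_cor genetic correlation matrix among the traits (PD).
#' @param n_founders,n_generations,n_per_generation population structure:
#'   discrete non-overlapping generations, parents drawn from the previous
#'   generation. The defaults give a five-known-generation pedigree.
#' @param offspring_per_mating litter size per sampled mating pair.
#' @param mating `"random"` or `"fullsib"` (repeated full-sib line, which
#'   drives F above 0.25 within three generations).
#' @param n_studs number of birth studs (matings are clustered by stud, so
#'   the stud-size effect is estimable).
#' @param age_mean,age_sd,age_range evaluation-age distribution (years),
#'   truncated to the range.
#' @return a `sim_config` list.
#' @export
sim_config <- function(traits = default_sim_traits(), g_cor = NULL,
                       n_founders = 200L, n_generations = 5L,
                       n_per_generation = 360L, offspring_per_mating = 2L,
                       mating = c("random", "fullsib"), n_studs = 30L,
                       age_mean = 4.86, age_sd = 2.25, age_range = c(2, 23)) {
  mating <- match.arg(mating)
  if (inherits(traits, "sim_trait")) traits <- list(traits)
  T <- length(traits)
  if (is.null(g_cor)) g_cor <- if (T == 6) default_g_cor() else diag(T)
  stopifnot(nrow(g_cor) == T, n_generations >= 1)
  ev <- eigen(g_cor, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-8) stop("genetic correlation matrix is not positive definite")
  structure(list(traits = traits, g_cor = g_cor,
                 n_founders = as.integer(n_founders),
                 n_generations = as.integer(n_generations),
                 n_per_generation = as.integer(n_per_generation),
                 offspring_per_mating = as.integer(offspring_per_mating),
                 mating = mating, n_studs = as.integer(n_studs),
                 age_mean = age_mean, age_sd = age_sd, age_range = age_range),
            class = "sim_config")
}

#' True genetic and residual covariance matrices of a configuration
#' @param cfg a [sim_config()].
#' @return list with `G`, `R` and the per-trait additive sds.
#' @export
true_covariances <- function(cfg) {
  sd_u <- vapply(cfg$traits, function(tr)
    if (tr$kind == "ordinal") sqrt(tr$h2 / (1 - tr$h2)) else sqrt(tr$h2) * tr$sd, 0)
  r_v <- vapply(cfg$traits, function(tr)
    if (tr$kind == "ordinal") 1 else (1 - tr$h2) * tr$sd^2, 0)
  G <- diag(sd_u, length(sd_u)) %*% cfg$g_cor %*% diag(sd_u, length(sd_u))
  tn <- vapply(cfg$traits, `[[`, "", "name")
  dimnames(G) <- list(tn, tn)
  list(G = G, R = diag(r_v, length(r_v)), sd_u = sd_u)
}

#' Simulate a multi-generation pedigree
#'
#' Discrete non-overlapping generations; parents are sampled within the
#' previous generation. Birth year is the generation number; sexes are
#' balanced. Each mating is assigned to a birth stud whose size class
#' (small/medium/large) is a fixed property of the stud; offspring inherit
#' the mating's stud (stored as `attr(ped, "stud")`).
#' @param cfg a [sim_config()].
#' @param seed optional seed.
#' @return a [parse_pedigree()] object with `sex`, `birth_year` and a
#'   per-animal `stud` attribute.
#' @export
simulate_pedigree <- function(cfg, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stud_class <- sample(rep(c("small", "medium", "large"),
                           length.out = cfg$n_studs))
  id <- paste0("G0_", seq_len(cfg$n_founders))
  sex <- rep(c("male", "female"), length.out = cfg$n_founders)
  sire <- dam <- rep(NA_character_, cfg$n_founders)
  year <- rep(0L, cfg$n_founders)
  stud <- stud_class[sample.int(cfg$n_studs, cfg$n_founders, replace = TRUE)]

  prev <- seq_len(cfg$n_founders)
  for (g in seq_len(cfg$n_generations)) {
    males <- prev[sex[prev] == "male"]
    females <- prev[sex[prev] == "female"]
    if (cfg$mating == "fullsib") {
      n_pairs <- min(length(males), length(females))
      sires <- males[seq_len(n_pairs)]
      dams <- females[seq_len(n_pairs)]
      n_off <- rep(2L, n_pairs)
    } else {
      n_mat <- ceiling(cfg$n_per_generation / cfg$offspring_per_mating)
      sires <- sample(males, n_mat, replace = TRUE)
      dams <- sample(females, n_mat, replace = TRUE)
      n_off <- rep(cfg$offspring_per_mating, n_mat)
    }
    mat_stud <- stud_class[sample.int(cfg$n_studs, length(sires), replace = TRUE)]
    midx <- rep(seq_along(sires), n_off)   # mating index per offspring
    within <- sequence(n_off)              # birth order within mating
    n_new <- length(midx)
    if (n_new == 0L) { prev <- integer(0); next }
    id <- c(id, paste0("G", g, "_", seq_len(n_new)))
    sire <- c(sire, id[sires[midx]])
    dam <- c(dam, id[dams[midx]])
    sex <- c(sex, ifelse(within %% 2 == 1, "male", "female"))
    year <- c(year, rep(g, n_new))
    stud <- c(stud, mat_stud[midx])
    prev <- seq.int(length(id) - n_new + 1L, length(id))
  }
  ped <- parse_pedigree(data.frame(id = id, sire = sire, dam = dam,
                                   birth_year = year, sex = sex))
  attr(ped, "stud") <- stud[match(ped$id, id)]
  ped
}

#' Gene-drop simulation of true breeding values
#'
#' Founders draw from N(0, G); offspring receive the parent average plus a
#' Mendelian-sampling deviation with covariance d_i G, where
#' d_i = 1/2 - (F_s + F_d)/4 (3/4 - F/4 with one known parent, 1 for
#' founders), so that Var(u_i) = (1 + F_i) G_ii.
#' @param ped a pedigree.
#' @param G true genetic covariance matrix.
#' @param seed optional seed.
#' @return matrix of true breeding values (animals x traits).
#' @export
gene_drop <- function(ped, G, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  G <- as.matrix(G)
  T <- nrow(G)
  L <- chol(G)
  F <- inbreeding(ped)
  u <- matrix(0, ped$n, T)
  Z <- matrix(stats::rnorm(ped$n * T), ped$n, T) %*% L
  for (i in seq_len(ped$n)) {
    s <- ped$sire[i]; d <- ped$dam[i]
    Fs <- if (is.na(s)) -1 else F[s]
    Fd <- if (is.na(d)) -1 else F[d]
    di <- 0.5 - 0.25 * (Fs + Fd)
    pa <- numeric(T)
    if (!is.na(s)) pa <- pa + 0.5 * u[s, ]
    if (!is.na(d)) pa <- pa + 0.5 * u[d, ]
    u[i, ] <- pa + sqrt(di) * Z[i, ]
  }
  rownames(u) <- ped$id
  colnames(u) <- rownames(G)
  u
}

#' Simulate phenotypes from true breeding values
#'
#' Liabilities l = fixed effects + covariate terms + u + e are thresholded
#' into ordinal categories (Gaussian traits are emitted directly). When a
#' trait carries target category frequencies, thresholds are calibrated as
#' inverse-CDF quantiles of the realised liabilities.
#' @param ped pedigree from [simulate_pedigree()].
#' @param u true breeding values from [gene_drop()].
#' @param cfg a [sim_config()].
#' @param phenotyped indices of phenotyped animals (default: all
#'   non-founders).
#' @param seed optional seed.
#' @return data frame `id,sex,stud_size,age,F,<traits>` with attributes
#'   `thresholds` (per ordinal trait, on the liability scale) and
#'   `liabilities`.
#' @export
simulate_phenotypes <- function(ped, u, cfg, phenotyped = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(phenotyped))
    phenotyped <- which(!(is.na(ped$sire) & is.na(ped$dam)))
  n <- length(phenotyped)
  T <- length(cfg$traits)
  tv <- true_covariances(cfg)
  F <- inbreeding(ped)[phenotyped]
  sex <- if (is.null(ped$sex)) rep(c("male", "female"), length.out = n)
         else ped$sex[phenotyped]
  stud <- attr(ped, "stud")[phenotyped]
  if (is.null(stud) || length(stud) == 0) stud <- rep("small", n)
  age <- pmin(cfg$age_range[2],
              pmax(cfg$age_range[1],
                   round(stats::rnorm(n, cfg$age_mean, cfg$age_sd))))

  phen <- data.frame(id = ped$id[phenotyped], sex = sex, stud_size = stud,
                     age = age, F = as.numeric(F))
  thresholds <- list()
  liab_all <- matrix(NA_real_, n, T)
  for (k in seq_len(T)) {
    tr <- cfg$traits[[k]]
    xb <- tr$b_sex * (sex == "male") +
      ifelse(stud == "medium", tr$b_stud[1],
             ifelse(stud == "large", tr$b_stud[2], 0)) +
      tr$b_age * age + tr$b_F * F
    e <- stats::rnorm(n, 0, sqrt(tv$R[k, k]))
    liab <- xb + u[phenotyped, k] + e
    if (tr$kind == "gaussian") {
      y <- tr$mean + liab
    } else {
      K <- tr$n_categories
      thr <- if (!is.null(tr$freq)) {
        as.numeric(stats::quantile(liab, cumsum(tr$freq)[-K], type = 1))
      } else if (!is.null(tr$thresholds)) tr$thresholds
      else c(0, seq_len(K - 2))
      y <- tr$base + rowSums(outer(liab, thr, `>=`))
      thresholds[[tr$name]] <- thr
    }
    if (tr$missing_rate > 0)
      y[stats::runif(n) < tr$missing_rate] <- NA
    phen[[tr$name]] <- y
    liab_all[, k] <- liab
  }
  attr(phen, "thresholds") <- thresholds
  attr(phen, "liabilities") <- liab_all
  phen
}

#' Simulate a complete dataset with known truth
#'
#' Pedigree, true breeding values and phenotypes under one configuration,
#' bundled with the ground-truth parameter record used by the
#' parameter-recovery tests.
#' @param cfg a [sim_config()].
#' @param seed integer seed (single source of randomness for the dataset).
#' @return a `hoof_sim` list: `ped`, `phen`, `u_true`, `truth` (G, R, h2,
#'   slopes, thresholds, seed).
#' @export
simulate_dataset <- function(cfg, seed = 1L) {
  set.seed(seed)
  ped <- simulate_pedigree(cfg)
  tv <- true_covariances(cfg)
  u <- gene_drop(ped, tv$G)
  phen <- simulate_phenotypes(ped, u, cfg)
  tn <- vapply(cfg$traits, `[[`, "", "name")
  truth <- list(G = tv$G, R = tv$R,
                h2 = stats::setNames(vapply(cfg$traits, `[[`, 0, "h2"), tn),
                b_sex = stats::setNames(vapply(cfg$traits, `[[`, 0, "b_sex"), tn),
                b_age = stats::setNames(vapply(cfg$traits, `[[`, 0, "b_age"), tn),
                b_F = stats::setNames(vapply(cfg$traits, `[[`, 0, "b_F"), tn),
                thresholds = attr(phen, "thresholds"), seed = seed)
  structure(list(ped = ped, phen = phen, u_true = u, truth = truth),
            class = "hoof_sim")
}

#' Write a simulated dataset to plain-text files
#'
#' Emits `ped.csv`, `phen.csv` and `truth.json` into a directory; the round
#' trip through [read_dataset()] restores the tables and truth record.
#' @param ds a `hoof_sim` from [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @return invisibly, the file paths.
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "hoof_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ped_df <- data.frame(id = ds$ped$id,
                       sire = ifelse(is.na(ds$ped$sire), "0", ds$ped$id[ds$ped$sire]),
                       dam = ifelse(is.na(ds$ped$dam), "0", ds$ped$id[ds$ped$dam]),
                       birth_year = ds$ped$birth_year, sex = ds$ped$sex)
  files <- file.path(dir, c("ped.csv", "phen.csv", "truth.json"))
  utils::write.csv(ped_df, files[1], row.names = FALSE, quote = FALSE)
  utils::write.csv(ds$phen, files[2], row.names = FALSE, quote = FALSE)
  jsonlite::write_json(ds$truth, files[3], digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(files)
}

#' Read back a dataset written by [write_dataset()]
#' @param dir directory holding `ped.csv`, `phen.csv`, `truth.json`.
#' @return list with `ped`, `phen`, `truth`.
#' @export
read_dataset <- function(dir) {
  ped <- read_pedigree(file.path(dir, "ped.csv"))
  phen <- read_phenotypes(file.path(dir, "phen.csv"))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  if (!is.null(truth$G)) truth$G <- as.matrix(truth$G)
  if (!is.null(truth$R)) truth$R <- as.matrix(truth$R)
  list(ped = ped, phen = phen, truth = truth)
}
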