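#' Trait specification
#'
#' Describes how one trait enters the threshold model: an ordinal trait with
#' K consecutive integer categories starting at `base` (0 for the defect
#' scores, 1 for the tendon-diameter scale), or a Gaussian trait observed
#' directly on its own scale.
#'
#' @param name trait name (column in the phenotype table).
#' @param kind `"ordinal"` or `"gaussian"`.
#' @param n_categories number of ordinal categories (K >= 2); ignored for
#'   Gaussian traits.
#' @param base first category code of an ordinal trait.
#' @return a `trait_spec` list.
#' @export
trait_spec <- function(name, kind = c("ordinal", "gaussian"),
                       n_categories = 3L, base = 0L) {
  kind <- match.arg(kind)
  if (kind == "ordinal" && n_categories < 2)
    stop("ordinal traits need at least 2 categories")
  structure(list(name = name, kind = kind,
                 n_categories = if (kind == "ordinal") as.integer(n_categories) else NA_integer_,
                 base = as.integer(base)),
            class = "trait_spec")
}

#' Standard defect-trait sets
#'
#' The four angular hoof deviations under the three-category coding
#' (`traits_modelA`: 0 none / 1 minor / 2 pronounced) or the dichotomous
#' coding (`traits_modelB`: 0 absent / 1 present).
#' @param names trait names.
#' @return list of [trait_spec()] objects.
#' @export
traits_modelA <- function(names = c("SFF", "PTF", "SFR", "PTR")) {
  lapply(names, trait_spec, kind = "ordinal", n_categories = 3L)
}

#' @rdname traits_modelA
#' @export
traits_modelB <- function(names = c("SFF", "PTF", "SFR", "PTR")) {
  lapply(names, trait_spec, kind = "ordinal", n_categories = 2L)
}

#' Collapse three-category scores to the dichotomous coding
#'
#' Category 0 stays 0; categories 1 and 2 (defect present) are joined into
#' category 1. Missing values are preserved.
#' @param scores vector of scores in `{0, 1, 2, NA}`.
#' @return integer vector of 0/1/NA.
#' @examples
#' recode_modelA_to_modelB(c(0, 1, 2, NA))
#' @export
recode_modelA_to_modelB <- function(scores) {
  bad <- !is.na(scores) & !(scores %in% 0:2)
  if (any(bad))
    stop("scores outside {0,1,2}: ", paste(unique(scores[bad]), collapse = ", "))
  as.integer(pmin(scores, 1L))
}

#' Read a phenotype CSV
#'
#' Columns `id,sex,stud_size,age,F,<trait columns...>`; empty cells are
#' missing values.
#' @param file path.
#' @return data frame with `id` as character.
#' @export
read_phenotypes <- function(file) {
  phen <- utils::read.csv(file, na.strings = c("", "NA"))
  phen$id <- as.character(phen$id)
  phen
}

#' Build design matrices for the threshold animal model
#'
#' Constructs the fixed-effect incidence matrix X (shared across traits),
#' the response matrix with per-trait missingness, and the animal index
#' mapping records to the pedigree. Categorical effects are coded by
#' treatment contrasts against their first (alphabetical) level; empty
#' levels are dropped, and an effect that collapses to a single level is
#' removed entirely with a warning. Covariates are centred so the intercept
#' sits at the covariate mean.
#'
#' @param phen phenotype data frame (see [read_phenotypes()]).
#' @param ped a [parse_pedigree()] object; every phenotyped animal must
#'   appear in it.
#' @param traits list of [trait_spec()] objects naming columns of `phen`.
#' @param fixed character vector of categorical fixed-effect columns.
#' @param covariates character vector of linear covariate columns.
#' @param intercept include an intercept column (disabled only for
#'   prior-validation runs where every location effect needs a proper
#'   prior).
#' @return a `hoof_design` list with elements `X`, `Y` (ordinal codes
#'   shifted to start at 0), `kind` (0 = Gaussian, else K), `animal`
#'   (pedigree index per record), `trait_names`, `x_names`, `n_animals`,
#'   `animal_id`, `base`.
#' @export
build_design <- function(phen, ped, traits,
                         fixed = c("sex", "stud_size"),
                         covariates = c("age", "F"),
                         intercept = TRUE) {
  stopifnot(is.data.frame(phen), inherits(ped, "pedigree"))
  if (inherits(traits, "trait_spec")) traits <- list(traits)
  idx <- match(as.character(phen$id), ped$id)
  if (anyNA(idx))
    stop("phenotyped animals absent from pedigree: ",
         paste(utils::head(phen$id[is.na(idx)], 10), collapse = ", "))
  if (anyDuplicated(idx))
    stop("more than one record per animal is not supported")

  keep_fixed <- character(0)
  for (f in fixed) {
    lev <- unique(stats::na.omit(as.character(phen[[f]])))
    if (length(lev) < 2) {
      warning("fixed effect '", f, "' has a single level and was dropped")
    } else keep_fixed <- c(keep_fixed, f)
  }
  df <- data.frame(row.names = seq_len(nrow(phen)))
  for (f in keep_fixed) df[[f]] <- droplevels(factor(phen[[f]]))
  for (v in covariates) df[[v]] <- as.numeric(phen[[v]]) - mean(as.numeric(phen[[v]]), na.rm = TRUE)
  terms <- c(keep_fixed, covariates)
  fml <- if (length(terms)) stats::reformulate(terms, intercept = intercept)
         else if (intercept) ~1 else ~0
  X <- stats::model.matrix(fml, df)

  tn <- vapply(traits, `[[`, "", "name")
  kind <- vapply(traits, function(tr)
    if (tr$kind == "gaussian") 0L else tr$n_categories, 0L)
  base <- vapply(traits, `[[`, 0L, "base")
  Y <- matrix(NA_real_, nrow(phen), length(traits),
              dimnames = list(NULL, tn))
  for (k in seq_along(traits)) {
    y <- as.numeric(phen[[tn[k]]])
    if (kind[k] > 0) {
      code <- y - base[k]
      ok <- is.na(code) | (code %in% 0:(kind[k] - 1))
      if (!all(ok))
        stop("trait ", tn[k], ": scores outside its category set: ",
             paste(unique(y[!ok]), collapse = ", "))
      Y[, k] <- code
    } else Y[, k] <- y
  }

  structure(list(X = X, Y = Y, kind = kind, base = base,
                 animal = idx, trait_names = tn,
                 x_names = colnames(X),
                 n_animals = ped$n, animal_id = ped$id),
            class = "hoof_design")
}

#' Gibbs sampler configuration
#'
#' Schedule and prior specification for [gibbs_run()]. Defaults follow the
#' long single-chain convention for these models: 100,000 iterations with a
#' 20,000-iteration burn-in and every 10th sample stored (8,000 draws).
#' Priors are proper inverse-Wisharts; with `prior_df = T + 2` the prior
#' mean of the genetic covariance is `prior_scale_g * I` and of the
#' residual covariance `prior_scale_r * I` (weakly informative, centred at
#' a liability-scale heritability of 0.2).
#'
#' @param n_iter,burn_in,thin Gibbs schedule; `burn_in < n_iter`, `thin >= 1`.
#' @param seed integer seed; the run is bit-reproducible given the seed.
#' @param prior_df_g,prior_df_r inverse-Wishart degrees of freedom (must
#'   exceed `n_traits + 1` for a proper prior with finite mean); `NULL`
#'   resolves to `n_traits + 2` at fit time.
#' @param prior_scale_g,prior_scale_r scalar multiples of the identity used
#'   as inverse-Wishart scale matrices, or full matrices.
#' @param prior_b_var variance multiplier of the weakly informative normal
#'   prior on each location effect, `b ~ N(0, prior_b_var * R_tt)`. The
#'   prior is scale-covariant, which keeps the working-scale posterior of
#'   ordinal traits proper; at the default (prior sd = 10 residual sds) it
#'   carries no practical information about identified effects.
#' @return a `model_config` list.
#' @export
model_config <- function(n_iter = 100000L, burn_in = 20000L, thin = 10L,
                         seed = 1L,
                         prior_df_g = NULL, prior_scale_g = 0.2,
                         prior_df_r = NULL, prior_scale_r = 0.8,
                         prior_b_var = 100) {
  stopifnot(burn_in < n_iter, thin >= 1, n_iter > 0, prior_b_var > 0)
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), seed = as.integer(seed),
                 prior_df_g = prior_df_g, prior_scale_g = prior_scale_g,
                 prior_df_r = prior_df_r, prior_scale_r = prior_scale_r,
                 prior_b_var = prior_b_var),
            class = "model_config")
}
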