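#' Run the multi-trait threshold animal model Gibbs sampler
#'
#' Samples the joint posterior of fixed effects, breeding values, latent
#' liabilities, thresholds and the genetic/residual covariance matrices for
#' the model \eqn{y = Xb + Zu + e}, \eqn{u \sim N(0, G \otimes A)},
#' \eqn{e \sim N(0, I \otimes R)}, where ordinal traits observe the category
#' of a Gaussian liability cut at ordered thresholds. Updates per iteration,
#' in order: liabilities, location effects (b, u), thresholds, G, R.
#'
#' Identification: the ordinal block of the residual covariance is fixed at
#' the identity (unit liability variances; zero residual covariance among
#' ordinal traits), and the remaining blocks are drawn from the exact
#' conditional inverse-Wishart given that block, which keeps the update
#' conjugate. Stored ordinal residual variances are therefore exactly 1 and
#' ordinal heritabilities are on the liability scale,
#' \eqn{G_{tt}/(G_{tt}+1)}. The first threshold of every ordinal trait is
#' fixed at 0; interior thresholds are sampled.
#'
#' @param design a [build_design()] object.
#' @param ainv sparse A-inverse from [a_inverse()] (dimension = pedigree
#'   size).
#' @param config a [model_config()].
#' @param sc_mode successive-conditional mode: after each parameter cycle
#'   the data are re-simulated from the current model, so the marginal
#'   distribution of the stored parameters is their prior (used for
#'   joint-distribution validation of the sampler, not for data analysis).
#' @param store_liab also return the final liability matrix.
#' @return a `hoof_fit` object: stored draws (`G`, `R`, `b`, `thresholds`
#'   matrices with one row per draw), per-draw deviances, plug-in deviance,
#'   EBV posterior means, and run metadata.
#' @export
gibbs_run <- function(design, ainv, config = model_config(),
                      sc_mode = FALSE, store_liab = FALSE) {
  stopifnot(inherits(design, "hoof_design"), inherits(config, "model_config"))
  T <- length(design$trait_names)
  df_g <- if (is.null(config$prior_df_g)) T + 2 else config$prior_df_g
  df_r <- if (is.null(config$prior_df_r)) T + 2 else config$prior_df_r
  if (df_g <= T + 1 || df_r <= T + 1)
    stop("prior degrees of freedom must exceed n_traits + 1")
  as_scale <- function(s) if (is.matrix(s)) s else diag(s, T)
  Sg <- as_scale(config$prior_scale_g)
  Sr <- as_scale(config$prior_scale_r)

  n <- design$n_animals
  if (!all(dim(ainv) == c(n, n)))
    stop("ainv dimension does not match the pedigree size")
  tri <- methods::as(methods::as(ainv, "generalMatrix"), "TsparseMatrix")
  ij <- cbind(tri@i + 1L, tri@j + 1L)
  storage.mode(ij) <- "integer"

  set.seed(config$seed)
  raw <- gibbs_threshold_cpp(design$Y, design$X, design$animal, n,
                             ij, tri@x, as.integer(design$kind),
                             df_g, Sg, df_r, Sr, config$prior_b_var,
                             config$n_iter, config$burn_in, config$thin,
                             sc_mode, store_liab)

  gg <- expand.grid(i = design$trait_names, j = design$trait_names)
  colnames(raw$G) <- colnames(raw$R) <- paste0(gg$i, ":", gg$j)
  if (ncol(raw$b))
    colnames(raw$b) <- paste0(rep(design$trait_names, each = length(design$x_names)),
                              ":", design$x_names)
  thr_names <- unlist(lapply(seq_len(T), function(t)
    if (design$kind[t] >= 2)
      paste0(design$trait_names[t], ":t", seq_len(design$kind[t] - 1))))
  if (length(thr_names)) colnames(raw$thresholds) <- thr_names
  rownames(raw$ebv) <- design$animal_id
  colnames(raw$ebv) <- design$trait_names

  structure(list(G = raw$G, R = raw$R, b = raw$b,
                 thresholds = if (length(thr_names))
                   raw$thresholds[, thr_names, drop = FALSE] else NULL,
                 deviance = as.numeric(raw$deviance),
                 deviance_plugin = raw$deviance_plugin,
                 ebv = raw$ebv,
                 n_keep = raw$n_keep,
                 R_expanded_diag = raw$R_expanded_diag,
                 pd_rejects = raw$pd_rejects,
                 threshold_fallbacks = raw$threshold_fallbacks,
                 final_liab = raw$final_liab,
                 trait_names = design$trait_names,
                 kind = design$kind,
                 x_names = design$x_names,
                 config = config),
            class = "hoof_fit")
}

#' @export
#' @method print hoof_fit
print.hoof_fit <- function(x, ...) {
  cat("threshold animal model fit:", length(x$trait_names), "trait(s),",
      x$n_keep, "stored draws\n")
  cat("posterior mean h2:",
      paste(sprintf("%s=%.3f", x$trait_names,
                    vapply(x$trait_names, function(tr)
                      mean(h2_draws(x, tr)), 0)), collapse = ", "), "\n")
  invisible(x)
}

#' Convenience end-to-end fit
#'
#' Parses nothing: takes in-memory phenotypes and pedigree, builds the
#' design and A-inverse, and runs the sampler.
#' @inheritParams build_design
#' @inheritParams gibbs_run
#' @param model `"A"` keeps the scores as given; `"B"` first collapses
#'   every 3-category ordinal trait with [recode_modelA_to_modelB()].
#' @return a `hoof_fit`.
#' @export
fit_threshold_model <- function(phen, ped, traits, config = model_config(),
                                model = c("A", "B"),
                                fixed = c("sex", "stud_size"),
                                covariates = c("age", "F")) {
  model <- match.arg(model)
  if (model == "B") {
    for (k in seq_along(traits)) {
      tr <- traits[[k]]
      if (tr$kind == "ordinal" && tr$n_categories == 3L && tr$base == 0L) {
        phen[[tr$name]] <- recode_modelA_to_modelB(phen[[tr$name]])
        traits[[k]] <- trait_spec(tr$name, "ordinal", 2L)
      }
    }
  }
  design <- build_design(phen, ped, traits, fixed = fixed,
                         covariates = covariates)
  gibbs_run(design, a_inverse(ped), config)
}

#' Deviance information criterion of a fit
#'
#' DIC = 2 mean(D) - D(posterior means), with the deviance D computed from
#' the observed-data likelihood (univariate normal CDF differences per
#' ordinal record, normal densities for Gaussian records); category
#' probabilities are floored at 1e-12.
#' @param fit a `hoof_fit` with at least 100 stored draws.
#' @return list with `dic`, `p_d` (effective parameters), `mean_deviance`
#'   and `plugin_deviance`.
#' @export
compute_dic <- function(fit) {
  stopifnot(inherits(fit, "hoof_fit"))
  if (fit$n_keep < 100) stop("DIC needs at least 100 stored draws")
  mean_dev <- mean(fit$deviance)
  list(dic = 2 * mean_dev - fit$deviance_plugin,
       p_d = mean_dev - fit$deviance_plugin,
       mean_deviance = mean_dev,
       plugin_deviance = fit$deviance_plugin)
}

#' Posterior draws of variance components and derived parameters
#'
#' `h2_draws` returns the chain of liability-scale heritabilities
#' \eqn{\sigma^2_u / (\sigma^2_u + \sigma^2_e)} for one trait; `rg_draws`
#' the chain of genetic correlations for a trait pair; `ebv` the posterior
#' means of breeding values.
#' @param fit a `hoof_fit`.
#' @param trait,trait_i,trait_j trait names.
#' @return numeric vector of draws (or the EBV matrix).
#' @export
h2_draws <- function(fit, trait) {
  k <- match(trait, fit$trait_names)
  if (is.na(k)) stop("unknown trait: ", trait)
  nm <- paste0(trait, ":", trait)
  fit$G[, nm] / (fit$G[, nm] + fit$R[, nm])
}

#' @rdname h2_draws
#' @export
rg_draws <- function(fit, trait_i, trait_j) {
  for (tr in c(trait_i, trait_j))
    if (!tr %in% fit$trait_names) stop("unknown trait: ", tr)
  gij <- fit$G[, paste0(trait_i, ":", trait_j)]
  gii <- fit$G[, paste0(trait_i, ":", trait_i)]
  gjj <- fit$G[, paste0(trait_j, ":", trait_j)]
  gij / sqrt(gii * gjj)
}

#' @rdname h2_draws
#' @export
ebv <- function(fit) fit$ebv

#' Write stored draws and breeding values to plain-text files
#'
#' Emits the thinned chains as one long-format CSV
#' (`draw, parameter, trait_i, trait_j, value`) and the EBV posterior means
#' as a two-plus-column CSV (`id` plus one column per trait).
#' @param fit a `hoof_fit`.
#' @param dir output directory (created if needed).
#' @return invisibly, the two file paths.
#' @export
write_draws <- function(fit, dir) {
  stopifnot(inherits(fit, "hoof_fit"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  long_block <- function(mat, param) {
    if (is.null(mat) || ncol(mat) == 0) return(NULL)
    parts <- strsplit(colnames(mat), ":", fixed = TRUE)
    data.frame(draw = rep(seq_len(nrow(mat)), ncol(mat)),
               parameter = param,
               trait_i = rep(vapply(parts, `[`, "", 1), each = nrow(mat)),
               trait_j = rep(vapply(parts, `[`, "", 2), each = nrow(mat)),
               value = as.vector(mat))
  }
  draws <- rbind(long_block(fit$G, "G"), long_block(fit$R, "R"),
                 long_block(fit$b, "b"), long_block(fit$thresholds, "threshold"))
  f1 <- file.path(dir, "draws.csv")
  f2 <- file.path(dir, "ebv.csv")
  utils::write.csv(draws, f1, row.names = FALSE, quote = FALSE)
  utils::write.csv(data.frame(id = rownames(fit$ebv), fit$ebv,
                              check.names = FALSE),
                   f2, row.names = FALSE, quote = FALSE)
  invisible(c(f1, f2))
}
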