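#' Parse and validate a pedigree
#'
#' Builds a topologically sorted pedigree from a table of animal/sire/dam
#' rows. Unknown parents are coded `0`, the empty string, or `NA`. Animals
#' that appear only as parents are appended as founders. The returned order
#' guarantees that every parent precedes its offspring, which all downstream
#' pedigree algebra relies on.
#'
#' @param table a data frame whose first three columns are animal id, sire
#'   and dam; optional columns `birth_year` and `sex` are carried along.
#' @param unknown codes interpreted as an unknown parent.
#' @return an object of class `pedigree`: a list with character `id`, integer
#'   parent indices `sire`/`dam` (`NA` = unknown, always less than the
#'   animal's own index), optional `birth_year` and `sex`, and the size `n`.
#' @examples
#' ped <- parse_pedigree(data.frame(id = c("C", "A", "B"),
#'                                  sire = c("A", 0, 0),
#'                                  dam  = c("B", 0, 0)))
#' ped$id  # parents first
#' @export
parse_pedigree <- function(table, unknown = c("0", "", NA)) {
  stopifnot(is.data.frame(table), ncol(table) >= 3)
  id <- as.character(table[[1]])
  sire <- as.character(table[[2]])
  dam <- as.character(table[[3]])
  sire[sire %in% unknown | is.na(sire)] <- NA
  dam[dam %in% unknown | is.na(dam)] <- NA
  if (anyDuplicated(id))
    stop("duplicate animal id(s): ",
         paste(unique(id[duplicated(id)]), collapse = ", "))

  extra <- setdiff(c(sire, dam), c(id, NA))
  all_id <- c(id, extra)
  n <- length(all_id)
  pos <- match(all_id, all_id)
  names(pos) <- all_id
  s_idx <- ifelse(is.na(sire), NA_integer_, pos[sire])
  d_idx <- ifelse(is.na(dam), NA_integer_, pos[dam])
  s_idx <- c(s_idx, rep(NA_integer_, length(extra)))
  d_idx <- c(d_idx, rep(NA_integer_, length(extra)))

  by <- if ("birth_year" %in% names(table))
    c(as.integer(table$birth_year), rep(NA_integer_, length(extra))) else NULL
  sx <- if ("sex" %in% names(table))
    c(as.character(table$sex), rep(NA_character_, length(extra))) else NULL

  # Kahn topological sort; leftover nodes expose a cycle
  n_par <- (!is.na(s_idx)) + (!is.na(d_idx))
  pe <- c(s_idx, d_idx); ce <- c(seq_len(n), seq_len(n))
  keep <- !is.na(pe)
  children <- split(ce[keep], factor(pe[keep], levels = seq_len(n)))
  order <- integer(n)
  queue <- integer(n)
  roots <- which(n_par == 0L)
  queue[seq_along(roots)] <- roots
  qh <- 1L; qt <- length(roots); cnt <- 0L
  remaining <- n_par
  while (qh <= qt) {
    v <- queue[qh]; qh <- qh + 1L
    cnt <- cnt + 1L; order[cnt] <- v
    for (ch in children[[v]]) {
      remaining[ch] <- remaining[ch] - 1L
      if (remaining[ch] == 0L) { qt <- qt + 1L; queue[qt] <- ch }
    }
  }
  order <- order[seq_len(cnt)]
  if (length(order) < n) {
    member <- all_id[setdiff(seq_len(n), order)][1]
    stop("pedigree contains a cycle involving animal '", member, "'")
  }

  rank <- integer(n); rank[order] <- seq_len(n)
  remap <- function(ix) ifelse(is.na(ix), NA_integer_, rank[ix])
  ped <- list(id = all_id[order],
              sire = remap(s_idx)[order],
              dam = remap(d_idx)[order],
              birth_year = if (is.null(by)) NULL else by[order],
              sex = if (is.null(sx)) NULL else sx[order],
              n = n)
  class(ped) <- "pedigree"
  ped
}

#' Read a pedigree CSV
#'
#' Expects a header with columns `id,sire,dam[,birth_year,sex]`; `0` or an
#' empty cell marks an unknown parent.
#' @param file path to the CSV file.
#' @inheritParams parse_pedigree
#' @return a [parse_pedigree()] object.
#' @export
read_pedigree <- function(file, unknown = c("0", "", NA)) {
  tab <- utils::read.csv(file, colClasses = "character")
  if ("birth_year" %in% names(tab))
    tab$birth_year <- as.integer(tab$birth_year)
  parse_pedigree(tab, unknown = unknown)
}

#' @export
#' @method print pedigree
print.pedigree <- function(x, ...) {
  cat("pedigree:", x$n, "animals,",
      sum(is.na(x$sire) & is.na(x$dam)), "founders\n")
  cat("mean complete generation equivalents:",
      round(mean(generation_equivalents(x)), 3), "\n")
  invisible(x)
}

#' Complete generation equivalents
#'
#' Pedigree-depth metadata: for each animal, the sum of \eqn{(1/2)^g} over
#' all known ancestors \eqn{g} generations back. Reported for data-curation
#' purposes; no computation in the package enforces a minimum depth.
#' @param ped a [parse_pedigree()] object.
#' @return numeric vector, one value per animal.
#' @export
generation_equivalents <- function(ped) {
  g <- numeric(ped$n)
  for (i in seq_len(ped$n)) {
    gs <- if (is.na(ped$sire[i])) 0 else (g[ped$sire[i]] + 1) / 2
    gd <- if (is.na(ped$dam[i])) 0 else (g[ped$dam[i]] + 1) / 2
    g[i] <- gs + gd
  }
  g
}

#' Wright's inbreeding coefficients
#'
#' Computes F, the probability that the two alleles at a locus are identical
#' by descent, for every animal, using the Meuwissen-Luo recursive
#' algorithm. Unknown parents are treated as unrelated non-inbred founders,
#' so founders have F = 0 and the result does not depend on the original
#' file row order.
#'
#' @param ped a [parse_pedigree()] object.
#' @return numeric vector of inbreeding coefficients, named by animal id.
#' @examples
#' # offspring of two full sibs has F = 0.25
#' ped <- parse_pedigree(data.frame(id = c("a", "b", "s1", "s2", "x"),
#'                                  sire = c(0, 0, "a", "a", "s1"),
#'                                  dam  = c(0, 0, "b", "b", "s2")))
#' inbreeding(ped)["x"]
#' @export
inbreeding <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  s <- ifelse(is.na(ped$sire), 0L, ped$sire)
  d <- ifelse(is.na(ped$dam), 0L, ped$dam)
  F <- inbreeding_ml_cpp(s, d)
  names(F) <- ped$id
  F
}

#' Numerator relationship matrix (tabular method)
#'
#' Dense additive relationship matrix A with \eqn{a_{ij}} the expected
#' additive relationship and \eqn{a_{ii} = 1 + F_i}. Built by the tabular
#' recursion \eqn{a_{j,i} = (a_{j,s_i} + a_{j,d_i})/2}. Intended for small
#' pedigrees; the sampler itself only ever consumes the sparse inverse from
#' [a_inverse()].
#'
#' @param ped a [parse_pedigree()] object.
#' @param max_n refuse to build a dense matrix beyond this size.
#' @return dense symmetric matrix with dimnames = animal ids.
#' @export
relationship_matrix <- function(ped, max_n = 5000L) {
  stopifnot(inherits(ped, "pedigree"))
  n <- ped$n
  if (n > max_n)
    stop("pedigree has ", n, " animals (> ", max_n,
         "); use a_inverse() for large pedigrees")
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s <- ped$sire[i]; d <- ped$dam[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      as_ <- if (is.na(s)) numeric(i - 1L) else A[j, s]
      ad_ <- if (is.na(d)) numeric(i - 1L) else A[j, d]
      v <- 0.5 * (as_ + ad_)
      A[j, i] <- v
      A[i, j] <- v
    }
    A[i, i] <- 1 + if (is.na(s) || is.na(d)) 0 else 0.5 * A[s, d]
  }
  dimnames(A) <- list(ped$id, ped$id)
  A
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Assembles A^-1 directly in one pedigree pass by Henderson's rules with
#' the Quaas correction for inbred parents: each animal contributes
#' 1/d_i to its own diagonal, -1/(2 d_i) to animal-parent pairs and
#' 1/(4 d_i) among parents, where d_i is the Mendelian-sampling variance
#' d_i = 0.5 - 0.25 (F_s + F_d) (0.75 - 0.25 F for one known parent, 1 for
#' founders).
#'
#' @param ped a [parse_pedigree()] object.
#' @param F optional precomputed inbreeding coefficients (from
#'   [inbreeding()]); computed if missing.
#' @return a sparse symmetric [Matrix::Matrix] with dimnames = animal ids.
#' @export
a_inverse <- function(ped, F = NULL) {
  stopifnot(inherits(ped, "pedigree"))
  if (is.null(F)) F <- inbreeding(ped)
  n <- ped$n
  s <- ped$sire; d <- ped$dam
  Fs <- ifelse(is.na(s), -1, F[ifelse(is.na(s), 1L, s)])
  Fd <- ifelse(is.na(d), -1, F[ifelse(is.na(d), 1L, d)])
  dv <- 0.5 - 0.25 * (Fs + Fd)
  if (any(dv <= 1e-12))
    stop("non-positive Mendelian-sampling variance for animal(s): ",
         paste(ped$id[dv <= 1e-12], collapse = ", "))
  w <- 1 / dv
  i_idx <- seq_len(n); j_idx <- seq_len(n); x <- w
  ks <- which(!is.na(s)); kd <- which(!is.na(d)); kb <- which(!is.na(s) & !is.na(d))
  add <- function(i, j, v) {
    i_idx <<- c(i_idx, i, j); j_idx <<- c(j_idx, j, i); x <<- c(x, v, v)
  }
  if (length(ks)) add(ks, s[ks], -w[ks] / 2)
  if (length(kd)) add(kd, d[kd], -w[kd] / 2)
  if (length(ks)) { i_idx <- c(i_idx, s[ks]); j_idx <- c(j_idx, s[ks]); x <- c(x, w[ks] / 4) }
  if (length(kd)) { i_idx <- c(i_idx, d[kd]); j_idx <- c(j_idx, d[kd]); x <- c(x, w[kd] / 4) }
  if (length(kb)) add(s[kb], d[kb], w[kb] / 4)
  Ainv <- Matrix::sparseMatrix(i = i_idx, j = j_idx, x = x, dims = c(n, n),
                               dimnames = list(ped$id, ped$id))
  Matrix::forceSymmetric(Ainv)
}

#' Write inbreeding coefficients to CSV
#' @param F named vector from [inbreeding()].
#' @param file output path; columns `id,F`.
#' @export
write_inbreeding <- function(F, file) {
  utils::write.csv(data.frame(id = names(F), F = as.numeric(F)),
                   file, row.names = FALSE, quote = FALSE)
}

#' Write a sparse A-inverse as coordinate triplets
#'
#' Lower triangle only, columns `row,col,value` with 1-based indices in
#' pedigree order.
#' @param Ainv matrix from [a_inverse()].
#' @param file output path.
#' @export
write_a_inverse <- function(Ainv, file) {
  tri <- methods::as(methods::as(Ainv, "generalMatrix"), "TsparseMatrix")
  keep <- tri@i >= tri@j
  utils::write.csv(data.frame(row = tri@i[keep] + 1L, col = tri@j[keep] + 1L,
                              value = tri@x[keep]),
                   file, row.names = FALSE, quote = FALSE)
}
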