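#' Tissue-of-origin deconvolution by constrained least squares
#'
#' Models the sample methylation vector at informative loci as a linear
#' mixture of reference tissue methylomes: with reference matrix `A` (loci
#' x tissues, methylation fractions) and measured locus methylation `m`,
#' solves
#'
#' \deqn{\min_X \|A X - m\|^2 \quad \mathrm{s.t.}\ 0 \le X_j \le 1,\ \sum_j X_j \le 1}
#'
#' The inequality \eqn{\sum X \le 1} allows mass from tissues absent from
#' the reference; that unexplained mass is reported as `unknown_fraction =
#' 1 - sum(X)`. Nonnegativity is imposed because negative tissue fractions
#' are physically meaningless. Loci missing (NA) in either the reference or
#' the sample are dropped pairwise, never imputed; at least as many usable
#' loci as tissues are required so that the system is overdetermined.
#'
#' The minimizer is found by accelerated projected gradient descent (FISTA)
#' with an exact Euclidean projection onto the feasible set, deterministic
#' all-zero initialization, and a relative objective-decrease tolerance of
#' 1e-12 (well below the 1e-9 contract).
#'
#' @param ref Reference matrix: a data frame with column `locus_id` plus one
#'   numeric column per tissue (fractions in 0..1), or a numeric matrix with
#'   locus-id rownames and tissue colnames.
#' @param sample A data frame `locus_id`, `meth_fraction` (e.g. from
#'   [locus_methylation()]); `NA` fractions are dropped.
#' @param max_iter,tol Solver iteration cap and relative objective
#'   tolerance.
#' @return A `tissue_composition` object: list with `coefficients` (tibble
#'   `tissue`, `coefficient`), `unknown_fraction`, `residual_norm`
#'   (Euclidean norm of `A X - m`), `n_loci_used`, `n_iter`. [tidy()]
#'   returns the coefficient tibble; [glance()] a one-row summary.
#' @examples
#' sim <- simulate_methylation_mixture(n_tissues = 3, n_loci = 60, depth = 1e5,
#'                                     true_coefficients = c(0.6, 0.3, 0.1),
#'                                     seed = 1)
#' fit <- deconvolve(sim$reference, sim$sample)
#' tidy(fit)
#' @export
deconvolve <- function(ref, sample, max_iter = 50000, tol = 1e-12) {
  pre <- align_ref_sample(ref, sample)
  A <- pre$A
  m <- pre$m
  if (nrow(A) < ncol(A)) {
    abort(paste0("need at least as many usable loci (", nrow(A),
                 ") as tissues (", ncol(A), ") for an overdetermined system"))
  }
  if (!all(is.finite(A)) || !all(is.finite(m))) abort("non-finite inputs")

  sol <- solve_box_simplex_ls(A, m, max_iter = max_iter, tol = tol)
  x <- sol$x
  structure(
    list(
      coefficients = tibble(tissue = colnames(A), coefficient = unname(x)),
      unknown_fraction = max(0, 1 - sum(x)),
      residual_norm = sqrt(sum((A %*% x - m)^2)),
      n_loci_used = nrow(A),
      n_iter = sol$n_iter
    ),
    class = "tissue_composition"
  )
}

align_ref_sample <- function(ref, sample) {
  if (is.matrix(ref)) {
    ref <- tibble::rownames_to_column(as.data.frame(ref), "locus_id")
  }
  if (!"locus_id" %in% names(ref)) abort("reference needs a locus_id column")
  tissues <- setdiff(names(ref), "locus_id")
  if (length(tissues) < 2) abort("reference needs at least 2 tissue columns")
  if (anyDuplicated(ref$locus_id)) abort("reference locus ids must be unique")
  A_full <- as.matrix(ref[, tissues])
  storage.mode(A_full) <- "double"
  rng <- range(A_full, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 1) abort("reference entries must lie in [0, 1]")

  s <- tibble(locus_id = as.character(sample$locus_id),
              meth_fraction = as.numeric(sample$meth_fraction))
  s <- s[!is.na(s$meth_fraction), ]
  idx <- match(s$locus_id, as.character(ref$locus_id))
  usable <- !is.na(idx)
  A <- A_full[idx[usable], , drop = FALSE]
  m <- s$meth_fraction[usable]
  complete <- stats::complete.cases(A)
  list(A = A[complete, , drop = FALSE], m = m[complete])
}

# exact Euclidean projection onto {0 <= x <= 1, sum(x) <= 1}
project_box_simplex <- function(x) {
  y <- pmin(pmax(x, 0), 1)
  if (sum(y) <= 1) return(y)
  # find shift lambda > 0 with sum(clamp(x - lambda, 0, 1)) == 1 (monotone)
  lo <- 0
  hi <- max(x)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (sum(pmin(pmax(x - mid, 0), 1)) > 1) lo <- mid else hi <- mid
  }
  pmin(pmax(x - hi, 0), 1)
}

solve_box_simplex_ls <- function(A, m, max_iter = 50000, tol = 1e-12) {
  AtA <- crossprod(A)
  Atm <- drop(crossprod(A, m))
  # Lipschitz constant of the gradient: largest eigenvalue of AtA
  L <- max(eigen(AtA, symmetric = TRUE, only.values = TRUE)$values)
  if (L <= 0) return(list(x = rep(0, ncol(A)), n_iter = 0L))
  obj <- function(x) sum((A %*% x - m)^2)

  x <- rep(0, ncol(A))
  z <- x
  t_k <- 1
  f_prev <- obj(x)
  n_iter <- 0L
  for (k in seq_len(max_iter)) {
    n_iter <- k
    grad <- 2 * (AtA %*% z - Atm)
    x_new <- project_box_simplex(drop(z - grad / (2 * L)))
    f_new <- obj(x_new)
    if (f_new > f_prev) { # restart acceleration on objective increase
      z <- x
      t_k <- 1
      grad <- 2 * (AtA %*% z - Atm)
      x_new <- project_box_simplex(drop(z - grad / (2 * L)))
      f_new <- obj(x_new)
    }
    t_next <- (1 + sqrt(1 + 4 * t_k^2)) / 2
    z <- x_new + ((t_k - 1) / t_next) * (x_new - x)
    converged <- abs(f_prev - f_new) <= tol * max(1, abs(f_prev)) && k > 1
    x <- x_new
    t_k <- t_next
    f_prev <- f_new
    if (converged) break
  }
  list(x = drop(x), n_iter = n_iter)
}

#' @export
print.tissue_composition <- function(x, ...) {
  cat("<tissue_composition> ", x$n_loci_used, " loci, residual norm ",
      format(x$residual_norm, digits = 4), ", unknown fraction ",
      format(x$unknown_fraction, digits = 4), "\n", sep = "")
  top <- dplyr::arrange(x$coefficients, dplyr::desc(.data$coefficient))
  print(head(top, 10))
  invisible(x)
}

#' @method tidy tissue_composition
#' @export
tidy.tissue_composition <- function(x, ...) x$coefficients

#' @method glance tissue_composition
#' @export
glance.tissue_composition <- function(x, ...) {
  tibble(
    n_loci_used = x$n_loci_used,
    residual_norm = x$residual_norm,
    explained_fraction = sum(x$coefficients$coefficient),
    unknown_fraction = x$unknown_fraction,
    n_iter = x$n_iter
  )
}

#' Deconvolve a batch of samples and report replicate concordance
#'
#' Runs [deconvolve()] per sample, collecting errors without aborting the
#' batch, and reports the Pearson correlation matrix of the coefficient
#' vectors across successfully deconvolved samples (the replicate
#' concordance statistic).
#'
#' @param ref Reference matrix as in [deconvolve()].
#' @param samples Named list of sample data frames (`locus_id`,
#'   `meth_fraction`).
#' @param ... Passed to [deconvolve()].
#' @return A `batch_deconvolution` object: list with `compositions` (named
#'   list of `tissue_composition`), `errors` (named character vector),
#'   `correlation` (matrix). [tidy()] returns a long tibble `sample`,
#'   `tissue`, `coefficient`.
#' @export
batch_deconvolve <- function(ref, samples, ...) {
  if (length(samples) == 0) abort("at least one sample is required")
  nm <- names(samples) %||% paste0("sample", seq_along(samples))
  fits <- purrr::map(samples, function(s) {
    tryCatch(deconvolve(ref, s, ...), error = function(e) conditionMessage(e))
  })
  names(fits) <- nm
  ok <- purrr::map_lgl(fits, inherits, "tissue_composition")
  errors <- unlist(fits[!ok])
  comps <- fits[ok]
  corr <- if (length(comps) >= 2) {
    mat <- vapply(comps, function(f) f$coefficients$coefficient,
                  numeric(nrow(comps[[1]]$coefficients)))
    cor(mat)
  } else {
    NULL
  }
  structure(list(compositions = comps, errors = errors, correlation = corr),
            class = "batch_deconvolution")
}

#' @method tidy batch_deconvolution
#' @export
tidy.batch_deconvolution <- function(x, ...) {
  purrr::imap_dfr(x$compositions, function(f, nm) {
    dplyr::mutate(f$coefficients, sample = nm, .before = 1)
  })
}

#' @export
print.batch_deconvolution <- function(x, ...) {
  cat("<batch_deconvolution> ", length(x$compositions), " sample(s), ",
      length(x$errors), " error(s)\n", sep = "")
  if (!is.null(x$correlation)) {
    cat("replicate coefficient correlations:\n")
    print(round(x$correlation, 3))
  }
  invisible(x)
}
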