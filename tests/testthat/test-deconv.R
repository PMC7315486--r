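random_feasible_x <- function(k, seed) {
  withr::with_seed(seed, {
    raw <- rexp(k)
    raw / sum(raw) * runif(1, 0.5, 1) # random direction, sum in [0.5, 1]
  })
}

check_constraints <- function(fit, tol = 1e-6) {
  x <- fit$coefficients$coefficient
  expect_true(all(x >= -tol & x <= 1 + tol))
  expect_lte(sum(x), 1 + tol)
  expect_gte(fit$unknown_fraction, -tol)
}

test_that("exact single-tissue and symmetric two-tissue mixtures are recovered", {
  sim <- simulate_methylation_mixture(4, 120, depth = 1e6,
                                      true_coefficients = c(0, 1, 0, 0), seed = 1)
  ref <- sim$reference
  # sample equal to the second reference column exactly
  pure <- tibble::tibble(locus_id = ref$locus_id, meth_fraction = ref$tissue2)
  fit <- deconvolve(ref, pure)
  expect_equal(fit$coefficients$coefficient, c(0, 1, 0, 0), tolerance = 1e-6)
  expect_lt(fit$residual_norm, 1e-6)
  check_constraints(fit)
  # two tissues all-0 / all-1, sample all 0.5: the fully methylated tissue
  # must carry exactly 0.5; the all-zero column is unidentifiable (any value
  # in [0, 0.5] fits perfectly), so only the determined part is asserted
  ref2 <- tibble::tibble(locus_id = paste0("L", 1:50),
                         low = rep(0, 50), high = rep(1, 50))
  fit2 <- deconvolve(ref2, tibble::tibble(locus_id = ref2$locus_id,
                                          meth_fraction = 0.5))
  expect_equal(fit2$coefficients$coefficient[fit2$coefficients$tissue == "high"],
               0.5, tolerance = 1e-6)
  expect_lt(fit2$residual_norm, 1e-9)
  check_constraints(fit2)
})

test_that("noiseless mixtures are recovered to 1e-3 elementwise over many seeds", {
  for (seed in 1:20) {
    x_true <- random_feasible_x(5, seed)
    sim <- simulate_methylation_mixture(5, 200, depth = 1,
                                        true_coefficients = x_true, seed = seed)
    # replace the binomial sample by the exact mixture (noiseless system)
    A <- as.matrix(sim$reference[, -1])
    exact <- tibble::tibble(locus_id = sim$reference$locus_id,
                            meth_fraction = drop(A %*% x_true))
    fit <- deconvolve(sim$reference, exact)
    expect_lt(max(abs(fit$coefficients$coefficient - x_true)), 1e-3)
    check_constraints(fit)
  }
})

test_that("solution beats the zero vector and every single-tissue vertex", {
  sim <- simulate_methylation_mixture(6, 150, depth = 50,
                                      true_coefficients = rep(0.15, 6), seed = 31)
  A <- as.matrix(sim$reference[, -1])
  m <- sim$sample$meth_fraction
  fit <- deconvolve(sim$reference, sim$sample)
  obj <- function(x) sum((A %*% x - m)^2)
  best <- obj(fit$coefficients$coefficient)
  expect_lte(best, obj(rep(0, 6)) + 1e-12)
  for (j in 1:6) expect_lte(best, obj(replace(rep(0, 6), j, 1)) + 1e-12)
})

test_that("solver agrees with constrOptim on small well-conditioned problems", {
  for (seed in c(3, 14)) {
    x_true <- random_feasible_x(3, seed + 200)
    sim <- simulate_methylation_mixture(3, 80, depth = 100,
                                        true_coefficients = x_true, seed = seed)
    A <- as.matrix(sim$reference[, -1])
    m <- sim$sample$meth_fraction
    fit <- deconvolve(sim$reference, sim$sample)
    # independent route: barrier method on the same constrained objective
    ui <- rbind(diag(3), -diag(3), -rep(1, 3))
    ci <- c(rep(0, 3), rep(-1, 3), -1)
    ref_fit <- stats::constrOptim(rep(0.2, 3), f = function(x) sum((A %*% x - m)^2),
                                  grad = function(x) drop(2 * crossprod(A, A %*% x - m)),
                                  ui = ui, ci = ci - 1e-9)
    expect_lt(max(abs(fit$coefficients$coefficient - ref_fit$par)), 1e-3)
  }
})

test_that("pairwise deletion drops missing loci and underdetermined systems error", {
  sim <- simulate_methylation_mixture(5, 40, depth = 1e5,
                                      true_coefficients = rep(0.2, 5), seed = 41)
  s <- sim$sample
  s$meth_fraction[1:10] <- NA
  fit <- deconvolve(sim$reference, s)
  expect_equal(fit$n_loci_used, 30)
  s$meth_fraction[1:37] <- NA # 3 usable loci < 5 tissues
  expect_error(deconvolve(sim$reference, s), "overdetermined")
  bad <- sim$sample
  bad$meth_fraction[1] <- Inf
  expect_error(deconvolve(sim$reference, bad), "non-finite")
})

test_that("noisy replicates of one mixture deconvolve concordantly", {
  x_true <- c(0.35, 0.25, 0.2, 0.1, 0.05)
  sims <- lapply(1:3, function(r) {
    simulate_methylation_mixture(5, 300, depth = 50, true_coefficients = x_true,
                                 seed = 100) # same reference/truth ...
  })
  samples <- lapply(1:3, function(r) {
    # ... but independent binomial noise per replicate
    A <- as.matrix(sims[[1]]$reference[, -1])
    expected <- drop(A %*% x_true)
    withr::with_seed(300 + r, tibble::tibble(
      locus_id = sims[[1]]$reference$locus_id,
      meth_fraction = rbinom(300, 50, pmin(1, expected)) / 50))
  })
  names(samples) <- paste0("rep", 1:3)
  batch <- batch_deconvolve(sims[[1]]$reference, samples)
  expect_length(batch$compositions, 3)
  off_diag <- batch$correlation[lower.tri(batch$correlation)]
  expect_true(all(off_diag > 0.95))
  # identical samples correlate exactly
  batch2 <- batch_deconvolve(sims[[1]]$reference,
                             list(a = samples[[1]], b = samples[[1]]))
  expect_equal(unname(batch2$correlation["a", "b"]), 1)
  # one failing sample does not abort the batch
  broken <- samples
  broken$rep2 <- tibble::tibble(locus_id = "nope", meth_fraction = 0.5)
  batch3 <- batch_deconvolve(sims[[1]]$reference, broken)
  expect_length(batch3$compositions, 2)
  expect_length(batch3$errors, 1)
})

test_that("recovery error grows monotonically with binomial noise", {
  x_true <- c(0.3, 0.25, 0.2, 0.15, 0.1)
  rmse <- vapply(c(200, 100, 50, 20), function(depth) {
    errs <- vapply(1:5, function(r) {
      sim <- simulate_methylation_mixture(5, 250, depth = depth,
                                          true_coefficients = x_true,
                                          seed = 1000 + r)
      fit <- deconvolve(sim$reference, sim$sample)
      sqrt(mean((fit$coefficients$coefficient - x_true)^2))
    }, numeric(1))
    mean(errs)
  }, numeric(1))
  expect_gte(cor(seq_along(rmse), rmse, method = "spearman"), 0)
  expect_gt(rmse[4], rmse[1])
})

test_that("tidiers expose coefficients and fit summary", {
  sim <- simulate_methylation_mixture(3, 60, depth = 1e4,
                                      true_coefficients = c(0.5, 0.3, 0.2), seed = 8)
  fit <- deconvolve(sim$reference, sim$sample)
  td <- tidy(fit)
  expect_named(td, c("tissue", "coefficient"))
  g <- glance(fit)
  expect_equal(g$explained_fraction + g$unknown_fraction, 1, tolerance = 1e-9)
})
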