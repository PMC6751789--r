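test_that("a single ICA run recovers noiseless Laplace sources", {
  set.seed(21)
  n <- 1000; m <- 50
  S_true <- named_mat(rlaplace_test(n * 2), n, 2, sprefix = "src")
  M_true <- matrix(rnorm(2 * m), 2, m)
  E <- S_true %*% M_true
  colnames(E) <- paste0("s", 1:m)
  res <- run_single_ica(E, k = 2, seed = 4)
  mm <- match_components(S_true, res$S)
  expect_true(all(mm$r > 0.99))
})

test_that("rank-1 data yields an exactly matching single metagene", {
  set.seed(22)
  v <- rlaplace_test(500)
  E <- named_mat(v %o% rnorm(20), 500, 20)
  res <- run_single_ica(E, k = 1, seed = 1)
  expect_gt(abs(cor(res$S[, 1], v)), 0.999)
})

test_that("a run is bitwise deterministic given its seed", {
  set.seed(23)
  E <- named_mat(rnorm(200 * 30), 200, 30)
  r1 <- run_single_ica(E, k = 3, seed = 99)
  r2 <- run_single_ica(E, k = 3, seed = 99)
  expect_identical(r1$S, r2$S)
  expect_identical(r1$M, r2$M)
})

test_that("weight projection solves the least-squares problem", {
  set.seed(24)
  S <- named_mat(rnorm(100 * 4), 100, 4)
  W_true <- matrix(rnorm(4 * 12), 4, 12,
                   dimnames = list(colnames(S), paste0("s", 1:12)))
  E <- S %*% W_true
  W <- project_weights(S, E, center = rep(0, 100))
  expect_equal(unname(W), unname(W_true), tolerance = 1e-8)

  # orthonormal basis: projection equals the transpose product
  Q <- qr.Q(qr(S))
  dimnames(Q) <- dimnames(S)
  Eq <- Q %*% W_true + rnorm(100 * 12, sd = 0.1)
  colnames(Eq) <- colnames(E)
  Wq <- project_weights(Q, Eq, center = rep(0, 100))
  expect_equal(unname(Wq), unname(t(Q) %*% Eq), tolerance = 1e-8)

  # optimality: no random alternative beats the LS residual
  resid_norm <- function(W) norm(Eq - Q %*% W, "F")
  base <- resid_norm(Wq)
  alt <- replicate(100, resid_norm(Wq + matrix(rnorm(48, sd = 0.05), 4, 12)))
  expect_true(all(alt >= base))

  S_def <- cbind(S[, 1], S[, 1])  # rank deficient
  expect_error(project_weights(S_def, E), "rank deficient")
})

test_that("component matching resolves permutation and sign", {
  set.seed(25)
  S <- named_mat(rlaplace_test(300 * 2), 300, 2)
  S_run <- S[, c(2, 1)]
  S_run[, 1] <- -S_run[, 1]
  mm <- match_components(S, S_run)
  expect_identical(mm$perm, c(2L, 1L))
  # signs are indexed in aligned (standard) order: standard component 2
  # matched the negated run column, so it carries the -1
  expect_identical(mm$sign, c(1, -1))
  realigned <- sweep(S_run[, mm$perm], 2, mm$sign, `*`)
  expect_equal(realigned, S, tolerance = 1e-12, ignore_attr = TRUE)

  id <- match_components(S, S)
  expect_identical(id$perm, 1:2)
  expect_true(all(id$sign == 1))
})

test_that("greedy matching is near the exhaustive optimum across runs", {
  sim <- simulate_mixture(synthetic_scenario(n = 800, m = 60, k_true = 5,
                                             noise_sd = 1, seed = 26))
  X <- unclass(sim$E)
  for (rep in 1:10) {
    ra <- run_single_ica(X[, -rep, drop = FALSE], k = 4, seed = rep)
    rb <- run_single_ica(X[, -(rep + 1), drop = FALSE], k = 4,
                         seed = rep + 100)
    greedy <- sum(match_components(ra$S, rb$S)$r)
    best <- exhaustive_match_total(ra$S, rb$S)
    expect_gte(greedy, 0.95 * best)
  }
})

test_that("consensus decomposition recovers well-separated sources stably", {
  sim <- simulate_mixture(synthetic_scenario(n = 2000, m = 100, k_true = 5,
                                             noise_sd = 0.1, seed = 31))
  fit <- consica(sim$E, k = 5, nt = 20, seed = 31)
  mm <- match_components(sim$S_true, fit$S)
  expect_true(all(mm$r > 0.95))
  expect_true(all(fit$stability > 0.9))
  expect_identical(anyDuplicated(mm$perm), 0L)
})

test_that("over-decomposition produces unstable excess components", {
  sim <- simulate_mixture(synthetic_scenario(n = 1000, m = 80, k_true = 5,
                                             noise_sd = 1, seed = 32))
  fit <- consica(sim$E, k = 8, nt = 15, seed = 32)
  expect_gte(sum(fit$stability < 0.9), 3)
})

test_that("consensus fit is deterministic and serialisation round-trips", {
  sim <- simulate_mixture(synthetic_scenario(n = 400, m = 40, k_true = 3,
                                             seed = 33))
  f1 <- consica(sim$E, k = 3, nt = 6, seed = 7)
  f2 <- consica(sim$E, k = 3, nt = 6, seed = 7)
  expect_identical(f1$S, f2$S)
  expect_identical(f1$M, f2$M)
  expect_identical(f1$stability, f2$stability)

  d <- tempfile("decomp_")
  write_decomposition(f1, d)
  back <- read_decomposition(d)
  expect_equal(back$S, f1$S, tolerance = 1e-12)
  expect_equal(back$M, f1$M, tolerance = 1e-12)
  expect_equal(unname(back$stability), unname(f1$stability),
               tolerance = 1e-12)
  expect_identical(back$k, f1$k)
})

test_that("permuting feature rows permutes S and leaves M unchanged", {
  sim <- simulate_mixture(synthetic_scenario(n = 300, m = 40, k_true = 3,
                                             seed = 34))
  fit <- consica(sim$E, k = 3, nt = 5, seed = 5)
  perm <- sample(nrow(sim$E))
  fit_p <- consica(unclass(sim$E)[perm, ], k = 3, nt = 5, seed = 5)
  expect_equal(fit_p$S, fit$S[perm, ], tolerance = 1e-6)
  expect_equal(fit_p$M, fit$M, tolerance = 1e-6)
})

test_that("reconstruction is exact at the true rank and monotone in k", {
  sim <- simulate_mixture(synthetic_scenario(n = 400, m = 40, k_true = 3,
                                             noise_sd = 0, seed = 35))
  fit <- consica(sim$E, k = 3, nt = 5, seed = 3)
  rel <- norm(fitted(fit) - unclass(sim$E), "F") / norm(unclass(sim$E), "F")
  expect_lt(rel, 1e-6)
  expect_true(all(fit$stability > 0.99))

  noisy <- simulate_mixture(synthetic_scenario(n = 400, m = 30, k_true = 3,
                                               noise_sd = 1, seed = 36))
  err_at <- vapply(c(2, 4), function(k) {
    f <- consica(noisy$E, k = k, nt = 4, seed = 2)
    norm(fitted(f) - unclass(noisy$E), "F")
  }, numeric(1))
  expect_lte(err_at[2], err_at[1])
})

test_that("new-sample projection reproduces training weights", {
  sim <- simulate_mixture(synthetic_scenario(n = 300, m = 50, k_true = 3,
                                             seed = 37))
  fit <- consica(sim$E, k = 3, nt = 5, seed = 1)
  W <- predict(fit, sim$E)
  expect_equal(W, fit$M, tolerance = 1e-8)
  expect_error(predict(fit, unclass(sim$E)[1:10, ]), "lacks")
})
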