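test_that("carrying capacity decomposes additively", {
  none <- carrying_capacity(7, numeric(0), numeric(0), logical(0))
  expect_equal(none$k, 7)

  k <- carrying_capacity(10, c(0.5, 0.2), c(5, 3), c(TRUE, FALSE))
  expect_equal(k$k, 13.1)
  expect_equal(k$limiting_ts, 2.5)
  expect_equal(k$limiting_nts, 0.6)
  expect_equal(k$n_own + k$limiting_ts + k$limiting_nts, k$k)
  expect_equal(sum(k$pct), 100)

  # doubling competitor densities doubles the limiting component
  k2 <- carrying_capacity(10, c(0.5, 0.2), 2 * c(5, 3), c(TRUE, FALSE))
  expect_equal(k2$k - 10, 2 * (k$k - 10))

  expect_error(carrying_capacity(-1, 0.5, 5), "non-negative")
})

test_that("two-species outcomes follow the classical inequalities", {
  expect_equal(pairwise_outcome(10, 8, 0.5, 0.5)$classification,
               "stable_coexistence")
  expect_equal(pairwise_outcome(10, 8, 2, 2)$classification,
               "unstable_priority_effect")
  expect_equal(pairwise_outcome(10, 8, 1e-9, 1e-9)$classification,
               "stable_coexistence")
  # one-sided dominance
  expect_equal(pairwise_outcome(20, 8, 0.5, 2)$classification,
               "exclusion_of_j")
  expect_equal(pairwise_outcome(8, 20, 2, 0.5)$classification,
               "exclusion_of_i")
  expect_true(pairwise_outcome(10, 5, 2, 1)$boundary)
  expect_error(pairwise_outcome(10, 8, 0, 1))
})

test_that("community matrix assembly places coefficients by row", {
  expect_equal(community_matrix(data.frame(i = character(0),
                                           j = character(0),
                                           value = numeric(0)), "only"),
               matrix(1, 1, 1, dimnames = list("only", "only")))
  coefs <- expand.grid(i = letters[1:3], j = letters[1:3],
                       stringsAsFactors = FALSE)
  coefs <- coefs[coefs$i != coefs$j, ]
  coefs$value <- seq(0.1, 0.6, by = 0.1)
  m <- community_matrix(coefs, letters[1:3])
  expect_equal(diag(m), c(a = 1, b = 1, c = 1))
  for (r in seq_len(nrow(coefs))) {
    expect_equal(m[coefs$i[r], coefs$j[r]], coefs$value[r])
  }
  sym <- coefs; sym$value <- 0.3
  expect_equal(community_matrix(sym, letters[1:3]),
               t(community_matrix(sym, letters[1:3])))
  expect_error(community_matrix(coefs[-1, ], letters[1:3]), "missing")
})

test_that("Jacobian equals the derivative of the LV right-hand side", {
  expect_equal(jacobian(matrix(1, 1, 1), 5, 5, 1), matrix(-1, 1, 1))
  m0 <- diag(3)
  expect_equal(jacobian(m0, c(2, 2, 2), c(4, 4, 4)), -0.5 * diag(3))

  set.seed(1)
  m <- random_community_matrix(3)
  N <- runif(3, 2, 10); K <- runif(3, 10, 20); r <- c(1, 0.8, 1.3)
  J <- jacobian(m, N, K, r)
  # finite-difference oracle at the equilibrium condition K = m N* is not
  # required: the analytic Jacobian of f_i = r_i N_i (K_i - (mN)_i)/K_i at
  # a point where K = m N is exactly -(r N / K) m; verify numerically there
  Nstar <- drop(solve(m, K))
  Jstar <- jacobian(m, Nstar, K, r)
  f <- function(N) r * N * (K - drop(m %*% N)) / K
  h <- 1e-6
  fd <- sapply(seq_len(3), function(j) {
    e <- rep(0, 3); e[j] <- h
    (f(Nstar + e) - f(Nstar - e)) / (2 * h)
  })
  expect_equal(Jstar, unname(fd), tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("leading eigenvalue is the maximum real part", {
  expect_equal(leading_eigenvalue(diag(c(-1, -2))), -1)
  expect_equal(leading_eigenvalue(rbind(c(0, 1), c(-1, 0))), 0)
  set.seed(2)
  A <- matrix(rnorm(25), 5)
  # oracle: characteristic-polynomial coefficients via the
  # Faddeev-LeVerrier recurrence (no eigendecomposition), then polyroot
  n <- 5L
  M <- diag(n); cs <- numeric(n)
  for (k in seq_len(n)) {
    M <- A %*% M
    cs[k] <- -sum(diag(M)) / k
    M <- M + cs[k] * diag(n)
  }
  roots <- polyroot(c(rev(cs), 1))
  expect_equal(leading_eigenvalue(A), max(Re(roots)), tolerance = 1e-8)
})

test_that("net-effect analysis inverts the Jacobian", {
  ne <- net_effect_analysis(-diag(2))
  expect_equal(ne$j_inv, -diag(2))
  expect_equal(ne$lambda_inv, -1)

  expect_equal(net_effect_analysis(diag(c(-0.5, -2)))$lambda_inv, -0.5)

  set.seed(3)
  J <- -diag(3) + matrix(rnorm(9, 0, 0.2), 3)
  ne3 <- net_effect_analysis(J)
  expect_equal(J %*% ne3$j_inv, diag(3), tolerance = 1e-9)

  sing <- matrix(1, 2, 2)
  expect_error(net_effect_analysis(sing), "singular|ill-conditioned")
})

test_that("uniform perturbation scales eigenvalues exactly", {
  set.seed(4)
  for (f in c(0.2, 0.5)) {
    A <- matrix(rnorm(9), 3)
    p <- perturbed_matrices(A, f)
    ev <- eigen(A, only.values = TRUE)$values
    scale_cmp <- function(got, want) {
      expect_equal(sort(Re(got)), sort(Re(want)), tolerance = 1e-10)
    }
    scale_cmp(eigen(p$down, only.values = TRUE)$values, (1 - f) * ev)
    scale_cmp(eigen(p$up, only.values = TRUE)$values, (1 + f) * ev)
    # sign of the leading eigenvalue is preserved under both scalings
    expect_equal(sign(p$lambda_down), sign(leading_eigenvalue(A)))
    expect_equal(sign(p$lambda_up), sign(leading_eigenvalue(A)))
  }
  expect_error(perturbed_matrices(diag(2), 0))
})

test_that("randomized null permutes off-diagonal elements", {
  # all off-diagonal elements equal: every rearrangement has the same
  # spectrum
  m <- diag(3) * -1; m[row(m) != col(m)] <- 0.4
  rn <- randomized_null(m, 10L, seed = 5)
  expect_true(all(abs(rn$lambdas - leading_eigenvalue(m)) < 1e-12))

  set.seed(6)
  A <- -diag(3); A[row(A) != col(A)] <- runif(6, -0.5, 0.5)
  r1 <- randomized_null(A, 10L, seed = 7)
  r2 <- randomized_null(A, 10L, seed = 7)
  expect_identical(r1$lambdas, r2$lambdas)

  ex <- randomized_null(A, exhaustive = TRUE)
  expect_equal(ex$n, factorial(6))
  # stochastic draws are a subset of the exhaustive set
  expect_true(all(vapply(r1$lambdas, function(l) {
    any(abs(ex$lambdas - l) < 1e-9)
  }, logical(1))))
  expect_error(randomized_null(matrix(-1, 1, 1)), "off-diagonal")
})

test_that("LV dynamics reach the analytically expected states", {
  # logistic: single species converges to K
  one <- simulate_lv(2, 10, matrix(1, 1, 1), horizon = 200)
  expect_true(one$converged)
  expect_equal(one$final, 10, tolerance = 1e-6)

  # coexistence pair: equilibrium matches the linear solve
  m <- rbind(c(1, 0.5), c(0.5, 1))
  ks <- c(10, 8)
  sim <- simulate_lv(c(1, 1), ks, m, horizon = 500)
  expect_true(sim$converged)
  expect_equal(sim$final, drop(solve(m, ks)), tolerance = 1e-6)

  # mutual-exclusion pair: the winner depends on the starting point
  m2 <- rbind(c(1, 2), c(2, 1))
  ks2 <- c(10, 8)
  from_i <- simulate_lv(c(9, 0.5), ks2, m2, horizon = 2000)
  from_j <- simulate_lv(c(0.5, 7), ks2, m2, horizon = 2000)
  expect_false(from_i$converged)
  expect_false(from_j$converged)
  expect_equal(from_i$excluded, 2L)
  expect_equal(from_j$excluded, 1L)
})

test_that("spectral reciprocity holds for analyzed communities", {
  set.seed(8)
  for (i in 1:20) {
    m <- random_community_matrix(3)
    N <- runif(3, 2, 12)
    K <- drop(m %*% N)  # Eq.-style K makes N the interior equilibrium
    J <- jacobian(m, N, K)
    ne <- net_effect_analysis(J)
    ev <- eigen(J, only.values = TRUE)$values
    ev_inv <- eigen(ne$j_inv, only.values = TRUE)$values
    expect_equal(sort(Re(1 / ev)), sort(Re(ev_inv)), tolerance = 1e-9)
  }
})

test_that("stability report bundles a consistent analysis", {
  set.seed(9)
  m <- random_community_matrix(3, max_alpha = 0.6)
  dimnames(m) <- list(letters[1:3], letters[1:3])
  N <- c(a = 10, b = 7, c = 4)
  K <- drop(m %*% N)
  rep_ <- stability_report(m, N, K, run_config(seed = 2L))
  expect_equal(rep_$lambda_inv, net_effect_analysis(rep_$j)$lambda_inv)
  expect_equal(rep_$lambda_down, 0.8 * rep_$lambda_inv, tolerance = 1e-10)
  expect_equal(rep_$lambda_up, 1.2 * rep_$lambda_inv, tolerance = 1e-10)
  expect_length(rep_$lambda_random, 10L)
  # consistency triangle: lambda sign, feasibility, and LV convergence
  sim <- simulate_lv(N * 1.05, K, m, horizon = 5000)
  feasible <- all(drop(solve(m, K)) > 0)
  expect_equal(rep_$lambda < 0, sim$converged)
  expect_true(feasible)
})
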