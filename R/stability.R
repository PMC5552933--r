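# Lotka-Volterra carrying capacities, pairwise coexistence classification,
# community and Jacobian matrices, inverse-Jacobian net effects, perturbed
# and randomized stability nulls, and numerical LV dynamics.

#' Carrying capacity with additive decomposition
#'
#' `K_i = N_i + sum_j alpha_ij N_j`: the species' own observed density plus
#' the limiting effect (`alpha_ij * N_j`) of every competitor, split into
#' target-species and nontarget-species components.
#'
#' @param density_i Observed density of the focal species (>= 0).
#' @param alpha Competitor coefficients `alpha_ij` (>= 0), aligned with
#'   `densities`.
#' @param densities Competitor densities `N_j` (>= 0).
#' @param is_target Logical flags: is each competitor a target species?
#'   Defaults to all `TRUE`.
#' @return List with `n_own`, `limiting_ts`, `limiting_nts`, `k`, and
#'   `pct` (percentage breakdown summing to 100).
#' @export
carrying_capacity <- function(density_i, alpha, densities,
                              is_target = rep(TRUE, length(alpha))) {
  stopifnot(length(alpha) == length(densities),
            length(is_target) == length(alpha))
  if (density_i < 0 || any(alpha < 0) || any(densities < 0)) {
    stop("densities and coefficients must be non-negative", call. = FALSE)
  }
  lim <- alpha * densities
  limiting_ts <- sum(lim[is_target])
  limiting_nts <- sum(lim[!is_target])
  k <- density_i + limiting_ts + limiting_nts
  pct <- if (k > 0) {
    100 * c(own = density_i, ts = limiting_ts, nts = limiting_nts) / k
  } else c(own = NA_real_, ts = NA_real_, nts = NA_real_)
  list(n_own = density_i, limiting_ts = limiting_ts,
       limiting_nts = limiting_nts, k = k, pct = pct)
}

#' Two-species competition outcome
#'
#' Classifies the pair by the classical inequalities: stable coexistence
#' when `K_i / alpha_ij > K_j` and `K_j / alpha_ji > K_i`; exclusion of one
#' species when exactly one inequality holds; an unstable priority effect
#' when neither does. Equalities are flagged as boundary cases.
#'
#' @param k_i,k_j Carrying capacities.
#' @param alpha_ij,alpha_ji Competition coefficients (> 0).
#' @return List with `classification`, `boundary` flag, and the four
#'   compared quantities.
#' @export
pairwise_outcome <- function(k_i, k_j, alpha_ij, alpha_ji) {
  stopifnot(alpha_ij > 0, alpha_ji > 0)
  qi <- k_i / alpha_ij  # i's zero-growth intercept on j's axis
  qj <- k_j / alpha_ji
  boundary <- (qi == k_j) || (qj == k_i)
  cls <- if (qi > k_j && qj > k_i) "stable_coexistence"
         else if (qi > k_j && qj < k_i) "exclusion_of_j"
         else if (qi < k_j && qj > k_i) "exclusion_of_i"
         else "unstable_priority_effect"
  list(classification = cls, boundary = boundary,
       k_i = k_i, k_j = k_j, k_i_over_alpha = qi, k_j_over_alpha = qj)
}

#' Assemble the community matrix
#'
#' Square matrix of pairwise competition coefficients with unit diagonal
#' (intraspecific competition normalized to 1). Row i holds the effects ON
#' species i; entry (i, j) is the coefficient of species j's effect on i.
#'
#' @param coefficients Data frame with columns `i`, `j`, `value` covering
#'   every ordered off-diagonal pair.
#' @param species Character vector fixing the row/column order.
#' @return Named square matrix.
#' @export
community_matrix <- function(coefficients, species) {
  n <- length(species)
  m <- diag(1, n)
  dimnames(m) <- list(species, species)
  for (r in seq_len(nrow(coefficients))) {
    m[coefficients$i[r], coefficients$j[r]] <- coefficients$value[r]
  }
  if (n > 1L) {
    off <- row(m) != col(m)
    pairs <- paste(coefficients$i, coefficients$j)
    need <- expand.grid(i = species, j = species,
                        stringsAsFactors = FALSE)
    need <- need[need$i != need$j, ]
    missing <- setdiff(paste(need$i, need$j), pairs)
    if (length(missing) > 0L) {
      stop("missing coefficient for pair(s): ",
           paste(missing, collapse = "; "), call. = FALSE)
    }
    if (any(m[off] < 0)) stop("negative coefficient", call. = FALSE)
  }
  m
}

#' Jacobian of the Lotka-Volterra competition system
#'
#' For `dN_i/dt = r_i N_i (K_i - sum_j m_ij N_j) / K_i` (with `m_ii = 1`),
#' the Jacobian evaluated at densities equal to the interior equilibrium is
#' `J_ij = -(r_i N_i / K_i) m_ij`. Densities and carrying capacities are
#' supplied, so the matrix can be evaluated at observed densities or at the
#' solved equilibrium.
#'
#' @param m Community matrix (unit diagonal).
#' @param densities Evaluation densities `N_i` (>= 0).
#' @param ks Carrying capacities `K_i` (> 0).
#' @param r_growth Per-capita growth rate(s), recycled; default 1.
#' @return The Jacobian matrix.
#' @export
jacobian <- function(m, densities, ks, r_growth = 1) {
  n <- nrow(m)
  stopifnot(length(densities) == n, length(ks) == n, all(ks > 0),
            all(densities >= 0))
  r <- rep_len(r_growth, n)
  -(r * densities / ks) * m
}

#' Leading eigenvalue (maximum real part)
#'
#' @param m Square matrix.
#' @return Real part of the eigenvalue with the largest real part; negative
#'   for locally (Lyapunov) stable Jacobians.
#' @export
leading_eigenvalue <- function(m) {
  max(Re(eigen(m, only.values = TRUE)$values))
}

#' Net-effect (inverse Jacobian) analysis
#'
#' Each element of the inverse Jacobian describes the net effect of species
#' j on species i including all indirect pathways through intermediate
#' competitors.
#'
#' @param j Jacobian matrix (invertible).
#' @param max_condition Condition-number threshold above which inversion is
#'   refused.
#' @return List with `j_inv`, `lambda_inv` (leading eigenvalue of the
#'   inverse), and `condition`.
#' @export
net_effect_analysis <- function(j, max_condition = 1e12) {
  kap <- kappa(j, exact = TRUE)
  if (!is.finite(kap) || kap > max_condition) {
    stop("Jacobian is singular or ill-conditioned (condition number ",
         format(kap, digits = 3), ")", call. = FALSE)
  }
  j_inv <- solve(j)
  list(j_inv = j_inv, lambda_inv = leading_eigenvalue(j_inv),
       condition = kap)
}

#' Element-wise perturbed matrices
#'
#' Scales every element of the matrix by `(1 - fraction)` and
#' `(1 + fraction)` to simulate systematic under- and overestimation of
#' interaction strengths. Because this is a uniform scalar multiple, every
#' eigenvalue scales by the same factor and sign conclusions are preserved.
#'
#' @param j_inv Matrix to perturb (typically the inverse Jacobian).
#' @param fraction Perturbation fraction in (0, 1); default 0.2.
#' @return List with `down`, `up`, `lambda_down`, `lambda_up`.
#' @export
perturbed_matrices <- function(j_inv, fraction = 0.2) {
  stopifnot(fraction > 0, fraction < 1)
  down <- (1 - fraction) * j_inv
  up <- (1 + fraction) * j_inv
  list(down = down, up = up,
       lambda_down = leading_eigenvalue(down),
       lambda_up = leading_eigenvalue(up))
}

# All permutations of seq_len(n) (n small), rows = permutations.
.permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .permutations(n - 1L)
  out <- matrix(0L, 0L, n)
  for (pos in seq_len(n)) {
    block <- cbind(sub[, seq_len(pos - 1L), drop = FALSE], n,
                   sub[, seq.int(pos, n - 1L)[seq_len(n - pos)],
                       drop = FALSE])
    out <- rbind(out, block)
  }
  out
}

.apply_offdiag_perm <- function(m, perm) {
  off <- which(row(m) != col(m))
  m2 <- m
  m2[off] <- m[off][perm]
  m2
}

#' Randomization null for the net-effect matrix
#'
#' Rearranges the off-diagonal elements of the matrix uniformly at random
#' (diagonal fixed, elements permuted without replacement) and records the
#' leading eigenvalue of each rearranged matrix. For a 3 x 3 matrix an
#' exhaustive mode enumerates all 720 off-diagonal permutations.
#'
#' @param j_inv Matrix whose off-diagonal elements are rearranged.
#' @param n_matrices Number of random rearrangements (default 10).
#' @param seed Integer seed.
#' @param exhaustive If `TRUE`, enumerate every permutation instead of
#'   sampling.
#' @return List with `lambdas`, `mean`, `se`, and the permuted matrices'
#'   count `n`.
#' @export
randomized_null <- function(j_inv, n_matrices = 10L, seed = 1L,
                            exhaustive = FALSE) {
  off <- which(row(j_inv) != col(j_inv))
  if (length(off) < 2L) stop("need at least two off-diagonal elements",
                             call. = FALSE)
  if (!exhaustive && n_matrices < 1L) stop("n_matrices must be >= 1",
                                           call. = FALSE)
  if (exhaustive) {
    perms <- .permutations(length(off))
  } else {
    set.seed(as.integer(seed))
    perms <- t(vapply(seq_len(n_matrices),
                      function(i) sample.int(length(off)),
                      integer(length(off))))
  }
  lambdas <- apply(perms, 1L, function(p) {
    leading_eigenvalue(.apply_offdiag_perm(j_inv, p))
  })
  list(lambdas = lambdas, mean = mean(lambdas),
       se = if (length(lambdas) > 1L) {
         stats::sd(lambdas) / sqrt(length(lambdas))
       } else NA_real_,
       n = length(lambdas))
}

#' Simulate Lotka-Volterra competition dynamics
#'
#' Integrates `dN_i/dt = r_i N_i (K_i - sum_j m_ij N_j) / K_i` with an
#' adaptive solver (deSolve, lsoda). Convergence is declared when no
#' species is excluded and either every `|dN_i/dt|` falls below `tol` or
#' the deviation from the interior equilibrium `M^-1 K` has contracted to
#' less than a tenth of its initial value (this second route makes the flag
#' robust when the leading eigenvalue is negative but very close to zero,
#' so relaxation is slow on the integration horizon). A species dropping
#' below `extinction_frac` times its initial density is recorded as
#' excluded.
#'
#' @param n0 Initial densities (>= 0).
#' @param ks Carrying capacities (> 0).
#' @param m Community matrix (unit diagonal).
#' @param r_growth Per-capita growth rate(s), recycled.
#' @param horizon Integration horizon in time units (default 1000).
#' @param tol Derivative tolerance for convergence (default 1e-8).
#' @param extinction_frac Extinction threshold as a fraction of initial
#'   density (default 1e-6).
#' @return List with `trajectory` (times x species), `final`, `converged`,
#'   `excluded` (species indices), `equilibrium` (the linear-solve
#'   interior equilibrium `M^-1 K`).
#' @export
simulate_lv <- function(n0, ks, m, r_growth = 1, horizon = 1000,
                        tol = 1e-8, extinction_frac = 1e-6) {
  n <- length(n0)
  stopifnot(nrow(m) == n, length(ks) == n, all(ks > 0), all(n0 >= 0))
  r <- rep_len(r_growth, n)
  deriv <- function(t, N, parms) {
    list(r * N * (ks - drop(m %*% N)) / ks)
  }
  times <- seq(0, horizon, length.out = 201L)
  sol <- deSolve::lsoda(y = n0, times = times, func = deriv,
                        parms = NULL, rtol = 1e-10, atol = 1e-12)
  if (any(!is.finite(sol))) {
    bad_t <- sol[which(!is.finite(sol), arr.ind = TRUE)[1L, 1L], 1L]
    stop("integration produced non-finite state near t = ", bad_t,
         call. = FALSE)
  }
  final <- as.numeric(sol[nrow(sol), -1L])
  dfinal <- deriv(horizon, final, NULL)[[1L]]
  thresh <- extinction_frac * pmax(n0, .Machine$double.eps)
  excluded <- which(final < thresh)
  equilibrium <- tryCatch(drop(solve(m, ks)), error = function(e) rep(NA_real_, n))
  contracted <- FALSE
  if (all(is.finite(equilibrium)) && all(equilibrium > 0)) {
    dev0 <- sqrt(sum((n0 - equilibrium)^2))
    dev1 <- sqrt(sum((final - equilibrium)^2))
    contracted <- dev0 > 0 && dev1 < 0.1 * dev0
  }
  converged <- length(excluded) == 0L &&
    (all(abs(dfinal) < tol) || contracted)
  list(trajectory = sol, final = final, converged = converged,
       excluded = excluded, equilibrium = equilibrium)
}

#' Full stability report for one community matrix
#'
#' Bundles the Jacobian, its leading eigenvalue, the inverse-Jacobian net
#' effects, the +/- perturbed matrices, and the randomization null.
#'
#' @param m Community matrix (unit diagonal).
#' @param densities Evaluation densities.
#' @param ks Carrying capacities.
#' @param config A [run_config()] (supplies `r_growth`,
#'   `perturbation_fraction`, `n_random_matrices`, `seed`).
#' @return List of class `"stability_result"`.
#' @export
stability_report <- function(m, densities, ks, config = run_config()) {
  j <- jacobian(m, densities, ks, config$r_growth)
  lambda <- leading_eigenvalue(j)
  net <- net_effect_analysis(j)
  pert <- perturbed_matrices(net$j_inv, config$perturbation_fraction)
  rnd <- randomized_null(net$j_inv, config$n_random_matrices,
                         seed = config$seed)
  structure(list(species = rownames(m), m = m, j = j, j_inv = net$j_inv,
                 lambda = lambda, lambda_inv = net$lambda_inv,
                 lambda_down = pert$lambda_down,
                 lambda_up = pert$lambda_up,
                 lambda_random = rnd$lambdas,
                 lambda_random_mean = rnd$mean,
                 lambda_random_se = rnd$se,
                 densities = densities, ks = ks,
                 r_growth = config$r_growth),
            class = "stability_result")
}
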