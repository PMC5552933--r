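# Bayesian stable-isotope mixing model and diet-derived statistics.
#
# Population-level model: one diet proportion vector p per species-location
# fitted to all of its specimens. Per isotope axis the likelihood is
#   x_s ~ Normal( sum_k p_k (mu_k + tef),  sum_k p_k^2 sigma_k^2 + sigma_r^2 )
# i.e. source uncertainty enters through the p-weighted variance term, with
# an additional per-axis residual SD sigma_r. Priors: Dirichlet(1,...,1) on
# p, half-Cauchy(0, 2.5) on each residual SD. Sampling is random-walk
# Metropolis on additive-log-ratio coordinates of p (with the Jacobian
# correction) plus log residual SDs; the proposal scale is tuned during
# burn-in toward 20-40 percent acceptance.

.softmax_alr <- function(z) {
  e <- exp(c(z, 0) - max(c(z, 0), 0))
  e / sum(e)
}

# Log posterior kernel given sufficient statistics per axis.
.mix_logpost <- function(theta, K, stats_c, stats_n, mu_c, mu_n,
                         s2_c, s2_n) {
  if (K > 1L) {
    p <- .softmax_alr(theta[seq_len(K - 1L)])
  } else {
    p <- 1
  }
  if (any(p <= 0)) return(-Inf)
  lsc <- theta[K]; lsn <- theta[K + 1L]
  if (abs(lsc) > 20 || abs(lsn) > 20) return(-Inf)
  sc2 <- exp(2 * lsc); sn2 <- exp(2 * lsn)
  ax_ll <- function(st, mu, s2, sr2) {
    m <- sum(p * mu)
    v <- sum(p^2 * s2) + sr2
    -st$n / 2 * log(2 * pi * v) -
      (st$sxx - 2 * m * st$sx + st$n * m^2) / (2 * v)
  }
  ll <- ax_ll(stats_c, mu_c, s2_c, sc2) + ax_ll(stats_n, mu_n, s2_n, sn2)
  # Dirichlet(1) prior on p + ALR Jacobian; half-Cauchy(2.5) on sigma with
  # log-scale Jacobian.
  lp <- sum(log(p)) +
    stats::dcauchy(exp(lsc), 0, 2.5, log = TRUE) + log(2) + lsc +
    stats::dcauchy(exp(lsn), 0, 2.5, log = TRUE) + log(2) + lsn
  ll + lp
}

# Split-chain potential scale reduction factor on a draws matrix
# (iterations x chains).
.split_rhat <- function(draws) {
  n <- nrow(draws)
  if (n < 4L) return(NA_real_)
  half <- floor(n / 2)
  segs <- cbind(draws[seq_len(half), , drop = FALSE],
                draws[(n - half + 1L):n, , drop = FALSE])
  m <- ncol(segs)
  means <- colMeans(segs)
  vars <- apply(segs, 2L, stats::var)
  W <- mean(vars)
  B <- half * stats::var(means)
  if (W <= 0) return(1)
  sqrt(((half - 1) / half * W + B / half) / W)
}

#' Fit the Bayesian mixing model for one population
#'
#' @param consumers n x 2 matrix or data frame (`d13c`, `d15n`) of consumer
#'   specimens.
#' @param sources Data frame with `resource`, `d13c_mean`, `d13c_sd`,
#'   `d15n_mean`, `d15n_sd` (one row per source).
#' @param tef Length-2 trophic enrichment (d13C, d15N), permil; default
#'   `c(0.4, 2.3)`.
#' @param mcmc List with `iterations`, `burnin`, `thin`, `chains`.
#' @param seed Integer seed; chains use `seed + chain`.
#' @return List of class `"diet_posterior"`: `resources`, `draws`
#'   (draws x K proportion matrix), `sigma_draws`, `summary` (posterior
#'   mean and 95 percent credible interval per resource), `rhat`,
#'   `converged`, `acceptance`.
#' @export
fit_mixing_model <- function(consumers, sources, tef = c(0.4, 2.3),
                             mcmc = list(iterations = 30000L,
                                         burnin = 10000L, thin = 10L,
                                         chains = 4L),
                             seed = 1L) {
  x <- .as_points(consumers)
  K <- nrow(sources)
  if (K < 1L) stop("need at least one source", call. = FALSE)
  if (nrow(x) < 3L) warning("fewer than 3 consumer specimens: ",
                            "posterior will be diffuse")
  sig <- round(cbind(sources$d13c_mean, sources$d15n_mean), 6)
  if (anyDuplicated(sig)) {
    warning("sources with identical signatures on both axes: ",
            "proportions are unidentifiable between them")
  }
  stats_c <- list(n = nrow(x), sx = sum(x[, 1L]), sxx = sum(x[, 1L]^2))
  stats_n <- list(n = nrow(x), sx = sum(x[, 2L]), sxx = sum(x[, 2L]^2))
  mu_c <- sources$d13c_mean + tef[1L]
  mu_n <- sources$d15n_mean + tef[2L]
  s2_c <- sources$d13c_sd^2
  s2_n <- sources$d15n_sd^2

  iters <- as.integer(mcmc$iterations)
  burnin <- as.integer(mcmc$burnin)
  thin <- as.integer(mcmc$thin)
  chains <- as.integer(mcmc$chains)
  stopifnot(iters > burnin, thin >= 1L, chains >= 1L)
  kept_per_chain <- (iters - burnin) %/% thin
  npar <- (K - 1L) + 2L

  p_draws <- vector("list", chains)
  s_draws <- vector("list", chains)
  acc_rates <- numeric(chains)
  for (ch in seq_len(chains)) {
    set.seed(as.integer(seed) + ch)
    theta <- c(stats::rnorm(max(K - 1L, 0L), 0, 1),
               log(0.5) + stats::rnorm(2L, 0, 0.3))
    lp <- .mix_logpost(theta, K, stats_c, stats_n, mu_c, mu_n, s2_c, s2_n)
    scale <- 0.5
    keep_p <- matrix(NA_real_, kept_per_chain, K)
    keep_s <- matrix(NA_real_, kept_per_chain, 2L)
    kept <- 0L
    acc <- 0L; acc_win <- 0L
    for (it in seq_len(iters)) {
      prop <- theta + stats::rnorm(npar, 0, scale)
      lp_prop <- .mix_logpost(prop, K, stats_c, stats_n, mu_c, mu_n,
                              s2_c, s2_n)
      if (is.finite(lp_prop) && log(stats::runif(1)) < lp_prop - lp) {
        theta <- prop; lp <- lp_prop
        acc <- acc + 1L; acc_win <- acc_win + 1L
      }
      # Robbins-Monro style tuning toward ~30 percent acceptance
      if (it <= burnin && it %% 50L == 0L) {
        rate <- acc_win / 50
        scale <- scale * exp(rate - 0.3)
        scale <- min(max(scale, 1e-3), 10)
        acc_win <- 0L
      }
      if (it > burnin && (it - burnin) %% thin == 0L) {
        kept <- kept + 1L
        keep_p[kept, ] <- if (K > 1L) {
          .softmax_alr(theta[seq_len(K - 1L)])
        } else 1
        keep_s[kept, ] <- exp(theta[c(K, K + 1L)])
      }
    }
    p_draws[[ch]] <- keep_p
    s_draws[[ch]] <- keep_s
    acc_rates[ch] <- acc / iters
  }

  rhat <- vapply(seq_len(K), function(k) {
    .split_rhat(do.call(cbind, lapply(p_draws, function(m) m[, k])))
  }, numeric(1))
  converged <- all(is.na(rhat) | rhat < 1.1)
  if (!converged) {
    warning("mixing model did not converge (split R-hat > 1.1)")
  }
  draws <- do.call(rbind, p_draws)
  colnames(draws) <- sources$resource
  summ <- data.frame(
    resource = sources$resource,
    mean = colMeans(draws),
    lower = apply(draws, 2L, stats::quantile, probs = 0.025),
    upper = apply(draws, 2L, stats::quantile, probs = 0.975),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(resources = sources$resource, draws = draws,
                 sigma_draws = do.call(rbind, s_draws), summary = summ,
                 rhat = rhat, converged = converged,
                 acceptance = acc_rates),
            class = "diet_posterior")
}

#' Density-weighted meadow-scale diet
#'
#' Aggregates per-location diet proportion vectors into a meadow-scale diet,
#' weighting each location by the species' population density there:
#' `P_meadow = sum_loc P_loc * N_loc / sum_loc N_loc`, per resource.
#'
#' @param proportions Matrix (locations x resources) or list of equal-length
#'   proportion vectors with matching resource order.
#' @param densities Non-negative per-location densities, not all zero.
#' @return Meadow-scale proportion vector.
#' @export
meadow_diet <- function(proportions, densities) {
  if (is.list(proportions) && !is.data.frame(proportions)) {
    lens <- lengths(proportions)
    if (length(unique(lens)) != 1L) {
      stop("mismatched resource sets across locations", call. = FALSE)
    }
    nms <- lapply(proportions, names)
    if (any(!vapply(nms, function(x) is.null(x) || identical(x, nms[[1L]]),
                    logical(1)))) {
      stop("mismatched resource ordering across locations", call. = FALSE)
    }
    proportions <- do.call(rbind, proportions)
  }
  proportions <- as.matrix(proportions)
  stopifnot(nrow(proportions) == length(densities), all(densities >= 0))
  if (sum(densities) <= 0) stop("all densities are zero", call. = FALSE)
  drop(crossprod(proportions, densities) / sum(densities))
}

#' Shannon diversity of a diet (Hs)
#'
#' Trophic niche width as `-sum p log p` (nats), with `0 log 0 = 0`.
#'
#' @param p Probability vector of resource contributions.
#' @return Hs in `[0, log(length(p))]`.
#' @export
diet_diversity <- function(p) {
  stopifnot(all(p >= 0), abs(sum(p) - 1) < 1e-6)
  q <- p[p > 0]
  -sum(q * log(q))
}

#' Bray-Curtis similarity of two diets
#'
#' For probability vectors this is `sum_k min(p_ik, p_jk)`, equivalently
#' `1 - 0.5 * sum_k |p_ik - p_jk|`.
#'
#' @param p_i,p_j Probability vectors over the same resource ordering.
#' @return Similarity in `[0, 1]`.
#' @export
diet_similarity <- function(p_i, p_j) {
  if (length(p_i) != length(p_j)) {
    stop("mismatched resource sets", call. = FALSE)
  }
  sum(pmin(p_i, p_j))
}

#' Coefficient of variation of one resource's use across species
#'
#' Sample SD divided by mean of the focal resource's dietary proportion
#' across species; quantifies between-species variability in the use of a
#' resource.
#'
#' @param proportions Matrix (species x resources), columns named by
#'   resource, or plain numeric vector of the focal proportions.
#' @param resource Column name or index when `proportions` is a matrix.
#' @return The C.V. (dimensionless); `NaN` with a warning if the mean is 0.
#' @export
resource_cv <- function(proportions, resource = NULL) {
  if (is.matrix(proportions) || is.data.frame(proportions)) {
    stopifnot(!is.null(resource))
    vals <- as.numeric(as.matrix(proportions)[, resource])
  } else {
    vals <- as.numeric(proportions)
  }
  if (length(vals) < 2L) stop("need at least two species", call. = FALSE)
  m <- mean(vals)
  if (m == 0) {
    warning("mean proportion is zero: C.V. undefined")
    return(NaN)
  }
  stats::sd(vals) / m
}
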