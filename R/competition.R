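# Competition coefficients: Levins' diet-overlap beta_ij and the
# isotope-distance alpha_ij (ratio of intra- to interspecific specimen
# distances), with uncertainty, asymmetry testing, target-vs-nontarget
# aggregation, and the alpha-vs-beta agreement regression.

#' Levins diet-overlap competition coefficient (beta)
#'
#' Effect of species j on species i from proportional resource use:
#' `beta_ij = sum_h p_ih p_jh / sum_h p_ih^2`. Equal to 1 whenever the two
#' diets are identical; generally asymmetric.
#'
#' @param p_i,p_j Diet proportion vectors over the same resource ordering.
#' @return Scalar `beta_ij >= 0`.
#' @export
beta_coefficient <- function(p_i, p_j) {
  if (length(p_i) != length(p_j)) {
    stop("mismatched resource sets", call. = FALSE)
  }
  den <- sum(p_i^2)
  if (den <= 0) stop("focal diet has zero norm", call. = FALSE)
  sum(p_i * p_j) / den
}

#' Posterior beta from two diet posteriors
#'
#' Evaluates `beta_ij` per matched posterior draw pair and summarizes, so
#' mixing-model uncertainty propagates into the coefficient.
#'
#' @param posterior_i,posterior_j `diet_posterior` objects over the same
#'   resources.
#' @return List with `mean`, `lower`, `upper` (95 percent interval), and
#'   the per-draw values.
#' @export
beta_from_posterior <- function(posterior_i, posterior_j) {
  di <- posterior_i$draws; dj <- posterior_j$draws
  if (!identical(colnames(di), colnames(dj))) {
    stop("mismatched resource sets", call. = FALSE)
  }
  n <- min(nrow(di), nrow(dj))
  vals <- rowSums(di[seq_len(n), , drop = FALSE] *
                  dj[seq_len(n), , drop = FALSE]) /
          rowSums(di[seq_len(n), , drop = FALSE]^2)
  list(mean = mean(vals),
       lower = unname(stats::quantile(vals, 0.025)),
       upper = unname(stats::quantile(vals, 0.975)),
       draws = vals)
}

#' Isotope-distance competition coefficient (alpha)
#'
#' Effect of species j on species i from specimen-level isotopic distances:
#' the mean over i's specimens of `ND_ii / ND_ij`, where ND_ii is the
#' specimen's mean Euclidean distance to conspecifics and ND_ij its mean
#' distance to specimens of j. The SE comes from the specimen-level
#' dispersion of the ratios. The companion average-then-ratio variant
#' `MND_ii / MND_ij` is also reported.
#'
#' @param points_i Focal species' point set (>= 2 specimens).
#' @param points_j Competitor's point set (>= 1 specimen).
#' @return List with `value`, `se`, `n`, `ratios`, `mnd_ratio`; `NULL` with
#'   a warning for a singleton focal population.
#' @export
alpha_coefficient <- function(points_i, points_j) {
  nd_ii <- nd_distances(points_i)
  if (is.null(nd_ii)) return(NULL)
  nd_ij <- nd_distances(points_i, points_j)
  if (any(nd_ij$nd == 0)) {
    bad <- which(nd_ij$nd == 0)[1L]
    stop("specimen ", bad, " of the focal species coincides with all ",
         "competitor specimens (ND_ij = 0)", call. = FALSE)
  }
  ratios <- nd_ii$nd / nd_ij$nd
  list(value = mean(ratios),
       se = stats::sd(ratios) / sqrt(length(ratios)),
       n = length(ratios), ratios = ratios,
       mnd_ratio = nd_ii$mnd / nd_ij$mnd)
}

#' Welch t test of interaction asymmetry
#'
#' Compares the specimen-level ratio samples underlying `alpha_ij` and
#' `alpha_ji`.
#'
#' @param ratios_ij,ratios_ji Per-specimen `ND_ii / ND_ij` ratio samples
#'   (>= 2 each).
#' @return List with `t`, `p`, `df`.
#' @export
asymmetry_test <- function(ratios_ij, ratios_ji) {
  stopifnot(length(ratios_ij) >= 2L, length(ratios_ji) >= 2L)
  tt <- stats::t.test(ratios_ij, ratios_ji, var.equal = FALSE)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter))
}

#' Mean direct competition from nontarget species
#'
#' Computes alpha of each nontarget population on the focal target species
#' and averages over nontarget species (each NTS counts once); pairs whose
#' preconditions fail are skipped with a warning.
#'
#' @param points_ts Focal target species' point set.
#' @param nts_points Named list of nontarget point sets.
#' @return List with `mean`, `se` (across NTS), `n_nts`, `per_nts`.
#' @export
nontarget_alpha <- function(points_ts, nts_points) {
  if (length(nts_points) == 0L) stop("no nontarget species", call. = FALSE)
  vals <- numeric(0)
  for (nm in names(nts_points)) {
    a <- tryCatch(alpha_coefficient(points_ts, nts_points[[nm]]),
                  error = function(e) NULL)
    if (is.null(a)) {
      warning("skipping nontarget species ", sQuote(nm),
              ": alpha undefined")
      next
    }
    vals[nm] <- a$value
  }
  if (length(vals) == 0L) {
    stop("no nontarget pair satisfied the preconditions", call. = FALSE)
  }
  list(mean = mean(vals),
       se = if (length(vals) > 1L) stats::sd(vals) / sqrt(length(vals))
            else NA_real_,
       n_nts = length(vals), per_nts = vals)
}

#' Agreement regression of alpha on beta
#'
#' Ordinary least squares of the isotope-distance coefficients on the
#' diet-overlap coefficients across species pairs (and locations), with 95
#' percent confidence intervals on slope and intercept.
#'
#' @param alpha,beta Paired coefficient vectors (>= 3 pairs).
#' @return List with `slope`, `intercept`, `r2`, `slope_ci`,
#'   `intercept_ci`, `p`, and the fitted `lm` object.
#' @export
compare_alpha_beta <- function(alpha, beta) {
  stopifnot(length(alpha) == length(beta))
  if (length(alpha) < 3L) stop("need at least 3 pairs", call. = FALSE)
  fit <- stats::lm(alpha ~ beta)
  ci <- suppressWarnings(stats::confint(fit, level = 0.95))
  s <- summary(fit)
  r2 <- s$r.squared
  if (!is.finite(r2)) r2 <- 0  # constant response: no variance explained
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r2 = r2,
       slope_ci = unname(ci["beta", ]),
       intercept_ci = unname(ci["(Intercept)", ]),
       p = unname(s$coefficients["beta", "Pr(>|t|)"]),
       fit = fit)
}
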