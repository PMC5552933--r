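# Isotopic niche geometry in the d13C x d15N plane: univariate carbon
# metrics, convex-hull total area (TA), standard ellipse areas (SEA, SEAc),
# hull/ellipse overlaps, resource-centroid standardization, specimen
# distance summaries (ND/MND), spatial evenness, and a bootstrap SEAc
# comparison.

.as_points <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x[, c("d13c", "d15n")])
  x <- as.matrix(x)
  stopifnot(ncol(x) == 2L, all(is.finite(x)))
  unname(x)
}

#' d13C range (CR)
#'
#' Difference between the maximum and minimum d13C value, a proxy for the
#' span of exploited resources.
#'
#' @param values Numeric d13C values (permil).
#' @return CR in permil.
#' @export
carbon_range <- function(values) {
  if (length(values) < 1L) stop("need at least one value", call. = FALSE)
  max(values) - min(values)
}

#' d13C sample variance
#'
#' One-dimensional niche width: sample variance (n - 1 denominator) of
#' d13C.
#'
#' @param values Numeric d13C values (permil), length >= 2.
#' @return Variance in permil squared.
#' @export
carbon_variance <- function(values) {
  if (length(values) < 2L) stop("need at least two values", call. = FALSE)
  stats::var(values)
}

# Shoelace area of a polygon given as an n x 2 matrix of vertices.
.polygon_area <- function(v) {
  n <- nrow(v)
  if (is.null(n) || n < 3L) return(0)
  x <- v[, 1L]; y <- v[, 2L]
  abs(sum(x * c(y[-1L], y[1L]) - c(x[-1L], x[1L]) * y)) / 2
}

# Convex hull vertices in counterclockwise order (grDevices::chull returns
# clockwise).
.hull_vertices <- function(points) {
  idx <- grDevices::chull(points)
  points[rev(idx), , drop = FALSE]
}

#' Convex-hull total area (TA)
#'
#' Area of the convex hull of the specimen cloud in isotope space. Fewer
#' than three points, or a collinear cloud, yields area 0 with a warning.
#'
#' @param points n x 2 matrix or data frame with `d13c`, `d15n`.
#' @return TA in permil squared.
#' @export
convex_hull_area <- function(points) {
  points <- .as_points(points)
  if (nrow(points) < 3L) {
    warning("fewer than 3 points: total area is 0")
    return(0)
  }
  area <- .polygon_area(.hull_vertices(points))
  if (area == 0) warning("collinear points: total area is 0")
  area
}

#' Standard ellipse area (SEA, SEAc)
#'
#' SEA is `pi * sqrt(lambda1 * lambda2)` with lambdas the eigenvalues of the
#' 2 x 2 sample covariance; the standard ellipse is the Mahalanobis unit
#' ellipse, containing about 39.3 percent (1 - exp(-1/2)) of bivariate
#' normal observations. SEAc applies the small-sample correction
#' `(n - 1) / (n - 2)`.
#'
#' @param points n x 2 matrix or data frame with `d13c`, `d15n`; n >= 4.
#' @return List of class `"standard_ellipse"` with `sea`, `seac`,
#'   `centroid`, `cov`, `n`.
#' @export
standard_ellipse <- function(points) {
  points <- .as_points(points)
  n <- nrow(points)
  if (n < 4L) stop("need at least 4 points for a standard ellipse",
                   call. = FALSE)
  S <- stats::cov(points)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= .Machine$double.eps * max(abs(ev), 1)) {
    stop("degenerate covariance: points are (near-)collinear", call. = FALSE)
  }
  sea <- pi * sqrt(prod(ev))
  structure(list(sea = sea, seac = sea * (n - 1) / (n - 2),
                 centroid = colMeans(points), cov = S, n = n),
            class = "standard_ellipse")
}

# Polygonal approximation of the Mahalanobis unit ellipse with m vertices.
.ellipse_polygon <- function(ellipse, m = 256L) {
  eg <- eigen(ellipse$cov, symmetric = TRUE)
  A <- eg$vectors %*% diag(sqrt(pmax(eg$values, 0)))
  theta <- seq(0, 2 * pi, length.out = m + 1L)[-(m + 1L)]
  t(ellipse$centroid + A %*% rbind(cos(theta), sin(theta)))
}

# Sutherland-Hodgman clipping of convex polygon `subject` by convex polygon
# `clip`; both counterclockwise n x 2 matrices. Returns the intersection
# polygon (possibly with 0 rows).
.clip_convex <- function(subject, clip) {
  out <- subject
  nc <- nrow(clip)
  for (i in seq_len(nc)) {
    if (is.null(out) || nrow(out) == 0L) return(matrix(numeric(0), ncol = 2L))
    a <- clip[i, ]; b <- clip[if (i == nc) 1L else i + 1L, ]
    # signed distance > 0 means inside (left of a->b for CCW clip polygon)
    side <- function(p) (b[1L] - a[1L]) * (p[2L] - a[2L]) -
                        (b[2L] - a[2L]) * (p[1L] - a[1L])
    inp <- out
    out <- matrix(numeric(0), ncol = 2L)
    np <- nrow(inp)
    for (j in seq_len(np)) {
      cur <- inp[j, ]; prv <- inp[if (j == 1L) np else j - 1L, ]
      cs <- side(cur); ps <- side(prv)
      if (cs >= 0) {
        if (ps < 0) {
          t <- ps / (ps - cs)
          out <- rbind(out, prv + t * (cur - prv))
        }
        out <- rbind(out, cur)
      } else if (ps >= 0) {
        t <- ps / (ps - cs)
        out <- rbind(out, prv + t * (cur - prv))
      }
    }
  }
  out
}

.overlap_result <- function(kind, overlap, area_i, area_j) {
  structure(list(kind = kind, area_overlap = overlap,
                 area_i = area_i, area_j = area_j,
                 pct_of_i = 100 * overlap / area_i,
                 pct_of_j = 100 * overlap / area_j),
            class = "overlap_result")
}

#' Convex-hull (TA) overlap between two specimen clouds
#'
#' Intersection area of the two convex hulls, also expressed as a
#' percentage of each species' hull area.
#'
#' @param points_i,points_j Point sets (n x 2 or data frames).
#' @return List of class `"overlap_result"` with `area_overlap`,
#'   `pct_of_i`, `pct_of_j`.
#' @export
hull_overlap <- function(points_i, points_j) {
  hi <- .hull_vertices(.as_points(points_i))
  hj <- .hull_vertices(.as_points(points_j))
  ai <- .polygon_area(hi); aj <- .polygon_area(hj)
  if (ai == 0 || aj == 0) stop("degenerate hull", call. = FALSE)
  ov <- .polygon_area(.clip_convex(hi, hj))
  .overlap_result("hull", ov, ai, aj)
}

#' Standard-ellipse overlap
#'
#' Intersection area of two Mahalanobis unit ellipses, computed by convex
#' clipping of polygonal approximations refined (vertex doubling from 256)
#' until the area changes by less than `tol` relatively. Deterministic for
#' fixed inputs.
#'
#' @param ellipse_i,ellipse_j `standard_ellipse` objects.
#' @param tol Relative tolerance of the refinement (default 1e-3).
#' @return List of class `"overlap_result"`; percentages are relative to
#'   the exact ellipse areas (SEA).
#' @export
ellipse_overlap <- function(ellipse_i, ellipse_j, tol = 1e-3) {
  stopifnot(inherits(ellipse_i, "standard_ellipse"),
            inherits(ellipse_j, "standard_ellipse"))
  m <- 256L
  prev <- NA_real_
  repeat {
    pi_poly <- .ellipse_polygon(ellipse_i, m)
    pj_poly <- .ellipse_polygon(ellipse_j, m)
    ov <- .polygon_area(.clip_convex(pi_poly, pj_poly))
    if (!is.na(prev) &&
        (abs(ov - prev) <= tol * max(ov, .Machine$double.eps) || m >= 4096L)) {
      break
    }
    prev <- ov
    m <- m * 2L
  }
  .overlap_result("ellipse", ov, ellipse_i$sea, ellipse_j$sea)
}

#' Standardize specimens to the per-location resource centroid
#'
#' Subtracts from each specimen's (d13C, d15N) the unweighted mean of the
#' resource means at its location, placing all locations in a common
#' (meadow-scale) isotope space.
#'
#' @param specimens Specimen data frame (columns `location`, `d13c`,
#'   `d15n`).
#' @param resources Resource table (columns `location`, `d13c_mean`,
#'   `d15n_mean`).
#' @return The specimen frame with `d13c`, `d15n` replaced by standardized
#'   values.
#' @export
standardize_to_resource_centroid <- function(specimens, resources) {
  out <- specimens
  for (loc in unique(specimens$location)) {
    res <- resources[resources$location == loc, , drop = FALSE]
    if (nrow(res) == 0L) {
      stop("no resources for location ", sQuote(loc), call. = FALSE)
    }
    sel <- out$location == loc
    out$d13c[sel] <- out$d13c[sel] - mean(res$d13c_mean)
    out$d15n[sel] <- out$d15n[sel] - mean(res$d15n_mean)
  }
  out
}

#' Specimen-level isotopic distance summaries (ND, MND)
#'
#' With one point set: for each specimen, the mean Euclidean distance to all
#' remaining conspecifics (ND_ii), and the population mean MND_ii with SE.
#' With two sets: for each specimen of i, the mean distance to all
#' specimens of j (ND_ij) and the corresponding MND_ij. MND_ij computed
#' from i's specimens equals MND_ji from j's (both are the grand mean of
#' the full pairwise distance matrix).
#'
#' @param points_i Point set of the focal species.
#' @param points_j Optional point set of another species.
#' @return List with `nd` (per-specimen means), `mnd`, `se`, `n`; `NULL`
#'   with a warning for a conspecific singleton.
#' @export
nd_distances <- function(points_i, points_j = NULL) {
  pi_ <- .as_points(points_i)
  if (is.null(points_j)) {
    n <- nrow(pi_)
    if (n < 2L) {
      warning("singleton population: intraspecific distances undefined")
      return(NULL)
    }
    D <- as.matrix(stats::dist(pi_))
    nd <- unname(rowSums(D)) / (n - 1L)
  } else {
    pj <- .as_points(points_j)
    if (nrow(pj) < 1L) stop("empty heterospecific set", call. = FALSE)
    D <- outer(seq_len(nrow(pi_)), seq_len(nrow(pj)),
               function(a, b) sqrt((pi_[a, 1L] - pj[b, 1L])^2 +
                                   (pi_[a, 2L] - pj[b, 2L])^2))
    nd <- rowMeans(D)
  }
  list(nd = nd, mnd = mean(nd),
       se = if (length(nd) > 1L) stats::sd(nd) / sqrt(length(nd)) else NA_real_,
       n = length(nd))
}

#' Pielou evenness of counts across litterbags
#'
#' Shannon entropy of the count proportions divided by `log(L)` where L is
#' the number of litterbags; 1 for perfectly even spread, 0 when all
#' individuals share one litterbag.
#'
#' @param counts Non-negative counts, one per litterbag (length >= 2).
#' @return Evenness in `[0, 1]`.
#' @export
pielou_evenness <- function(counts) {
  if (length(counts) < 2L) stop("need at least two litterbags", call. = FALSE)
  total <- sum(counts)
  if (total <= 0) stop("zero total count", call. = FALSE)
  p <- counts / total
  p <- p[p > 0]
  H <- -sum(p * log(p))
  H / log(length(counts))
}

#' Per-population niche summary
#'
#' CR, carbon variance, hull total area, and standard ellipse areas for one
#' specimen cloud.
#'
#' @param points Point set (n x 2 or data frame).
#' @return List with `n`, `cr`, `sigma2`, `ta`, `sea`, `seac`, `ellipse`.
#' @export
niche_summary <- function(points) {
  pts <- .as_points(points)
  ell <- standard_ellipse(pts)
  list(n = nrow(pts),
       cr = carbon_range(pts[, 1L]),
       sigma2 = carbon_variance(pts[, 1L]),
       ta = suppressWarnings(convex_hull_area(pts)),
       sea = ell$sea, seac = ell$seac, ellipse = ell)
}

#' Bootstrap comparison of two SEAc values
#'
#' Resamples each specimen set with replacement `B` times, computes SEAc per
#' replicate, and compares the two bootstrap distributions with a Welch
#' two-sample t test. Seeded and reproducible.
#'
#' @param points_i,points_j Point sets.
#' @param B Number of bootstrap replicates (warning below 100).
#' @param seed Integer seed.
#' @return List with `t`, `p`, `seac_i`, `seac_j`, and the replicate
#'   vectors.
#' @export
compare_seac <- function(points_i, points_j, B = 999L, seed = 1L) {
  if (B < 100L) warning("B < 100 bootstrap replicates: comparison is crude")
  pi_ <- .as_points(points_i); pj <- .as_points(points_j)
  boot_seac <- function(p) {
    vapply(seq_len(B), function(b) {
      idx <- sample.int(nrow(p), replace = TRUE)
      e <- tryCatch(standard_ellipse(p[idx, , drop = FALSE]),
                    error = function(err) NULL)
      if (is.null(e)) NA_real_ else e$seac
    }, numeric(1))
  }
  set.seed(seed)
  ri <- boot_seac(pi_); rj <- boot_seac(pj)
  ri <- ri[is.finite(ri)]; rj <- rj[is.finite(rj)]
  tt <- stats::t.test(ri, rj, var.equal = FALSE)
  list(t = unname(tt$statistic), p = tt$p.value,
       seac_i = standard_ellipse(pi_)$seac,
       seac_j = standard_ellipse(pj)$seac,
       replicates_i = ri, replicates_j = rj)
}
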