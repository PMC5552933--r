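# Fixture builders shared across the suite. Everything is generated in
# code; files are written to tempdir().

write_fixture <- function(lines, sep = "\t") {
  path <- tempfile(fileext = ".tsv")
  writeLines(vapply(lines, function(x) paste(x, collapse = sep),
                    character(1)), path)
  path
}

specimen_header <- c("specimen_id", "species", "location", "site",
                     "litterbag", "d13c", "d15n")

specimen_fixture <- function(n = 6L, sep = "\t") {
  rows <- lapply(seq_len(n), function(i) {
    c(sprintf("id%02d", i), "amphipod_ts", "H", "S1",
      sprintf("B%02d", (i - 1L) %% 3L + 1L), -20 + i * 0.1, 5 + i * 0.05)
  })
  write_fixture(c(list(specimen_header), rows), sep)
}

resource_fixture <- function(sep = "\t") {
  header <- c("resource", "location", "d13c_mean", "d13c_sd",
              "d15n_mean", "d15n_sd", "n")
  rows <- list()
  for (loc in c("H", "I", "L")) {
    for (rn in c("leaves", "green", "brown", "epi", "som")) {
      rows[[length(rows) + 1L]] <- c(rn, loc, -15, 0.5, 3, 0.4, 5)
    }
  }
  write_fixture(c(list(header), rows), sep)
}

census_fixture <- function(sep = "\t") {
  header <- c("species", "location", "litterbag", "count")
  rows <- list()
  for (sp in c("a", "b", "c", "d")) {
    for (bag in sprintf("B%02d", 1:12)) {
      rows[[length(rows) + 1L]] <- c(sp, "H", bag, 2L)
    }
  }
  write_fixture(c(list(header), rows), sep)
}

# Well-separated source set for identifiable mixing-model tests.
separated_sources <- function() {
  data.frame(resource = paste0("s", 1:5),
             d13c_mean = c(-24, -19, -14, -21, -16),
             d13c_sd = rep(0.5, 5),
             d15n_mean = c(2, 8, 3, 10, 6.5),
             d15n_sd = rep(0.5, 5),
             stringsAsFactors = FALSE)
}

# Consumers simulated from the mixing model's own generative form.
simulate_consumers <- function(n, p, sources, tef = c(0.4, 2.3),
                               residual_sd = 0.3, seed = 1L) {
  set.seed(seed)
  K <- nrow(sources)
  sc <- matrix(rnorm(n * K, rep(sources$d13c_mean, each = n),
                     rep(sources$d13c_sd, each = n)), n)
  sn <- matrix(rnorm(n * K, rep(sources$d15n_mean, each = n),
                     rep(sources$d15n_sd, each = n)), n)
  cbind(drop((sc + tef[1]) %*% p) + rnorm(n, 0, residual_sd),
        drop((sn + tef[2]) %*% p) + rnorm(n, 0, residual_sd))
}

fast_mcmc <- list(iterations = 12000L, burnin = 4000L, thin = 4L,
                  chains = 2L)

# O(n^3) brute-force convex hull area: an ordered pair (i, j) is a hull
# edge iff every other point lies on its left; vertices are ordered by
# angle about their centroid and the shoelace formula applied.
brute_hull_area <- function(pts) {
  n <- nrow(pts)
  on_hull <- logical(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    a <- pts[i, ]; b <- pts[j, ]
    cr <- (b[1] - a[1]) * (pts[, 2] - a[2]) -
          (b[2] - a[2]) * (pts[, 1] - a[1])
    if (all(cr[-c(i, j)] > 0)) on_hull[c(i, j)] <- TRUE
  }
  v <- pts[on_hull, , drop = FALSE]
  cen <- colMeans(v)
  v <- v[order(atan2(v[, 2] - cen[2], v[, 1] - cen[1])), , drop = FALSE]
  isocompete:::.polygon_area(v)
}

# Vectorized membership test for a convex CCW polygon.
in_convex <- function(pts, poly) {
  inside <- rep(TRUE, nrow(pts))
  np <- nrow(poly)
  for (i in seq_len(np)) {
    a <- poly[i, ]; b <- poly[if (i == np) 1L else i + 1L, ]
    cr <- (b[1] - a[1]) * (pts[, 2] - a[2]) -
          (b[2] - a[2]) * (pts[, 1] - a[1])
    inside <- inside & cr >= 0
  }
  inside
}

# Random community matrix with unit diagonal and positive off-diagonals.
random_community_matrix <- function(n = 3L, max_alpha = 0.9) {
  m <- diag(1, n)
  m[row(m) != col(m)] <- runif(n * (n - 1L), 0.05, max_alpha)
  m
}
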