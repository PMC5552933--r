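#!/usr/bin/env Rscript
# Isotopic niche metrics of the three target species per location and at
# the meadow scale (resource-centroid standardized): d13C range (CR) and
# variance, convex-hull total area (TA), standard ellipse areas (SEA,
# SEAc), pairwise hull/ellipse overlaps, distance summaries (MND) and
# spatial evenness. Reads results/data/ written by 01_simulate.R.

suppressPackageStartupMessages(library(isocompete))

dir <- "results/data"
specimens <- read_specimen_table(file.path(dir, "specimens.tsv"))
resources <- read_resource_table(file.path(dir, "resources.tsv"))
census <- read_census_table(file.path(dir, "census.tsv"))
targets <- identify_targets(census)$target

std <- standardize_to_resource_centroid(specimens, resources)
scales <- c(unique(specimens$location), "meadow")

rows <- list(); ov_rows <- list()
for (sc in scales) {
  at <- if (sc == "meadow") std else
    specimens[specimens$location == sc, , drop = FALSE]
  pts <- lapply(targets, function(sp) {
    as.matrix(at[at$species == sp, c("d13c", "d15n")])
  })
  names(pts) <- targets
  for (sp in targets) {
    ns <- niche_summary(pts[[sp]])
    nd <- nd_distances(pts[[sp]])
    ev <- if (sc == "meadow") NA_real_ else
      pielou_evenness(census_counts(census, sp, sc))
    rows[[length(rows) + 1L]] <- data.frame(
      scale = sc, species = sp, n = ns$n, cr = ns$cr, sigma2 = ns$sigma2,
      ta = ns$ta, sea = ns$sea, seac = ns$seac,
      mnd_ii = nd$mnd, mnd_ii_se = nd$se, evenness = ev)
  }
  for (i in seq_along(targets)) for (j in seq_along(targets)) {
    if (i < j) {
      ho <- hull_overlap(pts[[i]], pts[[j]])
      eo <- ellipse_overlap(standard_ellipse(pts[[i]]),
                            standard_ellipse(pts[[j]]))
      ov_rows[[length(ov_rows) + 1L]] <- data.frame(
        scale = sc, species_i = targets[i], species_j = targets[j],
        ta_overlap_pct_i = ho$pct_of_i, ta_overlap_pct_j = ho$pct_of_j,
        seac_overlap_pct_i = eo$pct_of_i, seac_overlap_pct_j = eo$pct_of_j)
    }
  }
}
niche <- do.call(rbind, rows)
overlaps <- do.call(rbind, ov_rows)
write_table(niche, "results/niche_metrics.tsv")
write_table(overlaps, "results/niche_overlaps.tsv")

cat("Niche metrics written to results/niche_metrics.tsv\n\n")
print(cbind(niche[, 1:2], round(niche[, -(1:2)], 2)))
cat("\nThe meadow-scale niche of every species is far wider than any",
    "location-scale niche (spatial segregation of diets inflates the",
    "pooled cloud). Under the population-level diet model, flattening a",
    "shared diet narrows a population's own cloud slightly, so the",
    "within-location width signal is carried by diet composition and",
    "between-species convergence rather than by TA/SEAc alone; enable",
    "individual_diets in the generator to emulate individual",
    "specialization instead.\n")
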