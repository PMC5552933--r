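#!/usr/bin/env Rscript
# Bayesian mixing-model diets of the target species per location, the
# density-weighted meadow-scale diets, and diet-derived statistics
# (Shannon diversity Hs, Bray-Curtis similarity, per-resource C.V.).
# Reads results/data/; writes diet summaries and posterior draws.

suppressPackageStartupMessages(library(isocompete))

dir <- "results/data"
specimens <- read_specimen_table(file.path(dir, "specimens.tsv"))
resources <- read_resource_table(file.path(dir, "resources.tsv"))
census <- read_census_table(file.path(dir, "census.tsv"))
truth <- utils::read.table(file.path(dir, "true_diets.tsv"),
                           header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
targets <- identify_targets(census)$target
locs <- unique(specimens$location)
mcmc <- list(iterations = 30000L, burnin = 10000L, thin = 10L,
             chains = 4L)

summ_rows <- list(); post_means <- list()
for (l in locs) {
  src <- resources[resources$location == l, ]
  for (sp in targets) {
    pts <- specimens[specimens$species == sp & specimens$location == l,
                     c("d13c", "d15n")]
    post <- suppressWarnings(
      fit_mixing_model(pts, src, mcmc = mcmc,
                       seed = 20260928L + match(sp, targets) +
                         10L * match(l, locs)))
    s <- post$summary
    s$species <- sp; s$location <- l
    tr <- truth[truth$species == sp & truth$location == l, ]
    s$truth <- tr$proportion[match(s$resource, tr$resource)]
    summ_rows[[length(summ_rows) + 1L]] <- s
    post_means[[paste(sp, l)]] <- setNames(s$mean, s$resource)
  }
}
diets <- do.call(rbind, summ_rows)
write_table(diets, "results/diet_posteriors.tsv")

# meadow aggregation weighted by population density, plus diet statistics
stat_rows <- list()
for (sp in targets) {
  P <- do.call(rbind, lapply(locs, function(l) post_means[[paste(sp, l)]]))
  N <- vapply(locs, function(l) mean_density(census, sp, l)$mean,
              numeric(1))
  pm <- meadow_diet(P, N)
  stat_rows[[length(stat_rows) + 1L]] <- data.frame(
    species = sp, scale = "meadow", hs = diet_diversity(pm),
    t(as.matrix(pm)))
  for (l in locs) {
    stat_rows[[length(stat_rows) + 1L]] <- data.frame(
      species = sp, scale = l, hs = diet_diversity(post_means[[paste(sp, l)]]),
      t(as.matrix(post_means[[paste(sp, l)]])))
  }
}
diet_stats <- do.call(rbind, stat_rows)
write_table(diet_stats, "results/diet_statistics.tsv")

cat("Diet posteriors written to results/diet_posteriors.tsv\n")
cov95 <- mean(diets$truth >= diets$lower & diets$truth <= diets$upper)
cat(sprintf("95%% credible intervals cover the generator's true proportions for %.0f%% of resource-population pairs.\n",
            100 * cov95))
for (l in locs) {
  sims <- combn(targets, 2, function(pr) {
    diet_similarity(post_means[[paste(pr[1], l)]],
                    post_means[[paste(pr[2], l)]])
  })
  cat(sprintf("Mean Bray-Curtis diet similarity between target species at %s: %.2f\n",
              l, mean(sims)))
}
cat("Diets flatten and converge as resources become limiting; similarity",
    "in any single community carries one Dirichlet draw of noise per",
    "population, so the monotone trend is established by the replicated",
    "experiment (06_gradient_experiment.R).\n")
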