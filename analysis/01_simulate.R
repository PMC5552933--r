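#!/usr/bin/env Rscript
# Generate the synthetic seagrass-litter community used by the rest of the
# workflow: three locations on a degradation gradient (seagrass coverage
# 92.5 / 70 / 50 percent), five basal resources, three abundant target
# species plus a tail of five rarer species. Writes the three standard
# tables plus the ground-truth diets under results/data/.

suppressPackageStartupMessages(library(isocompete))

seed <- 20260928L
cfg <- synthetic_config(seed = seed)
com <- generate_community(cfg)

out <- "results/data"
write_community(com, out)

dens <- do.call(rbind, lapply(cfg$locations, function(l) {
  do.call(rbind, lapply(unique(com$census$species), function(sp) {
    d <- mean_density(com$census, sp, l)
    data.frame(species = sp, location = l, mean = d$mean, se = d$se)
  }))
}))
write_table(dens, file.path(out, "densities.tsv"))

cat("Synthetic community written to", out, "\n")
cat("Specimens:", nrow(com$specimens), " census records:",
    nrow(com$census), "\n")
cat("Total density per litterbag by location:\n")
print(round(tapply(dens$mean, dens$location, sum), 1))
cat("Density declines along the degradation gradient, as constructed.\n")
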