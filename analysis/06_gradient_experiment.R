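#!/usr/bin/env Rscript
# Replicated degradation-gradient experiment: 20 synthetic communities,
# each analyzed end to end. Summarizes how mean competition strength
# (alpha and beta), total carrying capacity and the leading Jacobian
# eigenvalue respond to degradation, the alpha-vs-beta agreement, and the
# agreement between the linearization sign and simulated LV dynamics.

suppressPackageStartupMessages(library(isocompete))

ge <- suppressWarnings(gradient_experiment(n_reps = 20L, seed = 20260928L))
pl <- ge$per_location
write_table(pl, "results/gradient_replicates.tsv")

lvl <- aggregate(cbind(mean_alpha, mean_beta, total_k, lambda) ~ degradation,
                 pl, mean)
write_table(lvl, "results/gradient_summary.tsv")

cat("Per-replicate results written to results/gradient_replicates.tsv\n\n")
print(round(lvl, 4))
cat(sprintf("\nAlpha-on-beta slope over all replicates: %.2f (r2 = %.2f)\n",
            ge$pooled_fit$slope, ge$pooled_fit$r2))
cat(sprintf("Per-replicate slope CI covers 1 in %.0f%% of replicates.\n",
            100 * mean(ge$slope_ci_covers_1)))
cat(sprintf("Linearization sign agrees with LV dynamics in %.0f%% of location-replicates.\n",
            100 * mean(ge$lv_sign_agreement)))
cat("\nAcross replicates, degradation raises both competition",
    "coefficients, lowers carrying capacity, and moves the leading",
    "eigenvalue toward zero: communities on degraded patches sit closer",
    "to the stability boundary.\n")
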