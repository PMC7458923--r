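#!/usr/bin/env Rscript
# Stage 3: Bray-Curtis dissimilarity, nMDS and PCoA ordination, and the
# PERMDISP-style homogeneity screen (with Tukey HSD pairwise comparisons)
# that licenses the PERMANOVA in stage 4.

library(iguanachem)

tab <- read_compound_table("results/profiles.csv")
md <- read_sample_metadata("results/metadata.csv", tab)

d <- bray_curtis_matrix(tab)

pc <- pcoa(d)
cat(sprintf("PCoA: axis 1 explains %.2f%%, axis 2 %.2f%% of variance; %d imaginary axes\n",
            100 * pc$variance_explained[1], 100 * pc$variance_explained[2],
            ncol(pc$imaginary_coordinates)))

nm <- nmds(d, k = 3, n_starts = 10, seed = 42)
cat(sprintf("nMDS (k = 3): stress %.4f after %d iterations (converged: %s)\n",
            nm$stress, nm$n_iterations, nm$converged))

coords <- data.frame(sample_id = rownames(nm$coordinates),
                     nm$coordinates,
                     pc$coordinates[, 1:2],
                     md[c("species", "sex", "year")])
write.csv(coords, "results/ordination_coordinates.csv", row.names = FALSE)

grp <- interaction(md$year, md$species, md$sex, drop = TRUE)
disp <- permdisp(d, grp)
tk <- tukey_hsd_dispersion(disp)
cat(sprintf("Dispersion ANOVA: F = %.2f, p = %.3g\n",
            disp$anova_f, disp$anova_p))
cat(sprintf("Homogeneity upheld in %.0f%% of the %d Tukey pairwise comparisons\n",
            100 * tk$percent_homogeneous, nrow(tk$tukey_table)))
write.csv(tk$tukey_table, "results/dispersion_tukey.csv", row.names = FALSE)
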