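#!/usr/bin/env Rscript
# Simulate the default two-group dual-echo cohort (28 young / 43 old,
# 12x12x6 grid, planted young > old SD_BOLD effect, independent coupling)
# and record its ground truth. Downstream scripts regenerate the cohort
# deterministically from the same spec, so nothing binary is stored.

library(boldvar)

out <- "results/analysis"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

spec <- cohort_spec(rng_seed = 1L)
truth <- simulate_cohort_subjects(spec)

write.table(truth, file.path(out, "ground_truth_subjects.tsv"),
            sep = "\t", row.names = FALSE, quote = FALSE)

fx <- make_design("fixation")
hy <- make_design("hypercapnia")
write.table(fx$design$blocks, file.path(out, "design_fixation.tsv"),
            sep = "\t", row.names = FALSE, quote = FALSE)
write.table(cbind(hy$design$blocks),
            file.path(out, "design_hypercapnia.tsv"),
            sep = "\t", row.names = FALSE, quote = FALSE)
write.table(data.frame(frame = seq_along(hy$endtidal$pco2),
                       pco2 = hy$endtidal$pco2, po2 = hy$endtidal$po2),
            file.path(out, "endtidal_hypercapnia.tsv"),
            sep = "\t", row.names = FALSE, quote = FALSE)

cat(sprintf("cohort: %d young, %d old; sex table:\n",
            spec$n_young, spec$n_old))
print(table(truth$group, truth$sex))
cat(sprintf("planted SD (young/old/background): %.2f / %.2f / %.2f\n",
            spec$sd_young, spec$sd_old, spec$sd_background))
cat(sprintf("effect region: %d voxels of %d GM voxels\n",
            sum(spec$effect_region), sum(spec$masks$gm)))
cat("wrote ground truth and design tables to", out, "\n")
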