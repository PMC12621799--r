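#!/usr/bin/env Rscript
# Generate the synthetic study inputs: cell masks with known geometry for
# the morphometrics chain, and coupled protein/phenotype blocks with
# planted latent structure for the RPPA/PLSR chain. Masks are pure
# functions of their configs, so downstream scripts regenerate them from
# the shared arm definitions in helper_arms.R rather than reading rasters.
suppressPackageStartupMessages(library(cardiomorph))
source(file.path("analysis", "helper_arms.R"))

out <- "results"
dir.create(out, showWarnings = FALSE)

truth <- do.call(rbind, lapply(study_arm_configs(), function(arm) {
  do.call(rbind, lapply(arm, function(cw) {
    gen_cell_masks(cw$config, n = cw$n, well_id = cw$well_id)$truth
  }))
}))
write.csv(truth, file.path(out, "mask_truth.csv"), row.names = FALSE)
cat("masks:", nrow(truth), "cells;",
    "true elongation", paste(unique(round(truth$true_feret_elongation, 2)),
                             collapse = " / "), "\n")

# Omics blocks at the study's shape: 172 probes x (4 ligands x 2 timepoints),
# 15 phenotype outputs, 2 planted latent factors, noise sd 0.05.
blocks <- gen_omics_blocks(omics_config(seed = 1L))
write.csv(data.frame(condition = rownames(blocks$X), blocks$X,
                     check.names = FALSE),
          file.path(out, "omics_X.csv"), row.names = FALSE)
write.csv(data.frame(condition = rownames(blocks$Y), blocks$Y,
                     check.names = FALSE),
          file.path(out, "omics_Y.csv"), row.names = FALSE)
cat("omics: X", paste(dim(blocks$X), collapse = " x "),
    "| Y", paste(dim(blocks$Y), collapse = " x "),
    "| latent rank", blocks$config$n_latent, "\n")
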