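#!/usr/bin/env Rscript
# RPPA preprocessing chain: wrap the simulated log2 fold-changes into a raw
# replicated matrix with serum-free controls, then normalize, log-transform,
# select the top 20% responders per ligand, and tabulate Venn overlaps.
suppressPackageStartupMessages(library(cardiomorph))

out <- "results"
dir.create(out, showWarnings = FALSE)
blocks <- gen_omics_blocks(omics_config(seed = 1L))

raw <- gen_rppa_raw(blocks$X, n_replicates = 2L, seed = 2L)
write_response_matrix(raw, file.path(out, "rppa_raw.csv"))
lfc <- log2fc(normalize_to_control(raw, "serumfree"))
write_response_matrix(lfc, file.path(out, "rppa_log2fc.csv"))

ligands <- blocks$config$ligands
tops <- lapply(setNames(ligands, ligands), function(lg) {
  select_top_responders(lfc, paste0(lg, "_1h"), fraction = 0.20)
})
venn <- venn_overlaps(tops)
write.csv(data.frame(ligand = rep(names(tops), lengths(tops)),
                     rank = unlist(lapply(tops, seq_along)),
                     probe_id = unlist(tops)),
          file.path(out, "rppa_top_responders.csv"), row.names = FALSE)
jsonlite::write_json(as.list(venn), file.path(out, "rppa_venn.json"),
                     auto_unbox = TRUE)

cat("top 20% per ligand:", lengths(tops)[1], "probes each\n")
cat("Venn: shared by all four =", venn[[paste(ligands, collapse = "&")]],
    "| union =", sum(venn), "\n")
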