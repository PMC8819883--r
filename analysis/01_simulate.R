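#!/usr/bin/env Rscript
# Simulate the study: GF vs SPF dams (6 per group, 2 fetuses each), three
# fetal/placental organs, four LC-MS modes, interleaved pooled QCs, smooth
# injection-order drift, intensity-dependent missingness, and planted effects
# of all five classes. A handful of planted SPF-higher features are given the
# m/z and RT of compounds in the bundled synthetic reference library so the
# annotation step downstream has genuine targets.
#
# Writes per-mode feature tables, injection metadata and the ground truth
# under results/data/.

suppressMessages(library(fetometab))

seed <- 20260921L
cfg <- synthetic_config(n_features_per_mode = 300, seed = seed)
ds <- generate_dataset(cfg)

# plant library compounds onto SPF-higher RP+ features ([M+H]+ m/z, library RT)
lib <- read_msp_library(system.file("extdata", "synthetic_library.msp",
                                    package = "fetometab"))
tr_rp <- ds$truth[ds$truth$mode == "RP+" & ds$truth$effect_class == "spf_up", ]
plant <- head(tr_rp$feature_id, length(lib))
tab <- ds$tables[["RP+"]]
ix <- match(plant, tab$features$feature_id)
for (k in seq_along(ix)) {
  tab$features$mz[ix[k]] <- lib[[k]]$monoisotopic_mass + 1.007276
  tab$features$rt[ix[k]] <- ifelse(is.na(lib[[k]]$rt), 5, lib[[k]]$rt)
}
ds$tables[["RP+"]] <- tab
planted_compounds <- data.frame(
  feature_id = plant, compound_name = vapply(lib, `[[`, "", "compound_name"),
  stringsAsFactors = FALSE
)

out_dir <- file.path("results", "data")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
slug <- function(md) gsub("[+]", "pos", gsub("-", "neg", md))
for (md in names(ds$tables)) {
  write_feature_table(ds$tables[[md]],
                      file.path(out_dir, sprintf("feature_table_%s.tsv", slug(md))),
                      file.path(out_dir, sprintf("injections_%s.tsv", slug(md))))
}
write_results(list(truth = ds$truth, drift_params = ds$drift,
                   samples = ds$samples,
                   planted_compounds = planted_compounds),
              out_dir, config = list(seed = seed, noise_floor = ds$noise_floor),
              seed = seed)

cat("Simulated", length(ds$tables), "modes x",
    nrow(ds$tables[[1]]$intensities), "features;",
    sum(ds$samples$group == "GF"), "GF and",
    sum(ds$samples$group == "SPF"), "SPF organ samples per mode, plus",
    sum(ds$tables[[1]]$injections$sample_type == "qc"), "QC injections.\n")
print(table(ds$truth$effect_class))
cat("Planted", nrow(planted_compounds),
    "library compounds onto SPF-higher RP+ features for annotation.\n")
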