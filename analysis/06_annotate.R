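#!/usr/bin/env Rscript
# Annotate the significant features against the bundled synthetic reference
# library and assign identification confidence levels (1 = standard-confirmed,
# 2 = putative m/z + MS2 or RT + formula vs an in-house standard, 3 = class
# only, 4 = unknown). For features that carry a planted library compound we
# attach the library spectrum as the acquired MS2 (simulating the instrument's
# MS2 acquisition on significant features), then order the annotated features
# by hierarchical clustering of their abundance profiles. Writes
# results/annotation/.

suppressMessages(library(fetometab))

pre_dir <- file.path("results", "preprocessed")
diff_dir <- file.path("results", "differential")
out_dir <- file.path("results", "annotation")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

imputed <- read_feature_table(file.path(pre_dir, "imputed.tsv"),
                              file.path(pre_dir, "injections_imputed.tsv"))
diff <- read_results_table(file.path(diff_dir, "differential.tsv"))
lib <- read_msp_library(system.file("extdata", "synthetic_library.msp",
                                    package = "fetometab"))

sig_ids <- unique(diff$feature_id[diff$significant])
feats <- imputed$features[imputed$features$feature_id %in% sig_ids, ]
cat("Annotating", nrow(feats), "significant features against",
    length(lib), "library entries.\n")

# simulated MS2 acquisition: features at a library precursor m/z get that
# entry's spectrum
lib_mz <- vapply(lib, function(e) e$monoisotopic_mass + 1.007276, numeric(1))
feats$ms2 <- lapply(feats$mz, function(mz) {
  k <- which(abs(mz - lib_mz) / lib_mz * 1e6 <= 10)
  if (length(k)) lib[[k[1]]]$ms2 else NULL
})

ann <- annotate_features(feats, lib)
cat("Identification level counts:\n")
print(table(ann$msi_level))
named <- ann[!is.na(ann$compound_name) & ann$representative, ]
cat("Annotated compounds:",
    paste(sort(named$compound_name), collapse = ", "), "\n")

# hierarchical ordering of the annotated features by abundance similarity
ann_ids <- ann$feature_id[!is.na(ann$compound_name)]
if (length(ann_ids) >= 2) {
  m <- log(imputed$intensities[ann_ids, , drop = FALSE])
  ord <- hierarchical_order(m)
  write_results(list(annotation = ann[setdiff(names(ann), "ms2")],
                     heatmap_order = data.frame(feature_id = ord,
                                                position = seq_along(ord))),
                out_dir)
} else {
  write_results(list(annotation = ann[setdiff(names(ann), "ms2")]), out_dir)
}
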