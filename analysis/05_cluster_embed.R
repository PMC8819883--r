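#!/usr/bin/env Rscript
# Unsupervised structure: t-SNE of all samples and of each organ separately,
# k-means (k = 10) row ordering per organ for heatmap display, and GF-vs-SPF
# separation measured as a silhouette score on the embedding coordinates.
# Writes results/cluster/.

suppressMessages(library(fetometab))

pre_dir <- file.path("results", "preprocessed")
out_dir <- file.path("results", "cluster")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

imputed <- read_feature_table(file.path(pre_dir, "imputed.tsv"),
                              file.path(pre_dir, "injections_imputed.tsv"))
organs <- c("brain", "intestine", "placenta")

emb <- rbind(tsne_embed(imputed, "all", perplexity = 7, seed = 11),
             do.call(rbind, lapply(organs, function(o)
               tsne_embed(imputed, o, perplexity = 7, seed = 11))))

sil_group <- function(scope) {
  e <- emb[emb$scope == scope, ]
  lab <- imputed$injections$group[match(e$injection_id,
                                        imputed$injections$injection_id)]
  d <- as.matrix(dist(as.matrix(e[c("x", "y")])))
  mean(vapply(seq_len(nrow(d)), function(i) {
    same <- lab == lab[i]; same[i] <- FALSE
    a <- mean(d[i, same]); b <- mean(d[i, !same & seq_len(nrow(d)) != i])
    (b - a) / max(a, b)
  }, numeric(1)))
}
for (o in organs) {
  cat(sprintf("%-10s GF/SPF silhouette on the t-SNE embedding: %+.3f\n",
              o, sil_group(o)))
}

km <- do.call(rbind, lapply(organs, function(o)
  kmeans_rows(imputed, o, k = 10, seed = 13)))
cat("k-means (k = 10) cluster sizes per organ:\n")
print(with(km, table(organ, cluster_id)))

write_results(list(embedding = emb, clusters = km), out_dir)
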