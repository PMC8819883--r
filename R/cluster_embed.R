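# per-feature z-score of log intensities; constant features map to 0
zscore_rows <- function(m, log_scale = TRUE) {
  if (log_scale) m <- log(m)
  mu <- rowMeans(m)
  sd <- apply(m, 1, stats::sd)
  z <- (m - mu) / ifelse(sd > 0, sd, 1)
  z[sd == 0, ] <- 0
  z
}

#' t-SNE embedding of biological injections
#'
#' Embeds samples in 2-D from per-feature z-scored log intensities, either
#' for the whole dataset or restricted to one organ. Exact (theta = 0)
#' Barnes-Hut is used since sample counts are small; a fixed seed gives
#' reproducible coordinates.
#'
#' @param table an imputed, QC-free `FeatureTable`.
#' @param scope `"all"` or one organ.
#' @param perplexity t-SNE perplexity; must satisfy `n > 3 * perplexity`.
#'   Default 10 suits the 24-sample per-organ scope.
#' @param seed integer seed.
#' @return data.frame: `injection_id`, `x`, `y`, `scope`.
#' @export
tsne_embed <- function(table, scope = "all", perplexity = 10, seed = 1) {
  tab <- ft_drop_qc(table)
  if (scope != "all") {
    tab <- ft_subset(tab, injections = tab$injections$organ == scope)
  }
  n <- ncol(tab$intensities)
  if (n - 1 < 3 * perplexity) {
    stop("perplexity ", perplexity, " too large for ", n,
         " samples; feasible maximum is ", floor((n - 1) / 3))
  }
  z <- zscore_rows(tab$intensities)
  x <- t(z)
  # PCA initialization: reproducible coordinates (the seed only covers any
  # internal stochastic steps) and identical samples stay identical, since
  # they start together and share gradients throughout
  pcs <- stats::prcomp(x, rank. = 2)$x
  sd1 <- stats::sd(pcs[, 1])
  y0 <- if (sd1 > 0) pcs / sd1 * 1e-4 else
    matrix(0, nrow(x), 2)
  set.seed(seed)
  fit <- Rtsne::Rtsne(x, dims = 2, perplexity = perplexity, theta = 0,
                      check_duplicates = FALSE, pca = FALSE, Y_init = y0,
                      max_iter = 500, verbose = FALSE)
  data.frame(injection_id = tab$injections$injection_id,
             x = fit$Y[, 1], y = fit$Y[, 2], scope = scope,
             stringsAsFactors = FALSE)
}

#' k-means clustering of features for heatmap row ordering
#'
#' Clusters per-feature z-scored profiles within one organ (k = 10 by
#' default, multiple restarts, fixed seed) and orders rows by cluster, then
#' within cluster by decreasing correlation with the cluster's mean profile.
#' Clustering is independent per organ.
#'
#' @param table an imputed, QC-free `FeatureTable`.
#' @param organ the organ scope.
#' @param k number of clusters.
#' @param seed integer seed.
#' @param nstart k-means restarts (best by total within-cluster SS).
#' @return data.frame: `feature_id`, `organ`, `cluster_id`, `row_order`
#'   (a permutation of the features within the organ).
#' @export
kmeans_rows <- function(table, organ, k = 10, seed = 1, nstart = 100) {
  tab <- ft_drop_qc(table)
  tab <- ft_subset(tab, injections = tab$injections$organ == organ)
  z <- zscore_rows(tab$intensities)
  if (k > nrow(z)) stop("k = ", k, " exceeds the ", nrow(z), " features")
  set.seed(seed)
  km <- stats::kmeans(z, centers = k, nstart = nstart, iter.max = 100)
  cl <- km$cluster
  score <- numeric(length(cl))
  for (cid in seq_len(k)) {
    ix <- which(cl == cid)
    if (length(ix) == 1) { score[ix] <- 1; next }
    centre <- colMeans(z[ix, , drop = FALSE])
    if (stats::sd(centre) == 0) { score[ix] <- 0; next }
    score[ix] <- apply(z[ix, , drop = FALSE], 1, function(r) {
      if (stats::sd(r) == 0) 0 else stats::cor(r, centre)
    })
  }
  ord <- order(cl, -score, seq_along(cl))
  data.frame(feature_id = tab$features$feature_id, organ = organ,
             cluster_id = cl, row_order = order(ord),
             stringsAsFactors = FALSE)
}

#' Hierarchical leaf order of features by profile similarity
#'
#' Average-linkage hierarchical clustering on correlation distance
#' (1 - Pearson r) of per-feature profiles; the dendrogram's deterministic
#' traversal gives the leaf order. Constant (zero-variance) features have no
#' defined correlation and are placed last with a warning.
#'
#' @param mat numeric matrix, features in rows (e.g. the annotated subset of
#'   an imputed table, log scale).
#' @return character vector of row names (or indices) in leaf order.
#' @export
hierarchical_order <- function(mat) {
  if (nrow(mat) < 2) stop("need at least 2 features")
  ids <- rownames(mat)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(mat)))
  sds <- apply(mat, 1, stats::sd)
  const <- sds == 0
  if (any(const)) {
    warning(sum(const), " constant feature(s) placed last (correlation undefined)")
  }
  keep <- which(!const)
  if (length(keep) < 2) return(c(ids[keep], ids[const]))
  d <- stats::as.dist(1 - stats::cor(t(mat[keep, , drop = FALSE])))
  hc <- stats::hclust(d, method = "average")
  c(ids[keep][hc$order], ids[const])
}
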