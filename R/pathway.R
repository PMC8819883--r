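#' MetaboAnalyst-style normalization for pathway analysis
#'
#' Per-sample median normalization (divide by the sample median, multiply by
#' the grand median), cube-root transform, then per-feature autoscaling
#' (mean 0, sd 1). Requires strictly positive intensities (the cube root
#' precedes centring).
#'
#' @param m numeric matrix, features in rows, samples in columns, or a
#'   `FeatureTable` (its matrix is used).
#' @return the normalized matrix.
#' @export
normalize_for_pathway <- function(m) {
  if (inherits(m, "FeatureTable")) m <- m$intensities
  if (anyNA(m) || any(m <= 0)) {
    stop("normalize_for_pathway requires complete, positive intensities")
  }
  med <- apply(m, 2, stats::median)
  grand <- stats::median(med)
  m <- sweep(m, 2, med, "/") * grand
  m <- m^(1 / 3)
  mu <- rowMeans(m)
  sd <- apply(m, 1, stats::sd)
  z <- (m - mu) / ifelse(sd > 0, sd, 1)
  z[sd == 0, ] <- 0
  z
}

#' Map m/z values to candidate compounds under adduct rules
#'
#' Each m/z maps to every compound whose adduct mass lies within `tol_ppm`;
#' a compound is significant if any significant m/z maps to it (mummichog's
#' putative-matching step, primary ions only by default).
#'
#' @param mz numeric vector of feature m/z values.
#' @param significant logical vector marking the significant features.
#' @param polarity character vector (`"+"`/`"-"`) per feature.
#' @param universe data.frame with `compound_id` and `monoisotopic_mass`.
#' @param adducts adduct table, see [default_adducts()].
#' @param tol_ppm mass tolerance (10 ppm).
#' @return list with `matches` (data.frame `mz`, `significant`,
#'   `compound_id`, `adduct`, `ppm_error`), `compounds` (reachable compound
#'   ids) and `significant_compounds`.
#' @export
mz_to_compounds <- function(mz, significant, polarity, universe,
                            adducts = default_adducts(), tol_ppm = 10) {
  if (nrow(adducts) == 0) stop("empty adduct set")
  if (length(mz) == 0) {
    return(list(matches = data.frame(), compounds = character(0),
                significant_compounds = character(0)))
  }
  rows <- list()
  for (i in seq_along(mz)) {
    add <- adducts[adducts$polarity == polarity[i], , drop = FALSE]
    for (k in seq_len(nrow(add))) {
      expected <- universe$monoisotopic_mass + add$shift[k]
      ppm <- abs(mz[i] - expected) / expected * 1e6
      hit <- which(ppm <= tol_ppm)
      if (length(hit)) {
        rows[[length(rows) + 1L]] <- data.frame(
          feature_idx = i, mz = mz[i], significant = significant[i],
          compound_id = universe$compound_id[hit], adduct = add$name[k],
          ppm_error = ppm[hit], stringsAsFactors = FALSE
        )
      }
    }
  }
  matches <- if (length(rows)) do.call(rbind, rows) else
    data.frame(feature_idx = integer(0), mz = numeric(0),
               significant = logical(0), compound_id = character(0),
               adduct = character(0), ppm_error = numeric(0))
  list(matches = matches,
       compounds = unique(matches$compound_id),
       significant_compounds = unique(matches$compound_id[matches$significant]))
}

# one-sided enrichment p: P(X >= hits) for hypergeometric draws
fisher_enrichment_p <- function(hits, n_path, n_universe, n_sig) {
  stats::phyper(hits - 1, n_path, n_universe - n_path, n_sig,
                lower.tail = FALSE)
}

#' Pathway over-representation with a permutation null
#'
#' Simplified mummichog: the compound universe defaults to all compounds
#' reachable from the observed m/z list under the adduct rules; per pathway,
#' a one-sided Fisher exact test on significant-vs-universe compound counts;
#' and a permutation null drawing as many random m/z from the full feature
#' list as were significant, `n_perm` times, recomputing pathway hits.
#' `perm_p` is the add-one-smoothed fraction of permutations with at least
#' the observed hits; a pathway is enriched when `perm_p < 0.05`. Pathways
#' with no member in the universe are excluded with a warning.
#'
#' @param mz,significant,polarity the observed features, as in
#'   [mz_to_compounds()].
#' @param universe compound universe data.frame (`compound_id`,
#'   `monoisotopic_mass`).
#' @param pathways named list of compound-id vectors (see [read_gmt()]).
#' @param adducts,tol_ppm adduct rules and tolerance.
#' @param n_perm permutations.
#' @param seed integer seed for the permutation draws.
#' @return data.frame: `pathway_id`, `n_members_in_universe`,
#'   `n_significant_hits`, `fisher_p`, `perm_p`, `enriched`.
#' @export
enrich_pathways <- function(mz, significant, polarity, universe, pathways,
                            adducts = default_adducts(), tol_ppm = 10,
                            n_perm = 1000, seed = 1) {
  cand <- mz_to_compounds(mz, significant, polarity, universe, adducts,
                          tol_ppm)
  cmp_universe <- cand$compounds      # mummichog convention: reachable set
  sig_cmp <- cand$significant_compounds
  n_u <- length(cmp_universe)
  n_s <- length(sig_cmp)

  members <- lapply(pathways, function(p) intersect(p, cmp_universe))
  empty <- vapply(members, length, integer(1)) == 0
  if (any(empty)) {
    warning("excluding ", sum(empty), " pathway(s) with no members in universe")
    members <- members[!empty]
  }
  if (length(members) == 0) {
    return(data.frame(pathway_id = character(0)))
  }
  obs_hits <- vapply(members, function(p) length(intersect(p, sig_cmp)),
                     integer(1))
  fisher_p <- mapply(function(hits, p) {
    fisher_enrichment_p(hits, length(p), n_u, n_s)
  }, obs_hits, members)

  # permutation null over random draws of |significant| m/z
  set.seed(seed)
  ge_count <- integer(length(members))
  mz_map <- split(cand$matches$compound_id,
                  cand$matches$feature_idx)      # feature index -> compounds
  for (b in seq_len(n_perm)) {
    pick <- sample(length(mz), sum(significant))
    perm_cmp <- unique(unlist(mz_map[as.character(pick)], use.names = FALSE))
    hits <- vapply(members, function(p) length(intersect(p, perm_cmp)),
                   integer(1))
    ge_count <- ge_count + (hits >= obs_hits)
  }
  perm_p <- (1 + ge_count) / (1 + n_perm)
  data.frame(
    pathway_id = names(members),
    n_members_in_universe = vapply(members, length, integer(1)),
    n_significant_hits = obs_hits,
    fisher_p = unname(fisher_p),
    perm_p = perm_p,
    enriched = perm_p < 0.05,
    row.names = NULL, stringsAsFactors = FALSE
  )
}
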