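#' Benjamini-Hochberg step-up adjustment
#'
#' `q_i = min over j >= rank(i) of m * p_(j) / j`, capped at 1, stable under
#' ties. `NA` p-values (undefined tests) are excluded from the family size
#' `m` and returned as `NA`.
#'
#' @param pvals numeric vector of p-values in `[0, 1]` (`NA` allowed).
#' @return q-values of the same length.
#' @export
bh_adjust <- function(pvals) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  q <- rep(NA_real_, length(pvals))
  ok <- which(!is.na(pvals))
  m <- length(ok)
  if (m == 0) return(q)
  p <- pvals[ok]
  o <- order(p)
  adj <- rev(cummin(rev(m * p[o] / seq_len(m))))  # step-up from largest p
  q[ok[o]] <- pmin(adj, 1)
  q
}

# pooled-variance two-sample t statistics, vectorised over features (rows)
pooled_t_rows <- function(x, y) {
  n1 <- ncol(x); n2 <- ncol(y)
  m1 <- rowMeans(x); m2 <- rowMeans(y)
  v1 <- apply(x, 1, stats::var); v2 <- apply(y, 1, stats::var)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  t <- (m1 - m2) / se
  df <- n1 + n2 - 2
  p <- 2 * stats::pt(-abs(t), df)
  d <- (m1 - m2) / sqrt(sp2)
  zero_var <- sp2 == 0
  t[zero_var] <- NA_real_
  p[zero_var] <- NA_real_
  d[zero_var] <- ifelse(m1[zero_var] == m2[zero_var], 0, NA_real_)
  list(mean_1 = m1, mean_2 = m2, t = t, p = p, d = d)
}

#' Per-organ differential abundance between GF and SPF
#'
#' For each feature within one organ: a pooled-variance (Student) two-sample
#' t test comparing GF vs SPF, Cohen's d `(mean_GF - mean_SPF) / s_pooled`
#' (GF-minus-SPF sign convention: SPF-higher features have d < 0), and
#' Benjamini-Hochberg q-values over all features of the organ. A feature is
#' significant when `q < 0.05` and `|d| > 0.8`. Tests run on log-transformed
#' intensities by default. Features with zero pooled variance get a missing
#' p and are excluded from the BH family size.
#'
#' @param table an imputed, QC-free `FeatureTable`.
#' @param organ one of `"brain"`, `"intestine"`, `"placenta"`.
#' @param log_transform test log intensities (default) or raw.
#' @param var_equal pooled-variance Student test (default); `FALSE` gives
#'   Welch.
#' @param q_threshold,d_threshold the significance double threshold.
#' @return data.frame: `feature_id`, `organ`, `mean_gf`, `mean_spf` (on the
#'   analysis scale), `t_stat`, `p`, `q`, `cohens_d`, `significant`,
#'   `direction` (`"spf_higher"`, `"gf_higher"`, `"none"`).
#' @export
differential_test <- function(table, organ, log_transform = TRUE,
                              var_equal = TRUE, q_threshold = 0.05,
                              d_threshold = 0.8) {
  inj <- table$injections
  sel <- inj$sample_type == "biological" & inj$organ == organ
  gf <- sel & inj$group == "GF"
  spf <- sel & inj$group == "SPF"
  if (sum(gf) < 2 || sum(spf) < 2) {
    stop("need at least 2 samples per group in organ ", organ)
  }
  m <- table$intensities
  if (anyNA(m[, gf | spf])) {
    stop("differential_test expects a complete (imputed) table")
  }
  if (log_transform) m <- log(m)
  x <- m[, gf, drop = FALSE]
  y <- m[, spf, drop = FALSE]
  if (var_equal) {
    st <- pooled_t_rows(x, y)
  } else {
    st <- welch_t_rows(x, y)
  }
  q <- bh_adjust(st$p)
  sig <- !is.na(q) & q < q_threshold & !is.na(st$d) & abs(st$d) > d_threshold
  direction <- rep("none", nrow(m))
  direction[sig & st$d < 0] <- "spf_higher"
  direction[sig & st$d > 0] <- "gf_higher"
  data.frame(
    feature_id = table$features$feature_id, organ = organ,
    mean_gf = st$mean_1, mean_spf = st$mean_2,
    t_stat = st$t, p = st$p, q = q, cohens_d = st$d,
    significant = sig, direction = direction,
    stringsAsFactors = FALSE
  )
}

welch_t_rows <- function(x, y) {
  n1 <- ncol(x); n2 <- ncol(y)
  m1 <- rowMeans(x); m2 <- rowMeans(y)
  v1 <- apply(x, 1, stats::var); v2 <- apply(y, 1, stats::var)
  se2 <- v1 / n1 + v2 / n2
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(t), df)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  d <- (m1 - m2) / sqrt(sp2)
  zero <- se2 == 0
  t[zero] <- NA_real_; p[zero] <- NA_real_
  d[sp2 == 0] <- ifelse(m1[sp2 == 0] == m2[sp2 == 0], 0, NA_real_)
  list(mean_1 = m1, mean_2 = m2, t = t, p = p, d = d)
}

#' Run the differential test for every organ
#'
#' BH adjustment is applied within each organ (each organ its own family).
#'
#' @inheritParams differential_test
#' @param organs organs to test.
#' @return row-bound data.frame of [differential_test()] results.
#' @export
differential_all_organs <- function(table, organs = VALID_ORGANS, ...) {
  out <- do.call(rbind, lapply(organs, function(o)
    differential_test(table, o, ...)))
  rownames(out) <- NULL
  out
}

#' Signal-to-noise presence/absence calls per organ
#'
#' A feature is called `spf_only` in an organ when its signal-to-noise ratio
#' (mean of detected raw intensities in that group and organ over the
#' per-mode noise floor) exceeds 5 in SPF and stays below 5 in GF, and the
#' organ's differential result passes `q < 0.05` with `d < -0.8` (GF minus
#' SPF); `gf_only` is the mirror image. Features detected above threshold in
#' both groups -- or with an exclusive SNR pattern that fails the
#' significance thresholds -- are `both`; features under threshold in both
#' groups are `neither`. SNR is computed on the raw (pre-imputation)
#' intensities; a group with no detected values gets SNR 0.
#'
#' @param raw_table pre-imputation `FeatureTable` (QCs allowed, ignored).
#' @param diff output of [differential_all_organs()] on the imputed table.
#' @param noise_floor positive per-mode noise floor, either a single number
#'   or a named vector by mode; `NULL` estimates it per mode as the 1st
#'   percentile of detected intensities.
#' @param snr_threshold the calling threshold (5).
#' @return data.frame: `feature_id`, `organ`, `snr_spf`, `snr_gf`, `call`.
#' @export
call_presence <- function(raw_table, diff, noise_floor = NULL,
                          snr_threshold = 5) {
  inj <- raw_table$injections
  m <- raw_table$intensities
  feats <- raw_table$features
  if (is.null(noise_floor)) {
    noise_floor <- vapply(split(seq_len(nrow(feats)), feats$mode),
                          function(ix) {
      stats::quantile(m[ix, , drop = FALSE], 0.01, na.rm = TRUE, names = FALSE)
    }, numeric(1))
  }
  nf <- if (length(noise_floor) == 1 && is.null(names(noise_floor))) {
    stats::setNames(rep(noise_floor, length(unique(feats$mode))),
                    unique(feats$mode))
  } else noise_floor
  if (any(nf <= 0)) stop("noise_floor must be positive")
  floor_i <- nf[feats$mode]

  snr_of <- function(group, organ) {
    sel <- inj$sample_type == "biological" & inj$group == group &
      inj$organ == organ
    sub <- m[, sel, drop = FALSE]
    mu <- rowMeans(sub, na.rm = TRUE)
    mu[is.nan(mu)] <- 0                     # undetected everywhere => SNR 0
    mu / floor_i
  }
  out <- lapply(unique(diff$organ), function(o) {
    s_spf <- snr_of("SPF", o)
    s_gf <- snr_of("GF", o)
    d0 <- diff[diff$organ == o, ]
    idx <- match(feats$feature_id, d0$feature_id)
    qv <- d0$q[idx]; dv <- d0$cohens_d[idx]
    spf_only <- s_spf > snr_threshold & s_gf < snr_threshold &
      !is.na(qv) & qv < 0.05 & !is.na(dv) & dv < -0.8
    gf_only <- s_gf > snr_threshold & s_spf < snr_threshold &
      !is.na(qv) & qv < 0.05 & !is.na(dv) & dv > 0.8
    call <- ifelse(spf_only, "spf_only",
            ifelse(gf_only, "gf_only",
            ifelse(s_spf < snr_threshold & s_gf < snr_threshold,
                   "neither", "both")))
    data.frame(feature_id = feats$feature_id, organ = o,
               snr_spf = s_spf, snr_gf = s_gf, call = call,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Organ-wise Venn partition of differential features
#'
#' Per feature, the exact set of organs where it is SPF-higher and where it
#' is GF-higher (a feature can contribute to both diagrams), plus per-cell
#' counts for the seven non-empty Venn cells of each direction and the
#' "at least one organ" margins. When presence calls are supplied, the same
#' partition is built for `spf_only` / `gf_only` exclusivity calls.
#'
#' @param diff output of [differential_all_organs()].
#' @param presence optional output of [call_presence()].
#' @param organs the organ universe (fixes cell ordering).
#' @return list with `assignments` (per feature: comma-joined `spf_organs`,
#'   `gf_organs`), `spf_counts`/`gf_counts` (named 7-cell count vectors),
#'   `spf_margin`/`gf_margin`, and when presence is given,
#'   `exclusive_assignments`, `spf_only_counts`, `gf_only_counts` and their
#'   margins.
#' @export
venn_partition <- function(diff, presence = NULL, organs = VALID_ORGANS) {
  cells <- unlist(lapply(seq_along(organs), function(k)
    utils::combn(organs, k, paste, collapse = ",", simplify = FALSE)))
  org_sets <- function(df, col, value) {
    hit <- df[df[[col]] == value, c("feature_id", "organ")]
    sp <- split(hit$organ, hit$feature_id)
    vapply(sp, function(o) paste(organs[sort(match(o, organs))],
                                 collapse = ","), character(1))
  }
  count_cells <- function(sets) {
    cnt <- stats::setNames(integer(length(cells)), cells)
    tb <- table(sets)
    cnt[names(tb)] <- as.integer(tb)
    cnt
  }
  spf_sets <- org_sets(diff, "direction", "spf_higher")
  gf_sets <- org_sets(diff, "direction", "gf_higher")
  fids <- unique(diff$feature_id)
  assignments <- data.frame(
    feature_id = fids,
    spf_organs = unname(spf_sets[match(fids, names(spf_sets))]),
    gf_organs = unname(gf_sets[match(fids, names(gf_sets))]),
    stringsAsFactors = FALSE
  )
  assignments$spf_organs[is.na(assignments$spf_organs)] <- ""
  assignments$gf_organs[is.na(assignments$gf_organs)] <- ""
  res <- list(assignments = assignments,
              spf_counts = count_cells(spf_sets),
              gf_counts = count_cells(gf_sets),
              spf_margin = length(spf_sets),
              gf_margin = length(gf_sets))
  if (!is.null(presence)) {
    so <- org_sets(presence, "call", "spf_only")
    go <- org_sets(presence, "call", "gf_only")
    res$exclusive_assignments <- data.frame(
      feature_id = union(names(so), names(go)),
      stringsAsFactors = FALSE
    )
    res$exclusive_assignments$spf_only_organs <-
      unname(so[match(res$exclusive_assignments$feature_id, names(so))])
    res$exclusive_assignments$gf_only_organs <-
      unname(go[match(res$exclusive_assignments$feature_id, names(go))])
    res$spf_only_counts <- count_cells(so)
    res$gf_only_counts <- count_cells(go)
    res$spf_only_margin <- length(so)
    res$gf_only_margin <- length(go)
  }
  res
}
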