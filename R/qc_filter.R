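#' Per-feature quality metrics from QC and biological injections
#'
#' Using detected (non-missing) values only, computes for each feature:
#' detection rates (fraction of QC injections detected; the best per-group
#' detection rate over biological injections; the overall detection rate),
#' the classic relative standard deviation of the QC intensities
#' `sd(QC)/mean(QC)`, its non-parametric version
#' `RSD* = 1.4826 * MAD(QC) / median(QC)`, and the spread of the QC
#' injections relative to the biological ones: `D-ratio = sd(QC)/sd(bio)`
#' and `D-ratio* = MAD(QC)/MAD(bio)` (raw MADs; the consistency constant
#' cancels in the ratio). Metrics that need at least two detected values are
#' reported as missing with reason code `insufficient_qc` /
#' `insufficient_bio`.
#'
#' @param table a `FeatureTable` for one analytical mode, containing both QC
#'   and biological injections.
#' @return data.frame with one row per feature: `feature_id`,
#'   `qc_detection_rate`, `best_group_detection_rate`,
#'   `overall_detection_rate`, `rsd_classic`, `rsd_star`, `d_ratio`,
#'   `d_ratio_star`, `reason_codes` (metric-availability codes only; the
#'   keep decision is [apply_cleanup()]'s).
#' @export
compute_quality_metrics <- function(table) {
  inj <- table$injections
  qc_idx <- inj$sample_type == "qc"
  bio_idx <- inj$sample_type == "biological"
  if (!any(qc_idx)) stop("no QC injections in table")
  m <- table$intensities
  groups <- unique(inj$group[bio_idx])

  one <- function(i) {
    q <- m[i, qc_idx]
    b <- m[i, bio_idx]
    qd <- q[!is.na(q)]
    bd <- b[!is.na(b)]
    grp_rates <- vapply(groups, function(g) {
      gi <- bio_idx & inj$group == g
      mean(!is.na(m[i, gi]))
    }, numeric(1))
    codes <- character(0)
    rsd_c <- rsd_s <- dr <- drs <- NA_real_
    if (length(qd) >= 2) {
      rsd_c <- stats::sd(qd) / mean(qd)
      rsd_s <- 1.4826 * stats::mad(qd, constant = 1) / stats::median(qd)
    } else codes <- c(codes, "insufficient_qc")
    if (length(bd) >= 2 && length(qd) >= 2) {
      sb <- stats::sd(bd)
      mb <- stats::mad(bd, constant = 1)
      dr <- if (sb > 0) stats::sd(qd) / sb else NA_real_
      drs <- if (mb > 0) stats::mad(qd, constant = 1) / mb else NA_real_
      if (sb == 0 || mb == 0) codes <- c(codes, "zero_bio_dispersion")
    } else if (length(bd) < 2) codes <- c(codes, "insufficient_bio")
    data.frame(
      feature_id = table$features$feature_id[i],
      qc_detection_rate = mean(!is.na(q)),
      best_group_detection_rate = if (length(grp_rates)) max(grp_rates) else 0,
      overall_detection_rate = mean(!is.na(m[i, ])),
      rsd_classic = rsd_c, rsd_star = rsd_s,
      d_ratio = dr, d_ratio_star = drs,
      reason_codes = paste(codes, collapse = ","),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, lapply(seq_len(nrow(m)), one))
  rownames(out) <- NULL
  out
}

#' Default cleanup thresholds
#'
#' Detection: QC detection rate strictly above 0.70; detection at or above
#' 0.60 in at least one study group; overall detection at or above 0.50 (the
#' separately listed "low number of missing values" criterion, quantified
#' here as a mild explicit default). Dispersion: RSD* below 0.20 and
#' D-ratio* below 0.10; rescue clause: a feature failing dispersion is still
#' kept if classic RSD, RSD* and basic D-ratio are all below 0.10.
#'
#' @return a named list of thresholds.
#' @export
default_cleanup_thresholds <- function() {
  list(qc_detection = 0.70, group_detection = 0.60, overall_detection = 0.50,
       rsd_star = 0.20, d_ratio_star = 0.10, rescue = 0.10)
}

#' Apply the feature-cleanup decision rule
#'
#' A feature is kept iff all detection criteria pass and either the starred
#' dispersion criteria pass (`rsd_star < 0.20` and `d_ratio_star < 0.10`) or
#' the rescue clause does (`rsd_classic`, `rsd_star` and `d_ratio` all below
#' 0.10). Missing metrics fail their criterion. Flagged features are
#' excluded from statistical analyses but retained for raw-signal
#' presence/absence lookups.
#'
#' @param metrics output of [compute_quality_metrics()].
#' @param thresholds see [default_cleanup_thresholds()].
#' @return list with `kept` and `flagged` feature-id vectors and `metrics`,
#'   the input augmented with `kept` and failure `reason_codes`.
#' @export
apply_cleanup <- function(metrics, thresholds = default_cleanup_thresholds()) {
  th <- thresholds
  gt <- function(x, t) !is.na(x) & x > t
  ge <- function(x, t) !is.na(x) & x >= t
  lt <- function(x, t) !is.na(x) & x < t

  det_qc <- gt(metrics$qc_detection_rate, th$qc_detection)
  det_grp <- ge(metrics$best_group_detection_rate, th$group_detection)
  det_all <- ge(metrics$overall_detection_rate, th$overall_detection)
  disp <- lt(metrics$rsd_star, th$rsd_star) &
    lt(metrics$d_ratio_star, th$d_ratio_star)
  rescue <- lt(metrics$rsd_classic, th$rescue) &
    lt(metrics$rsd_star, th$rescue) &
    lt(metrics$d_ratio, th$rescue)
  kept <- det_qc & det_grp & det_all & (disp | rescue)

  reasons <- mapply(function(k, a, b, c, d, r, base) {
    if (k) return(base)
    rc <- c(if (!a) "qc_detection", if (!b) "group_detection",
            if (!c) "overall_detection", if (!d && !r) "dispersion")
    paste(c(if (nzchar(base)) base, rc), collapse = ",")
  }, kept, det_qc, det_grp, det_all, disp, rescue, metrics$reason_codes)

  metrics$kept <- kept
  metrics$reason_codes <- unname(reasons)
  list(kept = metrics$feature_id[kept],
       flagged = metrics$feature_id[!kept],
       metrics = metrics)
}
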