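#' QC-anchored injection-order drift correction
#'
#' For each feature, fits a cubic smoothing spline (smoothness chosen by
#' generalized cross-validation) to the log intensities of the detected QC
#' injections against injection order, and divides all intensities by
#' `exp(ghat(order) - ghat(order_ref))` where `order_ref` is the first QC's
#' order. With fewer than 4 detected QC values the fit falls back to a
#' least-squares line; with fewer than 2 no correction is attempted. The
#' correction is applied only if it strictly reduces the feature's QC
#' classic RSD (the gate), so applied corrections never make the QCs worse;
#' set `gate = FALSE` to always apply. Missing values stay missing.
#'
#' @param table a `FeatureTable` with QC injections.
#' @param gate apply a correction only when it strictly improves QC RSD.
#' @return list with `table` (corrected) and `models`, a data.frame per
#'   feature: `method` (`"spline"`, `"linear"`, `"none"`), `qc_rsd_before`,
#'   `qc_rsd_after`, `applied`.
#' @export
correct_drift <- function(table, gate = TRUE) {
  inj <- table$injections
  qc_idx <- which(inj$sample_type == "qc")
  if (!length(qc_idx)) stop("no QC injections in table")
  orders <- inj$injection_order
  m <- table$intensities
  out <- m
  models <- vector("list", nrow(m))
  for (i in seq_len(nrow(m))) {
    q <- m[i, qc_idx]
    det <- !is.na(q)
    xq <- orders[qc_idx][det]
    yq <- log(q[det])
    rsd_before <- if (sum(det) >= 2) stats::sd(q[det]) / mean(q[det]) else NA_real_
    method <- "none"; applied <- FALSE; rsd_after <- rsd_before
    if (sum(det) >= 2) {
      yq <- yq - mean(yq)   # center: correction uses ghat differences only,
                            # and this makes it exactly scale-equivariant
      ghat <- NULL
      if (sum(det) >= 4) {
        fit <- try(stats::smooth.spline(xq, yq, cv = FALSE), silent = TRUE)
        if (!inherits(fit, "try-error")) {
          ghat <- function(x) stats::predict(fit, x)$y
          method <- "spline"
        }
      }
      if (is.null(ghat)) {
        fit <- stats::lm(yq ~ xq)
        ghat <- function(x) unname(cbind(1, x) %*% stats::coef(fit))[, 1]
        method <- "linear"
      }
      ref <- min(orders[qc_idx])
      corr <- exp(ghat(orders) - ghat(ref))
      cand <- m[i, ] / corr
      qa <- cand[qc_idx][det]
      rsd_cand <- stats::sd(qa) / mean(qa)
      if (!gate || (is.finite(rsd_cand) && rsd_cand < rsd_before)) {
        out[i, ] <- cand
        applied <- TRUE
        rsd_after <- rsd_cand
      } else {
        method <- "none"
      }
    }
    models[[i]] <- data.frame(
      feature_id = table$features$feature_id[i], method = method,
      qc_rsd_before = rsd_before, qc_rsd_after = rsd_after,
      applied = applied, stringsAsFactors = FALSE
    )
  }
  table$intensities <- out
  list(table = table, models = do.call(rbind, models))
}

#' Iterative random-forest imputation of missing intensities
#'
#' missForest-style imputation on the merged, cleaned table: QC injections
#' are removed first (enforced -- they would bias the procedure), missing
#' cells are initialized at half the feature's minimum detected intensity
#' (detection-limit missingness makes a low start the right prior), then
#' features are visited in order of increasing missingness and each is
#' regressed on all others with a random forest, iterating until the total
#' squared change in the imputed cells rises or `max_iter` is reached.
#' Observed values are never altered. Runs on the log scale by default.
#'
#' @param table a merged `FeatureTable` (modes combined).
#' @param seed integer seed; fixed seed gives identical imputed values.
#' @param num_trees trees per forest.
#' @param max_iter iteration cap.
#' @param log_scale impute log intensities (default) or raw.
#' @return list with `table` (complete), `oob_error` (mean normalized OOB
#'   MSE -- OOB MSE over the feature's observed variance -- across imputed
#'   features; `NA` when nothing was missing) and `n_imputed` cells.
#' @export
impute_rf <- function(table, seed = 1, num_trees = 100, max_iter = 10,
                      log_scale = TRUE) {
  if (any(table$injections$sample_type == "qc")) {
    message("impute_rf: removing ", sum(table$injections$sample_type == "qc"),
            " QC injections before imputation")
    table <- ft_drop_qc(table)
  }
  raw <- table$intensities
  all_miss <- rowSums(!is.na(raw)) == 0
  if (any(all_miss)) {
    stop("feature(s) missing in all biological injections: ",
         paste(utils::head(table$features$feature_id[all_miss], 5),
               collapse = ", "),
         " -- such features cannot survive the detection criteria; run cleanup first")
  }
  miss <- is.na(raw)
  if (!any(miss)) {
    return(list(table = table, oob_error = NA_real_, n_imputed = 0L))
  }
  X <- t(if (log_scale) log(raw) else raw)   # samples x features
  Xmiss <- is.na(X)
  # half-minimum start
  for (j in seq_len(ncol(X))) {
    if (any(Xmiss[, j])) {
      mn <- min(X[!Xmiss[, j], j])
      X[Xmiss[, j], j] <- if (log_scale) mn + log(0.5) else mn / 2
    }
  }
  n_miss_per_feat <- colSums(Xmiss)
  todo <- order(n_miss_per_feat)
  todo <- todo[n_miss_per_feat[todo] > 0]
  set.seed(seed)
  prev_change <- Inf
  oob <- rep(NA_real_, ncol(X))
  X_prev <- X
  for (it in seq_len(max_iter)) {
    for (j in todo) {
      obs <- !Xmiss[, j]
      fit <- ranger::ranger(
        x = X[obs, -j, drop = FALSE], y = X[obs, j],
        num.trees = num_trees, num.threads = 1,
        seed = seed + 1000L * it + j, verbose = FALSE
      )
      X[!obs, j] <- stats::predict(fit, X[!obs, -j, drop = FALSE],
                                   num.threads = 1)$predictions
      v <- stats::var(X[obs, j])
      oob[j] <- if (v > 0) fit$prediction.error / v else NA_real_
    }
    change <- sum((X[Xmiss] - X_prev[Xmiss])^2) / max(sum(X[Xmiss]^2), 1e-12)
    if (it > 1 && change >= prev_change) {
      X <- X_prev                       # keep the last improving iterate
      break
    }
    prev_change <- change
    X_prev <- X
  }
  filled <- t(if (log_scale) exp(X) else X)
  out <- raw
  out[miss] <- filled[miss]            # observed cells preserved exactly
  table$intensities <- out
  list(table = table,
       oob_error = mean(oob[todo], na.rm = TRUE),
       n_imputed = sum(miss))
}
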