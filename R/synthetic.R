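#' Configuration for the synthetic study generator
#'
#' Encodes the study design being emulated: two maternal-microbiota groups
#' (GF, SPF) of 6 dams each with 2 fetuses per dam (12 fetuses per group,
#' 7 male / 5 female), three organs per fetus (brain, intestine, placenta),
#' four analytical modes, pooled-QC injections interleaved by injection
#' order, multiplicative injection-order drift, intensity-dependent
#' missingness, and planted per-feature effects of five classes (null,
#' SPF-higher, GF-higher, SPF-exclusive, GF-exclusive).
#'
#' @param n_features_per_mode features simulated per analytical mode. The
#'   default 1500 (about 6000 over four modes) is a desk-scale stand-in for a
#'   cleaned real table roughly twice that size.
#' @param modes analytical modes to simulate.
#' @param n_dams_per_group,n_fetuses_per_dam,organs the nested design.
#' @param n_sex_split integer vector `c(M=, F=)` fetus sexes per group.
#' @param n_qc pooled-QC injections per mode, interleaved evenly.
#' @param drift_amplitude relative amplitude of the smooth multiplicative
#'   injection-order drift (0 disables it); `drift_type` one of
#'   `"polynomial"`, `"linear"`, `"sinusoidal"`.
#' @param noise_floor per-mode raw-intensity noise floor used both by the
#'   detection model and as the SNR denominator for exclusivity calls.
#' @param detection_midpoint,detection_steepness logistic detection model:
#'   a cell of log-intensity `L` is detected with probability
#'   `plogis(detection_steepness * (L - detection_midpoint))`. The midpoint
#'   defaults to the log noise floor: a signal at the floor has even odds
#'   of detection, anchoring the missingness model and the SNR denominator
#'   to the same per-mode constant.
#' @param effect_classes named proportions of `spf_up`, `gf_up`,
#'   `spf_exclusive`, `gf_exclusive` features (remainder null; sum must be
#'   at most 1).
#' @param effect_size_log2 planted |log2 fold change| for the up/down
#'   classes (GF-minus-SPF sign convention; `spf_up` features get the
#'   negative sign).
#' @param qc_noise_cv,biological_cv coefficients of variation of the QC
#'   technical noise and the biological residual (QC < biological makes the
#'   D-ratio meaningful).
#' @param dam_sd SD of the per-feature dam-level random intercept (log
#'   scale): the two fetuses of a dam share it within each feature,
#'   modelling the litter nesting.
#' @param organ_sd SD of per-feature per-organ offsets (log scale); gives
#'   organs distinct profiles.
#' @param baseline_log_mean,baseline_log_sd distribution of per-feature
#'   baseline log intensities.
#' @param exclusive_present_snr,exclusive_absent_snr target signal-to-noise
#'   (multiples of `noise_floor`) of exclusive features in the group where
#'   they are present / absent; must clear / stay under the calling
#'   threshold of 5. The absent level defaults to the noise floor itself,
#'   so absent-group cells are mostly-but-not-entirely missing -- the
#'   detection-limit behaviour real exclusive features show.
#' @param seed integer seed; a fixed seed yields byte-identical output.
#' @return a `SyntheticConfig` list.
#' @export
synthetic_config <- function(n_features_per_mode = 1500,
                             modes = VALID_MODES,
                             n_dams_per_group = 6,
                             n_fetuses_per_dam = 2,
                             organs = VALID_ORGANS,
                             n_sex_split = c(M = 7, F = 5),
                             n_qc = 9,
                             drift_amplitude = 0.1,
                             drift_type = "polynomial",
                             noise_floor = 100,
                             detection_midpoint = log(noise_floor),
                             detection_steepness = 1.5,
                             effect_classes = c(spf_up = 0.15, gf_up = 0.10,
                                                spf_exclusive = 0.008,
                                                gf_exclusive = 0.001),
                             effect_size_log2 = 1.5,
                             qc_noise_cv = 0.05,
                             biological_cv = 0.5,
                             dam_sd = 0.1,
                             organ_sd = 0.5,
                             baseline_log_mean = log(5000),
                             baseline_log_sd = 0.8,
                             exclusive_present_snr = 20,
                             exclusive_absent_snr = 1,
                             seed = 1) {
  cfg <- as.list(environment())
  class(cfg) <- "SyntheticConfig"
  validate_synthetic_config(cfg)
  cfg
}

validate_synthetic_config <- function(cfg) {
  if (sum(cfg$effect_classes) > 1 + 1e-12) {
    stop("effect-class proportions must sum to at most 1")
  }
  bad <- setdiff(names(cfg$effect_classes),
                 c("spf_up", "gf_up", "spf_exclusive", "gf_exclusive"))
  if (length(bad)) stop("unknown effect class: ", paste(bad, collapse = ", "))
  if (cfg$qc_noise_cv <= 0 || cfg$biological_cv <= 0) stop("CVs must be > 0")
  if (cfg$noise_floor <= 0) stop("noise_floor must be > 0")
  has_excl <- any(cfg$effect_classes[c("spf_exclusive", "gf_exclusive")] > 0,
                  na.rm = TRUE)
  if (has_excl &&
      (cfg$exclusive_present_snr <= 5 || cfg$exclusive_absent_snr >= 5)) {
    stop("infeasible config: exclusive effect size too small to clear the ",
         "SNR threshold of 5 (present SNR must exceed 5, absent SNR stay below)")
  }
  sum_fet <- sum(cfg$n_sex_split)
  if (sum_fet != cfg$n_dams_per_group * cfg$n_fetuses_per_dam) {
    stop("n_sex_split must sum to n_dams_per_group * n_fetuses_per_dam")
  }
  invisible(cfg)
}

cv_to_sdlog <- function(cv) sqrt(log(1 + cv^2))

#' Planted log2 effect for a target Cohen's d
#'
#' Converts a target standardized mean difference on the log scale into the
#' log2 effect the generator should plant, given the config's within-group
#' log-scale variance (biological CV plus dam intercept).
#'
#' @param config a `SyntheticConfig`.
#' @param d target |Cohen's d|.
#' @return the |log2 fold change| to pass as `effect_size_log2`.
#' @export
planted_effect_log2 <- function(config, d) {
  sd_tot <- sqrt(cv_to_sdlog(config$biological_cv)^2 + config$dam_sd^2)
  d * sd_tot / log(2)
}

# smooth positive drift multiplier g(order) for one feature
drift_multipliers <- function(row, orders) {
  a <- row$amplitude
  if (a == 0) return(rep(1, length(orders)))
  if (row$type == "linear") {
    g <- 1 + row$p1 * orders
  } else if (row$type == "sinusoidal") {
    g <- 1 + a * sin(2 * pi * orders / row$p1 + row$p2)
  } else if (row$type == "polynomial") {
    t <- (orders - min(orders)) / max(1, diff(range(orders)))
    h <- row$p1 * t + row$p2 * t^2
    h <- h - mean(h)
    mx <- max(abs(h))
    g <- if (mx > 0) 1 + a * h / mx else rep(1, length(orders))
  } else {
    stop("unknown drift type: ", row$type)
  }
  g
}

#' Multiply a table by per-feature injection-order drift curves
#'
#' Creates the condition that QC-anchored drift correction is meant to
#' remove: each feature's intensities are multiplied by a smooth positive
#' function of injection order. Missingness is untouched.
#'
#' @param table a `FeatureTable`.
#' @param drift_params data.frame with `feature_id`, `type`
#'   (`"polynomial"`, `"linear"`, `"sinusoidal"`), `amplitude`, `p1`, `p2`.
#'   Linear: `g = 1 + p1 * order`. Sinusoidal: `g = 1 + amplitude *
#'   sin(2*pi*order/p1 + p2)`. Polynomial: quadratic in rescaled order,
#'   centred and scaled into `[1 - amplitude, 1 + amplitude]`.
#' @return the drifted `FeatureTable`.
#' @export
inject_drift <- function(table, drift_params) {
  orders <- table$injections$injection_order
  m <- table$intensities
  idx <- match(table$features$feature_id, drift_params$feature_id)
  if (any(is.na(idx))) stop("drift_params missing features")
  for (i in seq_len(nrow(m))) {
    g <- drift_multipliers(drift_params[idx[i], ], orders)
    if (any(g <= 0)) {
      stop("drift multiplier non-positive for feature ",
           table$features$feature_id[i])
    }
    m[i, ] <- m[i, ] * g
  }
  table$intensities <- m
  table
}

#' Generate a synthetic study dataset with known ground truth
#'
#' Simulates the full design of [synthetic_config()]: log-normal biological
#' intensities with dam intercepts, per-organ offsets and planted group
#' effects; pooled-QC injections equal to the per-feature mean of the
#' biological log intensities plus technical noise; multiplicative
#' injection-order drift; and logistic intensity-dependent detection
#' (low-intensity cells go missing more often). Exclusive-class features are
#' placed at `exclusive_present_snr` times the noise floor in the group
#' where they are present and `exclusive_absent_snr` times it where absent,
#' so the SNR-based exclusivity rule holds by construction.
#'
#' @param config a `SyntheticConfig`.
#' @return a list with `tables` (named list of per-mode `FeatureTable`s,
#'   sharing one injection layout so they can be merged), `truth`
#'   (data.frame: `feature_id`, `mode`, `effect_class`, `affected_organs`
#'   comma-separated, `log2_effect` with GF-minus-SPF sign,
#'   `baseline_log_mean`), `drift` (per-feature drift parameters usable with
#'   [inject_drift()]), `samples` (the biological sample sheet) and
#'   `noise_floor`.
#' @export
generate_dataset <- function(config) {
  validate_synthetic_config(config)
  cfg <- config
  set.seed(cfg$seed)

  # --- sample sheet: groups x dams x fetuses x organs -----------------------
  samples <- do.call(rbind, lapply(VALID_GROUPS, function(g) {
    fet <- expand.grid(dam = seq_len(cfg$n_dams_per_group),
                       fetus = seq_len(cfg$n_fetuses_per_dam))
    fet <- fet[order(fet$dam, fet$fetus), ]
    sexes <- rep(names(cfg$n_sex_split), cfg$n_sex_split)
    fet$sex <- sample(sexes)          # which fetuses are male is random
    do.call(rbind, lapply(seq_len(nrow(fet)), function(i) {
      data.frame(group = g,
                 dam_id = sprintf("%s_dam%d", g, fet$dam[i]),
                 fetus = sprintf("%s_d%d_f%d", g, fet$dam[i], fet$fetus[i]),
                 fetus_sex = fet$sex[i],
                 organ = cfg$organs,
                 stringsAsFactors = FALSE)
    }))
  }))
  samples$injection_id <- paste(samples$fetus, samples$organ, sep = "_")
  n_bio <- nrow(samples)

  # one injection layout shared by all modes (same aliquots run per mode)
  n_total <- n_bio + cfg$n_qc
  qc_pos <- unique(round(seq(1, n_total, length.out = cfg$n_qc)))
  bio_pos <- setdiff(seq_len(n_total), qc_pos)
  bio_order <- sample(n_bio)           # randomized run order
  injections <- data.frame(
    injection_id = character(n_total), injection_order = seq_len(n_total),
    sample_type = "biological", group = NA_character_, organ = NA_character_,
    dam_id = NA_character_, fetus_sex = NA_character_,
    stringsAsFactors = FALSE
  )
  injections$sample_type[qc_pos] <- "qc"
  injections$injection_id[qc_pos] <- sprintf("QC_%02d", seq_along(qc_pos))
  ord_samples <- samples[bio_order, ]
  injections$injection_id[bio_pos] <- ord_samples$injection_id
  injections$group[bio_pos] <- ord_samples$group
  injections$organ[bio_pos] <- ord_samples$organ
  injections$dam_id[bio_pos] <- ord_samples$dam_id
  injections$fetus_sex[bio_pos] <- ord_samples$fetus_sex

  dam_ids <- unique(samples$dam_id)
  sd_bio <- cv_to_sdlog(cfg$biological_cv)
  sd_qc <- cv_to_sdlog(cfg$qc_noise_cv)
  classes <- c("null", names(cfg$effect_classes))
  probs <- c(1 - sum(cfg$effect_classes), cfg$effect_classes)
  organ_subsets <- unlist(lapply(seq_along(cfg$organs), function(k) {
    utils::combn(cfg$organs, k, paste, collapse = ",", simplify = FALSE)
  }))

  tables <- list()
  truth_all <- list()
  drift_all <- list()
  for (mode in cfg$modes) {
    nf <- cfg$n_features_per_mode
    fid <- sprintf("%s_%04d", mode, seq_len(nf))
    eclass <- sample(classes, nf, replace = TRUE, prob = probs)
    aff <- ifelse(eclass == "null", "",
                  unlist(sample(organ_subsets, nf, replace = TRUE)))
    base <- stats::rnorm(nf, cfg$baseline_log_mean, cfg$baseline_log_sd)
    present_log <- log(cfg$noise_floor * cfg$exclusive_present_snr)
    absent_log <- log(cfg$noise_floor * cfg$exclusive_absent_snr)
    excl <- eclass %in% c("spf_exclusive", "gf_exclusive")
    base[excl] <- pmax(base[excl], present_log)
    l2e <- numeric(nf)
    l2e[eclass == "gf_up"] <- cfg$effect_size_log2
    l2e[eclass == "spf_up"] <- -cfg$effect_size_log2
    l2e[eclass == "gf_exclusive"] <- (base[eclass == "gf_exclusive"] - absent_log) / log(2)
    l2e[eclass == "spf_exclusive"] <- -(base[eclass == "spf_exclusive"] - absent_log) / log(2)
    organ_off <- matrix(stats::rnorm(nf * length(cfg$organs), 0, cfg$organ_sd),
                        nf, length(cfg$organs),
                        dimnames = list(NULL, cfg$organs))
    # per-feature dam intercepts: fetuses nested in dams share them within a
    # feature, but they average out across features (no global group shift)
    dam_eff <- matrix(stats::rnorm(nf * length(dam_ids), 0, cfg$dam_sd),
                      nf, length(dam_ids), dimnames = list(NULL, dam_ids))

    # biological log intensities
    logm <- matrix(NA_real_, nf, n_total,
                   dimnames = list(fid, injections$injection_id))
    bio_cols <- which(injections$sample_type == "biological")
    for (j in bio_cols) {
      g <- injections$group[j]; o <- injections$organ[j]
      mu <- base + organ_off[, o] + dam_eff[, injections$dam_id[j]]
      hit <- aff != "" & vapply(strsplit(aff, ","), function(s) o %in% s,
                                logical(1))
      up_g <- hit & ((eclass == "gf_up" & g == "GF") |
                     (eclass == "spf_up" & g == "SPF"))
      mu[up_g] <- mu[up_g] + cfg$effect_size_log2 * log(2)
      ab <- hit & ((eclass == "gf_exclusive" & g == "SPF") |
                   (eclass == "spf_exclusive" & g == "GF"))
      mu[ab] <- absent_log
      logm[, j] <- mu + stats::rnorm(nf, 0, sd_bio)
    }
    # pooled QC: per-feature mean of biological log intensities + tech noise
    qc_base <- rowMeans(logm[, bio_cols, drop = FALSE])
    for (j in which(injections$sample_type == "qc")) {
      logm[, j] <- qc_base + stats::rnorm(nf, 0, sd_qc)
    }
    intens <- exp(logm)

    # smooth multiplicative drift, then logistic detection
    drift <- data.frame(feature_id = fid, mode = mode, type = cfg$drift_type,
                        amplitude = cfg$drift_amplitude,
                        p1 = stats::rnorm(nf), p2 = stats::rnorm(nf),
                        stringsAsFactors = FALSE)
    if (cfg$drift_type == "sinusoidal") {
      drift$p1 <- stats::runif(nf, n_total / 2, n_total)  # period
      drift$p2 <- stats::runif(nf, 0, 2 * pi)             # phase
    }
    feats <- data.frame(feature_id = fid, mode = mode,
                        mz = stats::runif(nf, 50, 1500),
                        rt = stats::runif(nf, 0.5, 15),
                        stringsAsFactors = FALSE)
    tab <- feature_table(intens, feats, injections)
    if (cfg$drift_amplitude > 0) tab <- inject_drift(tab, drift)
    det_p <- stats::plogis(cfg$detection_steepness *
                             (log(tab$intensities) - cfg$detection_midpoint))
    miss <- matrix(stats::runif(length(det_p)) > det_p, nrow = nf)
    tab$intensities[miss] <- NA_real_

    tables[[mode]] <- tab
    truth_all[[mode]] <- data.frame(
      feature_id = fid, mode = mode, effect_class = eclass,
      affected_organs = aff, log2_effect = l2e, baseline_log_mean = base,
      stringsAsFactors = FALSE
    )
    drift_all[[mode]] <- drift
  }

  list(tables = tables,
       truth = do.call(rbind, truth_all),
       drift = do.call(rbind, drift_all),
       samples = samples,
       noise_floor = cfg$noise_floor,
       config = cfg)
}
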