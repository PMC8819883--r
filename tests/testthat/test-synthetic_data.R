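test_that("generator is deterministic under a fixed seed", {
  cfg <- synthetic_config(n_features_per_mode = 40, modes = c("RP+", "RP-"),
                          seed = 5)
  a <- generate_dataset(cfg)
  b <- generate_dataset(cfg)
  expect_identical(a$tables, b$tables)
  expect_identical(a$truth, b$truth)
})

test_that("study design is emulated: dams, fetuses, sexes, organs, QCs", {
  ds <- small_dataset(n = 50)
  s <- ds$samples
  expect_identical(nrow(s), 2L * 12L * 3L)
  for (g in c("GF", "SPF")) {
    sg <- s[s$group == g, ]
    expect_identical(length(unique(sg$dam_id)), 6L)
    expect_identical(length(unique(sg$fetus)), 12L)
    sex <- unique(sg[c("fetus", "fetus_sex")])
    expect_identical(sum(sex$fetus_sex == "M"), 7L)
    expect_identical(sum(sex$fetus_sex == "F"), 5L)
  }
  inj <- ds$tables[[1]]$injections
  expect_identical(sum(inj$sample_type == "qc"), 9L)
  # QCs interleaved: no two QCs adjacent over an 81-injection run
  qc_ord <- sort(inj$injection_order[inj$sample_type == "qc"])
  expect_true(all(diff(qc_ord) >= 2))
})

test_that("all-null driftless generator controls raw type-I error near 0.05", {
  cfg <- synthetic_config(n_features_per_mode = 1500, modes = "RP+",
                          drift_amplitude = 0, effect_classes = c(spf_up = 0),
                          seed = 101)
  ds <- generate_dataset(cfg)
  tab <- ft_drop_qc(ds$tables[[1]])
  # complete-case analysis: baselines sit far above the detection midpoint
  tab$intensities[is.na(tab$intensities)] <-
    exp(cfg$detection_midpoint)  # rare low cells; value irrelevant at alpha
  res <- differential_test(tab, "brain")
  frac <- mean(res$p < 0.05, na.rm = TRUE)
  # binomial tolerance at n = 1500: 3 sd of sqrt(.05*.95/1500) ~ 0.017
  expect_lt(abs(frac - 0.05), 0.02)
})

test_that("group means recover planted log2 effects within Monte-Carlo error", {
  # detection midpoint far below baselines: no censoring, isolating the
  # planted-effect recovery from the (separately tested) missingness model
  cfg <- synthetic_config(n_features_per_mode = 400, modes = "RP+",
                          drift_amplitude = 0,
                          detection_midpoint = log(1e-6),
                          effect_classes = c(spf_up = 0.3, gf_up = 0.3),
                          effect_size_log2 = 1.5, seed = 77)
  ds <- generate_dataset(cfg)
  tab <- ft_drop_qc(ds$tables[[1]])
  tr <- ds$truth
  inj <- tab$injections
  est <- vapply(seq_len(nrow(tr)), function(i) {
    orgs <- strsplit(tr$affected_organs[i], ",")[[1]]
    if (!length(orgs)) return(NA_real_)
    o <- orgs[1]
    gf <- inj$group == "GF" & inj$organ == o
    spf <- inj$group == "SPF" & inj$organ == o
    v <- log2(tab$intensities[i, ])
    mean(v[gf], na.rm = TRUE) - mean(v[spf], na.rm = TRUE)
  }, numeric(1))
  up <- tr$effect_class %in% c("spf_up", "gf_up")
  bias <- mean(est[up] - tr$log2_effect[up], na.rm = TRUE)
  # per-feature SE ~ sd_log2 * sqrt(2/12) ~ 0.28; mean over ~240 features
  expect_lt(abs(bias), 0.06)
})

test_that("exclusive features satisfy the SNR rule by construction", {
  cfg <- synthetic_config(n_features_per_mode = 300, modes = "RP+",
                          effect_classes = c(spf_exclusive = 0.1),
                          drift_amplitude = 0, seed = 13)
  ds <- generate_dataset(cfg)
  tab <- ds$tables[[1]]
  inj <- tab$injections
  tr <- ds$truth[ds$truth$effect_class == "spf_exclusive", ]
  expect_gt(nrow(tr), 15)
  for (i in seq_len(nrow(tr))) {
    row <- match(tr$feature_id[i], tab$features$feature_id)
    for (o in strsplit(tr$affected_organs[i], ",")[[1]]) {
      for (g in c("SPF", "GF")) {
        sel <- inj$sample_type == "biological" & inj$group == g &
          inj$organ == o
        v <- tab$intensities[row, sel]
        snr <- if (all(is.na(v))) 0 else mean(v, na.rm = TRUE) / ds$noise_floor
        if (g == "SPF") expect_gt(snr, 5) else expect_lt(snr, 5)
      }
    }
  }
})

test_that("infeasible exclusive configs error at generation time", {
  expect_error(
    synthetic_config(exclusive_present_snr = 3),
    "infeasible"
  )
  expect_error(
    synthetic_config(exclusive_absent_snr = 6),
    "infeasible"
  )
})

test_that("QC injections disperse less than biological ones", {
  ds <- small_dataset(n = 150)
  tab <- ds$tables[[1]]
  qc <- tab$injections$sample_type == "qc"
  rat <- apply(tab$intensities, 1, function(v) {
    q <- v[qc]; b <- v[!qc]
    if (sum(!is.na(q)) < 3 || sum(!is.na(b)) < 3) return(NA_real_)
    stats::sd(q, na.rm = TRUE) / stats::sd(b, na.rm = TRUE)
  })
  expect_gt(mean(rat < 1, na.rm = TRUE), 0.95)
})

test_that("inject_drift: identity at zero amplitude, monotone linear case, RSD increase", {
  tab <- tiny_table()
  dp0 <- data.frame(feature_id = c("F1", "F2", "F3"), type = "polynomial",
                    amplitude = 0, p1 = 1, p2 = -1, stringsAsFactors = FALSE)
  expect_identical(inject_drift(tab, dp0)$intensities, tab$intensities)

  # constant-valued feature under linear drift: strictly increasing in order
  inj <- tab$injections
  m <- matrix(100, 1, 6, dimnames = list("F1", inj$injection_id))
  one <- feature_table(m, tab$features[1, ], inj)
  dlin <- data.frame(feature_id = "F1", type = "linear", amplitude = 0.1,
                     p1 = 0.01, p2 = 0, stringsAsFactors = FALSE)
  drifted <- inject_drift(one, dlin)
  expect_true(all(diff(drifted$intensities[1, order(inj$injection_order)]) > 0))

  # drift raises QC classic RSD of a near-constant feature
  set.seed(1)
  qcv <- 100 * exp(rnorm(6, 0, 0.02))
  m2 <- matrix(qcv, 1, 6, dimnames = list("F1", inj$injection_id))
  inj2 <- inj; inj2$sample_type <- "qc"; inj2$group <- NA; inj2$organ <- NA
  one2 <- feature_table(m2, tab$features[1, ], inj2)
  rsd_before <- sd(qcv) / mean(qcv)
  dr <- inject_drift(one2, data.frame(feature_id = "F1", type = "linear",
                                      amplitude = 0.2, p1 = 0.05, p2 = 0))
  v <- dr$intensities[1, ]
  expect_gt(sd(v) / mean(v), rsd_before)

  # non-positive multiplier errors
  expect_error(inject_drift(one, data.frame(feature_id = "F1", type = "linear",
                                            amplitude = 1, p1 = -0.5, p2 = 0)),
               "non-positive")
})
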