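# helper: a one-feature table with specified QC and biological values
metrics_for <- function(qc, bio) {
  n <- length(qc) + length(bio)
  inj <- data.frame(
    injection_id = sprintf("i%02d", seq_len(n)),
    injection_order = seq_len(n),
    sample_type = c(rep("biological", length(bio)), rep("qc", length(qc))),
    group = c(rep(c("GF", "SPF"), length.out = length(bio)), rep(NA, length(qc))),
    organ = c(rep("brain", length(bio)), rep(NA, length(qc))),
    dam_id = NA, fetus_sex = NA, stringsAsFactors = FALSE
  )
  feats <- data.frame(feature_id = "F1", mode = "RP+", mz = 100, rt = 1)
  tab <- feature_table(matrix(c(bio, qc), 1), feats, inj)
  compute_quality_metrics(tab)
}

test_that("dispersion metric formulas match hand-derived values", {
  bio <- c(50, 80, 120, 160, 240, 400)
  m <- metrics_for(qc = c(90, 95, 100, 105, 110), bio = bio)
  # median 100, MAD 5 -> RSD* = 1.4826 * 5 / 100; sd = 7.9057 -> RSD = 0.0791
  expect_equal(m$rsd_star, 0.0741, tolerance = 1e-4 / 0.0741)
  expect_equal(m$rsd_classic, 0.0791, tolerance = 1e-4 / 0.0791)
  # cross-check against independent statistics routines
  expect_equal(m$rsd_classic, sd(c(90, 95, 100, 105, 110)) / 100,
               tolerance = 1e-12)
  expect_equal(m$rsd_star, mad(c(90, 95, 100, 105, 110)) / 100,
               tolerance = 1e-12)
  expect_equal(m$d_ratio, sd(c(90, 95, 100, 105, 110)) / sd(bio),
               tolerance = 1e-12)
  expect_equal(m$d_ratio_star,
               mad(c(90, 95, 100, 105, 110), constant = 1) /
                 mad(bio, constant = 1), tolerance = 1e-12)
})

test_that("zero-dispersion QC values give zero RSDs and known D-ratio", {
  m <- metrics_for(qc = rep(100, 5), bio = c(10, 50, 100, 150, 200, 300))
  expect_identical(m$rsd_classic, 0)
  expect_identical(m$rsd_star, 0)
  # QC sd 5 vs biological sd 50 -> D-ratio 0.10
  bio <- c(100, 150, 200)
  bio <- bio[c(1, 2, 3)]
  m2 <- metrics_for(qc = c(95, 100, 105), bio = c(50, 100, 150, 200))
  expect_equal(m2$d_ratio, sd(c(95, 100, 105)) / sd(c(50, 100, 150, 200)),
               tolerance = 1e-12)
})

test_that("detection rates count detected cells per QC, group and overall", {
  qc <- c(100, NA, 100, 100, NA)
  bio <- c(100, NA, 100, 100, 100, NA)   # groups alternate GF/SPF
  m <- metrics_for(qc, bio)
  expect_equal(m$qc_detection_rate, 3 / 5)
  # GF gets positions 1,3,5 -> all detected; SPF positions 2,4,6 -> 1/3
  expect_equal(m$best_group_detection_rate, 1)
  expect_equal(m$overall_detection_rate, 7 / 11)
})

test_that("cleanup boundary cases follow the stated rule and rescue clause", {
  base <- data.frame(feature_id = "F", qc_detection_rate = 0.9,
                     best_group_detection_rate = 0.9,
                     overall_detection_rate = 0.9,
                     rsd_classic = 0.05, rsd_star = 0.05,
                     d_ratio = 0.05, d_ratio_star = 0.05,
                     reason_codes = "", stringsAsFactors = FALSE)
  keep <- function(...) {
    m <- modifyList(base, list(...))
    apply_cleanup(as.data.frame(m, stringsAsFactors = FALSE))$metrics$kept
  }
  expect_true(keep())
  # rescue fails when rsd_star >= 0.10 even with excellent classic RSD
  expect_false(keep(rsd_star = 0.25, d_ratio_star = 0.12, rsd_classic = 0.08))
  # rescue saves a feature failing d_ratio_star when all three basics < 0.10
  expect_true(keep(rsd_star = 0.09, rsd_classic = 0.08, d_ratio = 0.09,
                   d_ratio_star = 0.15))
  # detection clause: "more than 70%" is strict
  expect_false(keep(qc_detection_rate = 0.65))
  expect_false(keep(qc_detection_rate = 0.70))
  expect_true(keep(qc_detection_rate = 0.71))
  # group detection is "at least 60%"
  expect_true(keep(best_group_detection_rate = 0.60))
  expect_false(keep(best_group_detection_rate = 0.59))
  # starred dispersion thresholds
  expect_false(keep(rsd_star = 0.20, rsd_classic = 0.15))
  expect_true(keep(rsd_star = 0.199))
  expect_false(keep(d_ratio_star = 0.10, d_ratio = 0.11))
  # missing metrics flag with a reason, never keep
  expect_false(keep(rsd_star = NA_real_, reason_codes = "insufficient_qc"))
})

test_that("apply_cleanup agrees with a brute-force oracle on random metrics", {
  set.seed(99)
  n <- 2000
  rnd <- function(vals) sample(vals, n, replace = TRUE)
  m <- data.frame(
    feature_id = sprintf("F%04d", seq_len(n)),
    qc_detection_rate = rnd(c(0.2, 0.6, 0.65, 0.70, 0.701, 0.75, 1)),
    best_group_detection_rate = rnd(c(0.3, 0.59, 0.60, 0.61, 1)),
    overall_detection_rate = rnd(c(0.2, 0.49, 0.50, 0.51, 1)),
    rsd_classic = rnd(c(0.01, 0.09, 0.0999, 0.10, 0.11, 0.3, NA)),
    rsd_star = rnd(c(0.01, 0.09, 0.10, 0.19, 0.20, 0.21, 0.5, NA)),
    d_ratio = rnd(c(0.01, 0.09, 0.10, 0.11, 0.4, NA)),
    d_ratio_star = rnd(c(0.01, 0.09, 0.0999, 0.10, 0.11, 0.4, NA)),
    reason_codes = "", stringsAsFactors = FALSE
  )
  got <- apply_cleanup(m)$metrics$kept
  want <- vapply(seq_len(n), function(i) {
    cleanup_oracle(m$qc_detection_rate[i], m$best_group_detection_rate[i],
                   m$overall_detection_rate[i], m$rsd_classic[i],
                   m$rsd_star[i], m$d_ratio[i], m$d_ratio_star[i])
  }, logical(1))
  expect_identical(got, want)
})

test_that("decreasing a dispersion metric never flips kept to flagged", {
  set.seed(7)
  base <- data.frame(
    feature_id = "F", qc_detection_rate = 0.9,
    best_group_detection_rate = 0.8, overall_detection_rate = 0.8,
    rsd_classic = runif(1, 0, 0.3), rsd_star = runif(1, 0, 0.3),
    d_ratio = runif(1, 0, 0.3), d_ratio_star = runif(1, 0, 0.3),
    reason_codes = "", stringsAsFactors = FALSE
  )
  for (rep in 1:200) {
    m <- base
    m$rsd_classic <- runif(1, 0, 0.3); m$rsd_star <- runif(1, 0, 0.3)
    m$d_ratio <- runif(1, 0, 0.3); m$d_ratio_star <- runif(1, 0, 0.3)
    before <- apply_cleanup(m)$metrics$kept
    col <- sample(c("rsd_classic", "rsd_star", "d_ratio", "d_ratio_star"), 1)
    m[[col]] <- m[[col]] * runif(1)
    after <- apply_cleanup(m)$metrics$kept
    expect_false(before && !after)
  }
})

test_that("most fully-detected null features survive cleanup under study noise", {
  cfg <- synthetic_config(n_features_per_mode = 500, modes = "RP+",
                          qc_noise_cv = 0.05, biological_cv = 0.5,
                          effect_classes = c(spf_up = 0), seed = 31)
  ds <- generate_dataset(cfg)
  tab <- correct_drift(ds$tables[[1]])$table
  cl <- apply_cleanup(compute_quality_metrics(tab))
  full <- rownames(tab$intensities)[rowSums(is.na(tab$intensities)) == 0]
  expect_gt(mean(full %in% cl$kept), 0.95)
})

test_that("a table without QC injections is a hard error", {
  tab <- ft_drop_qc(tiny_table())
  expect_error(compute_quality_metrics(tab), "no QC injections")
})
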