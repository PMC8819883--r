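# helper: FeatureTable from explicit per-group value matrices for one organ
two_group_table <- function(gf, spf, organ = "brain") {
  gf <- as.matrix(gf); spf <- as.matrix(spf)
  n1 <- ncol(gf); n2 <- ncol(spf)
  inj <- data.frame(
    injection_id = c(sprintf("g%d", 1:n1), sprintf("s%d", 1:n2)),
    injection_order = seq_len(n1 + n2), sample_type = "biological",
    group = c(rep("GF", n1), rep("SPF", n2)), organ = organ,
    dam_id = "d", fetus_sex = "M", stringsAsFactors = FALSE
  )
  nf <- nrow(gf)
  feats <- data.frame(feature_id = sprintf("F%d", seq_len(nf)), mode = "RP+",
                      mz = 100 + seq_len(nf), rt = 1, stringsAsFactors = FALSE)
  feature_table(cbind(gf, spf), feats, inj)
}

test_that("pooled t test and Cohen's d match hand-derived values", {
  # GF = (1,2,3), SPF = (4,5,6): means 2 and 5, pooled sd 1, d = -3
  tab <- two_group_table(exp(matrix(1:3, 1)), exp(matrix(4:6, 1)))
  res <- differential_test(tab, "brain")
  expect_equal(res$cohens_d, -3, tolerance = 1e-12)
  expect_equal(res$mean_gf, 2, tolerance = 1e-12)
  expect_equal(res$mean_spf, 5, tolerance = 1e-12)
  # cross-check t and p against the independent routine
  tt <- t.test(1:3, 4:6, var.equal = TRUE)
  expect_equal(res$t_stat, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(res$p, tt$p.value, tolerance = 1e-12)
})

test_that("identical groups give d = 0 and no direction", {
  v <- exp(matrix(rnorm(8, 5), 2))
  tab <- two_group_table(v, v)
  res <- differential_test(tab, "brain")
  expect_equal(res$cohens_d, c(0, 0))
  expect_identical(res$direction, c("none", "none"))
})

test_that("zero pooled variance yields missing p excluded from the BH family", {
  gf <- exp(rbind(c(1, 1, 1), c(1, 2, 3)))
  spf <- exp(rbind(c(2, 2, 2), c(4, 5, 6)))
  tab <- two_group_table(gf, spf)
  res <- differential_test(tab, "brain")
  expect_true(is.na(res$p[1]))
  expect_true(is.na(res$q[1]))
  # family size m = 1: the remaining q equals its p
  expect_equal(res$q[2], res$p[2], tolerance = 1e-12)
})

test_that("BH step-up matches hand-derived examples", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(rep(0.02, 5)), rep(0.02, 5))
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4),
               tolerance = 1e-12)
  expect_equal(bh_adjust(c(0.001, 0.01, 0.1, 0.9)),
               c(0.004, 0.02, 0.13333333333333333, 0.9), tolerance = 1e-12)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("BH agrees with independent implementations on random vectors", {
  set.seed(123)
  for (rep in 1:400) {
    n <- sample(1:40, 1)
    p <- round(runif(n), sample(c(1, 2, 6), 1))   # ties likely
    q <- bh_adjust(p)
    expect_equal(q, p.adjust(p, "BH"), tolerance = 1e-12)
    expect_equal(q, bh_oracle(p), tolerance = 1e-12)
  }
})

test_that("flipping group labels negates d and swaps directions exactly", {
  ds <- small_dataset(n = 120)
  merged <- merge_modes(ds$tables)
  tab <- ft_drop_qc(merged)
  tab$intensities[is.na(tab$intensities)] <- 1
  res <- differential_all_organs(tab)
  flipped <- tab
  flipped$injections$group <- ifelse(flipped$injections$group == "GF",
                                     "SPF", "GF")
  res2 <- differential_all_organs(flipped)
  expect_equal(res2$cohens_d, -res$cohens_d, tolerance = 1e-12)
  expect_identical(res2$direction == "spf_higher", res$direction == "gf_higher")
  expect_identical(res2$direction == "gf_higher", res$direction == "spf_higher")
})

test_that("presence calls follow the SNR + significance rule", {
  # feature 1: SPF >> floor, GF << floor, strongly significant -> spf_only
  # feature 2: both groups above floor -> both, regardless of stats
  # feature 3: GF undetected entirely -> snr_gf = 0 -> spf_only
  # feature 4: both below floor -> neither
  gf <- rbind(c(200, 210, 190), c(900, 950, 920), c(NA, NA, NA),
              c(30, 35, 25))
  spf <- rbind(c(800, 820, 790), c(600, 640, 610), c(2000, 2100, 1900),
               c(40, 45, 35))
  tab <- two_group_table(gf, spf)
  diff <- data.frame(
    feature_id = sprintf("F%d", 1:4), organ = "brain",
    q = c(0.01, 0.001, 0.001, 0.01),
    cohens_d = c(-1.2, -2, -2, -1.5), stringsAsFactors = FALSE
  )
  calls <- call_presence(tab, diff, noise_floor = 100)
  expect_identical(calls$call, c("spf_only", "both", "spf_only", "neither"))
  expect_equal(calls$snr_gf[3], 0)

  # exclusivity requires the stats: q too large -> both
  diff$q[1] <- 0.2
  expect_identical(call_presence(tab, diff, noise_floor = 100)$call[1], "both")
  # and d must clear -0.8 for spf_only
  diff$q[1] <- 0.01; diff$cohens_d[1] <- -0.5
  expect_identical(call_presence(tab, diff, noise_floor = 100)$call[1], "both")
  expect_error(call_presence(tab, diff, noise_floor = 0), "positive")
})

test_that("venn partition assigns exact organ subsets and conserves margins", {
  fid <- sprintf("F%d", 1:5)
  mk <- function(f, o, dir) data.frame(feature_id = f, organ = o,
                                       direction = dir,
                                       stringsAsFactors = FALSE)
  diff <- rbind(
    mk(fid, "brain", c("spf_higher", "none", "gf_higher", "spf_higher", "none")),
    mk(fid, "intestine", c("spf_higher", "spf_higher", "none", "none", "none")),
    mk(fid, "placenta", c("spf_higher", "none", "spf_higher", "none", "none"))
  )
  vp <- venn_partition(diff)
  expect_identical(unname(vp$spf_counts[["brain,intestine,placenta"]]), 1L)
  expect_identical(unname(vp$spf_counts[["intestine"]]), 1L)
  expect_identical(unname(vp$spf_counts[["brain"]]), 1L)
  expect_identical(unname(vp$spf_counts[["placenta"]]), 1L)
  expect_identical(vp$spf_margin, 4L)
  expect_identical(sum(vp$spf_counts), vp$spf_margin)
  expect_identical(sum(vp$gf_counts), vp$gf_margin)
  # F3 is in both diagrams: SPF {placenta}, GF {brain}
  a <- vp$assignments[vp$assignments$feature_id == "F3", ]
  expect_identical(a$spf_organs, "placenta")
  expect_identical(a$gf_organs, "brain")
})

test_that("null synthetic data keeps the significant fraction at/below 0.05", {
  cfg <- synthetic_config(n_features_per_mode = 1200, modes = "RP+",
                          drift_amplitude = 0, detection_midpoint = log(1e-6),
                          effect_classes = c(spf_up = 0), seed = 55)
  ds <- generate_dataset(cfg)
  tab <- ft_drop_qc(ds$tables[[1]])
  res <- differential_all_organs(tab)
  sig_any <- tapply(res$significant, res$feature_id, any)
  expect_lte(mean(sig_any), 0.05)
})

test_that("planted d = 2 effects are recovered with correct direction and organs", {
  cfg0 <- synthetic_config()
  cfg <- synthetic_config(
    n_features_per_mode = 600, modes = "RP+", drift_amplitude = 0,
    detection_midpoint = log(1e-6),
    effect_classes = c(spf_up = 0.25, gf_up = 0.25),
    effect_size_log2 = planted_effect_log2(cfg0, 2), seed = 66
  )
  ds <- generate_dataset(cfg)
  tab <- ft_drop_qc(ds$tables[[1]])
  res <- differential_all_organs(tab)
  vp <- venn_partition(res)
  tr <- ds$truth
  planted <- tr[tr$effect_class %in% c("spf_up", "gf_up"), ]
  expect_gt(nrow(planted), 200)
  got <- vp$assignments[match(planted$feature_id, vp$assignments$feature_id), ]
  want_col <- ifelse(planted$effect_class == "spf_up", "spf_organs", "gf_organs")
  hit <- vapply(seq_len(nrow(planted)), function(i) {
    identical(got[[want_col[i]]][i], planted$affected_organs[i])
  }, logical(1))
  expect_gt(mean(hit), 0.90)
})
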