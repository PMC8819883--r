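# small in-code fixtures shared across test files

# tiny hand-built table: 3 features x (4 bio + 2 qc) injections, one mode
tiny_table <- function() {
  inj <- data.frame(
    injection_id = c("b1", "b2", "b3", "b4", "q1", "q2"),
    injection_order = 1:6,
    sample_type = c(rep("biological", 4), "qc", "qc"),
    group = c("GF", "GF", "SPF", "SPF", NA, NA),
    organ = c(rep("brain", 4), NA, NA),
    dam_id = c("d1", "d1", "d2", "d2", NA, NA),
    fetus_sex = c("M", "F", "M", "F", NA, NA),
    stringsAsFactors = FALSE
  )
  feats <- data.frame(feature_id = c("F1", "F2", "F3"),
                      mode = "RP+", mz = c(100.1, 200.2, 300.3),
                      rt = c(1.5, 2.5, 3.5), stringsAsFactors = FALSE)
  m <- matrix(c(10, 20, 30, 40, 25, 25,
                100, 110, 120, 130, 115, 114,
                5, NA, 7, 8, 6, 6), nrow = 3, byrow = TRUE)
  feature_table(m, feats, inj)
}

# a small but realistic generated dataset, memoised per options
small_dataset <- local({
  cache <- list()
  function(n = 200, seed = 42, ...) {
    key <- paste(n, seed, paste(deparse(substitute(list(...))), collapse = ""),
                 sep = "|")
    if (is.null(cache[[key]])) {
      cfg <- synthetic_config(n_features_per_mode = n, seed = seed, ...)
      cache[[key]] <<- generate_dataset(cfg)
    }
    cache[[key]]
  }
})

# independent straight-line reimplementation of the cleanup boolean rule
cleanup_oracle <- function(qc_det, grp_det, all_det, rsd_c, rsd_s, dr, drs,
                           th = default_cleanup_thresholds()) {
  ok <- function(x) !is.na(x)
  detection <- ok(qc_det) && qc_det > th$qc_detection &&
    ok(grp_det) && grp_det >= th$group_detection &&
    ok(all_det) && all_det >= th$overall_detection
  starred <- ok(rsd_s) && rsd_s < th$rsd_star &&
    ok(drs) && drs < th$d_ratio_star
  rescue <- ok(rsd_c) && rsd_c < th$rescue &&
    ok(rsd_s) && rsd_s < th$rescue &&
    ok(dr) && dr < th$rescue
  detection && (starred || rescue)
}

# independent BH step-up oracle (literal definition: q_i = min_{j: p_j >= p_i,
# by rank} m * p_(j) / j)
bh_oracle <- function(p) {
  m <- length(p)
  r <- rank(p, ties.method = "first")
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[o[i]] <- min(1, min(m * ps[i:m] / (i:m)))
  }
  q
}

# brute hypergeometric upper tail via choose()
hyper_tail_oracle <- function(hits, n_path, n_universe, n_sig) {
  ks <- hits:min(n_path, n_sig)
  sum(choose(n_path, ks) * choose(n_universe - n_path, n_sig - ks)) /
    choose(n_universe, n_sig)
}

# toy in-house/public MSP library written to a temp file
write_toy_msp <- function(path) {
  writeLines(c(
    "NAME: Glucose",
    "FORMULA: C6H12O6",
    "EXACTMASS: 180.0634",
    "RETENTIONTIME: 2.10",
    "SOURCE: in_house",
    "Num Peaks: 3",
    "60.0211 45",
    "85.0290 100",
    "127.0390 30",
    "",
    "NAME: Hippuric acid",
    "FORMULA: C9H9NO3",
    "EXACTMASS: 179.0582",
    "SOURCE: public",
    "Num Peaks: 2",
    "77.0386 60",
    "105.0335 100",
    "",
    "NAME: Creatinine",
    "FORMULA: C4H7N3O",
    "EXACTMASS: 113.0589",
    "RETENTIONTIME: 1.05",
    "SOURCE: in_house"
  ), path)
  path
}

# adjusted Rand index between two labelings (contingency-table formula)
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  n <- ch2(length(a))
  exp_ind <- sum_a * sum_b / n
  (sum_ij - exp_ind) / ((sum_a + sum_b) / 2 - exp_ind)
}
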