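#' Pipeline run configuration
#'
#' Bundles stage toggles, all thresholds (defaults are the study values:
#' QC detection 0.70 / group detection 0.60 / RSD* 0.20 / D-ratio* 0.10,
#' rescue 0.10, q 0.05, |d| 0.8, SNR 5, 10 ppm, k = 10) and the seed. The
#' config is serialized verbatim into the run manifest; re-running from the
#' manifest reproduces every output byte-identically.
#'
#' @param synthetic a `SyntheticConfig` describing the dataset to generate
#'   (its seed is overridden by `seed`); alternatively supply `input_dir`
#'   with `feature_table_<mode>.tsv` / `injections_<mode>.tsv` pairs.
#' @param input_dir optional directory of feature tables to load instead of
#'   simulating.
#' @param stages character vector of enabled stages, a subset of
#'   `c("qc", "drift", "impute", "diff", "cluster")` (annotation and pathway
#'   enrichment run via their own functions on the written results).
#' @param qc_thresholds see [default_cleanup_thresholds()].
#' @param q_threshold,d_threshold,snr_threshold significance and exclusivity
#'   thresholds.
#' @param k,perplexity clustering/embedding parameters.
#' @param impute_num_trees trees per forest in imputation.
#' @param noise_floor SNR denominator; `NULL` takes the synthetic config's.
#' @param seed master seed for every stochastic stage.
#' @return a `RunConfig` list.
#' @export
run_config <- function(synthetic = synthetic_config(n_features_per_mode = 200),
                       input_dir = NULL,
                       stages = c("qc", "drift", "impute", "diff", "cluster"),
                       qc_thresholds = default_cleanup_thresholds(),
                       q_threshold = 0.05, d_threshold = 0.8,
                       snr_threshold = 5, k = 10, perplexity = 7,
                       impute_num_trees = 50, noise_floor = NULL,
                       seed = 1) {
  cfg <- as.list(environment())
  class(cfg) <- "RunConfig"
  cfg
}

#' Run the full pipeline and write a reproducible run directory
#'
#' Stage order: simulate (or load) per-mode tables; drift correction per
#' mode; cleanup per mode; merge modes; random-forest imputation (QCs
#' removed);
#' per-organ differential tests, Venn partition and SNR exclusivity calls;
#' t-SNE and k-means structure. Every stage's input/output feature counts
#' are logged and conservation (`features_in = kept + flagged`) asserted.
#' All result tables plus a manifest (config, seed, versions, file hashes)
#' are written to `out_dir`.
#'
#' @param config a `RunConfig`.
#' @param out_dir output directory.
#' @return invisibly, a list with the main in-memory results and the
#'   manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  cfg <- config
  log_lines <- character(0)
  say <- function(...) {
    msg <- paste0(...)
    message(msg)
    log_lines <<- c(log_lines, msg)
  }

  if (!is.null(cfg$input_dir)) {
    modes <- cfg$synthetic$modes
    tables <- lapply(modes, function(md) {
      slug <- gsub("[+]", "pos", gsub("-", "neg", md))
      read_feature_table(
        file.path(cfg$input_dir, paste0("feature_table_", slug, ".tsv")),
        file.path(cfg$input_dir, paste0("injections_", slug, ".tsv"))
      )
    })
    names(tables) <- modes
    truth <- NULL
    noise_floor <- cfg$noise_floor
    say("loaded ", length(tables), " mode tables from ", cfg$input_dir)
  } else {
    syn <- cfg$synthetic
    syn$seed <- cfg$seed
    ds <- generate_dataset(syn)
    tables <- ds$tables
    truth <- ds$truth
    noise_floor <- if (is.null(cfg$noise_floor)) ds$noise_floor else cfg$noise_floor
    say("simulated ", length(tables), " modes x ",
        nrow(tables[[1]]$intensities), " features")
  }

  results <- list()

  # drift correction first, per mode: QC metrics are then computed on
  # corrected data, so drift does not masquerade as technical dispersion
  if ("drift" %in% cfg$stages) {
    drift_reports <- list()
    for (md in names(tables)) {
      dc <- correct_drift(tables[[md]])
      tables[[md]] <- dc$table
      dc$models$mode <- md
      drift_reports[[md]] <- dc$models
      say("drift [", md, "]: correction applied to ",
          sum(dc$models$applied), "/", nrow(dc$models), " features")
    }
    results$drift_models <- do.call(rbind, drift_reports)
  }

  kept_tabs <- tables
  if ("qc" %in% cfg$stages) {
    qcm <- list(); kept_tabs <- list()
    for (md in names(tables)) {
      met <- compute_quality_metrics(tables[[md]])
      cl <- apply_cleanup(met, cfg$qc_thresholds)
      stopifnot(length(cl$kept) + length(cl$flagged) == nrow(met))
      say("qc [", md, "]: ", nrow(met), " features in = ",
          length(cl$kept), " kept + ", length(cl$flagged), " flagged")
      qcm[[md]] <- cl$metrics
      kept_tabs[[md]] <- ft_subset(tables[[md]],
                                   features = tables[[md]]$features$feature_id
                                   %in% cl$kept)
    }
    results$qc_metrics <- do.call(rbind, qcm)
  } else {
    say("qc stage disabled; downstream stages run on uncleaned data")
  }

  merged <- merge_modes(kept_tabs)
  merged_raw_all <- merge_modes(tables)  # incl. flagged, for presence SNR
  say("merged: ", nrow(merged$intensities), " features x ",
      ncol(merged$intensities), " injections")

  imputed <- ft_drop_qc(merged)
  oob <- NA_real_
  if ("impute" %in% cfg$stages) {
    imp <- impute_rf(merged, seed = cfg$seed + 1L,
                     num_trees = cfg$impute_num_trees)
    imputed <- imp$table
    oob <- imp$oob_error
    say("imputation: ", imp$n_imputed, " cells filled, OOB error ",
        format(oob, digits = 3))
  } else if (anyNA(imputed$intensities)) {
    say("impute stage disabled but missing values remain; ",
        "differential tests will fail on incomplete data")
  }

  if ("diff" %in% cfg$stages) {
    diff <- differential_all_organs(imputed, q_threshold = cfg$q_threshold,
                                    d_threshold = cfg$d_threshold)
    presence <- call_presence(merged_raw_all, diff, noise_floor,
                              cfg$snr_threshold)
    venn <- venn_partition(diff, presence)
    say("diff: ", sum(diff$significant), " significant feature-organ pairs; ",
        venn$spf_margin, " SPF-higher / ", venn$gf_margin,
        " GF-higher features in >=1 organ")
    results$differential <- diff
    results$presence_calls <- presence
    results$venn_assignments <- venn$assignments
    results$venn_counts <- data.frame(
      cell = names(venn$spf_counts),
      spf_higher = as.integer(venn$spf_counts),
      gf_higher = as.integer(venn$gf_counts),
      spf_only = as.integer(venn$spf_only_counts),
      gf_only = as.integer(venn$gf_only_counts),
      stringsAsFactors = FALSE
    )
  }

  if ("cluster" %in% cfg$stages) {
    organs <- unique(imputed$injections$organ)
    organs <- organs[!is.na(organs)]
    emb <- rbind(
      tsne_embed(imputed, "all", cfg$perplexity, seed = cfg$seed + 2L),
      do.call(rbind, lapply(organs, function(o)
        tsne_embed(imputed, o, cfg$perplexity, seed = cfg$seed + 2L)))
    )
    km <- do.call(rbind, lapply(organs, function(o)
      kmeans_rows(imputed, o, k = cfg$k, seed = cfg$seed + 3L)))
    say("cluster: embeddings for ", length(organs) + 1,
        " scopes; k-means k=", cfg$k, " per organ")
    results$embedding <- emb
    results$clusters <- km
  }

  if (!is.null(truth)) results$truth <- truth
  results$run_log <- data.frame(message = log_lines, stringsAsFactors = FALSE)
  manifest <- write_results(results, out_dir,
                            config = serialize_config(cfg), seed = cfg$seed)
  invisible(list(results = results, manifest = manifest,
                 imputed = imputed, merged_raw = merged_raw_all,
                 oob_error = oob))
}

serialize_config <- function(cfg) {
  out <- unclass(cfg)
  syn <- unclass(out$synthetic)
  # named vectors must become lists: JSON arrays drop names
  syn$effect_classes <- as.list(syn$effect_classes)
  syn$n_sex_split <- as.list(syn$n_sex_split)
  out$synthetic <- syn
  out
}

restore_config <- function(lst) {
  syn <- lst$synthetic
  syn$effect_classes <- unlist(syn$effect_classes)
  syn$n_sex_split <- unlist(syn$n_sex_split)
  syn$modes <- unlist(syn$modes)
  syn$organs <- unlist(syn$organs)
  syn <- do.call(synthetic_config, syn)
  args <- lst[setdiff(names(lst), "synthetic")]
  args$qc_thresholds <- lapply(args$qc_thresholds, as.numeric)
  args$stages <- unlist(args$stages)
  do.call(run_config, c(list(synthetic = syn), args))
}

#' Re-run a pipeline from its manifest
#'
#' Reads the config and seed stored in a run's `manifest.json` and re-runs
#' the pipeline; deterministic stages and seeded stochastic stages reproduce
#' the stored outputs exactly.
#'
#' @param manifest_path path to `manifest.json`.
#' @param out_dir output directory for the re-run.
#' @return invisibly, as [run_pipeline()].
#' @export
run_pipeline_from_manifest <- function(manifest_path, out_dir) {
  man <- jsonlite::fromJSON(manifest_path, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE)
  cfg <- restore_config(man$config)
  cfg$seed <- man$seed
  run_pipeline(cfg, out_dir)
}
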