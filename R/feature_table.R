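#' @keywords internal
"_PACKAGE"

VALID_MODES <- c("RP+", "RP-", "HILIC+", "HILIC-")
VALID_ORGANS <- c("brain", "intestine", "placenta")
VALID_GROUPS <- c("GF", "SPF")

#' Construct a FeatureTable
#'
#' The central exchange object of the pipeline: an intensity matrix
#' (features x injections, `NA` = not detected) plus per-feature and
#' per-injection metadata.
#'
#' @param intensities numeric matrix, features in rows, injections in columns.
#'   Row names are feature ids, column names injection ids. Values are raw
#'   (non-negative) intensities; missing cells are `NA`.
#' @param features data.frame with columns `feature_id`, `mode`
#'   (one of `"RP+"`, `"RP-"`, `"HILIC+"`, `"HILIC-"`), `mz` (Da, within
#'   the 50-1500 peak-collection window) and `rt` (minutes).
#' @param injections data.frame with columns `injection_id`,
#'   `injection_order` (positive integer, unique within a mode),
#'   `sample_type` (`"biological"` or `"qc"`), `group` (`"GF"`, `"SPF"` or
#'   `NA` for QCs), `organ` (`"brain"`, `"intestine"`, `"placenta"` or `NA`),
#'   `dam_id` and `fetus_sex` (`"M"`, `"F"` or `NA`).
#' @return an object of class `FeatureTable`.
#' @export
feature_table <- function(intensities, features, injections) {
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  features <- as.data.frame(features, stringsAsFactors = FALSE)
  injections <- as.data.frame(injections, stringsAsFactors = FALSE)
  rownames(features) <- NULL
  rownames(injections) <- NULL
  rownames(intensities) <- as.character(features$feature_id)
  colnames(intensities) <- as.character(injections$injection_id)
  x <- structure(
    list(intensities = intensities, features = features,
         injections = injections),
    class = "FeatureTable"
  )
  validate_feature_table(x)
  x
}

#' Validate FeatureTable invariants
#'
#' Checks feature-id uniqueness, injection-order uniqueness within mode,
#' group/organ presence for biological injections, non-negative intensities
#' and the m/z window.
#'
#' @param x a `FeatureTable`.
#' @return `x`, invisibly; errors on any violation.
#' @export
validate_feature_table <- function(x) {
  ft <- x$features
  inj <- x$injections
  m <- x$intensities
  if (anyDuplicated(ft$feature_id)) {
    stop("duplicate feature_id: ",
         paste(unique(ft$feature_id[duplicated(ft$feature_id)]), collapse = ", "))
  }
  if (!all(ft$mode %in% VALID_MODES)) {
    stop("unknown mode label: ",
         paste(setdiff(unique(ft$mode), VALID_MODES), collapse = ", "))
  }
  if (anyDuplicated(inj$injection_id)) stop("duplicate injection_id")
  for (md in unique(ft$mode)) {
    if (anyDuplicated(inj$injection_order)) {
      stop("injection_order not unique within mode ", md)
    }
  }
  if (any(inj$injection_order < 1)) stop("injection_order must be positive")
  bio <- inj$sample_type == "biological"
  if (any(bio & (is.na(inj$group) | is.na(inj$organ)))) {
    stop("biological injection lacking group/organ: ",
         paste(inj$injection_id[bio & (is.na(inj$group) | is.na(inj$organ))],
               collapse = ", "))
  }
  if (!all(inj$group[bio] %in% VALID_GROUPS)) stop("unknown group label")
  if (!all(inj$organ[bio] %in% VALID_ORGANS)) stop("unknown organ label")
  if (any(m < 0, na.rm = TRUE)) stop("negative intensities")
  if (any(ft$mz < 50 | ft$mz > 1500, na.rm = TRUE)) {
    stop("m/z outside the 50-1500 collection window")
  }
  if (nrow(m) != nrow(ft) || ncol(m) != nrow(inj)) {
    stop("intensity matrix dimensions do not match metadata")
  }
  invisible(x)
}

#' @export
print.FeatureTable <- function(x, ...) {
  inj <- x$injections
  cat("FeatureTable:", nrow(x$intensities), "features x",
      ncol(x$intensities), "injections\n")
  cat("  modes:", paste(unique(x$features$mode), collapse = ", "), "\n")
  cat("  biological:", sum(inj$sample_type == "biological"),
      " qc:", sum(inj$sample_type == "qc"), "\n")
  cat("  missing cells:", sum(is.na(x$intensities)),
      sprintf("(%.1f%%)", 100 * mean(is.na(x$intensities))), "\n")
  invisible(x)
}

#' Subset a FeatureTable
#'
#' @param x a `FeatureTable`.
#' @param features logical/integer/character index over features.
#' @param injections logical/integer/character index over injections.
#' @return the subsetted `FeatureTable`.
#' @export
ft_subset <- function(x, features = NULL, injections = NULL) {
  fi <- if (is.null(features)) seq_len(nrow(x$intensities)) else features
  if (is.character(fi)) fi <- match(fi, x$features$feature_id)
  ii <- if (is.null(injections)) seq_len(ncol(x$intensities)) else injections
  if (is.character(ii)) ii <- match(ii, x$injections$injection_id)
  feature_table(x$intensities[fi, ii, drop = FALSE],
                x$features[fi, , drop = FALSE],
                x$injections[ii, , drop = FALSE])
}

#' Drop QC injections
#'
#' @param x a `FeatureTable`.
#' @return the table restricted to biological injections.
#' @export
ft_drop_qc <- function(x) {
  ft_subset(x, injections = x$injections$sample_type == "biological")
}

#' Read a feature table from delimited text
#'
#' The matrix file has one header row, a `feature_id` column, `mode`, `mz`
#' and `rt` columns, and one column per injection. The sidecar metadata file
#' is keyed by `injection_id`.
#'
#' @param path path to the feature matrix (TSV/CSV).
#' @param metadata_path path to the injection metadata table.
#' @param dialect list with `sep` (default tab) and `zero_as_missing`
#'   (default `FALSE`; MS-DIAL exports 0-fill, in which case set `TRUE` so 0
#'   cells become missing). Empty cells and `"NA"` are always missing.
#' @return a `FeatureTable`.
#' @export
read_feature_table <- function(path, metadata_path,
                               dialect = list(sep = "\t",
                                              zero_as_missing = FALSE)) {
  sep <- if (is.null(dialect$sep)) "\t" else dialect$sep
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           na.strings = c("", "NA"))
  meta_cols <- c("feature_id", "mode", "mz", "rt")
  if (!all(meta_cols %in% names(raw))) {
    stop("feature matrix must have columns: ", paste(meta_cols, collapse = ", "))
  }
  inj <- utils::read.table(metadata_path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           na.strings = c("", "NA"))
  features <- raw[meta_cols]
  intens <- as.matrix(raw[setdiff(names(raw), meta_cols)])
  storage.mode(intens) <- "double"
  if (isTRUE(dialect$zero_as_missing)) intens[intens == 0] <- NA_real_
  inj <- inj[match(colnames(intens), inj$injection_id), , drop = FALSE]
  if (any(is.na(inj$injection_id))) {
    stop("metadata missing for injections: ",
         paste(setdiff(colnames(intens), inj$injection_id), collapse = ", "))
  }
  feature_table(intens, features, inj)
}

#' Write a FeatureTable to delimited text
#'
#' Writes the matrix with feature metadata columns plus a sidecar injection
#' metadata file; `read_feature_table()` on the pair reproduces the object.
#'
#' @param x a `FeatureTable`.
#' @param path output path for the matrix TSV.
#' @param metadata_path output path for the injection metadata TSV.
#' @return invisibly, the two paths.
#' @export
write_feature_table <- function(x, path, metadata_path) {
  out <- cbind(x$features,
               as.data.frame(x$intensities, check.names = FALSE))
  write_tsv_(out, path)
  write_tsv_(x$injections, metadata_path)
  invisible(c(path, metadata_path))
}

# fixed TSV dialect: tab, "." decimal, UTF-8, NA as empty for bit-stable diffs
write_tsv_ <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  for (j in which(num)) {
    df[[j]] <- ifelse(is.na(df[[j]]), NA_character_,
                      sprintf("%.15g", df[[j]]))
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, na = "",
                     row.names = FALSE, fileEncoding = "UTF-8")
}

#' Merge per-mode feature tables
#'
#' Row-concatenates the cleaned per-mode matrices over a shared injection
#' set (the merge precedes imputation in the pipeline). Feature ids clashing
#' across modes are prefixed with their mode.
#'
#' @param tables list of `FeatureTable`s sharing an identical injection set.
#' @return a single merged `FeatureTable`; per-mode provenance is retained
#'   in the feature records.
#' @export
merge_modes <- function(tables) {
  stopifnot(length(tables) >= 1)
  ids0 <- sort(tables[[1]]$injections$injection_id)
  for (t in tables[-1]) {
    if (!identical(sort(t$injections$injection_id), ids0)) {
      stop("mismatched injection sets across modes")
    }
  }
  ord <- tables[[1]]$injections$injection_id
  tabs <- lapply(tables, function(t) {
    ft_subset(t, injections = match(ord, t$injections$injection_id))
  })
  feats <- do.call(rbind, lapply(tabs, function(t) t$features))
  if (anyDuplicated(feats$feature_id)) {
    for (i in seq_along(tabs)) {
      tabs[[i]]$features$feature_id <-
        paste0(tabs[[i]]$features$mode, "_", tabs[[i]]$features$feature_id)
    }
    feats <- do.call(rbind, lapply(tabs, function(t) t$features))
  }
  intens <- do.call(rbind, lapply(tabs, function(t) t$intensities))
  feature_table(intens, feats, tabs[[1]]$injections)
}
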