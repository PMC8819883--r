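#' Read an MSP spectral library
#'
#' Parses the NIST MSP dialect as written by MS-DIAL: records begin with
#' `NAME:`, carry `PRECURSORMZ`/`EXACTMASS`/`FORMULA`, optionally
#' `RETENTIONTIME`, and end with `Num Peaks:` followed by `mz intensity`
#' lines. Records without peaks get no `ms2` element.
#'
#' @param path path to the MSP text file.
#' @return a list of reference-library entries, each a list with
#'   `compound_name`, `formula`, `monoisotopic_mass` (Da), `rt` (minutes,
#'   `NA` if absent), `ms2` (two-column matrix `mz`, `intensity`, or `NULL`),
#'   `source` (`"in_house"` or `"public"`) and `compound_class` (`NA` if
#'   absent).
#' @export
read_msp_library <- function(path) {
  lines <- readLines(path, warn = FALSE)
  entries <- list()
  cur <- NULL
  peaks_left <- 0L
  peaks <- NULL
  flush <- function(cur, peaks) {
    if (is.null(cur)) return(NULL)
    if (!is.null(peaks) && nrow(peaks) > 0) cur$ms2 <- peaks else cur$ms2 <- NULL
    if (is.na(cur$monoisotopic_mass) || cur$monoisotopic_mass <= 0) {
      stop("entry '", cur$compound_name, "' lacks a positive mass")
    }
    cur
  }
  new_entry <- function(name) {
    list(compound_name = name, formula = NA_character_,
         monoisotopic_mass = NA_real_, rt = NA_real_, ms2 = NULL,
         source = "public", compound_class = NA_character_)
  }
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (peaks_left > 0L) {
      if (!grepl("^[0-9.eE+-]+[ \t]+[0-9.eE+-]+", ln)) {
        stop("malformed peak line at line ", i, ": '", ln, "'")
      }
      parts <- strsplit(ln, "[ \t]+")[[1]]
      mzv <- suppressWarnings(as.numeric(parts[1]))
      iv <- suppressWarnings(as.numeric(parts[2]))
      if (is.na(mzv) || is.na(iv) || iv < 0) {
        stop("malformed peak line at line ", i, ": '", ln, "'")
      }
      peaks <- rbind(peaks, c(mzv, iv))
      peaks_left <- peaks_left - 1L
      next
    }
    if (ln == "") next
    kv <- regmatches(ln, regexec("^([^:]+):\\s*(.*)$", ln))[[1]]
    if (length(kv) != 3) stop("unparseable line ", i, ": '", ln, "'")
    key <- toupper(gsub("\\s+", "", kv[2]))
    val <- kv[3]
    if (key == "NAME") {
      if (!is.null(cur)) entries[[length(entries) + 1L]] <- flush(cur, peaks)
      cur <- new_entry(val)
      peaks <- NULL
    } else if (is.null(cur)) {
      stop("field before first NAME at line ", i)
    } else if (key %in% c("PRECURSORMZ", "EXACTMASS", "MONOISOTOPICMASS")) {
      cur$monoisotopic_mass <- as.numeric(val)
    } else if (key == "FORMULA") {
      cur$formula <- val
    } else if (key == "RETENTIONTIME") {
      cur$rt <- as.numeric(val)
    } else if (key == "SOURCE") {
      cur$source <- if (tolower(val) %in% c("in_house", "in-house", "inhouse"))
        "in_house" else "public"
    } else if (key %in% c("COMPOUNDCLASS", "ONTOLOGY")) {
      cur$compound_class <- val
    } else if (key == "NUMPEAKS") {
      peaks_left <- as.integer(val)
      peaks <- matrix(numeric(0), ncol = 2)
    }
    # unknown keys are ignored (MSP files carry many optional fields)
  }
  if (peaks_left > 0L) stop("file ends inside a peak list")
  if (!is.null(cur)) entries[[length(entries) + 1L]] <- flush(cur, peaks)
  for (i in seq_along(entries)) {
    if (!is.null(entries[[i]]$ms2)) colnames(entries[[i]]$ms2) <- c("mz", "intensity")
  }
  entries
}

#' Read pathway definitions from a GMT file
#'
#' GMT format: `pathway_id TAB pathway_name TAB member TAB member ...`.
#'
#' @param path path to the GMT file.
#' @return a named list of character vectors of member compound ids; names
#'   are pathway ids, with the display name in the `"pathway_name"` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  nms <- character(0)
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) stop("GMT line with fewer than 3 fields: '", ln, "'")
    members <- unique(parts[-(1:2)])
    members <- members[nzchar(members)]
    if (length(members) == 0) stop("empty member set for pathway ", parts[1])
    out[[parts[1]]] <- members
    nms <- c(nms, parts[2])
  }
  attr(out, "pathway_name") <- stats::setNames(nms, names(out))
  out
}

#' Write result tables with a run manifest
#'
#' Writes each data.frame as TSV (tab, "." decimal, UTF-8; missing as empty)
#' plus a `manifest.json` recording the config, seed, package version and a
#' content hash per file. Re-reading reproduces numeric values to 1e-9.
#'
#' @param tables named list of data.frames.
#' @param out_dir output directory (created if needed).
#' @param config optional list serialized verbatim into the manifest.
#' @param seed optional integer seed recorded in the manifest.
#' @return the manifest, invisibly.
#' @export
write_results <- function(tables, out_dir, config = NULL, seed = NULL) {
  stopifnot(is.list(tables), !is.null(names(tables)))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  }
  files <- character(0)
  for (nm in names(tables)) {
    p <- file.path(out_dir, paste0(nm, ".tsv"))
    write_tsv_(as.data.frame(tables[[nm]]), p)
    files[nm] <- p
  }
  manifest <- list(
    package = "fetometab",
    version = as.character(utils::packageVersion("fetometab")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = seed,
    config = config,
    files = as.list(stats::setNames(unname(tools::md5sum(files)),
                                    basename(files)))
  )
  # I(17) significant digits: doubles in the config round-trip exactly,
  # which the re-run-from-manifest reproducibility contract depends on
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = I(17), pretty = TRUE,
                       null = "null")
  invisible(manifest)
}

#' Read back a results table written by [write_results()]
#'
#' @param path path to the TSV.
#' @return a data.frame.
#' @export
read_results_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    na.strings = "")
}
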