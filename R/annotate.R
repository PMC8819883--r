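#' Primary adducts by polarity
#'
#' Default adduct rules: `[M+H]+` and `[M+Na]+` for positive modes, `[M-H]-`
#' and `[M+Cl]-` for negative (primary ions only). Shifts include the
#' electron mass.
#'
#' @return data.frame: `name`, `shift` (Da added to the neutral
#'   monoisotopic mass), `polarity` (`"+"` or `"-"`).
#' @export
default_adducts <- function() {
  data.frame(
    name = c("[M+H]+", "[M+Na]+", "[M-H]-", "[M+Cl]-"),
    shift = c(1.007276, 22.989218, -1.007276, 34.969402),
    polarity = c("+", "+", "-", "-"),
    stringsAsFactors = FALSE
  )
}

#' Modified cosine similarity between two MS2 spectra
#'
#' Greedy one-to-one peak matching: candidate pairs within the fragment
#' tolerance are taken in order of increasing m/z difference, each peak used
#' at most once; the score is the cosine of the square-root-intensity
#' vectors, with unmatched peaks contributing to the norms only. Symmetric
#' in its arguments.
#'
#' @param spec_a,spec_b two-column matrices (`mz`, `intensity`), non-empty.
#' @param fragment_tol_da matching tolerance in Da.
#' @return similarity in `[0, 1]`.
#' @export
ms2_cosine <- function(spec_a, spec_b, fragment_tol_da = 0.02) {
  if (is.null(spec_a) || is.null(spec_b) ||
      nrow(spec_a) == 0 || nrow(spec_b) == 0) {
    stop("empty spectrum")
  }
  a_mz <- unname(spec_a[, 1]); a_in <- unname(sqrt(spec_a[, 2]))
  b_mz <- unname(spec_b[, 1]); b_in <- unname(sqrt(spec_b[, 2]))
  pairs <- expand.grid(i = seq_along(a_mz), j = seq_along(b_mz))
  pairs$dmz <- abs(a_mz[pairs$i] - b_mz[pairs$j])
  pairs <- pairs[pairs$dmz <= fragment_tol_da, , drop = FALSE]
  # symmetric tie-breaks so ms2_cosine(a, b) == ms2_cosine(b, a)
  pairs <- pairs[order(pairs$dmz, a_mz[pairs$i] + b_mz[pairs$j],
                       a_in[pairs$i] * b_in[pairs$j]), , drop = FALSE]
  used_a <- logical(length(a_mz)); used_b <- logical(length(b_mz))
  num <- 0
  for (r in seq_len(nrow(pairs))) {
    i <- pairs$i[r]; j <- pairs$j[r]
    if (used_a[i] || used_b[j]) next
    used_a[i] <- TRUE; used_b[j] <- TRUE
    num <- num + a_in[i] * b_in[j]
  }
  num / (sqrt(sum(a_in^2)) * sqrt(sum(b_in^2)))
}

#' Match one feature against a reference library and assign an MSI level
#'
#' Evidence per entry and adduct: `mz_match` iff the relative error to the
#' adduct mass is within `mz_ppm`; `rt_match` iff the entry has a retention
#' time within `rt_window` minutes; `ms2_match` iff the modified cosine is
#' at or above `ms2_threshold`. Identification levels (first satisfied
#' wins): level 1 -- in-house standard with m/z, RT and MS2 all matching;
#' level 2 -- m/z and MS2 matching any source, or (when the feature has no
#' MS2) RT and formula-derived mass matching an in-house standard; level 3
#' -- compound-class evidence from an optional user-supplied class-rule
#' table; level 4 -- no assignment. Ties across entries break on highest
#' MS2 score, then smallest ppm error.
#'
#' @param feature list with `feature_id`, `mz`, `rt`, `polarity` (`"+"` or
#'   `"-"`), optional `ms2` (two-column matrix).
#' @param library list of entries from [read_msp_library()].
#' @param mz_ppm,rt_window,ms2_threshold tolerances (defaults 10 ppm, 0.1
#'   min, 0.7).
#' @param adducts adduct table, see [default_adducts()].
#' @param class_rules optional data.frame (`compound_class`, `mz_min`,
#'   `mz_max`) assigning a class from the feature m/z alone; without it no
#'   level-3 calls are made.
#' @return one-row data.frame: `feature_id`, `compound_name`, `msi_level`,
#'   evidence flags (`mz_match`, `rt_match`, `ms2_match`, `formula_match`,
#'   `class_only`), `matched_source`, `ms2_score`, `adduct`, `ppm_error`.
#' @export
match_feature <- function(feature, library, mz_ppm = 10, rt_window = 0.1,
                          ms2_threshold = 0.7, adducts = default_adducts(),
                          class_rules = NULL) {
  pol <- feature$polarity
  add <- adducts[adducts$polarity == pol, , drop = FALSE]
  if (nrow(add) == 0) stop("no adducts for polarity ", pol)
  best <- NULL
  for (e in library) {
    for (k in seq_len(nrow(add))) {
      expected <- e$monoisotopic_mass + add$shift[k]
      ppm <- abs(feature$mz - expected) / expected * 1e6
      if (ppm > mz_ppm) next
      rt_match <- !is.na(e$rt) && !is.null(feature$rt) &&
        abs(feature$rt - e$rt) <= rt_window
      ms2_score <- NA_real_
      ms2_match <- FALSE
      if (!is.null(feature$ms2) && !is.null(e$ms2)) {
        ms2_score <- ms2_cosine(feature$ms2, e$ms2)
        ms2_match <- ms2_score >= ms2_threshold
      }
      formula_match <- !is.na(e$formula)   # mass already matched at this point
      level <- NA_integer_
      if (e$source == "in_house" && rt_match && ms2_match) {
        level <- 1L
      } else if (ms2_match) {
        level <- 2L
      } else if (is.null(feature$ms2) && e$source == "in_house" &&
                 rt_match && formula_match) {
        level <- 2L
      }
      if (is.na(level)) next
      cand <- list(level = level, name = e$compound_name, source = e$source,
                   rt_match = rt_match, ms2_match = ms2_match,
                   formula_match = formula_match, ms2_score = ms2_score,
                   ppm = ppm, adduct = add$name[k])
      if (is.null(best) ||
          cand$level < best$level ||
          (cand$level == best$level &&
           (is.na(best$ms2_score) ||
            (!is.na(cand$ms2_score) && cand$ms2_score > best$ms2_score) ||
            (identical(cand$ms2_score, best$ms2_score) && cand$ppm < best$ppm)))) {
        best <- cand
      }
    }
  }
  if (is.null(best) && !is.null(class_rules)) {
    hit <- class_rules[feature$mz >= class_rules$mz_min &
                       feature$mz <= class_rules$mz_max, , drop = FALSE]
    if (nrow(hit) > 0) {
      return(data.frame(feature_id = feature$feature_id,
                        compound_name = NA_character_, msi_level = 3L,
                        mz_match = FALSE, rt_match = FALSE, ms2_match = FALSE,
                        formula_match = FALSE, class_only = TRUE,
                        compound_class = hit$compound_class[1],
                        matched_source = "none", ms2_score = NA_real_,
                        adduct = NA_character_, ppm_error = NA_real_,
                        stringsAsFactors = FALSE))
    }
  }
  if (is.null(best)) {
    return(data.frame(feature_id = feature$feature_id,
                      compound_name = NA_character_, msi_level = 4L,
                      mz_match = FALSE, rt_match = FALSE, ms2_match = FALSE,
                      formula_match = FALSE, class_only = FALSE,
                      compound_class = NA_character_,
                      matched_source = "none", ms2_score = NA_real_,
                      adduct = NA_character_, ppm_error = NA_real_,
                      stringsAsFactors = FALSE))
  }
  data.frame(feature_id = feature$feature_id, compound_name = best$name,
             msi_level = best$level, mz_match = TRUE,
             rt_match = best$rt_match, ms2_match = best$ms2_match,
             formula_match = best$formula_match, class_only = FALSE,
             compound_class = NA_character_,
             matched_source = best$source, ms2_score = best$ms2_score,
             adduct = best$adduct, ppm_error = best$ppm,
             stringsAsFactors = FALSE)
}

#' Annotate a set of features against a library
#'
#' Applies [match_feature()] to each feature and flags, per matched
#' compound, the feature with the best evidence (lowest level, then highest
#' MS2 score, then smallest ppm error) as the compound's representative --
#' one metabolite commonly yields several features across modes, adducts
#' and fragments.
#'
#' @param features data.frame with `feature_id`, `mz`, `rt`, `mode`;
#'   optional list-column `ms2`.
#' @param library list of entries from [read_msp_library()].
#' @param ... passed to [match_feature()].
#' @return data.frame of annotation records with a `representative` flag.
#' @export
annotate_features <- function(features, library, ...) {
  pol <- ifelse(grepl("\\+$", features$mode), "+", "-")
  recs <- lapply(seq_len(nrow(features)), function(i) {
    f <- list(feature_id = features$feature_id[i], mz = features$mz[i],
              rt = features$rt[i], polarity = pol[i],
              ms2 = if ("ms2" %in% names(features)) features$ms2[[i]] else NULL)
    match_feature(f, library, ...)
  })
  out <- do.call(rbind, recs)
  out$representative <- FALSE
  ann <- which(!is.na(out$compound_name))
  if (length(ann)) {
    for (cmp in unique(out$compound_name[ann])) {
      ix <- which(out$compound_name == cmp)
      o <- ix[order(out$msi_level[ix], -ifelse(is.na(out$ms2_score[ix]), -1,
                                               out$ms2_score[ix]),
                    out$ppm_error[ix])]
      out$representative[o[1]] <- TRUE
    }
  }
  out
}
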