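# Suspect-screening engine: feature detection, blank subtraction, the filter
# cascade, library matching with source-priority ranking, class-coverage
# filtering, fragmentation-coverage (FISh-style) scoring and Schymanski
# confidence levels.

#' Screening parameters
#'
#' @param tolerance_ppm Global mass tolerance (ppm).
#' @param min_intensity Minimum apex intensity (area units).
#' @param min_rating Peak-quality rating threshold; features must score
#'   strictly greater.
#' @param rt_range Retention-time window (minutes) retained by the cascade.
#' @param sn_threshold Minimum S/N for detection.
#' @param blank_ratio Sample/blank area ratio at or below which a
#'   blank-matched feature is treated as background.
#' @return list of class `screen_params`.
#' @export
screen_params <- function(tolerance_ppm = 5, min_intensity = 1e5,
                          min_rating = 4, rt_range = c(1, 15),
                          sn_threshold = 3, blank_ratio = 5) {
  structure(list(tolerance_ppm = tolerance_ppm, min_intensity = min_intensity,
                 min_rating = min_rating, rt_range = rt_range,
                 sn_threshold = sn_threshold, blank_ratio = blank_ratio),
            class = "screen_params")
}

#' Detect features in a synthetic run
#'
#' Converts the run's peak list into screening features with apex intensity,
#' S/N (apex over the run's baseline level) and MS2 links; peaks whose S/N
#' falls below the detection threshold are not reported.
#'
#' @param run `raw_run`.
#' @param params [screen_params()].
#' @return data.frame of features with columns `feature_id`, `sample_id`,
#'   `mz`, `rt`, `area`, `apex_intensity`, `peak_rating`, `snr`, `n_ms2`;
#'   MS2 spectra retrievable via [feature_ms2()].
#' @export
detect_features <- function(run, params = screen_params()) {
  stopifnot(inherits(run, "raw_run"))
  f <- run$features
  if (nrow(f) == 0L) return(.empty_features(run$sample_id))
  apex <- f$area  # unit-width synthetic peaks: apex tracks area
  snr <- apex / run$noise_model$baseline
  ms2_ids <- vapply(run$ms2, function(s) s$feature_id, character(1))
  out <- data.frame(
    feature_id = f$feature_id, sample_id = run$sample_id,
    mz = f$mz, rt = f$rt, area = f$area, apex_intensity = apex,
    peak_rating = f$peak_rating, snr = snr,
    n_ms2 = as.integer(vapply(f$feature_id,
                              function(id) sum(ms2_ids == id), numeric(1))),
    is_background = f$is_background, compound = f$compound,
    stringsAsFactors = FALSE
  )
  out <- out[out$snr >= params$sn_threshold, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "ms2") <- run$ms2
  out
}

.empty_features <- function(sample_id) {
  data.frame(feature_id = character(0), sample_id = character(0),
             mz = numeric(0), rt = numeric(0), area = numeric(0),
             apex_intensity = numeric(0), peak_rating = numeric(0),
             snr = numeric(0), n_ms2 = integer(0),
             is_background = logical(0), compound = character(0),
             stringsAsFactors = FALSE)
}

#' MS2 spectra linked to a feature
#'
#' @param features Feature table from [detect_features()].
#' @param feature_id Feature identifier.
#' @return list of `spectrum_record` (possibly empty).
#' @export
feature_ms2 <- function(features, feature_id) {
  ms2 <- attr(features, "ms2")
  if (is.null(ms2)) return(list())
  ms2[vapply(ms2, function(s) identical(s$feature_id, feature_id),
             logical(1))]
}

#' Blank subtraction
#'
#' A sample feature matching a blank feature within the mass and RT
#' tolerances is removed iff its area is at most `blank_ratio` times the
#' blank area; features without a blank match, or exceeding the ratio, are
#' retained.
#'
#' @param sample_features,blank_features Feature tables.
#' @param params [screen_params()] (`blank_ratio`, `tolerance_ppm`).
#' @param rt_tol RT matching tolerance (minutes).
#' @return Filtered sample feature table.
#' @export
blank_subtract <- function(sample_features, blank_features,
                           params = screen_params(), rt_tol = 0.2) {
  if (nrow(sample_features) == 0L || nrow(blank_features) == 0L) {
    return(sample_features)
  }
  keep <- vapply(seq_len(nrow(sample_features)), function(i) {
    hit <- ppm_match(blank_features$mz, sample_features$mz[i],
                     params$tolerance_ppm) &
      abs(blank_features$rt - sample_features$rt[i]) <= rt_tol
    if (!any(hit)) return(TRUE)
    ratio <- sample_features$area[i] / max(blank_features$area[hit])
    ratio > params$blank_ratio
  }, logical(1))
  out <- sample_features[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "ms2") <- attr(sample_features, "ms2")
  out
}

#' The screening filter cascade
#'
#' Ordered application of the quality filters: apex intensity >=
#' `min_intensity`, peak rating strictly > `min_rating`, RT inside
#' `rt_range`. (The mass-error filter applies at annotation time, where a
#' reference m/z exists.) Per-stage survivor counts are attached as the
#' `"stage_counts"` attribute.
#'
#' @param features Feature table.
#' @param params [screen_params()].
#' @return Surviving features with a `stage_counts` attribute.
#' @export
filter_cascade <- function(features, params = screen_params()) {
  ms2 <- attr(features, "ms2")
  counts <- c(input = nrow(features))
  features <- features[features$apex_intensity >= params$min_intensity, ,
                       drop = FALSE]
  counts <- c(counts, intensity = nrow(features))
  features <- features[features$peak_rating > params$min_rating, ,
                       drop = FALSE]
  counts <- c(counts, rating = nrow(features))
  features <- features[features$rt >= params$rt_range[1] &
                         features$rt <= params$rt_range[2], , drop = FALSE]
  counts <- c(counts, rt = nrow(features))
  rownames(features) <- NULL
  attr(features, "ms2") <- ms2
  attr(features, "stage_counts") <- counts
  features
}

#' Class-coverage count of a feature
#'
#' Number of class-diagnostic ions present (within tolerance) in any MS2
#' spectrum of the feature. The class-coverage filter retains features with
#' a count of at least one.
#'
#' @param features Feature table (with MS2 attribute).
#' @param feature_id Feature identifier.
#' @param ion_list [default_class_ion_list()] or compatible.
#' @return Integer count.
#' @export
class_coverage <- function(features, feature_id, ion_list) {
  spectra <- feature_ms2(features, feature_id)
  if (!length(spectra)) return(0L)
  mz <- unlist(lapply(spectra, function(s) s$peaks$mz))
  sum(vapply(ion_list$ions$mz,
             function(ref) any(ppm_match(mz, ref, ion_list$tolerance_ppm)),
             logical(1)))
}

#' Apply the class-coverage filter
#'
#' @param features Feature table.
#' @param ion_list `class_ion_list`.
#' @param min_count Minimum diagnostic-ion count (default 1).
#' @return Features whose MS2 contains at least `min_count` class ions
#'   (features without MS2 are removed), with a `class_coverage` column.
#' @export
class_coverage_filter <- function(features, ion_list, min_count = 1L) {
  if (nrow(features) == 0L) {
    features$class_coverage <- integer(0)
    return(features)
  }
  cc <- vapply(features$feature_id,
               function(id) class_coverage(features, id, ion_list),
               integer(1))
  out <- features[cc >= min_count, , drop = FALSE]
  out$class_coverage <- cc[cc >= min_count]
  rownames(out) <- NULL
  attr(out, "ms2") <- attr(features, "ms2")
  out
}

# source priority for annotation ranking
.source_priority <- c(inhouse_msms = 1, external_msms = 2, mass_list = 3,
                      formula_prediction = 4)

#' Match features against spectral libraries
#'
#' Gathers candidate identities by precursor match within tolerance across
#' the supplied libraries, scores MS2-bearing features by spectral
#' similarity (forward = similarity of the feature spectrum explained by the
#' library spectrum, reverse = vice versa) and ranks annotations by source
#' priority (`inhouse_msms` > `external_msms` > `mass_list` >
#' `formula_prediction`), then forward score, then absolute mass error.
#' Candidates belonging to a co-elution group carry the group label so that
#' unresolved isomers are reported as a group sum.
#'
#' @param features Feature table.
#' @param libraries Named list; elements `inhouse_msms` / `external_msms`
#'   are lists of `spectrum_record`, `mass_list` is a data.frame with
#'   `name`, `mz`.
#' @param params [screen_params()].
#' @return data.frame of annotations (one row per feature-candidate pair).
#' @export
match_library <- function(features, libraries, params = screen_params()) {
  if (!length(libraries) || !any(nzchar(names(libraries)))) {
    stop("no libraries supplied", call. = FALSE)
  }
  panel <- rbind(regulated_panel(), related_compounds())
  groups <- panel_reporting_groups()
  group_of <- function(cmp) {
    g <- panel$coelution_group[match(cmp, panel$name)]
    if (is.na(g) || is.na(cmp)) return(cmp)
    hit <- vapply(groups$members, function(m) cmp %in% m, logical(1))
    if (any(hit)) groups$analyte[which(hit)[1]] else cmp
  }
  rows <- list()
  for (i in seq_len(nrow(features))) {
    fmz <- features$mz[i]
    fid <- features$feature_id[i]
    spectra <- feature_ms2(features, fid)
    for (libname in names(libraries)) {
      lib <- libraries[[libname]]
      if (libname %in% c("inhouse_msms", "external_msms")) {
        for (s in lib) {
          if (!ppm_match(fmz, s$precursor_mz, params$tolerance_ppm)) next
          fs <- 0; rs <- 0; nm <- 0L
          if (length(spectra)) {
            sim <- spectral_similarity(spectra[[1]], s,
                                       tolerance_ppm = params$tolerance_ppm)
            fs <- sim$score; rs <- sim$reverse_coverage
            nm <- sim$n_matched
          }
          rows[[length(rows) + 1L]] <- data.frame(
            feature_id = fid, candidate = s$name,
            reporting_group = group_of(s$name), source = libname,
            forward_score = fs, reverse_score = rs,
            n_matched_fragments = nm,
            mass_error_ppm = ppm_error(fmz, s$precursor_mz),
            stringsAsFactors = FALSE)
        }
      } else if (libname == "mass_list") {
        hit <- which(ppm_match(lib$mz, fmz, params$tolerance_ppm))
        for (j in hit) {
          rows[[length(rows) + 1L]] <- data.frame(
            feature_id = fid, candidate = lib$name[j],
            reporting_group = group_of(lib$name[j]), source = "mass_list",
            forward_score = 0, reverse_score = 0, n_matched_fragments = 0L,
            mass_error_ppm = ppm_error(fmz, lib$mz[j]),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(feature_id = character(0), candidate = character(0),
                      reporting_group = character(0), source = character(0),
                      forward_score = numeric(0), reverse_score = numeric(0),
                      n_matched_fragments = integer(0),
                      mass_error_ppm = numeric(0), rank = integer(0),
                      stringsAsFactors = FALSE))
  }
  ann <- do.call(rbind, rows)
  ord <- order(ann$feature_id, .source_priority[ann$source],
               -ann$forward_score, abs(ann$mass_error_ppm))
  ann <- ann[ord, , drop = FALSE]
  ann$rank <- stats::ave(seq_len(nrow(ann)), ann$feature_id,
                         FUN = seq_along)
  rownames(ann) <- NULL
  ann
}

#' Fragmentation-coverage (FISh-style) score
#'
#' Percentage of the spectrum's peaks (above a relative-intensity floor)
#' explained by any candidate fragment within tolerance.
#'
#' @param spectrum `spectrum_record`.
#' @param candidate_fragments Numeric m/z vector of in-silico fragments.
#' @param tolerance_ppm Matching tolerance.
#' @param intensity_floor Relative-intensity floor (%) below which peaks are
#'   ignored.
#' @return Percentage in \[0, 100\].
#' @export
fish_score <- function(spectrum, candidate_fragments, tolerance_ppm = 5,
                       intensity_floor = 1) {
  pk <- spectrum$peaks[spectrum$peaks$intensity >= intensity_floor, ,
                       drop = FALSE]
  stopifnot(nrow(pk) >= 1L)
  if (!length(candidate_fragments)) {
    warning("empty candidate fragment list; FISh score is 0")
    return(0)
  }
  explained <- vapply(pk$mz, function(m) {
    any(ppm_match(m, candidate_fragments, tolerance_ppm))
  }, logical(1))
  100 * sum(explained) / nrow(pk)
}

#' Assign a Schymanski-style confidence level
#'
#' Level 1: MS2 library match plus retention-time match to an authentic
#' standard. Level 2: MS2 library / diagnostic-fragment evidence without a
#' standard. Level 3: formula plus class evidence (e.g. class-coverage hit)
#' only. Level 4: formula-only match. Level 5: exact mass only.
#'
#' @param source Annotation source (see [match_library()]).
#' @param n_matched_fragments Matched MS2 fragments for the candidate.
#' @param class_coverage_count Diagnostic-ion count.
#' @param has_standard_rt_match RT match to an authentic standard.
#' @return Integer level 1-5.
#' @export
assign_confidence <- function(source, n_matched_fragments = 0L,
                              class_coverage_count = 0L,
                              has_standard_rt_match = FALSE) {
  ms2_evidence <- source %in% c("inhouse_msms", "external_msms") &&
    n_matched_fragments >= 1L
  if (ms2_evidence && has_standard_rt_match) return(1L)
  if (ms2_evidence) return(2L)
  if (class_coverage_count >= 1L) return(3L)
  if (source %in% c("mass_list", "formula_prediction")) return(4L)
  5L
}

#' Screen one run end to end
#'
#' Convenience wrapper: detect features, subtract the blank, run the filter
#' cascade and the class-coverage filter, annotate against the in-house
#' library and assign confidence levels.
#'
#' @param run `raw_run` for the sample.
#' @param blank `raw_run` procedure blank (or NULL).
#' @param library In-house MS2 library.
#' @param ion_list Class-ion list.
#' @param params [screen_params()].
#' @return list with `features` (post-cascade), `annotations`, and
#'   `stage_counts`.
#' @export
screen_run <- function(run, blank = NULL, library = in_silico_library(),
                       ion_list = default_class_ion_list(),
                       params = screen_params()) {
  feats <- detect_features(run, params)
  if (!is.null(blank)) {
    feats <- blank_subtract(feats, detect_features(blank, params), params)
  }
  feats <- filter_cascade(feats, params)
  counts <- attr(feats, "stage_counts")
  feats <- class_coverage_filter(feats, ion_list)
  counts <- c(counts, class_coverage = nrow(feats))
  ann <- match_library(feats, list(inhouse_msms = library), params)
  ann <- ann[abs(ann$mass_error_ppm) <= params$tolerance_ppm, , drop = FALSE]
  if (nrow(ann)) {
    cc <- feats$class_coverage[match(ann$feature_id, feats$feature_id)]
    ann$confidence_level <- mapply(assign_confidence, ann$source,
                                   ann$n_matched_fragments, cc,
                                   MoreArgs = list(has_standard_rt_match = FALSE))
  } else {
    ann$confidence_level <- integer(0)
  }
  list(features = feats, annotations = ann, stage_counts = counts)
}
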