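# Synthetic DDA-style raw runs: ground-truth features + MS/MS spectra,
# procedure blanks and matrix-matched calibration series.

#' Run simulation configuration
#'
#' @param slope Calibration slope: peak area units per µg/kg (all analytes
#'   share one nominal response factor; matrix effects scale it).
#' @param ppm_jitter_sd Mass-accuracy jitter (ppm, 1 s.d.); the default 5/3
#'   keeps >= 99% of true features inside a 5 ppm window.
#' @param intensity_cv Multiplicative coefficient of variation on areas and
#'   MS2 intensities (0 = noise-free).
#' @param baseline Baseline intensity level used for S/N estimation.
#' @param n_background Number of background (non-PA) features per run.
#' @param dda_trigger Apex intensity above which a feature is fragmented
#'   (Top-N data-dependent acquisition trigger).
#' @param mz_range,rt_range Acquisition windows for background features.
#' @param bg_ms2_fraction Fraction of background features carrying an MS2
#'   spectrum of random fragments.
#' @return list of class `run_config`.
#' @export
run_config <- function(slope = 2e6, ppm_jitter_sd = 5 / 3,
                       intensity_cv = 0.05, baseline = 1000,
                       n_background = 400, dda_trigger = 1e5,
                       mz_range = c(50, 750), rt_range = c(0.3, 16),
                       bg_ms2_fraction = 0.3) {
  structure(list(slope = slope, ppm_jitter_sd = ppm_jitter_sd,
                 intensity_cv = intensity_cv, baseline = baseline,
                 n_background = n_background, dda_trigger = dda_trigger,
                 mz_range = mz_range, rt_range = rt_range,
                 bg_ms2_fraction = bg_ms2_fraction),
            class = "run_config")
}

#' Retention-time assignments for the panel
#'
#' Fixed synthetic retention times (minutes) for the reporting analytes and
#' the necine bases: bases elute first (low polarity retention on C8 near the
#' void), esters spread over 2-15 min in order of increasing mass. These are
#' simulation constants, not measured values.
#'
#' @return Named numeric vector, minutes.
#' @export
rt_assignments <- function() {
  groups <- panel_reporting_groups()
  panel <- regulated_panel()
  rep_cmp <- vapply(groups$members, function(m) m[[1]], character(1))
  mass <- panel$monoisotopic_mass[match(rep_cmp, panel$name)]
  rt <- 2 + 12.5 * (rank(mass, ties.method = "first") - 1) /
    (nrow(groups) - 1)
  names(rt) <- groups$analyte
  c(rt, platynecine = 1.8, retronecine = 1.6, heliotridine = 1.7)
}

# representative panel compound (first member) per reporting analyte
.group_representative <- function(analyte) {
  groups <- panel_reporting_groups()
  i <- match(analyte, groups$analyte)
  if (!is.na(i)) return(groups$members[[i]][1])
  analyte
}

.mult_noise <- function(n, cv) {
  if (cv <= 0) rep(1, n) else exp(stats::rnorm(n, -cv^2 / 2, cv))
}

.jitter_mz <- function(mz, ppm_sd) {
  if (ppm_sd <= 0) return(mz)
  mz * (1 + stats::rnorm(length(mz), 0, ppm_sd * 1e-6))
}

.find_library_spectrum <- function(library, compound) {
  for (s in library) if (identical(s$name, compound)) return(s)
  NULL
}

.background_features <- function(config, id_prefix) {
  n <- config$n_background
  if (n == 0L) {
    return(data.frame(feature_id = character(0), mz = numeric(0),
                      rt = numeric(0), area = numeric(0),
                      peak_rating = numeric(0), is_background = logical(0),
                      compound = character(0), true_mz = numeric(0),
                      true_concentration = numeric(0),
                      stringsAsFactors = FALSE))
  }
  data.frame(
    feature_id = sprintf("%s_bg%03d", id_prefix, seq_len(n)),
    mz = stats::runif(n, config$mz_range[1], config$mz_range[2]),
    rt = stats::runif(n, config$rt_range[1], config$rt_range[2]),
    area = stats::rlnorm(n, log(5e4), 1.2),
    peak_rating = stats::runif(n, 0, 10),
    is_background = TRUE,
    compound = NA_character_,
    true_mz = NA_real_, true_concentration = NA_real_,
    stringsAsFactors = FALSE
  )
}

.background_ms2 <- function(features, config) {
  ms2 <- list()
  if (config$bg_ms2_fraction <= 0) return(ms2)
  pick <- stats::runif(nrow(features)) < config$bg_ms2_fraction
  for (i in which(pick)) {
    if (features$mz[i] < 60) next   # too little room below the precursor
    npk <- sample(3:10, 1L)
    frag <- sort(stats::runif(npk, 50, features$mz[i] - 1))
    sp <- spectrum_record(
      name = features$feature_id[i], precursor_mz = features$mz[i],
      mz = frag, intensity = stats::runif(npk, 5, 100),
      retention_time = features$rt[i], provenance = "synthetic_run",
      source_citation = "background")
    sp$feature_id <- features$feature_id[i]
    ms2 <- c(ms2, list(sp))
  }
  ms2
}

#' Generate one synthetic DDA run
#'
#' Builds a raw run for one sample: a spiked feature per analyte with
#' non-zero concentration (area = concentration x slope before noise, m/z
#' jittered by the configured mass accuracy) plus background features, and
#' MS2 spectra drawn from the library (with multiplicative intensity noise)
#' for every feature above the DDA trigger.
#'
#' @param concentrations Named numeric vector of true concentrations (µg/kg)
#'   per reporting analyte (zeros/absent analytes ignored).
#' @param library list of `spectrum_record` (must contain the representative
#'   compound of every spiked analyte).
#' @param config [run_config()].
#' @param sample_id Identifier.
#' @param seed Optional integer seed.
#' @param rt Named RT lookup; defaults to [rt_assignments()].
#' @return Object of class `raw_run`: list(`sample_id`, `features`
#'   data.frame, `ms2` list, `noise_model`).
#' @export
generate_run <- function(concentrations, library, config = run_config(),
                         sample_id = "sample", seed = NULL,
                         rt = rt_assignments()) {
  if (!is.null(seed)) set.seed(seed)
  spiked <- concentrations[!is.na(concentrations) & concentrations > 0]
  if (length(spiked)) {
    missing_rt <- setdiff(names(spiked), names(rt))
    if (length(missing_rt)) {
      stop("no RT assignment for analyte(s): ",
           paste(missing_rt, collapse = ", "), call. = FALSE)
    }
  }
  feats <- .background_features(config, sample_id)
  ms2 <- .background_ms2(feats, config)
  for (a in names(spiked)) {
    cmp <- .group_representative(a)
    sp <- .find_library_spectrum(library, cmp)
    if (is.null(sp)) {
      stop("library has no spectrum for '", cmp, "'", call. = FALSE)
    }
    true_mz <- sp$precursor_mz
    area <- spiked[[a]] * config$slope * .mult_noise(1, config$intensity_cv)
    fid <- sprintf("%s_%s", sample_id, gsub("[^A-Za-z0-9]+", "_", a))
    f <- data.frame(
      feature_id = fid,
      mz = .jitter_mz(true_mz, config$ppm_jitter_sd),
      rt = rt[[a]] + stats::rnorm(1, 0, 0.02),
      area = area,
      peak_rating = stats::runif(1, 8, 10),
      is_background = FALSE,
      compound = a,
      true_mz = true_mz, true_concentration = spiked[[a]],
      stringsAsFactors = FALSE
    )
    feats <- rbind(feats, f)
    if (area >= config$dda_trigger) {
      pk_mz <- .jitter_mz(sp$peaks$mz, config$ppm_jitter_sd)
      pk_int <- sp$peaks$intensity * .mult_noise(nrow(sp$peaks),
                                                 config$intensity_cv)
      ssp <- spectrum_record(
        name = cmp, precursor_mz = f$mz, mz = pk_mz, intensity = pk_int,
        adduct = sp$adduct, formula = sp$formula,
        retention_time = f$rt, provenance = "synthetic_run",
        source_citation = "simulated DDA")
      ssp$feature_id <- fid
      ms2 <- c(ms2, list(ssp))
    }
  }
  structure(list(
    sample_id = sample_id, features = feats, ms2 = ms2,
    noise_model = list(ppm_jitter_sd = config$ppm_jitter_sd,
                       intensity_cv = config$intensity_cv,
                       baseline = config$baseline)
  ), class = "raw_run")
}

#' @export
print.raw_run <- function(x, ...) {
  cat(sprintf("<raw_run> %s: %d features (%d spiked), %d MS2 spectra\n",
              x$sample_id, nrow(x$features),
              sum(!x$features$is_background), length(x$ms2)))
  invisible(x)
}

#' Generate a procedure blank
#'
#' A run that shares the background-population model with samples but
#' contains no spiked PAs.
#'
#' @inheritParams generate_run
#' @return `raw_run`.
#' @export
generate_blank <- function(config = run_config(), sample_id = "blank",
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  feats <- .background_features(config, sample_id)
  ms2 <- .background_ms2(feats, config)
  structure(list(sample_id = sample_id, features = feats, ms2 = ms2,
                 noise_model = list(ppm_jitter_sd = config$ppm_jitter_sd,
                                    intensity_cv = config$intensity_cv,
                                    baseline = config$baseline)),
            class = "raw_run")
}

#' Generate a calibration series
#'
#' One run per level with every requested analyte spiked at that level;
#' areas are level x slope x `matrix_slope_factor` before noise, so a factor
#' of e.g. 0.86 emulates -14% ionization suppression in matrix.
#'
#' @param levels Ascending positive concentrations (µg/kg); default
#'   0.1, 1, 10, 100.
#' @param matrix_slope_factor Multiplier on the solvent slope (1 = solvent
#'   equivalent).
#' @param analytes Reporting analytes to spike (default: all non-N-oxide
#'   groups).
#' @param library,config,seed As in [generate_run()].
#' @return list of `raw_run`, one per level, names = level.
#' @export
generate_calibration <- function(levels = c(0.1, 1, 10, 100),
                                 matrix_slope_factor = 1,
                                 analytes = NULL,
                                 library = in_silico_library(),
                                 config = run_config(), seed = NULL) {
  stopifnot(all(levels > 0), !is.unsorted(levels))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(analytes)) {
    groups <- panel_reporting_groups()
    analytes <- groups$analyte[!groups$is_n_oxide]
  }
  cfg <- config
  cfg$slope <- config$slope * matrix_slope_factor
  out <- lapply(seq_along(levels), function(i) {
    conc <- stats::setNames(rep(levels[i], length(analytes)), analytes)
    generate_run(conc, library, cfg,
                 sample_id = sprintf("cal_%g", levels[i]))
  })
  names(out) <- as.character(levels)
  out
}
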