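# shared fixtures, built in code

# quick spectrum with default intensities 100
make_spectrum <- function(mz, intensity = NULL, name = "spec",
                          precursor = max(mz) + 50, ...) {
  spectrum_record(name = name, precursor_mz = precursor, mz = mz,
                  intensity = intensity, ...)
}

# independently transcribed monoisotopic element masses (the oracle table;
# kept separate from the package's own table on purpose)
oracle_masses <- c(C = 12.0, H = 1.00782503, N = 14.00307401,
                   O = 15.99491462, Na = 22.98976928, K = 38.96370649,
                   S = 31.97207100, Cl = 34.96885268)
oracle_electron <- 0.00054858

# brute-force [M+H]+ from a formula string, independent of the package parser
oracle_mh <- function(formula) {
  toks <- regmatches(formula,
                     gregexpr("[A-Z][a-z]?[0-9]*", formula))[[1]]
  m <- 0
  for (t in toks) {
    sym <- gsub("[0-9]", "", t)
    cnt <- suppressWarnings(as.numeric(gsub("[A-Za-z]", "", t)))
    if (is.na(cnt)) cnt <- 1
    m <- m + oracle_masses[[sym]] * cnt
  }
  m + oracle_masses[["H"]] - oracle_electron
}

# a small feature table in the screening layout, for direct filter tests
make_features <- function(n, mz = runif(n, 100, 700), rt = runif(n, 1, 15),
                          area = rep(2e5, n), rating = rep(9, n),
                          snr = rep(100, n), id = sprintf("f%02d", seq_len(n))) {
  data.frame(feature_id = id, sample_id = "t", mz = mz, rt = rt,
             area = area, apex_intensity = area, peak_rating = rating,
             snr = snr, n_ms2 = 0L, is_background = TRUE,
             compound = NA_character_, stringsAsFactors = FALSE)
}

# cohort config scaled down for fast stochastic tests
small_cohort_config <- function(...) {
  cohort_config(
    type_counts = c("eucalyptus" = 11, "wildflower" = 18, "rosemary" = 17),
    type_prevalence = c("eucalyptus" = 0.91, "wildflower" = 0.78,
                        "rosemary" = 0.35),
    ...
  )
}
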