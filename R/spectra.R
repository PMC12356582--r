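# MS/MS spectrum records, literature fragmentation tables, the in-silico
# library and the class-diagnostic ion list.

#' Construct an MS/MS spectrum record
#'
#' @param name Compound name (or `NA` for unknowns).
#' @param precursor_mz Precursor m/z.
#' @param mz,intensity Fragment peak vectors; `intensity` is relative (%).
#'   When no intensities are supplied all peaks are set to 100.
#' @param adduct Adduct label, see [supported_adducts()].
#' @param formula Optional neutral formula.
#' @param retention_time Minutes, optional.
#' @param provenance One of `"in_silico_literature"`, `"standard_acquired"`,
#'   `"synthetic_run"`.
#' @param source_citation Free-text provenance.
#' @return An object of class `spectrum_record`.
#' @export
spectrum_record <- function(name, precursor_mz, mz, intensity = NULL,
                            adduct = "[M+H]+", formula = NA_character_,
                            retention_time = NA_real_,
                            provenance = "in_silico_literature",
                            source_citation = "") {
  stopifnot(is.numeric(precursor_mz), length(precursor_mz) == 1L,
            is.numeric(mz), length(mz) >= 1L)
  provenance <- match.arg(provenance,
    c("in_silico_literature", "standard_acquired", "synthetic_run"))
  if (is.null(intensity)) {
    # literature rows without intensities: every ion carries equal weight
    intensity <- rep(100, length(mz))
  }
  stopifnot(length(intensity) == length(mz), all(intensity > 0))
  if (any(mz >= precursor_mz + 0.5)) {
    stop("fragment m/z at or above precursor + 0.5 for '", name, "'",
         call. = FALSE)
  }
  ord <- order(mz)
  intensity <- intensity / max(intensity) * 100
  structure(list(
    name = name, formula = formula, adduct = adduct,
    precursor_mz = precursor_mz, retention_time = retention_time,
    peaks = data.frame(mz = mz[ord], intensity = intensity[ord]),
    provenance = provenance, source_citation = source_citation
  ), class = "spectrum_record")
}

#' @export
print.spectrum_record <- function(x, ...) {
  cat(sprintf("<spectrum_record> %s %s precursor %.4f, %d peaks (%s)\n",
              x$name, x$adduct, x$precursor_mz, nrow(x$peaks), x$provenance))
  invisible(x)
}

# ---- literature fragmentation tables -------------------------------------

#' Parse a literature fragmentation table into spectrum records
#'
#' Converts a tabular compilation of published fragmentation data (one row
#' per compound/adduct with `";"`-separated fragment lists) into a list of
#' [spectrum_record()]s. Missing intensities are assigned the value 100 for
#' every fragment so that ion presence, not ion ratio, drives matching;
#' missing precursors are computed from the formula and adduct.
#'
#' @param rows data.frame with columns `name`, `formula`, and optionally
#'   `adduct`, `precursor_mz`, `fragment_mz`, `fragment_intensity`,
#'   `retention_time`, `citation`.
#' @return list of `spectrum_record`.
#' @export
parse_fragmentation_table <- function(rows) {
  if (is.null(rows) || nrow(rows) == 0L) return(list())
  stopifnot(all(c("name", "formula") %in% names(rows)))
  get_col <- function(col, default) {
    if (col %in% names(rows)) rows[[col]] else rep(default, nrow(rows))
  }
  adduct <- get_col("adduct", "[M+H]+")
  adduct[is.na(adduct) | adduct == ""] <- "[M+H]+"
  key <- paste(rows$name, adduct)
  if (anyDuplicated(key)) {
    stop("duplicate (name, adduct) rows: ",
         paste(unique(key[duplicated(key)]), collapse = "; "), call. = FALSE)
  }
  precursor <- suppressWarnings(as.numeric(get_col("precursor_mz", NA)))
  frag_str <- as.character(get_col("fragment_mz", ""))
  int_str <- as.character(get_col("fragment_intensity", ""))
  rt <- suppressWarnings(as.numeric(get_col("retention_time", NA)))
  citation <- as.character(get_col("citation", ""))

  split_num <- function(s) {
    if (is.na(s) || !nzchar(trimws(s))) return(numeric(0))
    as.numeric(strsplit(trimws(s), "\\s*;\\s*")[[1]])
  }
  out <- vector("list", nrow(rows))
  for (i in seq_len(nrow(rows))) {
    frags <- split_num(frag_str[i])
    ints <- split_num(int_str[i])
    has_formula <- !is.na(rows$formula[i]) && nzchar(rows$formula[i])
    prec <- precursor[i]
    if (is.na(prec)) {
      if (!has_formula) {
        stop("row ", i, " ('", rows$name[i],
             "') has fragments but neither formula nor precursor",
             call. = FALSE)
      }
      prec <- compute_ion_mz(rows$formula[i], adduct[i])
    }
    if (length(frags) == 0L) frags <- prec   # precursor-only entry
    out[[i]] <- spectrum_record(
      name = rows$name[i], precursor_mz = prec, mz = frags,
      intensity = if (length(ints)) ints else NULL,
      adduct = adduct[i],
      formula = if (has_formula) rows$formula[i] else NA_character_,
      retention_time = rt[i],
      provenance = "in_silico_literature",
      source_citation = citation[i]
    )
  }
  out
}

# necine-core fragment cations by structural class; PANOs additionally retain
# the free-base core series after N-O bond cleavage
.core_fragments <- function(necine_class, is_n_oxide) {
  base_cores <- c("C6H8N", "C8H10N", "C8H12NO", "C8H14NO2")
  if (is_n_oxide) {
    return(c("C6H8N", "C8H10N", "C8H12NO", "C8H10NO", "C8H12NO2", "C8H14NO3"))
  }
  switch(necine_class,
    otonecine = c("C6H8N", "C8H10N", "C8H12NO", "C8H12N", "C9H12NO", "C9H14NO2"),
    # saturated necines still yield the dehydropyrrolizidinium series
    # (94/120/138) by H2 losses under HCD, alongside their own core ions
    platynecine = c("C6H8N", "C8H10N", "C8H12NO", "C6H10N", "C8H12N",
                    "C8H14NO"),
    base_cores
  )
}

#' Default literature fragmentation table
#'
#' A synthetic reconstruction of a literature fragmentation compilation for
#' the 35-compound regulated panel plus the necine bases of
#' [related_compounds()]: each compound carries the fragment cations typical
#' of its necine class plus its own in-source water loss. Fragment m/z are
#' formula-derived; no intensities are included, mirroring compilations where
#' published spectra report ions but not ratios.
#'
#' @return data.frame in the layout accepted by [parse_fragmentation_table()].
#' @export
default_fragmentation_table <- function() {
  cmp <- rbind(regulated_panel(), related_compounds())
  frag_mz <- character(nrow(cmp))
  for (i in seq_len(nrow(cmp))) {
    cores <- .core_fragments(cmp$necine_class[i], cmp$is_n_oxide[i])
    mz <- vapply(cores, fragment_mz, numeric(1))
    if (cmp$ester_type[i] != "necine_base") {
      mz <- c(mz, compute_ion_mz(cmp$formula[i], "[M+H-H2O]+"))
    }
    frag_mz[i] <- paste(sprintf("%.4f", sort(mz)), collapse = ";")
  }
  data.frame(
    name = cmp$name, formula = cmp$formula, adduct = "[M+H]+",
    precursor_mz = NA_real_, fragment_mz = frag_mz,
    fragment_intensity = "", retention_time = NA_real_,
    citation = "synthetic reconstruction from necine-class fragment chemistry",
    stringsAsFactors = FALSE
  )
}

#' The default in-silico MS/MS library
#'
#' @param include_related Include the non-regulated necine bases
#'   (platynecine etc.) alongside the 35-compound panel.
#' @return list of `spectrum_record`.
#' @export
in_silico_library <- function(include_related = TRUE) {
  tab <- default_fragmentation_table()
  if (!include_related) {
    tab <- tab[tab$name %in% regulated_panel()$name, , drop = FALSE]
  }
  parse_fragmentation_table(tab)
}

# ---- MSP I/O --------------------------------------------------------------

#' Write spectrum records to a NIST-style MSP file
#'
#' One text block per spectrum (`Name`, `Formula`, `PrecursorMZ`, `Adduct`,
#' `RT`, `Comments` with provenance key=value pairs, `Num Peaks`, one
#' `mz intensity` line per peak), blank-line separated, UTF-8.
#'
#' @param library list of [spectrum_record()]s, non-empty.
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
write_msp <- function(library, path) {
  stopifnot(length(library) > 0L)
  blocks <- vapply(library, function(s) {
    hdr <- c(
      paste0("Name: ", s$name),
      if (!is.na(s$formula)) paste0("Formula: ", s$formula),
      sprintf("PrecursorMZ: %.4f", s$precursor_mz),
      paste0("Adduct: ", s$adduct),
      if (!is.na(s$retention_time)) sprintf("RT: %.3f", s$retention_time),
      sprintf("Comments: provenance=%s citation=\"%s\"",
              s$provenance, s$source_citation),
      sprintf("Num Peaks: %d", nrow(s$peaks))
    )
    pk <- sprintf("%.4f %.2f", s$peaks$mz, s$peaks$intensity)
    paste(c(hdr, pk), collapse = "\n")
  }, character(1))
  writeLines(paste(blocks, collapse = "\n\n"), path, useBytes = TRUE)
  invisible(path)
}

#' Read a NIST-style MSP file
#'
#' @param path MSP file written by [write_msp()] or compatible.
#' @return list of `spectrum_record`.
#' @export
read_msp <- function(path) {
  lines <- readLines(path, warn = FALSE)
  # split on blank lines
  grp <- cumsum(!nzchar(trimws(lines)))
  blocks <- split(lines[nzchar(trimws(lines))], grp[nzchar(trimws(lines))])
  out <- vector("list", length(blocks))
  for (bi in seq_along(blocks)) {
    bl <- blocks[[bi]]
    fields <- list()
    npk_line <- grep("^Num Peaks:", bl)
    if (!length(npk_line)) {
      stop("malformed MSP block ", bi, ": missing 'Num Peaks'", call. = FALSE)
    }
    for (ln in bl[seq_len(npk_line)]) {
      kv <- regmatches(ln, regexec("^([^:]+):\\s*(.*)$", ln))[[1]]
      if (length(kv) == 3L) fields[[kv[2]]] <- kv[3]
    }
    n_peaks <- as.integer(fields[["Num Peaks"]])
    pk_lines <- bl[-seq_len(npk_line)]
    if (length(pk_lines) != n_peaks) {
      stop("malformed MSP block ", bi, ": expected ", n_peaks,
           " peaks, found ", length(pk_lines), call. = FALSE)
    }
    pk <- do.call(rbind, lapply(strsplit(trimws(pk_lines), "\\s+"), as.numeric))
    prov <- "in_silico_literature"
    cit <- ""
    if (!is.null(fields[["Comments"]])) {
      pm <- regmatches(fields[["Comments"]],
                       regexec("provenance=(\\S+)", fields[["Comments"]]))[[1]]
      if (length(pm) == 2L) prov <- pm[2]
      cm <- regmatches(fields[["Comments"]],
                       regexec("citation=\"([^\"]*)\"", fields[["Comments"]]))[[1]]
      if (length(cm) == 2L) cit <- cm[2]
    }
    out[[bi]] <- spectrum_record(
      name = fields[["Name"]],
      precursor_mz = as.numeric(fields[["PrecursorMZ"]]),
      mz = pk[, 1], intensity = pk[, 2],
      adduct = if (is.null(fields[["Adduct"]])) "[M+H]+" else fields[["Adduct"]],
      formula = if (is.null(fields[["Formula"]])) NA_character_ else fields[["Formula"]],
      retention_time = if (is.null(fields[["RT"]])) NA_real_ else as.numeric(fields[["RT"]]),
      provenance = prov, source_citation = cit
    )
  }
  out
}

# ---- class-diagnostic ion list -------------------------------------------

#' Build a class-diagnostic ion list from a spectral library
#'
#' Fragment ions recurring in at least `min_compounds` library spectra are
#' merged with a curated list of extra ions and deduplicated within
#' `tolerance_ppm` (ppm-close ions collapse to the first-seen entry).
#'
#' @param library list of `spectrum_record`.
#' @param extra_ions data.frame with columns `mz`, `label`, `source`
#'   (may be empty).
#' @param min_compounds Recurrence threshold k (default 3).
#' @param tolerance_ppm Deduplication / matching tolerance.
#' @return Object of class `class_ion_list`: data.frame `ions`
#'   (`mz`, `label`, `source`) plus `tolerance_ppm` attribute.
#' @export
build_class_ion_list <- function(library, extra_ions = NULL,
                                 min_compounds = 3, tolerance_ppm = 5) {
  ions <- data.frame(mz = numeric(0), label = character(0),
                     source = character(0), stringsAsFactors = FALSE)
  if (length(library)) {
    all_mz <- unlist(lapply(library, function(s) s$peaks$mz))
    uniq <- sort(unique(round(all_mz, 4)))
    n_cmp <- vapply(uniq, function(m) {
      sum(vapply(library, function(s) any(ppm_match(s$peaks$mz, m, tolerance_ppm)),
                 logical(1)))
    }, numeric(1))
    rec <- uniq[n_cmp >= min_compounds]
    if (length(rec)) {
      ions <- data.frame(mz = rec,
                         label = sprintf("recurrent_%.4f", rec),
                         source = "library_recurrence",
                         stringsAsFactors = FALSE)
    }
  }
  if (!is.null(extra_ions) && nrow(extra_ions)) {
    ions <- rbind(ions, extra_ions[, c("mz", "label", "source")])
  }
  # dedupe within tolerance, keeping the earliest entry
  keep <- rep(TRUE, nrow(ions))
  for (i in seq_len(nrow(ions))) {
    if (!keep[i]) next
    if (i < nrow(ions)) {
      later <- (i + 1):nrow(ions)
      dup <- later[ppm_match(ions$mz[later], ions$mz[i], tolerance_ppm)]
      keep[dup] <- FALSE
    }
  }
  ions <- ions[keep, , drop = FALSE]
  ions <- ions[order(ions$mz), , drop = FALSE]
  rownames(ions) <- NULL
  structure(list(ions = ions, tolerance_ppm = tolerance_ppm),
            class = "class_ion_list")
}

# curated ions observed for pyrrolizidine standards (fragment-cation formulas;
# a synthetic stand-in for the published experimental ion compilation)
.curated_class_ions <- function() {
  formulas <- c("C5H8N", "C6H10N", "C5H10NO", "C7H8N", "C7H10N", "C8H8N",
                "C8H12N", "C8H14NO", "C8H16NO", "C7H14NO2", "C9H12NO",
                "C8H16NO2", "C9H14NO2", "C9H16NO2", "C10H14NO2", "C9H14NO3",
                "C10H16NO3", "C12H18NO3", "C13H20NO4")
  data.frame(
    mz = round(vapply(formulas, fragment_mz, numeric(1)), 4),
    label = formulas,
    source = "curated_standard_ions",
    stringsAsFactors = FALSE
  )
}

#' The default 30-ion class-coverage list
#'
#' Characteristic pyrrolizidine fragment ions used by the class-coverage
#' filter: ions recurring in at least three compounds of the default
#' in-silico library merged with a curated set of standard-observed fragment
#' cations. This list is a synthetic reconstruction (the underlying published
#' ion table is not redistributed); it is regenerated deterministically.
#'
#' @param tolerance_ppm Matching tolerance.
#' @return `class_ion_list` of 30 ions.
#' @export
default_class_ion_list <- function(tolerance_ppm = 5) {
  build_class_ion_list(in_silico_library(include_related = FALSE),
                       .curated_class_ions(),
                       min_compounds = 3, tolerance_ppm = tolerance_ppm)
}

#' @export
print.class_ion_list <- function(x, ...) {
  cat(sprintf("<class_ion_list> %d ions, tolerance %g ppm\n",
              nrow(x$ions), x$tolerance_ppm))
  invisible(x)
}

#' Write / read a class-ion list as JSON
#'
#' @param x `class_ion_list`.
#' @param path JSON file.
#' @return `path` (write) or `class_ion_list` (read).
#' @export
write_class_ion_list <- function(x, path) {
  jsonlite::write_json(list(tolerance_ppm = x$tolerance_ppm, ions = x$ions),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_class_ion_list
#' @export
read_class_ion_list <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(ions = as.data.frame(obj$ions),
                 tolerance_ppm = obj$tolerance_ppm),
            class = "class_ion_list")
}
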