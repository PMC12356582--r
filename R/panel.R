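# The regulated pyrrolizidine-alkaloid panel and related compounds.
#
# The 35-compound panel follows Regulation (EU) 2023/915: 21 marker PAs plus
# 14 co-eluting isomers counted in the regulatory sum. Necine classes and
# ester types follow the usual structural classification (lycopsamine-type
# monoesters, open-chain diesters of the echimidine type, senecionine-type
# macrocyclic diesters, otonecine-type senkirkine).

.panel_def <- function() {
  # name, formula, necine_class, ester_type, n_oxide, coelution group ("")
  rows <- list(
    # lycopsamine-type monoesters (C15H25NO5 isomer block)
    c("intermedine",            "C15H25NO5", "retronecine",  "monoester", "0", ""),
    c("lycopsamine",            "C15H25NO5", "retronecine",  "monoester", "0", "indicine_lycopsamine"),
    c("indicine",               "C15H25NO5", "retronecine",  "monoester", "0", "indicine_lycopsamine"),
    c("echinatine",             "C15H25NO5", "heliotridine", "monoester", "0", "echinatine_rinderine"),
    c("rinderine",              "C15H25NO5", "heliotridine", "monoester", "0", "echinatine_rinderine"),
    c("intermedine N-oxide",    "C15H25NO6", "retronecine",  "monoester", "1", "indicineNO_intermedineNO"),
    c("lycopsamine N-oxide",    "C15H25NO6", "retronecine",  "monoester", "1", ""),
    c("indicine N-oxide",       "C15H25NO6", "retronecine",  "monoester", "1", "indicineNO_intermedineNO"),
    c("echinatine N-oxide",     "C15H25NO6", "heliotridine", "monoester", "1", ""),
    c("rinderine N-oxide",      "C15H25NO6", "heliotridine", "monoester", "1", ""),
    # heliotrine-type monoesters
    c("heliotrine",             "C16H27NO5", "heliotridine", "monoester", "0", ""),
    c("heliotrine N-oxide",     "C16H27NO6", "heliotridine", "monoester", "1", ""),
    c("europine",               "C16H27NO6", "heliotridine", "monoester", "0", ""),
    c("europine N-oxide",       "C16H27NO7", "heliotridine", "monoester", "1", ""),
    # open-chain diesters
    c("echimidine",             "C20H31NO7", "retronecine",  "open_diester", "0", ""),
    c("echimidine N-oxide",     "C20H31NO8", "retronecine",  "open_diester", "1", ""),
    c("heliosupine",            "C20H31NO7", "heliotridine", "open_diester", "0", ""),
    c("heliosupine N-oxide",    "C20H31NO8", "heliotridine", "open_diester", "1", ""),
    c("lasiocarpine",           "C21H33NO7", "heliotridine", "open_diester", "0", ""),
    c("lasiocarpine N-oxide",   "C21H33NO8", "heliotridine", "open_diester", "1", ""),
    # senecionine-type macrocyclic diesters
    c("senecionine",            "C18H25NO5", "retronecine",  "cyclic_diester", "0", ""),
    c("senecionine N-oxide",    "C18H25NO6", "retronecine",  "cyclic_diester", "1", ""),
    c("integerrimine",          "C18H25NO5", "retronecine",  "cyclic_diester", "0", ""),
    c("integerrimine N-oxide",  "C18H25NO6", "retronecine",  "cyclic_diester", "1", ""),
    c("senecivernine",          "C18H25NO5", "retronecine",  "cyclic_diester", "0", ""),
    c("senecivernine N-oxide",  "C18H25NO6", "retronecine",  "cyclic_diester", "1", ""),
    c("seneciphylline",         "C18H23NO5", "retronecine",  "cyclic_diester", "0", ""),
    c("seneciphylline N-oxide", "C18H23NO6", "retronecine",  "cyclic_diester", "1", ""),
    c("spartioidine",           "C18H23NO5", "retronecine",  "cyclic_diester", "0", ""),
    c("spartioidine N-oxide",   "C18H23NO6", "retronecine",  "cyclic_diester", "1", ""),
    c("retrorsine",             "C18H25NO6", "retronecine",  "cyclic_diester", "0", ""),
    c("retrorsine N-oxide",     "C18H25NO7", "retronecine",  "cyclic_diester", "1", ""),
    c("usaramine",              "C18H25NO6", "retronecine",  "cyclic_diester", "0", ""),
    c("usaramine N-oxide",      "C18H25NO7", "retronecine",  "cyclic_diester", "1", ""),
    # otonecine type
    c("senkirkine",             "C19H27NO6", "otonecine",    "cyclic_diester", "0", "")
  )
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(df) <- c("name", "formula", "necine_class", "ester_type",
                 "is_n_oxide", "coelution_group")
  df$is_n_oxide <- df$is_n_oxide == "1"
  df$coelution_group[df$coelution_group == ""] <- NA_character_
  df$regulated <- TRUE
  df
}

#' The regulated 35-compound PA/PANO panel
#'
#' Returns the panel of 35 pyrrolizidine alkaloids and N-oxides whose sum is
#' regulated in honey (Regulation (EU) 2023/915): free bases and N-oxides of
#' the lycopsamine, heliotrine, echimidine and senecionine structural types
#' plus senkirkine. Co-elution groups mark isomer pairs that are not
#' chromatographically resolved and are therefore quantified as a sum
#' (indicine + lycopsamine, echinatine + rinderine,
#' indicine N-oxide + intermedine N-oxide).
#'
#' @return A data.frame with one row per compound and columns `name`,
#'   `formula`, `monoisotopic_mass`, `necine_class`, `ester_type`,
#'   `is_n_oxide`, `regulated`, `coelution_group` (NA when resolved).
#' @examples
#' nrow(regulated_panel())  # 35
#' @export
regulated_panel <- function() {
  df <- .panel_def()
  df$monoisotopic_mass <- vapply(df$formula, monoisotopic_mass, numeric(1))
  df[, c("name", "formula", "monoisotopic_mass", "necine_class",
         "ester_type", "is_n_oxide", "regulated", "coelution_group")]
}

#' Panel reporting groups
#'
#' Collapses the 35-compound panel into its reporting analytes: co-eluting
#' isomer pairs become a single `"a + b"` group, all other compounds report
#' individually (32 analytes in total).
#'
#' @return data.frame with columns `analyte` (reporting label), `members`
#'   (list column of panel compound names), `is_n_oxide`.
#' @export
panel_reporting_groups <- function() {
  panel <- regulated_panel()
  grp <- panel$coelution_group
  singles <- panel[is.na(grp), ]
  out <- data.frame(analyte = singles$name, stringsAsFactors = FALSE)
  out$members <- as.list(singles$name)
  out$is_n_oxide <- singles$is_n_oxide
  for (g in unique(grp[!is.na(grp)])) {
    members <- panel$name[!is.na(grp) & grp == g]
    out <- rbind(out, data.frame(
      analyte = paste(sort(members), collapse = " + "),
      members = I(list(sort(members))),
      is_n_oxide = panel$is_n_oxide[match(members[1], panel$name)]
    ))
  }
  rownames(out) <- NULL
  out[order(out$analyte), , drop = FALSE]
}

#' Non-regulated reference compounds
#'
#' Necine bases and other pyrrolizidine-family compounds that are not part of
#' the regulated panel but recur in suspect screening (platynecine,
#' retronecine, heliotridine).
#'
#' @return data.frame in the same layout as [regulated_panel()].
#' @export
related_compounds <- function() {
  df <- data.frame(
    name = c("platynecine", "retronecine", "heliotridine"),
    formula = c("C8H15NO2", "C8H13NO2", "C8H13NO2"),
    necine_class = c("platynecine", "retronecine", "heliotridine"),
    ester_type = "necine_base",
    is_n_oxide = FALSE,
    regulated = FALSE,
    coelution_group = NA_character_,
    stringsAsFactors = FALSE
  )
  df$monoisotopic_mass <- vapply(df$formula, monoisotopic_mass, numeric(1))
  df[, c("name", "formula", "monoisotopic_mass", "necine_class",
         "ester_type", "is_n_oxide", "regulated", "coelution_group")]
}

#' Known literature m/z discrepancies
#'
#' Documented inconsistencies between values printed in the source literature
#' and the formula-derived exact masses used by this package. The package
#' always stores the formula-derived value.
#'
#' @return data.frame with `compound`, `printed_mz`, `formula`,
#'   `formula_derived_mz`, `note`.
#' @export
known_literature_discrepancies <- function() {
  data.frame(
    compound = "platynecine",
    printed_mz = 156.1,
    formula = "C8H15NO2",
    formula_derived_mz = round(compute_ion_mz("C8H15NO2", "[M+H]+"), 4),
    note = paste("literature prints [M+H]+ 156.1, which matches retronecine",
                 "(C8H13NO2), not platynecine; formula-derived 158.1176 kept"),
    stringsAsFactors = FALSE
  )
}
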