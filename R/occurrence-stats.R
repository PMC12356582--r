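# Occurrence and cohort statistics over samples-by-analytes tables.

.check_table <- function(table) {
  stopifnot(inherits(table, "occurrence_table"))
  if (nrow(table$samples) == 0L) stop("empty occurrence table", call. = FALSE)
}

# logical matrix: analyte positive (>= LOQ) / detected (incl. censored)
.positive_matrix <- function(table, strict_loq = TRUE) {
  if (strict_loq) table$status == "quantified"
  else table$status != "absent"
}

#' Prevalence of PA-positive samples
#'
#' Percentage of samples with at least one positive analyte, overall and by
#' honey type. `strict_loq = TRUE` counts quantifiable detections only
#' (>= LOQ); `FALSE` counts any detection including "<LOQ".
#'
#' @param table `occurrence_table`.
#' @param by_type Also report per honey type.
#' @param strict_loq Positivity definition (see above).
#' @return list(`overall_percent`, `overall_fraction`, and with `by_type`
#'   a data.frame `by_type` with n, n positive, percent).
#' @export
prevalence <- function(table, by_type = TRUE, strict_loq = TRUE) {
  .check_table(table)
  pos <- rowSums(.positive_matrix(table, strict_loq)) > 0
  out <- list(overall_percent = round(100 * mean(pos)),
              overall_fraction = mean(pos))
  if (by_type) {
    tt <- table$samples$honey_type
    agg <- data.frame(
      honey_type = sort(unique(tt)),
      stringsAsFactors = FALSE)
    agg$n <- as.integer(table(tt)[agg$honey_type])
    agg$n_positive <- vapply(agg$honey_type,
                             function(h) sum(pos[tt == h]), integer(1))
    agg$fraction <- agg$n_positive / agg$n
    agg$percent <- round(100 * agg$fraction)
    out$by_type <- agg
  }
  out
}

#' Per-analyte detection frequency
#'
#' Percentage of samples in which each reporting analyte is detected,
#' ranked descending (ties alphabetical).
#'
#' @param table `occurrence_table`.
#' @param strict_loq Count quantifiable detections only.
#' @return data.frame `analyte`, `n_detected`, `percent`, `fraction`.
#' @export
analyte_frequency <- function(table, strict_loq = FALSE) {
  stopifnot(inherits(table, "occurrence_table"))
  if (nrow(table$samples) == 0L) {
    return(data.frame(analyte = character(0), n_detected = integer(0),
                      percent = numeric(0), fraction = numeric(0)))
  }
  det <- colSums(.positive_matrix(table, strict_loq))
  df <- data.frame(analyte = table$analytes, n_detected = as.integer(det),
                   fraction = det / nrow(table$samples),
                   stringsAsFactors = FALSE)
  df$percent <- round(100 * df$fraction)
  df <- df[order(-df$fraction, df$analyte), , drop = FALSE]
  rownames(df) <- NULL
  df[, c("analyte", "n_detected", "percent", "fraction")]
}

#' Co-occurrence distribution
#'
#' Histogram of the number of PAs per positive sample in the bins 1-2, 3-5,
#' 6-10, >10, overall and per honey type.
#'
#' @param table `occurrence_table`.
#' @param strict_loq Positivity definition.
#' @return list(`overall` named counts, `by_type` matrix, `per_sample`
#'   counts for positive samples).
#' @export
cooccurrence_distribution <- function(table, strict_loq = TRUE) {
  stopifnot(inherits(table, "occurrence_table"))
  npa <- rowSums(.positive_matrix(table, strict_loq))
  bins <- c("1-2", "3-5", "6-10", ">10")
  bin_of <- function(k) bins[findInterval(k, c(1, 3, 6, 11))]
  pos <- npa > 0
  overall <- stats::setNames(integer(4), bins)
  tab <- table(factor(bin_of(npa[pos]), levels = bins))
  overall[names(tab)] <- as.integer(tab)
  types <- sort(unique(table$samples$honey_type))
  by_type <- sapply(types, function(h) {
    sel <- pos & table$samples$honey_type == h
    t2 <- table(factor(bin_of(npa[sel]), levels = bins))
    as.integer(t2)
  })
  rownames(by_type) <- bins
  list(overall = overall, by_type = by_type, per_sample = npa[pos])
}

#' One-way ANOVA of an analyte against honey type
#'
#' Fixed-effects one-way ANOVA of the analyte concentration (censored
#' values coded as zero, the lower-bound convention, or omitted) on honey
#' type, after excluding types with fewer than `min_group_n` samples.
#'
#' @param table `occurrence_table`.
#' @param analyte Reporting analyte name, or `"total"` for the lower-bound
#'   panel sum.
#' @param min_group_n Exclusion threshold (default 5).
#' @param censored `"zero"` (lower bound) or `"omit"`.
#' @return list(`analyte`, `f_statistic`, `p_value`, `group_ns`).
#' @export
anova_by_type <- function(table, analyte, min_group_n = 5,
                          censored = c("zero", "omit")) {
  .check_table(table)
  censored <- match.arg(censored)
  y <- if (identical(analyte, "total")) rowSums(table$value)
  else {
    stopifnot(analyte %in% table$analytes)
    table$value[, analyte]
  }
  type <- table$samples$honey_type
  if (censored == "omit" && !identical(analyte, "total")) {
    drop <- table$status[, analyte] == "censored"
    y <- y[!drop]; type <- type[!drop]
  }
  counts <- table(type)
  eligible <- names(counts)[counts >= min_group_n]
  if (length(eligible) < 2L) {
    stop("fewer than two honey types with n >= ", min_group_n, call. = FALSE)
  }
  sel <- type %in% eligible
  fit <- stats::aov(y[sel] ~ factor(type[sel]))
  s <- summary(fit)[[1]]
  list(analyte = analyte, f_statistic = s$`F value`[1],
       p_value = s$`Pr(>F)`[1],
       group_ns = stats::setNames(as.integer(counts[eligible]), eligible))
}

#' Pearson correlation matrix of analytes
#'
#' Symmetric analyte-by-analyte Pearson correlation (censored values coded
#' zero); constant columns yield NA rows/columns; pairs at or above the
#' reporting threshold are listed.
#'
#' @param table `occurrence_table`.
#' @param threshold Strong-correlation report threshold (default 0.7).
#' @param drop_empty Drop analytes never detected.
#' @return list(`matrix`, `strong_pairs` data.frame).
#' @export
pearson_matrix <- function(table, threshold = 0.7, drop_empty = TRUE) {
  .check_table(table)
  if (nrow(table$samples) < 3L) stop("need >= 3 samples", call. = FALSE)
  x <- table$value
  if (drop_empty) x <- x[, colSums(table$status != "absent") > 0, drop = FALSE]
  const <- apply(x, 2, function(v) stats::sd(v) == 0)
  m <- suppressWarnings(stats::cor(x, method = "pearson"))
  m[const, ] <- NA; m[, const] <- NA
  diag(m)[!const] <- 1
  pairs <- which(upper.tri(m) & m >= threshold, arr.ind = TRUE)
  strong <- data.frame(
    analyte_a = colnames(m)[pairs[, 1]],
    analyte_b = colnames(m)[pairs[, 2]],
    r = m[pairs], stringsAsFactors = FALSE)
  strong <- strong[order(-strong$r), , drop = FALSE]
  rownames(strong) <- NULL
  list(matrix = m, strong_pairs = strong)
}

#' Hierarchical clustering of samples
#'
#' Agglomerative clustering of sample PA profiles with Euclidean distance
#' and Ward's linkage (`ward.D2`, the Ward criterion on Euclidean
#' distances). Analytes are z-scored by default; honey types below the
#' group-size threshold are excluded, mirroring the ANOVA exclusion rule.
#'
#' @param table `occurrence_table`.
#' @param standardize z-score analyte columns (constant columns dropped).
#' @param min_group_n Honey-type exclusion threshold (default 5).
#' @return list(`hclust`, `samples` used, `merge_heights`, `leaf_order`).
#' @export
hca <- function(table, standardize = TRUE, min_group_n = 5) {
  .check_table(table)
  counts <- table(table$samples$honey_type)
  keep_type <- names(counts)[counts >= min_group_n]
  sel <- table$samples$honey_type %in% keep_type
  x <- table$value[sel, , drop = FALSE]
  if (nrow(x) < 2L) stop("fewer than two samples after exclusion",
                         call. = FALSE)
  if (standardize) {
    keep_col <- apply(x, 2, function(v) stats::sd(v) > 0)
    x <- scale(x[, keep_col, drop = FALSE])
  }
  hc <- stats::hclust(stats::dist(x, method = "euclidean"),
                      method = "ward.D2")
  hc$labels <- table$samples$sample_id[sel]
  list(hclust = hc,
       samples = table$samples[sel, , drop = FALSE],
       merge_heights = hc$height, leaf_order = hc$order)
}
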