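# construct a small occurrence table directly (bypassing the generator)
make_table <- function(types, conc, status = NULL, loq = 0.1) {
  n <- length(types)
  analytes <- colnames(conc)
  if (is.null(status)) {
    status <- matrix(ifelse(conc >= loq, "quantified", "absent"),
                     n, ncol(conc), dimnames = dimnames(conc))
  }
  value <- ifelse(status == "quantified", conc, 0)
  dimnames(value) <- dimnames(conc)
  structure(list(
    samples = data.frame(sample_id = sprintf("S%02d", seq_len(n)),
                         honey_type = types, stringsAsFactors = FALSE),
    analytes = analytes, value = value, status = status,
    loq = loq, panel_version = "test"
  ), class = "occurrence_table")
}

test_that("prevalence counts positive samples overall and per type", {
  conc <- matrix(0, 4, 2, dimnames = list(NULL, c("a", "b")))
  tab0 <- make_table(rep("eucalyptus", 4), conc)
  expect_equal(prevalence(tab0)$overall_percent, 0)

  # 10 of 11 eucalyptus positive -> 91%
  conc <- matrix(c(rep(5, 10), 0), 11, 1, dimnames = list(NULL, "a"))
  tab <- make_table(rep("eucalyptus", 11), conc)
  p <- prevalence(tab)
  expect_equal(p$overall_percent, 91)
  expect_equal(p$by_type$percent[p$by_type$honey_type == "eucalyptus"], 91)

  # per-type positives sum to the overall count
  tab2 <- generate_cohort(seed = 9)
  p2 <- prevalence(tab2)
  expect_equal(sum(p2$by_type$n_positive),
               round(p2$overall_fraction * nrow(tab2$samples)))
  expect_equal(sum(p2$by_type$n), 80L)
})

test_that("strict and detected-any positivity are both exposed", {
  conc <- matrix(c(5, 0.05), 2, 1, dimnames = list(NULL, "a"))
  status <- matrix(c("quantified", "censored"), 2, 1,
                   dimnames = list(NULL, "a"))
  tab <- make_table(rep("thyme", 2), conc, status)
  expect_equal(prevalence(tab, strict_loq = TRUE)$overall_percent, 50)
  expect_equal(prevalence(tab, strict_loq = FALSE)$overall_percent, 100)
})

test_that("analyte frequency ranks by detection percentage", {
  conc <- cbind(a = c(rep(1, 3), rep(0, 7)), b = c(rep(1, 5), rep(0, 5)))
  tab <- make_table(rep("thyme", 10), conc)
  f <- analyte_frequency(tab)
  expect_equal(f$analyte, c("b", "a"))
  expect_equal(f$percent, c(50, 30))

  empty <- make_table(character(0),
                      matrix(0, 0, 1, dimnames = list(NULL, "a")))
  expect_equal(nrow(analyte_frequency(empty)), 0L)
})

test_that("co-occurrence bins follow the 1-2 / 3-5 / 6-10 / >10 scheme", {
  conc <- matrix(0, 3, 12,
                 dimnames = list(NULL, paste0("a", 1:12)))
  conc[1, 1:7] <- 1    # 7 analytes -> 6-10 bin
  conc[2, 1] <- 1      # 1 analyte  -> 1-2 bin
  tab <- make_table(rep("thyme", 3), conc)
  h <- cooccurrence_distribution(tab)
  expect_equal(unname(h$overall), c(1L, 0L, 1L, 0L))

  all_neg <- make_table(rep("thyme", 2),
                        matrix(0, 2, 2, dimnames = list(NULL, c("a", "b"))))
  expect_true(all(cooccurrence_distribution(all_neg)$overall == 0))

  # the default synthetic cohort is dominated by 1-2 PAs per positive sample
  co <- cooccurrence_distribution(generate_cohort(seed = 12))
  expect_equal(names(which.max(co$overall)), "1-2")
})

test_that("one-way ANOVA matches hand computation and brute force", {
  conc <- cbind(a = c(1, 2, 3, 4, 5, 6))
  tab <- make_table(rep(c("g1", "g2"), each = 3), conc)
  res <- anova_by_type(tab, "a", min_group_n = 3)
  expect_equal(round(res$f_statistic, 1), 13.5)

  same <- make_table(rep(c("g1", "g2"), each = 3), cbind(a = rep(1:3, 2)))
  res0 <- anova_by_type(same, "a", min_group_n = 3)
  expect_equal(res0$f_statistic, 0)
  expect_equal(res0$p_value, 1)

  # brute-force sums of squares on random tables
  set.seed(13)
  for (i in 1:5) {
    y <- rnorm(20)
    g <- rep(c("u", "v", "w", "x"), each = 5)
    tabr <- make_table(g, cbind(a = abs(y) + 1))
    res <- anova_by_type(tabr, "a", min_group_n = 5)
    yy <- abs(y) + 1
    gm <- mean(yy)
    ssb <- sum(tapply(yy, g, function(v) length(v) * (mean(v) - gm)^2))
    ssw <- sum(tapply(yy, g, function(v) sum((v - mean(v))^2)))
    f_oracle <- (ssb / 3) / (ssw / 16)
    expect_equal(res$f_statistic, f_oracle, tolerance = 1e-9)
  }
})

test_that("small honey types are excluded from ANOVA and HCA", {
  tab <- generate_cohort(seed = 21)
  res <- anova_by_type(tab, "total")
  excluded <- c("heather", "albaida", "oak", "anise")
  expect_false(any(excluded %in% names(res$group_ns)))
  expect_true(all(res$group_ns >= 5))

  h <- hca(tab)
  expect_false(any(excluded %in% h$samples$honey_type))

  few <- make_table(rep(c("g1", "g2"), each = 2), cbind(a = rnorm(4) + 5))
  expect_error(anova_by_type(few, "a"), "fewer than two")
})

test_that("the censored-omit ANOVA mode drops <LOQ rows", {
  conc <- cbind(a = c(1, 2, 3, 0.05, 4, 5, 6, 0.05))
  status <- matrix(ifelse(conc >= 0.1, "quantified", "censored"), 8, 1,
                   dimnames = list(NULL, "a"))
  tab <- make_table(rep(c("g1", "g2"), each = 4), conc, status)
  z <- anova_by_type(tab, "a", min_group_n = 3, censored = "zero")
  o <- anova_by_type(tab, "a", min_group_n = 3, censored = "omit")
  expect_false(isTRUE(all.equal(z$f_statistic, o$f_statistic)))
})

test_that("Pearson correlations detect co-generated analytes", {
  x <- c(1, 2, 3, 4, 5)
  conc <- cbind(a = x, b = 2 * x, c = 10 - 2 * x + 0.5,
                d = c(5, 1, 4, 2, 3))
  tab <- make_table(rep("thyme", 5), conc)
  pm <- pearson_matrix(tab, threshold = 0.7)
  expect_equal(diag(pm$matrix), rep(1, 4), ignore_attr = TRUE)
  expect_equal(pm$matrix["a", "b"], 1)
  expect_equal(pm$matrix["a", "c"], -1)
  expect_true(any(pm$strong_pairs$analyte_a == "a" &
                    pm$strong_pairs$analyte_b == "b"))

  # constant columns are masked
  conc2 <- cbind(a = x, k = rep(2, 5))
  pm2 <- pearson_matrix(make_table(rep("thyme", 5), conc2), drop_empty = FALSE)
  expect_true(all(is.na(pm2$matrix["k", ])))
})

test_that("correlated co-occurrence shows up in synthetic cohorts", {
  # co-generate two analytes in the same samples at proportional levels
  set.seed(30)
  n <- 40
  base <- rlnorm(n, 0, 1) * rbinom(n, 1, 0.4)
  conc <- cbind("echinatine + rinderine" = base,
                "integerrimine" = 0.8 * base,
                "echimidine" = rlnorm(n, 0, 1) * rbinom(n, 1, 0.4))
  tab <- make_table(rep(c("eucalyptus", "wildflower"), each = 20), conc)
  pm <- pearson_matrix(tab)
  expect_true(any(
    pm$strong_pairs$analyte_a == "echinatine + rinderine" &
      pm$strong_pairs$analyte_b == "integerrimine"))
})

test_that("Ward/Euclidean clustering merges nearest profiles first", {
  conc <- cbind(a = c(1, 1, 5), b = c(2, 2, 9))
  tab <- make_table(rep("thyme", 3), conc)
  h <- hca(tab, standardize = FALSE, min_group_n = 1)
  expect_equal(h$merge_heights[1], 0)            # identical profiles first
  expect_equal(sort(h$hclust$merge[1, ]), c(-2, -1))

  lin <- make_table(rep("thyme", 3), cbind(a = c(0, 1, 10)))
  h2 <- hca(lin, standardize = FALSE, min_group_n = 1)
  expect_equal(sort(h2$hclust$merge[1, ]), c(-2, -1))  # {0,1} merge first
})
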