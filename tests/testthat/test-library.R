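test_that("the regulated panel has the expected structure", {
  panel <- regulated_panel()
  expect_equal(nrow(panel), 35L)
  expect_true(all(c("echinatine", "echinatine N-oxide") %in% panel$name))
  # free bases + N-oxides partition the panel
  expect_equal(sum(panel$is_n_oxide) + sum(!panel$is_n_oxide), 35L)
  # every co-elution group has at least two members
  grp <- table(panel$coelution_group[!is.na(panel$coelution_group)])
  expect_true(all(grp >= 2))
  expect_setequal(names(grp), c("indicine_lycopsamine",
                                "echinatine_rinderine",
                                "indicineNO_intermedineNO"))
  # reported masses equal the formula-derived masses
  expect_equal(panel$monoisotopic_mass,
               vapply(panel$formula, monoisotopic_mass, numeric(1)),
               ignore_attr = TRUE)
})

test_that("reporting groups collapse co-eluting isomers", {
  g <- panel_reporting_groups()
  expect_equal(nrow(g), 32L)
  expect_true("indicine + lycopsamine" %in% g$analyte)
  expect_equal(sum(lengths(g$members)), 35L)
})

test_that("fragmentation tables parse into spectrum records", {
  row <- data.frame(name = "platynecine", formula = "C8H15NO2",
                    adduct = "[M+H]+", precursor_mz = NA,
                    fragment_mz = "140.1070", fragment_intensity = "",
                    stringsAsFactors = FALSE)
  sp <- parse_fragmentation_table(row)
  expect_length(sp, 1L)
  expect_equal(sp[[1]]$peaks$mz, 140.1070)
  expect_equal(sp[[1]]$peaks$intensity, 100)        # missing intensity rule
  expect_equal(round(sp[[1]]$precursor_mz, 4), 158.1176)

  expect_length(parse_fragmentation_table(row[0, ]), 0L)

  # count conservation on a large table
  big <- data.frame(name = sprintf("pa%03d", 1:148), formula = "C15H25NO5",
                    fragment_mz = "94.0651;120.0808",
                    stringsAsFactors = FALSE)
  expect_length(parse_fragmentation_table(big), 148L)
})

test_that("fragmentation-table validation rejects bad rows", {
  dup <- data.frame(name = c("a", "a"), formula = "C15H25NO5",
                    adduct = "[M+H]+", stringsAsFactors = FALSE)
  expect_error(parse_fragmentation_table(dup), "duplicate")

  high <- data.frame(name = "a", formula = "C15H25NO5",
                     fragment_mz = "400.0", stringsAsFactors = FALSE)
  expect_error(parse_fragmentation_table(high), "precursor")

  orphan <- data.frame(name = "a", formula = "", precursor_mz = NA,
                       fragment_mz = "94.0651", stringsAsFactors = FALSE)
  expect_error(parse_fragmentation_table(orphan), "neither formula")
})

test_that("intensities are normalised to a max of 100 when provided", {
  sp <- make_spectrum(c(100, 200), intensity = c(25, 50))
  expect_equal(max(sp$peaks$intensity), 100)
  expect_equal(sp$peaks$intensity, c(50, 100))
})

test_that("MSP round-trips preserve the library", {
  lib <- in_silico_library()
  path <- withr::local_tempfile(fileext = ".msp")
  write_msp(lib, path)
  # block count by separator scan, independent of the reader
  blocks <- sum(grepl("^Name:", readLines(path)))
  expect_equal(blocks, length(lib))

  back <- read_msp(path)
  expect_length(back, length(lib))
  for (i in seq_along(lib)) {
    expect_equal(back[[i]]$name, lib[[i]]$name)
    expect_equal(back[[i]]$adduct, lib[[i]]$adduct)
    expect_equal(back[[i]]$provenance, lib[[i]]$provenance)
    expect_equal(back[[i]]$peaks$mz, lib[[i]]$peaks$mz, tolerance = 1e-4)
    expect_equal(back[[i]]$peaks$intensity, lib[[i]]$peaks$intensity,
                 tolerance = 0.01)
    expect_equal(back[[i]]$precursor_mz, lib[[i]]$precursor_mz,
                 tolerance = 1e-4)
  }
})

test_that("MSP round-trip holds for randomly generated libraries", {
  set.seed(42)
  for (rep in 1:5) {
    n <- sample(1:6, 1)
    lib <- lapply(seq_len(n), function(i) {
      npk <- sample(1:12, 1)
      make_spectrum(sort(runif(npk, 50, 400)),
                    intensity = runif(npk, 1, 100),
                    name = sprintf("rand%d_%d", rep, i), precursor = 450,
                    provenance = "synthetic_run")
    })
    path <- withr::local_tempfile(fileext = ".msp")
    write_msp(lib, path)
    back <- read_msp(path)
    for (i in seq_len(n)) {
      expect_equal(back[[i]]$peaks$mz, lib[[i]]$peaks$mz, tolerance = 1e-4)
      expect_equal(back[[i]]$peaks$intensity, lib[[i]]$peaks$intensity,
                   tolerance = 0.01)
    }
  }
})

test_that("single-peak spectra serialise with Num Peaks: 1", {
  path <- withr::local_tempfile(fileext = ".msp")
  write_msp(list(make_spectrum(140.1070, name = "one")), path)
  expect_true(any(grepl("^Num Peaks: 1$", readLines(path))))
  expect_error(read_msp(textConnection("Name: broken\nno peaks here")),
               "Num Peaks")
})

test_that("class-ion list construction merges and deduplicates", {
  expect_equal(nrow(build_class_ion_list(list(), NULL)$ions), 0L)

  # two ions 2 ppm apart at 5 ppm tolerance collapse to one
  extras <- data.frame(mz = c(200.0000, 200.0004),
                       label = c("a", "b"), source = "x",
                       stringsAsFactors = FALSE)
  merged <- build_class_ion_list(list(), extras, tolerance_ppm = 5)
  expect_equal(nrow(merged$ions), 1L)

  # the shipped default list has 30 unique ions
  cil <- default_class_ion_list()
  expect_equal(nrow(cil$ions), 30L)
  d <- outer(cil$ions$mz, cil$ions$mz, function(a, b) abs(a - b) / b * 1e6)
  diag(d) <- Inf
  expect_true(all(d > 5))

  # JSON round trip
  path <- withr::local_tempfile(fileext = ".json")
  write_class_ion_list(cil, path)
  back <- read_class_ion_list(path)
  expect_equal(back$ions$mz, cil$ions$mz)
  expect_equal(back$tolerance_ppm, cil$tolerance_ppm)
})

test_that("the printed platynecine mass discrepancy is flagged, not copied", {
  d <- known_literature_discrepancies()
  plat <- d[d$compound == "platynecine", ]
  expect_equal(plat$printed_mz, 156.1)
  expect_equal(plat$formula_derived_mz, 158.1176)
  # the package does not reproduce the printed value
  expect_gt(abs(plat$formula_derived_mz - plat$printed_mz), 1)
})

test_that("shipped fixtures match the code that generates them", {
  json <- system.file("extdata", "class_ions_synthetic.json",
                      package = "patox")
  shipped <- read_class_ion_list(json)
  expect_equal(shipped$ions$mz, default_class_ion_list()$ions$mz)

  csv <- system.file("extdata", "fragmentation_table_synthetic.csv",
                     package = "patox")
  tab <- utils::read.csv(csv, stringsAsFactors = FALSE)
  lib <- parse_fragmentation_table(tab)
  ref <- in_silico_library()
  expect_length(lib, length(ref))
  expect_equal(vapply(lib, function(s) s$name, character(1)),
               vapply(ref, function(s) s$name, character(1)))
})
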