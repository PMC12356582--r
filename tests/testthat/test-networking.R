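# brute-force similarity oracle: enumerate all one-to-one peak pairings
# within tolerance and take the best total intensity product
oracle_similarity <- function(a, b, tol_ppm = 5) {
  pa <- a$peaks; pb <- b$peaks
  best <- list(dot = 0, n = 0L, ia = 0, ib = 0)
  recurse <- function(i, used_b, dot, n, ia, ib) {
    if (i > nrow(pa)) {
      if (dot > best$dot ||
          (dot == best$dot && n > best$n)) {
        best <<- list(dot = dot, n = n, ia = ia, ib = ib)
      }
      return(invisible())
    }
    recurse(i + 1L, used_b, dot, n, ia, ib)   # leave peak i unmatched
    for (j in seq_len(nrow(pb))) {
      if (used_b[j]) next
      if (abs(pa$mz[i] - pb$mz[j]) / pb$mz[j] * 1e6 > tol_ppm) next
      used_b2 <- used_b; used_b2[j] <- TRUE
      recurse(i + 1L, used_b2, dot + pa$intensity[i] * pb$intensity[j],
              n + 1L, ia + pa$intensity[i], ib + pb$intensity[j])
    }
  }
  recurse(1L, logical(nrow(pb)), 0, 0L, 0, 0)
  norm <- sqrt(sum(pa$intensity^2)) * sqrt(sum(pb$intensity^2))
  list(score = 100 * best$dot / norm,
       forward = 100 * best$ia / sum(pa$intensity),
       reverse = 100 * best$ib / sum(pb$intensity),
       n_matched = best$n)
}

test_that("self-similarity is exact and disjoint spectra score zero", {
  sp <- make_spectrum(c(94.0651, 120.0808, 138.0913),
                      intensity = c(40, 100, 60))
  s <- spectral_similarity(sp, sp)
  expect_equal(s$score, 100)
  expect_equal(s$forward_coverage, 100)
  expect_equal(s$reverse_coverage, 100)
  expect_equal(s$n_matched, 3L)

  other <- make_spectrum(c(200.1, 210.2))
  d <- spectral_similarity(sp, other)
  expect_equal(d$score, 0)
  expect_equal(d$n_matched, 0L)
  expect_error(spectral_similarity(sp, make_spectrum(numeric(0), precursor = 100)))
})

test_that("partial overlap matches the hand-computed cosine", {
  a <- make_spectrum(c(100, 150, 200, 250, 300), precursor = 400)
  b <- make_spectrum(c(100, 150, 200, 350.5, 370.7), precursor = 400)
  s <- spectral_similarity(a, b)
  expect_equal(s$n_matched, 3L)
  expect_equal(s$score, 100 * 3 / 5)           # equal intensities: 3/(sqrt5*sqrt5)
  expect_equal(s$forward_coverage, 60)
  # swapping arguments preserves score and swaps coverages
  s2 <- spectral_similarity(b, a)
  expect_equal(s2$score, s$score)
  expect_equal(s2$forward_coverage, s$reverse_coverage)
  expect_equal(s2$reverse_coverage, s$forward_coverage)
})

test_that("greedy matching agrees with the exhaustive-pairing oracle", {
  set.seed(8)
  for (i in 1:10) {
    a <- make_spectrum(sort(runif(4, 100, 300)),
                       intensity = runif(4, 10, 100), precursor = 400)
    # derive b from a so that some peaks fall inside tolerance
    shift <- sample(c(0, 2e-6, 1e-4), 4, replace = TRUE)
    b <- make_spectrum(sort(a$peaks$mz * (1 + shift)),
                       intensity = runif(4, 10, 100), precursor = 400)
    got <- spectral_similarity(a, b)
    ora <- oracle_similarity(a, b)
    expect_equal(got$n_matched, ora$n_matched)
    expect_equal(got$score, ora$score, tolerance = 1e-6)
  }
})

test_that("count-based coverage is available as an alternative", {
  a <- make_spectrum(c(100, 150, 200, 250), intensity = c(100, 1, 1, 1),
                     precursor = 300)
  b <- make_spectrum(c(100), precursor = 300)
  s_int <- spectral_similarity(a, b, coverage = "intensity")
  s_cnt <- spectral_similarity(a, b, coverage = "count")
  expect_gt(s_int$forward_coverage, 90)
  expect_equal(s_cnt$forward_coverage, 25)
})

test_that("the panel network interconnects all standards", {
  lib <- in_silico_library(include_related = FALSE)
  names(lib) <- vapply(lib, function(s) s$name, character(1))
  labels <- stats::setNames(rep("PA", length(lib)), names(lib))
  g <- build_network(lib, network_params(), labels = labels)
  expect_equal(nrow(g$nodes), 35L)
  # every standard connects to at least one other standard
  expect_true(all(igraph::degree(g$graph) >= 1))
  expect_true(all(igraph::degree(g$graph) <= network_params()$max_edges_per_node + 35))
  expect_true(all(table(g$nodes$cluster) <= 100))
  # no self edges
  expect_false(any(g$edges$a == g$edges$b))
})

test_that("edges are deterministic under input permutation", {
  lib <- in_silico_library(include_related = FALSE)
  names(lib) <- vapply(lib, function(s) s$name, character(1))
  g1 <- build_network(lib, network_params())
  set.seed(1)
  g2 <- build_network(sample(lib), network_params())
  expect_equal(g1$edges, g2$edges)
})

test_that("two disjoint spectra give an empty edge set", {
  a <- make_spectrum(c(100, 110, 120), name = "a", precursor = 200)
  b <- make_spectrum(c(150, 160, 170), name = "b", precursor = 200)
  g <- build_network(list(a = a, b = b), network_params())
  expect_equal(nrow(g$edges), 0L)
  expect_equal(length(unique(g$nodes$cluster)), 2L)
})

test_that("raising thresholds never adds edges", {
  lib <- in_silico_library()
  names(lib) <- vapply(lib, function(s) s$name, character(1))
  base <- build_network(lib, network_params(max_edges_per_node = Inf))
  for (p in list(network_params(min_score = 40, max_edges_per_node = Inf),
                 network_params(min_matched_fragments = 5,
                                max_edges_per_node = Inf),
                 network_params(min_coverage_percent = 60,
                                max_edges_per_node = Inf))) {
    g <- build_network(lib, p)
    key <- function(e) paste(e$a, e$b)
    expect_true(all(key(g$edges) %in% key(base$edges)))
  }
})

test_that("the cluster cap splits oversized components", {
  set.seed(5)
  mz <- sort(runif(6, 100, 300))
  spectra <- lapply(1:120, function(i) {
    make_spectrum(mz, intensity = runif(6, 50, 100),
                  name = sprintf("n%03d", i), precursor = 400)
  })
  names(spectra) <- sprintf("n%03d", 1:120)
  g <- build_network(spectra, network_params(max_cluster_size = 100))
  expect_true(all(table(g$nodes$cluster) <= 100))
})

test_that("cluster membership flags putative PAs by association", {
  lib <- in_silico_library(include_related = FALSE)
  names(lib) <- vapply(lib, function(s) s$name, character(1))
  labels <- stats::setNames(rep("PA", length(lib)), names(lib))
  rel <- in_silico_library()
  plat <- rel[[which(vapply(rel, function(s) s$name,
                            character(1)) == "platynecine")]]
  g <- build_network(c(lib, platynecine = list(plat)), network_params(),
                     labels = c(labels, platynecine = NA))
  cm <- cluster_membership(g, "platynecine")
  expect_true(cm$putative_pa)
  expect_gte(cm$n_annotated_pa, 3L)

  # an isolated node is not flagged
  iso <- make_spectrum(c(500.1, 600.2, 700.3), name = "iso", precursor = 745)
  g2 <- build_network(c(lib, iso = list(iso)), network_params(),
                      labels = c(labels, iso = NA))
  cm2 <- cluster_membership(g2, "iso")
  expect_length(cm2$members, 1L)
  expect_false(cm2$putative_pa)

  expect_error(cluster_membership(g2, "nope"), "unknown node")
})

test_that("network exports round-trip through GraphML", {
  lib <- in_silico_library(include_related = FALSE)[1:8]
  names(lib) <- vapply(lib, function(s) s$name, character(1))
  g <- build_network(lib, network_params())
  path <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(g, path)
  back <- igraph::read_graph(path, format = "graphml")
  expect_equal(igraph::vcount(back), nrow(g$nodes))
  expect_equal(igraph::ecount(back), nrow(g$edges))
  expect_equal(sort(igraph::edge_attr(back, "score")), sort(g$edges$score))

  csv <- withr::local_tempfile(fileext = ".csv")
  write_edge_list(g, csv)
  expect_equal(nrow(utils::read.csv(csv)), nrow(g$edges))
})
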