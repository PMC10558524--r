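test_that("the contact graph mirrors the denoised matrix", {
  m <- matrix(0, 3, 3); m[1, 2] <- m[2, 1] <- 2
  g <- build_graph(toy_cm(m, state = "denoised"))
  expect_equal(igraph::vcount(g), 3) # isolated contig kept as a vertex
  expect_equal(igraph::ecount(g), 1)
  expect_equal(unname(igraph::strength(g)), c(2, 2, 0))
  expect_equal(sum(igraph::E(g)$weight), 2)
  expect_error(build_graph(toy_cm(diag(c(1, 2, 0)), state = "raw")),
               "off-diagonal")
  # 4-contig toy, hand-tabulated degrees
  m4 <- matrix(0, 4, 4)
  m4[1, 2] <- m4[2, 1] <- 1.5; m4[1, 3] <- m4[3, 1] <- 0.5
  m4[3, 4] <- m4[4, 3] <- 2.5
  g4 <- build_graph(toy_cm(m4, state = "denoised"))
  expect_equal(unname(igraph::strength(g4)), c(2, 1.5, 3, 2.5))
})

test_that("RB modularity matches the exhaustive ordered-pair oracle", {
  for (n in 4:8) {
    A <- random_adjacency(n, seed = 100 + n)
    g <- graph_from_adjacency(A)
    partitions <- enum_set_partitions(n)
    # subsample large partition sets to keep the sweep quick but unbiased
    if (length(partitions) > 600) {
      set.seed(n)
      partitions <- partitions[sample(length(partitions), 600)]
    }
    for (r in c(0, 1, 2.5)) {
      got <- vapply(partitions, function(p) rb_modularity(g, p, r), numeric(1))
      want <- vapply(partitions, function(p) rb_oracle(A, p, r), numeric(1))
      expect_equal(got, want, tolerance = 1e-9)
    }
  }
})

test_that("RB modularity limit cases", {
  A <- random_adjacency(6, seed = 1)
  g <- graph_from_adjacency(A)
  # whole graph in one bin at r = 0: sum of e_ij over ordered pairs
  expect_equal(rb_modularity(g, rep(1, 6), r = 0), sum(A))
  # singleton bins: no same-bin pairs
  expect_equal(rb_modularity(g, 1:6, r = 1), 0)
})

test_that("Leiden recovers planted cliques and attains the exhaustive optimum", {
  # two 4-cliques joined by one light edge
  A <- matrix(0, 8, 8)
  A[1:4, 1:4] <- 1; A[5:8, 5:8] <- 1; diag(A) <- 0
  A[4, 5] <- A[5, 4] <- 0.1
  g <- graph_from_adjacency(A)
  part <- leiden_cluster(g, r = 1, seed = 42)
  expect_equal(length(unique(part$bin_id)), 2)
  expect_equal(length(unique(part$bin_id[1:4])), 1)
  expect_equal(length(unique(part$bin_id[5:8])), 1)
  # exhaustive maximisation over all 4140 partitions of 8 vertices
  best <- max(vapply(enum_set_partitions(8),
                     function(p) rb_modularity(g, p, 1), numeric(1)))
  expect_equal(rb_modularity(g, part, 1), best, tolerance = 1e-9)
  expect_true(is_move_stable(g, part, 1))
})

test_that("disconnected components are not merged at r >= 1", {
  A <- matrix(0, 6, 6)
  A[1:3, 1:3] <- 2; A[4:6, 4:6] <- 2; diag(A) <- 0
  g <- graph_from_adjacency(A)
  part <- leiden_cluster(g, r = 1, seed = 42)
  expect_equal(length(unique(part$bin_id)), 2)
  # merging the components strictly lowers the objective
  split <- rep(c(1, 2), each = 3)
  merged <- rep(1, 6)
  expect_lt(rb_modularity(g, merged, 1), rb_modularity(g, split, 1))
})

test_that("clustering is deterministic given (graph, r, seed)", {
  A <- random_adjacency(20, seed = 77)
  g <- graph_from_adjacency(A)
  p1 <- leiden_cluster(g, r = 1, seed = 42)
  p2 <- leiden_cluster(g, r = 1, seed = 42)
  expect_identical(p1$bin_id, p2$bin_id)
  expect_true(is_move_stable(g, p1, 1))
})

test_that("genome count estimation is the median-ceiling with override", {
  expect_equal(estimate_genome_count(c(10, 10, 10, 10))$k, 10)
  expect_equal(estimate_genome_count(c(0, 10, 10, 12))$k, 10)
  expect_equal(estimate_genome_count(c(3, 4))$k, 4) # median 3.5, ceiling
  est <- estimate_genome_count(data.frame(marker_id = "m1", count = 7),
                               k = 25)
  expect_equal(est$k, 25)
  expect_false(est$estimated)
  expect_error(estimate_genome_count(numeric(0)), "empty")
  expect_error(estimate_genome_count(NULL), "empty")
})

test_that("resolution search returns the first r with k_r > k and logs a trace", {
  # two heavy 3-cliques of 60 kbp contigs: r = 1 yields 2 resolved bins
  A <- matrix(0, 6, 6)
  A[1:3, 1:3] <- 5; A[4:6, 4:6] <- 5; diag(A) <- 0
  ids <- paste0("c", 1:6)
  g <- graph_from_adjacency(A, ids)
  catalog <- toy_catalog(ids, length = 60000L)
  sel <- select_resolution(g, k = 1, catalog, seed = 42)
  expect_equal(sel$r, 1)
  expect_equal(sel$trace$k_r[1], 2)
  expect_identical(names(sel$trace), c("r", "k_r"))
  # grid exhaustion falls back to the best k_r with a warning
  expect_warning(
    sel2 <- select_resolution(g, k = 5, catalog, grid = c(1, 20), seed = 42),
    "exhausted")
  expect_equal(nrow(sel2$trace), 2)
})

test_that("bin size flags respect the 150 kbp boundary inclusively", {
  part <- structure(data.frame(contig_id = c("a", "b", "c", "d", "e"),
                               bin_id = c("B1", "B2", "B2", "B2", "B3")),
                    class = c("Partition", "data.frame"))
  catalog <- contig_catalog(c("a", "b", "c", "d", "e"),
                            length = c(200000, 40000, 40000, 40000, 150000),
                            n_sites = 1)
  out <- make_initial_bins(part, catalog)
  bins <- attr(out, "bins")
  expect_true(bins$resolved[bins$bin_id == "B1"])   # 200 kbp
  expect_false(bins$resolved[bins$bin_id == "B2"])  # 120 kbp total
  expect_true(bins$resolved[bins$bin_id == "B3"])   # exactly 150 kbp
  expect_equal(bins$size_bp[bins$bin_id == "B2"], 120000)
})

test_that("bin cleaning re-clusters contaminated bins at resolution 1", {
  # bin B1: two disconnected 2-vertex halves, each 200 kbp
  ids <- paste0("v", 1:6)
  A <- matrix(0, 6, 6, dimnames = list(ids, ids))
  A[1, 2] <- A[2, 1] <- 3 # half 1 of B1
  A[3, 4] <- A[4, 3] <- 3 # half 2 of B1
  A[5, 6] <- A[6, 5] <- 3 # B2
  g <- graph_from_adjacency(A, ids)
  catalog <- toy_catalog(ids, length = 100000L)
  part <- structure(data.frame(contig_id = ids,
                               bin_id = rep(c("B1", "B2"), c(4, 2))),
                    class = c("Partition", "data.frame"))
  part <- make_initial_bins(part, catalog)
  quality <- data.frame(bin_id = c("B1", "B2"),
                        completeness = c(90, 95),
                        contamination = c(40, 2))
  cleaned <- clean_bins(part, quality, g, catalog)
  bins <- attr(cleaned, "bins")
  expect_false("B1" %in% bins$bin_id) # parent replaced
  subs <- grep("^B1_", bins$bin_id, value = TRUE)
  expect_length(subs, 2)
  expect_true(all(bins$resolved[bins$bin_id %in% subs])) # 200 kbp each
  expect_true("B2" %in% bins$bin_id) # clean bin untouched
  expect_identical(cleaned$bin_id[cleaned$contig_id %in% c("v5", "v6")],
                   c("B2", "B2"))

  # no bin contaminated: output identical to input
  quality_ok <- data.frame(bin_id = c("B1", "B2"),
                           completeness = c(90, 95),
                           contamination = c(5, 2))
  same <- clean_bins(part, quality_ok, g, catalog)
  expect_identical(same$bin_id, part$bin_id)

  # contaminated bin whose sub-bins are all too small: parent removed,
  # nothing merged back as resolved
  small_cat <- toy_catalog(ids, length = 60000L)
  part_small <- make_initial_bins(part, small_cat)
  cleaned_small <- clean_bins(part_small, quality, g, small_cat)
  bins_small <- attr(cleaned_small, "bins")
  expect_false("B1" %in% bins_small$bin_id)
  expect_false(any(bins_small$resolved[grep("^B1_", bins_small$bin_id)]))

  expect_error(clean_bins(part, data.frame(bin_id = "nope",
                                           completeness = 60,
                                           contamination = 20),
                          g, catalog), "unknown")
})

test_that("communities never shrink in number as resolution grows (observed)", {
  set.seed(7)
  A <- random_adjacency(30, seed = 30)
  g <- graph_from_adjacency(A)
  ncomm <- vapply(c(1, 5, 20, 60),
                  function(r) length(unique(leiden_cluster(g, r, seed = 1)$bin_id)),
                  numeric(1))
  expect_true(all(diff(ncomm) >= 0))
})
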