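test_that("uniform generator satisfies the hypernetwork invariants", {
  cases <- list(c(100, 15, 10), c(100, 20, 10), c(30, 3, 10), c(10, 1, 10),
                c(50, 25, 2))
  for (cs in cases) {
    for (seed in 1:5) {
      hn <- generate_uniform_hypernetwork(cs[1], cs[2], cs[3], seed = seed)
      expect_length(hn$hyperedges, cs[2])
      expect_true(all(lengths(hn$hyperedges) == cs[3]))
      expect_true(all(vapply(hn$hyperedges,
                             function(e) !anyDuplicated(e), logical(1))))
      covered <- sort(unique(unlist(hn$hyperedges)))
      expect_identical(covered, seq_len(cs[1]))
    }
  }
})

test_that("a single hyperedge of full size contains every node", {
  hn <- generate_uniform_hypernetwork(10, 1, 10, seed = 1)
  expect_identical(sort(hn$hyperedges[[1]]), 1:10)
})

test_that("infeasible sizes are rejected", {
  expect_error(generate_uniform_hypernetwork(5, 2, 10),
               class = "hyperurn_invalid_config")
  expect_error(generate_uniform_hypernetwork(100, 5, 10),
               class = "hyperurn_invalid_config")
  expect_error(generate_overlapping_hypernetwork(5, 2, 10, 0.5),
               class = "hyperurn_invalid_config")
})

test_that("generation is reproducible from the seed", {
  a <- generate_uniform_hypernetwork(100, 15, 10, seed = 42)
  b <- generate_uniform_hypernetwork(100, 15, 10, seed = 42)
  expect_identical(a, b)
  d <- generate_overlapping_hypernetwork(100, 20, 10, 0.5, seed = 7)
  e <- generate_overlapping_hypernetwork(100, 20, 10, 0.5, seed = 7)
  expect_identical(d, e)
})

test_that("overlap generator hits the requested multi-membership rate", {
  frac <- vapply(1:150, function(seed) {
    hn <- generate_overlapping_hypernetwork(100, 20, 10, 0.5, seed = seed)
    deg <- tabulate(unlist(hn$hyperedges), nbins = 100)
    mean(deg >= 2)
  }, numeric(1))
  n_obs <- 150 * 100
  half_width <- 2.576 * sqrt(0.25 / n_obs)
  expect_lt(abs(mean(frac) - 0.5), half_width + 0.01)
})

test_that("zero multi-membership with exact slot budget gives a partition", {
  hn <- generate_overlapping_hypernetwork(100, 10, 10, 0, seed = 3)
  deg <- tabulate(unlist(hn$hyperedges), nbins = 100)
  expect_true(all(deg == 1L))
})

test_that("base structure has the expected membership-slot budget", {
  hn <- generate_overlapping_hypernetwork(100, 15, 10, 0.5, seed = 11)
  expect_identical(sum(lengths(hn$hyperedges)), 150L)
  expect_true(all(lengths(hn$hyperedges) == 10L))
})

test_that("purpose assignment is Bernoulli(delta1) and independent", {
  hn <- generate_uniform_hypernetwork(100, 15, 10, seed = 1)
  expect_true(all(assign_purposes(hn, 1, seed = 1)$purposes == "RED"))
  expect_true(all(assign_purposes(hn, 0, seed = 1)$purposes == "BLUE"))
  draws <- vapply(1:1000, function(seed)
    assign_purposes(hn, 0.5, seed = seed)$purposes == "RED",
    logical(15))
  frac_red <- mean(draws)
  expect_lt(abs(frac_red - 0.5), 3 * sqrt(0.25 / length(draws)))
  # pairwise covariance of purpose indicators across hyperedges ~ 0
  covs <- stats::cov(t(draws))
  off_diag <- covs[upper.tri(covs)]
  expect_lt(max(abs(off_diag)), 0.05)
})

test_that("neighbours are the deduplicated union of shared hyperedges", {
  hn <- two_edge_fixture()
  expect_identical(hn_neighbors(hn, 1), c(2L, 3L, 4L, 5L))
  expect_identical(hn_neighbors(hn, 5), c(1:4, 6:9))
  # node in two size-10 edges overlapping only in itself: 18 neighbours
  big <- hypernetwork(19, list(c(1:9, 19), c(10:18, 19)))
  expect_length(hn_neighbors(big, 19), 18L)
  # fully-connected: everyone has m - 1 neighbours
  fc <- fully_connected_hypernetwork(12)
  expect_true(all(vapply(1:12, function(v) length(hn_neighbors(fc, v)),
                         integer(1)) == 11L))
  expect_error(hn_neighbors(hn, 99), class = "hyperurn_invalid_config")
})

test_that("neighbourhood is symmetric on random structures", {
  for (seed in 1:3) {
    hn <- generate_overlapping_hypernetwork(40, 8, 6, 0.5, seed = seed)
    for (a in c(1L, 7L, 20L, 40L)) {
      for (b in hn_neighbors(hn, a)) {
        expect_true(a %in% hn_neighbors(hn, b))
      }
    }
  }
})

test_that("JSON round-trip reproduces the hypernetwork", {
  hn <- assign_purposes(
    generate_overlapping_hypernetwork(100, 15, 10, 0.5, seed = 5),
    0.5, seed = 6)
  path <- withr::local_tempfile(fileext = ".json")
  write_hypernetwork(hn, path)
  back <- read_hypernetwork(path)
  expect_identical(back$node_count, hn$node_count)
  expect_identical(back$hyperedges, hn$hyperedges)
  expect_identical(back$purposes, hn$purposes)
  # write(read(f)) is stable
  path2 <- withr::local_tempfile(fileext = ".json")
  write_hypernetwork(back, path2)
  expect_identical(jsonlite::fromJSON(path), jsonlite::fromJSON(path2))
})

test_that("malformed files are rejected on load", {
  path <- withr::local_tempfile(fileext = ".json")
  writeLines('{"node_count": 5, "hyperedges": [[0, 1, 1]]}', path)
  expect_error(read_hypernetwork(path),
               class = "hyperurn_invalid_hypernetwork")
  writeLines('{"nodes": 5}', path)
  expect_error(read_hypernetwork(path),
               class = "hyperurn_invalid_hypernetwork")
  writeLines('{"node_count": 5, "hyperedges": [[0, 1, 7]]}', path)
  expect_error(read_hypernetwork(path),
               class = "hyperurn_invalid_hypernetwork")
})

test_that("validation enforces purposes and uniform size", {
  expect_error(hypernetwork(5, list(1:3), purposes = c("RED", "BLUE")),
               class = "hyperurn_invalid_hypernetwork")
  expect_error(hypernetwork(5, list(1:3), purposes = "GREEN"),
               class = "hyperurn_invalid_hypernetwork")
  expect_error(hypernetwork(5, list(1:3, 4:5), uniform_size = 3),
               class = "hyperurn_invalid_hypernetwork")
  expect_warning(hypernetwork(5, list(1:3)), regexp = "no hyperedge")
})

test_that("membership tibble is tidy and ordered", {
  hn <- two_edge_fixture()
  tab <- tibble::as_tibble(hn)
  expect_identical(nrow(tab), 10L)
  expect_identical(tab$purpose[tab$edge == 2][1], "BLUE")
})
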