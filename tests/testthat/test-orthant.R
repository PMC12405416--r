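# ETCN points, the equidistant-network correspondence and geodesics.

test_that("points store rank differences on chain positions", {
  p <- fx$etcn_point5
  expect_equal(unname(p$values[system_key(sys_of(c("a", "b"), c("b", "c"),
                                                 "d", "e"))]), 2.0)
  expect_length(p$values, 4L)
  expect_true(validate_point(p)$ok)
  # zero values drop systems from the support
  chain <- chain_of(letters[1:3], sys_of("a", "b", "c"),
                    sys_of(c("a", "b"), "c"), sys_of(c("a", "b", "c")))
  z <- make_point(chain, c(1, 0))
  expect_length(z$values, 1L)
  origin <- make_point(chain, c(0, 0))
  expect_length(origin$values, 0L)
  expect_true(validate_point(origin)$ok)
  expect_error(make_point(chain, c(1, -1)), "non-negative")
  expect_error(make_point(chain, 1), "values")
})

test_that("a point maps to an equidistant weighted network and back", {
  p <- fx$etcn_point5
  pn <- point_to_network(p)
  expect_true(validate_network(pn$network)$ok)
  # every root-to-leaf path sums to the total of the rank differences
  net <- pn$network
  depth <- rep(NA_real_, net$n_vertices)
  depth[[net$root]] <- 0
  # accumulate leaf depths by following arcs repeatedly
  repeat {
    done <- TRUE
    for (a in seq_len(nrow(net$arcs))) {
      u <- net$arcs[a, 1L]; v <- net$arcs[a, 2L]
      if (!is.na(depth[[u]]) && is.na(depth[[v]])) {
        depth[[v]] <- depth[[u]] + pn$weights[[a]]
        done <- FALSE
      }
    }
    if (done) break
  }
  leaves <- which(!is.na(net$leaf_label))
  expect_equal(unname(depth[leaves]), rep(1.3 + 2.0 + 1.9 + 0.8, 5))
  p2 <- point_from_network(pn$network, pn$weights)
  expect_equal(sort(names(p2$values)), sort(names(p$values)))
  expect_equal(p2$values[sort(names(p2$values))],
               p$values[sort(names(p$values))])
})

test_that("boundary points build non-binary networks and round-trip", {
  chain <- chain_of(letters[1:3], sys_of("a", "b", "c"),
                    sys_of(c("a", "b"), "c"), sys_of(c("a", "b", "c")))
  origin <- make_point(chain, c(0, 0))
  pn <- point_to_network(origin)
  expect_equal(sum(pn$weights), 0)
  # star-like: the root is the only interior vertex
  expect_equal(sum(is.na(pn$network$leaf_label)), 1L)
  back <- point_from_network(pn$network, pn$weights)
  expect_length(back$values, 0L)
  # support omitting an interior position skips that system
  skip <- make_point(chain, c(2, 0))
  pn2 <- point_to_network(skip)
  expect_true(is_ranked_tree(pn2$network))
  back2 <- point_from_network(pn2$network, pn2$weights)
  expect_equal(unname(back2$values), 2)
})

test_that("perturbing one arc weight breaks the equidistance validation", {
  pn <- point_to_network(fx$etcn_point5)
  w <- pn$weights
  target <- which(w > 0.5)[[1L]]
  w[[target]] <- w[[target]] + 0.25
  expect_error(point_from_network(pn$network, w), "equidistant|rank")
})

test_that("geodesics reduce to Euclidean distance within one orthant", {
  p <- fx$etcn_point5
  expect_equal(geodesic_distance(p, p)$distance, 0)
  chain <- chain_of(letters[1:4], sys_of("a", "b", "c", "d"),
                    sys_of(c("a", "b"), "c", "d"), sys_of(letters[1:4]))
  a <- make_point(chain, c(0, 1))
  b <- make_point(chain, c(0, 3))
  expect_equal(geodesic_distance(a, b)$distance, 2)
  # nested supports stay Euclidean
  c1 <- make_point(chain, c(1, 1))
  c2 <- make_point(chain, c(2, 0))
  expect_equal(geodesic_distance(c1, c2)$distance, sqrt(1 + 1))
  bounds <- lower_and_upper_bounds(c1, c2)
  expect_equal(unname(bounds[["lower"]]), unname(bounds[["upper"]]))
})

test_that("incomparable single supports force the cone path through the origin", {
  chain1 <- chain_of(letters[1:4], sys_of("a", "b", "c", "d"),
                     sys_of(c("a", "b"), "c", "d"), sys_of(letters[1:4]))
  chain2 <- chain_of(letters[1:4], sys_of("a", "b", "c", "d"),
                     sys_of(c("a", "c"), "b", "d"), sys_of(letters[1:4]))
  a <- make_point(chain1, c(0, 1))
  b <- make_point(chain2, c(0, 1))
  g <- geodesic_distance(a, b)
  expect_equal(g$distance, 2)
  bounds <- lower_and_upper_bounds(a, b)
  expect_equal(unname(bounds[["lower"]]), sqrt(2))
  expect_equal(unname(bounds[["upper"]]), 2)
  mid <- geodesic_point(a, b, 0.5)
  expect_length(mid$values, 0L)
})

test_that("geodesic endpoints and midpoints are consistent", {
  set.seed(31)
  for (rep in 1:12) {
    p <- random_point(5, p_ret = 0.4, p_skip = 0.3)
    q <- random_point(5, p_ret = 0.4, p_skip = 0.3)
    d <- geodesic_distance(p, q)$distance
    s0 <- geodesic_point(p, q, 0)
    s1 <- geodesic_point(p, q, 1)
    expect_equal(s0$values[sort(names(s0$values))],
                 p$values[sort(names(p$values))], tolerance = 1e-9)
    expect_equal(s1$values[sort(names(s1$values))],
                 q$values[sort(names(q$values))], tolerance = 1e-9)
    mid <- geodesic_point(p, q, 0.5)
    expect_true(validate_point(mid)$ok)
    expect_true(all(names(mid$values) %in%
                      union(names(p$values), names(q$values))))
    expect_equal(geodesic_distance(p, mid)$distance, d / 2, tolerance = 1e-8)
    expect_equal(geodesic_distance(mid, q)$distance, d / 2, tolerance = 1e-8)
  }
})

test_that("the refinement algorithm matches the brute-force path-space oracle", {
  set.seed(47)
  tried <- 0L
  while (tried < 25L) {
    n <- sample(4:5, 1)
    p <- random_point(n, p_ret = 0.5, p_skip = 0.25)
    q <- random_point(n, p_ret = 0.5, p_skip = 0.25)
    A <- setdiff(names(p$values), names(q$values))
    B <- setdiff(names(q$values), names(p$values))
    if (length(A) > 4L || length(B) > 4L) next
    tried <- tried + 1L
    expect_equal(geodesic_distance(p, q)$distance, oracle_geodesic(p, q),
                 tolerance = 1e-9)
  }
})

test_that("geodesic distance satisfies the metric axioms on sampled triples", {
  set.seed(53)
  pts <- replicate(10, random_point(4, p_ret = 0.4, p_skip = 0.3),
                   simplify = FALSE)
  pts5 <- replicate(10, random_point(5, p_ret = 0.4, p_skip = 0.3),
                    simplify = FALSE)
  check_triples <- function(pool, m) {
    for (rep in seq_len(m)) {
      idx <- sample.int(length(pool), 3L, replace = TRUE)
      x <- pool[[idx[[1L]]]]; y <- pool[[idx[[2L]]]]; z <- pool[[idx[[3L]]]]
      dxy <- geodesic_distance(x, y)$distance
      expect_equal(dxy, geodesic_distance(y, x)$distance, tolerance = 1e-9)
      expect_gte(dxy, 0)
      same <- setequal(names(x$values), names(y$values)) &&
        isTRUE(all.equal(x$values[sort(names(x$values))],
                         y$values[sort(names(y$values))], tolerance = 1e-12))
      expect_equal(dxy < 1e-12, same)
      expect_lte(dxy, geodesic_distance(x, z)$distance +
                   geodesic_distance(z, y)$distance + 1e-9)
    }
  }
  check_triples(pts, 100L)
  check_triples(pts5, 100L)
})

test_that("geodesic distance lies between the independent and cone bounds", {
  set.seed(59)
  for (rep in 1:30) {
    p <- random_point(5, p_ret = 0.4, p_skip = 0.3)
    q <- random_point(5, p_ret = 0.4, p_skip = 0.3)
    b <- lower_and_upper_bounds(p, q)
    d <- geodesic_distance(p, q)$distance
    expect_gte(d, unname(b[["lower"]]) - 1e-9)
    expect_lte(d, unname(b[["upper"]]) + 1e-9)
  }
})

test_that("geodesics between ultrametric tree points stay in tree space", {
  set.seed(61)
  for (rep in 1:10) {
    p <- random_point(5, p_ret = 0, p_skip = 0.3)
    q <- random_point(5, p_ret = 0, p_skip = 0.3)
    for (s in c(0.25, 0.5, 0.75)) {
      w <- geodesic_point(p, q, s)
      expect_true(all(vapply(w$systems, is_partition, logical(1),
                             taxa = w$taxa)))
    }
  }
})

test_that("point JSON round-trips with validation", {
  p <- fx$etcn_point5
  path <- withr::local_tempfile(fileext = ".json")
  write_point_json(p, path)
  again <- read_point_json(path)
  expect_equal(again$values[sort(names(again$values))],
               p$values[sort(names(p$values))])
  path2 <- withr::local_tempfile(fileext = ".json")
  write_point_json(again, path2)
  expect_identical(readLines(path), readLines(path2))
})
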