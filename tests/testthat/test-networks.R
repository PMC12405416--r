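# Decoding chains to ranked networks, the general construction, encoding,
# validation and serialization.

test_that("decoding the reticulated 4-taxon chain gives the expected network", {
  net <- decode_binary(fx$net4_chain)
  expect_true(validate_network(net)$ok)
  expect_true(is_binary_network(net))
  expect_length(hybrid_vertices(net), 1L)
  hy <- hybrid_vertices(net)[[1L]]
  clus <- hardwired_clusters(net)
  expect_equal(clus[[hy]], "c")
  expect_equal(net$rank[[hy]], 3L)
  # the two rank-3 tree vertices above the hybrid carry the unions
  parents <- net$arcs[net$arcs[, 2L] == hy, 1L]
  expect_setequal(vapply(clus[parents], cluster_key, character(1)),
                  c("a,b,c", "c,d"))
  expect_equal(clus[[net$root]], letters[1:4])
})

test_that("a join-only chain decodes to a ranked tree with the right cherry", {
  chain <- chain_of(letters[1:3], sys_of("a", "b", "c"),
                    sys_of(c("a", "b"), "c"), sys_of(c("a", "b", "c")))
  net <- decode_binary(chain)
  expect_true(is_ranked_tree(net))
  cherry <- which(vapply(hardwired_clusters(net), function(cl) {
    identical(cl, c("a", "b"))
  }, logical(1)))
  expect_length(cherry, 1L)
  expect_equal(net$rank[[cherry]], 2L)
})

test_that("encode is a left inverse of decode_binary on all n <= 4 chains", {
  for (n in 2:4) {
    chains <- enumerate_maximal_chains(letters[1:n])
    for (ch in chains) {
      expect_true(ch == encode(decode_binary(ch)))
    }
  }
})

test_that("encode/decode round-trips random chains at n in 5..7", {
  set.seed(101)
  for (rep in 1:60) {
    n <- sample(5:7, 1)
    ch <- random_maximal_chain(n, p_ret = 0.4)
    net <- decode_binary(ch)
    expect_true(ch == encode(net))
    # decode after encode reproduces the network up to isomorphism
    expect_identical(rtcnspace:::network_signature(decode_binary(encode(net))),
                     rtcnspace:::network_signature(net))
  }
})

test_that("the rank-2 cherry chain on two taxa encodes both ways", {
  chain <- chain_of(letters[1:2], sys_of("a", "b"), sys_of(c("a", "b")))
  net <- decode_binary(chain)
  expect_equal(to_enewick(net), "(a[r=1],b[r=1])[r=2];")
  expect_true(chain == encode(net))
})

test_that("the three-phase construction reproduces the length-4 chain on 8 taxa", {
  chain <- fx$chain8_len4
  # H-sets of the second step, computed straight from the definition
  c1 <- chain$systems[[1L]]; c2 <- chain$systems[[2L]]
  H <- lapply(c1, function(A) {
    Filter(function(B) all(A %in% B), c2)
  })
  names(H) <- vapply(c1, cluster_key, character(1))
  hkey <- function(h) paste(sort(vapply(h, cluster_key, character(1))),
                            collapse = "|")
  expect_equal(hkey(H[["a"]]), "a,b,c,d")
  expect_equal(hkey(H[["b"]]), "a,b,c,d")
  expect_equal(hkey(H[["c"]]), "a,b,c,d|c,d,e")
  expect_equal(hkey(H[["d"]]), "a,b,c,d|c,d,e")
  expect_equal(hkey(H[["e"]]), "c,d,e")
  expect_equal(hkey(H[["f"]]), "f")
  expect_equal(hkey(H[["g"]]), "g,h")
  expect_equal(hkey(H[["h"]]), "g,h")
  net <- build_network(chain)
  expect_true(validate_network(net)$ok)
  expect_false(is_binary_network(net))
  expect_true(chain == encode(net))
  # exactly one hybrid: the merged {c,d} vertex fed by both H-set parents
  expect_length(hybrid_vertices(net), 1L)
  hy <- hybrid_vertices(net)[[1L]]
  expect_equal(hardwired_clusters(net)[[hy]], c("c", "d"))
})

test_that("build_network equals decode_binary on maximal chains", {
  chains <- enumerate_maximal_chains(letters[1:4])
  for (ch in chains[seq(1, 108, by = 4)]) {
    expect_identical(rtcnspace:::network_signature(build_network(ch)),
                     rtcnspace:::network_signature(decode_binary(ch)))
  }
})

test_that("the overlapping-triple chain builds the canonical one-hybrid network", {
  net <- build_network(fx$nonmax_chain4)
  expect_true(validate_network(net)$ok)
  expect_false(is_binary_network(net))
  expect_length(hybrid_vertices(net), 1L)
  hy <- hybrid_vertices(net)[[1L]]
  expect_equal(hardwired_clusters(net)[[hy]], c("b", "c"))
  expect_equal(sum(net$arcs[, 2L] == hy), 2L)
  expect_equal(sum(net$arcs[, 1L] == hy), 2L)
  expect_true(fx$nonmax_chain4 == encode(net))
  ene <- to_enewick(net)
  expect_equal(lengths(regmatches(ene, gregexpr("#H1", ene))), 2L)
  expect_false(grepl("#H2", ene))
})

test_that("network validation flags rank and tree-child violations", {
  net <- decode_binary(fx$net4_chain)
  expect_true(validate_network(net)$ok)
  broken <- net
  interior <- setdiff(which(is.na(net$leaf_label)), net$root)
  v <- interior[[1L]]
  broken$rank[[v]] <- 0L
  res <- validate_network(broken)
  expect_false(res$ok)
  expect_true(any(grepl("rank", res$violations)))
  # rewire a tree child of a tree vertex to be hybrid: parent loses tree-child
  outdeg <- tabulate(net$arcs[, 1L], nbins = net$n_vertices)
  indeg <- tabulate(net$arcs[, 2L], nbins = net$n_vertices)
  hyb <- hybrid_vertices(net)[[1L]]
  tails <- net$arcs[net$arcs[, 2L] == hyb, 1L]
  # give the tree child of `tails[1]` a second in-arc from elsewhere
  kid <- setdiff(net$arcs[net$arcs[, 1L] == tails[[1L]], 2L], hyb)[[1L]]
  broken2 <- net
  broken2$arcs <- rbind(broken2$arcs, c(tails[[2L]], kid))
  res2 <- validate_network(broken2)
  expect_false(res2$ok)
})

test_that("ranked-tree recognition works on chains and networks", {
  expect_true(is_ranked_tree(fx$tree_pair5[[1L]]))
  expect_false(is_ranked_tree(fx$net4_chain))
  point_chain <- chain_of(letters[1:5],
                          sys_of("a", "b", "c", "d", "e"),
                          sys_of(c("a", "b"), c("b", "c"), "d", "e"),
                          sys_of(c("a", "b", "c"), c("b", "c", "d"), "e"),
                          sys_of(c("a", "b", "c"), c("b", "c", "d", "e")),
                          sys_of(letters[1:5]))
  expect_false(is_ranked_tree(point_chain))
  expect_true(is_ranked_tree(decode_binary(fx$tree_pair5[[1L]])))
  expect_false(is_ranked_tree(decode_binary(fx$net4_chain)))
})

test_that("hybrid count equals the number of reticulation steps", {
  set.seed(19)
  for (rep in 1:25) {
    ch <- random_maximal_chain(6, p_ret = 0.5)
    tags <- is_maximal_chain(ch)$tags
    net <- decode_binary(ch)
    expect_length(hybrid_vertices(net), sum(tags == "ret"))
  }
})

test_that("eNewick export is deterministic and tags hybrids once per parent", {
  net <- decode_binary(fx$net4_chain)
  ene <- to_enewick(net)
  expect_equal(lengths(regmatches(ene, gregexpr("#H1", ene))), 2L)
  expect_false(grepl("#H2", ene))
  expect_identical(ene, to_enewick(decode_binary(fx$net4_chain)))
  # weighted export appends branch lengths
  p <- fx$etcn_point5
  pn <- point_to_network(p)
  ew <- to_enewick(pn$network, pn$weights)
  expect_true(grepl(":", ew, fixed = TRUE))
})

test_that("network JSON round-trips through the reader", {
  net <- decode_binary(fx$net4_chain)
  path <- withr::local_tempfile(fileext = ".json")
  write_network_json(net, path)
  again <- read_network_json(path)
  expect_true(validate_network(again)$ok)
  expect_identical(rtcnspace:::network_signature(again),
                   rtcnspace:::network_signature(net))
})
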