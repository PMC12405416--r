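# The orthant space of equidistant tree-child networks (ETCNs).
#
# A point is a sparse non-negative map from cluster systems (excluding {X})
# to rank-difference weights whose support, together with the singleton
# partition and {X}, forms a chain in the poset.  Each maximal chain spans a
# Euclidean orthant; orthants are glued along shared coordinate axes, and
# the resulting complex is CAT(0), so geodesics are unique and computable by
# a successive path-space refinement (GTP-style) algorithm in which two
# coordinate axes are compatible exactly when their cluster systems are
# comparable in the poset.

GEO_TOL <- 1e-9

new_etcn_point <- function(taxa, systems, values) {
  keys <- vapply(systems, system_key, character(1))
  keep <- values > 0
  structure(list(taxa = taxa,
                 systems = stats::setNames(systems[keep], keys[keep]),
                 values = stats::setNames(values[keep], keys[keep])),
            class = "etcn_point")
}

#' @export
print.etcn_point <- function(x, ...) {
  cat(sprintf("ETCN point on %d taxa, support size %d:\n", length(x$taxa),
              length(x$values)))
  for (k in names(x$values)) {
    cat(sprintf("  %g at %s\n", x$values[[k]], k))
  }
  if (length(x$values) == 0L) cat("  (origin: the all-zero map)\n")
  invisible(x)
}

#' Construct an ETCN point from a chain and rank differences
#'
#' Assigns `values[i]` to `chain[i]` for positions `1..t-1` (the final
#' system `{X}` carries no coordinate).  Zero values are permitted and
#' simply drop the system from the support, giving boundary points.
#'
#' @param chain An `rtcn_chain` passing [is_chain()] (maximal or not).
#' @param values Non-negative numeric vector of length `t - 1`.
#' @return An object of class `etcn_point`.
#' @export
make_point <- function(chain, values) {
  v <- is_chain(chain)
  if (!v$ok) stop("not a chain: ", v$reason)
  t <- length(chain$systems)
  if (length(values) != t - 1L) {
    stop(sprintf("need %d values for a chain of length %d, got %d",
                 t - 1L, t, length(values)))
  }
  if (any(values < 0)) stop("rank differences must be non-negative")
  new_etcn_point(chain$taxa, chain$systems[seq_len(t - 1L)], values)
}

#' Validate an ETCN point
#'
#' Checks non-negativity, exclusion of `{X}`, poset membership of every
#' support system, and that the support (with the endpoints added) forms a
#' chain.  Support systems of a chain have pairwise distinct sizes, so
#' sorting by decreasing size and checking consecutive comparability
#' suffices.
#'
#' @param p An `etcn_point`.
#' @return List with `$ok` and `$reason`.
#' @export
validate_point <- function(p) {
  verdict <- function(ok, reason = NA_character_) list(ok = ok, reason = reason)
  taxa <- p$taxa
  if (any(p$values <= 0)) return(verdict(FALSE, "stored values must be positive"))
  full_key <- system_key(cluster_system(list(taxa)))
  if (full_key %in% names(p$values)) {
    return(verdict(FALSE, "the system {X} carries no coordinate"))
  }
  sizes <- lengths(p$systems)
  if (anyDuplicated(sizes)) {
    return(verdict(FALSE, "support systems of equal size cannot form a chain"))
  }
  ord <- order(sizes, decreasing = TRUE)
  syss <- p$systems[ord]
  for (s in syss) {
    if (!is_member(s, taxa)) {
      return(verdict(FALSE, paste("support system not chain-realizable:",
                                  system_key(s))))
    }
  }
  if (length(syss) >= 2L) {
    for (i in seq_len(length(syss) - 1L)) {
      if (!precedes(syss[[i]], syss[[i + 1L]], taxa)) {
        return(verdict(FALSE, "support is not totally ordered by the poset"))
      }
    }
  }
  verdict(TRUE)
}

# support chain: supp + singleton partition + {X}, sorted by decreasing size
support_chain <- function(p) {
  taxa <- p$taxa
  systems <- p$systems
  keys <- names(p$values)
  sing <- singleton_partition(taxa)
  if (!(system_key(sing) %in% keys)) systems <- c(systems, list(sing))
  systems <- c(systems, list(cluster_system(list(taxa))))
  ord <- order(lengths(systems), decreasing = TRUE)
  systems <- systems[ord]
  vals <- vapply(systems, function(s) {
    k <- system_key(s)
    if (k %in% keys) p$values[[k]] else 0
  }, numeric(1))
  list(chain = new_chain(taxa, systems),
       values = vals[-length(vals)])   # one value per position 1..t-1
}

#' Convert an ETCN point to a weighted ranked network
#'
#' Builds the canonical network of the support chain and assigns each arc
#' the total rank difference spanned between its head and tail, which
#' produces an equidistant weighting consistent with the ranks (every
#' root-to-leaf path has total weight equal to the sum of all rank
#' differences).
#'
#' @param p A valid `etcn_point`.
#' @return List with `$network` (a `ranked_network`) and `$weights`
#'   (numeric vector aligned with the rows of `network$arcs`).
#' @export
point_to_network <- function(p) {
  v <- validate_point(p)
  if (!v$ok) stop("invalid point: ", v$reason)
  sc <- support_chain(p)
  net <- build_network(sc$chain)
  w <- sc$values
  cums <- c(0, cumsum(w))    # cums[r] = distance of rank level r above leaves
  weights <- cums[net$rank[net$arcs[, 1L]]] - cums[net$rank[net$arcs[, 2L]]]
  list(network = net, weights = weights)
}

#' Recover an ETCN point from an equidistant weighted network
#'
#' Inverse of [point_to_network()] on its image.  The weighting is
#' validated: depths from the root must be path-independent, all leaves
#' equidistant from the root, vertices of equal rank at equal depth, and
#' rank differences non-negative.
#'
#' @param net A `ranked_network`.
#' @param weights Numeric arc weights aligned with rows of `net$arcs`.
#' @return An `etcn_point`.
#' @export
point_from_network <- function(net, weights) {
  v <- validate_network(net)
  if (!v$ok) stop("invalid network: ", v$violations[[1L]])
  if (length(weights) != nrow(net$arcs)) {
    stop("need one weight per arc")
  }
  if (any(weights < -GEO_TOL)) stop("arc weights must be non-negative")
  depth <- rep(NA_real_, net$n_vertices)
  depth[[net$root]] <- 0
  # relax arcs whose tail depth is known until settled; re-visits must agree
  pending <- seq_len(nrow(net$arcs))
  while (length(pending) > 0L) {
    ready <- pending[!is.na(depth[net$arcs[pending, 1L]])]
    if (length(ready) == 0L) stop("network is not connected from the root")
    for (a in ready) {
      u <- net$arcs[a, 1L]; vv <- net$arcs[a, 2L]
      d <- depth[[u]] + weights[[a]]
      if (is.na(depth[[vv]])) {
        depth[[vv]] <- d
      } else if (abs(depth[[vv]] - d) > GEO_TOL) {
        stop(sprintf(
          "weighting is not equidistant: two paths to vertex %d differ (%.12g vs %.12g)",
          vv, depth[[vv]], d))
      }
    }
    pending <- setdiff(pending, ready)
  }
  leaves <- which(!is.na(net$leaf_label))
  if (diff(range(depth[leaves])) > GEO_TOL) {
    stop("weighting is not equidistant: leaves at unequal depth from the root")
  }
  t <- max(net$rank)
  level_depth <- rep(NA_real_, t)
  for (r in seq_len(t)) {
    dr <- depth[net$rank == r]
    if (length(dr) == 0L) next
    if (diff(range(dr)) > GEO_TOL) {
      stop(sprintf("weighting inconsistent with ranks: vertices of rank %d at unequal depth", r))
    }
    level_depth[[r]] <- dr[[1L]]
  }
  if (anyNA(level_depth)) stop("some rank level has no vertex")
  w <- level_depth[seq_len(t - 1L)] - level_depth[seq.int(2L, t)]
  if (any(w < -GEO_TOL)) {
    stop("weighting inconsistent with ranks: higher rank farther from root")
  }
  w <- pmax(w, 0)
  chain <- encode(net)
  make_point(chain, w)
}

# --- geodesics -------------------------------------------------------------

# memoized comparability of two support systems
axes_comparable <- function(ka, kb, sys_of, taxa) {
  tk <- paste(taxa, collapse = ",")
  key <- paste0("cmp|", tk, "|", ka, "|", kb)
  hit <- cache_get(key)
  if (!is.null(hit)) return(hit)
  res <- comparable(sys_of[[ka]], sys_of[[kb]], taxa)
  cache_set(key, res)
  cache_set(paste0("cmp|", tk, "|", kb, "|", ka), res)
  res
}

# exact min-weight vertex cover of the bipartite incompatibility graph via
# max-flow/min-cut; edges is a 2-col matrix of (a-index, b-index)
min_vertex_cover <- function(wa, wb, edges) {
  na <- length(wa); nb <- length(wb)
  if (nrow(edges) == 0L) {
    return(list(weight = 0, cover_a = integer(0), cover_b = integer(0)))
  }
  s <- 1L; t <- 2L
  a_ids <- 2L + seq_len(na)
  b_ids <- 2L + na + seq_len(nb)
  inf <- sum(wa) + sum(wb) + 1
  from <- c(rep(s, na), b_ids, a_ids[edges[, 1L]])
  to <- c(a_ids, rep(t, nb), b_ids[edges[, 2L]])
  cap <- c(wa, wb, rep(inf, nrow(edges)))
  g <- igraph::graph_from_edgelist(cbind(from, to), directed = TRUE)
  fl <- igraph::max_flow(g, source = s, target = t, capacity = cap)
  src_side <- as.integer(fl$partition1)
  cover_a <- which(!(a_ids %in% src_side))
  cover_b <- which(b_ids %in% src_side)
  list(weight = sum(wa[cover_a]) + sum(wb[cover_b]),
       cover_a = cover_a, cover_b = cover_b)
}

block_norm <- function(vals) sqrt(sum(vals^2))

#' Geodesic distance between two ETCN points
#'
#' Coordinates shared by both supports contribute a plain Euclidean term
#' (each shared system is comparable with every system of either support
#' chain).  The remaining supports A (only `p`) and B (only `q`) are
#' refined from the single-block cone path: a block is split whenever the
#' bipartite incompatibility graph between its two sides admits a vertex
#' cover of weight < 1 under the squared normalized coordinate weights,
#' with the exact cover found by max-flow/min-cut.  The resulting ordered
#' partition pair gives the squared path length
#' `sum_i (||A_i|| + ||B_i||)^2`.
#'
#' @param p,q Valid `etcn_point`s on the same taxon set.
#' @return An object of class `rtcn_geodesic` with `$distance`, `$blocks`
#'   (list of lists of support keys), `$common` (shared keys with
#'   coordinate differences), and the endpoints.
#' @export
geodesic_distance <- function(p, q) {
  if (!identical(p$taxa, q$taxa)) stop("points are on different taxon sets")
  taxa <- p$taxa
  kp <- names(p$values); kq <- names(q$values)
  K <- intersect(kp, kq)
  A <- setdiff(kp, kq)
  B <- setdiff(kq, kp)
  common_diff <- stats::setNames(
    vapply(K, function(k) p$values[[k]] - q$values[[k]], numeric(1)), K)
  common_sq <- sum(common_diff^2)
  sys_of <- c(p$systems[A], q$systems[B])
  incompat <- function(a_keys, b_keys) {
    # rows (i, j) of incomparable pairs
    out <- matrix(integer(0), ncol = 2L)
    for (i in seq_along(a_keys)) {
      for (j in seq_along(b_keys)) {
        if (!axes_comparable(a_keys[[i]], b_keys[[j]], sys_of, taxa)) {
          out <- rbind(out, c(i, j))
        }
      }
    }
    out
  }
  blocks <- list()
  if (length(A) > 0L || length(B) > 0L) {
    queue <- list(list(A = A, B = B))
    done <- list()
    while (length(queue) > 0L) {
      blk <- queue[[1L]]
      rest <- queue[-1L]
      split_done <- FALSE
      if (length(blk$A) > 0L && length(blk$B) > 0L) {
        pa <- vapply(blk$A, function(k) p$values[[k]], numeric(1))
        qb <- vapply(blk$B, function(k) q$values[[k]], numeric(1))
        edges <- incompat(blk$A, blk$B)
        mvc <- min_vertex_cover((pa / block_norm(pa))^2,
                                (qb / block_norm(qb))^2, edges)
        if (mvc$weight < 1 - GEO_TOL) {
          first <- list(A = blk$A[mvc$cover_a],
                        B = blk$B[setdiff(seq_along(blk$B), mvc$cover_b)])
          second <- list(A = blk$A[setdiff(seq_along(blk$A), mvc$cover_a)],
                         B = blk$B[mvc$cover_b])
          # re-queue the two pieces in place (processed left to right, so
          # finished blocks accumulate in final path order)
          queue <- c(list(first, second), rest)
          split_done <- TRUE
        }
      }
      if (!split_done) {
        done[[length(done) + 1L]] <- blk
        queue <- rest
      }
    }
    blocks <- done
  }
  Lsq <- sum(vapply(blocks, function(blk) {
    na <- block_norm(vapply(blk$A, function(k) p$values[[k]], numeric(1)))
    nb <- block_norm(vapply(blk$B, function(k) q$values[[k]], numeric(1)))
    (na + nb)^2
  }, numeric(1)))
  structure(list(distance = sqrt(common_sq + Lsq),
                 path_length = sqrt(Lsq),
                 blocks = blocks,
                 common = common_diff,
                 p = p, q = q),
            class = "rtcn_geodesic")
}

#' @export
print.rtcn_geodesic <- function(x, ...) {
  cat(sprintf("Geodesic of length %.12g (%d path block(s), %d shared axes)\n",
              x$distance, length(x$blocks), length(x$common)))
  invisible(x)
}

#' Point at a fraction along the geodesic between two ETCN points
#'
#' Evaluates the unique geodesic at arc-length fraction `s`.  Shared
#' coordinates interpolate linearly; within path block i the coordinates of
#' `p` shrink by the factor `((1-s)||A_i|| - s||B_i||) / ||A_i||` until the
#' block's bend, after which the coordinates of `q` grow symmetrically.
#' The support at any `s` lies inside the union of the two supports and
#' forms a chain.
#'
#' @param p,q Valid `etcn_point`s on the same taxon set.
#' @param s Number in `[0, 1]`.
#' @return An `etcn_point`.
#' @export
geodesic_point <- function(p, q, s) {
  if (s < 0 || s > 1) stop("s must lie in [0, 1]")
  geo <- geodesic_distance(p, q)
  systems <- list()
  values <- numeric(0)
  push <- function(sys, val) {
    if (val > GEO_TOL) {
      systems[[length(systems) + 1L]] <<- sys
      values[[length(values) + 1L]] <<- val
    }
  }
  for (k in names(geo$common)) {
    push(p$systems[[k]], (1 - s) * p$values[[k]] + s * q$values[[k]])
  }
  for (blk in geo$blocks) {
    na <- block_norm(vapply(blk$A, function(k) p$values[[k]], numeric(1)))
    nb <- block_norm(vapply(blk$B, function(k) q$values[[k]], numeric(1)))
    if (length(blk$A) > 0L) {
      coef <- ((1 - s) * na - s * nb) / na
      if (coef > 0) for (k in blk$A) push(p$systems[[k]], coef * p$values[[k]])
    }
    if (length(blk$B) > 0L) {
      coef <- (s * nb - (1 - s) * na) / nb
      if (coef > 0) for (k in blk$B) push(q$systems[[k]], coef * q$values[[k]])
    }
  }
  if (length(systems) == 0L) {
    return(new_etcn_point(p$taxa, list(), numeric(0)))
  }
  new_etcn_point(p$taxa, systems, values)
}

#' Lower and upper bounds for the geodesic distance
#'
#' The lower bound treats all non-shared coordinates as independent
#' (Euclidean on the disjoint union); the upper bound is the two-segment
#' cone path through the shared face.  Always `lower <= distance <= upper`.
#'
#' @param p,q Valid `etcn_point`s on the same taxon set.
#' @return Named numeric vector `c(lower = ..., upper = ...)`.
#' @export
lower_and_upper_bounds <- function(p, q) {
  if (!identical(p$taxa, q$taxa)) stop("points are on different taxon sets")
  kp <- names(p$values); kq <- names(q$values)
  K <- intersect(kp, kq)
  A <- setdiff(kp, kq); B <- setdiff(kq, kp)
  csq <- sum(vapply(K, function(k) (p$values[[k]] - q$values[[k]])^2,
                    numeric(1)))
  asq <- sum(vapply(A, function(k) p$values[[k]]^2, numeric(1)))
  bsq <- sum(vapply(B, function(k) q$values[[k]]^2, numeric(1)))
  c(lower = sqrt(csq + asq + bsq),
    upper = sqrt(csq + (sqrt(asq) + sqrt(bsq))^2))
}

#' Read an ETCN point from JSON
#'
#' Package format: `{"taxa": [...], "coords": [{"system": [[...]], "value":
#' x}, ...]}`.
#'
#' @param path Path to a JSON file.
#' @return An `etcn_point` (validated).
#' @export
read_point_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(obj$taxa) || is.null(obj$coords)) {
    stop("point JSON must have fields 'taxa' and 'coords'")
  }
  taxa <- taxon_set(unlist(obj$taxa))
  systems <- lapply(obj$coords, function(co) {
    cluster_system(lapply(co$system, unlist), taxa = taxa)
  })
  values <- vapply(obj$coords, function(co) as.numeric(co$value), numeric(1))
  p <- new_etcn_point(taxa, systems, values)
  v <- validate_point(p)
  if (!v$ok) stop("invalid point: ", v$reason)
  p
}

#' Write an ETCN point to JSON
#'
#' @param p An `etcn_point`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_point_json <- function(p, path) {
  ord <- order(lengths(p$systems), decreasing = TRUE)
  obj <- list(
    taxa = p$taxa,
    coords = lapply(ord, function(i) {
      list(system = p$systems[[i]],
           value = jsonlite::unbox(unname(p$values[[i]])))
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}
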