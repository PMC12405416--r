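# Successor relations on cluster systems and maximal chains.
#
# The two generative events of a ranked tree-child network translate to two
# successor relations on cluster systems:
#   join        C' = (C - {A,B})   + {A u B}          (a branching event)
#   reticulate  C' = (C - {A,B,C}) + {A u B, B u C}   (a hybridization; B is
#                                                      the hybrid cluster)
# A maximal chain is a sequence of n systems from the singleton partition to
# {X} linked by these relations; maximal chains are in bijection with binary
# ranked tree-child networks.

#' Apply a join event to a cluster system
#'
#' Replaces two distinct clusters `A`, `B` of `sys` by their union.
#'
#' @param sys A cluster system.
#' @param A,B Clusters (character vectors) that must be members of `sys`.
#' @return The cluster system `(sys - {A,B}) + {A u B}`, with one cluster
#'   fewer than `sys`.
#' @export
#' @examples
#' sys <- cluster_system(list("a", "b", "c", "d"))
#' apply_join(sys, "a", "b")
apply_join <- function(sys, A, B) {
  ia <- cluster_index(sys, A)
  ib <- cluster_index(sys, B)
  if (ia == 0L) stop("cluster not in system: {", cluster_key(cluster(A)), "}")
  if (ib == 0L) stop("cluster not in system: {", cluster_key(cluster(B)), "}")
  if (ia == ib) stop("join requires two distinct clusters, got {",
                     cluster_key(cluster(A)), "} twice")
  merged <- cluster(c(sys[[ia]], sys[[ib]]))
  out <- c(sys[-c(ia, ib)], list(merged))
  keys <- vapply(out, cluster_key, character(1))
  if (anyDuplicated(keys)) {
    stop("cluster collision: {", cluster_key(merged),
         "} already present in the remaining system")
  }
  cluster_system(out)
}

#' Apply a reticulation event to a cluster system
#'
#' Replaces three pairwise distinct clusters `A`, `B`, `C` of `sys` by the
#' two unions `A u B` and `B u C`.  `B` is the cluster below the hybrid
#' vertex, so the pair `{A, C}` is unordered while `B` is distinguished.
#'
#' @param sys A cluster system.
#' @param A,B,C Clusters that must be members of `sys`, pairwise distinct.
#' @return The cluster system `(sys - {A,B,C}) + {A u B, B u C}`, with one
#'   cluster fewer than `sys`.
#' @export
#' @examples
#' sys <- cluster_system(list(c("a", "b"), "c", "d"))
#' apply_reticulate(sys, c("a", "b"), "c", "d")
apply_reticulate <- function(sys, A, B, C) {
  ia <- cluster_index(sys, A)
  ib <- cluster_index(sys, B)
  ic <- cluster_index(sys, C)
  for (cl in list(A, B, C)[c(ia, ib, ic) == 0L]) {
    stop("cluster not in system: {", cluster_key(cluster(cl)), "}")
  }
  if (anyDuplicated(c(ia, ib, ic))) {
    stop("reticulation requires three pairwise distinct clusters")
  }
  ab <- cluster(c(sys[[ia]], sys[[ib]]))
  bc <- cluster(c(sys[[ib]], sys[[ic]]))
  out <- c(sys[-c(ia, ib, ic)], list(ab, bc))
  keys <- vapply(out, cluster_key, character(1))
  if (anyDuplicated(keys)) {
    stop("cluster collision: the unions coincide with each other or with a ",
         "remaining cluster")
  }
  cluster_system(out)
}

#' All successor systems of a cluster system
#'
#' Applies every join over unordered pairs and every reticulation over
#' (middle, unordered outer pair) choices, skipping applications that would
#' collapse clusters, and deduplicates the results.
#'
#' @param sys A cluster system with at least 2 clusters.
#' @param within Optional cluster system used for pruning: only successors
#'   all of whose clusters are contained in some cluster of `within` are
#'   returned (every system below `within` in a chain has this property).
#' @return List of distinct cluster systems.
#' @export
successors <- function(sys, within = NULL) {
  k <- length(sys)
  if (k < 2L) stop("no successors of {X}")
  fits <- function(cl) {
    is.null(within) ||
      any(vapply(within, function(w) all(cl %in% w), logical(1)))
  }
  out <- list()
  seen <- character(0)
  push <- function(cand) {
    key <- system_key(cand)
    if (!(key %in% seen)) {
      seen[[length(seen) + 1L]] <<- key
      out[[length(out) + 1L]] <<- cand
    }
  }
  # joins over unordered pairs
  for (i in seq_len(k - 1L)) {
    for (j in seq.int(i + 1L, k)) {
      merged <- cluster(c(sys[[i]], sys[[j]]))
      if (!fits(merged)) next
      cand <- tryCatch(apply_join(sys, sys[[i]], sys[[j]]),
                       error = function(e) NULL)
      if (!is.null(cand)) push(cand)
    }
  }
  # reticulations: middle b, unordered outer pair {i, j}
  if (k >= 3L) {
    for (b in seq_len(k)) {
      rest <- setdiff(seq_len(k), b)
      m <- length(rest)
      for (ii in seq_len(m - 1L)) {
        for (jj in seq.int(ii + 1L, m)) {
          i <- rest[[ii]]; j <- rest[[jj]]
          ab <- cluster(c(sys[[i]], sys[[b]]))
          bc <- cluster(c(sys[[b]], sys[[j]]))
          if (!fits(ab) || !fits(bc)) next
          cand <- tryCatch(apply_reticulate(sys, sys[[i]], sys[[b]], sys[[j]]),
                           error = function(e) NULL)
          if (!is.null(cand)) push(cand)
        }
      }
    }
  }
  out
}

#' Witnesses of the successor relation between two cluster systems
#'
#' Finds every decomposition showing that `nxt` arises from `sys` by a
#' single join or reticulation.  Reticulation witnesses are reported with
#' the outer pair in canonical order (A before C); the middle cluster B is
#' the hybrid cluster.  An empty list means the relation does not hold.
#'
#' @param sys,nxt Cluster systems.
#' @return List of witnesses; each is a list with `$type` (`"join"` or
#'   `"ret"`) and the participating clusters (`$A`, `$B` and, for
#'   reticulations, `$C`).
#' @export
relation <- function(sys, nxt) {
  out <- list()
  if (length(nxt) != length(sys) - 1L) return(out)
  target <- system_key(cluster_system(nxt))
  k <- length(sys)
  for (i in seq_len(k - 1L)) {
    for (j in seq.int(i + 1L, k)) {
      cand <- tryCatch(apply_join(sys, sys[[i]], sys[[j]]),
                       error = function(e) NULL)
      if (!is.null(cand) && system_key(cand) == target) {
        out[[length(out) + 1L]] <-
          list(type = "join", A = sys[[i]], B = sys[[j]])
      }
    }
  }
  if (k >= 3L) {
    for (b in seq_len(k)) {
      rest <- setdiff(seq_len(k), b)
      m <- length(rest)
      for (ii in seq_len(m - 1L)) {
        for (jj in seq.int(ii + 1L, m)) {
          i <- rest[[ii]]; j <- rest[[jj]]
          cand <- tryCatch(apply_reticulate(sys, sys[[i]], sys[[b]], sys[[j]]),
                           error = function(e) NULL)
          if (!is.null(cand) && system_key(cand) == target) {
            # canonical outer order: A < C by cluster key
            a <- sys[[i]]; cc <- sys[[j]]
            if (cluster_key(a) > cluster_key(cc)) { tmp <- a; a <- cc; cc <- tmp }
            out[[length(out) + 1L]] <-
              list(type = "ret", A = a, B = sys[[b]], C = cc)
          }
        }
      }
    }
  }
  out
}

#' Witnesses of the restricted (cactus) successor relation
#'
#' Filters the witnesses of [relation()] by the disjointness side
#' conditions that characterize ranked cactuses: a join witness is kept
#' when A and B overlap, or A is disjoint from every other cluster of
#' `sys`, or B is; a reticulation witness is kept when each of A, B, C is
#' disjoint from every other cluster of `sys`.
#'
#' @inheritParams relation
#' @return List of witnesses (possibly empty), as for [relation()].
#' @export
cactus_relation <- function(sys, nxt) {
  wits <- relation(sys, nxt)
  keys <- vapply(sys, cluster_key, character(1))
  disjoint_from_rest <- function(cl) {
    key <- cluster_key(cl)
    others <- sys[keys != key]
    !any(vapply(others, function(o) length(intersect(cl, o)) > 0, logical(1)))
  }
  keep <- vapply(wits, function(w) {
    if (w$type == "join") {
      length(intersect(w$A, w$B)) > 0 ||
        disjoint_from_rest(w$A) || disjoint_from_rest(w$B)
    } else {
      disjoint_from_rest(w$A) && disjoint_from_rest(w$B) &&
        disjoint_from_rest(w$C)
    }
  }, logical(1))
  wits[keep]
}

#' Private elements of the clusters of a system
#'
#' For each cluster, the taxa that appear in no other cluster of the
#' system.  Every system occurring in a maximal chain has a non-empty
#' private set for every cluster; an empty private set certifies that the
#' system occurs in no maximal chain.
#'
#' @param sys A cluster system.
#' @return Named list (by cluster key) of character vectors of private
#'   labels, in the canonical cluster order of `sys`.
#' @export
private_elements <- function(sys) {
  counts <- table(unlist(sys, use.names = FALSE))
  out <- lapply(sys, function(cl) cl[counts[cl] == 1L])
  names(out) <- vapply(sys, cluster_key, character(1))
  out
}

#' Construct a chain of cluster systems
#'
#' A light S3 container holding a taxon set and a sequence of cluster
#' systems.  No chain axioms are checked here; use [is_maximal_chain()] or
#' [is_chain()] to validate.
#'
#' @param taxa A taxon set.
#' @param systems List of cluster systems.
#' @return An object of class `rtcn_chain`.
#' @export
new_chain <- function(taxa, systems) {
  taxa <- taxon_set(taxa)
  systems <- lapply(systems, cluster_system, taxa = taxa)
  structure(list(taxa = taxa, systems = systems), class = "rtcn_chain")
}

chain_systems <- function(x) {
  if (inherits(x, "rtcn_chain")) x$systems else x
}

chain_key <- function(chain) {
  paste(vapply(chain_systems(chain), system_key, character(1)),
        collapse = ";")
}

#' @export
print.rtcn_chain <- function(x, ...) {
  cat(sprintf("Chain on %d taxa (%s), length %d:\n", length(x$taxa),
              paste(x$taxa, collapse = ","), length(x$systems)))
  for (i in seq_along(x$systems)) {
    cat(sprintf("  [%d] %s\n", i, system_key(x$systems[[i]])))
  }
  invisible(x)
}

#' @export
`==.rtcn_chain` <- function(e1, e2) {
  chain_key(e1) == chain_key(e2) && identical(e1$taxa, e2$taxa)
}

#' Validate a maximal chain
#'
#' Checks that the sequence has length `n = |X|`, starts at the singleton
#' partition, ends at `{X}`, and that every consecutive pair is linked by
#' the successor relation.  When valid, reports the event type of each of
#' the `n - 1` steps.
#'
#' @param x An `rtcn_chain`, or a list of cluster systems (then `taxa` is
#'   inferred from the union of the first system).
#' @return A list with `$ok` (logical), `$tags` (per-step `"join"`,
#'   `"ret"`, or `"both"` when both decompositions exist), and `$reason`
#'   (string, `NA` when valid).
#' @export
is_maximal_chain <- function(x) {
  systems <- chain_systems(x)
  verdict <- function(ok, tags = character(0), reason = NA_character_) {
    list(ok = ok, tags = tags, reason = reason)
  }
  if (length(systems) < 2L) return(verdict(FALSE, reason = "fewer than 2 systems"))
  taxa <- if (inherits(x, "rtcn_chain")) x$taxa else system_union(systems[[1L]])
  n <- length(taxa)
  if (length(systems) != n) {
    return(verdict(FALSE, reason = sprintf(
      "chain has %d systems but |X| = %d", length(systems), n)))
  }
  if (system_key(systems[[1L]]) != system_key(singleton_partition(taxa))) {
    return(verdict(FALSE, reason = "does not start at the singleton partition"))
  }
  if (system_key(systems[[n]]) != system_key(cluster_system(list(taxa)))) {
    return(verdict(FALSE, reason = "does not end at {X}"))
  }
  tags <- character(n - 1L)
  for (i in seq_len(n - 1L)) {
    wits <- relation(systems[[i]], systems[[i + 1L]])
    if (length(wits) == 0L) {
      return(verdict(FALSE, reason = sprintf(
        "no successor relation at step %d -> %d", i, i + 1L)))
    }
    types <- unique(vapply(wits, `[[`, character(1), "type"))
    tags[[i]] <- if (length(types) == 1L) types else "both"
  }
  verdict(TRUE, tags = tags)
}

#' Read a chain from JSON
#'
#' Accepts the package chain format
#' `{"taxa": [...], "systems": [[["a"],["b"]], ...]}` and validates
#' cluster membership and distinctness.
#'
#' @param path Path to a JSON file.
#' @return An `rtcn_chain`.
#' @export
read_chain_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(obj$taxa) || is.null(obj$systems)) {
    stop("chain JSON must have fields 'taxa' and 'systems'")
  }
  taxa <- taxon_set(unlist(obj$taxa))
  systems <- lapply(obj$systems, function(sys) {
    cluster_system(lapply(sys, function(cl) unlist(cl)), taxa = taxa)
  })
  new_chain(taxa, systems)
}

#' Write a chain to JSON
#'
#' Output is canonical (sorted labels, canonical cluster order), so the
#' writer/reader round trip is byte-exact.
#'
#' @param chain An `rtcn_chain`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_chain_json <- function(chain, path) {
  obj <- list(taxa = chain$taxa,
              systems = lapply(chain$systems, function(sys) sys))
  jsonlite::write_json(obj, path, auto_unbox = FALSE, pretty = FALSE,
                       digits = NA)
  invisible(path)
}
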