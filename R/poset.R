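# The graded poset of chain-realizable cluster systems.
#
# T(X) is the set of all cluster systems occurring in some maximal chain on
# X, ordered by co-occurrence in a maximal chain.  Membership and
# comparability are decided by memoized breadth-first search over the
# successor relation, starting from the singleton partition.  The search is
# pruned by a monotonicity property of chains: every cluster of a system is
# contained in some cluster of any later system of the same chain, so while
# searching for a fixed target we only ever generate clusters that fit
# inside a target cluster.

.rtcn_cache <- new.env(parent = emptyenv())

cache_get <- function(key) {
  if (exists(key, envir = .rtcn_cache, inherits = FALSE)) {
    get(key, envir = .rtcn_cache, inherits = FALSE)
  } else NULL
}

cache_set <- function(key, value) {
  assign(key, value, envir = .rtcn_cache)
  value
}

# --- reachability machinery ------------------------------------------------
#
# Internally, reachability queries run on integer bitmask clusters (one bit
# per taxon) and are decomposed over the connected components of the target
# system's cluster-overlap graph: every cluster generated on the way to a
# fixed target fits inside a target cluster, and both generative events only
# combine clusters fitting inside overlapping target clusters, so the search
# factorizes into independent searches per component.  A component whose
# target is a single cluster is always reachable (repeated joins).

sys_to_masks <- function(sys, taxa) {
  if (length(taxa) > 30L) stop("reachability queries support at most 30 taxa")
  bit <- stats::setNames(bitwShiftL(1L, seq_along(taxa) - 1L), taxa)
  sort(vapply(sys, function(cl) {
    Reduce(bitwOr, bit[cl], 0L)
  }, integer(1)))
}

# BFS on bitmask systems within one target component
mask_reach <- function(from, to) {
  g <- length(from) - length(to)
  if (g < 0L) return(FALSE)
  if (g == 0L) return(identical(from, to))
  target_key <- paste(to, collapse = ".")
  frontier <- list(from)
  for (step in seq_len(g)) {
    nxt <- list()
    seen <- new.env(parent = emptyenv())
    for (sys in frontier) {
      k <- length(sys)
      emit <- function(cand) {
        ck <- paste(cand, collapse = ".")
        if (step == g) {
          if (ck == target_key) return(TRUE)
        } else if (!exists(ck, envir = seen, inherits = FALSE)) {
          assign(ck, TRUE, envir = seen)
          nxt[[length(nxt) + 1L]] <<- cand
        }
        FALSE
      }
      fits <- function(m) any(bitwAnd(m, to) == m)
      for (i in seq_len(k - 1L)) {
        for (j in seq.int(i + 1L, k)) {
          m <- bitwOr(sys[[i]], sys[[j]])
          if (!fits(m)) next
          rest <- sys[-c(i, j)]
          if (m %in% rest) next
          if (emit(sort(c(rest, m)))) return(TRUE)
        }
      }
      if (k >= 3L) {
        for (b in seq_len(k)) {
          restidx <- setdiff(seq_len(k), b)
          for (ii in seq_len(k - 2L)) {
            for (jj in seq.int(ii + 1L, k - 1L)) {
              i <- restidx[[ii]]; j <- restidx[[jj]]
              m1 <- bitwOr(sys[[i]], sys[[b]])
              if (!fits(m1)) next
              m2 <- bitwOr(sys[[b]], sys[[j]])
              if (!fits(m2) || m1 == m2) next
              rest <- sys[-c(i, b, j)]
              if (m1 %in% rest || m2 %in% rest) next
              if (emit(sort(c(rest, m1, m2)))) return(TRUE)
            }
          }
        }
      }
    }
    if (step < g && length(nxt) == 0L) return(FALSE)
    frontier <- nxt
  }
  FALSE
}

# BFS with component decomposition: is `to` reachable from `from`?
reachable_between <- function(from, to) {
  g <- length(from) - length(to)
  if (g < 0L) return(FALSE)
  if (g == 0L) return(system_key(from) == system_key(to))
  taxa <- system_union(from)
  if (!identical(system_union(to), taxa)) return(FALSE)
  key <- paste0("reach|", system_key(from), "|", system_key(to))
  hit <- cache_get(key)
  if (!is.null(hit)) return(hit)
  fm <- sys_to_masks(from, taxa)
  tm <- sys_to_masks(to, taxa)
  # every source cluster must fit inside some target cluster
  if (!all(vapply(fm, function(m) any(bitwAnd(m, tm) == m), logical(1)))) {
    return(cache_set(key, FALSE))
  }
  # connected components of the target overlap graph, as component masks
  comp <- seq_along(tm)
  repeat {
    changed <- FALSE
    for (i in seq_along(tm)) {
      for (j in seq_along(tm)) {
        if (comp[[j]] != comp[[i]] && bitwAnd(tm[[i]], tm[[j]]) != 0L) {
          comp[comp == comp[[j]]] <- comp[[i]]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  for (cid in unique(comp)) {
    cmask <- Reduce(bitwOr, tm[comp == cid], 0L)
    to_c <- sort(tm[comp == cid])
    from_c <- sort(fm[bitwAnd(fm, cmask) == fm])
    if (length(from_c) < length(to_c)) return(cache_set(key, FALSE))
    if (Reduce(bitwOr, from_c, 0L) != cmask) return(cache_set(key, FALSE))
    if (length(to_c) == 1L) next  # repeated joins always reach one cluster
    if (!mask_reach(from_c, to_c)) return(cache_set(key, FALSE))
  }
  cache_set(key, TRUE)
}

#' Membership in the poset of chain-realizable cluster systems
#'
#' Decides whether some maximal chain on `taxa` contains `sys`.  Fast
#' negative filters (union must be `taxa`; every cluster must have a
#' private element) are applied before the breadth-first reachability
#' search from the singleton partition.  Upward extension to `{X}` always
#' exists by repeated joins, so reachability from the singleton partition
#' is sufficient.
#'
#' @param sys A cluster system.
#' @param taxa The taxon set.
#' @return Logical.
#' @export
is_member <- function(sys, taxa) {
  taxa <- taxon_set(taxa)
  sys <- cluster_system(sys, taxa = taxa)
  if (!identical(system_union(sys), taxa)) return(FALSE)
  if (length(sys) > length(taxa)) return(FALSE)
  if (any(lengths(private_elements(sys)) == 0L)) return(FALSE)
  reachable_between(singleton_partition(taxa), sys)
}

#' Comparability in the poset
#'
#' `precedes(lo, hi, taxa)` is `TRUE` when some maximal chain on `taxa`
#' contains `lo` at an earlier-or-equal position than `hi`; the relation is
#' reflexive.  Implemented as membership of `lo` plus reachability of `hi`
#' from `lo` under iterated successors (any reachable pair extends to a
#' maximal chain: downward to the singleton partition because `lo` is a
#' member, upward to `{X}` by repeated joins).
#'
#' @param lo,hi Cluster systems.
#' @param taxa The taxon set.
#' @return Logical.
#' @export
precedes <- function(lo, hi, taxa) {
  taxa <- taxon_set(taxa)
  lo <- cluster_system(lo, taxa = taxa)
  hi <- cluster_system(hi, taxa = taxa)
  if (system_key(lo) == system_key(hi)) return(is_member(lo, taxa))
  is_member(lo, taxa) && is_member(hi, taxa) && reachable_between(lo, hi)
}

comparable <- function(a, b, taxa) {
  precedes(a, b, taxa) || precedes(b, a, taxa)
}

#' Validate a general chain in the poset
#'
#' A chain is a sequence of `2 <= t <= n` pairwise distinct member systems
#' from the singleton partition to `{X}` in which every consecutive pair is
#' comparable.  Chains of length `n` are exactly the maximal chains.
#'
#' @param x An `rtcn_chain` or list of cluster systems.
#' @param taxa Taxon set; inferred from the chain when omitted.
#' @return A list with `$ok`, `$length` and `$reason`.
#' @export
is_chain <- function(x, taxa = NULL) {
  systems <- chain_systems(x)
  if (is.null(taxa)) {
    taxa <- if (inherits(x, "rtcn_chain")) x$taxa else
      system_union(systems[[1L]])
  }
  taxa <- taxon_set(taxa)
  t <- length(systems)
  verdict <- function(ok, reason = NA_character_) {
    list(ok = ok, length = t, reason = reason)
  }
  n <- length(taxa)
  if (t < 2L || t > n) {
    return(verdict(FALSE, sprintf("chain length %d outside [2, %d]", t, n)))
  }
  keys <- vapply(systems, system_key, character(1))
  if (anyDuplicated(keys)) return(verdict(FALSE, "systems not pairwise distinct"))
  if (keys[[1L]] != system_key(singleton_partition(taxa))) {
    return(verdict(FALSE, "does not start at the singleton partition"))
  }
  if (keys[[t]] != system_key(cluster_system(list(taxa)))) {
    return(verdict(FALSE, "does not end at {X}"))
  }
  for (i in seq_len(t - 1L)) {
    if (!precedes(systems[[i]], systems[[i + 1L]], taxa)) {
      return(verdict(FALSE, sprintf("systems %d and %d not comparable in order",
                                    i, i + 1L)))
    }
  }
  verdict(TRUE)
}

#' Grade of a member system
#'
#' The poset is graded by `n - |sys|`: 0 for the singleton partition,
#' `n - 1` for `{X}`.
#'
#' @param sys A cluster system that must be a poset member.
#' @param taxa The taxon set.
#' @return Integer grade.
#' @export
grade <- function(sys, taxa) {
  taxa <- taxon_set(taxa)
  sys <- cluster_system(sys, taxa = taxa)
  if (!is_member(sys, taxa)) {
    stop("system {", system_key(sys), "} occurs in no maximal chain on the ",
         "given taxa")
  }
  length(taxa) - length(sys)
}

#' Enumerate all maximal chains on a taxon set
#'
#' Depth-first enumeration in canonical lexicographic order (successor
#' systems visited in key order).  The number of maximal chains grows as
#' `prod_{k=3..n} (choose(k,2) + 3*choose(k,3))`, so enumeration is capped.
#'
#' @param taxa The taxon set.
#' @param cap Maximum allowed `n` (default 6).
#' @param callback Optional function applied to each chain as it is found;
#'   when supplied, chains are not accumulated and `NULL` is returned
#'   (streaming mode for large `n`).
#' @return List of `rtcn_chain` objects (unless `callback` is given).
#' @export
enumerate_maximal_chains <- function(taxa, cap = 6L, callback = NULL) {
  taxa <- taxon_set(taxa)
  n <- length(taxa)
  if (n > cap) {
    stop(sprintf(
      "n = %d exceeds the enumeration cap (%d); the number of maximal chains grows too quickly -- raise `cap` explicitly to override",
      n, cap))
  }
  acc <- if (is.null(callback)) vector("list", 0L) else NULL
  emit <- function(systems) {
    ch <- new_chain(taxa, systems)
    if (is.null(callback)) {
      acc[[length(acc) + 1L]] <<- ch
    } else {
      callback(ch)
    }
  }
  recurse <- function(prefix) {
    last <- prefix[[length(prefix)]]
    if (length(last) == 1L) {
      emit(prefix)
      return(invisible())
    }
    succ <- successors(last)
    keys <- vapply(succ, system_key, character(1))
    for (s in succ[order(keys, method = "radix")]) {
      recurse(c(prefix, list(s)))
    }
  }
  recurse(list(singleton_partition(taxa)))
  if (is.null(callback)) acc else invisible(NULL)
}

#' Number of maximal chains on n taxa
#'
#' Closed form `prod_{k=3..n} (choose(k,2) + 3*choose(k,3))`, counting the
#' per-step generative choices.
#'
#' @param n Number of taxa (`n >= 2`).
#' @return Numeric count.
#' @export
count_maximal_chains <- function(n) {
  if (n < 2) stop("n must be at least 2")
  if (n == 2) return(1)
  prod(vapply(3:n, function(k) choose(k, 2) + 3 * choose(k, 3), numeric(1)))
}
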