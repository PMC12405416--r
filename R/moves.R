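# Discrete distances on binary ranked tree-child networks, through their
# chain encodings.  An rNNI* move replaces exactly one interior system of a
# maximal chain; on ranked trees this restricts to the classical rNNI.

#' Ranked Robinson-Foulds distance between two maximal chains
#'
#' The cardinality of the symmetric difference of the two chains viewed as
#' sets of cluster systems.  Zero exactly when the chains (equivalently,
#' the encoded networks) are equal.
#'
#' @param c1,c2 `rtcn_chain` objects on the same taxon set.
#' @return Integer distance.
#' @export
rf_distance <- function(c1, c2) {
  if (!identical(c1$taxa, c2$taxa)) {
    stop("chains are on different taxon sets")
  }
  k1 <- unique(vapply(c1$systems, system_key, character(1)))
  k2 <- unique(vapply(c2$systems, system_key, character(1)))
  length(setdiff(k1, k2)) + length(setdiff(k2, k1))
}

#' rNNI* neighbors of a maximal chain
#'
#' All maximal chains that agree with `chain` everywhere except at one
#' interior position i, where the replacement system D satisfies
#' `chain[i-1] |- D |- chain[i+1]` and differs from `chain[i]`.  Computed
#' by filtering the successors of `chain[i-1]` through the relation with
#' `chain[i+1]`.
#'
#' @param chain An `rtcn_chain` passing [is_maximal_chain()].
#' @return List of `rtcn_chain` objects (neighbors), deduplicated.
#' @export
star_neighbors <- function(chain) {
  v <- is_maximal_chain(chain)
  if (!v$ok) stop("not a maximal chain: ", v$reason)
  key <- paste0("nbr|", chain_key(chain))
  hit <- cache_get(key)
  if (!is.null(hit)) return(hit)
  systems <- chain$systems
  n <- length(systems)
  out <- list()
  if (n >= 3L) {
    for (i in seq.int(2L, n - 1L)) {
      cur_key <- system_key(systems[[i]])
      for (D in successors(systems[[i - 1L]])) {
        if (system_key(D) == cur_key) next
        if (length(relation(D, systems[[i + 1L]])) > 0L) {
          repl <- systems
          repl[[i]] <- D
          out[[length(out) + 1L]] <- new_chain(chain$taxa, repl)
        }
      }
    }
  }
  cache_set(key, out)
}

#' rNNI neighbors of a ranked-tree chain
#'
#' The rNNI* neighbors restricted to partition-only (ranked tree) chains.
#'
#' @param chain An `rtcn_chain` with [is_ranked_tree()] `TRUE`.
#' @return List of `rtcn_chain` objects.
#' @export
tree_neighbors <- function(chain) {
  if (!is_ranked_tree(chain)) {
    stop("tree moves require a ranked-tree (partition-only) chain")
  }
  Filter(is_ranked_tree, star_neighbors(chain))
}

#' Exact move distance between two maximal chains
#'
#' Shortest-path length in the rNNI* (or rNNI) move graph by breadth-first
#' search with canonical hashing, together with one witness walk.
#'
#' @param c1,c2 `rtcn_chain` objects on the same taxon set.
#' @param move_set `"star"` (rNNI* on all binary networks) or `"tree"`
#'   (rNNI restricted to ranked trees; both inputs must then be trees).
#' @param cap Refuse taxon sets larger than this (the state space is the
#'   set of all maximal chains); default 6.
#' @return List with `$distance` (integer) and `$path` (a `move_sequence`:
#'   list of chains from `c1` to `c2`, consecutive entries differing in
#'   exactly one position).
#' @export
bfs_distance <- function(c1, c2, move_set = c("star", "tree"), cap = 6L) {
  move_set <- match.arg(move_set)
  if (!identical(c1$taxa, c2$taxa)) stop("chains are on different taxon sets")
  n <- length(c1$taxa)
  if (n > cap) {
    stop(sprintf("n = %d exceeds the BFS cap (%d); raise `cap` to override",
                 n, cap))
  }
  neighbors <- if (move_set == "tree") tree_neighbors else star_neighbors
  if (move_set == "tree" && (!is_ranked_tree(c1) || !is_ranked_tree(c2))) {
    stop("tree moves require ranked-tree chains at both endpoints")
  }
  start <- chain_key(c1)
  goal <- chain_key(c2)
  parent <- new.env(parent = emptyenv())
  assign(start, list(prev = NA_character_, chain = c1), envir = parent)
  if (start == goal) {
    return(list(distance = 0L,
                path = new_move_sequence(list(c1))))
  }
  frontier <- list(c1)
  dist <- 0L
  repeat {
    dist <- dist + 1L
    nxt <- list()
    for (ch in frontier) {
      ck <- chain_key(ch)
      for (nb in neighbors(ch)) {
        nk <- chain_key(nb)
        if (exists(nk, envir = parent, inherits = FALSE)) next
        assign(nk, list(prev = ck, chain = nb), envir = parent)
        if (nk == goal) {
          path <- list()
          cur <- nk
          while (!is.na(cur)) {
            entry <- get(cur, envir = parent, inherits = FALSE)
            path <- c(list(entry$chain), path)
            cur <- entry$prev
          }
          return(list(distance = dist, path = new_move_sequence(path)))
        }
        nxt[[length(nxt) + 1L]] <- nb
      }
    }
    if (length(nxt) == 0L) {
      stop("move graph exhausted without reaching the target chain")
    }
    frontier <- nxt
  }
}

#' Construct a move sequence
#'
#' @param chains List of `rtcn_chain` objects in which consecutive entries
#'   differ in exactly one position; checked.
#' @return An object of class `move_sequence`.
#' @export
new_move_sequence <- function(chains) {
  if (length(chains) == 0L) stop("a move sequence contains at least one chain")
  if (length(chains) > 1L) {
    for (i in seq_len(length(chains) - 1L)) {
      a <- chains[[i]]$systems
      b <- chains[[i + 1L]]$systems
      diffs <- sum(vapply(seq_along(a), function(j) {
        system_key(a[[j]]) != system_key(b[[j]])
      }, logical(1)))
      if (length(a) != length(b) || diffs != 1L) {
        stop("consecutive chains must differ in exactly one position (entries ",
             i, " and ", i + 1L, " differ in ", diffs, ")")
      }
    }
  }
  structure(list(chains = chains), class = "move_sequence")
}

#' Number of moves in a move sequence
#'
#' @param seq A `move_sequence`.
#' @return Integer: number of chains minus one.
#' @export
move_count <- function(seq) length(seq$chains) - 1L

#' @export
print.move_sequence <- function(x, ...) {
  cat(sprintf("Move sequence of %d rNNI* move(s):\n", move_count(x)))
  if (move_count(x) > 0L) {
    for (i in seq_len(move_count(x))) {
      a <- x$chains[[i]]$systems
      b <- x$chains[[i + 1L]]$systems
      j <- which(vapply(seq_along(a), function(k) {
        system_key(a[[k]]) != system_key(b[[k]])
      }, logical(1)))
      cat(sprintf("  move %d at position %d: %s -> %s\n", i, j,
                  system_key(a[[j]]), system_key(b[[j]])))
    }
  }
  invisible(x)
}

#' Transform a binary network chain into a ranked-tree chain by rNNI* moves
#'
#' Constructive elimination of reticulation steps, one round per
#' reticulation: take the last reticulation step i with witness (A, B, C);
#' restrict positions i..n to a set of private representatives (smallest
#' private label per cluster of position i), giving a ranked tree on the
#' representatives; walk that tree by rNNI moves to a caterpillar whose
#' rank-2 cherry pairs the representatives of A u B and B u C; lift each
#' restricted move back to the full chain; finally replace position i by
#' the join system `(chain[i-1] - {A,B}) + {A u B}`, which removes the
#' reticulation.  Rounds repeat until no reticulation step remains.
#'
#' @param chain An `rtcn_chain` passing [is_maximal_chain()].
#' @return A `move_sequence` from `chain` to a partition-only chain.
#' @export
detangle_to_tree <- function(chain) {
  v <- is_maximal_chain(chain)
  if (!v$ok) stop("not a maximal chain: ", v$reason)
  walk <- list(chain)
  current <- chain
  repeat {
    tags <- is_maximal_chain(current)$tags
    # a "both" step admits a join decomposition, so only pure reticulation
    # steps need eliminating; all-join-witness chains consist of partitions
    rets <- which(tags == "ret")
    if (length(rets) == 0L) break
    i <- max(rets) + 1L           # position of the system *after* the ret step
    systems <- current$systems
    n <- length(systems)
    wits <- relation(systems[[i - 1L]], systems[[i]])
    wits <- wits[vapply(wits, `[[`, character(1), "type") == "ret"]
    w <- wits[[1L]]
    # private representatives of position i: smallest private label each
    priv <- private_elements(systems[[i]])
    reps <- vapply(priv, function(p) p[[1L]], character(1))
    rep_of <- stats::setNames(reps, vapply(systems[[i]], cluster_key,
                                           character(1)))
    xprime <- taxon_set(reps)
    # lift map: representative -> full cluster of position i
    lift_cluster <- function(restricted) {
      cluster(unlist(lapply(restricted, function(x) {
        systems[[i]][[match(x, reps)]]
      })))
    }
    restrict_sys <- function(sys) {
      cluster_system(lapply(sys, function(cl) intersect(cl, xprime)))
    }
    t1 <- new_chain(xprime, lapply(systems[i:n], restrict_sys))
    y <- rep_of[[cluster_key(cluster(c(w$A, w$B)))]]
    z <- rep_of[[cluster_key(cluster(c(w$B, w$C)))]]
    t2 <- caterpillar_chain(xprime, cherry = c(y, z))
    inner <- bfs_distance(t1, t2, move_set = "tree",
                          cap = length(xprime))$path
    if (move_count(inner) > 0L) {
      for (k in seq.int(2L, length(inner$chains))) {
        prev_r <- inner$chains[[k - 1L]]$systems
        cur_r <- inner$chains[[k]]$systems
        jj <- which(vapply(seq_along(cur_r), function(m) {
          system_key(cur_r[[m]]) != system_key(prev_r[[m]])
        }, logical(1)))
        lifted <- cluster_system(lapply(cur_r[[jj]], lift_cluster))
        systems[[i + jj - 1L]] <- lifted
        current <- new_chain(current$taxa, systems)
        stopifnot(is_maximal_chain(current)$ok)
        walk[[length(walk) + 1L]] <- current
      }
    }
    # final move of the round: de-reticulate position i
    systems[[i]] <- apply_join(systems[[i - 1L]], w$A, w$B)
    current <- new_chain(current$taxa, systems)
    stopifnot(is_maximal_chain(current)$ok)
    walk[[length(walk) + 1L]] <- current
  }
  new_move_sequence(walk)
}

#' Canonical caterpillar chain with a prescribed cherry
#'
#' The ranked-tree chain that first joins the two cherry taxa and then
#' attaches the remaining taxa one at a time in canonical label order.
#'
#' @param taxa A taxon set.
#' @param cherry Two labels forming the rank-2 cherry; default the two
#'   smallest.
#' @return An `rtcn_chain` (a valid maximal chain of joins).
#' @export
caterpillar_chain <- function(taxa, cherry = NULL) {
  taxa <- taxon_set(taxa)
  if (is.null(cherry)) cherry <- taxa[1:2]
  stopifnot(length(cherry) == 2L, all(cherry %in% taxa))
  systems <- list(singleton_partition(taxa))
  cur <- systems[[1L]]
  grown <- cluster(cherry)
  cur <- apply_join(cur, cherry[[1L]], cherry[[2L]])
  systems <- c(systems, list(cur))
  for (x in setdiff(taxa, cherry)) {
    cur <- apply_join(cur, grown, x)
    grown <- cluster(c(grown, x))
    systems <- c(systems, list(cur))
  }
  new_chain(taxa, systems)
}
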