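# Ranked networks as DAGs, and the two constructions from chains:
#  * decode_binary(): the step-guided construction for maximal chains, where
#    each step applies the generative event named by a witness of the
#    successor relation (the private-element property makes the participating
#    frontier vertices unique);
#  * build_network(): the three-phase construction for general chains, which
#    merges frontier vertices with equal H-sets, wires hybrid vertices, and
#    adds stems above out-degree >= 2 frontier vertices.
# encode() is the inverse map reading the i-th cluster system off the arcs
# that span rank level i.
#
# A network is a plain list: integer vertex ids 1..n_vertices, an arc matrix
# (tail, head), the root id, leaf labels (NA for interior vertices), and the
# rank map.  Leaves have rank 1 and the root rank t.

new_ranked_network <- function(taxa, arcs, root, leaf_label, rank) {
  structure(list(taxa = taxa,
                 n_vertices = length(rank),
                 arcs = arcs,
                 root = root,
                 leaf_label = leaf_label,
                 rank = rank),
            class = "ranked_network")
}

#' @export
print.ranked_network <- function(x, ...) {
  n_hyb <- sum(tabulate(x$arcs[, 2L], nbins = x$n_vertices) >= 2L)
  cat(sprintf(
    "Ranked network on %d taxa: %d vertices, %d arcs, %d hybrid vertices, max rank %d\n",
    length(x$taxa), x$n_vertices, nrow(x$arcs), n_hyb, max(x$rank)))
  invisible(x)
}

in_degrees <- function(net) tabulate(net$arcs[, 2L], nbins = net$n_vertices)
out_degrees <- function(net) tabulate(net$arcs[, 1L], nbins = net$n_vertices)

#' Hybrid vertex ids of a ranked network
#'
#' @param net A `ranked_network`.
#' @return Integer vector of vertices with in-degree at least 2.
#' @export
hybrid_vertices <- function(net) which(in_degrees(net) >= 2L)

# mutable builder used by both constructions
net_builder <- function(taxa) {
  env <- new.env(parent = emptyenv())
  env$taxa <- taxa
  env$rank <- rep(NA_integer_, length(taxa))
  env$leaf_label <- taxa          # vertices 1..n are the leaves, rank 1
  env$rank[seq_along(taxa)] <- 1L
  env$tails <- integer(0)
  env$heads <- integer(0)
  env$new_vertex <- function(rank) {
    env$rank <- c(env$rank, as.integer(rank))
    env$leaf_label <- c(env$leaf_label, NA_character_)
    length(env$rank)
  }
  env$add_arc <- function(tail, head) {
    env$tails <- c(env$tails, tail)
    env$heads <- c(env$heads, head)
  }
  env$finish <- function(root) {
    new_ranked_network(env$taxa,
                       cbind(tail = env$tails, head = env$heads),
                       root, env$leaf_label, env$rank)
  }
  env
}

#' Decode a maximal chain into its binary ranked tree-child network
#'
#' Replays the generative process guided by the chain: at step i a witness
#' of the successor relation between consecutive systems names the
#' participating frontier clusters, which identify the participating
#' frontier vertices uniquely (each cluster of a chain system has a private
#' taxon).  The result is the unique binary ranked tree-child network whose
#' encoding is the input chain.
#'
#' @param chain An `rtcn_chain` passing [is_maximal_chain()].
#' @return A `ranked_network`.
#' @export
decode_binary <- function(chain) {
  v <- is_maximal_chain(chain)
  if (!v$ok) stop("not a maximal chain: ", v$reason)
  taxa <- chain$taxa
  systems <- chain$systems
  n <- length(taxa)
  b <- net_builder(taxa)
  # frontier: cluster key -> id of the *head* vertex under the pending stem
  frontier <- new.env(parent = emptyenv())
  for (i in seq_along(taxa)) {
    assign(cluster_key(taxa[[i]]), i, envir = frontier)
  }
  fget <- function(cl) get(cluster_key(cl), envir = frontier, inherits = FALSE)
  fdel <- function(cl) rm(list = cluster_key(cl), envir = frontier)
  fset <- function(cl, id) assign(cluster_key(cl), id, envir = frontier)
  for (i in seq.int(2L, n)) {
    w <- relation(systems[[i - 1L]], systems[[i]])[[1L]]
    if (i == n) {
      # the two remaining frontier vertices are identified as the root
      heads <- vapply(systems[[n - 1L]], fget, integer(1))
      root <- b$new_vertex(n)
      for (h in heads) b$add_arc(root, h)
      return(b$finish(root))
    }
    if (w$type == "join") {
      u <- b$new_vertex(i)
      b$add_arc(u, fget(w$A))
      b$add_arc(u, fget(w$B))
      fdel(w$A); fdel(w$B)
      fset(cluster(c(w$A, w$B)), u)
    } else {
      hy <- b$new_vertex(i)          # hybrid above the middle cluster B
      pa <- b$new_vertex(i)
      pc <- b$new_vertex(i)
      b$add_arc(hy, fget(w$B))
      b$add_arc(pa, fget(w$A)); b$add_arc(pa, hy)
      b$add_arc(pc, fget(w$C)); b$add_arc(pc, hy)
      fdel(w$A); fdel(w$B); fdel(w$C)
      fset(cluster(c(w$A, w$B)), pa)
      fset(cluster(c(w$B, w$C)), pc)
    }
  }
}

#' Build the canonical ranked tree-child network of a general chain
#'
#' The three-phase construction per step i: frontier vertices whose
#' clusters have equal H-sets (`H(A) = {B in C_i : A subset B}`) are
#' identified; each frontier vertex with a singleton H-set contained in a
#' larger H-set sends an arc into the latter's vertex, creating hybrids;
#' and a stem is added above every frontier vertex of out-degree at least
#' two.  For maximal chains this coincides with [decode_binary()].
#'
#' @param chain An `rtcn_chain` passing [is_chain()].
#' @return A `ranked_network` whose [encode()] equals `chain`.
#' @export
build_network <- function(chain) {
  v <- is_chain(chain)
  if (!v$ok) stop("not a chain: ", v$reason)
  taxa <- chain$taxa
  systems <- chain$systems
  t <- length(systems)
  b <- net_builder(taxa)
  # frontier: one entry per cluster of the current system, head vertex id
  fr_keys <- vapply(taxa, function(x) cluster_key(x), character(1))
  fr_heads <- seq_along(taxa)
  fr_clusters <- as.list(taxa)
  if (t > 2L) {
    for (i in seq.int(2L, t - 1L)) {
      ci <- systems[[i]]
      ci_keys <- vapply(ci, cluster_key, character(1))
      # H-set of each frontier cluster, as sorted indices into ci
      Hsets <- lapply(fr_clusters, function(A) {
        which(vapply(ci, function(B) all(A %in% B), logical(1)))
      })
      hkeys <- vapply(Hsets, function(ix) paste(ix, collapse = "+"), character(1))
      groups <- split(seq_along(fr_heads), hkeys)
      # Phase 1 + 2 for hybrid groups (|H| >= 2): materialize the merged
      # vertex now so supplier groups can point at it.
      hybrid_of_group <- list()   # hkey -> vertex id
      group_H <- lapply(groups, function(g) Hsets[[g[[1L]]]])
      for (gk in names(groups)) {
        if (length(group_H[[gk]]) >= 2L) {
          y <- b$new_vertex(i)
          for (m in groups[[gk]]) b$add_arc(y, fr_heads[[m]])
          hybrid_of_group[[gk]] <- y
        }
      }
      # Phases 1-3 for singleton-H groups: out-targets are the members'
      # heads plus every hybrid vertex whose H-set contains this group's
      # target cluster; a new ranked vertex is created iff there are >= 2
      # targets (merging and/or stem above out-degree >= 2).
      new_keys <- character(0); new_heads <- integer(0); new_clusters <- list()
      for (gk in names(groups)) {
        H <- group_H[[gk]]
        if (length(H) != 1L) next
        Bidx <- H[[1L]]
        targets <- fr_heads[groups[[gk]]]
        for (hk in names(hybrid_of_group)) {
          if (Bidx %in% group_H[[hk]]) {
            targets <- c(targets, hybrid_of_group[[hk]])
          }
        }
        head_id <- if (length(targets) >= 2L) {
          w <- b$new_vertex(i)
          for (tg in targets) b$add_arc(w, tg)
          w
        } else {
          targets[[1L]]
        }
        new_keys <- c(new_keys, ci_keys[[Bidx]])
        new_heads <- c(new_heads, head_id)
        new_clusters <- c(new_clusters, list(ci[[Bidx]]))
      }
      if (length(new_keys) != length(ci)) {
        stop("internal error: frontier does not match the next system at step ", i)
      }
      fr_keys <- new_keys; fr_heads <- new_heads; fr_clusters <- new_clusters
    }
  }
  root <- b$new_vertex(t)
  for (h in fr_heads) b$add_arc(root, h)
  b$finish(root)
}

#' Hard-wired clusters of a ranked network
#'
#' The cluster of a vertex is the set of leaf labels reachable from it by
#' directed paths.
#'
#' @param net A `ranked_network`.
#' @return List, indexed by vertex id, of clusters (character vectors).
#' @export
hardwired_clusters <- function(net) {
  children <- split(net$arcs[, 2L], factor(net$arcs[, 1L],
                                           levels = seq_len(net$n_vertices)))
  clus <- vector("list", net$n_vertices)
  # process in increasing rank order; within equal rank, hybrids (which sit
  # below their same-rank parents) first -- but a same-rank parent may point
  # at a same-rank hybrid, so just iterate until settled.
  todo <- order(net$rank)
  repeat {
    progressed <- FALSE
    for (v in todo) {
      if (!is.null(clus[[v]])) next
      kids <- children[[v]]
      if (length(kids) == 0L) {
        clus[[v]] <- cluster(net$leaf_label[[v]])
        progressed <- TRUE
      } else if (all(!vapply(clus[kids], is.null, logical(1)))) {
        clus[[v]] <- cluster(unlist(clus[kids]))
        progressed <- TRUE
      }
    }
    if (all(!vapply(clus, is.null, logical(1)))) break
    if (!progressed) stop("cycle detected while computing hard-wired clusters")
  }
  clus
}

#' Encode a ranked network as its chain of cluster systems
#'
#' Level i of the chain collects the hard-wired clusters of the heads of
#' all arcs spanning rank level i (tail rank > i >= head rank); the final
#' system is `{X}`.
#'
#' @param net A `ranked_network` passing [validate_network()].
#' @return An `rtcn_chain` of length `max(rank)`.
#' @export
encode <- function(net) {
  v <- validate_network(net)
  if (!v$ok) stop("invalid network: ", v$violations[[1L]])
  t <- max(net$rank)
  clus <- hardwired_clusters(net)
  systems <- vector("list", t)
  for (i in seq_len(t - 1L)) {
    span <- net$rank[net$arcs[, 1L]] > i & net$rank[net$arcs[, 2L]] <= i
    heads <- unique(net$arcs[span, 2L])
    systems[[i]] <- cluster_system(unique(clus[heads]))
  }
  systems[[t]] <- cluster_system(list(net$taxa))
  new_chain(net$taxa, systems)
}

#' Validate a ranked network
#'
#' Checks acyclicity, the unique root, the leaf labeling, the tree-child
#' condition, and the rank rules (leaves rank 1, root maximal, tails never
#' below heads; in binary networks rank equality across an arc exactly at
#' hybrid heads).
#'
#' @param net A `ranked_network`.
#' @return A list with `$ok` and `$violations` (character vector).
#' @export
validate_network <- function(net) {
  bad <- character(0)
  nv <- net$n_vertices
  indeg <- in_degrees(net)
  outdeg <- out_degrees(net)
  if (sum(indeg == 0L) != 1L || indeg[[net$root]] != 0L) {
    bad <- c(bad, sprintf("root: expected unique in-degree-0 vertex %d", net$root))
  }
  leaves <- which(outdeg == 0L)
  labs <- net$leaf_label[leaves]
  if (anyNA(labs) || !setequal(labs, net$taxa) ||
      length(labs) != length(net$taxa)) {
    bad <- c(bad, "leaves: out-degree-0 vertices not labeled bijectively by X")
  }
  # acyclicity via repeated removal of in-degree-0 vertices
  deg <- indeg
  alive <- rep(TRUE, nv)
  repeat {
    src <- which(alive & deg == 0L)
    if (length(src) == 0L) break
    alive[src] <- FALSE
    out_arcs <- net$arcs[, 1L] %in% src
    heads <- net$arcs[out_arcs & alive[net$arcs[, 2L]], 2L]
    for (h in heads) deg[[h]] <- deg[[h]] - 1L
  }
  if (any(alive)) {
    bad <- c(bad, paste("cycle involving vertices",
                        paste(which(alive), collapse = ",")))
  }
  # tree-child: every interior vertex has an arc to a tree vertex
  interior <- which(outdeg > 0L)
  for (u in interior) {
    kids <- net$arcs[net$arcs[, 1L] == u, 2L]
    if (all(indeg[kids] >= 2L)) {
      bad <- c(bad, sprintf("tree-child violated at vertex %d", u))
    }
  }
  # ranks
  if (any(net$rank[leaves] != 1L)) bad <- c(bad, "rank: some leaf has rank != 1")
  if (length(net$rank) && net$rank[[net$root]] != max(net$rank)) {
    bad <- c(bad, "rank: root is not of maximal rank")
  }
  ru <- net$rank[net$arcs[, 1L]]
  rv <- net$rank[net$arcs[, 2L]]
  if (any(ru < rv)) {
    i <- which(ru < rv)[[1L]]
    bad <- c(bad, sprintf("rank monotonicity violated on arc (%d,%d)",
                          net$arcs[i, 1L], net$arcs[i, 2L]))
  }
  if (is_binary_network(net)) {
    eq <- ru == rv
    hyb_head <- indeg[net$arcs[, 2L]] >= 2L
    if (any(eq != hyb_head)) {
      i <- which(eq != hyb_head)[[1L]]
      bad <- c(bad, sprintf(
        "binary rank rule violated on arc (%d,%d): equality iff hybrid head",
        net$arcs[i, 1L], net$arcs[i, 2L]))
    }
  }
  list(ok = length(bad) == 0L, violations = bad)
}

#' Is a ranked network binary?
#'
#' Root of out-degree 2; every other interior vertex has degrees (1,2) or
#' (2,1).
#'
#' @param net A `ranked_network`.
#' @return Logical.
#' @export
is_binary_network <- function(net) {
  indeg <- in_degrees(net)
  outdeg <- out_degrees(net)
  if (outdeg[[net$root]] != 2L) return(FALSE)
  interior <- setdiff(which(outdeg > 0L), net$root)
  all((indeg[interior] == 1L & outdeg[interior] == 2L) |
        (indeg[interior] == 2L & outdeg[interior] == 1L))
}

#' Does a chain or network correspond to a ranked tree?
#'
#' A chain corresponds to a (binary) ranked tree exactly when every step
#' admits a join witness and every system is a partition; a network is a
#' ranked tree when it has no hybrid vertex.
#'
#' @param x An `rtcn_chain` or `ranked_network`.
#' @return Logical.
#' @export
is_ranked_tree <- function(x) {
  if (inherits(x, "ranked_network")) {
    return(length(hybrid_vertices(x)) == 0L)
  }
  systems <- chain_systems(x)
  taxa <- if (inherits(x, "rtcn_chain")) x$taxa else system_union(systems[[1L]])
  all(vapply(systems, is_partition, logical(1), taxa = taxa))
}

# canonical signature for isomorphism tests: vertices of a chain-derived
# network are distinguished by (rank, hard-wired cluster)
network_signature <- function(net) {
  clus <- hardwired_clusters(net)
  sig <- sprintf("%d|%s", net$rank,
                 vapply(clus, cluster_key, character(1)))
  if (anyDuplicated(sig)) {
    stop("vertices not distinguished by (rank, cluster); signature unusable")
  }
  arcs <- sprintf("%s->%s", sig[net$arcs[, 1L]], sig[net$arcs[, 2L]])
  paste(sort(arcs), collapse = ";")
}

#' Export a ranked network as an extended Newick string
#'
#' Deterministic dialect: children ordered by minimum descendant label,
#' hybrid vertices tagged `#Hk` (k assigned in traversal order) with the
#' full subtree written at the first occurrence and a stub afterwards,
#' ranks emitted as bracketed `[r=<rank>]` labels, and optional arc weights
#' as branch lengths.
#'
#' @param net A `ranked_network`.
#' @param weights Optional numeric vector of arc weights aligned with the
#'   rows of `net$arcs`.
#' @return A single string terminated by `";"`.
#' @export
to_enewick <- function(net, weights = NULL) {
  v <- validate_network(net)
  if (!v$ok) stop("invalid network: ", v$violations[[1L]])
  clus <- hardwired_clusters(net)
  minlab <- vapply(clus, function(cl) cl[[1L]], character(1))
  indeg <- in_degrees(net)
  hyb_tag <- integer(net$n_vertices)   # 0 = not hybrid; else tag number
  next_tag <- 0L
  written <- logical(net$n_vertices)
  arc_weight <- function(u, vtx) {
    if (is.null(weights)) return("")
    i <- which(net$arcs[, 1L] == u & net$arcs[, 2L] == vtx)[[1L]]
    sprintf(":%.12g", weights[[i]])
  }
  render <- function(vtx) {
    lab <- if (!is.na(net$leaf_label[[vtx]])) net$leaf_label[[vtx]] else ""
    tag <- ""
    if (indeg[[vtx]] >= 2L) {
      if (hyb_tag[[vtx]] == 0L) {
        next_tag <<- next_tag + 1L
        hyb_tag[[vtx]] <<- next_tag
      }
      tag <- sprintf("#H%d", hyb_tag[[vtx]])
      if (written[[vtx]]) {
        return(sprintf("%s%s[r=%d]", lab, tag, net$rank[[vtx]]))
      }
    }
    written[[vtx]] <<- TRUE
    kids <- net$arcs[net$arcs[, 1L] == vtx, 2L]
    if (length(kids) == 0L) {
      return(sprintf("%s%s[r=%d]", lab, tag, net$rank[[vtx]]))
    }
    kids <- kids[order(minlab[kids], net$rank[kids], method = "radix")]
    parts <- vapply(kids, function(k) {
      paste0(render(k), arc_weight(vtx, k))
    }, character(1))
    sprintf("(%s)%s%s[r=%d]", paste(parts, collapse = ","), lab, tag,
            net$rank[[vtx]])
  }
  paste0(render(net$root), ";")
}

#' Read a ranked network from JSON
#'
#' Package format: `{"vertices": [...], "arcs": [[u,v], ...], "root": id,
#' "leaves": {"id": "label", ...}, "rank": {"id": r, ...}}`.
#'
#' @param path Path to a JSON file.
#' @return A `ranked_network`.
#' @export
read_network_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  for (f in c("vertices", "arcs", "root", "leaves", "rank")) {
    if (is.null(obj[[f]])) stop("network JSON must have field '", f, "'")
  }
  ids <- as.integer(unlist(obj$vertices))
  nv <- length(ids)
  if (!identical(sort(ids), seq_len(nv))) {
    stop("network JSON vertices must be the integers 1..n")
  }
  arcs <- do.call(rbind, lapply(obj$arcs, function(a) as.integer(unlist(a))))
  colnames(arcs) <- c("tail", "head")
  leaf_label <- rep(NA_character_, nv)
  for (id in names(obj$leaves)) leaf_label[[as.integer(id)]] <- obj$leaves[[id]]
  rank <- rep(NA_integer_, nv)
  for (id in names(obj$rank)) rank[[as.integer(id)]] <- as.integer(obj$rank[[id]])
  taxa <- taxon_set(leaf_label[!is.na(leaf_label)])
  new_ranked_network(taxa, arcs, as.integer(obj$root), leaf_label, rank)
}

#' Write a ranked network to JSON
#'
#' @param net A `ranked_network`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_network_json <- function(net, path) {
  leaves <- which(!is.na(net$leaf_label))
  obj <- list(
    vertices = seq_len(net$n_vertices),
    arcs = lapply(seq_len(nrow(net$arcs)),
                  function(i) as.integer(net$arcs[i, ])),
    root = jsonlite::unbox(as.integer(net$root)),
    leaves = stats::setNames(as.list(net$leaf_label[leaves]),
                             as.character(leaves)),
    rank = stats::setNames(as.list(as.integer(net$rank)),
                           as.character(seq_len(net$n_vertices)))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
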