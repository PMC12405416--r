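# Canonical forms for taxa, clusters and cluster systems.
#
# A cluster is a non-empty subset of the taxon set X, represented as a sorted
# character vector.  A cluster system is a non-empty set of pairwise-distinct
# clusters, represented as a list of clusters in a fixed canonical order.
# Canonical order makes systems hashable by a string key, which everything
# downstream (deduplication, BFS visited sets, memoized poset queries) relies
# on.

#' Construct a canonical taxon set
#'
#' Taxon labels are deduplicated-checked and stored in lexicographic order;
#' this fixed total order is used for all deterministic output of the
#' package.
#'
#' @param labels Character vector of at least two distinct taxon labels.
#' @return Sorted character vector of labels.
#' @export
#' @examples
#' taxon_set(c("b", "a", "c"))
taxon_set <- function(labels) {
  labels <- as.character(labels)
  if (length(labels) < 2L) {
    stop("a taxon set must contain at least 2 labels")
  }
  if (anyDuplicated(labels)) {
    stop("taxon labels must be pairwise distinct")
  }
  sort(labels, method = "radix")
}

#' Construct a canonical cluster
#'
#' @param members Character vector of taxon labels (non-empty).
#' @param taxa Optional taxon set; when given, membership is checked.
#' @return Sorted character vector of distinct labels.
#' @export
cluster <- function(members, taxa = NULL) {
  members <- unique(as.character(members))
  if (length(members) == 0L) stop("a cluster must be non-empty")
  if (!is.null(taxa) && !all(members %in% taxa)) {
    bad <- setdiff(members, taxa)
    stop("cluster members not in taxon set: ", paste(bad, collapse = ", "))
  }
  sort(members, method = "radix")
}

cluster_key <- function(cl) paste(cl, collapse = ",")

#' Construct a canonical cluster system
#'
#' Clusters are put into a canonical order (minimum label, then size, then
#' lexicographic on the comma-joined members) and checked for pairwise
#' distinctness.
#'
#' @param clusters List of clusters (character vectors).
#' @param taxa Optional taxon set for membership checking.
#' @return List of clusters in canonical order.
#' @export
cluster_system <- function(clusters, taxa = NULL) {
  if (length(clusters) == 0L) stop("a cluster system must be non-empty")
  clusters <- lapply(clusters, cluster, taxa = taxa)
  keys <- vapply(clusters, cluster_key, character(1))
  if (anyDuplicated(keys)) {
    stop("clusters in a system must be pairwise distinct")
  }
  mins <- vapply(clusters, function(cl) cl[[1L]], character(1))
  sizes <- lengths(clusters)
  clusters[order(mins, sizes, keys, method = "radix")]
}

#' Canonical string key of a cluster system
#'
#' Two cluster systems are equal as sets of sets if and only if their keys
#' are equal.  Used for hashing and deduplication throughout the package.
#'
#' @param sys A cluster system (list of clusters).
#' @return A single string such as `"{a,b}{c}{d}"`.
#' @export
system_key <- function(sys) {
  paste0("{", vapply(sys, cluster_key, character(1)), "}", collapse = "")
}

system_union <- function(sys) {
  sort(unique(unlist(sys, use.names = FALSE)), method = "radix")
}

#' The singleton partition of a taxon set
#'
#' @param taxa A taxon set.
#' @return The cluster system `{{x} : x in X}`.
#' @export
singleton_partition <- function(taxa) {
  cluster_system(as.list(taxon_set(taxa)))
}

#' Test whether a cluster system is a partition of the taxon set
#'
#' @param sys A cluster system.
#' @param taxa A taxon set.
#' @return `TRUE` if the clusters are pairwise disjoint and cover `taxa`.
#' @export
is_partition <- function(sys, taxa) {
  all_members <- unlist(sys, use.names = FALSE)
  !anyDuplicated(all_members) && setequal(all_members, taxa)
}

# internal: index of a cluster (by key) inside a system, 0 if absent
cluster_index <- function(sys, cl) {
  key <- cluster_key(cluster(cl))
  keys <- vapply(sys, cluster_key, character(1))
  idx <- match(key, keys)
  if (is.na(idx)) 0L else idx
}
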