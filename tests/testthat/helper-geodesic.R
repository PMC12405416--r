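# Brute-force oracle for the geodesic path length: enumerate every ordered
# partition pair of the two exclusive supports that satisfies both
# path-space conditions -- (i) compatibility between earlier B-blocks and
# later A-blocks, and (ii) nondecreasing norm ratios ||A_i||/||B_i|| (the
# path length formula sum_i (||A_i||+||B_i||)^2 is attained by an actual
# path only under (ii)) -- and take the minimum.  Support systems comparable
# with the whole opposite support factor out as independent Euclidean axes
# first (the complex is locally a product along such axes), which also lets
# the enumeration use non-empty blocks only.

ordered_partitions <- function(items, k) {
  # all ways to distribute items into k labeled non-empty blocks
  n <- length(items)
  if (k > n) return(list())
  out <- list()
  assign_next <- function(i, blocks) {
    if (i > n) {
      if (all(lengths(blocks) > 0L)) out[[length(out) + 1L]] <<- blocks
      return(invisible())
    }
    for (b in seq_len(k)) {
      blocks[[b]] <- c(blocks[[b]], items[[i]])
      assign_next(i + 1L, blocks)
      blocks[[b]] <- blocks[[b]][-length(blocks[[b]])]
    }
  }
  assign_next(1L, rep(list(character(0)), k))
  out
}

oracle_geodesic <- function(p, q) {
  taxa <- p$taxa
  kp <- names(p$values); kq <- names(q$values)
  K <- intersect(kp, kq)
  A <- setdiff(kp, kq); B <- setdiff(kq, kp)
  sysmap <- c(p$systems[A], q$systems[B])
  comp <- function(a, b) {
    precedes(sysmap[[a]], sysmap[[b]], taxa) ||
      precedes(sysmap[[b]], sysmap[[a]], taxa)
  }
  csq <- sum(vapply(K, function(k) (p$values[[k]] - q$values[[k]])^2,
                    numeric(1)))
  # factor out axes comparable with the entire opposite side (iterate: each
  # removal can free further axes)
  extra <- 0
  repeat {
    freeA <- A[vapply(A, function(a) all(vapply(B, function(b) comp(a, b),
                                                logical(1))), logical(1))]
    freeB <- B[vapply(B, function(b) all(vapply(A, function(a) comp(a, b),
                                                logical(1))), logical(1))]
    if (length(freeA) == 0L && length(freeB) == 0L) break
    extra <- extra +
      sum(vapply(freeA, function(k) p$values[[k]]^2, numeric(1))) +
      sum(vapply(freeB, function(k) q$values[[k]]^2, numeric(1)))
    A <- setdiff(A, freeA); B <- setdiff(B, freeB)
  }
  if (length(A) == 0L && length(B) == 0L) return(sqrt(csq + extra))
  if (length(A) == 0L || length(B) == 0L) {
    solo <- sum(vapply(A, function(k) p$values[[k]]^2, numeric(1))) +
      sum(vapply(B, function(k) q$values[[k]]^2, numeric(1)))
    return(sqrt(csq + extra + solo))
  }
  best <- Inf
  for (k in seq_len(min(length(A), length(B)))) {
    partsA <- ordered_partitions(A, k)
    partsB <- ordered_partitions(B, k)
    for (pa in partsA) {
      for (pb in partsB) {
        ok <- TRUE
        for (i in seq_len(k - 1L)) {
          for (j in seq.int(i + 1L, k)) {
            for (b in pb[[i]]) {
              for (a in pa[[j]]) {
                if (!comp(a, b)) { ok <- FALSE; break }
              }
              if (!ok) break
            }
            if (!ok) break
          }
          if (!ok) break
        }
        if (!ok) next
        nas <- vapply(seq_len(k), function(i) {
          sqrt(sum(vapply(pa[[i]], function(x) p$values[[x]]^2, numeric(1))))
        }, numeric(1))
        nbs <- vapply(seq_len(k), function(i) {
          sqrt(sum(vapply(pb[[i]], function(x) q$values[[x]]^2, numeric(1))))
        }, numeric(1))
        ratios <- nas / nbs
        if (k > 1L && any(diff(ratios) < -1e-12)) next   # condition (ii)
        lsq <- sum((nas + nbs)^2)
        if (lsq < best) best <- lsq
      }
    }
  }
  sqrt(csq + extra + best)
}
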