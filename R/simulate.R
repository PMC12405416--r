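# Random generators and the bundled worked examples.  All randomness flows
# through R's RNG, so set.seed() makes every draw reproducible; the draw
# order (step type first, then witness) is fixed so seeds are portable.

#' Random maximal chain
#'
#' Replays the generative process: at each step with k >= 3 frontier
#' clusters a reticulation is performed with probability `p_ret` (uniform
#' over the `3 * choose(k,3)` middle/outer-pair choices), otherwise a join
#' (uniform over the `choose(k,2)` pairs); two remaining clusters force the
#' final join.
#'
#' @param n Number of taxa (labels default to `letters[1:n]` style).
#' @param p_ret Probability of a reticulation step, in `[0, 1]`.
#' @param taxa Optional explicit taxon labels.
#' @return An `rtcn_chain` (always a valid maximal chain).
#' @export
#' @examples
#' set.seed(1)
#' random_maximal_chain(5, p_ret = 0.3)
random_maximal_chain <- function(n, p_ret = 0.25, taxa = NULL) {
  if (p_ret < 0 || p_ret > 1) stop("p_ret must lie in [0, 1]")
  if (is.null(taxa)) {
    taxa <- if (n <= 26) letters[seq_len(n)] else sprintf("t%02d", seq_len(n))
  }
  taxa <- taxon_set(taxa)
  n <- length(taxa)
  systems <- list(singleton_partition(taxa))
  cur <- systems[[1L]]
  while (length(cur) > 1L) {
    k <- length(cur)
    do_ret <- k >= 3L && stats::runif(1) < p_ret
    if (do_ret) {
      b <- sample.int(k, 1L)
      outer <- sample(setdiff(seq_len(k), b), 2L)
      cur <- apply_reticulate(cur, cur[[outer[[1L]]]], cur[[b]],
                              cur[[outer[[2L]]]])
    } else {
      pair <- sample.int(k, 2L)
      cur <- apply_join(cur, cur[[pair[[1L]]]], cur[[pair[[2L]]]])
    }
    systems <- c(systems, list(cur))
  }
  new_chain(taxa, systems)
}

#' Random ETCN point
#'
#' Draws a random maximal chain, drops each interior position independently
#' with probability `p_skip` (the singleton partition and `{X}` are never
#' dropped), and assigns the surviving positions independent exponential
#' rank differences with mean `rate`.
#'
#' @param n Number of taxa.
#' @param p_ret Reticulation probability for the underlying chain.
#' @param p_skip Probability of dropping an interior chain position, in
#'   `[0, 1)`.
#' @param rate Mean of the exponential coordinate draws (positive).
#' @param taxa Optional explicit taxon labels.
#' @return A valid `etcn_point`.
#' @export
random_point <- function(n, p_ret = 0.25, p_skip = 0.25, rate = 1,
                         taxa = NULL) {
  if (p_skip < 0 || p_skip >= 1) stop("p_skip must lie in [0, 1)")
  if (rate <= 0) stop("rate must be positive")
  chain <- random_maximal_chain(n, p_ret = p_ret, taxa = taxa)
  t <- length(chain$systems)
  keep <- c(TRUE, stats::runif(t - 2L) >= p_skip)   # position 1 always kept
  systems <- c(chain$systems[seq_len(t - 1L)][keep],
               chain$systems[t])
  sub <- new_chain(chain$taxa, systems)
  make_point(sub, stats::rexp(length(systems) - 1L, rate = 1 / rate))
}

#' Bundled worked examples
#'
#' A named collection of small validated objects used throughout the
#' documentation and tests:
#' \describe{
#'   \item{net4_chain}{a maximal chain on `{a,b,c,d}` with one
#'     reticulation step (through `{{a,b,c},{c,d}}`).}
#'   \item{tree_pair5}{two ranked-tree chains on `{a,...,e}` that differ in
#'     exactly one position (a single rNNI apart).}
#'   \item{chain8_len4}{a non-maximal chain of length 4 on `{a,...,h}`
#'     whose second system is `{{a,b,c,d},{c,d,e},{f},{g,h}}`.}
#'   \item{nonmax_chain4}{the length-3 chain on `{a,b,c,d}` through
#'     `{{a,b,c},{b,c,d}}`, whose canonical network is non-binary.}
#'   \item{etcn_point5}{an ETCN point on `{a,...,e}` supported on a maximal
#'     chain with one reticulated system, with rank differences 1.3, 2.0,
#'     1.9, 0.8.}
#' }
#'
#' @return Named list of `rtcn_chain` / `etcn_point` objects.
#' @export
worked_examples <- function() {
  ch <- function(taxa, ...) new_chain(taxa, list(...))
  s <- function(...) lapply(list(...), cluster)
  taxa4 <- letters[1:4]
  taxa5 <- letters[1:5]
  taxa8 <- letters[1:8]
  net4_chain <- ch(taxa4,
                   s("a", "b", "c", "d"),
                   s(c("a", "b"), "c", "d"),
                   s(c("a", "b", "c"), c("c", "d")),
                   s(c("a", "b", "c", "d")))
  tree_a <- ch(taxa5,
               s("a", "b", "c", "d", "e"),
               s(c("a", "b"), "c", "d", "e"),
               s(c("a", "b"), "c", c("d", "e")),
               s(c("a", "b", "c"), c("d", "e")),
               s(c("a", "b", "c", "d", "e")))
  tree_b <- ch(taxa5,
               s("a", "b", "c", "d", "e"),
               s("a", "b", "c", c("d", "e")),
               s(c("a", "b"), "c", c("d", "e")),
               s(c("a", "b", "c"), c("d", "e")),
               s(c("a", "b", "c", "d", "e")))
  chain8_len4 <- ch(taxa8,
                    s("a", "b", "c", "d", "e", "f", "g", "h"),
                    s(c("a", "b", "c", "d"), c("c", "d", "e"), "f",
                      c("g", "h")),
                    s(c("a", "b", "c", "d", "e"), c("f", "g", "h")),
                    s(letters[1:8]))
  nonmax_chain4 <- ch(taxa4,
                      s("a", "b", "c", "d"),
                      s(c("a", "b", "c"), c("b", "c", "d")),
                      s(c("a", "b", "c", "d")))
  point_chain <- ch(taxa5,
                    s("a", "b", "c", "d", "e"),
                    s(c("a", "b"), c("b", "c"), "d", "e"),
                    s(c("a", "b", "c"), c("b", "c", "d"), "e"),
                    s(c("a", "b", "c"), c("b", "c", "d", "e")),
                    s(c("a", "b", "c", "d", "e")))
  list(net4_chain = net4_chain,
       tree_pair5 = list(tree_a, tree_b),
       chain8_len4 = chain8_len4,
       nonmax_chain4 = nonmax_chain4,
       etcn_point5 = make_point(point_chain, c(1.3, 2.0, 1.9, 0.8)))
}
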