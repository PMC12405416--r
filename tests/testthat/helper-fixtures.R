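# Shared fixture shorthand for the test suite.

fx <- worked_examples()

sys_of <- function(...) cluster_system(lapply(list(...), cluster))

chain_of <- function(taxa, ...) new_chain(taxa, list(...))

skeys <- function(chain) vapply(chain$systems, system_key, character(1))

ckey <- function(chain) paste(skeys(chain), collapse = ";")

# number of positions at which two equal-length chains differ
n_diff_positions <- function(c1, c2) {
  sum(skeys(c1) != skeys(c2))
}
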