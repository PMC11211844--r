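## shared fixtures built in code

cherry <- function() parse_newick("((A:1,B:1)u:1)r;")

## a fixed 4-leaf tree used across modules
quartet <- function() {
  parse_newick("(((A:1,B:1)u:1,(C:1.5,D:1.5)v:0.5)w:1)r;")
}

## random ultrametric tree via the package generator (small n)
rand_tree <- function(n, tau = 10, seed = NULL) {
  simulate_topology(n, tau_end = tau, seed = seed)
}

rand_locations <- function(tree, seed = 1) {
  with_seed <- function(s, code) { set.seed(s); code }
  with_seed(seed, data.frame(cell = leaf_names(tree),
                             x = rnorm(n_leaves(tree), 0, 5),
                             y = rnorm(n_leaves(tree), 0, 5)))
}

## theta vector aligned to a tree's division nodes
theta_for_tree <- function(tree, values) {
  stats::setNames(rep_len(values, length(bifurcations(tree))),
                  bifurcations(tree))
}
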