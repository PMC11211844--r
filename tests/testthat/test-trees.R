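test_that("Newick parsing enforces the root-unifurcation tree shape", {
  tr <- cherry()
  expect_s3_class(tr, "lineage_tree")
  expect_equal(tr$nnode, 4L)
  expect_equal(sort(leaf_names(tr)), c("A", "B"))
  expect_equal(length(tr$children[[tr$root]]), 1L)
  ## bifurcating root rejected in strict mode, wrapped in lenient mode
  expect_error(parse_newick("(A:1,B:1);"), "unifurcating")
  lt <- parse_newick("(A:1,B:1);", lenient_root = TRUE)
  expect_equal(length(lt$children[[lt$root]]), 1L)
  expect_match(attr(lt, "diagnostics"), "zero-length unifurcation")
  ## malformed input and duplicate labels
  expect_error(parse_newick("((A:1,B:1)u:1r;"), "malformed")
  expect_error(parse_newick("((A:1,A:1)u:1)r;"), "duplicate")
  ## polytomies rejected
  expect_error(parse_newick("((A:1,B:1,C:1)u:1)r;"), "two children")
})

test_that("parse-write-parse is the identity on topology, order, lengths", {
  cases <- c("((A:1,B:1)u:1)r;",
             "(((A:1,B:1)u:1,(C:1.5,D:1.5)v:0.5)w:1)r;",
             "((B:1,A:1)u:1)r;",          # swapped child order is preserved
             "((A:0.123456789,B:0.123456789)u:2)r;")
  for (s in cases) {
    t1 <- parse_newick(s)
    s2 <- write_newick(t1)
    t2 <- parse_newick(s2)
    expect_equal(write_newick(t2), s2)
    expect_equal(leaf_names(t2), leaf_names(t1))
    expect_equal(t2$brlen[order(t2$labels)], t1$brlen[order(t1$labels)],
                 tolerance = 1e-9)
  }
  ## single-leaf tree
  expect_equal(write_newick(parse_newick("(A:2)r;")), "(A:2)r;")
  ## topology-only writing requires the flag when lengths are unset
  topo <- cherry(); topo$brlen[] <- NA
  expect_error(write_newick(topo), "unset")
  expect_match(write_newick(topo, topology_only = TRUE), "\\(\\(A,B\\)u\\)r;")
})

test_that("lca and times follow the path structure", {
  tr <- quartet()
  expect_equal(tr$labels[lca(tr, "A", "B")], "u")
  expect_equal(tr$labels[lca(tr, "A", "C")], "w")
  expect_equal(lca(tr, "A", "A"), which(tr$labels == "A"))
  expect_equal(tr$labels[lca(tr, "A", "u")], "u") # ancestor case
  expect_error(lca(tr, "A", "Z"), "unknown")

  expect_equal(time_from_root(tr, "A"), 3)
  expect_equal(time_from_root(tr, "u"), 2)
  expect_equal(time_from_root(tr, tr$root), 0)
  ## recursion invariant: t(v) = t(parent) + brlen(v)
  tt <- time_from_root(tr)
  for (v in seq_len(tr$nnode)) {
    if (v == tr$root) next
    expect_equal(tt[v], tt[tr$parent[v]] + tr$brlen[v])
  }
  ## lca time never exceeds either leaf time
  for (a in leaf_names(tr)) for (b in leaf_names(tr)) {
    expect_lte(tt[lca(tr, a, b)], min(time_from_root(tr, a), time_from_root(tr, b)))
  }
})

test_that("ultrametric checks measure the worst leaf deviation", {
  tr <- cherry()
  expect_true(is_ultrametric(tr, 2)$ultrametric)
  u3 <- is_ultrametric(tr, 3)
  expect_false(u3$ultrametric)
  expect_equal(u3$max_deviation, 1)
  expect_false(is_ultrametric(parse_newick("((A:1,B:1.5)u:1)r;"), 2)$ultrametric)
})

test_that("apply_node_times rebuilds exactly ultrametric branch lengths", {
  tr <- cherry()
  ids <- setNames(seq_len(tr$nnode), tr$labels)
  times <- numeric(tr$nnode)
  times[tr$root] <- 0
  times[ids[["u"]]] <- 1.25
  times[ids[["A"]]] <- 2; times[ids[["B"]]] <- 2
  tr2 <- apply_node_times(tr, times, tau_end = 2)
  expect_equal(tr2$brlen[ids[["u"]]], 1.25)
  expect_equal(tr2$brlen[ids[["A"]]], 0.75)
  expect_true(is_ultrametric(tr2, 2, tol = 0)$ultrametric)
  ## ordering violation names the edge
  bad <- times; bad[ids[["u"]]] <- 2.5
  expect_error(apply_node_times(tr, bad), "ordering violated")
  ## property: any valid unconstrained vector maps to an exactly ultrametric tree
  for (seed in 1:5) {
    set.seed(seed)
    tq <- quartet()
    raw <- rnorm(length(sdlineage:::.free_internal(tq)), 0, 2)
    tt <- unconstrained_to_times(tq, raw, 7)
    expect_true(is_ultrametric(apply_node_times(tq, tt, 7), 7, tol = 0)$ultrametric)
  }
})

test_that("delimited readers and writers round-trip matrices and locations", {
  tr <- rand_tree(6, seed = 3)
  mat <- simulate_sequences(tr, pmm_params(0.1, 0.02, 0.2), K = 4, seed = 4)
  loc <- simulate_locations(tr, sd_params(1, r = 2), seed = 5)
  d <- withr::local_tempdir()
  write_character_matrix(mat, file.path(d, "m.csv"))
  write_locations(loc, file.path(d, "l.csv"))
  m2 <- read_character_matrix(file.path(d, "m.csv"))
  expect_identical(unname(m2), unname(mat[, , drop = FALSE]))
  expect_identical(rownames(m2), rownames(mat))
  l2 <- read_locations(file.path(d, "l.csv"))
  expect_equal(l2$x, loc$x)
  expect_equal(l2$cell, loc$cell)
  ## tab-separated autodetection
  write_locations(loc, file.path(d, "l.tsv"), sep = "\t")
  expect_equal(read_locations(file.path(d, "l.tsv"))$y, loc$y)
})

test_that("validate_inputs cross-checks and optionally prunes cell sets", {
  tr <- quartet()
  mat <- matrix(0L, 4, 2, dimnames = list(c("A", "B", "C", "D"), NULL))
  loc <- data.frame(cell = c("A", "B", "C", "D"), x = 1:4, y = 1:4)
  ok <- validate_inputs(tr, mat, loc)
  expect_length(ok$diagnostics, 0L)
  ## missing cell reported by name
  expect_error(validate_inputs(tr, mat[c("A", "C", "D"), ], loc), "B")
  ## prune mode restricts all inputs to the intersection
  pr <- validate_inputs(tr, mat[c("A", "C", "D"), ], loc, prune = TRUE)
  expect_equal(sort(leaf_names(pr$tree)), c("A", "C", "D"))
  expect_equal(nrow(pr$matrix), 3L)
  expect_true(any(grepl("pruned", pr$diagnostics)))
  ## pruned tree keeps total root-to-leaf times
  expect_equal(time_from_root(pr$tree, "A"), 3)
  expect_error(validate_inputs(tr, mat[0, , drop = FALSE], loc), "no cell")
})
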