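#' @useDynLib sdlineage, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats optim rnorm runif rexp dnorm ks.test cor sd setNames
#' @importFrom utils read.table write.table
NULL

## ---------------------------------------------------------------------------
## Lineage-tree data structure
##
## A lineage tree is a rooted tree whose root has exactly one child (the
## progenitor cell needs time to divide) and whose other internal nodes have
## exactly two children (cells divide in two). Branch lengths measure time.
## Child order is meaningful: the first-listed child of a division node is the
## "left" daughter and carries displacement sign +1, the second sign -1.
## ---------------------------------------------------------------------------

new_lineage_tree <- function(parent, children, brlen, labels, root) {
  n <- length(parent)
  tips <- which(vapply(children, length, 1L) == 0L)
  tr <- structure(
    list(
      nnode = n, root = root, parent = parent, children = children,
      brlen = brlen, labels = labels, tips = tips
    ),
    class = "lineage_tree"
  )
  tr$postorder <- .postorder(tr)
  tr$preorder <- .preorder(tr)
  tr
}

.preorder <- function(tree) {
  ## root-first DFS with left-to-right sibling order
  out <- integer(tree$nnode)
  st <- integer(tree$nnode)
  sp <- 1L
  st[1L] <- tree$root
  i <- 0L
  while (sp > 0L) {
    v <- st[sp]; sp <- sp - 1L
    i <- i + 1L
    out[i] <- v
    for (c in rev(tree$children[[v]])) {
      sp <- sp + 1L
      st[sp] <- c
    }
  }
  out
}

.postorder <- function(tree) {
  ## reversing a DFS that pops the last-pushed child first yields a postorder
  ## in which every child precedes its parent and sibling order is preserved
  out <- integer(tree$nnode)
  st <- integer(tree$nnode)
  sp <- 1L
  st[1L] <- tree$root
  i <- 0L
  while (sp > 0L) {
    v <- st[sp]; sp <- sp - 1L
    i <- i + 1L
    out[i] <- v
    for (c in tree$children[[v]]) {
      sp <- sp + 1L
      st[sp] <- c
    }
  }
  rev(out)
}

#' Number of leaves of a lineage tree
#' @param tree a `lineage_tree`
#' @return integer count of leaves
#' @export
n_leaves <- function(tree) length(tree$tips)

#' Leaf (cell) names of a lineage tree
#' @param tree a `lineage_tree`
#' @return character vector of cell names, in tree (Newick) order
#' @export
leaf_names <- function(tree) tree$labels[tree$tips]

#' Division (bifurcating internal) nodes
#'
#' Internal nodes with exactly two children, in preorder. This is the
#' canonical ordering used for the per-division displacement angles.
#' @param tree a `lineage_tree`
#' @return integer vector of node ids
#' @export
bifurcations <- function(tree) {
  deg <- vapply(tree$children, length, 1L)
  tree$preorder[deg[tree$preorder] == 2L]
}

#' @export
print.lineage_tree <- function(x, ...) {
  cat(sprintf(
    "<lineage_tree> %d leaves, %d nodes, root '%s' (unifurcating)\n",
    n_leaves(x), x$nnode,
    if (nzchar(x$labels[x$root])) x$labels[x$root] else x$root
  ))
  if (all(!is.na(x$brlen[-x$root]))) {
    tt <- time_from_root(x)
    cat(sprintf("  leaf times: [%g, %g]\n",
                min(tt[x$tips]), max(tt[x$tips])))
  } else {
    cat("  branch lengths: unset\n")
  }
  invisible(x)
}

## node lookup: integer id, leaf name, or internal label
node_id <- function(tree, v) {
  if (is.numeric(v)) {
    v <- as.integer(v)
    if (any(v < 1L | v > tree$nnode)) {
      stop("unknown node id: ", paste(v[v < 1L | v > tree$nnode], collapse = ", "))
    }
    return(v)
  }
  idx <- match(v, tree$labels)
  if (anyNA(idx)) stop("unknown node label: ", paste(v[is.na(idx)], collapse = ", "))
  idx
}

.validate_shape <- function(parent, children, labels, root) {
  ndesc <- vapply(children, length, 1L)
  if (ndesc[root] != 1L) {
    stop("root must have exactly one child (found ", ndesc[root], ")")
  }
  internal <- which(ndesc > 0L)
  bad <- setdiff(internal[ndesc[internal] != 2L], root)
  if (length(bad)) {
    stop("internal nodes must have exactly two children; offending node(s): ",
         paste(bad, collapse = ", "))
  }
  tips <- which(ndesc == 0L)
  nm <- labels[tips]
  if (any(!nzchar(nm))) stop("leaf names must be non-empty")
  if (anyDuplicated(nm)) {
    stop("duplicate leaf labels: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  invisible(TRUE)
}

## ---------------------------------------------------------------------------
## Newick I/O (delegated to ape; converted to/from the internal structure so
## singleton nodes and child order survive)
## ---------------------------------------------------------------------------

from_phylo <- function(phy, strict = TRUE, lenient_root = FALSE) {
  ntip <- length(phy$tip.label)
  n <- ntip + phy$Nnode
  parent <- integer(n)
  children <- vector("list", n)
  for (i in seq_len(n)) children[[i]] <- integer(0)
  for (i in seq_len(nrow(phy$edge))) {
    u <- phy$edge[i, 1L]; v <- phy$edge[i, 2L]
    parent[v] <- u
    children[[u]] <- c(children[[u]], v)
  }
  root <- which(parent == 0L)
  if (length(root) != 1L) stop("tree must have a single root")
  brlen <- rep(NA_real_, n)
  if (!is.null(phy$edge.length)) brlen[phy$edge[, 2L]] <- phy$edge.length
  labels <- character(n)
  labels[seq_len(ntip)] <- phy$tip.label
  if (!is.null(phy$node.label)) {
    labels[ntip + seq_len(phy$Nnode)] <- phy$node.label
  }
  diag <- character(0)
  if (length(children[[root]]) == 2L) {
    if (lenient_root) {
      ## wrap a bifurcating root with a zero-length unifurcation
      parent <- c(parent, 0L)
      parent[root] <- n + 1L
      children[[n + 1L]] <- root
      brlen <- c(brlen, NA_real_)
      brlen[root] <- 0
      labels <- c(labels, "")
      root <- n + 1L
      diag <- "inserted zero-length unifurcation above bifurcating root"
    } else if (strict) {
      stop("root is bifurcating; the model requires a unifurcating root ",
           "(use lenient_root = TRUE to wrap it)")
    }
  }
  .validate_shape(parent, children, labels, root)
  tr <- new_lineage_tree(parent, children, brlen, labels, root)
  attr(tr, "diagnostics") <- diag
  tr
}

to_phylo <- function(tree) {
  ntip <- n_leaves(tree)
  newid <- integer(tree$nnode)
  newid[tree$tips] <- seq_along(tree$tips)
  internals <- tree$preorder[!(tree$preorder %in% tree$tips)]
  newid[internals] <- ntip + seq_along(internals)
  edge <- matrix(0L, tree$nnode - 1L, 2L)
  len <- numeric(tree$nnode - 1L)
  k <- 0L
  for (v in tree$preorder) {
    if (v == tree$root) next
    k <- k + 1L
    edge[k, ] <- c(newid[tree$parent[v]], newid[v])
    len[k] <- tree$brlen[v]
  }
  phy <- list(
    edge = edge, Nnode = length(internals),
    tip.label = tree$labels[tree$tips],
    node.label = tree$labels[internals]
  )
  if (!all(is.na(len))) phy$edge.length <- len
  class(phy) <- "phylo"
  phy
}

#' Parse a Newick string into a lineage tree
#'
#' The expected shape is a rooted tree with a unifurcating root (the
#' progenitor's pre-division branch) and bifurcating internal nodes. In strict
#' mode (default) any other shape is rejected; with `lenient_root = TRUE` a
#' bifurcating root is wrapped with a zero-length unifurcation and the action
#' recorded in `attr(tree, "diagnostics")`.
#'
#' @param text Newick string.
#' @param strict reject a bifurcating root instead of wrapping it.
#' @param lenient_root wrap a bifurcating root with a zero-length root edge.
#' @return a `lineage_tree`
#' @export
parse_newick <- function(text, strict = TRUE, lenient_root = FALSE) {
  phy <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) stop("malformed Newick: ", conditionMessage(e)),
    warning = function(w) stop("malformed Newick: ", conditionMessage(w))
  )
  if (is.null(phy)) stop("malformed Newick: parser returned no tree")
  if (inherits(phy, "multiPhylo")) phy <- phy[[1L]]
  if (anyDuplicated(phy$tip.label)) {
    stop("duplicate leaf labels: ",
         paste(unique(phy$tip.label[duplicated(phy$tip.label)]), collapse = ", "))
  }
  from_phylo(phy, strict = strict, lenient_root = lenient_root)
}

#' Read a lineage tree from a Newick file
#' @param path file containing one Newick tree.
#' @inheritParams parse_newick
#' @return a `lineage_tree`
#' @export
read_newick <- function(path, strict = TRUE, lenient_root = FALSE) {
  parse_newick(paste(readLines(path, warn = FALSE), collapse = ""),
               strict = strict, lenient_root = lenient_root)
}

#' Serialize a lineage tree to Newick
#'
#' Child order and internal labels are preserved; branch lengths are written
#' with enough digits to round-trip (15 significant digits by default).
#'
#' @param tree a `lineage_tree`.
#' @param path optional file to write to.
#' @param digits significant digits for branch lengths.
#' @param topology_only drop branch lengths.
#' @return the Newick string, invisibly when `path` is given.
#' @export
write_newick <- function(tree, path = NULL, digits = 15, topology_only = FALSE) {
  br <- tree$brlen[-tree$root]
  if (!topology_only && anyNA(br)) {
    stop("branch lengths are unset; use topology_only = TRUE")
  }
  phy <- to_phylo(tree)
  if (topology_only) phy$edge.length <- NULL
  s <- ape::write.tree(phy, digits = digits)
  if (!is.null(path)) {
    writeLines(s, path)
    return(invisible(s))
  }
  s
}

## ---------------------------------------------------------------------------
## Tree queries
## ---------------------------------------------------------------------------

node_depths <- function(tree) {
  d <- integer(tree$nnode)
  for (v in tree$preorder) {
    if (v != tree$root) d[v] <- d[tree$parent[v]] + 1L
  }
  d
}

#' Last common ancestor of two nodes
#' @param tree a `lineage_tree`
#' @param v,w node ids or labels
#' @return the node id of the deepest common ancestor
#' @export
lca <- function(tree, v, w) {
  v <- node_id(tree, v); w <- node_id(tree, w)
  d <- node_depths(tree)
  while (d[v] > d[w]) v <- tree$parent[v]
  while (d[w] > d[v]) w <- tree$parent[w]
  while (v != w) {
    v <- tree$parent[v]
    w <- tree$parent[w]
  }
  v
}

#' Time from the root to a node
#'
#' Sum of branch lengths along the root-to-node path (0 at the root).
#'
#' @param tree a `lineage_tree` with branch lengths set.
#' @param v node id/label, or `NULL` for all nodes.
#' @return numeric time(s)
#' @export
time_from_root <- function(tree, v = NULL) {
  br <- tree$brlen
  if (anyNA(br[-tree$root])) stop("branch lengths are unset")
  t <- numeric(tree$nnode)
  for (u in tree$preorder) {
    if (u != tree$root) t[u] <- t[tree$parent[u]] + br[u]
  }
  if (is.null(v)) t else t[node_id(tree, v)]
}

#' Check that all leaves sit at the sampling time
#'
#' All cells are sampled together at the end of the experiment, so every
#' root-to-leaf path must sum to the experiment duration `tau_end`.
#'
#' @param tree a `lineage_tree` with branch lengths.
#' @param tau_end the experiment duration; defaults to the maximum leaf time.
#' @param tol relative tolerance (fraction of `tau_end`).
#' @return list with `ultrametric` (logical) and `max_deviation`
#' @export
is_ultrametric <- function(tree, tau_end = NULL, tol = 1e-6) {
  lt <- time_from_root(tree)[tree$tips]
  if (is.null(tau_end)) tau_end <- max(lt)
  dev <- max(abs(lt - tau_end))
  list(ultrametric = dev <= tol * abs(tau_end), max_deviation = dev)
}

#' Node times of a tree
#' @param tree a `lineage_tree` with branch lengths.
#' @return numeric vector of times since the root, indexed by node id.
#' @export
node_times <- function(tree) time_from_root(tree)

#' Set branch lengths from node times
#'
#' Given a time for every node (root at 0, leaves at `tau_end`), sets
#' `brlen[v] = time(v) - time(parent(v))`. The resulting tree satisfies the
#' common-sampling-time constraint exactly by construction.
#'
#' @param tree a `lineage_tree`.
#' @param times numeric vector of length `tree$nnode` (times since root).
#' @param tau_end optional; when given, every leaf time must equal it.
#' @return the tree with updated branch lengths.
#' @export
apply_node_times <- function(tree, times, tau_end = NULL) {
  if (length(times) != tree$nnode) stop("need one time per node")
  if (abs(times[tree$root]) > 0) stop("root time must be 0")
  for (v in seq_len(tree$nnode)) {
    if (v == tree$root) next
    if (times[v] <= times[tree$parent[v]]) {
      stop(sprintf("time ordering violated on edge (%d -> %d): %g <= %g",
                   tree$parent[v], v, times[v], times[tree$parent[v]]))
    }
  }
  if (!is.null(tau_end)) {
    lt <- times[tree$tips]
    if (any(abs(lt - tau_end) > 1e-9 * max(1, abs(tau_end)))) {
      stop("leaf times must all equal tau_end")
    }
  }
  tree$brlen <- ifelse(seq_len(tree$nnode) == tree$root, NA_real_,
                       times - times[pmax(tree$parent, 1L)])
  tree$brlen[tree$root] <- NA_real_
  tree
}

## ---------------------------------------------------------------------------
## Pruning a tree to a leaf subset (used by validate_inputs)
## ---------------------------------------------------------------------------

prune_to_leaves <- function(tree, keep) {
  keep_id <- tree$tips[tree$labels[tree$tips] %in% keep]
  if (!length(keep_id)) stop("no leaves left after pruning")
  alive <- logical(tree$nnode)
  alive[keep_id] <- TRUE
  for (v in tree$postorder) {
    ch <- tree$children[[v]][alive[tree$children[[v]]]]
    if (length(ch) || v %in% keep_id) alive[v] <- TRUE
  }
  ## rebuild, suppressing unary internal nodes (merge lengths); the root's own
  ## unifurcation is kept
  parent <- tree$parent; children <- tree$children; brlen <- tree$brlen
  for (v in tree$preorder) {
    if (!alive[v]) next
    ch <- children[[v]][alive[children[[v]]]]
    children[[v]] <- ch
    if (v != tree$root && length(ch) == 1L) {
      ## splice v out
      c1 <- ch[1L]
      p <- parent[v]
      brlen[c1] <- brlen[c1] + brlen[v]
      parent[c1] <- p
      children[[p]][children[[p]] == v] <- c1
      alive[v] <- FALSE
    }
  }
  ids <- which(alive)
  remap <- integer(tree$nnode)
  remap[ids] <- seq_along(ids)
  np <- integer(length(ids)); nc <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    v <- ids[i]
    np[i] <- if (v == tree$root) 0L else remap[parent[v]]
    nc[[i]] <- remap[children[[v]][alive[children[[v]]]]]
  }
  new_lineage_tree(np, nc, brlen[ids], tree$labels[ids], remap[tree$root])
}

## ---------------------------------------------------------------------------
## Delimited-text inputs: character matrix + leaf locations
## ---------------------------------------------------------------------------

.detect_sep <- function(path) {
  l1 <- readLines(path, n = 1L)
  if (grepl("\t", l1)) "\t" else ","
}

#' Read a CRISPR character matrix
#'
#' Delimited text (CSV/TSV autodetected), first column the cell name, the
#' remaining K columns the observed state per target site. Missing entries
#' (`?` by default, configurable) become `NA`; `-1` marks the silenced state.
#'
#' @param path file path.
#' @param missing_codes strings to read as missing.
#' @return integer matrix (cells x sites) with cell-name rownames; `NA` =
#'   missing, `-1` = silenced, `0` = unmutated, `1..M` mutated states.
#' @export
read_character_matrix <- function(path, missing_codes = c("?", "-")) {
  sep <- .detect_sep(path)
  df <- read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                   colClasses = "character", comment.char = "")
  cells <- df[[1L]]
  if (anyDuplicated(cells)) stop("duplicate cell names in character matrix")
  vals <- as.matrix(df[, -1L, drop = FALSE])
  m <- matrix(NA_integer_, nrow(vals), ncol(vals),
              dimnames = list(cells, colnames(vals)))
  miss <- vals %in% missing_codes
  ints <- suppressWarnings(as.integer(vals))
  m[] <- ints
  m[miss] <- NA_integer_
  bad <- !miss & is.na(ints)
  if (any(bad)) stop("non-integer entries in character matrix: ",
                     paste(unique(vals[bad]), collapse = ", "))
  m
}

#' Write a character matrix
#' @param mat integer matrix as returned by [read_character_matrix()].
#' @param path output file.
#' @param sep field separator.
#' @export
write_character_matrix <- function(mat, path, sep = ",") {
  out <- cbind(cell = rownames(mat),
               as.data.frame(ifelse(is.na(mat), "?", mat)))
  write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read leaf 2D locations
#'
#' Delimited text with columns name, x, y (header optional).
#' @param path file path.
#' @return data.frame with columns `cell`, `x`, `y`.
#' @export
read_locations <- function(path) {
  sep <- .detect_sep(path)
  first <- strsplit(readLines(path, n = 1L), sep, fixed = TRUE)[[1L]]
  has_header <- is.na(suppressWarnings(as.numeric(first[2L])))
  df <- read.table(path, sep = sep, header = has_header,
                   colClasses = c("character", "numeric", "numeric"))
  names(df) <- c("cell", "x", "y")
  if (anyDuplicated(df$cell)) stop("duplicate cell names in locations")
  if (any(!is.finite(df$x)) || any(!is.finite(df$y))) {
    stop("non-finite coordinates in locations")
  }
  df
}

#' Write leaf locations
#' @param loc data.frame with columns `cell`, `x`, `y`.
#' @param path output file.
#' @param sep field separator.
#' @export
write_locations <- function(loc, path, sep = ",") {
  write.table(loc[, c("cell", "x", "y")], path, sep = sep,
              row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Cross-validate tree, character matrix, and locations
#'
#' Checks that the three inputs name the same set of cells. With
#' `prune = TRUE` all inputs are restricted to the common cell set (recorded
#' in the diagnostics); otherwise any mismatch is an error.
#'
#' @param tree a `lineage_tree`.
#' @param matrix character matrix (or `NULL` if the modality excludes it).
#' @param locations locations data.frame (or `NULL`).
#' @param prune intersect-and-prune instead of erroring on mismatch.
#' @return list with possibly pruned `tree`, `matrix`, `locations`, and a
#'   character vector `diagnostics`.
#' @export
validate_inputs <- function(tree, matrix = NULL, locations = NULL,
                            prune = FALSE) {
  sets <- list(tree = leaf_names(tree))
  if (!is.null(matrix)) {
    if (is.null(rownames(matrix)) || !nrow(matrix)) {
      stop("character matrix must name its cells (no cell names shared)")
    }
    sets$matrix <- rownames(matrix)
  }
  if (!is.null(locations)) sets$locations <- locations$cell
  common <- Reduce(intersect, sets)
  if (!length(common)) stop("no cell names shared by all inputs")
  diagnostics <- character(0)
  for (nm in names(sets)) {
    extra <- setdiff(sets[[nm]], common)
    if (length(extra)) {
      diagnostics <- c(diagnostics, sprintf(
        "%s has %d cell(s) absent elsewhere: %s", nm, length(extra),
        paste(utils::head(extra, 10L), collapse = ", ")))
    }
  }
  if (length(diagnostics) && !prune) {
    stop("input cell names do not match:\n  ",
         paste(diagnostics, collapse = "\n  "))
  }
  if (length(diagnostics)) {
    tree <- prune_to_leaves(tree, common)
    if (!is.null(matrix)) matrix <- matrix[common, , drop = FALSE]
    if (!is.null(locations)) {
      locations <- locations[match(common, locations$cell), , drop = FALSE]
    }
    diagnostics <- c(diagnostics,
                     sprintf("pruned all inputs to %d common cells",
                             length(common)))
  }
  list(tree = tree, matrix = matrix, locations = locations,
       diagnostics = diagnostics)
}
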