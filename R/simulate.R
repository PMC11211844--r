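## ---------------------------------------------------------------------------
## Forward simulation: topologies, locations, barcode matrices, frame tracks
## ---------------------------------------------------------------------------

## run code under a seed without clobbering the caller's RNG stream
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Named simulation presets
#'
#' Study conditions for the simulation experiments: diffusion rate
#' `sigma = 1.5` (low/high variants 0.5 and 3.0), displacement magnitude
#' (cell radius) `r = 6.68`, `K = 10` target sites with a 3-state alphabet
#' (`M = 2`), mutation rate `lambda = 0.006` per frame, over a 216-frame
#' horizon with 30-cell trees. Silencing is off (`nu = 0`) and dropout is
#' modest (`phi = 0.05`).
#'
#' @param name one of "paper-default", "sigma-low", "sigma-high".
#' @return list of simulation parameters
#' @export
sim_preset <- function(name = c("paper-default", "sigma-low", "sigma-high")) {
  name <- tryCatch(match.arg(name), error = function(e) {
    stop("unknown preset '", name[1L], "'; available: paper-default, ",
         "sigma-low, sigma-high")
  })
  p <- list(sigma = 1.5, r = 6.68, K = 10L, M = 2L, lambda = 0.006,
            nu = 0, phi = 0.05, tau_end = 216, n = 30L, x0 = 0, y0 = 0)
  if (name == "sigma-low") p$sigma <- 0.5
  if (name == "sigma-high") p$sigma <- 3.0
  p$name <- name
  p
}

#' Simulate a pure-birth (Yule) lineage-tree topology
#'
#' A single progenitor lineage starts at time 0; each extant lineage divides
#' at rate `birth_rate` until `n` lineages exist; the horizon is then drawn
#' just before the next division and all times rescaled so the leaves sit
#' exactly at `tau_end`. The root is unifurcating by construction.
#'
#' @param n number of leaves (>= 2).
#' @param tau_end experiment duration.
#' @param seed optional integer seed.
#' @param birth_rate division rate before rescaling (scale-free).
#' @return a `lineage_tree` with leaves named `c01`, `c02`, ...
#' @export
simulate_topology <- function(n, tau_end = 216, seed = NULL, birth_rate = 1) {
  n <- as.integer(n)
  if (n < 2L) stop("n must be >= 2")
  with_seed(seed, {
    ## active lineages are open edges; record their start times and parents
    max_nodes <- 2L * n
    parent <- integer(max_nodes)
    children <- rep(list(integer(0)), max_nodes)
    time <- numeric(max_nodes) # division time of internal nodes
    root <- 1L
    nxt <- 2L
    ## the progenitor edge root -> first division
    active_parent <- root
    t <- 0
    active <- list(root) # parents of currently open edges
    k <- 1L
    while (k < n) {
      t <- t + rexp(1L, birth_rate * k)
      i <- sample.int(k, 1L)
      u <- active[[i]]
      v <- nxt; nxt <- nxt + 1L
      parent[v] <- u
      children[[u]] <- c(children[[u]], v)
      time[v] <- t
      active[[i]] <- v
      active[[length(active) + 1L]] <- v
      k <- k + 1L
    }
    horizon <- t + rexp(1L, birth_rate * n)
    scale <- tau_end / horizon
    time <- time * scale
    ## close the open edges with leaves at tau_end
    labels <- character(nxt - 1L + n)
    leaf_id <- 0L
    for (i in seq_along(active)) {
      u <- active[[i]]
      v <- nxt; nxt <- nxt + 1L
      parent[v] <- u
      children[[u]] <- c(children[[u]], v)
      time[v] <- tau_end
      leaf_id <- leaf_id + 1L
      labels[v] <- sprintf("c%02d", leaf_id)
    }
    nn <- nxt - 1L
    brlen <- rep(NA_real_, nn)
    for (v in seq_len(nn)) {
      if (v != root) brlen[v] <- time[v] - time[parent[v]]
    }
    new_lineage_tree(parent[seq_len(nn)], children[seq_len(nn)],
                     brlen, labels[seq_len(nn)], root)
  })
}

#' Simulate leaf locations under the SD model
#'
#' The progenitor sits at `(x0, y0)`. At each division the first-listed
#' daughter is displaced by `+r (cos theta_u, sin theta_u)` and the second by
#' the negative; every edge then adds independent Gaussian diffusion with
#' per-axis variance `sigma^2 * branch time`. The root's single child
#' diffuses without displacement.
#'
#' @param tree a `lineage_tree` with branch lengths.
#' @param params an [sd_params()]; angles are drawn Uniform(0, 2*pi) per
#'   division when unset.
#' @param seed optional integer seed.
#' @param all_nodes also return internal-node positions.
#' @return data.frame (cell, x, y) over leaves, with attributes `theta`
#'   (angles used, named by division node) and optionally `nodes`.
#' @export
simulate_locations <- function(tree, params, seed = NULL, all_nodes = FALSE) {
  with_seed(seed, {
    bif <- bifurcations(tree)
    th <- params$theta
    if (is.null(th)) {
      th <- setNames(runif(length(bif), 0, 2 * pi), bif)
    } else {
      th <- .theta_for(tree, params)
    }
    px <- numeric(tree$nnode); py <- numeric(tree$nnode)
    px[tree$root] <- params$x0; py[tree$root] <- params$y0
    for (u in tree$preorder) {
      ch <- tree$children[[u]]
      if (!length(ch)) next
      if (length(ch) == 2L) {
        a <- th[[as.character(u)]]
        dx <- params$r * cos(a); dy <- params$r * sin(a)
      } else {
        dx <- 0; dy <- 0
      }
      s <- c(1, -1)[seq_along(ch)]
      for (j in seq_along(ch)) {
        v <- ch[j]
        px[v] <- px[u] + s[j] * dx + rnorm(1L, 0, params$sigma * sqrt(tree$brlen[v]))
        py[v] <- py[u] + s[j] * dy + rnorm(1L, 0, params$sigma * sqrt(tree$brlen[v]))
      }
    }
    out <- data.frame(cell = tree$labels[tree$tips],
                      x = px[tree$tips], y = py[tree$tips])
    attr(out, "theta") <- th
    if (all_nodes) attr(out, "nodes") <- cbind(x = px, y = py)
    out
  })
}

#' Simulate a barcode character matrix
#'
#' Hidden states start unedited at the root and evolve edge-wise under the
#' barcode chain; leaf states pass through the dropout emission.
#'
#' @param tree a `lineage_tree` with branch lengths.
#' @param params a [pmm_params()].
#' @param K number of target sites.
#' @param M mutated states per site (scalar or length-K).
#' @param pi optional prior over mutated states (shared across sites).
#' @param seed optional integer seed.
#' @return integer matrix (cells x sites), `NA` = missing `?`, with the
#'   hidden leaf states in `attr(, "hidden")`.
#' @export
simulate_sequences <- function(tree, params, K = 10, M = 2, pi = NULL,
                               seed = NULL) {
  K <- as.integer(K)
  M <- rep_len(as.integer(M), K)
  with_seed(seed, {
    nm <- tree$labels[tree$tips]
    obs <- matrix(NA_integer_, length(nm), K,
                  dimnames = list(nm, sprintf("site%02d", seq_len(K))))
    hidden_leaf <- obs
    for (k in seq_len(K)) {
      site <- site_alphabet(M[k], pi)
      ## hidden state per node: 0..M, silent coded M+1
      h <- integer(tree$nnode)
      for (v in tree$preorder) {
        if (v == tree$root) next
        P <- transition_matrix(site, params, tree$brlen[v])
        from <- h[tree$parent[v]] + 1L
        h[v] <- sample.int(M[k] + 2L, 1L, prob = P[from, ]) - 1L
      }
      hl <- h[tree$tips]
      hidden_leaf[, k] <- ifelse(hl == M[k] + 1L, -1L, hl)
      drop <- hl == M[k] + 1L | runif(length(hl)) < params$phi
      obs[, k] <- ifelse(drop, NA_integer_, hl)
    }
    attr(obs, "hidden") <- hidden_leaf
    obs
  })
}

#' Simulate frame-by-frame tracked positions
#'
#' Positions of every cell (edge of the tree) are recorded on a regular frame
#' grid. A cell is recorded from the first frame after its birth through the
#' frame of its division (leaves through the final frame). At division the
#' daughters start from the parent's division-time position displaced by
#' `+/- r (cos theta, sin theta)`; between recordings cells diffuse by
#' Brownian motion.
#'
#' @param tree a `lineage_tree` with branch lengths.
#' @param params an [sd_params()]; angles drawn uniformly when unset.
#' @param frame_interval time between frames (> 0).
#' @param seed optional integer seed.
#' @return data.frame (frame, cell, parent, x, y); `frame` is the integer
#'   frame index (frame * frame_interval = time). Attribute `theta` records
#'   the angles used.
#' @export
simulate_frames <- function(tree, params, frame_interval = 1, seed = NULL) {
  if (frame_interval <= 0) stop("frame_interval must be > 0")
  with_seed(seed, {
    bif <- bifurcations(tree)
    th <- params$theta
    if (is.null(th)) th <- setNames(runif(length(bif), 0, 2 * pi), bif)
    else th <- .theta_for(tree, params)
    tt <- time_from_root(tree)
    tau <- max(tt[tree$tips])
    cell_name <- function(v) {
      if (nzchar(tree$labels[v])) tree$labels[v] else sprintf("n%03d", v)
    }
    rows <- vector("list", tree$nnode)
    endx <- numeric(tree$nnode); endy <- numeric(tree$nnode)
    endx[tree$root] <- params$x0; endy[tree$root] <- params$y0
    for (v in tree$preorder) {
      if (v == tree$root) next
      u <- tree$parent[v]
      ## birth position: parent's division-time position (+ displacement)
      if (length(tree$children[[u]]) == 2L) {
        a <- th[[as.character(u)]]
        s <- if (tree$children[[u]][1L] == v) 1 else -1
        x <- endx[u] + s * params$r * cos(a)
        y <- endy[u] + s * params$r * sin(a)
      } else {
        x <- endx[u]; y <- endy[u]
      }
      t0 <- tt[u]; t1 <- tt[v]
      is_leaf <- !length(tree$children[[v]])
      f_first <- if (u == tree$root && t0 == 0) 0L else floor(t0 / frame_interval) + 1L
      f_last <- floor(t1 / frame_interval + 1e-9)
      frames <- if (f_last >= f_first) f_first:f_last else integer(0)
      tprev <- t0
      n_f <- length(frames)
      fx <- numeric(n_f); fy <- numeric(n_f)
      for (j in seq_along(frames)) {
        ## a dividing cell's final frame records it at the division event
        ## (cytokinesis is what identifies the division frame in imaging)
        tf <- if (!is_leaf && j == n_f) t1 else frames[j] * frame_interval
        dt <- tf - tprev
        if (dt > 0) {
          x <- x + rnorm(1L, 0, params$sigma * sqrt(dt))
          y <- y + rnorm(1L, 0, params$sigma * sqrt(dt))
        }
        fx[j] <- x; fy[j] <- y
        tprev <- tf
      }
      if (t1 > tprev) {
        x <- x + rnorm(1L, 0, params$sigma * sqrt(t1 - tprev))
        y <- y + rnorm(1L, 0, params$sigma * sqrt(t1 - tprev))
      }
      endx[v] <- x; endy[v] <- y
      if (n_f) {
        rows[[v]] <- data.frame(
          frame = frames, cell = cell_name(v),
          parent = if (u == tree$root) "" else cell_name(u),
          x = fx, y = fy
        )
      }
    }
    out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
    out <- out[order(out$frame, out$cell), ]
    rownames(out) <- NULL
    attr(out, "theta") <- th
    out
  })
}

#' Write a complete simulated dataset to disk
#'
#' Generates a topology, locations, and a barcode matrix under a named
#' preset, and writes Newick, CSV inputs, and a ground-truth JSON (parameters,
#' node times, angles) for recovery scoring.
#'
#' @param dir output directory (created if missing).
#' @param preset preset name (see [sim_preset()]).
#' @param seed integer seed.
#' @param ... preset overrides (e.g. `sigma = 0.5`, `n = 20`).
#' @return invisible list with the generated objects and file paths
#' @export
make_fixture <- function(dir, preset = "paper-default", seed = 1, ...) {
  p <- sim_preset(preset)
  ov <- list(...)
  p[names(ov)] <- ov
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tree <- simulate_topology(p$n, p$tau_end, seed = seed)
  sdp <- sd_params(p$sigma, r = p$r, x0 = p$x0, y0 = p$y0)
  loc <- simulate_locations(tree, sdp, seed = seed + 1L)
  pmm <- pmm_params(p$lambda, p$nu, p$phi)
  mat <- simulate_sequences(tree, pmm, K = p$K, M = p$M, seed = seed + 2L)
  paths <- list(
    tree = file.path(dir, "tree.nwk"),
    matrix = file.path(dir, "characters.csv"),
    locations = file.path(dir, "locations.csv"),
    truth = file.path(dir, "truth.json")
  )
  write_newick(tree, paths$tree)
  write_character_matrix(mat, paths$matrix)
  write_locations(loc, paths$locations)
  truth <- list(
    preset = p$name, seed = seed,
    sigma = p$sigma, r = p$r, K = p$K, M = p$M,
    lambda = p$lambda, nu = p$nu, phi = p$phi,
    tau_end = p$tau_end, x0 = p$x0, y0 = p$y0,
    theta = as.list(attr(loc, "theta")),
    node_times = node_times(tree),
    newick = write_newick(tree)
  )
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(list(tree = tree, locations = loc, matrix = mat,
                 params = p, paths = paths))
}
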