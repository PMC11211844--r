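## ---------------------------------------------------------------------------
## Symmetric-displacement (SD) spatial model
##
## At each division the two daughters are placed at +/- r*(cos(theta_u),
## sin(theta_u)) from the parent, then diffuse independently by Brownian
## motion with rate sigma (per-axis variance sigma^2 * branch time). At r = 0
## the model reduces to plain Brownian motion. The leaf locations on each axis
## are multivariate normal: the mean accumulates the signed displacements
## along the root-to-leaf path and the covariance of two leaves is
## sigma^2 times the root-to-LCA time.
## ---------------------------------------------------------------------------

#' Spatial (SD) model parameters
#'
#' @param sigma diffusion rate (> 0), in length per sqrt(time).
#' @param r displacement magnitude at division (the cell radius, >= 0).
#' @param theta numeric vector of per-division displacement angles (radians),
#'   named by internal node id; may be `NULL` when `r = 0`.
#' @param x0,y0 the progenitor (root) location.
#' @return an `sd_params` list
#' @export
sd_params <- function(sigma, r = 0, theta = NULL, x0 = 0, y0 = 0) {
  if (!is.finite(sigma) || sigma <= 0) stop("sigma must be > 0")
  if (!is.finite(r) || r < 0) stop("r must be >= 0")
  structure(list(sigma = sigma, r = r, theta = theta, x0 = x0, y0 = y0),
            class = "sd_params")
}

## theta aligned to bifurcations(tree); error when any division lacks an angle
.theta_for <- function(tree, params) {
  bif <- bifurcations(tree)
  th <- params$theta
  if (params$r == 0) return(setNames(rep(0, length(bif)), bif))
  if (is.null(th)) stop("theta must be set for every division node when r > 0")
  if (!is.null(names(th))) {
    th <- th[as.character(bif)]
    if (anyNA(th)) {
      stop("theta missing for division node(s): ",
           paste(bif[is.na(th)], collapse = ", "))
    }
  } else {
    if (length(th) != length(bif)) {
      stop("theta must have one angle per division node (",
           length(bif), " needed)")
    }
    names(th) <- bif
  }
  th
}

## per-node cumulative displacement of the mean, x and y; the root's single
## child receives no displacement (the progenitor does not divide at time 0)
displacement_offsets <- function(tree, params) {
  th <- .theta_for(tree, params)
  offx <- numeric(tree$nnode)
  offy <- numeric(tree$nnode)
  for (u in tree$preorder) {
    ch <- tree$children[[u]]
    if (length(ch) == 2L) {
      a <- th[[as.character(u)]]
      dx <- params$r * cos(a)
      dy <- params$r * sin(a)
      offx[ch] <- offx[u] + c(dx, -dx)
      offy[ch] <- offy[u] + c(dy, -dy)
    } else if (length(ch) == 1L) {
      offx[ch] <- offx[u]
      offy[ch] <- offy[u]
    }
  }
  list(x = offx, y = offy)
}

## floored branch lengths used inside likelihoods; eps = 1e-6 * tree height
## prevents a singular covariance from zero-length terminal branches
.floored_brlen <- function(tree, floor = 0) {
  br <- tree$brlen
  if (floor > 0) br[-tree$root] <- pmax(br[-tree$root], floor)
  br
}

#' Leaf covariance matrix of the spatial model
#'
#' `Sigma[v, w] = sigma^2 * t(lca(v, w))` where `t()` is time from the root;
#' diagonal entries are `sigma^2` times the leaf's root-to-leaf time. Rows and
#' columns are ordered lexicographically by leaf name.
#'
#' @param tree a `lineage_tree` with branch lengths.
#' @param sigma diffusion rate (> 0).
#' @param floor optional lower bound applied to branch lengths.
#' @return named square matrix over leaves
#' @export
sd_covariance <- function(tree, sigma, floor = 0) {
  if (!is.finite(sigma) || sigma <= 0) stop("sigma must be > 0")
  tr <- tree
  tr$brlen <- .floored_brlen(tree, floor)
  tt <- time_from_root(tr)
  nm <- sort(leaf_names(tree))
  n <- length(nm)
  S <- matrix(0, n, n, dimnames = list(nm, nm))
  pos <- setNames(seq_len(n), nm)
  ## leaves below each child subtree: pairs split across an internal node u
  ## have lca u
  below <- vector("list", tree$nnode)
  for (v in tree$postorder) {
    if (!length(tree$children[[v]])) {
      below[[v]] <- pos[[tree$labels[v]]]
      S[below[[v]], below[[v]]] <- sigma^2 * tt[v]
    } else {
      ch <- tree$children[[v]]
      if (length(ch) == 2L) {
        S[below[[ch[1L]]], below[[ch[2L]]]] <- sigma^2 * tt[v]
        S[below[[ch[2L]]], below[[ch[1L]]]] <- sigma^2 * tt[v]
      }
      below[[v]] <- unlist(below[ch], use.names = FALSE)
    }
  }
  S
}

#' Leaf mean vector of the spatial model
#'
#' The mean of a leaf on the x axis is `x0` plus the sum over path divisions
#' of `s * r * cos(theta_u)` where `s` is +1 for the first-listed daughter and
#' -1 for the second; the y axis uses `sin(theta_u)`.
#'
#' @param tree a `lineage_tree`.
#' @param params an [sd_params()] object with theta set for every division.
#' @param axis "x" or "y".
#' @return named numeric vector over leaves (lexicographic order)
#' @export
sd_mean <- function(tree, params, axis = c("x", "y")) {
  axis <- match.arg(axis)
  off <- displacement_offsets(tree, params)
  nm <- sort(leaf_names(tree))
  ids <- node_id(tree, nm)
  if (axis == "x") setNames(params$x0 + off$x[ids], nm)
  else setNames(params$y0 + off$y[ids], nm)
}

.loc_vectors <- function(tree, locations) {
  nm <- sort(leaf_names(tree))
  idx <- match(nm, locations$cell)
  if (anyNA(idx)) {
    stop("locations missing for cell(s): ", paste(nm[is.na(idx)], collapse = ", "))
  }
  list(nm = nm, x = locations$x[idx], y = locations$y[idx])
}

#' Spatial log-likelihood, dense multivariate-normal evaluation
#'
#' Reference implementation: builds the N x N covariance and evaluates the
#' product of the x- and y-axis MVN densities through a Cholesky solve. Used
#' as the oracle for the linear-time pruning evaluation ([sd_loglik()]).
#'
#' @param tree a `lineage_tree` with branch lengths.
#' @param locations data.frame with columns cell, x, y covering all leaves.
#' @param params an [sd_params()] object.
#' @param floor lower bound on branch lengths inside the evaluation.
#' @return log-likelihood (x and y axes combined)
#' @export
sd_loglik_dense <- function(tree, locations, params, floor = 0) {
  lv <- .loc_vectors(tree, locations)
  S <- sd_covariance(tree, params$sigma, floor = floor)
  mux <- sd_mean(tree, params, "x")
  muy <- sd_mean(tree, params, "y")
  R <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(R) || any(diag(R) <= sqrt(.Machine$double.eps) * max(diag(R)))) {
    stop("covariance is singular (zero-length terminal branches?); ",
         "set a minimum branch-length floor")
  }
  n <- length(lv$nm)
  logdet <- 2 * sum(log(diag(R)))
  qx <- sum(backsolve(R, lv$x - mux, transpose = TRUE)^2)
  qy <- sum(backsolve(R, lv$y - muy, transpose = TRUE)^2)
  -n * log(2 * pi) - logdet - 0.5 * (qx + qy)
}

#' Spatial log-likelihood, linear-time pruning evaluation
#'
#' Computes the same value as [sd_loglik_dense()] by Gaussian message passing
#' on the tree (a continuous-trait pruning recursion), without materializing
#' the leaf covariance matrix. Cost is linear in the number of nodes.
#'
#' @inheritParams sd_loglik_dense
#' @return log-likelihood
#' @export
sd_loglik <- function(tree, locations, params, floor = 0) {
  lv <- .loc_vectors(tree, locations)
  off <- displacement_offsets(tree, params)
  ids <- node_id(tree, lv$nm)
  zx <- rep(NA_real_, tree$nnode)
  zy <- rep(NA_real_, tree$nnode)
  ## subtract the deterministic displacement so the residuals are Brownian
  zx[ids] <- lv$x - off$x[ids]
  zy[ids] <- lv$y - off$y[ids]
  br <- .floored_brlen(tree, floor)
  br[tree$root] <- 0
  ll <- bm_prune_cpp(tree$postorder, tree$parent, br, zx, zy,
                     params$sigma^2, params$x0, params$y0, tree$root)
  if (!is.finite(ll)) {
    stop("covariance is singular (zero-length terminal branches?); ",
         "set a minimum branch-length floor")
  }
  ll
}

#' @rdname sd_loglik
#' @export
sd_loglik_fast <- sd_loglik

#' Brownian-motion spatial log-likelihood
#'
#' Convenience wrapper for the SD likelihood at `r = 0` (no division
#' displacement), the standard phylogeographic Brownian model.
#'
#' @inheritParams sd_loglik_dense
#' @param sigma diffusion rate.
#' @param x0,y0 root location.
#' @return log-likelihood
#' @export
brownian_loglik <- function(tree, locations, sigma, x0 = 0, y0 = 0,
                            floor = 0) {
  sd_loglik(tree, locations, sd_params(sigma, r = 0, x0 = x0, y0 = y0),
            floor = floor)
}
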