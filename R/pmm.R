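## ---------------------------------------------------------------------------
## Evolution of CRISPR-induced barcodes
##
## Per-site continuous-time Markov chain over hidden states
## {0, 1..M, -1(silenced)}: the unedited state 0 mutates to state a at rate
## lambda * pi_a; any non-silenced state is silenced (heritably missing) at
## rate nu; mutations are irreversible and non-modifiable; the silenced state
## is absorbing. At the leaves an unsilenced state drops out (is read as "?")
## with probability phi; the silenced state is always read as "?".
##
## Because silencing runs as an independent exponential clock, the transition
## probabilities have closed forms: with el = exp(-lambda*t), en = exp(-nu*t),
##   P(0 -> 0)  = el * en          P(0 -> a) = pi_a * (1 - el) * en
##   P(0 -> -1) = 1 - en           P(a -> a) = en
##   P(a -> -1) = 1 - en           P(-1 -> -1) = 1
## ---------------------------------------------------------------------------

#' Barcode mutation-model parameters
#'
#' @param lambda mutation rate (events per unit time, >= 0): total rate of
#'   leaving the unedited state by mutation, split across mutated states by
#'   their priors.
#' @param nu heritable silencing rate (>= 0).
#' @param phi dropout probability at the leaves (in `[0, 1)`).
#' @return a `pmm_params` list
#' @export
pmm_params <- function(lambda, nu = 0, phi = 0) {
  if (!is.finite(lambda) || lambda < 0) stop("lambda must be >= 0")
  if (!is.finite(nu) || nu < 0) stop("nu must be >= 0")
  if (!is.finite(phi) || phi < 0 || phi >= 1) stop("phi must be in [0, 1)")
  structure(list(lambda = lambda, nu = nu, phi = phi), class = "pmm_params")
}

#' Per-site alphabet
#'
#' @param M number of mutated states (>= 1).
#' @param pi prior over mutated states (defaults to uniform); must sum to 1.
#' @return a `site_alphabet` list
#' @export
site_alphabet <- function(M, pi = NULL) {
  M <- as.integer(M)
  if (M < 1L) stop("M must be >= 1")
  if (is.null(pi)) pi <- rep(1 / M, M)
  if (length(pi) != M || abs(sum(pi) - 1) > 1e-9 || any(pi < 0)) {
    stop("pi must be a probability vector over the ", M, " mutated states")
  }
  structure(list(M = M, pi = pi), class = "site_alphabet")
}

.state_names <- function(M) c("0", as.character(seq_len(M)), "-1")

#' Transition probability matrix of the barcode chain
#'
#' Hidden-state order: unedited `0`, mutated `1..M`, silenced `-1`. Rows sum
#' to one; the chain is irreversible (no return to `0`, no change between
#' mutated states) and the silenced state is absorbing.
#'
#' @param site a [site_alphabet()].
#' @param params a [pmm_params()].
#' @param delta elapsed time (>= 0).
#' @return (M+2) x (M+2) stochastic matrix
#' @export
transition_matrix <- function(site, params, delta) {
  if (!is.finite(delta) || delta < 0) stop("delta must be >= 0")
  M <- site$M
  el <- exp(-params$lambda * delta)
  en <- exp(-params$nu * delta)
  P <- matrix(0, M + 2L, M + 2L,
              dimnames = list(.state_names(M), .state_names(M)))
  P[1L, 1L] <- el * en
  P[1L, 1L + seq_len(M)] <- site$pi * (1 - el) * en
  P[1L, M + 2L] <- 1 - en
  for (a in seq_len(M)) {
    P[1L + a, 1L + a] <- en
    P[1L + a, M + 2L] <- 1 - en
  }
  P[M + 2L, M + 2L] <- 1
  P
}

## generator of the chain; the matrix-exponential cross-check in the tests
## exponentiates this
pmm_generator <- function(site, params) {
  M <- site$M
  Q <- matrix(0, M + 2L, M + 2L,
              dimnames = list(.state_names(M), .state_names(M)))
  Q[1L, 1L + seq_len(M)] <- params$lambda * site$pi
  Q[1L, M + 2L] <- params$nu
  Q[1L, 1L] <- -(params$lambda + params$nu)
  for (a in seq_len(M)) {
    Q[1L + a, M + 2L] <- params$nu
    Q[1L + a, 1L + a] <- -params$nu
  }
  Q
}

#' Dropout emission table
#'
#' Probability of each observed symbol given the hidden state at a leaf.
#' Observed symbols are `?` (missing) and `0..M`; the silenced hidden state
#' is always read as `?`, any other state is read as itself with probability
#' `1 - phi` and as `?` with probability `phi`.
#'
#' @param site a [site_alphabet()].
#' @param phi dropout probability.
#' @return matrix with hidden-state rows (`0`, `1..M`, `-1`) and observed
#'   columns (`?`, `0`, `1..M`); rows sum to 1.
#' @export
dropout_emission <- function(site, phi) {
  if (!is.finite(phi) || phi < 0 || phi >= 1) stop("phi must be in [0, 1)")
  M <- site$M
  E <- matrix(0, M + 2L, M + 2L,
              dimnames = list(.state_names(M),
                              c("?", "0", as.character(seq_len(M)))))
  for (h in 0:M) {
    E[h + 1L, "?"] <- phi
    E[h + 1L, as.character(h)] <- 1 - phi
  }
  E[M + 2L, "?"] <- 1
  E
}

## ---------------------------------------------------------------------------
## Likelihood of a character matrix
## ---------------------------------------------------------------------------

## map an observed integer column (NA = ?, -1 silent, 0..M) to the internal
## coding (-2 = ?); observed -1 is unobservable under the emission model, so
## by default it is treated as missing; strict mode rejects it
.encode_obs <- function(mat, strict_silent = FALSE) {
  if (any(mat < -1, na.rm = TRUE)) stop("invalid negative state in matrix")
  if (any(mat == -1L, na.rm = TRUE)) {
    if (strict_silent) {
      stop("observed -1 entries present; the emission model renders the ",
           "silenced state unobservable (rerun with strict_silent = FALSE ",
           "to treat them as missing)")
    }
    mat[mat == -1L] <- NA_integer_
  }
  mat[is.na(mat)] <- -2L
  mat
}

## alphabets inferred from the observed symbols (M = largest observed state,
## at least 1), unless given
infer_alphabets <- function(mat, M = NULL) {
  K <- ncol(mat)
  if (!is.null(M)) {
    M <- rep_len(as.integer(M), K)
    return(lapply(M, site_alphabet))
  }
  lapply(seq_len(K), function(k) {
    mk <- suppressWarnings(max(1L, mat[, k][mat[, k] >= 1L], na.rm = TRUE))
    site_alphabet(mk)
  })
}

.pmm_prepare <- function(tree, mat, sites, strict_silent = FALSE) {
  nm <- leaf_names(tree)
  if (is.null(rownames(mat))) {
    if (nrow(mat) != length(nm)) stop("matrix rows do not match tree leaves")
    rownames(mat) <- nm
  }
  idx <- match(nm, rownames(mat))
  if (anyNA(idx)) {
    stop("character matrix missing cell(s): ",
         paste(nm[is.na(idx)], collapse = ", "))
  }
  mat <- .encode_obs(mat[idx, , drop = FALSE], strict_silent)
  Mk <- vapply(sites, function(s) s$M, 1L)
  for (k in seq_len(ncol(mat))) {
    bad <- mat[, k] > Mk[k]
    if (any(bad)) {
      stop(sprintf("site %d: observed state exceeds alphabet (M = %d)",
                   k, Mk[k]))
    }
  }
  obsidx <- rep(-1L, tree$nnode)
  obsidx[tree$tips] <- match(tree$labels[tree$tips], nm) - 1L
  pivals <- unlist(lapply(sites, function(s) s$pi))
  pioff <- c(0L, cumsum(Mk))[seq_along(Mk)]
  list(mat = mat, obsidx = obsidx, Mk = Mk, pivals = pivals, pioff = pioff)
}

#' Log-likelihood of one barcode site
#'
#' Marginal probability of the observed leaf symbols of one target site,
#' summed over all hidden ancestral states by postorder pruning, with the
#' root (progenitor) fixed in the unedited state.
#'
#' @param tree a `lineage_tree` with branch lengths.
#' @param column observed states, named by cell or ordered as
#'   `leaf_names(tree)`; `NA` = missing, `-1` silenced, `0..M` states.
#' @param site a [site_alphabet()].
#' @param params a [pmm_params()].
#' @param strict_silent error on observed `-1` instead of treating it as
#'   missing.
#' @return log-likelihood (<= 0); `-Inf` when the column is impossible under
#'   the parameters (e.g. silenced observations with `nu = 0`).
#' @export
site_loglik <- function(tree, column, site, params, strict_silent = FALSE) {
  mat <- matrix(as.integer(column), ncol = 1L)
  rownames(mat) <- if (!is.null(names(column))) names(column)
  sequence_loglik(tree, mat, params, sites = list(site),
                  strict_silent = strict_silent)
}

#' Log-likelihood of a barcode character matrix
#'
#' Sites evolve independently, so the matrix log-likelihood is the sum of
#' per-site values. Evaluated by a scaled pruning recursion, linear in the
#' number of nodes per site.
#'
#' @param tree a `lineage_tree` with branch lengths.
#' @param mat integer matrix (cells x sites), `NA` = missing.
#' @param params a [pmm_params()].
#' @param sites list of [site_alphabet()] per site; inferred from the data
#'   when `NULL`.
#' @param per_site return the per-site vector instead of the sum.
#' @param strict_silent error on observed `-1`.
#' @return total (or per-site) log-likelihood
#' @export
sequence_loglik <- function(tree, mat, params, sites = NULL,
                            per_site = FALSE, strict_silent = FALSE) {
  if (is.null(sites)) sites <- infer_alphabets(mat)
  if (length(sites) != ncol(mat)) stop("need one site alphabet per column")
  pp <- .pmm_prepare(tree, mat, sites, strict_silent)
  br <- tree$brlen
  if (anyNA(br[-tree$root])) stop("branch lengths are unset")
  br[tree$root] <- 0
  ll <- pmm_prune_cpp(tree$postorder, tree$parent, br, pp$obsidx, pp$mat,
                      pp$Mk, pp$pivals, pp$pioff,
                      params$lambda, params$nu, params$phi, tree$root)
  if (per_site) ll else sum(ll)
}

#' Brute-force site log-likelihood by enumeration
#'
#' Exact sum over every assignment of hidden states to the non-root internal
#' nodes (leaf states are summed analytically against the emission table),
#' with transition probabilities obtained by matrix exponentiation of the
#' generator. Exponential cost; testing oracle for [site_loglik()] on small
#' trees only.
#'
#' @inheritParams site_loglik
#' @param max_internal refuse trees with more enumerated nodes than this.
#' @return log-likelihood
#' @export
brute_force_site_loglik <- function(tree, column, site, params,
                                    max_internal = 7L) {
  if (!requireNamespace("Matrix", quietly = TRUE)) {
    stop("the enumeration oracle needs the Matrix package")
  }
  internal <- setdiff(which(vapply(tree$children, length, 1L) > 0L),
                      tree$root)
  if (length(internal) > max_internal) {
    stop("tree too large for enumeration (", length(internal),
         " internal nodes > ", max_internal, ")")
  }
  nm <- leaf_names(tree)
  if (!is.null(names(column))) column <- column[nm]
  obs <- .encode_obs(matrix(as.integer(column), ncol = 1L))[, 1L]
  M <- site$M
  ns <- M + 2L
  Q <- pmm_generator(site, params)
  E <- dropout_emission(site, params$phi)
  Psi <- lapply(seq_len(tree$nnode), function(v) {
    if (v == tree$root) return(NULL)
    as.matrix(Matrix::expm(Q * tree$brlen[v]))
  })
  ## leaf factor given parent state: sum_a Psi(p -> a) * E(a, obs)
  obs_col <- ifelse(obs == -2L, 1L, obs + 2L) # column index into E
  states <- vector("list", length(internal))
  total <- 0
  n_int <- length(internal)
  grid <- rep(1L, n_int)
  repeat {
    x <- integer(tree$nnode)
    x[tree$root] <- 1L # state "0"
    x[internal] <- grid
    p <- 1
    for (v in seq_len(tree$nnode)) {
      if (v == tree$root) next
      u <- tree$parent[v]
      if (length(tree$children[[v]])) {
        p <- p * Psi[[v]][x[u], x[v]]
      } else {
        i <- match(tree$labels[v], nm)
        p <- p * sum(Psi[[v]][x[u], ] * E[, obs_col[i]])
      }
      if (p == 0) break
    }
    total <- total + p
    ## next assignment
    j <- 1L
    while (j <= n_int) {
      grid[j] <- grid[j] + 1L
      if (grid[j] <= ns) break
      grid[j] <- 1L
      j <- j + 1L
    }
    if (j > n_int) break
    if (n_int == 0L) break
  }
  log(total)
}
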