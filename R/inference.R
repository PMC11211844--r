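## ---------------------------------------------------------------------------
## Joint constrained maximum-likelihood inference
##
## On a fixed topology, co-estimate the node times (equivalently branch
## lengths, constrained so every leaf sits at tau_end), the diffusion rate
## sigma, the per-division displacement angles, the root location, and the
## barcode parameters (lambda, nu, phi), with the displacement magnitude r a
## fixed input. Modalities: sequence-only "S", location-only "L", joint "S+L".
## ---------------------------------------------------------------------------

.norm_modality <- function(m) {
  m <- toupper(gsub("[^A-Za-z]", "", m))
  if (m %in% c("SL", "LS", "JOINT")) return("SL")
  if (m == "S" || m == "SEQUENCE" || m == "SEQUENCEONLY") return("S")
  if (m == "L" || m == "LOCATION" || m == "LOCATIONONLY") return("L")
  stop("unknown modality: ", m, " (use 'S+L', 'S', or 'L')")
}

#' Joint log-likelihood of locations and barcodes
#'
#' The two data modalities are independent given the tree, so the joint
#' log-likelihood is the sum of the spatial and sequence terms; single-
#' modality calls return just that term.
#'
#' @param tree a `lineage_tree` with branch lengths.
#' @param mat character matrix (needed for modalities "S", "S+L").
#' @param locations locations data.frame (needed for "L", "S+L").
#' @param sd an [sd_params()] (spatial modalities).
#' @param pmm a [pmm_params()] (sequence modalities).
#' @param modality one of "S+L", "S", "L".
#' @param sites per-site alphabets (see [sequence_loglik()]).
#' @param floor branch-length floor inside the spatial likelihood.
#' @return log-likelihood
#' @export
joint_loglik <- function(tree, mat = NULL, locations = NULL, sd = NULL,
                         pmm = NULL, modality = "S+L", sites = NULL,
                         floor = 0) {
  modality <- .norm_modality(modality)
  ll <- 0
  if (modality %in% c("SL", "L")) {
    if (is.null(locations) || is.null(sd)) {
      stop("modality ", modality, " needs locations and spatial parameters")
    }
    ll <- ll + sd_loglik(tree, locations, sd, floor = floor)
  }
  if (modality %in% c("SL", "S")) {
    if (is.null(mat) || is.null(pmm)) {
      stop("modality ", modality, " needs a character matrix and ",
           "sequence parameters")
    }
    ll <- ll + sequence_loglik(tree, mat, pmm, sites = sites)
  }
  ll
}

## ---------------------------------------------------------------------------
## Node-time reparameterization: each internal node's time is
## parent_time + (tau_end - parent_time) * logistic(raw), evaluated root-down
## with leaves pinned at tau_end. The common-sampling-time constraint holds
## exactly by construction and the raw vector is unconstrained.
## ---------------------------------------------------------------------------

.free_internal <- function(tree) {
  deg <- vapply(tree$children, length, 1L)
  tree$preorder[deg[tree$preorder] > 0L & tree$preorder != tree$root]
}

#' Map an unconstrained vector to valid node times
#'
#' @param tree a `lineage_tree` (topology only is enough).
#' @param raw numeric vector, one entry per non-root internal node in
#'   preorder; the zero vector puts each node at the midpoint of its feasible
#'   interval.
#' @param tau_end experiment duration.
#' @return numeric node-time vector (root 0, leaves `tau_end`)
#' @export
unconstrained_to_times <- function(tree, raw, tau_end) {
  ord <- .free_internal(tree)
  if (length(raw) != length(ord)) {
    stop("raw must have one entry per non-root internal node (",
         length(ord), ")")
  }
  t <- numeric(tree$nnode)
  t[tree$tips] <- tau_end
  for (i in seq_along(ord)) {
    v <- ord[i]
    tp <- t[tree$parent[v]]
    t[v] <- tp + (tau_end - tp) * stats::plogis(raw[i])
  }
  t
}

#' Map node times to the unconstrained vector
#'
#' Inverse of [unconstrained_to_times()]; round trip is exact to numerical
#' precision for any ordering-valid time map.
#'
#' @param tree a `lineage_tree`.
#' @param times node-time vector (root 0, leaves at `tau_end`).
#' @param tau_end experiment duration.
#' @return unconstrained numeric vector
#' @export
times_to_unconstrained <- function(tree, times, tau_end) {
  ord <- .free_internal(tree)
  raw <- numeric(length(ord))
  for (i in seq_along(ord)) {
    v <- ord[i]
    tp <- times[tree$parent[v]]
    raw[i] <- stats::qlogis((times[v] - tp) / (tau_end - tp))
  }
  raw
}

#' Model configuration for fitting
#'
#' @param modality "S+L" (default), "S", or "L".
#' @param r fixed displacement magnitude (cell radius); never optimized
#'   because co-estimating r with sigma is systematically biased.
#' @param tau_end experiment duration (time from the progenitor to sampling).
#' @param restarts number of random restarts (>= 1).
#' @param seed integer seed; restart i uses `seed + i - 1`.
#' @param tol relative log-likelihood convergence tolerance.
#' @param maxit maximum optimizer iterations per restart.
#' @param fixed named list of parameters to hold fixed, e.g.
#'   `list(nu = 0, x0 = 0, y0 = 0)`; allowed names: sigma, x0, y0, lambda,
#'   nu, phi.
#' @param floor branch-length floor inside the spatial likelihood, as a
#'   fraction of `tau_end`.
#' @param sites per-site alphabets (see [sequence_loglik()]).
#' @return a `model_config` list
#' @export
model_config <- function(modality = "S+L", r = 0, tau_end, restarts = 10,
                         seed = 1, tol = 1e-8, maxit = 2000,
                         fixed = list(), floor = 1e-6, sites = NULL) {
  modality <- .norm_modality(modality)
  if (tau_end <= 0) stop("tau_end must be > 0")
  if (r < 0) stop("r must be >= 0")
  if (restarts < 1) stop("restarts must be >= 1")
  bad <- setdiff(names(fixed), c("sigma", "x0", "y0", "lambda", "nu", "phi"))
  if (length(bad)) stop("unknown fixed parameter(s): ", paste(bad, collapse = ", "))
  structure(list(modality = modality, r = r, tau_end = tau_end,
                 restarts = as.integer(restarts), seed = as.integer(seed),
                 tol = tol, maxit = as.integer(maxit), fixed = fixed,
                 floor = floor, sites = sites),
            class = "model_config")
}

## parameter-block bookkeeping: which free scalars enter the optimizer
.par_layout <- function(tree, config) {
  n_times <- length(.free_internal(tree))
  spatial <- config$modality %in% c("SL", "L")
  seqm <- config$modality %in% c("SL", "S")
  blocks <- list(times = n_times)
  if (spatial) {
    if (config$r > 0) blocks$theta <- length(bifurcations(tree))
    for (p in c("sigma", "x0", "y0")) {
      if (is.null(config$fixed[[p]])) blocks[[p]] <- 1L
    }
  }
  if (seqm) {
    for (p in c("lambda", "nu", "phi")) {
      if (is.null(config$fixed[[p]])) blocks[[p]] <- 1L
    }
  }
  offs <- cumsum(c(0L, unlist(blocks)))
  list(blocks = blocks, offsets = offs[-length(offs)],
       total = offs[length(offs)], spatial = spatial, seq = seqm)
}

.unpack <- function(par, layout, tree, config) {
  get_block <- function(nm) {
    i <- match(nm, names(layout$blocks))
    if (is.na(i)) return(NULL)
    par[(layout$offsets[i] + 1L):(layout$offsets[i] + layout$blocks[[i]])]
  }
  clamp <- function(x, lo = -25, hi = 25) pmin(pmax(x, lo), hi)
  ## clamped so node times cannot collapse onto their parent in floating
  ## point; the optimizer additionally box-bounds every block (see .par_bounds)
  out <- list(raw_times = clamp(get_block("times")))
  if (layout$spatial) {
    th <- get_block("theta")
    out$theta <- if (is.null(th)) NULL else
      setNames(th %% (2 * pi), bifurcations(tree))
    out$sigma <- if (is.null(config$fixed$sigma))
      exp(clamp(get_block("sigma"))) else config$fixed$sigma
    out$x0 <- if (is.null(config$fixed$x0)) get_block("x0") else config$fixed$x0
    out$y0 <- if (is.null(config$fixed$y0)) get_block("y0") else config$fixed$y0
  }
  if (layout$seq) {
    out$lambda <- if (is.null(config$fixed$lambda))
      exp(clamp(get_block("lambda"))) else config$fixed$lambda
    out$nu <- if (is.null(config$fixed$nu))
      exp(clamp(get_block("nu"))) else config$fixed$nu
    out$phi <- if (is.null(config$fixed$phi))
      stats::plogis(clamp(get_block("phi"))) else config$fixed$phi
  }
  out
}

## box bounds per parameter block (transformed scale), keeping the optimizer
## away from the flat numerical plateaus at extreme transformed values
.par_bounds <- function(layout) {
  lim <- list(times = c(-25, 25), theta = c(-50, 50), sigma = c(-9, 9),
              x0 = c(-1e6, 1e6), y0 = c(-1e6, 1e6), lambda = c(-25, 5),
              nu = c(-25, 5), phi = c(-15, 15))
  lo <- numeric(0); hi <- numeric(0)
  for (nm in names(layout$blocks)) {
    k <- layout$blocks[[nm]]
    lo <- c(lo, rep(lim[[nm]][1L], k))
    hi <- c(hi, rep(lim[[nm]][2L], k))
  }
  list(lower = lo, upper = hi)
}

.objective_factory <- function(tree, mat, locations, config, layout) {
  floor_abs <- config$floor * config$tau_end
  function(par) {
    ll <- tryCatch({
      pp <- .unpack(par, layout, tree, config)
      times <- unconstrained_to_times(tree, pp$raw_times, config$tau_end)
      tr <- apply_node_times(tree, times)
      v <- 0
      if (layout$spatial) {
        sdp <- sd_params(pp$sigma, r = config$r, theta = pp$theta,
                         x0 = pp$x0, y0 = pp$y0)
        v <- v + sd_loglik(tr, locations, sdp, floor = floor_abs)
      }
      if (layout$seq) {
        pmm <- pmm_params(pp$lambda, pp$nu, pp$phi)
        v <- v + sequence_loglik(tr, mat, pmm, sites = config$sites)
      }
      v
    }, error = function(e) -Inf)
    if (!is.finite(ll)) return(1e10)
    -ll
  }
}

## moment-based displacement-angle start: the displacement shifts the whole
## first daughter subtree by +r(cos, sin) and the second by the negative, so
## the direction between the daughter-subtree centroids estimates theta
.theta_moment_init <- function(tree, locations) {
  idx <- match(tree$labels, locations$cell)
  below <- vector("list", tree$nnode)
  cx <- numeric(tree$nnode); cy <- numeric(tree$nnode)
  for (v in tree$postorder) {
    ch <- tree$children[[v]]
    below[[v]] <- if (!length(ch)) v else unlist(below[ch])
    ii <- idx[below[[v]]]
    cx[v] <- mean(locations$x[ii]); cy[v] <- mean(locations$y[ii])
  }
  vapply(bifurcations(tree), function(u) {
    ch <- tree$children[[u]]
    atan2(cy[ch[1L]] - cy[ch[2L]], cx[ch[1L]] - cx[ch[2L]]) %% (2 * pi)
  }, 1)
}

## analytic gradient of the negative joint log-likelihood on the transformed
## parameter scale; mirrors .objective_factory (belief propagation for the
## spatial component, inside-outside for the sequence component)
.gradient_factory <- function(tree, mat, locations, config, layout) {
  floor_abs <- config$floor * config$tau_end
  ord <- .free_internal(tree)
  bif <- bifurcations(tree)
  lv <- if (layout$spatial) .loc_vectors(tree, locations)
  ids <- if (layout$spatial) node_id(tree, lv$nm)
  pp_seq <- if (layout$seq) {
    .pmm_prepare(tree, mat, config$sites, strict_silent = FALSE)
  }
  nb <- layout$blocks
  function(par) {
    pp <- .unpack(par, layout, tree, config)
    times <- unconstrained_to_times(tree, pp$raw_times, config$tau_end)
    tr <- apply_node_times(tree, times)
    br <- tr$brlen
    br[tree$root] <- 0
    g_delta <- numeric(tree$nnode)
    g <- numeric(length(par))
    ok <- TRUE
    if (layout$spatial) {
      brf <- pmax(br, floor_abs)
      brf[tree$root] <- 0
      W <- pp$sigma^2 * brf
      Dx <- numeric(tree$nnode); Dy <- numeric(tree$nnode)
      th <- pp$theta
      if (config$r > 0) {
        for (u in bif) {
          a <- th[[as.character(u)]]
          ch <- tree$children[[u]]
          Dx[ch] <- c(1, -1) * config$r * cos(a)
          Dy[ch] <- c(1, -1) * config$r * sin(a)
        }
      }
      zx <- rep(NA_real_, tree$nnode); zy <- zx
      zx[ids] <- lv$x; zy[ids] <- lv$y
      gs <- bm_bp_grad_cpp(tr$postorder, tr$preorder, tr$parent, W, Dx, Dy,
                           zx, zy, pp$x0, pp$y0, tree$root)
      if (!is.finite(gs$ll)) ok <- FALSE else {
        ## branch lengths (only where the floor is inactive)
        g_delta <- g_delta + gs$gW * pp$sigma^2 * (br >= floor_abs)
        if (!is.null(nb$theta)) {
          gth <- vapply(bif, function(u) {
            a <- th[[as.character(u)]]
            ch <- tree$children[[u]]
            dd <- config$r * ((gs$gDx[ch[1L]] - gs$gDx[ch[2L]]) * (-sin(a)) +
                                (gs$gDy[ch[1L]] - gs$gDy[ch[2L]]) * cos(a))
            dd
          }, 1)
          i <- match("theta", names(nb))
          g[(layout$offsets[i] + 1L):(layout$offsets[i] + nb$theta)] <- -gth
        }
        if (is.null(config$fixed$sigma)) {
          gls <- 2 * pp$sigma^2 * sum(gs$gW * brf)
          i <- match("sigma", names(nb))
          g[layout$offsets[i] + 1L] <- -gls
        }
        if (is.null(config$fixed$x0)) {
          i <- match("x0", names(nb)); g[layout$offsets[i] + 1L] <- -gs$gx0
        }
        if (is.null(config$fixed$y0)) {
          i <- match("y0", names(nb)); g[layout$offsets[i] + 1L] <- -gs$gy0
        }
      }
    }
    if (ok && layout$seq) {
      gq <- pmm_grad_cpp(tr$postorder, tr$preorder, tr$parent, br,
                         pp_seq$obsidx, pp_seq$mat, pp_seq$Mk, pp_seq$pivals,
                         pp_seq$pioff, pp$lambda, pp$nu, pp$phi, tree$root)
      if (!is.finite(gq$ll)) ok <- FALSE else {
        g_delta <- g_delta + gq$gdelta
        if (is.null(config$fixed$lambda)) {
          i <- match("lambda", names(nb))
          g[layout$offsets[i] + 1L] <- -gq$glambda * pp$lambda
        }
        if (is.null(config$fixed$nu)) {
          i <- match("nu", names(nb))
          g[layout$offsets[i] + 1L] <- -gq$gnu * pp$nu
        }
        if (is.null(config$fixed$phi)) {
          i <- match("phi", names(nb))
          g[layout$offsets[i] + 1L] <- -gq$gphi * pp$phi * (1 - pp$phi)
        }
      }
    }
    if (!ok) return(g) # flat fallback at infeasible points
    ## chain rule through the node-time recursion: delta_v = t_v - t_parent
    g_t <- numeric(tree$nnode)
    for (v in seq_len(tree$nnode)) {
      if (v == tree$root) next
      g_t[v] <- g_t[v] + g_delta[v]
      g_t[tree$parent[v]] <- g_t[tree$parent[v]] - g_delta[v]
    }
    adj <- g_t
    g_raw <- numeric(length(ord))
    sv <- stats::plogis(pp$raw_times)
    for (i in rev(seq_along(ord))) {
      v <- ord[i]
      p <- tree$parent[v]
      g_raw[i] <- adj[v] * (config$tau_end - times[p]) * sv[i] * (1 - sv[i])
      if (p != tree$root) adj[p] <- adj[p] + adj[v] * (1 - sv[i])
    }
    i <- match("times", names(nb))
    g[(layout$offsets[i] + 1L):(layout$offsets[i] + nb$times)] <- -g_raw
    g
  }
}

.start_point <- function(tree, mat, locations, config, layout, restart) {
  set.seed(config$seed + restart - 1L)
  jit <- restart > 1L
  n_times <- layout$blocks$times
  raw0 <- rep(0, n_times)
  if (!anyNA(tree$brlen[-tree$root])) {
    tt <- time_from_root(tree)
    um <- is_ultrametric(tree, config$tau_end, tol = 1e-6)
    if (um$ultrametric) {
      raw0 <- times_to_unconstrained(tree, tt * config$tau_end /
                                       max(tt[tree$tips]), config$tau_end)
      raw0[!is.finite(raw0)] <- 0
    }
  }
  if (jit) raw0 <- raw0 + rnorm(n_times, 0, 0.5)
  par <- raw0
  if (layout$spatial) {
    if (!is.null(layout$blocks$theta)) {
      ## odd restarts start from the moment-based angles (jittered), even
      ## restarts from uniform random angles
      if (restart %% 2L == 1L) {
        th0 <- .theta_moment_init(tree, locations)
        if (jit) th0 <- th0 + rnorm(length(th0), 0, 0.3)
        par <- c(par, th0)
      } else {
        par <- c(par, runif(layout$blocks$theta, 0, 2 * pi))
      }
    }
    cx <- mean(locations$x); cy <- mean(locations$y)
    s0 <- sqrt(mean((locations$x - cx)^2 + (locations$y - cy)^2) / 2 /
                 config$tau_end)
    s0 <- max(s0, 1e-3)
    if (is.null(config$fixed$sigma)) {
      par <- c(par, log(s0) + if (jit) rnorm(1, 0, 0.3) else 0)
    }
    if (is.null(config$fixed$x0)) par <- c(par, cx + if (jit) rnorm(1, 0, s0) else 0)
    if (is.null(config$fixed$y0)) par <- c(par, cy + if (jit) rnorm(1, 0, s0) else 0)
  }
  if (layout$seq) {
    nonmiss <- sum(!is.na(mat))
    frac0 <- if (nonmiss) sum(mat == 0L, na.rm = TRUE) / nonmiss else 0.5
    l0 <- -log(min(max(frac0, 1e-3), 1 - 1e-3)) / config$tau_end
    if (is.null(config$fixed$lambda)) {
      par <- c(par, log(l0) + if (jit) rnorm(1, 0, 0.3) else 0)
    }
    if (is.null(config$fixed$nu)) {
      ## start at a silencing rate giving ~10% expected loss over tau_end
      par <- c(par, log(0.1 / config$tau_end) +
                 if (jit) rnorm(1, 0, 0.5) else 0)
    }
    if (is.null(config$fixed$phi)) {
      par <- c(par, stats::qlogis(0.01) + if (jit) rnorm(1, 0, 0.5) else 0)
    }
  }
  par
}

#' Fit a spatial lineage tree by maximum likelihood
#'
#' Multi-restart quasi-Newton optimization of the joint (or single-modality)
#' log-likelihood over node times and free model parameters, on the fixed
#' input topology, with every leaf pinned at `tau_end`. Deterministic given
#' the config seed; the best restart is returned.
#'
#' @param tree a `lineage_tree`; input branch lengths, when present and
#'   consistent with `tau_end`, seed the node-time start point.
#' @param mat character matrix (or `NULL` for modality "L").
#' @param locations locations data.frame (or `NULL` for modality "S").
#' @param config a [model_config()].
#' @return an `sd_fit` with the fitted tree, parameter estimates, component
#'   log-likelihoods, and a per-restart table.
#' @export
fit_lineage <- function(tree, mat = NULL, locations = NULL, config) {
  stopifnot(inherits(config, "model_config"))
  layout <- .par_layout(tree, config)
  if (layout$spatial && is.null(locations)) stop("modality needs locations")
  if (layout$seq && is.null(mat)) stop("modality needs a character matrix")
  if (layout$seq && is.null(config$sites)) {
    config$sites <- infer_alphabets(mat)
  }
  if (layout$seq) {
    ## encode once: -1 -> missing
    mat <- .encode_obs(mat)
    mat[mat == -2L] <- NA_integer_
  }
  fn <- .objective_factory(tree, mat, locations, config, layout)
  gr <- .gradient_factory(tree, mat, locations, config, layout)
  bounds <- .par_bounds(layout)
  runs <- vector("list", config$restarts)
  for (i in seq_len(config$restarts)) {
    p0 <- .start_point(tree, mat, locations, config, layout, i)
    p0 <- pmin(pmax(p0, bounds$lower), bounds$upper)
    f0 <- fn(p0)
    opt <- tryCatch(
      optim(p0, fn, gr, method = "L-BFGS-B",
            lower = bounds$lower, upper = bounds$upper,
            control = list(maxit = config$maxit,
                           factr = config$tol / .Machine$double.eps)),
      error = function(e) list(par = p0, value = f0, convergence = 99L)
    )
    if (opt$value > f0) opt <- list(par = p0, value = f0, convergence = 99L)
    runs[[i]] <- list(par = opt$par, value = opt$value, start_value = f0,
                      converged = isTRUE(opt$convergence == 0),
                      seed = config$seed + i - 1L)
  }
  vals <- vapply(runs, function(r) r$value, 1)
  best <- runs[[which.min(vals)]]
  pp <- .unpack(best$par, layout, tree, config)
  times <- unconstrained_to_times(tree, pp$raw_times, config$tau_end)
  fitted <- apply_node_times(tree, times, tau_end = config$tau_end)
  floor_abs <- config$floor * config$tau_end
  ll_sp <- NA_real_
  ll_seq <- NA_real_
  dense_gap <- NA_real_
  sigma_corr <- NA_real_
  sdp <- NULL
  if (layout$spatial) {
    sdp <- sd_params(pp$sigma, r = config$r, theta = pp$theta,
                     x0 = pp$x0, y0 = pp$y0)
    ll_sp <- sd_loglik(fitted, locations, sdp, floor = floor_abs)
    dense_gap <- abs(ll_sp -
                       sd_loglik_dense(fitted, locations, sdp,
                                       floor = floor_abs))
    ## degrees-of-freedom correction of the diffusion rate: each fitted mean
    ## parameter (one per displacement angle, one per free root coordinate)
    ## absorbs about one dimension of spatial noise out of the 2N observed
    ## coordinates, deflating the ML variance by (2N - p)/2N exactly as in
    ## ordinary Gaussian regression; the reported sigma undoes this (the
    ## REML-style estimate). The uncorrected ML value is kept alongside.
    n_obs <- 2L * n_leaves(tree)
    p_mean <- (if (!is.null(pp$theta)) length(pp$theta) else 0L) +
      sum(is.null(config$fixed$x0), is.null(config$fixed$y0))
    sigma_corr <- pp$sigma * sqrt(n_obs / max(n_obs - p_mean, 1L))
  }
  pmm <- NULL
  if (layout$seq) {
    pmm <- pmm_params(pp$lambda, pp$nu, pp$phi)
    ll_seq <- sequence_loglik(fitted, mat, pmm, sites = config$sites)
  }
  restart_table <- data.frame(
    restart = seq_len(config$restarts),
    seed = vapply(runs, function(r) r$seed, 1L),
    start_loglik = -vapply(runs, function(r) r$start_value, 1),
    final_loglik = -vals,
    converged = vapply(runs, function(r) r$converged, TRUE)
  )
  structure(list(
    tree = fitted,
    modality = config$modality,
    sigma = sigma_corr,
    sigma_ml = if (layout$spatial) pp$sigma else NA_real_,
    r = config$r,
    theta = pp$theta,
    x0 = if (layout$spatial) pp$x0 else NA_real_,
    y0 = if (layout$spatial) pp$y0 else NA_real_,
    lambda = if (layout$seq) pp$lambda else NA_real_,
    nu = if (layout$seq) pp$nu else NA_real_,
    phi = if (layout$seq) pp$phi else NA_real_,
    loglik = sum(c(ll_sp, ll_seq), na.rm = TRUE),
    loglik_spatial = ll_sp,
    loglik_sequence = ll_seq,
    dense_check = dense_gap,
    restarts = restart_table,
    converged = any(restart_table$converged),
    config = config
  ), class = "sd_fit")
}

#' @export
print.sd_fit <- function(x, ...) {
  cat(sprintf("<sd_fit> modality %s, r = %g, log-likelihood %.4f%s\n",
              x$modality, x$r, x$loglik,
              if (x$converged) "" else " (NOT converged)"))
  if (!is.na(x$sigma)) {
    cat(sprintf("  sigma = %.4f, root = (%.3f, %.3f)\n", x$sigma, x$x0, x$y0))
  }
  if (!is.na(x$lambda)) {
    cat(sprintf("  lambda = %.5f, nu = %.5f, phi = %.4f\n",
                x$lambda, x$nu, x$phi))
  }
  invisible(x)
}

#' Fit over a grid of displacement magnitudes
#'
#' Refits the model at each supplied `r` value (r itself is never optimized).
#'
#' @param tree,mat,locations as in [fit_lineage()].
#' @param config a [model_config()]; its `r` is overridden per grid point.
#' @param r_values numeric grid of displacement magnitudes.
#' @return named list of `sd_fit` objects keyed by r
#' @export
fit_r_sweep <- function(tree, mat = NULL, locations = NULL, config,
                        r_values) {
  fits <- lapply(r_values, function(r) {
    cfg <- config
    cfg$r <- r
    fit_lineage(tree, mat, locations, cfg)
  })
  names(fits) <- as.character(r_values)
  fits
}
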