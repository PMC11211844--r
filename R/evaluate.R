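## ---------------------------------------------------------------------------
## Evaluation: branch-length error, diffusion-rate bias, division-angle
## analysis of frame-by-frame tracks, displacement-radius sweeps
## ---------------------------------------------------------------------------

#' Mean absolute percentage error of branch lengths
#'
#' `mean(|estimate - truth| / truth)`, reported as a fraction (0.75 means
#' 75%). Truth lengths must be strictly positive.
#'
#' @param truth,estimate matched numeric vectors of branch lengths.
#' @return nonnegative scalar
#' @export
mape <- function(truth, estimate) {
  if (length(truth) != length(estimate)) stop("lengths differ")
  if (any(truth <= 0)) stop("MAPE is undefined for non-positive true lengths")
  mean(abs(estimate - truth) / truth)
}

## branch lengths of two same-topology trees matched by the leaf set below
## each edge's child (robust to node renumbering)
.edge_signature <- function(tree) {
  sig <- character(tree$nnode)
  for (v in tree$postorder) {
    ch <- tree$children[[v]]
    if (!length(ch)) sig[v] <- tree$labels[v]
    else sig[v] <- paste(sort(unlist(strsplit(sig[ch], "\u1f"))),
                         collapse = "\u1f")
  }
  sig
}

#' Branch-length MAPE between two trees on the same topology
#'
#' Edges are matched by the set of leaves below them, so node numbering may
#' differ between the two trees.
#'
#' @param true_tree,est_tree `lineage_tree`s over the same leaves/topology.
#' @return MAPE over all branches (fraction)
#' @export
branch_mape <- function(true_tree, est_tree) {
  s1 <- .edge_signature(true_tree)
  s2 <- .edge_signature(est_tree)
  i1 <- setdiff(seq_len(true_tree$nnode), true_tree$root)
  i2 <- setdiff(seq_len(est_tree$nnode), est_tree$root)
  idx <- i2[match(s1[i1], s2[i2])]
  if (anyNA(idx)) stop("trees do not share a topology")
  mape(true_tree$brlen[i1], est_tree$brlen[idx])
}

#' Summarize diffusion-rate estimation bias
#'
#' @param fits list of `sd_fit` objects sharing the same true sigma.
#' @param sigma_true the generating diffusion rate.
#' @return data.frame keyed by (modality, r) with mean and spread of
#'   `sigma_hat - sigma_true`
#' @export
sigma_bias <- function(fits, sigma_true) {
  if (!length(fits)) stop("no fits supplied")
  d <- data.frame(
    modality = vapply(fits, function(f) f$modality, ""),
    r = vapply(fits, function(f) f$r, 1),
    err = vapply(fits, function(f) f$sigma, 1) - sigma_true
  )
  out <- do.call(rbind, lapply(split(d, list(d$modality, d$r), drop = TRUE),
    function(g) data.frame(modality = g$modality[1L], r = g$r[1L],
                           n = nrow(g), bias = mean(g$err),
                           sd = if (nrow(g) > 1L) sd(g$err) else 0)))
  rownames(out) <- NULL
  out
}

#' Extract division triplets from frame-by-frame tracks
#'
#' For every recorded cell that divides (its two daughters appear in the next
#' frame), pairs the parent's last position with both daughters' positions
#' `lag` frames later. Divisions with an untracked parent or a daughter lost
#' before `lag` frames are skipped and counted.
#'
#' @param frames data.frame as produced by [simulate_frames()] (columns
#'   frame, cell, parent, x, y).
#' @param lag number of frames after division (>= 1).
#' @return data.frame of triplets (one row per division) with the parent and
#'   daughter coordinates; `attr(, "skipped")` counts unusable divisions.
#' @export
extract_triplets <- function(frames, lag = 1) {
  lag <- as.integer(lag)
  if (lag < 1L) stop("lag must be >= 1")
  kids <- unique(frames[frames$parent != "", c("cell", "parent")])
  fam <- split(kids$cell, kids$parent)
  fam <- fam[vapply(fam, length, 1L) == 2L]
  if (!length(fam)) {
    warning("no divisions found in frames")
    out <- data.frame(parent = character(0), d1 = character(0),
                      d2 = character(0), px = numeric(0), py = numeric(0),
                      x1 = numeric(0), y1 = numeric(0), x2 = numeric(0),
                      y2 = numeric(0), lag = integer(0))
    attr(out, "skipped") <- 0L
    return(out)
  }
  key <- paste(frames$cell, frames$frame)
  skipped <- 0L
  recs <- lapply(names(fam), function(p) {
    prow <- frames[frames$cell == p, ]
    if (!nrow(prow)) {
      skipped <<- skipped + 1L
      return(NULL)
    }
    t0 <- max(prow$frame)
    tf <- t0 + lag
    d <- fam[[p]]
    i1 <- match(paste(d[1L], tf), key)
    i2 <- match(paste(d[2L], tf), key)
    if (is.na(i1) || is.na(i2)) {
      skipped <<- skipped + 1L
      return(NULL)
    }
    data.frame(parent = p, d1 = d[1L], d2 = d[2L],
               px = prow$x[prow$frame == t0], py = prow$y[prow$frame == t0],
               x1 = frames$x[i1], y1 = frames$y[i1],
               x2 = frames$x[i2], y2 = frames$y[i2], lag = lag)
  })
  out <- do.call(rbind, recs[!vapply(recs, is.null, TRUE)])
  if (is.null(out)) out <- data.frame()
  attr(out, "skipped") <- skipped
  out
}

#' Daughter-parent-daughter angle
#'
#' Angle at the parent position subtended by the two daughter positions, in
#' degrees in `[0, 180]`. Degenerate records (a daughter exactly at the
#' parent position) give `NA`.
#'
#' @param triplets data.frame from [extract_triplets()], or coordinates via
#'   `px, py, x1, y1, x2, y2`.
#' @param px,py,x1,y1,x2,y2 coordinates (used when `triplets` is missing).
#' @return numeric vector of angles in degrees
#' @export
dpd_angle <- function(triplets = NULL, px, py, x1, y1, x2, y2) {
  if (!is.null(triplets)) {
    px <- triplets$px; py <- triplets$py
    x1 <- triplets$x1; y1 <- triplets$y1
    x2 <- triplets$x2; y2 <- triplets$y2
  }
  ux <- x1 - px; uy <- y1 - py
  vx <- x2 - px; vy <- y2 - py
  nu <- sqrt(ux^2 + uy^2); nv <- sqrt(vx^2 + vy^2)
  cosang <- (ux * vx + uy * vy) / (nu * nv)
  ang <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
  ang[nu == 0 | nv == 0] <- NA_real_
  ang
}

#' Test division angles against the Brownian (uniform) null
#'
#' Under pure Brownian motion the two daughters' displacement directions are
#' independent and isotropic, so the daughter-parent-daughter angle is
#' uniform on `[0, 180]` degrees; symmetric displacement concentrates it near
#' 180. Uses the Kolmogorov-Smirnov distance from the uniform CDF.
#'
#' @param angles numeric vector of angles in degrees (>= 20 required).
#' @return list with `n`, `statistic` (KS distance), `p_value`, and
#'   `mean_angle`
#' @export
angle_uniformity <- function(angles) {
  angles <- angles[is.finite(angles)]
  if (length(angles) < 20L) stop("need at least 20 angles")
  ks <- suppressWarnings(ks.test(angles, "punif", 0, 180))
  list(n = length(angles), statistic = unname(ks$statistic),
       p_value = ks$p.value, mean_angle = mean(angles))
}

#' Division-angle profile across lags
#'
#' Computes the angle distribution and its distance from the uniform null at
#' each requested lag, summarizing how quickly the division-displacement
#' signal washes out under diffusion.
#'
#' @param frames data.frame of tracked positions.
#' @param lags integer vector of frame lags.
#' @return data.frame (lag, n, statistic, p_value, mean_angle)
#' @export
angle_lag_profile <- function(frames, lags) {
  do.call(rbind, lapply(lags, function(l) {
    tr <- suppressWarnings(extract_triplets(frames, lag = l))
    ang <- if (nrow(tr)) dpd_angle(tr) else numeric(0)
    ang <- ang[is.finite(ang)]
    if (length(ang) < 20L) {
      ## too few divisions for the uniformity test; report what there is
      return(data.frame(lag = l, n = length(ang), statistic = NA_real_,
                        p_value = NA_real_,
                        mean_angle = if (length(ang)) mean(ang) else NA_real_))
    }
    u <- angle_uniformity(ang)
    data.frame(lag = l, n = u$n, statistic = u$statistic,
               p_value = u$p_value, mean_angle = u$mean_angle)
  }))
}

#' Summarize a displacement-radius sweep
#'
#' @param fits named list of `sd_fit` objects keyed by r (from
#'   [fit_r_sweep()]); at least three r values.
#' @param true_tree the generating tree (for branch-length error).
#' @param sigma_true the generating diffusion rate.
#' @return list with a per-r `table` (r, sigma bias, MAPE) and `r_opt`, the
#'   MAPE-minimizing r (ties resolved to the smallest r)
#' @export
r_sweep_report <- function(fits, true_tree, sigma_true) {
  if (length(fits) < 3L) stop("need fits at >= 3 r values")
  tab <- do.call(rbind, lapply(fits, function(f) {
    data.frame(r = f$r,
               sigma_bias = f$sigma - sigma_true,
               mape = branch_mape(true_tree, f$tree))
  }))
  tab <- tab[order(tab$r), ]
  rownames(tab) <- NULL
  list(table = tab, r_opt = tab$r[which.min(tab$mape)])
}
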