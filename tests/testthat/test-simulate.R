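test_that("topology generator produces valid seeded ultrametric trees", {
  tr <- simulate_topology(2, tau_end = 5, seed = 1)
  expect_equal(n_leaves(tr), 2L)
  expect_equal(tr$nnode, 4L) # root, one division, two leaves
  for (n in c(2, 5, 17)) {
    tr <- simulate_topology(n, tau_end = 10, seed = n)
    expect_equal(n_leaves(tr), n)
    expect_true(is_ultrametric(tr, 10, tol = 1e-12)$ultrametric)
    expect_equal(length(tr$children[[tr$root]]), 1L)
    expect_true(all(tr$brlen[-tr$root] > 0))
  }
  expect_identical(write_newick(simulate_topology(9, 7, seed = 3)),
                   write_newick(simulate_topology(9, 7, seed = 3)))
  expect_false(identical(write_newick(simulate_topology(9, 7, seed = 3)),
                         write_newick(simulate_topology(9, 7, seed = 4))))
  expect_error(simulate_topology(1, 5), "n must be")
})

test_that("noise-free locations are the exact displacement geometry", {
  tr <- cherry()
  u <- which(tr$labels == "u")
  p <- sd_params(1e-12, r = 2, theta = setNames(0, u))
  loc <- simulate_locations(tr, p, seed = 1)
  expect_equal(loc$x[loc$cell == "A"], 2, tolerance = 1e-9)
  expect_equal(loc$x[loc$cell == "B"], -2, tolerance = 1e-9)
  expect_equal(loc$y, c(0, 0), tolerance = 1e-9)
})

test_that("simulated location moments match the model mean and covariance", {
  ## moment check against the constructed MVN, pooled over replicates
  nrep <- 3000
  set.seed(77)
  for (case in 1:3) {
    tr <- rand_tree(5, tau = 6, seed = 700 + case)
    th <- theta_for_tree(tr, runif(length(bifurcations(tr)), 0, 2 * pi))
    p <- sd_params(runif(1, 0.5, 2), r = runif(1, 0, 4), theta = th)
    X <- matrix(0, nrep, n_leaves(tr))
    Y <- matrix(0, nrep, n_leaves(tr))
    for (i in seq_len(nrep)) {
      loc <- simulate_locations(tr, p)
      o <- order(loc$cell)
      X[i, ] <- loc$x[o]; Y[i, ] <- loc$y[o]
    }
    S <- sd_covariance(tr, p$sigma)
    mx <- sd_mean(tr, p, "x"); my <- sd_mean(tr, p, "y")
    se_mean <- sqrt(diag(S) / nrep)
    zx <- abs(colMeans(X) - mx) / se_mean
    zy <- abs(colMeans(Y) - my) / se_mean
    CX <- cov(X); CY <- cov(Y)
    se_cov <- sqrt((outer(diag(S), diag(S)) + S^2) / nrep)
    zc <- abs(cbind(CX - S, CY - S)) / cbind(se_cov, se_cov)
    z <- c(zx, zy, zc)
    ## standardized errors behave like z-scores: nearly all within 3 MC
    ## standard errors, none grossly out
    expect_gt(mean(z < 3), 0.99)
    expect_lt(max(z), 5)
  }
})

test_that("sequence simulator respects degenerate and marginal behaviour", {
  tr <- rand_tree(8, tau = 5, seed = 55)
  expect_true(all(simulate_sequences(tr, pmm_params(0, 0, 0), K = 4,
                                     seed = 1) == 0L))
  m1 <- simulate_sequences(tr, pmm_params(0.3, 0, 0.999999), K = 3, seed = 2)
  expect_true(all(is.na(m1)))
  ## unmutated fraction matches the chain marginal e^{-lambda tau} (nu=0)
  lam <- 0.3
  nrep <- 400
  set.seed(8)
  frac <- mean(vapply(seq_len(nrep), function(i) {
    m <- simulate_sequences(tr, pmm_params(lam, 0, 0), K = 2, M = 2)
    mean(m == 0L)
  }, 1))
  p0 <- exp(-lam * 5)
  se <- sqrt(p0 * (1 - p0) / (nrep * 2 * 8))
  expect_lt(abs(frac - p0), 4 * se)
  ## determinism and stream independence
  a <- simulate_sequences(tr, pmm_params(0.1, 0, 0.1), K = 3, seed = 99)
  b <- simulate_sequences(tr, pmm_params(0.1, 0, 0.1), K = 3, seed = 99)
  expect_identical(a, b)
})

test_that("frame tracks link lineages and agree with endpoint simulation", {
  tr <- rand_tree(12, tau = 30, seed = 66)
  p <- sd_params(1.5, r = 6.68)
  fr <- simulate_frames(tr, p, frame_interval = 1, seed = 67)
  expect_true(all(c("frame", "cell", "parent", "x", "y") %in% names(fr)))
  ## every recorded daughter's parent divides one frame before it appears
  kids <- unique(fr[fr$parent != "", c("cell", "parent")])
  fam <- split(kids$cell, kids$parent)
  fam <- fam[vapply(fam, length, 1L) == 2L]
  expect_gt(length(fam), 0L)
  for (pr in names(fam)[1:min(3, length(fam))]) {
    tlast <- max(fr$frame[fr$cell == pr])
    tfirst <- min(fr$frame[fr$cell %in% fam[[pr]]])
    expect_equal(tfirst, tlast + 1L)
  }
  ## immediately post-division, high displacement implies near-180 angles
  tp <- extract_triplets(fr, lag = 1)
  ang <- dpd_angle(tp)
  expect_gt(mean(ang, na.rm = TRUE), 120)
  ## final-frame positions distribute like the endpoint simulator:
  ## two-sample KS on pooled leaf x over replicates
  xs_frames <- unlist(lapply(1:30, function(i) {
    f <- simulate_frames(tr, p, frame_interval = 1, seed = 100 + i)
    f$x[f$frame == 30]
  }))
  xs_end <- unlist(lapply(1:30, function(i) {
    simulate_locations(tr, p, seed = 300 + i)$x
  }))
  expect_gt(suppressWarnings(ks.test(xs_frames, xs_end))$p.value, 0.01)
})

test_that("fixtures round-trip through the readers with consistent truth", {
  d <- withr::local_tempdir()
  fx <- make_fixture(d, preset = "paper-default", seed = 42, n = 12)
  expect_true(all(file.exists(unlist(fx$paths))))
  tr <- read_newick(fx$paths$tree)
  mat <- read_character_matrix(fx$paths$matrix)
  loc <- read_locations(fx$paths$locations)
  vi <- validate_inputs(tr, mat, loc)
  expect_length(vi$diagnostics, 0L)
  truth <- jsonlite::read_json(fx$paths$truth, simplifyVector = TRUE)
  expect_equal(truth$sigma, 1.5)
  expect_equal(truth$r, 6.68)
  expect_equal(truth$K, 10)
  expect_equal(truth$lambda, 0.006)
  expect_identical(unname(mat), unname(fx$matrix[, , drop = FALSE]))
  ## sigma variants
  expect_equal(sim_preset("sigma-low")$sigma, 0.5)
  expect_equal(sim_preset("sigma-high")$sigma, 3.0)
  expect_error(sim_preset("nope"), "available")
  ## byte-identical regeneration under the same seed
  d2 <- withr::local_tempdir()
  make_fixture(d2, preset = "paper-default", seed = 42, n = 12)
  expect_identical(readLines(file.path(d2, "tree.nwk")),
                   readLines(fx$paths$tree))
  expect_identical(readLines(file.path(d2, "characters.csv")),
                   readLines(fx$paths$matrix))
})
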