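test_that("transition matrix has the irreversible structure and closed form", {
  site <- site_alphabet(2)
  p <- pmm_params(0.3, 0.1, 0)
  ## delta = 0 and rate-0 chains are the identity
  expect_equal(unname(transition_matrix(site, p, 0)), diag(4))
  expect_equal(unname(transition_matrix(site, pmm_params(0, 0, 0), 5)), diag(4))
  P <- transition_matrix(site, p, 0.7)
  expect_equal(rowSums(P), setNames(rep(1, 4), rownames(P)))
  ## irreversibility / non-modifiability / absorbing silence
  expect_equal(P["1", "0"], 0)
  expect_equal(P["1", "2"], 0)
  expect_equal(P["-1", "-1"], 1)
  ## M = 1 closed forms: no-return and independent silencing clock
  s1 <- site_alphabet(1)
  P1 <- transition_matrix(s1, p, 2)
  expect_equal(P1["0", "0"], exp(-(0.3 + 0.1) * 2))
  expect_equal(P1["1", "-1"], 1 - exp(-0.1 * 2))
  expect_equal(transition_matrix(s1, pmm_params(0.3, 0, 0), 2)["0", "1"],
               1 - exp(-0.3 * 2))
  expect_error(transition_matrix(site, p, -1), "delta")
})

test_that("transition matrix equals the matrix exponential of the generator", {
  skip_if_not_installed("Matrix")
  set.seed(5)
  for (i in 1:10) {
    M <- sample(1:3, 1)
    pi <- as.vector(stats::rgamma(M, 2)); pi <- pi / sum(pi)
    site <- site_alphabet(M, pi)
    p <- pmm_params(runif(1, 0, 1), runif(1, 0, 0.5), 0)
    d <- runif(1, 0, 4)
    P <- transition_matrix(site, p, d)
    Pexp <- as.matrix(Matrix::expm(sdlineage:::pmm_generator(site, p) * d))
    expect_equal(unname(P), unname(Pexp), tolerance = 1e-12)
    ## Chapman-Kolmogorov
    expect_equal(transition_matrix(site, p, d / 3) %*%
                   transition_matrix(site, p, 2 * d / 3), P,
                 tolerance = 1e-12)
  }
})

test_that("dropout emission table is the stated lookup", {
  site <- site_alphabet(2)
  E0 <- dropout_emission(site, 0)
  expect_equal(E0["2", "2"], 1); expect_equal(E0["2", "?"], 0)
  E <- dropout_emission(site, 0.1)
  expect_equal(E["2", "?"], 0.1)
  expect_equal(E["2", "2"], 0.9)
  expect_equal(E["2", "1"], 0)
  expect_equal(E["-1", "?"], 1) # silenced state is always unobserved
  expect_equal(rowSums(E), setNames(rep(1, 4), rownames(E)))
})

test_that("single-branch site likelihood has the closed form", {
  tr <- parse_newick("(A:3)r;")
  s1 <- site_alphabet(1)
  p <- pmm_params(0.2, 0.05, 0)
  expect_equal(site_loglik(tr, c(A = 0L), s1, p), -(0.2 + 0.05) * 3)
  ## no time, no events
  t0 <- parse_newick("(A:1e-12)r;")
  expect_equal(site_loglik(t0, c(A = 0L), s1, p), 0, tolerance = 1e-9)
})

test_that("all-missing columns marginalize correctly, -Inf when impossible", {
  tr <- cherry()
  site <- site_alphabet(2)
  ## phi = 0, nu = 0: '?' can only come from silencing, which cannot happen
  expect_identical(site_loglik(tr, c(A = NA, B = NA), site,
                               pmm_params(0.3, 0, 0)), -Inf)
  ## with silencing the column has the enumerable probability
  p <- pmm_params(0.3, 0.2, 0)
  expect_equal(site_loglik(tr, c(A = NA, B = NA), site, p),
               brute_force_site_loglik(tr, c(A = NA, B = NA), site, p),
               tolerance = 1e-10)
  ## with dropout, missing entries are cheap, likelihood close to 2*log-ish
  expect_gt(site_loglik(tr, c(A = NA, B = NA), site, pmm_params(0.3, 0, 0.5)),
            -Inf)
})

test_that("pruning agrees with the enumeration oracle on random small cases", {
  skip_if_not_installed("Matrix")
  set.seed(11)
  worst <- 0
  for (i in 1:40) {
    n <- sample(2:6, 1)
    tr <- rand_tree(n, tau = runif(1, 0.5, 5), seed = 500 + i)
    M <- sample(1:3, 1)
    site <- site_alphabet(M)
    p <- pmm_params(runif(1, 0.05, 1.5), runif(1, 0, 0.4), runif(1, 0, 0.5))
    col <- simulate_sequences(tr, p, K = 1, M = M, seed = 600 + i)[, 1L]
    a <- site_loglik(tr, col, site, p)
    b <- brute_force_site_loglik(tr, col, site, p)
    worst <- max(worst, abs(a - b) / max(abs(b), 1e-12))
  }
  expect_lt(worst, 1e-10)
  expect_error(
    brute_force_site_loglik(rand_tree(12, seed = 1),
                            rep(0L, 12), site_alphabet(1), pmm_params(0.1)),
    "too large")
})

test_that("matrix likelihood is additive over independent sites", {
  tr <- quartet()
  p <- pmm_params(0.4, 0.05, 0.1)
  mat <- simulate_sequences(tr, p, K = 6, M = 2, seed = 31)
  sites <- replicate(6, site_alphabet(2), simplify = FALSE)
  per <- sequence_loglik(tr, mat, p, sites = sites, per_site = TRUE)
  expect_equal(sequence_loglik(tr, mat, p, sites = sites), sum(per))
  ## K = 1 equals site_loglik; duplicated column doubles its contribution
  expect_equal(per[1L],
               site_loglik(tr, mat[, 1L], site_alphabet(2), p))
  dup <- cbind(mat, mat[, 1L])
  expect_equal(sequence_loglik(tr, dup, p, sites = c(sites, sites[1L])),
               sum(per) + per[1L])
})

test_that("likelihood is monotone in rates for an all-unmutated column", {
  tr <- quartet()
  site <- site_alphabet(2)
  col <- setNames(rep(0L, 4), leaf_names(tr))
  lams <- c(0.01, 0.05, 0.2, 1)
  ll <- vapply(lams, function(l) site_loglik(tr, col, site, pmm_params(l, 0, 0)), 1)
  expect_true(all(diff(ll) < 0))
  nus <- c(0, 0.1, 0.5)
  ll2 <- vapply(nus, function(nv) site_loglik(tr, col, site, pmm_params(0.1, nv, 0)), 1)
  expect_true(all(diff(ll2) < 0))
  ## longer tree, lower likelihood of staying unmutated
  tr2 <- tr; tr2$brlen <- tr$brlen * 2
  expect_lt(site_loglik(tr2, col, site, pmm_params(0.1, 0, 0)),
            site_loglik(tr, col, site, pmm_params(0.1, 0, 0)))
})

test_that("observed silent entries are treated as missing unless strict", {
  tr <- cherry()
  site <- site_alphabet(2)
  p <- pmm_params(0.3, 0.2, 0.1)
  expect_equal(site_loglik(tr, c(A = -1L, B = 1L), site, p),
               site_loglik(tr, c(A = NA, B = 1L), site, p))
  expect_error(site_loglik(tr, c(A = -1L, B = 1L), site, p,
                           strict_silent = TRUE), "unobservable")
})
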