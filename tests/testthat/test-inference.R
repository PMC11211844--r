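test_that("joint log-likelihood factorizes over modalities", {
  tr <- quartet()
  loc <- rand_locations(tr, seed = 21)
  p <- pmm_params(0.3, 0.02, 0.1)
  mat <- simulate_sequences(tr, p, K = 5, M = 2, seed = 22)
  sdp <- sd_params(1.2, r = 2, theta = theta_for_tree(tr, c(0.3, 1, 2)))
  lS <- joint_loglik(tr, mat = mat, pmm = p, modality = "S")
  lL <- joint_loglik(tr, locations = loc, sd = sdp, modality = "L")
  lSL <- joint_loglik(tr, mat, loc, sdp, p, modality = "S+L")
  expect_equal(lSL, lS + lL)
  ## location-only with r = 0 is the Brownian likelihood
  expect_equal(joint_loglik(tr, locations = loc,
                            sd = sd_params(1.2, r = 0), modality = "L"),
               brownian_loglik(tr, loc, 1.2))
  ## modality-L ignores the matrix entirely
  expect_equal(joint_loglik(tr, mat * 0L, loc, sdp, p, modality = "L"), lL)
  expect_error(joint_loglik(tr, modality = "L"), "locations")
})

test_that("node-time transform is a bijection onto valid ultrametric times", {
  for (seed in 1:6) {
    tr <- rand_tree(8, tau = 12, seed = 40 + seed)
    set.seed(seed)
    raw <- rnorm(length(sdlineage:::.free_internal(tr)), 0, 2)
    tt <- unconstrained_to_times(tr, raw, 12)
    expect_true(is_ultrametric(apply_node_times(tr, tt, 12), 12, tol = 0)$ultrametric)
    back <- times_to_unconstrained(tr, tt, 12)
    expect_equal(back, raw, tolerance = 1e-12)
  }
  ## the zero vector puts each internal node at its feasible midpoint
  tr <- cherry()
  tt <- unconstrained_to_times(tr, 0, 2)
  u <- which(tr$labels == "u")
  expect_equal(tt[u], 1)
})

test_that("analytic gradients match central finite differences", {
  tr <- rand_tree(8, tau = 40, seed = 71)
  loc <- simulate_locations(tr, sd_params(1.3, r = 4), seed = 72)
  mat <- simulate_sequences(tr, pmm_params(0.02, 0.005, 0.1), K = 4,
                            seed = 73)
  topo <- tr; topo$brlen[] <- NA
  for (modal in c("S+L", "S", "L")) {
    cfg <- model_config(modal, r = 4, tau_end = 40, restarts = 1, seed = 1)
    if (modal != "L") cfg$sites <- sdlineage:::infer_alphabets(mat)
    layout <- sdlineage:::.par_layout(topo, cfg)
    fn <- sdlineage:::.objective_factory(topo, mat, loc, cfg, layout)
    gr <- sdlineage:::.gradient_factory(topo, mat, loc, cfg, layout)
    set.seed(99)
    p <- sdlineage:::.start_point(topo, mat, loc, cfg, layout, 1) +
      rnorm(layout$total, 0, 0.2)
    ga <- gr(p)
    h <- 1e-5
    gn <- vapply(seq_along(p), function(j) {
      e <- replace(rep(0, length(p)), j, h)
      (fn(p + e) - fn(p - e)) / (2 * h)
    }, 1)
    expect_equal(ga, gn, tolerance = 1e-5)
  }
})

test_that("fitting is deterministic, respects the constraint, never worsens", {
  tr <- rand_tree(10, tau = 30, seed = 81)
  loc <- simulate_locations(tr, sd_params(1.5, r = 3), seed = 82)
  mat <- simulate_sequences(tr, pmm_params(0.02, 0, 0.05), K = 5, seed = 83)
  topo <- tr; topo$brlen[] <- NA
  cfg <- model_config("S+L", r = 3, tau_end = 30, restarts = 2, seed = 7,
                      fixed = list(nu = 0))
  f1 <- fit_lineage(topo, mat, loc, cfg)
  f2 <- fit_lineage(topo, mat, loc, cfg)
  expect_identical(f1$loglik, f2$loglik)
  expect_identical(f1$tree$brlen, f2$tree$brlen)
  expect_identical(f1$sigma, f2$sigma)
  ## exact ultrametricity of the output
  expect_true(is_ultrametric(f1$tree, 30, tol = 0)$ultrametric)
  ## no restart ends below its start
  expect_true(all(f1$restarts$final_loglik >= f1$restarts$start_loglik - 1e-9))
  ## reported log-likelihood re-evaluates to the same value
  sdp <- sd_params(f1$sigma_ml, r = 3, theta = f1$theta,
                   x0 = f1$x0, y0 = f1$y0)
  re <- sd_loglik(f1$tree, loc, sdp, floor = cfg$floor * 30) +
    sequence_loglik(f1$tree, mat, pmm_params(f1$lambda, 0, f1$phi))
  expect_equal(re, f1$loglik, tolerance = 1e-8)
  ## fast-vs-dense cross-check at the optimum was recorded and is tiny
  expect_lt(f1$dense_check, 1e-8)
})

test_that("single-modality fits ignore the other data source", {
  tr <- rand_tree(8, tau = 30, seed = 91)
  loc <- simulate_locations(tr, sd_params(1.5, r = 0), seed = 92)
  mat <- simulate_sequences(tr, pmm_params(0.03, 0, 0.05), K = 5, seed = 93)
  topo <- tr; topo$brlen[] <- NA
  cfgS <- model_config("S", tau_end = 30, restarts = 1, seed = 2,
                       fixed = list(nu = 0))
  fS1 <- fit_lineage(topo, mat, NULL, cfgS)
  fS2 <- fit_lineage(topo, mat, rand_locations(tr, seed = 94), cfgS)
  expect_equal(fS1$loglik, fS2$loglik)
  expect_true(is.na(fS1$sigma))
  cfgL <- model_config("L", r = 0, tau_end = 30, restarts = 1, seed = 2)
  fL1 <- fit_lineage(topo, NULL, loc, cfgL)
  mat2 <- mat; mat2[] <- 0L
  fL2 <- fit_lineage(topo, mat2, loc, cfgL)
  expect_equal(fL1$loglik, fL2$loglik)
  expect_true(is.na(fL1$lambda))
})

test_that("r sweep refits at each grid value and reports per-r results", {
  tr <- rand_tree(8, tau = 30, seed = 95)
  loc <- simulate_locations(tr, sd_params(1.5, r = 3), seed = 96)
  topo <- tr; topo$brlen[] <- NA
  cfg <- model_config("L", r = 3, tau_end = 30, restarts = 1, seed = 5)
  fits <- fit_r_sweep(topo, NULL, loc, cfg, r_values = c(0, 3, 6))
  expect_named(fits, c("0", "3", "6"))
  expect_equal(vapply(fits, function(f) f$r, 1), c("0" = 0, "3" = 3, "6" = 6))
  rep <- r_sweep_report(fits, tr, 1.5)
  expect_equal(nrow(rep$table), 3L)
  expect_true(rep$r_opt %in% c(0, 3, 6))
  expect_error(r_sweep_report(fits[1:2], tr, 1.5), "3 r values")
})
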