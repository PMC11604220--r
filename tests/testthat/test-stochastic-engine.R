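test_that("fixed seed gives bit-identical results; seeds matter", {
  r <- default_rates("TFO")
  arch <- reduced_arch()
  p1 <- simulate_population(r, arch, quick_cfg(seed = 42))
  p2 <- simulate_population(r, arch, quick_cfg(seed = 42))
  p3 <- simulate_population(r, arch, quick_cfg(seed = 43))
  expect_identical(p1$mean, p2$mean)
  expect_identical(p1$events, p2$events)
  expect_false(identical(p1$mean, p3$mean))
})

test_that("a single-gene run equals gene 1 of the population", {
  r <- default_rates("TFO")
  arch <- reduced_arch()
  cfg1 <- sim_config(n_genes = 1, seed = 9)
  p <- simulate_population(r, arch, cfg1)
  g <- simulate_gene(r, arch, cfg1, gene_index = 1)
  expect_identical(unname(p$mean), unname(g$occupancy))
  expect_true(all(is.na(p$se)))  # no degrees of freedom at n = 1
})

test_that("pure recruitment makes the promoter an absorbing occupied state", {
  r <- rate_set(k3 = 0.05, gene_class = "TFO")  # all other rates zero
  arch <- reduced_arch()
  p <- simulate_population(r, arch, quick_cfg(n_genes = 500, seed = 2))
  # recruitment precedes the window w.h.p. (mean wait 20 s << 940 s)
  expect_gt(p$mean[["promoter"]], 0.999)
  expect_equal(p$events$terminations, 0)
  expect_equal(p$mean[["terminator"]], 0)
})

test_that("two-state promoter equilibrium matches the closed form", {
  r <- rate_set(k3 = 0.002, k_rev3 = 0.002, k4 = 0, k5 = 0.1, k7 = 0.0325,
                gene_class = "TFO")
  arch <- reduced_arch()
  o <- ctmc_stationary_occupancy(r, arch)
  expect_equal(o[["promoter"]], 0.5, tolerance = 1e-12)
  # measure late so the window samples stationarity (relaxation time 250 s)
  cfg <- sim_config(t_total = 3000, measure_window = c(2940, 3000),
                    n_genes = 10000, seed = 1)
  p <- simulate_population(r, arch, cfg)
  expect_lt(abs(p$mean[["promoter"]] - 0.5), 3 * p$se[["promoter"]])
})

test_that("no initiation means exactly empty transcript and terminator", {
  r <- default_rates("TFO", k5 = 0)
  p <- simulate_population(r, reduced_arch(), quick_cfg(seed = 5))
  expect_identical(unname(p$mean[c("bin_1", "bin_2", "terminator")]),
                   c(0, 0, 0))
})

test_that("standard errors shrink like 1/sqrt(n)", {
  r <- default_rates("TFO")
  arch <- reduced_arch()
  p1 <- simulate_population(r, arch, sim_config(n_genes = 4000, seed = 21))
  p2 <- simulate_population(r, arch, sim_config(n_genes = 8000, seed = 22))
  ratio <- p2$se[["promoter"]] / p1$se[["promoter"]]
  expect_gt(ratio, (1 / sqrt(2)) * 0.8)
  expect_lt(ratio, (1 / sqrt(2)) * 1.2)
})

test_that("the pure-R reference engine agrees with the exact oracle", {
  r <- default_rates("TFO")
  arch <- reduced_arch()
  o <- ctmc_stationary_occupancy(r, arch)
  p <- simulate_population(r, arch, sim_config(n_genes = 300, seed = 7),
                           engine = "reference")
  expect_true(all(abs(oracle_z(p, o)) < 3.5))
})

test_that("stationary oracle is a probability distribution with balanced flux", {
  r <- default_rates("TFO")
  arch <- reduced_arch()
  o <- ctmc_stationary_occupancy(r, arch)
  probs <- attr(o, "probs")
  expect_true(all(probs >= 0))
  expect_equal(sum(probs), 1, tolerance = 1e-10)
  f <- stationary_fluxes(o, r)
  expect_lt(abs(f[["initiation"]] - f[["termination"]]), 1e-10)
  expect_true(all(as.numeric(o) >= 0 & as.numeric(o) <= 1))
})

test_that("the oracle refuses oversized state spaces, naming the cap", {
  arch <- gene_architecture(n_transcript_bins = 10)
  err <- tryCatch(
    ctmc_stationary_occupancy(default_rates("TFO"), arch, max_states = 100),
    error = function(e) conditionMessage(e))
  expect_match(err, "6144")
})

test_that("stationary occupancy responds monotonically to rates", {
  arch <- reduced_arch()
  proms <- vapply(c(0.005, 0.015, 0.03), function(kr3)
    ctmc_stationary_occupancy(default_rates("TFO", k_rev3 = kr3),
                              arch)[["promoter"]], numeric(1))
  expect_true(all(diff(proms) < 0))  # more dissociation, less occupancy

  arch_s <- reduced_arch(has_uas = TRUE)
  uas <- vapply(c(0.001, 0.002, 0.004), function(k1)
    ctmc_stationary_occupancy(default_rates("STM", k1 = k1),
                              arch_s)[["UAS"]], numeric(1))
  expect_true(all(diff(uas) > 0))
})

test_that("window termination flux matches k7 times terminator occupancy", {
  r <- default_rates("TFO")
  arch <- reduced_arch()
  p <- simulate_population(r, arch, sim_config(n_genes = 10000, seed = 12))
  flux <- p$events$window_terminations / (10000 * 60)
  se <- sqrt(max(p$events$window_terminations, 1)) / (10000 * 60) +
    r$k7 * p$se[["terminator"]]
  expect_lt(abs(flux - r$k7 * p$mean[["terminator"]]), 3 * se)
})
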