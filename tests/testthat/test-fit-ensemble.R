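test_that("region aggregation copies singles and averages transcript bins", {
  prof <- make_profile(c(promoter = 0.5, bin_1 = 0.1, bin_2 = 0.1,
                         bin_3 = 0.1, terminator = 0.3))
  rv <- aggregate_regions(prof, "TFO")
  expect_equal(unname(rv$values), c(0.5, 0.1, 0.3))

  prof2 <- make_profile(c(promoter = 0.5, bin_1 = 0.2, bin_2 = 0,
                          bin_3 = 0, bin_4 = 0, bin_5 = 0, bin_6 = 0,
                          bin_7 = 0, bin_8 = 0, bin_9 = 0, bin_10 = 0,
                          terminator = 0.3))
  expect_equal(aggregate_regions(prof2, "TFO")$values[["transcript"]], 0.02)

  expect_error(aggregate_regions(prof, "STM"), "UAS")
  prof3 <- make_profile(c(UAS = 0.1, promoter = 0.5, bin_1 = 0.1,
                          terminator = 0.3))
  expect_error(aggregate_regions(prof3, "TFO"), "UAS")
  expect_equal(unname(aggregate_regions(prof3, "STM")$values),
               c(0.1, 0.5, 0.1, 0.3))
})

test_that("cosine similarity follows the exact formula", {
  expect_equal(cosine_similarity(c(1, 2, 2), c(2, 4, 4)), 1)
  expect_equal(cosine_similarity(c(1, 0, 0), c(0, 1, 0)), 0)
  expect_equal(cosine_similarity(c(1, 1), c(1, 0)), 1 / sqrt(2))
  expect_error(cosine_similarity(c(0, 0), c(1, 1)), "zero vector")
  a <- region_vector(c(promoter = 1, transcript = 2, utr3 = 3), "TFO")
  b <- region_vector(c(promoter = 2, transcript = 4, utr3 = 6), "TFO")
  expect_equal(cosine_similarity(a, b), 1)
})

test_that("L2 scaling matches empirical magnitude, preserving similarity", {
  expect_equal(l2_scale(c(3, 4), c(6, 8)), c(6, 8))
  expect_equal(l2_scale(c(3, 4), c(10, 0)), c(6, 8))
  v <- c(1.5, 2.5, 9)
  expect_equal(l2_scale(v, v), v)
  expect_error(l2_scale(c(0, 0), c(1, 1)), "zero")
  set.seed(31)
  for (i in 1:25) {
    m <- runif(4); e <- runif(4)
    s <- l2_scale(m, e)
    expect_equal(sqrt(sum(s^2)), sqrt(sum(e^2)), tolerance = 1e-12)
    expect_equal(cosine_similarity(s, e), cosine_similarity(m, e),
                 tolerance = 1e-12)
  }
})

test_that("fit configuration rejects invalid thresholds and ranges", {
  expect_error(fit_config("TFO", threshold = 1.0001), "threshold")
  expect_error(fit_config("TFO", resolution = 1), "resolution")
  expect_error(fit_config("TFO", ranges = list(k_rev3 = c(0, 0.03))),
               "free rates")
  expect_error(fit_config("TFO",
                          ranges = list(k_rev3 = c(0.03, 0), k4 = c(0, 1))),
               "lower")
})

test_that("grid search recovers the generating rates from a noise-free target", {
  truth <- default_rates("TFO", k_rev3 = 0.0225, k4 = 0.0125)
  sv <- synth_region_vectors(truth, cfg = sim_config(n_genes = 8000, seed = 11),
                             noise = noise_spec("none"))
  cfg <- fit_config("TFO", resolution = 5,
                    sim = sim_config(n_genes = 4000, seed = 5))
  ens <- grid_search(sv$truth$scaled, cfg)
  expect_false(ens$fallback)
  expect_true(any(abs(ens$entries$k_rev3 - 0.0225) < 1e-12 &
                    abs(ens$entries$k4 - 0.0125) < 1e-12))
  expect_true(all(ens$entries$score >= 0.995))
  expect_true(all(diff(ens$entries$score) <= 0))  # sorted by score
  expect_gte(cosine_similarity(ens$average, sv$truth$scaled), 0.995)

  # membership is invariant under rescaling of the empirical vector
  scaled_emp <- region_vector(sv$truth$scaled$values * 7.3, "TFO",
                              units = "pseudo-CPMn")
  ens2 <- grid_search(scaled_emp, cfg)
  expect_equal(ens2$entries$score, ens$entries$score, tolerance = 1e-12)
})

test_that("unreachable target shapes trigger the fallback ensemble", {
  # transcript-dominated, promoter-depleted shape (ChIP-like)
  emp <- region_vector(c(promoter = 0.02, transcript = 1, utr3 = 0.1), "TFO",
                       units = "CPMn")
  cfg <- fit_config("TFO", resolution = 3, fallback_top_n = 4,
                    sim = sim_config(n_genes = 1500, seed = 3))
  ens <- grid_search(emp, cfg)
  expect_true(ens$fallback)
  expect_equal(nrow(ens$entries), 4)
  expect_true(all(ens$entries$score < 0.995))
})

test_that("perturbation scenarios validate rates and resolve presets", {
  expect_error(perturbation_scenario("x", list(k9 = 1)), "unknown rate")
  expect_error(preset_scenario("tfiib-20min", "TFO", 9), "models 1")
  expect_error(preset_scenario("gcn4-pd", "TFO"), "no TFO models")
  sc <- preset_scenario("tfiib-20min", "TFO", 1)
  expect_equal(sc$replacements$k3, 0.0008)
  sc2 <- preset_scenario("kin28-cmk", "STM", 2)
  expect_equal(sc2$replacements$k5, 0.02)
  expect_equal(sc2$replacements$k_rev3, c(0, 0.24))
  expect_equal(preset_scenario("gcn4-null", "STM")$replacements$k1, 0.0006)
})

test_that("identity perturbation changes nothing; scores behave", {
  truth <- default_rates("TFO", k_rev3 = 0.0225, k4 = 0.0125)
  sv <- synth_region_vectors(truth, cfg = sim_config(n_genes = 4000, seed = 11),
                             noise = noise_spec("none"))
  cfg <- fit_config("TFO", resolution = 3,
                    sim = sim_config(n_genes = 2000, seed = 5))
  ens <- grid_search(sv$truth$scaled, cfg)
  d0 <- apply_perturbation(ens, perturbation_scenario("identity", list()),
                           max_members = 3)
  expect_equal(max(abs(d0$delta_mean)), 0, tolerance = 1e-12)

  expect_equal(score_perturbation_fit(c(-1, -2, -1), c(-2, -4, -2)), 1)
  expect_equal(score_perturbation_fit(c(1, 2, 1), c(-1, -2, -1)), -1)
  expect_error(score_perturbation_fit(c(0, 0, 0), c(1, 1, 1)), "zero")
})

test_that("replicate noise widens the recovered parameter range", {
  truth <- default_rates("TFO", k_rev3 = 0.015, k4 = 0.0175)
  widths <- vapply(c(0.02, 0.35), function(amp) {
    sv <- synth_region_vectors(truth,
                               cfg = sim_config(n_genes = 6000, seed = 13),
                               noise = noise_spec("gaussian-on-regions",
                                                  amplitude = amp,
                                                  n_replicates = 3,
                                                  seed = 17))
    cfg <- fit_config("TFO", resolution = 5, threshold = 0.995,
                      fallback_top_n = 25,
                      sim = sim_config(n_genes = 4000, seed = 5))
    ens <- grid_search(sv$mean, cfg)
    diff(range(ens$entries$k_rev3))
  }, numeric(1))
  expect_gte(widths[2], widths[1])
})
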