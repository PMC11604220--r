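test_that("rate sets enforce class-specific structure and validity", {
  r <- rate_set(k1 = 0.1, k2 = 0.05, k3 = 0.002, gene_class = "TFO")
  expect_equal(r$k1, 0)   # UAS rates unused for TFO
  expect_equal(r$k2, 0)
  expect_equal(r$k3, 0.002)

  s <- rate_set(k1 = 0.002, k3 = 0.5, gene_class = "STM")
  expect_equal(s$k3, 0)   # direct recruitment unused for STM
  expect_equal(s$k1, 0.002)

  expect_error(rate_set(k3 = -1, gene_class = "TFO"), "non-negative")
  expect_error(rate_set(k5 = Inf, gene_class = "TFO"), "finite")

  # elongation stored in bp/s from the bp/min user unit
  expect_equal(rate_set(k6_bp_min = 1000, gene_class = "TFO")$k6, 1000 / 60)
})

test_that("hop rate converts bp/min to per-compartment /s", {
  expect_equal(hop_rate(1000, 120), 1000 / 60 / 120)
  expect_equal(round(hop_rate(1000, 120), 5), 0.13889)
  expect_equal(round(hop_rate(3000, 120), 5), 0.41667)
  expect_error(hop_rate(1000, 0), "positive")
  expect_error(hop_rate(-5, 120), "positive")
})

test_that("published presets carry the standard-growth rates and ranges", {
  r <- default_rates("TFO")
  expect_equal(r$k3, 0.002)
  expect_equal(r$k5, 0.1)
  expect_equal(r$k7, 0.0325)
  expect_equal(r$k6_bp_min, 1000)
  # free rates default to functional-range midpoints
  expect_equal(r$k_rev3, 0.015)
  expect_equal(r$k4, 0.0175)
  fr <- functional_ranges("STM", "chec")
  expect_named(fr, c("k2", "k_rev2", "k_rev3", "k4"))
  expect_equal(fr$k2, c(0.03, 0.1))
  expect_named(functional_ranges("TFO"), c("k_rev3", "k4"))
  chip <- chip_forced_rates("TFO")
  expect_equal(chip$k_rev3, 0)
  expect_equal(chip$k5, 0.2)
  expect_equal(chip$k7, 0.14)
})

test_that("transitions from an empty TFO gene are recruitment only", {
  r <- default_rates("TFO")
  arch <- default_architecture("TFO")
  st <- transcription_state(arch, "TFO")
  tr <- list_transitions(st, r, arch)
  expect_equal(tr$event, "promoter_recruit")
  expect_equal(tr$propensity, 0.002)
})

test_that("a pre-TFIIH promoter can only dissociate or mature", {
  r <- default_rates("TFO")
  arch <- default_architecture("TFO")
  st <- transcription_state(arch, "TFO")
  st$promoter_state <- "PRE"
  tr <- list_transitions(st, r, arch)
  expect_setequal(tr$event, c("promoter_dissociate", "tfiih_arrival"))
  expect_equal(tr$propensity[tr$event == "promoter_dissociate"], r$k_rev3)
  expect_equal(tr$propensity[tr$event == "tfiih_arrival"], r$k4)
})

test_that("commitment after TFIIH: no dissociation or reversal from POST", {
  arch <- default_architecture("STM")
  r <- default_rates("STM")
  st <- transcription_state(arch, "STM")
  st$promoter_state <- "POST"
  tr <- list_transitions(st, r, arch)
  expect_false(any(tr$event %in% c("promoter_dissociate", "promoter_to_uas")))
  expect_true("initiation" %in% tr$event)
})

test_that("exclusion removes blocked moves from the transition set", {
  r <- default_rates("TFO")
  arch <- default_architecture("TFO")
  st <- transcription_state(arch, "TFO")
  st$promoter_state <- "POST"
  st$transcript_occupancy[1] <- TRUE
  tr <- list_transitions(st, r, arch)
  expect_false("initiation" %in% tr$event)
  # hop out of bin 1 present at k6 / compartment_length; blocked if bin 2 full
  expect_true("hop_1" %in% tr$event)
  expect_equal(tr$propensity[tr$event == "hop_1"],
               r$k6 / arch$compartment_length)
  st$transcript_occupancy[2] <- TRUE
  tr2 <- list_transitions(st, r, arch)
  expect_false("hop_1" %in% tr2$event)

  # occupied UAS blocks further recruitment (STM)
  archs <- default_architecture("STM")
  rs <- default_rates("STM")
  sts <- transcription_state(archs, "STM")
  sts$uas_occupied <- TRUE
  trs <- list_transitions(sts, rs, archs)
  expect_false("uas_recruit" %in% trs$event)
})

test_that("state, rates and architecture must be mutually consistent", {
  expect_error(transcription_state(default_architecture("STM"), "TFO"), "UAS")
  expect_error(transcription_state(default_architecture("TFO"), "STM"), "UAS")
  arch <- default_architecture("TFO")
  st <- transcription_state(arch, "TFO")
  expect_error(list_transitions(st, default_rates("STM"), arch), "UAS")
  bad <- st; bad$transcript_occupancy <- logical(3)
  expect_error(
    list_transitions(bad, default_rates("TFO"),
                     gene_architecture(n_transcript_bins = 10)),
    "architecture")
})

test_that("apply_event moves polymerase and guards exclusion", {
  arch <- reduced_arch()
  st <- transcription_state(arch, "TFO")
  st <- apply_event(st, "promoter_recruit")
  expect_equal(st$promoter_state, "PRE")
  st <- apply_event(st, "tfiih_arrival")
  st <- apply_event(st, "initiation")
  expect_equal(st$promoter_state, "EMPTY")
  expect_true(st$transcript_occupancy[1])
  st <- apply_event(st, "hop_1")
  st <- apply_event(st, "hop_2")
  expect_true(st$terminator_occupied)
  st2 <- apply_event(st, "terminator_release")
  expect_false(st2$terminator_occupied)
  # driving a second polymerase into an occupied compartment fails loudly
  st$transcript_occupancy[2] <- TRUE
  expect_error(apply_event(st, "hop_2"), "exclusion")
  expect_error(apply_event(st, "unheard_of"), "unknown event")
})

test_that("zero total propensity arises only in absorbing states", {
  # promoter occupied pre-TFIIH with dissociation and maturation switched off
  r <- rate_set(k3 = 0.002, k_rev3 = 0, k4 = 0, k5 = 0.1, k7 = 0.03,
                gene_class = "TFO")
  arch <- reduced_arch()
  st <- transcription_state(arch, "TFO")
  st$promoter_state <- "PRE"
  tr <- list_transitions(st, r, arch)
  expect_equal(sum(tr$propensity), 0)
  # but any enabled event keeps the chain alive
  st$promoter_state <- "POST"
  expect_gt(sum(list_transitions(st, r, arch)$propensity), 0)
})
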