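test_that("noiseless construction peaks exactly at the planted phase", {
  p <- rhythm_sim_params(n_transcripts = 2, frac_rhythmic = 1,
                         noise_sd = 0, seed = 1)
  sim <- simulate_nascent_pair(p, phases = c(8, 6))
  # transcript 1 peaks at CT8, a grid point of dataset A (0, 4, ..., 44)
  va <- sim$dataset_a$values[1, ]
  expect_equal(unname(which(va == max(va))),
               which(sim$dataset_a$time %% 24 == 8))
  # transcript 2 peaks at CT6, a grid point of dataset B (0, 3, ..., 21)
  vb <- sim$dataset_b$values[2, ]
  expect_equal(unname(which.max(vb)), which(sim$dataset_b$time == 6))
  expect_equal(sim$truth$phase, c(8, 6))
})

test_that("frac_rhythmic = 0 plants no rhythm", {
  sim <- simulate_nascent_pair(rhythm_sim_params(n_transcripts = 50,
                                                 frac_rhythmic = 0,
                                                 seed = 2))
  expect_false(any(sim$truth$rhythmic))
  expect_true(all(sim$truth$amplitude_a == 0))
})

test_that("simulators are deterministic given params and seed", {
  p <- rhythm_sim_params(n_transcripts = 30, seed = 17)
  s1 <- simulate_nascent_pair(p)
  s2 <- simulate_nascent_pair(p)
  expect_identical(s1, s2)
  o <- oe_sim_params(n_genes = 40, seed = 17)
  expect_identical(simulate_overexpression(o), simulate_overexpression(o))
  b1 <- simulate_binding(n_transcripts = 40, seed = 17)
  b2 <- simulate_binding(n_transcripts = 40, seed = 17)
  expect_identical(b1$calls, b2$calls)
})

test_that("simulated expression is positive with phases in [0, 24)", {
  sim <- simulate_nascent_pair(rhythm_sim_params(n_transcripts = 100,
                                                 frac_rhythmic = 0.5,
                                                 noise_sd = 0.4, seed = 3))
  expect_true(all(sim$dataset_a$values > 0))
  expect_true(all(sim$dataset_b$values > 0))
  ph <- sim$truth$phase[sim$truth$rhythmic]
  expect_true(all(ph >= 0 & ph < 24))
})

test_that("parameter validation rejects degenerate designs", {
  expect_error(rhythm_sim_params(n_points = 3), "underdetermined")
  expect_error(rhythm_sim_params(frac_rhythmic = 1.2))
  expect_error(rhythm_sim_params(noise_sd = -1))
  expect_error(oe_sim_params(reps_per_cell = 1), "residual df")
  p <- rhythm_sim_params(n_transcripts = 3, frac_rhythmic = 1)
  expect_error(simulate_nascent_pair(p, amplitudes = 1.2), "negative")
})

test_that("mature series is an attenuated, delayed copy of the primary", {
  p <- rhythm_sim_params(n_transcripts = 10, frac_rhythmic = 1, seed = 8)
  sim <- simulate_nascent_pair(p)
  # k = omega: attenuation 1/sqrt(2), lag = period/8 = 3 h
  hl <- 24 * log(2) / (2 * pi)
  mat <- simulate_mature(sim$truth, half_life = hl, sampling_step = 2,
                         n_points = 12, reps = 1, noise_sd = 0, seed = 8)
  fits <- fit_cosine_matrix(mat)
  a_m <- fits$amplitude / fits$mesor
  expect_equal(a_m, sim$truth$amplitude_a / sqrt(2), tolerance = 1e-6)
  expect_equal(circular_diff(fits$phase, sim$truth$phase),
               rep(3, 10), tolerance = 1e-6)
  # attenuation <= 1 always: mature never oscillates harder than primary
  mat119 <- simulate_mature(sim$truth, half_life = 119, noise_sd = 0,
                            seed = 8)
  f119 <- fit_cosine_matrix(mat119)
  expect_true(all(f119$amplitude / f119$mesor <=
                    sim$truth$amplitude_a + 1e-9))
  # fast turnover limit: mature tracks the primary (attenuation -> 1)
  mat0 <- simulate_mature(sim$truth, half_life = 1e-4, sampling_step = 2,
                          n_points = 12, reps = 1, noise_sd = 0, seed = 8)
  f0 <- fit_cosine_matrix(mat0)
  expect_equal(f0$amplitude / f0$mesor, sim$truth$amplitude_a,
               tolerance = 1e-6)
  expect_equal(circular_diff(f0$phase, sim$truth$phase), rep(0, 10),
               tolerance = 1e-3)
})

test_that("null over-expression design gives uniform treatment p-values", {
  sim <- simulate_overexpression(oe_sim_params(
    n_genes = 1000, frac_treatment_affected = 0, frac_time_affected = 0,
    seed = 4))
  av <- two_way_anova(sim$expression)
  expect_gt(ks.test(av$p_treatment, "punif")$p.value, 0.01)
  rej <- mean(av$p_treatment < 0.05)
  expect_gt(rej, 0.02)
  expect_lt(rej, 0.09)
})

test_that("target annotation is independent of repression when odds = 1", {
  sim <- simulate_overexpression(oe_sim_params(
    n_genes = 3000, target_enrichment = 1, seed = 6))
  under <- !is.na(sim$truth$treatment_direction) &
    sim$truth$treatment_direction == "under"
  enr <- fisher_enrichment(sum(sim$truth$is_target & under), sum(under),
                           sum(sim$truth$is_target & !under), sum(!under))
  expect_gt(enr$p_value, 0.01)
  expect_lt(abs(log2(enr$odds_ratio)), 0.6)
})

test_that("planted over-expression truth is internally consistent", {
  sim <- simulate_overexpression(oe_sim_params(n_genes = 500,
                                               frac_ra_shift = 0.3,
                                               seed = 7))
  tr <- sim$truth
  both <- tr$treatment_affected & tr$time_affected
  expect_true(all((tr$group != "none") == both))
  expect_true(all(tr$gene[tr$is_target] %in% sim$targets))
  # group definitions follow peak side x direction
  gI <- tr$group == "I"
  expect_true(all(tr$time_direction[gI] == "CT10>CT22"))
  expect_true(all(tr$treatment_direction[gI] == "under"))
  gIV <- tr$group == "IV"
  expect_true(all(tr$time_direction[gIV] == "CT10<CT22"))
  expect_true(all(tr$treatment_direction[gIV] == "over"))
})

test_that("binding simulation respects windows and the null case", {
  b <- simulate_binding(n_transcripts = 60, enrichment_odds = 1, seed = 9)
  edges <- assign_regulators(b$transcripts, b$calls)
  circ <- b$transcripts$transcript_id[b$transcripts$circadian]
  allt <- b$transcripts$transcript_id
  enr <- binding_enrichment(circ, allt, edges, "CLOCK")
  expect_gt(enr$p_value, 0.05)
  # peaks all placed outside every window yield no edges
  far <- GenomicRanges::shift(b$calls, 2e8)
  expect_equal(nrow(assign_regulators(b$transcripts, far)), 0L)
})

test_that("planted binding enrichment is detected reliably", {
  hits <- 0L
  for (s in 1:100) {
    b <- simulate_binding(n_transcripts = 400, enrichment_odds = 5,
                          regulators = "BMAL1", seed = 1000 + s)
    edges <- assign_regulators(b$transcripts, b$calls)
    circ <- b$transcripts$transcript_id[b$transcripts$circadian]
    enr <- binding_enrichment(circ, b$transcripts$transcript_id, edges,
                              "BMAL1")
    hits <- hits + (enr$p_value < 0.05)
  }
  expect_gte(hits, 95)
})
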