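test_that("epoch simulation is a pure function of (config, seed)", {
  cfg <- sim_config(n_subjects = 2, n_epochs_per_class = 5, mesh_level = 0,
                    epoch_ms = c(0, 50))
  a <- simulate_epochs(cfg, "two_word", "s01")
  b <- simulate_epochs(cfg, "two_word", "s01")
  expect_identical(a$data, b$data)
  # different subject or paradigm gives different draws
  c1 <- simulate_epochs(cfg, "two_word", "s02")
  c2 <- simulate_epochs(cfg, "naturalistic", "s01")
  expect_false(identical(a$data, c1$data))
  expect_false(identical(a$data, c2$data))
})

test_that("default epoch grid is 175 samples at 5 ms steps over [0, 875)", {
  cfg <- sim_config(n_subjects = 2, n_epochs_per_class = 2, mesh_level = 0)
  es <- simulate_epochs(cfg, "two_word", "s01")
  expect_identical(dim(es$data)[3], 175L)
  expect_equal(es$time_ms, seq(0, 870, by = 5))
  expect_true(all(diff(es$time_ms) == 5))
  expect_true(all(is.finite(es$data)))
  expect_identical(as.vector(table(es$labels)), c(2L, 2L))
})

test_that("injected effect reproduces the generative mean difference", {
  verts <- 1:6
  cfg <- sim_config(n_subjects = 2, n_epochs_per_class = 100,
                    mesh_level = 0, epoch_ms = c(0, 100),
                    effects = list(two_word = list(
                      effect_spec(verts, c(20, 60), amplitude = 5,
                                  pattern_seed = 7))))
  es <- simulate_epochs(cfg, "two_word", "s01")
  pattern <- crossdecode:::unit_pattern(6, 7L)
  v <- which.max(abs(pattern))
  ti <- which(es$time_ms == 40)
  diff_emp <- mean(es$data[es$labels == "phrase", v, ti]) -
    mean(es$data[es$labels == "noun", v, ti])
  expect_lt(abs(diff_emp - 5 * pattern[v]), abs(0.1 * 5 * pattern[v]) + 0.1)
  # outside the window the class difference is pure noise
  to <- which(es$time_ms == 90)
  diff_out <- mean(es$data[es$labels == "phrase", v, to]) -
    mean(es$data[es$labels == "noun", v, to])
  expect_lt(abs(diff_out), 0.5)
  # effect vertices outside the mask are a configuration error
  bad <- sim_config(n_subjects = 2, n_epochs_per_class = 5, mesh_level = 0,
                    mask_regions = "LATL",
                    effects = list(two_word = list(
                      effect_spec(1:12, c(20, 60), 1))))
  expect_error(simulate_epochs(bad, "two_word", "s01"), "outside")
})

test_that("null simulation gives ~5% rejections for the two-sample t", {
  cfg <- sim_config(n_subjects = 2, n_epochs_per_class = 30, mesh_level = 0,
                    epoch_ms = c(0, 250), spatial_smoothing_passes = 0,
                    temporal_ar1_phi = 0)
  es <- simulate_epochs(cfg, "two_word", "s01")
  p <- vapply(seq_along(es$time_ms), function(t)
    t.test(es$data[es$labels == "phrase", 1, t],
           es$data[es$labels == "noun", 1, t])$p.value, numeric(1))
  expect_lt(mean(p < 0.05), 0.2)   # 50 null tests, generous binomial bound
})

test_that("confound simulation shifts the regressor and loads on the epochs", {
  cfg <- sim_config(n_subjects = 2, n_epochs_per_class = 200,
                    mesh_level = 0, epoch_ms = c(0, 100),
                    confounds = list(confound_spec(
                      "surprisal", class_shift = 1.5,
                      loading_vertices = 1:4,
                      loading_window_ms = c(50, 90), loading_gain = 3,
                      pattern_seed = 11)))
  out <- simulate_naturalistic_with_confounds(cfg, "s01")
  tab <- out$table
  expect_identical(nrow(tab), 400L)
  expect_identical(tab$word_id, out$epochs$word_ids)
  lab <- out$epochs$labels
  shift <- mean(tab$surprisal[lab == "phrase"]) -
    mean(tab$surprisal[lab == "noun"])
  expect_lt(abs(shift - 1.5), 0.35)
  # loading: epochs correlate with the z-scored regressor inside the window
  pattern <- crossdecode:::unit_pattern(4, 11L)
  v <- which.max(abs(pattern))
  ti <- which(out$epochs$time_ms == 70)
  r_in <- cor(out$epochs$data[, v, ti], tab$surprisal)
  to <- which(out$epochs$time_ms == 20)
  r_out <- cor(out$epochs$data[, v, to], tab$surprisal)
  expect_gt(abs(r_in), 0.5)
  expect_lt(abs(r_out), 0.2)
  expect_error(confound_spec("no_such_regressor"), "unknown regressor")
})

test_that("word tables have ordered non-overlapping intervals", {
  wt <- simulate_word_table(50, n_sentences = 7, seed = 3)
  expect_identical(nrow(wt), 50L)
  expect_equal(wt$onset_ms[1], 0)
  expect_true(all(diff(wt$onset_ms) > 0))
  ends <- wt$onset_ms + wt$duration_ms
  expect_true(all(wt$onset_ms[-1] >= ends[-50] - 1e-9))
  expect_true(all(wt$duration_ms >= 150 & wt$duration_ms <= 600))
  expect_true(all(wt$n_letters >= 2 & wt$n_letters <= 10))
  expect_identical(sort(unique(wt$sentence_index)), 1:7)
  expect_identical(wt, simulate_word_table(50, 7, seed = 3))
  w1 <- simulate_word_table(1, 1, seed = 1)
  expect_equal(w1$onset_ms, 0)
})

test_that("prosody frames cover the span and record their own maxima", {
  wt <- simulate_word_table(20, 4, seed = 5)
  pf <- simulate_prosody_frames(wt, frame_ms = 10, seed = 6)
  span <- max(wt$onset_ms + wt$duration_ms)
  expect_identical(nrow(pf$frames), as.integer(ceiling(span / 10)))
  peaks <- peak_prosody(pf$frames, wt)
  expect_equal(peaks$peak_rms, pf$ground_truth$sim_true_peak_rms)
  expect_equal(peaks$peak_f0, pf$ground_truth$sim_true_peak_f0)
  expect_error(simulate_prosody_frames(wt, frame_ms = 0), "positive")
})

test_that("ratings generator matches its signal/noise construction", {
  # noise_sd = 0: all raters identical, ISC exactly 1
  r0 <- simulate_ratings(5, 20, signal_sd = 1, noise_sd = 0, seed = 2)
  expect_true(all(apply(r0, 2, function(col) diff(range(col)) == 0)))
  expect_equal(isc(r0)$mean_isc, 1)
  # signal_sd = 0: no shared signal; under the including-self definition
  # the correlation with the rater mean concentrates at sqrt(1/R), and
  # vanishes as the rater pool grows
  rn <- simulate_ratings(10, 2000, signal_sd = 0, noise_sd = 1, seed = 3)
  expect_lt(abs(isc(rn)$mean_isc - sqrt(1 / 10)), 0.06)
  rbig <- simulate_ratings(100, 500, signal_sd = 0, noise_sd = 1, seed = 4)
  expect_lt(abs(isc(rbig)$mean_isc), 0.15)
})

test_that("embedding generator separates classes and contexts as configured", {
  # zero separation: cross-context accuracy at chance
  e0 <- simulate_embeddings(40, dim = 8, class_separation = 0, seed = 4)
  acc0 <- cross_context_classify(e0, "two_word", spec = quick_spec())
  expect_lt(abs(acc0$test_accuracy - 0.5), 0.15)
  # large separation, small noise: both near 100%
  e1 <- simulate_embeddings(40, dim = 8, class_separation = 10,
                            noise_sd = 0.5, seed = 5)
  acc1 <- cross_context_classify(e1, "two_word", spec = quick_spec())
  expect_gt(acc1$train_accuracy, 0.95)
  expect_gt(acc1$test_accuracy, 0.95)
})
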