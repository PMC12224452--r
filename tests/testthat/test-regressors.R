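# Word-level confound regressors, ISC, z-scoring and residualization.

test_that("regressor formulas are exact", {
  expect_equal(word_rate(500, 5), 100)
  expect_equal(word_rate(300, 3), 100)
  expect_equal(word_rate(150, 10), 15)
  expect_error(word_rate(0, 5), "positive")
  expect_error(word_rate(500, 0), ">= 1")

  expect_equal(log_frequency(1), 0)
  expect_equal(log_frequency(exp(2)), 2)
  expect_true(all(diff(log_frequency(c(1, 10, 100, 1000))) > 0))
  expect_error(log_frequency(0), ">= 1")

  expect_equal(surprisal(1), 0)
  expect_equal(surprisal(0.5), 1)
  expect_equal(surprisal(0.25), 2)
  expect_equal(surprisal(0.25, base = exp(1)), -log(0.25))
  expect_error(surprisal(0), "\\(0, 1\\]")
  expect_error(surprisal(1.5), "\\(0, 1\\]")
})

test_that("peak prosody takes the frame maximum over each word", {
  wt <- data.frame(word_id = c("w1", "w2"), onset_ms = c(0, 30),
                   duration_ms = c(30, 30))
  frames <- data.frame(time_ms = seq(0, 50, by = 10),
                       rms = c(10, 20, 15, 4, 8, 6),
                       f0 = c(100, 130, 120, 90, 95, 92))
  pk <- peak_prosody(frames, wt)
  expect_equal(pk$peak_rms, c(20, 8))
  expect_equal(pk$peak_f0, c(130, 95))
  # constant frames: peak = the constant for every word
  frames$rms <- 7; frames$f0 <- 200
  pk2 <- peak_prosody(frames, wt)
  expect_true(all(pk2$peak_rms == 7) && all(pk2$peak_f0 == 200))
  wt_bad <- data.frame(word_id = "late", onset_ms = 500, duration_ms = 20)
  expect_error(peak_prosody(frames, wt_bad), "late")
})

test_that("lm_surprisal applies the provider with sentence-reset context", {
  wt <- data.frame(word_id = paste0("w", 1:6),
                   token = c("a", "b", "c", "d", "e", "f"),
                   sentence_index = c(1, 1, 1, 2, 2, 2))
  s <- lm_surprisal(wt, uniform_provider(1024))
  expect_equal(s, rep(10, 6))
  # context resets at sentence boundaries; first word sees empty context
  seen <- list()
  recorder <- function(token, context) {
    seen[[length(seen) + 1]] <<- context
    1
  }
  z <- lm_surprisal(wt, recorder)
  expect_equal(z, rep(0, 6))           # deterministic provider -> all zeros
  expect_identical(seen[[1]], character(0))
  expect_identical(seen[[4]], character(0))
  expect_identical(seen[[3]], c("a", "b"))
  expect_identical(seen[[6]], c("d", "e"))
  expect_error(lm_surprisal(wt, function(t, c) 2), "word index 1")
})

test_that("sentence emotion is broadcast as rater means", {
  wt <- data.frame(word_id = paste0("w", 1:4),
                   sentence_index = c(1, 1, 2, 2))
  val <- matrix(c(1, 3, 0, 2), nrow = 2, byrow = TRUE)  # raters x sentences
  aro <- matrix(c(5, 7, 6, 8), nrow = 2, byrow = TRUE)
  em <- propagate_sentence_emotion(val, aro, wt)
  expect_equal(em$valence, c(0.5, 0.5, 2.5, 2.5))
  expect_equal(em$arousal, c(5.5, 5.5, 7.5, 7.5))
  wt$sentence_index <- c(1, 1, 2, 3)
  expect_error(propagate_sentence_emotion(val, aro, wt), "missing")
})

test_that("ISC matches its definition and the closed-form attenuation", {
  m <- matrix(rep(c(1, 5, 3, 2, 4), 4), nrow = 4, byrow = TRUE)
  out <- isc(m)
  expect_equal(unname(out$per_rater), rep(1, 4))
  expect_equal(out$mean_isc, 1)
  # one rater equal to the overall mean has r = 1
  m2 <- rbind(c(1, 2, 3, 4), c(3, 2, 1, 4), c(2, 2, 2, 4))
  out2 <- isc(m2)
  expect_equal(unname(out2$per_rater[3]),
               unname(cor(m2[3, ], colMeans(m2))))
  # Monte-Carlo vs analytic r of one rater with the rater mean:
  # sqrt((s^2 + n^2/R) / (s^2 + n^2))
  R <- 10
  rat <- simulate_ratings(R, 10000, signal_sd = 1, noise_sd = 1, seed = 9)
  theory <- sqrt((1 + 1 / R) / 2)
  expect_lt(abs(isc(rat)$mean_isc - theory), 0.05)
  # zero-variance rater excluded with warning, or error in strict mode
  m3 <- rbind(c(1, 2, 3), c(2, 2, 2), c(3, 1, 2))
  expect_warning(isc(m3), "excluded")
  expect_error(isc(m3, strict = TRUE), "zero-variance")
})

test_that("z-scoring is exact, idempotent, and rejects constant columns", {
  tab <- data.frame(word_id = c("a", "b", "c"),
                    peak_rms = c(1, 2, 3), peak_f0 = c(10, 30, 20),
                    word_rate = c(100, 50, 75), log_frequency = c(1, 4, 2),
                    surprisal = c(3, 1, 2), valence = c(-1, 0, 1),
                    arousal = c(5, 6, 7))
  z <- zscore_columns(tab)
  expect_equal(z$peak_rms, c(-1, 0, 1))
  for (cn in crossdecode:::REGRESSOR_NAMES) {
    expect_lt(abs(mean(z[[cn]])), 1e-9)
    expect_lt(abs(sd(z[[cn]]) - 1), 1e-9)
  }
  z2 <- zscore_columns(z)
  expect_equal(as.matrix(z2[-1]), as.matrix(z[-1]), tolerance = 1e-12)
  tab$arousal <- 5
  expect_error(zscore_columns(tab), "arousal")
})

test_that("collinearity report flags duplicated columns", {
  set.seed(31)
  tab <- as.data.frame(matrix(rnorm(7 * 500), ncol = 7))
  names(tab) <- crossdecode:::REGRESSOR_NAMES
  rep0 <- collinearity_report(tab)
  expect_equal(diag(rep0$correlation), rep(1, 7), ignore_attr = TRUE)
  expect_equal(rep0$correlation, t(rep0$correlation))
  expect_lt(rep0$max_abs_r, 0.15)
  expect_identical(nrow(rep0$flagged), 0L)
  tab$peak_f0 <- tab$peak_rms
  rep1 <- collinearity_report(tab)
  expect_identical(nrow(rep1$flagged), 1L)
  expect_equal(rep1$flagged$r, 1)
})

test_that("residualization zeroes regressor-driven data and is idempotent", {
  cfg <- sim_config(n_subjects = 2, n_epochs_per_class = 30, mesh_level = 0,
                    epoch_ms = c(0, 50))
  out <- simulate_naturalistic_with_confounds(cfg, "s01")
  tab <- zscore_columns(out$table)
  # (a) data exactly linear in regressors -> residuals all zero
  lin <- out$epochs
  X <- as.matrix(tab[crossdecode:::REGRESSOR_NAMES])
  beta <- matrix(seq(-1, 1, length.out = 7 * 12), 7, 12)
  for (t in seq_along(lin$time_ms)) lin$data[, , t] <- X %*% beta
  res_lin <- residualize_epochs(lin, tab)
  expect_lt(max(abs(res_lin$data)), 1e-9)
  # (b) residuals orthogonal to every regressor at every cell
  res <- residualize_epochs(out$epochs, tab)
  d <- dim(res$data)
  Y <- matrix(res$data, nrow = d[1])
  expect_lt(max(abs(crossprod(X, Y))), 1e-6)
  # (c) idempotence
  res2 <- residualize_epochs(res, tab)
  expect_lt(max(abs(res2$data - res$data)), 1e-8)
  # (d) misalignment and rank deficiency are errors
  bad <- tab[c(2, 1, 3:nrow(tab)), ]
  expect_error(residualize_epochs(out$epochs, bad), "misaligned")
  dup <- out$table
  dup$peak_f0 <- dup$peak_rms
  expect_error(residualize_epochs(out$epochs, zscore_columns(dup)),
               "rank-deficient")
  expect_error(residualize_epochs(out$epochs, out$table), "z-scored")
})

test_that("residualizing a confound-only set removes its decodability", {
  cfg <- sim_config(n_subjects = 2, n_epochs_per_class = 30, mesh_level = 0,
                    epoch_ms = c(0, 100), master_seed = 7,
                    confounds = list(confound_spec(
                      "arousal", class_shift = 1.5, loading_vertices = 1:6,
                      loading_window_ms = c(50, 90), loading_gain = 6,
                      pattern_seed = 13)))
  geom <- crossdecode:::config_geometry(cfg)
  nbh <- searchlight_neighborhoods(geom$mesh, geom$mask, k = 6)
  out <- simulate_naturalistic_with_confounds(cfg, "s01", geom)
  pre <- searchlight_decode(out$epochs, nbh, quick_spec(), cv_folds = 5)
  win <- pre$time_ms >= 50 & pre$time_ms <= 90
  expect_gt(mean(pre$values[1:6, win]), 0.7)   # confound is decodable
  res <- residualize_epochs(out$epochs, zscore_columns(out$table))
  post <- decode_residuals(res, nbh, quick_spec(), cv_folds = 5)
  expect_lt(mean(post$values[1:6, win]), 0.6)  # back toward chance
})
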