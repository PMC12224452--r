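# End-to-end orchestration: simulate -> decode -> group stats -> TGM ->
# regress -> re-decode -> state space, with deterministic hierarchical
# seeding, plus the analytic power utility.

#' Pipeline configuration
#'
#' @param sim A [sim_config()] defining the synthetic study conditions.
#' @param classifier A [classifier_spec()].
#' @param tfce A [tfce_params()].
#' @param k Searchlight size in sources.
#' @param cv_folds Stratified CV folds for within-paradigm decoding.
#' @param alpha Significance level for cluster inference.
#' @param decode_times_ms Optional subset of the epoch time grid to decode
#'   (decimation keeps desk-scale runs fast); `NULL` decodes every
#'   timepoint.
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), classifier = classifier_spec(),
                            tfce = tfce_params(), k = 20L, cv_folds = 5L,
                            alpha = 0.05, decode_times_ms = NULL) {
  stopifnot(inherits(sim, "sim_config"),
            inherits(classifier, "classifier_spec"),
            inherits(tfce, "tfce_params"))
  if (!is_count(k) || !is_count(cv_folds, 2L))
    stop("`k` must be >= 1 and `cv_folds` >= 2", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must lie in (0, 1)",
                                     call. = FALSE)
  structure(list(sim = sim, classifier = classifier, tfce = tfce,
                 k = as.integer(k), cv_folds = as.integer(cv_folds),
                 alpha = alpha, decode_times_ms = decode_times_ms),
            class = "pipeline_config")
}

cluster_summary <- function(clusters) {
  lapply(clusters, function(cl) {
    out <- list(extent_cells = cl$extent_cells, peak_t = cl$peak_t,
                mass = cl$mass, p = cl$p, method = cl$method)
    if (!is.null(cl$times_ms)) {
      out$extent_sources <- cl$extent_sources
      out$window_ms <- range(cl$times_ms)
    }
    if (!is.null(cl$train_window_ms)) {
      out$train_window_ms <- cl$train_window_ms
      out$test_window_ms <- cl$test_window_ms
    }
    out
  })
}

run_stage <- function(name, expr) {
  tryCatch(force(expr),
           error = function(e)
             stop("pipeline stage '", name, "' failed: ",
                  conditionMessage(e), call. = FALSE))
}

#' Run the full cross-paradigm analysis
#'
#' Executes, in order: per-subject simulation of both paradigms;
#' within-paradigm searchlight decoding; TFCE sign-flip group inference;
#' cluster-restricted temporal generalization in both directions with the
#' 2-D cluster-mass permutation test; regressor z-scoring, collinearity
#' check and residualization of the naturalistic epochs; re-decoding and
#' re-inference on the residuals; TGM from the residual-trained
#' classifiers to the raw two-word data; and state-space trajectories for
#' the leading clusters.  The report compares the pre- vs
#' post-residualization cluster time windows of the naturalistic
#' paradigm.
#'
#' A paradigm without a significant cluster records
#' `"no significant cluster"` and skips its TGM and state-space stages.
#'
#' @param config A [pipeline_config()].
#' @return A `run_report` list with per-stage summaries, seeds and
#'   content hashes.
#' @export
run_full <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  sim <- config$sim
  report <- list(master_seed = sim$master_seed, stages = list())

  geom <- run_stage("geometry", config_geometry(sim))
  nbh <- run_stage("neighborhoods",
                   searchlight_neighborhoods(geom$mesh, geom$mask,
                                             k = config$k))
  subjects <- sprintf("s%02d", seq_len(sim$n_subjects))

  two_word <- run_stage("simulate_two_word",
    lapply(subjects, function(s) simulate_epochs(sim, "two_word", s, geom)))
  nat <- run_stage("simulate_naturalistic",
    lapply(subjects, function(s)
      simulate_naturalistic_with_confounds(sim, s, geom)))
  nat_epochs <- lapply(nat, `[[`, "epochs")
  report$stages$simulate <- list(
    n_subjects = sim$n_subjects,
    data_hash = rlang::hash(list(lapply(two_word, `[[`, "data"),
                                 lapply(nat_epochs, `[[`, "data"))))

  decode_par <- function(sets, tag) {
    lapply(sets, function(es)
      searchlight_decode(es, nbh, config$classifier, config$cv_folds,
                         times_ms = config$decode_times_ms))
  }
  maps_tw <- run_stage("decode_two_word", decode_par(two_word, "two_word"))
  maps_nat <- run_stage("decode_naturalistic", decode_par(nat_epochs, "nat"))

  n_t <- length(maps_tw[[1L]]$time_ms)
  adj <- spatiotemporal_adjacency(geom$mesh, geom$mask, n_t)
  infer <- function(maps) sign_flip_permutation(maps, adj, config$tfce,
                                                alpha = config$alpha)
  inf_tw <- run_stage("inference_two_word", infer(maps_tw))
  inf_nat <- run_stage("inference_naturalistic", infer(maps_nat))
  report$stages$decoding <- list(
    mean_accuracy_two_word = mean(vapply(maps_tw, function(m)
      mean(m$values), numeric(1))),
    mean_accuracy_naturalistic = mean(vapply(maps_nat, function(m)
      mean(m$values), numeric(1))),
    maps_hash = rlang::hash(list(lapply(maps_tw, `[[`, "values"),
                                 lapply(maps_nat, `[[`, "values"))))
  report$stages$inference <- list(
    two_word = cluster_summary(inf_tw$clusters),
    naturalistic = cluster_summary(inf_nat$clusters))

  run_tgm_direction <- function(inf, train_sets, test_sets, label) {
    if (length(inf$clusters) == 0L)
      return(list(status = "no significant cluster"))
    sel <- restrict_to_cluster(inf$clusters[[1L]])
    tgms <- lapply(seq_along(train_sets), function(i)
      tgm(train_sets[[i]], test_sets[[i]], sel$source_set,
          sel$train_window_ms, config$classifier))
    stat <- cluster_mass_permutation_2d(
      tgms, n_permutations = config$tfce$n_permutations,
      seed = derive_seed(sim$master_seed, "tgm", label),
      alpha = config$alpha)
    list(status = "ok", train_window_ms = sel$train_window_ms,
         n_sources = length(sel$source_set),
         mean_tgm = mean(Reduce(`+`, lapply(tgms, `[[`, "values")) /
                           length(tgms)),
         clusters = cluster_summary(stat$significant))
  }
  report$stages$tgm <- list(
    two_word_to_naturalistic = run_stage("tgm_tw_to_nat",
      run_tgm_direction(inf_tw, two_word, nat_epochs, "tw2nat")),
    naturalistic_to_two_word = run_stage("tgm_nat_to_tw",
      run_tgm_direction(inf_nat, nat_epochs, two_word, "nat2tw")))

  resid <- run_stage("residualize", lapply(nat, function(x) {
    tab <- zscore_columns(x$table)
    residualize_epochs(x$epochs, tab)
  }))
  coll <- collinearity_report(zscore_columns(nat[[1L]]$table))
  report$stages$regression <- list(max_abs_r = coll$max_abs_r,
                                   n_flagged = nrow(coll$flagged))

  maps_res <- run_stage("decode_residuals", lapply(resid, function(es)
    decode_residuals(es, nbh, config$classifier, config$cv_folds,
                     times_ms = config$decode_times_ms)))
  inf_res <- run_stage("inference_residuals", infer(maps_res))
  report$stages$residual_inference <- cluster_summary(inf_res$clusters)

  report$stages$tgm_residual <- run_stage("tgm_residual",
    run_tgm_direction(inf_res, resid, two_word, "res2tw"))

  window_of <- function(inf) if (length(inf$clusters) > 0L)
    range(inf$clusters[[1L]]$times_ms) else NULL
  report$comparison <- list(
    naturalistic_window_pre_ms = window_of(inf_nat),
    naturalistic_window_post_ms = window_of(inf_res),
    two_word_window_ms = window_of(inf_tw))

  report$stages$statespace <- run_stage("statespace", {
    if (length(inf_tw$clusters) > 0L) {
      ss <- condition_trajectories(two_word[[1L]], inf_tw$clusters[[1L]])
      list(status = "ok",
           peak_distance_ms = ss$distance_timecourse$time_ms[
             which.max(ss$distance_timecourse$dist_full)])
    } else list(status = "no significant cluster")
  })

  report$report_hash <- rlang::hash(report)
  class(report) <- "run_report"
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report> master seed", x$master_seed, "\n")
  cmp <- x$comparison
  fmt <- function(w) if (is.null(w)) "none" else paste(w, collapse = "-")
  cat("  two-word cluster window:     ", fmt(cmp$two_word_window_ms),
      "ms\n")
  cat("  naturalistic window (pre):   ",
      fmt(cmp$naturalistic_window_pre_ms), "ms\n")
  cat("  naturalistic window (post):  ",
      fmt(cmp$naturalistic_window_post_ms), "ms\n")
  invisible(x)
}

#' Analytic power of the one-sample t-test
#'
#' Power from the noncentral t distribution with `df = n - 1` and
#' noncentrality `d * sqrt(n)` against the central-t critical value.  A
#' design of 31 subjects detecting a medium effect (`d = 0.6`) at
#' `alpha = 0.05` has power 0.9 to one decimal under either tail choice.
#'
#' @param n Sample size (>= 2).
#' @param effect_size_d Cohen's d (>= 0).
#' @param alpha Significance level in (0, 1).
#' @param tails 1 or 2 (default 2).
#' @return Power in `[0, 1]`.
#' @export
power_one_sample_t <- function(n, effect_size_d, alpha = 0.05, tails = 2) {
  if (!is_count(n, 2L)) stop("`n` must be >= 2", call. = FALSE)
  if (effect_size_d < 0) stop("`effect_size_d` must be >= 0", call. = FALSE)
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("`alpha` must lie in (0, 1)", call. = FALSE)
  if (!tails %in% c(1, 2)) stop("`tails` must be 1 or 2", call. = FALSE)
  df <- n - 1
  ncp <- effect_size_d * sqrt(n)
  crit <- stats::qt(1 - alpha / tails, df)
  pw <- stats::pt(crit, df, ncp = ncp, lower.tail = FALSE)
  if (tails == 2) pw <- pw + stats::pt(-crit, df, ncp = ncp)
  pw
}
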