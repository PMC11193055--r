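# Reusable desk-scale simulation studies.  These are the package's own
# validation experiments: they regenerate synthetic data, run the pipeline
# and summarize accuracy, so the same code backs the test suite and the
# reproduction script.

#' Subarea scene preset
#'
#' A scene whose well disk covers the whole field: the geometry of an inner
#' subarea of a well mosaic, fully covered by cells, with no well rim in
#' view.  This is the setting in which software counts are compared with
#' ground truth (rim-free, like the inner subareas used for manual-count
#' validation).
#'
#' @param n_cells number of nuclei.
#' @param seed scene seed.
#' @param field_size image size `c(height, width)` in pixels.
#' @param noise_sd additive Gaussian noise sd.
#' @param ... passed to [generate_scene()].
#' @return a `synthetic_scene`.
#' @export
subarea_scene <- function(n_cells, seed, field_size = c(800L, 800L),
                          noise_sd = 0.005, ...) {
  # radius beyond the half-diagonal puts every pixel inside the well disk
  r <- ceiling(sqrt(sum((field_size / 2)^2))) + 50
  generate_scene(n_cells, field_size = field_size,
                 well_center_xy = c((field_size[2] + 1) / 2,
                                    (field_size[1] + 1) / 2),
                 well_radius_px = r, noise_sd = noise_sd, seed = seed, ...)
}

#' Detection accuracy study on synthetic subarea images
#'
#' Renders one subarea scene per seed (nucleus numbers evenly spaced over
#' `n_range`, minimum separation 8 px, noise sd 0.02), counts nuclei with the
#' default detection parameters, and scores the software counts against the
#' ground truth: total relative count error, OLS agreement of truth on
#' software (slope, R-squared), and position-matched precision/recall within
#' 3 px.
#'
#' @param seeds integer vector of scene seeds (one scene per seed).
#' @param n_range range of nuclei per scene `c(min, max)`.
#' @param field_size scene size in pixels.
#' @param noise_sd additive noise sd.
#' @param params detection parameters.
#' @param ... further scene arguments passed to [subarea_scene()] (e.g.
#'   `min_separation_px`).
#' @return list with per-scene data frame `scenes` (`seed`, `truth`,
#'   `software`, `precision`, `recall`), `total_truth`, `total_software`,
#'   `total_error_pct`, `slope`, `r_squared`.
#' @export
detection_accuracy_study <- function(seeds = 1:20, n_range = c(800L, 2000L),
                                     field_size = c(800L, 800L),
                                     noise_sd = 0.02,
                                     params = detection_params(), ...) {
  ns <- round(seq(n_range[1], n_range[2], length.out = length(seeds)))
  res <- data.frame(seed = seeds, truth = ns, software = NA_integer_,
                    precision = NA_real_, recall = NA_real_)
  for (i in seq_along(seeds)) {
    scene <- subarea_scene(ns[i], seed = seeds[i], field_size = field_size,
                           noise_sd = noise_sd, ...)
    img <- render_channels(scene)$hoechst
    smoothed <- median_smooth(img, params$median_neighborhood)
    blobs <- detect_blobs(smoothed, params)
    res$software[i] <- nrow(blobs)
    mt <- match_detections(scene$nuclei, blobs, max_dist = 3)
    res$precision[i] <- mt$precision
    res$recall[i] <- mt$recall
  }
  fit <- agreement_model(res$truth, res$software)
  list(scenes = res,
       total_truth = sum(res$truth),
       total_software = sum(res$software),
       total_error_pct = 100 * abs(sum(res$software) - sum(res$truth)) /
         sum(res$truth),
       slope = fit$slope,
       r_squared = fit$r_squared)
}

#' Simulate one dose-response dataset
#'
#' @param model `"EXD3"` or `"LL4"` truth family.
#' @param par named truth parameters for the family.
#' @param doses dose levels (uM).
#' @param reps replicates per dose.
#' @param noise_sd Gaussian response noise sd.
#' @param seed simulation seed.
#' @return data frame `dose`, `response`, `replicate`.
#' @export
simulate_dose_response <- function(model = c("LL4", "EXD3"),
                                   par = c(b = 1, c = 0.05, d = 1, e = 5),
                                   doses = c(0.5, 1, 2, 5, 10, 20, 50),
                                   reps = 3L, noise_sd = 0.05, seed = 1L) {
  model <- match.arg(model)
  dose <- rep(doses, each = reps)
  mu <- drc_predict(model, par, dose)
  resp <- mu + with_seed(seed, rnorm(length(dose), 0, noise_sd))
  data.frame(dose = dose, response = resp,
             replicate = rep(seq_len(reps), times = length(doses)))
}

#' ED50 recovery study under LL4 truth
#'
#' Simulates `n_sims` datasets from LL4 truth (default b = 1, c = 0.05,
#' d = 1, e = 5 uM; 7 doses x 3 replicates, noise sd 0.05), fits LL4 and
#' computes the bootstrap ED50 interval for each, and summarizes the median
#' relative ED50 error and the interval coverage of the true value.
#'
#' @param n_sims number of simulated datasets.
#' @param par LL4 truth parameters.
#' @param doses,reps,noise_sd simulation design.
#' @param B bootstrap resamples per dataset.
#' @param seed master seed (per-dataset seeds derived from it).
#' @return list with per-sim data frame `sims` (`ed50`, `lo`, `hi`,
#'   `covered`, `rel_error`), `median_rel_error_pct`, `coverage_pct`,
#'   `true_ed50`.
#' @export
ed50_recovery_study <- function(n_sims = 100L,
                                par = c(b = 1, c = 0.05, d = 1, e = 5),
                                doses = c(0.5, 1, 2, 5, 10, 20, 50),
                                reps = 3L, noise_sd = 0.05, B = 999L,
                                seed = 11L) {
  true_ed50 <- unname(par[["e"]])
  sims <- data.frame(ed50 = rep(NA_real_, n_sims), lo = NA_real_,
                     hi = NA_real_, covered = NA, rel_error = NA_real_)
  for (s in seq_len(n_sims)) {
    dat <- simulate_dose_response("LL4", par, doses, reps, noise_sd,
                                  seed = child_seed(seed, s))
    fit <- fit_drc(dat, "LL4", seed = child_seed(seed, s + n_sims))
    if (!fit$converged) next
    e <- ed50(fit, B = B, seed = child_seed(seed, s + 2L * n_sims))
    sims$ed50[s] <- e$ed50
    sims$lo[s] <- e$ci[["lo"]]
    sims$hi[s] <- e$ci[["hi"]]
    sims$covered[s] <- is.finite(e$ci[["lo"]]) &&
      e$ci[["lo"]] <= true_ed50 && true_ed50 <= e$ci[["hi"]]
    sims$rel_error[s] <- abs(e$ed50 - true_ed50) / true_ed50
  }
  ok <- !is.na(sims$ed50)
  list(sims = sims,
       n_converged = sum(ok),
       median_rel_error_pct = 100 * median(sims$rel_error[ok]),
       coverage_pct = 100 * mean(sims$covered[ok]),
       true_ed50 = true_ed50)
}

#' AIC model-selection consistency study
#'
#' Simulates low-noise datasets from each truth family (LL4 with a clear
#' low-dose plateau, EXD3 exponential decay), runs [select_model()] on each,
#' and reports how often the generating family is selected.
#'
#' @param n_sims simulations per truth family.
#' @param noise_sd response noise sd.
#' @param doses,reps simulation design.
#' @param seed master seed.
#' @return list with `ll4_selected_pct`, `exd3_selected_pct`.
#' @export
aic_selection_study <- function(n_sims = 100L, noise_sd = 0.02,
                                doses = c(0.5, 1, 2, 5, 10, 20, 50),
                                reps = 3L, seed = 21L) {
  par_ll4 <- c(b = 2, c = 0.05, d = 1, e = 5)
  par_exd <- c(c = 0.05, d = 1, e = 10)
  hit_ll4 <- logical(n_sims)
  hit_exd <- logical(n_sims)
  for (s in seq_len(n_sims)) {
    d1 <- simulate_dose_response("LL4", par_ll4, doses, reps, noise_sd,
                                 seed = child_seed(seed, s))
    hit_ll4[s] <- select_model(d1, seed = child_seed(seed, s))$model == "LL4"
    d2 <- simulate_dose_response("EXD3", par_exd, doses, reps, noise_sd,
                                 seed = child_seed(seed, s + n_sims))
    hit_exd[s] <- select_model(d2,
                               seed = child_seed(seed, s + n_sims))$model == "EXD3"
  }
  list(ll4_selected_pct = 100 * mean(hit_ll4),
       exd3_selected_pct = 100 * mean(hit_exd))
}

#' Family-wise error of the Tukey-Kramer procedure under a true null
#'
#' Simulates groups with equal means and normal noise, runs [tukey_hsd()]
#' and reports the fraction of simulations in which any adjusted p-value
#' falls below `alpha` (the family-wise error rate, nominally `alpha`).
#'
#' @param n_sims number of simulations.
#' @param k number of groups.
#' @param n observations per group.
#' @param alpha nominal significance level.
#' @param seed master seed.
#' @return list with `fwer` and `n_sims`.
#' @export
tukey_fwer_study <- function(n_sims = 1000L, k = 3L, n = 5L, alpha = 0.05,
                             seed = 31L) {
  any_sig <- with_seed(seed, {
    vapply(seq_len(n_sims), function(s) {
      groups <- lapply(seq_len(k), function(i) rnorm(n))
      any(tukey_hsd(groups)$p_adj < alpha)
    }, logical(1))
  })
  list(fwer = mean(any_sig), n_sims = n_sims)
}
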