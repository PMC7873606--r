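#' Measurement-noise model for profile-mode cohorts
#'
#' Profile mode emulates the end product of the imaging chain — one
#' per-segment median per subject, hemisphere and metric — without
#' simulating DWI volumes. `sd_subject` is the between-subject SD of the
#' random intercept shared by both hemispheres; `sd_resid` the residual
#' per-segment SD (streamline-sampling plus fit noise). Units: FA and FD
#' dimensionless, ADC mm^2/s.
#'
#' @param sd_subject,sd_resid named numeric vectors over `fa`, `adc`, `fd`.
#' @return List of class `profile_noise`.
#' @export
profile_noise <- function(sd_subject = c(fa = 0.02, adc = 4e-5, fd = 0.03),
                          sd_resid = c(fa = 0.012, adc = 3e-5, fd = 0.018)) {
  structure(list(sd_subject = sd_subject, sd_resid = sd_resid),
            class = "profile_noise")
}

# metric baselines along the centerline: zero-noise tensor-fit FA/ADC of
# the centerline voxel configuration, and the tract fiber fraction for FD
.profile_baselines <- function(scheme, tissue, n_segments = 100L) {
  s <- (seq_len(n_segments) - 1) / (n_segments - 1)
  cl <- bundle_centerline("left")
  tan <- cl$tangents[vapply(s, function(si) which.min(abs(cl$s - si)),
                            integer(1)), , drop = FALSE]
  f_t <- .f_tract_profile(s, tissue)
  cfg <- list(f_iso = 1 - f_t, d_iso = rep(tissue$d_iso, n_segments),
              S0 = rep(tissue$S0, n_segments), f_t = f_t, dir_t = tan,
              lam_par = rep(tissue$lambda_par, n_segments),
              lam_perp = rep(tissue$lambda_perp, n_segments),
              f_c = rep(0, n_segments),
              lam_par_c = tissue$lambda_par,
              lam_perp_c = tissue$lambda_perp)
  met <- .config_metrics(cfg, NULL, scheme)
  list(fa = met$fa, adc = met$adc, fd = f_t)
}

#' Generate a profile-mode cohort (scalar fast path)
#'
#' Directly generates the long-format segment table a full imaging run
#' would produce: per-segment baselines are the zero-noise metric values
#' along the bundle centerline; the pathological hemisphere receives the
#' injected lesion effects exactly (FA minus `effect_fa`, ADC times
#' `1 + effect_adc`, FD times `1 - effect_fd`) inside the lesional
#' range; subject intercepts and residual noise are added per metric.
#'
#' @param n_subjects number of subjects.
#' @param lesion a [lesion_spec()] (all-zero effects give a null cohort).
#' @param seed master seed (subject sampling and noise).
#' @param noise a [profile_noise()].
#' @param scheme,tissue forward-model parameters for the baselines.
#' @param n_segments segments per tract (default 100).
#' @param common_range optional fixed lesional range `c(a, b)` applied to
#'   every subject instead of per-subject sampling.
#' @return List of class `profile_cohort`: `records`
#'   ([assemble_table()] layout), `truth`, `baselines`, `labels`
#'   (per-subject [label_peritumoral()]).
#' @export
make_profile_cohort <- function(n_subjects, lesion = lesion_spec(),
                                seed = 1L, noise = profile_noise(),
                                scheme = default_scheme(),
                                tissue = tissue_params(),
                                n_segments = 100L, common_range = NULL) {
  truth <- make_cohort_truth(n_subjects, lesion, seed)
  if (!is.null(common_range)) {
    for (i in seq_len(n_subjects)) {
      truth$subjects[[i]]$lesion_range <- as.integer(common_range)
    }
  }
  key <- paste0("baseline_", digest_params(scheme, tissue, n_segments))
  base <- .tractfd_cache[[key]]
  if (is.null(base)) {
    base <- .profile_baselines(scheme, tissue, n_segments)
    assign(key, base, envir = .tractfd_cache)
  }
  metrics <- c("fa", "adc", "fd")
  cl <- bundle_centerline("left")
  seg_len <- cl$length / (n_segments - 1)

  profiles <- vector("list", n_subjects)
  peritumoral <- vector("list", n_subjects)
  labels <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    sub <- truth$subjects[[i]]
    rng <- sub$lesion_range
    les <- seq_len(n_segments) >= rng[1] & seq_len(n_segments) <= rng[2]
    peritumoral[[i]] <- les
    labels[[i]] <- label_peritumoral(rng, n_segments,
                                     voxel_size = 1.3,
                                     mean_segment_length = seg_len)
    intercepts <- rnorm(3) * noise$sd_subject[metrics]
    hemi <- list()
    for (h in c("healthy", "pathological")) {
      vals <- list()
      for (m in metrics) {
        v <- base[[m]]
        if (h == "pathological") {
          eff <- sub$effects
          v <- ifelse(les,
                      switch(m,
                             fa = v - eff$fa,
                             adc = v * (1 + eff$adc),
                             fd = v * (1 - eff$fd)),
                      v)
        }
        vals[[m]] <- v + intercepts[match(m, metrics)] +
          rnorm(n_segments, 0, noise$sd_resid[m])
      }
      hemi[[h]] <- vals
    }
    profiles[[i]] <- hemi
  }
  records <- assemble_table(profiles, peritumoral)
  structure(list(records = records, truth = truth, baselines = base,
                 labels = labels, noise = noise),
            class = "profile_cohort")
}

# short deterministic key for the baseline cache
digest_params <- function(scheme, tissue, n_segments) {
  paste(signif(sum(scheme$bvals), 8), length(scheme$bvals),
        signif(unlist(tissue[c("lambda_par", "lambda_perp", "d_iso",
                               "f_tract_base", "f_tract_amp")]), 8),
        n_segments, collapse = "_")
}

#' @export
print.profile_cohort <- function(x, ...) {
  cat("profile_cohort:", length(unique(x$records$subject)), "subjects,",
      nrow(x$records), "records\n")
  invisible(x)
}
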