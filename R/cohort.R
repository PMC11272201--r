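#' Cohort specification for reliability simulations
#'
#' Variance structure of a simulated multi-measurement cohort of ALPS
#' indices, mirroring a two-way random-effects design: subject i carries a
#' latent perivascular gain g_i ~ Normal(`mean_gain`, `sigma_subject`);
#' measurement j of subject i realizes ALPS_ij = g_i + `rater_bias[j]` +
#' Normal(0, `sigma_error`). Systematic scanner/rater differences are the
#' fixed per-measurement offsets in `rater_bias`.
#'
#' The theoretical absolute-agreement ICC implied by the spec is
#' sigma_subject^2 / (sigma_subject^2 + var(rater_bias) + sigma_error^2),
#' with `var()` the (k-1)-denominator variance of the bias vector (what the
#' column mean square estimates under fixed offsets).
#'
#' @param n_subjects number of subjects (>= 2).
#' @param k_measurements measurements per subject (>= 2).
#' @param mean_gain cohort-mean perivascular gain / ALPS index.
#' @param sigma_subject between-subject SD of the gain.
#' @param sigma_error within-subject measurement SD on the ALPS scale.
#' @param rater_bias length-`k_measurements` additive offsets (default all 0).
#' @param min_gain lower clip bound for realized gains (clipped draws are
#'   counted and reported).
#' @param seed RNG seed.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects, k_measurements, mean_gain = 1.5,
                        sigma_subject = 0.15, sigma_error = 0.05,
                        rater_bias = rep(0, k_measurements),
                        min_gain = 0.05, seed = 1L) {
  if (n_subjects < 2L || k_measurements < 2L)
    abort_dtialps("need n_subjects >= 2 and k_measurements >= 2",
                  "dtialps_spec_error")
  if (sigma_subject < 0 || sigma_error < 0)
    abort_dtialps("standard deviations must be >= 0", "dtialps_spec_error")
  rater_bias <- rep_len(as.numeric(rater_bias), k_measurements)
  structure(list(n_subjects = as.integer(n_subjects),
                 k_measurements = as.integer(k_measurements),
                 mean_gain = mean_gain, sigma_subject = sigma_subject,
                 sigma_error = sigma_error, rater_bias = rater_bias,
                 min_gain = min_gain, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Theoretical absolute-agreement ICC of a cohort spec
#'
#' @param spec a [cohort_spec()].
#' @return sigma_subject^2 / (sigma_subject^2 + var(rater_bias) +
#'   sigma_error^2); `NaN` when all three components are zero.
#' @export
theoretical_icc <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  vb <- stats::var(spec$rater_bias)
  spec$sigma_subject^2 / (spec$sigma_subject^2 + vb + spec$sigma_error^2)
}

#' Simulate a cohort of ALPS measurements
#'
#' Draws the cohort's latent gains and measurement-level ALPS targets on the
#' ALPS scale. With `out_dir` set, additionally synthesizes one full DWI
#' dataset per (subject, measurement) — the phantom's gain is set so its
#' analytic ALPS equals the target — and writes NIfTI + bval/bvec files plus
#' a manifest; reliability statistics only need the ALPS-scale table, so
#' image synthesis is opt-in.
#'
#' @param spec a [cohort_spec()].
#' @param base base [phantom_spec()] used when synthesizing images; defaults
#'   to the DSI-preset phantom.
#' @param table acquisition scheme for synthesized images.
#' @param out_dir directory for synthesized datasets, or `NULL` (default) for
#'   the ALPS-scale table only.
#' @return object of class `alps_cohort`: list with `truth` (data frame
#'   `subject_id`, `measurement_id`, `true_alps`), `theoretical_icc`,
#'   `n_clipped`, `spec`, and (when images were written) `manifest` with one
#'   file prefix per row.
#' @export
simulate_cohort <- function(spec, base = NULL, table = single_shell_scheme(),
                            out_dir = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_subjects; k <- spec$k_measurements
  draws <- withr::with_seed(spec$seed, {
    g_i <- rnorm(n, spec$mean_gain, spec$sigma_subject)
    eps <- matrix(rnorm(n * k, 0, spec$sigma_error), n, k)
    sub_seeds <- sample.int(.Machine$integer.max - 1L, n * k)
    list(g_i = g_i, eps = eps, sub_seeds = sub_seeds)
  })
  target <- outer(draws$g_i, spec$rater_bias, `+`) + draws$eps
  n_clipped <- sum(target < spec$min_gain)
  if (n_clipped > 0) {
    message(n_clipped, " simulated gain(s) fell below ", spec$min_gain,
            " and were clipped")
    target <- pmax(target, spec$min_gain)
  }
  subj <- sprintf("S%03d", seq_len(n))
  meas <- sprintf("M%d", seq_len(k))
  truth <- data.frame(subject_id = rep(subj, times = k),
                      measurement_id = rep(meas, each = n),
                      true_alps = as.vector(target),
                      stringsAsFactors = FALSE)
  out <- list(truth = truth, theoretical_icc = theoretical_icc(spec),
              n_clipped = n_clipped, spec = spec)

  if (!is.null(out_dir)) {
    if (is.null(base)) base <- default_phantom_spec("DSI_DEFAULT")
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    prefixes <- character(nrow(truth))
    for (r in seq_len(nrow(truth))) {
      ps <- base
      ps$gain <- truth$true_alps[r]
      ps$seed <- draws$sub_seeds[r]
      sim <- simulate_phantom(ps, table)
      prefix <- file.path(out_dir, paste0(truth$subject_id[r], "_",
                                          truth$measurement_id[r]))
      write_dwi(sim$dwi, table, prefix)
      prefixes[r] <- prefix
    }
    manifest <- cbind(truth, prefix = prefixes, stringsAsFactors = FALSE)
    write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
    write.csv(truth, file.path(out_dir, "ground_truth.csv"), row.names = FALSE)
    out$manifest <- manifest
  }
  class(out) <- "alps_cohort"
  out
}

#' @export
print.alps_cohort <- function(x, ...) {
  cat(sprintf("<alps_cohort> %d subjects x %d measurements | theoretical agreement ICC %.3f\n",
              x$spec$n_subjects, x$spec$k_measurements, x$theoretical_icc))
  invisible(x)
}
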