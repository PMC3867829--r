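# Synthetic cohort generator: per-animal EEG recordings with group-dependent
# recovery parameters, daily neurologic deficit scores linked to the recovery
# metrics through a logistic model, and survival over 96 h.

#' Cohort specification
#'
#' Defines a two-arm synthetic cohort. Group-level parameter distributions
#' (means and SDs of the stage boundaries, burst-rate scaling and band
#' fractions) control the EEG recordings; a logistic link from the (true)
#' recovery time to a latent deficit severity generates daily NDS category
#' scores; survival follows a per-day death probability that increases with
#' the daily NDS, with a total score of 500 (brain death) fatal by
#' definition.
#'
#' The defaults use a compressed 600 s timeline so a full cohort can be
#' simulated and analyzed in seconds; the treated arm has an earlier burst
#' onset, earlier recovery of continuous activity, a steeper burst-rate ramp
#' and a flatter (higher-entropy) continuous spectrum than the control arm,
#' mirroring the direction of hypothermia effects after cardiac arrest.
#'
#' @param n_per_group Animals per arm (>= 2).
#' @param groups Arm names; the first is the treated arm.
#' @param fs Sample rate (Hz).
#' @param duration_s Record duration, seconds.
#' @param iso_end_mean,iso_end_sd Per-arm mean/SD (seconds) of the isoelectric
#'   stage end.
#' @param bs_end_mean,bs_end_sd Per-arm mean/SD (seconds) of the burst-
#'   suppression stage end.
#' @param rate_start,rate_end Per-arm burst rate (bursts/min) at the start and
#'   end of the burst-suppression stage (linear ramp).
#' @param band_fractions List of two length-4 vectors: mean band-power
#'   fractions per arm (delta, theta, alpha, beta).
#' @param band_conc Dirichlet-style concentration controlling per-animal
#'   jitter of the band fractions (larger = less jitter).
#' @param total_rms Continuous-stage RMS amplitude, microvolts.
#' @param nds_intercept Per-arm intercept of the latent deficit severity on
#'   the logit scale (higher = worse).
#' @param nds_recovery_coef Effect of the standardized true recovery time on
#'   the latent severity (per second of `bs_end`, applied after centering and
#'   scaling within the cohort spec by `recovery_center`/`recovery_scale`).
#' @param recovery_center,recovery_scale Centering/scaling (seconds) applied
#'   to `bs_end` before entering the severity model.
#' @param nds_day_coef Day effect on the latent severity (per day after day 1).
#' @param nds_noise_sd SD of the animal- and day-level logit noise.
#' @param death_intercept,death_slope Per-day death probability is
#'   `plogis(death_intercept + death_slope * nds_total)`; a total of 500 is
#'   always fatal.
#' @param death_scale Multiplier on the per-day death probability; 0 disables
#'   all death (including the brain-death rule), so every animal survives.
#' @param seed Master seed; per-animal seeds are derived by a fixed counter
#'   scheme, so cohorts are reproducible animal by animal.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = 10,
                        groups = c("hypothermia", "normothermia"),
                        fs = 300, duration_s = 600,
                        iso_end_mean = c(90, 130), iso_end_sd = c(12, 25),
                        bs_end_mean = c(300, 420), bs_end_sd = c(25, 40),
                        rate_start = c(6, 5), rate_end = c(20, 10),
                        band_fractions = list(c(0.65, 0.15, 0.10, 0.10),
                                              c(0.75, 0.12, 0.07, 0.06)),
                        band_conc = 400, total_rms = 30,
                        nds_intercept = c(-1.5, 1.0),
                        nds_recovery_coef = 1.0,
                        recovery_center = 360, recovery_scale = 80,
                        nds_day_coef = c(-0.4, 0.6),
                        nds_noise_sd = 0.8,
                        death_intercept = -5.5, death_slope = 0.011,
                        death_scale = 1, seed = 1L) {
  if (n_per_group < 2) stop("'n_per_group' must be >= 2", call. = FALSE)
  if (length(groups) != 2) stop("exactly two groups are required", call. = FALSE)
  sds <- c(iso_end_sd, bs_end_sd, nds_noise_sd)
  if (any(sds < 0)) stop("all SDs must be >= 0", call. = FALSE)
  if (death_scale < 0 || death_scale > 1)
    stop("'death_scale' must be in [0, 1]", call. = FALSE)
  for (bf in band_fractions)
    continuous_spec(bf, total_rms)  # validates fractions
  structure(as.list(environment()), class = "cohort_spec")
}

# Per-animal jitter of band fractions: normalized Gamma draws
# (Dirichlet with concentration band_conc * fractions).
jitter_fractions <- function(frac, conc) {
  g <- stats::rgamma(length(frac), shape = pmax(conc * frac, 1e-6), rate = 1)
  g / sum(g)
}

#' Generate a synthetic cohort
#'
#' Draws per-animal recovery parameters from the arm-level distributions in
#' the [cohort_spec()], generates one EEG recording per animal (unless
#' `signals = FALSE`), and simulates daily NDS and 96 h survival from the
#' generating (true) recovery times.
#'
#' @param spec A [cohort_spec()].
#' @param signals Generate the EEG recordings (set `FALSE` to simulate only
#'   parameters and outcomes, e.g. for calibration studies).
#' @return A list of class `cohort`:
#'   \describe{
#'     \item{recordings}{named list of [eeg_record()] (or `NULL`).}
#'     \item{truth}{`data.frame` of generating parameters per animal
#'       (stage boundaries, rates, band fractions, event counts).}
#'     \item{outcomes}{`data.frame`: `animal_id`, `group`, `nds_day1..4`
#'       (totals), `survival_hr`, `event`.}
#'     \item{nds_detail}{long `data.frame` of per-category scores per day.}
#'   }
#' @export
generate_cohort <- function(spec, signals = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_per_group * 2L
  arm <- rep(1:2, each = spec$n_per_group)
  ids <- sprintf("a%02d", seq_len(n))
  cats <- names(nds_categories())
  maxima <- vapply(nds_categories(), max, numeric(1))
  mids <- vapply(nds_categories(), function(v) v[2], numeric(1))

  recordings <- if (signals) stats::setNames(vector("list", n), ids) else NULL
  truth <- vector("list", n)
  outcomes <- vector("list", n)
  nds_detail <- vector("list", n)

  for (i in seq_len(n)) {
    g <- arm[i]
    sd_i <- derive_seed(spec$seed, i)
    with_seed(sd_i, {
      iso_end <- max(30, stats::rnorm(1, spec$iso_end_mean[g], spec$iso_end_sd[g]))
      bs_end <- stats::rnorm(1, spec$bs_end_mean[g], spec$bs_end_sd[g])
      bs_end <- min(max(bs_end, iso_end + 60), spec$duration_s - 60)
      frac <- jitter_fractions(spec$band_fractions[[g]], spec$band_conc)
      rate <- data.frame(t_min = c(0, (bs_end - iso_end) / 60),
                         rate = c(spec$rate_start[g], spec$rate_end[g]))
      prof <- stage_profile(iso_end, bs_end, burst_rate = rate)
      cont <- continuous_spec(frac, spec$total_rms)

      rec <- NULL
      n_events <- NA_integer_
      onset_true <- NA_real_
      if (signals) {
        rec <- generate_recording(prof, cont, fs = spec$fs,
                                  duration = spec$duration_s,
                                  seed = derive_seed(sd_i, 1L))
        n_events <- nrow(attr(rec, "events"))
        onset_true <- attr(rec, "stages")$isoelectric_end_realized
      }

      # latent deficit severity -> daily NDS category scores
      rec_z <- (bs_end - spec$recovery_center) / spec$recovery_scale
      a_noise <- stats::rnorm(1, 0, spec$nds_noise_sd)
      nds_days <- numeric(4)
      detail <- vector("list", 4)
      dead_day <- NA_integer_
      for (day in 1:4) {
        if (!is.na(dead_day)) {
          sc <- maxima  # brain death carried forward
        } else {
          eta <- spec$nds_intercept[g] + spec$nds_recovery_coef * rec_z +
            spec$nds_day_coef[g] * (day - 1) + a_noise +
            stats::rnorm(1, 0, spec$nds_noise_sd)
          sev <- stats::plogis(eta)
          sc <- vapply(cats, function(ct) {
            s <- stats::plogis(eta + stats::rnorm(1, 0, 0.5))
            if (s < 1 / 3) 0 else if (s < 2 / 3) mids[[ct]] else maxima[[ct]]
          }, numeric(1))
        }
        total <- sum(sc)
        nds_days[day] <- total
        detail[[day]] <- data.frame(animal_id = ids[i], day = day,
                                    t(sc), total = total)
        if (is.na(dead_day) && spec$death_scale > 0) {
          p_die <- if (total >= 500) 1 else
            spec$death_scale * stats::plogis(spec$death_intercept +
                                             spec$death_slope * total)
          if (stats::runif(1) < p_die) dead_day <- day
        }
      }
      event <- as.integer(!is.na(dead_day))
      surv_hr <- if (event) 24 * dead_day else 96
      if (event) nds_days[dead_day:4] <- 500

      if (signals) recordings[[i]] <- rec
      truth[[i]] <- data.frame(
        animal_id = ids[i], group = spec$groups[g],
        isoelectric_end = iso_end, onset_true_s = onset_true, bs_end = bs_end,
        rate_start = spec$rate_start[g], rate_end = spec$rate_end[g],
        frac_delta = frac[1], frac_theta = frac[2],
        frac_alpha = frac[3], frac_beta = frac[4],
        n_burst_events = n_events)
      outcomes[[i]] <- data.frame(
        animal_id = ids[i], group = spec$groups[g],
        nds_day1 = nds_days[1], nds_day2 = nds_days[2],
        nds_day3 = nds_days[3], nds_day4 = nds_days[4],
        survival_hr = surv_hr, event = event)
      nds_detail[[i]] <- do.call(rbind, detail)
    })
  }
  structure(list(recordings = recordings,
                 truth = do.call(rbind, truth),
                 outcomes = do.call(rbind, outcomes),
                 nds_detail = do.call(rbind, nds_detail),
                 spec = spec),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d animals (%s)\n", nrow(x$outcomes),
              paste(unique(x$outcomes$group), collapse = " vs ")))
  cat(sprintf("  recordings: %s; deaths: %d/%d\n",
              if (is.null(x$recordings)) "not generated" else
                sprintf("%d x %.0f s @ %g Hz", length(x$recordings),
                        x$spec$duration_s, x$spec$fs),
              sum(x$outcomes$event), nrow(x$outcomes)))
  invisible(x)
}
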