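#' Specification for a simulated paired EEG cohort
#'
#' Describes the study conditions for a synthetic resting-state cohort:
#' band-limited oscillatory components (narrowband random-phase processes),
#' 1/f background noise, and optional phase-lagged cross-channel couplings
#' whose strength can change multiplicatively in the post condition. With a
#' coupling of strength `s` and phase lag `phi`, the band-averaged imaginary
#' coherence of the coupled pair approaches `s * sin(phi)` in closed form,
#' which is what makes injected effects recoverable by construction.
#'
#' @param n_subjects Number of subjects (each gets a pre and a post
#'   recording).
#' @param n_channels Number of channels (default 21; the standard montage
#'   labels are used for up to 21 channels).
#' @param fs Sampling rate in Hz (default 500); must exceed twice the
#'   highest component frequency.
#' @param duration Recording length in seconds (default 60).
#' @param band_components Tibble with columns `center` (Hz) and `amplitude`
#'   (uV RMS); every channel receives an independent narrowband process per
#'   component. Default: a resting-like mix with dominant alpha.
#' @param noise_exponent Spectral slope of the 1/f background (power ~
#'   `f^-exponent`), default 1.
#' @param noise_amplitude RMS amplitude of the background in uV (default 10).
#' @param couplings Tibble with columns `ch_i`, `ch_j` (channel indices),
#'   `band` (canonical band name), `lag` (radians, in `(0, pi)` for nonzero
#'   strength) and `strength` in `[0, 1]`. The target channel's in-band
#'   component becomes `sqrt(1 - s^2) * own + s * phase-shifted source`.
#' @param effect Named list of post-condition multipliers:
#'   `coupling`, `amplitude`, `noise` (all default 1 = no change).
#' @param amp_jitter_sd Log-normal sigma of the per-subject amplitude jitter
#'   (default 0.1).
#' @param coupling_jitter_sd Log-normal sigma of the per-subject coupling
#'   strength jitter, shared between a subject's pre and post recordings
#'   (default 0.15).
#' @param seed Integer seed; the same spec and seed reproduce the cohort
#'   exactly.
#' @return An `eeg_sim_spec` object.
#' @export
eeg_sim_spec <- function(n_subjects,
                         n_channels = 21,
                         fs = 500,
                         duration = 60,
                         band_components = tibble::tibble(
                           center = c(2, 6, 10, 20, 40),
                           amplitude = c(15, 10, 25, 6, 3)
                         ),
                         noise_exponent = 1,
                         noise_amplitude = 10,
                         couplings = NULL,
                         effect = list(coupling = 1, amplitude = 1, noise = 1),
                         amp_jitter_sd = 0.1,
                         coupling_jitter_sd = 0.15,
                         seed = 1) {
  if (!is.numeric(n_subjects) || n_subjects < 1) {
    abort_field("n_subjects", "need at least one subject")
  }
  if (!is.numeric(n_channels) || n_channels < 1) {
    abort_field("n_channels", "need at least one channel")
  }
  if (!is.numeric(fs) || fs <= 0) abort_field("fs", "must be positive (Hz)")
  if (!is.numeric(duration) || duration <= 0) {
    abort_field("duration", "must be positive (seconds)")
  }
  band_components <- tibble::as_tibble(band_components)
  if (!all(c("center", "amplitude") %in% names(band_components))) {
    abort_field("band_components", "need columns center (Hz), amplitude (uV)")
  }
  if (fs <= 2 * max(band_components$center)) {
    abort_field("fs", sprintf("sampling rate %g Hz too low for a %g Hz component",
                              fs, max(band_components$center)))
  }
  if (noise_amplitude < 0) abort_field("noise_amplitude", "must be nonnegative")
  if (!is.null(couplings)) {
    couplings <- tibble::as_tibble(couplings)
    need <- c("ch_i", "ch_j", "band", "lag", "strength")
    if (!all(need %in% names(couplings))) {
      abort_field("couplings", paste("need columns", paste(need, collapse = ", ")))
    }
    if (any(couplings$strength < 0 | couplings$strength > 1)) {
      abort_field("couplings", "strength must lie in [0, 1]")
    }
    nz <- couplings$strength > 0
    if (any(couplings$lag[nz] <= 0 | couplings$lag[nz] >= pi)) {
      abort_field("couplings", "phase lag must lie in (0, pi) for nonzero strength")
    }
    if (any(couplings$ch_i > n_channels | couplings$ch_j > n_channels |
              couplings$ch_i < 1 | couplings$ch_j < 1 |
              couplings$ch_i == couplings$ch_j)) {
      abort_field("couplings", "channel indices out of range or equal")
    }
    bad <- setdiff(couplings$band, eeg_bands()$band)
    if (length(bad)) {
      abort_field("couplings", paste("unknown band:", paste(bad, collapse = ", ")))
    }
  }
  effect <- utils::modifyList(list(coupling = 1, amplitude = 1, noise = 1),
                              as.list(effect))
  structure(
    list(
      n_subjects = as.integer(n_subjects), n_channels = as.integer(n_channels),
      fs = fs, duration = duration, band_components = band_components,
      noise_exponent = noise_exponent, noise_amplitude = noise_amplitude,
      couplings = couplings, effect = effect,
      amp_jitter_sd = amp_jitter_sd, coupling_jitter_sd = coupling_jitter_sd,
      seed = as.integer(seed)
    ),
    class = "eeg_sim_spec"
  )
}

# Hermitian spectral synthesis: real signal of length n whose one-sided
# amplitude spectrum follows `shape` (length floor(n/2)+1, freqs 0..Nyquist),
# with i.i.d. complex Gaussian phases. Returns the time series (unnormalized).
.spectral_noise <- function(n, shape) {
  half <- n %/% 2
  z <- complex(real = rnorm(half + 1), imaginary = rnorm(half + 1))
  z[1] <- 0
  if (n %% 2 == 0) z[half + 1] <- complex(real = Re(z[half + 1]) * sqrt(2))
  pos <- z * shape
  X <- complex(length.out = n)
  X[seq_len(half + 1)] <- pos
  if (n %% 2 == 0) {
    if (half > 1) X[(half + 2):n] <- Conj(pos[half:2])
  } else {
    X[(half + 2):n] <- Conj(pos[(half + 1):2])
  }
  Re(stats::fft(X, inverse = TRUE)) / n
}

.freq_grid <- function(n, fs) seq(0, n %/% 2) * fs / n

# Gaussian spectral bump centered on f0 (sd = bw Hz).
.band_shape <- function(freqs, f0, bw) exp(-((freqs - f0)^2) / (2 * bw^2))

.scale_rms <- function(x, rms) {
  s <- stats::sd(x)
  if (s == 0 || rms == 0) return(x * 0)
  x * (rms / s)
}

# Constant phase shift of a real signal: positive frequencies rotated by
# exp(-1i * lag) (Hermitian-symmetric, so the result is real).
.phase_shift <- function(x, lag) {
  n <- length(x)
  X <- stats::fft(x)
  half <- n %/% 2
  rot <- complex(length.out = n, real = 1)
  if (half >= 1) rot[2:(half + 1)] <- exp(-1i * lag)
  if (n %% 2 == 0) rot[half + 1] <- cos(lag)  # Nyquist bin stays real
  if (half >= 1 && n > 2) rot[(half + 2):n] <- exp(1i * lag)
  Re(stats::fft(X * rot, inverse = TRUE)) / n
}

#' Simulate a paired pre/post EEG cohort
#'
#' Generates, for every subject, one pre and one post recording under the
#' conditions of an [eeg_sim_spec()]: per-channel narrowband components plus
#' 1/f background, with the spec's couplings mixed in and the post-condition
#' `effect` multipliers applied. A subject's amplitude and coupling jitters
#' are shared between their two recordings, so paired contrasts see
#' subject-level variance. Deterministic under the spec's seed.
#'
#' @param spec An [eeg_sim_spec()].
#' @return Tibble with columns `subject`, `condition` (`"pre"`/`"post"`) and
#'   a `recording` list-column of [eeg_recording()] objects.
#' @export
#' @examples
#' spec <- eeg_sim_spec(n_subjects = 1, n_channels = 3, duration = 4,
#'                      fs = 100, band_components = tibble::tibble(
#'                        center = 10, amplitude = 20), seed = 7)
#' simulate_eeg_cohort(spec)
simulate_eeg_cohort <- function(spec) {
  stopifnot(inherits(spec, "eeg_sim_spec"))
  n <- as.integer(round(spec$duration * spec$fs))
  freqs <- .freq_grid(n, spec$fs)
  labels <- if (spec$n_channels <= 21) {
    montage_1020()[seq_len(spec$n_channels)]
  } else {
    paste0("ch", seq_len(spec$n_channels))
  }
  noise_shape <- ifelse(freqs > 0, pmax(freqs, 0.5)^(-spec$noise_exponent / 2), 0)
  bands <- eeg_bands()
  with_seed(spec$seed, {
    rows <- purrr::map(seq_len(spec$n_subjects), function(sub) {
      amp_j <- rlnorm(1, 0, spec$amp_jitter_sd)
      cpl <- spec$couplings
      if (!is.null(cpl) && nrow(cpl)) {
        cpl$strength_subj <- pmin(1, cpl$strength *
                                    rlnorm(nrow(cpl), 0, spec$coupling_jitter_sd))
      }
      one_condition <- function(condition) {
        eff <- if (condition == "post") spec$effect else
          list(coupling = 1, amplitude = 1, noise = 1)
        # per-component, per-channel narrowband processes
        comp <- purrr::pmap(spec$band_components, function(center, amplitude) {
          shape <- .band_shape(freqs, center, max(1, 0.1 * center))
          sig <- vapply(seq_len(spec$n_channels),
                        function(ch) .spectral_noise(n, shape), numeric(n))
          amp <- amplitude * amp_j * eff$amplitude
          apply(sig, 2, .scale_rms, rms = amp)  # n x channels
        })
        centers <- spec$band_components$center
        if (!is.null(cpl) && nrow(cpl)) {
          for (r in seq_len(nrow(cpl))) {
            s <- min(1, cpl$strength_subj[r] * eff$coupling)
            if (s <= 0) next
            brow <- bands[bands$band == cpl$band[r], ]
            in_band <- which(centers >= brow$lo & centers <= brow$hi)
            for (ci in in_band) {
              src <- comp[[ci]][, cpl$ch_i[r]]
              own <- comp[[ci]][, cpl$ch_j[r]]
              comp[[ci]][, cpl$ch_j[r]] <-
                sqrt(1 - s^2) * own + s * .phase_shift(src, cpl$lag[r])
            }
          }
        }
        dat <- matrix(0, spec$n_channels, n)
        for (ci in seq_along(comp)) dat <- dat + t(comp[[ci]])
        if (spec$noise_amplitude > 0) {
          nz <- vapply(seq_len(spec$n_channels),
                       function(ch) .spectral_noise(n, noise_shape), numeric(n))
          nz <- apply(nz, 2, .scale_rms,
                      rms = spec$noise_amplitude * amp_j * eff$noise)
          dat <- dat + t(nz)
        }
        eeg_recording(dat, fs = spec$fs, labels = labels)
      }
      tibble::tibble(
        subject = sprintf("sub%02d", sub),
        condition = c("pre", "post"),
        recording = list(one_condition("pre"), one_condition("post"))
      )
    })
    dplyr::bind_rows(rows)
  })
}
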