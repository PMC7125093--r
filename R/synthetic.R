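#' Specification of a synthetic EEG dataset
#'
#' The generator emulates the shape and gross statistics of an
#' ERP-style EEG study: multiple subjects recorded over sessions as
#' fixed-length epochs at 200 Hz, with subject-specific oscillatory
#' signatures concentrated on a known subset of "informative" channels, an
#' ERP-like transient about 300 ms after epoch onset on those channels,
#' 1/f background noise on every channel, and a session-to-session
#' amplitude perturbation. The informative-channel set is the ground truth
#' against which channel-selection recovery is tested; real recordings
#' have no such ground truth.
#'
#' Full-scale defaults mirror the study conditions (26 subjects, 56
#' channels, 2 sessions, 25 epochs per session, 200 Hz, 1-s epochs).
#' Amplitudes are in microvolts.
#'
#' @param n_subjects Number of subjects (default 26).
#' @param n_sessions Number of sessions (default 2).
#' @param epochs_per_session Epochs per (subject, session) (default 25).
#' @param n_channels Number of channels (default 56; uses
#'   [default_montage_56()] when 56, generic labels otherwise).
#' @param sampling_rate Hz (default 200).
#' @param epoch_seconds Epoch length in seconds (default 1).
#' @param n_informative Number of informative channels drawn at spec
#'   creation (default 10); ignored when `informative_channels` is given.
#' @param informative_channels Optional explicit informative channel
#'   indices (1-based).
#' @param n_carriers Oscillatory components per subject signature
#'   (default 3).
#' @param carrier_freq_range Frequency range (Hz) the per-subject carrier
#'   frequencies are drawn from (default 6-30 Hz).
#' @param carrier_freq_choices Optional discrete frequency pool; when set,
#'   carriers are sampled from it with replacement (subjects then share
#'   frequencies and differ mainly in channel loadings — harder).
#' @param signature_amplitude Base carrier amplitude in microvolts
#'   (default 8).
#' @param erp_amplitude Amplitude of the ERP-like bump (default 5).
#' @param erp_latency Bump latency in seconds (default 0.3).
#' @param erp_width Bump Gaussian width (s.d.) in seconds (default 0.05).
#' @param noise_exponent Spectral exponent of the 1/f background
#'   (default 1).
#' @param noise_level Background noise s.d. in microvolts (default 5).
#' @param session_jitter Relative log-normal amplitude perturbation per
#'   (subject, session) (default 0.1).
#' @param seed RNG seed; the whole dataset is a deterministic function of
#'   the spec.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_subjects = 26, n_sessions = 2,
                           epochs_per_session = 25, n_channels = 56,
                           sampling_rate = 200, epoch_seconds = 1,
                           n_informative = 10,
                           informative_channels = NULL,
                           n_carriers = 3,
                           carrier_freq_range = c(6, 30),
                           carrier_freq_choices = NULL,
                           signature_amplitude = 8,
                           erp_amplitude = 5, erp_latency = 0.3,
                           erp_width = 0.05,
                           noise_exponent = 1, noise_level = 5,
                           session_jitter = 0.1, seed = 1) {
  stopifnot(n_subjects >= 1, n_sessions >= 1, epochs_per_session >= 1,
            n_channels >= 2, sampling_rate > 0, epoch_seconds > 0,
            session_jitter >= 0, noise_level >= 0)
  if (is.null(informative_channels)) {
    stopifnot(n_informative >= 1, n_informative <= n_channels)
    informative_channels <- withr::with_seed(
      seed, sort(sample.int(n_channels, n_informative))
    )
  }
  informative_channels <- sort(unique(as.integer(informative_channels)))
  stopifnot(all(informative_channels >= 1),
            all(informative_channels <= n_channels))
  structure(
    list(n_subjects = as.integer(n_subjects),
         n_sessions = as.integer(n_sessions),
         epochs_per_session = as.integer(epochs_per_session),
         n_channels = as.integer(n_channels),
         sampling_rate = sampling_rate, epoch_seconds = epoch_seconds,
         informative_channels = informative_channels,
         n_carriers = as.integer(n_carriers),
         carrier_freq_range = carrier_freq_range,
         carrier_freq_choices = carrier_freq_choices,
         signature_amplitude = signature_amplitude,
         erp_amplitude = erp_amplitude, erp_latency = erp_latency,
         erp_width = erp_width,
         noise_exponent = noise_exponent, noise_level = noise_level,
         session_jitter = session_jitter, seed = seed),
    class = "synthetic_spec"
  )
}

# 1/f^alpha noise via spectral shaping of white Gaussian noise,
# normalized to unit standard deviation.
colored_noise <- function(n, exponent) {
  white <- rnorm(n)
  spec <- fft(white)
  freqs <- c(1, seq_len(n - 1))            # guard DC
  shape <- 1 / (freqs^(exponent / 2))
  shaped <- Re(fft(spec * shape, inverse = TRUE)) / n
  s <- sd(shaped)
  if (s == 0) shaped else shaped / s
}

#' Generate a synthetic epoch set
#'
#' Realizes the generative model of a [synthetic_spec()]: each epoch is the
#' subject's oscillatory signature (carrier sinusoids with random phases
#' per epoch, mixed through subject-specific channel loadings on the
#' informative channels), plus an ERP-like Gaussian bump at the configured
#' latency on informative channels, plus 1/f noise on every channel;
#' carrier amplitudes carry a per-(subject, session) multiplicative jitter.
#' Bitwise reproducible for a given spec.
#'
#' @param spec A `synthetic_spec`.
#' @return An [epoch_set()]; subject ids are `"S01"`, `"S02"`, ...
#' @export
generate_epochset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  L <- round(spec$sampling_rate * spec$epoch_seconds)
  t <- (seq_len(L) - 1) / spec$sampling_rate
  info <- spec$informative_channels
  n_info <- length(info)
  ids <- sprintf("S%02d", seq_len(spec$n_subjects))
  montage <- if (spec$n_channels == 56L) default_montage_56() else
    sprintf("CH%02d", seq_len(spec$n_channels))
  bump <- exp(-(t - spec$erp_latency)^2 / (2 * spec$erp_width^2))

  withr::with_seed(spec$seed, {
    sig <- lapply(ids, function(id) {
      freqs <- if (is.null(spec$carrier_freq_choices)) {
        runif(spec$n_carriers, spec$carrier_freq_range[1],
              spec$carrier_freq_range[2])
      } else {
        sample(spec$carrier_freq_choices, spec$n_carriers, replace = TRUE)
      }
      list(
        freqs = freqs,
        amps = spec$signature_amplitude * runif(spec$n_carriers, 0.8, 1.2),
        loadings = matrix(runif(n_info * spec$n_carriers, 0.3, 1),
                          n_info, spec$n_carriers),
        erp_weights = runif(n_info, 0.5, 1)
      )
    })
    names(sig) <- ids
    jitter <- matrix(exp(spec$session_jitter *
                           rnorm(spec$n_subjects * spec$n_sessions)),
                     spec$n_subjects, spec$n_sessions)

    rows <- list()
    for (si in seq_along(ids)) {
      s <- sig[[si]]
      for (se in seq_len(spec$n_sessions)) {
        jf <- jitter[si, se]
        for (ep in seq_len(spec$epochs_per_session)) {
          m <- matrix(0, spec$n_channels, L)
          phases <- runif(spec$n_carriers, 0, 2 * pi)
          carriers <- vapply(seq_len(spec$n_carriers), function(k) {
            jf * s$amps[k] * sin(2 * pi * s$freqs[k] * t + phases[k])
          }, numeric(L))                       # L x n_carriers
          m[info, ] <- m[info, ] + s$loadings %*% t(carriers)
          m[info, ] <- m[info, ] +
            spec$erp_amplitude * s$erp_weights %o% bump
          noise <- t(vapply(seq_len(spec$n_channels), function(ch) {
            spec$noise_level * colored_noise(L, spec$noise_exponent)
          }, numeric(L)))
          m <- m + noise
          rows[[length(rows) + 1L]] <- tibble::tibble(
            subject = ids[si], session = se, epoch = ep, data = list(m)
          )
        }
      }
    }
    epoch_set(dplyr::bind_rows(rows), montage, spec$sampling_rate)
  })
}

#' Ready-made benchmark instances with known ground truth
#'
#' Small, fast instances for exercising the full pipeline. The `"easy"`
#' instance has well-separated subject signatures and low noise, so the
#' pipeline should approach perfect identification and authentication with
#' all channels, and channel selection should recover the ground-truth
#' informative set. The `"hard"` instance draws carriers from a shared
#' 3-frequency pool with weak amplitudes, strong noise and large
#' session-to-session jitter, so signatures overlap and authentication
#' rates stay clearly below 1.
#'
#' @param difficulty `"easy"` or `"hard"`.
#' @param seed RNG seed for the instance.
#' @return List with `epochs` (an `epoch_set`), `split` (a
#'   [subject_split()]; first half of the subjects are non-intruders),
#'   `informative` (ground-truth informative channel indices) and `spec`.
#' @export
make_benchmark_instance <- function(difficulty = c("easy", "hard"),
                                    seed = 1) {
  difficulty <- match.arg(difficulty)
  spec <- if (difficulty == "easy") {
    synthetic_spec(
      n_subjects = 6, n_sessions = 2, epochs_per_session = 20,
      n_channels = 16, n_informative = 6,
      signature_amplitude = 12, noise_level = 1.5, session_jitter = 0.02,
      seed = seed
    )
  } else {
    synthetic_spec(
      n_subjects = 6, n_sessions = 2, epochs_per_session = 20,
      n_channels = 16, n_informative = 6,
      carrier_freq_choices = c(8, 10, 12),
      signature_amplitude = 2.5, noise_level = 10, session_jitter = 0.3,
      seed = seed
    )
  }
  es <- generate_epochset(spec)
  ids <- subjects(es)
  half <- ceiling(length(ids) / 2)
  list(
    epochs = es,
    split = subject_split(ids[seq_len(half)], ids[-seq_len(half)]),
    informative = spec$informative_channels,
    spec = spec
  )
}

#' Mean band power of each channel
#'
#' Diagnostic used to verify that subject signatures concentrate on the
#' informative channels: the mean power of each channel's samples within a
#' frequency band, averaged over epochs, per subject.
#'
#' @param x An `epoch_set`.
#' @param band Frequency band in Hz (default 6-30).
#' @return Tibble with `subject`, `channel_index`, `band_power`.
#' @export
band_power_by_channel <- function(x, band = c(6, 30)) {
  validate_epoch_set(x)
  fs <- x$sampling_rate
  L <- n_samples(x)
  freqs <- (seq_len(L) - 1) * fs / L
  sel <- freqs >= band[1] & freqs <= band[2]
  pw <- purrr::pmap_dfr(x$epochs, function(subject, session, epoch, data) {
    p <- apply(data, 1L, function(ch) {
      sp <- Mod(fft(ch))^2 / L
      sum(sp[sel])
    })
    tibble::tibble(subject = subject,
                   channel_index = seq_len(nrow(data)), power = p)
  })
  dplyr::summarise(dplyr::group_by(pw, .data$subject, .data$channel_index),
                   band_power = mean(.data$power), .groups = "drop")
}
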