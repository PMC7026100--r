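#' Synthesize a mother vocalization with motherese-like or flat prosody
#'
#' A harmonic voice source (five harmonics with 1/h amplitudes) whose pitch
#' contour mimics the prosodic contrast between infant-directed and adult
#' speech: motherese segments get a high, strongly modulated F0 (sinusoidal
#' sweep around 280-400 Hz with wide excursions) and a pronounced amplitude
#' arc; other-speech segments get a low, nearly flat contour (170-220 Hz)
#' and steady amplitude. A touch of white noise keeps spectra realistic.
#' This emulates only the prosodic/spectral contrast the detector relies on,
#' not intelligible speech.
#'
#' @param class "motherese" or "other_speech".
#' @param duration_s Segment duration in seconds. Default 0.8.
#' @param sample_rate Samples per second. Default 8000.
#' @param seed Integer seed.
#' @return A list \code{(wave, sample_rate, label)}.
#' @export
make_voice_segment <- function(class = c("motherese", "other_speech"),
                               duration_s = 0.8, sample_rate = 8000,
                               seed = 1) {
  class <- match.arg(class)
  set.seed(seed)
  n <- round(duration_s * sample_rate)
  t <- (seq_len(n) - 1) / sample_rate
  if (class == "motherese") {
    f0_base <- stats::runif(1, 280, 400)
    excursion <- stats::runif(1, 60, 140)
    mod_rate <- stats::runif(1, 1.5, 4)
    f0 <- f0_base + excursion * sin(2 * pi * mod_rate * t +
                                    stats::runif(1, 0, 2 * pi))
    env <- 0.4 + 0.6 * sin(pi * t / duration_s)^2
  } else {
    f0_base <- stats::runif(1, 170, 220)
    f0 <- f0_base + stats::rnorm(1, 0, 3) + 4 * sin(2 * pi * 1 * t)
    env <- rep(0.8, n)
  }
  phase <- 2 * pi * cumsum(f0) / sample_rate
  wave <- rep(0, n)
  for (h in 1:5) wave <- wave + sin(h * phase) / h
  wave <- env * wave / max(abs(wave))
  wave <- wave + stats::rnorm(n, sd = 0.01)
  list(wave = wave, sample_rate = sample_rate, label = class)
}

#' Generate a balanced synthetic motherese corpus
#'
#' @param n_per_class Segments per class. Default 100.
#' @param duration_s Segment duration. Default 0.8.
#' @param sample_rate Samples per second. Default 8000.
#' @param seed Integer seed.
#' @return A list of \code{2 * n_per_class} segments (see
#'   [make_voice_segment()]), motherese first.
#' @export
make_motherese_corpus <- function(n_per_class = 100, duration_s = 0.8,
                                  sample_rate = 8000, seed = 1) {
  c(
    lapply(seq_len(n_per_class), function(i) {
      make_voice_segment("motherese", duration_s, sample_rate,
                         seed = seed + i)
    }),
    lapply(seq_len(n_per_class), function(i) {
      make_voice_segment("other_speech", duration_s, sample_rate,
                         seed = seed + 100000L + i)
    })
  )
}
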