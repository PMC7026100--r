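#' Mel-frequency cepstral coefficients of a mono waveform
#'
#' Standard cepstral front end for the segmental stream: 25-ms Hamming
#' windows with a 10-ms hop, power spectrum, 26 triangular mel filters up to
#' Nyquist, log energies, orthonormal DCT-II, first 13 coefficients
#' (including the energy-like coefficient 0).
#'
#' @param wave Numeric mono waveform.
#' @param sample_rate Samples per second.
#' @param n_ceps Number of cepstral coefficients. Default 13.
#' @param n_mels Number of mel filters. Default 26.
#' @return A frames x \code{n_ceps} matrix.
#' @export
extract_segmental <- function(wave, sample_rate, n_ceps = 13, n_mels = 26) {
  win <- round(0.025 * sample_rate)
  hop <- round(0.010 * sample_rate)
  if (length(wave) < max(win, round(0.1 * sample_rate))) {
    stop("segment shorter than 100 ms", call. = FALSE)
  }
  n_frames <- floor((length(wave) - win) / hop) + 1
  nfft <- 2^ceiling(log2(win))
  hamming <- 0.54 - 0.46 * cos(2 * pi * (seq_len(win) - 1) / (win - 1))
  fb <- mel_filterbank(n_mels, nfft, sample_rate)
  dct <- dct_matrix(n_ceps, n_mels)
  out <- matrix(0, n_frames, n_ceps)
  for (f in seq_len(n_frames)) {
    seg <- wave[((f - 1) * hop + 1):((f - 1) * hop + win)] * hamming
    spec <- stats::fft(c(seg, rep(0, nfft - win)))
    p <- Mod(spec[1:(nfft / 2 + 1)])^2
    out[f, ] <- dct %*% log(pmax(as.vector(fb %*% p), 1e-12))
  }
  out
}

hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

mel_filterbank <- function(n_mels, nfft, sample_rate) {
  pts <- mel_to_hz(seq(0, hz_to_mel(sample_rate / 2), length.out = n_mels + 2))
  bins <- pts / (sample_rate / 2) * (nfft / 2)
  fb <- matrix(0, n_mels, nfft / 2 + 1)
  k <- 0:(nfft / 2)
  for (m in seq_len(n_mels)) {
    lo <- bins[m]; mid <- bins[m + 1]; hi <- bins[m + 2]
    up <- (k - lo) / (mid - lo)
    down <- (hi - k) / (hi - mid)
    fb[m, ] <- pmax(0, pmin(up, down))
  }
  fb
}

dct_matrix <- function(n_out, n_in) {
  m <- outer(0:(n_out - 1), 0:(n_in - 1),
             function(i, j) cos(pi * i * (j + 0.5) / n_in))
  m * sqrt(2 / n_in) * ifelse(seq_len(n_out) == 1, sqrt(0.5), 1)
}

#' Prosodic (suprasegmental) features of a mono waveform
#'
#' Frame-wise fundamental frequency by normalized autocorrelation with
#' parabolic peak refinement (search band 75-500 Hz), RMS energy, and a
#' voicing decision (autocorrelation peak and energy gates). Summary
#' statistics are taken over the voiced frames.
#'
#' @param wave Numeric mono waveform.
#' @param sample_rate Samples per second.
#' @return Named numeric vector: \code{f0_mean, f0_sd, f0_range, f0_slope}
#'   (Hz, Hz/s), \code{energy_mean, energy_sd, energy_range},
#'   \code{voiced_fraction}, \code{duration_s}. F0 fields are \code{NA} when
#'   no frame is voiced.
#' @export
extract_suprasegmental <- function(wave, sample_rate) {
  win <- round(0.025 * sample_rate)
  hop <- round(0.010 * sample_rate)
  n_frames <- max(floor((length(wave) - win) / hop) + 1, 0)
  lag_min <- max(2, floor(sample_rate / 500))
  lag_max <- min(win - 2, ceiling(sample_rate / 75))
  f0 <- rep(NA_real_, n_frames)
  energy <- rep(0, n_frames)
  t_s <- rep(NA_real_, n_frames)
  for (f in seq_len(n_frames)) {
    seg <- wave[((f - 1) * hop + 1):((f - 1) * hop + win)]
    seg <- seg - mean(seg)
    energy[f] <- sqrt(mean(seg^2))
    t_s[f] <- ((f - 1) * hop + win / 2) / sample_rate
    r0 <- sum(seg^2)
    if (r0 < 1e-10) next
    lags <- lag_min:lag_max
    r <- vapply(lags, function(l) {
      sum(seg[1:(win - l)] * seg[(l + 1):win]) / r0
    }, 0)
    j <- which.max(r)
    if (r[j] < 0.5) next
    lag <- lags[j]
    if (j > 1 && j < length(r)) { # parabolic refinement
      denom <- r[j - 1] - 2 * r[j] + r[j + 1]
      if (abs(denom) > 1e-12) {
        lag <- lag + 0.5 * (r[j - 1] - r[j + 1]) / denom
      }
    }
    f0[f] <- sample_rate / lag
  }
  voiced <- !is.na(f0) & energy > 0.25 * max(energy)
  fv <- f0[voiced]
  slope <- if (sum(voiced) >= 3 && stats::sd(t_s[voiced]) > 0) {
    unname(stats::coef(stats::lm(fv ~ t_s[voiced]))[2])
  } else if (sum(voiced) > 0) 0 else NA_real_
  c(f0_mean = if (length(fv)) mean(fv) else NA_real_,
    f0_sd = if (length(fv) > 1) stats::sd(fv) else if (length(fv)) 0
            else NA_real_,
    f0_range = if (length(fv)) max(fv) - min(fv) else NA_real_,
    f0_slope = slope,
    energy_mean = if (n_frames) mean(energy) else NA_real_,
    energy_sd = if (n_frames > 1) stats::sd(energy) else NA_real_,
    energy_range = if (n_frames) max(energy) - min(energy) else NA_real_,
    voiced_fraction = if (n_frames) mean(voiced) else NA_real_,
    duration_s = length(wave) / sample_rate)
}

#' Fit a diagonal-covariance Gaussian mixture by EM
#'
#' K-means initialization, expectation-maximization with per-dimension
#' variances floored at \code{var_floor}; iterates until the relative
#' log-likelihood change is below \code{tol} or \code{max_iter} iterations.
#' The log-likelihood trace is non-decreasing.
#'
#' @param x Numeric matrix (observations x dimensions) or vector.
#' @param m Number of mixture components.
#' @param seed Integer seed (initialization).
#' @param max_iter,tol,var_floor EM controls.
#' @return A list of class \code{"gaussian_mixture"}: \code{weights} (sums
#'   to 1), \code{means} and \code{vars} (\code{m} x d), and the
#'   \code{loglik} trace.
#' @export
fit_gmm <- function(x, m, seed = 1, max_iter = 200, tol = 1e-6,
                    var_floor = 1e-6) {
  x <- as.matrix(x)
  n <- nrow(x); d <- ncol(x)
  if (n < m) stop("need at least as many vectors as components", call. = FALSE)
  set.seed(seed)
  centers <- tryCatch(
    stats::kmeans(x, centers = m, nstart = 3, iter.max = 50)$centers,
    error = function(e) x[sample.int(n, m), , drop = FALSE])
  means <- matrix(centers, m, d)
  gvar <- pmax(apply(x, 2, stats::var), var_floor)
  if (any(is.na(gvar))) gvar <- rep(1, d)
  vars <- matrix(rep(gvar, each = m), m, d)
  weights <- rep(1 / m, m)
  ll_trace <- numeric(0)
  prev <- -Inf
  for (it in seq_len(max_iter)) {
    lp <- component_logdens(x, means, vars) +
      rep(log(weights), each = n) # n x m
    mx <- apply(lp, 1, max)
    lse <- mx + log(rowSums(exp(lp - mx)))
    ll <- sum(lse)
    ll_trace <- c(ll_trace, ll)
    resp <- exp(lp - lse)
    nk <- colSums(resp)
    nk <- pmax(nk, 1e-10)
    weights <- nk / n
    means <- t(resp) %*% x / nk
    for (k in seq_len(m)) {
      diff2 <- sweep(x, 2, means[k, ])^2
      vars[k, ] <- pmax(colSums(resp[, k] * diff2) / nk[k], var_floor)
    }
    if (is.finite(prev) && abs(ll - prev) < tol * abs(prev)) break
    prev <- ll
  }
  structure(list(weights = weights, means = means, vars = vars,
                 loglik = ll_trace, d = d),
            class = "gaussian_mixture")
}

component_logdens <- function(x, means, vars) {
  n <- nrow(x); m <- nrow(means)
  out <- matrix(0, n, m)
  for (k in seq_len(m)) {
    z2 <- sweep(sweep(x, 2, means[k, ])^2, 2, vars[k, ], "/")
    out[, k] <- -0.5 * (rowSums(z2) + sum(log(2 * pi * vars[k, ])))
  }
  out
}

#' Log density of observations under a Gaussian mixture
#'
#' @param model A \code{gaussian_mixture}.
#' @param x Matrix or vector of observations.
#' @return Numeric vector of per-observation log densities.
#' @export
gmm_logdens <- function(model, x) {
  x <- matrix(as.matrix(x), ncol = model$d)
  lp <- component_logdens(x, model$means, model$vars) +
    rep(log(model$weights), each = nrow(x))
  mx <- apply(lp, 1, max)
  mx + log(rowSums(exp(lp - mx)))
}

#' Train the two-stream motherese model
#'
#' Fits, per class (motherese / other speech), one GMM on the pooled
#' cepstral frames (segmental stream, default 12 components) and one on the
#' per-segment prosodic vectors (suprasegmental stream, default 15
#' components). Prosodic vectors with missing F0 statistics are imputed with
#' the class mean before fitting.
#'
#' @param corpus List of segments, each \code{list(wave, sample_rate,
#'   label)} with label "motherese" or "other_speech"; e.g. from
#'   [make_motherese_corpus()].
#' @param config A [run_config()] (component counts, fusion weight, seed).
#' @return A list of class \code{"motherese_model"}.
#' @export
train_motherese_model <- function(corpus, config = run_config()) {
  labels <- vapply(corpus, function(s) s$label, "")
  stopifnot(all(labels %in% c("motherese", "other_speech")))
  seg_feats <- lapply(corpus, function(s) {
    extract_segmental(s$wave, s$sample_rate)
  })
  sup_feats <- t(vapply(corpus, function(s) {
    extract_suprasegmental(s$wave, s$sample_rate)
  }, numeric(9)))
  model <- list(fusion_lambda = config$fusion_lambda, streams = list())
  for (cl in c("motherese", "other_speech")) {
    idx <- which(labels == cl)
    segm <- do.call(rbind, seg_feats[idx])
    supm <- sup_feats[idx, , drop = FALSE]
    for (j in seq_len(ncol(supm))) {
      nas <- is.na(supm[, j])
      if (any(nas)) supm[nas, j] <- mean(supm[, j], na.rm = TRUE)
    }
    model$streams[[cl]] <- list(
      segmental = fit_gmm(segm, config$gmm_components_segmental,
                          seed = config$random_seed),
      suprasegmental = fit_gmm(supm, config$gmm_components_suprasegmental,
                               seed = config$random_seed + 1L))
  }
  class(model) <- "motherese_model"
  model
}

#' Fused motherese score of one segment
#'
#' Per-stream score is the log-likelihood ratio motherese vs other speech
#' (mean per-frame for the segmental stream, so duration does not dominate;
#' single-vector for the suprasegmental stream). The fusion is
#' \eqn{\lambda \cdot s_{seg} + (1-\lambda) \cdot s_{supra}}; the segment is
#' classified motherese iff the fused score is positive. When the prosodic
#' vector has missing F0 statistics the weight falls entirely on the
#' segmental stream.
#'
#' @param model A \code{motherese_model}.
#' @param segmental Cepstral frame matrix from [extract_segmental()].
#' @param suprasegmental Prosodic vector from [extract_suprasegmental()].
#' @param lambda Fusion weight of the segmental stream; defaults to the
#'   model's.
#' @return The fused score (positive = motherese).
#' @export
fused_score <- function(model, segmental, suprasegmental,
                        lambda = model$fusion_lambda) {
  s_seg <- mean(gmm_logdens(model$streams$motherese$segmental, segmental) -
                gmm_logdens(model$streams$other_speech$segmental, segmental))
  if (anyNA(suprasegmental)) {
    dyad_log("prosodic stream unavailable; using segmental stream only")
    return(s_seg)
  }
  s_sup <- gmm_logdens(model$streams$motherese$suprasegmental,
                       suprasegmental) -
           gmm_logdens(model$streams$other_speech$suprasegmental,
                       suprasegmental)
  lambda * s_seg + (1 - lambda) * as.numeric(s_sup)
}

#' Classify one waveform as motherese vs other speech
#'
#' @param model A \code{motherese_model}.
#' @param wave,sample_rate Mono waveform and its rate.
#' @return List: \code{label} ("motherese"/"other_speech") and \code{score}.
#' @export
classify_motherese <- function(model, wave, sample_rate) {
  s <- fused_score(model,
                   extract_segmental(wave, sample_rate),
                   extract_suprasegmental(wave, sample_rate))
  list(label = if (s > 0) "motherese" else "other_speech", score = s)
}

#' Label mother vocalizations of a timeline with the motherese classifier
#'
#' @param model A \code{motherese_model}.
#' @param timeline A \code{speech_timeline}.
#' @param waveforms List parallel to \code{timeline$turns} rows; each element
#'   \code{list(wave, sample_rate)} or \code{NULL}. Turns without a waveform
#'   stay unlabeled; non-mother-vocalization turns are untouched.
#' @return The timeline with updated motherese labels.
#' @export
label_timeline <- function(model, timeline, waveforms) {
  t <- timeline$turns
  stopifnot(length(waveforms) == nrow(t))
  for (i in seq_len(nrow(t))) {
    if (t$speaker[i] != "mother" || t$category[i] != "vocalization") next
    wf <- waveforms[[i]]
    if (is.null(wf)) {
      t$motherese[i] <- "unlabeled"
      next
    }
    t$motherese[i] <- classify_motherese(model, wf$wave, wf$sample_rate)$label
  }
  timeline$turns <- t
  timeline
}

#' Intraclass correlation ICC(2,1) with 95% confidence interval
#'
#' Two-way random-effects, absolute-agreement, single-rater ICC from the
#' mean squares of the two-way layout (targets x raters), with the
#' F-distribution confidence interval.
#'
#' @param ratings_a,ratings_b Equal-length numeric ratings of the same
#'   targets by two raters.
#' @param conf Confidence level. Default 0.95.
#' @return Named vector \code{icc, ci_low, ci_high}.
#' @export
icc <- function(ratings_a, ratings_b, conf = 0.95) {
  stopifnot(length(ratings_a) == length(ratings_b), length(ratings_a) >= 3)
  x <- cbind(ratings_a, ratings_b)
  n <- nrow(x); k <- 2
  rm <- rowMeans(x); cm <- colMeans(x); gm <- mean(x)
  if (stats::var(rm) < 1e-14) {
    warning("zero between-target variance; ICC reported as 0")
    return(c(icc = 0, ci_low = NA_real_, ci_high = NA_real_))
  }
  msr <- k * sum((rm - gm)^2) / (n - 1)
  msc <- n * sum((cm - gm)^2) / (k - 1)
  mse <- sum((x - outer(rm, rep(1, k)) - outer(rep(1, n), cm) + gm)^2) /
    ((n - 1) * (k - 1))
  r <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  alpha <- 1 - conf
  if (mse < 1e-14 && msc < 1e-14) {
    return(c(icc = r, ci_low = 1, ci_high = 1))
  }
  a <- (k * r) / (n * (1 - r))
  b <- 1 + (k * r * (n - 1)) / (n * (1 - r))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  f_l <- stats::qf(1 - alpha / 2, n - 1, v)
  f_u <- stats::qf(1 - alpha / 2, v, n - 1)
  lo <- n * (msr - f_l * mse) /
    (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
  hi <- n * (f_u * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f_u * msr)
  c(icc = r, ci_low = lo, ci_high = hi)
}

#' Save or load a motherese model as JSON
#'
#' @param model A \code{motherese_model}.
#' @param path JSON file.
#' @return \code{path} invisibly (save); the model (load).
#' @export
save_motherese_model <- function(model, path) {
  ser <- list(fusion_lambda = model$fusion_lambda, streams = lapply(
    model$streams, function(cl) lapply(cl, function(g) {
      list(weights = g$weights, means = g$means, vars = g$vars, d = g$d)
    })))
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_motherese_model
#' @export
load_motherese_model <- function(path) {
  ser <- jsonlite::read_json(path, simplifyVector = TRUE)
  model <- list(fusion_lambda = ser$fusion_lambda, streams = lapply(
    ser$streams, function(cl) lapply(cl, function(g) {
      structure(list(weights = g$weights, means = as.matrix(g$means),
                     vars = as.matrix(g$vars), loglik = numeric(0),
                     d = g$d),
                class = "gaussian_mixture")
    })))
  class(model) <- "motherese_model"
  model
}
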