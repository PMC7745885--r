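running_mean <- function(x, k) {
  # centred running mean, window shrunk at the edges
  n <- length(x)
  half <- (k - 1) %/% 2
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(1L, i - half)
  hi <- pmin(n, i + half)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  i <- 2:(n - 1)
  i[x[i] > x[i - 1] & x[i] >= x[i + 1]]
}

window_idx <- function(x, centre, half) {
  # indices of sorted x within [centre - half, centre + half]
  lo <- findInterval(centre - half, x) + 1L
  hi <- findInterval(centre + half, x)
  if (hi < lo) integer(0) else lo:hi
}

refine_peak <- function(x, r, centre, sigma0, sig = NULL,
                        centre_bounds = NULL,
                        width_bounds = c(sigma0 / 2, 2 * sigma0)) {
  # weighted least-squares refinement of (centre, width) at closed-form
  # amplitude: maximize Q(c, s) = (sum g r w)^2 / sum g^2 w with
  # g = exp(-(x - c)^2 / (2 s^2)), c within +/- 2 sigma0 (clipped to
  # centre_bounds), s within [sigma0/3, 3 sigma0]
  j <- window_idx(x, centre, 8 * sigma0)
  xs <- x[j]; rs <- r[j]
  w <- if (is.null(sig)) rep(1, length(j)) else 1 / sig[j]^2
  # centre parametrized in units of sigma0 so L-BFGS-B finite differences
  # see O(1) parameters
  q <- function(par) {
    cc <- centre + par[1] * sigma0
    g <- exp(-(xs - cc)^2 / (2 * exp(2 * par[2])))
    s2 <- sum(g^2 * w)
    if (s2 <= 0) return(0)
    -sum(g * rs * w)^2 / s2
  }
  lo_c <- centre - 2 * sigma0
  hi_c <- centre + 2 * sigma0
  if (!is.null(centre_bounds)) {
    lo_c <- max(lo_c, centre_bounds[1])
    hi_c <- min(hi_c, centre_bounds[2])
  }
  if (hi_c <= lo_c) return(list(centre = centre, sigma = sigma0))
  opt <- tryCatch(
    stats::optim(c(0, log(sigma0)), q, method = "L-BFGS-B",
                 lower = c((lo_c - centre) / sigma0, log(width_bounds[1])),
                 upper = c((hi_c - centre) / sigma0, log(width_bounds[2]))),
    error = function(e) NULL)
  if (is.null(opt)) return(list(centre = centre, sigma = sigma0))
  list(centre = centre + opt$par[1] * sigma0, sigma = exp(opt$par[2]))
}

#' Estimate the local noise scale of a residual profile
#'
#' Fragment-count noise grows with the local mean, so fragments near the
#' viewpoint fluctuate far more than far-cis fragments and a single global
#' scale misstates both. When the profile carries raw counts (the usual
#' case), the noise is modelled as negative binomial on the count scale,
#' `var(c) = mu + mu^2 / phi`, with the dispersion estimated in two steps:
#' a trimmed-mean moment pilot of the per-fragment statistic
#' `((c - mu)^2 - mu) / mu^2` (exactly unbiased for `1/phi` at any `mu`),
#' then maximum likelihood restricted to fragments within 5 pilot standard
#' deviations (clipping removes peak-inflated fragments). On the
#' normalized signal scale
#' this gives `sigma(m) = sqrt(nc * m + m^2 / phi)` with `nc` the
#' normalization constant and `m` the expected signal. Without counts it
#' falls back to a power law `sigma(m) = A * m^b` fitted to binned MADs of
#' the residuals, or to the constant global MAD when even that is
#' impossible.
#'
#' @param residual_profile Output of [subtract_background()].
#' @param trim Trim fraction per tail for the dispersion estimate
#'   (default 0.05).
#' @return A function `sigma(m)` mapping expected signal level to noise
#'   scale, with attributes `method` (`"nb"`, `"power"` or `"constant"`)
#'   and the estimated coefficients.
#' @export
estimate_noise_model <- function(residual_profile, trim = 0.05) {
  bg <- attr(residual_profile, "background")
  vp <- attr(residual_profile, "viewpoint")
  stopifnot(inherits(bg, "fourc_background"))
  cis <- residual_profile[
    residual_profile$chrom == vp$chrom &
      abs(residual_profile$midpoint - vp$centre) <= vp$norm_radius, ]
  m <- predict(bg, abs(cis$midpoint - vp$centre))
  r <- cis$residual
  global <- estimate_noise(r)
  floor_s <- global / 10  # never let the local scale collapse

  nc <- attr(residual_profile, "norm_constant")
  counts <- cis$count
  if (!is.null(nc) && !is.null(counts) && !anyNA(counts) && nc > 0) {
    mu <- pmax(m / nc, .Machine$double.eps)   # expected raw count
    # moment pilot, then maximum likelihood on fragments not grossly
    # inflated by peaks (clip at 5 pilot standard deviations)
    tstat <- ((counts - mu)^2 - mu) / mu^2    # E[t] = 1/phi for NB(mu, phi)
    inv_phi0 <- max(1e-6, mean(tstat, trim = trim))
    sd0 <- sqrt(mu + inv_phi0 * mu^2)
    ok_mle <- abs(counts - mu) < 5 * sd0
    nll <- function(log_phi) {
      -sum(stats::dnbinom(counts[ok_mle], mu = mu[ok_mle],
                          size = exp(log_phi), log = TRUE))
    }
    opt <- tryCatch(
      stats::optimize(nll, interval = log(c(1e-2, 1e6))),
      error = function(e) NULL)
    inv_phi <- if (is.null(opt)) inv_phi0 else {
      if (opt$minimum >= log(1e6) - 0.01) 0 else exp(-opt$minimum)
    }
    f <- function(mm) {
      mm <- pmax(mm, 0)
      pmax(floor_s, sqrt(nc * mm + inv_phi * mm^2))
    }
    attr(f, "method") <- "nb"
    attr(f, "coef") <- c(nc = nc, inv_phi = inv_phi,
                         phi = if (inv_phi > 0) 1 / inv_phi else Inf)
    return(f)
  }

  # fallback: power law sigma(m) = A * m^b from distance-binned MADs
  d <- abs(cis$midpoint - vp$centre)
  ok <- is.finite(m) & m > 0
  if (sum(ok) >= 200 && diff(range(log(m[ok]))) > 0.5) {
    qs <- unique(stats::quantile(log(pmax(d[ok], 1)),
                                 probs = seq(0, 1, length.out = 25)))
    bin <- cut(log(pmax(d[ok], 1)), breaks = qs, include.lowest = TRUE)
    tb <- tibble(m = m[ok], r = r[ok], bin = bin) |>
      group_by(.data$bin) |>
      summarise(mu = mean(.data$m), s = mad(.data$r), n = n(),
                .groups = "drop") |>
      filter(.data$s > 0, .data$n >= 10)
    if (nrow(tb) >= 3 && diff(range(log(tb$mu))) > 0.1) {
      fit <- stats::lm(log(s) ~ log(mu), data = tb, weights = tb$n)
      b <- max(0, min(1.5, unname(coef(fit)[2])))
      A <- exp(unname(coef(fit)[1]))
      f <- function(mm) pmax(floor_s, A * pmax(mm, .Machine$double.eps)^b)
      attr(f, "method") <- "power"
      attr(f, "coef") <- c(A = A, b = b)
      return(f)
    }
  }
  f <- function(mm) rep(global, length(mm))
  attr(f, "method") <- "constant"
  attr(f, "coef") <- c(A = global, b = 0)
  f
}

joint_refine_peaks <- function(x_all, r_all, sig_all, centres, sigmas,
                               sigma0, side_bounds) {
  # joint weighted least-squares refit of all called peaks: centres and
  # log-widths by L-BFGS-B, amplitudes profiled out by weighted linear LS;
  # restricted to the union of +/- 6 sigma0 windows around the calls
  K <- length(centres)
  J <- sort(unique(unlist(lapply(centres, function(c0)
    window_idx(x_all, c0, 6 * sigma0)))))
  x <- x_all[J]; r <- r_all[J]; sig <- sig_all[J]
  w <- 1 / sig^2
  shapes <- function(cc, ss) {
    G <- matrix(0, length(x), K)
    for (k in seq_len(K)) G[, k] <- exp(-(x - cc[k])^2 / (2 * ss[k]^2))
    G
  }
  amps_for <- function(G) {
    M <- crossprod(G, G * w)
    b <- crossprod(G, r * w)
    A <- tryCatch(drop(solve(M, b)), error = function(e) rep(0, K))
    pmax(A, 0)
  }
  # centres parametrized as offsets in units of sigma0 (O(1) for L-BFGS-B)
  obj <- function(par) {
    cc <- centres + par[seq_len(K)] * sigma0
    ss <- exp(par[K + seq_len(K)])
    G <- shapes(cc, ss)
    A <- amps_for(G)
    sum(w * (r - drop(G %*% A))^2)
  }
  lo <- c(pmax(-2, (side_bounds[, 1] - centres) / sigma0),
          rep(log(sigma0 / 3), K))
  hi <- c(pmin(2, (side_bounds[, 2] - centres) / sigma0),
          rep(log(3 * sigma0), K))
  par0 <- pmin(pmax(c(rep(0, K), log(sigmas)), lo), hi)
  opt <- tryCatch(
    stats::optim(par0, obj, method = "L-BFGS-B", lower = lo, upper = hi,
                 control = list(maxit = 200)),
    error = function(e) NULL)
  par <- if (is.null(opt)) par0 else opt$par
  cc <- centres + par[seq_len(K)] * sigma0
  ss <- exp(par[K + seq_len(K)])
  G <- shapes(cc, ss)
  A <- amps_for(G)
  G_full <- matrix(0, length(x_all), K)
  for (k in seq_len(K)) {
    G_full[, k] <- exp(-(x_all - cc[k])^2 / (2 * ss[k]^2))
  }
  list(centres = cc, sigmas = ss, amps = A, shapes = G_full)
}

gls_amplitude <- function(x, r, sig, centre, sigma, bg_var = NULL) {
  # weighted LS amplitude of a fixed-width Gaussian at `centre` and its z:
  # P = sum(g r / sig^2) / sum(g^2 / sig^2), z = P / sd(P) with
  # var(P) = 1 / sum(g^2 / sig^2) plus, when `bg_var` is given, the
  # delta-method variance of the kernel-weighted background prediction --
  # near the viewpoint the subtracted decay curve is itself uncertain and
  # ignoring that inflates z at the exclusion-window edge; for constant sig
  # and an exact background this is z = P * sqrt(k_eff) / scale
  j <- window_idx(x, centre, 4 * sigma)
  g <- exp(-(x[j] - centre)^2 / (2 * sigma^2))
  w <- 1 / sig[j]^2
  denom <- sum(g^2 * w)
  if (denom <= 0) return(list(P = 0, z = 0, k_eff = 0))
  P <- sum(g * r[j] * w) / denom
  v <- 1 / denom
  if (!is.null(bg_var)) {
    a <- drop(crossprod(bg_var$J[j, , drop = FALSE], g * w)) / denom
    v <- v + drop(t(a) %*% bg_var$cov %*% a)
  }
  list(P = P, z = P / sqrt(v), k_eff = sum(g^2))
}

bg_gradient <- function(bg, d) {
  # jacobian of B + I_v exp(-d/lambda) wrt (B, I_v, lambda)
  e <- exp(-d / bg$lambda)
  cbind(1, e, bg$I_v * e * d / bg$lambda^2)
}

#' Detect Gaussian interaction peaks in a background-subtracted profile
#'
#' Candidate positions are local maxima of the noise-standardized residual
#' series after a centred running-mean smoothing over `smooth_k` retained
#' fragments. Each candidate is scored by the least-squares amplitude `P` of
#' a fixed-width Gaussian kernel (width `sigma`) at its position, weighted by
#' the local noise scale; under the noise model the statistic
#' `z = P * sqrt(sum(g^2 / sigma_noise^2))` is standard normal (for constant
#' noise `scale` this is `z = P * sqrt(k_eff) / scale` with `k_eff` the
#' effective number of fragments under the kernel), and the one-sided
#' upper-tail probability is the peak's p-value.
#'
#' Significant peaks (`p < alpha`) are called greedily: the best candidate
#' is accepted, its centre and width refined by least squares (centre free
#' within `+/- 2 * sigma` but never inside the exclusion window, width
#' within a factor 2 of `sigma`), its fitted Gaussian subtracted from the
#' residuals (raising the local noise model by its mean), and the series
#' rescanned, so one physical interaction cannot be called twice through
#' its shoulders. Candidates closer than `sigma` to the exclusion window
#' are ineligible (half-truncated kernel). The called set is then refitted
#' jointly and each call re-tested against the full model of the others;
#' calls closer than `2 * sigma` are merged, keeping the smaller p-value.
#' Remaining candidates of the final scan are reported as non-significant
#' with their p-values.
#'
#' @param residual_profile Output of [subtract_background()].
#' @param scale Global noise scale from [estimate_noise()]; used as the
#'   constant noise model when `variance` is `NULL`.
#' @param sigma Shared Gaussian peak width, bp (default 20 kb).
#' @param alpha Significance threshold on the p-value (default 0.0005).
#' @param smooth_k Running-mean window in fragments (odd, default 5).
#' @param variance Optional per-fragment noise scale: a function `sigma(m)`
#'   from [estimate_noise_model()] or a numeric vector aligned with the
#'   in-window fragments; `NULL` means constant `scale`.
#' @param refine Refine significant peak centres by least squares
#'   (default TRUE).
#' @param max_peaks Cap on greedy iterations (default 30).
#' @return A tibble of peak calls sorted by position: `chrom`, `centre`,
#'   `centre_raw`, `amplitude`, `sigma`, `k_eff`, `z`, `p_value`,
#'   `significant`.
#' @export
detect_peaks <- function(residual_profile, scale, sigma = 2e4, alpha = 5e-4,
                         smooth_k = 5, variance = NULL, refine = TRUE,
                         max_peaks = 30) {
  if (sigma <= 0) abort("`sigma` must be positive.")
  if (scale <= 0) abort("`scale` must be positive.")
  if (smooth_k < 1 || smooth_k %% 2 == 0) {
    abort("`smooth_k` must be a positive odd integer.")
  }
  vp <- attr(residual_profile, "viewpoint")
  cis <- residual_profile[
    residual_profile$chrom == vp$chrom &
      abs(residual_profile$midpoint - vp$centre) <= vp$norm_radius, ]
  empty <- tibble(chrom = character(), centre = numeric(),
                  centre_raw = numeric(), amplitude = numeric(),
                  sigma = numeric(), k_eff = numeric(), z = numeric(),
                  p_value = numeric(), significant = logical())
  if (nrow(cis) == 0) return(empty)
  cis <- cis[order(cis$midpoint), ]
  x <- cis$midpoint
  r <- cis$residual

  bg <- attr(residual_profile, "background")
  sig_fun <- NULL
  m_model <- NULL
  sig_local <- if (is.null(variance)) {
    rep(scale, length(x))
  } else if (is.function(variance)) {
    if (is.null(bg)) abort("variance function needs a background attribute.")
    sig_fun <- variance
    m_model <- predict(bg, abs(x - vp$centre))
    sig_fun(m_model)
  } else {
    stopifnot(length(variance) == length(x))
    as.numeric(variance)
  }
  if (any(sig_local <= 0)) abort("noise scale must be strictly positive.")
  bgv <- if (!is.null(bg) && !is.null(bg$cov)) {
    list(J = bg_gradient(bg, abs(x - vp$centre)), cov = bg$cov)
  } else NULL

  scan <- function(r_cur) {
    smoothed <- running_mean(r_cur / sig_local, smooth_k)
    cand <- local_maxima(smoothed)
    # candidates closer than sigma to the exclusion window have a
    # half-truncated kernel and cannot be told apart from decay misfit
    cand <- cand[abs(x[cand] - vp$centre) >= vp$exclusion_radius + sigma]
    if (length(cand) == 0) return(empty[0, ])
    res <- purrr::map(x[cand],
                      ~ gls_amplitude(x, r_cur, sig_local, .x, sigma,
                                      bg_var = bgv))
    P <- purrr::map_dbl(res, "P")
    z <- purrr::map_dbl(res, "z")
    k_eff <- purrr::map_dbl(res, "k_eff")
    keep <- is.finite(P) & is.finite(z) & P > 0
    if (!any(keep)) return(empty[0, ])
    zk <- z[keep]
    pk <- pnorm(zk, lower.tail = FALSE)
    tibble(chrom = vp$chrom, centre = x[cand][keep],
           centre_raw = x[cand][keep], amplitude = P[keep],
           sigma = sigma, k_eff = k_eff[keep], z = zk,
           p_value = pk, significant = pk < alpha)
  }

  calls <- empty
  r_cur <- r
  for (iter in seq_len(max_peaks)) {
    cands <- scan(r_cur)
    if (nrow(cands) == 0 || min(cands$p_value) >= alpha) {
      # final scan: keep the remaining candidates as non-significant records
      if (nrow(cands) > 0) {
        cands$significant <- FALSE
        calls <- bind_rows(calls, cands)
      }
      break
    }
    best <- cands[which.max(cands$z), ]  # max z: p underflows to 0 for z > 38
    sub_sigma <- best$sigma
    if (refine) {
      # refined centre stays on the candidate's side of the viewpoint,
      # outside the exclusion window
      margin <- vp$exclusion_radius + sigma
      bounds <- if (best$centre_raw >= vp$centre) {
        c(vp$centre + margin, vp$centre + vp$norm_radius)
      } else {
        c(vp$centre - vp$norm_radius, vp$centre - margin)
      }
      ref <- refine_peak(x, r_cur, best$centre_raw, sigma, sig_local,
                         centre_bounds = bounds)
      a_ref <- gls_amplitude(x, r_cur, sig_local, ref$centre, ref$sigma,
                             bg_var = bgv)
      if (a_ref$P > 0) {
        best$centre <- ref$centre
        best$sigma <- ref$sigma
        best$amplitude <- a_ref$P
        sub_sigma <- ref$sigma
      }
    }
    calls <- bind_rows(calls, best)
    contrib <- best$amplitude * exp(-(x - best$centre)^2 / (2 * sub_sigma^2))
    r_cur <- r_cur - contrib
    if (!is.null(sig_fun)) {
      # called peaks raise the local mean, hence the local count noise
      m_model <- m_model + contrib
      sig_local <- sig_fun(m_model)
    }
  }

  # joint refinement of the called set: the greedy pass fits each peak
  # against the residual of its predecessors, so neighbouring peaks bias
  # each other's centre and width; the joint weighted refit removes that,
  # and each call is then re-tested against the full model of the others
  sig_idx <- which(calls$significant)
  if (refine && length(sig_idx) > 0) {
    margin <- vp$exclusion_radius + sigma
    side <- t(vapply(calls$centre_raw[sig_idx], function(c0) {
      if (c0 >= vp$centre) {
        c(vp$centre + margin, vp$centre + vp$norm_radius)
      } else {
        c(vp$centre - vp$norm_radius, vp$centre - margin)
      }
    }, numeric(2)))
    jr <- joint_refine_peaks(x, r, sig_local, calls$centre[sig_idx],
                             calls$sigma[sig_idx], sigma, side)
    calls$centre[sig_idx] <- jr$centres
    calls$sigma[sig_idx] <- jr$sigmas
    calls$amplitude[sig_idx] <- jr$amps
    if (!is.null(sig_fun)) {
      m_model <- predict(bg, abs(x - vp$centre)) +
        drop(jr$shapes %*% jr$amps)
      sig_local <- sig_fun(m_model)
    }
    for (k in seq_along(sig_idx)) {
      i <- sig_idx[k]
      others <- drop(jr$shapes[, -k, drop = FALSE] %*% jr$amps[-k])
      rt <- gls_amplitude(x, r - others, sig_local, calls$centre[i], sigma,
                          bg_var = bgv)
      calls$z[i] <- rt$z
      calls$k_eff[i] <- rt$k_eff
      calls$p_value[i] <- pnorm(rt$z, lower.tail = FALSE)
      calls$significant[i] <- calls$p_value[i] < alpha &&
        calls$amplitude[i] > 0
    }
  }

  # merge calls closer than 2*sigma (refined centres may collide), best p wins
  sig_calls <- calls[calls$significant, ]
  if (nrow(sig_calls) > 1) {
    sig_calls <- sig_calls[order(sig_calls$p_value, -sig_calls$z), ]
    kept <- sig_calls[0, ]
    for (i in seq_len(nrow(sig_calls))) {
      if (nrow(kept) == 0 ||
          all(abs(kept$centre - sig_calls$centre[i]) >= 2 * sigma)) {
        kept <- bind_rows(kept, sig_calls[i, ])
      }
    }
    calls <- bind_rows(kept, calls[!calls$significant, ])
  }
  arrange(calls, .data$centre)
}

#' Evaluate the fitted 4C signal model
#'
#' Reconstructs `S(x) = B + I_v * exp(-|x - x_v| / lambda) +
#' sum_i P_i * exp(-(x - x_i)^2 / (2 sigma_i^2))` from the stored fit, the
#' sum running over the significant interaction peaks.
#'
#' @param fit A `fourc_fit` from [call_interactions()].
#' @param x Coordinates (bp) on the viewpoint chromosome.
#' @return Numeric vector `S(x)`.
#' @export
evaluate_model <- function(fit, x) {
  stopifnot(inherits(fit, "fourc_fit"))
  bg <- fit$background
  s <- predict(bg, abs(x - fit$viewpoint$centre))
  pk <- fit$peaks[fit$peaks$significant, , drop = FALSE]
  for (i in seq_len(nrow(pk))) {
    s <- s + pk$amplitude[i] * exp(-(x - pk$centre[i])^2 / (2 * pk$sigma[i]^2))
  }
  s
}

#' Fit the full 4C signal model and call interaction peaks
#'
#' Composition of the analysis stages: fold the profile around the viewpoint,
#' fit the constant + exponential-decay background on the folded profile,
#' subtract it, estimate the residual noise scale by MAD, and detect
#' significant Gaussian interaction peaks. Deterministic given the profile
#' and the configuration.
#'
#' @param profile A `fourc_profile` from [normalize_profile()].
#' @param sigma Shared peak width, bp (default 20 kb).
#' @param alpha Peak significance threshold (default 0.0005).
#' @param smooth_k Running-mean window, fragments (default 5).
#' @param bin_width Folding bin width, bp (default 5 kb).
#' @param trim,trim_cycles Robust-trimming controls for [fit_background()].
#' @param refine Refine significant peak centres (default TRUE).
#' @param local_noise Use the count-level-dependent noise model from
#'   [estimate_noise_model()] for peak significance (default TRUE); `FALSE`
#'   falls back to the constant global MAD scale.
#' @return A `fourc_fit` object with fields `background`, `peaks`,
#'   `residual_scale`, `alpha`, `sigma`, `viewpoint`, `profile` (with
#'   residuals), `folded` and `diagnostics`. Supports [tidy()], [glance()],
#'   [augment()], [evaluate_model()] and `autoplot()`.
#' @export
call_interactions <- function(profile, sigma = 2e4, alpha = 5e-4,
                              smooth_k = 5, bin_width = 5000, trim = 0.10,
                              trim_cycles = 2, refine = TRUE,
                              local_noise = TRUE) {
  folded <- fold_profile(profile, bin_width = bin_width)
  bg <- fit_background(folded, trim = trim, trim_cycles = trim_cycles)
  resid_prof <- subtract_background(profile, bg)
  vp <- attr(profile, "viewpoint")
  in_win <- resid_prof$chrom == vp$chrom &
    abs(resid_prof$midpoint - vp$centre) <= vp$norm_radius
  scale <- estimate_noise(resid_prof$residual[in_win])
  noise_model <- if (local_noise) estimate_noise_model(resid_prof) else NULL
  if (!is.null(noise_model)) {
    # second pass: refit the decay at fragment resolution (the binned fold
    # is a smoothing device; per-fragment fitting on the folded distance
    # axis is what it approximates) with generalized-least-squares weights
    # from the estimated noise model, then re-estimate the noise model --
    # decay-length precision directly limits near-viewpoint specificity
    cis_w <- profile[in_win, ]
    d_frag <- abs(cis_w$midpoint - vp$centre)
    # fit only fragments from distance bins the robust binned pass kept:
    # peak contamination is identified at bin level, where count skew
    # averages out; per-fragment one-sided trimming would bias the fit
    kept_bin <- floor(bg$kept_distances / bin_width)
    clean <- floor(d_frag / bin_width) %in% kept_bin
    folded_frag <- tibble(
      distance = d_frag[clean], signal = cis_w$signal[clean],
      support = 1) |>
      arrange(.data$distance)
    bg <- fit_background(folded_frag, trim = 0, trim_cycles = 2,
                         variance_fun = function(m) noise_model(m)^2)
    resid_prof <- subtract_background(profile, bg)
    scale <- estimate_noise(resid_prof$residual[in_win])
    noise_model <- estimate_noise_model(resid_prof)
  }
  peaks <- detect_peaks(resid_prof, scale, sigma = sigma, alpha = alpha,
                        smooth_k = smooth_k, variance = noise_model,
                        refine = refine)
  structure(
    list(background = bg, peaks = peaks, residual_scale = scale,
         noise_model = noise_model,
         alpha = alpha, sigma = sigma, smooth_k = smooth_k,
         bin_width = bin_width, viewpoint = vp, profile = resid_prof,
         folded = folded,
         diagnostics = list(converged = bg$converged,
                            iterations = bg$iterations,
                            n_fragments = sum(in_win),
                            n_candidates = nrow(peaks),
                            n_significant = sum(peaks$significant))),
    class = "fourc_fit"
  )
}

#' @export
print.fourc_fit <- function(x, ...) {
  cat("<fourc_fit>\n")
  cat(sprintf("  viewpoint  %s:%s (centre)\n", x$viewpoint$chrom,
              format(x$viewpoint$centre, scientific = FALSE)))
  cat(sprintf("  background B = %.4g, I_v = %.4g, lambda = %.4g kb%s\n",
              x$background$B, x$background$I_v, x$background$lambda / 1e3,
              if (x$background$converged) "" else " (not converged)"))
  cat(sprintf("  noise      MAD scale = %.4g\n", x$residual_scale))
  cat(sprintf("  peaks      %d significant of %d candidates (alpha = %g)\n",
              x$diagnostics$n_significant, x$diagnostics$n_candidates,
              x$alpha))
  sig <- x$peaks[x$peaks$significant, ]
  if (nrow(sig) > 0) {
    print(as_tibble(sig[, c("chrom", "centre", "amplitude", "sigma", "p_value")]))
  }
  invisible(x)
}

#' Tidy a 4C model fit into its peak calls
#'
#' @param x A `fourc_fit`.
#' @param ... Unused.
#' @return The peak-call tibble (all candidates, with `significant` flags).
#' @exportS3Method generics::tidy
tidy.fourc_fit <- function(x, ...) x$peaks

#' One-row summary of a 4C model fit
#'
#' @param x A `fourc_fit`.
#' @param ... Unused.
#' @return A one-row tibble with the background parameters, noise scale and
#'   call counts.
#' @exportS3Method generics::glance
glance.fourc_fit <- function(x, ...) {
  tibble(B = x$background$B, I_v = x$background$I_v,
         lambda = x$background$lambda,
         residual_scale = x$residual_scale,
         n_fragments = x$diagnostics$n_fragments,
         n_candidates = x$diagnostics$n_candidates,
         n_significant = x$diagnostics$n_significant,
         alpha = x$alpha, sigma = x$sigma,
         converged = x$background$converged)
}

#' Per-fragment fitted values and residuals
#'
#' @param x A `fourc_fit`.
#' @param ... Unused.
#' @return The profile tibble with `.fitted` (full model) and `.resid`
#'   (signal minus full model) columns.
#' @exportS3Method generics::augment
augment.fourc_fit <- function(x, ...) {
  out <- x$profile
  vp <- x$viewpoint
  fitted <- ifelse(out$chrom == vp$chrom,
                   evaluate_model(x, out$midpoint), x$background$B)
  out$.fitted <- fitted
  out$.resid <- out$signal - fitted
  as_tibble(out)
}
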