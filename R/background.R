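#' Fold a profile around the viewpoint
#'
#' Maps every retained in-window fragment on the viewpoint chromosome to its
#' absolute distance `d = |midpoint - centre|` and averages the signal within
#' distance bins, pooling the left and right arms. 4C contact decay is
#' assumed symmetric around the viewpoint, so the folded profile doubles the
#' support available for the background fit. Bins with no fragments are
#' absent from the result.
#'
#' @param profile A `fourc_profile` from [normalize_profile()].
#' @param bin_width Distance-bin width in bp (default 5 kb).
#' @return A tibble with columns `distance` (bin centre, bp), `signal`
#'   (mean in-bin signal) and `support` (number of contributing fragments).
#' @export
fold_profile <- function(profile, bin_width = 5000) {
  vp <- attr(profile, "viewpoint")
  stopifnot(inherits(vp, "fourc_viewpoint"), bin_width > 0)
  cis <- profile[profile$chrom == vp$chrom &
                   abs(profile$midpoint - vp$centre) <= vp$norm_radius, ]
  if (nrow(cis) == 0) abort("empty profile: no fragments on the viewpoint chromosome.")
  side <- sign(cis$midpoint - vp$centre)
  if (all(side >= 0) || all(side <= 0)) {
    warn("profile is one-sided around the viewpoint; folding uses one arm only.")
  }
  d <- abs(cis$midpoint - vp$centre)
  folded <- tibble(bin = floor(d / bin_width), signal = cis$signal) |>
    group_by(.data$bin) |>
    summarise(signal = mean(.data$signal), support = n(), .groups = "drop") |>
    mutate(distance = (.data$bin + 0.5) * bin_width) |>
    arrange(.data$distance) |>
    select("distance", "signal", "support")
  attr(folded, "bin_width") <- bin_width
  attr(folded, "viewpoint") <- vp
  folded
}

#' Fit the constant + exponential-decay background
#'
#' Models the folded profile as `a(d) = B + I_v * exp(-d / lambda)`: a
#' constant far-cis background `B` plus the monotonic distance decay of 4C
#' signal away from the viewpoint, with amplitude `I_v` at the viewpoint and
#' decay length `lambda`. Fitting is bounded Levenberg-Marquardt nonlinear
#' least squares, initialized by a 50%-breakdown Theil-Sen backbone over a
#' decay-length grid and made robust to interaction peaks by threshold
#' trimming: per cycle, bins whose standardized positive residual exceeds 3
#' (putative peaks) are discarded, at most a `trim` fraction of bins, and
#' the model refit with variance-tracking weights.
#'
#' Bounds: `lambda` in `[1 kb, 10 Mb]`, `B, I_v >= 0`. A flat profile
#' degenerates to `B = mean(a)`, `I_v = 0`, `lambda` at its lower bound,
#' flagged as not converged.
#'
#' @param folded Output of [fold_profile()] (needs >= 3 distinct bins); any
#'   tibble with `distance`, `signal`, `support` columns works, including a
#'   per-fragment one (`support = 1`).
#' @param trim Maximum fraction of bins dropped per robust cycle; 0
#'   disables trimming (weights still iterate).
#' @param trim_cycles Number of trim/reweight cycles (default 2).
#' @param lambda_bounds Length-2 numeric, bp (default `c(1e3, 1e7)`).
#' @param variance_fun Optional per-fragment variance as a function of the
#'   expected signal level; supplies generalized-least-squares weights
#'   (`support / variance`).
#' @return A `fourc_background` object: list with `B`, `I_v`, `lambda`,
#'   `converged`, `iterations`, `n_bins_used`, the parameter covariance
#'   `cov` and the retained `kept_distances`.
#' @export
fit_background <- function(folded, trim = 0.10, trim_cycles = 2,
                           lambda_bounds = c(1e3, 1e7),
                           variance_fun = NULL) {
  stopifnot(all(c("distance", "signal", "support") %in% names(folded)))
  d <- folded$distance
  a <- folded$signal
  w0 <- folded$support
  if (length(unique(d)) < 3) abort("need at least 3 distinct distance bins.")

  if (diff(range(a)) < .Machine$double.eps * max(1, max(abs(a)))) {
    return(new_fourc_background(B = mean(a), I_v = 0,
                                lambda = lambda_bounds[1],
                                converged = FALSE, iterations = 0L,
                                n_bins_used = length(d),
                                degenerate = TRUE))
  }

  # starting values
  outer <- d >= stats::quantile(d, 0.8)
  B0 <- max(0, median(a[outer]))
  excess <- a - B0
  pos <- excess > 0
  if (sum(pos) >= 3) {
    sl <- stats::lm(log(excess[pos]) ~ d[pos])
    slope <- coef(sl)[2]
    lambda0 <- if (is.finite(slope) && slope < 0) -1 / slope else median(d)
    Iv0 <- max(exp(coef(sl)[1]), .Machine$double.eps)
  } else {
    lambda0 <- median(d)
    Iv0 <- max(max(a) - B0, .Machine$double.eps)
  }
  lambda0 <- min(max(lambda0, lambda_bounds[1]), lambda_bounds[2])

  fit_once <- function(d, a, w, start) {
    tryCatch(
      minpack.lm::nlsLM(
        a ~ B + Iv * exp(-d / lambda),
        data = data.frame(d = d, a = a),
        start = start, weights = w,
        lower = c(B = 0, Iv = 0, lambda = lambda_bounds[1]),
        upper = c(B = Inf, Iv = Inf, lambda = lambda_bounds[2]),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
  }

  # robust backbone: for each decay length on a log grid, fit the linear
  # pair (B, I_v) against t = exp(-d/lambda) by Theil-Sen (50% breakdown)
  # and keep the lambda with the smallest median absolute residual; heavy
  # peak contamination cannot steer this the way it steers least squares
  robust_init <- function() {
    # deterministic systematic pair sample (index gaps at several scales):
    # no RNG, O(budget) memory even for fragment-resolution input
    n <- length(d)
    budget <- 2e4
    gaps <- unique(pmax(1L, round(n / c(2, 3, 5, 8, 13, 21))))
    per_gap <- ceiling(budget / length(gaps))
    pairs_i <- integer(0); pairs_j <- integer(0)
    for (g in gaps) {
      if (g >= n) next
      ii <- seq.int(1L, n - g, by = max(1L, ceiling((n - g) / per_gap)))
      pairs_i <- c(pairs_i, ii)
      pairs_j <- c(pairs_j, ii + g)
    }
    lam_grid <- exp(seq(log(max(lambda_bounds[1], min(d[d > 0]))),
                        log(min(lambda_bounds[2], 2 * max(d))),
                        length.out = 25))
    best <- list(crit = Inf, B = B0, Iv = Iv0, lambda = lambda0)
    for (lam in lam_grid) {
      t <- exp(-d / lam)
      dt <- t[pairs_i] - t[pairs_j]
      use <- abs(dt) > 1e-9
      if (sum(use) < 10) next
      slope <- median((a[pairs_i] - a[pairs_j])[use] / dt[use])
      slope <- max(slope, 0)
      inter <- max(median(a - slope * t), 0)
      crit <- median(abs(a - inter - slope * t))
      if (crit < best$crit) {
        best <- list(crit = crit, B = inter, Iv = slope, lambda = lam)
      }
    }
    best
  }
  rob <- robust_init()
  start <- list(B = rob$B, Iv = rob$Iv,
                lambda = min(max(rob$lambda, lambda_bounds[1]),
                             lambda_bounds[2]))

  keep <- rep(TRUE, length(d))
  # pre-trim gross outliers against the robust backbone before any least
  # squares touches the data (only when trimming is enabled: for skewed
  # per-fragment counts a one-sided cut biases the mean)
  if (trim > 0 && trim_cycles > 0) {
    res0 <- a - (start$B + start$Iv * exp(-d / start$lambda))
    s0 <- mad(res0)
    if (is.finite(s0) && s0 > 0) {
      keep[res0 / s0 > 3] <- FALSE
    }
  }
  bin_var <- function(m_hat) {
    # per-bin residual variance: from the supplied per-fragment variance
    # model when available (GLS), else estimated from the data each cycle
    if (is.null(variance_fun)) return(NULL)
    pmax(variance_fun(m_hat), .Machine$double.eps) / w0
  }
  m_rob <- start$B + start$Iv * exp(-d / start$lambda)
  weights <- if (is.null(variance_fun)) w0 else 1 / bin_var(pmax(m_rob, 0))
  fit <- NULL
  iterations <- 0L
  for (cycle in seq_len(trim_cycles + 1)) {
    f <- fit_once(d[keep], a[keep], weights[keep], start)
    if (is.null(f)) break
    fit <- f
    iterations <- iterations + f$convInfo$finIter
    p <- coef(f)
    start <- list(B = unname(p["B"]), Iv = unname(p["Iv"]),
                  lambda = unname(p["lambda"]))
    if (cycle > trim_cycles) break

    # peak-robust trimming with a noise model that tracks the signal level:
    # bin noise scales roughly as m^gamma, with gamma fit from the absolute
    # residuals; only bins whose standardized positive residual exceeds 3
    # are putative peaks, and at most `trim` of all bins go per cycle --
    # a fixed-fraction cut would clip the upper noise tail under a peakless
    # profile and bias the whole fit low
    m_hat <- pmax(start$B + start$Iv * exp(-d / start$lambda),
                  .Machine$double.eps)
    res <- a - m_hat
    if (is.null(variance_fun)) {
      g_fit <- stats::lm(log(pmax(abs(res), 1e-12)) ~ log(m_hat),
                         subset = keep)
      gamma <- max(0, min(1.5, unname(coef(g_fit)[2])))
      u <- res / m_hat^gamma
      s_u <- mad(u[keep])
      if (!is.finite(s_u) || s_u <= 0) next
      std <- u / s_u
      weights <- w0 / m_hat^(2 * gamma)
    } else {
      v <- bin_var(m_hat)
      std <- res / sqrt(v)
      s_std <- mad(std[keep])
      if (is.finite(s_std) && s_std > 0) std <- std / max(s_std, 1)
      weights <- 1 / v
    }
    if (trim <= 0) next  # IRLS weight update only, no trimming
    cand <- which(keep & std > 3)
    n_max <- floor(trim * length(d))
    if (length(cand) == 0 || n_max == 0) next
    drop <- cand[order(std[cand], decreasing = TRUE)][
      seq_len(min(n_max, length(cand)))]
    keep[drop] <- FALSE
  }

  if (is.null(fit)) {
    return(new_fourc_background(B = start$B, I_v = start$Iv,
                                lambda = start$lambda, converged = FALSE,
                                iterations = iterations,
                                n_bins_used = sum(keep)))
  }
  p <- coef(fit)
  cov <- tryCatch(unname(stats::vcov(fit)), error = function(e) NULL)
  out <- new_fourc_background(B = unname(p["B"]), I_v = unname(p["Iv"]),
                              lambda = unname(p["lambda"]),
                              converged = fit$convInfo$isConv,
                              iterations = iterations,
                              n_bins_used = sum(keep), cov = cov)
  out$kept_distances <- d[keep]
  out
}

new_fourc_background <- function(B, I_v, lambda, converged, iterations,
                                 n_bins_used, degenerate = FALSE,
                                 cov = NULL) {
  stopifnot(is.finite(B), is.finite(I_v), is.finite(lambda),
            B >= 0, I_v >= 0, lambda > 0)
  if (!is.null(cov) && (!is.matrix(cov) || any(!is.finite(cov)))) cov <- NULL
  structure(
    list(B = B, I_v = I_v, lambda = lambda, converged = converged,
         iterations = as.integer(iterations),
         n_bins_used = as.integer(n_bins_used), degenerate = degenerate,
         cov = cov),
    class = "fourc_background"
  )
}

#' @export
print.fourc_background <- function(x, ...) {
  cat(sprintf(
    "<fourc_background> B = %.4g, I_v = %.4g, lambda = %.4g kb (%s, %d bins)\n",
    x$B, x$I_v, x$lambda / 1e3,
    if (x$converged) "converged" else "NOT converged", x$n_bins_used))
  invisible(x)
}

#' Predicted background level at given distances
#'
#' @param object A `fourc_background`.
#' @param distance Non-negative distances from the viewpoint centre, bp.
#' @param ... Unused.
#' @return `B + I_v * exp(-distance / lambda)`.
#' @export
predict.fourc_background <- function(object, distance, ...) {
  object$B + object$I_v * exp(-distance / object$lambda)
}

#' Subtract the fitted background from a profile
#'
#' Computes `r(x) = s(x) - B - I_v * exp(-|x - x_v| / lambda)` per retained
#' fragment. Fragments on other chromosomes are infinitely distant, so only
#' the constant `B` is subtracted there. Residuals may be negative.
#'
#' @param profile A `fourc_profile`.
#' @param bg A `fourc_background`.
#' @return The profile with a `residual` column and a `background` attribute.
#' @export
subtract_background <- function(profile, bg) {
  stopifnot(inherits(bg, "fourc_background"))
  vp <- attr(profile, "viewpoint")
  d <- ifelse(profile$chrom == vp$chrom,
              abs(profile$midpoint - vp$centre), Inf)
  out <- profile
  out$residual <- profile$signal - predict(bg, d)
  attr(out, "background") <- bg
  out
}

#' Robust residual noise scale
#'
#' The median absolute deviation of the residuals, scaled by 1.4826 so it
#' estimates the standard deviation for Gaussian noise while ignoring the
#' interaction peaks themselves.
#'
#' @param r Numeric residual vector (>= 10 values).
#' @return Strictly positive scale estimate.
#' @export
estimate_noise <- function(r) {
  r <- r[is.finite(r)]
  if (length(r) < 10) abort("need at least 10 residual points.")
  s <- mad(r, constant = 1.4826)
  if (s <= 0) abort("zero noise estimate: residuals are (nearly) constant.")
  s
}
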