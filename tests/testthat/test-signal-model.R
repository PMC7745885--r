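# helpers for hand-built profiles -------------------------------------------

# minimal normalized profile on one chromosome from midpoints + signals
make_profile <- function(mid, signal, vp, counts = NULL, nc = NULL) {
  stopifnot(length(mid) == length(signal))
  prof <- tibble::tibble(
    chrom = vp$chrom, start = mid - 50, end = mid + 50, length = 100,
    midpoint = mid, frag_class = "valid",
    count = counts %||% rep(NA_real_, length(mid)), signal = signal)
  attr(prof, "viewpoint") <- vp
  if (!is.null(nc)) attr(prof, "norm_constant") <- nc
  class(prof) <- unique(c("fourc_profile", class(prof)))
  prof
}

flat_background <- function(B = 0) {
  fourcall:::new_fourc_background(B = B, I_v = 0, lambda = 1e3,
                                  converged = TRUE, iterations = 0L,
                                  n_bins_used = 0L)
}

test_vp <- function() viewpoint("chrV", 2e6 - 50, 2e6 + 50)

test_that("folding averages left and right arms at matched distances", {
  vp <- test_vp()
  prof <- make_profile(c(2e6 - 1e4, 2e6 + 1e4, 2e6 - 3e4, 2e6 + 3e4),
                       c(4, 4, 2, 6), vp)
  folded <- fold_profile(prof, bin_width = 5000)
  expect_equal(folded$signal[folded$distance == 12500], 4)  # symmetric
  expect_equal(folded$signal[folded$distance == 32500], 4)  # mean of 2 and 6
  expect_equal(folded$support, c(2, 2))
})

test_that("one-sided profiles fold with a warning", {
  vp <- test_vp()
  prof <- make_profile(2e6 + c(1e4, 2e4, 3e4), c(1, 2, 3), vp)
  expect_warning(folded <- fold_profile(prof), "one-sided")
  expect_equal(nrow(folded), 3)
  expect_equal(folded$signal, c(1, 2, 3))
})

test_that("background fit recovers noiseless parameters to 1e-6", {
  d <- (seq_len(100) - 0.5) * 5000
  folded <- tibble::tibble(distance = d,
                           signal = 2 + 8 * exp(-d / 5e4),
                           support = rep(10, 100))
  bg <- fit_background(folded)
  expect_true(bg$converged)
  expect_equal(bg$B, 2, tolerance = 1e-6)
  expect_equal(bg$I_v, 8, tolerance = 1e-6)
  expect_equal(bg$lambda, 5e4, tolerance = 1e-6)
})

test_that("flat profiles degenerate to a pure constant background", {
  folded <- tibble::tibble(distance = c(1, 2, 3) * 1e4,
                           signal = rep(3, 3), support = rep(5, 3))
  bg <- fit_background(folded)
  expect_equal(bg$B, 3, tolerance = 1e-8)
  expect_equal(bg$I_v, 0, tolerance = 1e-8)
  expect_false(bg$converged)  # flagged degenerate
})

test_that("robust trimming keeps lambda near truth under peak contamination", {
  withr::with_seed(2024, {
    d <- (seq_len(100) - 0.5) * 5000
    a <- 2 + 8 * exp(-d / 5e4)
    contaminated <- sample(100, 20)
    a[contaminated] <- a[contaminated] * 10
    folded <- tibble::tibble(distance = d, signal = a,
                             support = rep(10, 100))
    bg <- fit_background(folded)
    expect_lt(abs(bg$lambda - 5e4) / 5e4, 0.15)
  })
})

test_that("background subtraction reproduces the residual identity", {
  vp <- test_vp()
  mid <- 2e6 + seq(-5e5, 5e5, by = 1e4)
  bgt <- fourcall:::new_fourc_background(1.5, 10, 8e4, TRUE, 1L, 10L)
  s <- predict(bgt, abs(mid - vp$centre))
  prof <- make_profile(mid, s, vp)
  rp <- subtract_background(prof, bgt)
  expect_equal(rp$residual, rep(0, length(mid)), tolerance = 1e-12)

  # zero background: residual equals the signal
  rp0 <- subtract_background(prof, flat_background(0))
  expect_equal(rp0$residual, prof$signal)
})

test_that("MAD noise estimate is consistent and robust", {
  withr::with_seed(7, {
    r <- rnorm(10000)
    expect_equal(estimate_noise(r), 1, tolerance = 0.05)
    clean <- estimate_noise(r)
    r_out <- r
    idx <- sample(10000, 500)
    r_out[idx] <- r_out[idx] + rnorm(500, 20, 5)   # 5% gross outliers
    expect_lt(abs(estimate_noise(r_out) - clean) / clean, 0.10)
  })
  expect_error(estimate_noise(rep(2, 100)), "zero noise")
  expect_error(estimate_noise(rnorm(5)), "at least 10")
})

test_that("flat zero residuals yield no peak calls", {
  vp <- test_vp()
  mid <- 2e6 + seq(-1e6, 1e6, by = 500)
  prof <- make_profile(mid, rep(1, length(mid)), vp)
  rp <- subtract_background(prof, flat_background(1))
  calls <- detect_peaks(rp, scale = 1)
  expect_equal(nrow(calls[calls$significant, ]), 0)
})

test_that("an injected Gaussian of 10x noise is called once, near its centre", {
  vp <- test_vp()
  withr::with_seed(99, {
    mid <- 2e6 + seq(-1.5e6, 1.5e6, by = 400)
    mid <- mid[abs(mid - vp$centre) > vp$exclusion_radius]
    for (rep_i in 1:5) {
      x0 <- sample(c(-1, 1), 1) * runif(1, 2e5, 1e6) + 2e6
      r <- rnorm(length(mid)) + 10 * exp(-(mid - x0)^2 / (2 * 2e4^2))
      prof <- make_profile(mid, r, vp)
      rp <- subtract_background(prof, flat_background(0))
      calls <- detect_peaks(rp, scale = 1, sigma = 2e4, alpha = 5e-4)
      sig <- calls[calls$significant, ]
      expect_equal(nrow(sig), 1)
      expect_lt(abs(sig$centre - x0), 2e4)   # within sigma of truth
    }
  })
})

test_that("null peak tests are calibrated in the decision tail", {
  # candidates are local maxima, so moderate p-value quantiles are mildly
  # selection-inflated by construction; what must hold is that the far tail
  # that drives calls is at (or below) nominal and that significant calls
  # on pure noise are rare
  vp <- test_vp()
  n_sig <- 0
  withr::with_seed(314, {
    mid <- 2e6 + seq(-1.5e6, 1.5e6, by = 400)
    mid <- mid[abs(mid - vp$centre) > vp$exclusion_radius]
    pvals <- unlist(lapply(1:30, function(i) {
      prof <- make_profile(mid, rnorm(length(mid)), vp)
      rp <- subtract_background(prof, flat_background(0))
      calls <- detect_peaks(rp, scale = 1)
      n_sig <<- n_sig + sum(calls$significant)
      calls$p_value
    }))
  })
  expect_lt(mean(pvals < 5e-4), 2e-3)   # decision tail at most 4x nominal
  expect_lt(mean(pvals < 1e-2), 4e-2)
  expect_gt(mean(pvals < 0.5), 0.3)     # not degenerate
  expect_lt(n_sig / 30, 0.3)            # well under one false call per profile
})

test_that("evaluate_model reproduces the three-component signal equation", {
  vp <- test_vp()
  mid <- 2e6 + seq(-1e6, 1e6, by = 1e3)
  fit <- structure(
    list(background = fourcall:::new_fourc_background(2, 10, 5e4, TRUE, 1L, 5L),
         peaks = tibble::tibble(
           chrom = "chrV", centre = 2e6 + 3e5, centre_raw = 2e6 + 3e5,
           amplitude = 7, sigma = 2e4, k_eff = 100, z = 50,
           p_value = 0, significant = TRUE),
         viewpoint = vp),
    class = "fourc_fit")
  # at the viewpoint centre with the peak far away: B + I_v
  expect_equal(evaluate_model(fit, vp$centre), 12, tolerance = 1e-6)
  # at the peak centre, decay term ~ e^(-6) * 10 is small but exact
  expect_equal(evaluate_model(fit, 2e6 + 3e5),
               2 + 10 * exp(-3e5 / 5e4) + 7, tolerance = 1e-9)
  # far asymptote -> B
  expect_equal(evaluate_model(fit, 2e6 + 5e7), 2, tolerance = 1e-9)
  # exact closed form on a grid
  expected <- 2 + 10 * exp(-abs(mid - vp$centre) / 5e4) +
    7 * exp(-(mid - (2e6 + 3e5))^2 / (2 * 2e4^2))
  expect_equal(evaluate_model(fit, mid), expected, tolerance = 1e-12)
})

test_that("fitted background is non-increasing in distance", {
  sim <- local_sim_profile(seed = 5)
  fit <- call_interactions(sim$profile)
  d_grid <- seq(0, 2e6, length.out = 500)
  pred <- predict(fit$background, d_grid)
  expect_true(all(diff(pred) <= 1e-12))
})

test_that("call_interactions is deterministic and self-consistent", {
  sim <- local_sim_profile(seed = 11)
  f1 <- call_interactions(sim$profile)
  f2 <- call_interactions(sim$profile)
  expect_equal(tidy(f1), tidy(f2))
  expect_equal(glance(f1), glance(f2))

  # stored residual identity: residual = signal - background prediction
  vp <- f1$viewpoint
  d <- abs(f1$profile$midpoint - vp$centre)
  expect_equal(f1$profile$residual,
               f1$profile$signal - predict(f1$background, d),
               tolerance = 1e-9)
  # augment: .resid = residual - significant-peak component
  aug <- augment(f1)
  pk <- f1$peaks[f1$peaks$significant, ]
  peak_part <- rep(0, nrow(aug))
  for (i in seq_len(nrow(pk))) {
    peak_part <- peak_part +
      pk$amplitude[i] * exp(-(aug$midpoint - pk$centre[i])^2 /
                              (2 * pk$sigma[i]^2))
  }
  expect_equal(aug$.resid, f1$profile$residual - peak_part,
               tolerance = 1e-9)
})

test_that("the fit is equivariant under coordinate translation", {
  shift <- 7.3e5
  sim <- local_sim_profile(seed = 21)
  f1 <- call_interactions(sim$profile)

  prof2 <- sim$profile
  prof2$start <- prof2$start + shift
  prof2$end <- prof2$end + shift
  prof2$midpoint <- prof2$midpoint + shift
  vp1 <- attr(sim$profile, "viewpoint")
  attr(prof2, "viewpoint") <- viewpoint(
    vp1$chrom, vp1$start + shift, vp1$end + shift,
    exclusion_radius = vp1$exclusion_radius, norm_radius = vp1$norm_radius)
  f2 <- call_interactions(prof2)

  expect_equal(f2$background$B, f1$background$B, tolerance = 1e-6)
  expect_equal(f2$background$lambda, f1$background$lambda, tolerance = 1e-6)
  expect_equal(f2$residual_scale, f1$residual_scale, tolerance = 1e-9)
  s1 <- f1$peaks[f1$peaks$significant, ]
  s2 <- f2$peaks[f2$peaks$significant, ]
  expect_equal(nrow(s2), nrow(s1))
  expect_equal(s2$centre, s1$centre + shift, tolerance = 1e-3)
  expect_equal(s2$p_value, s1$p_value, tolerance = 1e-9)
})

test_that("tidy/glance/autoplot expose the fit in broom style", {
  sim <- local_sim_profile(seed = 31)
  fit <- call_interactions(sim$profile)
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("centre", "amplitude", "sigma", "p_value",
                    "significant") %in% names(td)))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_true(all(c("B", "I_v", "lambda", "n_significant") %in% names(gl)))
  p <- ggplot2::autoplot(fit)
  expect_s3_class(p, "ggplot")
})
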