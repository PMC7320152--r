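# Descriptive statistics over a corpus: lag-1 correlations of duration/ISI
# and parametric density fits (exponential durations, power-law sequence
# lengths) scored by repeated two-sample Kolmogorov-Smirnov tests.

#' Pearson correlation between adjacent syllables
#'
#' Collects all pairs of consecutive values *within* sequences (pairs never
#' span a sequence boundary) and runs a Pearson correlation test. For
#' `field = "duration"` the pairs are consecutive syllable durations; for
#' `field = "isi"` they are consecutive inter-syllable intervals.
#'
#' @param corpus a `usv_corpus`.
#' @param field `"duration"` or `"isi"`.
#' @return list with `r`, `p` (t-approximation) and `n_pairs`.
#' @export
adjacent_pair_correlation <- function(corpus, field = c("duration", "isi")) {
  field <- match.arg(field)
  vals <- if (field == "duration") {
    unname(split(corpus$syllables$duration_s, corpus$syllables$seq_id))
  } else {
    corpus_isis(corpus)
  }
  x <- unlist(lapply(vals, function(v) if (length(v) >= 2) v[-length(v)] else numeric(0)))
  y <- unlist(lapply(vals, function(v) if (length(v) >= 2) v[-1] else numeric(0)))
  if (length(x) < 3) {
    stop("only ", length(x), " adjacent pairs; need at least 3 for a correlation")
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n_pairs = length(x))
}

#' Fit a parametric density to binned data and score it by KS resampling
#'
#' Fits `a * exp(b*x)` or `a * x^b` to the histogram density of `values` by
#' nonlinear least squares, then scores the fit by repeatedly drawing
#' `n_sample` values from the empirical sample and from the fitted density
#' (normalized over the observed range) and applying a two-sample
#' Kolmogorov-Smirnov test; the reported statistic and p-value are means over
#' `reps` repetitions.
#'
#' Binning: for the exponential family the histogram bins are anchored at the
#' sample minimum (the support boundary of a shifted exponential), so the
#' first bin is fully inside the support; for the power family the bins are
#' centered on the values (integer sequence lengths fall at bin centers).
#' `a` and `b` are therefore expressed in units of `binwidth`, matching how
#' such fits are conventionally reported.
#'
#' @param values positive numeric vector (at least 100 values).
#' @param family `"exponential"` or `"power"`.
#' @param n_sample draws per KS repetition (default 1000).
#' @param reps number of KS repetitions (default 1000).
#' @param seed optional integer seed for the resampling.
#' @param binwidth histogram bin width in the units of `values`.
#' @return object of class `usv_pdf_fit`: list with `family`, `a`, `b`,
#'   `ks_D`, `ks_p`, `binwidth`.
#' @export
fit_pdf_with_ks <- function(values, family = c("exponential", "power"),
                            n_sample = 1000, reps = 1000, seed = NULL,
                            binwidth = 1) {
  family <- match.arg(family)
  values <- as.numeric(values)
  if (length(values) < 100) stop("need at least 100 values, got ", length(values))
  if (family == "power" && any(values <= 0)) {
    stop("power-law fit requires strictly positive values")
  }
  if (any(!is.finite(values))) stop("non-finite values")
  x <- values / binwidth  # work in bin units

  if (family == "exponential") {
    breaks <- seq(min(x), max(x) + 1, by = 1)
  } else {
    breaks <- seq(min(x) - 0.5, max(x) + 0.5 + 1, by = 1)
  }
  h <- graphics::hist(x, breaks = breaks, plot = FALSE)
  keep <- h$counts > 0
  d <- h$density[keep]
  m <- h$mids[keep]

  # log-linear start, refined by nonlinear least squares on the density scale
  if (family == "exponential") {
    st <- stats::coef(stats::lm(log(d) ~ m))
    start <- list(a = exp(unname(st[1])), b = unname(st[2]))
    fit <- tryCatch(
      stats::nls(d ~ a * exp(b * m), start = start,
                 control = stats::nls.control(warnOnly = TRUE)),
      error = function(e) NULL)
  } else {
    st <- stats::coef(stats::lm(log(d) ~ log(m)))
    start <- list(a = exp(unname(st[1])), b = unname(st[2]))
    fit <- tryCatch(
      stats::nls(d ~ a * m^b, start = start,
                 control = stats::nls.control(warnOnly = TRUE)),
      error = function(e) NULL)
  }
  ab <- if (is.null(fit)) unlist(start) else stats::coef(fit)
  a <- unname(ab["a"]); b <- unname(ab["b"])

  if (!is.null(seed)) set.seed(seed)
  rng <- range(x)
  draw_fitted <- fitted_sampler(family, b, rng, discrete = all(x == round(x)))
  Ds <- numeric(reps); ps <- numeric(reps)
  for (i in seq_len(reps)) {
    s1 <- sample(x, n_sample, replace = TRUE)
    s2 <- draw_fitted(n_sample)
    kt <- suppressWarnings(stats::ks.test(s1, s2))
    Ds[i] <- unname(kt$statistic); ps[i] <- kt$p.value
  }
  structure(list(family = family, a = a, b = b,
                 ks_D = mean(Ds), ks_p = mean(ps), binwidth = binwidth),
            class = "usv_pdf_fit")
}

# Sampler from the fitted family, normalized over the observed range
# (inverse-CDF; for integer-valued power-law data, a discrete sampler over
# the observed integer support).
fitted_sampler <- function(family, b, rng, discrete = FALSE) {
  mn <- rng[1]; mx <- rng[2]
  if (family == "exponential") {
    function(n) {
      u <- stats::runif(n)
      log(exp(b * mn) - u * (exp(b * mn) - exp(b * mx))) / b
    }
  } else if (discrete) {
    support <- seq(max(1, round(mn)), round(mx))
    pr <- support^b
    function(n) sample(support, n, replace = TRUE, prob = pr)
  } else {
    function(n) {
      u <- stats::runif(n)
      if (abs(b + 1) < 1e-12) {
        exp(log(mn) + u * (log(mx) - log(mn)))
      } else {
        (mn^(b + 1) + u * (mx^(b + 1) - mn^(b + 1)))^(1 / (b + 1))
      }
    }
  }
}

#' @export
print.usv_pdf_fit <- function(x, ...) {
  form <- if (x$family == "exponential") "a*exp(b*x)" else "a*x^b"
  cat(sprintf("usv_pdf_fit: %s with a = %.3g, b = %.3g (x in units of %g)\n",
              form, x$a, x$b, x$binwidth))
  cat(sprintf("  mean KS D = %.3f, mean KS p = %.3f\n", x$ks_D, x$ks_p))
  invisible(x)
}
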