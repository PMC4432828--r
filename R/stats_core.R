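#' Two-sided Fisher exact test on a 2x2 table
#'
#' Two-sided p-value by the minimum-likelihood method: the sum of
#' probabilities of all tables (under the hypergeometric null with fixed
#' margins) no more probable than the observed one. This is the convention of
#' `stats::fisher.test`, which does the computation; other tools use the
#' doubling method and can differ.
#'
#' @param table 2x2 matrix of non-negative integer counts, or a length-4
#'   vector filled by row.
#' @return List with `p_value` and `odds_ratio` (conditional MLE).
#' @export
fisher_exact_2x2 <- function(table) {
  m <- as_2x2(table)
  ft <- fisher.test(m, alternative = "two.sided")
  list(p_value = unname(ft$p.value), odds_ratio = unname(ft$estimate))
}

as_2x2 <- function(table) {
  if (is.matrix(table)) {
    stopifnot(all(dim(table) == c(2, 2)))
    m <- table
  } else {
    stopifnot(length(table) == 4)
    m <- matrix(table, 2, 2, byrow = TRUE)
  }
  if (any(m < 0)) stop("negative cell in 2x2 table", call. = FALSE)
  if (any(m != round(m))) stop("non-integer cell in 2x2 table", call. = FALSE)
  if (all(rowSums(m) == 0) || all(colSums(m) == 0)) {
    stop("2x2 table needs at least one positive marginal", call. = FALSE)
  }
  m
}

#' Chi-square test with Yates continuity correction on a 2x2 table
#'
#' Statistic `sum((|O - E| - 0.5)^2 / E)` with the correction floored so the
#' corrected deviation is never negative; p-value from the 1-df chi-square
#' tail (the computation is `stats::chisq.test(correct = TRUE)`).
#'
#' @inheritParams fisher_exact_2x2
#' @return List with `statistic` and `p_value`.
#' @export
chi_square_yates <- function(table) {
  m <- as_2x2(table)
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  if (any(expected == 0)) {
    stop("zero expected count; Yates chi-square undefined", call. = FALSE)
  }
  ct <- suppressWarnings(chisq.test(m, correct = TRUE))
  list(statistic = unname(ct$statistic), p_value = unname(ct$p.value))
}

#' Ratio paired t-test
#'
#' A paired t-test on log10-transformed values — the standard definition of a
#' ratio paired t-test (it tests whether the mean log ratio differs from
#' zero; the base of the logarithm does not change the p-value).
#'
#' @param values_a,values_b Equal-length vectors of positive paired values,
#'   n >= 2.
#' @return List with `t`, `df`, `p_value`, `mean_log10_ratio`.
#' @export
ratio_paired_t <- function(values_a, values_b) {
  stopifnot(length(values_a) == length(values_b), length(values_a) >= 2)
  if (any(values_a <= 0) || any(values_b <= 0)) {
    stop("ratio paired t-test requires positive values (log undefined)",
         call. = FALSE)
  }
  d <- log10(values_a) - log10(values_b)
  if (var(d) == 0) {
    if (all(d == 0)) {
      # identical pairs: no change, by convention t = 0, p = 1
      return(list(t = 0, df = length(d) - 1, p_value = 1,
                  mean_log10_ratio = 0))
    }
    stop("constant non-zero log-ratio with zero variance; ",
         "ratio paired t-test undefined", call. = FALSE)
  }
  tt <- t.test(log10(values_a), log10(values_b), paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = unname(tt$p.value), mean_log10_ratio = mean(d))
}

#' Two-sample t-test
#'
#' Welch by default (no equal-variance assumption); set `welch = FALSE` for
#' the pooled-variance test. Two identical constant samples return `p = 1` by
#' convention rather than erroring.
#'
#' @param sample_a,sample_b Numeric vectors, n >= 2 each.
#' @param welch Use the Welch correction (default `TRUE`).
#' @return List with `t`, `df`, `p_value`, `mean_a`, `mean_b`.
#' @export
two_sample_t <- function(sample_a, sample_b, welch = TRUE) {
  stopifnot(length(sample_a) >= 2, length(sample_b) >= 2)
  if (var(sample_a) == 0 && var(sample_b) == 0) {
    if (mean(sample_a) == mean(sample_b)) {
      return(list(t = 0, df = NA_real_, p_value = 1,
                  mean_a = mean(sample_a), mean_b = mean(sample_b)))
    }
    stop("both samples have zero variance with different means; ",
         "t-test undefined", call. = FALSE)
  }
  tt <- t.test(sample_a, sample_b, var.equal = !welch)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = unname(tt$p.value),
       mean_a = mean(sample_a), mean_b = mean(sample_b))
}

#' Ordinary least-squares fit with slope test
#'
#' Simple linear regression of `y` on `x` with the standard R-squared and the
#' two-sided t-test on the slope (computed through `stats::lm`).
#'
#' @param x,y Numeric vectors, n >= 3, `var(x) > 0`.
#' @return List with `slope`, `intercept`, `r_squared`, `p_value` (slope
#'   test), `n`.
#' @export
ols_fit <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("OLS needs at least 3 complete pairs", call. = FALSE)
  if (var(x) == 0) stop("OLS undefined: zero variance in x", call. = FALSE)
  if (var(y) == 0) {
    # y carries no signal: flat fit, R^2 = 0, slope test undefined
    return(list(slope = 0, intercept = mean(y), r_squared = 0,
                p_value = NA_real_, n = length(x)))
  }
  fit <- lm(y ~ x)
  # suppressWarnings: summary.lm warns on exact fits; outputs stay exact
  sm <- suppressWarnings(summary(fit))
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = sm$r.squared,
       p_value = unname(sm$coefficients["x", "Pr(>|t|)"]),
       n = length(x))
}

#' Gaussian mixture fit by expectation-maximization
#'
#' Fits a k-component univariate Gaussian mixture by maximum likelihood.
#' `k = 1` is closed form (sample mean, maximum-likelihood SD). For `k >= 2`
#' the EM iteration runs from several k-means-style initializations and the
#' best log-likelihood wins; component SDs are floored at `1e-4` of the data
#' range so the likelihood cannot degenerate onto a point mass. The
#' log-likelihood trace is returned; it is non-decreasing by construction of
#' EM.
#'
#' @param values Numeric vector, `n >= 10 * k`.
#' @param k Number of components (1 or 2).
#' @param restarts Number of seeded initializations for `k >= 2`.
#' @param seed Integer seed (results are deterministic given the seed).
#' @param tol Relative log-likelihood convergence tolerance.
#' @param max_iter Maximum EM iterations per restart.
#' @return List with `weights`, `means`, `sds` (components ordered by mean),
#'   `loglik`, `ll_trace` (best restart), `n_iter`, `converged`, `n`, `k`.
#' @export
gaussian_em <- function(values, k, restarts = 10, seed = 1L,
                        tol = 1e-8, max_iter = 500) {
  x <- as.numeric(values)
  n <- length(x)
  stopifnot(k %in% c(1L, 2L))
  if (n < 10 * k) {
    stop(sprintf("gaussian_em needs n >= %d for k = %d (got %d)",
                 10 * k, k, n), call. = FALSE)
  }
  rng <- diff(range(x))
  sd_floor <- max(1e-4 * rng, .Machine$double.eps^0.5)
  if (rng == 0 && k > 1) {
    stop("zero-variance input; a multi-component mixture is undefined",
         call. = FALSE)
  }
  if (k == 1) {
    s <- max(sqrt(mean((x - mean(x))^2)), sd_floor)
    ll <- sum(dnorm(x, mean(x), s, log = TRUE))
    return(list(weights = 1, means = mean(x), sds = s, loglik = ll,
                ll_trace = ll, n_iter = 0L, converged = TRUE, n = n, k = 1L))
  }
  loglik_of <- function(w, m, s) {
    dens <- vapply(seq_len(k), function(j) w[j] * dnorm(x, m[j], s[j]),
                   numeric(n))
    sum(log(rowSums(dens)))
  }
  run_em <- function(w, m, s) {
    trace <- loglik_of(w, m, s)
    converged <- FALSE
    iter <- 0L
    repeat {
      iter <- iter + 1L
      dens <- vapply(seq_len(k), function(j) w[j] * dnorm(x, m[j], s[j]),
                     numeric(n))
      tot <- rowSums(dens)
      tot[tot == 0] <- .Machine$double.xmin
      resp <- dens / tot
      nk <- colSums(resp)
      nk[nk == 0] <- .Machine$double.xmin
      w <- nk / n
      m <- colSums(resp * x) / nk
      s <- sqrt(colSums(resp * (outer(x, m, "-"))^2) / nk)
      s <- pmax(s, sd_floor)
      ll <- loglik_of(w, m, s)
      trace <- c(trace, ll)
      prev <- trace[length(trace) - 1L]
      if (abs(ll - prev) <= tol * (abs(prev) + tol)) {
        converged <- TRUE
        break
      }
      if (iter >= max_iter) break
    }
    list(w = w, m = m, s = s, ll = trace[length(trace)], trace = trace,
         iter = iter, converged = converged)
  }
  seeds <- derive_seeds(seed, restarts)
  best <- NULL
  for (r in seq_len(restarts)) {
    init <- with_seed(seeds[r], {
      km <- suppressWarnings(
        kmeans(x, centers = k, nstart = 1, iter.max = 20)
      )
      m0 <- as.numeric(km$centers)
      s0 <- vapply(seq_len(k), function(j) {
        xi <- x[km$cluster == j]
        if (length(xi) > 1) sd(xi) else sd_floor
      }, numeric(1))
      s0[!is.finite(s0) | s0 < sd_floor] <- max(sd(x) / k, sd_floor)
      w0 <- pmax(km$size, 1) / sum(pmax(km$size, 1))
      list(w = w0, m = m0, s = pmax(s0, sd_floor))
    })
    fit <- run_em(init$w, init$m, init$s)
    if (is.null(best) || fit$ll > best$ll) best <- fit
  }
  o <- order(best$m)
  list(weights = best$w[o], means = best$m[o], sds = best$s[o],
       loglik = best$ll, ll_trace = best$trace, n_iter = best$iter,
       converged = best$converged, n = n, k = as.integer(k))
}
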