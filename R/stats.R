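#' Two-sample Kolmogorov-Smirnov test
#'
#' D is the supremum distance between the two empirical CDFs.  The
#' asymptotic p-value uses the Kolmogorov tail series at
#' `sqrt(ne) * D` with effective size `ne = n1 n2 / (n1 + n2)`; the
#' permutation p-value resamples group labels (`(1 + #{D* >= D}) /
#' (n_perm + 1)`, valid by construction).  Default mode is permutation for
#' min(n1, n2) < 30 and asymptotic otherwise.
#'
#' @param a,b numeric samples with at least 2 observations each.
#' @param p_mode `"auto"`, `"asymptotic"`, `"permutation"`, or (KS only)
#'   `"exact"` for the exact conditional null distribution of D.
#' @param n_perm number of permutations (permutation mode).
#' @param seed integer seed for the permutation resampling.
#' @return an `mt_test` object: `statistic`, `p_value`, `n1`, `n2`,
#'   `method`, `p_mode`.
#' @examples
#' ks_two_sample(rnorm(30), rnorm(30, 2))
#' @export
ks_two_sample <- function(a, b, p_mode = c("auto", "asymptotic", "permutation",
                                            "exact"),
                          n_perm = 9999L, seed = 1L) {
  two_sample_test(a, b, "ks_two_sample", match.arg(p_mode), n_perm, seed)
}

#' Two-sample Kuiper test
#'
#' The circular analogue of the KS test: `V = D+ + D-`, the sum of the
#' largest positive and negative ECDF differences.  V is invariant under a
#' common circular shift of both samples, which makes the test appropriate
#' for nematic angles; use [angles_to_unit()] to map degrees in (-90, 90]
#' onto the unit circle first (done automatically when `circular = TRUE`).
#' The asymptotic p-value uses the standard Kuiper tail series with
#' Stephens' effective-size correction.
#'
#' @inheritParams ks_two_sample
#' @param circular if TRUE treat inputs as angles in degrees on the
#'   180-degree-periodic nematic circle and map them to [0, 1) first.
#' @examples
#' kuiper_two_sample(runif(30, -90, 90), runif(30, -90, 90), circular = TRUE)
#' @export
kuiper_two_sample <- function(a, b,
                              p_mode = c("auto", "asymptotic", "permutation"),
                              n_perm = 9999L, seed = 1L, circular = FALSE) {
  if (circular) {
    a <- angles_to_unit(a)
    b <- angles_to_unit(b)
  }
  two_sample_test(a, b, "kuiper_two_sample", match.arg(p_mode), n_perm, seed)
}

#' Map nematic angles to the unit interval
#'
#' Angles in degrees on the 180-degree-periodic (nematic) circle are mapped
#' to [0, 1) via `((theta + 90) mod 180) / 180`, the parameterization under
#' which the Kuiper statistic's circular invariance applies.
#'
#' @param theta angles in degrees.
#' @return values in [0, 1).
#' @export
angles_to_unit <- function(theta) ((theta + 90) %% 180) / 180

two_sample_test <- function(a, b, method, p_mode, n_perm, seed) {
  a <- as.numeric(a[is.finite(a)])
  b <- as.numeric(b[is.finite(b)])
  n1 <- length(a); n2 <- length(b)
  if (n1 < 2 || n2 < 2) stop("both samples need at least 2 observations")
  if (p_mode == "auto") p_mode <- if (min(n1, n2) < 30) "permutation" else "asymptotic"
  st <- cpp_ks_kuiper_stat(a, b)
  stat <- if (method == "ks_two_sample") st[["D"]] else st[["V"]]
  ne <- n1 * n2 / (n1 + n2)
  if (p_mode == "exact") {
    if (method != "ks_two_sample")
      stop("exact p-values are available for the KS test only")
    p <- 1 - stats::psmirnov(stat, sizes = c(n1, n2), two.sided = TRUE)
  } else if (p_mode == "asymptotic") {
    p <- if (method == "ks_two_sample") ks_p_asymptotic(stat, ne)
         else kuiper_p_asymptotic(stat, ne)
  } else {
    kind <- if (method == "ks_two_sample") "ks" else "kuiper"
    perm <- cpp_perm_stats(a, b, as.integer(n_perm), kind, as.integer(seed))
    p <- (1 + sum(perm >= stat - 1e-12)) / (n_perm + 1)
  }
  structure(list(statistic = stat, p_value = p, n1 = n1, n2 = n2,
                 method = method, p_mode = p_mode),
            class = "mt_test")
}

#' @export
print.mt_test <- function(x, ...) {
  lab <- if (x$method == "ks_two_sample") "D" else "V"
  cat(sprintf("<mt_test> %s: %s = %.4f, p = %.4g (%s, n1 = %d, n2 = %d)\n",
              x$method, lab, x$statistic, x$p_value, x$p_mode, x$n1, x$n2))
  invisible(x)
}

# Kolmogorov tail series: P(sqrt(ne) D > lambda)
ks_p_asymptotic <- function(D, ne) {
  lambda <- sqrt(ne) * D
  if (lambda < 1e-10) return(1)
  k <- 1:100
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  min(max(p, 0), 1)
}

# Kuiper tail series with Stephens' small-sample correction
kuiper_p_asymptotic <- function(V, ne) {
  lambda <- (sqrt(ne) + 0.155 + 0.24 / sqrt(ne)) * V
  if (lambda < 0.4) return(1)
  k <- 1:100
  p <- sum((4 * k^2 * lambda^2 - 1) * 2 * exp(-2 * k^2 * lambda^2))
  min(max(p, 0), 1)
}

#' Uniformity test for angle distributions
#'
#' Tests a sample of nematic angles against uniformity by the generated-
#' uniform procedure: draw a uniform sample of the same size on (-90, 90],
#' run a two-sample Kuiper test against the data, and repeat `n_rep` times;
#' the reported p-value is the median across repetitions (a single draw
#' makes p itself random; `n_rep = 1` reproduces the single-draw variant).
#' By the p > 0.05 convention, `significant` means the angle distribution
#' departs from uniform.
#'
#' @param angles angles in degrees.
#' @param n_rep number of generated uniform reference samples.
#' @param p_mode,n_perm passed to [kuiper_two_sample()].
#' @param seed integer seed (uniform draws and permutations).
#' @return list: `p_median`, `p_values` (length `n_rep`), `significant`
#'   (`p_median <= 0.05`), `n`.
#' @export
uniformity_test <- function(angles, n_rep = 99L,
                            p_mode = c("auto", "asymptotic", "permutation"),
                            n_perm = 999L, seed = 1L) {
  p_mode <- match.arg(p_mode)
  angles <- angles[is.finite(angles)]
  n <- length(angles)
  if (n < 5) stop("need at least 5 angles")
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(seed)
  ps <- vapply(seq_len(n_rep), function(r) {
    ref <- runif(n, -90, 90)
    kuiper_two_sample(angles, ref, p_mode = p_mode, n_perm = n_perm,
                      seed = seed + r, circular = TRUE)$p_value
  }, numeric(1))
  list(p_median = median(ps), p_values = ps,
       significant = median(ps) <= 0.05, n = n)
}

#' Bootstrap distribution, CI and sample-size curve
#'
#' Resamples the data with replacement to get the bootstrap distribution of
#' a statistic with a percentile 95% CI, and (optionally) subsampling
#' curves of the statistic versus subsample size to assess the effect of
#' sample size.
#'
#' @param x numeric sample, n >= 3.
#' @param statistic_fn function of a numeric vector returning a scalar.
#' @param n_boot number of bootstrap resamples (>= 200).
#' @param conf confidence level of the percentile interval.
#' @param subsample_sizes optional integer vector of subsample sizes; for
#'   each, the mean statistic over `n_boot` subsamples (without replacement)
#'   is reported. The full-n entry equals the plain statistic.
#' @param seed integer seed.
#' @return list: `statistic` (on the full sample), `boot` (bootstrap
#'   distribution), `ci` (length-2), `subsample_curve` (data frame or NULL).
#' @examples
#' bootstrap_effect(rnorm(50), mean, n_boot = 500)$ci
#' @export
bootstrap_effect <- function(x, statistic_fn, n_boot = 2000L, conf = 0.95,
                             subsample_sizes = NULL, seed = 1L) {
  x <- as.numeric(x[is.finite(x)])
  n <- length(x)
  if (n < 3) stop("need at least 3 observations")
  if (n_boot < 200) stop("n_boot must be >= 200")
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(seed)
  boot <- vapply(seq_len(n_boot),
                 function(i) statistic_fn(x[sample.int(n, n, replace = TRUE)]),
                 numeric(1))
  alpha <- (1 - conf) / 2
  ci <- unname(quantile(boot, c(alpha, 1 - alpha), type = 7))
  curve <- NULL
  if (!is.null(subsample_sizes)) {
    subsample_sizes <- sort(unique(pmin(as.integer(subsample_sizes), n)))
    curve <- data.frame(size = subsample_sizes, statistic = NA_real_)
    for (i in seq_along(subsample_sizes)) {
      m <- subsample_sizes[i]
      curve$statistic[i] <- if (m == n) statistic_fn(x) else
        mean(vapply(seq_len(n_boot),
                    function(j) statistic_fn(x[sample.int(n, m)]),
                    numeric(1)))
    }
  }
  list(statistic = statistic_fn(x), boot = boot, ci = ci,
       subsample_curve = curve)
}

#' Circular mean of nematic angles
#'
#' The axis of the resultant of doubled angles: `atan2(mean sin 2theta,
#' mean cos 2theta) / 2`, in degrees in (-90, 90].  This is the appropriate
#' average for 180-degree-periodic orientations.
#'
#' @param theta angles in degrees.
#' @param w optional weights.
#' @return mean axis in degrees.
#' @export
circular_mean_axis <- function(theta, w = NULL) {
  theta <- theta[is.finite(theta)]
  if (!length(theta)) return(NA_real_)
  if (is.null(w)) w <- rep(1, length(theta))
  rad2 <- 2 * theta * pi / 180
  wrap_angle(atan2(sum(w * sin(rad2)), sum(w * cos(rad2))) / 2 * 180 / pi)
}

#' One-sided permutation test for a difference in means
#'
#' Tests H1: mean(a) > mean(b) by permuting group labels.  Used for the
#' shape and severing contrasts of mean S2 across replicate simulations.
#'
#' @param a,b numeric samples.
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @return list: `observed` (mean difference), `p_value`.
#' @export
perm_test_mean_greater <- function(a, b, n_perm = 9999L, seed = 1L) {
  a <- as.numeric(a[is.finite(a)]); b <- as.numeric(b[is.finite(b)])
  obs <- mean(a) - mean(b)
  pool <- c(a, b)
  n1 <- length(a)
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(seed)
  perm <- vapply(seq_len(n_perm), function(i) {
    idx <- sample.int(length(pool), n1)
    mean(pool[idx]) - mean(pool[-idx])
  }, numeric(1))
  list(observed = obs, p_value = (1 + sum(perm >= obs - 1e-12)) / (n_perm + 1))
}
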