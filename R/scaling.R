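#' Hurwitz zeta function
#'
#' `zeta(s, a) = sum_{j >= 0} (a + j)^(-s)` for `s > 1`, `a >= 1`, the
#' normalizing constant of the discrete power-law distribution with lower
#' cutoff `a`. Computed by direct summation of the first terms plus an
#' Euler-Maclaurin tail correction; absolute accuracy is ~1e-14 over the
#' parameter ranges used here. Vectorized over `a`.
#'
#' @param s Exponent (> 1).
#' @param a Lower cutoff (>= 1); may be a vector.
#' @return `zeta(s, a)`, same length as `a`.
#' @export
hurwitz_zeta <- function(s, a) {
  if (s <= 1) stop("hurwitz_zeta requires s > 1")
  nterm <- 64
  j <- 0:(nterm - 1)
  head_sum <- vapply(a, function(ai) sum((ai + j)^(-s)), 0)
  b <- a + nterm
  # Euler-Maclaurin: integral + half-term + Bernoulli corrections
  tail <- b^(1 - s) / (s - 1) + 0.5 * b^(-s) +
    s * b^(-s - 1) / 12 -
    s * (s + 1) * (s + 2) * b^(-s - 3) / 720 +
    s * (s + 1) * (s + 2) * (s + 3) * (s + 4) * b^(-s - 5) / 30240
  head_sum + tail
}

# Negative log-likelihood of the discrete power law on tail x >= xmin.
discrete_pl_nll <- function(alpha, sum_log, n, xmin) {
  n * log(hurwitz_zeta(alpha, xmin)) + alpha * sum_log
}

# MLE of alpha for a fixed xmin; exact discrete likelihood, optimized on
# (1 + 1e-4, 25).
fit_alpha_discrete <- function(tail, xmin) {
  sum_log <- sum(log(tail))
  n <- length(tail)
  stats::optimize(discrete_pl_nll, interval = c(1.0001, 25),
                  sum_log = sum_log, n = n, xmin = xmin, tol = 1e-6)$minimum
}

# KS distance between the empirical tail CDF and the fitted discrete
# power-law CDF, evaluated at the observed support.
discrete_pl_ks <- function(tail, xmin, alpha) {
  n <- length(tail)
  xs <- sort(unique(tail))
  z <- hurwitz_zeta(alpha, xmin)
  # fitted survival above each support point: zeta(alpha, x + 1) / z
  surv_fit <- hurwitz_zeta(alpha, xs + 1) / z
  cdf_fit <- 1 - surv_fit
  cdf_emp <- cumsum(tabulate(factor(tail, levels = xs))) / n
  max(abs(cdf_emp - cdf_fit))
}

#' Power-law fit records
#'
#' Both fitting routes return a `powerlaw_fit`: the exponent uses a fixed
#' sign convention in which positive values mean the quantity decays with
#' degree (`y ~ k^(-exponent)`); negative values mean an increasing
#' relation. `ks_stat` holds the Kolmogorov-Smirnov distance for MLE fits
#' and the maximum absolute log-space residual for slope fits.
#'
#' @param measure Measure name.
#' @param exponent Fitted exponent (sign convention above).
#' @param intercept Log-scale intercept (slope fits only).
#' @param method `"mle_ks"` or `"loglog_ols"`.
#' @param ks_stat Goodness-of-fit statistic (>= 0).
#' @param p_value Bootstrap p-value in `[0, 1]`, or `NA` for slope fits.
#' @param x_min Lower cutoff of the fitted tail (MLE only).
#' @param n_points Number of samples (MLE) or usable bins (OLS) in the fit.
#' @return A `powerlaw_fit` list.
#' @export
powerlaw_fit <- function(measure, exponent, intercept = NA_real_,
                         method = c("mle_ks", "loglog_ols"),
                         ks_stat, p_value = NA_real_, x_min = NA_integer_,
                         n_points) {
  method <- match.arg(method)
  if (n_points < 3L) stop("a reported fit needs n_points >= 3")
  structure(list(measure = measure, exponent = exponent,
                 intercept = intercept, method = method, ks_stat = ks_stat,
                 p_value = p_value, x_min = x_min,
                 n_points = as.integer(n_points)),
            class = "powerlaw_fit")
}

#' @export
print.powerlaw_fit <- function(x, ...) {
  cat(sprintf("power-law fit [%s] of '%s': exponent %.4f", x$method,
              x$measure, x$exponent))
  if (!is.na(x$x_min)) cat(sprintf(", x_min %d", x$x_min))
  cat(sprintf(", gof %.4f", x$ks_stat))
  if (!is.na(x$p_value)) cat(sprintf(", p = %.3f", x$p_value))
  cat(sprintf(" (n = %d)\n", x$n_points))
  invisible(x)
}

#' Discrete power-law fit by maximum likelihood with KS bootstrap
#'
#' Clauset-style procedure on an integer sample (typically per-node
#' degrees): for every candidate lower cutoff `x_min` (unique sample values
#' up to the `xmin_quantile` quantile), the tail exponent is estimated by
#' exact discrete maximum likelihood and the candidate minimizing the
#' Kolmogorov-Smirnov distance between empirical and fitted tail CDFs is
#' selected. The goodness-of-fit p-value is the fraction of `n_boot`
#' semi-parametric bootstrap datasets (power-law tail from the fitted
#' model, empirical body below `x_min`) whose refitted KS distance is at
#' least the observed one; p-values above ~0.1 mean the power law is a
#' plausible generating model.
#'
#' @param samples Integer sample, all values >= 1, length >= 50.
#' @param n_boot Bootstrap replicates (0 skips the p-value).
#' @param rng_seed Seed for the bootstrap.
#' @param measure Measure label for the fit record.
#' @param xmin_quantile Cap on the `x_min` search, as a sample quantile;
#'   keeps enough tail to fit.
#' @param min_tail Minimum tail size for a candidate `x_min`.
#' @return A `powerlaw_fit` with `method = "mle_ks"`.
#' @export
fit_powerlaw_mle <- function(samples, n_boot = 2500L, rng_seed = 42L,
                             measure = "p", xmin_quantile = 0.8,
                             min_tail = 10L) {
  samples <- as.integer(samples)
  if (length(samples) < 50L) stop("need >= 50 samples")
  if (any(samples < 1L)) stop("samples must be >= 1")
  if (length(unique(samples)) == 1L) stop("degenerate support")

  scan <- function(x) {
    cap <- stats::quantile(x, xmin_quantile, type = 1L)
    cands <- sort(unique(x[x <= cap]))
    cands <- cands[vapply(cands, function(xm) sum(x >= xm) >= min_tail &&
                            length(unique(x[x >= xm])) >= 2L, TRUE)]
    if (length(cands) == 0L) cands <- min(x)
    best <- NULL
    for (xm in cands) {
      tail <- x[x >= xm]
      alpha <- fit_alpha_discrete(tail, xm)
      ks <- discrete_pl_ks(tail, xm, alpha)
      if (is.null(best) || ks < best$ks) {
        best <- list(xmin = xm, alpha = alpha, ks = ks, ntail = length(tail))
      }
    }
    best
  }

  obs <- scan(samples)
  pval <- NA_real_
  if (n_boot > 0L) {
    n <- length(samples)
    body <- samples[samples < obs$xmin]
    p_tail <- obs$ntail / n
    pval <- with_seed(rng_seed, {
      hits <- 0L
      for (b in seq_len(n_boot)) {
        from_tail <- stats::rbinom(1L, n, p_tail)
        synth <- c(
          if (from_tail > 0L)
            sample_discrete_powerlaw(obs$alpha, obs$xmin, from_tail)
          else integer(0),
          if (n - from_tail > 0L)
            sample(body, n - from_tail, replace = TRUE)
          else integer(0)
        )
        if (scan(synth)$ks >= obs$ks) hits <- hits + 1L
      }
      hits / n_boot
    })
  }
  powerlaw_fit(measure, exponent = obs$alpha, method = "mle_ks",
               ks_stat = obs$ks, p_value = pval, x_min = as.integer(obs$xmin),
               n_points = obs$ntail)
}

# Inverse-CDF sampler on the Hurwitz-zeta normalized pmf. The CDF table
# covers the support up to `cap`; draws beyond it (tail mass ~1e-8 for the
# exponents used here) fall back to the continuous approximation
# x = floor((xmin - 1/2) (1 - u)^(-1/(alpha-1)) + 1/2).
sample_discrete_powerlaw <- function(alpha, xmin, n, cap = 1e6L) {
  xs <- xmin:cap
  pmf <- xs^(-alpha) / hurwitz_zeta(alpha, xmin)
  cdf <- cumsum(pmf)
  u <- stats::runif(n)
  idx <- findInterval(u, cdf) # 0 => first support point
  out <- xmin + idx
  over <- u > cdf[length(cdf)]
  if (any(over)) {
    out[over] <- floor((xmin - 0.5) * (1 - u[over])^(-1 / (alpha - 1)) + 0.5)
  }
  as.integer(out)
}

#' Log-log slope fit of a degree profile
#'
#' Ordinary least squares of `log(value)` on `log(k)` over the profile's
#' usable bins (`k >= 1`, `value > 0`; zero-valued bins are dropped with a
#' message). The reported exponent is the negated slope, so a decaying
#' profile yields a positive exponent. `ks_stat` is the maximum absolute
#' residual in log space.
#'
#' @param profile A `degree_profile`.
#' @param min_points Minimum usable bins (default 3).
#' @param weighted Weight bins by their node counts instead of equally.
#' @return A `powerlaw_fit` with `method = "loglog_ols"`.
#' @export
fit_loglog_slope <- function(profile, min_points = 3L, weighted = FALSE) {
  usable <- profile$k >= 1L & profile$value > 0
  dropped <- sum(!usable)
  if (dropped > 0L) message("dropping ", dropped, " zero/undefined bin(s)")
  d <- profile[usable, , drop = FALSE]
  if (nrow(d) < min_points) {
    stop("insufficient support: ", nrow(d), " usable bin(s), need ",
         min_points)
  }
  w <- if (weighted) d$count else rep(1, nrow(d))
  fit <- stats::lm(log(value) ~ log(k), data = d, weights = w)
  resid_max <- max(abs(stats::residuals(fit)))
  se <- tryCatch(
    suppressWarnings(summary(fit)$coefficients[2L, 2L]),
    error = function(e) NA_real_)
  out <- powerlaw_fit(attr(profile, "measure") %||% "profile",
                      exponent = -unname(stats::coef(fit)[2L]),
                      intercept = unname(stats::coef(fit)[1L]),
                      method = "loglog_ols", ks_stat = resid_max,
                      n_points = nrow(d))
  out$exponent_se <- unname(se)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Classify network topology from the six scaling fits
#'
#' Decision rule: the degree distribution decaying as a power law marks the
#' network scale-free; a simultaneously decaying clustering-versus-degree
#' profile (the `c(k) ~ k^-1`-type signature) upgrades it to hierarchical
#' scale-free, whereas a flat `c(k)` (within `flat_band`) leaves it plain
#' scale-free. Assortativity is read from the sign of the neighborhood-
#' connectivity slope: an increasing `C_N(k)` (exponent < -`flat_band`)
#' means assortative mixing. Decaying claims must also pass fit quality:
#' KS/residual statistic at most `gof_max` and, when a bootstrap p-value is
#' present, at least `p_min`.
#'
#' @param fits Named list of six `powerlaw_fit` records, keys
#'   `p, c, cn, cb, cc, ce`.
#' @param thresholds List with `gof_max` (default 0.33), `p_min` (0.1) and
#'   `flat_band` (0.05 absolute exponent units).
#' @return A `topology_summary`: the fits, `topology_class` (one of
#'   `hierarchical_scale_free`, `scale_free`, `unclassified`),
#'   `assortative`/`disassortative` flags and the thresholds in effect.
#'   The class is a pure function of the stored fits and thresholds.
#' @export
classify_topology <- function(fits,
                              thresholds = list(gof_max = 0.33, p_min = 0.1,
                                                flat_band = 0.25)) {
  need <- c("p", "c", "cn", "cb", "cc", "ce")
  if (!all(need %in% names(fits))) {
    stop("fits must contain: ", paste(need, collapse = ", "))
  }
  th <- utils::modifyList(list(gof_max = 0.33, p_min = 0.1, flat_band = 0.25),
                          as.list(thresholds))
  fit_ok <- function(f) {
    if (is.null(f)) return(FALSE)
    ok <- f$ks_stat <= th$gof_max
    if (!is.na(f$p_value)) ok <- ok && f$p_value >= th$p_min
    ok
  }
  exp_of <- function(f) if (is.null(f)) NA_real_ else f$exponent
  p_decays <- !is.na(exp_of(fits$p)) && exp_of(fits$p) > th$flat_band &&
    fit_ok(fits$p)
  c_exp <- exp_of(fits$c)
  c_decays <- !is.na(c_exp) && c_exp > th$flat_band && fit_ok(fits$c)
  c_flat <- !is.na(c_exp) && abs(c_exp) <= th$flat_band
  cls <- if (p_decays && c_decays) "hierarchical_scale_free"
  else if (p_decays && c_flat) "scale_free"
  else "unclassified"
  cn_exp <- exp_of(fits$cn)
  structure(list(fits = fits, topology_class = cls,
                 assortative = !is.na(cn_exp) && cn_exp < -th$flat_band,
                 disassortative = !is.na(cn_exp) && cn_exp > th$flat_band,
                 thresholds = th),
            class = "topology_summary")
}

#' @export
print.topology_summary <- function(x, ...) {
  cat("topology:", x$topology_class,
      if (x$assortative) "(assortative)"
      else if (x$disassortative) "(disassortative)" else "", "\n")
  for (f in x$fits) if (!is.null(f)) print(f)
  invisible(x)
}

#' Full topological characterization of a network
#'
#' Computes the six degree profiles/centralities, fits each scaling
#' relation (discrete MLE with KS bootstrap for the degree distribution
#' when the sample supports it, log-log OLS slope for the five
#' measure-versus-degree profiles) and classifies the topology. Isolated
#' nodes are excluded from all fits.
#'
#' @param net A network.
#' @param n_boot Bootstrap replicates for the degree-distribution p-value
#'   (0 skips it, which is the fast choice inside knockout trajectories).
#' @param rng_seed Seed for the bootstrap.
#' @param thresholds Classification thresholds, see [classify_topology()].
#' @param min_points Minimum usable bins for each slope fit; profiles with
#'   fewer usable bins are recorded as `NULL` rather than extrapolated.
#' @return A `topology_summary`.
#' @export
summarize_topology <- function(net, n_boot = 2500L, rng_seed = 42L,
                               thresholds = list(gof_max = 0.33, p_min = 0.1,
                                                 flat_band = 0.25),
                               min_points = 3L) {
  deg <- igraph::degree(net)
  degs <- deg[deg >= 1L]
  try_fit <- function(expr) {
    tryCatch(suppressMessages(expr), error = function(e) NULL)
  }
  p_fit <- NULL
  if (length(degs) >= 50L && length(unique(degs)) > 1L) {
    p_fit <- try_fit(fit_powerlaw_mle(degs, n_boot = n_boot,
                                      rng_seed = rng_seed, measure = "p"))
  }
  if (is.null(p_fit)) {
    p_fit <- try_fit(fit_loglog_slope(degree_distribution_profile(net),
                                      min_points = min_points))
    if (!is.null(p_fit)) p_fit$measure <- "p"
  }
  fits <- list(
    p = p_fit,
    c = try_fit(fit_loglog_slope(clustering_by_degree(net), min_points)),
    cn = try_fit(fit_loglog_slope(neighborhood_connectivity(net), min_points)),
    cb = try_fit(fit_loglog_slope(
      bin_measure_by_degree(net, betweenness_centrality(net)), min_points)),
    cc = try_fit(fit_loglog_slope(
      bin_measure_by_degree(net, closeness_centrality(net)), min_points)),
    ce = try_fit(fit_loglog_slope(
      bin_measure_by_degree(net, eigenvector_centrality(net)), min_points))
  )
  classify_topology(fits, thresholds)
}

#' Serialize a topology summary to JSON
#' @param x A `topology_summary`.
#' @param path Output path.
#' @export
write_topology_json <- function(x, path) {
  out <- list(topology_class = x$topology_class,
              assortative = x$assortative,
              disassortative = x$disassortative,
              thresholds = x$thresholds,
              fits = lapply(x$fits, function(f) {
                if (is.null(f)) NULL else unclass(f)
              }))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}
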