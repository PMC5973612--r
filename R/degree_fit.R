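#' Cumulative (survival) degree distribution
#'
#' P(k) = fraction of nodes with degree >= k, evaluated at each distinct
#' observed degree. This is the presentation form conventionally plotted
#' for small, noisy degree data; model fitting itself is done by maximum
#' likelihood on the raw degree sequence, not on this curve.
#'
#' @param degrees Integer vector of node degrees (>= 0).
#' @return A tibble with columns `k` (sorted distinct degrees) and `p_ge`
#'   (non-increasing, starting at 1).
#' @examples
#' cumulative_degree_distribution(c(1, 2, 3))
#' @export
cumulative_degree_distribution <- function(degrees) {
  if (length(degrees) == 0) abort("Need at least one degree.")
  if (any(degrees < 0)) abort("Degrees must be >= 0.")
  k <- sort(unique(degrees))
  n <- length(degrees)
  p_ge <- vapply(k, function(kk) sum(degrees >= kk) / n, numeric(1))
  tibble(k = k, p_ge = p_ge)
}

#' Akaike Information Criterion corrected for small samples
#'
#' AICc = -2 logL + 2K + 2K(K+1)/(n - K - 1).
#'
#' @param loglik Log-likelihood (nats).
#' @param K Number of estimated parameters.
#' @param n Sample size (here: number of nodes). Must exceed K + 1.
#' @return The AICc value.
#' @examples
#' aicc(-100, 2, 50) # 204 + 12/47
#' @export
aicc <- function(loglik, K, n) {
  if (n <= K + 1) abort("AICc undefined: need n > K + 1.")
  -2 * loglik + 2 * K + 2 * K * (K + 1) / (n - K - 1)
}

# Hurwitz zeta sum_{k>=kmin} k^-alpha via direct sum + Euler-Maclaurin tail.
hurwitz_zeta <- function(alpha, kmin) {
  stopifnot(alpha > 1, kmin >= 1)
  N <- kmin + 1000
  direct <- sum((kmin:(N - 1))^(-alpha))
  tail <- N^(1 - alpha) / (alpha - 1) + N^(-alpha) / 2 +
    alpha * N^(-alpha - 1) / 12
  direct + tail
}

# Normalizing sum of an unnormalized pmf over k = kmin, kmin+1, ...;
# extends the support until the added mass is negligible (cap 2e5).
norm_sum <- function(f, kmin, cut0 = 1000, cap = 200000) {
  cut <- min(max(cut0, kmin + 100), cap)
  Z <- sum(f(kmin:cut))
  while (cut < cap) {
    nxt <- min(cut * 2, cap)
    add <- sum(f((cut + 1):nxt))
    Z <- Z + add
    cut <- nxt
    if (add < 1e-13 * Z) break
  }
  Z
}

degree_models <- c("poisson", "exponential", "power_law",
                   "truncated_power_law", "lognormal", "uniform")
model_n_params <- c(poisson = 1L, exponential = 1L, power_law = 1L,
                    truncated_power_law = 2L, lognormal = 2L, uniform = 2L)

new_degree_fit <- function(model, params, loglik, n, converged, pmf,
                           kmin, note = NA_character_) {
  K <- model_n_params[[model]]
  structure(
    list(
      model = model, params = params, loglik = loglik, K = K, n = n,
      aicc = if (converged && is.finite(loglik) && n > K + 1) {
        aicc(loglik, K, n)
      } else NA_real_,
      delta_aicc = NA_real_, selected = FALSE,
      converged = converged, pmf = pmf, kmin = kmin, note = note
    ),
    class = "degree_fit"
  )
}

failed_fit <- function(model, n, kmin, note) {
  new_degree_fit(model, params = numeric(0), loglik = NA_real_, n = n,
                 converged = FALSE, pmf = NULL, kmin = kmin, note = note)
}

fit_poisson <- function(degs, kmin) {
  lambda <- mean(degs)
  ll <- sum(dpois(degs, lambda, log = TRUE))
  new_degree_fit("poisson", c(lambda = lambda), ll, length(degs), TRUE,
                 function(k) dpois(k, lambda), kmin = 0L)
}

fit_exponential <- function(degs, kmin) {
  # pmf (1-q) q^(k-kmin) on k >= kmin, i.e. exp(-k/kappa) with q = exp(-1/kappa)
  m <- mean(degs - kmin)
  q <- m / (1 + m)
  kappa <- if (q > 0) 1 / log(1 / q) else 0
  ll <- length(degs) * log(1 - q) +
    if (q > 0) sum(degs - kmin) * log(q) else 0
  new_degree_fit("exponential", c(kappa = kappa, q = q), ll, length(degs),
                 TRUE, function(k) ifelse(k >= kmin, (1 - q) * q^(k - kmin), 0),
                 kmin)
}

fit_power_law <- function(degs, kmin) {
  n <- length(degs)
  slog <- sum(log(degs))
  ll_fun <- function(alpha) -alpha * slog - n * log(hurwitz_zeta(alpha, kmin))
  opt <- optimize(ll_fun, interval = c(1 + 1e-6, 25), maximum = TRUE)
  alpha <- opt$maximum
  note <- if (alpha > 24.5) "alpha at upper search bound" else NA_character_
  new_degree_fit("power_law", c(alpha = alpha), opt$objective, n,
                 is.na(note),
                 function(k) {
                   ifelse(k >= kmin, k^(-alpha) / hurwitz_zeta(alpha, kmin), 0)
                 },
                 kmin, note)
}

fit_truncated_power_law <- function(degs, kmin, alpha0 = 1.5) {
  n <- length(degs)
  slog <- sum(log(degs))
  sdeg <- sum(degs)
  unnorm <- function(alpha, kappa) function(k) k^(-alpha) * exp(-k / kappa)
  negll <- function(par) {
    alpha <- min(max(par[1], -5), 25)
    kappa <- min(max(exp(par[2]), 1e-3), 1e4)
    Z <- norm_sum(unnorm(alpha, kappa), kmin)
    -(-alpha * slog - sdeg / kappa - n * log(Z))
  }
  opt <- optim(c(alpha0, log(max(degs))), negll, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-10))
  alpha <- min(max(opt$par[1], -5), 25)
  kappa <- min(max(exp(opt$par[2]), 1e-3), 1e4)
  Z <- norm_sum(unnorm(alpha, kappa), kmin)
  new_degree_fit("truncated_power_law", c(alpha = alpha, kappa = kappa),
                 -opt$value, n, opt$convergence == 0,
                 function(k) ifelse(k >= kmin, k^(-alpha) * exp(-k / kappa) / Z, 0),
                 kmin)
}

fit_lognormal <- function(degs, kmin) {
  n <- length(degs)
  lk <- log(degs)
  unnorm <- function(mu, sigma) {
    function(k) exp(-(log(k) - mu)^2 / (2 * sigma^2)) / k
  }
  negll <- function(par) {
    mu <- min(max(par[1], -20), 20)
    sigma <- min(max(exp(par[2]), 1e-2), 50)
    Z <- norm_sum(unnorm(mu, sigma), kmin)
    -(sum(-(lk - mu)^2 / (2 * sigma^2) - lk) - n * log(Z))
  }
  s0 <- max(sd(lk), 0.2)
  opt <- optim(c(mean(lk), log(s0)), negll, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-10))
  mu <- min(max(opt$par[1], -20), 20)
  sigma <- min(max(exp(opt$par[2]), 1e-2), 50)
  Z <- norm_sum(unnorm(mu, sigma), kmin)
  new_degree_fit("lognormal", c(mu = mu, sigma = sigma), -opt$value, n,
                 opt$convergence == 0,
                 function(k) {
                   ifelse(k >= kmin,
                          exp(-(log(k) - mu)^2 / (2 * sigma^2)) / k / Z, 0)
                 },
                 kmin)
}

fit_uniform <- function(degs, kmin) {
  lo <- min(degs)
  hi <- max(degs)
  w <- hi - lo + 1
  ll <- -length(degs) * log(w)
  new_degree_fit("uniform", c(kmin = lo, kmax = hi), ll, length(degs), TRUE,
                 function(k) ifelse(k >= lo & k <= hi, 1 / w, 0), lo)
}

#' Fit one candidate degree-distribution model by maximum likelihood
#'
#' Discrete models fitted on the raw degree sequence (not on the cumulative
#' curve). Supports: `poisson` (all k >= 0), `exponential` (geometric-type
#' pmf proportional to exp(-k/kappa) on k >= kmin, closed-form MLE),
#' `power_law` (pmf proportional to k^-alpha, Hurwitz-zeta normalized, 1-D
#' numerical ML), `truncated_power_law` (k^-alpha exp(-k/kappa), 2-D
#' numerical ML), `lognormal` (discretized, numerically normalized) and
#' `uniform` (constant on the observed degree range; its data-determined
#' bounds count as 2 parameters). `kmin` is the minimum observed degree
#' throughout (no Clauset-style lower-cutoff optimization).
#'
#' @param degrees Integer vector of node degrees.
#' @param model One of the six model names.
#' @param kmin Lower support bound; default the minimum observed degree.
#' @return An object of class `degree_fit`: `model`, `params`, `loglik`,
#'   `K`, `n`, `aicc`, `converged`, `kmin`, plus the normalized `pmf`
#'   function for diagnostics. Models whose support cannot accommodate the
#'   data (for example a power law with zero-degree nodes) come back
#'   unconverged with an explanatory `note` instead of erroring.
#' @examples
#' fit_degree_model(c(2, 4, 6), "poisson")$params # lambda = 4
#' @export
fit_degree_model <- function(degrees, model = degree_models,
                             kmin = min(degrees)) {
  model <- match.arg(model)
  degrees <- as.integer(degrees)
  if (length(degrees) < 1) abort("Need at least one degree.")
  if (any(degrees < 0)) abort("Degrees must be >= 0.")
  n <- length(degrees)
  single <- length(unique(degrees)) == 1
  if (single && !model %in% c("uniform", "poisson")) {
    return(failed_fit(model, n, kmin,
                      "degenerate support: single distinct degree"))
  }
  needs_positive <- model %in% c("power_law", "truncated_power_law", "lognormal")
  if (needs_positive && (kmin < 1 || any(degrees < 1))) {
    return(failed_fit(model, n, kmin,
                      "support requires degrees >= 1"))
  }
  switch(model,
    poisson = fit_poisson(degrees, kmin),
    exponential = fit_exponential(degrees, kmin),
    power_law = fit_power_law(degrees, kmin),
    truncated_power_law = fit_truncated_power_law(degrees, kmin),
    lognormal = fit_lognormal(degrees, kmin),
    uniform = fit_uniform(degrees, kmin)
  )
}

#' Evaluate a fitted model's probability mass function
#'
#' @param fit A `degree_fit`.
#' @param k Integer degrees at which to evaluate.
#' @return Probabilities (0 outside the model's support).
#' @export
degree_model_pmf <- function(fit, k) {
  stopifnot(inherits(fit, "degree_fit"))
  if (!fit$converged || is.null(fit$pmf)) {
    abort(sprintf("No fitted pmf for model '%s' (not converged).", fit$model))
  }
  fit$pmf(k)
}

#' Fit all candidate degree models and select by AICc
#'
#' Fits each requested model by maximum likelihood, computes AICc with
#' n = number of nodes, and selects the model with minimal AICc among the
#' converged fits. Exact ties are broken in favour of fewer parameters,
#' then by the fixed model order of `models`.
#'
#' @param degrees Integer vector of node degrees.
#' @param models Character vector of model names (default: all six).
#' @return An object of class `degree_fits`: a list with `fits` (named list
#'   of `degree_fit`, with `delta_aicc` and `selected` populated),
#'   `selected` (name of the winning model) and `n`. [tidy()] gives the
#'   per-model table; [glance()] the selected row.
#' @examples
#' set.seed(1)
#' fits <- fit_degree_models(rpois(100, 5))
#' fits$selected
#' @export
fit_degree_models <- function(degrees, models = degree_models) {
  models <- match.arg(models, degree_models, several.ok = TRUE)
  fits <- lapply(models, function(m) fit_degree_model(degrees, m))
  names(fits) <- models
  best <- select_model(fits)
  aiccs <- vapply(fits, function(f) {
    if (isTRUE(f$converged) && is.finite(f$aicc)) f$aicc else NA_real_
  }, numeric(1))
  min_aicc <- min(aiccs, na.rm = TRUE)
  fits <- lapply(fits, function(f) {
    f$delta_aicc <- f$aicc - min_aicc
    f$selected <- identical(f$model, best$model)
    f
  })
  structure(
    list(fits = fits, selected = best$model, n = length(degrees)),
    class = "degree_fits"
  )
}

#' Select the minimum-AICc model from a set of fits
#'
#' @param fits A list of `degree_fit` objects or a `degree_fits`.
#' @return The winning `degree_fit` (smallest AICc among converged fits;
#'   ties broken by smaller K, then input order). Errors if nothing
#'   converged.
#' @export
select_model <- function(fits) {
  if (inherits(fits, "degree_fits")) fits <- fits$fits
  stopifnot(length(fits) >= 1)
  aiccs <- vapply(fits, function(f) {
    if (isTRUE(f$converged) && is.finite(f$aicc)) f$aicc else NA_real_
  }, numeric(1))
  Ks <- vapply(fits, function(f) f$K, integer(1))
  ok <- which(!is.na(aiccs))
  if (length(ok) == 0) abort("No converged fit with a defined AICc.")
  # order() sorts by AICc, then K, then original position
  best <- ok[order(aiccs[ok], Ks[ok], ok)][1]
  fit <- fits[[best]]
  fit$delta_aicc <- 0
  fit$selected <- TRUE
  fit
}

#' @export
print.degree_fit <- function(x, ...) {
  pars <- paste(sprintf("%s = %.4g", names(x$params), x$params),
                collapse = ", ")
  cat(sprintf("<degree_fit> %s(%s): logLik %.3f, AICc %.3f%s\n",
              x$model, pars, x$loglik, x$aicc,
              if (!x$converged) paste0(" [NOT CONVERGED: ", x$note, "]") else ""))
  invisible(x)
}

#' @rdname fit_degree_models
#' @param x A `degree_fit` or `degree_fits`.
#' @param ... Unused.
#' @export
tidy.degree_fit <- function(x, ...) {
  tibble(
    model = x$model,
    params = list(x$params),
    loglik = x$loglik, K = x$K, n = x$n,
    aicc = x$aicc, delta_aicc = x$delta_aicc,
    selected = x$selected, converged = x$converged
  )
}

#' @rdname fit_degree_models
#' @export
tidy.degree_fits <- function(x, ...) {
  dplyr::arrange(purrr::map_dfr(x$fits, tidy), .data$aicc)
}

#' @rdname fit_degree_models
#' @export
glance.degree_fits <- function(x, ...) {
  tidy(x$fits[[x$selected]])
}

#' @export
print.degree_fits <- function(x, ...) {
  cat(sprintf("<degree_fits> %d models on %d degrees; selected: %s\n",
              length(x$fits), x$n, x$selected))
  print(dplyr::select(tidy(x), -"params"))
  invisible(x)
}

#' Cumulative degree distribution with fitted survival curves
#'
#' @param object A `degree_fits` object.
#' @param degrees The degree sequence the fits were computed from.
#' @param ... Unused.
#' @return A ggplot object: empirical P(degree >= k) on log-log axes with
#'   the converged models' fitted survival functions overlaid.
#' @export
autoplot.degree_fits <- function(object, degrees, ...) {
  emp <- cumulative_degree_distribution(degrees)
  kmax <- max(degrees)
  curves <- purrr::map_dfr(object$fits, function(f) {
    if (!isTRUE(f$converged)) return(NULL)
    ks <- max(f$kmin, 1):kmax
    p <- f$pmf(ks)
    tibble(model = f$model, k = ks,
           p_ge = rev(cumsum(rev(p))) + max(0, 1 - sum(p)))
  })
  ggplot2::ggplot(emp, ggplot2::aes(x = .data$k, y = .data$p_ge)) +
    ggplot2::geom_line(
      data = curves,
      ggplot2::aes(colour = .data$model), linewidth = 0.4
    ) +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "degree k", y = "P(degree >= k)",
                  title = "Cumulative degree distribution",
                  subtitle = sprintf("selected model: %s", object$selected))
}
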