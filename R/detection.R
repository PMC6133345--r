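## Covariate-scaled line-transect detection functions (hazard-rate and
## half-normal keys), fitted by maximising the conditional likelihood of the
## observed perpendicular distances, with Cramer-von Mises goodness of fit.
## Sighting-condition covariates enter the scale parameter log-linearly
## (sigma_i = exp(z_i' beta), the standard MCDS convention); the hazard-rate
## shape b is global.

#' Detection key function g(x)
#'
#' Probability of detecting an available animal at perpendicular distance x.
#' Hazard-rate: \eqn{g(x) = 1 - \exp(-(x/\sigma)^{-b})} (a shoulder-shaped
#' curve; \eqn{g(0) = 1} as the limit). Half-normal:
#' \eqn{g(x) = \exp(-x^2 / (2\sigma^2))}.
#'
#' @param x distance(s), >= 0 (same units as `sigma`).
#' @param key `"hazard_rate"` or `"half_normal"`.
#' @param sigma scale parameter, > 0.
#' @param shape hazard-rate shape b, > 0 (ignored for half-normal).
#' @return detection probabilities in \[0, 1\].
#' @export
key_function <- function(x, key = c("hazard_rate", "half_normal"), sigma,
                         shape = NULL) {
  key <- match.arg(key)
  stopifnot(all(x >= 0), all(sigma > 0))
  n <- max(length(x), length(sigma))
  x <- rep_len(x, n); sigma <- rep_len(sigma, n)
  if (key == "hazard_rate") {
    if (is.null(shape) || any(shape <= 0)) {
      stop("key_function: hazard_rate needs shape > 0")
    }
    g <- numeric(n)
    z <- x > 0
    g[!z] <- 1
    g[z] <- 1 - exp(-(x[z] / sigma[z])^(-shape))
  } else {
    g <- exp(-x^2 / (2 * sigma^2))
  }
  g
}

#' Pool sightings for detection-function fitting
#'
#' Retains blue sharks and unidentified sharks (likely blue, and of similar
#' size/detectability) and drops other species; larger-bodied species would
#' distort the detection curve. Unidentified rows are flagged
#' `use_in_abundance = FALSE`: they inform the detection function only and
#' must be excluded from the abundance stage so estimates are not inflated.
#'
#' @param sightings data.frame with a `species` column
#'   (`blue_shark`, `unidentified_shark`, other labels).
#' @param min_n minimum observations recommended for a stable detection
#'   function fit (default 60); fewer triggers a warning.
#' @return filtered data.frame with logical `use_in_abundance`.
#' @export
detection_pool <- function(sightings, min_n = 60) {
  keep <- sightings$species %in% c("blue_shark", "unidentified_shark")
  out <- sightings[keep, , drop = FALSE]
  out$use_in_abundance <- out$species == "blue_shark"
  if (nrow(out) < min_n) {
    warning("detection_pool: ", nrow(out), " observations is below the ",
            "minimum recommended for fitting a detection function (n = ",
            min_n, ")")
  }
  rownames(out) <- NULL
  out
}

## sigma per observation from scale coefficients and design matrix.
detection_sigma <- function(Z, beta) exp(drop(Z %*% beta))

## Effective strip half-widths mu_i = int_0^w g(u; sigma_i, b) du by
## Gauss-Legendre quadrature (shared nodes; g is smooth on [0, w]).
esw_quadrature <- function(key, sigma, shape, w, nodes) {
  G <- vapply(seq_along(nodes$x), function(k) {
    key_function(nodes$x[k], key, sigma, shape)
  }, numeric(length(sigma)))
  drop(matrix(G, nrow = length(sigma)) %*% nodes$w)
}

#' Fit a detection function by maximum conditional likelihood
#'
#' Maximises \eqn{\prod_i g(x_i; \sigma_i, b) / \mu_i} with
#' \eqn{\mu_i = \int_0^w g(u; \sigma_i, b)\,du} evaluated by Gauss-Legendre
#' quadrature, where \eqn{\sigma_i = \exp(z_i'\beta)} carries the
#' sighting-condition covariates. Distances are exact (clinometer-measured),
#' not binned.
#'
#' @param data data.frame with column `distance` (metres) plus any covariates
#'   named in `formula`; rows beyond `w` are truncated.
#' @param key `"hazard_rate"` or `"half_normal"`.
#' @param formula RHS-only formula for the scale covariates (default `~1`).
#' @param w truncation distance in metres (default 500, the searched strip).
#' @param n_nodes quadrature nodes (default 80).
#' @return object of class `detection_fit`: `scale_coefs` (log-scale),
#'   `shape` (hazard-rate only), `w`, `loglik`, `aic`, `n`, covariance of the
#'   MLE, and the fitting data.
#' @export
fit_detection <- function(data, key = c("hazard_rate", "half_normal"),
                          formula = ~1, w = 500, n_nodes = 80) {
  key <- match.arg(key)
  stopifnot(w > 0, "distance" %in% names(data))
  data <- data[data$distance >= 0 & data$distance <= w, , drop = FALSE]
  n <- nrow(data)
  if (n < 2) stop("fit_detection: not enough observations within [0, w]")
  mf <- stats::model.frame(formula, data)
  Z <- stats::model.matrix(formula, mf)
  xlev <- stats::.getXlevels(stats::terms(formula), mf)
  q <- ncol(Z)
  x <- data$distance
  nodes <- gauss_legendre(n_nodes, 0, w)
  has_shape <- key == "hazard_rate"

  nll <- function(th) {
    beta <- th[seq_len(q)]
    b <- if (has_shape) exp(th[q + 1]) else NULL
    sig <- detection_sigma(Z, beta)
    if (any(!is.finite(sig)) || any(sig <= 0)) return(1e10)
    g <- key_function(x, key, sig, b)
    if (any(g <= 0)) return(1e10)
    mu <- esw_quadrature(key, sig, b, w, nodes)
    -sum(log(g) - log(mu))
  }
  start <- if (has_shape) {
    c(log(stats::quantile(x[x > 0], 0.7)), rep(0, q - 1), log(2.5))
  } else {
    c(log(stats::sd(x)), rep(0, q - 1))
  }
  names(start) <- NULL
  opt <- stats::optim(start, nll, method = "BFGS", hessian = TRUE,
                      control = list(maxit = 1000, reltol = 1e-12))
  if (opt$convergence != 0 || !is.finite(opt$value)) {
    stop("fit_detection: optimiser did not converge (code ", opt$convergence,
         "; value ", signif(opt$value, 6), "; evals ",
         paste(opt$counts, collapse = "/"), ")")
  }
  k <- length(opt$par)
  vcov <- tryCatch(solve(opt$hessian),
                   error = function(e) matrix(NA_real_, k, k))
  beta <- opt$par[seq_len(q)]
  names(beta) <- colnames(Z)
  structure(list(
    key = key, scale_coefs = beta,
    shape = if (has_shape) exp(opt$par[q + 1]) else NULL,
    log_shape_se = if (has_shape) sqrt(pmax(vcov[q + 1, q + 1], 0)) else NULL,
    w = w, loglik = -opt$value, aic = 2 * k + 2 * opt$value, n = n, k = k,
    vcov = vcov, formula = formula, xlevels = xlev, data = data,
    n_nodes = n_nodes
  ), class = "detection_fit")
}

#' @export
print.detection_fit <- function(x, ...) {
  cat(sprintf("Detection function: %s, w = %g m, n = %d\n", x$key, x$w, x$n))
  cat("  scale coefficients (log sigma):\n")
  print(round(x$scale_coefs, 4))
  if (!is.null(x$shape)) cat(sprintf("  shape b = %.3f\n", x$shape))
  cat(sprintf("  logLik = %.3f, AIC = %.3f, mean p = %.4f\n",
              x$loglik, x$aic, mean(average_p(x))))
  invisible(x)
}

## Design matrix for new data honouring the fitted factor levels.
detection_design <- function(fit, newdata) {
  tt <- stats::terms(fit$formula)
  vars <- all.vars(tt)
  for (v in vars) {
    if (v %in% names(fit$xlevels)) {
      bad <- setdiff(unique(as.character(newdata[[v]])), fit$xlevels[[v]])
      if (length(bad)) {
        stop("detection_design: factor level(s) absent from the fit: ",
             v, " = ", paste(bad, collapse = ", "))
      }
      newdata[[v]] <- factor(newdata[[v]], levels = fit$xlevels[[v]])
    }
  }
  stats::model.matrix(fit$formula, stats::model.frame(tt, newdata))
}

#' Average detection probability within the strip
#'
#' \eqn{p_i = \mu_i / w} with \eqn{\mu_i = \int_0^w g(u;\sigma_i,b)\,du}
#' evaluated by adaptive quadrature (relative tolerance 1e-8); the effective
#' strip half-width is `p * w`.
#'
#' @param fit a `detection_fit`.
#' @param newdata optional data.frame of covariates (defaults to the fitting
#'   data).
#' @return vector of per-row detection probabilities in (0, 1\].
#' @export
average_p <- function(fit, newdata = NULL) {
  newdata <- newdata %||% fit$data
  Z <- detection_design(fit, newdata)
  sig <- detection_sigma(Z, fit$scale_coefs)
  usig <- unique(sig)
  pu <- vapply(usig, function(s) {
    stats::integrate(function(u) key_function(u, fit$key, s, fit$shape),
                     0, fit$w, rel.tol = 1e-8, abs.tol = 1e-10)$value / fit$w
  }, numeric(1))
  pu[match(sig, usig)]
}

#' Limiting Cramer-von Mises distribution function
#'
#' CDF of the asymptotic null distribution of the one-sample Cramer-von Mises
#' statistic W^2, evaluated by the Bessel-function series representation.
#'
#' @param q quantile(s), > 0.
#' @return P(W^2 <= q).
#' @export
pcvm_asymptotic <- function(q) {
  vapply(q, function(x) {
    if (x <= 0.002) return(0)
    k <- 0:12
    z <- (4 * k + 1)^2 / (16 * x)
    ## exp(-z) * K_{1/4}(z) via the exponentially scaled Bessel function
    term <- (-1)^k * choose(-1/2, k) * sqrt(4 * k + 1) *
      besselK(z, 0.25, expon.scaled = TRUE) * exp(-2 * z)
    min(1, max(0, sum(term) / (pi * sqrt(x))))
  }, numeric(1))
}

## One-sample Cramer-von Mises statistic for sorted-or-not values in [0,1].
cvm_statistic <- function(u) {
  u <- sort(u)
  n <- length(u)
  1 / (12 * n) + sum((u - (2 * seq_len(n) - 1) / (2 * n))^2)
}

#' Cramer-von Mises goodness-of-fit test for a detection function
#'
#' Transforms each observed distance to its fitted CDF value
#' \eqn{F_i = \int_0^{x_i} g / \int_0^w g} (each sighting under its own
#' covariate-specific scale) and tests the transformed sample against
#' Uniform(0, 1) with the Cramer-von Mises W^2 statistic and its asymptotic
#' p-value.
#'
#' @param fit a `detection_fit`.
#' @return list with `statistic` (W^2), `p_value`, and `qq` (data.frame of
#'   fitted vs empirical CDF values for a quantile-quantile plot).
#' @export
cvm_gof <- function(fit) {
  x <- fit$data$distance
  Z <- detection_design(fit, fit$data)
  sig <- detection_sigma(Z, fit$scale_coefs)
  cdf1 <- function(xi, s) {
    top <- stats::integrate(function(u) key_function(u, fit$key, s, fit$shape),
                            0, xi, rel.tol = 1e-8, abs.tol = 1e-10)$value
    bot <- stats::integrate(function(u) key_function(u, fit$key, s, fit$shape),
                            0, fit$w, rel.tol = 1e-8, abs.tol = 1e-10)$value
    top / bot
  }
  Fi <- mapply(cdf1, x, sig)
  u <- sort(Fi)
  n <- length(u)
  W2 <- cvm_statistic(u)
  list(statistic = W2,
       p_value = 1 - pcvm_asymptotic(W2),
       qq = data.frame(fitted = u, empirical = seq_len(n) / n))
}

#' Select among candidate detection functions
#'
#' Ranks candidates by AIC, then applies a goodness-of-fit override: if the
#' AIC-best model fails the Cramer-von Mises p-value floor while another
#' candidate within `delta_aic_max` AIC units passes it, the passing model
#' with the lowest AIC is preferred (a poorly fitting detection function
#' biases the effective strip width regardless of its AIC rank).
#'
#' @param candidates either a *named* list of `detection_fit` objects (CvM
#'   p-values are computed) or a data.frame with columns
#'   `model`, `aic`, `cvm_p` (e.g. an external comparison table).
#' @param gof_floor minimum acceptable CvM p-value (default 0.10).
#' @param delta_aic_max maximum AIC penalty accepted for the override
#'   (default 10).
#' @return list with `selected` (model name), `fit` (the selected
#'   `detection_fit`, when fits were supplied) and `table` (comparison table
#'   ordered by AIC with a `selected` flag).
#' @export
select_detection_model <- function(candidates, gof_floor = 0.10,
                                   delta_aic_max = 10) {
  if (is.data.frame(candidates)) {
    tab <- candidates[c("model", "aic", "cvm_p")]
    fits <- NULL
  } else {
    stopifnot(length(candidates) >= 1, !is.null(names(candidates)))
    tab <- data.frame(
      model = names(candidates),
      aic = vapply(candidates, function(f) f$aic, numeric(1)),
      cvm_p = vapply(candidates, function(f) cvm_gof(f)$p_value, numeric(1)),
      row.names = NULL)
    fits <- candidates
  }
  tab <- tab[order(tab$aic), , drop = FALSE]
  tab$delta_aic <- tab$aic - tab$aic[1]
  pick <- 1L
  if (tab$cvm_p[1] < gof_floor) {
    ok <- which(tab$cvm_p >= gof_floor & tab$delta_aic <= delta_aic_max)
    if (length(ok)) pick <- ok[1]
  }
  tab$selected <- seq_len(nrow(tab)) == pick
  list(selected = tab$model[pick],
       fit = if (!is.null(fits)) fits[[tab$model[pick]]] else NULL,
       table = tab)
}

#' Simulate perpendicular detection distances
#'
#' Draws distances of *detected* animals given uniformly distributed
#' perpendicular distances in \[0, w\] thinned by the detection function
#' (rejection sampling).
#'
#' @param n number of detections to draw.
#' @inheritParams key_function
#' @param w truncation distance.
#' @return numeric vector of n distances.
#' @export
rdetect <- function(n, key = c("hazard_rate", "half_normal"), sigma, shape = NULL,
                    w = 500) {
  key <- match.arg(key)
  out <- numeric(0)
  while (length(out) < n) {
    m <- max(2 * (n - length(out)), 100)
    x <- stats::runif(m, 0, w)
    keep <- stats::runif(m) < key_function(x, key, sigma, shape)
    out <- c(out, x[keep])
  }
  out[seq_len(n)]
}
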