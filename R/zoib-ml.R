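## Per-shark maximum-likelihood ZOIB model with a cubic-spline smooth of
## observation index, the frequentist companion to the Bayesian mixed model
## (used for visualising individual trajectories; all four time bins enter).
##
## The zero and one components are intercept-only, so their MLEs separate
## from the beta component: p0_hat is the observed zero fraction and p1_hat
## the observed one fraction among positive bins. Only the beta-mean
## coefficients and log(phi) require numerical optimisation.

#' Fit a per-shark ML ZOIB model with a smooth of time
#'
#' Mean linear predictor (logit scale): intercept + natural cubic spline of
#' the running observation index + optional time-bin and shelf factors.
#' All four six-hour bins are used (baseline bin 1, 00--06).
#'
#' @param observations availability rows for a *single* shark.
#' @param smooth_df spline degrees of freedom (default 3).
#' @param terms character subset of `c("time", "time_bin", "shelf")`.
#' @return object of class `zoib_ml_fit` with coefficients, standard errors,
#'   log-likelihood, AIC, the empirical zero/one intercepts, and a
#'   `partial_time` data.frame (observation index vs centred smooth effect)
#'   for plotting. `smooth_slope` / `smooth_slope_se` give the average slope
#'   of the fitted smooth (per observation, logit scale) with a delta-method
#'   standard error.
#' @export
fit_zoib_ml <- function(observations, smooth_df = 3,
                        terms = c("time", "time_bin", "shelf")) {
  if (length(unique(observations$shark_id)) != 1) {
    stop("fit_zoib_ml: supply observations for a single shark")
  }
  obs <- observations[order(observations$bin_start), , drop = FALSE]
  y <- obs$surface_proportion
  n <- length(y)
  idx <- seq_len(n)

  Xl <- list(`(Intercept)` = rep(1, n))
  S <- NULL
  if ("time" %in% terms) {
    S <- splines::ns(idx, df = smooth_df)
    colnames(S) <- paste0("s(time)", seq_len(ncol(S)))
    for (j in seq_len(ncol(S))) Xl[[colnames(S)[j]]] <- S[, j]
  }
  if ("time_bin" %in% terms) {
    tb <- factor(obs$time_bin, levels = sort(unique(obs$time_bin)))
    if (nlevels(tb) > 1) {
      M <- stats::model.matrix(~tb)[, -1, drop = FALSE]
      colnames(M) <- sub("^tb", "time_bin", colnames(M))
      for (j in seq_len(ncol(M))) Xl[[colnames(M)[j]]] <- M[, j]
    }
  }
  if ("shelf" %in% terms && length(unique(obs$on_shelf)) > 1) {
    Xl[["shelfon"]] <- as.numeric(obs$on_shelf)
  }
  X <- do.call(cbind, Xl)
  colnames(X) <- names(Xl)
  P <- ncol(X)

  ## separable zero/one intercepts
  p0_hat <- mean(y == 0)
  n_pos <- sum(y > 0)
  p1_hat <- if (n_pos) sum(y == 1) / n_pos else 0

  int <- y > 0 & y < 1
  if (sum(int) <= P + 1) stop("fit_zoib_ml: too few interior observations")
  yi <- y[int]; Xi <- X[int, , drop = FALSE]
  nll <- function(th) {
    beta <- th[seq_len(P)]; phi <- exp(th[P + 1])
    mu <- invlogit(drop(Xi %*% beta))
    -sum(stats::dbeta(yi, mu * phi, (1 - mu) * phi, log = TRUE))
  }
  start <- c(logit(min(max(mean(yi), 1e-3), 1 - 1e-3)), rep(0, P - 1), 1)
  opt <- stats::optim(start, nll, method = "BFGS", hessian = TRUE,
                      control = list(maxit = 500, reltol = 1e-10))
  if (opt$convergence != 0) {
    stop("fit_zoib_ml: optimiser failed to converge (code ", opt$convergence,
         "): ", opt$message %||% "", "; counts = ",
         paste(opt$counts, collapse = "/"))
  }
  V <- tryCatch(solve(opt$hessian), error = function(e) {
    matrix(NA_real_, P + 1, P + 1)
  })
  se <- sqrt(pmax(diag(V), 0))
  beta <- opt$par[seq_len(P)]
  names(beta) <- colnames(X)
  names(se) <- c(colnames(X), "log_phi")

  ## total log-likelihood includes the zero/one point masses
  ll_disc <- sum(y == 0) * log(max(p0_hat, .Machine$double.xmin)) +
    sum(y > 0) * log1p(-min(p0_hat, 1 - 1e-12)) +
    sum(y == 1) * log(max(p1_hat, .Machine$double.xmin)) +
    (n_pos - sum(y == 1)) * log1p(-min(p1_hat, 1 - 1e-12))
  loglik <- -opt$value + ll_disc
  k <- P + 3  # beta coefs + log_phi + two inflation intercepts
  aic <- 2 * k - 2 * loglik

  smooth_slope <- smooth_slope_se <- NA_real_
  partial_time <- NULL
  if (!is.null(S)) {
    sc <- grep("^s\\(time\\)", colnames(X))
    eff <- drop(S %*% beta[sc])
    partial_time <- data.frame(observation = idx, effect = eff - mean(eff))
    ## average slope of the smooth: OLS projection of the partial effect on
    ## the index is w' beta_s with fixed weights w -> delta-method SE
    xc <- idx - mean(idx)
    w <- drop(crossprod(xc, S)) / sum(xc^2)
    smooth_slope <- sum(w * beta[sc])
    Vs <- V[sc, sc, drop = FALSE]
    smooth_slope_se <- sqrt(drop(t(w) %*% Vs %*% w))
  }

  structure(list(
    coefficients = beta, se = se[seq_len(P)],
    log_phi = opt$par[P + 1], log_phi_se = se[P + 1],
    p0 = p0_hat, p1 = p1_hat,
    loglik = loglik, aic = aic, n = n, k = k,
    smooth_df = if (is.null(S)) 0 else ncol(S),
    smooth_slope = smooth_slope, smooth_slope_se = smooth_slope_se,
    partial_time = partial_time, terms = terms
  ), class = "zoib_ml_fit")
}

#' @export
print.zoib_ml_fit <- function(x, ...) {
  cat("Per-shark ML zero-one-inflated beta fit\n")
  cat(sprintf("  n = %d, logLik = %.2f, AIC = %.2f\n", x$n, x$loglik, x$aic))
  tab <- data.frame(estimate = round(x$coefficients, 4),
                    se = round(x$se, 4))
  print(tab)
  cat(sprintf("  phi = %.2f; p0 = %.3f, p1 = %.3f\n",
              exp(x$log_phi), x$p0, x$p1))
  if (is.finite(x$smooth_slope)) {
    cat(sprintf("  smooth-of-time average slope %.4f (SE %.4f)\n",
                x$smooth_slope, x$smooth_slope_se))
  }
  invisible(x)
}

#' @export
AIC.zoib_ml_fit <- function(object, ...) object$aic
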