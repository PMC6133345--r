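## Bayesian zero-one-inflated beta mixed model for surface availability.
##
## The ZOIB likelihood factorises exactly into three independent pieces:
##   * a Bernoulli model for the zero indicator  [y = 0] with probability p0,
##   * a Bernoulli model for the one indicator   [y = 1 | y > 0] with p1,
##   * a beta density for the interior observations 0 < y < 1.
## Each piece carries its own logit-linear predictor over the same fixed
## effects; the shark-by-day random intercept enters the mean (beta) component
## only. Sampling is by adaptive random-walk Metropolis within Gibbs blocks
## (fixed effects / random effects / dispersion), with proposal scales tuned
## to target acceptance 0.234 (multivariate) and 0.44 (univariate) during
## burn-in and frozen afterwards.

#' Build ZOIB design matrices and random-effect blocks
#'
#' Restricts observations to the modelled daytime bins (the headline model
#' uses only the 06--12 and 12--18 bins because aerial surveys fly in
#' daylight), dummy-codes shelf (baseline off-shelf) and time bin (baseline =
#' lowest included bin), and indexes one random-intercept block per distinct
#' (shark, day) pair.
#'
#' @param observations availability data.frame from [as_availability()].
#' @param terms character subset of `c("shelf", "time_bin")`.
#' @param time_bins integer bins to keep (default `c(2, 3)`).
#' @return list with `y`, fixed-effect design `X` (shared by the three model
#'   components), `block` integer index, `block_labels`, and metadata.
#' @export
build_zoib_design <- function(observations, terms = c("shelf", "time_bin"),
                              time_bins = c(2, 3)) {
  obs <- observations[observations$time_bin %in% time_bins, , drop = FALSE]
  if (!nrow(obs)) stop("build_zoib_design: no observations in requested time bins")
  obs$shelf <- factor(ifelse(obs$on_shelf, "on", "off"), levels = c("off", "on"))
  obs$time_bin_f <- factor(obs$time_bin, levels = sort(unique(time_bins)))
  use <- character(0)
  if ("shelf" %in% terms) use <- c(use, "shelf")
  if ("time_bin" %in% terms) use <- c(use, "time_bin_f")
  for (v in use) {
    if (nlevels(droplevels(obs[[v]])) < 2) {
      stop("build_zoib_design: term '", v, "' has a single level after ",
           "restriction to time bins ", paste(time_bins, collapse = ","))
    }
  }
  fm <- if (length(use)) stats::reformulate(use) else ~1
  X <- stats::model.matrix(fm, data = obs)
  colnames(X) <- sub("time_bin_f", "time_bin", colnames(X))
  blockf <- factor(paste(obs$shark_id, obs$day_index, sep = ":"))
  list(y = obs$surface_proportion, X = X,
       block = as.integer(blockf), block_labels = levels(blockf),
       terms = terms, time_bins = sort(unique(time_bins)), n = nrow(obs))
}

## Full-data ZOIB log-likelihood given design pieces; used by the sampler's
## bookkeeping and by the DIC plug-in deviance.
zoib_loglik_parts <- function(design) {
  y <- design$y; X <- design$X; blk <- design$block
  pos <- y > 0; int <- y > 0 & y < 1
  B <- max(blk); P <- ncol(X)
  blki <- blk[int]
  Xi <- X[int, , drop = FALSE]
  ## mean-component columns constant within blocks support an interweaving
  ## sweep (coefficient shifted against the block intercepts)
  sweep_cols <- list()
  for (j in seq_len(P)) {
    rng <- tapply(Xi[, j], blki, function(v) diff(range(v)))
    if (all(unlist(rng) == 0)) {
      xb <- rep(0, B)
      xb[as.integer(names(rng))] <- vapply(
        split(Xi[, j], blki), function(v) v[1], numeric(1))
      sweep_cols[[length(sweep_cols) + 1L]] <- list(j = j, xb = xb)
    }
  }
  list(
    X = X, Xp = X[pos, , drop = FALSE], Xi = Xi,
    z0 = as.numeric(y == 0), z1 = as.numeric(y[pos] == 1),
    yi = y[int], lyi = log(y[int]), l1yi = log1p(-y[int]),
    blki = blki, B = B, P = P,
    has_int = tabulate(blki, B) > 0,
    sweep_cols = sweep_cols
  )
}

bern_loglik <- function(beta, X, z) {
  eta <- drop(X %*% beta)
  sum(z * eta - log1p(exp(eta)))
}

## Per-block beta log-likelihood of interior observations (length-B vector).
beta_loglik_blocks <- function(parts, bm, u, lphi) {
  eta <- drop(parts$Xi %*% bm) + u[parts$blki]
  m <- invlogit(eta)
  phi <- exp(lphi)
  a <- m * phi; b <- (1 - m) * phi
  ll <- (a - 1) * parts$lyi + (b - 1) * parts$l1yi - lbeta(a, b)
  v <- numeric(parts$B)
  v[sort(unique(parts$blki))] <- rowsum(ll, parts$blki)  # rowsum sorts groups
  v
}

zoib_chain <- function(parts, n_iter, n_burn, seed, coef_sd, sigma_sd,
                       thin = 1) {
  set.seed(seed)
  P <- parts$P; B <- parts$B
  pri <- function(b) sum(stats::dnorm(b, 0, coef_sd, log = TRUE))

  ## empirical initialisation
  clamp <- function(x, lo = -5, hi = 5) pmin(hi, pmax(lo, x))
  pz <- mean(parts$z0); po <- if (length(parts$z1)) mean(parts$z1) else 0
  b0 <- c(clamp(logit(max(pz, 1e-3))), rep(0, P - 1))
  b1 <- c(clamp(logit(max(po, 1e-3))), rep(0, P - 1))
  ybar <- mean(parts$yi)
  bm <- c(logit(min(max(ybar, 1e-3), 1 - 1e-3)), rep(0, P - 1))
  lphi <- 1; lsig <- 0; u <- rep(0, B)

  ll0 <- bern_loglik(b0, parts$X, parts$z0)
  ll1 <- bern_loglik(b1, parts$Xp, parts$z1)
  bll <- beta_loglik_blocks(parts, bm, u, lphi)
  init_ll <- c("zero (p0)" = ll0, "one (p1)" = ll1, "mean/beta" = sum(bll))
  if (any(!is.finite(init_ll))) {
    stop("fit_zoib: non-finite log-posterior at initialisation in component ",
         paste(names(init_ll)[!is.finite(init_ll)], collapse = ", "))
  }

  s0 <- s1 <- sm <- 0.1; su <- rep(0.5, B); sdisp <- 0.1; ssig <- 0.2
  n_keep <- (n_iter - n_burn) %/% thin
  draws <- matrix(NA_real_, n_keep, 3 * P + 3)
  u_sum <- rep(0, B); kept <- 0L

  for (it in seq_len(n_iter)) {
    ad <- if (it <= n_burn) 1 / sqrt(it) else 0

    ## zero component fixed effects
    prop <- b0 + stats::rnorm(P, 0, s0)
    llp <- bern_loglik(prop, parts$X, parts$z0)
    acc <- log(stats::runif(1)) < llp - ll0 + pri(prop) - pri(b0)
    if (acc) { b0 <- prop; ll0 <- llp }
    s0 <- s0 * exp(ad * (acc - 0.234))

    ## one component fixed effects
    prop <- b1 + stats::rnorm(P, 0, s1)
    llp <- bern_loglik(prop, parts$Xp, parts$z1)
    acc <- log(stats::runif(1)) < llp - ll1 + pri(prop) - pri(b1)
    if (acc) { b1 <- prop; ll1 <- llp }
    s1 <- s1 * exp(ad * (acc - 0.234))

    ## mean component fixed effects
    prop <- bm + stats::rnorm(P, 0, sm)
    bllp <- beta_loglik_blocks(parts, prop, u, lphi)
    acc <- log(stats::runif(1)) < sum(bllp) - sum(bll) + pri(prop) - pri(bm)
    if (acc) { bm <- prop; bll <- bllp }
    sm <- sm * exp(ad * (acc - 0.234))

    ## random intercepts: independent univariate updates, vectorised over
    ## blocks (interior likelihood decomposes by block given bm, phi)
    sig <- exp(lsig)
    up <- u + stats::rnorm(B, 0, su)
    bllp <- beta_loglik_blocks(parts, bm, up, lphi)
    lr <- bllp - bll +
      stats::dnorm(up, 0, sig, log = TRUE) - stats::dnorm(u, 0, sig, log = TRUE)
    accv <- log(stats::runif(B)) < lr
    u <- ifelse(accv, up, u)
    bll <- ifelse(accv, bllp, bll)
    ## blocks with no interior data: conditional is the prior -> exact draw
    ni <- !parts$has_int
    if (any(ni)) { u[ni] <- stats::rnorm(sum(ni), 0, sig); accv[ni] <- TRUE }
    su <- su * exp(ad * (accv - 0.44))

    ## interweaving sweeps: shift each block-constant mean coefficient
    ## against the random effects (interior likelihood invariant because
    ## eta is unchanged; only the u prior and the coefficient prior move)
    for (sw in parts$sweep_cols) {
      del <- stats::rnorm(1, 0, 0.1)
      shift <- del * sw$xb
      lr <- sum(stats::dnorm(u - shift, 0, sig, log = TRUE) -
                  stats::dnorm(u, 0, sig, log = TRUE)) +
        stats::dnorm(bm[sw$j] + del, 0, coef_sd, log = TRUE) -
        stats::dnorm(bm[sw$j], 0, coef_sd, log = TRUE)
      if (log(stats::runif(1)) < lr) {
        bm[sw$j] <- bm[sw$j] + del
        u <- u - shift
      }
    }

    ## log-precision d = log(phi)
    prop <- lphi + stats::rnorm(1, 0, sdisp)
    bllp <- beta_loglik_blocks(parts, bm, u, prop)
    acc <- log(stats::runif(1)) < sum(bllp) - sum(bll) +
      stats::dnorm(prop, 0, coef_sd, log = TRUE) -
      stats::dnorm(lphi, 0, coef_sd, log = TRUE)
    if (acc) { lphi <- prop; bll <- bllp }
    sdisp <- sdisp * exp(ad * (acc - 0.44))

    ## random-effect SD (random walk on log sigma; half-normal prior)
    prop <- lsig + stats::rnorm(1, 0, ssig)
    lr <- sum(stats::dnorm(u, 0, exp(prop), log = TRUE) -
                stats::dnorm(u, 0, exp(lsig), log = TRUE)) +
      stats::dnorm(exp(prop), 0, sigma_sd, log = TRUE) -
      stats::dnorm(exp(lsig), 0, sigma_sd, log = TRUE) +
      prop - lsig
    acc <- log(stats::runif(1)) < lr
    if (acc) lsig <- prop
    ssig <- ssig * exp(ad * (acc - 0.44))

    if (it > n_burn && (it - n_burn) %% thin == 0) {
      kept <- kept + 1L
      dev <- -2 * (ll0 + ll1 + sum(bll))
      draws[kept, ] <- c(bm, b0, b1, lphi, exp(lsig), dev)
      u_sum <- u_sum + u
    }
  }
  list(draws = draws[seq_len(kept), , drop = FALSE], u_mean = u_sum / kept)
}

#' Fit the Bayesian ZOIB mixed model by MCMC
#'
#' Adaptive random-walk Metropolis-within-Gibbs sampler for the zero-one
#' inflated beta mixed model of surface availability: logit-linear fixed
#' effects in all three mixture components, i.i.d. Normal(0, sigma^2)
#' shark-by-day random intercepts in the mean component, priors
#' Normal(0, `coef_sd`^2) on all coefficients and on d = log(phi), and
#' Half-Normal(0, `sigma_sd`) on sigma. Chains are independently seeded from
#' `seed`, so results are exactly reproducible.
#'
#' Default run lengths are working-scale (5,000 iterations, 1,000 burn-in,
#' 3 chains); production-scale settings such as 50,000/5,000 are available
#' through the arguments.
#'
#' @param observations availability data.frame from [as_availability()].
#' @param terms fixed-effect terms, subset of `c("shelf", "time_bin")`.
#' @param time_bins time bins retained (default daytime bins `c(2, 3)`).
#' @param n_iter total iterations per chain (including burn-in).
#' @param n_burn burn-in iterations discarded (adaptation happens here).
#' @param n_chains number of chains (>= 2 for PSRF diagnostics).
#' @param thin keep every `thin`-th post-burn-in draw.
#' @param seed integer seed; chain c uses `seed + c - 1`.
#' @param coef_sd,sigma_sd prior scales (see Description).
#' @return object of class `zoib_fit`: per-chain draw matrices (parameters
#'   named `mean_*`, `zero_*`, `one_*`, `d`, `sigma`, plus `deviance`),
#'   PSRF per parameter, DIC decomposition, random-intercept posterior means,
#'   and design metadata. `sigma` is the random-effect *SD*; its square is
#'   reported alongside as the variance.
#' @export
fit_zoib <- function(observations, terms = c("shelf", "time_bin"),
                     time_bins = c(2, 3), n_iter = 5000, n_burn = 1000,
                     n_chains = 3, thin = 1, seed = 1,
                     coef_sd = 10, sigma_sd = 5) {
  stopifnot(n_iter > n_burn, n_chains >= 1)
  design <- build_zoib_design(observations, terms = terms, time_bins = time_bins)
  parts <- zoib_loglik_parts(design)
  pn <- c(paste0("mean_", colnames(design$X)),
          paste0("zero_", colnames(design$X)),
          paste0("one_", colnames(design$X)),
          "d", "sigma", "deviance")
  chains <- vector("list", n_chains)
  u_means <- matrix(0, n_chains, parts$B)
  for (ch in seq_len(n_chains)) {
    res <- zoib_chain(parts, n_iter, n_burn, seed + ch - 1L,
                      coef_sd, sigma_sd, thin)
    colnames(res$draws) <- pn
    chains[[ch]] <- res$draws
    u_means[ch, ] <- res$u_mean
  }
  all_draws <- do.call(rbind, chains)
  npar <- length(pn) - 1L
  psrf <- rep(NA_real_, npar)
  names(psrf) <- pn[seq_len(npar)]
  if (n_chains >= 2) {
    ml <- coda::mcmc.list(lapply(chains, function(m) {
      coda::mcmc(m[, seq_len(npar), drop = FALSE])
    }))
    gd <- try(coda::gelman.diag(ml, autoburnin = FALSE, multivariate = FALSE),
              silent = TRUE)
    if (!inherits(gd, "try-error")) psrf <- gd$psrf[, 1]
    if (any(psrf > 1.1, na.rm = TRUE)) {
      warning("fit_zoib: PSRF > 1.1 for ",
              paste(names(psrf)[which(psrf > 1.1)], collapse = ", "),
              "; chains may not have converged")
    }
  }
  ## DIC: Dbar + pD with pD = Dbar - D(posterior means incl. random effects)
  dbar <- mean(all_draws[, "deviance"])
  pm <- colMeans(all_draws)
  u_hat <- colMeans(u_means)
  P <- parts$P
  dhat <- -2 * (bern_loglik(pm[paste0("zero_", colnames(design$X))], parts$X, parts$z0) +
                bern_loglik(pm[paste0("one_", colnames(design$X))], parts$Xp, parts$z1) +
                sum(beta_loglik_blocks(parts, pm[paste0("mean_", colnames(design$X))],
                                       u_hat, pm["d"])))
  dic <- list(dic = dbar + (dbar - dhat), dbar = dbar, dhat = dhat,
              pd = dbar - dhat)
  structure(list(
    chains = chains, par_names = pn[seq_len(npar)],
    design_cols = colnames(design$X), terms = terms,
    time_bins = design$time_bins,
    n_obs = design$n, n_blocks = parts$B, block_labels = design$block_labels,
    u_mean = u_hat,
    n_iter = n_iter, n_burn = n_burn, n_chains = n_chains, thin = thin,
    seed = seed, psrf = psrf, dic = dic,
    sigma = list(sd = unname(pm["sigma"]), variance = unname(pm["sigma"]^2))
  ), class = "zoib_fit")
}

#' Posterior draw matrix of a ZOIB fit
#'
#' @param fit a `zoib_fit`.
#' @param include_deviance keep the per-draw deviance column?
#' @return matrix with all chains stacked.
#' @export
zoib_draws <- function(fit, include_deviance = FALSE) {
  m <- do.call(rbind, fit$chains)
  if (!include_deviance && "deviance" %in% colnames(m)) {
    m <- m[, colnames(m) != "deviance", drop = FALSE]
  }
  m
}

#' @export
summary.zoib_fit <- function(object, ...) {
  m <- zoib_draws(object)
  q <- t(apply(m, 2, stats::quantile, c(0.025, 0.975)))
  data.frame(parameter = colnames(m), mean = colMeans(m),
             sd = apply(m, 2, stats::sd),
             q2.5 = q[, 1], q97.5 = q[, 2],
             psrf = object$psrf[colnames(m)], row.names = NULL)
}

#' @export
print.zoib_fit <- function(x, ...) {
  cat("Bayesian zero-one-inflated beta mixed model\n")
  cat(sprintf("  %d observations, %d shark-day blocks; time bins %s\n",
              x$n_obs, x$n_blocks, paste(x$time_bins, collapse = ",")))
  cat(sprintf("  %d chains x %d iterations (%d burn-in)\n",
              x$n_chains, x$n_iter, x$n_burn))
  s <- summary(x)
  s[, -1] <- round(s[, -1], 3)
  print(s, row.names = FALSE)
  cat(sprintf("  random-effect SD %.3f (variance %.3f)\n",
              x$sigma$sd, x$sigma$variance))
  cat(sprintf("  DIC %.2f (Dbar %.2f, pD %.2f)\n",
              x$dic$dic, x$dic$dbar, x$dic$pd))
  invisible(x)
}

#' Deviance information criterion of a ZOIB fit
#'
#' DIC = Dbar + pD with D = -2 log L, pD = Dbar - D(theta_bar), the plug-in
#' deviance evaluated at the posterior means of all parameters including the
#' random intercepts. Lower is better.
#'
#' @param fit a `zoib_fit`.
#' @return scalar DIC.
#' @export
zoib_dic <- function(fit) fit$dic$dic

#' Compare candidate ZOIB models by DIC
#'
#' @param fits named list of `zoib_fit` objects on the same data.
#' @return data.frame `model, dic, pd, delta_dic` (delta relative to the
#'   first/reference model), ordered as supplied.
#' @export
compare_zoib <- function(fits) {
  stopifnot(length(fits) >= 1, !is.null(names(fits)))
  d <- vapply(fits, zoib_dic, numeric(1))
  data.frame(model = names(fits), dic = d,
             pd = vapply(fits, function(f) f$dic$pd, numeric(1)),
             delta_dic = d - d[1], row.names = NULL)
}

## Design row for a (stratum, time_bin) cell, matching stored column names.
zoib_design_row <- function(cols, stratum, bin) {
  x <- numeric(length(cols))
  names(x) <- cols
  x["(Intercept)"] <- 1
  if ("shelfon" %in% cols) x["shelfon"] <- as.numeric(stratum == "on")
  bc <- paste0("time_bin", bin)
  if (bc %in% cols) x[bc] <- 1
  x
}

#' Predict stratum availability from a ZOIB fit
#'
#' For each posterior draw, computes the expected surface proportion for a
#' stratum with the shark-by-day random intercept integrated out by Monte
#' Carlo over new blocks (u ~ Normal(0, sigma_draw^2)) and time of day
#' averaged over the modelled daytime bins (time of day cannot be carried to
#' a prediction grid). Reports the posterior mean and SD of that expectation.
#'
#' @param fit a `zoib_fit` (or an object with compatible `chains`,
#'   `design_cols` and `time_bins` entries).
#' @param strata character subset of `c("on", "off")`.
#' @param time_bins bins to average over (default: the fit's modelled bins).
#' @param marginalize_re integrate random effects out (`TRUE`, default) or
#'   condition on a typical block (u = 0).
#' @param n_re Monte Carlo size for the random-effect integral.
#' @param seed seed for the (shared) random-effect quadrature draws.
#' @return data.frame `stratum, mean, sd`.
#' @export
predict_availability <- function(fit, strata = c("on", "off"),
                                 time_bins = NULL, marginalize_re = TRUE,
                                 n_re = 200, seed = 1) {
  time_bins <- time_bins %||% fit$time_bins
  m <- zoib_draws(fit)
  cols <- fit$design_cols
  z <- if (marginalize_re) {
    set.seed(seed)
    stats::rnorm(n_re)
  } else 0
  out <- lapply(strata, function(st) {
    ey_bins <- sapply(time_bins, function(b) {
      x <- zoib_design_row(cols, st, b)
      eta_m <- drop(m[, paste0("mean_", cols), drop = FALSE] %*% x)
      p0 <- invlogit(drop(m[, paste0("zero_", cols), drop = FALSE] %*% x))
      p1 <- invlogit(drop(m[, paste0("one_", cols), drop = FALSE] %*% x))
      if (marginalize_re) {
        sig <- m[, "sigma"]
        mu <- rowMeans(invlogit(outer(eta_m, rep(1, length(z))) +
                                  outer(sig, z)))
      } else {
        mu <- invlogit(eta_m)
      }
      zoib_mean(mu, p0, p1)
    })
    ey <- rowMeans(as.matrix(ey_bins))
    data.frame(stratum = st, mean = mean(ey), sd = stats::sd(ey))
  })
  do.call(rbind, out)
}
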