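test_that("design restricts to daytime bins and indexes shark-day blocks", {
  obs <- toy_availability(n_sharks = 2, n_days = 3, switch_day = 2, seed = 5)
  d <- build_zoib_design(obs)
  expect_equal(max(d$block), 6)           # 2 sharks x 3 days
  expect_equal(d$n, 2 * 3 * 2)            # bins 2 and 3 only
  expect_equal(colnames(d$X), c("(Intercept)", "shelfon", "time_bin3"))
  ## treatment-coded row for on-shelf, bin 3
  i <- which(obs$time_bin == 3 & obs$on_shelf)[1]
  keep <- obs[obs$time_bin %in% c(2, 3), ]
  j <- which(keep$time_bin == 3 & keep$on_shelf)[1]
  expect_equal(unname(d$X[j, ]), c(1, 1, 1))
  ## single-level factor after restriction errors
  all_on <- obs; all_on$on_shelf <- TRUE
  expect_error(build_zoib_design(all_on), "single level")
})

test_that("identical seeds give identical chains; different seeds differ", {
  obs <- toy_availability(seed = 9)
  f1 <- suppressWarnings(
    fit_zoib(obs, n_iter = 400, n_burn = 200, n_chains = 2, seed = 4))
  f2 <- suppressWarnings(
    fit_zoib(obs, n_iter = 400, n_burn = 200, n_chains = 2, seed = 4))
  expect_identical(f1$chains, f2$chains)
  expect_identical(zoib_dic(f1), zoib_dic(f2))
  f3 <- suppressWarnings(
    fit_zoib(obs, n_iter = 400, n_burn = 200, n_chains = 2, seed = 5))
  expect_false(identical(f1$chains[[1]], f3$chains[[1]]))
})

test_that("posterior means agree with an independent JAGS fit", {
  obs <- toy_availability(n_sharks = 10, n_days = 10, switch_day = 5,
                          seed = 21)
  fit <- fit_zoib(obs, n_iter = 4000, n_burn = 1000, n_chains = 2, seed = 2)
  s <- summary(fit)
  ## same model, same priors, in JAGS (exact ZOIB likelihood factorisation)
  d <- build_zoib_design(obs)
  y <- d$y; X <- d$X; blk <- d$block
  pos <- y > 0; int <- y > 0 & y < 1
  model_str <- "model {
    for (i in 1:N) { z0[i] ~ dbern(p0[i]); logit(p0[i]) <- inprod(X[i,], b0[]) }
    for (j in 1:Np) { z1[j] ~ dbern(p1[j]); logit(p1[j]) <- inprod(Xp[j,], b1[]) }
    for (k in 1:Ni) {
      yi[k] ~ dbeta(mu[k] * phi, (1 - mu[k]) * phi)
      logit(mu[k]) <- inprod(Xi[k,], bm[]) + u[blk[k]]
    }
    for (b in 1:B) { u[b] ~ dnorm(0, tau) }
    for (p in 1:P) {
      b0[p] ~ dnorm(0, 0.01); b1[p] ~ dnorm(0, 0.01); bm[p] ~ dnorm(0, 0.01)
    }
    dd ~ dnorm(0, 0.01); phi <- exp(dd)
    sigma ~ dnorm(0, 0.04) T(0,); tau <- 1 / (sigma * sigma)
  }"
  jd <- list(N = length(y), z0 = as.integer(y == 0), X = X,
             Np = sum(pos), z1 = as.integer(y[pos] == 1),
             Xp = X[pos, , drop = FALSE],
             Ni = sum(int), yi = y[int], Xi = X[int, , drop = FALSE],
             blk = blk[int], B = max(blk), P = ncol(X))
  jm <- rjags::jags.model(
    textConnection(model_str), data = jd, n.chains = 1, n.adapt = 500,
    inits = list(.RNG.name = "base::Mersenne-Twister", .RNG.seed = 11),
    quiet = TRUE)
  update(jm, 500, progress.bar = "none")
  js <- rjags::coda.samples(jm, c("bm", "dd", "sigma"), n.iter = 4000,
                            progress.bar = "none")
  jm_mean <- colMeans(as.matrix(js))
  mine <- s$mean[match(c("mean_(Intercept)", "mean_shelfon",
                         "mean_time_bin3", "d", "sigma"), s$parameter)]
  theirs <- jm_mean[c("bm[1]", "bm[2]", "bm[3]", "dd", "sigma")]
  expect_equal(unname(mine), unname(theirs), tolerance = 0.12)
})

test_that("data without zeros or ones still fit, inflation drifting low", {
  cf <- availbias:::default_zoib_truth()
  cf$zero[] <- c(-20, 0, 0); cf$one[] <- c(-20, 0, 0)
  obs <- toy_availability(coefs = cf, seed = 3)
  expect_true(all(obs$surface_proportion > 0 & obs$surface_proportion < 1))
  fit <- suppressWarnings(
    fit_zoib(obs, n_iter = 600, n_burn = 200, n_chains = 2, seed = 1))
  s <- summary(fit)
  expect_lt(s$mean[s$parameter == "zero_(Intercept)"], -2)
  expect_lt(s$mean[s$parameter == "one_(Intercept)"], -2)
})

test_that("a short fit recovers the generating coefficients roughly", {
  obs <- toy_availability(n_sharks = 12, n_days = 14, switch_day = 7,
                          seed = 13)
  fit <- suppressWarnings(
    fit_zoib(obs, n_iter = 1200, n_burn = 500, n_chains = 2, seed = 6))
  s <- summary(fit)
  expect_lt(abs(s$mean[s$parameter == "mean_shelfon"] - 1.889), 0.5)
  expect_lt(abs(s$mean[s$parameter == "d"] - 1.828), 0.4)
  expect_gt(fit$sigma$sd, 0)
  expect_equal(fit$sigma$variance, fit$sigma$sd^2)
})

test_that("DIC is reproducible and rewards a real shelf effect", {
  obs <- toy_availability(n_sharks = 10, n_days = 10, switch_day = 5,
                          seed = 17)
  a <- suppressWarnings(
    fit_zoib(obs, n_iter = 800, n_burn = 300, n_chains = 2, seed = 8))
  b <- suppressWarnings(
    fit_zoib(obs, n_iter = 800, n_burn = 300, n_chains = 2, seed = 8))
  expect_equal(zoib_dic(a) - zoib_dic(b), 0)
  cmp <- compare_zoib(list(full = a, again = b))
  expect_equal(cmp$delta_dic, c(0, 0))
  ## the true shelf effect (+1.889 logits) should beat an intercept-only
  ## mean model decisively in each of a few replicates
  wins <- vapply(1:3, function(r) {
    o <- toy_availability(n_sharks = 8, n_days = 10, switch_day = 5,
                          seed = 40 + r)
    with_shelf <- suppressWarnings(
      fit_zoib(o, terms = "shelf", n_iter = 700, n_burn = 300,
               n_chains = 2, seed = r))
    no_shelf <- suppressWarnings(
      fit_zoib(o, terms = character(0), n_iter = 700, n_burn = 300,
               n_chains = 2, seed = r))
    zoib_dic(with_shelf) < zoib_dic(no_shelf)
  }, logical(1))
  expect_true(all(wins))
})

## A degenerate one-draw posterior concentrated at given coefficients.
point_mass_fit <- function(mean_coefs, zero_coefs, one_coefs, d = 1.828,
                           sigma = 1e-9, n_draws = 1) {
  cols <- c("(Intercept)", "shelfon", "time_bin3")
  m <- matrix(rep(c(mean_coefs, zero_coefs, one_coefs, d, sigma),
                  each = n_draws), nrow = n_draws)
  colnames(m) <- c(paste0("mean_", cols), paste0("zero_", cols),
                   paste0("one_", cols), "d", "sigma")
  structure(list(chains = list(m), design_cols = cols, time_bins = c(2, 3)),
            class = "zoib_fit")
}

test_that("prediction at the fitted point estimates reduces to the plug-in", {
  fit <- point_mass_fit(c(-1.110, 1.889, -0.236), c(-0.364, -5.757, 0.643),
                        c(-71.576, 34.001, 32.529))
  p_on <- predict_availability(fit, strata = "on", time_bins = 2,
                               marginalize_re = FALSE)
  expect_equal(p_on$mean, 0.6840, tolerance = 5e-4)
  p_off <- predict_availability(fit, strata = "off", time_bins = 2,
                                marginalize_re = FALSE)
  expect_equal(p_off$mean, 0.1463, tolerance = 5e-4)
  ## with sigma ~ 0, marginalising the random effect changes nothing
  p_marg <- predict_availability(fit, strata = "on", time_bins = 2,
                                 marginalize_re = TRUE, seed = 2)
  expect_equal(p_marg$mean, p_on$mean, tolerance = 1e-6)
})

test_that("predicted on-shelf availability is monotone in the shelf effect", {
  vals <- vapply(c(0.5, 1.0, 1.889, 2.5), function(sh) {
    f <- point_mass_fit(c(-1.110, sh, -0.236), c(-0.364, -5.757, 0.643),
                        c(-71.576, 34.001, 32.529))
    predict_availability(f, strata = "on", marginalize_re = FALSE)$mean
  }, numeric(1))
  expect_true(all(diff(vals) > 0))
})
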