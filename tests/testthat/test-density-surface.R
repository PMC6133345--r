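## Straight-line effort along a geodesic through the projection centre, so
## planar segment lengths equal great-circle distances.
line_effort <- function(length_km, centre = c(-10, 52), step = 0.5) {
  xy <- data.frame(x = seq(0, length_km, by = step), y = 0)
  ll <- unproject_aeqd(xy$x, xy$y, centre)
  data.frame(lon = ll$lon, lat = ll$lat, on_effort = TRUE)
}

test_that("segmentising cuts tracks into target lengths with remainder rule", {
  segs <- segmentize(line_effort(95), 10, centre = c(-10, 52))
  expect_equal(nrow(segs), 10)
  expect_equal(segs$length, c(rep(10, 9), 5), tolerance = 1e-6)
  ## conservation: kept segments sum to the on-effort track length
  expect_equal(sum(segs$length), 95, tolerance = 1e-6)
  ## a 3 km track is below half the target: nothing kept
  expect_warning(none <- segmentize(line_effort(3), 10, centre = c(-10, 52)),
                 "half the target")
  expect_equal(nrow(none), 0)
  ## off-effort-only input
  eff <- line_effort(50); eff$on_effort <- FALSE
  expect_warning(segmentize(eff, 10), "no on-effort")
  ## exact multiples leave no remainder to drop
  segs80 <- segmentize(line_effort(80), 10, centre = c(-10, 52))
  expect_equal(sum(segs80$length), 80, tolerance = 1e-6)
})

test_that("sightings are counted into segments, honouring the abundance flag", {
  segs <- segmentize(line_effort(50), 10, centre = c(-10, 52))
  ll <- unproject_aeqd(c(5, 5, 25, 48), c(0, 0, 0, 0), c(-10, 52))
  sg <- data.frame(lon = ll$lon, lat = ll$lat,
                   use_in_abundance = c(TRUE, TRUE, FALSE, TRUE),
                   group_size = c(1, 2, 1, 1))
  out <- segment_counts(segs, sg)
  expect_equal(sum(out$count), 4)          # 1 + 2 in seg 1, 1 in seg 5
  expect_equal(out$count[1], 3)
  expect_equal(out$count[3], 0)            # flagged-out sighting not counted
  expect_equal(out$count[5], 1)
})

test_that("scenario availability vectors follow the three definitions", {
  d <- data.frame(on_shelf = c(TRUE, FALSE, TRUE))
  expect_equal(scenario_availability(d, "uncorrected"), c(1, 1, 1))
  expect_equal(scenario_availability(d, "average", constant = 0.41),
               rep(0.41, 3))
  pred <- data.frame(stratum = c("on", "off"), mean = c(0.633, 0.136))
  expect_equal(scenario_availability(d, "modelled", pred),
               c(0.633, 0.136, 0.633))
  expect_error(scenario_availability(d, "average", constant = 0), "\\(0, 1\\]")
  expect_error(scenario_availability(d, "modelled"), "both strata")
})

test_that("Tweedie log-density agrees with a series-evaluation oracle", {
  ldtw_series <- function(y, mu, phi, p) {
    theta_part <- -y / ((p - 1) * mu^(p - 1) * phi) -
      mu^(2 - p) / (phi * (2 - p))
    if (y == 0) return(theta_part)
    alpha <- (2 - p) / (p - 1)
    j <- 1:250
    logW <- j * (alpha * log(y) - alpha * log(p - 1) -
                   (1 + alpha) * log(phi) - log(2 - p)) -
      lgamma(j + 1) - lgamma(j * alpha)
    m <- max(logW)
    -log(y) + m + log(sum(exp(logW - m))) + theta_part
  }
  set.seed(14)
  for (p in c(1.2, 1.5, 1.8)) {
    y <- c(0, rgamma(99, 2, 1))
    mu <- runif(100, 0.5, 4)
    phi <- runif(100, 0.5, 2)
    ours <- vapply(seq_along(y), function(i) {
      mgcv::ldTweedie(y[i], mu[i], p = p, phi = phi[i])[1]
    }, numeric(1))
    oracle <- vapply(seq_along(y), function(i) {
      ldtw_series(y[i], mu[i], phi[i], p)
    }, numeric(1))
    expect_equal(ours, oracle, tolerance = 1e-6)
  }
})

test_that("all-zero counts give a degenerate zero-abundance fit", {
  seg <- toy_segments(seed = 2)
  seg$count <- 0L
  fit <- fit_dsm(seg, availability = 1, p_hat = 0.5)
  expect_true(fit$all_zero)
  grid <- data.frame(x = runif(20, 0, 300), y = runif(20, 0, 300),
                     area = 100)
  pr <- predict_abundance(fit, grid)
  expect_equal(pr$estimate$N_hat, 0)
  expect_true(all(pr$cells$abundance == 0))
})

test_that("an intercept-only fit on unit density returns the total area", {
  ## counts Poisson around (area searched) x (density 1 per km^2): the
  ## fitted intercept is ~0 and the predicted total is ~the region area
  set.seed(4)
  n <- 400
  seg <- data.frame(x = runif(n, 0, 100), y = runif(n, 0, 100),
                    length = runif(n, 8, 12))
  seg$count <- rpois(n, 2 * 0.5 * seg$length * 0.5)
  fit <- fit_dsm(seg, availability = 1, p_hat = 0.5, w = 500,
                 spatial = FALSE, tweedie_power = 1.5)
  expect_equal(unname(coef(fit$gam)[1]), 0, tolerance = 0.1)
  grid <- expand.grid(x = seq(5, 95, by = 10), y = seq(5, 95, by = 10))
  grid$area <- 100
  pr <- predict_abundance(fit, grid, n_sims = 50)
  expect_equal(pr$estimate$N_hat, 10000,
               tolerance = 3 * pr$estimate$cv)
})

test_that("design-based and intercept-only model estimates agree", {
  seg <- toy_segments(n = 400, density = 0.02, p = 0.5, avail = 0.4,
                      seed = 21)
  ht <- ht_abundance(seg, p = 0.5, availability = 0.4, area = 300^2, w = 500)
  fit <- suppressWarnings(fit_dsm(seg, availability = 0.4, p_hat = 0.5,
                                  w = 500, spatial = FALSE))
  grid <- expand.grid(x = seq(10, 290, by = 20), y = seq(10, 290, by = 20))
  grid$area <- 20^2
  pr <- predict_abundance(fit, grid, n_sims = 10)
  expect_equal(pr$estimate$N_hat, ht, tolerance = 0.02)
  ## and both sit near the simulated truth
  expect_equal(pr$estimate$N_hat, 0.02 * 300^2, tolerance = 0.2)
})

test_that("constant-availability scaling is an exact equivariance", {
  seg <- toy_segments(n = 350, seed = 31)
  fit1 <- suppressWarnings(fit_dsm(seg, availability = 1, p_hat = 0.5))
  fit_a <- suppressWarnings(fit_dsm(seg, availability = 0.41, p_hat = 0.5))
  grid <- expand.grid(x = seq(10, 290, by = 20), y = seq(10, 290, by = 20))
  grid$area <- 400
  N1 <- predict_abundance(fit1, grid, n_sims = 5)$estimate$N_hat
  Na <- predict_abundance(fit_a, grid, n_sims = 5)$estimate$N_hat
  expect_equal(Na * 0.41, N1, tolerance = 1e-6)
  ## availability-in-offset variant is algebraically identical
  fit_o <- suppressWarnings(fit_dsm(seg, availability = 0.41, p_hat = 0.5,
                                    availability_in = "offset"))
  No <- predict_abundance(fit_o, grid, n_sims = 5)$estimate$N_hat
  expect_equal(No, Na, tolerance = 1e-4)
})

test_that("doubling lengths and counts leaves density predictions unchanged", {
  seg <- toy_segments(n = 300, seed = 41)
  fit1 <- suppressWarnings(fit_dsm(seg, availability = 1, p_hat = 0.5))
  seg2 <- seg; seg2$length <- 2 * seg$length; seg2$count <- 2L * seg$count
  fit2 <- suppressWarnings(fit_dsm(seg2, availability = 1, p_hat = 0.5))
  grid <- expand.grid(x = seq(25, 275, by = 50), y = seq(25, 275, by = 50))
  grid$area <- 1
  d1 <- predict_abundance(fit1, grid, n_sims = 5)$cells$density
  d2 <- predict_abundance(fit2, grid, n_sims = 5)$cells$density
  expect_equal(d2, d1, tolerance = 1e-6)
})

test_that("shrinkage drops an uninformative covariate and the dropped-term
           prediction matches the reduced model", {
  drops <- vapply(1:4, function(r) {
    set.seed(60 + r)
    n <- 300
    seg <- data.frame(x = runif(n, 0, 300), y = runif(n, 0, 300), length = 10)
    lam <- 0.03 * exp(1.0 * exp(-((seg$x - 150)^2 + (seg$y - 150)^2) / 8000))
    seg$count <- rpois(n, lam * 2 * 0.5 * seg$length * 0.5)
    seg$noise <- rnorm(n)
    fit <- suppressWarnings(fit_dsm(seg, covariates = "noise",
                                    availability = 1, p_hat = 0.5))
    tr <- term_report(fit)
    tr$edf[tr$term == "s(noise)"]
  }, numeric(1))
  expect_gte(sum(drops < 0.5), 3)
  ## dropped-term prediction equals the fit without the term within 1%
  set.seed(61)
  n <- 300
  seg <- data.frame(x = runif(n, 0, 300), y = runif(n, 0, 300), length = 10)
  lam <- 0.03 * exp(1.0 * exp(-((seg$x - 150)^2 + (seg$y - 150)^2) / 8000))
  seg$count <- rpois(n, lam * 2 * 0.5 * seg$length * 0.5)
  seg$noise <- rnorm(n)
  grid <- expand.grid(x = seq(25, 275, by = 25), y = seq(25, 275, by = 25))
  grid$area <- 625; grid$noise <- 0
  with_term <- suppressWarnings(fit_dsm(seg, covariates = "noise",
                                        availability = 1, p_hat = 0.5))
  without <- suppressWarnings(fit_dsm(seg, covariates = character(),
                                      availability = 1, p_hat = 0.5))
  N_with <- predict_abundance(with_term, grid, n_sims = 5)$estimate$N_hat
  N_without <- predict_abundance(without, grid, n_sims = 5)$estimate$N_hat
  expect_equal(N_with, N_without, tolerance = 0.01)
  ## report metadata
  tr <- term_report(with_term)
  expect_true(all(c("term", "edf", "retained") %in% names(tr)))
  expect_true(is.numeric(attr(tr, "deviance_explained")))
})
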