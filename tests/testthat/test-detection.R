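test_that("key functions match closed forms and are non-increasing", {
  expect_equal(key_function(180, "hazard_rate", 180, 3), 1 - exp(-1))
  expect_equal(key_function(0, "hazard_rate", 150, 2.5), 1)
  expect_equal(key_function(0, "half_normal", 150), 1)
  expect_equal(key_function(150, "half_normal", 150), exp(-0.5))
  xg <- seq(0, 500, length.out = 1000)
  for (b in c(1.5, 3, 6)) {
    expect_true(all(diff(key_function(xg, "hazard_rate", 180, b)) <= 1e-12))
  }
  expect_true(all(diff(key_function(xg, "half_normal", 150)) <= 0))
})

test_that("pooling keeps blue and unidentified sharks and flags the latter", {
  sg <- data.frame(species = c(rep("blue_shark", 20),
                               rep("unidentified_shark", 45),
                               rep("basking_shark", 3)),
                   distance = runif(68, 0, 500))
  pooled <- detection_pool(sg)
  expect_equal(nrow(pooled), 65)
  expect_equal(sum(pooled$use_in_abundance), 20)
  expect_warning(empty <- detection_pool(sg[sg$species == "basking_shark", ]),
                 "n = 60")
  expect_equal(nrow(empty), 0)
})

test_that("covariate-free fits match a brute-force grid-search oracle", {
  set.seed(5)
  x <- rdetect(200, "hazard_rate", 180, 3, 500)
  fit <- fit_detection(data.frame(distance = x), "hazard_rate", w = 500)
  expect_length(fit$scale_coefs, 1)
  ## independent conditional-likelihood maximiser: nested grid refinement
  nll <- function(s, b) {
    mu <- integrate(function(u) 1 - exp(-(u / s)^(-b)), 0, 500,
                    rel.tol = 1e-10)$value
    -sum(log(1 - exp(-(x / s)^(-b))) - log(mu))
  }
  s_rng <- c(80, 400); b_rng <- c(1.2, 8)
  for (pass in 1:4) {
    sg <- seq(s_rng[1], s_rng[2], length.out = 21)
    bg <- seq(b_rng[1], b_rng[2], length.out = 21)
    val <- outer(sg, bg, Vectorize(nll))
    ij <- which(val == min(val), arr.ind = TRUE)[1, ]
    s_best <- sg[ij[1]]; b_best <- bg[ij[2]]
    ds <- diff(sg)[1]; db <- diff(bg)[1]
    s_rng <- c(s_best - ds, s_best + ds); b_rng <- c(b_best - db, b_best + db)
  }
  expect_equal(exp(unname(fit$scale_coefs[1])), s_best, tolerance = 0.005)
  expect_equal(fit$shape, b_best, tolerance = 0.005)
})

test_that("half-normal scale is recovered from simulated distances", {
  set.seed(8)
  x <- rdetect(2000, "half_normal", 150, w = 500)
  fit <- fit_detection(data.frame(distance = x), "half_normal", w = 500)
  expect_equal(exp(unname(fit$scale_coefs[1])), 150, tolerance = 0.05)
})

test_that("covariate effects on the detection scale are recovered", {
  set.seed(9)
  lev <- rep(c("clear", "overcast"), times = c(700, 700))
  x <- c(rdetect(700, "hazard_rate", 200, 2.5, 500),
         rdetect(700, "hazard_rate", 120, 2.5, 500))
  d <- data.frame(distance = x, cloud = factor(lev))
  fit <- fit_detection(d, "hazard_rate", ~cloud, w = 500)
  expect_equal(unname(fit$scale_coefs["(Intercept)"]), log(200),
               tolerance = 0.1)
  expect_equal(unname(fit$scale_coefs["cloudovercast"]), log(120 / 200),
               tolerance = 0.35)
  ## unseen factor level at prediction is an error, not silent nonsense
  expect_error(average_p(fit, data.frame(cloud = "foggy")), "absent")
})

test_that("conditional likelihood is invariant to distance units", {
  set.seed(12)
  x <- rdetect(400, "hazard_rate", 180, 3, 500)
  f_m_hr <- fit_detection(data.frame(distance = x), "hazard_rate", w = 500)
  f_m_hn <- fit_detection(data.frame(distance = x), "half_normal", w = 500)
  f_k_hr <- fit_detection(data.frame(distance = x / 1000), "hazard_rate",
                          w = 0.5)
  f_k_hn <- fit_detection(data.frame(distance = x / 1000), "half_normal",
                          w = 0.5)
  ## sigma scales linearly with units
  expect_equal(exp(unname(f_k_hr$scale_coefs[1])) * 1000,
               exp(unname(f_m_hr$scale_coefs[1])), tolerance = 1e-3)
  ## AIC differences between keys are unit-free (Jacobian cancels)
  expect_equal(f_m_hn$aic - f_m_hr$aic, f_k_hn$aic - f_k_hr$aic,
               tolerance = 1e-3)
})

test_that("average detection probability matches closed forms and is
           monotone in sigma", {
  hn_fit <- function(s) {
    structure(list(key = "half_normal", scale_coefs = c(`(Intercept)` = log(s)),
                   shape = NULL, w = 500, formula = ~1, xlevels = list(),
                   data = data.frame(distance = 0)),
              class = "detection_fit")
  }
  p150 <- average_p(hn_fit(150))
  expect_equal(p150, 150 * sqrt(pi / 2) * (2 * pnorm(500 / 150) - 1) / 500,
               tolerance = 1e-7)
  p_grid <- vapply(c(50, 100, 200, 400, 1000, 1e5), function(s) {
    average_p(hn_fit(s))
  }, numeric(1))
  expect_true(all(diff(p_grid) > 0))
  expect_true(all(p_grid > 0 & p_grid <= 1))
  expect_equal(p_grid[6], 1, tolerance = 1e-4)  # sigma -> Inf limit
})

test_that("Cramer-von Mises statistic and p-value match hand computation", {
  n <- 25
  u <- (seq_len(n) - 0.5) / n
  expect_equal(availbias:::cvm_statistic(u), 1 / (12 * n))
  ## published asymptotic quantiles of the limiting distribution
  expect_equal(pcvm_asymptotic(c(0.34730, 0.46136, 0.74346)),
               c(0.90, 0.95, 0.99), tolerance = 2e-3)
  ## three equal distances under a half-normal model: CDF value has a
  ## closed form, and W^2 follows by direct summation
  fit <- structure(list(key = "half_normal",
                        scale_coefs = c(`(Intercept)` = log(150)),
                        shape = NULL, w = 500, formula = ~1, xlevels = list(),
                        data = data.frame(distance = rep(150, 3))),
                   class = "detection_fit")
  gof <- cvm_gof(fit)
  Fx <- (pnorm(150 / 150) - 0.5) / (pnorm(500 / 150) - 0.5)
  W2_hand <- 1 / 36 + sum((rep(Fx, 3) - (2 * (1:3) - 1) / 6)^2)
  expect_equal(gof$statistic, W2_hand, tolerance = 1e-7)
  expect_equal(nrow(gof$qq), 3)
})

test_that("model selection applies the goodness-of-fit override", {
  ## single candidate comes back unchanged
  set.seed(3)
  x <- rdetect(120, "hazard_rate", 180, 3, 500)
  f <- fit_detection(data.frame(distance = x), "hazard_rate", w = 500)
  one <- select_detection_model(list(only = f))
  expect_equal(one$selected, "only")
  expect_identical(one$fit, f)
  ## external comparison table: AIC-best fails the floor, runner-up passes
  tab <- data.frame(
    model = c("hr full", "hr cloud", "hr null"),
    aic = c(1365.261, 1369.405, 1372.248),
    cvm_p = c(0.098, 0.544, 0.389))
  sel <- select_detection_model(tab, gof_floor = 0.10, delta_aic_max = 10)
  expect_equal(sel$selected, "hr cloud")
  expect_equal(sel$table$model[sel$table$selected], "hr cloud")
  ## when every candidate passes the floor, pure AIC ranking applies
  tab$cvm_p <- c(0.5, 0.544, 0.389)
  expect_equal(select_detection_model(tab)$selected, "hr full")
  ## an AIC-best failure with no passing candidate in range stays selected
  tab$cvm_p <- c(0.01, 0.02, 0.03)
  expect_equal(select_detection_model(tab)$selected, "hr full")
})
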