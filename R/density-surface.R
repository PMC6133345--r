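## Density surface modelling: effort segments, the Tweedie log-link GAM with
## availability entering as a count divisor, and grid prediction of total
## abundance with coefficient-simulation uncertainty.

## Interpolate a point at arc-length s along a polyline given as x/y vectors.
interp_along <- function(x, y, cum, s) {
  j <- findInterval(s, cum, rightmost.closed = TRUE)
  j <- pmin(pmax(j, 1), length(x) - 1)
  f <- (s - cum[j]) / pmax(cum[j + 1] - cum[j], 1e-12)
  data.frame(x = x[j] + f * (x[j + 1] - x[j]),
             y = y[j] + f * (y[j + 1] - y[j]))
}

#' Cut on-effort track into effort segments
#'
#' Projects the GPS fixes to planar km, splits the track into contiguous
#' on-effort runs (also breaking at transect boundaries when a `transect`
#' column is present), and cuts each run into segments of `target_length` km.
#' A final remainder shorter than half the target is dropped (with a
#' warning); otherwise it is kept as a short segment.
#'
#' @param effort data.frame of ordered fixes with columns `lon`, `lat`,
#'   `on_effort` (logical), optionally `transect` and condition covariates
#'   (e.g. `cloud`); condition covariates are carried over from the fix
#'   nearest each segment midpoint.
#' @param target_length segment length in km (default 10).
#' @param grid optional environmental grid (`lon`, `lat` + covariates);
#'   covariates are sampled at the segment midpoint from the nearest cell.
#' @param centre projection centre `c(lon, lat)`; defaults to the effort
#'   centroid.
#' @return data.frame of segments: `segment_id`, `transect`, `x`, `y`,
#'   `lon`, `lat`, `length`, plus covariate columns.
#' @export
segmentize <- function(effort, target_length = 10, grid = NULL,
                       centre = NULL) {
  eff <- effort[as.logical(effort$on_effort), , drop = FALSE]
  if (!nrow(eff)) {
    warning("segmentize: no on-effort fixes; returning empty segment table")
    return(data.frame())
  }
  centre <- centre %||% c(mean(effort$lon), mean(effort$lat))
  xy <- project_aeqd(eff$lon, eff$lat, centre)
  eff$x <- xy$x; eff$y <- xy$y
  tr <- if ("transect" %in% names(eff)) eff$transect else rep(1, nrow(eff))
  ## break runs at transect changes and at gaps in the original row order
  ridx <- which(as.logical(effort$on_effort))
  run <- cumsum(c(TRUE, diff(ridx) != 1 | tr[-1] != tr[-length(tr)]))
  segs <- list(); dropped <- 0
  sid <- 0L
  for (r in unique(run)) {
    e <- eff[run == r, , drop = FALSE]
    if (nrow(e) < 2) { dropped <- dropped + 0; next }
    d <- sqrt(diff(e$x)^2 + diff(e$y)^2)
    cum <- c(0, cumsum(d))
    L <- cum[length(cum)]
    n_full <- floor(L / target_length)
    rem <- L - n_full * target_length
    lens <- rep(target_length, n_full)
    if (rem >= target_length / 2) lens <- c(lens, rem) else dropped <- dropped + rem
    if (!length(lens)) next
    ends <- cumsum(lens); starts <- ends - lens
    mids <- (starts + ends) / 2
    pm <- interp_along(e$x, e$y, cum, mids)
    for (j in seq_along(lens)) {
      sid <- sid + 1L
      nearest_fix <- which.min((e$x - pm$x[j])^2 + (e$y - pm$y[j])^2)
      row <- data.frame(segment_id = sid,
                        transect = if ("transect" %in% names(e)) e$transect[1] else NA,
                        x = pm$x[j], y = pm$y[j], length = lens[j])
      for (cv in setdiff(names(effort),
                         c("lon", "lat", "on_effort", "transect", "x", "y"))) {
        row[[cv]] <- e[[cv]][nearest_fix]
      }
      segs[[length(segs) + 1L]] <- row
    }
  }
  if (!length(segs)) {
    warning("segmentize: all runs shorter than half the target length")
    return(data.frame())
  }
  out <- do.call(rbind, segs)
  ll <- unproject_aeqd(out$x, out$y, centre)
  out$lon <- ll$lon; out$lat <- ll$lat
  if (dropped > 0) {
    message(sprintf("segmentize: dropped %.2f km of remainder track", dropped))
  }
  if (!is.null(grid)) {
    gxy <- project_aeqd(grid$lon, grid$lat, centre)
    gcov <- setdiff(names(grid), c("lon", "lat", "area"))
    for (cv in gcov) out[[cv]] <- grid[[cv]][NA_integer_]
    for (j in seq_len(nrow(out))) {
      k <- which.min((gxy$x - out$x[j])^2 + (gxy$y - out$y[j])^2)
      for (cv in gcov) out[[cv]][j] <- grid[[cv]][k]
    }
  }
  attr(out, "centre") <- centre
  rownames(out) <- NULL
  out
}

#' Attach sighting counts to effort segments
#'
#' Counts abundance-stage animals (`use_in_abundance`, see
#' [detection_pool()]) per segment. Sightings carrying a `segment_id` column
#' are used directly; otherwise each sighting is assigned to the nearest
#' segment midpoint (sightings are located at the trackline foot of the
#' perpendicular).
#'
#' @param segments output of [segmentize()].
#' @param sightings pooled sightings (with `use_in_abundance`); group sizes
#'   in a `group_size` column are summed (default 1).
#' @return `segments` with an integer `count` column.
#' @export
segment_counts <- function(segments, sightings) {
  segments$count <- 0L
  use_flag <- sightings$use_in_abundance
  if (is.null(use_flag)) use_flag <- rep(TRUE, nrow(sightings))
  use <- sightings[use_flag, , drop = FALSE]
  if (!nrow(use)) return(segments)
  gs <- use$group_size %||% rep(1L, nrow(use))
  if (!is.null(use$segment_id) && all(use$segment_id %in% segments$segment_id)) {
    agg <- tapply(gs, use$segment_id, sum)
    m <- match(names(agg), segments$segment_id)
    segments$count[m] <- as.integer(agg)
  } else {
    centre <- attr(segments, "centre")
    xy <- project_aeqd(use$lon, use$lat, centre)
    for (i in seq_len(nrow(use))) {
      k <- which.min((segments$x - xy$x[i])^2 + (segments$y - xy$y[i])^2)
      segments$count[k] <- segments$count[k] + as.integer(gs[i])
    }
  }
  segments
}

#' Availability vector for a correction scenario
#'
#' Three scenarios: `"uncorrected"` (availability 1 everywhere, i.e. no
#' correction), `"average"` (a single constant, e.g. the mean time at the
#' surface over the whole deployment), `"modelled"` (stratum-specific
#' predicted mean availability, on-shelf vs off-shelf, from the ZOIB model).
#'
#' @param data data.frame with an `on_shelf` column (needed for
#'   `"modelled"`).
#' @param scenario one of `"uncorrected"`, `"average"`, `"modelled"`.
#' @param zoib_prediction data.frame `stratum, mean` from
#'   [predict_availability()] (for `"modelled"`).
#' @param constant availability constant in (0, 1\] (for `"average"`).
#' @return numeric availability vector, one value per row of `data`.
#' @export
scenario_availability <- function(data,
                                  scenario = c("uncorrected", "average", "modelled"),
                                  zoib_prediction = NULL, constant = 0.41) {
  scenario <- match.arg(scenario)
  n <- nrow(data)
  switch(scenario,
    uncorrected = rep(1, n),
    average = {
      if (!is.numeric(constant) || constant <= 0 || constant > 1) {
        stop("scenario_availability: constant availability must be in (0, 1]")
      }
      rep(constant, n)
    },
    modelled = {
      if (is.null(zoib_prediction) ||
          !all(c("on", "off") %in% zoib_prediction$stratum)) {
        stop("scenario_availability: 'modelled' needs predictions for both strata")
      }
      a_on <- zoib_prediction$mean[zoib_prediction$stratum == "on"]
      a_off <- zoib_prediction$mean[zoib_prediction$stratum == "off"]
      ifelse(data$on_shelf, a_on, a_off)
    })
}

## Estimated Tweedie power from an mgcv tw() fit (or the fixed value).
dsm_tweedie_power <- function(gam_fit) {
  fam <- gam_fit$family
  if (!is.null(fam$getTheta)) {
    th <- fam$getTheta(TRUE)
    return(unname(th[length(th)]))
  }
  ## fixed Tweedie(p): parse "Tweedie(p=...)"
  p <- suppressWarnings(as.numeric(sub(".*p *= *([0-9.]+).*", "\\1",
                                       fam$family)))
  p
}

#' Fit the Tweedie density surface model
#'
#' Penalised log-link Tweedie regression of availability-divided counts
#' (`count / availability`) on a bivariate spatial smooth of (x, y) plus
#' univariate smooths of habitat covariates, with offset
#' `log(2 * w * length * p_hat)` (the area effectively searched per segment,
#' in km^2). Smoothing parameters are selected by REML with the effective
#' degrees of freedom inflated by `gamma` = 1.4 to guard against overfitting,
#' each smooth uses a shrinkage basis (`bs = "ts"`) whose null space is also
#' penalised so that unneeded terms shrink to the zero function, and the
#' Tweedie power p in (1, 2) is estimated alongside unless fixed.
#'
#' The algebraically equivalent variant with availability in the offset
#' instead of the response (`availability_in = "offset"`) is provided for
#' variance comparison.
#'
#' @param segments data.frame from [segment_counts()]: `x`, `y`, `length`
#'   (km), `count`, plus covariate columns.
#' @param covariates character vector of candidate covariate smooth terms
#'   (columns of `segments`).
#' @param availability availability divisor per segment (scalar or vector)
#'   in (0, 1].
#' @param p_hat mean detection probability per segment (scalar or vector).
#' @param w truncation distance in metres (default 500).
#' @param spatial include the bivariate (x, y) smooth? (default TRUE)
#' @param k_spatial,k_cov basis dimensions (defaults 30 and 10; reduced
#'   automatically when segments are few).
#' @param tweedie_power NULL to estimate (REML profile within (1.1, 1.9)) or
#'   a fixed value in (1, 2).
#' @param gamma REML effective-df inflation (default 1.4).
#' @param availability_in `"response"` (divide counts, default) or
#'   `"offset"`.
#' @return object of class `dsm_fit` wrapping the `mgcv::gam` fit, with
#'   `tweedie_power`, `deviance_explained` and the modelling choices.
#' @export
fit_dsm <- function(segments, covariates = character(), availability = 1,
                    p_hat, w = 500, spatial = TRUE, k_spatial = 30,
                    k_cov = 10, tweedie_power = NULL, gamma = 1.4,
                    availability_in = c("response", "offset")) {
  availability_in <- match.arg(availability_in)
  stopifnot(all(availability > 0 & availability <= 1), all(p_hat > 0))
  n <- nrow(segments)
  w_km <- w / 1000
  availability <- rep_len(availability, n)
  p_hat <- rep_len(p_hat, n)
  seg <- segments
  seg$.offset <- log(2 * w_km * seg$length * p_hat)
  if (availability_in == "response") {
    seg$.y <- seg$count / availability
  } else {
    seg$.y <- seg$count
    seg$.offset <- seg$.offset + log(availability)
  }
  if (all(seg$count == 0)) {
    out <- structure(list(all_zero = TRUE, n = n, scenario_availability =
                            availability, w_km = w_km,
                          availability_in = availability_in),
                     class = "dsm_fit")
    return(out)
  }
  terms <- "offset(.offset)"
  if (spatial) {
    ks <- min(k_spatial, max(10, floor(n / 4)))
    if (ks < k_spatial) message("fit_dsm: spatial basis reduced to k = ", ks)
    terms <- c(terms, sprintf("s(x, y, bs = 'ts', k = %d)", ks))
  }
  for (cv in covariates) {
    kc <- min(k_cov, max(4, floor(n / 8)))
    terms <- c(terms, sprintf("s(%s, bs = 'ts', k = %d)", cv, kc))
  }
  if (length(terms) == 1) terms <- c(terms, "1")
  fm <- stats::as.formula(paste(".y ~", paste(terms, collapse = " + ")))
  fam <- if (is.null(tweedie_power)) {
    mgcv::tw(a = 1.1, b = 1.9)
  } else {
    stopifnot(tweedie_power > 1, tweedie_power < 2)
    mgcv::Tweedie(p = tweedie_power, link = "log")
  }
  g <- mgcv::gam(fm, family = fam, data = seg, method = "REML", gamma = gamma)
  p_est <- dsm_tweedie_power(g)
  if (is.null(tweedie_power) && (p_est < 1.11 || p_est > 1.89)) {
    warning("fit_dsm: estimated Tweedie power ", round(p_est, 3),
            " is at the search boundary")
  }
  structure(list(
    gam = g, all_zero = FALSE, n = n, covariates = covariates,
    spatial = spatial, tweedie_power = p_est,
    deviance_explained = summary(g)$dev.expl,
    w_km = w_km, gamma = gamma, availability_in = availability_in,
    scenario_availability = availability
  ), class = "dsm_fit")
}

#' @export
print.dsm_fit <- function(x, ...) {
  if (x$all_zero) {
    cat("Density surface model: all segment counts zero (degenerate fit)\n")
    return(invisible(x))
  }
  cat(sprintf("Tweedie density surface model (%d segments)\n", x$n))
  cat(sprintf("  power p = %.3f, deviance explained = %.1f%%\n",
              x$tweedie_power, 100 * x$deviance_explained))
  print(term_report(x))
  invisible(x)
}

#' Per-term effective degrees of freedom and shrinkage status
#'
#' Shrinkage smooths (`bs = "ts"`) penalise the null space, so a term that
#' contributes nothing is shrunk to effectively zero df; terms with edf
#' below 0.05 are reported as dropped.
#'
#' @param fit a `dsm_fit`.
#' @return data.frame `term, edf, retained`, with the model's deviance
#'   explained as attribute `deviance_explained`.
#' @export
term_report <- function(fit) {
  if (fit$all_zero) {
    return(structure(data.frame(term = character(), edf = numeric(),
                                retained = logical()),
                     deviance_explained = NA_real_))
  }
  s <- summary(fit$gam)
  st <- s$s.table
  out <- data.frame(term = rownames(st), edf = st[, "edf"],
                    retained = st[, "edf"] >= 0.05, row.names = NULL)
  attr(out, "deviance_explained") <- s$dev.expl
  out
}

#' Predict total abundance over a grid
#'
#' Per-cell abundance is `area * exp(eta)` with eta the fitted linear
#' predictor (density per km^2 on the log scale; the effort offset does not
#' enter prediction). Uncertainty comes from simulating `n_sims` coefficient
#' vectors from the approximate posterior N(beta_hat, V_p) of the penalised
#' fit; the CV of the simulated totals is combined with a lognormal
#' confidence interval. Because counts were divided by availability before
#' fitting, predictions are on the availability-corrected scale; availability
#' uncertainty itself is not propagated.
#'
#' @param fit a `dsm_fit`.
#' @param grid data.frame with `x`, `y`, `area` (km^2) and the covariates
#'   used in the fit.
#' @param n_sims coefficient draws (default 1000).
#' @param seed seed for the coefficient simulation.
#' @param ci_level confidence level (default 0.95).
#' @return list with `estimate` (data.frame `N_hat, cv, ci_low, ci_high`),
#'   `cells` (per-cell density and abundance), and `N_draws`.
#' @export
predict_abundance <- function(fit, grid, n_sims = 1000, seed = 1,
                              ci_level = 0.95) {
  if (fit$all_zero) {
    return(list(estimate = data.frame(N_hat = 0, cv = NA_real_,
                                      ci_low = 0, ci_high = 0),
                cells = data.frame(grid, density = 0, abundance = 0),
                N_draws = rep(0, n_sims)))
  }
  g <- fit$gam
  ## flag covariate extrapolation (not blocked; predictions degrade smoothly)
  mfr <- g$model
  for (cv in fit$covariates) {
    if (cv %in% names(mfr) && cv %in% names(grid)) {
      r <- range(mfr[[cv]])
      outside <- sum(grid[[cv]] < r[1] | grid[[cv]] > r[2])
      if (outside > 0) {
        warning("predict_abundance: covariate '", cv, "' outside fitted ",
                "range in ", outside, " grid cell(s); extrapolating")
      }
    }
  }
  grid$.offset <- 0
  Xp <- stats::predict(g, newdata = grid, type = "lpmatrix")
  eta <- drop(Xp %*% stats::coef(g))
  dens <- exp(eta)
  abund <- grid$area * dens
  N_hat <- sum(abund)
  set.seed(seed)
  beta_sim <- rmvn_chol(n_sims, stats::coef(g), g$Vp)
  N_draws <- colSums(grid$area * exp(Xp %*% t(beta_sim)))
  cv <- stats::sd(N_draws) / mean(N_draws)
  z <- stats::qnorm(1 - (1 - ci_level) / 2)
  C <- exp(z * sqrt(log(1 + cv^2)))
  list(estimate = data.frame(N_hat = N_hat, cv = cv,
                             ci_low = N_hat / C, ci_high = N_hat * C),
       cells = data.frame(grid[setdiff(names(grid), ".offset")],
                          density = dens, abundance = abund),
       N_draws = N_draws)
}

#' Project a prediction grid into a segment table's coordinate system
#'
#' Replaces/creates the `x`, `y` columns of a grid by projecting its
#' lon/lat with the same azimuthal-equidistant centre used when the effort
#' was segmentised, so grid predictions and the fitted spatial smooth share
#' one coordinate system.
#'
#' @param grid data.frame with `lon`, `lat`.
#' @param segments output of [segmentize()] (carries the projection centre).
#' @return `grid` with consistent `x`, `y` (km).
#' @export
project_grid <- function(grid, segments) {
  centre <- attr(segments, "centre")
  if (is.null(centre)) stop("project_grid: segments carry no projection centre")
  xy <- project_aeqd(grid$lon, grid$lat, centre)
  grid$x <- xy$x; grid$y <- xy$y
  grid
}

#' Design-based (Horvitz-Thompson-like) abundance estimate
#'
#' Strip-transect estimator used as a model-free sanity check:
#' \eqn{\hat D = \sum_i c_i / (p_i a_i) \; / \; (2 w \sum_i L_i)} and
#' \eqn{\hat N = \hat D \cdot A}.
#'
#' @param segments data.frame with `count` and `length` (km).
#' @param p detection probability per segment (scalar or vector).
#' @param availability availability per segment (scalar or vector).
#' @param area total study area in km^2.
#' @param w truncation distance in metres.
#' @return abundance estimate (numeric).
#' @export
ht_abundance <- function(segments, p, availability, area, w = 500) {
  w_km <- w / 1000
  n <- nrow(segments)
  p <- rep_len(p, n); availability <- rep_len(availability, n)
  D <- sum(segments$count / (p * availability)) /
    (2 * w_km * sum(segments$length))
  D * area
}
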