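## Synthetic tag and survey data with known truth, matching the statistical
## structure the analysis assumes: ZOIB surface proportions with shark-by-day
## random intercepts and shelf/time-bin effects on the tag side; an
## inhomogeneous Poisson animal distribution thinned by stratum availability
## and a hazard-rate detection process on the survey side.

## Default ZOIB truth: the posterior point estimates of the two-shark study
## design (mean / zero / one components over intercept, shelf-on, daytime
## bin-3; d = log precision; random-effect variance 1.273, SD 1.128).
default_zoib_truth <- function() {
  list(mean = c(intercept = -1.110, shelf_on = 1.889, bin3 = -0.236),
       zero = c(intercept = -0.364, shelf_on = -5.757, bin3 = 0.643),
       one = c(intercept = -71.576, shelf_on = 34.001, bin3 = 32.529),
       d = 1.828, sigma = sqrt(1.273))
}

#' Tag-simulation configuration
#'
#' Defaults mirror the study design: two sharks tagged in September with
#' 6-hour depth bins, one switching from shelf to off-shelf waters mid
#' deployment, the other remaining on the shelf throughout; ZOIB truth set to
#' the fitted availability-model coefficients. `night_offsets` lower the mean
#' linear predictor in the unmodelled night bins (1: 00--06, 4: 18--24) to
#' reproduce the observed diel pattern (most surface time in daylight).
#'
#' @param n_sharks number of sharks.
#' @param n_days deployment length in days (scalar or per-shark vector).
#' @param coefs ZOIB truth, a list with `mean`, `zero`, `one` (each length-3:
#'   intercept, shelf-on, bin-3), `d` (log precision) and `sigma`
#'   (random-effect SD).
#' @param shelf_switch_day day index at which each shark moves off-shelf
#'   (`NA` = stays on-shelf; recycled).
#' @param night_offsets additive logit-scale offsets to the mean component
#'   for time bins 1..4 (bin 3 additionally gets the `bin3` coefficient).
#' @param start date-time (UTC) of the first bin.
#' @param layer_edges depth-layer breakpoints in metres (first layer 0--1).
#' @param seed integer seed.
#' @return config list for [simulate_tags()].
#' @export
tag_sim_config <- function(n_sharks = 2, n_days = c(120, 70),
                           coefs = default_zoib_truth(),
                           shelf_switch_day = c(35, NA),
                           night_offsets = c(-0.82, 0, 0, -0.48),
                           start = "2012-09-15 00:00:00",
                           layer_edges = c(0, 1, 5, 10, 25, 50, 100, 150,
                                           200, 300, 500),
                           seed = 1) {
  stopifnot(all(n_days >= 3), length(night_offsets) == 4,
            layer_edges[1] == 0, layer_edges[2] == 1)
  list(n_sharks = n_sharks, n_days = rep_len(n_days, n_sharks),
       coefs = coefs,
       shelf_switch_day = rep_len(shelf_switch_day, n_sharks),
       night_offsets = night_offsets, start = start,
       layer_edges = layer_edges, seed = seed)
}

#' Simulate depth-bin tag records from ZOIB truth
#'
#' For every shark x day x 6-h bin, draws a shark-by-day random intercept
#' u ~ Normal(0, sigma^2), forms the three ZOIB linear predictors from the
#' shelf state and time bin, and draws the surface proportion from the
#' mixture. The remaining (1 - y) is spread uniformly over the deeper
#' layers available to the shark's current habitat: on-shelf bins occupy
#' layers above 150 m only, off-shelf bins the full column, so the
#' dive-depth changepoint rule can recover the shelf switch.
#'
#' @param config a [tag_sim_config()].
#' @return list with `records` (a [depth_records()] object), and `truth`
#'   (config, per-block random effects, per-bin latent values including the
#'   emitted surface proportions, and the implied per-stratum availability).
#' @export
simulate_tags <- function(config = tag_sim_config()) {
  set.seed(config$seed)
  cf <- config$coefs
  sid_all <- sprintf("shark_%s",
                     vapply(seq_len(config$n_sharks), function(s) {
                       paste(LETTERS[1 + (s - 1) %% 26],
                             if (s > 26) (s - 1) %/% 26 else "", sep = "")
                     }, character(1)))
  ## one row per shark x day x bin
  lat <- do.call(rbind, lapply(seq_len(config$n_sharks), function(s) {
    nd <- config$n_days[s]
    expand.grid(time_bin = 1:4, day_index = seq_len(nd) - 1L,
                shark = s, KEEP.OUT.ATTRS = FALSE)
  }))
  lat$shark_id <- sid_all[lat$shark]
  sw <- config$shelf_switch_day[lat$shark]
  lat$on_shelf <- is.na(sw) | lat$day_index < sw
  blockf <- factor(paste(lat$shark, lat$day_index))
  u_block <- stats::rnorm(nlevels(blockf), 0, cf$sigma)
  lat$u <- u_block[as.integer(blockf)]
  on <- as.numeric(lat$on_shelf); b3 <- as.numeric(lat$time_bin == 3)
  eta_m <- cf$mean[1] + cf$mean[2] * on + cf$mean[3] * b3 +
    config$night_offsets[lat$time_bin] + lat$u
  eta_0 <- cf$zero[1] + cf$zero[2] * on + cf$zero[3] * b3
  eta_1 <- cf$one[1] + cf$one[2] * on + cf$one[3] * b3
  lat$y <- rzoib(nrow(lat), invlogit(eta_m), invlogit(eta_0),
                 invlogit(eta_1), exp(cf$d))
  lat$bin_start <- as.POSIXct(config$start, tz = "UTC") +
    (lat$day_index * 24 + (lat$time_bin - 1) * 6) * 3600

  ## expand to depth layers: surface layer gets y, the rest is spread
  ## uniformly over the layers available to the current habitat
  edges <- config$layer_edges
  nl <- length(edges) - 1
  lmin <- edges[-length(edges)]; lmax <- edges[-1]
  deep_on <- lmin > 0 & lmin < 150
  deep_off <- lmin > 0
  n_on <- sum(deep_on); n_off <- sum(deep_off)
  nb <- nrow(lat)
  prop <- matrix(0, nb, nl)
  prop[, 1] <- lat$y
  share <- (1 - lat$y) / ifelse(lat$on_shelf, n_on, n_off)
  for (j in which(deep_off)) {
    active <- if (deep_on[j]) rep(TRUE, nb) else !lat$on_shelf
    prop[active, j] <- prop[active, j] + share[active]
  }
  rows <- data.frame(
    shark_id = rep(lat$shark_id, each = nl),
    bin_start = rep(lat$bin_start, each = nl),
    layer_min = rep(lmin, nb), layer_max = rep(lmax, nb),
    proportion = as.vector(t(prop)))
  records <- depth_records(rows)
  truth <- list(config = config,
                latent = lat[c("shark_id", "bin_start", "day_index",
                               "time_bin", "on_shelf", "y", "u")],
                availability = implied_availability(cf))
  list(records = records, truth = truth)
}

#' Stratum availability implied by ZOIB coefficients
#'
#' Marginal expected surface proportion per shelf stratum, averaging over the
#' daytime bins and integrating the shark-by-day random intercept out of the
#' mean component by Gauss-Hermite quadrature. This is the population
#' quantity the availability model estimates, and the self-consistent
#' thinning probability for the survey simulator.
#'
#' @param coefs ZOIB truth list (see [tag_sim_config()]).
#' @param time_bins daytime bins averaged over (default `c(2, 3)`).
#' @param n_quad Gauss-Hermite nodes (default 41).
#' @return named vector `c(on = ..., off = ...)`.
#' @export
implied_availability <- function(coefs = default_zoib_truth(),
                                 time_bins = c(2, 3), n_quad = 41) {
  gh <- pracma::gaussHermite(n_quad)
  out <- vapply(c(on = 1, off = 0), function(on) {
    ey <- vapply(time_bins, function(b) {
      x <- c(1, on, as.numeric(b == 3))
      mu <- sum(gh$w / sqrt(pi) *
                  invlogit(sum(coefs$mean * x) + sqrt(2) * coefs$sigma * gh$x))
      zoib_mean(mu, invlogit(sum(coefs$zero * x)),
                invlogit(sum(coefs$one * x)))
    }, numeric(1))
    mean(ey)
  }, numeric(1))
  out
}

#' Survey-simulation configuration
#'
#' A rectangular study region (planar km, with a lon/lat georeference via an
#' azimuthal equidistant centre) containing a continental shelf in the west:
#' depth increases eastward through the 150 m shelf break and the 200 m
#' contour. Animal intensity concentrates along the shelf margin (a Gaussian
#' ridge in distance-to-200 m), the survey flies equally spaced zig-zag
#' transects, and detections arise by thinning: exposure within `w` of the
#' trackline, then stratum availability, then the hazard-rate detection
#' probability.
#'
#' @param width,height region size in km.
#' @param centre lon/lat of the region centre (default mirrors the Northeast
#'   Atlantic survey area).
#' @param shelf_edge_x easting (km, from the western edge) of the mid-slope;
#'   depth is `40 + 460 * plogis((x - shelf_edge_x) / 20)` m.
#' @param n_expected expected number of animals in the region.
#' @param hotspot_amp,hotspot_sd log-intensity ridge amplitude and width (km)
#'   around the 200 m contour.
#' @param detection list: `key`, `sigma` (m), `shape`, `w` (m), and
#'   `cloud_effect`, additive log-scale offsets to `sigma` per cloud level.
#' @param availability per-stratum surface availability `c(on=, off=)`;
#'   `NULL` (default) derives it from `tag_coefs` via
#'   [implied_availability()] so that tag and survey truths agree.
#' @param tag_coefs ZOIB truth used when `availability` is `NULL`.
#' @param n_legs number of zig-zag legs.
#' @param fix_spacing_km spacing of effort GPS fixes along the trackline.
#' @param frac_unidentified fraction of shark detections recorded as
#'   `unidentified_shark` (they still are blue sharks in truth).
#' @param n_basking extra basking-shark sightings (excluded by pooling).
#' @param grid_res prediction-grid cell size in km.
#' @param seed integer seed.
#' @return config list for [simulate_survey()].
#' @export
survey_sim_config <- function(width = 300, height = 300,
                              centre = c(-10.5, 52.5), shelf_edge_x = 150,
                              n_expected = 6000, hotspot_amp = 1.2,
                              hotspot_sd = 30,
                              detection = list(key = "hazard_rate",
                                               sigma = 180, shape = 3,
                                               w = 500,
                                               cloud_effect = c(clear = 0,
                                                                partial = 0,
                                                                overcast = 0)),
                              availability = NULL,
                              tag_coefs = default_zoib_truth(),
                              n_legs = 24, fix_spacing_km = 1,
                              frac_unidentified = 0, n_basking = 0,
                              grid_res = 10, seed = 1) {
  if (is.null(availability)) {
    availability <- implied_availability(tag_coefs)
  }
  stopifnot(all(availability > 0 & availability <= 1),
            all(c("on", "off") %in% names(availability)))
  list(width = width, height = height, centre = centre,
       shelf_edge_x = shelf_edge_x, n_expected = n_expected,
       hotspot_amp = hotspot_amp, hotspot_sd = hotspot_sd,
       detection = detection, availability = availability,
       n_legs = n_legs, fix_spacing_km = fix_spacing_km,
       frac_unidentified = frac_unidentified, n_basking = n_basking,
       grid_res = grid_res, seed = seed)
}

## Environmental fields of the synthetic region (deterministic functions of
## position; x measured from the western edge).
survey_fields <- function(cfg, x, y) {
  f <- invlogit((x - cfg$shelf_edge_x) / 20)
  depth <- 40 + 460 * f
  x200 <- cfg$shelf_edge_x + 20 * logit(160 / 460)
  data.frame(
    depth_m = depth,
    slope = 460 / 20 * f * (1 - f),
    dist_shore_km = x,
    dist_200m_km = abs(x - x200),
    sst_c = 13.5 + 1.2 * sin(2 * pi * y / cfg$height) +
      0.8 * cos(2 * pi * x / cfg$width),
    mld_m = 20 + 15 * f,
    chla_mg_m3 = 1.5 * exp(-depth / 300) + 0.3 * sin(2.6 * pi * y / cfg$height),
    on_shelf = depth < 150
  )
}

## Unnormalised log-intensity ridge along the 200 m contour.
survey_log_shape <- function(cfg, x, y) {
  fl <- survey_fields(cfg, x, y)
  cfg$hotspot_amp * exp(-fl$dist_200m_km^2 / (2 * cfg$hotspot_sd^2))
}

## Perpendicular distance from points to a finite segment, plus the foot of
## the perpendicular (clamped to the segment).
point_segment_distance <- function(px, py, x1, y1, x2, y2) {
  vx <- x2 - x1; vy <- y2 - y1
  len2 <- vx^2 + vy^2
  t <- pmin(1, pmax(0, ((px - x1) * vx + (py - y1) * vy) / len2))
  fx <- x1 + t * vx; fy <- y1 + t * vy
  list(dist = sqrt((px - fx)^2 + (py - fy)^2), fx = fx, fy = fy, t = t)
}

#' Simulate an aerial line-transect survey with availability thinning
#'
#' Animals are placed by an inhomogeneous Poisson process with the
#' configured intensity; equally spaced zig-zag transects are flown; each
#' animal within `w` of a trackline is exposed, is at the surface with its
#' stratum's availability probability, and, if available, is detected with
#' probability g(perpendicular distance) under the true detection function.
#' Detected animals become sightings at the trackline foot of the
#' perpendicular.
#'
#' @param config a [survey_sim_config()].
#' @return list: `effort` (GPS fixes with `transect`, `lon`, `lat`,
#'   `on_effort`, `cloud`), `sightings` (`distance` in m, `species`,
#'   `group_size`, `cloud`, `lon`, `lat`, `transect`), `grid` (prediction
#'   cells with environmental covariates, `area`, `on_shelf` and the true
#'   expected abundance `true_abundance` per cell), and `truth` (realised
#'   `N_true`, expected N, availability, detection parameters, seed).
#' @export
simulate_survey <- function(config = survey_sim_config()) {
  cfg <- config
  set.seed(cfg$seed)
  W <- cfg$width; H <- cfg$height
  w_km <- cfg$detection$w / 1000

  ## normalising constant of the intensity on a fine grid
  gx <- seq(0.5, W - 0.5, by = 1); gy <- seq(0.5, H - 0.5, by = 1)
  gg <- expand.grid(x = gx, y = gy)
  shp <- exp(survey_log_shape(cfg, gg$x, gg$y))
  c0 <- cfg$n_expected / sum(shp)          # intensity per 1 km^2 cell / shape
  lambda_max <- c0 * max(shp)

  ## animals: Poisson number, positions by thinning a uniform proposal
  N <- stats::rpois(1, cfg$n_expected)
  ax <- numeric(0); ay <- numeric(0)
  while (length(ax) < N) {
    m <- 2 * (N - length(ax)) + 100
    px <- stats::runif(m, 0, W); py <- stats::runif(m, 0, H)
    keep <- stats::runif(m) < c0 * exp(survey_log_shape(cfg, px, py)) / lambda_max
    ax <- c(ax, px[keep]); ay <- c(ay, py[keep])
  }
  ax <- ax[seq_len(N)]; ay <- ay[seq_len(N)]
  afl <- survey_fields(cfg, ax, ay)

  ## zig-zag transects: apexes alternate between the south and north edges
  K <- cfg$n_legs
  apex_x <- seq(0, W, length.out = K + 1)
  apex_y <- rep(c(0, H), length.out = K + 1)
  cloud_levels <- names(cfg$detection$cloud_effect)
  leg_cloud <- sample(cloud_levels, K, replace = TRUE)

  ## effort fixes along each leg
  eff <- list()
  for (k in seq_len(K)) {
    x1 <- apex_x[k]; y1 <- apex_y[k]; x2 <- apex_x[k + 1]; y2 <- apex_y[k + 1]
    L <- sqrt((x2 - x1)^2 + (y2 - y1)^2)
    s <- seq(0, L, by = cfg$fix_spacing_km)
    if (s[length(s)] < L) s <- c(s, L)
    eff[[k]] <- data.frame(transect = k,
                           x = x1 + s / L * (x2 - x1),
                           y = y1 + s / L * (y2 - y1),
                           on_effort = TRUE, cloud = leg_cloud[k])
  }
  effort <- do.call(rbind, eff)
  ## georeference: planar km relative to the region's south-west corner
  ll <- unproject_aeqd(effort$x - W / 2, effort$y - H / 2, cfg$centre)
  effort$lon <- ll$lon; effort$lat <- ll$lat

  ## exposure: nearest leg within w
  dmin <- rep(Inf, N); leg <- rep(NA_integer_, N)
  fx <- fy <- rep(NA_real_, N)
  for (k in seq_len(K)) {
    ps <- point_segment_distance(ax, ay, apex_x[k], apex_y[k],
                                 apex_x[k + 1], apex_y[k + 1])
    upd <- ps$dist < dmin
    dmin[upd] <- ps$dist[upd]; leg[upd] <- k
    fx[upd] <- ps$fx[upd]; fy[upd] <- ps$fy[upd]
  }
  exposed <- dmin <= w_km
  avail_p <- ifelse(afl$on_shelf, cfg$availability["on"], cfg$availability["off"])
  available <- stats::runif(N) < avail_p
  sig <- cfg$detection$sigma *
    exp(cfg$detection$cloud_effect[leg_cloud[ifelse(is.na(leg), 1L, leg)]])
  gdet <- key_function(dmin * 1000, cfg$detection$key, sig,
                       cfg$detection$shape)
  detected <- exposed & available & (stats::runif(N) < gdet)

  idx <- which(detected)
  species <- rep("blue_shark", length(idx))
  if (cfg$frac_unidentified > 0 && length(idx)) {
    species[stats::runif(length(idx)) < cfg$frac_unidentified] <-
      "unidentified_shark"
  }
  sll <- unproject_aeqd(fx[idx] - W / 2, fy[idx] - H / 2, cfg$centre)
  sightings <- data.frame(
    sighting_id = seq_along(idx), transect = leg[idx],
    distance = dmin[idx] * 1000, species = species, group_size = 1L,
    cloud = leg_cloud[leg[idx]], lon = sll$lon, lat = sll$lat)
  if (cfg$n_basking > 0) {
    bl <- sample(K, cfg$n_basking, replace = TRUE)
    bt <- stats::runif(cfg$n_basking)
    bx <- apex_x[bl] + bt * (apex_x[bl + 1] - apex_x[bl])
    by <- apex_y[bl] + bt * (apex_y[bl + 1] - apex_y[bl])
    bll <- unproject_aeqd(bx - W / 2, by - H / 2, cfg$centre)
    sightings <- rbind(sightings, data.frame(
      sighting_id = nrow(sightings) + seq_len(cfg$n_basking),
      transect = bl, distance = stats::runif(cfg$n_basking, 0,
                                             cfg$detection$w),
      species = "basking_shark", group_size = 1L, cloud = leg_cloud[bl],
      lon = bll$lon, lat = bll$lat))
  }

  ## prediction grid with the true expected abundance per cell
  res <- cfg$grid_res
  cx <- seq(res / 2, W - res / 2, by = res)
  cy <- seq(res / 2, H - res / 2, by = res)
  grid <- expand.grid(x = cx, y = cy)
  gfl <- survey_fields(cfg, grid$x, grid$y)
  grid <- cbind(grid, gfl)
  grid$area <- res^2
  grid$true_abundance <- c0 * exp(survey_log_shape(cfg, grid$x, grid$y)) *
    res^2
  gll <- unproject_aeqd(grid$x - W / 2, grid$y - H / 2, cfg$centre)
  grid$lon <- gll$lon; grid$lat <- gll$lat

  ## rough expected sighting count at this configuration
  L_tot <- sum(sqrt(diff(apex_x)^2 + diff(apex_y)^2))
  aw <- sum(grid$true_abundance *
              ifelse(grid$on_shelf, cfg$availability["on"],
                     cfg$availability["off"])) / sum(grid$true_abundance)
  p_bar <- stats::integrate(function(u) {
    key_function(u, cfg$detection$key, cfg$detection$sigma,
                 cfg$detection$shape)
  }, 0, cfg$detection$w)$value / cfg$detection$w
  e_sight <- cfg$n_expected * (2 * w_km * L_tot) / (W * H) * aw * p_bar
  if (e_sight < 60) {
    warning("simulate_survey: expected sighting count ", round(e_sight),
            " is below the minimum observations recommended for fitting a ",
            "detection function (n = 60)")
  }

  truth <- list(N_true = N, n_expected = cfg$n_expected,
                availability = cfg$availability,
                detection = cfg$detection,
                n_exposed = sum(exposed),
                n_available = sum(exposed & available),
                n_detected = length(idx),
                effort_km = sum(sqrt(diff(apex_x)^2 + diff(apex_y)^2)),
                seed = cfg$seed)
  list(effort = effort, sightings = sightings, grid = grid, truth = truth,
       config = cfg)
}

#' Write the standard synthetic fixture suite
#'
#' A two-shark tag deployment (120- and 70-day programmes, one mid-deployment
#' shelf switch) and a one-summer survey sized to yield a few tens of blue
#' shark sightings, with some detections recorded as unidentified sharks and
#' a couple of basking sharks, plus the complete generator truth as JSON.
#'
#' @param dir output directory (created if needed).
#' @param seed integer seed driving both generators.
#' @return invisibly, the named list of files written.
#' @export
make_fixture_suite <- function(dir, seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tcfg <- tag_sim_config(seed = seed)
  tags <- simulate_tags(tcfg)
  scfg <- survey_sim_config(n_legs = 14, frac_unidentified = 0.3,
                            n_basking = 2, seed = seed + 1)
  surv <- simulate_survey(scfg)
  prov <- list(seed = seed, generator = "availbias::make_fixture_suite")
  files <- list(
    tags = file.path(dir, "tags.csv"),
    effort = file.path(dir, "effort.csv"),
    sightings = file.path(dir, "sightings.csv"),
    grid = file.path(dir, "grid.csv"),
    truth = file.path(dir, "truth.json"))
  write_depth_records(tags$records, files$tags, dialect = "long",
                      provenance = prov)
  write_csv_provenance(surv$effort[c("transect", "lon", "lat", "on_effort",
                                     "cloud")], files$effort, prov)
  write_csv_provenance(surv$sightings, files$sightings, prov)
  gcols <- c("lon", "lat", "depth_m", "slope", "dist_shore_km",
             "dist_200m_km", "sst_c", "mld_m", "chla_mg_m3", "area",
             "on_shelf", "true_abundance")
  write_csv_provenance(surv$grid[gcols], files$grid, prov)
  truth <- list(
    seed = seed,
    tag = list(config = tcfg[setdiff(names(tcfg), "coefs")],
               coefs = tcfg$coefs,
               availability_implied = as.list(tags$truth$availability)),
    survey = list(config = scfg[setdiff(names(scfg),
                                        c("detection", "availability"))],
                  detection = scfg$detection,
                  availability = as.list(scfg$availability),
                  N_true = surv$truth$N_true,
                  n_detected = surv$truth$n_detected,
                  effort_km = surv$truth$effort_km))
  writeLines(jsonlite::toJSON(truth, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE), files$truth)
  invisible(files)
}
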