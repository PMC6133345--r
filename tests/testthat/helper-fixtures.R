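## Shared builders for small in-code fixtures.

## One shark, `n_bins` consecutive 6-h bins over three layers (0-1, 1-5,
## 5-200), with the given surface proportions.
toy_records <- function(surface, shark_id = "S1",
                        start = as.POSIXct("2015-06-01 00:00:00", tz = "UTC"),
                        deep_split = 0.5) {
  n <- length(surface)
  bins <- start + (seq_len(n) - 1) * 6 * 3600
  df <- do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- 1 - surface[i]
    data.frame(shark_id = shark_id, bin_start = bins[i],
               layer_min = c(0, 1, 5), layer_max = c(1, 5, 200),
               proportion = c(surface[i], rest * deep_split,
                              rest * (1 - deep_split)))
  }))
  depth_records(df)
}

## Availability observations drawn from a ZOIB truth without going through
## depth records (for model-fitting tests).
toy_availability <- function(n_sharks = 6, n_days = 12, switch_day = 6,
                             coefs = NULL, seed = 1) {
  cfg <- tag_sim_config(n_sharks = n_sharks, n_days = n_days,
                        shelf_switch_day = switch_day,
                        coefs = coefs %||% availbias:::default_zoib_truth(),
                        seed = seed)
  sim <- simulate_tags(cfg)
  lat <- sim$truth$latent
  data.frame(shark_id = lat$shark_id, bin_start = lat$bin_start,
             day_index = lat$day_index, time_bin = lat$time_bin,
             on_shelf = lat$on_shelf, surface_proportion = lat$y)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Uniform-density effort segments with Poisson counts (for DSM tests).
toy_segments <- function(n = 300, density = 0.02, length_km = 10, p = 0.5,
                         avail = 0.4, w = 500, seed = 1) {
  set.seed(seed)
  seg <- data.frame(segment_id = seq_len(n),
                    x = runif(n, 0, 300), y = runif(n, 0, 300),
                    length = length_km, on_shelf = runif(n) < 0.5)
  mu <- density * 2 * (w / 1000) * seg$length * p * avail
  seg$count <- rpois(n, mu)
  seg
}
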