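## Internal helpers shared across modules.

invlogit <- stats::plogis

logit <- stats::qlogis

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Gauss-Legendre nodes and weights on an interval
#' @noRd
gauss_legendre <- function(n, a, b) {
  gl <- pracma::gaussLegendre(n, a, b)
  list(x = gl$x, w = gl$w)
}

## Azimuthal equidistant projection on a sphere (km), centred at (lon0, lat0).
## Adequate for survey regions a few hundred km across.
EARTH_RADIUS_KM <- 6371.0088

#' Project lon/lat to planar km coordinates
#'
#' Azimuthal equidistant projection centred on `centre`; distances from the
#' centre are preserved exactly, shape distortion is negligible at survey
#' scales (a few hundred km).
#'
#' @param lon,lat coordinates in decimal degrees.
#' @param centre numeric length-2, `c(lon0, lat0)` of the projection centre.
#' @return data.frame with columns `x`, `y` in km.
#' @export
project_aeqd <- function(lon, lat, centre) {
  to_rad <- pi / 180
  lam <- lon * to_rad; phi <- lat * to_rad
  lam0 <- centre[1] * to_rad; phi0 <- centre[2] * to_rad
  cosc <- sin(phi0) * sin(phi) + cos(phi0) * cos(phi) * cos(lam - lam0)
  cosc <- pmin(1, pmax(-1, cosc))
  c_ang <- acos(cosc)
  k <- ifelse(c_ang < 1e-12, 1, c_ang / sin(c_ang))
  x <- EARTH_RADIUS_KM * k * cos(phi) * sin(lam - lam0)
  y <- EARTH_RADIUS_KM * k * (cos(phi0) * sin(phi) - sin(phi0) * cos(phi) * cos(lam - lam0))
  data.frame(x = x, y = y)
}

#' Inverse azimuthal equidistant projection
#'
#' @param x,y planar coordinates in km (as produced by [project_aeqd()]).
#' @param centre numeric length-2, `c(lon0, lat0)`.
#' @return data.frame with columns `lon`, `lat` in decimal degrees.
#' @export
unproject_aeqd <- function(x, y, centre) {
  to_rad <- pi / 180
  lam0 <- centre[1] * to_rad; phi0 <- centre[2] * to_rad
  rho <- sqrt(x^2 + y^2)
  c_ang <- rho / EARTH_RADIUS_KM
  phi <- ifelse(rho < 1e-12, phi0,
                asin(cos(c_ang) * sin(phi0) + y * sin(c_ang) * cos(phi0) / rho))
  lam <- lam0 + ifelse(rho < 1e-12, 0,
                       atan2(x * sin(c_ang),
                             rho * cos(phi0) * cos(c_ang) - y * sin(phi0) * sin(c_ang)))
  data.frame(lon = lam / to_rad, lat = phi / to_rad)
}

## Provenance-aware CSV I/O: a few '# key: value' comment lines precede the
## header so every artifact records the seed and config hash that produced it.
write_csv_provenance <- function(df, path, provenance = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(provenance)) {
    for (k in names(provenance)) {
      writeLines(sprintf("# %s: %s", k, provenance[[k]]), con)
    }
  }
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

read_csv_provenance <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

## Stable short hash of an R object (used for config provenance).
config_hash <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  saveRDS(x, tf, version = 2, compress = FALSE)
  unname(tools::md5sum(tf))
}

## Draw from N(mu, Sigma) given a Cholesky-factorisable covariance.
rmvn_chol <- function(n, mu, Sigma) {
  L <- chol(Sigma)
  p <- length(mu)
  z <- matrix(stats::rnorm(n * p), n, p)
  sweep(z %*% L, 2, mu, `+`)
}
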