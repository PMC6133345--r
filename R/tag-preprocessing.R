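## Tag preprocessing: from raw depth-bin records (pop-up satellite archival
## tags summarise each 6-hour interval as proportions of time spent in stated
## depth layers) to model-ready availability observations.

SUM_TOLERANCE <- 0.02  # tag firmware rounds bin proportions; tolerate rounding

#' Construct a depth-record table
#'
#' Canonical long form: one row per shark x 6-h bin x depth layer, with
#' columns `shark_id`, `bin_start` (UTC), `layer_min`, `layer_max`,
#' `proportion`. Validates the per-bin invariants: proportions in \[0, 1\],
#' per-bin proportions summing to 1 within a tolerance of 0.02, and strictly
#' increasing layer edges starting at 0.
#'
#' @param df data.frame in long form (see above).
#' @param bin_duration_h bin length in hours (tags used here record 6-h bins).
#' @return object of class `depth_records`; the per-shark deployment start
#'   (first bin) is stored as an attribute so that burn-in filtering is
#'   anchored to deployment, not to whatever data survive earlier filters.
#' @export
depth_records <- function(df, bin_duration_h = 6) {
  req <- c("shark_id", "bin_start", "layer_min", "layer_max", "proportion")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stop("depth record schema error: missing column(s) ", paste(miss, collapse = ", "))
  }
  df$shark_id <- as.character(df$shark_id)
  if (!inherits(df$bin_start, "POSIXct")) {
    df$bin_start <- as.POSIXct(df$bin_start, tz = "UTC")
  }
  attr(df$bin_start, "tzone") <- "UTC"
  bad <- which(df$proportion < 0 | df$proportion > 1 | is.na(df$proportion))
  if (length(bad)) {
    stop("depth record validation error: proportion outside [0,1] in row(s) ",
         paste(utils::head(bad, 20), collapse = ", "))
  }
  df <- df[order(df$shark_id, df$bin_start, df$layer_min), , drop = FALSE]
  key <- paste(df$shark_id, format(df$bin_start, "%Y-%m-%d %H:%M:%S"))
  sums <- tapply(df$proportion, key, sum)
  off <- which(abs(sums - 1) > SUM_TOLERANCE)
  if (length(off)) {
    rows <- which(key %in% names(sums)[off])
    stop("depth record validation error: layer proportions do not sum to 1 ",
         "(tolerance 0.02) for bin(s) ", paste(utils::head(names(sums)[off], 10), collapse = "; "),
         " [rows ", paste(utils::head(rows, 20), collapse = ", "), "]")
  }
  firsts <- tapply(df$layer_min, key, function(v) v[1])
  if (any(firsts != 0)) {
    stop("depth record validation error: first layer must start at 0 m")
  }
  incr <- tapply(seq_len(nrow(df)), key, function(i) {
    all(diff(df$layer_min[i]) > 0) && all(df$layer_max[i] > df$layer_min[i])
  })
  if (!all(unlist(incr))) {
    stop("depth record validation error: layer edges must be strictly increasing")
  }
  deploy <- tapply(as.numeric(df$bin_start), df$shark_id, min)
  structure(df,
            class = c("depth_records", "data.frame"),
            bin_duration_h = bin_duration_h,
            deploy_start = deploy)
}

#' Read depth-bin records from CSV
#'
#' Two layouts are supported. `"long"`: one row per shark x bin x layer with
#' columns `shark_id, bin_start, layer_min, layer_max, proportion`. `"wide"`:
#' one row per shark x bin with columns `shark_id, bin_start` plus one column
#' per layer named `d<min>_<max>` (e.g. `d0_1`, `d1_5`, `d5_10`).
#'
#' @param path CSV file path (UTF-8, header row; `#` comment lines ignored).
#' @param dialect `"long"` or `"wide"`.
#' @return a [depth_records()] object.
#' @export
read_depth_records <- function(path, dialect = c("long", "wide")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("depth record file not found: ", path)
  df <- read_csv_provenance(path)
  if (dialect == "wide") {
    layer_cols <- grep("^d[0-9.]+_[0-9.]+$", names(df), value = TRUE)
    if (!length(layer_cols)) {
      stop("depth record schema error: wide layout needs layer columns d<min>_<max>")
    }
    edges <- do.call(rbind, lapply(strsplit(sub("^d", "", layer_cols), "_"),
                                   as.numeric))
    ord <- order(edges[, 1])
    layer_cols <- layer_cols[ord]; edges <- edges[ord, , drop = FALSE]
    long <- do.call(rbind, lapply(seq_along(layer_cols), function(j) {
      data.frame(shark_id = df$shark_id, bin_start = df$bin_start,
                 layer_min = edges[j, 1], layer_max = edges[j, 2],
                 proportion = df[[layer_cols[j]]])
    }))
    df <- long
  }
  depth_records(df)
}

#' Write depth-bin records to CSV
#'
#' Inverse of [read_depth_records()]; useful for fixtures and round-trip
#' checks between the long and wide dialects.
#'
#' @param records a [depth_records()] object.
#' @param path output CSV path.
#' @param dialect `"long"` or `"wide"`.
#' @param provenance optional named list written as `# key: value` comments.
#' @export
write_depth_records <- function(records, path, dialect = c("long", "wide"),
                                provenance = NULL) {
  dialect <- match.arg(dialect)
  df <- as.data.frame(records)
  df$bin_start <- format(df$bin_start, "%Y-%m-%d %H:%M:%S")
  if (dialect == "long") {
    out <- df
  } else {
    key <- unique(df[c("shark_id", "bin_start")])
    lays <- unique(df[c("layer_min", "layer_max")])
    lays <- lays[order(lays$layer_min), ]
    out <- key
    for (j in seq_len(nrow(lays))) {
      cn <- sprintf("d%g_%g", lays$layer_min[j], lays$layer_max[j])
      m <- merge(key, df[df$layer_min == lays$layer_min[j],
                         c("shark_id", "bin_start", "proportion")],
                 by = c("shark_id", "bin_start"), all.x = TRUE, sort = FALSE)
      m <- m[match(paste(key$shark_id, key$bin_start),
                   paste(m$shark_id, m$bin_start)), ]
      out[[cn]] <- ifelse(is.na(m$proportion), 0, m$proportion)
    }
  }
  write_csv_provenance(out, path, provenance)
}

#' Remove post-tagging burn-in days
#'
#' Drops, for each shark, every bin starting earlier than
#' `deployment start + days * 24 h`, excluding behaviour potentially altered
#' by capture stress. The deployment start recorded when the records were
#' constructed is used as the anchor, so the filter is idempotent.
#'
#' @param records a [depth_records()] object.
#' @param days number of days to drop (default 2).
#' @return filtered `depth_records`; sharks left with no bins are dropped
#'   with a warning.
#' @export
filter_burn_in <- function(records, days = 2) {
  stopifnot(inherits(records, "depth_records"), days >= 0)
  deploy <- attr(records, "deploy_start")
  cutoff <- deploy[records$shark_id] + days * 86400
  keep <- as.numeric(records$bin_start) >= cutoff
  gone <- setdiff(names(deploy), unique(records$shark_id[keep]))
  if (length(gone)) {
    warning("filter_burn_in: shark(s) dropped (no bins after burn-in): ",
            paste(gone, collapse = ", "))
  }
  out <- records[keep, , drop = FALSE]
  structure(out, class = class(records),
            bin_duration_h = attr(records, "bin_duration_h"),
            deploy_start = deploy[names(deploy) %in% unique(out$shark_id)])
}

## One row per shark x bin, in deterministic order.
bins_of <- function(records) {
  df <- as.data.frame(records)
  out <- unique(df[c("shark_id", "bin_start")])
  out[order(out$shark_id, out$bin_start), , drop = FALSE]
}

#' Extract the surface (0--1 m) proportion of each bin
#'
#' @param records a [depth_records()] object whose first layer is 0--1 m.
#' @return data.frame with one row per shark x bin: `shark_id`, `bin_start`,
#'   `surface_proportion` (clamped to \[0, 1\]).
#' @export
surface_proportion <- function(records) {
  df <- as.data.frame(records)
  surf <- df[df$layer_min == 0, , drop = FALSE]
  if (any(surf$layer_max != 1)) {
    stop("surface layer configuration error: first depth layer is not 0-1 m; ",
         "refusing to re-bin silently")
  }
  out <- bins_of(records)
  m <- match(paste(out$shark_id, out$bin_start), paste(surf$shark_id, surf$bin_start))
  if (anyNA(m)) stop("surface layer configuration error: bins without a 0-1 m layer")
  out$surface_proportion <- pmin(1, pmax(0, surf$proportion[m]))
  rownames(out) <- NULL
  out
}

#' Classify bins as on-shelf or off-shelf
#'
#' `"dive-rule"` mode implements a single-changepoint rule for animals whose
#' tags carry no position: a shark is taken to be in continental-shelf waters
#' until the first bin in which its deepest occupied depth layer starts below
#' `depth_threshold` (i.e. the animal demonstrably dived deeper than the
#' threshold); that bin and all later bins are off-shelf. A shark that never
#' dives past the threshold stays on-shelf throughout (logged via `message`).
#' `"track"` mode joins a reconstructed track to a bathymetry grid and marks a
#' bin on-shelf iff water depth at the matched position is shallower than
#' `shelf_depth`.
#'
#' @param records a [depth_records()] object.
#' @param mode `"dive-rule"` or `"track"`.
#' @param depth_threshold dive-depth changepoint threshold in metres
#'   (default 175, the midpoint of the 150--200 m range that signals a move
#'   into off-shelf waters).
#' @param track optional data.frame `shark_id, time, lon, lat` (track mode).
#' @param bathymetry optional gridded data.frame `lon, lat, depth_m`
#'   (track mode).
#' @param shelf_depth shelf definition in metres (track mode; default 150).
#' @return data.frame `shark_id, bin_start, on_shelf`.
#' @export
classify_shelf <- function(records, mode = c("dive-rule", "track"),
                           depth_threshold = 175, track = NULL,
                           bathymetry = NULL, shelf_depth = 150) {
  mode <- match.arg(mode)
  out <- bins_of(records)
  if (mode == "dive-rule") {
    df <- as.data.frame(records)
    occ <- df[df$proportion > 0, , drop = FALSE]
    deepest <- tapply(occ$layer_min, paste(occ$shark_id, occ$bin_start),
                      max)
    key <- paste(out$shark_id, out$bin_start)
    out$max_layer_min <- as.numeric(deepest[key])
    out$on_shelf <- TRUE
    for (s in unique(out$shark_id)) {
      i <- which(out$shark_id == s)
      trig <- which(out$max_layer_min[i] >= depth_threshold)
      if (length(trig)) {
        out$on_shelf[i[trig[1]:length(i)]] <- FALSE
      } else {
        message("classify_shelf: shark ", s, " never dived past ",
                depth_threshold, " m; all bins classed on-shelf")
      }
    }
    out$max_layer_min <- NULL
  } else {
    if (is.null(track) || is.null(bathymetry)) {
      stop("classify_shelf: mode 'track' requires 'track' and 'bathymetry'")
    }
    track$time <- as.POSIXct(track$time, tz = "UTC")
    out$on_shelf <- NA
    for (r in seq_len(nrow(out))) {
      tr <- track[track$shark_id == out$shark_id[r], , drop = FALSE]
      if (!nrow(tr)) stop("classify_shelf: no track for shark ", out$shark_id[r])
      j <- which.min(abs(as.numeric(tr$time) - as.numeric(out$bin_start[r])))
      k <- which.min((bathymetry$lon - tr$lon[j])^2 + (bathymetry$lat - tr$lat[j])^2)
      out$on_shelf[r] <- bathymetry$depth_m[k] < shelf_depth
    }
  }
  rownames(out) <- NULL
  out
}

#' Build availability observations from depth records
#'
#' Combines the surface proportions with a shelf classification into the tidy
#' analysis table: one row per shark x 6-h bin with `day_index` (integer days
#' since deployment, 0-based), `time_bin` (1: 00--06, 2: 06--12, 3: 12--18,
#' 4: 18--24, from the recorded UTC clock), `on_shelf` and
#' `surface_proportion`.
#'
#' @param records a [depth_records()] object (typically after
#'   [filter_burn_in()]).
#' @param shelf data.frame from [classify_shelf()], or a single logical
#'   applied to all bins.
#' @return data.frame of availability observations.
#' @export
as_availability <- function(records, shelf) {
  obs <- surface_proportion(records)
  if (anyDuplicated(paste(obs$shark_id, obs$bin_start))) {
    stop("as_availability: duplicate (shark_id, bin_start) bins")
  }
  deploy <- attr(records, "deploy_start")
  obs$day_index <- as.integer(floor(
    (as.numeric(obs$bin_start) - deploy[obs$shark_id]) / 86400))
  hr <- as.integer(format(obs$bin_start, "%H", tz = "UTC"))
  obs$time_bin <- hr %/% 6L + 1L
  if (is.logical(shelf) && length(shelf) == 1) {
    obs$on_shelf <- shelf
  } else {
    m <- match(paste(obs$shark_id, obs$bin_start),
               paste(shelf$shark_id, shelf$bin_start))
    if (anyNA(m)) stop("as_availability: shelf classification missing for some bins")
    obs$on_shelf <- shelf$on_shelf[m]
  }
  obs[c("shark_id", "bin_start", "day_index", "time_bin", "on_shelf",
        "surface_proportion")]
}

#' Average availability across observations
#'
#' @param observations availability data.frame (from [as_availability()]).
#' @param method `"pooled"` (unweighted mean over all observations of all
#'   sharks, the default) or `"by_shark"` (mean of per-shark means; differs
#'   from pooled when sharks contribute unequal numbers of bins).
#' @return a single proportion (full precision; round to 2 decimals for
#'   reporting).
#' @export
average_availability <- function(observations, method = c("pooled", "by_shark")) {
  method <- match.arg(method)
  if (!nrow(observations)) stop("average_availability: empty input")
  if (method == "pooled") {
    mean(observations$surface_proportion)
  } else {
    mean(tapply(observations$surface_proportion, observations$shark_id, mean))
  }
}

#' Generalized variance inflation factors
#'
#' Collinearity diagnostic for (possibly multi-column) model terms:
#' \eqn{\mathrm{GVIF}_j = \det(R_{11}) \det(R_{22}) / \det(R)} on the
#' correlation matrix of the dummy-coded design, where \eqn{R_{11}} is the
#' block for term j and \eqn{R_{22}} for the remaining terms. Also reports
#' \eqn{\mathrm{GVIF}^{1/(2\,df)}}, comparable across terms of different
#' dimension.
#'
#' @param design data.frame of covariates.
#' @param terms character vector (>= 2) of column names in `design`.
#' @return data.frame `term, df, gvif, gvif_adj`.
#' @export
gvif <- function(design, terms) {
  stopifnot(length(terms) >= 2, all(terms %in% names(design)))
  fm <- stats::reformulate(terms)
  mm <- stats::model.matrix(fm, data = design)
  asgn <- attr(mm, "assign")
  mm <- mm[, asgn != 0, drop = FALSE]
  asgn <- asgn[asgn != 0]
  if (any(apply(mm, 2, stats::sd) == 0)) {
    stop("gvif: constant column in design (single-level factor?)")
  }
  R <- stats::cor(mm)
  detR <- det(R)
  if (!is.finite(detR) || detR < 1e-12) {
    qr_ <- qr(scale(mm))
    aliased <- colnames(mm)[setdiff(seq_len(ncol(mm)), qr_$pivot[seq_len(qr_$rank)])]
    stop("gvif: singular design; aliased column(s): ",
         paste(aliased, collapse = ", "))
  }
  out <- lapply(seq_along(terms), function(j) {
    idx <- which(asgn == j)
    g <- det(R[idx, idx, drop = FALSE]) *
      det(R[-idx, -idx, drop = FALSE]) / detR
    data.frame(term = terms[j], df = length(idx), gvif = g,
               gvif_adj = g^(1 / (2 * length(idx))))
  })
  do.call(rbind, out)
}
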