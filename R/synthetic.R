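# Synthetic study generator: landscape, features, telemetry and litter fates
# with known selection coefficients, so every downstream stage can be tested
# against ground truth without any proprietary collar data.

#' Ground-truth configuration for the synthetic study
#'
#' Holds the generating selection coefficients for the two litter-fate groups
#' and the observation process (fix schedule, fix loss, DOP contamination,
#' litter-loss timing). Coefficients are log-scale weights of the exponential
#' RSF, applied to landscape-standardized continuous covariates (z-scored over
#' all grid cells) and raw 0/1 land-cover indicators. Defaults reproduce the
#' magnitude and sign structure of selection reported for Scandinavian brown
#' bear mothers, expressed on the distance scale (a positive coefficient on a
#' `dist_` covariate means larger distances are selected, i.e. avoidance of
#' the feature).
#'
#' @param beta_unsuccessful,beta_successful Named coefficient vectors; the two
#'   must cover identical covariate names (continuous layer names and
#'   land-cover classes).
#' @param p_litter_loss Probability a litter is lost (used by
#'   [simulate_fates()]; the study-level generator fixes group counts).
#' @param loss_date_dist Beta-distribution shape parameters for the loss date,
#'   rescaled onto \[`season_start`, `loss_end`\]; the default Beta(2, 3) puts
#'   most mass early in the mating season.
#' @param season_start,loss_end,season_end Month-day strings ("MM-DD"): start
#'   of the analysis season, end of the litter-loss window, and end of the
#'   simulated monitoring window.
#' @param n_bear_years,n_individuals Named counts (`successful`,
#'   `unsuccessful`) of monitored bear-years and of distinct mothers.
#' @param fixes_per_day GPS schedule (48 = one fix per 30 min).
#' @param fix_success_rate Probability a scheduled fix is acquired at all.
#' @param dop_dist Mixture for dilution-of-precision: with probability
#'   `p_high` DOP is uniform on `high`, otherwise uniform on `low`. The
#'   default sends ~40% of fixes to DOP >= 5, so the DOP filter leaves a
#'   retained fix rate near the ~60% observed in the field.
#' @param home_radius Radius (m) of the simulated circular home ranges.
#' @param years Calendar years bear-years are drawn from.
#' @return An object of class `truth_config`.
#' @export
truth_config <- function(
    beta_unsuccessful = c(dist_habitation = 0.210, dist_forest_road = 0.420,
                          dist_road = 0.557, ndvi = 0.188, bog = -0.761,
                          TRB = 0.452, clearcut = -0.501, young = 0.504,
                          mid_aged = 0.348, old = 0.675),
    beta_successful = c(dist_habitation = -0.524, dist_forest_road = 0.349,
                        dist_road = 0.338, ndvi = 0.182, bog = -1.159,
                        TRB = 0.188, clearcut = 0.560, young = 0.437,
                        mid_aged = 0.557, old = 0.190),
    p_litter_loss = 0.35,
    loss_date_dist = list(shape1 = 2, shape2 = 3),
    season_start = "05-01", loss_end = "06-16", season_end = "06-30",
    n_bear_years = c(successful = 19, unsuccessful = 11),
    n_individuals = c(successful = 16, unsuccessful = 10),
    fixes_per_day = 48, fix_success_rate = 0.95,
    dop_dist = list(p_high = 0.40, low = c(1, 5), high = c(5, 12)),
    home_radius = 1500,
    years = 2005:2012) {
  if (!setequal(names(beta_unsuccessful), names(beta_successful)))
    stop("the two beta mappings must cover the same covariate names")
  stopifnot(p_litter_loss >= 0, p_litter_loss <= 1,
            fix_success_rate >= 0, fix_success_rate <= 1,
            dop_dist$p_high >= 0, dop_dist$p_high <= 1,
            fixes_per_day >= 1, home_radius > 0)
  structure(list(
    beta_unsuccessful = beta_unsuccessful, beta_successful = beta_successful,
    p_litter_loss = p_litter_loss, loss_date_dist = loss_date_dist,
    season_start = season_start, loss_end = loss_end, season_end = season_end,
    n_bear_years = n_bear_years, n_individuals = n_individuals,
    fixes_per_day = fixes_per_day, fix_success_rate = fix_success_rate,
    dop_dist = dop_dist, home_radius = home_radius, years = years),
    class = "truth_config")
}

#' Landscape generator configuration
#'
#' @param habitation_intensity Homogeneous point-process intensity for
#'   habitations, per square metre (the default puts ~30 points on a
#'   10 x 10 km grid).
#' @param n_roads,n_forest_roads Number of high-traffic roads / forest roads
#'   (random polylines crossing the extent).
#' @param landcover_props Named target proportions of the seven land-cover
#'   classes; must sum to 1.
#' @param landcover_smooth,ndvi_smooth Smoothing range, in cells, of the noise
#'   fields behind land cover and NDVI.
#' @param ndvi_range Range the NDVI field is rescaled into (within \[-1, 1\]).
#' @return A list of class `landscape_config`.
#' @export
landscape_config <- function(habitation_intensity = 3e-7,
                             n_roads = 3, n_forest_roads = 8,
                             landcover_props = c(bog = 0.10, TRB = 0.10,
                                                 clearcut = 0.15, young = 0.20,
                                                 mid_aged = 0.20, old = 0.15,
                                                 other = 0.10),
                             landcover_smooth = 12, ndvi_smooth = 8,
                             ndvi_range = c(-0.1, 0.9)) {
  if (!setequal(names(landcover_props), landcover_classes()))
    stop("`landcover_props` must name all seven land-cover classes")
  if (abs(sum(landcover_props) - 1) > 1e-8)
    stop("`landcover_props` must sum to 1")
  if (ndvi_range[1] < -1 || ndvi_range[2] > 1 || ndvi_range[1] >= ndvi_range[2])
    stop("`ndvi_range` must be an increasing interval within [-1, 1]")
  structure(list(habitation_intensity = habitation_intensity,
                 n_roads = n_roads, n_forest_roads = n_forest_roads,
                 landcover_props = landcover_props[landcover_classes()],
                 landcover_smooth = landcover_smooth,
                 ndvi_smooth = ndvi_smooth, ndvi_range = ndvi_range),
            class = "landscape_config")
}

# Smoothed Gaussian noise field: white noise passed through a separable
# moving-average filter (circular boundaries keep the field stationary).
smooth_noise_field <- function(n_rows, n_cols, range_cells, n_pass = 3) {
  z <- matrix(stats::rnorm(n_rows * n_cols), n_rows, n_cols)
  w <- max(1L, as.integer(range_cells))
  k <- rep(1, w) / w
  for (p in seq_len(n_pass)) {
    z <- apply(z, 2, function(col) as.numeric(stats::filter(col, k, circular = TRUE)))
    z <- t(apply(z, 1, function(row) as.numeric(stats::filter(row, k, circular = TRUE))))
  }
  z
}

random_polyline <- function(ext, n_vertices = 6) {
  # crosses the extent between two opposite edges, with lateral jitter
  horiz <- stats::runif(1) < 0.5
  span <- if (horiz) ext[2] - ext[1] else ext[4] - ext[3]
  along <- seq(0, 1, length.out = n_vertices)
  lateral0 <- stats::runif(2)
  lateral <- lateral0[1] + (lateral0[2] - lateral0[1]) * along +
    c(0, stats::rnorm(n_vertices - 2, 0, 0.06), 0)
  lateral <- pmin(1, pmax(0, lateral))
  if (horiz)
    cbind(ext[1] + along * span, ext[3] + lateral * (ext[4] - ext[3]))
  else
    cbind(ext[1] + lateral * (ext[2] - ext[1]), ext[3] + along * span)
}

#' Generate a synthetic landscape
#'
#' Habitations come from a homogeneous point process, roads and forest roads
#' are random polylines crossing the extent, land cover is a smoothed noise
#' field thresholded at the target class proportions, and NDVI is an
#' independent smoothed field rescaled into `ndvi_range`. Distance layers
#' (`dist_habitation`, `dist_road`, `dist_forest_road`, in km) are computed
#' with [distance_to_features()].
#'
#' @param grid A [grid_spec()].
#' @param config A [landscape_config()].
#' @param seed Integer seed; identical (config, seed) reproduces the stack
#'   exactly.
#' @return List with `landscape` (a [landscape_stack()]) and `features`
#'   (a [feature_set()]).
#' @export
gen_landscape <- function(grid, config = landscape_config(), seed = 1) {
  set.seed(seed)
  ext <- grid_extent(grid)
  area <- (ext[2] - ext[1]) * (ext[4] - ext[3])
  n_hab <- max(1L, stats::rpois(1, config$habitation_intensity * area))
  habitations <- cbind(stats::runif(n_hab, ext[1], ext[2]),
                       stats::runif(n_hab, ext[3], ext[4]))
  roads <- replicate(config$n_roads, random_polyline(ext), simplify = FALSE)
  forest_roads <- replicate(config$n_forest_roads, random_polyline(ext),
                            simplify = FALSE)
  features <- feature_set(habitations, roads, forest_roads)

  z <- smooth_noise_field(grid$n_rows, grid$n_cols, config$landcover_smooth)
  props <- config$landcover_props
  brks <- stats::quantile(z, probs = cumsum(props)[-length(props)])
  landcover <- matrix(findInterval(z, brks, left.open = TRUE) + 1L,
                      grid$n_rows, grid$n_cols)

  nz <- smooth_noise_field(grid$n_rows, grid$n_cols, config$ndvi_smooth)
  rng <- range(nz)
  ndvi <- config$ndvi_range[1] +
    (nz - rng[1]) / (rng[2] - rng[1]) * diff(config$ndvi_range)

  continuous <- list(
    dist_habitation = distance_to_features(grid, features, "habitation"),
    dist_road = distance_to_features(grid, features, "road"),
    dist_forest_road = distance_to_features(grid, features, "forest_road"),
    ndvi = ndvi)
  list(landscape = landscape_stack(grid, continuous, landcover),
       features = features)
}

# Per-layer mean/sd over all grid cells; the scale the generating betas act on.
landscape_standardization <- function(landscape) {
  means <- vapply(landscape$continuous, mean, 0)
  sds <- vapply(landscape$continuous, stats::sd, 0)
  list(mean = means, sd = sds)
}

#' One monitored mother-year
#'
#' Light container for identity, litter fate and the relocation table.
#'
#' @param bear_id,year Identity label and calendar year.
#' @param relocations Tibble with columns `bear_id`, `year`, `timestamp`
#'   (POSIXct, UTC), `x`, `y`, `dop`.
#' @param fate One of `"survived"`, `"lost"`, `"partial_loss"` (or `NA` before
#'   fates are assigned).
#' @param loss_date,end_date Dates; `loss_date` only for lost litters,
#'   `end_date` is the randomized monitoring end assigned to survivors.
#' @return An object of class `bear_year_record`.
#' @export
bear_year_record <- function(bear_id, year, relocations,
                             fate = NA_character_, loss_date = as.Date(NA),
                             end_date = as.Date(NA)) {
  if (!is.na(fate))
    fate <- match.arg(fate, c("survived", "lost", "partial_loss"))
  structure(list(bear_id = as.character(bear_id), year = as.integer(year),
                 fate = fate, loss_date = loss_date, end_date = end_date,
                 relocations = relocations, fix_rate = NA_real_,
                 excluded = FALSE, exclusion_reason = NA_character_),
            class = "bear_year_record")
}

#' @export
print.bear_year_record <- function(x, ...) {
  cat(sprintf("<bear_year_record> %s / %d, fate %s, %d relocations\n",
              x$bear_id, x$year, x$fate, nrow(x$relocations)))
  invisible(x)
}

# Linear predictor eta = sum_j beta_j * covariate_j at arbitrary points,
# continuous layers z-scored by the landscape-wide standardization.
eta_at_points <- function(landscape, std, beta, px, py) {
  idx <- cell_index(landscape$grid, px, py)
  lin <- cbind(idx$row, idx$col)
  eta <- numeric(length(px))
  for (nm in names(beta)) {
    if (nm %in% names(landscape$continuous)) {
      z <- (landscape$continuous[[nm]][lin] - std$mean[[nm]]) / std$sd[[nm]]
      eta <- eta + beta[[nm]] * z
    } else if (nm %in% landcover_classes()) {
      code <- match(nm, landcover_classes())
      eta <- eta + beta[[nm]] * (landscape$landcover[lin] == code)
    } else stop("beta names a covariate not in the landscape: ", nm)
  }
  eta
}

draw_dop <- function(n, dop_dist) {
  high <- stats::runif(n) < dop_dist$p_high
  out <- numeric(n)
  out[high] <- stats::runif(sum(high), dop_dist$high[1], dop_dist$high[2])
  out[!high] <- stats::runif(sum(!high), dop_dist$low[1], dop_dist$low[2])
  out
}

#' Simulate one bear-year of GPS telemetry
#'
#' Candidate fixes follow a 30-min schedule over `n_days` from `start_date`;
#' each is acquired with probability `fix_success_rate`. Acquired fix
#' locations are drawn by rejection sampling: uniform proposals in the home
#' disc, accepted with probability `exp(eta - eta_max)` where
#' `eta = sum(beta * x)` at the proposal — the defining exponential RSF.
#' DOP is drawn independently from the configured mixture.
#'
#' @param landscape A [landscape_stack()].
#' @param home_center Length-2 numeric, disc centre (m).
#' @param home_radius Disc radius (m); the disc must intersect the grid.
#' @param beta Named selection coefficients (see [truth_config()]).
#' @param start_date Date of the first scheduled fix.
#' @param n_days Number of scheduled days.
#' @param truth A [truth_config()] (observation-process parameters).
#' @param seed Integer seed.
#' @param bear_id,year Labels for the record.
#' @return A [bear_year_record()] (fate unassigned).
#' @export
simulate_bear_year <- function(landscape, home_center, home_radius, beta,
                               start_date, n_days, truth = truth_config(),
                               seed = 1, bear_id = "B1", year = 2005L) {
  set.seed(seed)
  grid <- landscape$grid
  ext <- grid_extent(grid)
  if (home_center[1] + home_radius < ext[1] || home_center[1] - home_radius > ext[2] ||
      home_center[2] + home_radius < ext[3] || home_center[2] - home_radius > ext[4])
    stop("home disc does not intersect the grid")
  std <- landscape_standardization(landscape)

  # eta over cells of the disc, for the acceptance envelope
  cc <- cell_centers(grid)
  cx <- cc$x[abs(cc$x - home_center[1]) <= home_radius + grid$cell_size]
  cy <- cc$y[abs(cc$y - home_center[2]) <= home_radius + grid$cell_size]
  gx <- rep(cx, each = length(cy)); gy <- rep(cy, times = length(cx))
  keep <- (gx - home_center[1])^2 + (gy - home_center[2])^2 <= home_radius^2
  if (!any(keep)) stop("home disc contains no grid cells")
  eta_cells <- eta_at_points(landscape, std, beta, gx[keep], gy[keep])
  if (max(abs(eta_cells)) > 50)
    stop("|eta| exceeds 50 on the home disc; rescale beta to avoid ",
         "acceptance-probability underflow")
  eta_max <- max(eta_cells)

  start_date <- as.Date(start_date)
  step <- 24 * 60 / truth$fixes_per_day  # minutes
  n_sched <- n_days * truth$fixes_per_day
  sched <- as.POSIXct(paste(start_date, "00:00:00"), tz = "UTC") +
    (seq_len(n_sched) - 1) * step * 60
  acquired <- stats::runif(n_sched) < truth$fix_success_rate
  n_need <- sum(acquired)

  xs <- numeric(0); ys <- numeric(0)
  while (length(xs) < n_need) {
    m <- max(2000L, ceiling((n_need - length(xs)) * 4))
    r <- home_radius * sqrt(stats::runif(m))
    a <- 2 * pi * stats::runif(m)
    px <- home_center[1] + r * cos(a)
    py <- home_center[2] + r * sin(a)
    inside <- px >= ext[1] & px < ext[2] & py >= ext[3] & py < ext[4]
    px <- px[inside]; py <- py[inside]
    if (!length(px)) next
    eta <- eta_at_points(landscape, std, beta, px, py)
    acc <- stats::runif(length(px)) < exp(eta - eta_max)
    xs <- c(xs, px[acc]); ys <- c(ys, py[acc])
  }
  xs <- xs[seq_len(n_need)]; ys <- ys[seq_len(n_need)]

  rel <- tibble::tibble(
    bear_id = as.character(bear_id), year = as.integer(year),
    timestamp = sched[acquired], x = xs, y = ys,
    dop = draw_dop(n_need, truth$dop_dist))
  rec <- bear_year_record(bear_id, year, rel)
  rec$home_center <- as.numeric(home_center)
  rec$home_radius <- home_radius
  rec
}

season_date <- function(year, mmdd) as.Date(paste0(year, "-", mmdd))

draw_loss_dates <- function(n, year, truth) {
  s <- season_date(year, truth$season_start)
  e <- season_date(year, truth$loss_end)
  span <- as.numeric(e - s)
  b <- stats::rbeta(n, truth$loss_date_dist$shape1, truth$loss_date_dist$shape2)
  s + round(b * span)
}

#' Assign litter fates by Bernoulli draw
#'
#' Each bear-year's litter is lost with probability `p_litter_loss`; lost
#' litters receive a loss date from the configured Beta distribution rescaled
#' onto the loss window, surviving litters get none.
#'
#' @param bear_years List of [bear_year_record()]s.
#' @param truth A [truth_config()].
#' @param seed Integer seed.
#' @return The list with `fate` and `loss_date` filled in.
#' @export
simulate_fates <- function(bear_years, truth = truth_config(), seed = 1) {
  set.seed(seed)
  if (!length(bear_years)) return(bear_years)
  lost <- stats::runif(length(bear_years)) < truth$p_litter_loss
  for (i in seq_along(bear_years)) {
    if (lost[i]) {
      bear_years[[i]]$fate <- "lost"
      bear_years[[i]]$loss_date <-
        draw_loss_dates(1, bear_years[[i]]$year, truth)
    } else {
      bear_years[[i]]$fate <- "survived"
      bear_years[[i]]$loss_date <- as.Date(NA)
    }
  }
  bear_years
}

#' Simulate a full study
#'
#' Generates (or reuses) a landscape, places circular home ranges, and
#' simulates the configured numbers of successful and unsuccessful bear-years
#' with group-specific selection coefficients. Group sizes are fixed (as in a
#' realized field sample), with a few mothers monitored in two years so that
#' bear identity and year are crossed grouping factors. Unsuccessful litters
#' get loss dates from the configured loss-date distribution; successful
#' mothers' monitoring end dates are left for the preparation stage to
#' randomize.
#'
#' @param truth A [truth_config()].
#' @param grid A [grid_spec()] (used when `landscape` is NULL).
#' @param lconfig A [landscape_config()].
#' @param landscape Optional pre-generated result of [gen_landscape()].
#' @param seed Integer seed driving everything downstream.
#' @return List of class `simulated_study`: `landscape`, `features`,
#'   `bear_years` (list of [bear_year_record()]), `truth`, `seed`.
#' @export
simulate_study <- function(truth = truth_config(),
                           grid = grid_spec(400, 400, cell_size = 25),
                           lconfig = landscape_config(),
                           landscape = NULL, seed = 1) {
  if (is.null(landscape)) landscape <- gen_landscape(grid, lconfig, seed = seed)
  grid <- landscape$landscape$grid
  set.seed(seed + 1L)
  ext <- grid_extent(grid)
  r <- truth$home_radius

  n_by <- truth$n_bear_years
  n_id <- truth$n_individuals
  groups <- rep(c("successful", "unsuccessful"), n_by[c("successful", "unsuccessful")])
  ids <- c(make_crossed_ids("S", n_by[["successful"]], n_id[["successful"]]),
           make_crossed_ids("U", n_by[["unsuccessful"]], n_id[["unsuccessful"]]))
  years <- integer(length(ids))
  for (id in unique(ids)) {
    k <- sum(ids == id)
    years[ids == id] <- sort(sample(truth$years, k))
  }

  n_days <- as.integer(season_date(2005, truth$season_end) -
                         season_date(2005, truth$season_start)) + 1L
  seeds <- sample.int(2^20, length(ids))
  centers <- cbind(stats::runif(length(ids), ext[1] + r, ext[2] - r),
                   stats::runif(length(ids), ext[3] + r, ext[4] - r))
  loss_seed <- sample.int(2^20, 1)

  bear_years <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    beta <- if (groups[i] == "successful") truth$beta_successful
            else truth$beta_unsuccessful
    rec <- simulate_bear_year(
      landscape$landscape, centers[i, ], r, beta,
      start_date = season_date(years[i], truth$season_start),
      n_days = n_days, truth = truth, seed = seeds[i],
      bear_id = ids[i], year = years[i])
    rec$fate <- if (groups[i] == "successful") "survived" else "lost"
    bear_years[[i]] <- rec
  }
  set.seed(loss_seed)
  for (i in which(groups == "unsuccessful"))
    bear_years[[i]]$loss_date <- draw_loss_dates(1, years[i],
                                                 truth)
  structure(list(landscape = landscape$landscape, features = landscape$features,
                 bear_years = bear_years, truth = truth, seed = seed),
            class = "simulated_study")
}

# n_by bear-years over n_id distinct mothers: the first (n_by - n_id) mothers
# contribute two years each.
make_crossed_ids <- function(prefix, n_by, n_id) {
  stopifnot(n_by >= n_id)
  base <- sprintf("%s%02d", prefix, seq_len(n_id))
  c(base, base[seq_len(n_by - n_id)])
}

#' @export
print.simulated_study <- function(x, ...) {
  fates <- vapply(x$bear_years, function(b) b$fate, "")
  cat(sprintf("<simulated_study> %d bear-years (%d survived, %d lost), seed %d\n",
              length(x$bear_years), sum(fates == "survived"),
              sum(fates == "lost"), x$seed))
  invisible(x)
}

#' Generating fixed effects on the fitted scale
#'
#' The generator applies its coefficients to landscape-standardized
#' continuous covariates (z-scored over all grid cells), whereas models are
#' fitted on covariates standardized over the pooled used + available sample.
#' This helper rescales the generating coefficients onto the fitted scale
#' (`beta * sd_sample / sd_landscape`; land-cover indicators are unscaled),
#' so parameter recovery can be assessed coefficient by coefficient.
#'
#' @param truth A [truth_config()].
#' @param landscape The [landscape_stack()] the study was generated on.
#' @param standardization The standardization tibble attached to the fitted
#'   use-availability table.
#' @return List with `main` (expected main effects: the unsuccessful group's
#'   coefficients) and `interaction` (expected survival interactions:
#'   successful minus unsuccessful), both named on the model's terms.
#' @export
truth_fixed_effects <- function(truth, landscape, standardization) {
  std_land <- landscape_standardization(landscape)
  scale_of <- function(nm) {
    if (nm %in% standardization$name)
      standardization$sd[standardization$name == nm] / std_land$sd[[nm]]
    else 1
  }
  sc <- vapply(names(truth$beta_unsuccessful), scale_of, 0)
  list(main = truth$beta_unsuccessful * sc,
       interaction = stats::setNames(
         (truth$beta_successful[names(truth$beta_unsuccessful)] -
            truth$beta_unsuccessful) * sc,
         paste0(names(truth$beta_unsuccessful), "_x_survival")))
}

#' Flatten bear-years to telemetry and fate tables
#'
#' @param bear_years List of [bear_year_record()]s.
#' @return `telemetry_table`: one row per relocation; `fate_table`: one row
#'   per bear-year (`bear_id`, `year`, `fate`, `loss_date`, `end_date`).
#' @export
telemetry_table <- function(bear_years) {
  do.call(rbind, lapply(bear_years, function(b) b$relocations))
}

#' @rdname telemetry_table
#' @export
fate_table <- function(bear_years) {
  tibble::tibble(
    bear_id = vapply(bear_years, function(b) b$bear_id, ""),
    year = vapply(bear_years, function(b) b$year, 1L),
    fate = vapply(bear_years, function(b) b$fate, ""),
    loss_date = as.Date(vapply(bear_years, function(b) as.character(b$loss_date), "")),
    end_date = as.Date(vapply(bear_years, function(b) as.character(b$end_date), "")))
}
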