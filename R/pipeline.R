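#' Pipeline run configuration
#'
#' Bundles every module's parameters with a single top-level seed. Stage
#' seeds are derived deterministically from \code{rng_seed}, so a fixed
#' configuration and seed reproduce every output bit for bit. The
#' \code{"test"} profile runs the whole pipeline on a 50 x 80 grid with a
#' 20 start / 20 end / 2 iteration path sampler; \code{"full"} uses the
#' 200 x 450 default valley and the 100 x 100 x 10 sampling design.
#'
#' @param profile \code{"test"} or \code{"full"}.
#' @param rng_seed Top-level integer seed.
#' @param scenarios Scenario ids to simulate (must include \code{"base"}).
#' @param historical_years Backcast years.
#' @param horizon_years Forecast length (years).
#' @param pop_growth Named fractional population growth from each historical
#'   year to the present (drives activity backcasting).
#' @param activity_growth_canmore_30yr,activity_growth_rural_30yr 30-year
#'   activity growth in the growing town and rural municipality (population
#'   projections).
#' @param growth A \code{\link{growth_spec}} for footprint forecasting.
#' @param scale An \code{\link{activity_scale}}.
#' @param bin_ratio Connectivity bin ratio.
#' @param window_radius Risk moving-window radius (m).
#' @param n_start,n_end,n_iter Path-sampling design (defaults by profile).
#' @param valley A \code{\link{valley_config}} (default by profile).
#' @return An object of class \code{"run_config"}.
#' @export
run_config <- function(profile = c("test", "full"), rng_seed = 1,
                       scenarios = c("base", "limited_urban_expansion",
                                     "no_informal_trails",
                                     "restricted_recreation"),
                       historical_years = c(1970, 1990, 2000, 2010),
                       horizon_years = 30,
                       pop_growth = c("1970" = 4.0, "1990" = 1.5,
                                      "2000" = 0.8, "2010" = 0.35),
                       activity_growth_canmore_30yr = 0.97,
                       activity_growth_rural_30yr = 0.61,
                       growth = growth_spec(),
                       scale = activity_scale(),
                       bin_ratio = 4, window_radius = 400,
                       n_start = NULL, n_end = NULL, n_iter = NULL,
                       valley = NULL) {
  profile <- match.arg(profile)
  if (!"base" %in% scenarios) stop("scenarios must include 'base'",
                                   call. = FALSE)
  dims <- if (profile == "test") c(50, 80) else c(200, 450)
  smp <- if (profile == "test") c(20, 20, 2) else c(100, 100, 10)
  if (is.null(n_start)) n_start <- smp[1]
  if (is.null(n_end)) n_end <- smp[2]
  if (is.null(n_iter)) n_iter <- smp[3]
  if (is.null(valley))
    valley <- valley_config(n_rows = dims[1], n_cols = dims[2],
                            scale = scale,
                            rng_seed = substream(rng_seed, 1))
  stopifnot(all(as.character(historical_years) %in% names(pop_growth)))
  structure(list(profile = profile, rng_seed = rng_seed,
                 scenarios = scenarios,
                 historical_years = sort(historical_years),
                 horizon_years = horizon_years, pop_growth = pop_growth,
                 activity_growth_canmore_30yr = activity_growth_canmore_30yr,
                 activity_growth_rural_30yr = activity_growth_rural_30yr,
                 growth = growth, scale = scale, bin_ratio = bin_ratio,
                 window_radius = window_radius,
                 n_start = n_start, n_end = n_end, n_iter = n_iter,
                 valley = valley),
            class = "run_config")
}

# deterministic per-stage substreams from the top-level seed (kept < 2^31)
substream <- function(seed, k) {
  as.integer((as.numeric(seed) * 1009 + 7919 * k) %% 2147483647)
}

decadal_frac <- function(frac_30yr) (1 + frac_30yr)^(1 / 3) - 1

forecast_chain <- function(gen, config, scenario, seed0) {
  # per-decade landscape + activity under one scenario's growth inputs
  sp <- scenario_spec(scenario)
  gs <- config$growth
  gs$canmore_growth_frac_30yr <- gs$canmore_growth_frac_30yr * sp$growth_scale
  if (!sp$allow_atbd) gs$staging <- setdiff(gs$staging,
                                            "area_to_be_determined")
  states <- forecast(gen$landscape, gs, config$horizon_years,
                     rng_seed = substream(seed0, 11))
  g_can <- decadal_frac(config$activity_growth_canmore_30yr *
                          sp$growth_scale)
  g_rur <- decadal_frac(config$activity_growth_rural_30yr)
  act <- gen$activity
  acts <- vector("list", length(states))
  for (i in seq_along(states)) {
    st <- states[[i]]
    new_cells <- unlist(lapply(st$events, function(e)
      if (e$class == "settlement" && e$origin_year == st$year) e$cells))
    act <- forecast_activity(act, st, as.integer(new_cells),
                             growth = c(canmore = g_can, rural = g_rur),
                             rng_seed = substream(seed0, 100 + i))
    acts[[i]] <- act
  }
  list(states = states, activities = acts)
}

run_connectivity <- function(state, collar, model, config, seed) {
  surf <- build_cost_surface(state, model)
  ens <- sample_paths(surf, collar, n_start = config$n_start,
                      n_end = config$n_end, n_iter = config$n_iter,
                      rng_seed = seed)
  list(surface = surf, ensemble = ens,
       index = bin_connectivity(ens, r = config$bin_ratio))
}

#' Run the full scenario pipeline
#'
#' Generates the synthetic valley, backcasts the historical landscapes and
#' activity, forecasts footprint and activity per scenario, runs the
#' stochastic least-cost-path sampler on every (year, scenario) landscape,
#' and maps conflict risk. Historical years are shared across scenarios
#' (mitigation acts on the forecast); connectivity is recomputed only where
#' a scenario changes the landscape itself.
#'
#' @param config A \code{run_config}.
#' @param workdir Optional directory; when given, rasters (TIFF + sidecar),
#'   the extent-summary CSV and a JSON manifest with per-file md5 hashes are
#'   written there.
#' @return List with \code{generated}, per-year-and-scenario \code{risks},
#'   \code{connectivity}, \code{activities}, \code{states}, the
#'   \code{extents} summary, per-year \code{area_reports},
#'   \code{mean_activity_level}, and (if written) the \code{manifest}.
#' @export
run_pipeline <- function(config, workdir = NULL) {
  seed <- config$rng_seed
  gen <- generate_landscape(config$valley)
  model <- calibrate_bounds(gen$landscape, default_permeability_model())
  cur_year <- gen$landscape$year
  future_years <- seq(cur_year + 10, cur_year + config$horizon_years, 10)

  states <- list(); acts <- list(); conns <- list(); risks <- list()
  # --- shared historical + current timeline ---------------------------------
  base_states <- list(); base_acts <- list()
  for (yr in config$historical_years) {
    st <- backcast(gen$landscape, yr)
    base_states[[as.character(yr)]] <- st
    base_acts[[as.character(yr)]] <-
      backcast_activity(gen$activity, gen$landscape, st,
                        config$pop_growth[[as.character(yr)]])
  }
  base_states[[as.character(cur_year)]] <- gen$landscape
  base_acts[[as.character(cur_year)]] <- gen$activity

  # --- per-scenario forecasts -----------------------------------------------
  chains <- list()
  chains$base <- forecast_chain(gen, config, "base", seed)
  if ("limited_urban_expansion" %in% config$scenarios)
    chains$limited_urban_expansion <-
      forecast_chain(gen, config, "limited_urban_expansion", seed)

  conn_cache <- list()
  get_conn <- function(state, key, k) {
    if (is.null(conn_cache[[key]]))
      conn_cache[[key]] <<- run_connectivity(state, gen$collar, model,
                                             config, substream(seed, k))
    conn_cache[[key]]
  }
  k <- 0
  for (sc in config$scenarios) {
    states[[sc]] <- base_states
    acts[[sc]] <- list()
    chain <- if (sc == "limited_urban_expansion")
      chains$limited_urban_expansion else chains$base
    for (yr in names(base_acts)) acts[[sc]][[yr]] <- base_acts[[yr]]
    for (i in seq_along(future_years)) {
      yr <- as.character(future_years[i])
      states[[sc]][[yr]] <- chain$states[[i]]
      acts[[sc]][[yr]] <- apply_scenario(chain$activities[[i]],
                                         chain$states[[i]], sc)
    }
    conns[[sc]] <- list(); risks[[sc]] <- list()
    for (yr in names(states[[sc]])) {
      k <- k + 1
      ckey <- if (sc != "limited_urban_expansion" ||
                  !(yr %in% as.character(future_years)))
        paste0("base_", yr) else paste0("lue_", yr)
      cn <- get_conn(states[[sc]][[yr]], ckey,
                     1000 + as.integer(yr) +
                       7 * startsWith(ckey, "lue"))
      conns[[sc]][[yr]] <- cn$index
      risks[[sc]][[yr]] <- risk_index(cn$index, acts[[sc]][[yr]],
                                      config$window_radius)
    }
  }
  extents <- extent_summary(risks)
  area_reports <- lapply(base_states, function(s)
    area_report(compose_landscape(s)))
  mean_lvl <- vapply(names(acts$base),
                     function(yr) mean(acts$base[[yr]]$level), numeric(1))

  out <- list(generated = gen, model = model, states = states,
              activities = acts, connectivity = conns, risks = risks,
              extents = extents, area_reports = area_reports,
              mean_activity_level = mean_lvl, config = config)
  if (!is.null(workdir)) out$manifest <- write_outputs(out, workdir)
  out
}

write_outputs <- function(result, workdir) {
  dir.create(workdir, showWarnings = FALSE, recursive = TRUE)
  g <- result$generated$landscape$grid
  entries <- list()
  for (sc in names(result$risks)) for (yr in names(result$risks[[sc]])) {
    stem <- file.path(workdir, sprintf("%s_%s", sc, yr))
    f1 <- paste0(stem, "_risk.tif")
    write_raster(list(index = result$risks[[sc]][[yr]]$index,
                      connectivity = result$connectivity[[sc]][[yr]]$level +
                        0,
                      activity_level = result$activities[[sc]][[yr]]$level +
                        0),
                 f1, g)
    entries[[paste(sc, yr)]] <- list(
      scenario = sc, year = yr, files = basename(f1),
      md5 = unname(tools::md5sum(f1)))
  }
  csv <- file.path(workdir, "extent_summary.csv")
  utils::write.csv(result$extents, csv, row.names = FALSE)
  mh <- file.path(workdir, "mod_high_extent.csv")
  utils::write.csv(attr(result$extents, "mod_high"), mh, row.names = FALSE)
  manifest <- list(
    rng_seed = result$config$rng_seed,
    profile = result$config$profile,
    parameters = list(
      n_start = result$config$n_start, n_end = result$config$n_end,
      n_iter = result$config$n_iter, bin_ratio = result$config$bin_ratio,
      window_radius = result$config$window_radius),
    entries = unname(entries),
    extent_summary = basename(csv),
    extent_md5 = unname(tools::md5sum(csv)))
  mpath <- file.path(workdir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA)
  manifest
}

#' Read a run configuration from YAML
#'
#' Accepts the subset of \code{\link{run_config}} arguments representable as
#' scalars/vectors under top-level keys (\code{profile}, \code{rng_seed},
#' \code{scenarios}, \code{growth}, \code{activity}, \code{sampler},
#' \code{bins}, \code{window_radius}).
#'
#' @param path YAML file path.
#' @return A \code{run_config}.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  for (nm in c("profile", "rng_seed", "scenarios", "historical_years",
               "horizon_years", "window_radius"))
    if (!is.null(y[[nm]])) args[[nm]] <- y[[nm]]
  if (!is.null(y$pop_growth)) args$pop_growth <- unlist(y$pop_growth)
  if (!is.null(y$growth))
    args$growth <- do.call(growth_spec, y$growth)
  if (!is.null(y$activity)) {
    if (!is.null(y$activity$A0) || !is.null(y$activity$g))
      args$scale <- activity_scale(A0 = y$activity$A0 %||% 1,
                                   g = y$activity$g %||% 3)
    if (!is.null(y$activity$growth_canmore_30yr))
      args$activity_growth_canmore_30yr <- y$activity$growth_canmore_30yr
    if (!is.null(y$activity$growth_rural_30yr))
      args$activity_growth_rural_30yr <- y$activity$growth_rural_30yr
  }
  if (!is.null(y$sampler)) {
    args$n_start <- y$sampler$n_start
    args$n_end <- y$sampler$n_end
    args$n_iter <- y$sampler$n_iter
  }
  if (!is.null(y$bins)) args$bin_ratio <- y$bins$ratio %||% 4
  do.call(run_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
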