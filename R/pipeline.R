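# End-to-end orchestration: allocate -> classify -> route (land, naval) ->
# summarise -> workforce/equity -> 2SFCA.

#' Pipeline configuration
#'
#' Gathers every tunable rule of the analysis; defaults are the study
#' thresholds (5 km road-proximity rule, 500 m beach adjacency, 10 km FCA
#' buffer) and the default modes.
#'
#' @param road_proximity_km naval-classification road rule (default 5).
#' @param beach_adjacency_km beach eligibility distance (default 0.5).
#' @param fca_radius_km 2SFCA buffer radius (default 10).
#' @param hub_local_km hub-to-facility legs at or below this are straight
#'   line, longer ones are road-routed (default 1).
#' @param snap_tolerance_km road endpoint merge tolerance (default 0.001).
#' @param restrict_district keep the within-district referral rule (default
#'   `TRUE`).
#' @param equity_form `"availability"` or `"ratio"`, see [equity_index()].
#' @param mean_mode `"centroid"` (default) or `"population"`: weighting of
#'   route-type means.
#' @param naval_mode `"total"` or `"chained"`, see [combined_route()].
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(road_proximity_km = 5, beach_adjacency_km = 0.5,
                            fca_radius_km = 10, hub_local_km = 1,
                            snap_tolerance_km = 0.001,
                            restrict_district = TRUE,
                            equity_form = c("availability", "ratio"),
                            mean_mode = c("centroid", "population"),
                            naval_mode = c("total", "chained")) {
  stopifnot(road_proximity_km > 0, beach_adjacency_km > 0, fca_radius_km > 0,
            hub_local_km > 0, snap_tolerance_km > 0)
  structure(list(road_proximity_km = road_proximity_km,
                 beach_adjacency_km = beach_adjacency_km,
                 fca_radius_km = fca_radius_km,
                 hub_local_km = hub_local_km,
                 snap_tolerance_km = snap_tolerance_km,
                 restrict_district = restrict_district,
                 equity_form = match.arg(equity_form),
                 mean_mode = match.arg(mean_mode),
                 naval_mode = match.arg(naval_mode)),
            class = "pipeline_config")
}

#' Run the full accessibility and equity pipeline on a region
#'
#' Stages, in order: dasymetric population allocation; land/naval access
#' classification per residence and facility type; district-restricted
#' closest-facility routing (road shortest paths for land access, three-leg
#' land+water+land routes otherwise); per-district segment statistics and
#' summary (access proportions, route-type means, weighted total distance z,
#' all-routes mean); workforce availability and the equity index with
#' district ranking; and the 2SFCA comparator. Identical region and config
#' give identical results.
#'
#' Districts lacking a facility kind get no routes of that kind (logged);
#' districts without any workforce get an `NA` equity value with the error
#' recorded in the log, leaving the other outputs intact.
#'
#' @param region a `study_region`.
#' @param config a [pipeline_config()].
#' @param weights worker weights, see [standard_weights()].
#' @return a `pipeline_result` list: `region` (with allocations),
#'   `classifications`, `routes` (long segment table), `segment_stats`,
#'   `district_summary`, `equity`, `fca_puskesmas`, `fca_hospital`, `log`.
#' @export
run_pipeline <- function(region, config = pipeline_config(),
                         weights = standard_weights()) {
  log <- character()
  say <- function(...) log <<- c(log, sprintf(...))
  say("thresholds: road_proximity=%g km, beach_adjacency=%g km, fca_radius=%g km, hub_local=%g km",
      config$road_proximity_km, config$beach_adjacency_km,
      config$fca_radius_km, config$hub_local_km)
  say("modes: restrict_district=%s, equity_form=%s, mean_mode=%s, naval_mode=%s",
      config$restrict_district, config$equity_form, config$mean_mode,
      config$naval_mode)

  v <- validate_region(region)
  if (nrow(v)) {
    stop(sprintf("stage validate: region has %d violation(s), first: %s (%s)",
                 nrow(v), v$entity[1], v$rule[1]))
  }

  region <- allocate_region_population(region)
  say("allocate: %d residences across %d districts",
      nrow(region$residences), nrow(region$districts))

  network <- build_region_network(region, config$snap_tolerance_km)
  vis <- water_vis_graph(region$islands)
  res <- region$residences
  fac <- region$facilities

  cls_rows <- list()
  route_rows <- list()
  for (kind in facility_kinds) {
    for (i in seq_len(nrow(res))) {
      r <- res[i, ]
      mode <- tryCatch(
        classify_access(r, kind, region, config$road_proximity_km),
        error = function(e) stop(sprintf("stage classify (%s, %s): %s",
                                         r$id, kind, conditionMessage(e))))
      cls_rows[[length(cls_rows) + 1]] <- data.frame(
        residence_id = r$id, district_id = r$district_id,
        population = r$population, facility_kind = kind, mode = mode)
      eligible <- fac$kind == kind &
        (!config$restrict_district | fac$district_id == r$district_id)
      if (!any(eligible)) next  # logged below per district
      if (mode == "land") {
        route <- closest_facility_land(r, kind, region, network,
                                       config$restrict_district)
        route_rows[[length(route_rows) + 1]] <- data.frame(
          residence_id = r$id, district_id = r$district_id,
          facility_kind = kind, mode = mode, facility_id = route$facility_id,
          segment = segment_letters[[kind]][["land"]],
          km = route$distance_km)
      } else {
        route <- combined_route(r, kind, region, network, vis,
                                mode = config$naval_mode,
                                restrict_district = config$restrict_district,
                                road_proximity_km = config$road_proximity_km,
                                beach_adjacency_km = config$beach_adjacency_km,
                                hub_local_km = config$hub_local_km)
        route_rows[[length(route_rows) + 1]] <- data.frame(
          residence_id = r$id, district_id = r$district_id,
          facility_kind = kind, mode = mode, facility_id = route$facility_id,
          segment = names(route$legs), km = as.numeric(route$legs))
      }
    }
  }
  classifications <- do.call(rbind, cls_rows)
  routes <- if (length(route_rows)) do.call(rbind, route_rows) else
    data.frame(residence_id = character(), district_id = character(),
               facility_kind = character(), mode = character(),
               facility_id = character(), segment = character(),
               km = numeric())
  rownames(routes) <- NULL

  for (d in region$districts$id) {
    for (kind in facility_kinds) {
      if (!any(fac$kind == kind & fac$district_id == d) &&
          config$restrict_district) {
        say("route: district %s has no %s; no routes of that kind", d, kind)
      }
    }
    n_land <- sum(classifications$district_id == d &
                    classifications$facility_kind == "puskesmas" &
                    classifications$mode == "land")
    n_all <- sum(classifications$district_id == d &
                   classifications$facility_kind == "puskesmas")
    say("classify: district %s: %d/%d residences land-connected to puskesmas",
        d, n_land, n_all)
  }

  seg_stats <- segment_stats(routes)

  summary_rows <- list()
  for (i in seq_len(nrow(region$districts))) {
    d <- region$districts[i, ]
    pr <- access_proportions(classifications, d$id)
    means <- district_mean_distances(
      routes, d$id, region$residences,
      population_weighted = config$mean_mode == "population")
    z <- weighted_total_distance(
      pr$c, means[["puskesmas_land"]], pr$e, means[["hospital_land"]],
      pr$c_nav, means[["puskesmas_naval"]], pr$e_nav, means[["hospital_naval"]])
    summary_rows[[i]] <- data.frame(
      district_id = d$id, name = d$name, population = d$total_population,
      c = pr$c, c_nav = pr$c_nav, e = pr$e, e_nav = pr$e_nav,
      n_puskesmas_land = pr$n_puskesmas_land,
      n_puskesmas_naval = pr$n_puskesmas_naval,
      n_hospital_land = pr$n_hospital_land,
      n_hospital_naval = pr$n_hospital_naval,
      mean_puskesmas_land = means[["puskesmas_land"]],
      mean_hospital_land = means[["hospital_land"]],
      mean_puskesmas_naval = means[["puskesmas_naval"]],
      mean_hospital_naval = means[["hospital_naval"]],
      z = z, all_routes_mean = all_routes_mean(means))
  }
  district_summary <- do.call(rbind, summary_rows)
  rownames(district_summary) <- NULL

  equity_rows <- list()
  for (i in seq_len(nrow(region$districts))) {
    d <- region$districts[i, ]
    av <- availability_terms(d$total_population,
                             fac[fac$district_id == d$id, , drop = FALSE],
                             weights)
    z <- district_summary$z[district_summary$district_id == d$id]
    eq <- tryCatch(equity_index(z, av[["x"]], av[["y"]],
                                form = config$equity_form),
                   error = function(e) {
                     say("equity: district %s: %s", d$id, conditionMessage(e))
                     NA_real_
                   })
    equity_rows[[i]] <- data.frame(
      district_id = d$id, name = d$name,
      mu_puskesmas = attr(av, "mu_puskesmas"),
      mu_hospital = attr(av, "mu_hospital"),
      a = attr(av, "a"), b = attr(av, "b"),
      x = av[["x"]], y = av[["y"]], z = z, equity = eq)
  }
  equity <- do.call(rbind, equity_rows)
  if (any(!is.na(equity$equity))) {
    ranked <- rank_districts(equity[!is.na(equity$equity), , drop = FALSE])
    equity$rank <- ranked$rank[match(equity$district_id, ranked$district_id)]
  } else {
    equity$rank <- NA_integer_
  }
  rownames(equity) <- NULL

  fca_of <- function(kind) {
    if (!any(fac$kind == kind)) return(NULL)
    two_step_fca(region, kind, config$fca_radius_km, weights = weights)
  }
  fca_puskesmas <- fca_of("puskesmas")
  fca_hospital <- fca_of("hospital")

  structure(list(region = region, classifications = classifications,
                 routes = routes, segment_stats = seg_stats,
                 district_summary = district_summary, equity = equity,
                 fca_puskesmas = fca_puskesmas, fca_hospital = fca_hospital,
                 log = log),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat(sprintf("  %d residences, %d districts, %d route segments\n",
              nrow(x$region$residences), nrow(x$district_summary),
              nrow(x$routes)))
  best <- x$equity[which(x$equity$rank == 1), ]
  if (nrow(best)) {
    cat(sprintf("  best equity: %s (equity = %.2f)\n", best$name, best$equity))
  }
  invisible(x)
}

#' Write pipeline outputs as CSV files
#'
#' Emits `allocations.csv`, `classifications.csv`, `routes.csv`,
#' `segment_stats.csv`, `district_summary.csv`, `equity.csv`, `fca.csv` and
#' `log.txt` into `dir`. Distances in the summary tables are rounded
#' half-up to 2 decimals (the reporting convention); the route table keeps
#' full precision.
#'
#' @param result a `pipeline_result`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_pipeline_result <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) {
    utils::write.csv(df, file.path(dir, name), row.names = FALSE)
  }
  alloc <- result$region$residences
  alloc <- alloc[, c("id", "district_id", "area_km2", "population")]
  w(alloc, "allocations.csv")
  w(result$classifications, "classifications.csv")
  w(result$routes, "routes.csv")
  seg <- result$segment_stats
  for (col in c("mean", "se", "median", "min", "max")) {
    seg[[col]] <- round_half_up(seg[[col]], 2)
  }
  w(seg, "segment_stats.csv")
  ds <- result$district_summary
  for (col in c("mean_puskesmas_land", "mean_hospital_land",
                "mean_puskesmas_naval", "mean_hospital_naval", "z",
                "all_routes_mean")) {
    ds[[col]] <- round_half_up(ds[[col]], 2)
  }
  w(ds, "district_summary.csv")
  w(result$equity, "equity.csv")
  fca <- rbind(
    if (!is.null(result$fca_puskesmas))
      cbind(facility_kind = "puskesmas", result$fca_puskesmas),
    if (!is.null(result$fca_hospital))
      cbind(facility_kind = "hospital", result$fca_hospital))
  if (!is.null(fca)) w(fca, "fca.csv")
  writeLines(result$log, file.path(dir, "log.txt"))
  invisible(dir)
}
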