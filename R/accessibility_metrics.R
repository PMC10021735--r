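# Per-district route statistics, access proportions, the weighted
# total-distance score z, province aggregates, and compact letter displays
# from pairwise t-tests.
#
# Route tables are long data frames with one row per route segment:
# residence_id, district_id, facility_kind, mode ("land"/"land_naval"),
# facility_id, segment (one of A-H), km. A land route is its single A/B
# segment; a naval route has C/D, E/F and G/H rows whose sum is the total.

route_totals <- function(routes) {
  if (!nrow(routes)) {
    return(data.frame(residence_id = character(), district_id = character(),
                      facility_kind = character(), mode = character(),
                      total_km = numeric()))
  }
  agg <- stats::aggregate(km ~ residence_id + district_id + facility_kind + mode,
                          data = routes, FUN = sum)
  names(agg)[names(agg) == "km"] <- "total_km"
  agg
}

#' Descriptive statistics of route segments in a district
#'
#' For each segment letter (A-H) present among a district's routes, reports
#' N, mean, standard error (sample SD / sqrt(N), absent when N = 1), median,
#' minimum and maximum of the per-segment leg lengths.
#'
#' @param routes a long route table (see package route-table format).
#' @param district_id district to summarise (default: all, grouped).
#' @return data frame with columns `district_id`, `segment`, `n`, `mean`,
#'   `se`, `median`, `min`, `max` (km, full precision).
#' @export
segment_stats <- function(routes, district_id = NULL) {
  r <- if (is.null(district_id)) routes else
    routes[routes$district_id %in% district_id, , drop = FALSE]
  if (!nrow(r)) {
    return(data.frame(district_id = character(), segment = character(),
                      n = integer(), mean = numeric(), se = numeric(),
                      median = numeric(), min = numeric(), max = numeric()))
  }
  out <- list()
  for (d in unique(r$district_id)) {
    rd <- r[r$district_id == d, , drop = FALSE]
    for (s in sort(unique(rd$segment))) {
      x <- rd$km[rd$segment == s]
      out[[length(out) + 1]] <- data.frame(
        district_id = d, segment = s, n = length(x), mean = mean(x),
        se = if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else NA_real_,
        median = stats::median(x), min = min(x), max = max(x))
    }
  }
  do.call(rbind, out)
}

#' Mean route distances by type for one district
#'
#' Returns the four route-type means -- puskesmas by land, hospital by land,
#' puskesmas by land+naval, hospital by land+naval -- over the district's
#' residential centroids. By default every centroid counts once (matching
#' the N counts of the segment-statistics table); `population_weighted =
#' TRUE` weights each centroid by its allocated population instead. A route
#' type with no members is `NA` (reported as "-").
#'
#' @param routes long route table.
#' @param residences residence table with allocated `population` (only needed
#'   when weighting).
#' @param district_id the district.
#' @param population_weighted logical, default `FALSE`.
#' @return named numeric vector
#'   `c(puskesmas_land, hospital_land, puskesmas_naval, hospital_naval)`.
#' @export
district_mean_distances <- function(routes, district_id, residences = NULL,
                                    population_weighted = FALSE) {
  tot <- route_totals(routes)
  tot <- tot[tot$district_id == district_id, , drop = FALSE]
  one <- function(kind, mode) {
    x <- tot[tot$facility_kind == kind & tot$mode == mode, , drop = FALSE]
    if (!nrow(x)) return(NA_real_)
    if (population_weighted) {
      w <- residences$population[match(x$residence_id, residences$id)]
      sum(w * x$total_km) / sum(w)
    } else {
      mean(x$total_km)
    }
  }
  c(puskesmas_land = one("puskesmas", "land"),
    hospital_land = one("hospital", "land"),
    puskesmas_naval = one("puskesmas", "land_naval"),
    hospital_naval = one("hospital", "land_naval"))
}

#' Population shares by access mode
#'
#' Population-weighted proportions of a district's residents who reach each
#' facility type by land versus by combined land+naval routes, with the
#' underlying head counts. `c + c_nav = 1` and `e + e_nav = 1` exactly
#' (classification partitions the population).
#'
#' @param classifications data frame with columns `residence_id`,
#'   `district_id`, `population`, `facility_kind`, `mode`.
#' @param district_id the district.
#' @return list with fractions `c`, `c_nav`, `e`, `e_nav` and head counts
#'   `n_*` plus `population`.
#' @export
access_proportions <- function(classifications, district_id) {
  cl <- classifications[classifications$district_id == district_id, ,
                        drop = FALSE]
  pop_of <- function(kind, mode) {
    sum(cl$population[cl$facility_kind == kind & cl$mode == mode])
  }
  total <- sum(cl$population[cl$facility_kind == "puskesmas"])
  n_c <- pop_of("puskesmas", "land")
  n_cn <- pop_of("puskesmas", "land_naval")
  n_e <- pop_of("hospital", "land")
  n_en <- pop_of("hospital", "land_naval")
  list(c = n_c / total, c_nav = 1 - n_c / total,
       e = n_e / total, e_nav = 1 - n_e / total,
       n_puskesmas_land = n_c, n_puskesmas_naval = n_cn,
       n_hospital_land = n_e, n_hospital_naval = n_en,
       population = total)
}

#' Population-weighted total travel distance z of a district
#'
#' z = c*d + c_nav*d_nav + e*f + e_nav*f_nav, where c/e are the fractions of
#' the population reaching puskesmas/hospital by land, d/f the corresponding
#' mean distances, and the `_nav` terms their land+naval analogues.
#' Fractions are in [0,1]; a route type with no members (mean `NA`)
#' contributes 0. The result is a km-scale distance score.
#'
#' @param c,d,e,f_ land fractions and mean distances (puskesmas, hospital).
#' @param c_nav,d_nav,e_nav,f_nav land+naval analogues.
#' @return z in km.
#' @export
weighted_total_distance <- function(c, d, e, f_, c_nav = 0, d_nav = NA,
                                    e_nav = 0, f_nav = NA) {
  term <- function(p, m) if (is.na(m) || p == 0) 0 else p * m
  term(c, d) + term(c_nav, d_nav) + term(e, f_) + term(e_nav, f_nav)
}

#' Mean of the available route-type means of a district
#'
#' The "All routes" summary: the unweighted arithmetic mean of the
#' route-type means that exist for the district (two for districts with no
#' naval routes, four otherwise).
#'
#' @param means numeric vector of route-type means, `NA` for absent types.
#' @return mean in km, full precision.
#' @export
all_routes_mean <- function(means) {
  if (all(is.na(means))) stop("no route-type mean present")
  mean(means, na.rm = TRUE)
}

#' Province-level aggregate of district values
#'
#' Unweighted arithmetic mean over the districts with a present (non-NA)
#' value; how the province column of a district summary table is formed.
#'
#' @param values per-district numeric vector, `NA` allowed.
#' @return the mean, full precision (round at the reporting layer).
#' @export
province_aggregate <- function(values) {
  if (all(is.na(values))) stop("no district value present")
  mean(values, na.rm = TRUE)
}

#' Compact letter display from pairwise t-tests
#'
#' Compares group means by all pairwise two-sample Student's t-tests (equal
#' variance) and assigns letters by the insert-and-absorb construction:
#' groups that are not significantly different at `alpha` share at least one
#' letter, significantly different groups share none. Letters are ordered by
#' descending mean ("A" covers the highest-mean group). Groups with fewer
#' than two observations are excluded with a warning.
#'
#' @param samples named list of numeric vectors.
#' @param alpha significance level (default 0.05).
#' @return data frame with `group`, `n`, `mean`, `letters`, sorted by
#'   descending mean.
#' @export
letter_groups <- function(samples, alpha = 0.05) {
  if (length(samples) < 2) stop("need >= 2 groups")
  sizes <- vapply(samples, length, integer(1))
  if (any(sizes < 2)) {
    warning(sprintf("excluding groups with < 2 observations: %s",
                    paste(names(samples)[sizes < 2], collapse = ", ")))
    samples <- samples[sizes >= 2]
  }
  k <- length(samples)
  if (k < 2) stop("fewer than 2 usable groups")
  means <- vapply(samples, mean, numeric(1))
  ord <- order(-means)
  samples <- samples[ord]
  means <- means[ord]

  sig <- matrix(FALSE, k, k)
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      constant <- stats::sd(c(samples[[i]], samples[[j]])) == 0
      p <- if (constant) 1 else
        stats::t.test(samples[[i]], samples[[j]], var.equal = TRUE)$p.value
      sig[i, j] <- sig[j, i] <- p < alpha
    }
  }

  cols <- list(seq_len(k))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      if (!sig[i, j]) next
      new_cols <- list()
      for (col in cols) {
        if (i %in% col && j %in% col) {
          new_cols[[length(new_cols) + 1]] <- setdiff(col, i)
          new_cols[[length(new_cols) + 1]] <- setdiff(col, j)
        } else {
          new_cols[[length(new_cols) + 1]] <- col
        }
      }
      # absorb: drop columns that are subsets of another
      keep <- rep(TRUE, length(new_cols))
      for (a in seq_along(new_cols)) {
        for (b in seq_along(new_cols)) {
          if (a != b && keep[b] &&
              all(new_cols[[a]] %in% new_cols[[b]]) &&
              (length(new_cols[[a]]) < length(new_cols[[b]]) || a > b)) {
            keep[a] <- FALSE
            break
          }
        }
      }
      cols <- new_cols[keep]
    }
  }
  cols <- cols[order(vapply(cols, min, numeric(1)))]
  labels <- vapply(seq_len(k), function(g) {
    paste(LETTERS[which(vapply(cols, function(col) g %in% col, logical(1)))],
          collapse = "")
  }, character(1))
  data.frame(group = names(samples), n = vapply(samples, length, integer(1)),
             mean = means, letters = labels, row.names = NULL)
}
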