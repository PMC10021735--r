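# Published district-level statistics for Maluku Province, Indonesia: the
# 2020 census populations, Ministry of Health facility and staffing
# registries, and the district route-type summaries derived from them. These
# serve as worked-example inputs for the aggregation layer: the province
# column and the "all routes" row of such a summary table are reproducible
# with province_aggregate() and all_routes_mean(), and the printed access
# percentages with the head counts divided by the census totals.

#' District summary statistics for Maluku Province
#'
#' One row per district of Maluku Province, Indonesia (11 districts,
#' 2020 census): facility and staffing counts, census population, head
#' counts of individuals reaching puskesmas/hospital by land versus needing
#' combined land+naval routes, and mean travel distances by route type (km,
#' as printed, i.e. rounded to at most 2 decimals). Districts without naval
#' routes (Ambon) carry `NA` in the naval columns and in the corresponding
#' head counts.
#'
#' @return data frame with columns `district`, `puskesmas`, `hospitals`,
#'   `physicians`, `nurses`, `midwives`, `population`,
#'   `reach_puskesmas_land`, `reach_hospital_land`, `need_naval_puskesmas`,
#'   `need_naval_hospital` (head counts), `mean_puskesmas_land`,
#'   `mean_hospital_land`, `mean_puskesmas_naval`, `mean_hospital_naval`,
#'   `all_routes` (km).
#' @export
maluku_districts <- function() {
  data.frame(
    district = c("Ambon", "Aru Islands", "Buru", "Central Maluku",
                 "East Ceram", "South Buru", "Southeast Maluku",
                 "Southwest Maluku", "Tual", "West Ceram",
                 "West Southeast Maluku"),
    puskesmas = c(22, 27, 10, 33, 19, 12, 18, 21, 15, 17, 13),
    hospitals = c(9, 1, 1, 4, 1, 1, 3, 1, 1, 1, 3),
    physicians = c(125, 12, 14, 69, 24, 5, 31, 14, 22, 16, 38),
    nurses = c(899, 257, 298, 592, 404, 179, 336, 242, 249, 349, 243),
    midwives = c(253, 59, 112, 407, 149, 83, 115, 80, 105, 193, 44),
    population = c(347288, 102237, 135238, 425631, 137972, 75410, 121511,
                   81928, 88280, 209856, 123572),
    reach_puskesmas_land = c(347288, 63342, 115982, 411834, 125378, 71800,
                             112533, 39934, 84242, 179359, 107273),
    reach_hospital_land = c(347288, 37212, 115982, 386641, 94118, 55085,
                            102988, 18505, 75011, 173637, 89060),
    need_naval_puskesmas = c(NA, 38895, 19256, 13797, 12594, 3610, 8978,
                             41994, 4038, 30497, 16299),
    need_naval_hospital = c(NA, 65025, 19256, 38990, 43854, 20325, 18523,
                            63423, 13269, 36219, 34512),
    mean_puskesmas_land = c(2.98, 2.88, 22.3, 11.8, 7.69, 12.13, 5.61, 5.89,
                            1.6, 12.11, 12.75),
    mean_hospital_land = c(5.96, 4.87, 63.39, 85.71, 254.18, 92.43, 22.37,
                           2.53, 7.76, 44.31, 34.56),
    mean_puskesmas_naval = c(NA, 16.31, 26.04, 32.18, 15.36, 19.19, 12.12,
                             19.39, 11.02, 15.92, 16.76),
    mean_hospital_naval = c(NA, 99.10, 56.20, 73.83, 107.33, 60.13, 25.46,
                            178.58, 64.78, 25.94, 39.50),
    all_routes = c(4.47, 30.79, 41.98, 50.88, 96.14, 45.97, 16.39, 51.60,
                   21.29, 24.57, 25.89)
  )
}
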