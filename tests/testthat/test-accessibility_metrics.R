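toy_routes <- function() {
  # two districts, mixed modes, hand-enumerable
  rbind(
    data.frame(residence_id = "R1", district_id = "D1",
               facility_kind = "puskesmas", mode = "land", facility_id = "F1",
               segment = "A", km = 2),
    data.frame(residence_id = "R2", district_id = "D1",
               facility_kind = "puskesmas", mode = "land", facility_id = "F1",
               segment = "A", km = 4),
    data.frame(residence_id = "R2", district_id = "D1",
               facility_kind = "hospital", mode = "land_naval",
               facility_id = "F2", segment = c("D", "F", "H"),
               km = c(1, 6, 1)),
    data.frame(residence_id = "R1", district_id = "D1",
               facility_kind = "hospital", mode = "land", facility_id = "F2",
               segment = "B", km = 10)
  )
}

test_that("segment statistics match hand arithmetic", {
  routes <- rbind(
    data.frame(residence_id = c("a", "b", "c"), district_id = "D1",
               facility_kind = "puskesmas", mode = "land",
               facility_id = "F", segment = "A", km = c(2, 3, 4)),
    data.frame(residence_id = "d", district_id = "D1",
               facility_kind = "hospital", mode = "land",
               facility_id = "F", segment = "B", km = 5))
  st <- segment_stats(routes, "D1")
  a <- st[st$segment == "A", ]
  expect_equal(a$n, 3)
  expect_equal(a$mean, 3)
  expect_equal(a$median, 3)
  expect_equal(a$min, 2)
  expect_equal(a$max, 4)
  expect_equal(round(a$se, 3), 0.577)
  b <- st[st$segment == "B", ]
  expect_equal(b$n, 1)
  expect_equal(b$mean, 5)
  expect_true(is.na(b$se))
  expect_true(all(st$min <= st$median & st$median <= st$max))
})

test_that("segment statistics agree with an independent computation on random legs", {
  set.seed(4)
  km <- stats::runif(100, 0.1, 50)
  routes <- data.frame(residence_id = paste0("r", 1:100), district_id = "D",
                       facility_kind = "puskesmas", mode = "land",
                       facility_id = "F", segment = "A", km = km)
  st <- segment_stats(routes)
  # two-pass / sorted-order oracle
  s <- sort(km)
  n <- length(s)
  expect_equal(st$mean, sum(s) / n)
  expect_equal(st$median, (s[50] + s[51]) / 2)
  expect_equal(st$min, s[1])
  expect_equal(st$max, s[n])
  expect_equal(st$se, sqrt(sum((s - mean(s))^2) / (n - 1)) / sqrt(n))
})

test_that("district route-type means cover present types and flag absent ones", {
  routes <- toy_routes()
  m <- district_mean_distances(routes, "D1")
  expect_equal(m[["puskesmas_land"]], 3)      # mean of 2, 4
  expect_equal(m[["hospital_land"]], 10)
  expect_equal(m[["hospital_naval"]], 8)      # 1 + 6 + 1
  expect_true(is.na(m[["puskesmas_naval"]]))  # no such routes: "-" cell

  res <- data.frame(id = c("R1", "R2"), population = c(100, 300))
  mw <- district_mean_distances(routes, "D1", res, population_weighted = TRUE)
  expect_equal(mw[["puskesmas_land"]], (100 * 2 + 300 * 4) / 400)
})

test_that("access proportions are population-weighted and partition to one", {
  cls <- rbind(
    data.frame(residence_id = "R1", district_id = "D1", population = 60,
               facility_kind = c("puskesmas", "hospital"),
               mode = c("land", "land")),
    data.frame(residence_id = "R2", district_id = "D1", population = 40,
               facility_kind = c("puskesmas", "hospital"),
               mode = c("land_naval", "land_naval")))
  pr <- access_proportions(cls, "D1")
  expect_equal(pr$c, 0.6)
  expect_equal(pr$c_nav, 0.4)
  expect_equal(pr$c + pr$c_nav, 1)
  expect_equal(pr$e + pr$e_nav, 1)
  expect_equal(pr$n_puskesmas_land, 60)
  expect_equal(pr$population, 100)

  cls$mode <- "land"
  pr <- access_proportions(cls, "D1")
  expect_equal(pr$c, 1)
  expect_equal(pr$c_nav, 0)
})

test_that("published head counts reproduce a printed access percentage", {
  expect_equal(round_half_up(100 * 63342 / 102237, 2), 61.96)
})

test_that("weighted total distance z composes the four terms", {
  expect_equal(weighted_total_distance(c = 1, d = 3, e = 1, f_ = 6), 9)
  expect_equal(weighted_total_distance(c = 0.5, d = 10, e = 1, f_ = 0,
                                       c_nav = 0.5, d_nav = 20), 15)
  expect_equal(weighted_total_distance(0, NA, 0, NA), 0)
  # absent naval means with zero weight contribute nothing
  expect_equal(weighted_total_distance(1, 5, 1, 7, c_nav = 0, d_nav = NA,
                                       e_nav = 0, f_nav = NA), 12)
})

test_that("z is consistent under reshuffling between equal-mean classes", {
  # if land and naval classes have equal means, the split fractions cancel
  for (cc in c(0.2, 0.5, 0.9)) {
    z <- weighted_total_distance(c = cc, d = 12, e = 1, f_ = 30,
                                 c_nav = 1 - cc, d_nav = 12)
    expect_equal(z, 12 + 30)
  }
})

test_that("all-routes and province aggregation reproduce printed identities", {
  expect_equal(round_half_up(all_routes_mean(c(2.98, 5.96, NA, NA))), 4.47)
  expect_equal(round_half_up(all_routes_mean(c(2.88, 4.87, 16.31, 99.10))),
               30.79)
  expect_equal(all_routes_mean(7), 7)
  expect_error(all_routes_mean(c(NA_real_, NA_real_)), "no route-type mean")
  expect_equal(province_aggregate(c(5, 5, 5)), 5)
  expect_equal(province_aggregate(c(1, NA, 3)), 2)
  expect_error(province_aggregate(NA_real_), "no district value")
})

test_that("letter displays mirror the pairwise significance structure", {
  set.seed(60)
  same <- list(g1 = rnorm(30, 10), g2 = rnorm(30, 10))
  cld <- letter_groups(same)
  expect_equal(cld$letters, c("A", "A"))

  apart <- list(hi = rnorm(30, 100), lo = rnorm(30, 0))
  cld <- letter_groups(apart)
  expect_equal(cld$letters[cld$group == "hi"], "A")
  expect_equal(cld$letters[cld$group == "lo"], "B")

  for (rep in 1:10) {
    k <- 4
    mu <- sample(c(0, 0.5, 5, 20), k)
    samples <- lapply(seq_len(k), function(i) rnorm(25, mu[i]))
    names(samples) <- paste0("g", seq_len(k))
    cld <- letter_groups(samples)
    # oracle: direct pairwise tests; sharing a letter <=> not significant
    for (i in 1:(k - 1)) {
      for (j in (i + 1):k) {
        p <- stats::t.test(samples[[i]], samples[[j]],
                           var.equal = TRUE)$p.value
        li <- strsplit(cld$letters[cld$group == names(samples)[i]], "")[[1]]
        lj <- strsplit(cld$letters[cld$group == names(samples)[j]], "")[[1]]
        shares <- length(intersect(li, lj)) > 0
        expect_equal(shares, p >= 0.05)
      }
    }
    # "A" belongs to the highest mean
    expect_true(grepl("A", cld$letters[1]))
    expect_equal(cld$group[1],
                 names(samples)[which.max(vapply(samples, mean, numeric(1)))])
  }
})

test_that("undersized groups are excluded with a warning", {
  expect_warning(
    cld <- letter_groups(list(a = rnorm(10), b = rnorm(10), tiny = 1)),
    "excluding")
  expect_equal(nrow(cld), 2)
  expect_error(letter_groups(list(a = rnorm(5))), ">= 2 groups")
})
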