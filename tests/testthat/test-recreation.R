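test_that("level and absolute activity convert exactly on the exponential scale", {
  sc <- activity_scale(A0 = 1, g = 3)
  expect_equal(level_to_absolute(0L, sc), 0)
  expect_equal(level_to_absolute(3L, sc), 9)
  expect_equal(level_to_absolute(matrix(0:5, 2, 3), sc),
               matrix(c(0, 1, 3, 9, 27, 81), 2, 3))
  # exhaustive round trip over the representable levels
  for (k in 0:5)
    expect_equal(absolute_to_level(level_to_absolute(k, sc), sc), k)
  # categorical change is slower than absolute change
  expect_equal(absolute_to_level(9, sc), 3L)
  expect_equal(absolute_to_level(26.9, sc), 3L)
  expect_equal(absolute_to_level(1e6, sc), 5L)   # saturates at 5
  expect_error(absolute_to_level(-1, sc), "non-negative")
  expect_error(level_to_absolute(6L, sc), "0..5")
})

test_that("doubling absolute activity raises mean level sublinearly", {
  set.seed(21)
  sc <- activity_scale()
  a <- matrix(rexp(200, rate = 1 / 20), 10, 20)
  l1 <- mean(absolute_to_level(a, sc))
  l2 <- mean(absolute_to_level(2 * a, sc))
  expect_gte(l2, l1)
  expect_lt(l2, 2 * l1)
})

test_that("activity backcast zeroes development-linked use and rescales the rest", {
  # world: settlement patch founded 2005 on a flat landscape, one far cell
  g <- grid_spec(20, 40)
  nat <- list(forest = matrix(1, 20, 40))
  sett <- as.integer(as.vector(outer(9:11, (5:7 - 1) * 20, `+`)))
  ev <- list(list(class = "settlement", origin_year = 2005, cells = sett,
                  frac = 1))
  zones <- list(banff = integer(0), canmore = integer(0),
                nordic_centre = integer(0), growth_boundary = integer(0),
                area_to_be_determined = integer(0), town_center = sett[1],
                rural = integer(0))
  now <- landscape_state(g, nat, ev, 2020,
                         data.frame(cell = integer(0),
                                    year_built = numeric(0)),
                         integer(0), zones, matrix(1400, 20, 40))
  near <- cell_at(g, 10, 21)    # 1.5 km east of the settlement
  far <- cell_at(g, 10, 40)     # > 3 km from any footprint
  a <- matrix(0, 20, 40); a[near] <- 12; a[far] <- 30
  act <- activity_raster(g, a,
                         trails = data.frame(trail_id = 1L,
                                             cell = c(near, far),
                                             designated = TRUE))
  back <- backcast_activity(act, now, backcast(now, 2000), pop_growth = 0.4)
  expect_equal(back$absolute[near], 0)              # tied to the 2005 town
  expect_gt(back$absolute[far], 0)                  # scaled, not zeroed
  # regional total reproduces the population trajectory exactly
  expect_equal(sum(back$absolute), sum(act$absolute) / 1.4,
               tolerance = 1e-3)
  # no growth and no post-dated footprint: identity
  same <- backcast_activity(act, now, backcast(now, 2010), pop_growth = 0)
  expect_equal(same$absolute, act$absolute, tolerance = 1e-12)
})

test_that("forecast activity balances mass per municipality and lifts park trails", {
  gen <- test_gen()
  st <- gen$landscape
  act <- gen$activity
  fc <- forecast(st, growth_spec(), 10, rng_seed = 2)[[1]]
  new_cells <- unlist(lapply(fc$events, function(e)
    if (e$class == "settlement" && e$origin_year == fc$year) e$cells))
  zm <- function(z) { m <- matrix(FALSE, st$grid$n_rows, st$grid$n_cols)
                      m[st$zones[[z]]] <- TRUE; m }
  g_can <- 0.25
  out <- forecast_activity(act, fc, as.integer(new_cells),
                           growth = c(canmore = g_can, rural = 0.17),
                           rng_seed = 9)
  expect_equal(sum(out$absolute[zm("canmore")]),
               (1 + g_can) * sum(act$absolute[zm("canmore")]),
               tolerance = 1e-3)
  # park-zone trail cells intensify by exactly 25% per decade
  btr <- intersect(act$trails$cell, which(zm("banff")))
  expect_equal(out$absolute[btr], act$absolute[btr] * 1.25)
  # zero growth (and no park lift) is the identity
  id <- forecast_activity(act, fc, integer(0),
                          growth = c(canmore = 0, rural = 0),
                          banff_decadal_growth = 0, rng_seed = 9)
  expect_equal(id$absolute, act$absolute)
})

test_that("mitigation scenarios modify activity as specified and never add any", {
  gen <- test_gen()
  st <- gen$landscape
  act <- gen$activity
  d <- distance_to(corridorsim:::settlement_mask(st), st$grid)

  rr <- apply_scenario(act, st, "restricted_recreation")
  inside <- d < 100; outside <- d >= 100
  expect_equal(rr$absolute[inside], act$absolute[inside])
  expect_equal(rr$absolute[outside], act$absolute[outside] * 0.5)

  ni <- apply_scenario(act, st, "no_informal_trails")
  inf_tr <- setdiff(act$trails$cell[!act$trails$designated],
                    act$trails$cell[act$trails$designated])
  fp <- corridorsim:::footprint_fraction(st) > 1e-9
  inf_off <- inf_tr[!fp[inf_tr]]
  expect_true(all(ni$absolute[inf_off] == 0))
  des_tr <- act$trails$cell[act$trails$designated]
  expect_equal(ni$absolute[des_tr], act$absolute[des_tr])

  expect_equal(apply_scenario(act, st, "base")$absolute, act$absolute)
  expect_error(apply_scenario(act, st, "close_the_valley"), "unknown")

  # cellwise dominance for every activity-side scenario
  for (sc in c("no_informal_trails", "restricted_recreation"))
    expect_true(all(apply_scenario(act, st, sc)$absolute <=
                      act$absolute + 1e-12))
})
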