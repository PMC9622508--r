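test_that("permeability reflects the documented habitat preferences", {
  gen <- test_gen()
  st <- gen$landscape
  model <- default_permeability_model()
  perm <- permeability(st, model)
  expect_true(all(perm >= 0 & perm <= 1))

  # a coefficient-free model is flat: documented degenerate normalization
  flat <- permeability_model(cover = c(forest = 0, shrub = 0, alpine = 0,
                                       water = 0, linear = 0,
                                       recreation_facility = 0,
                                       settlement = 0, industrial = 0,
                                       farmland = 0))
  expect_true(all(permeability(st, flat) == 1))

  # valley-bottom natural habitat scores above steep alpine terrain
  stack <- compose_landscape(st)
  fp <- corridorsim:::footprint_fraction(st)
  nat <- fp < 1e-9
  bottom <- nat & st$elevation < quantile(st$elevation, 0.2)
  high <- st$elevation > quantile(st$elevation, 0.9)
  expect_gt(mean(perm[bottom]), mean(perm[high]))

  # development is less permeable than its natural surroundings
  sett <- stack$layers$settlement > 0.5
  ring <- distance_to(sett, st$grid) <= 300 & !sett & nat
  expect_gt(mean(perm[ring]), mean(perm[sett]))

  # fixed bounds keep time steps comparable: same cell, same score scale
  mb <- calibrate_bounds(st, model)
  expect_equal(permeability(st, mb), perm, tolerance = 1e-12)
})

test_that("cost surface applies the 500 m highway decay and dated barriers", {
  gen <- test_gen()
  st <- gen$landscape
  model <- calibrate_bounds(st, default_permeability_model())
  perm <- permeability(st, model)
  surf <- build_cost_surface(st, model)
  hw <- matrix(FALSE, st$grid$n_rows, st$grid$n_cols)
  hw[st$highway_cells] <- TRUE
  d <- distance_to(hw, st$grid)
  # inside the band the linear factor d/500 applies...
  i250 <- which(abs(d - 200) < 1)
  expect_equal(surf$cost[i250], 1 - perm[i250] * (d[i250] / 500),
               tolerance = 1e-12)
  # ...and beyond 500 m the highway term has no effect
  far <- d >= 500
  expect_equal(surf$cost[far], (1 - perm)[far], tolerance = 1e-12)
  # explicit arithmetic: permeability 0.8 at 250 m gives cost 0.6
  expect_equal(1 - 0.8 * (250 / 500), 0.6)

  # crossings open only once built: a 1988 structure is a barrier in 1970
  surf70 <- build_cost_surface(backcast(st, 1970), model)
  built_after <- st$crossings$cell[st$crossings$year_built > 1970]
  expect_true(all(!built_after %in% surf70$crossing_cells))
  expect_true(all(surf70$barrier[built_after]))
  open70 <- st$crossings$cell[st$crossings$year_built <= 1970]
  expect_true(all(open70 %in% surf70$crossing_cells))
})

test_that("the path engine equals exhaustive enumeration on toy surfaces", {
  set.seed(99)
  for (n in 3:5) {
    for (rep in 1:3) {
      cost <- matrix(runif(n * n), n, n)
      surf <- make_surface(cost)
      from <- cell_at(surf$grid, 1, 1)
      to <- cell_at(surf$grid, n, n)
      expect_equal(engine_lcp(surf, from, to),
                   enumerate_lcp(cost, surf$grid, from, to),
                   tolerance = 1e-9)
    }
    # and with a barrier row pierced by one crossing
    cost <- matrix(runif(n * n), n, n)
    barrier <- matrix(FALSE, n, n); barrier[2, ] <- TRUE
    cross <- cell_at(grid_spec(n, n), 2, n)
    surf <- make_surface(cost, barrier, cross)
    from <- cell_at(surf$grid, 1, 1); to <- cell_at(surf$grid, n, 1)
    expect_equal(engine_lcp(surf, from, to),
                 enumerate_lcp(cost, surf$grid, from, to, barrier, cross),
                 tolerance = 1e-9)
  }
})

test_that("with perturbation off the sampler reproduces deterministic paths", {
  # uniform cost, one start/end pair on the same row: the straight line wins
  n <- 7
  cost <- matrix(0.5, n, n)
  surf <- make_surface(cost)
  collar <- data.frame(cell = rep(c(cell_at(surf$grid, 4, 1),
                                    cell_at(surf$grid, 4, n)), each = 2))
  ens <- sample_paths(surf, collar, n_start = 1, n_end = 1, n_iter = 2,
                      rng_seed = 1, sd = 0)
  expect_equal(ens$n_paths, 2)
  online <- cell_at(surf$grid, rep(4, n), 1:n)
  expect_true(all(ens$proportion[online] == 1))
  expect_true(all(ens$proportion[-online] == 0))
})

test_that("raising one cell's cost never shortens any route", {
  set.seed(5)
  cost <- matrix(runif(25, 0.2, 0.8), 5, 5)
  surf <- make_surface(cost)
  from <- cell_at(surf$grid, 1, 1); to <- cell_at(surf$grid, 5, 5)
  base_cost <- engine_lcp(surf, from, to)
  for (cell in sample(25, 6)) {
    up <- cost; up[cell] <- up[cell] + 0.5
    expect_gte(engine_lcp(make_surface(up), from, to), base_cost - 1e-12)
  }
})

test_that("no sampled path touches a closed barrier cell; closing all crossings isolates the sides", {
  gen <- test_gen()
  st <- gen$landscape
  model <- calibrate_bounds(st, default_permeability_model())
  surf <- build_cost_surface(st, model)
  ens <- sample_paths(surf, gen$collar, n_start = 12, n_end = 12,
                      n_iter = 2, rng_seed = 3)
  closed <- surf$barrier; closed[surf$crossing_cells] <- FALSE
  expect_equal(sum(ens$count[closed]), 0)

  # shut every crossing: pairs straddling the highway become disconnected
  # and no path ever reaches the far side of any start
  shut <- surf; shut$crossing_cells <- integer(0)
  nr <- st$grid$n_rows
  hw_row <- (st$highway_cells[1] - 1) %% nr + 1
  north <- gen$collar[(gen$collar$cell - 1) %% nr + 1 < hw_row, ]
  south <- gen$collar[(gen$collar$cell - 1) %% nr + 1 > hw_row, ]
  ncells <- unique(north$cell); scells <- unique(south$cell)
  expect_gte(length(ncells), 2)   # deterministic generator puts collar
  expect_gte(length(scells), 2)   # points on both valley sides
  collar2 <- data.frame(cell = rep(c(ncells[1:2], scells[1:2]), each = 2))
  expect_warning(
    ens2 <- sample_paths(shut, collar2, n_start = 2, n_end = 2, n_iter = 1,
                         rng_seed = 3),
    "disconnected")
  expect_equal(sum(ens2$count[st$highway_cells]), 0)
})

test_that("connectivity bins are geometric and anchored at the maximum", {
  g <- grid_spec(2, 3)
  prop <- matrix(c(0, 0.0004, 0.01, 0.04, 0.16, 0.64), 2, 3)
  ens <- structure(list(grid = g, n_paths = 10000, n_planned = 10000,
                        count = prop * 10000, proportion = prop),
                   class = "path_ensemble")
  ci <- bin_connectivity(ens, r = 4)
  expect_equal(ci$edges, c(0.0025, 0.01, 0.04, 0.16, 0.64))
  expect_equal(as.vector(ci$level), c(0L, 1L, 2L, 3L, 4L, 5L))
  # p_max always lands in the top bin; zero stays level 0
  expect_equal(max(ci$level[prop == max(prop)]), 5L)
  expect_true(all(ci$level[prop == 0] == 0L))
  # an all-zero ensemble warns and returns level 0
  ens0 <- structure(list(grid = g, n_paths = 0, n_planned = 0,
                         count = prop * 0, proportion = prop * 0),
                    class = "path_ensemble")
  expect_warning(ci0 <- bin_connectivity(ens0), "all-zero")
  expect_true(all(ci0$level == 0L))
})
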