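test_that("backcast removes post-dated footprint and restores natural cover", {
  tl <- toy_landscape(5)                     # settlement dated 1995
  back <- backcast(tl, 1990)
  s0 <- compose_landscape(tl); s1 <- compose_landscape(back)
  sett <- tl$events[[2]]$cells
  expect_true(all(s0$layers$settlement[sett] == 1))
  expect_true(all(s1$layers$settlement[sett] == 0))
  # natural fractions renormalized back to the pristine mix
  expect_equal(s1$layers$forest[sett], rep(0.7, length(sett)))
  # crossings built later disappear; the 1950 structure stays
  expect_equal(nrow(backcast(tl, 1949)$crossings), 0)
  expect_equal(nrow(back$crossings), 1)
  # identity at the state's own year; error in the future
  expect_identical(compose_landscape(backcast(tl, tl$year))$layers,
                   s0$layers)
  expect_error(backcast(tl, 2999), "future")
})

test_that("backcast then reapply is exactly the identity, any event subset", {
  gen <- test_gen()
  st <- gen$landscape
  cur <- compose_landscape(st)
  for (yr in c(1899, 1970, 1990, 2000, 2010)) {
    b <- backcast(st, yr)
    removed <- st$events[vapply(st$events, function(e) e$origin_year > yr,
                                logical(1))]
    rt <- reapply_events(b, removed, crossings = st$crossings,
                         year = st$year)
    expect_identical(compose_landscape(rt)$layers, cur$layers)
    # conservation holds at every intermediate state too
    expect_lt(max(abs(Reduce(`+`, compose_landscape(b)$layers) - 1)), 1e-9)
  }
})

# a controlled town for growth arithmetic: 100-cell settlement, a small
# growth-boundary ring, and a large area to be determined
make_growth_state <- function() {
  g <- grid_spec(30, 40)
  nat <- list(forest = matrix(1, 30, 40))
  town <- as.vector(outer(11:20, (16:25 - 1) * 30, `+`))   # 10 x 10 block
  ev <- list(list(class = "settlement", origin_year = 1950,
                  cells = as.integer(town), frac = 1))
  ring <- setdiff(as.vector(outer(9:22, (14:27 - 1) * 30, `+`)), town)
  ring <- as.integer(ring[seq_len(15)])                    # 15-cell boundary
  east <- as.integer(as.vector(outer(1:30, (28:40 - 1) * 30, `+`)))
  zones <- list(banff = integer(0),
                canmore = as.integer(c(town, ring, east)),
                nordic_centre = integer(0), growth_boundary = ring,
                area_to_be_determined = east, town_center = town[45],
                rural = integer(0))
  landscape_state(g, nat, ev, 2020,
                  data.frame(cell = integer(0), year_built = numeric(0)),
                  integer(0), zones, matrix(1400, 30, 40))
}

test_that("town growth hits the 30-year fraction and stages its zones", {
  st <- make_growth_state()
  out <- forecast(st, growth_spec(rural_growth_frac_30yr = 0),
                  horizon_years = 30, rng_seed = 1)
  expect_length(out, 3)
  final <- length(class_cells(out[[3]], "settlement"))
  expect_lte(abs(final - 187), 1)           # 100 cells x 1.87, +/- one cell
  # monotone growth through the decades
  areas <- vapply(out, function(s) length(class_cells(s, "settlement")),
                  numeric(1))
  expect_true(all(diff(c(100, areas)) >= 0))
  # staging: any converted area-to-be-determined cell implies the growth
  # boundary was exhausted first
  dev <- corridorsim:::footprint_fraction(out[[3]])
  if (any(dev[st$zones$area_to_be_determined] >= 0.5))
    expect_true(all(dev[st$zones$growth_boundary] >= 0.5))
  # all-zero growth is the identity
  same <- forecast(st, growth_spec(0, 0, 0), 30, rng_seed = 1)
  expect_identical(compose_landscape(same[[3]])$layers,
                   compose_landscape(st)$layers)
})

test_that("park townsite stays fixed while the rural fraction compounds", {
  gen <- test_gen()
  st <- gen$landscape
  out <- forecast(st, growth_spec(), horizon_years = 30, rng_seed = 5)
  b0 <- length(intersect(class_cells(st, "settlement"), st$zones$banff))
  b3 <- length(intersect(class_cells(out[[3]], "settlement"),
                         st$zones$banff))
  expect_equal(b0, b3)
  r0 <- length(intersect(class_cells(st, "settlement"), st$zones$rural))
  r3 <- length(intersect(class_cells(out[[3]], "settlement"),
                         st$zones$rural))
  expect_gte(r3, r0)
  # seeded determinism of the stochastic rural allocation
  again <- forecast(st, growth_spec(), horizon_years = 30, rng_seed = 5)
  expect_identical(compose_landscape(again[[3]])$layers,
                   compose_landscape(out[[3]])$layers)
})

test_that("candidate weights follow adjacent patch size and normalize", {
  g <- grid_spec(5, 12)
  nat <- list(forest = matrix(1, 5, 12))
  # two settlement patches: 10 cells (cols 1-2) and 5 cells (col 12)
  p1 <- as.integer(as.vector(outer(1:5, (1:2 - 1) * 5, `+`)))
  p2 <- as.integer(1:5 + (12 - 1) * 5)
  ev <- list(list(class = "settlement", origin_year = 1950, cells = p1,
                  frac = 1),
             list(class = "settlement", origin_year = 1950, cells = p2,
                  frac = 1))
  zones <- list(rural = as.integer(c(cell_at(g, 3, 3), cell_at(g, 3, 11))))
  st <- landscape_state(g, nat, ev, 2020,
                        data.frame(cell = integer(0),
                                   year_built = numeric(0)),
                        integer(0), zones, matrix(1400, 5, 12))
  w <- candidate_weights(st, st$zones$rural, exponent = 1)
  expect_equal(w[cell_at(g, 3, 3)], 2 / 3)    # adjacent to the 10-cell patch
  expect_equal(w[cell_at(g, 3, 11)], 1 / 3)   # adjacent to the 5-cell patch
  expect_equal(sum(w), 1)
  # a cell far from all settlement has weight zero
  expect_equal(w[cell_at(g, 3, 6)], 0)
})
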