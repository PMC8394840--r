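# Small study conditions used throughout: 40 cells in a 26^3 box (3D) or a
# 40 x 40 x 7 box (2D), so a full run takes well under a second.
tiny_config <- function(mode = "spheroid", f_dose = 0.15, theta = 0,
                        D = 0.1, eps_floor = 12, seed = 1,
                        max_mcs = 150, window = 30) {
  sim_config(
    geometry = geometry_config(mode, n_cells = 40,
                               dims = if (mode == "spheroid") c(26, 26, 26)
                                      else c(40, 40, 7),
                               margin = 2, f_dose = f_dose),
    field = field_params(D = D),
    damage = damage_params(theta = theta, eps_floor = eps_floor),
    run = list(max_mcs = max_mcs, plateau_window = window),
    seed = seed
  )
}

test_that("plateau detection follows the windowed-change rule", {
  flat <- data.frame(mcs = 0:100, dead = rep(10L, 101))
  expect_equal(detect_plateau(flat, 1, 50), 50)
  rising <- data.frame(mcs = 0:100, dead = c(0:40, rep(40L, 60)))
  # oracle: first t with dead[t] - dead[t - w] < eps
  w <- 20; eps <- 1
  dead <- rising$dead
  oracle <- NA
  for (t in w:100) if (dead[t + 1] - dead[t + 1 - w] < eps) {
    oracle <- t
    break
  }
  expect_equal(detect_plateau(rising, eps, w), oracle)
  never <- data.frame(mcs = 0:60, dead = 0:60)
  expect_warning(idx <- detect_plateau(never, 1, 20), "no plateau")
  expect_equal(idx, 60)
})

test_that("death fraction is the plateau dead share of initial cells", {
  fake <- structure(list(death_fraction_pct = 37), class = "bnct_run")
  expect_equal(death_fraction(fake), 37)
})

test_that("runs are bit-identical for the same seed and differ across seeds", {
  r1 <- suppressWarnings(run_condition(tiny_config(seed = 77)))
  r2 <- suppressWarnings(run_condition(tiny_config(seed = 77)))
  expect_same_series(r1, r2)
  r3 <- suppressWarnings(run_condition(tiny_config(seed = 78)))
  expect_false(identical(r1$series, r3$series))
})

test_that("zero dose means zero deaths at any threshold", {
  for (theta in c(0, 0.5)) {
    r <- suppressWarnings(run_condition(tiny_config(f_dose = 0,
                                                    theta = theta,
                                                    max_mcs = 60,
                                                    window = 30)))
    expect_equal(r$death_fraction_pct, 0)
    expect_equal(nrow(r$death_events), 0)
  }
})

test_that("live + dead is conserved at every recorded MCS", {
  r <- suppressWarnings(run_condition(tiny_config(seed = 5)))
  expect_true(all(r$series$live + r$series$dead == r$n_cells))
  expect_true(all(diff(r$series$dead) >= 0))
})

test_that("raising the threshold can only spare cells, on matched histories", {
  r0 <- suppressWarnings(run_condition(tiny_config(theta = 0, seed = 9)))
  r5 <- suppressWarnings(run_condition(tiny_config(theta = 0.5, seed = 9)))
  dead0 <- r0$cells$id[r0$cells$kind == "DEAD"]
  dead5 <- r5$cells$id[r5$cells$kind == "DEAD"]
  expect_true(all(dead5 %in% dead0))
  expect_lte(length(dead5), length(dead0))
})

test_that("mean death is nondecreasing in the effective dose", {
  mean_death <- function(f) {
    mean(vapply(1:4, function(s)
      suppressWarnings(run_condition(
        tiny_config(f_dose = f, seed = 100 + s))$death_fraction_pct),
      numeric(1)))
  }
  m0 <- mean_death(0)
  m05 <- mean_death(0.05)
  m15 <- mean_death(0.15)
  expect_lte(m0, m05 + 1e-9)
  expect_lte(m05, m15 + 1e-9)
  expect_gt(m15, 0)
})

test_that("the calibrated floor is monotone: higher floor, fewer deaths", {
  mean_death_at <- function(ef) {
    mean(vapply(1:3, function(s)
      suppressWarnings(run_condition(
        tiny_config(eps_floor = ef, seed = 200 + s))$death_fraction_pct),
      numeric(1)))
  }
  v <- vapply(c(6, 15, 80), mean_death_at, numeric(1))
  expect_true(v[1] >= v[2] && v[2] >= v[3])
  expect_gt(v[1], v[3])  # the grid spans a real response range
})

test_that("calibration fails loudly when the target is unreachable", {
  cfg <- tiny_config(max_mcs = 60, window = 30)
  expect_error(
    calibrate_floor(cfg, target_pct = 150, n_seeds = 1, bracket = c(5, 30),
                    max_iter = 2),
    "outside the achievable range")
})

test_that("calibration converges onto an attainable target", {
  cfg <- tiny_config(max_mcs = 120, window = 30)
  cal <- calibrate_floor(cfg, target_pct = 50, tol = 8, n_seeds = 2,
                         bracket = c(4, 100), max_iter = 6,
                         base_seed = 42)
  expect_true(cal$eps_floor > 4 && cal$eps_floor < 100)
  expect_lte(abs(cal$mean_pct - 50), 8)
  expect_true(nrow(cal$evaluations) >= 3)
})

test_that("a sweep covers the condition grid with per-condition summaries", {
  grid <- expand.grid(mode = c("monolayer", "spheroid"),
                      f_dose = c(0.05, 0.15), theta = 0, D = 0.1,
                      stringsAsFactors = FALSE)
  sw <- sweep_conditions(grid, replicates = 2, eps_floor = 12,
                         base_seed = 3, n_cells = 40,
                         run = list(max_mcs = 80, plateau_window = 30))
  expect_equal(nrow(sw$runs), 8)
  expect_equal(nrow(sw$summary), 4)
  expect_true(all(c("mean", "sd", "n") %in% names(sw$summary)))
  expect_true(all(sw$summary$n == 2))
  expect_true(all(sw$runs$death_fraction_pct >= 0 &
                  sw$runs$death_fraction_pct <= 100))
})

test_that("the full study grid enumerates 16 conditions", {
  g <- study_grid()
  expect_equal(nrow(g), 16)
  expect_equal(nrow(unique(g)), 16)
})
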