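test_that("total energy matches hand counts and the pair-enumeration oracle", {
  p <- cpm_params()
  empty <- build_lattice(c(6, 6, 2))
  expect_equal(total_energy(empty$lattice, empty$cells, p), 0)

  blk <- as.matrix(expand.grid(x = 3:7, y = 3:7, z = 1))
  geo <- build_lattice(c(12, 12, 1), list(list(id = 1, voxels = blk)))
  # 20 boundary voxel pairs x J = 8, cell exactly at target area
  expect_equal(total_energy(geo$lattice, geo$cells, p), 160)

  # one voxel removed: oracle contact term plus lam * (24 - 25)^2
  l2 <- geo$lattice
  l2$spin[3, 3, 1] <- 0L
  c2 <- geo$cells
  c2$area <- 24L
  expect_equal(total_energy(l2, c2, p),
               oracle_total_energy(l2, c2, p))
  expect_equal(total_energy(l2, c2, p) - oracle_total_energy(l2, c2,
                 cpm_params(lam_area = 0)), 2)

  # random multi-kind fixtures, both neighborhood orders
  for (seed in 1:4) {
    geo <- random_block_fixture(seed)
    for (ord in 1:2) {
      pp <- cpm_params(neighborhood_order = ord, lam_area = 1.5)
      expect_equal(total_energy(geo$lattice, geo$cells, pp),
                   oracle_total_energy(geo$lattice, geo$cells, pp))
    }
  }
})

test_that("energy is invariant under rigid translation", {
  blk <- as.matrix(expand.grid(x = 3:7, y = 3:7, z = 1))
  p <- cpm_params()
  e <- vapply(0:2, function(shift) {
    geo <- build_lattice(c(14, 14, 1),
                         list(list(id = 1, voxels = cbind(blk[, 1] + shift,
                                                          blk[, 2], blk[, 3]))))
    total_energy(geo$lattice, geo$cells, p)
  }, numeric(1))
  expect_true(all(e == e[1]))
})

test_that("delta energy equals the full-recompute difference for every flip", {
  for (fixture in list(make_fixture("two_cells_2d"),
                       random_block_fixture(11))) {
    lattice <- fixture$lattice
    cells <- fixture$cells
    p <- cpm_params(lam_area = 2)
    dims <- lattice$dims
    e0 <- total_energy(lattice, cells, p)
    for (x in 1:dims[1]) for (y in 1:dims[2]) for (z in 1:dims[3]) {
      site <- c(x, y, z)
      cur <- lattice$spin[x, y, z]
      cands <- unique(c(0L, bnctsim:::neighbor_ids(lattice, site, 1L)))
      for (cand in cands) {
        de <- suppressWarnings(delta_energy(lattice, cells, p, site, cand))
        if (cand == cur) {
          expect_identical(de, 0)
          next
        }
        l2 <- lattice
        l2$spin[x, y, z] <- cand
        c2 <- cells
        if (cur > 0) c2$area[c2$id == cur] <- c2$area[c2$id == cur] - 1L
        if (cand > 0) c2$area[c2$id == cand] <- c2$area[c2$id == cand] + 1L
        expect_equal(de, total_energy(l2, c2, p) - e0, tolerance = 1e-9)
      }
    }
  }
})

test_that("the area-constraint component of a growth flip is lam * (2a - 2At + 1)", {
  blk <- as.matrix(expand.grid(x = 3:7, y = 3:7, z = 1))
  geo <- build_lattice(c(12, 12, 1), list(list(id = 1, voxels = blk)))
  site <- c(8, 5, 1)  # medium voxel face-adjacent to the cell
  de2 <- delta_energy(geo$lattice, geo$cells, cpm_params(lam_area = 2),
                      site, 1L)
  de0 <- delta_energy(geo$lattice, geo$cells, cpm_params(lam_area = 0),
                      site, 1L)
  expect_equal(de2 - de0, 2)  # 2 * ((26 - 25)^2 - 0)
})

test_that("a non-neighboring candidate id is signalled, not fatal", {
  geo <- make_fixture("two_cells_2d")
  expect_warning(
    de <- delta_energy(geo$lattice, geo$cells, cpm_params(), c(1, 1, 1), 2L),
    "not medium or a neighboring")
  expect_true(is.na(de))
})

test_that("Metropolis acceptance follows exp(-dE/T)", {
  set.seed(42)
  n <- 10000
  acc <- bnctsim:::cpp_metropolis_accept(n, 4, 10)
  p_true <- exp(-0.4)
  expect_lt(abs(acc / n - p_true), 3 * sqrt(p_true * (1 - p_true) / n))
  # dE <= 0 is always accepted
  expect_equal(bnctsim:::cpp_metropolis_accept(100, -1, 10), 100)
})

test_that("no flips are accepted at vanishing temperature from a ground state", {
  blk <- as.matrix(expand.grid(x = 3:7, y = 3:7, z = 1))
  geo <- build_lattice(c(12, 12, 1), list(list(id = 1, voxels = blk)))
  set.seed(7)
  out <- monte_carlo_step(geo$lattice, geo$cells,
                          cpm_params(temperature = 1e-9))
  expect_equal(out$accepted, 0)
  expect_identical(out$lattice$spin, geo$lattice$spin)
})

test_that("cells never vanish and records persist over a long run", {
  geo <- make_fixture("two_cells_2d")
  p <- cpm_params(temperature = 12)
  set.seed(3)
  lattice <- geo$lattice
  cells <- geo$cells
  for (i in 1:100) {
    out <- monte_carlo_step(lattice, cells, p)
    lattice <- out$lattice
    cells <- out$cells
  }
  expect_equal(nrow(cells), 2)
  expect_true(all(cells$area >= 1))
  expect_setequal(unique(as.vector(lattice$spin[lattice$spin > 0])), c(1L, 2L))
  expect_silent(validate_state(lattice, cells))
})

test_that("energy relaxes when starting from a strained configuration", {
  # two 1 x 25 line cells are far from their preferred compact shape
  line1 <- cbind(2:26, 3, 1)
  line2 <- cbind(2:26, 6, 1)
  geo <- build_lattice(c(30, 10, 1), list(list(id = 1, voxels = line1),
                                          list(id = 2, voxels = line2)))
  p <- cpm_params(temperature = 4)
  set.seed(5)
  lattice <- geo$lattice
  cells <- geo$cells
  energies <- numeric(150)
  for (i in seq_along(energies)) {
    out <- monte_carlo_step(lattice, cells, p)
    lattice <- out$lattice
    cells <- out$cells
    energies[i] <- total_energy(lattice, cells, p)
  }
  expect_lt(median(energies[131:150]), median(energies[1:20]))
})
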