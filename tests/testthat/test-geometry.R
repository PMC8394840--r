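test_that("a single monolayer cell is a centered 25-voxel footprint", {
  geo <- init_monolayer(geometry_config("monolayer", n_cells = 1,
                                        dims = c(15, 15, 7), margin = 2))
  expect_equal(nrow(geo$cells), 1)
  expect_equal(geo$cells$area, 25L)
  cen <- cell_centroids(geo$lattice, geo$cells)
  expect_equal(unname(cen[1, 3]), 4)  # central z plane of nz = 7
})

test_that("a 100-cell sheet is flat, complete and connected", {
  geo <- init_monolayer(geometry_config("monolayer", n_cells = 100,
                                        dims = c(60, 60, 7), margin = 2))
  expect_equal(nrow(geo$cells), 100)
  expect_equal(sum(geo$lattice$spin > 0), 2500)
  cen <- cell_centroids(geo$lattice, geo$cells)
  expect_equal(length(unique(cen[, 3])), 1)
  expect_true(oracle_connected(which(geo$lattice$spin > 0),
                               geo$lattice$dims))
  expect_silent(validate_state(geo$lattice, geo$cells))
})

test_that("sizing errors report the required dims", {
  expect_error(init_monolayer(geometry_config("monolayer", n_cells = 100,
                                              dims = c(30, 30, 7))),
               "needs dims of at least")
  expect_error(init_spheroid(geometry_config("spheroid", n_cells = 500,
                                             dims = c(32, 32, 32))),
               "does not fit")
})

test_that("a single spheroid cell is one compact 25-voxel ball", {
  set.seed(4)
  geo <- init_spheroid(geometry_config("spheroid", n_cells = 1,
                                       dims = c(11, 11, 11), margin = 2))
  expect_equal(geo$cells$area, 25L)
  expect_true(oracle_connected(which(geo$lattice$spin == 1),
                               geo$lattice$dims))
})

test_that("spheroid partitions are compact with near-nominal cell areas", {
  set.seed(9)
  geo <- init_spheroid(geometry_config("spheroid", n_cells = 60,
                                       dims = c(24, 24, 24), margin = 2))
  expect_equal(nrow(geo$cells), 60)
  expect_equal(sum(geo$cells$area), 60 * 25)
  expect_equal(mean(geo$cells$area), 25)
  r_bound <- 1.3 * (3 * 60 * 25 / (4 * pi))^(1 / 3)
  vox <- arrayInd(which(geo$lattice$spin > 0), geo$lattice$dims)
  ctr <- (geo$lattice$dims + 1) / 2
  d <- sqrt(rowSums(sweep(vox, 2, ctr)^2))
  expect_true(all(d <= r_bound))
  # every cell is one connected component
  for (id in geo$cells$id)
    expect_true(oracle_connected(which(geo$lattice$spin == id),
                                 geo$lattice$dims))
})

test_that("dose assignment labels exactly round(f * n) cells at random", {
  cells <- new_cell_table(1:200, "TUMOR", 25)
  set.seed(1)
  expect_equal(sum(assign_dose(cells, 0)$is_source), 0)
  d1 <- assign_dose(cells, 0.15)
  expect_equal(sum(d1$kind == "BPA_TUMOR"), 30)
  set.seed(2)
  d2 <- assign_dose(cells, 0.15)
  expect_equal(sum(d2$is_source), 30)
  expect_false(identical(which(d1$is_source), which(d2$is_source)))
  # round-half-up
  cells10 <- new_cell_table(1:10, "TUMOR", 25)
  set.seed(3)
  expect_equal(sum(assign_dose(cells10, 0.05)$is_source), 1)
})

test_that("neighborhood fraction matches the all-pairs oracle", {
  set.seed(12)
  geo <- init_spheroid(geometry_config("spheroid", n_cells = 40,
                                       dims = c(22, 22, 22), margin = 2))
  cells <- assign_dose(geo$cells, 0.2)
  expect_equal(exposure_neighborhood_fraction(geo$lattice, cells, 0), 0)
  diag_len <- sqrt(sum(geo$lattice$dims^2))
  expect_equal(exposure_neighborhood_fraction(geo$lattice, cells, diag_len), 1)
  for (rr in c(3, 5, 8)) {
    cen <- cell_centroids(geo$lattice, cells)
    src <- which(cells$is_source)
    non <- which(!cells$is_source)
    hit <- vapply(non, function(i) {
      any(vapply(src, function(j)
        sqrt(sum((cen[i, ] - cen[j, ])^2)) <= rr, logical(1)))
    }, logical(1))
    expect_equal(exposure_neighborhood_fraction(geo$lattice, cells, rr),
                 mean(hit))
  }
})

test_that("spheroids reach more neighbors than sheets at a fixed range", {
  n_seeds <- 20
  fr <- function(mode, dims, seed) {
    set.seed(seed)
    geo <- init_geometry(geometry_config(mode, n_cells = 60, dims = dims,
                                         margin = 2))
    cells <- assign_dose(geo$cells, 0.15)
    exposure_neighborhood_fraction(geo$lattice, cells, 6)
  }
  f3d <- vapply(1:n_seeds, function(s) fr("spheroid", c(24, 24, 24), s),
                numeric(1))
  f2d <- vapply(1:n_seeds, function(s) fr("monolayer", c(50, 50, 7), s),
                numeric(1))
  expect_gt(mean(f3d), mean(f2d))
})

test_that("cell count and label count are invariant under geometry mode", {
  set.seed(31)
  g3 <- init_spheroid(geometry_config("spheroid", n_cells = 60,
                                      dims = c(24, 24, 24), margin = 2))
  set.seed(31)
  g2 <- init_monolayer(geometry_config("monolayer", n_cells = 60,
                                       dims = c(50, 50, 7), margin = 2))
  set.seed(5)
  c3 <- assign_dose(g3$cells, 0.15)
  set.seed(6)
  c2 <- assign_dose(g2$cells, 0.15)
  expect_equal(nrow(c3), nrow(c2))
  expect_equal(sum(c3$is_source), sum(c2$is_source))
})
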