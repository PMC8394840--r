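# Independent brute-force oracles used across the test files. These
# deliberately re-derive quantities by naive enumeration, not by calling the
# package's optimized paths.

oracle_offsets <- function(order) {
  face <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                c(0, 0, 1), c(0, 0, -1))
  if (order == 1) return(face)
  rbind(face,
        c(1, 1, 0), c(1, -1, 0), c(-1, 1, 0), c(-1, -1, 0),
        c(1, 0, 1), c(1, 0, -1), c(-1, 0, 1), c(-1, 0, -1),
        c(0, 1, 1), c(0, 1, -1), c(0, -1, 1), c(0, -1, -1))
}

# total CPM energy by exhaustive voxel-pair enumeration
oracle_total_energy <- function(lattice, cells, params) {
  dims <- lattice$dims
  off <- oracle_offsets(params$neighborhood_order)
  kinds <- c(MEDIUM = 0, TUMOR = 1, BPA_TUMOR = 2, DEAD = 3)
  kind_of <- integer(max(c(0, cells$id)) + 1)
  if (nrow(cells)) kind_of[cells$id + 1] <- kinds[cells$kind]
  e <- 0
  for (x in 1:dims[1]) for (y in 1:dims[2]) for (z in 1:dims[3]) {
    a <- lattice$spin[x, y, z]
    for (k in seq_len(nrow(off))) {
      xx <- x + off[k, 1]; yy <- y + off[k, 2]; zz <- z + off[k, 3]
      if (xx < 1 || yy < 1 || zz < 1 || xx > dims[1] || yy > dims[2] ||
          zz > dims[3]) next
      b <- lattice$spin[xx, yy, zz]
      if (a != b) e <- e + params$J[kind_of[a + 1] + 1, kind_of[b + 1] + 1]
    }
  }
  e <- e / 2  # each unordered pair visited twice
  if (nrow(cells))
    e <- e + sum(params$lam_area * (cells$area - cells$target_area)^2)
  e
}

# count of face-adjacent voxel pairs between two specific cell ids
oracle_shared_faces <- function(lattice, id_a, id_b) {
  dims <- lattice$dims
  off <- oracle_offsets(1)
  cnt <- 0
  for (x in 1:dims[1]) for (y in 1:dims[2]) for (z in 1:dims[3]) {
    if (lattice$spin[x, y, z] != id_a) next
    for (k in seq_len(nrow(off))) {
      xx <- x + off[k, 1]; yy <- y + off[k, 2]; zz <- z + off[k, 3]
      if (xx < 1 || yy < 1 || zz < 1 || xx > dims[1] || yy > dims[2] ||
          zz > dims[3]) next
      if (lattice$spin[xx, yy, zz] == id_b) cnt <- cnt + 1
    }
  }
  cnt
}

# is the given set of flat voxel indices one face-connected component?
oracle_connected <- function(flat, dims) {
  if (length(flat) == 0) return(FALSE)
  coords <- arrayInd(flat, dims)
  key <- function(m) paste(m[, 1], m[, 2], m[, 3])
  inset <- new.env(parent = emptyenv())
  for (k in key(coords)) assign(k, TRUE, envir = inset)
  off <- oracle_offsets(1)
  seen <- character()
  queue <- key(coords[1, , drop = FALSE])
  seen <- queue
  while (length(queue)) {
    v <- as.integer(strsplit(queue[1], " ")[[1]])
    queue <- queue[-1]
    for (k in seq_len(nrow(off))) {
      nb <- v + off[k, ]
      kk <- paste(nb[1], nb[2], nb[3])
      if (!is.null(inset[[kk]]) && !(kk %in% seen)) {
        seen <- c(seen, kk)
        queue <- c(queue, kk)
      }
    }
  }
  length(seen) == length(flat)
}

# a small random multi-cell configuration for property tests (always built
# from connected blocks so build_lattice accepts it)
random_block_fixture <- function(seed, dims = c(8, 8, 2)) {
  set.seed(seed)
  kinds <- c("TUMOR", "BPA_TUMOR", "DEAD")
  spec <- list(
    list(id = 1, kind = sample(kinds, 1),
         voxels = as.matrix(expand.grid(x = 1:3, y = 1:4, z = 1))),
    list(id = 2, kind = sample(kinds, 1),
         voxels = as.matrix(expand.grid(x = 4:6, y = 2:4, z = 1:2))),
    list(id = 3, kind = sample(kinds, 1),
         voxels = as.matrix(expand.grid(x = 7:8, y = 5:8, z = 2)))
  )
  build_lattice(dims, spec)
}

expect_same_series <- function(a, b) {
  expect_identical(a$series, b$series)
  expect_identical(a$death_events, b$death_events)
  expect_identical(a$plateau_mcs, b$plateau_mcs)
}
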