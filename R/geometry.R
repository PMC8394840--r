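#' Geometry configuration for a simulated tissue
#'
#' Both arrangements use the same lattice representation and the same field
#' solver, so 2D-vs-3D differences come only from how cells are packed. The
#' default lattice sizes keep every cell at least `margin` voxels away from
#' the fixed walls in the populated axes.
#'
#' @param mode `"monolayer"` (one-cell-thick sheet of 5 x 5 x 1 footprints) or
#'   `"spheroid"` (compact ball partitioned into cells).
#' @param n_cells number of tumor cells (default 500).
#' @param dims lattice size; defaults to 64 x 64 x 64 for spheroids and
#'   136 x 136 x 16 for monolayers (a 500-cell sheet of 5 x 5 footprints does
#'   not fit a 64-voxel edge). The monolayer keeps the full 3D field solver
#'   above and below the sheet, so secreted alpha density can leave the
#'   plane just as it can leave the spheroid surface.
#' @param margin minimum clearance between cells and the lattice walls.
#' @param f_dose fraction of cells labelled as alpha sources (`BPA_TUMOR`);
#'   study values 0.15 (high dose) and 0.05 (low dose).
#' @return list of class `geometry_config`.
#' @export
geometry_config <- function(mode = c("spheroid", "monolayer"), n_cells = 500,
                            dims = NULL, margin = 8, f_dose = 0.15) {
  mode <- match.arg(mode)
  if (is.null(dims))
    dims <- if (mode == "spheroid") c(64L, 64L, 64L) else c(136L, 136L, 16L)
  dims <- as.integer(dims)
  n_cells <- as.integer(n_cells)
  if (n_cells < 1L) stop("n_cells must be >= 1")
  if (f_dose < 0 || f_dose > 1) stop("f_dose must be in [0, 1]")
  structure(list(mode = mode, n_cells = n_cells, dims = dims,
                 margin = as.integer(margin), f_dose = as.numeric(f_dose)),
            class = "geometry_config")
}

#' Initialize a one-cell-thick monolayer
#'
#' Cells tile the central z-plane as 5 x 5 x 1 footprints (target area 25) in
#' a centered, contiguous near-square grid, filled row-major; all centroids
#' share one z. The sheet sits in a 3D box so the alpha field is free to
#' spread out of the plane.
#'
#' @param config a [geometry_config()] with `mode = "monolayer"`.
#' @return list with `lattice` and `cells`.
#' @export
init_monolayer <- function(config) {
  stopifnot(config$mode == "monolayer")
  n <- config$n_cells
  dims <- config$dims
  ncol_ <- ceiling(sqrt(n))
  nrow_ <- ceiling(n / ncol_)
  need_x <- 5L * ncol_ + 2L * config$margin
  need_y <- 5L * nrow_ + 2L * config$margin
  if (need_x > dims[1] || need_y > dims[2] || dims[3] < 7L)
    stop("monolayer of ", n, " cells needs dims of at least ",
         need_x, " x ", need_y, " x 7 (got ",
         paste(dims, collapse = " x "), ")")
  x0 <- (dims[1] - 5L * ncol_) %/% 2L
  y0 <- (dims[2] - 5L * nrow_) %/% 2L
  zc <- (dims[3] + 1L) %/% 2L
  spec <- vector("list", n)
  for (i in seq_len(n)) {
    r <- (i - 1L) %/% ncol_
    cc <- (i - 1L) %% ncol_
    xs <- x0 + 5L * cc + 1:5
    ys <- y0 + 5L * r + 1:5
    spec[[i]] <- list(id = i, kind = "TUMOR",
                      voxels = as.matrix(expand.grid(x = xs, y = ys, z = zc)))
  }
  build_lattice(dims, spec)
}

#' Initialize a compact 3D spheroid
#'
#' Takes the `n_cells * 25` voxels nearest the lattice center (a digitized
#' solid sphere), draws `n_cells` seed voxels uniformly at random from that
#' set, and assigns every ball voxel to its nearest seed (exact integer
#' squared distances; ties to the lower cell id). Stray fragments produced by
#' the digital Voronoi partition are reassigned to the face-adjacent cell
#' with the largest contact so every cell is a single connected component.
#'
#' @param config a [geometry_config()] with `mode = "spheroid"`. Uses R's
#'   global RNG.
#' @return list with `lattice` and `cells`.
#' @export
init_spheroid <- function(config) {
  stopifnot(config$mode == "spheroid")
  n <- config$n_cells
  dims <- config$dims
  n_vox <- n * 25L
  ctr <- (dims + 1) / 2
  r_ball <- (3 * n_vox / (4 * pi))^(1 / 3)
  if (any(ctr - r_ball - config$margin < 1) ||
      any(ctr + r_ball + config$margin > dims))
    stop("spheroid of ", n, " cells (radius ~", round(r_ball, 1),
         ") plus margin ", config$margin, " does not fit dims ",
         paste(dims, collapse = " x "),
         "; needs at least ", ceiling(2 * (r_ball + config$margin) + 1),
         " per axis")
  # candidate voxels: everything within an r_ball + 2 box, ranked by distance
  lo <- pmax(1L, floor(ctr - r_ball - 2))
  hi <- pmin(dims, ceiling(ctr + r_ball + 2))
  cand <- as.matrix(expand.grid(x = lo[1]:hi[1], y = lo[2]:hi[2],
                                z = lo[3]:hi[3]))
  d2 <- (cand[, 1] - ctr[1])^2 + (cand[, 2] - ctr[2])^2 +
    (cand[, 3] - ctr[3])^2
  ord <- order(d2, cand[, 3], cand[, 2], cand[, 1])
  if (nrow(cand) < n_vox) stop("internal: candidate box too small")
  ball <- cand[ord[seq_len(n_vox)], , drop = FALSE]
  seeds <- ball[sample.int(n_vox, n), , drop = FALSE]
  assign <- nearest_seed(ball, seeds)
  spin <- array(0L, dim = dims)
  spin[flat_index(ball, dims)] <- assign
  spin <- repair_connectivity(spin, dims, n)
  areas <- tabulate(spin[spin > 0L], nbins = n)
  lattice <- structure(list(dims = dims, spin = spin), class = "bnct_lattice")
  cells <- new_cell_table(seq_len(n), "TUMOR", areas, 25)
  validate_state(lattice, cells)
  list(lattice = lattice, cells = cells)
}

# Exact integer nearest-seed assignment; ties go to the lower seed index.
nearest_seed <- function(vox, seeds) {
  v2 <- rowSums(vox^2)
  s2 <- rowSums(seeds^2)
  d2 <- matrix(v2, nrow(vox), nrow(seeds)) +
    matrix(s2, nrow(vox), nrow(seeds), byrow = TRUE) -
    2 * vox %*% t(seeds)
  max.col(-d2, ties.method = "first")
}

# Reassign fragments so every cell id forms one face-connected component.
repair_connectivity <- function(spin, dims, n) {
  strides <- c(1L, dims[1], dims[1] * dims[2])
  lat <- structure(list(dims = dims, spin = spin), class = "bnct_lattice")
  for (pass in 1:100) {
    changed <- FALSE
    for (id in seq_len(n)) {
      w <- which(lat$spin == id)
      comps <- label_components(w, lat$spin, dims, strides)
      if (length(comps) <= 1L) next
      sizes <- lengths(comps)
      keep <- which.max(sizes)
      for (k in seq_along(comps)) {
        if (k == keep) next
        for (v in comps[[k]]) {
          xyz <- arrayInd(v, dims)
          nb_ids <- integer(0)
          for (ax in 1:3) for (dsign in c(-1L, 1L)) {
            p <- xyz[1, ax] + dsign
            if (p < 1L || p > dims[ax]) next
            nid <- lat$spin[v + dsign * strides[ax]]
            if (nid > 0L && nid != id) nb_ids <- c(nb_ids, nid)
          }
          if (length(nb_ids)) {
            tb <- table(nb_ids)
            lat$spin[v] <- as.integer(names(tb)[which.max(tb)])
            changed <- TRUE
          }
        }
      }
    }
    if (!changed) {
      ok <- vapply(seq_len(n), function(id) cell_is_connected(lat, id),
                   logical(1))
      if (all(ok)) return(lat$spin)
      # no orphan voxel had a foreign cell neighbor this pass; give the
      # remaining fragments another sweep
    }
    all_ok <- vapply(seq_len(n), function(id) cell_is_connected(lat, id),
                     logical(1))
    if (all(all_ok)) return(lat$spin)
  }
  stop("could not repair cell connectivity after 100 passes")
}

label_components <- function(w, spin, dims, strides) {
  if (length(w) == 0L) return(list())
  inset <- logical(prod(dims))
  inset[w] <- TRUE
  seen <- logical(prod(dims))
  comps <- list()
  for (start in w) {
    if (seen[start]) next
    queue <- start
    seen[start] <- TRUE
    comp <- start
    while (length(queue)) {
      v <- queue[length(queue)]
      queue <- queue[-length(queue)]
      xyz <- arrayInd(v, dims)
      for (ax in 1:3) for (dsign in c(-1L, 1L)) {
        p <- xyz[1, ax] + dsign
        if (p < 1L || p > dims[ax]) next
        nb <- v + dsign * strides[ax]
        if (inset[nb] && !seen[nb]) {
          seen[nb] <- TRUE
          queue <- c(queue, nb)
          comp <- c(comp, nb)
        }
      }
    }
    comps[[length(comps) + 1L]] <- comp
  }
  comps
}

#' Initialize geometry according to its mode
#' @param config a [geometry_config()].
#' @return list with `lattice` and `cells`.
#' @export
init_geometry <- function(config) {
  if (config$mode == "monolayer") init_monolayer(config) else init_spheroid(config)
}

#' Randomly label the BPA-loaded source cells
#'
#' Relabels exactly `round(f_dose * n_cells)` cells (round-half-up) as
#' `BPA_TUMOR`, chosen uniformly at random without replacement from R's
#' global RNG.
#'
#' @param cells cell table (all `TUMOR`).
#' @param f_dose source fraction.
#' @return the cell table with `kind` and `is_source` updated.
#' @export
assign_dose <- function(cells, f_dose) {
  if (f_dose < 0 || f_dose > 1) stop("f_dose must be in [0, 1]")
  n_lab <- floor(f_dose * nrow(cells) + 0.5)
  if (n_lab > 0L) {
    pick <- sample.int(nrow(cells), n_lab)
    cells$kind[pick] <- "BPA_TUMOR"
    cells$is_source[pick] <- TRUE
  }
  cells
}

#' Cell centroids
#' @param lattice a `bnct_lattice`.
#' @param cells cell table.
#' @return n x 3 matrix of centroid coordinates, rows in `cells$id` order.
#' @export
cell_centroids <- function(lattice, cells) {
  w <- which(lattice$spin > 0L)
  xyz <- arrayInd(w, lattice$dims)
  id <- lattice$spin[w]
  cen <- vapply(1:3, function(ax) {
    tapply(xyz[, ax], id, mean)[as.character(cells$id)]
  }, numeric(nrow(cells)))
  cen <- matrix(cen, ncol = 3)
  rownames(cen) <- cells$id
  cen
}

#' Fraction of non-source cells within reach of a source
#'
#' The geometric mechanism behind the 2D/3D contrast: the fraction of
#' non-source cells whose centroid lies within Euclidean distance `range_R`
#' of at least one source-cell centroid. In a spheroid a source is surrounded
#' omnidirectionally, so at fixed range more neighbors fall inside it than in
#' a planar sheet.
#'
#' @param lattice a `bnct_lattice`.
#' @param cells cell table with dose assigned.
#' @param range_R Euclidean range in voxels.
#' @return fraction in `[0, 1]` (0 when there are no sources or no
#'   non-sources).
#' @export
exposure_neighborhood_fraction <- function(lattice, cells, range_R) {
  cen <- cell_centroids(lattice, cells)
  src <- cells$is_source
  if (!any(src) || all(src)) return(0)
  a <- cen[!src, , drop = FALSE]
  b <- cen[src, , drop = FALSE]
  d2 <- matrix(rowSums(a^2), nrow(a), nrow(b)) +
    matrix(rowSums(b^2), nrow(a), nrow(b), byrow = TRUE) -
    2 * a %*% t(b)
  mean(apply(d2, 1, function(r) any(r <= range_R^2)))
}
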