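#' Cellular Potts model parameters
#'
#' The CPM Hamiltonian is a contact-energy term summed over unlike neighbor
#' voxel pairs plus a quadratic area constraint per cell:
#' \deqn{H = \sum_{(a,b)} J(k_a, k_b) \, [id_a \ne id_b]
#'       + \lambda \sum_{cells} (A - A_t)^2.}
#' The default contact energy is a single value of 8 for every pair involving
#' at least one cell (all kinds, including dead cells, which stay in place as
#' inert objects) and 0 for medium--medium.
#'
#' @param J 4 x 4 symmetric contact-energy matrix over kinds
#'   (MEDIUM, TUMOR, BPA_TUMOR, DEAD); `J[MEDIUM, MEDIUM]` must be 0.
#' @param lam_area area-constraint strength (default 2).
#' @param temperature Metropolis temperature (> 0; default 10).
#' @param neighborhood_order 1 (6 face neighbors) or 2 (18 face + edge
#'   neighbors) for contact energy and copy-attempt candidates.
#' @return list of class `cpm_params`.
#' @export
cpm_params <- function(J = NULL, lam_area = 2, temperature = 10,
                       neighborhood_order = 1) {
  if (is.null(J)) {
    J <- matrix(8, 4, 4)
    J[1, 1] <- 0
  }
  if (!is.matrix(J)) {
    J <- unlist(J)
    if (length(J) != 16L) stop("J must be a 4 x 4 matrix")
    J <- matrix(as.numeric(J), 4, 4)
  }
  if (any(dim(J) != c(4L, 4L))) stop("J must be a 4 x 4 matrix")
  dimnames(J) <- list(names(.KINDS), names(.KINDS))
  if (!isTRUE(all.equal(J, t(J)))) stop("J must be symmetric")
  if (J[1, 1] != 0) stop("J(medium, medium) must be 0")
  if (lam_area < 0) stop("lam_area must be >= 0")
  if (temperature <= 0) stop("temperature must be > 0")
  if (!neighborhood_order %in% c(1L, 2L))
    stop("neighborhood_order must be 1 or 2")
  structure(list(J = J, lam_area = as.numeric(lam_area),
                 temperature = as.numeric(temperature),
                 neighborhood_order = as.integer(neighborhood_order)),
            class = "cpm_params")
}

#' Total CPM energy of a configuration
#'
#' @param lattice a `bnct_lattice`.
#' @param cells the matching cell table.
#' @param params a [cpm_params()] object.
#' @return dimensionless energy (contact + area-constraint terms).
#' @export
total_energy <- function(lattice, cells, params = cpm_params()) {
  pv <- pad_vectors(cells)
  cpp_total_energy(as.integer(lattice$spin), lattice$dims, pv$kind_of,
                   params$J, params$lam_area, pv$target, pv$area,
                   params$neighborhood_order)
}

#' Local energy change of a single copy attempt
#'
#' Energy difference of hypothetically copying `candidate_id` onto `site`,
#' identical to the full-recompute difference but evaluated locally. If
#' `candidate_id` is neither medium nor the id of a voxel in the site's
#' neighborhood shell, the attempt is not a valid copy: `NA` is returned with
#' a warning (signalled, not fatal).
#'
#' @inheritParams total_energy
#' @param site length-3 integer voxel coordinate (1-based).
#' @param candidate_id proposed id (0 = medium or a neighboring cell's id).
#' @return scalar energy difference, or `NA` for an invalid candidate.
#' @export
delta_energy <- function(lattice, cells, params, site, candidate_id) {
  site <- as.integer(site)
  dims <- lattice$dims
  if (any(site < 1L) || any(site > dims)) stop("site outside the lattice")
  candidate_id <- as.integer(candidate_id)
  if (candidate_id != 0L) {
    nb <- neighbor_ids(lattice, site, params$neighborhood_order)
    if (!candidate_id %in% nb) {
      warning("candidate id ", candidate_id,
              " is not medium or a neighboring cell's id; attempt rejected")
      return(NA_real_)
    }
  }
  pv <- pad_vectors(cells)
  cpp_delta_energy(as.integer(lattice$spin), dims, pv$kind_of, params$J,
                   params$lam_area, pv$target, pv$area, site, candidate_id,
                   params$neighborhood_order)
}

neighbor_offsets <- function(order) {
  face <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                c(0, 0, 1), c(0, 0, -1))
  if (order == 1L) return(face)
  edge <- rbind(c(1, 1, 0), c(1, -1, 0), c(-1, 1, 0), c(-1, -1, 0),
                c(1, 0, 1), c(1, 0, -1), c(-1, 0, 1), c(-1, 0, -1),
                c(0, 1, 1), c(0, 1, -1), c(0, -1, 1), c(0, -1, -1))
  rbind(face, edge)
}

neighbor_ids <- function(lattice, site, order) {
  off <- neighbor_offsets(order)
  nb <- sweep(off, 2, site, "+")
  ok <- nb[, 1] >= 1 & nb[, 2] >= 1 & nb[, 3] >= 1 &
    nb[, 1] <= lattice$dims[1] & nb[, 2] <= lattice$dims[2] &
    nb[, 3] <= lattice$dims[3]
  unique(lattice$spin[flat_index(nb[ok, , drop = FALSE], lattice$dims)])
}

#' One Monte Carlo step of Metropolis dynamics
#'
#' Performs `nx * ny * nz` copy attempts: each picks a random source voxel and
#' a random neighbor, proposing to copy the neighbor's id onto the voxel. The
#' attempt is accepted if the energy change is non-positive, otherwise with
#' probability `exp(-dE / temperature)`. Attempts that would shrink a cell
#' below one voxel are rejected (cells never vanish), and attempts never cross
#' the fixed lattice boundary. Randomness comes from R's global RNG, so runs
#' are reproducible with [set.seed()].
#'
#' @inheritParams total_energy
#' @return list with updated `lattice`, `cells` (areas refreshed) and the
#'   number of `accepted` flips.
#' @export
monte_carlo_step <- function(lattice, cells, params = cpm_params()) {
  pv <- pad_vectors(cells)
  spin <- force_copy(as.integer(lattice$spin))
  area <- force_copy(pv$area)
  accepted <- cpp_mcs_inplace(spin, lattice$dims, pv$kind_of, params$J,
                              params$lam_area, pv$target, area,
                              params$temperature, params$neighborhood_order)
  lattice$spin <- array(spin, dim = lattice$dims)
  cells$area <- area[cells$id + 1L]
  list(lattice = lattice, cells = cells, accepted = accepted)
}
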