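#' Radioresistance damage parameters
#'
#' Exposure is accumulated on a dimensionless scale: each MCS a live cell
#' gains the mean over its voxels of `max(c - floor, 0) / E_ref_rate`, where
#' `floor = eps_floor * E_ref_rate` and `E_ref_rate` is the single-source
#' adjacent steady state from [steady_state_reference()]. The floor encodes
#' the finite alpha track length: field levels below it register no damage.
#' `E_ref_rate` is proportional to the emission rate `s`, so the arbitrary
#' scale of `s` cancels from both the floor and the accumulated exposure.
#' A cell dies the MCS its cumulative exposure strictly exceeds `theta`
#' (and is positive), so `theta = 0` kills on any registered exposure.
#'
#' @param theta dimensionless radioresistance threshold (study values 0 and
#'   0.5).
#' @param eps_floor dimensionless detection floor, in units of `E_ref_rate`.
#'   The default of 30 is a nominal pre-calibration value; studies calibrate
#'   it once with [calibrate_floor()].
#' @param E_ref_rate reference exposure rate from [steady_state_reference()].
#' @return list of class `damage_params`.
#' @export
damage_params <- function(theta = 0, eps_floor = 30, E_ref_rate = NULL) {
  if (theta < 0) stop("theta must be >= 0")
  if (eps_floor <= 0) stop("eps_floor must be > 0")
  if (!is.null(E_ref_rate) && E_ref_rate <= 0)
    stop("E_ref_rate must be > 0 (is the propagation constant zero?)")
  structure(list(theta = as.numeric(theta), eps_floor = as.numeric(eps_floor),
                 E_ref_rate = E_ref_rate),
            class = "damage_params")
}

#' Accumulate one MCS of alpha exposure into the cell table
#'
#' @param cells cell table.
#' @param field a `bnct_field`.
#' @param lattice the matching `bnct_lattice`.
#' @param params a [damage_params()] with `E_ref_rate` set.
#' @return the cell table with `exposure` updated for live cells (dead cells
#'   accumulate nothing).
#' @export
accumulate_exposure <- function(cells, field, lattice, params) {
  if (is.null(params$E_ref_rate))
    stop("damage_params$E_ref_rate must be set (see steady_state_reference)")
  if (any(cells$area < 1L))
    stop("cell(s) with zero voxels: ",
         paste(cells$id[cells$area < 1L], collapse = ", "))
  floor_abs <- params$eps_floor * params$E_ref_rate
  max_id <- max(cells$id)
  sums <- cpp_supra_floor_sums(as.numeric(field$c), as.integer(lattice$spin),
                               max_id, floor_abs)
  alive <- cells$kind != "DEAD"
  gain <- sums[cells$id + 1L] / cells$area / params$E_ref_rate
  cells$exposure[alive] <- cells$exposure[alive] + gain[alive]
  cells
}

#' Apply the threshold death rule
#'
#' Every live cell whose cumulative exposure strictly exceeds `theta` (and is
#' positive) becomes `DEAD` with `death_mcs = mcs`. BPA-loaded source cells
#' are eligible (self-irradiation); dead cells stay on the lattice as inert
#' objects.
#'
#' @param cells cell table.
#' @param params a [damage_params()].
#' @param mcs current Monte Carlo step index.
#' @return list with the updated `cells` and a `death_events` data frame
#'   (columns `mcs`, `cell_id`, `kind_at_death`, `exposure_at_death`).
#' @export
apply_death <- function(cells, params, mcs) {
  dying <- cells$kind != "DEAD" & cells$exposure > params$theta &
    cells$exposure > 0
  events <- data.frame(
    mcs = rep(as.integer(mcs), sum(dying)),
    cell_id = cells$id[dying],
    kind_at_death = cells$kind[dying],
    exposure_at_death = cells$exposure[dying],
    stringsAsFactors = FALSE
  )
  cells$death_mcs[dying] <- as.integer(mcs)
  cells$kind[dying] <- "DEAD"
  list(cells = cells, death_events = events)
}
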