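#' Alpha-particle field parameters
#'
#' The secreted alpha-particle density evolves on the cell lattice by one
#' update per Monte Carlo step: `substeps` explicit diffusion substeps with a
#' 6-point stencil and zero-flux boundaries, then multiplicative decay by
#' `(1 - mu)`, then secretion of `s` onto every source voxel. The explicit
#' scheme is stable (and positivity-preserving) when
#' `D / substeps <= 1/6` in lattice units.
#'
#' @param D propagation constant in pixel^2/MCS (study range 0.1--0.2).
#' @param mu decay constant per MCS (default 0.01), applied as a
#'   multiplicative factor `1 - mu`.
#' @param s emission rate per source voxel per MCS (arbitrary field units;
#'   thresholds are expressed relative to [steady_state_reference()] so the
#'   scale of `s` cancels).
#' @param substeps diffusion substeps per MCS (default 2, so D = 0.2 is
#'   stable).
#' @param persist_sources if `TRUE` (default) source voxels keep emitting
#'   after the host cell's biological death.
#' @return list of class `field_params`.
#' @export
field_params <- function(D = 0.1, mu = 0.01, s = 1.0, substeps = 2,
                         persist_sources = TRUE) {
  if (D < 0) stop("D must be >= 0")
  if (mu < 0 || mu >= 1) stop("mu must be in [0, 1)")
  if (s <= 0) stop("s must be > 0")
  substeps <- as.integer(substeps)
  if (substeps < 1L) stop("substeps must be >= 1")
  if (D / substeps > 1 / 6 + 1e-12)
    stop("unstable field parameters: D/substeps = ", format(D / substeps),
         " exceeds the 3D explicit-scheme bound 1/6; raise substeps or lower D")
  structure(list(D = as.numeric(D), mu = as.numeric(mu), s = as.numeric(s),
                 substeps = substeps,
                 persist_sources = isTRUE(persist_sources)),
            class = "field_params")
}

#' Initialize an all-zero alpha field
#' @param dims integer length-3 lattice size.
#' @return object of class `bnct_field` with elements `dims` and the numeric
#'   concentration array `c`.
#' @export
init_field <- function(dims) {
  dims <- as.integer(dims)
  if (length(dims) != 3L || any(dims < 1L)) stop("dims must be 3 positive integers")
  structure(list(dims = dims, c = array(0, dim = dims)), class = "bnct_field")
}

#' Advance the alpha field by one Monte Carlo step
#'
#' @param field a `bnct_field`.
#' @param source_mask logical array (same dims) marking source voxels, or
#'   `NULL` for no sources.
#' @param params a [field_params()] object.
#' @return the updated `bnct_field`.
#' @export
step_field <- function(field, source_mask = NULL, params = field_params()) {
  if (is.null(source_mask)) {
    src <- logical(prod(field$dims))
  } else {
    src <- as.logical(source_mask)
    if (length(src) != prod(field$dims))
      stop("source_mask dims do not match the field")
  }
  conc <- force_copy(as.numeric(field$c))
  cpp_field_step_inplace(conc, field$dims, src, params$D, params$mu,
                         params$s, params$substeps)
  field$c <- array(conc, dim = field$dims)
  field
}

#' Total field mass
#' @param field a `bnct_field`.
#' @return sum of the concentration over all voxels.
#' @export
total_mass <- function(field) sum(field$c)

.bnct_cache <- new.env(parent = emptyenv())

#' Steady-state reference concentration of a single source voxel
#'
#' Iterates the field update with one persistent source voxel at the center of
#' an otherwise empty cubic lattice until the concentration at a face-adjacent
#' voxel converges, and returns that value. It is the natural exposure unit:
#' one MCS spent face-adjacent to an isolated saturated source voxel. All
#' damage thresholds and the detection floor are expressed relative to it, so
#' the arbitrary emission scale `s` cancels.
#'
#' @param params a [field_params()] object.
#' @param n lattice edge length (odd; default 41, large enough that the
#'   boundary is several decay lengths away for the study's D range).
#' @param tol convergence tolerance on the per-iteration change of the
#'   adjacent-voxel value (default 1e-12).
#' @param max_iter iteration cap (default 60000).
#' @return scalar reference concentration (field units per MCS of residence).
#' @export
steady_state_reference <- function(params, n = 41, tol = 1e-12,
                                   max_iter = 60000) {
  key <- paste("ssr", params$D, params$mu, params$s, params$substeps, n,
               sep = "_")
  hit <- .bnct_cache[[key]]
  if (!is.null(hit)) return(hit)
  n <- as.integer(n)
  dims <- c(n, n, n)
  mid <- (n + 1L) %/% 2L
  src <- array(FALSE, dim = dims)
  src[mid, mid, mid] <- TRUE
  src <- as.logical(src)
  conc <- numeric(prod(dims))
  adj <- flat_index(matrix(c(mid + 1L, mid, mid), 1), dims)
  prev <- 0
  delta <- Inf
  for (it in seq_len(max_iter)) {
    cpp_field_step_inplace(conc, dims, src, params$D, params$mu, params$s,
                           params$substeps)
    cur <- conc[adj]
    delta <- abs(cur - prev)
    if (it > 1L && delta < tol) {
      .bnct_cache[[key]] <- cur
      return(cur)
    }
    prev <- cur
  }
  if (params$D == 0) {  # nothing ever reaches the adjacent voxel
    .bnct_cache[[key]] <- prev
    return(prev)
  }
  stop("steady_state_reference did not converge in ", max_iter,
       " iterations (last per-step change ", format(delta), ")")
}
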