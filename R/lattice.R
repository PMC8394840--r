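#' @useDynLib bnctsim, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats setNames rnorm sd
#' @importFrom utils head write.csv read.csv
NULL

.KINDS <- c(MEDIUM = 0L, TUMOR = 1L, BPA_TUMOR = 2L, DEAD = 3L)
.CELL_KINDS <- c("TUMOR", "BPA_TUMOR", "DEAD")

kind_code <- function(kind) {
  code <- .KINDS[kind]
  if (anyNA(code)) stop("unknown cell kind: ", paste(kind[is.na(code)], collapse = ", "))
  unname(code)
}

#' Create an empty cell table
#'
#' One row per biological cell: id, kind (`TUMOR`, `BPA_TUMOR` or `DEAD`),
#' current and target voxel areas, cumulative dimensionless alpha exposure,
#' whether the cell is an alpha source (retained after death, when the kind
#' flips to `DEAD`), and the Monte Carlo step at which it died.
#'
#' @param id integer cell ids (positive, unique).
#' @param kind character vector of kinds, recycled.
#' @param area integer voxel counts.
#' @param target_area target voxel count for the area constraint (default 25).
#' @return a `data.frame` with class `bnct_cells`.
#' @export
new_cell_table <- function(id = integer(), kind = "TUMOR", area = integer(),
                           target_area = 25) {
  id <- as.integer(id)
  if (anyDuplicated(id)) stop("duplicate cell ids")
  if (length(id) && any(id <= 0L)) stop("cell ids must be positive")
  d <- data.frame(
    id = id,
    kind = rep_len(as.character(kind), length(id)),
    area = as.integer(rep_len(area, length(id))),
    target_area = rep_len(as.numeric(target_area), length(id)),
    exposure = numeric(length(id)),
    is_source = rep_len(FALSE, length(id)),
    death_mcs = rep_len(NA_integer_, length(id)),
    stringsAsFactors = FALSE
  )
  d$is_source <- d$kind == "BPA_TUMOR"
  kind_code(d$kind)  # validates
  class(d) <- c("bnct_cells", "data.frame")
  d
}

# Guaranteed-private copy of a vector before handing it to an in-place
# C++ kernel (subassignment on a shared object always duplicates).
force_copy <- function(x) {
  x[1L] <- x[1L]
  x
}

flat_index <- function(vox, dims) {
  # vox: n x 3 matrix of 1-based coordinates -> 1-based flat index
  as.integer(vox[, 1] + dims[1] * ((vox[, 2] - 1) + dims[2] * (vox[, 3] - 1)))
}

#' Build a cellular Potts lattice from explicit voxel sets
#'
#' Constructs the voxel-to-cell-id map (`spin`) and the matching cell table.
#' Cell voxel sets must be disjoint, in bounds, and face-connected; violations
#' are rejected with an error naming the offending cell id.
#'
#' @param dims integer length-3 lattice size `(nx, ny, nz)`.
#' @param cells_spec list of cells, each a list with elements `id` (positive
#'   integer), `voxels` (n x 3 matrix of 1-based voxel coordinates) and
#'   optionally `kind` (default `"TUMOR"`) and `target_area` (default 25).
#' @return list with elements `lattice` (class `bnct_lattice`: `dims` and the
#'   integer `spin` array, 0 = medium) and `cells` (a [new_cell_table()]).
#' @examples
#' blk <- as.matrix(expand.grid(x = 2:6, y = 2:6, z = 1))
#' geo <- build_lattice(c(10, 10, 1), list(list(id = 1, voxels = blk)))
#' geo$cells$area  # 25
#' @export
build_lattice <- function(dims, cells_spec = list()) {
  dims <- as.integer(dims)
  if (length(dims) != 3L || any(dims < 1L)) stop("dims must be 3 positive integers")
  spin <- array(0L, dim = dims)
  ids <- vapply(cells_spec, function(cs) as.integer(cs$id), integer(1))
  if (anyDuplicated(ids)) stop("duplicate cell ids in cells_spec")
  kinds <- vapply(cells_spec, function(cs) {
    if (is.null(cs$kind)) "TUMOR" else as.character(cs$kind)
  }, character(1))
  tareas <- vapply(cells_spec, function(cs) {
    if (is.null(cs$target_area)) 25 else as.numeric(cs$target_area)
  }, numeric(1))
  areas <- integer(length(cells_spec))
  for (i in seq_along(cells_spec)) {
    cs <- cells_spec[[i]]
    vox <- as.matrix(cs$voxels)
    if (ncol(vox) != 3L) stop("voxels for cell ", ids[i], " must be an n x 3 matrix")
    if (any(vox < 1L) || any(vox[, 1] > dims[1]) || any(vox[, 2] > dims[2]) ||
        any(vox[, 3] > dims[3]))
      stop("cell ", ids[i], " has voxels outside the lattice dims")
    fi <- flat_index(vox, dims)
    if (anyDuplicated(fi)) stop("cell ", ids[i], " lists a voxel twice")
    clash <- spin[fi] != 0L
    if (any(clash))
      stop("cell ", ids[i], " overlaps cell ", spin[fi][clash][1])
    spin[fi] <- ids[i]
    areas[i] <- nrow(vox)
  }
  lattice <- structure(list(dims = dims, spin = spin), class = "bnct_lattice")
  cells <- new_cell_table(ids, kinds, areas, tareas)
  bad <- ids[!vapply(ids, function(id) cell_is_connected(lattice, id), logical(1))]
  if (length(bad))
    stop("cell ", bad[1], " is not a single face-connected component")
  list(lattice = lattice, cells = cells)
}

#' @export
print.bnct_lattice <- function(x, ...) {
  cat("<bnct_lattice> ", paste(x$dims, collapse = " x "),
      " voxels, ", length(unique(x$spin[x$spin > 0L])), " cells\n", sep = "")
  invisible(x)
}

#' Voxel coordinates of one cell
#' @param lattice a `bnct_lattice`.
#' @param id cell id.
#' @return n x 3 matrix of 1-based coordinates.
#' @export
cell_voxels <- function(lattice, id) {
  w <- which(lattice$spin == id)
  arrayInd(w, lattice$dims)
}

# Face-connectivity flood fill over one cell's voxel set.
cell_is_connected <- function(lattice, id) {
  w <- which(lattice$spin == id)
  if (length(w) == 0L) return(FALSE)
  if (length(w) == 1L) return(TRUE)
  dims <- lattice$dims
  inset <- logical(prod(dims))
  inset[w] <- TRUE
  seen <- logical(prod(dims))
  queue <- w[1]
  seen[queue] <- TRUE
  count <- 1L
  strides <- c(1L, dims[1], dims[1] * dims[2])
  coord <- arrayInd(w, dims)
  rownames(coord) <- as.character(w)
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
        count <- count + 1L
        queue <- c(queue, nb)
      }
    }
  }
  count == length(w)
}

#' Check lattice / cell-table consistency
#'
#' Verifies that every nonzero id in `spin` has a cell record and that each
#' record's `area` equals its voxel count.
#' @inheritParams cell_voxels
#' @param cells the matching cell table.
#' @return `TRUE` invisibly; errors otherwise.
#' @export
validate_state <- function(lattice, cells) {
  present <- unique(lattice$spin[lattice$spin > 0L])
  if (!all(present %in% cells$id))
    stop("spin contains id(s) with no cell record: ",
         paste(setdiff(present, cells$id), collapse = ", "))
  tab <- tabulate(lattice$spin[lattice$spin > 0L], nbins = max(cells$id, 1L))
  got <- tab[cells$id]
  if (!all(got == cells$area))
    stop("recorded area mismatch for cell(s): ",
         paste(cells$id[got != cells$area], collapse = ", "))
  invisible(TRUE)
}

# id-padded vectors for the C++ kernels: element [id + 1] describes cell id,
# element [1] the medium. Unused ids get area -1 so they are skipped.
pad_vectors <- function(cells) {
  max_id <- if (nrow(cells)) max(cells$id) else 0L
  kind_of <- integer(max_id + 1L)
  area <- rep(-1L, max_id + 1L)
  target <- numeric(max_id + 1L)
  kind_of[cells$id + 1L] <- kind_code(cells$kind)
  area[cells$id + 1L] <- cells$area
  area[1L] <- 0L
  target[cells$id + 1L] <- cells$target_area
  list(kind_of = kind_of, area = area, target = target, max_id = max_id)
}
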