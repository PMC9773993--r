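## Internal array helpers shared by the anatomy, solver and field modules.
## All grids are 3D arrays indexed [x, y, z], 0-based voxel indices in the
## physical mapping: coordinate = origin + (index + 0.5) * voxel_size.
## Axis convention: +x subject-left, +y dorsal, +z rostral.

## Voxel-centre coordinates along one axis (mm).
axis_centers <- function(n, origin, h) origin + (seq_len(n) - 0.5) * h

## Full coordinate arrays for a grid (memory: 3 doubles per voxel).
coord_arrays <- function(dim, origin, h) {
  list(
    x = array(rep(axis_centers(dim[1], origin[1], h), times = dim[2] * dim[3]), dim),
    y = array(rep(rep(axis_centers(dim[2], origin[2], h), each = dim[1]), times = dim[3]), dim),
    z = array(rep(axis_centers(dim[3], origin[3], h), each = dim[1] * dim[2]), dim)
  )
}

## Shift an array by one voxel along `axis` (1, 2 or 3); vacated voxels get
## `fill`. shift = +1 means result[i] = a[i - 1] (value moves towards higher
## index), so a_shifted aligned with a gives each voxel its lower neighbour.
shift_array <- function(a, axis, shift, fill = NA) {
  d <- dim(a)
  out <- array(fill, d)
  idx_src <- vector("list", 3)
  idx_dst <- vector("list", 3)
  for (k in 1:3) {
    idx_src[[k]] <- seq_len(d[k])
    idx_dst[[k]] <- seq_len(d[k])
  }
  n <- d[axis]
  if (abs(shift) >= n) return(out)
  if (shift > 0) {
    idx_src[[axis]] <- seq_len(n - shift)
    idx_dst[[axis]] <- seq_len(n - shift) + shift
  } else if (shift < 0) {
    idx_src[[axis]] <- seq_len(n + shift) - shift
    idx_dst[[axis]] <- seq_len(n + shift)
  }
  out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
    a[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
  out
}

## Mirror an array about the mid-sagittal plane (x axis reversed). With an
## even x-count and x-origin at -nx*h/2 the voxel centres map exactly onto
## each other.
mirror_x <- function(a) a[rev(seq_len(dim(a)[1])), , , drop = FALSE]

## Convert array index (1-based triple) to physical coordinate.
index_to_coord <- function(idx, origin, h) origin + (idx - 0.5) * h

## Nearest voxel index (1-based) for a physical coordinate; may fall outside.
coord_to_index <- function(coord, origin, h) as.integer(floor((coord - origin) / h) + 1L)

stop_spinefield <- function(msg, class) {
  rlang::abort(msg, class = c(class, "spinefield_error"))
}
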