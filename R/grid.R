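# Bay grid: rectilinear stand-in for an orthogonal curvilinear coastal mesh.
# Mask codes: 0 = land, 1 = sea (interior), 2 = open boundary.

MASK_LAND <- 0L
MASK_SEA <- 1L
MASK_OPEN <- 2L

#' Construct a bay grid
#'
#' A rectilinear grid for a depth-averaged coastal model: cell-centre
#' bathymetry, a land/sea/open-boundary mask and uniform cell geometry.
#'
#' @param H numeric matrix (`nx` x `ny`) of still-water depths (m); ignored
#'   (may be 0) on land cells.
#' @param dx,dy cell edge lengths (m) along and across the channel.
#' @param mask integer matrix (`nx` x `ny`): 0 land, 1 sea, 2 open boundary.
#' @return An object of class `bay_grid` with fields `nx`, `ny`, `dx`, `dy`,
#'   `H`, `mask` and `area` (uniform cell area, m^2).
#' @export
bay_grid <- function(H, dx, dy, mask) {
  if (!is.matrix(H) || !is.matrix(mask) || !all(dim(H) == dim(mask))) {
    .stopf("H and mask must be matrices with identical dimensions")
  }
  g <- structure(
    list(nx = nrow(H), ny = ncol(H), dx = dx, dy = dy,
         H = H, mask = mask, area = dx * dy),
    class = "bay_grid"
  )
  validate_bay_grid(g)
  g
}

#' @rdname bay_grid
#' @param grid a `bay_grid`.
#' @export
validate_bay_grid <- function(grid) {
  stopifnot(inherits(grid, "bay_grid"))
  if (!(grid$dx > 0 && grid$dy > 0)) .stopf("dx and dy must be positive")
  if (grid$area != grid$dx * grid$dy) .stopf("area must equal dx*dy")
  if (!all(grid$mask %in% c(MASK_LAND, MASK_SEA, MASK_OPEN))) {
    .stopf("mask values must be 0 (land), 1 (sea) or 2 (open boundary)")
  }
  wet <- grid$mask != MASK_LAND
  if (any(!is.finite(grid$H[wet])) || any(grid$H[wet] <= 0)) {
    .stopf("still-water depth H must be positive and finite on all wet cells")
  }
  open <- which(grid$mask == MASK_OPEN, arr.ind = TRUE)
  if (nrow(open) == 0) .stopf("at least one open-boundary cell is required")
  on_rim <- open[, 1] == 1 | open[, 1] == grid$nx |
    open[, 2] == 1 | open[, 2] == grid$ny
  if (!all(on_rim)) .stopf("open-boundary cells must lie on the grid perimeter")
  invisible(grid)
}

#' Build an idealized semi-closed narrow bay
#'
#' A rectangular channel closed on three sides with a single open boundary
#' (the mouth) along one short side.  Depth varies linearly from
#' `depth_mouth_m` at the mouth column (i = 1) to `depth_head_m` at the head
#' column (i = nx).
#'
#' @param nx,ny cell counts along-channel and cross-channel (both >= 3).
#' @param length_m,width_m basin length and width (m).
#' @param depth_head_m,depth_mouth_m still-water depth (m) at the head and
#'   mouth columns.
#' @return A [bay_grid()].
#' @examples
#' g <- build_idealized_bay(60, 20, 30e3, 6e3, 5, 25)
#' n_cells(g)
#' @export
build_idealized_bay <- function(nx, ny, length_m, width_m,
                                depth_head_m, depth_mouth_m) {
  nx <- as.integer(nx); ny <- as.integer(ny)
  if (nx < 3 || ny < 3) .stopf("nx and ny must both be at least 3")
  if (!(length_m > 0 && width_m > 0)) .stopf("length_m and width_m must be positive")
  if (!(depth_head_m > 0 && depth_mouth_m > 0)) {
    .stopf("depths must be positive")
  }
  dx <- length_m / nx
  dy <- width_m / ny
  prof <- depth_mouth_m + (depth_head_m - depth_mouth_m) *
    (seq_len(nx) - 1) / (nx - 1)
  H <- matrix(prof, nx, ny)
  mask <- matrix(MASK_SEA, nx, ny)
  mask[1, ] <- MASK_OPEN
  bay_grid(H, dx, dy, mask)
}

#' Grid cell helpers
#'
#' `n_cells` counts all grid cells; `sea_cells` returns a logical matrix of
#' wet interior cells; `open_cells` the open-boundary cells; `wet_cells` their
#' union.
#' @param grid a [bay_grid()].
#' @export
n_cells <- function(grid) grid$nx * grid$ny

#' @rdname n_cells
#' @export
sea_cells <- function(grid) grid$mask == MASK_SEA

#' @rdname n_cells
#' @export
open_cells <- function(grid) grid$mask == MASK_OPEN

#' @rdname n_cells
#' @export
wet_cells <- function(grid) grid$mask != MASK_LAND

#' @export
print.bay_grid <- function(x, ...) {
  wet <- wet_cells(x)
  cat(sprintf("<bay_grid> %d x %d cells (%.0f m x %.0f m each)\n",
              x$nx, x$ny, x$dx, x$dy))
  cat(sprintf("  depth range %.1f-%.1f m; %d sea, %d open-boundary, %d land cells\n",
              min(x$H[wet]), max(x$H[wet]),
              sum(sea_cells(x)), sum(open_cells(x)), sum(!wet)))
  invisible(x)
}
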