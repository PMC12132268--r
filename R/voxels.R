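# Voxel observation grids and the mesh <-> voxel interpolation contract.

#' Build an axis-aligned voxel grid covering a tissue domain
#'
#' The grid bounding box covers the mesh; voxel centers follow the
#' center-of-voxel convention `origin + (index + 0.5) * spacing` with 0-based
#' indices. A voxel is "inside" (unmasked) iff its center lies in some mesh
#' cell; only unmasked voxels are observed, and their count is the data
#' dimension `nd` used by the likelihood.
#'
#' @param domain A `tissue_domain`.
#' @param spacing_mm Voxel spacing in mm, a scalar or per-axis vector.
#' @return An object of class `voxel_grid` with fields `origin`, `spacing`,
#'   `shape`, `inside_mask` (logical array), `centers` (unmasked voxel-center
#'   coordinates), `B` (sparse interpolation matrix from mesh vertices to
#'   unmasked voxel centers), and `nd`.
#' @export
make_voxel_grid <- function(domain, spacing_mm) {
  stopifnot(inherits(domain, "tissue_domain"))
  d <- domain$dim
  spacing <- rep_len(as.numeric(spacing_mm), d)
  if (any(spacing <= 0)) stop("spacing must be strictly positive")
  lo <- apply(domain$vertices, 2, min)
  hi <- apply(domain$vertices, 2, max)
  if (any(spacing > (hi - lo))) stop("spacing larger than the domain extent")
  shape <- as.integer(ceiling((hi - lo) / spacing + 1e-12))
  origin <- lo - (shape * spacing - (hi - lo)) / 2   # center the grid on the mesh
  idx <- lapply(seq_len(d), function(k) seq_len(shape[k]) - 1L)
  grid_idx <- as.matrix(do.call(expand.grid, idx))
  centers <- sweep(sweep(grid_idx + 0.5, 2, spacing, `*`), 2, origin, `+`)
  loc <- locate_points(domain, centers, nearest = FALSE)
  inside <- !is.na(loc$cell)
  B <- interp_matrix_from_location(domain, loc, which(inside))
  structure(list(
    origin = origin, spacing = spacing, shape = shape,
    inside_mask = array(inside, dim = shape),
    index = grid_idx[inside, , drop = FALSE],
    centers = centers[inside, , drop = FALSE],
    B = B, nd = sum(inside),
    mesh_signature = mesh_signature(domain)
  ), class = "voxel_grid")
}

mesh_signature <- function(domain) {
  c(nrow(domain$vertices), nrow(domain$cells), sum(domain$vertices^2))
}

check_grid_domain <- function(grid, domain) {
  if (!isTRUE(all.equal(grid$mesh_signature, mesh_signature(domain)))) {
    stop("voxel grid was not built for this mesh")
  }
}

# Locate points in the mesh: returns containing cell and barycentric weights.
# Uses a uniform spatial hash of the points so each cell only tests nearby
# candidates. Points in no cell get cell = NA (or the nearest cell with
# clamped weights when nearest = TRUE).
locate_points <- function(domain, pts, nearest = FALSE, tol = 1e-9) {
  d <- domain$dim
  pts <- matrix(as.numeric(pts), ncol = d)
  np <- nrow(pts)
  cells <- domain$cells; verts <- domain$vertices
  M <- nrow(cells); nvp <- d + 1L
  lo <- apply(verts, 2, min); hi <- apply(verts, 2, max)
  hbin <- max(domain$h, (max(hi - lo)) / 64)
  nb <- pmax(1L, as.integer(ceiling((hi - lo) / hbin)))
  binof <- function(x) {
    ix <- pmin(pmax(floor(sweep(sweep(x, 2, lo), 2, (hi - lo) / nb, `/`)), 0), nb - 1L)
    idx <- ix[, 1]
    if (d >= 2) idx <- idx + nb[1] * ix[, 2]
    if (d >= 3) idx <- idx + nb[1] * nb[2] * ix[, 3]
    as.integer(idx) + 1L
  }
  pts_in <- pts
  # clamp points slightly outside the bbox into it for binning only
  for (k in seq_len(d)) pts_in[, k] <- pmin(pmax(pts[, k], lo[k]), hi[k])
  pbin <- binof(pts_in)
  bins <- split(seq_len(np), pbin)
  cell_assign <- rep(NA_integer_, np)
  lam <- matrix(NA_real_, np, nvp)
  v0 <- verts[cells[, 1], , drop = FALSE]
  for (e in seq_len(M)) {
    X <- verts[cells[e, ], , drop = FALSE]
    elo <- apply(X, 2, min) - 1e-9; ehi <- apply(X, 2, max) + 1e-9
    # enumerate bins overlapped by the cell bbox
    rng <- lapply(seq_len(d), function(k) {
      a <- floor((elo[k] - lo[k]) / ((hi[k] - lo[k]) / nb[k]))
      b <- floor((ehi[k] - lo[k]) / ((hi[k] - lo[k]) / nb[k]))
      seq(max(0, a), min(nb[k] - 1L, b))
    })
    bb <- as.matrix(do.call(expand.grid, rng))
    bidx <- bb[, 1]
    if (d >= 2) bidx <- bidx + nb[1] * bb[, 2]
    if (d >= 3) bidx <- bidx + nb[1] * nb[2] * bb[, 3]
    cand <- unlist(bins[as.character(as.integer(bidx) + 1L)], use.names = FALSE)
    cand <- cand[is.na(cell_assign[cand])]
    if (!length(cand)) next
    dx <- pts[cand, , drop = FALSE] - rep(1, length(cand)) %o% v0[e, ]
    lb <- dx %*% t(matrix(domain$fem$Tinv[e, , ], d, d))   # lambda_{2..d+1}
    l0 <- 1 - rowSums(lb)
    ok <- l0 >= -tol & apply(lb >= -tol, 1, all)
    if (any(ok)) {
      hit <- cand[ok]
      cell_assign[hit] <- e
      lam[hit, ] <- cbind(l0[ok], lb[ok, , drop = FALSE])
    }
  }
  if (nearest && anyNA(cell_assign)) {
    missing <- which(is.na(cell_assign))
    cent <- t(vapply(seq_len(M), function(e) colMeans(verts[cells[e, ], , drop = FALSE]),
                     numeric(d)))
    for (p in missing) {
      e <- which.min(rowSums(sweep(cent, 2, pts[p, ])^2))
      dx <- pts[p, ] - v0[e, ]
      lb <- as.numeric(matrix(domain$fem$Tinv[e, , ], d, d) %*% dx)
      l <- c(1 - sum(lb), lb)
      l <- pmax(l, 0); l <- l / sum(l)
      cell_assign[p] <- e
      lam[p, ] <- l
    }
  }
  list(cell = cell_assign, lambda = lam)
}

interp_matrix_from_location <- function(domain, loc, rows) {
  nvp <- domain$dim + 1L
  n <- nrow(domain$vertices)
  if (!length(rows)) {
    return(Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                dims = c(0L, n)))
  }
  cellv <- domain$cells[loc$cell[rows], , drop = FALSE]
  Matrix::sparseMatrix(
    i = rep(seq_along(rows), nvp),
    j = as.vector(cellv),
    x = as.vector(loc$lambda[rows, , drop = FALSE]),
    dims = c(length(rows), n)
  )
}

# Sparse P1 interpolation matrix from mesh vertices to arbitrary points.
interp_matrix <- function(domain, pts, nearest = FALSE) {
  loc <- locate_points(domain, pts, nearest = nearest)
  if (anyNA(loc$cell)) stop("some points lie outside the mesh (set nearest = TRUE to clamp)")
  interp_matrix_from_location(domain, loc, seq_len(nrow(as.matrix(pts))))
}

#' Interpolate a nodal field onto the voxel grid
#'
#' Piecewise-linear (P1) interpolation of a nodal field at unmasked voxel
#' centers; masked voxels carry `NA`. Linear functions are reproduced exactly.
#'
#' @param field Numeric vector with one value per mesh vertex.
#' @param grid A `voxel_grid` built with [make_voxel_grid()] on the same mesh.
#' @param domain The `tissue_domain` the field lives on (used for validation).
#' @return A numeric array of the grid shape, `NA` outside the domain.
#' @export
fem_to_voxels <- function(field, grid, domain = NULL) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (!is.null(domain)) check_grid_domain(grid, domain)
  if (length(field) != ncol(grid$B)) stop("field length does not match the grid's mesh")
  out <- array(NA_real_, dim = grid$shape)
  out[grid$inside_mask] <- as.numeric(grid$B %*% field)
  out
}

# Unmasked-voxel observation vector (length nd) of a nodal field.
voxel_values <- function(field, grid) as.numeric(grid$B %*% field)

#' Estimate a nodal field from voxel data
#'
#' Multilinear interpolation of a voxel image at mesh vertex positions, used
#' to set initial states from (noisy) voxel observations. Masked / missing
#' voxels are ignored with renormalized weights; vertices with no informative
#' neighbor get 0.
#'
#' @param values Numeric array of the grid shape (or a length-`nd` vector of
#'   unmasked-voxel values).
#' @param grid A `voxel_grid`.
#' @param domain The target `tissue_domain`.
#' @return Numeric vector with one value per mesh vertex.
#' @export
voxels_to_fem <- function(values, grid, domain) {
  d <- domain$dim
  arr <- if (length(values) == grid$nd) {
    a <- array(NA_real_, grid$shape); a[grid$inside_mask] <- as.numeric(values); a
  } else array(as.numeric(values), grid$shape)
  verts <- domain$vertices
  # fractional voxel coordinates of each vertex (0-based cell-center convention)
  fc <- sweep(sweep(verts, 2, grid$origin), 2, grid$spacing, `/`) - 0.5
  i0 <- floor(fc); w1 <- fc - i0
  out <- numeric(nrow(verts)); wsum <- numeric(nrow(verts))
  corners <- as.matrix(do.call(expand.grid, rep(list(0:1), d)))
  for (r in seq_len(nrow(corners))) {
    off <- corners[r, ]
    idx <- sweep(i0, 2, off, `+`)
    w <- rep(1, nrow(verts))
    for (k in seq_len(d)) w <- w * (if (off[k] == 1) w1[, k] else 1 - w1[, k])
    ok <- rep(TRUE, nrow(verts))
    for (k in seq_len(d)) ok <- ok & idx[, k] >= 0 & idx[, k] < grid$shape[k]
    lin <- rep(1L, nrow(verts))
    mult <- 1L
    for (k in seq_len(d)) {
      lin <- lin + as.integer(idx[, k]) * mult
      mult <- mult * grid$shape[k]
    }
    val <- rep(NA_real_, nrow(verts))
    val[ok] <- arr[lin[ok]]
    use <- ok & !is.na(val) & w > 0
    out[use] <- out[use] + w[use] * val[use]
    wsum[use] <- wsum[use] + w[use]
  }
  ifelse(wsum > 0, out / wsum, 0)
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid> shape %s, spacing %s mm, nd = %d unmasked voxels\n",
              paste(x$shape, collapse = "x"),
              paste(signif(x$spacing, 3), collapse = "x"), x$nd))
  invisible(x)
}

#' Write a mesh to a legacy VTK (ASCII) file
#'
#' Unstructured-grid export with the tissue label and any number of nodal
#' fields attached as point data, for inspection in standard mesh viewers.
#'
#' @param domain A `tissue_domain`.
#' @param file Output path.
#' @param fields Named list of nodal fields to attach.
#' @export
write_mesh_vtk <- function(domain, file, fields = list()) {
  v <- domain$vertices
  if (ncol(v) == 2) v <- cbind(v, 0)
  cells <- domain$cells - 1L
  nvp <- domain$dim + 1L
  con <- file(file, "w"); on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "gliomatwin mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", nrow(v))), con)
  utils::write.table(v, con, row.names = FALSE, col.names = FALSE)
  writeLines(sprintf("CELLS %d %d", nrow(cells), nrow(cells) * (nvp + 1L)), con)
  utils::write.table(cbind(nvp, cells), con, row.names = FALSE, col.names = FALSE)
  writeLines(sprintf("CELL_TYPES %d", nrow(cells)), con)
  writeLines(as.character(rep(if (nvp == 3L) 5L else 10L, nrow(cells))), con)
  writeLines(sprintf("POINT_DATA %d", nrow(v)), con)
  fields <- c(list(tissue = as.numeric(domain$tissue)), fields)
  for (nm in names(fields)) {
    writeLines(c(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default"), con)
    writeLines(format(fields[[nm]], digits = 10), con)
  }
  invisible(file)
}

#' Write a voxel array as NIfTI
#'
#' Thin wrapper over the RNifti package for interoperability with medical
#' imaging tools; voxel spacing is recorded in the header.
#'
#' @param values Array of the grid shape (e.g. from [fem_to_voxels()]).
#' @param grid The `voxel_grid`.
#' @param file Output path (`.nii` / `.nii.gz`).
#' @export
write_voxels_nifti <- function(values, grid, file) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop("RNifti is required for NIfTI export")
  }
  arr <- array(as.numeric(values), grid$shape)
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- grid$spacing
  RNifti::writeNifti(img, file)
  invisible(file)
}
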