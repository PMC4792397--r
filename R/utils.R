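#' Neighborhood offsets on a 3-D grid
#'
#' Returns the integer offsets of a voxel's neighborhood, including the
#' center voxel itself. The 27-voxel neighborhood (center + 26 face, edge
#' and corner neighbors) is the convention used for ReHo; 7 and 19
#' restrict to face and face+edge neighbors.
#'
#' @param n One of 7, 19, 27 (center voxel included in the count).
#' @return An integer matrix with one row per offset and columns dx, dy, dz.
#' @keywords internal
neighborhood_offsets <- function(n = 27) {
  if (!n %in% c(7L, 19L, 27L)) {
    stop("neighborhood size must be 7, 19 or 27")
  }
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  dist2 <- rowSums(g^2)
  keep <- switch(as.character(n),
    "7"  = dist2 <= 1,
    "19" = dist2 <= 2,
    "27" = dist2 <= 3
  )
  g[keep, , drop = FALSE]
}

#' Linear indices of in-mask voxels
#' @param mask logical or 0/1 3-D array
#' @return integer vector of linear indices into the 3-D grid
#' @keywords internal
mask_indices <- function(mask) {
  which(as.logical(mask))
}

#' Convert linear grid indices to x,y,z coordinates
#' @keywords internal
index_to_coord <- function(idx, dim3) {
  cbind(
    x = ((idx - 1L) %% dim3[1]) + 1L,
    y = ((idx - 1L) %/% dim3[1]) %% dim3[2] + 1L,
    z = ((idx - 1L) %/% (dim3[1] * dim3[2])) + 1L
  )
}

#' Convert x,y,z coordinates to linear grid indices
#' @keywords internal
coord_to_index <- function(coord, dim3) {
  coord <- matrix(as.integer(coord), ncol = 3)
  as.integer(coord[, 1] + (coord[, 2] - 1L) * dim3[1] +
    (coord[, 3] - 1L) * dim3[1] * dim3[2])
}

#' Sparse neighbor-adjacency over an in-mask voxel set
#'
#' Builds the voxel x voxel sparse 0/1 matrix A with A[i, j] = 1 when
#' in-mask voxel j lies in the neighborhood of in-mask voxel i (the
#' center voxel is its own neighbor). Column sums give the effective
#' neighborhood size K of each voxel at mask edges.
#'
#' @param mask 3-D binary array
#' @param n neighborhood size (7, 19, 27)
#' @return list(adj = sparse matrix voxels x voxels, idx = linear indices)
#' @keywords internal
mask_adjacency <- function(mask, n = 27) {
  dim3 <- dim(mask)
  idx <- mask_indices(mask)
  if (length(idx) == 0L) stop("mask is empty")
  pos <- integer(prod(dim3))
  pos[idx] <- seq_along(idx)
  off <- neighborhood_offsets(n)
  coords <- index_to_coord(idx, dim3)
  ii <- jj <- vector("list", nrow(off))
  for (k in seq_len(nrow(off))) {
    shifted <- sweep(coords, 2L, off[k, ], "+")
    ok <- shifted[, 1] >= 1L & shifted[, 1] <= dim3[1] &
      shifted[, 2] >= 1L & shifted[, 2] <= dim3[2] &
      shifted[, 3] >= 1L & shifted[, 3] <= dim3[3]
    lin <- coord_to_index(shifted[ok, , drop = FALSE], dim3)
    inmask <- pos[lin] > 0L
    ii[[k]] <- which(ok)[inmask]
    jj[[k]] <- pos[lin[inmask]]
  }
  adj <- Matrix::sparseMatrix(
    i = unlist(jj), j = unlist(ii),
    x = 1, dims = c(length(idx), length(idx))
  )
  list(adj = adj, idx = idx)
}

#' Connected components of a voxel set on the grid
#'
#' Labels the connected components of a set of voxels (linear indices)
#' under 6, 18 or 26 connectivity and returns component sizes and
#' memberships, largest first.
#'
#' @param idx linear indices of suprathreshold voxels
#' @param dim3 grid dimensions
#' @param connectivity 6 (faces), 18 (faces+edges) or 26 (all)
#' @return list of integer vectors of linear indices, sorted by decreasing size
#' @keywords internal
connected_components <- function(idx, dim3, connectivity = 26) {
  if (length(idx) == 0L) return(list())
  nn <- switch(as.character(connectivity), "6" = 7L, "18" = 19L, "26" = 27L,
    stop("connectivity must be 6, 18 or 26"))
  pos <- integer(prod(dim3))
  pos[idx] <- seq_along(idx)
  off <- neighborhood_offsets(nn)
  off <- off[rowSums(abs(off)) > 0L, , drop = FALSE]
  coords <- index_to_coord(idx, dim3)
  ei <- ej <- vector("list", nrow(off))
  for (k in seq_len(nrow(off))) {
    shifted <- sweep(coords, 2L, off[k, ], "+")
    ok <- shifted[, 1] >= 1L & shifted[, 1] <= dim3[1] &
      shifted[, 2] >= 1L & shifted[, 2] <= dim3[2] &
      shifted[, 3] >= 1L & shifted[, 3] <= dim3[3]
    lin <- coord_to_index(shifted[ok, , drop = FALSE], dim3)
    hit <- pos[lin] > 0L
    ei[[k]] <- which(ok)[hit]
    ej[[k]] <- pos[lin[hit]]
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = unlist(ei), to = unlist(ej)),
    directed = FALSE,
    vertices = data.frame(name = seq_along(idx))
  )
  comp <- igraph::components(g)
  out <- split(idx, comp$membership)
  out[order(lengths(out), decreasing = TRUE)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
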