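#' Surface area of a triangle mesh
#'
#' Sum over faces of half the magnitude of the edge cross product,
#' \eqn{\sum_f \tfrac12 \lVert (b-a)\times(c-a) \rVert}. Units are the square
#' of the vertex coordinate unit.
#'
#' @param mesh a [tri_mesh()].
#' @return scalar surface area.
#' @export
surface_area <- function(mesh) {
  if (nrow(mesh$faces) == 0L) return(0)
  sum(face_areas_raw(mesh$vertices, mesh$faces))
}

#' Enclosed volume of a watertight mesh
#'
#' Divergence-theorem volume \eqn{\sum_f a\cdot(b\times c)/6} over outward
#' oriented faces. The mesh must be watertight: every edge shared by exactly
#' two consistently wound faces. For open meshes the volume of a segment is
#' undefined and the function refuses by default; `force = TRUE` returns the
#' absolute raw signed sum with a warning instead.
#'
#' @param mesh a [tri_mesh()].
#' @param force return the raw signed integral (as an absolute value, with a
#'   warning) even when the mesh is open.
#' @return scalar volume, always non-negative.
#' @export
enclosed_volume <- function(mesh, force = FALSE) {
  wt <- is_watertight(mesh)
  if (!wt) {
    if (!force)
      stop("open mesh: ", attr(wt, "boundary_edges"),
           " boundary edge(s); volume undefined (use force = TRUE for the raw integral)")
    warning("open mesh: returning |raw signed volume| of ",
            attr(wt, "boundary_edges"), " boundary-edge mesh")
  }
  abs(signed_volume_raw(mesh$vertices, mesh$faces))
}

#' Area-weighted surface centroid
#'
#' Mean of face centroids weighted by face area; a deterministic, landmark
#' free anchor point used e.g. as the default fixed point of
#' [angular_distribution()].
#'
#' @param mesh a [tri_mesh()].
#' @return numeric length-3 point.
#' @export
mesh_centroid <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  ar <- face_areas_raw(v, f)
  cen <- (v[f[, 1L], , drop = FALSE] + v[f[, 2L], , drop = FALSE] +
            v[f[, 3L], , drop = FALSE]) / 3
  colSums(cen * ar) / sum(ar)
}

#' Split a mesh into connected components
#'
#' Partitions faces by vertex connectivity. Vertices are re-indexed per
#' component; components are ordered by descending face count, ties broken by
#' the index of their first face.
#'
#' @param mesh a [tri_mesh()].
#' @return list of [tri_mesh()], names `<mesh name>_1`, `_2`, ...
#' @export
connected_components <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  if (nrow(f) == 0L) return(list())
  g <- igraph::graph_from_edgelist(face_edges(f), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, nrow(v) - igraph::vcount(g)))
  memb <- igraph::components(g)$membership
  fc <- memb[f[, 1L]]            # all three vertices share a component
  comp_ids <- unique(fc)
  first_face <- vapply(comp_ids, function(ci) min(which(fc == ci)), integer(1))
  n_faces <- vapply(comp_ids, function(ci) sum(fc == ci), integer(1))
  ord <- order(-n_faces, first_face)
  comp_ids <- comp_ids[ord]
  out <- vector("list", length(comp_ids))
  for (k in seq_along(comp_ids)) {
    rows <- fc == comp_ids[k]
    fsub <- f[rows, , drop = FALSE]
    used <- sort(unique(as.vector(fsub)))
    remap <- integer(nrow(v)); remap[used] <- seq_along(used)
    out[[k]] <- tri_mesh(v[used, , drop = FALSE],
                         matrix(remap[fsub], ncol = 3L),
                         name = sprintf("%s_%d", mesh$name, k),
                         provenance = mesh$provenance,
                         drop_degenerate = FALSE)
  }
  out
}

#' Measure a batch of meshes
#'
#' One row per mesh: surface area, enclosed volume (absent with a warning
#' code when the mesh is open), connected-component count, watertight flag
#' and the area-weighted surface centroid. Row order equals input order, so
#' the table is directly CSV-serializable for reports.
#'
#' @param meshes a [tri_mesh()] or list of them.
#' @return tibble with columns `name`, `surface_area`, `volume`,
#'   `components`, `watertight`, `centroid_x/y/z`, `note`.
#' @export
measure <- function(meshes) {
  if (inherits(meshes, "tri_mesh")) meshes <- list(meshes)
  if (length(meshes) == 0L) stop("no meshes to measure")
  rows <- lapply(meshes, function(m) {
    wt <- is_watertight(m)
    vol <- if (wt) enclosed_volume(m) else NA_real_
    cen <- mesh_centroid(m)
    tibble::tibble(
      name = m$name,
      surface_area = surface_area(m),
      volume = vol,
      components = length(unique(igraph::components(
        igraph::graph_from_edgelist(face_edges(m$faces), directed = FALSE)
      )$membership[m$faces[, 1L]])),
      watertight = as.logical(wt),
      centroid_x = cen[1L], centroid_y = cen[2L], centroid_z = cen[3L],
      note = if (wt) "" else
        sprintf("open_mesh:%d_boundary_edges", attr(wt, "boundary_edges"))
    )
  })
  do.call(rbind, rows)
}

#' @method glance tri_mesh
#' @export
glance.tri_mesh <- function(x, ...) {
  measure(list(x))[, c("name", "surface_area", "volume", "components",
                       "watertight")]
}

#' @method tidy tri_mesh
#' @export
tidy.tri_mesh <- function(x, ...) {
  v <- x$vertices
  tibble::tibble(
    vertex = seq_len(nrow(v)),
    x = v[, 1L], y = v[, 2L], z = v[, 3L]
  )
}
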