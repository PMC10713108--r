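#' Snap a point to the nearest mesh vertex
#'
#' Replaces interactive surface picking: the returned `surface_point` records
#' the snapped vertex index, the raw query point and the snap distance (so a
#' bad pick is detectable). Ties go to the lowest vertex index.
#'
#' @param mesh a [tri_mesh()].
#' @param p numeric length-3 query point.
#' @return a `surface_point`.
#' @export
snap_to_surface <- function(mesh, p) {
  v <- mesh$vertices
  if (nrow(v) == 0L) stop("empty mesh")
  d2 <- (v[, 1L] - p[1L])^2 + (v[, 2L] - p[2L])^2 + (v[, 3L] - p[3L])^2
  i <- which.min(d2)                      # first minimum = lowest index
  structure(list(mesh_name = mesh$name, vertex_index = i,
                 point = v[i, ], raw_point = as.numeric(p),
                 snap_distance = sqrt(d2[i])),
            class = "surface_point")
}

#' @export
print.surface_point <- function(x, ...) {
  cat(sprintf("<surface_point> %s vertex %d (snap %.4g)\n",
              x$mesh_name, x$vertex_index, x$snap_distance))
  invisible(x)
}

as_surface_point <- function(mesh, p) {
  if (inherits(p, "surface_point")) p else snap_to_surface(mesh, p)
}

#' Straight-line distance between two surface points
#'
#' Conventional Euclidean distance through space between the snapped vertex
#' positions; the two points may live on different meshes.
#'
#' @param a,b `surface_point`s (see [snap_to_surface()]).
#' @return scalar distance.
#' @export
straight_distance <- function(a, b) {
  sqrt(sum((a$point - b$point)^2))
}

#' On-surface (geodesic-graph) distance between two surface points
#'
#' Shortest path over the mesh's undirected vertex-edge graph with Euclidean
#' edge lengths as weights (Dijkstra). The graph distance is an upper bound
#' on the true surface geodesic, since paths are restricted to mesh edges.
#' Returns the straight distance, the surface distance and the vertex path
#' realizing it.
#'
#' @param mesh a [tri_mesh()].
#' @param a,b `surface_point`s on `mesh`, or raw 3D points (snapped first).
#' @return list with `straight`, `surface`, `path` (vertex indices), class
#'   `distance_result`.
#' @export
surface_distance <- function(mesh, a, b) {
  a <- as_surface_point(mesh, a)
  b <- as_surface_point(mesh, b)
  g <- mesh_edge_graph(mesh)
  if (a$vertex_index == b$vertex_index) {
    res <- list(straight = 0, surface = 0, path = a$vertex_index)
    class(res) <- "distance_result"
    return(res)
  }
  # unreachable targets are detected below; igraph's own warning is redundant
  sp <- suppressWarnings(
    igraph::shortest_paths(g, from = a$vertex_index, to = b$vertex_index,
                           weights = igraph::E(g)$weight, output = "vpath"))
  path <- as.integer(sp$vpath[[1L]])
  if (length(path) < 2L) {
    memb <- igraph::components(g)$membership
    stop(sprintf("vertices %d and %d are unreachable (components %d and %d)",
                 a$vertex_index, b$vertex_index,
                 memb[a$vertex_index], memb[b$vertex_index]))
  }
  seg <- mesh$vertices[path[-1L], , drop = FALSE] -
    mesh$vertices[path[-length(path)], , drop = FALSE]
  res <- list(straight = straight_distance(a, b),
              surface = sum(sqrt(rowSums(seg^2))),
              path = path)
  class(res) <- "distance_result"
  res
}

#' @export
print.distance_result <- function(x, ...) {
  cat(sprintf("<distance_result> straight %.6g, surface %.6g (%d path vertices)\n",
              x$straight, x$surface, length(x$path)))
  invisible(x)
}

# undirected vertex-edge graph with Euclidean weights (deduplicated edges)
mesh_edge_graph <- function(mesh) {
  ed <- face_edges(mesh$faces)
  key <- edge_keys(ed)
  ed <- ed[!duplicated(key), , drop = FALSE]
  w <- sqrt(rowSums((mesh$vertices[ed[, 1L], , drop = FALSE] -
                       mesh$vertices[ed[, 2L], , drop = FALSE])^2))
  g <- igraph::make_graph(t(ed), n = nrow(mesh$vertices), directed = FALSE)
  igraph::E(g)$weight <- w
  g
}
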