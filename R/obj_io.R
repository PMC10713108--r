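#' Read a Wavefront OBJ file
#'
#' Parses the geometry-bearing records of an ASCII OBJ file into a
#' [tri_mesh()]. Polygon faces are fan-triangulated from their first vertex,
#' 1-based OBJ indices become the internal indexing, negative (relative)
#' indices are resolved against the vertices defined so far, and `vt`/`vn`
#' components of face tokens (`i/t`, `i//n`, `i/t/n`) are discarded. `o`/`g`
#' names attach to the mesh name. Material, texture and normal records do not
#' affect geometry. After parsing, winding is made consistent and closed
#' components are oriented outward (see [orient_mesh()]).
#'
#' @param path path to an `.obj` file.
#' @param name mesh name; defaults to the first `o`/`g` record, else the
#'   file stem.
#' @param orient make winding consistent and volumes non-negative (default
#'   `TRUE`).
#' @return a [tri_mesh()].
#' @export
read_obj <- function(path, name = NULL, orient = TRUE) {
  if (!file.exists(path)) stop("OBJ file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  toks <- strsplit(trimws(lines), "[ \t]+")
  verts <- vector("list", length(toks))
  nv <- 0L
  tris <- vector("list", length(toks))
  nt <- 0L
  obj_name <- NULL
  for (li in seq_along(toks)) {
    tk <- toks[[li]]
    if (length(tk) == 0L || tk[1L] == "") next
    rec <- tk[1L]
    if (rec == "v") {
      if (length(tk) < 4L) stop("malformed vertex at line ", li)
      xyz <- suppressWarnings(as.numeric(tk[2:4]))
      if (any(is.na(xyz))) stop("non-numeric vertex at line ", li)
      nv <- nv + 1L
      verts[[nv]] <- xyz
    } else if (rec == "f") {
      if (length(tk) < 4L) stop("face with fewer than 3 vertices at line ", li)
      idx_txt <- sub("/.*$", "", tk[-1L])
      idx <- suppressWarnings(as.integer(idx_txt))
      if (any(is.na(idx))) stop("malformed face token at line ", li)
      idx <- ifelse(idx < 0L, nv + idx + 1L, idx)  # relative indices
      if (any(idx < 1L | idx > nv))
        stop("face index out of range at line ", li)
      # fan triangulation from the first vertex
      k <- length(idx)
      for (j in 2:(k - 1L)) {
        nt <- nt + 1L
        tris[[nt]] <- idx[c(1L, j, j + 1L)]
      }
    } else if (rec %in% c("o", "g") && length(tk) >= 2L && is.null(obj_name)) {
      obj_name <- tk[2L]
    }
  }
  if (nv == 0L) stop("no vertices in OBJ file: ", path)
  if (nt == 0L) stop("no faces in OBJ file: ", path)
  if (is.null(name))
    name <- if (!is.null(obj_name)) obj_name else
      sub("\\.[^.]*$", "", basename(path))
  m <- tri_mesh(
    do.call(rbind, verts[seq_len(nv)]),
    do.call(rbind, tris[seq_len(nt)]),
    name = name, provenance = path
  )
  if (orient) m <- orient_mesh(m)
  m
}

#' Write a triangle mesh as Wavefront OBJ
#'
#' Writes one `o <name>` record, vertex lines with 9 significant digits, and
#' 1-based `f i j k` lines. The output is parseable by [read_obj()] and the
#' face list round-trips exactly.
#'
#' @param mesh a [tri_mesh()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_obj <- function(mesh, path) {
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot open for writing: ", path))
  on.exit(close(con))
  writeLines(sprintf("o %s", mesh$name), con)
  v <- mesh$vertices
  writeLines(sprintf("v %.9g %.9g %.9g", v[, 1L], v[, 2L], v[, 3L]), con)
  f <- mesh$faces
  if (nrow(f) > 0L)
    writeLines(sprintf("f %d %d %d", f[, 1L], f[, 2L], f[, 3L]), con)
  invisible(path)
}

#' Import every OBJ file in a folder
#'
#' Reads all `*.obj` files (case-insensitive extension) in lexicographic
#' filename order, naming each mesh after its file stem. Unreadable files are
#' skipped with a warning rather than aborting the batch; skipped filenames
#' are recorded in the `skipped` attribute of the returned list.
#'
#' @param folder directory path.
#' @param orient passed to [read_obj()].
#' @return list of [tri_mesh()] with attribute `skipped` (character vector of
#'   filenames that failed to parse).
#' @export
bulk_import <- function(folder, orient = TRUE) {
  if (!dir.exists(folder)) stop("folder not found: ", folder)
  files <- list.files(folder, pattern = "\\.obj$", ignore.case = TRUE,
                      full.names = TRUE)
  files <- files[order(basename(files))]
  meshes <- list()
  skipped <- character()
  for (fp in files) {
    stem <- sub("\\.[^.]*$", "", basename(fp))
    m <- tryCatch(read_obj(fp, name = stem, orient = orient),
                  error = function(e) {
                    warning("skipping ", basename(fp), ": ",
                            conditionMessage(e), call. = FALSE)
                    NULL
                  })
    if (!is.null(m)) meshes[[stem]] <- m else skipped <- c(skipped, basename(fp))
  }
  structure(meshes, skipped = skipped)
}
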