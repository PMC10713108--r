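#' Write a skeleton in SWC format
#'
#' Standard morphology interchange rows `id type x y z radius parent` with
#' 1-based ids, parent -1 for roots and children after parents (topological
#' order per component). The type field is written as 0 (undefined).
#'
#' @param sk a [skeleton3d()]; must be a forest (tree per component).
#' @param path output path.
#' @param header optional comment lines (written with a leading `#`).
#' @return `path`, invisibly.
#' @export
write_swc <- function(sk, path, header = character()) {
  n <- nrow(sk$nodes)
  if (n == 0L) {
    writeLines(paste0("# ", c(header, "empty skeleton")), path)
    return(invisible(path))
  }
  g <- igraph::make_graph(t(sk$edges), n = n, directed = FALSE)
  comps <- igraph::components(g)
  if (nrow(sk$edges) != n - comps$no)
    stop("skeleton graph is not a forest; cannot serialize as SWC")
  order_out <- integer(0)
  parent_of <- rep(-1L, n)
  for (ci in seq_len(comps$no)) {
    members <- which(comps$membership == ci)
    root <- intersect(sk$roots, members)
    root <- if (length(root)) root[1L] else members[1L]
    bfs <- igraph::bfs(g, root = root, unreachable = FALSE, father = TRUE)
    ord <- as.integer(bfs$order)
    ord <- ord[!is.na(ord)]
    fa <- as.integer(bfs$father)
    parent_of[ord] <- ifelse(is.na(fa[ord]) | fa[ord] == 0L, -1L, fa[ord])
    order_out <- c(order_out, ord)
  }
  id_new <- integer(n)
  id_new[order_out] <- seq_len(n)
  par <- parent_of[order_out]
  par_id <- ifelse(par == -1L, -1L, id_new[pmax(par, 1L)])
  lines <- c(paste0("# ", header),
             sprintf("%d 0 %.9g %.9g %.9g %.9g %d",
                     seq_len(n),
                     sk$nodes[order_out, 1L], sk$nodes[order_out, 2L],
                     sk$nodes[order_out, 3L], sk$radius[order_out],
                     par_id))
  writeLines(lines, path)
  invisible(path)
}

#' Read an SWC skeleton
#'
#' @param path SWC file path.
#' @return a [skeleton3d()]; roots are the parent `-1` rows.
#' @export
read_swc <- function(path) {
  if (!file.exists(path)) stop("SWC file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L)
    return(skeleton3d(matrix(0, 0L, 3L), numeric(), matrix(0L, 0L, 2L)))
  fields <- do.call(rbind, lapply(strsplit(lines, "[ \t]+"), function(tk) {
    if (length(tk) < 7L) stop("malformed SWC row")
    as.numeric(tk[1:7])
  }))
  ids <- as.integer(fields[, 1L])
  row_of <- integer(max(ids)); row_of[ids] <- seq_along(ids)
  parents <- as.integer(fields[, 7L])
  has_parent <- parents > 0L
  edges <- cbind(row_of[ids[has_parent]], row_of[parents[has_parent]])
  skeleton3d(fields[, 3:5, drop = FALSE], fields[, 6L],
             if (nrow(edges)) edges else matrix(0L, 0L, 2L),
             roots = which(!has_parent))
}
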