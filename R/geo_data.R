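#' Construct an area map
#'
#' An `area_map` is the spatial support shared by the hierarchical model and
#' the scan statistic: an ordered set of area identifiers, one centroid
#' (longitude, latitude, decimal degrees) per area, and a symmetric adjacency
#' structure. Connected components of the adjacency graph are labelled at
#' construction time; islands (areas with no neighbours) are permitted and
#' form their own components.
#'
#' @param area_ids character vector of unique area identifiers (file order is
#'   the canonical internal order).
#' @param centroids numeric matrix or data frame with one row per area and
#'   columns longitude, latitude (decimal degrees).
#' @param neighbors list (one element per area) of character vectors of
#'   neighbouring area ids. One-directional entries are symmetrized with a
#'   warning; self-neighbours are an error.
#' @return An object of class `area_map`: list with `area_ids`, `centroids`
#'   (n x 2 matrix, columns `lon`, `lat`), `neighbors` (list of character
#'   vectors), `component` (integer component label per area) and
#'   `n_components`.
#' @export
area_map <- function(area_ids, centroids, neighbors) {
  area_ids <- as.character(area_ids)
  if (anyDuplicated(area_ids)) {
    stop("duplicate area id(s): ",
         paste(unique(area_ids[duplicated(area_ids)]), collapse = ", "))
  }
  centroids <- as.matrix(centroids)
  storage.mode(centroids) <- "double"
  if (nrow(centroids) != length(area_ids) || ncol(centroids) != 2) {
    stop("centroids must have one (lon, lat) row per area")
  }
  if (!all(is.finite(centroids))) stop("centroids must be finite numbers")
  colnames(centroids) <- c("lon", "lat")
  rownames(centroids) <- area_ids
  if (length(neighbors) != length(area_ids)) {
    stop("neighbors must have one entry per area")
  }
  neighbors <- lapply(neighbors, as.character)
  names(neighbors) <- area_ids
  unknown <- setdiff(unique(unlist(neighbors)), area_ids)
  if (length(unknown) > 0) {
    stop("unknown neighbor id(s): ", paste(unknown, collapse = ", "))
  }
  for (id in area_ids) {
    if (id %in% neighbors[[id]]) stop("area ", id, " lists itself as a neighbor")
  }
  # symmetrize, warning if any one-directional entry was found
  asym <- character(0)
  for (id in area_ids) {
    for (nb in neighbors[[id]]) {
      if (!(id %in% neighbors[[nb]])) {
        asym <- c(asym, paste0(id, "->", nb))
        neighbors[[nb]] <- c(neighbors[[nb]], id)
      }
    }
  }
  if (length(asym) > 0) {
    warning("one-directional adjacency entries symmetrized: ",
            paste(asym, collapse = ", "))
  }
  neighbors <- lapply(neighbors, function(x) unique(x))

  comp <- .graph_components(area_ids, neighbors)
  structure(
    list(area_ids = area_ids, centroids = centroids, neighbors = neighbors,
         component = comp,
         n_components = if (length(comp) > 0) max(comp) else 0L),
    class = "area_map"
  )
}

.graph_components <- function(area_ids, neighbors) {
  edges <- do.call(rbind, lapply(area_ids, function(id) {
    if (length(neighbors[[id]]) == 0) return(NULL)
    cbind(id, neighbors[[id]])
  }))
  g <- igraph::graph_from_data_frame(
    d = if (is.null(edges)) data.frame(from = character(0), to = character(0))
        else data.frame(from = edges[, 1], to = edges[, 2]),
    directed = FALSE,
    vertices = data.frame(name = area_ids)
  )
  comp <- igraph::components(g)$membership
  as.integer(comp[area_ids])
}

#' @export
print.area_map <- function(x, ...) {
  cat("area_map:", length(x$area_ids), "areas,",
      sum(lengths(x$neighbors)) / 2, "edges,",
      x$n_components, "connected component(s)\n")
  invisible(x)
}

#' Read an area map from a centroid table and a GAL adjacency file
#'
#' The centroid file is delimited text with a header `id,lon,lat`. The
#' adjacency file is GAL-dialect: a header line whose last numeric token is
#' the area count, then for each area a line `id k` followed (when k > 0) by
#' a line with its k neighbour ids.
#'
#' @param centroid_path path to the centroid CSV.
#' @param adjacency_path path to the GAL adjacency file.
#' @param sep field separator of the centroid file.
#' @return An [area_map].
#' @export
read_area_map <- function(centroid_path, adjacency_path, sep = ",") {
  cen <- utils::read.table(centroid_path, header = TRUE, sep = sep,
                           colClasses = c("character", "numeric", "numeric"))
  if (!all(c("id", "lon", "lat") %in% names(cen))) {
    stop("centroid file must have header columns id, lon, lat")
  }
  if (anyDuplicated(cen$id)) {
    stop("duplicate area id(s) in centroid file: ",
         paste(unique(cen$id[duplicated(cen$id)]), collapse = ", "))
  }
  nbs <- .read_gal(adjacency_path, cen$id)
  area_map(cen$id, as.matrix(cen[, c("lon", "lat")]), nbs)
}

# GAL dialect: header line (last numeric token = n areas); then per area an
# "id count" line and, if count > 0, one line of `count` neighbour ids.
.read_gal <- function(path, area_ids) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*$", lines) | seq_along(lines) > 1]
  if (length(lines) == 0) stop("empty GAL file")
  head_tok <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  n_declared <- suppressWarnings(as.integer(head_tok))
  n_declared <- n_declared[!is.na(n_declared)]
  if (length(n_declared) == 0) stop("GAL header line has no area count")
  n_declared <- n_declared[length(n_declared)]
  if (n_declared == 0 && length(head_tok) > 1) {
    # GeoDa-style "0 n file key" header: count is the second token
    n_declared <- suppressWarnings(as.integer(head_tok[2]))
  }
  nbs <- stats::setNames(vector("list", length(area_ids)), area_ids)
  i <- 2
  seen <- character(0)
  while (i <= length(lines)) {
    ln <- trimws(lines[i])
    if (ln == "") { i <- i + 1; next }
    tok <- strsplit(ln, "\\s+")[[1]]
    if (length(tok) != 2) {
      stop("malformed GAL id line: '", lines[i], "'")
    }
    id <- tok[1]
    k <- suppressWarnings(as.integer(tok[2]))
    if (is.na(k) || k < 0) stop("malformed neighbor count in line: '", lines[i], "'")
    if (!(id %in% area_ids)) stop("unknown area id in GAL file: ", id)
    if (id %in% seen) stop("duplicate area id in GAL file: ", id)
    seen <- c(seen, id)
    i <- i + 1
    if (k > 0) {
      if (i > length(lines)) stop("GAL file truncated after id ", id)
      nb <- strsplit(trimws(lines[i]), "\\s+")[[1]]
      if (length(nb) != k) {
        stop("area ", id, " declares ", k, " neighbors but line '",
             lines[i], "' lists ", length(nb))
      }
      bad <- setdiff(nb, area_ids)
      if (length(bad) > 0) {
        stop("unknown neighbor id(s) ", paste(bad, collapse = ", "),
             " in line: '", lines[i], "'")
      }
      nbs[[id]] <- nb
      i <- i + 1
    } else {
      nbs[[id]] <- character(0)
    }
  }
  if (length(seen) != n_declared) {
    warning("GAL header declares ", n_declared, " areas; file lists ",
            length(seen))
  }
  missing <- setdiff(area_ids, seen)
  for (id in missing) nbs[[id]] <- character(0)
  nbs
}

#' Intrinsic CAR structure matrix
#'
#' Builds the graph Laplacian Q of the adjacency graph: `Q[i,i]` is the degree
#' of area i and `Q[i,j] = -1` when i and j are neighbours. Q is the precision
#' structure of the intrinsic Gaussian Markov random field prior on the
#' spatially structured effect; it is positive semidefinite with rank
#' `n - k`, where k is the number of connected components.
#'
#' @param map an [area_map].
#' @return list with `Q` (n x n symmetric matrix, dimnames = area ids) and
#'   `n_components`.
#' @export
structure_matrix <- function(map) {
  stopifnot(inherits(map, "area_map"))
  n <- length(map$area_ids)
  Q <- matrix(0, n, n, dimnames = list(map$area_ids, map$area_ids))
  for (i in seq_len(n)) {
    nb <- match(map$neighbors[[i]], map$area_ids)
    Q[i, nb] <- -1
    Q[i, i] <- length(nb)
  }
  list(Q = Q, n_components = map$n_components)
}

#' Great-circle distance matrix between area centroids
#'
#' Pairwise haversine distances in kilometres (Earth radius 6371 km) between
#' area centroids. Used to build circular scan windows.
#'
#' @param map an [area_map].
#' @return symmetric n x n matrix of distances in km, zero diagonal.
#' @export
distance_matrix <- function(map) {
  stopifnot(inherits(map, "area_map"))
  n <- length(map$area_ids)
  D <- matrix(0, n, n, dimnames = list(map$area_ids, map$area_ids))
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      d <- geosphere::distHaversine(map$centroids[i, , drop = FALSE],
                                    map$centroids[(i + 1):n, , drop = FALSE],
                                    r = 6371)
      D[i, (i + 1):n] <- d
      D[(i + 1):n, i] <- d
    }
  }
  D
}
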