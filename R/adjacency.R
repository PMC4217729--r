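#' Construct an adjacency structure
#'
#' An `adjacency` object stores the binary contiguity graph used by the
#' intrinsic CAR prior: for each spatial unit, the indices of its neighbours
#' (`w_ij = 1`) and the neighbour count `n_i`. Weights are binary contiguity
#' only; no distance weighting is supported.
#'
#' @param unit_ids character vector of unique unit identifiers.
#' @param neighbors list of integer vectors, one per unit, giving the indices
#'   (1-based, into `unit_ids`) of that unit's neighbours.
#' @return An object of class `adjacency` with components `unit_ids`,
#'   `neighbors` and `n_neighbors`.
#' @details The graph must be symmetric (`j` is a neighbour of `i` iff `i` is
#'   a neighbour of `j`) and irreflexive (no unit neighbours itself); both are
#'   checked at construction.
#' @export
adjacency <- function(unit_ids, neighbors) {
  unit_ids <- as.character(unit_ids)
  n <- length(unit_ids)
  if (anyDuplicated(unit_ids))
    stop("unit_ids must be unique", call. = FALSE)
  if (length(neighbors) != n)
    stop("neighbors must have one entry per unit", call. = FALSE)
  neighbors <- lapply(neighbors, function(x) sort(unique(as.integer(x))))
  names(neighbors) <- NULL
  for (i in seq_len(n)) {
    nb <- neighbors[[i]]
    if (length(nb) && (min(nb) < 1L || max(nb) > n))
      stop("neighbor index out of range for unit ", unit_ids[i], call. = FALSE)
    if (i %in% nb)
      stop("unit ", unit_ids[i], " lists itself as a neighbor", call. = FALSE)
    for (j in nb) {
      if (!(i %in% neighbors[[j]]))
        stop(sprintf("asymmetric adjacency: %s lists %s but not conversely",
                     unit_ids[i], unit_ids[j]), call. = FALSE)
    }
  }
  structure(
    list(unit_ids = unit_ids,
         neighbors = neighbors,
         n_neighbors = vapply(neighbors, length, integer(1))),
    class = "adjacency")
}

#' @export
print.adjacency <- function(x, ...) {
  cat("Adjacency structure:", length(x$unit_ids), "units,",
      sum(x$n_neighbors) / 2, "edges\n")
  rep <- validate_adjacency(x)
  cat("  components:", rep$n_components,
      " islands:", rep$n_islands, "\n")
  invisible(x)
}

#' Read a neighbour list file
#'
#' Reads an adjacency graph from a GAL (GeoDa neighbour-list) file or from a
#' JSON object mapping each unit id to the array of its neighbour ids.
#'
#' @param path path to the file.
#' @param dialect `"gal"` or `"json"`; default guesses from the extension.
#' @return A validated [adjacency()] object; unit identifiers are preserved
#'   verbatim.
#' @details The GAL dialect expects a header line whose last field is the
#'   unit count (a leading `0` and trailing metadata fields are tolerated),
#'   then for each unit a record line `id n_neighbors` followed by a line of
#'   `n_neighbors` neighbour ids. Symmetry violations are reported with the
#'   offending pair.
#' @export
read_neighbor_list <- function(path, dialect = c("auto", "gal", "json")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto")
    dialect <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "gal"
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  if (dialect == "json") {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    ids <- names(obj)
    if (is.null(ids))
      stop("JSON adjacency must be an object of {unit_id: [neighbor ids]}",
           call. = FALSE)
    nb <- lapply(obj, function(v) {
      v <- as.character(v)
      idx <- match(v, ids)
      if (anyNA(idx))
        stop("unknown neighbor id: ", paste(v[is.na(idx)], collapse = ", "),
             call. = FALSE)
      idx
    })
    return(adjacency(ids, nb))
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines))
    stop("empty GAL file: ", path, call. = FALSE)
  header <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  n <- suppressWarnings(as.integer(
    if (length(header) >= 2 && header[1] == "0") header[2] else header[1]))
  if (is.na(n) || n < 1)
    stop("GAL parse error at line 1: cannot read unit count", call. = FALSE)
  ids <- character(n)
  raw_nb <- vector("list", n)
  ln <- 1L
  for (i in seq_len(n)) {
    ln <- ln + 1L
    if (ln > length(lines))
      stop("GAL parse error: unexpected end of file at record ", i,
           call. = FALSE)
    rec <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
    if (length(rec) != 2)
      stop("GAL parse error at line ", ln, ": expected 'id n_neighbors'",
           call. = FALSE)
    ids[i] <- rec[1]
    k <- suppressWarnings(as.integer(rec[2]))
    if (is.na(k) || k < 0)
      stop("GAL parse error at line ", ln, ": bad neighbor count", call. = FALSE)
    if (k > 0) {
      ln <- ln + 1L
      nbr <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
      if (length(nbr) != k)
        stop("GAL parse error at line ", ln, ": expected ", k, " neighbor ids",
             call. = FALSE)
      raw_nb[[i]] <- nbr
    } else raw_nb[[i]] <- character(0)
  }
  nb <- lapply(raw_nb, function(v) {
    idx <- match(v, ids)
    if (anyNA(idx))
      stop("GAL validation error: unknown neighbor id ",
           paste(v[is.na(idx)], collapse = ", "), call. = FALSE)
    idx
  })
  # symmetry check with a named pair in the message
  for (i in seq_len(n)) for (j in nb[[i]])
    if (!(i %in% nb[[j]]))
      stop(sprintf("asymmetric adjacency: (%s,%s) listed only once",
                   ids[i], ids[j]), call. = FALSE)
  adjacency(ids, nb)
}

#' Write an adjacency structure to a GAL or JSON file
#'
#' @param adj an [adjacency()] object.
#' @param path output path.
#' @param dialect `"gal"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_neighbor_list <- function(adj, path, dialect = c("gal", "json")) {
  dialect <- match.arg(dialect)
  if (dialect == "json") {
    obj <- lapply(adj$neighbors, function(ix) adj$unit_ids[ix])
    names(obj) <- adj$unit_ids
    jsonlite::write_json(obj, path, auto_unbox = FALSE)
    return(invisible(path))
  }
  out <- character(0)
  out <- c(out, as.character(length(adj$unit_ids)))
  for (i in seq_along(adj$unit_ids)) {
    out <- c(out, paste(adj$unit_ids[i], length(adj$neighbors[[i]])))
    if (length(adj$neighbors[[i]]))
      out <- c(out, paste(adj$unit_ids[adj$neighbors[[i]]], collapse = " "))
  }
  writeLines(out, path)
  invisible(path)
}

#' Rook-contiguity lattice adjacency
#'
#' Builds the adjacency of a `rows x cols` regular grid under rook
#' contiguity (shared edges only). Used by the synthetic-data generator to
#' stand in for real small-area geography.
#'
#' @param rows,cols positive integers; `rows * cols` must be at least 2.
#' @return An [adjacency()] object with unit ids `g001, g002, ...` in
#'   row-major order.
#' @export
build_lattice_adjacency <- function(rows, cols) {
  rows <- as.integer(rows); cols <- as.integer(cols)
  if (is.na(rows) || is.na(cols) || rows < 1 || cols < 1 || rows * cols < 2)
    stop("rows x cols must be at least 2", call. = FALSE)
  n <- rows * cols
  ids <- sprintf("g%03d", seq_len(n))
  idx <- function(r, c) (r - 1L) * cols + c
  nb <- vector("list", n)
  for (r in seq_len(rows)) for (c in seq_len(cols)) {
    i <- idx(r, c)
    v <- integer(0)
    if (r > 1L)    v <- c(v, idx(r - 1L, c))
    if (r < rows)  v <- c(v, idx(r + 1L, c))
    if (c > 1L)    v <- c(v, idx(r, c - 1L))
    if (c < cols)  v <- c(v, idx(r, c + 1L))
    nb[[i]] <- v
  }
  adjacency(ids, nb)
}

#' Validate an adjacency structure for CAR use
#'
#' Reports islands (units with no neighbours, for which the CAR conditional
#' variance `sigma_v^2 / n_i` is undefined) and the connected components of
#' the graph (the intrinsic CAR precision is rank-deficient by one per
#' component).
#'
#' @param adj an [adjacency()] object.
#' @return A list with `n_units`, `islands` (unit ids with `n_i = 0`),
#'   `n_islands`, `component` (integer component label per unit) and
#'   `n_components`.
#' @export
validate_adjacency <- function(adj) {
  stopifnot(inherits(adj, "adjacency"))
  n <- length(adj$unit_ids)
  comp <- integer(n)
  k <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    k <- k + 1L
    queue <- s
    comp[s] <- k
    while (length(queue)) {
      i <- queue[1]; queue <- queue[-1]
      for (j in adj$neighbors[[i]]) if (comp[j] == 0L) {
        comp[j] <- k
        queue <- c(queue, j)
      }
    }
  }
  islands <- adj$unit_ids[adj$n_neighbors == 0L]
  list(n_units = n,
       islands = islands,
       n_islands = length(islands),
       component = comp,
       n_components = k)
}

#' Read a centroid table
#'
#' @param path CSV with columns `unit_id`, `name`, `lon`, `lat`.
#' @return A data frame of spatial units; coordinates must be finite.
#' @export
read_centroids <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("unit_id", "lon", "lat")
  if (!all(need %in% names(df)))
    stop("centroid table must have columns unit_id, lon, lat", call. = FALSE)
  if (!"name" %in% names(df)) df$name <- df$unit_id
  df$unit_id <- as.character(df$unit_id)
  if (anyDuplicated(df$unit_id))
    stop("duplicate unit_id in centroid table", call. = FALSE)
  if (!all(is.finite(df$lon)) || !all(is.finite(df$lat)))
    stop("centroid coordinates must be finite", call. = FALSE)
  df[, c("unit_id", "name", "lon", "lat")]
}
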