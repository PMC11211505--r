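#' Adjacency graph of areal units
#'
#' Constructs and validates the symmetric neighbourhood structure used by the
#' intrinsic CAR prior. Areas are indexed 1..n; `neighbors[[i]]` holds the
#' sorted 1-based indices of the areas sharing a border with area `i`.
#' Areas with no neighbours ("islands") are permitted but flagged: their
#' spatially structured effect is pinned at zero and their variation must be
#' absorbed by the unstructured component.
#'
#' @param neighbors list of integer vectors, one per area (1-based indices).
#' @return An object of class `adjacency_graph`: a list with elements `n`,
#'   `neighbors` (sorted integer vectors), `islands` (indices of areas with no
#'   neighbours), `component` (integer component label per area) and
#'   `n_components`.
#' @examples
#' g <- adjacency_graph(list(2L, c(1L, 3L), 2L))
#' g$n_components
#' @export
adjacency_graph <- function(neighbors) {
  if (!is.list(neighbors) || length(neighbors) < 1L)
    stop("`neighbors` must be a non-empty list of integer vectors")
  n <- length(neighbors)
  nbr <- vector("list", n)
  for (i in seq_len(n)) {
    v <- neighbors[[i]]
    if (length(v) == 0L) {
      nbr[[i]] <- integer(0)
      next
    }
    if (!is.numeric(v) || any(v != as.integer(v)))
      stop("neighbour indices of area ", i, " are not integers")
    v <- as.integer(v)
    if (any(v < 1L | v > n))
      stop("neighbour index out of range 1..", n, " for area ", i)
    if (any(v == i))
      stop("self-loop at area ", i)
    if (anyDuplicated(v))
      stop("duplicate neighbour ", v[duplicated(v)][1L], " for area ", i)
    nbr[[i]] <- sort(v)
  }
  for (i in seq_len(n)) {
    for (j in nbr[[i]]) {
      if (!(i %in% nbr[[j]]))
        stop("asymmetric adjacency: area ", i, " lists ", j,
             " but ", j, " does not list ", i)
    }
  }
  comp <- graph_components_(nbr)
  structure(
    list(n = n, neighbors = nbr,
         islands = which(vapply(nbr, length, 1L) == 0L),
         component = comp, n_components = max(comp)),
    class = "adjacency_graph")
}

# label connected components by breadth-first search
graph_components_ <- function(nbr) {
  n <- length(nbr)
  comp <- integer(n)
  lab <- 0L
  for (start in seq_len(n)) {
    if (comp[start] > 0L) next
    lab <- lab + 1L
    queue <- start
    comp[start] <- lab
    while (length(queue)) {
      i <- queue[[1L]]
      queue <- queue[-1L]
      for (j in nbr[[i]]) {
        if (comp[j] == 0L) {
          comp[j] <- lab
          queue <- c(queue, j)
        }
      }
    }
  }
  comp
}

#' @export
print.adjacency_graph <- function(x, ...) {
  cat("Adjacency graph:", x$n, "areas,",
      sum(lengths(x$neighbors)) / 2L, "edges,",
      x$n_components, "connected component(s)\n")
  if (length(x$islands))
    cat("Islands (no neighbours):", paste(x$islands, collapse = ", "), "\n")
  invisible(x)
}

#' Number of edges of an adjacency graph
#' @param graph an `adjacency_graph`.
#' @return integer edge count.
#' @export
graph_n_edges <- function(graph) {
  stopifnot(inherits(graph, "adjacency_graph"))
  as.integer(sum(lengths(graph$neighbors)) / 2L)
}

#' Read an adjacency graph from a neighbour-list file
#'
#' Line 1 holds the number of areas `n`; each of the following `n` lines is
#' `<i> <n_i> <j1> ... <jn_i>` with 1-based indices. `<i> 0` declares an
#' island.
#'
#' @param path path to the graph file.
#' @return a validated [adjacency_graph].
#' @export
read_graph <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 1L) stop("empty graph file: ", path)
  n <- suppressWarnings(as.integer(trimws(lines[[1L]])))
  if (is.na(n) || n < 1L) stop("first line of ", path, " must be the area count")
  if (length(lines) != n + 1L)
    stop("expected ", n, " neighbour lines in ", path, ", found ", length(lines) - 1L)
  nbr <- vector("list", n)
  seen <- rep(FALSE, n)
  for (k in seq_len(n)) {
    f <- suppressWarnings(as.integer(strsplit(trimws(lines[[k + 1L]]), "\\s+")[[1L]]))
    if (anyNA(f) || length(f) < 2L)
      stop("malformed neighbour line ", k, " in ", path)
    i <- f[[1L]]
    if (i < 1L || i > n) stop("area index ", i, " out of range in ", path)
    if (seen[i]) stop("duplicate line for area ", i, " in ", path)
    seen[i] <- TRUE
    ni <- f[[2L]]
    if (length(f) != 2L + ni)
      stop("area ", i, " declares ", ni, " neighbours but lists ", length(f) - 2L)
    nbr[[i]] <- f[-(1:2)]
  }
  adjacency_graph(nbr)
}

#' Write an adjacency graph to a neighbour-list file
#' @param graph an `adjacency_graph`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_graph <- function(graph, path) {
  stopifnot(inherits(graph, "adjacency_graph"))
  lines <- c(as.character(graph$n),
             vapply(seq_len(graph$n), function(i) {
               v <- graph$neighbors[[i]]
               paste(c(i, length(v), v), collapse = " ")
             }, ""))
  writeLines(lines, path)
  invisible(path)
}

#' Rook-adjacency rectangular lattice graph
#'
#' @param rows,cols positive integers; the lattice has `rows * cols` areas,
#'   numbered row-major.
#' @return an [adjacency_graph].
#' @examples
#' make_lattice_graph(3, 3)
#' @export
make_lattice_graph <- function(rows, cols) {
  if (!is.numeric(rows) || !is.numeric(cols) || rows < 1 || cols < 1 ||
      rows != as.integer(rows) || cols != as.integer(cols))
    stop("`rows` and `cols` must be positive integers")
  rows <- as.integer(rows); cols <- as.integer(cols)
  idx <- function(r, c) (r - 1L) * cols + c
  nbr <- vector("list", rows * cols)
  for (r in seq_len(rows)) {
    for (c in seq_len(cols)) {
      v <- integer(0)
      if (r > 1L)    v <- c(v, idx(r - 1L, c))
      if (r < rows)  v <- c(v, idx(r + 1L, c))
      if (c > 1L)    v <- c(v, idx(r, c - 1L))
      if (c < cols)  v <- c(v, idx(r, c + 1L))
      nbr[[idx(r, c)]] <- v
    }
  }
  adjacency_graph(nbr)
}

#' Contiguity graph of the 19 SRS states
#'
#' Hard-coded geographic contiguity of the 19 Indian states for which the
#' Sample Registration System publishes maternal mortality ratio estimates.
#' Borders are counted only between states in the list; intervening states
#' absent from the SRS set do not create edges. States are indexed
#' alphabetically:
#' 1 Andhra Pradesh, 2 Assam, 3 Bihar, 4 Chhattisgarh, 5 Gujarat, 6 Haryana,
#' 7 Jharkhand, 8 Karnataka, 9 Kerala, 10 Madhya Pradesh, 11 Maharashtra,
#' 12 Odisha, 13 Punjab, 14 Rajasthan, 15 Tamil Nadu, 16 Telangana,
#' 17 Uttar Pradesh, 18 Uttarakhand, 19 West Bengal.
#'
#' @return an [adjacency_graph] with 19 nodes; area names are attached as
#'   attribute `area_names`.
#' @examples
#' g <- make_srs_graph()
#' attr(g, "area_names")[g$neighbors[[9]]]  # Kerala's neighbours
#' @export
make_srs_graph <- function() {
  nbr <- list(
    c(4L, 8L, 12L, 15L, 16L),          # Andhra Pradesh
    19L,                               # Assam
    c(7L, 17L, 19L),                   # Bihar
    c(1L, 7L, 10L, 11L, 12L, 16L, 17L),# Chhattisgarh
    c(10L, 11L, 14L),                  # Gujarat
    c(13L, 14L, 17L),                  # Haryana
    c(3L, 4L, 12L, 17L, 19L),          # Jharkhand
    c(1L, 9L, 11L, 15L, 16L),          # Karnataka
    c(8L, 15L),                        # Kerala
    c(4L, 5L, 11L, 14L, 17L),          # Madhya Pradesh
    c(4L, 5L, 8L, 10L, 16L),           # Maharashtra
    c(1L, 4L, 7L, 19L),                # Odisha
    c(6L, 14L),                        # Punjab
    c(5L, 6L, 10L, 13L, 17L),          # Rajasthan
    c(1L, 8L, 9L),                     # Tamil Nadu
    c(1L, 4L, 8L, 11L),                # Telangana
    c(3L, 4L, 6L, 7L, 10L, 14L, 18L),  # Uttar Pradesh
    17L,                               # Uttarakhand
    c(2L, 3L, 7L, 12L)                 # West Bengal
  )
  g <- adjacency_graph(nbr)
  attr(g, "area_names") <- c(
    "Andhra Pradesh", "Assam", "Bihar", "Chhattisgarh", "Gujarat", "Haryana",
    "Jharkhand", "Karnataka", "Kerala", "Madhya Pradesh", "Maharashtra",
    "Odisha", "Punjab", "Rajasthan", "Tamil Nadu", "Telangana",
    "Uttar Pradesh", "Uttarakhand", "West Bengal")
  g
}

# greedy vertex colouring: areas in one colour class share no edge, so their
# ICAR full conditionals are mutually independent and can be updated as a block
graph_coloring_ <- function(graph) {
  n <- graph$n
  color <- integer(n)
  for (i in order(-lengths(graph$neighbors))) {
    used <- color[graph$neighbors[[i]]]
    k <- 1L
    while (k %in% used) k <- k + 1L
    color[i] <- k
  }
  lapply(seq_len(max(color)), function(k) which(color == k))
}
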