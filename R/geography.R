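#' County adjacency graphs
#'
#' A `county_graph` is the spatial skeleton of the MSTCAR model: an undirected
#' graph whose vertices are areal units (counties) and whose edges encode
#' adjacency. The CAR prior shrinks each county's random effect toward the
#' average of its neighbours, so the graph fully determines the spatial
#' precision structure.
#'
#' @param edges a data frame with two character columns (`unit_id`,
#'   `neighbor_id`), one row per adjacency; the graph is undirected, so each
#'   pair needs to be listed only once. May have zero rows.
#' @param units optional character vector of the full unit-id set, so that
#'   isolated units (no neighbours) are representable. Defaults to the ids
#'   appearing in `edges`.
#' @param symmetrize if `TRUE` (default) the edge list is treated as
#'   undirected and symmetrized; if `FALSE`, an edge whose reverse is absent
#'   is an error.
#'
#' @return an object of class `county_graph` with elements `unit_ids`
#'   (ordered character vector), `neighbors` (named list of character
#'   vectors), `m` (named integer neighbour counts) and `component`
#'   (named integer membership of connected components).
#' @examples
#' g <- county_graph(data.frame(unit_id = "A", neighbor_id = "B"),
#'                   units = c("A", "B", "C"))
#' g$m
#' @export
county_graph <- function(edges, units = NULL, symmetrize = TRUE) {
  edges <- as.data.frame(edges)
  if (ncol(edges) < 2 && nrow(edges) > 0)
    stop("`edges` must have two columns: unit_id, neighbor_id")
  a <- as.character(if (nrow(edges)) edges[[1]] else character())
  b <- as.character(if (nrow(edges)) edges[[2]] else character())
  if (any(a == b)) stop("self-loops are not allowed")
  if (is.null(units)) units <- sort(unique(c(a, b)))
  units <- as.character(units)
  if (anyDuplicated(units)) stop("duplicate unit ids in `units`")
  unknown <- setdiff(c(a, b), units)
  if (length(unknown))
    stop("edge references undeclared unit id(s): ",
         paste(unique(unknown), collapse = ", "))

  if (symmetrize) {
    a2 <- c(a, b); b2 <- c(b, a)
  } else {
    key <- paste(a, b); rkey <- paste(b, a)
    if (!all(rkey %in% key))
      stop("asymmetric edge list (symmetrize = FALSE): missing reverse of ",
           paste(utils::head(key[!(rkey %in% key)], 3), collapse = "; "))
    a2 <- a; b2 <- b
  }
  key <- paste(a2, b2)
  if (anyDuplicated(key)) {
    dup <- sum(duplicated(paste(pmin(a, b), pmax(a, b))))
    if (dup > 0) warning(dup, " duplicate edge(s) removed")
    keep <- !duplicated(key)
    a2 <- a2[keep]; b2 <- b2[keep]
  }
  nbr <- split(b2, factor(a2, levels = units))
  nbr <- lapply(nbr, function(x) sort(unique(x)))
  names(nbr) <- units
  m <- vapply(nbr, length, integer(1))

  comp <- graph_components(units, nbr)
  structure(
    list(unit_ids = units, neighbors = nbr, m = m, component = comp),
    class = "county_graph"
  )
}

# connected components by breadth-first traversal
graph_components <- function(units, nbr) {
  n <- length(units)
  comp <- stats::setNames(rep(NA_integer_, n), units)
  cid <- 0L
  for (u in units) {
    if (!is.na(comp[[u]])) next
    cid <- cid + 1L
    queue <- u
    comp[[u]] <- cid
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      for (w in nbr[[v]]) {
        if (is.na(comp[[w]])) {
          comp[[w]] <- cid
          queue <- c(queue, w)
        }
      }
    }
  }
  comp
}

#' @export
print.county_graph <- function(x, ...) {
  cat("<county_graph> ", length(x$unit_ids), " units, ",
      sum(x$m) / 2, " edges, ",
      max(x$component), " connected component(s)\n", sep = "")
  invisible(x)
}

#' Rook-adjacency lattice graph
#'
#' Builds an `nrows` by `ncols` grid of areal units with rook adjacency
#' (horizontal and vertical neighbours). Used as a stand-in for a county
#' map in simulations and tests: interior cells have 4 neighbours, edge
#' cells 3, corner cells 2.
#'
#' @param nrows,ncols positive integers.
#' @return a [county_graph()].
#' @examples
#' g <- grid_graph(3, 3)
#' g$m[["r2c2"]] # centre cell: 4 neighbours
#' @export
grid_graph <- function(nrows, ncols) {
  if (length(nrows) != 1 || length(ncols) != 1 ||
      nrows < 1 || ncols < 1 || nrows %% 1 != 0 || ncols %% 1 != 0)
    stop("`nrows` and `ncols` must be positive integers")
  id <- function(r, c) paste0("r", r, "c", c)
  units <- as.vector(t(outer(seq_len(nrows), seq_len(ncols), id)))
  from <- character(); to <- character()
  for (r in seq_len(nrows)) for (c in seq_len(ncols)) {
    if (c < ncols) { from <- c(from, id(r, c)); to <- c(to, id(r, c + 1)) }
    if (r < nrows) { from <- c(from, id(r, c)); to <- c(to, id(r + 1, c)) }
  }
  county_graph(data.frame(unit_id = from, neighbor_id = to), units = units)
}

#' Read a neighbour-list file
#'
#' The format is one adjacency per line, `unit_id<TAB>neighbor_id`
#' (whitespace-delimited), with `#` comments. An optional header block of
#' lines starting with `units:` declares the full id set (whitespace
#' separated after the colon), so isolated units are representable.
#'
#' @param path path to the neighbour-list file.
#' @param symmetrize passed to [county_graph()]: symmetrize the edge list
#'   (default) or reject asymmetric input.
#' @return a [county_graph()].
#' @export
read_adjacency <- function(path, symmetrize = TRUE) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  unit_lines <- grepl("^units:", lines)
  units <- NULL
  if (any(unit_lines)) {
    decl <- sub("^units:", "", lines[unit_lines])
    units <- unlist(strsplit(trimws(decl), "[[:space:]]+"))
  }
  edge_lines <- lines[!unit_lines]
  if (length(edge_lines)) {
    parts <- strsplit(edge_lines, "[[:space:]]+")
    bad <- lengths(parts) != 2
    if (any(bad)) stop("malformed neighbour-list line: ", edge_lines[bad][1])
    edges <- data.frame(unit_id = vapply(parts, `[[`, "", 1),
                        neighbor_id = vapply(parts, `[[`, "", 2))
  } else {
    edges <- data.frame(unit_id = character(), neighbor_id = character())
  }
  county_graph(edges, units = units, symmetrize = symmetrize)
}

#' Write a neighbour-list file
#'
#' Inverse of [read_adjacency()]: writes a `units:` header and one line per
#' undirected edge.
#'
#' @param graph a [county_graph()].
#' @param path output path.
#' @export
write_adjacency <- function(graph, path) {
  stopifnot(inherits(graph, "county_graph"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste("units:", paste(graph$unit_ids, collapse = " ")), con)
  for (u in graph$unit_ids) {
    for (v in graph$neighbors[[u]]) {
      if (u < v) writeLines(paste(u, v, sep = "\t"), con)
    }
  }
  invisible(path)
}

#' Intrinsic CAR precision matrix
#'
#' Builds the precision structure of the intrinsic (improper) conditional
#' autoregressive prior from a county graph: `Q = D - W` with
#' `D = diag(m_i)` the neighbour counts and `W` the 0/1 adjacency matrix.
#' Every row of `Q` sums to zero; `Q` is positive semidefinite with null
#' space spanned by the indicator vectors of the connected components, so
#' the rank deficiency equals the number of components. Propriety of the
#' prior is restored downstream by sum-to-zero constraints per component.
#'
#' @param graph a [county_graph()].
#' @return a list of class `car_precision` with `Q` (sparse symmetric
#'   [Matrix::Matrix()]), `W` (sparse adjacency), `m` (neighbour counts),
#'   `rank_deficiency` (number of connected components) and `component`.
#' @examples
#' car_precision(grid_graph(2, 2))$Q
#' @export
car_precision <- function(graph) {
  stopifnot(inherits(graph, "county_graph"))
  units <- graph$unit_ids
  n <- length(units)
  idx <- stats::setNames(seq_len(n), units)
  from <- rep(seq_len(n), times = lengths(graph$neighbors))
  to <- idx[unlist(graph$neighbors, use.names = FALSE)]
  W <- Matrix::sparseMatrix(i = from, j = unname(to), x = 1, dims = c(n, n),
                            dimnames = list(units, units))
  Q <- Matrix::Diagonal(n, x = as.numeric(graph$m)) - W
  dimnames(Q) <- list(units, units)
  structure(
    list(Q = Q, W = W, m = graph$m,
         rank_deficiency = max(graph$component),
         component = graph$component),
    class = "car_precision"
  )
}

#' @export
print.car_precision <- function(x, ...) {
  cat("<car_precision> ", nrow(x$Q), " units, rank deficiency ",
      x$rank_deficiency, "\n", sep = "")
  invisible(x)
}
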