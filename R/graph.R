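#' Area adjacency graphs
#'
#' Contiguity between areas (counties) is represented as a symmetric
#' adjacency structure: a set of area identifiers and, for each, the set of
#' its neighbors.  Areas with no neighbors ("island" counties) are allowed
#' and receive the neutral value zero wherever a spatially averaged quantity
#' is needed.
#'
#' @param areas Character vector of area identifiers.
#' @param neighbors Named list (names = `areas`) of character vectors of
#'   neighboring area ids.  Must be symmetric and free of self-loops.
#' @return An object of class `area_graph`.
#' @seealso [make_county_graph()], [read_adjacency()]
#' @export
area_graph <- function(areas, neighbors) {
  areas <- as.character(areas)
  if (anyDuplicated(areas)) stop("duplicate area ids", call. = FALSE)
  if (!all(areas %in% names(neighbors))) {
    neighbors <- c(neighbors,
                   stats::setNames(rep(list(character(0)),
                                       sum(!(areas %in% names(neighbors)))),
                                   setdiff(areas, names(neighbors))))
  }
  neighbors <- lapply(neighbors[areas], function(v) sort(unique(as.character(v))))
  for (a in areas) {
    nb <- neighbors[[a]]
    if (a %in% nb) stop(sprintf("self-loop at area '%s'", a), call. = FALSE)
    if (!all(nb %in% areas)) {
      stop(sprintf("neighbor of '%s' not among areas", a), call. = FALSE)
    }
    for (b in nb) {
      if (!(a %in% neighbors[[b]])) {
        stop(sprintf("asymmetric adjacency between '%s' and '%s'", a, b),
             call. = FALSE)
      }
    }
  }
  structure(list(areas = areas, neighbors = neighbors), class = "area_graph")
}

#' @export
print.area_graph <- function(x, ...) {
  deg <- lengths(x$neighbors)
  cat(sprintf("area_graph: %d areas, %d edges, %d islands\n",
              length(x$areas), sum(deg) / 2, sum(deg == 0)))
  invisible(x)
}

#' Generate a county contiguity graph on a planar grid
#'
#' Arranges `n_counties` areas on a near-square grid and connects areas
#' sharing a grid edge, emulating county contiguity (neighboring counties
#' share a common boundary).  A requested number of areas is then turned
#' into islands -- areas with no defined neighbors -- by removing all their
#' edges; which areas become islands is drawn at random from the seed.
#'
#' @param n_counties Number of areas (>= 1).
#' @param n_islands Number of island areas (< `n_counties`).
#' @param seed Integer seed; the result is deterministic given the seed.
#' @return An [area_graph()] whose area ids are FIPS-like five-digit strings.
#' @examples
#' g <- make_county_graph(9, n_islands = 1, seed = 7)
#' lengths(g$neighbors)
#' @export
make_county_graph <- function(n_counties, n_islands = 0, seed = 1) {
  if (length(n_counties) != 1 || is.na(n_counties) || n_counties < 1) {
    stop("n_counties must be a positive integer", call. = FALSE)
  }
  if (n_islands >= n_counties) stop("n_islands must be < n_counties", call. = FALSE)
  n_counties <- as.integer(n_counties)
  ids <- sprintf("%05d", seq_len(n_counties))
  nrow_g <- floor(sqrt(n_counties))
  ncol_g <- ceiling(n_counties / nrow_g)
  row_i <- (seq_len(n_counties) - 1L) %/% ncol_g + 1L
  col_i <- (seq_len(n_counties) - 1L) %% ncol_g + 1L
  idx <- matrix(NA_integer_, nrow_g, ncol_g)
  idx[cbind(row_i, col_i)] <- seq_len(n_counties)
  nb <- vector("list", n_counties)
  for (k in seq_len(n_counties)) {
    r <- row_i[k]; cc <- col_i[k]
    cand <- c(if (r > 1) idx[r - 1, cc],
              if (r < nrow_g) idx[r + 1, cc],
              if (cc > 1) idx[r, cc - 1],
              if (cc < ncol_g) idx[r, cc + 1])
    nb[[k]] <- ids[cand[!is.na(cand)]]
  }
  names(nb) <- ids
  if (n_islands > 0) {
    set.seed(substream_seed(seed, 11L))
    isl <- sample(ids, n_islands)
    for (a in isl) {
      for (b in nb[[a]]) nb[[b]] <- setdiff(nb[[b]], a)
      nb[[a]] <- character(0)
    }
  }
  area_graph(ids, nb)
}

#' Read and write area adjacency lists
#'
#' The on-disk format is one line per area:
#' `area_id<TAB>comma-separated neighbor ids`, with an empty neighbor field
#' for island areas.  Asymmetric input (a neighbor relation recorded in one
#' direction only) is symmetrized with a warning; self-loops are an error.
#'
#' @param path File path.
#' @param graph An [area_graph()].
#' @return `read_adjacency` returns an [area_graph()]; `write_adjacency`
#'   returns `path` invisibly.
#' @export
read_adjacency <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  areas <- vapply(parts, function(p) trimws(p[[1]]), character(1))
  nb <- lapply(parts, function(p) {
    if (length(p) < 2 || !nzchar(trimws(p[[2]]))) return(character(0))
    trimws(strsplit(p[[2]], ",", fixed = TRUE)[[1]])
  })
  names(nb) <- areas
  for (a in areas) {
    if (a %in% nb[[a]]) stop(sprintf("self-loop at area '%s'", a), call. = FALSE)
  }
  ## symmetrize
  asym <- FALSE
  for (a in areas) {
    for (b in nb[[a]]) {
      if (!(b %in% areas)) stop(sprintf("neighbor '%s' of '%s' has no line", b, a),
                                call. = FALSE)
      if (!(a %in% nb[[b]])) {
        nb[[b]] <- c(nb[[b]], a)
        asym <- TRUE
      }
    }
  }
  if (asym) warning("asymmetric adjacency input was symmetrized", call. = FALSE)
  area_graph(areas, nb)
}

#' @rdname read_adjacency
#' @export
write_adjacency <- function(graph, path) {
  stopifnot(inherits(graph, "area_graph"))
  lines <- vapply(graph$areas, function(a) {
    paste0(a, "\t", paste(graph$neighbors[[a]], collapse = ","))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
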