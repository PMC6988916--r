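## Sphere-of-influence neighbor graph, row standardization, summaries, GAL.

#' Sphere-of-influence neighbor adjacency
#'
#' Two points are neighbors when the circles centered on them, each with
#' radius equal to its own nearest-neighbor distance, intersect in two
#' places: `|r_i - r_j| < d(i, j) < r_i + r_j`, with strict inequalities
#' (tangent circles do not qualify). The graph always contains the mutual
#' nearest-neighbor graph and is symmetric by construction.
#'
#' @param coords Two-column matrix or data frame of point coordinates:
#'   projected metres (`metric = "planar"`) or lon/lat degrees
#'   (`metric = "geodesic"`, great-circle distances; used for pooled
#'   pantropical samples that no single projected system covers).
#' @param metric Distance metric.
#' @return Symmetric logical adjacency matrix (base matrix) with ids as
#'   dimnames when available.
#' @export
soi_neighbors <- function(coords, metric = c("planar", "geodesic")) {
  metric <- match.arg(metric)
  m <- as.matrix(coords[, 1:2])
  n <- nrow(m)
  if (n < 2) abort("need at least two points")
  d <- if (metric == "planar") {
    as.matrix(dist(m))
  } else {
    geosphere::distm(m, fun = geosphere::distGeo)
  }
  diag(d) <- Inf
  zero <- which(d == 0, arr.ind = TRUE)
  if (nrow(zero)) {
    pair <- zero[1, ]
    abort(paste0("coincident points: ", pair[1], " and ", pair[2]))
  }
  r <- apply(d, 1, min)
  rs <- outer(r, r, "+")
  rd <- abs(outer(r, r, "-"))
  adj <- d < rs & d > rd
  diag(adj) <- FALSE
  ids <- rownames(coords) %||% as.character(seq_len(n))
  dimnames(adj) <- list(ids, ids)
  adj
}

#' Row-standardize a neighbor adjacency into a weights matrix
#'
#' Each unit's neighbor weights sum to one (`W_ij = 1/deg(i)`), so `W x`
#' is the neighbor average of `x`. The result is generally asymmetric when
#' degrees differ.
#'
#' @param adj Symmetric logical/binary adjacency matrix.
#' @return Sparse row-standardized weights matrix (`dgCMatrix`).
#' @export
row_standardize <- function(adj) {
  deg <- base::rowSums(adj)
  if (any(deg == 0)) {
    abort(paste0("isolated unit(s) cannot be row-standardized: ",
                 paste(head(which(deg == 0), 5), collapse = ", ")))
  }
  w <- Matrix::Matrix(adj * (1 / deg), sparse = TRUE)
  dimnames(w) <- dimnames(adj)
  w
}

#' Build SOI spatial weights for a set of units
#'
#' Convenience wrapper producing a `soi_weights` object holding the binary
#' adjacency, the row-standardized matrix and connectivity summaries.
#'
#' @inheritParams soi_neighbors
#' @return A `soi_weights` object.
#' @export
soi_weights <- function(coords, metric = c("planar", "geodesic")) {
  adj <- soi_neighbors(coords, metric)
  structure(list(
    ids = rownames(adj),
    adjacency = adj,
    W = row_standardize(adj),
    metric = match.arg(metric)
  ), class = "soi_weights")
}

#' Connectivity summaries of a spatial weights matrix
#'
#' Link counts follow the directed-pair convention (a mutual pair counts
#' twice); the non-zero share uses the full `N^2` cell count including the
#' diagonal.
#'
#' @param w A `soi_weights` object or adjacency matrix.
#' @return One-row tibble with `n`, `n_links`, `avg_links`, `pct_nonzero`,
#'   and a list-column `neighbor_histogram` (counts of units by neighbor
#'   count 1..max).
#' @export
summarize_weights <- function(w) {
  adj <- if (inherits(w, "soi_weights")) w$adjacency else w
  n <- nrow(adj)
  deg <- base::rowSums(adj)
  n_links <- sum(deg)
  hist <- tabulate(deg, nbins = max(deg))
  tibble(
    n = n,
    n_links = n_links,
    avg_links = n_links / n,
    pct_nonzero = 100 * n_links / n^2,
    neighbor_histogram = list(setNames(hist, seq_along(hist)))
  )
}

#' @exportS3Method base::print
print.soi_weights <- function(x, ...) {
  s <- summarize_weights(x)
  cat("<soi_weights> n =", s$n, " links =", s$n_links,
      " avg =", round(s$avg_links, 2),
      " %nonzero =", round(s$pct_nonzero, 2), "\n")
  invisible(x)
}

#' @export
glance.soi_weights <- function(x, ...) summarize_weights(x)

#' @export
tidy.soi_weights <- function(x, ...) {
  idx <- which(x$adjacency, arr.ind = TRUE)
  tibble(from = x$ids[idx[, 1]], to = x$ids[idx[, 2]],
         weight = x$W[idx])
}

#' Write spatial weights in GAL neighbor-list format
#' @param w A `soi_weights` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gal <- function(w, path) {
  con <- file(path, "w")
  on.exit(close(con))
  n <- length(w$ids)
  writeLines(paste("0", n, "forestdem", "unit_id"), con)
  for (i in seq_len(n)) {
    nb <- which(w$adjacency[i, ])
    writeLines(paste(w$ids[i], length(nb)), con)
    writeLines(paste(w$ids[nb], collapse = " "), con)
  }
  invisible(path)
}

#' Read spatial weights from a GAL neighbor-list file
#' @param path GAL file path.
#' @return A `soi_weights` object (metric recorded as written graph).
#' @export
read_gal <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  n <- as.integer(hdr[2])
  ids <- character(n)
  nb <- vector("list", n)
  li <- 2
  for (i in seq_len(n)) {
    head_i <- strsplit(trimws(lines[li]), "\\s+")[[1]]
    ids[i] <- head_i[1]
    k <- as.integer(head_i[2])
    nb[[i]] <- if (k > 0) strsplit(trimws(lines[li + 1]), "\\s+")[[1]]
      else character()
    li <- li + 2
  }
  adj <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) adj[i, match(nb[[i]], ids)] <- TRUE
  if (!isSymmetric(adj)) abort("GAL file encodes an asymmetric graph")
  structure(list(ids = ids, adjacency = adj, W = row_standardize(adj),
                 metric = "unknown"), class = "soi_weights")
}
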