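#' Four-neighbour pixel lattice
#'
#' Builds the regular square-grid graph used throughout: every pixel is
#' connected to its immediate neighbours above, below, left and right, so
#' interior pixels have degree 4, non-corner boundary pixels degree 3 and
#' corners degree 2.
#'
#' Pixels are indexed by (row, col); when a vector index is needed the
#' column-major order of R matrices is used (pixel i = (col-1)*n_rows + row).
#'
#' @param n_rows,n_cols positive integer lattice dimensions.
#' @return An object of class \code{"al_lattice"} with fields \code{n_rows},
#'   \code{n_cols}, \code{n} (pixel count), \code{edges} (two-column integer
#'   matrix of vertex pairs, each undirected edge once, i < j) and
#'   \code{degree} (integer vector of vertex degrees).
#' @examples
#' g <- build_lattice(3, 3)
#' g$n                 # 9
#' nrow(g$edges)       # 12
#' table(g$degree)     # 4 corners (2), 4 edge-midpoints (3), 1 centre (4)
#' @export
build_lattice <- function(n_rows, n_cols) {
  if (length(n_rows) != 1L || length(n_cols) != 1L ||
      is.na(n_rows) || is.na(n_cols) ||
      n_rows < 1 || n_cols < 1 ||
      n_rows != round(n_rows) || n_cols != round(n_cols)) {
    stop("lattice dimensions must be positive integers")
  }
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  n <- n_rows * n_cols
  idx <- matrix(seq_len(n), n_rows, n_cols)
  # vertical edges (r,c)-(r+1,c) and horizontal (r,c)-(r,c+1)
  ev <- if (n_rows > 1) cbind(as.vector(idx[-n_rows, , drop = FALSE]),
                              as.vector(idx[-1, , drop = FALSE])) else NULL
  eh <- if (n_cols > 1) cbind(as.vector(idx[, -n_cols, drop = FALSE]),
                              as.vector(idx[, -1, drop = FALSE])) else NULL
  edges <- rbind(ev, eh)
  if (is.null(edges)) edges <- matrix(integer(0), 0, 2)
  degree <- tabulate(edges, nbins = n)
  structure(
    list(n_rows = n_rows, n_cols = n_cols, n = n,
         edges = edges, degree = degree),
    class = "al_lattice"
  )
}

#' @export
print.al_lattice <- function(x, ...) {
  cat(sprintf("<%d x %d lattice: %d pixels, %d edges>\n",
              x$n_rows, x$n_cols, x$n, nrow(x$edges)))
  invisible(x)
}

#' Sum of neighbour values at every pixel
#'
#' For a per-pixel field z on a 4-neighbour lattice, computes
#' \eqn{\sum_{j \sim i} z_j} at every pixel i via shifted-matrix addition
#' (no adjacency matrix is materialised). A pixel with no neighbours (1x1
#' lattice) gets 0.
#'
#' @param z numeric matrix matching the lattice dimensions.
#' @param graph an \code{al_lattice}.
#' @return numeric matrix of neighbour sums, same shape as \code{z}.
#' @export
neighbor_sum <- function(z, graph) {
  if (!is.matrix(z) || nrow(z) != graph$n_rows || ncol(z) != graph$n_cols) {
    stop("field shape does not match lattice")
  }
  nr <- graph$n_rows; nc <- graph$n_cols
  s <- matrix(0, nr, nc)
  if (nr > 1) {
    s[-nr, ] <- s[-nr, , drop = FALSE] + z[-1, , drop = FALSE]
    s[-1, ]  <- s[-1, , drop = FALSE]  + z[-nr, , drop = FALSE]
  }
  if (nc > 1) {
    s[, -nc] <- s[, -nc, drop = FALSE] + z[, -1, drop = FALSE]
    s[, -1]  <- s[, -1, drop = FALSE]  + z[, -nc, drop = FALSE]
  }
  s
}

# Degree field as a matrix (used by coding conversion).
degree_matrix <- function(graph) {
  matrix(graph$degree, graph$n_rows, graph$n_cols)
}
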