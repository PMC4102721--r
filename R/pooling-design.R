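#' Seven-dimension pooling design over a plate/row/column clone library
#'
#' Maps every clone coordinate (plate, row, column) to exactly one pool in
#' each of seven screening dimensions. Two design families are provided:
#'
#' \describe{
#'   \item{\code{"std"} (default)}{a shifted-transversal-style design: the
#'     linear coordinate index, written in base q (q the smallest prime
#'     with q^3 >= library size, or user-supplied), yields digits
#'     (d0, d1, d2); layer j in 0..5 pools coordinate i into pool
#'     (d0 + j d1 + j^2 d2) mod q. Any two distinct coordinates share a
#'     pool in at most two of the six layers. Dimension 7 is one pool per
#'     plate. At the default 216x16x24 library this gives 6 x 47 = 282
#'     six-dimensional pools plus 216 plate pools.}
#'   \item{\code{"digits"}}{plate-index digits in mixed bases
#'     (\code{plate_bases}, default 6,6,6) give three dimensions; row and
#'     column give two more; a diagonal pool
#'     (plate_index + well_index) mod \code{diag_q} gives the sixth;
#'     dimension 7 is again one pool per plate.}
#' }
#'
#' Custom dimensions may be supplied as functions of
#' (plate, row, col, index) returning a 0-based pool index; each is checked
#' to partition the library.
#'
#' @param n_plates,rows,cols library geometry (defaults 216 x 16 x 24).
#' @param type design family, \code{"std"} or \code{"digits"}.
#' @param q pool count per layer for \code{"std"}; \code{NULL} picks the
#'   smallest prime whose cube covers the library.
#' @param plate_bases integer vector of plate-digit bases for
#'   \code{"digits"}; must multiply to \code{n_plates}.
#' @param diag_q modulus of the diagonal dimension for \code{"digits"}.
#' @param dims optional list of custom dimension functions; overrides
#'   \code{type}. Each element may carry a \code{pools} attribute giving
#'   its pool count.
#' @return an object of class \code{pooling_design}: the membership matrix
#'   (coordinates x 7, 0-based pool index within dimension), dimension
#'   sizes, global pool ids and the geometry.
#' @export
pooling_design <- function(n_plates = 216, rows = 16, cols = 24,
                           type = c("std", "digits"), q = NULL,
                           plate_bases = c(6, 6, 6), diag_q = 24,
                           dims = NULL) {
  type <- match.arg(type)
  stopifnot(is_count(n_plates), is_count(rows), is_count(cols),
            n_plates >= 1, rows >= 1, cols >= 1)
  n <- n_plates * rows * cols
  idx <- seq_len(n) - 1L
  plate <- idx %/% (rows * cols)
  well <- idx %% (rows * cols)
  row <- well %/% cols
  col <- well %% cols

  if (!is.null(dims)) {
    if (length(dims) != 7)
      stop("a pooling design needs exactly 7 dimensions, got ",
           length(dims))
    memb <- matrix(0L, nrow = n, ncol = 7)
    sizes <- integer(7)
    for (d in seq_len(7)) {
      v <- dims[[d]](plate, row, col, idx)
      if (length(v) != n || anyNA(v) || any(!is.finite(v)) ||
          any(v != floor(v)) || any(v < 0))
        stop("dimension ", d,
             " does not partition the library (invalid pool index)")
      memb[, d] <- as.integer(v)
      sizes[d] <- attr(dims[[d]], "pools") %||% (max(v) + 1L)
      if (any(v >= sizes[d]))
        stop("dimension ", d, " does not partition the library ",
             "(pool index exceeds declared pool count)")
    }
    dtype <- "custom"
  } else if (type == "std") {
    q <- as.integer(q %||% next_prime(ceiling(n^(1 / 3))))
    if (q^3 < n)
      stop("q^3 = ", q^3, " cannot index ", n, " coordinates")
    d0 <- idx %% q
    d1 <- (idx %/% q) %% q
    d2 <- idx %/% (q * q)
    memb <- vapply(0:5, function(j) as.integer((d0 + j * d1 + j * j * d2) %% q),
                   integer(n))
    memb <- cbind(memb, as.integer(plate))
    sizes <- c(rep(q, 6), n_plates)
    dtype <- "std"
  } else {
    plate_bases <- as.integer(plate_bases)
    if (prod(plate_bases) != n_plates)
      stop("n_plates = ", n_plates, " is not factorisable as ",
           paste(plate_bases, collapse = " x "))
    if (length(plate_bases) != 3)
      stop("plate_bases must have length 3")
    b <- plate_bases
    memb <- cbind(as.integer(plate %% b[1]),
                  as.integer((plate %/% b[1]) %% b[2]),
                  as.integer(plate %/% (b[1] * b[2])),
                  as.integer(row),
                  as.integer(col),
                  as.integer((plate + well) %% diag_q),
                  as.integer(plate))
    sizes <- c(b, rows, cols, as.integer(diag_q), n_plates)
    dtype <- "digits"
  }

  colnames(memb) <- paste0("dim", seq_len(7))
  offsets <- c(0L, cumsum(sizes))[seq_len(7)]
  pool_ids <- unlist(lapply(seq_len(7), function(d)
    sprintf("d%d.p%02d", d, seq_len(sizes[d]) - 1L)))

  structure(list(type = dtype, n_plates = as.integer(n_plates),
                 rows = as.integer(rows), cols = as.integer(cols),
                 n_coords = as.integer(n), q = if (dtype == "std") q else NULL,
                 plate_bases = if (dtype == "digits") plate_bases else NULL,
                 diag_q = if (dtype == "digits") as.integer(diag_q) else NULL,
                 membership = memb, dim_sizes = as.integer(sizes),
                 dim_offsets = offsets, pool_ids = pool_ids),
            class = "pooling_design")
}

#' @export
print.pooling_design <- function(x, ...) {
  cat(sprintf("Pooling design (%s): %d coordinates (%d plates x %d x %d), 7 dimensions with %s pools (%d total)\n",
              x$type, x$n_coords, x$n_plates, x$rows, x$cols,
              paste(x$dim_sizes, collapse = "+"), sum(x$dim_sizes)))
  invisible(x)
}

#' Linear index of a (plate, row, col) coordinate
#'
#' 0-based throughout; \code{index = (plate * rows + row) * cols + col}.
#' @param design a \code{pooling_design}.
#' @param plate,row,col 0-based coordinates (vectorised).
#' @return 0-based linear indices.
#' @export
coord_index <- function(design, plate, row, col) {
  if (any(plate < 0 | plate >= design$n_plates |
          row < 0 | row >= design$rows |
          col < 0 | col >= design$cols))
    stop("coordinate out of range for this library")
  (plate * design$rows + row) * design$cols + col
}

#' Coordinates of linear indices
#' @param design a \code{pooling_design}.
#' @param index 0-based linear indices.
#' @return data.frame with \code{plate}, \code{row}, \code{col}.
#' @export
index_coord <- function(design, index) {
  if (any(index < 0 | index >= design$n_coords))
    stop("linear index out of range for this library")
  wpp <- design$rows * design$cols
  data.frame(plate = index %/% wpp,
             row = (index %% wpp) %/% design$cols,
             col = index %% design$cols)
}

#' Human-readable clone name of a coordinate ("27D10" style)
#' @param plate,row,col 0-based coordinates.
#' @return character names: 1-based plate, row letter, 1-based column.
#' @export
coord_name <- function(plate, row, col) {
  paste0(plate + 1L, LETTERS[row + 1L], col + 1L)
}

#' The seven pools of a coordinate
#'
#' @param design a \code{pooling_design}.
#' @param index 0-based linear coordinate indices (vectorised).
#' @return character matrix (length(index) x 7) of pool ids.
#' @export
pools_of <- function(design, index) {
  if (any(index < 0 | index >= design$n_coords))
    stop("coordinate index out of range")
  m <- design$membership[index + 1L, , drop = FALSE]
  out <- matrix("", nrow = nrow(m), ncol = 7)
  for (d in seq_len(7))
    out[, d] <- sprintf("d%d.p%02d", d, m[, d])
  rownames(out) <- index
  out
}

# scalar recomputation of one coordinate's pool in one dimension, from the
# design parameters alone; used by the exhaustive decoding oracle so that it
# does not share the stored membership matrix with the optimised path
pool_of_scalar <- function(design, index, d) {
  plate <- index %/% (design$rows * design$cols)
  well <- index %% (design$rows * design$cols)
  if (design$type == "std") {
    q <- design$q
    d0 <- index %% q; d1 <- (index %/% q) %% q; d2 <- index %/% (q * q)
    if (d <= 6) {
      j <- d - 1
      return(sprintf("d%d.p%02d", d, (d0 + j * d1 + j * j * d2) %% q))
    }
    return(sprintf("d7.p%02d", plate))
  }
  if (design$type == "digits") {
    b <- design$plate_bases
    v <- switch(d,
                plate %% b[1],
                (plate %/% b[1]) %% b[2],
                plate %/% (b[1] * b[2]),
                well %/% design$cols,
                well %% design$cols,
                (plate + well) %% design$diag_q,
                plate)
    return(sprintf("d%d.p%02d", d, v))
  }
  sprintf("d%d.p%02d", d, design$membership[index + 1L, d])
}
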