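#' Decode one assay's pool calls into putative clone coordinates
#'
#' A pool counts as positive for nucleotide k if its call is allele-k
#' \emph{or} both (a pool holding clones of both subgenomes elicits both
#' fluorescences). A coordinate is reported for nucleotide k iff all
#' seven of its pools are positive for k. Coordinates reported for both
#' nucleotides are flagged ambiguous and scored with class \code{both};
#' downstream treats them as unassignable.
#'
#' The optimised path intersects per-dimension positive-pool candidate
#' sets via the design's membership matrix;
#' \code{\link{decode_bruteforce}} retains the defining per-coordinate
#' scan as an independent oracle.
#'
#' @param calls data.frame of one assay's pool calls (\code{pool_id},
#'   \code{call}).
#' @param design a \code{\link{pooling_design}}.
#' @return list with 0-based coordinate vectors \code{allele1},
#'   \code{allele2} (each excluding the ambiguous ones),
#'   \code{ambiguous}, and \code{score}: a data.frame of
#'   (index, clone_id, class).
#' @export
decode_assay <- function(calls, design) {
  stopifnot(all(c("pool_id", "call") %in% names(calls)))
  unknown <- setdiff(calls$pool_id, design$pool_ids)
  if (length(unknown) > 0)
    stop("calls reference unknown pools: ",
         paste(utils::head(unknown, 5), collapse = ", "))

  hit_coords <- function(classes) {
    pos <- calls$pool_id[calls$call %in% classes]
    if (length(pos) == 0) return(integer(0))
    gidx <- match(pos, design$pool_ids) - 1L   # 0-based global pool index
    ok <- rep(TRUE, design$n_coords)
    for (d in seq_len(7)) {
      lo <- design$dim_offsets[d]
      within <- gidx[gidx >= lo & gidx < lo + design$dim_sizes[d]] - lo
      if (length(within) == 0) return(integer(0))
      lut <- logical(design$dim_sizes[d])
      lut[within + 1L] <- TRUE
      ok <- ok & lut[design$membership[, d] + 1L]
      if (!any(ok)) return(integer(0))
    }
    which(ok) - 1L
  }

  set1 <- hit_coords(c("allele1", "both"))
  set2 <- hit_coords(c("allele2", "both"))
  amb <- intersect(set1, set2)
  only1 <- setdiff(set1, amb)
  only2 <- setdiff(set2, amb)

  idx <- c(only1, only2, amb)
  cls <- c(rep("allele1", length(only1)), rep("allele2", length(only2)),
           rep("both", length(amb)))
  o <- order(idx)
  co <- index_coord(design, idx[o])
  list(allele1 = only1, allele2 = only2, ambiguous = amb,
       score = data.frame(index = idx[o],
                          clone_id = coord_name(co$plate, co$row, co$col),
                          class = cls[o]))
}

#' Exhaustive per-coordinate decoding oracle
#'
#' The definition of deconvolution, executed literally: for every
#' coordinate in the library, recompute its seven pools from the design
#' parameters and check each against the positive-pool set. Used as an
#' independent check of \code{\link{decode_assay}}.
#'
#' @inheritParams decode_assay
#' @return same structure as \code{\link{decode_assay}}.
#' @export
decode_bruteforce <- function(calls, design) {
  pos1 <- calls$pool_id[calls$call %in% c("allele1", "both")]
  pos2 <- calls$pool_id[calls$call %in% c("allele2", "both")]
  set1 <- integer(0); set2 <- integer(0)
  for (i in seq_len(design$n_coords) - 1L) {
    ok1 <- TRUE; ok2 <- TRUE
    for (d in seq_len(7)) {
      p <- pool_of_scalar(design, i, d)
      if (ok1 && !(p %in% pos1)) ok1 <- FALSE
      if (ok2 && !(p %in% pos2)) ok2 <- FALSE
      if (!ok1 && !ok2) break
    }
    if (ok1) set1 <- c(set1, i)
    if (ok2) set2 <- c(set2, i)
  }
  amb <- intersect(set1, set2)
  only1 <- setdiff(set1, amb)
  only2 <- setdiff(set2, amb)
  idx <- c(only1, only2, amb)
  cls <- c(rep("allele1", length(only1)), rep("allele2", length(only2)),
           rep("both", length(amb)))
  o <- order(idx)
  co <- index_coord(design, idx[o])
  list(allele1 = only1, allele2 = only2, ambiguous = amb,
       score = data.frame(index = idx[o],
                          clone_id = coord_name(co$plate, co$row, co$col),
                          class = cls[o]))
}

#' Screen the whole library: decode every assay and build the score table
#'
#' @param calls data.frame of pool calls for all assays (\code{pool_id},
#'   \code{assay_id}, \code{call}).
#' @param design a \code{\link{pooling_design}}.
#' @return list of class \code{library_screen}:
#'   \item{score_table}{data.frame (index, clone_id, assay_id, class)}
#'   \item{per_assay}{per-assay hit counts: putative clones per
#'     nucleotide, ambiguous, and total distinct clones}
#' @export
screen_library <- function(calls, design) {
  stopifnot(all(c("pool_id", "assay_id", "call") %in% names(calls)))
  ids <- unique(calls$assay_id)
  st <- vector("list", length(ids))
  pa <- vector("list", length(ids))
  for (k in seq_along(ids)) {
    dec <- decode_assay(calls[calls$assay_id == ids[k], ], design)
    if (nrow(dec$score) > 0) {
      s <- dec$score
      s$assay_id <- ids[k]
      st[[k]] <- s[, c("index", "clone_id", "assay_id", "class")]
    }
    pa[[k]] <- data.frame(assay_id = ids[k],
                          n_allele1 = length(dec$allele1) +
                            length(dec$ambiguous),
                          n_allele2 = length(dec$allele2) +
                            length(dec$ambiguous),
                          n_ambiguous = length(dec$ambiguous),
                          n_total = length(dec$allele1) +
                            length(dec$allele2) + length(dec$ambiguous))
  }
  score_table <- do.call(rbind, st[!vapply(st, is.null, logical(1))])
  if (is.null(score_table))
    score_table <- data.frame(index = integer(0), clone_id = character(0),
                              assay_id = character(0), class = character(0))
  structure(list(score_table = score_table,
                 per_assay = do.call(rbind, pa)),
            class = "library_screen")
}

#' @export
print.library_screen <- function(x, ...) {
  cat(sprintf("Library screen: %d scores over %d putative clones, %d assays\n",
              nrow(x$score_table), length(unique(x$score_table$clone_id)),
              nrow(x$per_assay)))
  invisible(x)
}
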