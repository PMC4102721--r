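#' Simulate a BAC clone library over the amphidiploid genome
#'
#' Lays the two homoeologous regions out on a long genome coordinate line
#' with background sequence space on either side, then drops one clone
#' interval per library coordinate: the start is uniform over the genome
#' and the length Normal(\code{insert_size_mean_bp},
#' \code{insert_size_sd_bp}) truncated at 20 kbp. Clones overlapping a
#' region of interest are labelled with its subgenome.
#'
#' The background genome length is rescaled so that
#' \code{library size x mean insert / total genome = coverage_target};
#' the rescaling is reported via \code{message()}. If the caller pinned
#' \code{genome_length_bp} and the pinned value is inconsistent with the
#' coverage target by more than 10\%, an error is raised instead.
#'
#' @param amph an \code{\link{derive_amphidiploid}} result.
#' @param config a \code{\link{sim_config}} (defaults to the one recorded
#'   in \code{amph}).
#' @return an object of class \code{bac_library}: \code{clones} data.frame
#'   (index, clone_id, plate/row/col, start/end/len, subgenome in
#'   \{A, C, bg\}), the genome \code{layout}, and the realised coverage.
#' @export
simulate_bac_library <- function(amph, config = NULL) {
  stopifnot(inherits(amph, "amphidiploid"))
  config <- config %||% amph$pair$config
  set.seed(substream(config$seed, "bac_library"))

  n <- library_size(config)
  la <- length(amph$genome_a)
  lc <- length(amph$genome_c)

  if (n == 0) {
    layout <- list(total = la + lc, a_start = 0, a_len = la,
                   c_start = la, c_len = lc)
    clones <- data.frame(index = integer(0), clone_id = character(0),
                         plate = integer(0), row = integer(0),
                         col = integer(0), start = numeric(0),
                         end = numeric(0), len = numeric(0),
                         subgenome = character(0))
    return(structure(list(clones = clones, layout = layout,
                          coverage_realised = 0, config = config,
                          seed = config$seed), class = "bac_library"))
  }

  required_total <- n * config$insert_size_mean_bp / config$coverage_target
  required_bg <- required_total - la - lc
  if (required_bg <= 0)
    stop("coverage target, insert size and library size leave no room for ",
         "a background genome (regions alone exceed the implied genome)")
  if (!is.null(config$genome_length_bp)) {
    rel <- abs(config$genome_length_bp - required_bg) /
      max(required_bg, 1)
    if (rel > 0.10)
      stop(sprintf(paste0("configured genome_length_bp (%.0f) is inconsistent ",
                          "with the coverage target (requires %.0f bp of ",
                          "background, %.0f%% off)"),
                   config$genome_length_bp, required_bg, 100 * rel))
    if (rel > 0)
      message(sprintf("rescaling background genome from %.0f to %.0f bp to honour coverage target",
                      config$genome_length_bp, required_bg))
  } else {
    message(sprintf("background genome set to %.0f bp for %.1fx coverage",
                    required_bg, config$coverage_target))
  }
  bg <- max(round(required_bg), 0)
  total <- bg + la + lc

  # regions sit inside the line, separated by thirds of the background
  g <- bg %/% 3
  a_start <- g
  c_start <- 2 * g + la
  layout <- list(total = total, a_start = a_start, a_len = la,
                 c_start = c_start, c_len = lc)

  len <- pmax(round(rnorm(n, config$insert_size_mean_bp,
                          config$insert_size_sd_bp)), 20000)
  start <- floor(runif(n, 0, pmax(total - len, 1)))
  end <- start + len

  overlaps <- function(s, e, ws, wl) s < ws + wl & e > ws
  in_a <- overlaps(start, end, a_start, la)
  in_c <- overlaps(start, end, c_start, lc)
  subgenome <- ifelse(in_a, "A", ifelse(in_c, "C", "bg"))

  idx <- seq_len(n) - 1L
  wpp <- config$rows_per_plate * config$cols_per_plate
  plate <- idx %/% wpp
  row <- (idx %% wpp) %/% config$cols_per_plate
  col <- idx %% config$cols_per_plate

  clones <- data.frame(index = idx,
                       clone_id = coord_name(plate, row, col),
                       plate = plate, row = row, col = col,
                       start = start, end = end, len = len,
                       subgenome = subgenome)
  structure(list(clones = clones, layout = layout,
                 coverage_realised = sum(len) / total,
                 config = config, seed = config$seed),
            class = "bac_library")
}

#' @export
print.bac_library <- function(x, ...) {
  cat(sprintf("BAC library: %d clones, genome %.0f bp, realised coverage %.2fx; %d region-A clones, %d region-C clones\n",
              nrow(x$clones), x$layout$total, x$coverage_realised,
              sum(x$clones$subgenome == "A"),
              sum(x$clones$subgenome == "C")))
  invisible(x)
}

# global genome positions of an assay's two homoeologous loci
assay_locus_positions <- function(panel_row, layout) {
  c(A = layout$a_start + panel_row$a_pos - 1,
    C = layout$c_start + panel_row$c_pos - 1)
}
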