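#' Calling thresholds for pool genotyping signals
#'
#' The published thresholds: only pools with normalised R >= 0.2 are
#' evaluated; theta <= 0.05 and theta >= 0.95 assign the two alternative
#' assay nucleotides, anything between is called as containing both. All
#' thresholds are inclusive.
#'
#' @param r_min minimum normalised intensity for a pool to be evaluated.
#' @param theta_low,theta_high theta cut-offs for the two nucleotides.
#' @return an object of class \code{calling_params}.
#' @export
calling_params <- function(r_min = 0.2, theta_low = 0.05,
                           theta_high = 0.95) {
  stopifnot(r_min >= 0, theta_low >= 0, theta_high <= 1,
            theta_low < theta_high)
  structure(list(r_min = r_min, theta_low = theta_low,
                 theta_high = theta_high), class = "calling_params")
}

#' Classify pool signals into discrete calls
#'
#' Every (R, theta) pair maps to exactly one of four classes:
#' \code{negative} (R below \code{r_min}), \code{allele1}
#' (theta <= \code{theta_low}), \code{allele2} (theta >= \code{theta_high})
#' or \code{both} (theta strictly between the cut-offs). Thresholds are
#' inclusive, matching the published rule.
#'
#' @param signals data.frame with \code{pool_id}, \code{assay_id},
#'   \code{norm_r}, \code{norm_theta} (or a \code{pool_signals} object).
#' @param params a \code{\link{calling_params}}.
#' @return the input data.frame with a \code{call} column appended.
#' @export
classify_pools <- function(signals, params = calling_params()) {
  if (inherits(signals, "pool_signals")) signals <- signals$signals
  stopifnot(is.data.frame(signals),
            all(c("pool_id", "assay_id", "norm_r", "norm_theta") %in%
                names(signals)),
            inherits(params, "calling_params"))
  r <- signals$norm_r
  th <- signals$norm_theta
  bad_r <- !is.finite(r) | r < 0
  if (any(bad_r))
    stop("invalid normalised R for pool(s): ",
         paste(utils::head(signals$pool_id[bad_r], 5), collapse = ", "))
  evaluated <- r >= params$r_min
  bad_th <- evaluated & (!is.finite(th) | th < 0 | th > 1)
  if (any(bad_th))
    stop("invalid normalised theta for pool(s): ",
         paste(utils::head(signals$pool_id[bad_th], 5), collapse = ", "))
  call <- rep("negative", length(r))
  call[evaluated & th <= params$theta_low] <- "allele1"
  call[evaluated & th >= params$theta_high] <- "allele2"
  call[evaluated & th > params$theta_low & th < params$theta_high] <- "both"
  signals$call <- call
  signals
}

#' Classify a single pool signal
#' @param norm_r,norm_theta the signal.
#' @param params a \code{\link{calling_params}}.
#' @return one of \code{"negative"}, \code{"allele1"}, \code{"allele2"},
#'   \code{"both"}.
#' @export
classify_pool <- function(norm_r, norm_theta, params = calling_params()) {
  classify_pools(data.frame(pool_id = "p", assay_id = "a",
                            norm_r = norm_r, norm_theta = norm_theta),
                 params)$call
}

#' Per-assay counts of pools by call class
#' @param calls output of \code{\link{classify_pools}}.
#' @return data.frame assay_id x call-class counts, plus a total column.
#' @export
plate_summary <- function(calls) {
  stopifnot(all(c("assay_id", "call") %in% names(calls)))
  lv <- c("negative", "allele1", "allele2", "both")
  tab <- table(factor(calls$assay_id, levels = unique(calls$assay_id)),
               factor(calls$call, levels = lv))
  out <- as.data.frame.matrix(tab)
  out <- cbind(assay_id = rownames(out), out, total = rowSums(out))
  rownames(out) <- NULL
  out
}

#' Read a pool-signal table from TSV
#'
#' Expects columns pool_id, assay_id, norm_r, norm_theta; lines starting
#' with \code{#} (e.g. a seed header) are skipped.
#' @param path file path.
#' @return data.frame.
#' @export
read_pool_signals <- function(path) {
  df <- utils::read.delim(path, comment.char = "#",
                          stringsAsFactors = FALSE)
  need <- c("pool_id", "assay_id", "norm_r", "norm_theta")
  if (!all(need %in% names(df)))
    stop("signal table must have columns ", paste(need, collapse = ", "))
  df
}

#' Write pool calls (or any table) as TSV with a seed header
#'
#' Numeric columns are rendered with \code{\%.17g} so that a read back via
#' \code{\link{read_pool_signals}} (or \code{read.delim}) is lossless.
#' @param df data.frame to write.
#' @param path file path.
#' @param seed optional seed recorded as a \code{# seed:} comment line.
#' @return invisibly, the path.
#' @export
write_tsv <- function(df, path, seed = NULL) {
  out <- df
  for (j in seq_along(out))
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(seed)) writeLines(sprintf("# seed: %d", seed), con)
  utils::write.table(out, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
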