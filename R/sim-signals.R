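clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Simulate per-pool genotyping signals for an assay panel
#'
#' For every assay x pool combination, determines the pool's true content
#' from the clone library (clones covering the assay's homoeologous loci,
#' or an off-target locus, respond with their assay nucleotide), then
#' emits a normalised intensity R and allele-frequency angle theta:
#' pools holding only nucleotide-1 clones sit at theta ~ 0, only
#' nucleotide-2 clones at theta ~ 1, mixed pools in between, and empty
#' pools emit residual fluorescence. Dropout and nucleotide-flip noise are
#' applied per the \code{\link{noise_model}}; the ideal (pre-noise) call
#' of every pool is retained as ground truth.
#'
#' @param panel an \code{\link{simulate_assay_panel}} result.
#' @param library a \code{\link{simulate_bac_library}} result.
#' @param design a \code{\link{pooling_design}}.
#' @param noise a \code{\link{noise_model}}.
#' @param seed seed (defaults to the panel's).
#' @return an object of class \code{pool_signals}:
#'   \item{signals}{data.frame pool_id, assay_id, norm_r, norm_theta}
#'   \item{true_hits}{data.frame of truly responding clones per assay
#'     (index, clone_id, allele)}
#'   \item{pool_truth}{data.frame of per-pool ideal calls and which noise
#'     events were applied}
#' @export
simulate_pool_signals <- function(panel, library, design,
                                  noise = NULL, seed = NULL) {
  stopifnot(inherits(panel, "assay_panel"),
            inherits(library, "bac_library"),
            inherits(design, "pooling_design"))
  noise <- noise %||% panel$config$noise
  seed <- seed %||% panel$seed
  set.seed(substream(seed, "pool_signals"))

  clones <- library$clones
  if (nrow(clones) != design$n_coords)
    stop("library and pooling design disagree on the number of coordinates")
  lay <- panel$layout
  df <- panel$assays
  np <- length(design$pool_ids)
  offs <- design$dim_offsets

  # restrict interval scans to clones that can respond at all
  ia <- which(clones$subgenome == "A")
  ic <- which(clones$subgenome == "C")
  ibg <- which(clones$subgenome == "bg")

  covering <- function(rows, pos) {
    rows[clones$start[rows] <= pos & clones$end[rows] > pos]
  }
  global_pools <- function(clone_rows) {
    if (length(clone_rows) == 0) return(integer(0))
    m <- design$membership[clone_rows, , drop = FALSE]
    unique(as.integer(t(t(m) + offs)) + 1L)
  }

  sig_list <- vector("list", nrow(df))
  truth_list <- vector("list", nrow(df))
  hits_list <- vector("list", nrow(df))

  for (i in seq_len(nrow(df))) {
    pos_a <- lay$a_start + df$a_pos[i] - 1
    pos_c <- lay$c_start + df$c_pos[i] - 1
    rows_a <- covering(ia, pos_a)
    rows_c <- covering(ic, pos_c)
    resp <- data.frame(row = integer(0), allele = integer(0))
    if (!is.na(df$detect_a[i]) && length(rows_a) > 0)
      resp <- rbind(resp, data.frame(row = rows_a, allele = df$detect_a[i]))
    if (!is.na(df$detect_c[i]) && length(rows_c) > 0)
      resp <- rbind(resp, data.frame(row = rows_c, allele = df$detect_c[i]))
    if (!is.na(df$offtarget_pos[i])) {
      rows_o <- covering(ibg, df$offtarget_pos[i])
      if (length(rows_o) > 0)
        resp <- rbind(resp, data.frame(row = rows_o,
                                       allele = df$offtarget_allele[i]))
    }

    g1 <- global_pools(resp$row[resp$allele == 1L])
    g2 <- global_pools(resp$row[resp$allele == 2L])
    ideal <- rep("negative", np)
    ideal[g1] <- "allele1"
    ideal[g2] <- ifelse(ideal[g2] == "allele1", "both", "allele2")

    positive <- ideal != "negative"
    dropped <- positive & runif(np) < noise$pool_dropout_prob
    flipped <- positive & !dropped & runif(np) < noise$nucleotide_flip_prob

    eff <- ideal
    eff[dropped] <- "negative"
    fl1 <- flipped & ideal == "allele1"
    fl2 <- flipped & ideal == "allele2"
    flb <- flipped & ideal == "both"
    eff[fl1] <- "allele2"
    eff[fl2] <- "allele1"
    eff[flb] <- sample(c("allele1", "allele2"), sum(flb), replace = TRUE)

    r <- numeric(np)
    on <- eff != "negative"
    r[on] <- pmax(rnorm(sum(on), noise$positive_r_mean,
                        noise$positive_r_sd), 0.25)
    r[!on] <- clamp(abs(rnorm(sum(!on), noise$residual_r_mean,
                              noise$residual_r_sd)), 0, 0.19)

    th <- runif(np)
    j <- noise$theta_jitter_sd
    i1 <- eff == "allele1"; i2 <- eff == "allele2"; ib <- eff == "both"
    th[i1] <- clamp(abs(rnorm(sum(i1), 0, j)), 0, 0.05)
    th[i2] <- 1 - clamp(abs(rnorm(sum(i2), 0, j)), 0, 0.05)
    th[ib] <- clamp(rnorm(sum(ib), 0.5, 2 * j), 0.10, 0.90)

    sig_list[[i]] <- data.frame(pool_id = design$pool_ids,
                                assay_id = df$assay_id[i],
                                norm_r = r, norm_theta = th)
    truth_list[[i]] <- data.frame(pool_id = design$pool_ids,
                                  assay_id = df$assay_id[i],
                                  ideal_call = ideal, dropped = dropped,
                                  flipped = flipped)
    if (nrow(resp) > 0)
      hits_list[[i]] <- data.frame(assay_id = df$assay_id[i],
                                   index = clones$index[resp$row],
                                   clone_id = clones$clone_id[resp$row],
                                   allele = resp$allele)
  }

  structure(list(signals = do.call(rbind, sig_list),
                 true_hits = do.call(rbind, hits_list),
                 pool_truth = do.call(rbind, truth_list),
                 noise = noise, seed = seed),
            class = "pool_signals")
}

#' @export
print.pool_signals <- function(x, ...) {
  cat(sprintf("Pool signals: %d assays x %d pools; %d true clone hits\n",
              length(unique(x$signals$assay_id)),
              length(unique(x$signals$pool_id)),
              if (is.null(x$true_hits)) 0L else nrow(x$true_hits)))
  invisible(x)
}

#' Reference normalisation of raw two-channel intensities
#'
#' Converts raw channel intensities into the (R, theta) coordinates the
#' calling thresholds operate on: \code{theta = (2/pi) atan2(ch2, ch1)}
#' and \code{R = ch1 + ch2}. Real screens supply vendor-normalised values;
#' this reference implementation exists for the simulator and for tests.
#'
#' @param ch1,ch2 non-negative channel intensities (vectorised).
#' @return data.frame with \code{norm_r} and \code{norm_theta}.
#' @export
normalize_channels <- function(ch1, ch2) {
  stopifnot(all(ch1 >= 0), all(ch2 >= 0))
  data.frame(norm_r = ch1 + ch2,
             norm_theta = ifelse(ch1 + ch2 == 0, NA_real_,
                                 (2 / pi) * atan2(ch2, ch1)))
}
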