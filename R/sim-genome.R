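#' Simulate a pair of diverged progenitor regions
#'
#' Generates one region sequence, then derives its homoeologous counterpart
#' by applying substitutions at \code{divergence_rate} (uniform over the
#' three alternative bases) and indels at \code{indel_rate} with
#' geometrically distributed lengths. The full alignment between the two
#' sequences is recorded column by column, so downstream steps never have
#' to re-align: the truth is the alignment.
#'
#' @param config a \code{\link{sim_config}}.
#' @return an object of class \code{progenitor_pair} with elements
#'   \item{seq_a,seq_c}{integer-encoded sequences (1..4 = A,C,G,T)}
#'   \item{alignment}{list of parallel column vectors \code{a_pos},
#'     \code{c_pos} (1-based, NA at gaps), \code{a_base}, \code{c_base},
#'     \code{match}}
#'   \item{snp_sites}{data.frame of intergenomic substitution sites
#'     (\code{a_pos}, \code{c_pos}, \code{base_a}, \code{base_c})}
#'   \item{map_a_to_c}{integer vector mapping A positions to C positions
#'     (NA where deleted)}
#'   \item{identity}{realised fraction of matching alignment columns}
#' @export
simulate_progenitor_pair <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  L <- config$region_length_bp
  set.seed(substream(config$seed, "progenitor_pair"))

  a <- sample.int(4L, L, replace = TRUE)

  sub_at <- runif(L) < config$divergence_rate
  c_from_a <- a
  n_sub <- sum(sub_at)
  if (n_sub > 0) {
    c_from_a[sub_at] <- ((a[sub_at] - 1L +
                          sample.int(3L, n_sub, replace = TRUE)) %% 4L) + 1L
  }

  # indel events anchored at A positions; insertions go after the anchor
  ev_pos <- which(runif(L) < config$indel_rate)
  ev_ins <- runif(length(ev_pos)) < 0.5
  ev_len <- rgeom(length(ev_pos), prob = 1 / config$indel_mean_len) + 1L

  deleted <- logical(L)
  for (k in seq_along(ev_pos)) {
    if (!ev_ins[k]) {
      p <- ev_pos[k]
      deleted[p:min(p + ev_len[k] - 1L, L)] <- TRUE
    }
  }
  ins_at <- integer(L)
  if (any(ev_ins)) {
    ip <- ev_pos[ev_ins]
    il <- ev_len[ev_ins]
    for (k in seq_along(ip)) ins_at[ip[k]] <- ins_at[ip[k]] + il[k]
  }

  n_col <- L + sum(ins_at)
  cum_ins <- cumsum(ins_at)
  a_col <- seq_len(L) + c(0L, cum_ins[-L])   # column index of each A base

  col_a_pos <- rep(NA_integer_, n_col)
  col_a_pos[a_col] <- seq_len(L)
  col_a_base <- rep(NA_integer_, n_col)
  col_a_base[a_col] <- a

  col_c_base <- rep(NA_integer_, n_col)
  col_c_base[a_col] <- ifelse(deleted, NA_integer_, c_from_a)
  ins_cols <- which(is.na(col_a_pos))
  if (length(ins_cols) > 0)
    col_c_base[ins_cols] <- sample.int(4L, length(ins_cols), replace = TRUE)

  c_present <- !is.na(col_c_base)
  col_c_pos <- rep(NA_integer_, n_col)
  col_c_pos[c_present] <- cumsum(c_present)[c_present]
  seq_c <- col_c_base[c_present]

  match <- !is.na(col_a_base) & c_present & col_a_base == col_c_base
  snp_col <- which(!is.na(col_a_base) & c_present & col_a_base != col_c_base)

  map_a_to_c <- rep(NA_integer_, L)
  map_a_to_c[col_a_pos[a_col][!deleted]] <- col_c_pos[a_col][!deleted]

  structure(list(
    seq_a = a,
    seq_c = seq_c,
    alignment = list(a_pos = col_a_pos, c_pos = col_c_pos,
                     a_base = col_a_base, c_base = col_c_base,
                     match = match),
    snp_sites = data.frame(a_pos = col_a_pos[snp_col],
                           c_pos = col_c_pos[snp_col],
                           base_a = col_a_base[snp_col],
                           base_c = col_c_base[snp_col]),
    map_a_to_c = map_a_to_c,
    identity = sum(match) / n_col,
    config = config,
    seed = config$seed), class = "progenitor_pair")
}

#' @export
print.progenitor_pair <- function(x, ...) {
  cat(sprintf("Progenitor region pair: A %d bp, C %d bp, identity %.4f, %d intergenomic SNPs\n",
              length(x$seq_a), length(x$seq_c), x$identity,
              nrow(x$snp_sites)))
  invisible(x)
}

#' Render the recorded alignment as two gapped sequences
#'
#' @param pair a \code{progenitor_pair}.
#' @return character vector of two equal-length gapped strings (A then C).
#' @export
alignment_strings <- function(pair) {
  aln <- pair$alignment
  a <- ifelse(is.na(aln$a_base), "-", BASES[aln$a_base])
  c_ <- ifelse(is.na(aln$c_base), "-", BASES[aln$c_base])
  c(A = paste(a, collapse = ""), C = paste(c_, collapse = ""))
}

#' Derive the amphidiploid subgenomes from a progenitor pair
#'
#' Each subgenome differs from its progenitor by accession-level
#' substitutions at a per-site rate drawn uniformly from
#' \code{accession_snp_rate_range}. Intergenomic SNP sites whose alleles
#' changed are flagged, and sites at which the two subgenomes became
#' identical are flagged monomorphic (these later yield category-5 assays).
#' Accession changes are substitutions only, so subgenome coordinates stay
#' identical to progenitor coordinates.
#'
#' @param pair a \code{\link{simulate_progenitor_pair}} result.
#' @param rate_range optional override of the accession SNP rate range.
#' @param seed optional override of the master seed.
#' @return an object of class \code{amphidiploid} with the two subgenome
#'   sequences, the per-subgenome accession SNP tables, and
#'   \code{snp_truth}: the progenitor SNP table extended with the
#'   amphidiploid alleles and \code{mutated}/\code{monomorphic} flags.
#' @export
derive_amphidiploid <- function(pair, rate_range = NULL, seed = NULL) {
  stopifnot(inherits(pair, "progenitor_pair"))
  config <- pair$config
  rate_range <- rate_range %||% config$accession_snp_rate_range
  seed <- seed %||% config$seed
  set.seed(substream(seed, "amphidiploid"))

  mutate_seq <- function(s, rate) {
    pos <- which(runif(length(s)) < rate)
    new <- s
    if (length(pos) > 0) {
      new[pos] <- ((s[pos] - 1L +
                    sample.int(3L, length(pos), replace = TRUE)) %% 4L) + 1L
    }
    list(seq = new, snps = data.frame(pos = pos, from = s[pos],
                                      to = new[pos]))
  }

  rate_a <- runif(1, rate_range[1], rate_range[2])
  rate_c <- runif(1, rate_range[1], rate_range[2])
  ma <- mutate_seq(pair$seq_a, rate_a)
  mc <- mutate_seq(pair$seq_c, rate_c)

  st <- pair$snp_sites
  st$amph_a <- ma$seq[st$a_pos]
  st$amph_c <- mc$seq[st$c_pos]
  st$mutated <- st$amph_a != st$base_a | st$amph_c != st$base_c
  st$monomorphic <- st$amph_a == st$amph_c

  structure(list(genome_a = ma$seq, genome_c = mc$seq,
                 rate_a = rate_a, rate_c = rate_c,
                 acc_snps_a = ma$snps, acc_snps_c = mc$snps,
                 snp_truth = st, pair = pair,
                 seed = seed), class = "amphidiploid")
}

#' @export
print.amphidiploid <- function(x, ...) {
  cat(sprintf("Amphidiploid: accession SNP rates A %.4f / C %.4f; %d/%d intergenomic sites mutated, %d monomorphic\n",
              x$rate_a, x$rate_c, sum(x$snp_truth$mutated),
              nrow(x$snp_truth), sum(x$snp_truth$monomorphic)))
  invisible(x)
}
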