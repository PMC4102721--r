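#' Noise model for simulated pool signals
#'
#' Describes the stochastic pathologies of a multiplexed two-channel
#' genotyping screen of BAC pools: positive pools that fail to exceed the
#' intensity threshold (dropout), pools ascribed to the wrong assay
#' nucleotide (flips), the residual fluorescence of empty pools, and jitter
#' on the allele-frequency angle (theta).
#'
#' Positive intensities are Normal(\code{positive_r_mean},
#' \code{positive_r_sd}) truncated below at 0.25 so that, with all noise
#' probabilities at zero, every truly positive pool clears the 0.2 calling
#' threshold; signal loss is modelled explicitly through
#' \code{pool_dropout_prob} rather than through the tail of the intensity
#' distribution. Residual intensities are |Normal| truncated into
#' [0, 0.19].
#'
#' @param pool_dropout_prob probability that a truly positive pool emits
#'   only residual fluorescence.
#' @param nucleotide_flip_prob probability that a positive pool is ascribed
#'   to the wrong assay nucleotide (its theta lands in the opposite class).
#' @param residual_r_mean,residual_r_sd parameters of the residual
#'   (negative-pool) intensity distribution.
#' @param positive_r_mean,positive_r_sd parameters of the positive-pool
#'   intensity distribution.
#' @param theta_jitter_sd standard deviation of the jitter applied to the
#'   ideal theta of a positive pool.
#' @return an object of class \code{noise_model}.
#' @export
noise_model <- function(pool_dropout_prob = 0.02,
                        nucleotide_flip_prob = 0.005,
                        residual_r_mean = 0.05,
                        residual_r_sd = 0.03,
                        positive_r_mean = 0.9,
                        positive_r_sd = 0.2,
                        theta_jitter_sd = 0.015) {
  stopifnot(is_prob(pool_dropout_prob), is_prob(nucleotide_flip_prob),
            residual_r_mean >= 0, residual_r_sd >= 0,
            positive_r_mean >= 0, positive_r_sd >= 0,
            theta_jitter_sd >= 0)
  structure(list(pool_dropout_prob = pool_dropout_prob,
                 nucleotide_flip_prob = nucleotide_flip_prob,
                 residual_r_mean = residual_r_mean,
                 residual_r_sd = residual_r_sd,
                 positive_r_mean = positive_r_mean,
                 positive_r_sd = positive_r_sd,
                 theta_jitter_sd = theta_jitter_sd),
            class = "noise_model")
}

#' Zero-noise model
#'
#' Convenience constructor for a noiseless screen (no dropout, no flips,
#' no theta jitter); residual and positive intensity distributions keep
#' their defaults.
#' @return a \code{noise_model}.
#' @export
noise_free <- function() {
  noise_model(pool_dropout_prob = 0, nucleotide_flip_prob = 0,
              theta_jitter_sd = 0)
}

#' Simulation configuration
#'
#' Bundles every parameter of the synthetic study: the homoeologous region
#' pair, the amphidiploid, the clone library, the pooling design, the assay
#' panel and the noise model. The defaults reproduce the study conditions
#' of the underlying experiment: two ~1 Mbp progenitor regions diverged so
#' that local alignments average about 96.3% identity, accession-level SNP
#' rates drawn from [0.82%, 1.98%], a 216-plate 384-well library (82,944
#' coordinates) with ~10x genome coverage and 135-150 kbp inserts, and a
#' 50-assay panel with the observed mix of assay categories.
#'
#' @param region_length_bp length of each homoeologous region (>= 1000).
#' @param genome_length_bp length of the background genome hosting
#'   off-target clones; \code{NULL} derives it from the coverage target.
#' @param divergence_rate per-site substitution rate between the progenitor
#'   regions.
#' @param indel_rate per-site indel initiation rate between progenitors.
#' @param indel_mean_len mean indel length (geometric).
#' @param accession_snp_rate_range range of per-site substitution rates
#'   between each subgenome and its progenitor.
#' @param n_plates,rows_per_plate,cols_per_plate library geometry.
#' @param insert_size_mean_bp,insert_size_sd_bp clone insert length model
#'   (Normal, truncated at 20 kbp).
#' @param coverage_target genome equivalents held by the library.
#' @param n_assays number of SNP assays in the panel.
#' @param assay_category_mix fractions of assay categories 1-5.
#' @param assay_offtarget_prob probability that an assay has an additional
#'   homologous locus in the background genome.
#' @param noise a \code{\link{noise_model}}.
#' @param seed master seed; all stages derive sub-stream seeds from it.
#' @return an object of class \code{sim_config}.
#' @export
sim_config <- function(region_length_bp = 1e6,
                       genome_length_bp = NULL,
                       divergence_rate = 0.037,
                       indel_rate = 0.001,
                       indel_mean_len = 3,
                       accession_snp_rate_range = c(0.0082, 0.0198),
                       n_plates = 216,
                       rows_per_plate = 16,
                       cols_per_plate = 24,
                       insert_size_mean_bp = 142500,
                       insert_size_sd_bp = 15000,
                       coverage_target = 10,
                       n_assays = 50,
                       assay_category_mix = c(0.46, 0.26, 0.12, 0.08, 0.08),
                       assay_offtarget_prob = 0.02,
                       noise = noise_model(),
                       seed = 1L) {
  if (!is_count(region_length_bp) || region_length_bp < 1000)
    stop("region_length_bp must be an integer >= 1000 (degenerate region)")
  if (!is.null(genome_length_bp) &&
      (!is_count(genome_length_bp) || genome_length_bp < 0))
    stop("genome_length_bp must be a non-negative integer or NULL")
  stopifnot(is_prob(divergence_rate), is_prob(indel_rate),
            indel_mean_len >= 1,
            length(accession_snp_rate_range) == 2,
            all(accession_snp_rate_range >= 0),
            all(accession_snp_rate_range <= 1),
            accession_snp_rate_range[1] <= accession_snp_rate_range[2],
            is_count(n_plates), is_count(rows_per_plate),
            is_count(cols_per_plate),
            is_count(round(insert_size_mean_bp)),
            insert_size_sd_bp >= 0,
            coverage_target > 0,
            is_count(n_assays),
            length(assay_category_mix) == 5,
            all(assay_category_mix >= 0),
            is_prob(assay_offtarget_prob),
            inherits(noise, "noise_model"),
            is_count(abs(seed)))
  if (abs(sum(assay_category_mix) - 1) > 1e-8)
    stop("assay_category_mix must sum to 1")
  structure(list(region_length_bp = as.integer(region_length_bp),
                 genome_length_bp = genome_length_bp,
                 divergence_rate = divergence_rate,
                 indel_rate = indel_rate,
                 indel_mean_len = indel_mean_len,
                 accession_snp_rate_range = accession_snp_rate_range,
                 n_plates = as.integer(n_plates),
                 rows_per_plate = as.integer(rows_per_plate),
                 cols_per_plate = as.integer(cols_per_plate),
                 insert_size_mean_bp = insert_size_mean_bp,
                 insert_size_sd_bp = insert_size_sd_bp,
                 coverage_target = coverage_target,
                 n_assays = as.integer(n_assays),
                 assay_category_mix = assay_category_mix,
                 assay_offtarget_prob = assay_offtarget_prob,
                 noise = noise,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation configuration\n")
  cat(sprintf("  region: %d bp x2, divergence %.3f, indel %.4f\n",
              x$region_length_bp, x$divergence_rate, x$indel_rate))
  cat(sprintf("  library: %d plates x %d rows x %d cols = %d clones\n",
              x$n_plates, x$rows_per_plate, x$cols_per_plate,
              library_size(x)))
  cat(sprintf("  inserts: %.0f +- %.0f bp, coverage target %.1fx\n",
              x$insert_size_mean_bp, x$insert_size_sd_bp, x$coverage_target))
  cat(sprintf("  assays: %d, category mix %s\n", x$n_assays,
              paste(format(x$assay_category_mix), collapse = "/")))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

#' Number of clone coordinates in the configured library
#' @param config a \code{sim_config}.
#' @return integer library size.
#' @export
library_size <- function(config) {
  config$n_plates * config$rows_per_plate * config$cols_per_plate
}
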