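#' Simulate an intergenomic SNP assay panel with category pathologies
#'
#' Places \code{n_assays} assays at intergenomic SNP sites of the
#' amphidiploid, honouring the configured mix of assay categories:
#'
#' \describe{
#'   \item{1-3}{clean sites: the intergenomic SNP is conserved in the
#'     amphidiploid and neither subgenome carries an accession SNP within
#'     the oligonucleotide footprint. The categories differ only in the
#'     reference-panel evidence later generated for them.}
#'   \item{4}{sites where exactly one subgenome carries one or more
#'     accession SNPs within the footprint; that subgenome escapes
#'     detection, so the assay identifies clones with a single nucleotide.}
#'   \item{5}{sites monomorphic in the amphidiploid (an accession change
#'     converted one allele into the other), so clones of both subgenomes
#'     respond with the same nucleotide.}
#' }
#'
#' Assays are spread across the region by drafting sites bin by bin;
#' marker order is the order of the A-genome positions. With probability
#' \code{assay_offtarget_prob} an assay additionally matches a homologous
#' locus in the background genome.
#'
#' @param amph an \code{\link{derive_amphidiploid}} result.
#' @param library a \code{\link{simulate_bac_library}} result (provides
#'   the genome layout for off-target loci).
#' @param config a \code{\link{sim_config}}.
#' @param footprint_bp oligonucleotide footprint half-width used for the
#'   interference rule.
#' @return an object of class \code{assay_panel}: data.frame \code{assays}
#'   with assay_id, marker order, site positions, the two assay
#'   nucleotides, the true category, the responding allele index per
#'   subgenome (\code{detect_a}, \code{detect_c}; NA = undetectable) and
#'   any off-target locus.
#' @export
simulate_assay_panel <- function(amph, library, config = NULL,
                                 footprint_bp = 25) {
  stopifnot(inherits(amph, "amphidiploid"), inherits(library, "bac_library"))
  config <- config %||% amph$pair$config
  set.seed(substream(config$seed, "assay_panel"))

  st <- amph$snp_truth
  if (nrow(st) == 0) stop("no intergenomic SNP sites available")

  # footprint interference: accession SNPs within footprint_bp of the site
  # (excluding the site itself), per subgenome
  near <- function(acc_pos, site_pos) {
    if (length(acc_pos) == 0) return(rep(FALSE, length(site_pos)))
    hits <- findInterval(site_pos + footprint_bp, sort(acc_pos)) -
      findInterval(site_pos - footprint_bp - 1, sort(acc_pos))
    # subtract a hit landing exactly on the site (an accession SNP at the
    # site itself is the mutated-site case, not footprint interference)
    hits - (site_pos %in% acc_pos)
  }
  int_a <- near(amph$acc_snps_a$pos, st$a_pos) > 0
  int_c <- near(amph$acc_snps_c$pos, st$c_pos) > 0

  clean <- !st$mutated & !int_a & !int_c
  cat4_ok <- !st$mutated & xor(int_a, int_c)
  cat5_ok <- st$monomorphic & !int_a & !int_c &
    (st$amph_a == st$base_a | st$amph_a == st$base_c)

  n <- config$n_assays
  mix <- config$assay_category_mix
  want <- floor(mix * n)
  rem <- n - sum(want)
  if (rem > 0) {
    extra <- order(mix * n - want, decreasing = TRUE)[seq_len(rem)]
    want[extra] <- want[extra] + 1L
  }

  eligible <- list(`1` = which(clean), `2` = which(clean),
                   `3` = which(clean), `4` = which(cat4_ok),
                   `5` = which(cat5_ok))
  avail <- c(sum(clean), sum(cat4_ok), sum(cat5_ok))
  need_clean <- sum(want[1:3])
  shortfall <- character(0)
  if (avail[1] < need_clean)
    shortfall <- c(shortfall, sprintf("categories 1-3: need %d clean sites, have %d",
                                      need_clean, avail[1]))
  if (avail[2] < want[4])
    shortfall <- c(shortfall, sprintf("category 4: need %d interfered sites, have %d",
                                      want[4], avail[2]))
  if (avail[3] < want[5])
    shortfall <- c(shortfall, sprintf("category 5: need %d monomorphic sites, have %d",
                                      want[5], avail[3]))
  if (length(shortfall) > 0)
    stop("requested assay category mix infeasible: ",
         paste(shortfall, collapse = "; "))

  # draft sites bin by bin so markers spread over the region;
  # categories are shuffled over marker slots
  cats <- sample(rep.int(1:5, want))
  L <- length(amph$genome_a)
  bins <- floor(seq(0, L, length.out = n + 1))
  taken <- logical(nrow(st))
  site_of <- integer(n)
  for (k in seq_len(n)) {
    pool <- eligible[[as.character(cats[k])]]
    pool <- pool[!taken[pool]]
    if (length(pool) == 0)
      stop("ran out of eligible sites for category ", cats[k])
    inbin <- pool[st$a_pos[pool] > bins[k] & st$a_pos[pool] <= bins[k + 1]]
    pick <- if (length(inbin) > 0) {
      if (length(inbin) == 1) inbin else sample(inbin, 1)
    } else {
      # nearest eligible site to the bin centre
      pool[which.min(abs(st$a_pos[pool] - (bins[k] + bins[k + 1]) / 2))]
    }
    taken[pick] <- TRUE
    site_of[k] <- pick
  }

  df <- st[site_of, ]
  df$category_true <- cats
  ord <- order(df$a_pos)
  df <- df[ord, ]
  df$order <- seq_len(n)
  df$assay_id <- sprintf("SNP%03d", df$order)

  # responding allele index per subgenome: which assay nucleotide the
  # subgenome's base at the site matches (NA = no response)
  allele_of <- function(base) ifelse(base == df$base_a, 1L,
                                     ifelse(base == df$base_c, 2L, NA_integer_))
  df$detect_a <- allele_of(df$amph_a)
  df$detect_c <- allele_of(df$amph_c)
  # category 4: the interfered subgenome escapes detection
  c4 <- df$category_true == 4
  blocked_a <- int_a[site_of][ord]
  df$detect_a[c4 & blocked_a] <- NA_integer_
  df$detect_c[c4 & !blocked_a] <- NA_integer_

  # off-target homologous loci in the background genome
  df$offtarget_pos <- NA_real_
  df$offtarget_allele <- NA_integer_
  off <- runif(n) < config$assay_offtarget_prob
  if (any(off)) {
    lay <- library$layout
    bg_third <- max((lay$total - lay$a_len - lay$c_len) %/% 3, 1)
    df$offtarget_pos[off] <- floor(runif(sum(off), 0, bg_third))
    df$offtarget_allele[off] <- sample(1:2, sum(off), replace = TRUE)
  }

  rownames(df) <- NULL
  structure(list(assays = df, footprint_bp = footprint_bp,
                 layout = library$layout, config = config,
                 seed = config$seed), class = "assay_panel")
}

#' @export
print.assay_panel <- function(x, ...) {
  cat(sprintf("Assay panel: %d assays, true categories %s\n",
              nrow(x$assays),
              paste(table(x$assays$category_true), collapse = "/")))
  invisible(x)
}

#' Marker order of a panel
#' @param panel an \code{assay_panel} (or a data.frame with
#'   \code{assay_id} and \code{a_pos}).
#' @return data.frame \code{assay_id}, \code{order}, \code{pos}, sorted by
#'   position on the A-genome reference.
#' @export
marker_order <- function(panel) {
  df <- if (inherits(panel, "assay_panel")) panel$assays else panel
  df <- df[order(df$a_pos), ]
  data.frame(assay_id = df$assay_id, order = seq_len(nrow(df)),
             pos = df$a_pos)
}

#' Simulate the reference-panel genotype evidence for a panel
#'
#' Emits one evidence row per assay in the layout of the published
#' assignment table: two accessions plus a WGS call per progenitor (plus a
#' GSS call for the C-genome progenitor), the amphidiploid genotyping call,
#' the amphidiploid amplicon base(s), and the amplicon base of one
#' validated clone per subgenome. The pattern is driven by the assay's
#' true category: category 2 plants a discordant source on one progenitor
#' side, category 3 renders both sides uninformative, category 4 shows a
#' single nucleotide for the amphidiploid with discordant subgenome
#' amplicons, and category 5 is monomorphic throughout the amphidiploid.
#'
#' @param panel an \code{\link{simulate_assay_panel}} result.
#' @param seed optional seed override.
#' @return data.frame of class \code{genotype_evidence}.
#' @export
simulate_reference_panel <- function(panel, seed = NULL) {
  stopifnot(inherits(panel, "assay_panel"))
  seed <- seed %||% panel$seed
  set.seed(substream(seed, "reference_panel"))
  df <- panel$assays
  n <- nrow(df)

  a <- BASES[df$base_a]
  c_ <- BASES[df$base_c]
  ev <- data.frame(assay_id = df$assay_id,
                   rapa_acc1 = a, rapa_acc2 = a, rapa_wgs = a,
                   ole_acc1 = c_, ole_acc2 = c_, ole_wgs = c_,
                   ole_gss = c_,
                   express_call = paste0(a, "/", c_),
                   express_amplicon = mapply(iupac_pair, a, c_),
                   bac_a = a, bac_c = c_,
                   stringsAsFactors = FALSE)

  for (i in seq_len(n)) {
    cat_i <- df$category_true[i]
    if (cat_i == 2) {
      # one discordant source on one progenitor side
      side <- sample(c("rapa", "ole"), 1)
      src <- if (side == "rapa") sample(c("rapa_acc1", "rapa_acc2"), 1)
             else sample(c("ole_acc1", "ole_acc2", "ole_gss"), 1)
      ev[i, src] <- if (side == "rapa") c_[i] else a[i]
    } else if (cat_i == 3) {
      # both progenitor panels show the same base: uninformative
      keep <- sample(c(a[i], c_[i]), 1)
      ev[i, c("rapa_acc1", "rapa_acc2", "rapa_wgs",
              "ole_acc1", "ole_acc2", "ole_wgs", "ole_gss")] <- keep
    } else if (cat_i == 4) {
      detected <- if (is.na(df$detect_a[i])) df$detect_c[i] else df$detect_a[i]
      d <- BASES[if (detected == 1) df$base_a[i] else df$base_c[i]]
      ev$express_call[i] <- d
      ev$express_amplicon[i] <- d
      # the blocked subgenome's amplicon still reads its true allele
      ev$bac_a[i] <- BASES[df$amph_a[i]]
      ev$bac_c[i] <- BASES[df$amph_c[i]]
    } else if (cat_i == 5) {
      s <- BASES[df$amph_a[i]]
      ev$express_call[i] <- s
      ev$express_amplicon[i] <- s
      ev$bac_a[i] <- s
      ev$bac_c[i] <- s
    }
  }
  class(ev) <- c("genotype_evidence", "data.frame")
  ev
}

#' Ground-truth validation oracle over a simulated screen
#'
#' Returns a closure emulating the PCR-amplicon validation of a putative
#' clone: \code{oracle(clone_id, assay_id, subgenome = NULL)} reports
#' whether the clone truly carries a locus of the assay
#' (\code{"present"} / \code{"absent"}) together with the subgenome of the
#' locus it carries (\code{"A"}, \code{"C"} or \code{"offtarget"} for
#' clones matching only a homologous background locus). Amplicons listed
#' in \code{masked} are specific for one subgenome: claims concerning the
#' other subgenome return \code{"untestable"}.
#'
#' @param panel an \code{assay_panel}.
#' @param library a \code{bac_library}.
#' @param masked named character vector: \code{masked[assay_id]} is the
#'   subgenome that the assay's amplicon \emph{cannot} interrogate.
#' @return function \code{(clone_id, assay_id, subgenome = NULL)}.
#' @export
make_validation_oracle <- function(panel, library, masked = NULL) {
  df <- panel$assays
  lay <- panel$layout
  clones <- library$clones
  clone_lookup <- seq_len(nrow(clones))
  names(clone_lookup) <- clones$clone_id
  assay_lookup <- seq_len(nrow(df))
  names(assay_lookup) <- df$assay_id

  function(clone_id, assay_id, subgenome = NULL) {
    ci <- clone_lookup[clone_id]
    ai <- assay_lookup[assay_id]
    if (is.na(ci)) stop("unknown clone id: ", clone_id)
    if (is.na(ai)) stop("unknown assay id: ", assay_id)
    if (!is.null(subgenome) && !is.null(masked)) {
      m <- masked[assay_id]
      if (!is.na(m) && identical(unname(m), subgenome))
        return(list(outcome = "untestable", subgenome = NA_character_))
    }
    s <- clones$start[ci]; e <- clones$end[ci]
    pos_a <- lay$a_start + df$a_pos[ai] - 1
    pos_c <- lay$c_start + df$c_pos[ai] - 1
    if (s <= pos_a && e > pos_a)
      return(list(outcome = "present", subgenome = "A"))
    if (s <= pos_c && e > pos_c)
      return(list(outcome = "present", subgenome = "C"))
    if (!is.na(df$offtarget_pos[ai]) &&
        s <= df$offtarget_pos[ai] && e > df$offtarget_pos[ai])
      return(list(outcome = "present", subgenome = "offtarget"))
    list(outcome = "absent", subgenome = NA_character_)
  }
}
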