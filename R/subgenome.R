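# --- evidence parsing helpers ---------------------------------------------

RAPA_SOURCES <- c("rapa_acc1", "rapa_acc2", "rapa_wgs")
OLE_SOURCES <- c("ole_acc1", "ole_acc2", "ole_wgs", "ole_gss")
MISSING_CODES <- c("", "-", "nd", "NA", "na")

# shape of the amphidiploid call: list(kind = both|single|none, nts)
express_shape <- function(call, amplicon) {
  parse1 <- function(v) {
    if (is.na(v) || v %in% MISSING_CODES) return(NULL)
    if (grepl("/", v, fixed = TRUE)) {
      p <- strsplit(v, "/", fixed = TRUE)[[1]]
      if (length(p) == 2 && all(p %in% BASES) && p[1] != p[2])
        return(list(kind = "both", nts = p))
      return(NULL)
    }
    if (v %in% BASES) return(list(kind = "single", nts = v))
    ex <- iupac_expand(v)
    if (!is.null(ex)) return(list(kind = "both", nts = ex))
    NULL
  }
  parse1(call) %||% parse1(amplicon) %||% list(kind = "none", nts = NULL)
}

# a progenitor side is concordant iff it has >= 2 non-missing,
# non-heterozygous sources and they all name the same base
side_concordant <- function(values) {
  v <- values[!is.na(values) & !(values %in% MISSING_CODES)]
  v <- v[v %in% BASES]   # heterozygous / unreadable codes break concordance
  n_informative <- sum(!is.na(values) & !(values %in% MISSING_CODES))
  if (length(v) >= 2 && length(v) == n_informative &&
      length(unique(v)) == 1)
    unique(v)
  else
    NA_character_
}

#' Classify one assay from reference-panel evidence (pre-inference)
#'
#' Applies the evidence rules for assay categories: with a two-nucleotide
#' amphidiploid call, category 1 requires both progenitor sides to be
#' concordant on different nucleotides of the pair, category 2 exactly
#' one concordant side, and anything else is left pending (category 3
#' after clone-based inference). With a single-nucleotide call, the assay
#' is category 5 when the subgenome amplicons show the site monomorphic,
#' otherwise pending (category 4). Without a usable amphidiploid call the
#' assay stays unassigned; if \code{allow_alignment_only} is set and the
#' two progenitor WGS bases differ, they map the nucleotides directly
#' (the assay itself remains unassigned, mirroring assays whose pool data
#' were usable but whose genotyping evidence was not).
#'
#' A side claiming both nucleotides while the other side is entirely
#' missing is flagged as a contradiction and left unassigned.
#'
#' @param ev one evidence row (see
#'   \code{\link{simulate_reference_panel}} for the column layout).
#' @param allow_alignment_only map nucleotides from WGS evidence when the
#'   experimental call is unusable.
#' @return list: \code{assay_id}, \code{category} (one of \code{"1"},
#'   \code{"2"}, \code{"5"}, \code{"pending3"}, \code{"pending4"},
#'   \code{"unassigned"}), \code{nt1}, \code{nt2} (the call pair, if
#'   any), \code{sub1}, \code{sub2} (subgenome of each nucleotide or NA),
#'   \code{detected_nt} (single-call nucleotide), \code{contradiction}.
#' @export
classify_assay <- function(ev, allow_alignment_only = FALSE) {
  getv <- function(col) {
    v <- ev[[col]]
    if (is.null(v) || length(v) == 0) NA_character_ else as.character(v)
  }
  rapa <- vapply(RAPA_SOURCES, getv, character(1))
  ole <- vapply(OLE_SOURCES, getv, character(1))
  shape <- express_shape(getv("express_call"), getv("express_amplicon"))

  res <- list(assay_id = getv("assay_id"), category = "unassigned",
              nt1 = NA_character_, nt2 = NA_character_,
              sub1 = NA_character_, sub2 = NA_character_,
              detected_nt = NA_character_, contradiction = FALSE)

  if (shape$kind == "none") {
    if (allow_alignment_only) {
      wa <- getv("rapa_wgs"); wc <- getv("ole_wgs")
      if (wa %in% BASES && wc %in% BASES && wa != wc) {
        res$nt1 <- wa; res$nt2 <- wc
        res$sub1 <- "A"; res$sub2 <- "C"
      }
    }
    return(res)
  }

  if (shape$kind == "single") {
    s <- shape$nts
    res$detected_nt <- s
    ba <- getv("bac_a"); bc <- getv("bac_c")
    mono <- ba %in% BASES && bc %in% BASES && ba == bc && ba == s
    res$category <- if (mono) "5" else "pending4"
    return(res)
  }

  # two-nucleotide call
  x <- shape$nts[1]; y <- shape$nts[2]
  res$nt1 <- x; res$nt2 <- y
  ra <- side_concordant(rapa)
  ol <- side_concordant(ole)

  present <- function(v) v %in% BASES
  claims_both <- function(vals) all(c(x, y) %in% vals)
  all_missing <- function(vals)
    all(is.na(vals) | vals %in% MISSING_CODES)
  if ((claims_both(rapa) && all_missing(ole)) ||
      (claims_both(ole) && all_missing(rapa))) {
    res$contradiction <- TRUE
    return(res)
  }

  ra_ok <- present(ra) && ra %in% c(x, y)
  ol_ok <- present(ol) && ol %in% c(x, y)
  if (ra_ok && ol_ok && ra != ol) {
    res$category <- "1"
    res$sub1 <- if (x == ra) "A" else "C"
    res$sub2 <- if (res$sub1 == "A") "C" else "A"
  } else if (ra_ok && !ol_ok) {
    res$category <- "2"
    res$sub1 <- if (x == ra) "A" else "C"
    res$sub2 <- if (res$sub1 == "A") "C" else "A"
  } else if (ol_ok && !ra_ok) {
    res$category <- "2"
    res$sub1 <- if (x == ol) "C" else "A"
    res$sub2 <- if (res$sub1 == "A") "C" else "A"
  } else {
    # neither side concordant, or both concordant on the same base
    res$category <- "pending3"
  }
  res
}

#' Classify every assay in an evidence table
#' @param evidence a \code{genotype_evidence} data.frame.
#' @param allow_alignment_only see \code{\link{classify_assay}}.
#' @return data.frame of class \code{assay_categories} with one row per
#'   assay: category, nt1/nt2, sub1/sub2, detected_nt, contradiction.
#' @export
classify_assays <- function(evidence, allow_alignment_only = FALSE) {
  rows <- lapply(seq_len(nrow(evidence)), function(i)
    as.data.frame(classify_assay(evidence[i, ], allow_alignment_only),
                  stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  class(out) <- c("assay_categories", "data.frame")
  out
}

# implied subgenome of each score row, given assay categories and the
# assay nucleotide bases; NA where unassignable
implied_subgenomes <- function(score_table, categories, assay_defs) {
  m <- match(score_table$assay_id, categories$assay_id)
  d <- match(score_table$assay_id, assay_defs$assay_id)
  base <- ifelse(score_table$class == "allele1", assay_defs$nt1[d],
                 ifelse(score_table$class == "allele2",
                        assay_defs$nt2[d], NA_character_))
  sub <- ifelse(is.na(base), NA_character_,
                ifelse(!is.na(categories$nt1[m]) &
                         base == categories$nt1[m], categories$sub1[m],
                       ifelse(!is.na(categories$nt2[m]) &
                                base == categories$nt2[m],
                              categories$sub2[m], NA_character_)))
  # single-nucleotide (category 4) assays carry their map on detected_nt
  single <- !is.na(categories$detected_nt[m])
  sub[single] <- ifelse(!is.na(base[single]) &
                          base[single] == categories$detected_nt[m][single],
                        categories$sub1[m][single], NA_character_)[
                          seq_len(sum(single))]
  sub
}

# majority subgenome label per clone from category-1/2 scores only
clone_labels_from_cat12 <- function(score_table, categories, assay_defs) {
  keep <- categories$category %in% c("1", "2")
  st <- score_table[score_table$assay_id %in%
                      categories$assay_id[keep], , drop = FALSE]
  if (nrow(st) == 0)
    return(data.frame(clone_id = character(0), label = character(0)))
  sub <- implied_subgenomes(st, categories, assay_defs)
  ok <- !is.na(sub)
  st <- st[ok, , drop = FALSE]; sub <- sub[ok]
  tab <- table(st$clone_id, sub)
  na_ <- if ("A" %in% colnames(tab)) tab[, "A"] else rep(0, nrow(tab))
  nc_ <- if ("C" %in% colnames(tab)) tab[, "C"] else rep(0, nrow(tab))
  lab <- ifelse(na_ > nc_, "A", ifelse(nc_ > na_, "C", NA_character_))
  data.frame(clone_id = rownames(tab), label = lab,
             stringsAsFactors = FALSE)
}

#' Resolve pending assay categories from co-identified clones
#'
#' Clones already assignable through category-1/2 assays vote on the
#' subgenome of each pending assay nucleotide: a nucleotide is assigned
#' the majority subgenome of the clones it identified when the majority
#' fraction reaches \code{quorum} over at least \code{min_informative}
#' labelled clones. A pending two-nucleotide assay whose nucleotides
#' resolve to the two different subgenomes becomes category 3; a pending
#' single-nucleotide assay whose detected nucleotide resolves becomes
#' category 4. Anything else stays unassigned. Category-1/2/5 rows are
#' never altered, so the operation is idempotent.
#'
#' @param categories an \code{assay_categories} data.frame.
#' @param score_table a screen score table.
#' @param assay_defs data.frame assay_id, nt1, nt2 (bases as characters).
#' @param quorum required majority fraction (default 0.8).
#' @param min_informative minimum labelled clones per nucleotide.
#' @return the completed \code{assay_categories} data.frame.
#' @export
infer_pending <- function(categories, score_table, assay_defs,
                          quorum = 0.8, min_informative = 3) {
  labels <- clone_labels_from_cat12(score_table, categories, assay_defs)
  lab <- labels$label
  names(lab) <- labels$clone_id

  vote <- function(aid, allele_class) {
    ids <- score_table$clone_id[score_table$assay_id == aid &
                                  score_table$class == allele_class]
    v <- lab[ids]
    v <- v[!is.na(v)]
    if (length(v) < min_informative) return(NA_character_)
    tt <- table(v)
    top <- names(tt)[which.max(tt)]
    if (max(tt) / length(v) >= quorum) top else NA_character_
  }

  out <- categories
  for (i in seq_len(nrow(out))) {
    if (out$category[i] == "pending3") {
      s1 <- vote(out$assay_id[i], "allele1")
      s2 <- vote(out$assay_id[i], "allele2")
      if (!is.na(s1) && !is.na(s2) && s1 != s2) {
        out$category[i] <- "3"
        out$sub1[i] <- s1
        out$sub2[i] <- s2
      } else {
        out$category[i] <- "unassigned"
      }
    } else if (out$category[i] == "pending4") {
      d <- match(out$assay_id[i], assay_defs$assay_id)
      cls <- if (!is.na(d) && identical(out$detected_nt[i],
                                        assay_defs$nt1[d])) "allele1"
             else "allele2"
      s <- vote(out$assay_id[i], cls)
      if (!is.na(s)) {
        out$category[i] <- "4"
        out$sub1[i] <- s      # sub1 holds the detected nucleotide's map
        out$sub2[i] <- NA_character_
      } else {
        out$category[i] <- "unassigned"
      }
    }
  }
  out
}

#' Assign putative clones to subgenomes and report conflicts
#'
#' Each clone's label is the consensus of the subgenomes implied by its
#' category-1 to 4 scores (category-5 scores and ambiguous both-class
#' scores never contribute). Clones whose scores imply both subgenomes
#' are reported as conflicts with their score breakdown.
#'
#' @param score_table a screen score table.
#' @param categories completed \code{assay_categories}.
#' @param assay_defs data.frame assay_id, nt1, nt2.
#' @return list: \code{clones} (clone_id, n_A, n_C, n_scores,
#'   multi_marker, label, conflict) and \code{conflicts} (the conflicted
#'   subset).
#' @export
assign_clones <- function(score_table, categories, assay_defs) {
  sub <- implied_subgenomes(score_table, categories, assay_defs)
  contributing <- !is.na(sub) &
    categories$category[match(score_table$assay_id,
                              categories$assay_id)] %in% c("1", "2", "3", "4")
  st <- score_table[contributing, , drop = FALSE]
  sub <- sub[contributing]
  all_ids <- unique(score_table$clone_id)
  n_a <- tapply(sub == "A", st$clone_id, sum)
  n_c <- tapply(sub == "C", st$clone_id, sum)
  nA <- ifelse(is.na(n_a[all_ids]), 0L, n_a[all_ids])
  nC <- ifelse(is.na(n_c[all_ids]), 0L, n_c[all_ids])
  n_scores <- as.integer(table(score_table$clone_id)[all_ids])
  out <- data.frame(clone_id = all_ids, n_A = as.integer(nA),
                    n_C = as.integer(nC), n_scores = n_scores,
                    multi_marker = nA + nC >= 2,
                    label = ifelse(nA > nC, "A",
                                   ifelse(nC > nA, "C", NA_character_)),
                    conflict = nA > 0 & nC > 0,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  list(clones = out, conflicts = out[out$conflict, , drop = FALSE])
}

#' Monte-Carlo noise-propagation estimate of the clone conflict rate
#'
#' Re-simulates pool signals from the same frozen truth (library, panel,
#' design) under the same noise model, re-runs calling, deconvolution and
#' clone assignment, and returns the subgenome-conflict rate among
#' multi-marker clones for each replicate. The mean and spread of these
#' rates constitute the package's propagation model for how pool-level
#' noise (dropout, nucleotide flips) and decoding shadows translate into
#' conflicting clone assignments.
#'
#' @param panel,library,design,noise the frozen simulation inputs.
#' @param categories completed assay categories (held fixed).
#' @param assay_defs data.frame assay_id, nt1, nt2.
#' @param n_rep number of replicates.
#' @param seed base seed for the replicates.
#' @return numeric vector of conflict rates, one per replicate.
#' @export
estimate_conflict_rate <- function(panel, library, design, noise,
                                   categories, assay_defs,
                                   n_rep = 10, seed = 1) {
  vapply(seq_len(n_rep), function(r) {
    sig <- simulate_pool_signals(panel, library, design, noise = noise,
                                 seed = substream(seed, paste0("cr", r)))
    calls <- classify_pools(sig$signals)
    scr <- screen_library(calls, design)
    asg <- assign_clones(scr$score_table, categories, assay_defs)
    mm <- asg$clones[asg$clones$multi_marker, , drop = FALSE]
    if (nrow(mm) == 0) return(0)
    mean(mm$conflict)
  }, numeric(1))
}

#' Assay nucleotide definitions of a panel
#' @param panel an \code{assay_panel}.
#' @return data.frame assay_id, nt1, nt2 (character bases).
#' @export
assay_defs <- function(panel) {
  df <- panel$assays
  data.frame(assay_id = df$assay_id, nt1 = BASES[df$base_a],
             nt2 = BASES[df$base_c], stringsAsFactors = FALSE)
}
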