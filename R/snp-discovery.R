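#' Filter alignment HSPs for intergenomic SNP assay suitability
#'
#' An HSP is suitable when it is at least \code{min_len} long with
#' identity at least \code{min_id}, its subject span lies inside the
#' target region, and its query has no sibling hit of length
#' >= \code{off_len} and identity >= \code{off_id} outside the target
#' region (the off-target exclusion rule). Defaults are the published
#' thresholds: 500 bp / 95\% for suitability, 150 bp / 90\% for
#' off-target exclusion.
#'
#' @param hsps data.frame with columns \code{query_id},
#'   \code{subject_id}, \code{s_start}, \code{s_end} (0-based half-open
#'   on the subject), \code{length_bp}, \code{identity_pct}.
#' @param target_region list with \code{subject_id}, \code{start},
#'   \code{end} (0-based half-open).
#' @param min_len,min_id suitability thresholds.
#' @param off_len,off_id off-target exclusion thresholds.
#' @return the suitable subset of \code{hsps}, with an
#'   \code{in_target_region} column appended.
#' @export
filter_hsps <- function(hsps, target_region, min_len = 500, min_id = 95,
                        off_len = 150, off_id = 90) {
  need <- c("query_id", "subject_id", "s_start", "s_end", "length_bp",
            "identity_pct")
  if (nrow(hsps) == 0) {
    hsps$in_target_region <- logical(0)
    return(hsps)
  }
  stopifnot(all(need %in% names(hsps)))
  in_target <- hsps$subject_id == target_region$subject_id &
    hsps$s_start >= target_region$start &
    hsps$s_end <= target_region$end
  off_hit <- !in_target & hsps$length_bp >= off_len &
    hsps$identity_pct >= off_id
  bad_queries <- unique(hsps$query_id[off_hit])
  keep <- in_target & hsps$length_bp >= min_len &
    hsps$identity_pct >= min_id & !(hsps$query_id %in% bad_queries)
  out <- hsps[keep, , drop = FALSE]
  out$in_target_region <- rep(TRUE, nrow(out))
  rownames(out) <- NULL
  out
}

#' Summary statistics of an HSP set
#' @param hsps an HSP data.frame.
#' @return list: \code{n}, \code{mean_length_bp}, \code{mean_identity_pct}.
#' @export
hsp_summary <- function(hsps) {
  list(n = nrow(hsps),
       mean_length_bp = if (nrow(hsps) > 0) mean(hsps$length_bp) else NA,
       mean_identity_pct = if (nrow(hsps) > 0) mean(hsps$identity_pct)
                           else NA)
}

#' Read 12-column tabular alignment hits
#'
#' Standard tabular hit format (query, subject, identity, length,
#' mismatches, gap opens, q.start, q.end, s.start, s.end, e-value,
#' bitscore; 1-based inclusive coordinates). Coordinates are converted to
#' 0-based half-open; minus-strand subject spans are flipped.
#' @param path file path.
#' @return data.frame with the columns \code{\link{filter_hsps}} expects.
#' @export
read_blast_hits <- function(path) {
  df <- utils::read.delim(path, header = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 12) stop("expected 12 tab-separated columns")
  names(df)[1:12] <- c("query_id", "subject_id", "identity_pct",
                       "length_bp", "mismatches", "gap_opens",
                       "q_start", "q_end", "s_start", "s_end",
                       "evalue", "bitscore")
  ss <- pmin(df$s_start, df$s_end) - 1L
  se <- pmax(df$s_start, df$s_end)
  df$s_start <- ss
  df$s_end <- se
  df$q_start <- df$q_start - 1L
  df
}

#' Assemble GSS reads into identity-masked contigs
#'
#' Merges connected components of overlapping single-pass reads into
#' contigs whose consensus retains only bases on which every covering
#' read agrees; any column with a disagreement is masked with \code{N}.
#' Masked columns are thereby ineligible as assay sites or flank bases,
#' which suppresses both accession-level SNPs between the sequenced lines
#' and single-pass sequencing errors.
#'
#' @param reads data.frame with \code{read_id} and \code{sequence}.
#' @param overlaps data.frame with \code{read_a}, \code{read_b},
#'   \code{offset}: the start of \code{read_b} relative to the start of
#'   \code{read_a}. Offsets must be consistent across the overlap graph
#'   and every listed pair must actually overlap.
#' @return list of contigs, each a list with \code{members},
#'   \code{consensus} (character string, \code{N} at masked columns),
#'   \code{offsets} (named, 0-based) and \code{masked} (0-based masked
#'   column positions).
#' @export
assemble_gss_contigs <- function(reads, overlaps) {
  stopifnot(all(c("read_id", "sequence") %in% names(reads)))
  ids <- reads$read_id
  seqs <- strsplit(toupper(reads$sequence), "")
  names(seqs) <- ids
  lens <- vapply(seqs, length, integer(1))

  adj <- lapply(ids, function(i) list())
  names(adj) <- ids
  if (nrow(overlaps) > 0) {
    stopifnot(all(c("read_a", "read_b", "offset") %in% names(overlaps)))
    for (k in seq_len(nrow(overlaps))) {
      a <- overlaps$read_a[k]; b <- overlaps$read_b[k]
      o <- overlaps$offset[k]
      if (!(a %in% ids) || !(b %in% ids))
        stop("overlap references unknown read")
      ov <- min(lens[a], o + lens[b]) - max(0, o)
      if (ov <= 0)
        stop("inconsistent offsets: reads ", a, " and ", b,
             " do not overlap at offset ", o)
      adj[[a]] <- c(adj[[a]], list(c(b, o)))
      adj[[b]] <- c(adj[[b]], list(c(a, -o)))
    }
  }

  # BFS per component, assigning global offsets and checking consistency
  offset <- setNames(rep(NA_real_, length(ids)), ids)
  comp <- setNames(rep(NA_integer_, length(ids)), ids)
  nc <- 0L
  for (root in ids) {
    if (!is.na(comp[root])) next
    nc <- nc + 1L
    offset[root] <- 0
    comp[root] <- nc
    queue <- root
    while (length(queue) > 0) {
      u <- queue[1]; queue <- queue[-1]
      for (e in adj[[u]]) {
        v <- e[1]; o <- as.numeric(e[2])
        cand <- offset[u] + o
        if (is.na(comp[v])) {
          comp[v] <- nc
          offset[v] <- cand
          queue <- c(queue, v)
        } else if (offset[v] != cand) {
          stop("inconsistent offsets in overlap graph at read ", v)
        }
      }
    }
  }

  lapply(seq_len(nc), function(ci) {
    members <- ids[comp == ci]
    offs <- offset[members] - min(offset[members])
    width <- max(offs + lens[members])
    cov <- matrix(NA_character_, nrow = length(members), ncol = width)
    for (k in seq_along(members)) {
      s <- seqs[[members[k]]]
      cov[k, (offs[k] + 1):(offs[k] + length(s))] <- s
    }
    cons <- apply(cov, 2, function(col) {
      b <- col[!is.na(col)]
      if (length(b) == 0) return("N")
      u <- unique(b)
      if (length(u) == 1 && u %in% BASES) u else "N"
    })
    list(members = members,
         consensus = paste(cons, collapse = ""),
         offsets = offs,
         masked = which(cons == "N") - 1L)
  })
}

#' Surrogate designability score of an assay window
#'
#' A stand-in for vendor designability scoring, defined as one minus the
#' fraction of window bases that fall in a homopolymer run of length
#' >= 6 or inside a centred 21-bp subwindow whose GC content lies outside
#' [0.25, 0.75]. Candidates scoring <= 0.6 are dropped by
#' \code{\link{find_assay_sites}}.
#'
#' @param window_seq character string (the assay window).
#' @return numeric in [0, 1].
#' @export
designability_surrogate <- function(window_seq) {
  s <- strsplit(toupper(window_seq), "")[[1]]
  n <- length(s)
  if (n == 0) return(0)
  r <- rle(s)
  in_run <- rep(r$lengths >= 6, r$lengths)
  gc <- as.numeric(s %in% c("G", "C"))
  half <- 10
  gc_bad <- vapply(seq_len(n), function(i) {
    w <- gc[max(1, i - half):min(n, i + half)]
    m <- mean(w)
    m < 0.25 || m > 0.75
  }, logical(1))
  1 - mean(in_run | gc_bad)
}

#' Locate candidate intergenomic SNP assay sites in a pairwise alignment
#'
#' Scans aligned homoeologous sequences column by column and emits a
#' candidate at every substitution site whose neighbourhood satisfies the
#' oligonucleotide constraints: within \code{flank_max} bases on each
#' side there is no indel and at most one mismatch, any such mismatch
#' lies more than \code{mismatch_clearance} bases from the site, at least
#' \code{flank_min} alignable bases exist per side, a full
#' \code{window}-base sequence window is extractable on each side, and
#' the designability surrogate exceeds \code{surrogate_min}. Columns with
#' ambiguity codes at the site are skipped (ambiguous flank bases count
#' as mismatches).
#'
#' @param aln_a,aln_c equal-length gapped sequences (\code{-} for gaps).
#' @param flank_min minimum identical flank length per side.
#' @param flank_max width of the constrained flank window per side.
#' @param mismatch_clearance minimum distance (bases) of a tolerated
#'   flank mismatch from the site.
#' @param window bases extracted either side of the site.
#' @param surrogate_min designability surrogate cut-off.
#' @return data.frame of class \code{assay_candidates}: 0-based ungapped
#'   site positions on both sequences, the two nucleotides, flanks, the
#'   perfect-identity flank length, and the surrogate score.
#' @export
find_assay_sites <- function(aln_a, aln_c, flank_min = 20, flank_max = 25,
                             mismatch_clearance = 15, window = 60,
                             surrogate_min = 0.6) {
  va <- strsplit(toupper(aln_a), "")[[1]]
  vc <- strsplit(toupper(aln_c), "")[[1]]
  if (length(va) != length(vc))
    stop("aligned sequences must have equal length")
  n <- length(va)
  gap_a <- va == "-"
  gap_c <- vc == "-"
  pos_a <- cumsum(!gap_a)          # 1-based ungapped position at column
  pos_c <- cumsum(!gap_c)
  ua <- va[!gap_a]                 # ungapped sequences
  uc <- vc[!gap_c]

  is_base <- function(x) x %in% BASES
  gap_col <- gap_a | gap_c
  mism_col <- !gap_col & (va != vc | !is_base(va) | !is_base(vc))
  site_col <- which(!gap_col & is_base(va) & is_base(vc) & va != vc)

  check_side <- function(i, step) {
    # walk flank_max columns away from site column i; disqualify on gap,
    # >1 mismatch, or a mismatch at distance <= clearance
    d <- 0L; j <- i; mism <- 0L
    while (d < flank_max) {
      j <- j + step
      if (j < 1 || j > n) break    # alignment edge: fewer columns is fine
      d <- d + 1L
      if (gap_col[j]) return(FALSE)
      if (mism_col[j]) {
        mism <- mism + 1L
        if (mism > 1L || d <= mismatch_clearance) return(FALSE)
      }
    }
    TRUE
  }
  perfect_run <- function(i, step) {
    d <- 0L; j <- i
    repeat {
      j <- j + step
      if (j < 1 || j > n || gap_col[j] || mism_col[j]) return(d)
      d <- d + 1L
    }
  }

  out <- list()
  for (i in site_col) {
    if (!check_side(i, -1L) || !check_side(i, 1L)) next
    pa <- pos_a[i]; pc <- pos_c[i]
    if (pa <= window || pa + window > length(ua)) next
    if (pc <= window || pc + window > length(uc)) next
    run <- min(perfect_run(i, -1L), perfect_run(i, 1L))
    if (run < flank_min) next
    fl <- paste(ua[(pa - window):(pa - 1)], collapse = "")
    fr <- paste(ua[(pa + 1):(pa + window)], collapse = "")
    surr <- designability_surrogate(paste0(fl, ua[pa], fr))
    if (surr <= surrogate_min) next
    out[[length(out) + 1]] <- data.frame(
      site_a = pa - 1L, site_c = pc - 1L,
      nt1 = va[i], nt2 = vc[i],
      flank_left = fl, flank_right = fr,
      flank_identity_len = run,
      designability_surrogate = surr,
      uniqueness_ok = NA, stringsAsFactors = FALSE)
  }
  res <- if (length(out) > 0) do.call(rbind, out) else
    data.frame(site_a = integer(0), site_c = integer(0),
               nt1 = character(0), nt2 = character(0),
               flank_left = character(0), flank_right = character(0),
               flank_identity_len = integer(0),
               designability_surrogate = numeric(0),
               uniqueness_ok = logical(0))
  class(res) <- c("assay_candidates", "data.frame")
  res
}

#' Check a candidate assay site against the amphidiploid subgenomes
#'
#' Classifies how a candidate designed on the progenitor alignment
#' behaves in the amphidiploid:
#' \describe{
#'   \item{conserved}{the two subgenomes still carry the candidate's two
#'     alleles and both oligonucleotide footprints are free of
#'     accession-level changes}
#'   \item{monomorphic}{the subgenomes are identical at the site
#'     (expected assay category 5)}
#'   \item{interfering}{at least one subgenome carries an accession
#'     change within \code{footprint_bp} of the site (expected category
#'     4)}
#'   \item{changed}{the site is still polymorphic but with a different
#'     allele pair}
#'   \item{unmappable}{the site has no counterpart on the C sequence}
#' }
#'
#' @param candidate one row of \code{\link{find_assay_sites}} output
#'   (site positions interpreted on the progenitor pair coordinates).
#' @param pair the \code{progenitor_pair}.
#' @param amph the \code{amphidiploid}.
#' @param footprint_bp footprint half-width.
#' @return character status.
#' @export
verify_in_amphidiploid <- function(candidate, pair, amph,
                                   footprint_bp = 25) {
  sa <- candidate$site_a + 1L
  sc <- candidate$site_c
  if (is.na(sc)) return("unmappable")
  sc <- sc + 1L
  if (sa < 1 || sa > length(amph$genome_a) ||
      sc < 1 || sc > length(amph$genome_c)) return("unmappable")
  aa <- BASES[amph$genome_a[sa]]
  ac <- BASES[amph$genome_c[sc]]
  if (aa == ac) return("monomorphic")
  near <- function(acc, pos) {
    any(acc$pos != pos & abs(acc$pos - pos) <= footprint_bp)
  }
  if (near(amph$acc_snps_a, sa) || near(amph$acc_snps_c, sc))
    return("interfering")
  if (setequal(c(aa, ac), c(candidate$nt1, candidate$nt2)))
    return("conserved")
  "changed"
}
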