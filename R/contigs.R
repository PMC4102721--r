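# small union-find used for contig components
uf_new <- function(n) seq_len(n)
uf_find <- function(p, i) {
  while (p[i] != i) i <- p[i]
  i
}
uf_union <- function(p, i, j) {
  ri <- uf_find(p, i); rj <- uf_find(p, j)
  if (ri != rj) p[rj] <- ri
  p
}

#' Select putative clones for validation
#'
#' Applies the three published selection criteria, in order:
#' \describe{
#'   \item{A}{the clone was scored by at least \code{min_assays} assays,
#'     not counting promiscuous assays (assays whose total putative clone
#'     count exceeds \code{promiscuity_limit}).}
#'   \item{B}{(clones failing A) two of its scoring markers are
#'     separated in the reference marker order by at least
#'     \code{separation_min} intervening markers.}
#'   \item{C}{the clone was scored by at least two directly adjacent
#'     markers among the first or last \code{end_marker_count} markers of
#'     the region.}
#' }
#' A clone records every criterion it meets; its primary label is the
#' first met in A > B > C order.
#'
#' @param score_table a screen score table (index, clone_id, assay_id,
#'   class).
#' @param morder a \code{\link{marker_order}} data.frame.
#' @param min_assays criterion-A threshold (default 4).
#' @param promiscuity_limit assays with more putative clones than this
#'   are not counted (default 3000).
#' @param separation_min criterion-B minimum intervening markers
#'   (default 2).
#' @param end_marker_count criterion-C window at each region end
#'   (default 3).
#' @return data.frame: clone_id, n_countable, crit_a/b/c, selected,
#'   criterion (primary label).
#' @export
select_candidates <- function(score_table, morder, min_assays = 4,
                              promiscuity_limit = 3000,
                              separation_min = 2, end_marker_count = 3) {
  per_assay <- table(score_table$assay_id)
  promiscuous <- names(per_assay)[per_assay > promiscuity_limit]
  st <- score_table[!(score_table$assay_id %in% promiscuous), ,
                    drop = FALSE]
  ord <- morder$order
  names(ord) <- morder$assay_id
  n_markers <- nrow(morder)
  end_lo <- seq_len(min(end_marker_count, n_markers))
  end_hi <- seq(max(1, n_markers - end_marker_count + 1), n_markers)

  ids <- unique(score_table$clone_id)
  pos_by_clone <- split(unname(ord[st$assay_id]), st$clone_id)

  res <- lapply(ids, function(cl) {
    pos <- sort(unique(pos_by_clone[[cl]]))
    n <- length(pos)
    a <- n >= min_assays
    b <- n >= 2 && (max(pos) - min(pos) - 1) >= separation_min
    has_adjacent_in <- function(win) {
      p <- pos[pos %in% win]
      length(p) >= 2 && any(diff(p) == 1)
    }
    cc <- has_adjacent_in(end_lo) || has_adjacent_in(end_hi)
    data.frame(clone_id = cl, n_countable = n, crit_a = a,
               crit_b = !a && b, crit_c = cc,
               selected = a || (!a && b) || cc,
               criterion = if (a) "A" else if (b) "B" else if (cc) "C"
                           else NA_character_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  attr(out, "promiscuous") <- promiscuous
  out
}

#' Validate the scores of selected clones against an oracle
#'
#' Every score of every selected clone is checked with the validation
#' oracle (in the study: PCR amplicons spanning the assay). Scores whose
#' amplicon is untestable for the implied subgenome are excluded from the
#' false-positive denominator. A clone's subgenome label is the consensus
#' of the oracle subgenomes over its confirmed scores; clones confirmed
#' only at a homologous locus outside the regions of interest are
#' labelled \code{offtarget}.
#'
#' @param score_table a screen score table.
#' @param selection output of \code{\link{select_candidates}} (or a
#'   character vector of clone ids).
#' @param categories completed \code{assay_categories} (for implied
#'   subgenomes).
#' @param defs data.frame assay_id, nt1, nt2.
#' @param oracle a \code{\link{make_validation_oracle}} closure.
#' @return list: \code{records} (all validation records),
#'   \code{confirmed} (clone_id, assay_id, subgenome),
#'   \code{false_positives}, \code{untestable}, \code{clone_labels}.
#' @export
validate_scores <- function(score_table, selection, categories, defs,
                            oracle) {
  sel_ids <- if (is.character(selection)) selection
             else selection$clone_id[selection$selected]
  st <- score_table[score_table$clone_id %in% sel_ids, , drop = FALSE]
  if (nrow(st) == 0)
    return(list(records = data.frame(), confirmed = data.frame(
      clone_id = character(0), assay_id = character(0),
      subgenome = character(0)), false_positives = data.frame(),
      untestable = data.frame(), clone_labels = data.frame(
        clone_id = character(0), label = character(0))))
  implied <- implied_subgenomes(st, categories, defs)
  rec <- vector("list", nrow(st))
  for (k in seq_len(nrow(st))) {
    r <- oracle(st$clone_id[k], st$assay_id[k],
                subgenome = if (is.na(implied[k])) NULL else implied[k])
    rec[[k]] <- data.frame(clone_id = st$clone_id[k],
                           assay_id = st$assay_id[k],
                           class = st$class[k],
                           implied_subgenome = implied[k],
                           outcome = r$outcome,
                           subgenome = r$subgenome,
                           stringsAsFactors = FALSE)
  }
  records <- do.call(rbind, rec)
  confirmed <- records[records$outcome == "present", ,
                       drop = FALSE][, c("clone_id", "assay_id",
                                         "subgenome")]
  fp <- records[records$outcome == "absent", , drop = FALSE]
  ut <- records[records$outcome == "untestable", , drop = FALSE]

  lab <- vapply(split(confirmed$subgenome, confirmed$clone_id),
                function(s) {
                  s <- s[s %in% c("A", "C")]
                  if (length(s) == 0) return("offtarget")
                  tt <- table(s)
                  names(tt)[which.max(tt)]
                }, character(1))
  clone_labels <- data.frame(clone_id = names(lab), label = unname(lab),
                             stringsAsFactors = FALSE)
  list(records = records, confirmed = confirmed, false_positives = fp,
       untestable = ut, clone_labels = clone_labels)
}

#' Build subgenome contigs from confirmed scores
#'
#' Clones sharing a confirmed marker are connected; contigs are the
#' connected components, per subgenome, ordered along the reference
#' marker order. Clones are ordered by leftmost confirmed marker, then
#' rightmost, then id. Clones whose confirmed markers skip interior
#' markers are reported as marker-order violations (never auto-corrected).
#'
#' @param confirmed data.frame clone_id, assay_id, subgenome.
#' @param morder a \code{\link{marker_order}}.
#' @param clone_labels data.frame clone_id, label; clones labelled
#'   \code{offtarget} (or with no confirmed marker) are dropped with a
#'   message.
#' @return object of class \code{contig_set}: \code{contigs} (list of
#'   id, subgenome, members, first, last, intervals), \code{violations},
#'   \code{confirmed}, \code{clone_labels}.
#' @export
build_contigs <- function(confirmed, morder, clone_labels) {
  ord <- morder$order
  names(ord) <- morder$assay_id
  lab <- clone_labels$label
  names(lab) <- clone_labels$clone_id

  contigs <- list()
  violations <- list()
  for (sg in c("A", "C")) {
    ids <- clone_labels$clone_id[clone_labels$label == sg]
    cf <- confirmed[confirmed$clone_id %in% ids, , drop = FALSE]
    dropped <- setdiff(ids, unique(cf$clone_id))
    if (length(dropped) > 0)
      message("dropping ", length(dropped),
              " clone(s) with no confirmed marker on subgenome ", sg)
    ids <- unique(cf$clone_id)
    if (length(ids) == 0) next
    pos <- split(unname(ord[cf$assay_id]), cf$clone_id)[ids]
    first <- vapply(pos, min, numeric(1))
    last <- vapply(pos, max, numeric(1))

    # connect clones sharing a confirmed marker
    p <- uf_new(length(ids))
    by_marker <- split(match(cf$clone_id, ids), cf$assay_id)
    for (m in by_marker) {
      m <- unique(m)
      if (length(m) > 1)
        for (k in 2:length(m)) p <- uf_union(p, m[1], m[k])
    }
    roots <- vapply(seq_along(ids), function(i) uf_find(p, i), integer(1))
    comp_first <- tapply(first, roots, min)
    comp_order <- names(sort(comp_first))
    for (ci in seq_along(comp_order)) {
      sel <- which(roots == as.integer(comp_order[ci]))
      o <- sel[order(first[sel], last[sel], ids[sel])]
      contigs[[length(contigs) + 1]] <- list(
        id = sprintf("%s-%d", sg, ci), subgenome = sg,
        members = ids[o],
        first = min(first[sel]), last = max(last[sel]),
        intervals = data.frame(clone_id = ids[o],
                               first = unname(first[o]),
                               last = unname(last[o])))
    }
    # marker-order violations: interior markers missing from a clone
    for (i in seq_along(ids)) {
      missing <- setdiff(seq(first[i], last[i]), pos[[ids[i]]])
      if (length(missing) > 0)
        violations[[length(violations) + 1]] <-
          data.frame(clone_id = ids[i], subgenome = sg,
                     missing_order = missing)
    }
  }
  structure(list(contigs = contigs,
                 violations = if (length(violations) > 0)
                   do.call(rbind, violations)
                 else data.frame(clone_id = character(0),
                                 subgenome = character(0),
                                 missing_order = integer(0)),
                 confirmed = confirmed,
                 clone_labels = clone_labels,
                 morder = morder), class = "contig_set")
}

#' @export
print.contig_set <- function(x, ...) {
  for (ct in x$contigs)
    cat(sprintf("  %s: %d clones, markers %d..%d\n", ct$id,
                length(ct$members), ct$first, ct$last))
  if (length(x$contigs) == 0) cat("  (no contigs)\n")
  invisible(x)
}

#' Number of contigs per subgenome
#' @param contig_set a \code{contig_set}.
#' @return named integer vector.
#' @export
contig_counts <- function(contig_set) {
  sg <- vapply(contig_set$contigs, `[[`, character(1), "subgenome")
  c(A = sum(sg == "A"), C = sum(sg == "C"))
}

#' Refine contigs by recovering false-negative scores
#'
#' For every contig member, markers interior to its confirmed interval
#' and the markers directly adjacent to its ends are tested with the
#' oracle; presences are integrated as recovered false negatives. The
#' pass repeats until no clone's interval grows (each pass strictly
#' extends the total confirmed interval, so termination is guaranteed),
#' then contigs and marker-order violations are rebuilt.
#'
#' @param contig_set a \code{\link{build_contigs}} result.
#' @param oracle a validation oracle.
#' @return list: \code{contig_set} (rebuilt), \code{false_negatives}
#'   (clone_id, assay_id, subgenome), \code{n_tests}.
#' @export
refine_contigs <- function(contig_set, oracle) {
  morder <- contig_set$morder
  aid <- morder$assay_id
  names(aid) <- morder$order
  ord <- morder$order
  names(ord) <- morder$assay_id
  n_markers <- nrow(morder)

  confirmed <- contig_set$confirmed
  lab <- contig_set$clone_labels$label
  names(lab) <- contig_set$clone_labels$clone_id

  tested <- new.env(parent = emptyenv())
  fn <- list()
  n_tests <- 0L
  repeat {
    grown <- FALSE
    pos <- split(unname(ord[confirmed$assay_id]), confirmed$clone_id)
    for (cl in names(pos)) {
      if (!(lab[cl] %in% c("A", "C"))) next
      p <- sort(unique(pos[[cl]]))
      cand <- union(setdiff(seq(min(p), max(p)), p),
                    c(min(p) - 1, max(p) + 1))
      cand <- cand[cand >= 1 & cand <= n_markers]
      for (m in cand) {
        key <- paste(cl, m)
        if (!is.null(tested[[key]])) next
        n_tests <- n_tests + 1L
        r <- oracle(cl, aid[[as.character(m)]], subgenome = lab[[cl]])
        tested[[key]] <- r$outcome
        if (r$outcome == "present" && r$subgenome %in% c("A", "C")) {
          confirmed <- rbind(confirmed,
                             data.frame(clone_id = cl,
                                        assay_id = aid[[as.character(m)]],
                                        subgenome = r$subgenome))
          fn[[length(fn) + 1]] <- data.frame(
            clone_id = cl, assay_id = aid[[as.character(m)]],
            subgenome = r$subgenome)
          grown <- TRUE
        }
      }
    }
    if (!grown) break
  }
  rebuilt <- build_contigs(confirmed, morder, contig_set$clone_labels)
  list(contig_set = rebuilt,
       false_negatives = if (length(fn) > 0) do.call(rbind, fn)
       else data.frame(clone_id = character(0), assay_id = character(0),
                       subgenome = character(0)),
       n_tests = n_tests)
}

#' Bridge adjacent contigs with additional putative clones
#'
#' For each gap between consecutive contigs of a subgenome, putative
#' clones (from the full score table, not only the selected set) scored
#' by markers within \code{end_marker_window} of either contig end are
#' validated across the gap interval; a confirmed clone reaching into
#' both contigs' marker intervals merges them. Gaps that cannot be
#' bridged are reported with a diagnosis: no candidates, candidates
#' mapping elsewhere (confirmed only at homologous off-target loci, or
#' nowhere), or confirmed candidates that do not span the gap.
#'
#' @param contig_set a (refined) \code{contig_set}.
#' @param score_table the full screen score table.
#' @param oracle a validation oracle.
#' @param end_marker_window markers from each contig end whose putative
#'   clones are candidates (default 2).
#' @return list: \code{contig_set} (with merges applied),
#'   \code{report} data.frame, \code{recovered} (newly confirmed clone
#'   scores).
#' @export
bridge_contigs <- function(contig_set, score_table, oracle,
                           end_marker_window = 2) {
  morder <- contig_set$morder
  ord <- morder$order
  names(ord) <- morder$assay_id
  aid <- morder$assay_id
  names(aid) <- morder$order

  confirmed <- contig_set$confirmed
  clone_labels <- contig_set$clone_labels
  members <- unique(confirmed$clone_id)
  report <- list()
  recovered <- list()

  for (sg in c("A", "C")) {
    cts <- Filter(function(ct) ct$subgenome == sg, contig_set$contigs)
    if (length(cts) < 2) next
    firsts <- vapply(cts, `[[`, numeric(1), "first")
    cts <- cts[order(firsts)]
    for (g in seq_len(length(cts) - 1)) {
      left <- cts[[g]]; right <- cts[[g + 1]]
      win <- c(seq(max(1, left$last - end_marker_window + 1), left$last),
               seq(right$first,
                   min(nrow(morder), right$first + end_marker_window - 1)))
      win_assays <- aid[as.character(win)]
      cand <- setdiff(unique(
        score_table$clone_id[score_table$assay_id %in% win_assays]),
        members)
      bridged_by <- NA_character_
      n_conf_other <- 0L
      if (length(cand) > 0) {
        span <- seq(max(1, left$last - end_marker_window + 1),
                    min(nrow(morder), right$first + end_marker_window - 1))
        for (cl in cand) {
          conf_m <- integer(0)
          sub_seen <- character(0)
          for (m in span) {
            r <- oracle(cl, aid[[as.character(m)]], subgenome = sg)
            if (r$outcome == "present") {
              sub_seen <- c(sub_seen, r$subgenome)
              if (identical(r$subgenome, sg)) conf_m <- c(conf_m, m)
            }
          }
          if (length(conf_m) == 0) {
            if (any(sub_seen == "offtarget")) n_conf_other <- n_conf_other + 1L
            next
          }
          if (min(conf_m) <= left$last && max(conf_m) >= right$first) {
            bridged_by <- cl
            confirmed <- rbind(confirmed, data.frame(
              clone_id = cl, assay_id = unname(aid[as.character(conf_m)]),
              subgenome = sg))
            if (!(cl %in% clone_labels$clone_id))
              clone_labels <- rbind(clone_labels,
                                    data.frame(clone_id = cl, label = sg))
            recovered[[length(recovered) + 1]] <- data.frame(
              clone_id = cl, assay_id = unname(aid[as.character(conf_m)]),
              subgenome = sg)
            break
          }
        }
      }
      diagnosis <- if (!is.na(bridged_by)) "bridged"
                   else if (length(cand) == 0) "no_candidates"
                   else if (n_conf_other > 0) "candidates_map_elsewhere"
                   else "no_spanning_clone"
      report[[length(report) + 1]] <- data.frame(
        subgenome = sg, left = left$id, right = right$id,
        gap_first = left$last, gap_last = right$first,
        n_candidates = length(cand), bridged = !is.na(bridged_by),
        bridged_by = bridged_by, diagnosis = diagnosis,
        stringsAsFactors = FALSE)
    }
  }
  rebuilt <- build_contigs(confirmed, morder, clone_labels)
  list(contig_set = rebuilt,
       report = if (length(report) > 0) do.call(rbind, report)
       else data.frame(subgenome = character(0), left = character(0),
                       right = character(0), gap_first = integer(0),
                       gap_last = integer(0), n_candidates = integer(0),
                       bridged = logical(0), bridged_by = character(0),
                       diagnosis = character(0)),
       recovered = if (length(recovered) > 0) do.call(rbind, recovered)
       else data.frame(clone_id = character(0), assay_id = character(0),
                       subgenome = character(0)))
}

#' Plain-text contig diagram
#'
#' Renders contig members as rows of marker-spanning rectangles:
#' \code{#} at confirmed markers, \code{=} across the confirmed
#' interval, one column per marker in reference order.
#'
#' @param contig_set a \code{contig_set}.
#' @return character vector of lines (also printed invisibly by
#'   \code{cat} when assigned to a file via \code{writeLines}).
#' @export
contig_diagram <- function(contig_set) {
  morder <- contig_set$morder
  ord <- morder$order
  names(ord) <- morder$assay_id
  n <- nrow(morder)
  lines <- sprintf("markers: %s", paste(morder$assay_id, collapse = " "))
  for (ct in contig_set$contigs) {
    lines <- c(lines, sprintf("contig %s (markers %d..%d)", ct$id,
                              ct$first, ct$last))
    cf <- contig_set$confirmed
    for (cl in ct$members) {
      p <- sort(unique(unname(
        ord[cf$assay_id[cf$clone_id == cl]])))
      row <- rep(" ", n)
      row[seq(min(p), max(p))] <- "="
      row[p] <- "#"
      lines <- c(lines, sprintf("  %-10s %s", cl,
                                paste(row, collapse = "")))
    }
  }
  lines
}
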