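#' Percentage of a count pair
#' @param num numerator (must not exceed \code{den}).
#' @param den denominator (> 0).
#' @return numeric percentage (raw ratio x 100, unrounded).
#' @export
percent <- function(num, den) {
  if (any(den == 0)) stop("zero denominator")
  if (any(num > den)) stop("numerator exceeds denominator")
  100 * num / den
}

#' Render a percentage at printed precision (round half up)
#' @param x numeric percentage.
#' @param digits decimal places.
#' @return character rendering, e.g. \code{"9.1"}, \code{"99.97"},
#'   \code{"72"}.
#' @export
render_percent <- function(x, digits = 1) {
  formatC(round_half_up(x, digits), format = "f", digits = digits)
}

#' Summarise a library screen
#'
#' Computes the per-assay hit counts and the clone multiplicity histogram
#' (how many clones were identified by exactly k assays), both over all
#' assays and excluding promiscuous assays (total putative clones above
#' \code{promiscuity_limit}). The accounting identities
#' \eqn{\sum_k n_k = } distinct clones and \eqn{\sum_k k\, n_k = } total
#' scores are asserted before returning; a violation indicates a
#' decoding bug and raises an error.
#'
#' @param score_table a screen score table.
#' @param promiscuity_limit threshold above which an assay is excluded
#'   from the second histogram (default 3000).
#' @return object of class \code{screen_summary}: \code{per_assay},
#'   \code{multiplicity} (k, n_all, n_excl), \code{totals}.
#' @export
summarize_screen <- function(score_table, promiscuity_limit = 3000) {
  per_assay <- as.data.frame(table(score_table$assay_id),
                             stringsAsFactors = FALSE)
  names(per_assay) <- c("assay_id", "n_total")
  promiscuous <- per_assay$assay_id[per_assay$n_total > promiscuity_limit]

  hist_of <- function(st) {
    if (nrow(st) == 0) return(integer(0))
    table(table(st$clone_id))
  }
  h_all <- hist_of(score_table)
  st_ex <- score_table[!(score_table$assay_id %in% promiscuous), ,
                       drop = FALSE]
  h_ex <- hist_of(st_ex)
  kmax <- max(c(1, as.integer(names(h_all)), as.integer(names(h_ex))))
  k <- seq_len(kmax)
  n_all <- integer(kmax)
  n_all[as.integer(names(h_all))] <- as.integer(h_all)
  n_excl <- integer(kmax)
  n_excl[as.integer(names(h_ex))] <- as.integer(h_ex)

  totals <- list(n_scores = nrow(score_table),
                 n_clones = length(unique(score_table$clone_id)),
                 n_scores_excl = nrow(st_ex),
                 n_clones_excl = length(unique(st_ex$clone_id)),
                 promiscuous = promiscuous)
  if (sum(n_all) != totals$n_clones ||
      sum(k * n_all) != totals$n_scores ||
      sum(n_excl) != totals$n_clones_excl ||
      sum(k * n_excl) != totals$n_scores_excl)
    stop("screen summary identities violated; decoding output corrupt")

  structure(list(per_assay = per_assay,
                 multiplicity = data.frame(k = k, n_all = n_all,
                                           n_excl = n_excl),
                 totals = totals), class = "screen_summary")
}

#' @export
print.screen_summary <- function(x, ...) {
  cat(sprintf("Screen: %d scores, %d distinct putative clones; excluding promiscuous assays (%s): %d scores, %d clones\n",
              x$totals$n_scores, x$totals$n_clones,
              if (length(x$totals$promiscuous) > 0)
                paste(x$totals$promiscuous, collapse = ",") else "none",
              x$totals$n_scores_excl, x$totals$n_clones_excl))
  invisible(x)
}

read_fixture <- function(name, dir = NULL) {
  dir <- dir %||% system.file("extdata", package = "snpcontig")
  path <- file.path(dir, name)
  if (!file.exists(path)) stop("fixture missing: ", path)
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Re-derive the published summary numbers from the shipped tables
#'
#' Recomputes, from the machine-readable transcriptions of the published
#' screen-summary and multiplicity tables plus the printed counts, every
#' derivable total and percentage, and compares each against its printed
#' value: total scores, distinct putative clones, the weighted histogram
#' identities linking the two tables, the >= 4-assay selection counts,
#' the selection/ambiguity/conflict/yield percentages at their printed
#' precision, and the two-table cross-check excluding the promiscuous
#' assay.
#'
#' @param dir fixture directory (defaults to the installed package's
#'   \code{extdata}).
#' @return data.frame (check, expected, computed, pass) with attribute
#'   \code{ok}.
#' @export
fixture_checks <- function(dir = NULL) {
  t1 <- read_fixture("table1_screen.tsv", dir)
  t2 <- read_fixture("table2_multiplicity.tsv", dir)
  pc <- read_fixture("printed_counts.tsv", dir)
  cnt <- pc$value
  names(cnt) <- pc$name
  chk <- list()
  add <- function(name, expected, computed)
    chk[[length(chk) + 1]] <<- data.frame(
      check = name, expected = as.character(expected),
      computed = as.character(computed),
      pass = identical(as.character(expected), as.character(computed)),
      stringsAsFactors = FALSE)

  promiscuous <- t1$assay_id[t1$n_total > cnt[["promiscuity_limit"]]]

  add("table1 per-assay totals sum to the printed score total",
      cnt[["total_scores"]], sum(t1$n_total))
  add("table1 per-nucleotide counts exceed totals by the 2 ambiguous clones",
      cnt[["total_scores"]] + cnt[["ambiguous_clones"]],
      sum(t1$n_allele1) + sum(t1$n_allele2))
  add("table2 histogram sums to the printed distinct-clone count",
      cnt[["putative_clones"]], sum(t2$n_all))
  add("table2 weighted histogram equals the table1 score total",
      sum(t1$n_total), sum(t2$k * t2$n_all))
  add("table2 (excl promiscuous) weighted histogram equals scores minus the promiscuous assay's",
      sum(t1$n_total) - sum(t1$n_total[t1$assay_id %in% promiscuous]),
      sum(t2$k * t2$n_excl))
  add(">=4-assay clones excluding the promiscuous assay",
      cnt[["clones_ge4_excl"]], sum(t2$n_excl[t2$k >= 4]))
  add(">=4-assay clones over all assays exceed 550",
      TRUE, sum(t2$n_all[t2$k >= 4]) > 550)
  add("selected clone total = criterion A + B + C counts",
      cnt[["selected_clones"]],
      cnt[["clones_ge4_excl"]] + cnt[["crit_b_selected"]] +
        cnt[["end_marker_selected"]])
  add("selected fraction of putative coordinates (9.1%)",
      "9.1", render_percent(percent(cnt[["selected_clones"]],
                                    cnt[["putative_clones"]]), 1))
  add("unambiguous nucleotide classification (99.97%)",
      "99.97", render_percent(percent(cnt[["unambiguous_clones"]],
                                      cnt[["both_nt_clones"]]), 2))
  add("subgenome-conflict rate among multi-marker clones (3.8%)",
      "3.8", render_percent(percent(cnt[["conflicting_clones"]],
                                    cnt[["multi_marker_clones"]]), 1))
  add("false-positive scores among confirmed-clone scores (2.5%)",
      "2.5", render_percent(percent(
        cnt[["false_positive_scores"]],
        cnt[["confirmed_clone_scores"]] - cnt[["unverified_scores"]]), 1))
  add("criterion-B validation yield (6.9%)",
      "6.9", render_percent(percent(cnt[["crit_b_confirmed"]],
                                    cnt[["crit_b_selected"]]), 1))
  add("region-end candidate yield (28.2%)",
      "28.2", render_percent(percent(cnt[["end_marker_confirmed"]],
                                     cnt[["end_marker_selected"]]), 1))
  add("contig members selected by >=4 assays (72%)",
      "72", render_percent(percent(cnt[["contig_members_ge4"]],
                                   cnt[["contig_members"]]), 0))
  add("assay sites conserved between amphidiploid and progenitor alignments (75.4%)",
      "75.4", render_percent(percent(cnt[["amplicon_sites_conserved"]],
                                     cnt[["amplicon_sites_tested"]]), 1))
  add("assays with a two-nucleotide amphidiploid pattern (75%)",
      "75", render_percent(percent(cnt[["express_two_nt_assays"]],
                                   cnt[["assays_total"]]), 0))
  out <- do.call(rbind, chk)
  attr(out, "ok") <- all(out$pass)
  out
}
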