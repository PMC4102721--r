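#' Run the full screening-to-contigs pipeline on a synthetic study
#'
#' Executes every stage end to end with full ground truth retained:
#' progenitor region pair, amphidiploid, clone library, pooling design,
#' assay panel, reference-panel evidence, noisy pool signals, threshold
#' calling, seven-dimension deconvolution, assay classification and
#' pending-category inference, clone subgenome assignment, selection,
#' amplicon validation, contig building, false-negative refinement and
#' contig bridging.
#'
#' @param config a \code{\link{sim_config}}.
#' @param design optional \code{\link{pooling_design}} (defaults to the
#'   std design for the configured geometry).
#' @param noise optional \code{\link{noise_model}} override.
#' @param masked optional masked-amplicon spec for the oracle.
#' @param selection_params list overriding \code{\link{select_candidates}}
#'   defaults.
#' @param bridge run the bridging stage (default TRUE).
#' @return a list of class \code{snpcontig_run} holding every
#'   intermediate artifact, the final \code{contig_set}, validation and
#'   refinement outputs, and the screen summary.
#' @export
run_pipeline <- function(config, design = NULL, noise = NULL,
                         masked = NULL, selection_params = list(),
                         bridge = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  pair <- simulate_progenitor_pair(config)
  amph <- derive_amphidiploid(pair)
  library <- simulate_bac_library(amph, config)
  design <- design %||% pooling_design(config$n_plates,
                                       config$rows_per_plate,
                                       config$cols_per_plate)
  panel <- simulate_assay_panel(amph, library, config)
  evidence <- simulate_reference_panel(panel)
  signals <- simulate_pool_signals(panel, library, design,
                                   noise = noise %||% config$noise)
  calls <- classify_pools(signals)
  screen <- screen_library(calls, design)
  defs <- assay_defs(panel)
  categories <- infer_pending(classify_assays(evidence),
                              screen$score_table, defs)
  assignment <- assign_clones(screen$score_table, categories, defs)
  morder <- marker_order(panel)

  sel_args <- c(list(score_table = screen$score_table, morder = morder),
                selection_params)
  selection <- do.call(select_candidates, sel_args)
  oracle <- make_validation_oracle(panel, library, masked = masked)
  validation <- validate_scores(screen$score_table, selection,
                                categories, defs, oracle)
  contigs0 <- build_contigs(validation$confirmed, morder,
                            validation$clone_labels)
  refined <- refine_contigs(contigs0, oracle)
  bridged <- if (bridge)
    bridge_contigs(refined$contig_set, screen$score_table, oracle)
  else list(contig_set = refined$contig_set, report = NULL,
            recovered = NULL)

  structure(list(config = config, pair = pair, amph = amph,
                 library = library, design = design, panel = panel,
                 evidence = evidence, signals = signals, calls = calls,
                 screen = screen, categories = categories,
                 assignment = assignment, morder = morder,
                 selection = selection, oracle = oracle,
                 validation = validation, contigs_initial = contigs0,
                 refinement = refined, bridging = bridged,
                 contigs = bridged$contig_set,
                 summary = summarize_screen(screen$score_table)),
            class = "snpcontig_run")
}

#' @export
print.snpcontig_run <- function(x, ...) {
  cat("End-to-end screen of a synthetic amphidiploid library\n")
  print(x$summary)
  cat(sprintf("Selected %d clones; confirmed scores %d, false positives %d, recovered false negatives %d\n",
              sum(x$selection$selected), nrow(x$validation$confirmed),
              nrow(x$validation$false_positives),
              nrow(x$refinement$false_negatives)))
  cc <- contig_counts(x$contigs)
  cat(sprintf("Contigs: %d on subgenome A, %d on subgenome C\n",
              cc["A"], cc["C"]))
  invisible(x)
}

#' Ground-truth recovery metrics of a pipeline run
#'
#' Compares every stage of a run against the retained simulation truth:
#' raw-decode recall and shadow counts, the confirmed clone set against
#' the true region clones, truth-derived false-negative scores, the
#' conflict rate, assay-category recovery, and a truth-derived contig
#' set built from the same selected clones (so contig topology can be
#' compared like for like).
#'
#' @param run a \code{\link{run_pipeline}} result.
#' @return list of metrics; see the methods vignette for definitions.
#' @export
truth_metrics <- function(run) {
  th <- run$signals$true_hits
  st <- run$screen$score_table

  # raw decode: which true (assay, clone, allele) hits were recovered
  key_truth <- paste(th$assay_id, th$clone_id)
  cls_truth <- paste0("allele", th$allele)
  m <- match(key_truth, paste(st$assay_id, st$clone_id))
  found <- !is.na(m)
  class_ok <- found & (st$class[m] == cls_truth | st$class[m] == "both")
  decode_recall <- mean(class_ok)
  shadows <- nrow(st) - sum(!is.na(match(paste(st$assay_id, st$clone_id),
                                         key_truth)))

  # true region clones and their true markers (testable presences)
  cl <- run$library$clones
  lay <- run$library$layout
  pa <- run$panel$assays
  true_presence <- do.call(rbind, lapply(seq_len(nrow(pa)), function(i) {
    ga <- lay$a_start + pa$a_pos[i] - 1
    gc_ <- lay$c_start + pa$c_pos[i] - 1
    rows <- which((cl$start <= ga & cl$end > ga) |
                    (cl$start <= gc_ & cl$end > gc_))
    if (length(rows) == 0) return(NULL)
    data.frame(clone_id = cl$clone_id[rows], assay_id = pa$assay_id[i],
               subgenome = ifelse(cl$start[rows] <= ga & cl$end[rows] > ga,
                                  "A", "C"))
  }))
  true_region_clones <- unique(true_presence$clone_id)

  confirmed_ids <- unique(run$contigs$confirmed$clone_id)
  sel_ids <- run$selection$clone_id[run$selection$selected]
  sel_true <- intersect(sel_ids, true_region_clones)

  # truth contig set over the same clones the pipeline placed
  tp <- true_presence[true_presence$clone_id %in% confirmed_ids, ,
                      drop = FALSE]
  lab_true <- vapply(split(tp$subgenome, tp$clone_id), function(s)
    names(sort(table(s), decreasing = TRUE))[1], character(1))
  truth_contigs <- build_contigs(tp, run$morder,
                                 data.frame(clone_id = names(lab_true),
                                            label = unname(lab_true)))

  # truth-derived false negatives: true testable scores of confirmed
  # clones that the screen missed (accounted at the refinement stage,
  # before bridging adds clones whose full extent was never probed)
  refined_ids <- unique(run$refinement$contig_set$confirmed$clone_id)
  tsel <- true_presence[true_presence$clone_id %in% refined_ids, ,
                        drop = FALSE]
  k_screen <- paste(st$assay_id, st$clone_id)
  fn_truth <- sum(!(paste(tsel$assay_id, tsel$clone_id) %in% k_screen))

  cat_map <- c("1" = 1L, "2" = 2L, "3" = 3L, "4" = 4L, "5" = 5L)
  rec <- cat_map[run$categories$category[
    match(run$panel$assays$assay_id, run$categories$assay_id)]]
  category_recovery <- mean(!is.na(rec) &
                              rec == run$panel$assays$category_true)

  mm <- run$assignment$clones[run$assignment$clones$multi_marker, ,
                              drop = FALSE]
  list(decode_recall = decode_recall,
       n_true_hits = nrow(th),
       n_scores = nrow(st),
       shadow_scores = shadows,
       true_region_clones = true_region_clones,
       selected_true = sel_true,
       confirmed_clones = confirmed_ids,
       true_presence = true_presence,
       truth_contigs = truth_contigs,
       fn_truth = fn_truth,
       fn_recovered = nrow(run$refinement$false_negatives),
       conflict_rate = if (nrow(mm) > 0) mean(mm$conflict) else 0,
       n_multi_marker = nrow(mm),
       category_recovery = category_recovery)
}
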