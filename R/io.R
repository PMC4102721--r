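#' Write simulated genomes as FASTA
#'
#' Writes the two progenitor region sequences and the two amphidiploid
#' subgenome sequences of a simulation to FASTA files.
#'
#' @param amph an \code{\link{derive_amphidiploid}} result.
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
export_genomes <- function(amph, dir) {
  stopifnot(inherits(amph, "amphidiploid"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sets <- list(progenitors = Biostrings::DNAStringSet(
    c(progenitor_A = bases_to_string(amph$pair$seq_a),
      progenitor_C = bases_to_string(amph$pair$seq_c))),
    amphidiploid = Biostrings::DNAStringSet(
      c(subgenome_A = bases_to_string(amph$genome_a),
        subgenome_C = bases_to_string(amph$genome_c))))
  paths <- file.path(dir, paste0(names(sets), ".fasta"))
  for (i in seq_along(sets))
    Biostrings::writeXStringSet(sets[[i]], paths[i])
  invisible(paths)
}

#' Read a FASTA file as character sequences
#' @param path FASTA path.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Write assay candidates as FASTA windows
#'
#' Exports each candidate's full assay window (left flank, site base,
#' right flank) as one FASTA record named by the 0-based site position.
#'
#' @param candidates an \code{\link{find_assay_sites}} result.
#' @param path output FASTA path.
#' @return invisibly, the path.
#' @export
export_candidate_windows <- function(candidates, path) {
  if (nrow(candidates) == 0) {
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(), path)
    return(invisible(path))
  }
  seqs <- paste0(candidates$flank_left, candidates$nt1,
                 candidates$flank_right)
  names(seqs) <- sprintf("site_%d_%s/%s", candidates$site_a,
                         candidates$nt1, candidates$nt2)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Write a plain-text key: value configuration
#' @param config a \code{\link{sim_config}}.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_config <- function(config, path) {
  flat <- c(config[!(names(config) %in% "noise")],
            stats::setNames(unclass(config$noise),
                            paste0("noise.", names(config$noise))))
  flat <- flat[!vapply(flat, is.null, logical(1))]
  lines <- vapply(names(flat), function(k) {
    v <- flat[[k]]
    sprintf("%s: %s", k, paste(format(v, scientific = FALSE),
                               collapse = " "))
  }, character(1))
  writeLines(c(sprintf("# seed: %d", config$seed), lines), path)
  invisible(path)
}

#' Read a plain-text key: value configuration
#' @param path path written by \code{\link{write_config}}.
#' @return a \code{\link{sim_config}}.
#' @export
read_config <- function(path) {
  lines <- grep("^#", readLines(path), value = TRUE, invert = TRUE)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, ": ", fixed = TRUE)
  keys <- vapply(kv, `[`, character(1), 1)
  vals <- lapply(kv, function(p)
    as.numeric(strsplit(p[2], " ", fixed = TRUE)[[1]]))
  names(vals) <- keys
  noise_keys <- grep("^noise\\.", keys, value = TRUE)
  noise <- do.call(noise_model,
                   stats::setNames(vals[noise_keys],
                                   sub("^noise\\.", "", noise_keys)))
  main <- vals[setdiff(keys, noise_keys)]
  main <- main[!vapply(main, function(v) any(is.na(v)), logical(1))]
  do.call(sim_config, c(main, list(noise = noise)))
}

#' Export the core tables of a pipeline run as TSV
#'
#' Writes the clone-library truth, pool design membership, pool signals
#' and calls, score table, per-assay summary, assay categories, clone
#' assignments, selection, validation records and contig membership to
#' \code{dir}, every file carrying the run's seed as a header comment.
#'
#' @param run a \code{\link{run_pipeline}} result.
#' @param dir output directory.
#' @return invisibly, the directory.
#' @export
export_run <- function(run, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  s <- run$config$seed
  write_tsv(run$library$clones, file.path(dir, "library.tsv"), s)
  memb <- as.data.frame(run$design$membership)
  memb <- cbind(index = seq_len(nrow(memb)) - 1L, memb)
  write_tsv(memb, file.path(dir, "pool_design.tsv"), s)
  write_tsv(run$calls, file.path(dir, "pool_calls.tsv"), s)
  write_tsv(run$screen$score_table, file.path(dir, "score_table.tsv"), s)
  write_tsv(run$screen$per_assay, file.path(dir, "per_assay.tsv"), s)
  write_tsv(run$evidence, file.path(dir, "evidence.tsv"), s)
  write_tsv(run$categories, file.path(dir, "assay_categories.tsv"), s)
  write_tsv(run$assignment$clones, file.path(dir, "clone_assignment.tsv"), s)
  write_tsv(run$selection, file.path(dir, "selection.tsv"), s)
  if (nrow(run$validation$records) > 0)
    write_tsv(run$validation$records, file.path(dir, "validation.tsv"), s)
  contig_rows <- do.call(rbind, lapply(run$contigs$contigs, function(ct)
    data.frame(contig = ct$id, subgenome = ct$subgenome,
               clone_id = ct$intervals$clone_id,
               first_marker = ct$intervals$first,
               last_marker = ct$intervals$last)))
  if (!is.null(contig_rows))
    write_tsv(contig_rows, file.path(dir, "contigs.tsv"), s)
  writeLines(contig_diagram(run$contigs), file.path(dir, "contigs.txt"))
  invisible(dir)
}
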