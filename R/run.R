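# End-to-end search runs with on-disk outputs; this is what the command-line
# entry point (inst/cli/orthoseek.R) wraps.

.fmt_members_tsv <- function(members) {
  trimmed <- ifelse(is.na(members$trim_start), "",
                    paste0(members$trim_start, "-", members$trim_end))
  data.frame(
    accession = members$accession,
    organism = members$organism,
    length = members$length,
    identity_to_reference = sprintf("%.2f", members$identity_pct),
    evalue = sprintf("%.3e", members$evalue),
    iteration_found = members$iteration_found,
    trimmed_range = trimmed,
    stringsAsFactors = FALSE)
}

.write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.members_db <- function(members, name) {
  recs <- lapply(seq_len(nrow(members)), function(i) {
    sequence_record(members$accession[i], members$residues[i],
                    members$description[i], members$organism[i])
  })
  protein_db(recs, name = name)
}

#' Run a full homolog/ortholog search, optionally writing a run directory
#'
#' Convenience wrapper: [find_homologs()], then [classify_orthologs()] when
#' a source proteome is supplied, then [summarize_annotations()] when an
#' annotation table is supplied. With `out_dir` set, the run directory
#' receives `homologs.tsv`, `orthologs.tsv` (accession, organism, length,
#' identity to the reference, e-value, iteration found, trimmed range),
#' `homologs.fasta`, `orthologs.fasta`, `filter_decisions.tsv`,
#' `annotation_summary.tsv`, `run_config.yaml` and `run.log`. Identical
#' inputs and parameters produce byte-identical result tables.
#'
#' @param queries,db,params As for [find_homologs()].
#' @param source_proteome Optional [protein_db()] for the reciprocal-best-
#'   hit step.
#' @param annotations Optional [annotation_table()].
#' @param drop_iea,min_pct Passed to [summarize_annotations()].
#' @param out_dir Optional output directory (created if needed).
#' @return A list of class `orthoseek_run` with `homologs`, `orthologs`
#'   (or `NULL`) and `annotation_summary` (or `NULL`).
#' @export
orthoseek_search <- function(queries, db, params = search_params(),
                             source_proteome = NULL, annotations = NULL,
                             drop_iea = FALSE, min_pct = 5,
                             out_dir = NULL) {
  hres <- find_homologs(queries, db, params)
  ores <- if (!is.null(source_proteome)) {
    classify_orthologs(hres, source_proteome, params)
  }
  ann <- if (!is.null(annotations)) {
    ids <- if (!is.null(ores) && nrow(ores$members)) {
      ores$members$accession
    } else hres$members$accession
    if (length(ids)) {
      summarize_annotations(ids, annotations, drop_iea = drop_iea,
                            min_pct = min_pct)
    }
  }
  res <- structure(list(homologs = hres, orthologs = ores,
                        annotation_summary = ann),
                   class = "orthoseek_run")
  if (!is.null(out_dir)) .write_run_dir(res, db, out_dir)
  res
}

#' @export
print.orthoseek_run <- function(x, ...) {
  print(x$homologs)
  if (!is.null(x$orthologs)) print(x$orthologs)
  invisible(x)
}

.write_run_dir <- function(res, db, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hres <- res$homologs
  .write_tsv(.fmt_members_tsv(hres$members),
             file.path(out_dir, "homologs.tsv"))
  if (nrow(hres$members)) {
    write_fasta(.members_db(hres$members, "homologs"),
                file.path(out_dir, "homologs.fasta"))
  }
  if (!is.null(res$orthologs)) {
    .write_tsv(.fmt_members_tsv(res$orthologs$members),
               file.path(out_dir, "orthologs.tsv"))
    if (nrow(res$orthologs$members)) {
      write_fasta(.members_db(res$orthologs$members, "orthologs"),
                  file.path(out_dir, "orthologs.fasta"))
    }
  }
  .write_tsv(hres$decisions, file.path(out_dir, "filter_decisions.tsv"))
  if (!is.null(res$annotation_summary)) {
    .write_tsv(res$annotation_summary,
               file.path(out_dir, "annotation_summary.tsv"))
  }
  p <- hres$params
  yaml::write_yaml(list(
    reference = hres$reference_id,
    database = db$name,
    evalue_cutoff = p$evalue_cutoff,
    rost_n = p$filter$rost_n,
    min_domain_len = p$filter$min_domain_len,
    decay_constant = p$filter$decay_constant,
    max_iterations = p$max_iterations,
    engine = p$engine,
    matrix = p$scheme$matrix_name,
    gap_open = p$scheme$gap_open,
    gap_extend = p$scheme$gap_extend),
    file.path(out_dir, "run_config.yaml"))
  writeLines(c(
    sprintf("reference: %s", hres$reference_id),
    sprintf("database: %s (%d sequences, %d residues)", db$name,
            nrow(db$records), db$total_residues),
    sprintf("iterations run: %d", hres$iterations_run),
    sprintf("homologs: %d", nrow(hres$members)),
    if (!is.null(res$orthologs)) {
      sprintf("orthologs: %d", nrow(res$orthologs$members))
    },
    sprintf("filter decisions: %d", nrow(hres$decisions))),
    file.path(out_dir, "run.log"))
  invisible(out_dir)
}
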