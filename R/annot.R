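# Functional-annotation frequency summaries (Pfam domains, KEGG pathways,
# GO terms) over a result set, with IEA filtering and a display cutoff.
# Annotations arrive as a user- or simulator-supplied table; there are no
# live database lookups.

#' Construct an annotation table
#'
#' @param accessions Character vector of accessions.
#' @param pfam,kegg Lists (parallel to `accessions`) of character vectors of
#'   Pfam domain / KEGG pathway identifiers.
#' @param go List of data.frames with columns `term` and `evidence`
#'   (2-3-letter GO evidence codes, or `""`).
#' @return A named list of class `annotation_table`; each element has
#'   `pfam`, `kegg` and `go`.
#' @export
annotation_table <- function(accessions, pfam = NULL, kegg = NULL,
                             go = NULL) {
  n <- length(accessions)
  stopifnot(!anyDuplicated(accessions))
  empty_go <- data.frame(term = character(), evidence = character(),
                         stringsAsFactors = FALSE)
  out <- lapply(seq_len(n), function(i) {
    g <- if (is.null(go)) empty_go else go[[i]]
    stopifnot(all(grepl("^([A-Z]{2,3})?$", g$evidence)))
    list(pfam = if (is.null(pfam)) character() else pfam[[i]],
         kegg = if (is.null(kegg)) character() else kegg[[i]],
         go = g)
  })
  names(out) <- accessions
  structure(out, class = "annotation_table")
}

#' Read an annotation table from TSV
#'
#' Four tab-separated columns: accession, `;`-joined Pfam identifiers,
#' `;`-joined KEGG pathways, and `;`-joined GO entries of the form
#' `TERM|EVIDENCE`. A header line starting with `accession` is skipped.
#'
#' @param path File path.
#' @return An [annotation_table()].
#' @export
read_annotation_table <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(lines) && grepl("^accession\\b", lines[1])) lines <- lines[-1]
  if (length(lines) == 0L) return(annotation_table(character()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  split_semi <- function(x) {
    if (is.na(x) || !nzchar(x)) character() else
      strsplit(x, ";", fixed = TRUE)[[1]]
  }
  field <- function(p, k) if (length(p) >= k) p[k] else ""
  accs <- vapply(parts, `[[`, "", 1L)
  pf <- lapply(parts, function(p) split_semi(field(p, 2L)))
  kg <- lapply(parts, function(p) split_semi(field(p, 3L)))
  go <- lapply(parts, function(p) {
    entries <- split_semi(field(p, 4L))
    if (length(entries) == 0L) {
      return(data.frame(term = character(), evidence = character(),
                        stringsAsFactors = FALSE))
    }
    bits <- strsplit(entries, "|", fixed = TRUE)
    data.frame(term = vapply(bits, `[[`, "", 1L),
               evidence = vapply(bits, function(b)
                 if (length(b) > 1L) b[2] else "", ""),
               stringsAsFactors = FALSE)
  })
  annotation_table(accs, pf, kg, go)
}

#' Write an annotation table as TSV
#'
#' @param table An [annotation_table()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_annotation_table <- function(table, path) {
  lines <- c("accession\tpfam\tkegg\tgo",
             vapply(names(table), function(a) {
               e <- table[[a]]
               go <- if (nrow(e$go)) paste(paste0(e$go$term, "|",
                                                  e$go$evidence),
                                           collapse = ";") else ""
               paste(a, paste(e$pfam, collapse = ";"),
                     paste(e$kegg, collapse = ";"), go, sep = "\t")
             }, ""))
  writeLines(lines, path)
  invisible(path)
}

#' Annotation frequency summary of a result set
#'
#' For each namespace (pfam, kegg, go) the percentage of result sequences
#' carrying each term: `100 * n_sequences_with_term / n_result_sequences`,
#' each sequence counted once per term regardless of duplicate listings.
#' Sequences absent from the table still count in the denominator. GO terms
#' whose only evidence is filtered out by `drop_iea` disappear; terms whose
#' percentage is not strictly greater than `min_pct` are removed.
#'
#' @param result_ids Non-empty character vector of result accessions.
#' @param table An [annotation_table()].
#' @param drop_iea Remove GO annotations with the IEA evidence code
#'   (Inferred from Electronic Annotation) before counting.
#' @param min_pct Display cutoff: keep terms with percentage strictly
#'   greater than this (default 5).
#' @return A data.frame of class `frequency_summary` with columns
#'   `namespace`, `term`, `n_sequences`, `percentage`, sorted by descending
#'   percentage (then term) within namespace.
#' @export
summarize_annotations <- function(result_ids, table, drop_iea = FALSE,
                                  min_pct = 5) {
  if (length(result_ids) == 0L) stop("result_ids must be non-empty",
                                     call. = FALSE)
  result_ids <- unique(result_ids)
  denom <- length(result_ids)
  terms_of <- function(acc, ns) {
    e <- table[[acc]]
    if (is.null(e)) return(character())
    if (ns != "go") return(unique(e[[ns]]))
    g <- e$go
    if (drop_iea) g <- g[g$evidence != "IEA", , drop = FALSE]
    unique(g$term)
  }
  out <- lapply(c("pfam", "kegg", "go"), function(ns) {
    all_terms <- unlist(lapply(result_ids, terms_of, ns = ns))
    if (length(all_terms) == 0L) {
      return(data.frame(namespace = character(), term = character(),
                        n_sequences = integer(), percentage = numeric(),
                        stringsAsFactors = FALSE))
    }
    tab <- table(all_terms)
    df <- data.frame(namespace = ns, term = names(tab),
                     n_sequences = as.integer(tab),
                     percentage = 100 * as.integer(tab) / denom,
                     stringsAsFactors = FALSE)
    df <- df[df$percentage > min_pct, , drop = FALSE]
    df[order(-df$percentage, df$term), , drop = FALSE]
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  class(out) <- c("frequency_summary", "data.frame")
  out
}
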