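# Reading and writing the plain-text formats the pipeline touches:
# FASTA, BLAST tabular (outfmt 6) TSV, truth-pair TSV. All coordinates are
# 1-based inclusive, following the BLAST tabular convention.

#' Create a protein sequence record
#'
#' @param accession Unique identifier (first whitespace-delimited FASTA
#'   header token).
#' @param residues Amino-acid string over the 20 standard letters plus `X`;
#'   upper-cased on input, `*` stripped.
#' @param description Free-text remainder of the header.
#' @param organism Source-organism label; parsed from an `OS=...` header
#'   field by [read_fasta()], `"unknown"` otherwise.
#' @return A list of class `sequence_record`.
#' @export
sequence_record <- function(accession, residues, description = "",
                            organism = "unknown") {
  stopifnot(is.character(accession), length(accession) == 1L,
            nzchar(accession))
  residues <- gsub("*", "", toupper(residues), fixed = TRUE)
  if (!nzchar(residues)) {
    stop("record '", accession, "': residues must be non-empty",
         call. = FALSE)
  }
  bad <- regexpr(paste0("[^", paste(.AA21, collapse = ""), "]"), residues)
  if (bad > 0L) {
    stop("record '", accession, "': illegal residue character '",
         substr(residues, bad, bad), "' at position ", bad, call. = FALSE)
  }
  structure(list(accession = accession, description = description,
                 organism = organism, residues = residues),
            class = "sequence_record")
}

#' @export
print.sequence_record <- function(x, ...) {
  cat(sprintf("<sequence_record> %s [%s], %d aa\n", x$accession,
              x$organism, nchar(x$residues)))
  invisible(x)
}

#' Create a protein database
#'
#' An ordered collection of [sequence_record()]s with unique accessions.
#' `total_residues` (the summed sequence length) is used as the search-space
#' size for expect values.
#'
#' @param records List of `sequence_record`s.
#' @param name Database label.
#' @return A list of class `protein_db` with elements `records` (a
#'   data.frame), `name` and `total_residues`.
#' @export
protein_db <- function(records, name = "db") {
  if (inherits(records, "sequence_record")) records <- list(records)
  stopifnot(length(records) > 0L)
  df <- data.frame(
    accession = vapply(records, `[[`, "", "accession"),
    description = vapply(records, `[[`, "", "description"),
    organism = vapply(records, `[[`, "", "organism"),
    residues = vapply(records, `[[`, "", "residues"),
    stringsAsFactors = FALSE
  )
  dup <- df$accession[duplicated(df$accession)]
  if (length(dup)) {
    stop("duplicate accession: ", dup[1], call. = FALSE)
  }
  structure(list(records = df, name = name,
                 total_residues = sum(nchar(df$residues))),
            class = "protein_db")
}

#' @export
length.protein_db <- function(x) nrow(x$records)

#' @export
print.protein_db <- function(x, ...) {
  cat(sprintf("<protein_db> '%s': %d sequences, %d residues\n",
              x$name, nrow(x$records), x$total_residues))
  invisible(x)
}

#' Extract one record from a protein database
#'
#' @param db A `protein_db`.
#' @param accession Accession string or integer index.
#' @return A `sequence_record`.
#' @export
db_record <- function(db, accession) {
  i <- if (is.numeric(accession)) accession
       else match(accession, db$records$accession)
  if (is.na(i) || i < 1L || i > nrow(db$records)) {
    stop("no record '", accession, "' in database '", db$name, "'",
         call. = FALSE)
  }
  r <- db$records[i, ]
  sequence_record(r$accession, r$residues, r$description, r$organism)
}

.db_records <- function(db) {
  lapply(seq_len(nrow(db$records)), function(i) db_record(db, i))
}

.parse_organism <- function(description) {
  m <- regmatches(description,
                  regexpr("OS=.*?(?= [A-Z]{2}=|$)", description, perl = TRUE))
  if (length(m) && nzchar(m)) sub("^OS=", "", m) else "unknown"
}

#' Read a protein FASTA file
#'
#' One record per entry, order preserved. The accession is the first
#' whitespace-delimited header token; the organism is taken from a UniProt
#' style `OS=...` field when present, else `"unknown"`. Residues are
#' upper-cased, `*` is stripped, and any character outside the 20 standard
#' amino acids plus `X` is an error.
#'
#' @param path File path.
#' @param name Database label (defaults to the file name).
#' @return A [protein_db()].
#' @export
read_fasta <- function(path, name = basename(path)) {
  # parsed from the raw text (not via a tolerant reader) so that illegal
  # residue codes are reported with their position instead of being
  # silently dropped
  lines <- readLines(path)
  hdr <- grep("^>", lines)
  if (length(hdr) == 0L) stop("no sequences in '", path, "'", call. = FALSE)
  headers <- sub("^>\\s*", "", lines[hdr])
  accs <- sub("\\s.*$", "", headers)
  descs <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  bounds <- c(hdr, length(lines) + 1L)
  recs <- lapply(seq_along(hdr), function(i) {
    body <- if (bounds[i + 1L] - 1L > bounds[i]) {
      lines[(bounds[i] + 1L):(bounds[i + 1L] - 1L)]
    } else character()
    sequence_record(accs[i], paste(gsub("[ \t]", "", body), collapse = ""),
                    descs[i], .parse_organism(descs[i]))
  })
  protein_db(recs, name = name)
}

#' Write a protein database as FASTA
#'
#' Standard FASTA with headers `accession description` and sequence lines
#' wrapped at 60 columns.
#'
#' @param db A [protein_db()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(db, path) {
  stopifnot(inherits(db, "protein_db"), nrow(db$records) > 0L)
  x <- Biostrings::AAStringSet(db$records$residues)
  names(x) <- ifelse(nzchar(db$records$description),
                     paste(db$records$accession, db$records$description),
                     db$records$accession)
  Biostrings::writeXStringSet(x, filepath = path, width = 60L)
  invisible(path)
}

.HIT_COLS <- c("query_id", "subject_id", "identity_pct", "aln_length",
               "mismatches", "gap_opens", "q_start", "q_end",
               "s_start", "s_end", "evalue", "bit_score",
               "raw_score", "aligned_query", "aligned_subject")

.empty_hits <- function() {
  df <- data.frame(
    query_id = character(), subject_id = character(),
    identity_pct = numeric(), aln_length = integer(),
    mismatches = integer(), gap_opens = integer(),
    q_start = integer(), q_end = integer(),
    s_start = integer(), s_end = integer(),
    evalue = numeric(), bit_score = numeric(), raw_score = numeric(),
    aligned_query = character(), aligned_subject = character(),
    stringsAsFactors = FALSE
  )
  df
}

#' Read BLAST tabular (outfmt 6) hits
#'
#' Parses the 12-column tab-separated BLAST `-outfmt 6` dialect
#' (`qseqid sseqid pident length mismatch gapopen qstart qend sstart send
#' evalue bitscore`); coordinates are 1-based inclusive, percent identity is
#' kept on the 0-100 scale. Lines starting with `#` are skipped. This is the
#' adapter through which externally computed BLAST/PSI-BLAST hits enter the
#' pipeline.
#'
#' @param path File path.
#' @return A hit table (data.frame, one row per alignment); the alignment
#'   string columns are `NA` since outfmt 6 does not carry them.
#' @export
read_hits_tab <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) == 0L) return(.empty_hits())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(parts)
  if (any(ncols != 12L)) {
    bad <- which(ncols != 12L)[1]
    stop("line ", lineno[bad], ": expected 12 tab-separated columns, got ",
         ncols[bad], call. = FALSE)
  }
  m <- do.call(rbind, parts)
  num <- function(col, what) {
    v <- suppressWarnings(as.numeric(m[, col]))
    if (anyNA(v)) {
      bad <- which(is.na(v))[1]
      stop("line ", lineno[bad], ": non-numeric ", what, " field '",
           m[bad, col], "'", call. = FALSE)
    }
    v
  }
  data.frame(
    query_id = m[, 1], subject_id = m[, 2],
    identity_pct = num(3, "pident"), aln_length = as.integer(num(4, "length")),
    mismatches = as.integer(num(5, "mismatch")),
    gap_opens = as.integer(num(6, "gapopen")),
    q_start = as.integer(num(7, "qstart")), q_end = as.integer(num(8, "qend")),
    s_start = as.integer(num(9, "sstart")), s_end = as.integer(num(10, "send")),
    evalue = num(11, "evalue"), bit_score = num(12, "bitscore"),
    raw_score = NA_real_,
    aligned_query = NA_character_, aligned_subject = NA_character_,
    stringsAsFactors = FALSE
  )
}

#' Write hits as BLAST tabular (outfmt 6)
#'
#' @param hits A hit table as returned by [local_align()],
#'   [profile_search()] or [read_hits_tab()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_hits_tab <- function(hits, path) {
  out <- sprintf("%s\t%s\t%.2f\t%d\t%d\t%d\t%d\t%d\t%d\t%d\t%s\t%.1f",
                 hits$query_id, hits$subject_id, hits$identity_pct,
                 hits$aln_length, hits$mismatches, hits$gap_opens,
                 hits$q_start, hits$q_end, hits$s_start, hits$s_end,
                 formatC(hits$evalue, format = "e", digits = 2),
                 hits$bit_score)
  writeLines(out, path)
  invisible(path)
}

#' Read a truth-pair table
#'
#' Two tab-separated columns, `query_accession` and `true_ortholog_accession`;
#' `#` comment lines are skipped.
#'
#' @param path File path.
#' @return A data.frame with columns `query` and `ortholog`.
#' @export
read_truth_pairs <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(data.frame(query = character(), ortholog = character(),
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 2L)) stop("truth file needs 2 tab-separated columns",
                                     call. = FALSE)
  data.frame(query = vapply(parts, `[[`, "", 1L),
             ortholog = vapply(parts, `[[`, "", 2L),
             stringsAsFactors = FALSE)
}
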