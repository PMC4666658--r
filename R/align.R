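# The search engine: affine-gap Smith-Waterman local alignment against a
# substitution matrix, a Karlin-Altschul expect-value estimate, PSSM
# construction from accepted homologs, and profile search over a database.
# It stands in for BLAST/PSI-BLAST at desk scale; externally computed hits
# can be ingested instead via read_hits_tab().

#' Scoring scheme for local alignment
#'
#' Substitution matrix plus affine gap penalties and Karlin-Altschul
#' parameters. The matrices come from Biostrings; the `X` (unknown residue)
#' row and column are set to 0 so `X` is neutral against everything. A gap of
#' length k costs `gap_open + (k - 1) * gap_extend`, so equal penalties give
#' linear gap scoring.
#'
#' The Karlin-Altschul parameters drive the expect-value estimate
#' `E = K * m * n * exp(-lambda * S)`; the defaults are the standard ungapped
#' BLOSUM62 values applied uniformly, an approximation that is adequate here
#' because the pipeline only uses relative hit ordering and a cutoff.
#'
#' @param matrix_name `"BLOSUM62"` (default, half-bit units) or `"BLOSUM50"`
#'   (third-bit units).
#' @param gap_open,gap_extend Non-negative penalties, `gap_open >=
#'   gap_extend`.
#' @param karlin_K,karlin_lambda Positive Karlin-Altschul parameters (lambda
#'   in inverse matrix units).
#' @return A list of class `scoring_scheme`.
#' @export
scoring_scheme <- function(matrix_name = c("BLOSUM62", "BLOSUM50"),
                           gap_open = 11, gap_extend = 1,
                           karlin_K = 0.041, karlin_lambda = 0.267) {
  matrix_name <- match.arg(matrix_name)
  stopifnot(gap_open >= gap_extend, gap_extend >= 0,
            karlin_lambda > 0, karlin_K > 0)
  e <- new.env()
  utils::data(list = matrix_name, package = "Biostrings", envir = e)
  full <- e[[matrix_name]]
  mat <- full[.AA20, .AA20]
  mat <- rbind(cbind(mat, X = 0), X = 0)  # X scores 0 vs everything
  dimnames(mat) <- list(.AA21, .AA21)
  structure(list(matrix_name = matrix_name, matrix = mat,
                 gap_open = gap_open, gap_extend = gap_extend,
                 karlin_K = karlin_K, karlin_lambda = karlin_lambda,
                 # bits per raw matrix unit: BLOSUM62 is scaled in half-bits,
                 # BLOSUM50 in third-bits
                 bits_per_unit = if (matrix_name == "BLOSUM62") 0.5 else 1 / 3),
            class = "scoring_scheme")
}

#' @export
print.scoring_scheme <- function(x, ...) {
  cat(sprintf("<scoring_scheme> %s, gap open/extend %g/%g, K=%g lambda=%g\n",
              x$matrix_name, x$gap_open, x$gap_extend,
              x$karlin_K, x$karlin_lambda))
  invisible(x)
}

.as_record <- function(x, fallback_id = "seq") {
  if (inherits(x, "sequence_record")) return(x)
  if (is.character(x) && length(x) == 1L) {
    return(sequence_record(names(x) %||% fallback_id, x))
  }
  stop("expected a sequence_record or a single character string",
       call. = FALSE)
}

#' Karlin-Altschul expect value
#'
#' `E = K * m * n * exp(-lambda * S)` with `m` the query length and `n` the
#' searched database size in residues. A non-positive score returns the cap
#' `K * m * n`.
#'
#' @param raw_score Alignment score in matrix units (vectorised).
#' @param query_len Query length in residues.
#' @param db_residues Database size in residues.
#' @param scheme A [scoring_scheme()].
#' @return Expect value(s).
#' @export
estimate_evalue <- function(raw_score, query_len, db_residues,
                            scheme = scoring_scheme()) {
  stopifnot(query_len > 0, db_residues > 0)
  base <- scheme$karlin_K * query_len * db_residues
  base * exp(-scheme$karlin_lambda * pmax(raw_score, 0))
}

.bit_score <- function(raw_score, scheme) {
  (scheme$karlin_lambda * raw_score - log(scheme$karlin_K)) / log(2)
}

# Assemble one hit row from an engine result. The engine reports aligned
# 0-based positions (-1 = gap); qchars/schars are the residue letters the
# positions index (the reference residues for a profile hit).
.hit_row <- function(query_id, subject_id, sw, qchars, schars,
                     query_len, db_residues, scheme,
                     raw_score = sw$score) {
  qa <- sw$aligned_q
  sa <- sw$aligned_s
  qch <- rep("-", length(qa))
  qch[qa >= 0L] <- qchars[qa[qa >= 0L] + 1L]
  sch <- rep("-", length(sa))
  sch[sa >= 0L] <- schars[sa[sa >= 0L] + 1L]
  gap <- qa < 0L | sa < 0L
  ident <- sum(!gap & qch == sch)
  data.frame(
    query_id = query_id, subject_id = subject_id,
    identity_pct = 100 * ident / length(qa),
    aln_length = length(qa),
    mismatches = sum(!gap & qch != sch),
    gap_opens = sum(diff(c(FALSE, qa < 0L)) == 1L) +
                sum(diff(c(FALSE, sa < 0L)) == 1L),
    q_start = sw$q_start, q_end = sw$q_end,
    s_start = sw$s_start, s_end = sw$s_end,
    evalue = estimate_evalue(raw_score, query_len, db_residues, scheme),
    bit_score = .bit_score(raw_score, scheme),
    raw_score = raw_score,
    aligned_query = paste(qch, collapse = ""),
    aligned_subject = paste(sch, collapse = ""),
    stringsAsFactors = FALSE
  )
}

#' Optimal local alignment of two protein sequences
#'
#' Affine-gap Smith-Waterman with a deterministic traceback (at equal scores
#' the diagonal move is preferred over a gap in the subject, which is
#' preferred over a gap in the query), so results are bit-reproducible.
#'
#' @param query,subject [sequence_record()]s (or plain residue strings).
#' @param scheme A [scoring_scheme()].
#' @param db_residues Search-space size in residues for the expect value;
#'   defaults to the subject length (single-sequence search).
#' @return A one-row hit table, or `NULL` when the optimal score is <= 0.
#' @export
local_align <- function(query, subject, scheme = scoring_scheme(),
                        db_residues = NULL) {
  query <- .as_record(query, "query")
  subject <- .as_record(subject, "subject")
  sw <- .sw_align_seq(.encode(query$residues), .encode(subject$residues),
                      scheme$matrix, scheme$gap_open, scheme$gap_extend)
  if (isTRUE(sw$empty)) return(NULL)
  .hit_row(query$accession, subject$accession, sw,
           strsplit(query$residues, "")[[1]],
           strsplit(subject$residues, "")[[1]],
           nchar(query$residues),
           db_residues %||% nchar(subject$residues), scheme)
}

#' Percent identity of a hit
#'
#' 100 x identical columns / alignment length; gap columns count in the
#' denominator, never the numerator. Computed from the aligned strings when
#' the hit carries them, otherwise the stored `identity_pct` is returned.
#'
#' @param hit A one-row hit table.
#' @return Percentage in `[0, 100]`.
#' @export
percent_identity <- function(hit) {
  stopifnot(nrow(hit) == 1L)
  if (hit$aln_length == 0L) stop("alignment length is 0", call. = FALSE)
  if (is.na(hit$aligned_query)) return(hit$identity_pct)
  q <- strsplit(hit$aligned_query, "")[[1]]
  s <- strsplit(hit$aligned_subject, "")[[1]]
  100 * sum(q != "-" & s != "-" & q == s) / length(q)
}

#' Build a position-specific scoring matrix from accepted homologs
#'
#' One column per reference residue. Residue counts for a column are the hit
#' residues aligned to that reference position plus the reference's own
#' residue; the column score for residue `a` is the log-odds
#' `log2(((count_a + beta * p_a) / (N + beta)) / p_a)` in bits, with `beta`
#' the pseudocount weight and `p` the background frequencies. Columns where
#' no hit residue aligns fall back to the substitution-matrix row of the
#' reference residue, rescaled to bits. Gap columns in hits contribute
#' nothing; `X` residues are ignored in counts and always score 0.
#'
#' @param reference The reference [sequence_record()].
#' @param homolog_hits Hit table whose rows align the reference (as query)
#'   to accepted homologs, with alignment strings present.
#' @param pseudocount_weight Positive pseudocount mass `beta`.
#' @param background Named or ordered vector of 20 amino-acid frequencies
#'   summing to 1; defaults to Robinson-Robinson frequencies.
#' @param scheme [scoring_scheme()] providing the fallback rows and the
#'   bits-per-unit scale.
#' @return A list of class `pssm` with elements `scores` (L x 21 matrix,
#'   bits), `ref_residues`, `consensus_length`, `source_ids`,
#'   `reference_id`, `background` and `bits_per_unit`.
#' @export
build_pssm <- function(reference, homolog_hits = NULL,
                       pseudocount_weight = 1, background = NULL,
                       scheme = scoring_scheme()) {
  reference <- .as_record(reference, "reference")
  bg <- background %||% .AA_BACKGROUND
  stopifnot(length(bg) == 20L)
  if (abs(sum(bg) - 1) > 1e-3) stop("background must sum to 1", call. = FALSE)
  bg <- bg / sum(bg)
  names(bg) <- .AA20
  L <- nchar(reference$residues)
  refv <- strsplit(reference$residues, "")[[1]]
  counts <- matrix(0, nrow = 20L, ncol = L, dimnames = list(.AA20, NULL))
  if (!is.null(homolog_hits) && nrow(homolog_hits) > 0L) {
    if (any(is.na(homolog_hits$aligned_query))) {
      stop("homolog_hits must carry alignment strings (engine hits)",
           call. = FALSE)
    }
    for (i in seq_len(nrow(homolog_hits))) {
      q <- strsplit(homolog_hits$aligned_query[i], "")[[1]]
      s <- strsplit(homolog_hits$aligned_subject[i], "")[[1]]
      pos <- homolog_hits$q_start[i] - 1L
      for (k in seq_along(q)) {
        if (q[k] != "-") pos <- pos + 1L
        if (q[k] != "-" && s[k] != "-" && s[k] != "X") {
          counts[s[k], pos] <- counts[s[k], pos] + 1
        }
      }
    }
  }
  covered <- colSums(counts) > 0
  # the reference residue itself always counts once
  for (p in seq_len(L)) {
    if (refv[p] != "X") counts[refv[p], p] <- counts[refv[p], p] + 1
  }
  beta <- pseudocount_weight
  if (beta <= 0 && any(counts[, covered, drop = FALSE] == 0)) {
    stop("pseudocount_weight must be > 0 when some residues are unobserved",
         call. = FALSE)
  }
  scores <- matrix(0, nrow = L, ncol = 21L, dimnames = list(NULL, .AA21))
  for (p in seq_len(L)) {
    if (covered[p] || refv[p] == "X") {
      n_col <- sum(counts[, p])
      freq <- (counts[, p] + beta * bg) / (n_col + beta)
      scores[p, .AA20] <- log2(freq / bg)
    } else {
      # no aligned hit residue: substitution-matrix row in bits
      scores[p, ] <- scheme$matrix[refv[p], ] * scheme$bits_per_unit
    }
  }
  scores[, "X"] <- 0
  subj <- if (is.null(homolog_hits)) character() else
    unique(homolog_hits$subject_id)
  structure(list(scores = scores, ref_residues = refv,
                 consensus_length = L,
                 source_ids = unique(c(reference$accession, subj)),
                 reference_id = reference$accession,
                 background = bg, bits_per_unit = scheme$bits_per_unit),
            class = "pssm")
}

#' @export
print.pssm <- function(x, ...) {
  cat(sprintf("<pssm> %d columns from %d sequence(s), reference %s\n",
              x$consensus_length, length(x$source_ids), x$reference_id))
  invisible(x)
}

#' Search a database with a PSSM profile
#'
#' Smith-Waterman of the profile (columns as per-residue score vectors, in
#' bits) against every database sequence. Gap penalties are the scheme's
#' penalties rescaled to bits, so a single-sequence fallback profile
#' reproduces the plain sequence alignment exactly (up to the bit scale).
#' Hit identity is measured against the reference residues of the profile,
#' and `raw_score` is rescaled back to matrix units before the expect-value
#' estimate.
#'
#' @param pssm A [build_pssm()] profile.
#' @param db A [protein_db()].
#' @param scheme A [scoring_scheme()].
#' @return A hit table sorted by ascending expect value (ties by descending
#'   score, then subject accession); `query_id` is the reference accession.
#' @export
profile_search <- function(pssm, db, scheme = scoring_scheme()) {
  stopifnot(inherits(pssm, "pssm"), inherits(db, "protein_db"))
  bpu <- pssm$bits_per_unit
  rows <- vector("list", nrow(db$records))
  for (i in seq_len(nrow(db$records))) {
    sw <- .sw_align_profile(pssm$scores, .encode(db$records$residues[i]),
                            scheme$gap_open * bpu, scheme$gap_extend * bpu)
    if (isTRUE(sw$empty)) next
    # profile columns index the reference residues
    rows[[i]] <- .hit_row(pssm$reference_id, db$records$accession[i], sw,
                          pssm$ref_residues,
                          strsplit(db$records$residues[i], "")[[1]],
                          pssm$consensus_length, db$total_residues, scheme,
                          raw_score = sw$score / bpu)
  }
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0L) return(.empty_hits())
  hits <- do.call(rbind, rows)
  hits[order(hits$evalue, -hits$raw_score, hits$subject_id), ,
       drop = FALSE]
}
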