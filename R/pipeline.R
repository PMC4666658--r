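# Orchestration: initial pairwise search, the two admission filters,
# profile iteration until convergence, then reciprocal-best-hit orthology.

#' Search parameters
#'
#' The tunables of the homolog search. The defaults are the optimised
#' operating point: e-value cutoff 5e-05, minimal domain length m = 28 and
#' Rost offset n = 33 (which places the minimal identity threshold near 53%
#' at the curve's floor — 53% is not an independent constant).
#'
#' @param evalue_cutoff Expect-value cutoff for candidate hits.
#' @param filter [filter_params()].
#' @param max_iterations Iteration cap guaranteeing termination (the search
#'   normally stops when an iteration adds no member); a message is emitted
#'   when the cap is hit.
#' @param engine `"internal"` (built-in Smith-Waterman/PSSM engine) or
#'   `"precomputed-hits"` (consume BLAST tabular files, one per iteration,
#'   via `hits_files`).
#' @param scheme [scoring_scheme()].
#' @param hits_files For `engine = "precomputed-hits"`: character vector of
#'   outfmt-6 files, one per iteration.
#' @param pssm_pseudocount Pseudocount weight used when building the
#'   iteration profiles.
#' @return A list of class `search_params`.
#' @export
search_params <- function(evalue_cutoff = 5e-05, filter = filter_params(),
                          max_iterations = 10,
                          engine = c("internal", "precomputed-hits"),
                          scheme = scoring_scheme(), hits_files = NULL,
                          pssm_pseudocount = 1) {
  engine <- match.arg(engine)
  stopifnot(evalue_cutoff > 0, inherits(filter, "filter_params"),
            max_iterations >= 1, inherits(scheme, "scoring_scheme"),
            pssm_pseudocount > 0)
  if (engine == "precomputed-hits" && is.null(hits_files)) {
    stop("engine 'precomputed-hits' needs hits_files", call. = FALSE)
  }
  structure(list(evalue_cutoff = evalue_cutoff, filter = filter,
                 max_iterations = as.integer(max_iterations),
                 engine = engine, scheme = scheme, hits_files = hits_files,
                 pssm_pseudocount = pssm_pseudocount),
            class = "search_params")
}

#' @export
print.search_params <- function(x, ...) {
  cat(sprintf(
    "<search_params> evalue<=%g, m=%g, n=%g (decay %g), engine=%s, max_iter=%d\n",
    x$evalue_cutoff, x$filter$min_domain_len, x$filter$rost_n,
    x$filter$decay_constant, x$engine, x$max_iterations))
  invisible(x)
}

.as_query_list <- function(queries) {
  if (inherits(queries, "sequence_record")) return(list(queries))
  if (inherits(queries, "protein_db")) return(.db_records(queries))
  stopifnot(is.list(queries), length(queries) > 0L)
  lapply(queries, .as_record)
}

# Apply e-value cutoff, identity filter and length filter to candidate
# hits; returns accepted hits (with trim columns) and the filter decisions.
.admit <- function(hits, cand_lengths, accepted_lengths, params) {
  hits <- hits[hits$evalue <= params$evalue_cutoff, , drop = FALSE]
  idf <- identity_filter(hits, params$filter)
  lf <- length_filter(idf$kept, cand_lengths, accepted_lengths,
                      params$filter)
  decisions <- rbind(idf$decisions[!idf$decisions$kept, , drop = FALSE],
                     lf$decisions)
  list(kept = lf$kept, decisions = decisions)
}

.empty_members <- function() {
  data.frame(accession = character(), description = character(),
             organism = character(), residues = character(),
             length = integer(), eff_length = integer(),
             identity_pct = numeric(), evalue = numeric(),
             iteration_found = integer(),
             trim_start = integer(), trim_end = integer(),
             stringsAsFactors = FALSE)
}

.members_from_hits <- function(kept, db, iteration) {
  if (nrow(kept) == 0L) return(.empty_members())
  idx <- match(kept$subject_id, db$records$accession)
  data.frame(accession = kept$subject_id,
             description = db$records$description[idx],
             organism = db$records$organism[idx],
             residues = db$records$residues[idx],
             length = nchar(db$records$residues[idx]),
             eff_length = kept$eff_length,
             identity_pct = kept$identity_pct,
             evalue = kept$evalue,
             iteration_found = iteration,
             trim_start = kept$trim_start, trim_end = kept$trim_end,
             stringsAsFactors = FALSE)
}

#' Iterative homolog search
#'
#' The full admission loop: the reference (first query) is aligned against
#' every database sequence; hits passing the e-value cutoff, the Rost
#' identity filter and the length filter become homologs. Accepted members
#' (plus any further query sequences) then seed a PSSM profile which is
#' searched against the database, the same cutoff and filters are applied
#' to new accessions, and the process repeats until an iteration adds no
#' member or `max_iterations` is reached. Identity percentages and expect
#' values are always reported relative to the reference sequence. With
#' `engine = "precomputed-hits"` each iteration instead consumes one
#' externally computed BLAST tabular file.
#'
#' @param queries A [protein_db()], a list of [sequence_record()]s, or a
#'   single record; the first query is the reference sequence.
#' @param db The searched [protein_db()].
#' @param params [search_params()].
#' @return A list of class `homolog_result`: `reference_id`, `members` (one
#'   row per accepted sequence with organism, length, identity to the
#'   reference, e-value, iteration found and any trimmed range),
#'   `iterations_run`, `decisions` (every filter decision with its
#'   iteration) and `params`.
#' @export
find_homologs <- function(queries, db, params = search_params()) {
  stopifnot(inherits(db, "protein_db"))
  if (nrow(db$records) == 0L) stop("empty database", call. = FALSE)
  queries <- .as_query_list(queries)
  reference <- queries[[1]]
  query_lengths <- vapply(queries, function(q) nchar(q$residues), 0L)
  db_lengths <- setNames(nchar(db$records$residues), db$records$accession)

  members <- .empty_members()
  member_hits <- .empty_hits()   # reference-anchored alignments for the PSSM
  decisions <- list()
  precomputed <- params$engine == "precomputed-hits"
  n_iter_files <- if (precomputed) length(params$hits_files) else Inf

  # alignments of the further queries to the reference seed the first profile
  seed_hits <- .empty_hits()
  if (!precomputed && length(queries) > 1L) {
    for (q in queries[-1]) {
      h <- local_align(reference, q, params$scheme, db$total_residues)
      if (!is.null(h)) seed_hits <- rbind(seed_hits, h)
    }
  }

  it <- 0L
  last_adding <- 1L
  repeat {
    it <- it + 1L
    if (it > params$max_iterations) {
      message("iteration cap (", params$max_iterations, ") reached")
      break
    }
    if (precomputed && it > n_iter_files) break
    raw <- if (precomputed) {
      read_hits_tab(params$hits_files[[it]])
    } else if (it == 1L) {
      rows <- lapply(seq_len(nrow(db$records)), function(i) {
        local_align(reference, db_record(db, i), params$scheme,
                    db$total_residues)
      })
      rows <- rows[!vapply(rows, is.null, TRUE)]
      if (length(rows)) do.call(rbind, rows) else .empty_hits()
    } else {
      pssm <- build_pssm(reference, rbind(seed_hits, member_hits),
                         pseudocount_weight = params$pssm_pseudocount,
                         scheme = params$scheme)
      profile_search(pssm, db, params$scheme)
    }
    raw <- raw[!(raw$subject_id %in% members$accession), , drop = FALSE]
    accepted_lengths <- c(query_lengths, members$eff_length)
    res <- .admit(raw, db_lengths, accepted_lengths, params)
    if (nrow(res$decisions)) {
      res$decisions$iteration <- it
      decisions[[length(decisions) + 1L]] <- res$decisions
    }
    added <- nrow(res$kept) > 0L
    if (added) {
      members <- rbind(members, .members_from_hits(res$kept, db, it))
      member_hits <- rbind(member_hits,
                           res$kept[, .HIT_COLS, drop = FALSE])
      last_adding <- it
    }
    if (it == 1L) {
      # every input query present in the database is a member
      for (q in queries) {
        if (q$accession %in% db$records$accession &&
            !(q$accession %in% members$accession)) {
          h <- local_align(reference, q, params$scheme, db$total_residues)
          forced <- .members_from_hits(
            if (is.null(h)) .empty_hits() else
              cbind(h, trim_start = NA_integer_, trim_end = NA_integer_,
                    eff_length = nchar(q$residues)),
            db, 1L)
          if (nrow(forced) == 0L) {
            forced <- .members_from_hits(
              cbind(.hit_stub(reference$accession, q$accession,
                              nchar(q$residues)),
                    trim_start = NA_integer_, trim_end = NA_integer_,
                    eff_length = nchar(q$residues)), db, 1L)
          } else if (!is.null(h)) {
            member_hits <- rbind(member_hits, h)
          }
          members <- rbind(members, forced)
          last_adding <- max(last_adding, 1L)
        }
      }
    }
    if (!added && it > 1L) break
    if (it == 1L && nrow(members) == 0L && !precomputed) {
      # nothing to build a profile from beyond the queries; one profile
      # pass still runs (the seed queries may rescue remote homologs)
      if (nrow(seed_hits) == 0L) break
    }
  }

  members <- members[order(members$iteration_found, members$evalue,
                           members$accession), , drop = FALSE]
  rownames(members) <- NULL
  structure(list(reference_id = reference$accession, members = members,
                 iterations_run = last_adding,
                 decisions = if (length(decisions))
                   do.call(rbind, decisions) else
                   cbind(.decision(character(0), logical(0), character(0),
                                   character(0)),
                         iteration = integer(0)),
                 params = params),
            class = "homolog_result")
}

# placeholder hit row for a forced query member with no positive
# self-alignment to the reference (degenerate, but keeps the contract that
# every query present in the database appears among the members)
.hit_stub <- function(query_id, subject_id, len) {
  data.frame(query_id = query_id, subject_id = subject_id,
             identity_pct = NA_real_, aln_length = NA_integer_,
             mismatches = NA_integer_, gap_opens = NA_integer_,
             q_start = NA_integer_, q_end = NA_integer_,
             s_start = NA_integer_, s_end = NA_integer_,
             evalue = NA_real_, bit_score = NA_real_, raw_score = NA_real_,
             aligned_query = NA_character_,
             aligned_subject = NA_character_, stringsAsFactors = FALSE)
}

#' @export
print.homolog_result <- function(x, ...) {
  cat(sprintf("<homolog_result> reference %s: %d member(s) in %d iteration(s)\n",
              x$reference_id, nrow(x$members), x$iterations_run))
  if (nrow(x$members)) {
    print(utils::head(x$members[, c("accession", "organism", "length",
                                    "identity_pct", "evalue",
                                    "iteration_found")], 10L))
    if (nrow(x$members) > 10L) cat("  ...\n")
  }
  invisible(x)
}

#' Reciprocal-best-hit orthology classification
#'
#' Each homolog (the reference excluded) is aligned against every sequence
#' of the source proteome — the proteome the reference sequence comes from.
#' A homolog is an ortholog iff its best hit there (highest bit score; ties
#' broken by lower e-value, then higher identity, then lexicographic
#' accession) is the reference itself.
#'
#' @param hres A [find_homologs()] result.
#' @param source_proteome A [protein_db()] containing the reference.
#' @param params [search_params()] (scoring scheme).
#' @return A list of class `ortholog_result`: `reference_id` and `members`
#'   (the orthologous subset of the homolog members, with a
#'   `reciprocal_best` column recording the best source-proteome hit).
#' @export
classify_orthologs <- function(hres, source_proteome,
                               params = search_params()) {
  stopifnot(inherits(hres, "homolog_result"),
            inherits(source_proteome, "protein_db"))
  if (!(hres$reference_id %in% source_proteome$records$accession)) {
    stop("reference '", hres$reference_id,
         "' is not in the source proteome", call. = FALSE)
  }
  cand <- hres$members[hres$members$accession != hres$reference_id, ,
                       drop = FALSE]
  best <- character(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    h <- sequence_record(cand$accession[i], cand$residues[i])
    hits <- lapply(seq_len(nrow(source_proteome$records)), function(j) {
      local_align(h, db_record(source_proteome, j), params$scheme,
                  source_proteome$total_residues)
    })
    hits <- hits[!vapply(hits, is.null, TRUE)]
    if (length(hits) == 0L) {
      best[i] <- NA_character_
      next
    }
    hits <- do.call(rbind, hits)
    ord <- order(-hits$bit_score, hits$evalue, -hits$identity_pct,
                 hits$subject_id)
    best[i] <- hits$subject_id[ord[1]]
  }
  keep <- !is.na(best) & best == hres$reference_id
  members <- cand[keep, , drop = FALSE]
  members$reciprocal_best <- best[keep]
  rownames(members) <- NULL
  structure(list(reference_id = hres$reference_id, members = members),
            class = "ortholog_result")
}

#' @export
print.ortholog_result <- function(x, ...) {
  cat(sprintf("<ortholog_result> reference %s: %d ortholog(s)\n",
              x$reference_id, nrow(x$members)))
  if (nrow(x$members)) {
    print(utils::head(x$members[, c("accession", "organism", "length",
                                    "identity_pct", "evalue")], 10L))
  }
  invisible(x)
}
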