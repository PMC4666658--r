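# The two admission filters: the Rost identity/length curve and the
# length-based domain-architecture filter with terminal trimming.

#' Filter parameters
#'
#' @param rost_n Non-negative additive stringency offset `n` of the Rost
#'   curve, in identity percentage points. The default 33 is the optimised
#'   operating point, which puts the curve's floor near 53% identity.
#' @param min_domain_len Minimal length of a protein domain `m` in residues
#'   (default 28, the optimised value; 0 is legal and makes the length band
#'   degenerate, as used during parameter training). Length differences
#'   larger than `m` are taken as evidence of a different domain
#'   architecture.
#' @param decay_constant Decay length of the exponential in the Rost curve.
#'   The default 1000 is the original curve, whose ~20% identity floor is
#'   what the 53% default operating point (n = 33) presupposes; 100, a
#'   variant sometimes quoted, is selectable but raises the floor to ~63%.
#' @return A list of class `filter_params`.
#' @export
filter_params <- function(rost_n = 33, min_domain_len = 28,
                          decay_constant = 1000) {
  stopifnot(rost_n >= 0, min_domain_len >= 0, decay_constant > 0)
  structure(list(rost_n = rost_n, min_domain_len = min_domain_len,
                 decay_constant = decay_constant),
            class = "filter_params")
}

#' @export
print.filter_params <- function(x, ...) {
  cat(sprintf("<filter_params> rost_n=%g, min_domain_len=%d, decay=%g\n",
              x$rost_n, x$min_domain_len, x$decay_constant))
  invisible(x)
}

#' Rost twilight-zone identity threshold
#'
#' The length-dependent percent-identity threshold
#' `pI(L) = n + 480 * L^(-0.32 * (1 + exp(-L / decay)))`
#' separating reliable alignments from the twilight zone. The value may
#' exceed 100% at small `L` (such alignments can never pass).
#'
#' @param L Alignment length in columns (vectorised), `>= 1`.
#' @param n Additive stringency offset in percentage points.
#' @param decay Exponential decay length (see [filter_params()]).
#' @return Identity threshold(s) in percent.
#' @export
rost_threshold <- function(L, n = 0, decay = 1000) {
  if (any(L < 1)) stop("alignment length L must be >= 1", call. = FALSE)
  n + 480 * L^(-0.32 * (1 + exp(-L / decay)))
}

.decision <- function(id, kept, reason, trimmed = NA_character_) {
  data.frame(candidate_id = id, kept = kept, reason = reason,
             trimmed_range = trimmed, stringsAsFactors = FALSE)
}

#' Identity filter (Rost curve)
#'
#' Keeps a hit iff its percent identity reaches the Rost threshold at its
#' alignment length, `identity_pct >= rost_threshold(aln_length, rost_n,
#' decay)`. Every input hit receives a decision record.
#'
#' @param hits A hit table.
#' @param params [filter_params()].
#' @return A list with `kept` (hit table subset) and `decisions` (data.frame
#'   with columns candidate_id, kept, reason, trimmed_range).
#' @export
identity_filter <- function(hits, params = filter_params()) {
  if (nrow(hits) == 0L) {
    return(list(kept = hits, decisions = .decision(character(0), logical(0),
                                                   character(0), character(0))))
  }
  thr <- rost_threshold(hits$aln_length, params$rost_n, params$decay_constant)
  ok <- hits$identity_pct >= thr
  list(kept = hits[ok, , drop = FALSE],
       decisions = .decision(hits$subject_id, ok,
                             ifelse(ok, "kept", "below-rost-curve")))
}

#' Length filter (domain-architecture proxy)
#'
#' Protein length stands in for domain architecture. With `S`/`G` the
#' shortest/longest length in the current homolog set and `m =
#' min_domain_len`: a candidate of full length `l <= S - m` is removed
#' (missing-domain evidence); a candidate with `l > G + m` is kept but
#' trimmed, removing unaligned terminal overhangs (residues outside its
#' hit's subject span), longest overhang first, until `l <= G + m` or no
#' overhang remains. Aligned residues are never removed; the retained range
#' is recorded rather than mutating the database.
#'
#' @param hits Hit table of the candidates (one row per candidate; subject
#'   coordinates give the aligned span).
#' @param candidate_lengths Named vector of full candidate lengths, indexed
#'   by `hits$subject_id`.
#' @param accepted_lengths Lengths of the current homolog set (the query
#'   lengths at the first iteration); must be non-empty.
#' @param params [filter_params()].
#' @return A list with `kept` (hit table subset, plus columns `trim_start`,
#'   `trim_end`, `eff_length` giving the retained range and its length) and
#'   `decisions`.
#' @export
length_filter <- function(hits, candidate_lengths, accepted_lengths,
                          params = filter_params()) {
  if (length(accepted_lengths) == 0L) {
    stop("accepted_lengths must be non-empty", call. = FALSE)
  }
  m <- params$min_domain_len
  S <- min(accepted_lengths)
  G <- max(accepted_lengths)
  if (nrow(hits) == 0L) {
    out <- hits
    out$trim_start <- integer(0); out$trim_end <- integer(0)
    out$eff_length <- integer(0)
    return(list(kept = out, decisions = .decision(character(0), logical(0),
                                                  character(0), character(0))))
  }
  len <- candidate_lengths[hits$subject_id]
  if (anyNA(len)) {
    stop("missing candidate length for ",
         hits$subject_id[which(is.na(len))[1]], call. = FALSE)
  }
  n <- nrow(hits)
  kept <- !(len <= S - m)
  reason <- ifelse(kept, "kept", "too-short")
  trim_start <- rep(NA_integer_, n)
  trim_end <- rep(NA_integer_, n)
  eff_len <- as.integer(len)
  trimmed <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    if (!kept[i] || len[i] <= G + m) next
    a <- hits$s_start[i]; b <- hits$s_end[i]
    left <- a - 1L
    right <- as.integer(len[i]) - b
    cur_start <- 1L; cur_end <- as.integer(len[i])
    # remove unaligned terminal overhangs, longest first
    ord <- if (left >= right) c("L", "R") else c("R", "L")
    for (side in ord) {
      if (cur_end - cur_start + 1L <= G + m) break
      if (side == "L" && left > 0L) cur_start <- a
      if (side == "R" && right > 0L) cur_end <- b
    }
    if (cur_start != 1L || cur_end != len[i]) {
      trim_start[i] <- cur_start
      trim_end[i] <- cur_end
      eff_len[i] <- cur_end - cur_start + 1L
      reason[i] <- "kept-trimmed"
      trimmed[i] <- paste0(cur_start, "-", cur_end)
    }
  }
  out <- hits[kept, , drop = FALSE]
  out$trim_start <- trim_start[kept]
  out$trim_end <- trim_end[kept]
  out$eff_length <- eff_len[kept]
  list(kept = out,
       decisions = .decision(hits$subject_id, kept, reason, trimmed))
}
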