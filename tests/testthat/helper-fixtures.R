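# Programmatic fixtures shared across test files.

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

rand_protein <- function(n, alphabet = AA20) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

mutate_protein <- function(x, p) {
  v <- strsplit(x, "")[[1]]
  hit <- runif(length(v)) < p
  v[hit] <- vapply(v[hit], function(a) sample(setdiff(AA20, a), 1L), "")
  paste(v, collapse = "")
}

# minimal hit rows for filter-level tests (no alignment strings needed)
make_hits <- function(subject_id, identity_pct, aln_length,
                      s_start = 1L, s_end = aln_length,
                      query_id = "Q") {
  n <- length(subject_id)
  data.frame(
    query_id = rep_len(query_id, n), subject_id = subject_id,
    identity_pct = rep_len(identity_pct, n),
    aln_length = as.integer(rep_len(aln_length, n)),
    mismatches = rep_len(0L, n), gap_opens = rep_len(0L, n),
    q_start = rep_len(1L, n), q_end = as.integer(rep_len(aln_length, n)),
    s_start = as.integer(rep_len(s_start, n)),
    s_end = as.integer(rep_len(s_end, n)),
    evalue = rep_len(1e-20, n), bit_score = rep_len(100, n),
    raw_score = rep_len(100, n),
    aligned_query = rep_len(NA_character_, n),
    aligned_subject = rep_len(NA_character_, n),
    stringsAsFactors = FALSE)
}

# A reference with nested-similarity relatives: B is close to the
# reference, C is close to B but remote from the reference, so C's pairwise
# expect value against the reference sits above a cutoff that its
# profile-search expect value (profile built from reference + B) is below.
make_chain_fixture <- function(seed = 301) {
  set.seed(seed)
  D <- rand_protein(60)
  ref <- sequence_record("REF", paste0(rand_protein(20), D, rand_protein(20)))
  Bdom <- mutate_protein(D, 0.25)
  B <- sequence_record("B", paste0(rand_protein(20), Bdom, rand_protein(20)))
  Cdom <- mutate_protein(Bdom, 0.30)
  C <- sequence_record("C", paste0(rand_protein(20), Cdom, rand_protein(20)))
  db <- protein_db(list(B, C), name = "chain")
  # fixture construction: a cutoff strictly between C's pairwise and
  # profile expect values demonstrates the iterative gain
  hB <- local_align(ref, B, db_residues = db$total_residues)
  hC <- local_align(ref, C, db_residues = db$total_residues)
  prof <- profile_search(build_pssm(ref, hB), db)
  profC <- prof$evalue[prof$subject_id == "C"]
  list(reference = ref, db = db,
       pairwise_evalue_C = hC$evalue, profile_evalue_C = profC,
       cutoff = sqrt(hC$evalue * profC))
}

# Hand-constructed optimisation family: full-sequence homologs H1/H2, a
# short homolog rescued only when m is generous, a truncated paralog
# admitted only when m is excessive, a twilight-zone paralog admitted only
# at n = 0, a weak motif-sharing homolog, and a decoy sharing only a
# low-complexity 12-residue run with the reference.
make_opt_family <- function(seed) {
  set.seed(seed)
  motif <- paste(sample(c("A", "S", "T", "V"), 30, TRUE), collapse = "")
  arun <- strrep("A", 12)
  ref <- paste0(rand_protein(39), arun, rand_protein(48), motif,
                rand_protein(111))  # 240 aa
  recs <- list(
    sequence_record("REF", ref, organism = "src"),
    sequence_record("H1", paste0(mutate_protein(ref, 0.10), rand_protein(8))),
    sequence_record("H2", paste0(mutate_protein(ref, 0.15), rand_protein(8))),
    sequence_record("SHORT", mutate_protein(substr(ref, 1, 220), 0.12)),
    sequence_record("TRUNC", mutate_protein(substr(ref, 1, 80), 0.05)),
    sequence_record("DIV", paste0(mutate_protein(ref, 0.55), rand_protein(8))),
    sequence_record("WEAK", paste0(rand_protein(99), "W", motif, "W",
                                   rand_protein(107))),
    sequence_record("ADEC", paste0(rand_protein(99), "W", arun, "W",
                                   rand_protein(127)))
  )
  list(queries = protein_db(recs[1], "q"),
       db = protein_db(recs[-1], "db"),
       truth = c("H1", "H2", "SHORT", "WEAK"))
}

expect_same_bytes <- function(f1, f2) {
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
}
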