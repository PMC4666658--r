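test_that("self-alignment is perfect and spans the whole sequence", {
  h <- local_align(sequence_record("a", "MKVLAT"),
                   sequence_record("b", "MKVLAT"))
  expect_equal(h$identity_pct, 100)
  expect_equal(h$aln_length, 6L)
  expect_equal(c(h$q_start, h$q_end, h$s_start, h$s_end), c(1L, 6L, 1L, 6L))
  expect_equal(h$gap_opens, 0L)
})

test_that("classic BLOSUM50 linear-gap alignment matches the DP oracle", {
  sc <- scoring_scheme("BLOSUM50", gap_open = 8, gap_extend = 8)
  h <- local_align("HEAGAWGHEE", "PAWHEAE", sc)
  o <- oracle_local_align("HEAGAWGHEE", "PAWHEAE", sc$matrix, 8, 8)
  expect_equal(h$raw_score, 28)          # frozen from the oracle
  expect_equal(h$aligned_query, "AWGHE")
  expect_equal(h$aligned_subject, "AW-HE")
  expect_equal(h$raw_score, o$score)
  expect_equal(h$aligned_query, o$aligned_query)
  expect_equal(h$aligned_subject, o$aligned_subject)
})

test_that("pairs with no positive-scoring residue pair align to nothing", {
  expect_null(local_align("CCCC", "LLLL"))  # C/L scores -1 under BLOSUM62
})

test_that("engine equals the DP oracle on random reduced-alphabet pairs", {
  sc <- scoring_scheme()
  set.seed(41)
  for (k in 1:200) {
    q <- rand_protein(sample(3:12, 1), alphabet = c("A", "C", "G", "W"))
    s <- rand_protein(sample(3:12, 1), alphabet = c("A", "C", "G", "W"))
    h <- local_align(q, s, sc)
    o <- oracle_local_align(q, s, sc$matrix, sc$gap_open, sc$gap_extend)
    if (is.null(o)) {
      expect_null(h)
    } else {
      expect_equal(h$raw_score, o$score)
      expect_equal(h$identity_pct, o$identity_pct)
      expect_equal(h$aligned_query, o$aligned_query)
      expect_equal(h$aligned_subject, o$aligned_subject)
    }
  }
})

test_that("engine scores agree with an independent aligner", {
  # dual route: Biostrings pairwiseAlignment charges open + k*extend for a
  # length-k gap, ours charges open + (k-1)*extend, so its opening penalty
  # is ours minus one extension
  sc <- scoring_scheme()
  e <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = e)
  set.seed(42)
  for (k in 1:50) {
    q <- rand_protein(sample(5:30, 1))
    s <- rand_protein(sample(5:30, 1))
    h <- local_align(q, s, sc)
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(q), Biostrings::AAString(s), type = "local",
      substitutionMatrix = e$BLOSUM62,
      gapOpening = sc$gap_open - sc$gap_extend,
      gapExtension = sc$gap_extend)
    expect_equal(if (is.null(h)) 0 else h$raw_score,
                 max(0, Biostrings::score(pa)))
  }
})

test_that("alignment score is symmetric in query and subject", {
  set.seed(43)
  for (k in 1:25) {
    q <- rand_protein(sample(5:40, 1))
    s <- rand_protein(sample(5:40, 1))
    h1 <- local_align(q, s)
    h2 <- local_align(s, q)
    expect_equal(is.null(h1), is.null(h2))
    if (!is.null(h1)) expect_equal(h1$raw_score, h2$raw_score)
  }
})

test_that("percent identity counts gap columns in the denominator only", {
  h <- local_align("MAWGHEM", "MAWGHEM")
  expect_equal(percent_identity(h), 100)
  # forced 4-of-5 case via a hand-built hit
  hit <- make_hits("s", identity_pct = 80, aln_length = 5)
  hit$aligned_query <- "AWGHE"
  hit$aligned_subject <- "AW-HE"
  expect_equal(percent_identity(hit), 80)
  hit$aln_length <- 0L
  expect_error(percent_identity(hit), "length is 0")
  # random gapped pairs agree with a per-column count
  set.seed(44)
  for (k in 1:25) {
    h <- local_align(rand_protein(30, c("A", "C", "G", "W")),
                     rand_protein(30, c("A", "C", "G", "W")))
    if (is.null(h)) next
    q <- strsplit(h$aligned_query, "")[[1]]
    s <- strsplit(h$aligned_subject, "")[[1]]
    expect_equal(percent_identity(h),
                 100 * sum(q == s & q != "-") / length(q))
  }
})

test_that("expect value follows the Karlin-Altschul closed form", {
  sc <- scoring_scheme()
  # direct arithmetic oracle
  expect_equal(estimate_evalue(100, 100, 10000, sc),
               0.041 * 100 * 10000 * exp(-0.267 * 100))
  # linear in database size
  expect_equal(estimate_evalue(50, 100, 2e4, sc),
               2 * estimate_evalue(50, 100, 1e4, sc))
  # monotone decreasing in score, capped at K*m*n for non-positive scores
  s <- seq(0, 500, by = 25)
  ev <- estimate_evalue(s, 100, 1e4, sc)
  expect_true(all(diff(ev) < 0))
  expect_equal(estimate_evalue(-10, 100, 1e4, sc), 0.041 * 100 * 1e4)
})

test_that("PSSM log-odds are zero when observations match the background", {
  # reference 'A' plus one hit residue for each of the other 19 amino acids
  # gives uniform counts; with a uniform background every score is 0
  ref <- sequence_record("R", "A")
  others <- setdiff(AA20, "A")
  hits <- do.call(rbind, lapply(others, function(a) {
    h <- make_hits(paste0("s", a), 100, 1)
    h$aligned_query <- "A"; h$aligned_subject <- a
    h
  }))
  p <- build_pssm(ref, hits, pseudocount_weight = 1,
                  background = rep(1 / 20, 20))
  expect_equal(unname(p$scores[1, AA20]), rep(0, 20), tolerance = 1e-12)
})

test_that("PSSM single-observation column approaches log2(20) as beta -> 0", {
  ref <- sequence_record("R", "A")
  h <- make_hits("self", 100, 1)
  h$aligned_query <- "A"; h$aligned_subject <- "A"
  p <- build_pssm(ref, h, pseudocount_weight = 1e-9,
                  background = rep(1 / 20, 20))
  expect_equal(unname(p$scores[1, "A"]), log2(20), tolerance = 1e-6)
  expect_equal(p$consensus_length, 1L)
  expect_error(build_pssm(ref, h, pseudocount_weight = 0),
               "pseudocount_weight must be > 0")
  expect_error(build_pssm(ref, h, background = rep(1, 20)), "sum to 1")
})

test_that("uncovered PSSM columns fall back to matrix rows in bits", {
  sc <- scoring_scheme()
  ref <- sequence_record("R", "MKW")
  p <- build_pssm(ref, NULL, scheme = sc)
  expect_equal(p$consensus_length, 3L)
  for (i in 1:3) {
    aa <- substr("MKW", i, i)
    expect_equal(unname(p$scores[i, AA20]),
                 unname(sc$matrix[aa, AA20] * 0.5))
  }
  expect_equal(unname(p$scores[, "X"]), rep(0, 3))
})

test_that("profile search retrieves the reference itself first", {
  set.seed(45)
  seqs <- lapply(1:6, function(i)
    sequence_record(paste0("d", i), rand_protein(80)))
  ref <- seqs[[3]]
  db <- protein_db(seqs, name = "selfdb")
  p <- build_pssm(ref, NULL)
  hits <- profile_search(p, db)
  expect_equal(hits$subject_id[1], ref$accession)
  expect_equal(hits$query_id[1], ref$accession)
  expect_equal(hits$evalue, sort(hits$evalue))
})

test_that("single-sequence fallback profile ranks hits like pairwise search", {
  set.seed(46)
  ref <- sequence_record("R", rand_protein(60))
  seqs <- lapply(1:8, function(i) {
    sequence_record(paste0("m", i), mutate_protein(ref$residues, i * 0.08))
  })
  db <- protein_db(seqs, name = "rankdb")
  p <- build_pssm(ref, NULL)
  prof <- profile_search(p, db)
  pair <- do.call(rbind, lapply(seqs, function(s)
    local_align(ref, s, db_residues = db$total_residues)))
  pair <- pair[order(pair$evalue, -pair$raw_score, pair$subject_id), ]
  expect_equal(prof$subject_id, pair$subject_id)
  # fallback columns are half-bit rescalings, so raw scores coincide
  expect_equal(prof$raw_score, pair$raw_score)
  expect_equal(prof$evalue, pair$evalue)
})

test_that("planted family members outrank all decoys in a profile search", {
  fam <- generate_family(family_config(seed = 99))
  ref <- db_record(fam$queries, 1)
  h1 <- local_align(ref, db_record(fam$db, "F001_S1"),
                    db_residues = fam$db$total_residues)
  p <- build_pssm(ref, h1)
  hits <- profile_search(p, fam$db)
  roles <- setNames(fam$truth$role, fam$truth$accession)
  planted <- hits$subject_id[roles[hits$subject_id] == "ortholog"]
  decoy_hits <- hits$subject_id[roles[hits$subject_id] == "decoy"]
  expect_equal(length(planted), fam$config$n_species)
  if (length(decoy_hits)) {
    expect_true(max(match(planted, hits$subject_id)) <
                  min(match(decoy_hits, hits$subject_id)))
  }
})
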