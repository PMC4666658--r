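# Independent brute-force dynamic-programming oracle for affine-gap local
# alignment, written in plain R with the same stated conventions as the
# engine (gap of length k costs open + (k-1)*extend; traceback prefers
# diagonal over up over left; start cell is the first maximum in row-major
# order). Used to verify the compiled engine on small inputs.

oracle_local_align <- function(q, s, smat, open, extend) {
  qv <- strsplit(q, "")[[1]]
  sv <- strsplit(s, "")[[1]]
  n <- length(qv); m <- length(sv)
  M <- matrix(0, n + 1, m + 1)
  Ix <- matrix(-Inf, n + 1, m + 1)
  Iy <- matrix(-Inf, n + 1, m + 1)
  for (i in 1:n) {
    for (j in 1:m) {
      M[i + 1, j + 1] <- max(M[i, j], Ix[i, j], Iy[i, j], 0) +
        smat[qv[i], sv[j]]
      Ix[i + 1, j + 1] <- max(M[i, j + 1] - open, Ix[i, j + 1] - extend)
      Iy[i + 1, j + 1] <- max(M[i + 1, j] - open, Iy[i + 1, j] - extend)
    }
  }
  best <- max(M)
  if (best <= 0) return(NULL)
  bi <- bj <- NA_integer_
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      if (M[i, j] >= best - 1e-9) { bi <- i; bj <- j; break }
    }
    if (!is.na(bi)) break
  }
  i <- bi - 1L; j <- bj - 1L
  state <- "M"; aq <- character(); as_ <- character()
  repeat {
    if (state == "M") {
      aq <- c(qv[i], aq); as_ <- c(sv[j], as_)
      tgt <- M[i + 1, j + 1] - smat[qv[i], sv[j]]
      i <- i - 1L; j <- j - 1L
      if (tgt <= 1e-9) break
      if (abs(M[i + 1, j + 1] - tgt) < 1e-9) state <- "M"
      else if (abs(Ix[i + 1, j + 1] - tgt) < 1e-9) state <- "Ix"
      else state <- "Iy"
    } else if (state == "Ix") {
      aq <- c(qv[i], aq); as_ <- c("-", as_)
      tgt <- Ix[i + 1, j + 1]
      i <- i - 1L
      state <- if (abs(M[i + 1, j + 1] - open - tgt) < 1e-9) "M" else "Ix"
    } else {
      aq <- c("-", aq); as_ <- c(sv[j], as_)
      tgt <- Iy[i + 1, j + 1]
      j <- j - 1L
      state <- if (abs(M[i + 1, j + 1] - open - tgt) < 1e-9) "M" else "Iy"
    }
  }
  list(score = best,
       q_start = i + 1L, q_end = bi - 1L,
       s_start = j + 1L, s_end = bj - 1L,
       aligned_query = paste(aq, collapse = ""),
       aligned_subject = paste(as_, collapse = ""),
       identity_pct = 100 * sum(aq != "-" & aq == as_) / length(aq))
}
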