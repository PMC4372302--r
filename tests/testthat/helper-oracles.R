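# Independent oracles used by the tests. These deliberately re-derive
# results by brute force (enumeration, naive windowing, exhaustive DP) and
# never call the code paths they check.

SENSE_CODONS <- local({
  gc64 <- Biostrings::GENETIC_CODE
  names(gc64)[gc64 != "*"]
})

random_codon_seq <- function(n_codons) {
  paste(sample(SENSE_CODONS, n_codons, replace = TRUE), collapse = "")
}

random_protein <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n,
               replace = TRUE), collapse = "")
}

# --- NG86 enumeration oracle -------------------------------------------
# site counts: enumerate the 9 single-base mutations of each codon
oracle_ng86_sites <- function(codon) {
  gc64 <- Biostrings::GENETIC_CODE
  ch <- strsplit(codon, "")[[1]]
  s <- 0
  for (p in 1:3) for (n in setdiff(c("A", "C", "G", "T"), ch[p])) {
    alt <- ch; alt[p] <- n
    alt <- paste(alt, collapse = "")
    if (gc64[[alt]] != "*" && gc64[[alt]] == gc64[[codon]]) s <- s + 1 / 3
  }
  s
}

# differences: enumerate every ordering of the differing positions
oracle_ng86_diffs <- function(ca, cb) {
  gc64 <- Biostrings::GENETIC_CODE
  da <- strsplit(ca, "")[[1]]; db <- strsplit(cb, "")[[1]]
  pos <- which(da != db)
  if (length(pos) == 0) return(c(sd = 0, nd = 0))
  perm <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) for (r in perm(v[-i]))
      out[[length(out) + 1]] <- c(v[i], r)
    out
  }
  walk <- function(ord, allow_stop) {
    cur <- da; sd <- 0; nd <- 0
    for (p in ord) {
      nxt <- cur; nxt[p] <- db[p]
      c1 <- paste(cur, collapse = ""); c2 <- paste(nxt, collapse = "")
      if (gc64[[c2]] == "*") {
        if (!allow_stop) return(NULL)
        nd <- nd + 1
      } else if (gc64[[c1]] == gc64[[c2]]) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(sd = sd, nd = nd)
  }
  res <- Filter(Negate(is.null), lapply(perm(pos), walk, allow_stop = FALSE))
  if (length(res) == 0)
    res <- lapply(perm(pos), walk, allow_stop = TRUE)
  m <- do.call(rbind, res)
  c(sd = mean(m[, "sd"]), nd = mean(m[, "nd"]))
}

oracle_ng86 <- function(seq_a, seq_b) {
  n <- nchar(seq_a) / 3
  ca <- substring(seq_a, 3 * (1:n) - 2, 3 * (1:n))
  cb <- substring(seq_b, 3 * (1:n) - 2, 3 * (1:n))
  S <- (sum(vapply(ca, oracle_ng86_sites, 0)) +
          sum(vapply(cb, oracle_ng86_sites, 0))) / 2
  N <- 3 * n - S
  d <- mapply(oracle_ng86_diffs, ca, cb)
  Sd <- sum(unlist(d["sd", ])); Nd <- sum(unlist(d["nd", ]))
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  list(S = S, N = N, Sd = Sd, Nd = Nd,
       dS = jc(Sd / S), dN = jc(Nd / N))
}

# --- affine-gap global alignment score oracle (Gotoh DP) ----------------
# matches the convention: a gap of length L costs open + L * ext
oracle_nw_score <- function(a, b, open = 10, ext = 1) {
  sm <- local({
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    e$BLOSUM62
  })
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1); X <- matrix(NEG, n + 1, m + 1)
  Y <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in 2:(n + 1)) X[i, 1] <- -(open + ext * (i - 1))
  for (j in 2:(m + 1)) Y[1, j] <- -(open + ext * (j - 1))
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    sc <- sm[A[i - 1], B[j - 1]]
    M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + sc
    X[i, j] <- max(M[i - 1, j] - open - ext, X[i - 1, j] - ext,
                   Y[i - 1, j] - open - ext)
    Y[i, j] <- max(M[i, j - 1] - open - ext, Y[i, j - 1] - ext,
                   X[i, j - 1] - open - ext)
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# --- pairwise codon-model likelihood oracle -----------------------------
# direct summation over the root state for a 2-taxon tree
oracle_pair_loglik <- function(seq1, seq2, t1, t2, omega, kappa) {
  pi <- silkgland::codon_frequencies(method = "uniform")
  Q <- silkgland::codon_rate_matrix(omega, kappa, pi)
  P1 <- as.matrix(Matrix::expm(Q * t1))
  P2 <- as.matrix(Matrix::expm(Q * t2))
  n <- nchar(seq1) / 3
  c1 <- substring(seq1, 3 * (1:n) - 2, 3 * (1:n))
  c2 <- substring(seq2, 3 * (1:n) - 2, 3 * (1:n))
  i1 <- match(c1, SENSE_CODONS); i2 <- match(c2, SENSE_CODONS)
  sum(log(vapply(seq_len(n), function(k)
    sum(pi * P1[, i1[k]] * P2[, i2[k]]), 0)))
}
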