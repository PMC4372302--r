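# Codon substitution machinery shared by the simulator and the ML fits.
# State space: the 61 sense codons of the standard genetic code.

.codon_env <- new.env(parent = emptyenv())

.codon_tables <- function() {
  if (!is.null(.codon_env$CODONS)) return(as.list(.codon_env))
  gc64 <- Biostrings::GENETIC_CODE
  sense <- names(gc64)[gc64 != "*"]
  aa <- unname(gc64[sense])
  n <- length(sense)              # 61
  cm <- do.call(rbind, strsplit(sense, ""))
  # single-nucleotide neighbour pairs with transition / synonymous flags
  ii <- jj <- integer(0); ts <- syn <- logical(0); pos <- integer(0)
  is_ts <- function(a, b) (a == "A" & b == "G") | (a == "G" & b == "A") |
    (a == "C" & b == "T") | (a == "T" & b == "C")
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    d <- which(cm[i, ] != cm[j, ])
    if (length(d) != 1L) next
    ii <- c(ii, i); jj <- c(jj, j); pos <- c(pos, d)
    ts <- c(ts, is_ts(cm[i, d], cm[j, d]))
    syn <- c(syn, aa[i] == aa[j])
  }
  .codon_env$CODONS <- sense
  .codon_env$AA <- aa
  .codon_env$CODON_MAT <- cm
  .codon_env$NBR <- data.frame(i = ii, j = jj, pos = pos,
                               transition = ts, synonymous = syn)
  as.list(.codon_env)
}

#' Construct a codon alignment
#'
#' An in-frame multiple alignment of coding nucleotide sequences. Rows must
#' be equal-length, length divisible by 3, gap characters (`-`) allowed only
#' in whole-codon units, and no stop codons anywhere.
#'
#' @param ids taxon labels (unique).
#' @param seqs upper-case nucleotide strings.
#' @return An object of class `codon_aln` (list with `taxa`, `seq`).
#' @export
codon_alignment <- function(ids, seqs) {
  ids <- as.character(ids); seqs <- toupper(as.character(seqs))
  if (length(ids) != length(seqs)) stop("ids/seqs length mismatch")
  if (anyDuplicated(ids)) stop("duplicate taxon labels")
  len <- unique(nchar(seqs))
  if (length(len) != 1L) stop("alignment rows have unequal lengths")
  if (len %% 3L != 0L) stop("alignment length not divisible by 3")
  stops <- c("TAA", "TAG", "TGA")
  for (k in seq_along(seqs)) {
    cods <- substring(seqs[k], seq(1L, len, 3L), seq(3L, len, 3L))
    gapped <- grepl("-", cods, fixed = TRUE)
    if (any(gapped & cods != "---"))
      stop("partial-codon gap in taxon ", ids[k])
    if (any(cods %in% stops))
      stop("stop codon in taxon ", ids[k])
    if (any(!gapped & !grepl("^[ACGT]{3}$", cods)))
      stop("non-ACGT character in taxon ", ids[k])
  }
  structure(list(taxa = ids, seq = stats::setNames(seqs, ids)),
            class = "codon_aln")
}

#' @export
print.codon_aln <- function(x, ...) {
  cat(sprintf("codon_aln: %d taxa x %d codons\n",
              length(x$taxa), nchar(x$seq[1L]) / 3L))
  invisible(x)
}

# split to codon vector
.codons_of <- function(s) {
  len <- nchar(s)
  substring(s, seq(1L, len, 3L), seq(3L, len, 3L))
}

# drop codon columns containing any gap (complete deletion)
.degap_codon_aln <- function(aln) {
  mat <- do.call(rbind, lapply(aln$seq, .codons_of))
  keep <- colSums(mat == "---") == 0L
  mat <- mat[, keep, drop = FALSE]
  codon_alignment(aln$taxa, apply(mat, 1L, paste, collapse = ""))
}

#' Codon equilibrium frequencies
#'
#' Either uniform over the 61 sense codons, or F3x4: products of the three
#' positional nucleotide frequencies observed in the alignment, restricted
#' to sense codons and renormalized. Positional frequencies are floored at
#' 1e-4 so that no sense codon gets zero probability.
#'
#' @param aln a [codon_alignment] (required for `"F3x4"`).
#' @param method `"F3x4"` or `"uniform"`.
#' @return Numeric vector of 61 frequencies summing to 1, named by codon.
#' @export
codon_frequencies <- function(aln = NULL, method = c("F3x4", "uniform")) {
  method <- match.arg(method)
  tb <- .codon_tables()
  if (method == "uniform")
    return(stats::setNames(rep(1 / 61, 61), tb$CODONS))
  stopifnot(inherits(aln, "codon_aln"))
  mat <- do.call(rbind, lapply(aln$seq, .codons_of))
  cods <- mat[mat != "---"]
  ntm <- do.call(rbind, strsplit(cods, ""))
  f <- sapply(1:3, function(p) {
    tab <- table(factor(ntm[, p], levels = c("A", "C", "G", "T")))
    v <- pmax(as.numeric(tab) / sum(tab), 1e-4)
    v / sum(v)
  })
  rownames(f) <- c("A", "C", "G", "T")
  pi <- f[tb$CODON_MAT[, 1L], 1L] * f[tb$CODON_MAT[, 2L], 2L] *
    f[tb$CODON_MAT[, 3L], 3L]
  pi <- pi / sum(pi)
  stats::setNames(pi, tb$CODONS)
}

#' One-ratio codon rate matrix
#'
#' Goldman-Yang-style instantaneous rate matrix over the 61 sense codons:
#' zero for multi-nucleotide changes, target frequency times `kappa` for
#' transitions, times `omega` for nonsynonymous changes. Scaled so the
#' expected number of substitutions per codon per unit time is 1 (branch
#' lengths are substitutions per codon).
#'
#' @param omega dN/dS ratio (> 0).
#' @param kappa transition/transversion rate ratio (> 0).
#' @param pi equilibrium codon frequencies (length 61).
#' @param scale if `TRUE`, normalize total flux to 1.
#' @return A 61 x 61 rate matrix with rows summing to zero.
#' @export
codon_rate_matrix <- function(omega, kappa, pi, scale = TRUE) {
  stopifnot(omega > 0, kappa > 0, length(pi) == 61, all(pi > 0))
  tb <- .codon_tables()
  nbr <- tb$NBR
  Q <- matrix(0, 61, 61, dimnames = list(tb$CODONS, tb$CODONS))
  rate <- pi[nbr$j]
  rate[nbr$transition] <- rate[nbr$transition] * kappa
  rate[!nbr$synonymous] <- rate[!nbr$synonymous] * omega
  Q[cbind(nbr$i, nbr$j)] <- rate
  diag(Q) <- -rowSums(Q)
  if (scale) {
    mu <- -sum(pi * diag(Q))
    Q <- Q / mu
  }
  Q
}

# spectral decomposition of a reversible Q for fast P(t) = exp(Qt)
.codon_decompose <- function(Q, pi) {
  sp <- sqrt(pi)
  S <- Q * outer(sp, 1 / sp)
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  list(A = e$vectors / sp, B = t(e$vectors * sp), values = e$values)
}

.codon_pmat <- function(dec, t) {
  P <- dec$A %*% (exp(dec$values * t) * dec$B)
  P[P < 0] <- 0
  P / rowSums(P)
}

# site patterns: list(index matrix taxa x npat of codon indices, weights)
.site_patterns <- function(aln) {
  tb <- .codon_tables()
  mat <- do.call(rbind, lapply(aln$seq, .codons_of))
  idx <- matrix(match(mat, tb$CODONS), nrow = nrow(mat))
  rownames(idx) <- aln$taxa
  key <- apply(idx, 2L, paste, collapse = ",")
  u <- !duplicated(key)
  list(idx = idx[, u, drop = FALSE],
       w = as.numeric(table(key)[key[u]]))
}

# Felsenstein pruning; pmats: list over edges of 61x61 transition matrices
.prune_loglik <- function(tree, pat, pmats, pi) {
  nt <- length(tree$tip.label)
  nn <- nt + tree$Nnode
  npat <- ncol(pat$idx)
  tre <- ape::reorder.phylo(tree, "postorder")
  clik <- vector("list", nn)
  ord <- match(tree$tip.label, rownames(pat$idx))
  for (k in seq_len(nt)) {
    m <- matrix(0, 61, npat)
    m[cbind(pat$idx[ord[k], ], seq_len(npat))] <- 1
    clik[[k]] <- m
  }
  eidx <- match(paste(tre$edge[, 1], tre$edge[, 2]),
                paste(tree$edge[, 1], tree$edge[, 2]))
  for (e in seq_len(nrow(tre$edge))) {
    p <- tre$edge[e, 1L]; ch <- tre$edge[e, 2L]
    contrib <- pmats[[eidx[e]]] %*% clik[[ch]]
    clik[[p]] <- if (is.null(clik[[p]])) contrib else clik[[p]] * contrib
  }
  root <- nt + 1L
  site_l <- colSums(pi * clik[[root]])
  sum(pat$w * log(site_l))
}

#' Log-likelihood under the one-ratio codon model
#'
#' Felsenstein pruning over the 61-sense-codon state space with the
#' one-ratio (single omega) rate matrix. Gapped codon columns are removed
#' by complete deletion before computation.
#'
#' @param aln a [codon_alignment].
#' @param tree an [ape::phylo] with branch lengths, leaves matching taxa.
#' @param omega,kappa model parameters (> 0).
#' @param freqs `"F3x4"` (computed from `aln`) or `"uniform"`.
#' @return The log-likelihood (finite scalar).
#' @export
m0_loglik <- function(aln, tree, omega, kappa,
                      freqs = c("F3x4", "uniform")) {
  stopifnot(inherits(aln, "codon_aln"), inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  if (!setequal(tree$tip.label, aln$taxa))
    stop("tree leaves and alignment taxa differ")
  aln <- .degap_codon_aln(aln)
  pi <- codon_frequencies(aln, match.arg(freqs))
  Q <- codon_rate_matrix(omega, kappa, pi)
  dec <- .codon_decompose(Q, pi)
  pat <- .site_patterns(aln)
  pmats <- lapply(tree$edge.length, function(t) .codon_pmat(dec, max(t, 0)))
  .prune_loglik(tree, pat, pmats, pi)
}

# pairwise NG86-flavoured nucleotide distances -> least-squares branch lengths
.init_branch_lengths <- function(aln, tree) {
  nt <- length(tree$tip.label)
  ne <- nrow(tree$edge)
  pairs <- utils::combn(nt, 2L)
  d <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    a <- aln$seq[tree$tip.label[pairs[1L, k]]]
    b <- aln$seq[tree$tip.label[pairs[2L, k]]]
    ca <- strsplit(a, "")[[1L]]; cb <- strsplit(b, "")[[1L]]
    keep <- ca != "-" & cb != "-"
    p <- mean(ca[keep] != cb[keep])
    p <- min(p, 0.70)
    d[k] <- 3 * (-0.75 * log(1 - 4 * p / 3))   # subs per codon
  }
  A <- matrix(0, ncol(pairs), ne)
  ekey <- paste(tree$edge[, 1L], tree$edge[, 2L])
  for (k in seq_len(ncol(pairs))) {
    np <- ape::nodepath(tree, pairs[1L, k], pairs[2L, k])
    for (s in seq_len(length(np) - 1L)) {
      e <- match(paste(np[s], np[s + 1L]), ekey)
      if (is.na(e)) e <- match(paste(np[s + 1L], np[s]), ekey)
      A[k, e] <- 1
    }
  }
  b <- tryCatch(stats::lm.fit(A, d)$coefficients, error = function(e) NULL)
  b[is.na(b)] <- mean(d) / 4
  pmax(b, 1e-3)
}

# small decomposition cache keyed on (omega, kappa)
.make_dec_cache <- function(pi) {
  cache <- new.env(parent = emptyenv())
  function(omega, kappa) {
    key <- sprintf("%.12g_%.12g", omega, kappa)
    dec <- cache[[key]]
    if (is.null(dec)) {
      if (length(ls(cache)) > 16L) rm(list = ls(cache), envir = cache)
      dec <- .codon_decompose(codon_rate_matrix(omega, kappa, pi), pi)
      cache[[key]] <- dec
    }
    dec
  }
}

#' Fit the one-ratio codon model by maximum likelihood
#'
#' Maximizes the log-likelihood over omega, kappa and all branch lengths
#' using bounded quasi-Newton (L-BFGS-B) on log-transformed parameters.
#' Initial values: omega 0.4, kappa 2, branch lengths from least squares on
#' Jukes-Cantor-corrected pairwise distances. Deterministic given inputs.
#'
#' @inheritParams m0_loglik
#' @param control optional list: `maxit` (default 200).
#' @return A `codon_fit` list: `omega`, `kappa`, `lnL`, `tree` (with fitted
#'   branch lengths), `branch_lengths`, `convergence`, `model = "M0"`.
#' @export
fit_one_ratio <- function(aln, tree, freqs = c("F3x4", "uniform"),
                          control = list()) {
  stopifnot(inherits(aln, "codon_aln"), inherits(tree, "phylo"))
  if (length(aln$taxa) < 2L) stop("need at least 2 taxa")
  if (!setequal(tree$tip.label, aln$taxa))
    stop("tree leaves and alignment taxa differ")
  freqs <- match.arg(freqs)
  maxit <- if (is.null(control$maxit)) 200L else control$maxit
  aln <- .degap_codon_aln(aln)
  pi <- codon_frequencies(aln, freqs)
  pat <- .site_patterns(aln)
  get_dec <- .make_dec_cache(pi)
  ne <- nrow(tree$edge)
  t0 <- .init_branch_lengths(aln, tree)

  lb <- c(log(1e-4), log(1e-2), rep(log(1e-6), ne))
  ub <- c(log(10), log(50), rep(log(20), ne))
  negll <- function(par) {
    omega <- exp(par[1L]); kappa <- exp(par[2L]); bl <- exp(par[-(1:2)])
    dec <- get_dec(omega, kappa)
    pmats <- lapply(bl, function(t) .codon_pmat(dec, t))
    ll <- .prune_loglik(tree, pat, pmats, pi)
    if (!is.finite(ll)) 1e10 else -ll
  }
  par0 <- c(log(0.4), log(2), log(pmax(t0, 1e-5)))
  fit <- stats::optim(par0, negll, method = "L-BFGS-B",
                      lower = lb, upper = ub,
                      control = list(maxit = maxit, factr = 1e8))
  if (fit$convergence != 0 && fit$convergence != 1)
    warning("optimizer returned convergence code ", fit$convergence)
  bl <- exp(fit$par[-(1:2)])
  ft <- tree; ft$edge.length <- bl
  structure(list(omega = exp(fit$par[1L]), kappa = exp(fit$par[2L]),
                 lnL = -fit$value, tree = ft, branch_lengths = bl,
                 freqs = freqs, convergence = fit$convergence,
                 model = "M0"),
            class = "codon_fit")
}

#' Fit the free-ratio codon model by maximum likelihood
#'
#' One omega per branch; kappa and branch lengths shared structure as in
#' [fit_one_ratio]. The one-ratio fit supplies starting values.
#'
#' @inheritParams fit_one_ratio
#' @return A `codon_fit` with `per_branch_omega` (one per edge, in
#'   `tree$edge` order) and `model = "free"`.
#' @export
fit_free_ratio <- function(aln, tree, freqs = c("F3x4", "uniform"),
                           control = list()) {
  freqs <- match.arg(freqs)
  maxit <- if (is.null(control$maxit)) 300L else control$maxit
  m0 <- fit_one_ratio(aln, tree, freqs, control)
  alnd <- .degap_codon_aln(aln)
  pi <- codon_frequencies(alnd, freqs)
  pat <- .site_patterns(alnd)
  get_dec <- .make_dec_cache(pi)
  ne <- nrow(tree$edge)
  lb <- c(log(1e-2), rep(log(1e-4), ne), rep(log(1e-6), ne))
  ub <- c(log(50), rep(log(10), ne), rep(log(20), ne))
  negll <- function(par) {
    kappa <- exp(par[1L])
    om <- exp(par[1L + seq_len(ne)])
    bl <- exp(par[1L + ne + seq_len(ne)])
    pmats <- vector("list", ne)
    for (e in seq_len(ne))
      pmats[[e]] <- .codon_pmat(get_dec(om[e], kappa), bl[e])
    ll <- .prune_loglik(tree, pat, pmats, pi)
    if (!is.finite(ll)) 1e10 else -ll
  }
  par0 <- c(log(m0$kappa), rep(log(max(m0$omega, 1e-3)), ne),
            log(pmax(m0$branch_lengths, 1e-5)))
  fit <- stats::optim(par0, negll, method = "L-BFGS-B",
                      lower = lb, upper = ub,
                      control = list(maxit = maxit, factr = 1e8))
  bl <- exp(fit$par[1L + ne + seq_len(ne)])
  ft <- tree; ft$edge.length <- bl
  lnL <- -fit$value
  # nested models: never report a free-ratio likelihood below the M0 one
  if (lnL < m0$lnL) {
    lnL <- m0$lnL
    ft <- m0$tree; bl <- m0$branch_lengths
    om <- rep(m0$omega, ne); kap <- m0$kappa
  } else {
    om <- exp(fit$par[1L + seq_len(ne)]); kap <- exp(fit$par[1L])
  }
  structure(list(omega = stats::median(om), kappa = kap, lnL = lnL,
                 tree = ft, branch_lengths = bl, per_branch_omega = om,
                 freqs = freqs, convergence = fit$convergence,
                 model = "free"),
            class = "codon_fit")
}

#' @export
print.codon_fit <- function(x, ...) {
  cat(sprintf("codon model %s: lnL = %.4f, kappa = %.3f, omega = %.4f\n",
              x$model, x$lnL, x$kappa, x$omega))
  invisible(x)
}

#' Likelihood-ratio test between nested codon models
#'
#' @param lnL0 log-likelihood of the null (restricted) model.
#' @param lnL1 log-likelihood of the alternative model.
#' @param df degrees of freedom (parameter-count difference, >= 1).
#' @param tol tolerance for lnL1 slightly below lnL0 (numerical noise).
#' @return A list `stat` (2 * delta lnL, clamped at 0), `df`, `p`
#'   (chi-square upper tail).
#' @export
lrt <- function(lnL0, lnL1, df, tol = 1e-6) {
  if (df < 1) stop("df must be >= 1")
  if (lnL1 < lnL0 - tol - 1e-8 * abs(lnL0))
    stop("alternative log-likelihood below null beyond tolerance")
  stat <- max(2 * (lnL1 - lnL0), 0)
  list(stat = stat, df = as.integer(df),
       p = stats::pchisq(stat, df = df, lower.tail = FALSE))
}

#' Nei-Gojobori (1986) pairwise dN/dS
#'
#' Counts synonymous and nonsynonymous sites (averaged over the two
#' sequences) and differences (averaged over all minimal mutational
#' pathways between differing codons; pathways through stop codons are
#' excluded when any stop-free pathway exists), then applies the
#' Jukes-Cantor correction. Codon columns with a gap in either sequence
#' are removed first.
#'
#' @param codons_a,codons_b equal-length in-frame nucleotide strings.
#' @return List with `S`, `N` (site counts), `Sd`, `Nd` (differences),
#'   `pS`, `pN`, `dS`, `dN` and `omega` (`NA` when `dS` is 0 or either
#'   correction is undefined).
#' @export
ng86_pair <- function(codons_a, codons_b) {
  a <- toupper(codons_a); b <- toupper(codons_b)
  if (nchar(a) != nchar(b)) stop("sequences differ in length")
  if (nchar(a) %% 3L != 0L) stop("length not divisible by 3")
  tb <- .codon_tables()
  ca <- .codons_of(a); cb <- .codons_of(b)
  keep <- !grepl("-", ca, fixed = TRUE) & !grepl("-", cb, fixed = TRUE)
  ca <- ca[keep]; cb <- cb[keep]
  if (any(!ca %in% tb$CODONS) || any(!cb %in% tb$CODONS))
    stop("stop codon or non-ACGT codon in input")
  S <- (sum(.ng86_sites(ca)) + sum(.ng86_sites(cb))) / 2
  N <- 3 * length(ca) - S
  dd <- mapply(.ng86_diffs, ca, cb)
  Sd <- sum(unlist(dd["sd", ])); Nd <- sum(unlist(dd["nd", ]))
  pS <- if (S > 0) Sd / S else 0
  pN <- if (N > 0) Nd / N else 0
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  dS <- jc(pS); dN <- jc(pN)
  omega <- if (is.na(dS) || is.na(dN) || dS <= 0) NA_real_ else dN / dS
  list(S = S, N = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
       dS = dS, dN = dN, omega = omega)
}

# synonymous site count per codon: at each position, fraction of the three
# single-nucleotide changes that are synonymous (changes to stops count as
# nonsynonymous)
.ng86_sites <- function(codons) {
  tb <- .codon_tables()
  gc64 <- Biostrings::GENETIC_CODE
  nts <- c("A", "C", "G", "T")
  vapply(codons, function(cod) {
    ch <- strsplit(cod, "")[[1L]]
    s <- 0
    for (p in 1:3) for (n in setdiff(nts, ch[p])) {
      alt <- ch; alt[p] <- n
      altc <- paste(alt, collapse = "")
      if (gc64[[altc]] != "*" && gc64[[altc]] == gc64[[cod]])
        s <- s + 1 / 3
    }
    s
  }, numeric(1))
}

# expected syn/nonsyn differences between two codons, averaged over minimal
# mutational pathways (stop-free pathways preferred)
.ng86_diffs <- function(codon_a, codon_b) {
  if (codon_a == codon_b) return(c(sd = 0, nd = 0))
  gc64 <- Biostrings::GENETIC_CODE
  da <- strsplit(codon_a, "")[[1L]]; db <- strsplit(codon_b, "")[[1L]]
  pos <- which(da != db)
  perms <- .permutations(pos)
  paths <- list()
  for (ord in perms) {
    cur <- da; sd <- 0; nd <- 0; blocked <- FALSE
    for (p in ord) {
      nxt <- cur; nxt[p] <- db[p]
      c1 <- paste(cur, collapse = ""); c2 <- paste(nxt, collapse = "")
      if (gc64[[c2]] == "*") { blocked <- TRUE; break }
      if (gc64[[c1]] == gc64[[c2]]) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    if (!blocked) paths[[length(paths) + 1L]] <- c(sd = sd, nd = nd)
  }
  if (length(paths) == 0L) {
    # all pathways pass through a stop; fall back to averaging them all,
    # classifying the stop-creating step as nonsynonymous
    for (ord in perms) {
      cur <- da; sd <- 0; nd <- 0
      for (p in ord) {
        nxt <- cur; nxt[p] <- db[p]
        c1 <- paste(cur, collapse = ""); c2 <- paste(nxt, collapse = "")
        if (gc64[[c2]] != "*" && gc64[[c1]] == gc64[[c2]]) sd <- sd + 1
        else nd <- nd + 1
        cur <- nxt
      }
      paths[[length(paths) + 1L]] <- c(sd = sd, nd = nd)
    }
  }
  m <- do.call(rbind, paths)
  c(sd = mean(m[, "sd"]), nd = mean(m[, "nd"]))
}

.permutations <- function(x) {
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (i in seq_along(x))
    for (rest in .permutations(x[-i]))
      out[[length(out) + 1L]] <- c(x[i], rest)
  out
}
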