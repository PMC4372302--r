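# Family-level expression: RPKM, colored/non-colored group-specific
# families, PIC trait filtering, and NB exact-test differential expression.

#' Transcript RPKM
#'
#' Reads per kilobase of transcript per million mapped reads:
#' `reads / ((length/1000) * (library/1e6))`.
#'
#' @param reads read count (>= 0), vectorized.
#' @param length transcript length in bp (> 0).
#' @param library mapped reads in the library (> 0).
#' @return RPKM value(s).
#' @export
transcript_rpkm <- function(reads, length, library) {
  if (any(length <= 0)) stop("transcript length must be positive")
  if (any(library <= 0)) stop("library size must be positive")
  reads / ((length / 1e3) * (library / 1e6))
}

#' Family-level RPKM matrix
#'
#' The family RPKM in a species pools all members: total member reads per
#' kilobase of total member length per million mapped reads. Families with
#' no members in a species get 0.
#'
#' @param families data.frame with columns `family`, `species`,
#'   `transcript`.
#' @param expr data.frame with columns `transcript`, `species`, `length`,
#'   `reads`.
#' @param library_sizes named mapped-read totals per species.
#' @return Numeric matrix families x species.
#' @export
family_rpkm <- function(families, expr, library_sizes) {
  species <- names(library_sizes)
  fams <- sort(unique(families$family))
  families <- families[families$species %in% species, , drop = FALSE]
  idx <- match(families$transcript, expr$transcript)
  if (anyNA(idx))
    stop("transcript not in expression table: ",
         families$transcript[is.na(idx)][1L])
  df <- data.frame(family = families$family,
                   species = expr$species[idx],
                   length = expr$length[idx],
                   reads = expr$reads[idx])
  out <- matrix(0, length(fams), length(species),
                dimnames = list(fams, species))
  agg_r <- tapply(df$reads, list(df$family, df$species), sum)
  agg_l <- tapply(df$length, list(df$family, df$species), sum)
  for (sp in intersect(colnames(agg_r), species)) {
    v <- agg_r[, sp] / ((agg_l[, sp] / 1e3) * (library_sizes[[sp]] / 1e6))
    v[is.na(v)] <- 0
    out[rownames(agg_r), sp] <- v
  }
  out
}

#' Family-level read-count matrix
#'
#' Sums member transcript reads per family and species.
#'
#' @inheritParams family_rpkm
#' @param species species (column) order; default the species present.
#' @return Integer matrix families x species.
#' @export
family_counts <- function(families, expr, species = NULL) {
  if (is.null(species)) species <- sort(unique(expr$species))
  fams <- sort(unique(families$family))
  families <- families[families$species %in% species, , drop = FALSE]
  idx <- match(families$transcript, expr$transcript)
  if (anyNA(idx)) stop("transcript not in expression table")
  out <- matrix(0, length(fams), length(species),
                dimnames = list(fams, species))
  agg <- tapply(expr$reads[idx], list(families$family, expr$species[idx]),
                sum)
  cols <- intersect(colnames(agg), species)
  a <- agg[, cols, drop = FALSE]
  a[is.na(a)] <- 0
  out[rownames(agg), cols] <- a
  out
}

#' Group-specific gene families
#'
#' A family is specific to a group when its RPKM is at least
#' `presence_min` in every species of that group and below `presence_min`
#' in every species of the other group.
#'
#' @param famexpr family x species RPKM matrix.
#' @param groups named species -> group vector with two groups.
#' @param presence_min detection floor in RPKM units (default 1).
#' @return Named list of family-id vectors, one per group.
#' @export
group_specific_families <- function(famexpr, groups, presence_min = 1) {
  gs <- unique(groups)
  if (length(gs) != 2L) stop("exactly two groups required")
  sp <- names(groups)
  if (!all(sp %in% colnames(famexpr)))
    stop("species missing from RPKM matrix: ",
         setdiff(sp, colnames(famexpr))[1L])
  out <- list()
  for (g in gs) {
    own <- sp[groups == g]; other <- sp[groups != g]
    hit <- rowSums(famexpr[, own, drop = FALSE] >= presence_min) ==
      length(own) &
      rowSums(famexpr[, other, drop = FALSE] < presence_min) ==
      length(other)
    out[[g]] <- rownames(famexpr)[hit]
  }
  out
}

#' Phylogenetic trait filter for candidate families
#'
#' For each family, the correlation between its per-species RPKM profile
#' and a binary trait (e.g. stable cocoon coloration, 1/0) is computed
#' through phylogenetically independent contrasts; families whose
#' correlation is not significant at `alpha` (including zero-variance
#' profiles) are excluded.
#'
#' @param famexpr family x species RPKM matrix (columns must cover the
#'   tree's leaves).
#' @param tree rooted binary [ape::phylo] over the species.
#' @param trait named 0/1 vector per species.
#' @param alpha significance level (default 0.05).
#' @param alternative sidedness passed to [pic_correlation()].
#' @return List with `retained`, `excluded` (family ids) and `table`
#'   (family, r, p, retained flag).
#' @export
trait_filter <- function(famexpr, tree, trait, alpha = 0.05,
                         alternative = "two.sided") {
  sp <- tree$tip.label
  if (!all(sp %in% colnames(famexpr)))
    stop("RPKM matrix lacks species: ", setdiff(sp, colnames(famexpr))[1L])
  res <- lapply(rownames(famexpr), function(f) {
    x <- stats::setNames(famexpr[f, sp], sp)
    pc <- pic_correlation(tree, x, trait, alternative = alternative)
    data.frame(family = f, r = pc$r, p = pc$p,
               zero_variance = pc$zero_variance)
  })
  tab <- do.call(rbind, res)
  tab$retained <- tab$p < alpha & !tab$zero_variance
  list(retained = tab$family[tab$retained],
       excluded = tab$family[!tab$retained],
       table = tab)
}

#' Negative-binomial exact test for two groups of replicates
#'
#' Exact two-sided test on the group sums conditioned on the grand total,
#' assuming library-size-normalized counts: group sums are negative
#' binomial with common mean per replicate and dispersion `phi`
#' (`phi = 0` reduces to the binomial-conditioned Poisson test). The
#' two-sided p-value doubles the smaller conditional tail (capped at 1).
#'
#' @param counts_a,counts_b normalized pseudo-counts per replicate.
#' @param dispersion common dispersion phi (>= 0).
#' @return List with `p` and `zero_total` flag (p = 1 when all counts are
#'   zero).
#' @export
nb_exact_test <- function(counts_a, counts_b, dispersion = 0) {
  stopifnot(dispersion >= 0)
  n1 <- length(counts_a); n2 <- length(counts_b)
  a <- round(sum(counts_a)); b <- round(sum(counts_b))
  t <- a + b
  if (t == 0) return(list(p = 1, zero_total = TRUE))
  m <- t / (n1 + n2)
  x <- 0:t
  logf <- if (dispersion == 0) {
    stats::dpois(x, n1 * m, log = TRUE) +
      stats::dpois(t - x, n2 * m, log = TRUE)
  } else {
    stats::dnbinom(x, mu = n1 * m, size = n1 / dispersion, log = TRUE) +
      stats::dnbinom(t - x, mu = n2 * m, size = n2 / dispersion, log = TRUE)
  }
  w <- exp(logf - max(logf))
  pr <- w / sum(w)
  lower <- sum(pr[x <= a]); upper <- sum(pr[x >= a])
  list(p = min(2 * min(lower, upper), 1), zero_total = FALSE)
}

#' Common dispersion by conditional maximum likelihood
#'
#' Maximizes the negative-binomial conditional log-likelihood (counts
#' within each group conditioned on the group total, summed over families
#' and groups) over phi, using a coarse logarithmic grid refined by
#' golden-section search. Assumes library sizes have been equalized.
#'
#' @param mat family x species count matrix.
#' @param groups named species -> group vector (>= 2 species per group).
#' @param phi_max upper bound of the search interval.
#' @return The dispersion estimate (0 when the data are degenerate).
#' @export
estimate_common_dispersion <- function(mat, groups, phi_max = 5) {
  sp <- names(groups)
  if (!all(sp %in% colnames(mat))) stop("count matrix lacks group species")
  gs <- unique(groups)
  if (any(table(groups) < 2L)) stop("need >= 2 species per group")
  if (all(mat == mat[1L])) return(0)
  ymats <- lapply(gs, function(g) mat[, sp[groups == g], drop = FALSE])
  condll <- function(phi) {
    r <- 1 / phi
    s <- 0
    for (y in ymats) {
      n <- ncol(y); z <- rowSums(y)
      s <- s + sum(lgamma(y + r)) - length(y) * lgamma(r) +
        sum(lgamma(n * r) - lgamma(z + n * r))
    }
    s
  }
  grid <- exp(seq(log(1e-4), log(phi_max), length.out = 25))
  ll <- vapply(grid, condll, numeric(1))
  k <- which.max(ll)
  if (k == 1L && condll(1e-6) >= ll[1L]) return(0)
  lo <- grid[max(k - 1L, 1L)]; hi <- grid[min(k + 1L, length(grid))]
  gr <- (sqrt(5) - 1) / 2
  x1 <- hi - gr * (hi - lo); x2 <- lo + gr * (hi - lo)
  f1 <- condll(x1); f2 <- condll(x2)
  while (hi - lo > 1e-5) {
    if (f1 < f2) {
      lo <- x1; x1 <- x2; f1 <- f2
      x2 <- lo + gr * (hi - lo); f2 <- condll(x2)
    } else {
      hi <- x2; x2 <- x1; f2 <- f1
      x1 <- hi - gr * (hi - lo); f1 <- condll(x1)
    }
  }
  (lo + hi) / 2
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values with monotonicity enforcement, returned in
#' the input order (wraps [stats::p.adjust]).
#'
#' @param pvals numeric vector of p-values in [0, 1].
#' @return Adjusted p-values, same order.
#' @export
bh_fdr <- function(pvals) {
  stopifnot(all(pvals >= 0 & pvals <= 1, na.rm = TRUE))
  stats::p.adjust(pvals, method = "BH")
}

#' Differential gene families between two groups
#'
#' Family counts are scaled to the geometric mean of the library sizes,
#' the common dispersion is estimated by conditional maximum likelihood,
#' each family is tested with the NB exact test (species as replicates
#' within groups), and BH FDR control is applied.
#'
#' @param families,expr,library_sizes as in [family_rpkm()].
#' @param groups named species -> group vector with groups `"colored"`
#'   and `"noncolored"`.
#' @param alpha_fdr FDR threshold (default 0.05).
#' @param dispersion optional fixed dispersion; estimated when `NULL`.
#' @return data.frame `family`, `logFC` (log2 colored/noncolored),
#'   `p`, `fdr`, `significant`; attribute `"dispersion"` carries the
#'   dispersion used.
#' @export
de_families <- function(families, expr, library_sizes, groups,
                        alpha_fdr = 0.05, dispersion = NULL) {
  sp <- names(groups)
  cnt <- family_counts(families, expr, species = sp)
  geo <- exp(mean(log(library_sizes[sp])))
  pseudo <- round(sweep(cnt, 2L, geo / unlist(library_sizes[sp]), `*`))
  if (is.null(dispersion))
    dispersion <- estimate_common_dispersion(pseudo, groups)
  spA <- sp[groups == "colored"]; spB <- sp[groups == "noncolored"]
  ps <- vapply(rownames(pseudo), function(f)
    nb_exact_test(pseudo[f, spA], pseudo[f, spB], dispersion)$p,
    numeric(1))
  mA <- rowMeans(pseudo[, spA, drop = FALSE])
  mB <- rowMeans(pseudo[, spB, drop = FALSE])
  lfc <- log2((mA + 0.125) / (mB + 0.125))
  fdr <- bh_fdr(ps)
  out <- data.frame(family = rownames(pseudo), logFC = lfc, p = ps,
                    fdr = fdr, significant = fdr < alpha_fdr,
                    row.names = NULL)
  attr(out, "dispersion") <- dispersion
  out
}
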