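# Chi-square GO-term enrichment of a target gene set against a disjoint
# background set.

#' Chi-square GO-term enrichment
#'
#' For every term annotated in either set, a 2x2 Pearson chi-square test
#' (no continuity correction) of (annotated, not annotated) x (target,
#' background). The target and background sets must be disjoint. Terms
#' with any expected cell count below 5 are flagged. Rows are sorted by
#' p-value.
#'
#' @param target,background disjoint gene-id sets.
#' @param annotations data.frame with columns `gene`, `term` and
#'   optionally `class`.
#' @param adjust also compute BH-adjusted p-values (`fdr` column).
#' @return data.frame with columns `term`, `count_target`, `size_target`,
#'   `count_background`, `size_background`, `chi2`, `p`, `low_expected`
#'   (and `class`, `fdr` when available).
#' @export
chisq_enrichment <- function(target, background, annotations,
                             adjust = FALSE) {
  target <- unique(as.character(target))
  background <- unique(as.character(background))
  if (length(target) == 0L || length(background) == 0L)
    stop("target and background must be non-empty")
  if (length(intersect(target, background)))
    stop("target and background sets must be disjoint")
  ann <- annotations[annotations$gene %in% c(target, background), ,
                     drop = FALSE]
  terms <- sort(unique(ann$term))
  nT <- length(target); nB <- length(background)
  rows <- lapply(terms, function(tm) {
    g <- unique(ann$gene[ann$term == tm])
    a <- sum(target %in% g); c_ <- sum(background %in% g)
    tab <- matrix(c(a, nT - a, c_, nB - c_), nrow = 2L)
    exp_cnt <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
      chi2 <- 0; p <- 1
    } else {
      ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
      chi2 <- unname(ct$statistic); p <- unname(ct$p.value)
    }
    data.frame(term = tm, count_target = a, size_target = nT,
               count_background = c_, size_background = nB,
               chi2 = chi2, p = p,
               low_expected = any(exp_cnt < 5),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(term = character(0), count_target = integer(0),
                      size_target = integer(0),
                      count_background = integer(0),
                      size_background = integer(0), chi2 = numeric(0),
                      p = numeric(0), low_expected = logical(0))
  }
  if (!is.null(annotations$class) && nrow(out)) {
    cls <- annotations$class[match(out$term, annotations$term)]
    out$class <- cls
  }
  out <- out[order(out$p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  if (adjust && nrow(out)) out$fdr <- bh_fdr(out$p)
  out
}

#' Filtered, grouped enrichment report
#'
#' Retains rows with `p <= alpha` (or `fdr <= alpha` when present and
#' `use_fdr`), sorted by p within GO class when class metadata are
#' available.
#'
#' @param rows output of [chisq_enrichment()].
#' @param alpha retention level (1 keeps everything).
#' @param use_fdr filter on the `fdr` column when present.
#' @return The filtered data.frame.
#' @export
enrichment_report <- function(rows, alpha = 0.05, use_fdr = FALSE) {
  if (nrow(rows) == 0L) return(rows)
  crit <- if (use_fdr && !is.null(rows$fdr)) rows$fdr else rows$p
  out <- rows[crit <= alpha, , drop = FALSE]
  if (!is.null(out$class))
    out <- out[order(out$class, out$p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}
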