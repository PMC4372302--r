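# Tree utilities: pairwise distances, neighbor joining, independent
# contrasts, and gene-tree/species-tree reconciliation.

#' Pairwise distance matrix from an aligned DNA sequence set
#'
#' Computes p-distances or Tajima-Nei (1984) distances. Gap columns are
#' removed per pair (complete pairwise deletion).
#'
#' @param seqs an aligned [seq_set] with `alphabet = "dna"`.
#' @param model `"p"` or `"tajima_nei"`.
#' @return A symmetric numeric matrix with zero diagonal, dimnames set to
#'   the sequence identifiers.
#' @export
distance_matrix <- function(seqs, model = c("p", "tajima_nei")) {
  model <- match.arg(model)
  stopifnot(inherits(seqs, "seq_set"))
  if (length(unique(nchar(seqs$seq))) != 1L)
    stop("sequences are not aligned (unequal lengths)")
  n <- length(seqs$id)
  chars <- lapply(seqs$seq, function(s) strsplit(s, "")[[1L]])
  D <- matrix(0, n, n, dimnames = list(seqs$id, seqs$id))
  nts <- c("A", "C", "G", "T")
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    a <- chars[[i]]; b <- chars[[j]]
    keep <- a %in% nts & b %in% nts
    a <- a[keep]; b <- b[keep]
    if (length(a) == 0L) stop("no comparable sites for pair ",
                              seqs$id[i], " / ", seqs$id[j])
    p <- mean(a != b)
    if (model == "p") {
      d <- p
    } else if (p == 0) {
      d <- 0
    } else {
      g <- (table(factor(a, levels = nts)) +
              table(factor(b, levels = nts))) / (2 * length(a))
      g <- as.numeric(g)
      # unordered pair frequencies among differing sites
      h <- 0
      for (u in 1:3) for (v in (u + 1):4) {
        x_uv <- mean((a == nts[u] & b == nts[v]) |
                       (a == nts[v] & b == nts[u]))
        if (g[u] > 0 && g[v] > 0) h <- h + x_uv^2 / (2 * g[u] * g[v])
      }
      bcoef <- 0.5 * (1 - sum(g^2) + p^2 / h)
      if (p >= bcoef)
        stop("saturated pair ", seqs$id[i], " / ", seqs$id[j],
             ": Tajima-Nei distance undefined")
      d <- -bcoef * log(1 - p / bcoef)
    }
    D[i, j] <- D[j, i] <- d
  }
  D
}

#' Neighbor-joining tree
#'
#' Canonical neighbor joining on a symmetric distance matrix (Q-matrix
#' criterion). Ties are broken deterministically by the lexicographic order
#' of the smallest taxon label in each cluster. Negative branch lengths are
#' clamped to zero with the deficit moved to the sibling branch so that the
#' joined path length is preserved.
#'
#' @param d symmetric numeric matrix with dimnames (>= 3 taxa).
#' @return An unrooted [ape::phylo] tree with branch lengths.
#' @export
nj_tree <- function(d) {
  if (!is.matrix(d) || is.null(rownames(d))) stop("need a labelled matrix")
  if (!isSymmetric(unname(d), tol = 1e-8)) stop("distance matrix not symmetric")
  n <- nrow(d)
  if (n < 3L) stop("need at least 3 taxa")
  labs <- rownames(d)
  # each active cluster: newick fragment + smallest member label
  frag <- labs
  minlab <- labs
  D <- d
  while (nrow(D) > 3L) {
    m <- nrow(D)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin < 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    key <- apply(cand, 1L, function(ij) {
      p <- sort(c(minlab[ij[1L]], minlab[ij[2L]]))
      paste(p, collapse = "\r")
    })
    pick <- cand[order(key)[1L], ]
    i <- pick[1L]; j <- pick[2L]
    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- D[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    li <- max(li, 0); lj <- max(lj, 0)
    newfrag <- sprintf("(%s:%.10g,%s:%.10g)", frag[i], li, frag[j], lj)
    newmin <- min(minlab[i], minlab[j])
    dk <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dk[keep]),
                c(dk[keep], 0))
    frag <- c(frag[keep], newfrag)
    minlab <- c(minlab[keep], newmin)
    rownames(D2) <- colnames(D2) <- seq_len(m - 1L)
    D <- D2
  }
  la <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  lb <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  lc <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  la <- max(la, 0); lb <- max(lb, 0); lc <- max(lc, 0)
  txt <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
                 frag[1L], la, frag[2L], lb, frag[3L], lc)
  ape::read.tree(text = txt)
}

#' Resolve polytomies deterministically
#'
#' Expands multifurcations into bifurcations with zero-length branches,
#' grouping children in the order of their smallest descendant tip label.
#'
#' @param tree an [ape::phylo].
#' @return A binary [ape::phylo].
#' @export
resolve_polytomies <- function(tree) {
  tree <- ape::rotateConstr(tree, sort(tree$tip.label))
  ape::multi2di(tree, random = FALSE)
}

#' Phylogenetically independent contrasts
#'
#' Felsenstein's recursion on a rooted, fully bifurcating tree with branch
#' lengths: returns the standardized contrast at every internal node
#' together with the inferred node values and gap-adjusted branch lengths.
#'
#' @param tree rooted binary [ape::phylo] with branch lengths.
#' @param trait named numeric vector over all leaf labels.
#' @return List with `contrasts` (length leaves - 1, named by internal node
#'   number), `node_values`, `adjusted_lengths`.
#' @export
pic_contrasts <- function(tree, trait) {
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  if (!ape::is.binary(tree))
    stop("tree has polytomies; resolve them first (see resolve_polytomies)")
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  if (!all(tree$tip.label %in% names(trait)))
    stop("trait values missing for some leaves")
  nt <- length(tree$tip.label)
  nn <- nt + tree$Nnode
  x <- numeric(nn)
  v <- numeric(nn)                 # extra variance accumulated at each node
  x[seq_len(nt)] <- trait[tree$tip.label]
  contrasts <- stats::setNames(numeric(tree$Nnode),
                               seq(nt + 1L, nn))
  tre <- ape::reorder.phylo(tree, "postorder")
  elen <- tre$edge.length
  # process internal nodes in postorder (children come in edge pairs)
  for (e in seq(1L, nrow(tre$edge), by = 2L)) {
    node <- tre$edge[e, 1L]
    c1 <- tre$edge[e, 2L]; c2 <- tre$edge[e + 1L, 2L]
    b1 <- elen[e] + v[c1]; b2 <- elen[e + 1L] + v[c2]
    if (b1 + b2 <= 0)
      stop("zero total branch length at node ", node,
           ": contrast undefined")
    contrasts[as.character(node)] <- (x[c1] - x[c2]) / sqrt(b1 + b2)
    x[node] <- (x[c1] / b1 + x[c2] / b2) / (1 / b1 + 1 / b2)
    v[node] <- b1 * b2 / (b1 + b2)
  }
  list(contrasts = contrasts,
       node_values = x[seq(nt + 1L, nn)],
       adjusted_lengths = v)
}

#' Correlation of two traits through phylogenetically independent contrasts
#'
#' Contrasts are computed for both traits on the same tree; the correlation
#' is taken through the origin and tested against the t distribution with
#' (number of contrasts - 1) degrees of freedom.
#'
#' @inheritParams pic_contrasts
#' @param trait_x,trait_y named numeric vectors over the leaves.
#' @param alternative `"two.sided"`, `"greater"` or `"less"`.
#' @return List with `r`, `p`, `df`, `n_contrasts`, `zero_variance` flag.
#' @export
pic_correlation <- function(tree, trait_x, trait_y,
                            alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  cx <- pic_contrasts(tree, trait_x)$contrasts
  cy <- pic_contrasts(tree, trait_y)$contrasts
  # contrasts of a constant trait are zero up to rounding; use a
  # scale-relative floor
  tolx <- 1e-10 * (max(abs(trait_x)) + 1)
  toly <- 1e-10 * (max(abs(trait_y)) + 1)
  if (all(abs(cx) < tolx)) cx[] <- 0
  if (all(abs(cy) < toly)) cy[] <- 0
  sxx <- sum(cx^2); syy <- sum(cy^2)
  if (sxx <= 0 || syy <= 0)
    return(list(r = 0, p = 1, df = length(cx) - 1L,
                n_contrasts = length(cx), zero_variance = TRUE))
  r <- sum(cx * cy) / sqrt(sxx * syy)
  df <- length(cx) - 1L
  if (df < 1L) return(list(r = r, p = 1, df = df,
                           n_contrasts = length(cx), zero_variance = FALSE))
  r2 <- min(r^2, 1 - 1e-15)
  tstat <- r * sqrt(df) / sqrt(1 - r2)
  p <- switch(alternative,
              two.sided = 2 * stats::pt(-abs(tstat), df),
              greater = stats::pt(tstat, df, lower.tail = FALSE),
              less = stats::pt(tstat, df))
  list(r = r, p = min(p, 1), df = df, n_contrasts = length(cx),
       zero_variance = FALSE)
}

# species-node sets of descendant tip labels, by node number
.desc_tip_sets <- function(tree) {
  nt <- length(tree$tip.label)
  nn <- nt + tree$Nnode
  sets <- vector("list", nn)
  for (k in seq_len(nt)) sets[[k]] <- tree$tip.label[k]
  tre <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(tre$edge))) {
    p <- tre$edge[e, 1L]; ch <- tre$edge[e, 2L]
    sets[[p]] <- union(sets[[p]], sets[[ch]])
  }
  sets
}

#' Gene-tree / species-tree reconciliation (LCA mapping)
#'
#' Maps every gene-tree node to the most recent common ancestor (in the
#' species tree) of the species its leaves belong to. An internal gene node
#' is a duplication when it maps to the same species node as one of its
#' children. Losses are counted along each gene-tree edge as the number of
#' species-tree edges skipped, plus one extra when the parent is a
#' duplication; each lost lineage is attributed to the species node rooting
#' the lost subtree.
#'
#' @param gene_tree rooted [ape::phylo]; leaves are gene copies.
#' @param species_tree rooted [ape::phylo]; leaves are species.
#' @param leaf_map named character vector gene leaf -> species label. If
#'   `NULL`, the species is taken as the gene label prefix before the first
#'   `"|"`.
#' @return List with `mapping` (gene node -> species node number),
#'   `duplications`, `losses` (totals), `events` data.frame with one row
#'   per species node (`node`, `label`, `duplications`, `losses`).
#' @export
reconcile <- function(gene_tree, species_tree, leaf_map = NULL) {
  stopifnot(inherits(gene_tree, "phylo"), inherits(species_tree, "phylo"))
  if (!ape::is.rooted(gene_tree) || !ape::is.rooted(species_tree))
    stop("both trees must be rooted")
  if (is.null(leaf_map)) {
    leaf_map <- stats::setNames(sub("\\|.*$", "", gene_tree$tip.label),
                                gene_tree$tip.label)
  }
  if (!all(gene_tree$tip.label %in% names(leaf_map)))
    stop("unmapped gene leaf: ",
         setdiff(gene_tree$tip.label, names(leaf_map))[1L])
  sp_of <- leaf_map[gene_tree$tip.label]
  if (!all(sp_of %in% species_tree$tip.label))
    stop("leaf mapped to unknown species: ",
         setdiff(sp_of, species_tree$tip.label)[1L])

  snt <- length(species_tree$tip.label)
  snn <- snt + species_tree$Nnode
  sparent <- integer(snn)
  sparent[species_tree$edge[, 2L]] <- species_tree$edge[, 1L]
  sroot <- snt + 1L
  sdepth <- integer(snn); sdepth[sroot] <- 0L
  pre <- ape::reorder.phylo(species_tree, "cladewise")$edge
  for (e in seq_len(nrow(pre)))
    sdepth[pre[e, 2L]] <- sdepth[pre[e, 1L]] + 1L
  schildren <- split(species_tree$edge[, 2L], species_tree$edge[, 1L])
  sets <- .desc_tip_sets(species_tree)

  # LCA of two species nodes by depth walking
  slca <- function(a, b) {
    while (a != b) {
      if (sdepth[a] < sdepth[b]) b <- sparent[b] else a <- sparent[a]
    }
    a
  }
  gnt <- length(gene_tree$tip.label)
  gnn <- gnt + gene_tree$Nnode
  M <- integer(gnn)
  for (k in seq_len(gnt))
    M[k] <- match(sp_of[k], species_tree$tip.label)
  gtre <- ape::reorder.phylo(gene_tree, "postorder")
  gchildren <- split(gtre$edge[, 2L], gtre$edge[, 1L])
  for (e in seq_len(nrow(gtre$edge))) {
    p <- gtre$edge[e, 1L]; ch <- gtre$edge[e, 2L]
    M[p] <- if (M[p] == 0L) M[ch] else slca(M[p], M[ch])
  }
  is_dup <- rep(FALSE, gnn)
  for (p in as.integer(names(gchildren)))
    is_dup[p] <- any(M[gchildren[[as.character(p)]]] == M[p])

  dup_at <- integer(snn); loss_at <- integer(snn)
  for (p in which(is_dup)) dup_at[M[p]] <- dup_at[M[p]] + 1L
  # losses along each gene edge
  for (e in seq_len(nrow(gene_tree$edge))) {
    u <- gene_tree$edge[e, 1L]; v <- gene_tree$edge[e, 2L]
    top <- M[u]; bot <- M[v]
    # path species nodes from bot up to (excluding) top
    path <- bot
    while (path[length(path)] != top) path <- c(path, sparent[path[length(path)]])
    # nodes whose off-path child lineage is lost: strictly between top and
    # bot, plus top itself when u is a duplication
    mids <- if (length(path) >= 3L) path[seq(2L, length(path) - 1L)] else integer(0)
    anchors <- c(mids, if (is_dup[u] && top != bot) top)
    for (a in anchors) {
      onpath <- path[match(a, path) - 1L]
      lost <- setdiff(schildren[[as.character(a)]], onpath)
      for (l in lost) loss_at[l] <- loss_at[l] + 1L
    }
    if (is_dup[u] && top == bot) next
  }
  labels <- c(species_tree$tip.label,
              if (!is.null(species_tree$node.label) &&
                  length(species_tree$node.label) == species_tree$Nnode)
                species_tree$node.label
              else paste0("node", seq(snt + 1L, snn)))
  list(mapping = M,
       duplications = sum(dup_at), losses = sum(loss_at),
       events = data.frame(node = seq_len(snn), label = labels,
                           duplications = dup_at, losses = loss_at))
}
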