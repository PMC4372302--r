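# Synthetic-data generators with planted ground truth. Every generator is
# a pure function of (parameters, seed); the caller's RNG state is left
# untouched.

.with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

#' The seven-taxon silkmoth species tree
#'
#' Fixed rooted topology with Bombyx mori as outgroup sister to the
#' Saturniidae clade (((((A.per, A.yam), A.ass), Ac.sel), R.new), S.cyn):
#' within Antheraea, A. pernyi and A. yamamai are siblings, Actias selene
#' is next-closest to Antheraea, and S. cynthia is the deepest Saturniidae
#' split. Internal nodes are labelled N1..N6.
#'
#' @param branch_length branch length assigned to every edge (default 1).
#' @return A rooted binary [ape::phylo] with 7 leaves.
#' @export
make_species_tree <- function(branch_length = 1) {
  txt <- "(B.mor,(((((A.per,A.yam)N6,A.ass)N5,Ac.sel)N4,R.new)N3,S.cyn)N2)N1;"
  tree <- ape::read.tree(text = txt)
  tree$edge.length <- rep(branch_length, nrow(tree$edge))
  tree
}

#' Cocoon-color group labels
#'
#' Colored-cocoon group: A. yamamai, R. newara, A. assama (stable
#' coloration); non-colored group: A. pernyi, Ac. selene, S. cynthia.
#'
#' @return Named character vector species -> `"colored"`/`"noncolored"`.
#' @export
color_groups <- function() {
  c(A.yam = "colored", R.new = "colored", A.ass = "colored",
    A.per = "noncolored", Ac.sel = "noncolored", S.cyn = "noncolored")
}

# Recursive gene-family evolution along the species tree. Subtrees are
# built as nested lists (tips: list(tip=label); internal: list(children=
# list(...), lens=numeric)) and converted to Newick at the end, collapsing
# pass-through nodes by summing branch lengths.
.gf_env_new <- function() new.env(parent = emptyenv())

# lineage present at `node` (after surviving its incoming edge)
.gf_at_node <- function(tree, node, st) {
  nt <- length(tree$tip.label)
  if (node <= nt) {
    sp <- tree$tip.label[node]
    st$counter[[sp]] <- (st$counter[[sp]] %||% 0L) + 1L
    return(list(tip = sprintf("%s|%s|g%d", sp, st$fam, st$counter[[sp]])))
  }
  kids <- tree$edge[tree$edge[, 1L] == node, 2L]
  subs <- list(); lens <- numeric(0)
  for (ch in kids) {
    bl <- tree$edge.length[which(tree$edge[, 1L] == node &
                                   tree$edge[, 2L] == ch)]
    r <- .gf_edge(tree, ch, bl, st)
    if (!is.null(r)) { subs[[length(subs) + 1L]] <- r$sub; lens <- c(lens, r$len) }
  }
  if (length(subs) == 0L) return(NULL)
  if (length(subs) == 1L)
    return(list(pass = TRUE, sub = subs[[1L]], extra = lens[1L]))
  list(children = subs, lens = lens)
}

# lineage traversing the edge ending at `child` (length bl)
.gf_edge <- function(tree, child, bl, st) {
  lab <- st$labels[child]
  if (stats::runif(1) < st$p_loss) {
    st$events[[length(st$events) + 1L]] <-
      data.frame(family = st$fam, node = lab, event = "loss")
    return(NULL)
  }
  ndup <- stats::rpois(1, st$dup_rate)
  if (ndup > 0)
    for (k in seq_len(ndup))
      st$events[[length(st$events) + 1L]] <-
        data.frame(family = st$fam, node = lab, event = "duplication")
  copies <- list()
  for (cp in seq_len(ndup + 1L)) {
    r <- .gf_at_node(tree, child, st)
    if (is.null(r)) next
    if (isTRUE(r$pass)) copies[[length(copies) + 1L]] <-
        list(sub = r$sub, len = bl + r$extra)
    else copies[[length(copies) + 1L]] <- list(sub = r, len = bl)
  }
  if (length(copies) == 0L) return(NULL)
  if (length(copies) == 1L) return(copies[[1L]])
  # duplication node(s) at the top of the edge
  acc <- list(sub = list(children = list(copies[[1L]]$sub, copies[[2L]]$sub),
                         lens = c(copies[[1L]]$len, copies[[2L]]$len)),
              len = 0)
  if (length(copies) > 2L)
    for (k in seq(3L, length(copies)))
      acc <- list(sub = list(children = list(acc$sub, copies[[k]]$sub),
                             lens = c(0, copies[[k]]$len)),
                  len = 0)
  acc
}

.gf_newick <- function(sub, len = NULL) {
  s <- if (!is.null(sub$tip)) sub$tip else
    sprintf("(%s)", paste(mapply(.gf_newick, sub$children,
                                 as.list(sub$lens)), collapse = ","))
  if (is.null(len)) s else sprintf("%s:%g", s, len)
}

.gf_tips <- function(sub) {
  if (!is.null(sub$tip)) return(sub$tip)
  unlist(lapply(sub$children, .gf_tips))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Replay recorded family events to per-species copy counts
#'
#' The number of gene copies entering a node equals the count at its
#' parent minus the losses plus the duplications recorded on the incoming
#' edge; replaying the recorded events down the species tree therefore
#' reproduces each family's species membership.
#'
#' @param tree species tree with node labels.
#' @param events data.frame with columns `node`, `event` for one family.
#' @return Named integer vector of copy counts per species.
#' @export
replay_family_events <- function(tree, events) {
  nt <- length(tree$tip.label)
  labels <- c(tree$tip.label,
              if (!is.null(tree$node.label)) tree$node.label
              else paste0("node", seq_len(tree$Nnode)))
  cnt <- integer(nt + tree$Nnode)
  cnt[nt + 1L] <- 1L
  pre <- ape::reorder.phylo(tree, "cladewise")
  for (e in seq_len(nrow(pre$edge))) {
    p <- pre$edge[e, 1L]; ch <- pre$edge[e, 2L]
    l <- sum(events$node == labels[ch] & events$event == "loss")
    d <- sum(events$node == labels[ch] & events$event == "duplication")
    cnt[ch] <- max(cnt[p] - l + d, 0L)
  }
  stats::setNames(cnt[seq_len(nt)], tree$tip.label)
}

#' Simulate gene families by duplication and loss on a species tree
#'
#' Each family starts as a single gene at the root. Along every edge each
#' surviving lineage is lost with probability `1 - exp(-loss_rate)` and
#' otherwise acquires a Poisson(`dup_rate`) number of duplications placed
#' at the top of the edge. Events are recorded against the child node of
#' the edge (node labels for internal nodes, species names for leaves).
#'
#' @param tree rooted species tree with node labels (see
#'   [make_species_tree()]).
#' @param n_families number of families.
#' @param dup_rate,loss_rate expected events per branch (>= 0).
#' @param seed integer seed.
#' @return List: `families` (data.frame family/species/transcript),
#'   `gene_trees` (named list of [ape::phylo], `NULL` for extinct
#'   families), `truth` (list with `events` data.frame and `extinct`
#'   character vector).
#' @export
simulate_families <- function(tree, n_families, dup_rate = 0.1,
                              loss_rate = 0.1, seed = 1) {
  stopifnot(dup_rate >= 0, loss_rate >= 0)
  nt <- length(tree$tip.label)
  labels <- c(tree$tip.label,
              if (!is.null(tree$node.label)) tree$node.label
              else paste0("node", seq_len(tree$Nnode)))
  p_loss <- 1 - exp(-loss_rate)
  .with_seed(seed, {
    fam_rows <- list(); gene_trees <- list(); ev_rows <- list()
    extinct <- character(0)
    for (f in seq_len(n_families)) {
      fam <- sprintf("F%04d", f)
      st <- .gf_env_new()
      st$fam <- fam; st$labels <- labels; st$p_loss <- p_loss
      st$dup_rate <- dup_rate; st$counter <- list(); st$events <- list()
      r <- .gf_at_node(tree, nt + 1L, st)
      ev_rows <- c(ev_rows, st$events)
      if (is.null(r)) {
        extinct <- c(extinct, fam)
        gene_trees[fam] <- list(NULL)
        next
      }
      sub <- if (isTRUE(r$pass)) r$sub else r
      tips <- .gf_tips(sub)
      fam_rows[[length(fam_rows) + 1L]] <-
        data.frame(family = fam, species = sub("\\|.*$", "", tips),
                   transcript = tips, stringsAsFactors = FALSE)
      if (length(tips) >= 2L) {
        gene_trees[[fam]] <- ape::read.tree(
          text = paste0(.gf_newick(sub), ";"))
      } else {
        gene_trees[fam] <- list(NULL)
      }
    }
    families <- if (length(fam_rows)) do.call(rbind, fam_rows) else
      data.frame(family = character(0), species = character(0),
                 transcript = character(0))
    events <- if (length(ev_rows)) do.call(rbind, ev_rows) else
      data.frame(family = character(0), node = character(0),
                 event = character(0))
    list(families = families, gene_trees = gene_trees,
         truth = list(events = events, extinct = extinct))
  })
}

#' Simulate negative-binomial transcript counts with planted fold-changes
#'
#' Every transcript of a family shares the family's expression rate (an
#' RPKM-scale log-normal draw); for planted differentially expressed
#' families the rate is multiplied by `fold_change` in the colored group.
#' Transcript lengths are log-normal(6.5, 0.5) truncated at 200 bp, drawn
#' once per family (orthologous members conserve length); counts are
#' negative binomial with variance mu + phi * mu^2 (`phi = 0` gives
#' Poisson).
#'
#' @param families data.frame family/species/transcript (as from
#'   [simulate_families()]).
#' @param groups named species -> group vector (see [color_groups()]).
#' @param n_de number of planted DE families.
#' @param fold_change planted fold-change (> 0) applied in the colored
#'   group.
#' @param nb_dispersion dispersion phi (>= 0).
#' @param libsizes named mapped-read totals per species; default 2e7 each.
#' @param seed integer seed.
#' @return List: `expr` (data.frame transcript/species/length/reads),
#'   `library_sizes`, `truth` (de_families with fold, family base rates).
#' @export
simulate_counts <- function(families, groups, n_de = 0, fold_change = 1,
                            nb_dispersion = 0.2, libsizes = NULL, seed = 1) {
  stopifnot(fold_change > 0, nb_dispersion >= 0)
  gs <- unique(groups)
  if (length(unique(groups)) < 2L ||
      any(!c("colored", "noncolored") %in% groups))
    stop("both colored and noncolored groups must be non-empty")
  species <- names(groups)
  if (is.null(libsizes))
    libsizes <- stats::setNames(rep(2e7, length(species)), species)
  fams <- unique(families$family)
  .with_seed(seed, {
    de <- if (n_de > 0) sort(sample(fams, min(n_de, length(fams)))) else character(0)
    base_rate <- stats::setNames(stats::rlnorm(length(fams), 2, 1), fams)
    # orthologs conserve length: one log-normal draw per family
    fam_len <- stats::setNames(pmax(round(stats::rlnorm(length(fams), 6.5, 0.5)),
                                    200), fams)
    rows <- families[families$species %in% species, , drop = FALSE]
    len <- unname(fam_len[rows$family])
    rate <- base_rate[rows$family]
    shifted <- rows$family %in% de & groups[rows$species] == "colored"
    rate[shifted] <- rate[shifted] * fold_change
    mu <- rate * (len / 1e3) * (libsizes[rows$species] / 1e6)
    reads <- if (nb_dispersion == 0) stats::rpois(length(mu), mu) else
      stats::rnbinom(length(mu), mu = mu, size = 1 / nb_dispersion)
    expr <- data.frame(transcript = rows$transcript, species = rows$species,
                       length = len, reads = reads,
                       stringsAsFactors = FALSE)
    list(expr = expr, library_sizes = libsizes,
         truth = list(de_families = de, fold_change = fold_change,
                      base_rate = base_rate, dispersion = nb_dispersion))
  })
}

#' Simulate a codon alignment under the one-ratio model
#'
#' Root codons are drawn from the equilibrium frequencies and evolved along
#' every branch with the transition matrices of the scaled one-ratio
#' (Goldman-Yang-style) rate matrix, so no stop codons ever arise and the
#' alignment is gap-free.
#'
#' @param tree [ape::phylo] with branch lengths (substitutions/codon).
#' @param n_codons number of codon sites (>= 1).
#' @param omega,kappa simulation truth (> 0).
#' @param pi equilibrium codon frequencies; default uniform over the 61
#'   sense codons.
#' @param seed integer seed.
#' @return A [codon_alignment] over the tree's leaves.
#' @export
simulate_codon_alignment <- function(tree, n_codons, omega = 0.3,
                                     kappa = 2, pi = NULL, seed = 1) {
  stopifnot(n_codons >= 1, omega > 0, kappa > 0)
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  tb <- .codon_tables()
  if (is.null(pi)) pi <- codon_frequencies(method = "uniform")
  Q <- codon_rate_matrix(omega, kappa, pi)
  dec <- .codon_decompose(Q, pi)
  nt <- length(tree$tip.label)
  nn <- nt + tree$Nnode
  .with_seed(seed, {
    states <- matrix(NA_integer_, nn, n_codons)
    root <- nt + 1L
    states[root, ] <- sample.int(61, n_codons, replace = TRUE, prob = pi)
    pre <- ape::reorder.phylo(tree, "cladewise")
    for (e in seq_len(nrow(pre$edge))) {
      p <- pre$edge[e, 1L]; ch <- pre$edge[e, 2L]
      t <- pre$edge.length[e]
      if (t <= 0) {
        states[ch, ] <- states[p, ]
      } else {
        P <- .codon_pmat(dec, t)
        states[ch, ] <- vapply(states[p, ], function(s)
          sample.int(61, 1L, prob = P[s, ]), integer(1))
      }
    }
    seqs <- apply(states[seq_len(nt), , drop = FALSE], 1L, function(v)
      paste(tb$CODONS[v], collapse = ""))
    codon_alignment(tree$tip.label, seqs)
  })
}

#' Fibroin-like silk protein template
#'
#' @param head 14-residue conserved head.
#' @param nterm_range candidate lengths of the non-repetitive N terminus.
#' @param n_repeat_units number of polyA+spacer repeat units.
#' @param polyA_range poly-alanine run lengths sampled uniformly.
#' @param spacer_weights sampling weights over the GGGX/GGX/GX motifs.
#' @param x_weights named residue weights for the X of each motif
#'   (non-glycine).
#' @param spacer_motifs motifs per spacer block.
#' @return A `silk_template` list.
#' @export
silk_template <- function(head = "MRVTAFVILCCALQ",
                          nterm_range = 87:103,
                          n_repeat_units = 12,
                          polyA_range = 8:14,
                          spacer_weights = c(GGGX = 0.3, GGX = 0.4, GX = 0.3),
                          x_weights = c(S = 0.30, D = 0.12, R = 0.08,
                                        Y = 0.15, N = 0.10, W = 0.05,
                                        V = 0.05, A = 0.05, L = 0.10),
                          spacer_motifs = 6) {
  stopifnot(nchar(head) == 14, all(nterm_range >= 14),
            all(spacer_weights >= 0), sum(spacer_weights) > 0,
            all(x_weights >= 0), sum(x_weights) > 0,
            !"G" %in% names(x_weights))
  structure(list(head = toupper(head), nterm_range = nterm_range,
                 n_repeat_units = n_repeat_units, polyA_range = polyA_range,
                 spacer_weights = spacer_weights, x_weights = x_weights,
                 spacer_motifs = spacer_motifs),
            class = "silk_template")
}

#' Generate fibroin-like proteins with planted region spans
#'
#' One protein per species: an ancestral sequence is built from the
#' template (fixed 14-residue head, alanine-free N-terminal remainder,
#' repeat region alternating poly-alanine runs and glycine-motif spacers),
#' then each species receives independent substitutions outside the head
#' at probability `per_species_divergence`. Substitutions inside the
#' N terminus never introduce alanine and the first three alanines of the
#' repeat region are held fixed, so the planted boundary stays detectable
#' in every species.
#'
#' @param template a [silk_template].
#' @param species character vector of species names.
#' @param per_species_divergence per-residue substitution probability.
#' @param seed integer seed.
#' @return List: `proteins` (a [seq_set]), `truth` (nterm boundary,
#'   polyA block spans in 0-based half-open coordinates, repeat span).
#' @export
generate_silk_proteins <- function(template = silk_template(),
                                   species = names(color_groups()),
                                   per_species_divergence = 0.02,
                                   seed = 1) {
  stopifnot(inherits(template, "silk_template"))
  aas20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]
  no_a <- setdiff(aas20, "A")
  .with_seed(seed, {
    nterm_len <- sample(template$nterm_range, 1L)
    tail_len <- nterm_len - nchar(template$head)
    nterm_tail <- paste(sample(no_a, tail_len, replace = TRUE),
                        collapse = "")
    blocks <- list(); kinds <- character(0)
    for (u in seq_len(template$n_repeat_units)) {
      blocks[[length(blocks) + 1L]] <-
        strrep("A", sample(template$polyA_range, 1L))
      kinds <- c(kinds, "polyA")
      motifs <- sample(names(template$spacer_weights),
                       template$spacer_motifs, replace = TRUE,
                       prob = template$spacer_weights)
      spacer <- paste(vapply(motifs, function(m) {
        x <- sample(names(template$x_weights), 1L,
                    prob = template$x_weights)
        paste0(strrep("G", nchar(m) - 1L), x)
      }, character(1)), collapse = "")
      blocks[[length(blocks) + 1L]] <- spacer
      kinds <- c(kinds, "spacer")
    }
    repeat_region <- paste(unlist(blocks), collapse = "")
    anc <- paste0(template$head, nterm_tail, repeat_region)
    L <- nchar(anc)
    lens <- nchar(unlist(blocks))
    ends <- nterm_len + cumsum(lens)
    starts <- ends - lens
    truth <- list(nterm_span = c(0L, nterm_len),
                  repeat_span = c(nterm_len, L),
                  blocks = data.frame(kind = kinds, start = starts,
                                      end = ends))
    seqs <- vapply(species, function(sp) {
      res <- strsplit(anc, "")[[1L]]
      mut <- which(stats::runif(L) < per_species_divergence)
      mut <- mut[mut > nchar(template$head)]
      # the first alanines of the repeat region define the planted
      # boundary; keep them fixed like the head
      mut <- mut[mut <= nterm_len | mut > nterm_len + 3L]
      for (i in mut) {
        pool <- if (i <= nterm_len) no_a else aas20
        res[i] <- sample(setdiff(pool, res[i]), 1L)
      }
      paste(res, collapse = "")
    }, character(1))
    list(proteins = seq_set(species, seqs, "protein"), truth = truth)
  })
}

#' Generate serine-rich sericin-like proteins
#'
#' Independent draws from a serine-dominated residue distribution, one
#' protein per species.
#'
#' @param species species names.
#' @param length protein length.
#' @param weights named residue weights (default serine-rich).
#' @param seed integer seed.
#' @return List: `proteins` ([seq_set]), `weights` (normalized truth).
#' @export
generate_sericin_proteins <- function(species = names(color_groups()),
                                      length = 300,
                                      weights = c(S = 0.30, G = 0.12,
                                                  A = 0.08, T = 0.08,
                                                  D = 0.08, K = 0.08,
                                                  N = 0.06, E = 0.06,
                                                  R = 0.05, P = 0.05,
                                                  V = 0.04, Q = 0.04,
                                                  L = 0.04),
                                      seed = 1) {
  w <- weights / sum(weights)
  .with_seed(seed, {
    seqs <- vapply(species, function(sp)
      paste(sample(names(w), length, replace = TRUE, prob = w),
            collapse = ""), character(1))
    list(proteins = seq_set(species, seqs, "protein"), weights = w)
  })
}

#' Generate GO annotations with planted enrichment
#'
#' Each gene is annotated with each term independently; inside
#' `target_set` the annotation probability of enriched terms is multiplied
#' by `enrich_factor` (capped at 0.95).
#'
#' @param genes gene identifiers.
#' @param n_terms number of GO terms (ids `GO:0000001`...).
#' @param n_enriched number of planted enriched terms.
#' @param enrich_factor enrichment factor (1 = null).
#' @param target_set subset of `genes` carrying the enrichment.
#' @param base_prob baseline annotation probability per term.
#' @param seed integer seed.
#' @return List: `annotations` (data.frame gene/term/class), `truth`
#'   (enriched term ids).
#' @export
generate_go_annotations <- function(genes, n_terms = 50, n_enriched = 0,
                                    enrich_factor = 1, target_set = character(0),
                                    base_prob = 0.05, seed = 1) {
  stopifnot(all(target_set %in% genes), enrich_factor > 0)
  terms <- sprintf("GO:%07d", seq_len(n_terms))
  classes <- rep(c("biological_process", "molecular_function",
                   "cellular_component"), length.out = n_terms)
  .with_seed(seed, {
    enriched <- if (n_enriched > 0) sort(sample(terms, n_enriched)) else character(0)
    rows <- list()
    in_target <- genes %in% target_set
    for (k in seq_along(terms)) {
      p <- rep(base_prob, length(genes))
      if (terms[k] %in% enriched)
        p[in_target] <- pmin(base_prob * enrich_factor, 0.95)
      hit <- stats::runif(length(genes)) < p
      if (any(hit))
        rows[[length(rows) + 1L]] <-
          data.frame(gene = genes[hit], term = terms[k],
                     class = classes[k], stringsAsFactors = FALSE)
    }
    ann <- if (length(rows)) do.call(rbind, rows) else
      data.frame(gene = character(0), term = character(0),
                 class = character(0))
    list(annotations = ann, truth = list(enriched_terms = enriched))
  })
}
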