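test_that("species tree has the fixed silkmoth topology", {
  tr <- make_species_tree()
  expect_equal(length(tr$tip.label), 7)
  # A.per and A.yam are siblings
  mrca <- ape::getMRCA(tr, c("A.per", "A.yam"))
  expect_equal(sort(ape::extract.clade(tr, mrca)$tip.label),
               c("A.per", "A.yam"))
  # S.cyn is the deepest Saturniidae split: its sister clade holds the
  # other five Saturniidae species
  sat <- ape::extract.clade(tr, ape::getMRCA(tr, c("A.per", "S.cyn")))
  expect_equal(sort(sat$tip.label),
               c("A.ass", "A.per", "A.yam", "Ac.sel", "R.new", "S.cyn"))
  kids <- sat$edge[sat$edge[, 1] == length(sat$tip.label) + 1, 2]
  expect_true("S.cyn" %in% sat$tip.label[kids[kids <= 6]])
  # round trip
  tr2 <- parse_newick(write_newick(tr))
  expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(tr2)),
               structure(0, names = "PH85"), ignore_attr = TRUE)
})

test_that("family simulation: no events means one congruent copy per species", {
  tr <- make_species_tree()
  r <- simulate_families(tr, 5, dup_rate = 0, loss_rate = 0, seed = 1)
  expect_equal(nrow(r$families), 5 * 7)
  expect_equal(nrow(r$truth$events), 0)
  for (fam in unique(r$families$family)) {
    gt <- r$gene_trees[[fam]]
    expect_equal(sort(sub("\\|.*$", "", gt$tip.label)), sort(tr$tip.label))
    gt2 <- gt
    gt2$tip.label <- sub("\\|.*$", "", gt2$tip.label)
    expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(gt2)),
                 structure(0, names = "PH85"), ignore_attr = TRUE)
  }
})

test_that("recorded events replay to the emitted species membership", {
  tr <- make_species_tree()
  r <- simulate_families(tr, 40, dup_rate = 0.25, loss_rate = 0.25, seed = 9)
  fams <- unique(c(r$families$family, r$truth$extinct))
  for (fam in fams) {
    ev <- r$truth$events[r$truth$events$family == fam, , drop = FALSE]
    counts <- replay_family_events(tr, ev)
    obs <- table(factor(r$families$species[r$families$family == fam],
                        levels = tr$tip.label))
    expect_equal(unname(counts), unname(as.integer(obs)), label = fam)
  }
})

test_that("family simulation is seed-deterministic and flags extinctions", {
  tr <- make_species_tree()
  a <- simulate_families(tr, 15, 0.2, 0.4, seed = 5)
  b <- simulate_families(tr, 15, 0.2, 0.4, seed = 5)
  expect_identical(a$families, b$families)
  expect_identical(a$truth$events, b$truth$events)
  hi <- simulate_families(tr, 30, 0, loss_rate = 3, seed = 2)
  expect_gt(length(hi$truth$extinct), 0)
  expect_false(any(hi$truth$extinct %in% hi$families$family))
})

test_that("count simulation respects planted structure", {
  tr <- make_species_tree(); g <- color_groups()
  fams <- simulate_families(tr, 50, 0, 0, seed = 1)
  # degenerate noise: phi = 0, no DE -> counts close to means
  cts <- simulate_counts(fams$families, g, n_de = 0, nb_dispersion = 0,
                         seed = 2)
  expect_true(all(cts$expr$reads >= 0))
  expect_true(all(cts$expr$length >= 200))
  mu <- cts$truth$base_rate[fams$families$family[
    match(cts$expr$transcript, fams$families$transcript)]] *
    (cts$expr$length / 1e3) * (2e7 / 1e6)
  expect_lt(median(abs(cts$expr$reads - mu) / sqrt(mu + 1)), 3)
  # determinism
  cts2 <- simulate_counts(fams$families, g, n_de = 0, nb_dispersion = 0,
                          seed = 2)
  expect_identical(cts$expr, cts2$expr)
  expect_error(simulate_counts(fams$families,
                               c(A.per = "colored", A.yam = "colored"),
                               seed = 1),
               "group")
})

test_that("codon simulator: zero branches copy the root, no stops, determinism", {
  tr <- make_species_tree(0)
  a <- simulate_codon_alignment(tr, 40, omega = 0.5, kappa = 2, seed = 3)
  expect_equal(length(unique(unname(a$seq))), 1)
  tr2 <- make_species_tree(0.2)
  b1 <- simulate_codon_alignment(tr2, 60, omega = 0.3, seed = 4)
  b2 <- simulate_codon_alignment(tr2, 60, omega = 0.3, seed = 4)
  expect_identical(b1$seq, b2$seq)
  # codon_alignment() already rejects stop codons; construct survives
  expect_s3_class(b1, "codon_aln")
  expect_error(simulate_codon_alignment(ape::read.tree(text = "(A,B);"), 10),
               "branch length")
})

test_that("silk protein generator plants detectable structure", {
  g0 <- generate_silk_proteins(per_species_divergence = 0, seed = 6)
  expect_equal(length(unique(unname(g0$proteins$seq))), 1)
  g <- generate_silk_proteins(seed = 6)
  heads <- substr(g$proteins$seq, 1, 14)
  expect_equal(length(unique(unname(heads))), 1)
  # planted polyA recovery by decompose_repeats
  truth_blocks <- g$truth$blocks
  planted <- unlist(apply(truth_blocks[truth_blocks$kind == "polyA", ],
                          1, function(r)
                            seq(as.integer(r["start"]),
                                as.integer(r["end"]) - 1L)))
  for (i in seq_along(g$proteins$id)) {
    rec <- silk_protein_record(g$proteins$id[i], g$proteins$id[i],
                               g$proteins$seq[i],
                               nterm_span = g$truth$nterm_span,
                               repeat_span = g$truth$repeat_span)
    bl <- decompose_repeats(rec)
    rec_pos <- unlist(apply(bl[bl$kind == "polyA", ], 1, function(r)
      seq(as.integer(r["start"]), as.integer(r["end"]) - 1L)))
    expect_gte(mean(planted %in% rec_pos), 0.95)
  }
})

test_that("GO annotation generator plants enrichment and is deterministic", {
  genes <- sprintf("g%03d", 1:300)
  target <- genes[1:75]
  a <- generate_go_annotations(genes, n_terms = 30, n_enriched = 3,
                               enrich_factor = 10, target_set = target,
                               seed = 8)
  b <- generate_go_annotations(genes, n_terms = 30, n_enriched = 3,
                               enrich_factor = 10, target_set = target,
                               seed = 8)
  expect_identical(a$annotations, b$annotations)
  expect_equal(length(a$truth$enriched_terms), 3)
  frac_in <- function(tm) {
    gset <- a$annotations$gene[a$annotations$term == tm]
    c(mean(target %in% gset), mean(setdiff(genes, target) %in% gset))
  }
  for (tm in a$truth$enriched_terms) {
    fr <- frac_in(tm)
    expect_gt(fr[1], fr[2])
  }
})

test_that("sericin generator matches its residue weights", {
  g <- generate_sericin_proteins(length = 4000, seed = 10)
  comp <- aa_composition(g$proteins$seq[1])
  expect_lt(abs(comp[["S"]] - g$weights[["S"]]), 0.03)
  expect_gt(comp[["S"]], max(comp[setdiff(names(comp), "S")]))
})

test_that("generators leave the caller RNG state untouched", {
  set.seed(123); before <- .Random.seed
  invisible(simulate_families(make_species_tree(), 3, 0.1, 0.1, seed = 77))
  expect_identical(.Random.seed, before)
})
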