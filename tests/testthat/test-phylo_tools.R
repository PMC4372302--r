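test_that("distance matrix: p-distance and Tajima-Nei", {
  s <- seq_set(c("a", "b", "c"), c("ACGT", "ACGA", "ACGT"), "dna")
  d <- distance_matrix(s, "p")
  expect_equal(d["a", "b"], 0.25)
  expect_equal(d["a", "c"], 0)
  expect_true(isSymmetric(d))

  # Tajima-Nei on a 20-site toy pair, against the formula evaluated by
  # hand: d = -b log(1 - p/b), b = (1 - sum g^2 + p^2/h)/2,
  # h = sum over pairs x_ij^2 / (2 g_i g_j)
  a <- "AACCGGTTAACCGGTTAACC"
  b <- "AACCGGTTAACCGGTAAGCC"  # differs at sites 16 (T->A) and 18 (A->G)
  s2 <- seq_set(c("x", "y"), c(a, b), "dna")
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  p <- mean(av != bv)
  g <- (table(factor(av, levels = c("A","C","G","T"))) +
          table(factor(bv, levels = c("A","C","G","T")))) / 40
  x_at <- mean((av == "A" & bv == "T") | (av == "T" & bv == "A"))
  x_ag <- mean((av == "A" & bv == "G") | (av == "G" & bv == "A"))
  h <- x_at^2 / (2 * g[["A"]] * g[["T"]]) + x_ag^2 / (2 * g[["A"]] * g[["G"]])
  bb <- 0.5 * (1 - sum(g^2) + p^2 / h)
  want <- -bb * log(1 - p / bb)
  d2 <- distance_matrix(s2, "tajima_nei")
  expect_equal(d2["x", "y"], unname(want), tolerance = 1e-12)

  # identical pair has distance zero under both models
  expect_equal(distance_matrix(s, "tajima_nei")["a", "c"], 0)
})

test_that("neighbor joining is exact on additive matrices", {
  # distances generated by the tree ((A:1,B:2):1,(C:3,D:4))
  d <- matrix(c(0, 3, 5, 6,
                3, 0, 6, 7,
                5, 6, 0, 7,
                6, 7, 7, 0), 4, 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tr <- nj_tree(d)
  expect_false(ape::is.rooted(tr))
  # AB|CD split with exact branch lengths: path lengths reproduce d
  pd <- ape::cophenetic.phylo(tr)[LETTERS[1:4], LETTERS[1:4]]
  expect_equal(pd, d, tolerance = 1e-9)
  # agreement with the reference implementation on the same matrix
  expect_equal(ape::dist.topo(tr, ape::nj(d)),
               structure(0, names = "PH85"), ignore_attr = TRUE)

  # three taxa: forced topology, three-point branch lengths
  d3 <- matrix(c(0, 2, 3, 2, 0, 5, 3, 5, 0), 3, 3,
               dimnames = list(c("A","B","C"), c("A","B","C")))
  t3 <- nj_tree(d3)
  pd3 <- ape::cophenetic.phylo(t3)[c("A","B","C"), c("A","B","C")]
  expect_equal(pd3, d3, tolerance = 1e-9)

  expect_error(nj_tree(matrix(c(0, 1, 1, 0), 2, 2,
                              dimnames = list(c("a","b"), c("a","b")))),
               "3 taxa")
  dbad <- d; dbad[1, 2] <- 99
  expect_error(nj_tree(dbad), "symmetric")
})

test_that("NJ recovers the species topology from simulated codon data", {
  tr <- make_species_tree(0.15)
  aln <- simulate_codon_alignment(tr, 500, omega = 0.3, seed = 17)
  s <- seq_set(aln$taxa, unname(aln$seq), "dna")
  njt <- nj_tree(distance_matrix(s, "tajima_nei"))
  expect_equal(ape::dist.topo(ape::unroot(tr), njt),
               structure(0, names = "PH85"), ignore_attr = TRUE)
})

test_that("independent contrasts reproduce the hand recursion", {
  tr <- parse_newick("((A:1,B:1):1,C:2);")
  pc <- pic_contrasts(tr, c(A = 1, B = 3, C = 6))
  # hand recursion: contrast(A,B) = (1-3)/sqrt(2); ancestor value 2 with
  # adjusted length 1.5; contrast(anc, C) = (2-6)/sqrt(1.5+2)
  expect_equal(sort(unname(pc$contrasts)),
               sort(c(-2 / sqrt(2), -4 / sqrt(3.5))), tolerance = 1e-12)
  expect_equal(sort(unname(pc$node_values)), sort(c(2, (2/1.5 + 6/2)/(1/1.5 + 1/2))),
               tolerance = 1e-12)
  # agreement with the reference implementation
  ref <- ape::pic(c(A = 1, B = 3, C = 6)[tr$tip.label], tr)
  expect_equal(sort(abs(unname(pc$contrasts))), sort(abs(unname(ref))),
               tolerance = 1e-12)
  # constant trait gives all-zero contrasts
  expect_equal(unname(pic_contrasts(tr, c(A = 2, B = 2, C = 2))$contrasts),
               c(0, 0))
  # polytomy refused, resolvable by the helper
  tp <- parse_newick("((A:1,B:1,C:1):1,D:2);")
  expect_error(pic_contrasts(tp, c(A=1,B=2,C=3,D=4)), "polytom")
  tpr <- resolve_polytomies(tp)
  expect_true(ape::is.binary(tpr))
})

test_that("contrast correlation behaves at the extremes and under the null", {
  tr <- ape::drop.tip(make_species_tree(), "B.mor")
  x <- stats::setNames(c(1, 5, 2, 4, 3, 6), tr$tip.label)
  self <- pic_correlation(tr, x, x)
  expect_equal(self$r, 1, tolerance = 1e-12)
  expect_lt(self$p, 1e-6)
  const <- pic_correlation(tr, stats::setNames(rep(1, 6), tr$tip.label), x)
  expect_true(const$zero_variance)
  expect_equal(const$p, 1)
  # null calibration on Brownian traits (moderate replicate count here;
  # the acceptance suite runs the full calibration)
  set.seed(71)
  ps <- replicate(400, {
    a <- ape::rTraitCont(tr); b <- ape::rTraitCont(tr)
    pic_correlation(tr, a, b)$p
  })
  expect_gt(mean(ps < 0.05), 0.02)
  expect_lt(mean(ps < 0.05), 0.09)
})

test_that("reconciliation handles the canonical hand cases", {
  st <- parse_newick("(A,B);")
  # congruent one-copy gene tree
  g0 <- parse_newick("(a1,b1);")
  m0 <- c(a1 = "A", b1 = "B")
  r0 <- reconcile(g0, st, m0)
  expect_equal(r0$duplications, 0)
  expect_equal(r0$losses, 0)
  # duplication at the root, both copies complete
  g1 <- parse_newick("((a1,b1),(a2,b2));")
  r1 <- reconcile(g1, st, c(a1 = "A", b1 = "B", a2 = "A", b2 = "B"))
  expect_equal(r1$duplications, 1)
  expect_equal(r1$losses, 0)
  root_row <- r1$events[r1$events$label == "node3", ]
  expect_equal(root_row$duplications, 1)
  # duplication at the root with one copy losing the B lineage
  g2 <- parse_newick("(a1,(a2,b1));")
  r2 <- reconcile(g2, st, c(a1 = "A", a2 = "A", b1 = "B"))
  expect_equal(r2$duplications, 1)
  expect_equal(r2$losses, 1)
  expect_equal(r2$events$losses[r2$events$label == "B"], 1)
  expect_error(reconcile(g2, st, c(a1 = "A", a2 = "A")), "unmapped")
})

test_that("reconciliation recovers planted events from the simulator", {
  tr <- make_species_tree()
  # loss-free simulations: duplication counts match the planted events
  fams <- simulate_families(tr, 30, dup_rate = 0.15, loss_rate = 0, seed = 23)
  for (fam in unique(fams$families$family)) {
    gt <- fams$gene_trees[[fam]]
    if (is.null(gt)) next
    planted <- sum(fams$truth$events$family == fam &
                     fams$truth$events$event == "duplication")
    r <- reconcile(gt, tr)
    expect_equal(r$duplications, planted, label = fam)
    expect_equal(r$losses, 0, label = fam)
  }
  # congruent families reconcile with zero events
  f0 <- simulate_families(tr, 5, 0, 0, seed = 29)
  for (fam in unique(f0$families$family)) {
    r <- reconcile(f0$gene_trees[[fam]], tr)
    expect_equal(r$duplications + r$losses, 0)
  }
})
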