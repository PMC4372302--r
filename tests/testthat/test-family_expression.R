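test_that("transcript RPKM follows the defining arithmetic", {
  expect_equal(transcript_rpkm(100, 1000, 1e6), 100)
  expect_equal(transcript_rpkm(100, 1000, 2e6),
               transcript_rpkm(100, 1000, 1e6) / 2)
  expect_equal(transcript_rpkm(0, 500, 1e6), 0)
  expect_error(transcript_rpkm(1, 0, 1e6), "length")
  expect_error(transcript_rpkm(1, 100, 0), "library")
})

test_that("family RPKM pools member reads and lengths", {
  fams <- data.frame(family = "F1", species = "A.per",
                     transcript = c("t1", "t2"))
  expr <- data.frame(transcript = c("t1", "t2"), species = "A.per",
                     length = c(500, 1500), reads = c(10, 30))
  libs <- c(A.per = 1e6)
  fr <- family_rpkm(fams, expr, libs)
  expect_equal(fr["F1", "A.per"], 40 / 2)  # 40 reads over 2 kb at 1e6
  # single-member family equals transcript RPKM
  f1 <- family_rpkm(data.frame(family = "F", species = "A.per",
                               transcript = "t1"), expr, libs)
  expect_equal(f1["F", "A.per"], transcript_rpkm(10, 500, 1e6))
  # invariance to re-partitioning reads/lengths among members
  expr2 <- data.frame(transcript = c("u1", "u2", "u3"), species = "A.per",
                      length = c(250, 250, 1500), reads = c(7, 3, 30))
  fams2 <- data.frame(family = "F1", species = "A.per",
                      transcript = c("u1", "u2", "u3"))
  expect_equal(family_rpkm(fams2, expr2, libs)["F1", "A.per"],
               fr["F1", "A.per"])
  # absent species column gives zero
  libs2 <- c(A.per = 1e6, A.yam = 1e6)
  expect_equal(family_rpkm(fams, expr, libs2)["F1", "A.yam"], 0)
})

test_that("group-specific family calls respect the presence threshold", {
  g <- color_groups()
  fr <- matrix(0, 3, 6, dimnames = list(c("everywhere", "col", "non"),
                                        names(g)))
  fr["everywhere", ] <- 10
  fr["col", names(g)[g == "colored"]] <- c(2, 3, 4)
  fr["non", names(g)[g == "noncolored"]] <- c(1, 1, 9)
  sets <- group_specific_families(fr, g, presence_min = 1)
  expect_equal(sets$colored, "col")
  expect_equal(sets$noncolored, "non")
  # a family present everywhere is in neither set
  expect_false("everywhere" %in% unlist(sets))
  # raising the floor drops borderline families
  sets2 <- group_specific_families(fr, g, presence_min = 3)
  expect_false("col" %in% sets2$colored)
  # planted recovery from the generator
  tr <- make_species_tree()
  fams <- simulate_families(tr, 40, 0, 0, seed = 3)
  cts <- simulate_counts(fams$families, g, n_de = 0, nb_dispersion = 0.1,
                         seed = 4)
  keep <- fams$families$species %in% names(g)
  zero <- fams$families$family %in% sprintf("F%04d", 1:5) &
    g[fams$families$species] == "noncolored" & keep
  cts$expr$reads[match(fams$families$transcript[zero],
                       cts$expr$transcript)] <- 0
  frm <- family_rpkm(fams$families, cts$expr, cts$library_sizes)
  got <- group_specific_families(frm, g)
  expect_setequal(got$colored, sprintf("F%04d", 1:5))
  expect_length(got$noncolored, 0)
})

test_that("trait filter keeps correlated families and drops flat ones", {
  tr <- ape::drop.tip(make_species_tree(), "B.mor")
  g <- color_groups()
  trait <- stats::setNames(as.numeric(g[tr$tip.label] == "colored"),
                           tr$tip.label)
  fr <- matrix(0, 2, 6, dimnames = list(c("match", "flat"), tr$tip.label))
  fr["match", ] <- trait * 5
  fr["flat", ] <- 4
  tf <- trait_filter(fr, tr, trait)
  expect_equal(tf$retained, "match")
  expect_true("flat" %in% tf$excluded)
  expect_true(tf$table$zero_variance[tf$table$family == "flat"])
})

test_that("NB exact test: symmetry, binomial oracle and calibration", {
  expect_equal(nb_exact_test(c(5, 5, 5), c(5, 5, 5), 0.2)$p, 1)
  r0 <- nb_exact_test(c(0, 0), c(0, 0), 0.1)
  expect_equal(r0$p, 1)
  expect_true(r0$zero_total)
  # phi = 0, totals (10, 0): doubled binomial tail by direct summation
  r <- nb_exact_test(c(10, 0, 0), c(0, 0, 0), 0)
  expect_equal(r$p, 2 * dbinom(10, 10, 0.5), tolerance = 1e-12)
  # label swap symmetry
  set.seed(81)
  for (rep in 1:10) {
    a <- rnbinom(3, mu = 40, size = 5); b <- rnbinom(3, mu = 40, size = 5)
    expect_equal(nb_exact_test(a, b, 0.2)$p, nb_exact_test(b, a, 0.2)$p)
  }
  # quick null calibration (the acceptance suite runs 2000 reps)
  set.seed(82)
  ps <- replicate(600, {
    mu <- rlnorm(1, 4, 1)
    nb_exact_test(rnbinom(3, mu = mu, size = 5),
                  rnbinom(3, mu = mu, size = 5), 0.2)$p
  })
  expect_gt(mean(ps < 0.05), 0.02)
  expect_lt(mean(ps < 0.05), 0.08)
})

test_that("NB exact test agrees with edgeR on equalized libraries", {
  skip_if_not_installed("edgeR")
  set.seed(83)
  cnt <- matrix(rnbinom(300, mu = 60, size = 1 / 0.15), ncol = 6)
  rownames(cnt) <- sprintf("F%03d", seq_len(nrow(cnt)))
  grp <- rep(c("colored", "noncolored"), each = 3)
  dge <- edgeR::DGEList(counts = cnt, group = grp,
                        lib.size = rep(1e6, 6))
  dge$samples$norm.factors <- 1
  et <- edgeR::exactTest(dge, dispersion = 0.15)
  mine <- vapply(seq_len(nrow(cnt)), function(i)
    nb_exact_test(cnt[i, 1:3], cnt[i, 4:6], 0.15)$p, 0)
  # same construction (conditional NB, doubled tail); equal library sizes
  # make edgeR's quantile adjustment a no-op
  expect_equal(mine, unname(et$table$PValue), tolerance = 1e-4)
})

test_that("common dispersion recovery and boundary behaviour", {
  tr <- make_species_tree(); g <- color_groups()
  fams <- simulate_families(tr, 300, 0, 0, seed = 5)
  cts <- simulate_counts(fams$families, g, n_de = 0, nb_dispersion = 0.2,
                         seed = 6)
  mat <- family_counts(fams$families, cts$expr, species = names(g))
  phi <- estimate_common_dispersion(mat, g)
  expect_gt(phi, 0.1); expect_lt(phi, 0.3)
  # Poisson data drive the estimate to the boundary
  cts0 <- simulate_counts(fams$families, g, n_de = 0, nb_dispersion = 0,
                          seed = 7)
  mat0 <- family_counts(fams$families, cts0$expr, species = names(g))
  expect_lte(estimate_common_dispersion(mat0, g), 0.02)
  # invariance to family order
  perm <- sample(nrow(mat))
  expect_equal(estimate_common_dispersion(mat[perm, ], g), phi)
  # degenerate matrix
  flat <- matrix(5, 4, 6, dimnames = list(letters[1:4], names(g)))
  expect_equal(estimate_common_dispersion(flat, g), 0)
})

test_that("BH adjustment is the step-up procedure in input order", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.3), 0.3)
  set.seed(84)
  p <- runif(50)
  q <- bh_fdr(p)
  expect_true(all(q >= p))
  o <- order(p)
  expect_true(all(diff(q[o]) >= -1e-12))
  # shuffling and unshuffling gives the same adjusted values
  perm <- sample(50)
  expect_equal(bh_fdr(p[perm])[order(perm)], q)
})

test_that("differential family calls are powered and FDR-controlled", {
  tr <- make_species_tree(); g <- color_groups()
  fams <- simulate_families(tr, 600, 0, 0, seed = 8)
  cts <- simulate_counts(fams$families, g, n_de = 30, fold_change = 8,
                         nb_dispersion = 0.2, seed = 9)
  de <- de_families(fams$families, cts$expr, cts$library_sizes, g)
  expect_true(all(de$fdr >= de$p))
  sig <- de$family[de$significant]
  expect_true(all(sig %in% de$family))
  expect_gte(mean(cts$truth$de_families %in% sig), 0.8)
  expect_lte(mean(!sig %in% cts$truth$de_families), 0.1)
  # planted DE families shift in the right direction
  lfc <- de$logFC[match(cts$truth$de_families, de$family)]
  expect_gt(mean(lfc > 0), 0.9)
  # null run: significant calls are rare
  cts0 <- simulate_counts(fams$families, g, n_de = 0, nb_dispersion = 0.2,
                          seed = 10)
  de0 <- de_families(fams$families, cts0$expr, cts0$library_sizes, g)
  expect_lte(sum(de0$significant), 0.02 * nrow(de0))
})
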