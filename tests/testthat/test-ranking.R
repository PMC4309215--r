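# Brute-force pairwise-ratio oracle used against geNorm and delta-Ct.
oracle_pairwise <- function(mat) {
  g <- nrow(mat)
  out <- numeric(g)
  for (j in seq_len(g)) {
    acc <- 0
    for (k in seq_len(g)) {
      if (k == j) next
      acc <- acc + sd(mat[j, ] - mat[k, ])
    }
    out[j] <- acc / (g - 1)
  }
  names(out) <- rownames(mat)
  out
}

test_that("geNorm M matches a brute-force all-pairs SD oracle", {
  m <- random_candidate(4, 6, seed = 101)
  gn <- genorm(m)
  expect_equal(gn$m, oracle_pairwise(m), tolerance = 1e-10)
  expect_setequal(gn$ranking, rownames(m))
  expect_identical(unname(sort(gn$rank)), 1:4)
  expect_error(genorm(m[1:2, ]), "3 candidate")
})

test_that("constant-ratio genes contribute zero pairwise SD and M is scale-free", {
  m <- random_candidate(4, 8, seed = 102)
  m[2, ] <- m[1, ] + log2(3)   # planted constant linear ratio
  expect_equal(sd(m[1, ] - m[2, ]), 0)
  # the planted pair share every other pairwise term, so their M are equal
  gn <- genorm(m)
  expect_equal(unname(gn$m["G01"]), unname(gn$m["G02"]), tolerance = 1e-12)

  # multiplying one gene's linear values by a constant: additive log2 shift
  shifted <- m
  shifted[3, ] <- shifted[3, ] + log2(7.5)
  expect_equal(genorm(shifted)$m, gn$m, tolerance = 1e-12)
})

test_that("delta-Ct equals geNorm's initial M and matches the oracle", {
  for (seed in 103:105) {
    m <- random_candidate(5, 8, seed = seed)
    dc <- delta_ct_score(m)
    expect_equal(dc, genorm(m)$m, tolerance = 1e-10)
    expect_equal(dc, oracle_pairwise(m), tolerance = 1e-10)
  }
})

test_that("geNorm stepwise exclusion and pairwise variation behave", {
  m <- random_candidate(6, 10, seed = 106)
  m[6, ] <- m[6, ] + rnorm(10, 0, 3)   # clearly least stable
  gn <- genorm(m)
  expect_identical(gn$ranking[6], "G06")
  expect_equal(gn$pairwise_variation$n, 2:5)
  expect_true(all(gn$pairwise_variation$v >= 0))

  # V(n/n+1) against a direct normalization-factor computation
  top3 <- gn$ranking[1:3]
  nf2 <- colMeans(m[gn$ranking[1:2], ])
  nf3 <- colMeans(m[top3, ])
  expect_equal(gn$pairwise_variation$v[gn$pairwise_variation$n == 2],
               sd(nf2 - nf3), tolerance = 1e-12)
})

test_that("NormFinder matches a definitional variance-decomposition oracle", {
  m <- random_candidate(5, 8, seed = 107)
  groups <- rep(c("a", "b"), each = 4)
  rho <- normfinder(m, groups)

  z <- sweep(m, 2, colMeans(m))
  z <- sweep(z, 1, rowMeans(z))
  oracle <- numeric(5)
  for (i in 1:5) {
    per_group <- vapply(c("a", "b"), function(g) {
      zg <- z[i, groups == g]
      abs(mean(zg)) + sd(zg - mean(zg)) / sqrt(length(zg))
    }, numeric(1))
    oracle[i] <- mean(per_group)
  }
  expect_equal(unname(rho), oracle, tolerance = 1e-12)
  # oracle ordering agrees too
  expect_identical(order(rho), order(oracle))
})

test_that("NormFinder penalizes planted group shifts most", {
  m <- random_candidate(5, 12, seed = 108) * 0.02
  groups <- rep(c("a", "b"), each = 6)
  m[4, groups == "b"] <- m[4, groups == "b"] + 2
  rho <- normfinder(m, groups)
  expect_identical(names(which.max(rho)), "G04")

  flat <- matrix(10, 4, 6, dimnames = list(sprintf("G%02d", 1:4), NULL))
  rho0 <- normfinder(flat)
  expect_true(all(rho0 == 0))
  expect_error(normfinder(m, c(rep("a", 11), "b")), ">= 2 samples")
})

test_that("BestKeeper descriptives match hand formulas", {
  m <- random_candidate(3, 7, seed = 109)
  bk <- bestkeeper(m)
  idx <- colMeans(m)
  for (i in 1:3) {
    v <- m[i, ]
    r_hand <- sum((v - mean(v)) * (idx - mean(idx))) /
      ((length(v) - 1) * sd(v) * sd(idx))
    expect_equal(bk$pearson_r[i], r_hand, tolerance = 1e-12)
    expect_equal(bk$sd_log2[i], sd(v), tolerance = 1e-12)
  }

  # a gene equal to the index correlates perfectly: adding the column mean
  # as a gene leaves the index equal to that gene (fixed point)
  m2 <- rbind(m, IDX = colMeans(m))
  expect_equal(unname(colMeans(m2)), unname(m2["IDX", ]))
  bk2 <- bestkeeper(m2)
  expect_equal(bk2$pearson_r[bk2$gene_symbol == "IDX"], 1, tolerance = 1e-9)

  m3 <- m
  m3[2, ] <- 4
  expect_equal(bestkeeper(m3)$sd_log2[2], 0)
  expect_true(is.na(bestkeeper(m3)$pearson_r[2]))
})

test_that("composite ranking is the geometric mean of per-method ranks", {
  m <- random_candidate(5, 10, seed = 110)
  rs <- rank_stability(m)
  ranks <- as.matrix(rs$scores[paste0("rank_", c("genorm", "normfinder",
                                                 "bestkeeper", "delta_ct"))])
  expect_equal(rs$scores$composite, exp(rowMeans(log(ranks))),
               tolerance = 1e-12)
  expect_identical(sort(rs$scores$overall_rank), 1:5)

  single <- rank_stability(m, methods = "normfinder")
  expect_identical(single$scores$overall_rank,
                   single$scores$rank_normfinder)

  # if every method agrees, the composite order is that shared order
  agree <- rank_stability(m, methods = c("normfinder", "bestkeeper"))
  if (identical(agree$scores$rank_normfinder,
                agree$scores$rank_bestkeeper)) {
    expect_identical(agree$scores$overall_rank,
                     agree$scores$rank_normfinder)
  }

  td <- tidy(rs)
  expect_identical(td$gene_symbol, rs$scores$gene_symbol)
  gl <- glance(rs)
  expect_identical(gl$best_gene, rs$scores$gene_symbol[1])
  expect_equal(gl$n_genes, 5L)
})

test_that("tied composite ranks break lexicographically by gene symbol", {
  # two genes with mirrored ranks (1,2) and (2,1) across two methods
  m <- matrix(c(1, 2, 1.5, 2.5, 1.1, 2.2,
                2, 1, 2.5, 1.5, 2.2, 1.1), 2, 6, byrow = TRUE,
              dimnames = list(c("B_GENE", "A_GENE"), NULL))
  # construct directly on the rank combiner
  r1 <- c(B_GENE = 1L, A_GENE = 2L)
  r2 <- c(B_GENE = 2L, A_GENE = 1L)
  comp <- exp((log(r1) + log(r2)) / 2)
  expect_equal(unname(comp["B_GENE"]), unname(comp["A_GENE"]))
  # rank_stability's tie-break places A_GENE first on equal composites
  rs <- rank_stability(random_candidate(3, 6, seed = 111))
  expect_identical(sort(rs$scores$overall_rank), 1:3)
})

test_that("stability scores ignore per-gene rescaling except BestKeeper CV", {
  m <- random_candidate(4, 8, seed = 112)
  shifted <- m
  shifted[1, ] <- shifted[1, ] + log2(42)  # gene 1 rescaled on linear scale
  expect_equal(genorm(shifted)$m, genorm(m)$m, tolerance = 1e-12)
  expect_equal(delta_ct_score(shifted), delta_ct_score(m),
               tolerance = 1e-12)
  expect_equal(unname(normfinder(shifted)), unname(normfinder(m)),
               tolerance = 1e-12)
  bk_a <- bestkeeper(m); bk_b <- bestkeeper(shifted)
  expect_equal(bk_b$sd_log2, bk_a$sd_log2, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(bk_b$cv_log2[1], bk_a$cv_log2[1])))
})
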