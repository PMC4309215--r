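test_that("probe condensation averages replicate arrays per condition", {
  x <- toy_expr(matrix(c(100, 110, 120), 1, 3))
  d <- toy_design(rep("1g", 3), conditions = c("1g"),
                  contrasts = tibble::tibble(campaign = character(),
                                             contrast = character(),
                                             cond_a = character(),
                                             cond_b = character()))
  pm <- condense_probe_values(x, d)
  expect_equal(pm$mean_fi, 110)

  # constant probe stays constant
  x2 <- toy_expr(matrix(42, 1, 3))
  expect_equal(condense_probe_values(x2, d)$mean_fi, 42)
})

test_that("condensation matches a nested-loop oracle on a balanced design", {
  set.seed(3)
  vals <- matrix(rlnorm(2 * 6, 8, 1), 2, 6)
  x <- toy_expr(vals, genes = c("G1", "G1"))
  d <- toy_design(rep(c("1g", "ug"), each = 3), campaign = "PFC",
                  conditions = c("1g", "ug"),
                  contrasts = tibble::tibble(campaign = "PFC",
                                             contrast = "1g vs ug",
                                             cond_a = "1g", cond_b = "ug"))
  pm <- condense_probe_values(x, d)
  for (p in 1:2) {
    for (ci in list(c("1g", 1:3), c("ug", 4:6))) {
      expected <- mean(vals[p, as.integer(ci[2:4])])
      got <- pm$mean_fi[pm$probe_id == sprintf("P%02d", p) &
                          pm$condition == ci[1]]
      expect_equal(got, expected)
    }
  }
  expect_error(condense_probe_values(to_log2(x), d), "linear")
})

test_that("gene aggregation applies the minimum-probe rule and sample SD", {
  d <- toy_design(rep(c("1g", "ug"), each = 2), conditions = c("1g", "ug"),
                  contrasts = flight_contrasts()[4, ])
  vals <- rbind(matrix(rep(c(100, 120), each = 2), 1),
                matrix(rep(c(110, 125), each = 2), 1),
                matrix(rep(c(90, 115), each = 2), 1),
                matrix(rep(c(500, 600), each = 2), 1))
  x <- toy_expr(vals, genes = c("G1", "G1", "G1", "G2"))
  agg <- aggregate_genes(condense_probe_values(x, d))
  expect_identical(agg$genes$status[agg$genes$gene_symbol == "G1"],
                   "eligible")
  expect_identical(agg$genes$status[agg$genes$gene_symbol == "G2"],
                   "too_few_probes")
  s1 <- dplyr::filter(agg$summaries, gene_symbol == "G1", condition == "1g")
  expect_equal(s1$mean_fi, mean(c(100, 110, 90)))
  expect_equal(s1$sd, sd(c(100, 110, 90)))   # n-1 divisor
  expect_equal(s1$n, 3L)
  expect_false("G2" %in% agg$summaries$gene_symbol)

  # identical probe values give sd 0
  xz <- toy_expr(matrix(7, 3, 4), genes = rep("G1", 3))
  aggz <- aggregate_genes(condense_probe_values(xz, d))
  expect_true(all(aggz$summaries$sd == 0))
})

test_that("aggregation is invariant to probe and array order", {
  set.seed(9)
  vals <- matrix(rlnorm(4 * 6, 7, 0.5), 4, 6)
  d <- toy_design(rep(c("1g", "ug"), 3), conditions = c("1g", "ug"),
                  contrasts = flight_contrasts()[4, ])
  x <- toy_expr(vals, genes = rep("G1", 4))
  base <- aggregate_genes(condense_probe_values(x, d))$summaries

  perm_probes <- sample(4)
  xp <- toy_expr(vals[perm_probes, ], genes = rep("G1", 4))
  again <- aggregate_genes(condense_probe_values(xp, d))$summaries
  expect_equal(dplyr::arrange(again, condition),
               dplyr::arrange(base, condition))

  perm_arrays <- c(3, 1, 5, 2, 6, 4)
  xa <- tibble::as_tibble(x)[c(1, 2, 2 + perm_arrays)]
  names(xa)[3:8] <- sprintf("A%02d", 1:6)
  xa <- expression_table(xa, "linear")
  da <- toy_design(rep(c("1g", "ug"), 3)[perm_arrays],
                   conditions = c("1g", "ug"),
                   contrasts = flight_contrasts()[4, ])
  again2 <- aggregate_genes(condense_probe_values(xa, da))$summaries
  expect_equal(dplyr::arrange(again2, condition),
               dplyr::arrange(base, condition))
})

test_that("retained probe count is the same across a gene's conditions", {
  set.seed(21)
  vals <- matrix(rlnorm(5 * 4, 6, 1), 5, 4)
  vals[5, 1:2] <- vals[5, 1:2] * 500   # outlier probe in one condition only
  d <- toy_design(rep(c("1g", "ug"), each = 2), conditions = c("1g", "ug"),
                  contrasts = flight_contrasts()[4, ])
  x <- toy_expr(vals, genes = rep("G1", 5))
  agg <- aggregate_genes(condense_probe_values(x, d), outlier_rule = "mad")
  expect_identical(unique(agg$summaries$n), 4L)
  expect_identical(agg$genes$status, "outlier_trimmed")
})

test_that("MAD outlier rule removes wild probes and can be disabled", {
  d <- toy_design(c("1g", "1g"), conditions = "1g",
                  contrasts = tibble::tibble(campaign = "PFC",
                                             contrast = character(0),
                                             cond_a = character(0),
                                             cond_b = character(0))[0, ])
  x <- toy_expr(matrix(rep(c(100, 102, 98, 5000), 2), 4, 2, byrow = FALSE),
                genes = rep("G1", 4))
  pm <- condense_probe_values(x, d)
  flagged <- detect_probe_outliers(pm, rule = "mad")
  expect_identical(flagged$retained[flagged$probe_id == "P04"], FALSE)
  expect_true(all(flagged$retained[flagged$probe_id != "P04"]))

  tame <- detect_probe_outliers(
    dplyr::filter(pm, probe_id != "P04"), rule = "mad")
  expect_true(all(tame$retained))

  off <- detect_probe_outliers(pm, rule = "none")
  expect_true(all(off$retained))
})

test_that("high inter-probe variance excludes genes, by rule or by list", {
  sums <- tibble::tibble(
    gene_symbol = rep(c("CALM", "WILD"), each = 2),
    campaign = "PFC",
    condition = rep(c("1g", "ug"), 2),
    mean_fi = c(100, 101, 7010, 7300),
    sd = c(1, 1.2, 9000, 8500),
    n = 3L)
  agg <- structure(list(summaries = sums,
                        genes = tibble::tibble(
                          gene_symbol = c("CALM", "WILD"), campaign = "PFC",
                          n_probes = 3L, n_retained = 3L,
                          status = "eligible")),
                   class = "refstab_aggregation")
  out <- exclude_high_variance(agg, threshold = 50)
  expect_identical(out$genes$status,
                   c("eligible", "high_variance_excluded"))
  expect_identical(out$summaries$gene_symbol, rep("CALM", 2))

  out2 <- exclude_high_variance(agg, threshold = 5000,
                                exclude_genes = "CALM")
  expect_identical(out2$genes$status[out2$genes$gene_symbol == "CALM"],
                   "high_variance_excluded")
  expect_error(exclude_high_variance(agg, threshold = 0), "positive")
})
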