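test_that("functional profiles compute counts, standardized representation, shares", {
  gt <- data.frame(
    gene_id = sprintf("g%02d", 1:12),
    category = rep(c("carbon", "stress", "nitrogen"), times = c(6, 4, 2)),
    is_phylo = FALSE, taxon = "", stringsAsFactors = FALSE)
  assign <- setNames(rep(c("m01", "m02"), each = 6), gt$gene_id)
  # marker probes are not functional categories and must not add one
  gt_full <- rbind(gt, data.frame(gene_id = "p1",
                                  category = "phylogenetic_marker",
                                  is_phylo = TRUE, taxon = "taxA"))
  prof <- functional_profile(assign, gt_full)
  expect_setequal(unique(prof$category), c("carbon", "stress", "nitrogen"))
  m1 <- prof[prof$group == "m01", ]
  expect_equal(m1$count[m1$category == "carbon"], 6L)
  expect_equal(m1$standardized[m1$category == "carbon"], 1)  # all array carbon genes
  expect_equal(m1$share[m1$category == "carbon"], 1)
  m2 <- prof[prof$group == "m02", ]
  expect_equal(m2$count, c(0L, 2L, 4L))   # carbon, nitrogen, stress (sorted)
  expect_equal(m2$standardized[m2$category == "stress"], 1)
  # shares sum to 1 per group
  for (g in unique(prof$group))
    expect_equal(sum(prof$share[prof$group == g]), 1)
})

test_that("multi-membership genes count once per owning group", {
  gt <- data.frame(gene_id = c("g1", "g2"), category = c("carbon", "stress"),
                   is_phylo = FALSE, taxon = "", stringsAsFactors = FALSE)
  cent <- matrix(0.5, 2, 3, dimnames = list(c("c01", "c02"), paste0("S", 1:3)))
  clus <- geofuncnet:::new_cluster_assignment(
    list(g1 = c("c01", "c02"), g2 = "c02"), cent)
  prof <- functional_profile(clus, gt)
  expect_equal(prof$count[prof$group == "c01" & prof$category == "carbon"], 1L)
  expect_equal(prof$count[prof$group == "c02" & prof$category == "carbon"], 1L)
  expect_equal(attr(prof, "group_sizes"), c(c01 = 1L, c02 = 2L))
})

test_that("scaling regression recovers exact planted proportions", {
  # groups with every category at exact share 1/8 -> slope 0.125, R^2 1
  sizes <- c(40, 80, 160, 240)
  gt <- data.frame(
    gene_id = sprintf("g%03d", seq_len(sum(sizes))),
    category = unlist(lapply(sizes, function(n) rep(sprintf("f%d", 1:8), n / 8))),
    is_phylo = FALSE, taxon = "", stringsAsFactors = FALSE)
  assign <- setNames(rep(sprintf("m%02d", 1:4), sizes), gt$gene_id)
  fit <- scaling_regression(functional_profile(assign, gt))
  expect_equal(fit$per_category$slope, rep(0.125, 8), tolerance = 1e-12)
  expect_equal(fit$per_category$r_squared, rep(1, 8), tolerance = 1e-12)
  expect_equal(fit$pooled_slope, 0.125, tolerance = 1e-12)

  # a category absent everywhere: slope 0, flagged degenerate
  gt2 <- rbind(gt, data.frame(gene_id = "gX", category = "absent",
                              is_phylo = FALSE, taxon = ""))
  fit2 <- scaling_regression(functional_profile(assign, gt2))
  ab <- fit2$per_category[fit2$per_category$category == "absent", ]
  expect_equal(ab$slope, 0)
  expect_true(ab$degenerate)

  few <- functional_profile(setNames(rep("m01", nrow(gt)), gt$gene_id), gt)
  expect_error(scaling_regression(few), class = "gfn_parameter_error")
})

test_that("site distribution is the detected fraction with column equivariance", {
  pres <- tiny_presence()[1:4, ]
  assign <- setNames(c("m01", "m01", "m02", "m02"), rownames(pres))
  d <- site_distribution(assign, pres)
  expect_equal(d["m01", "S1"], 1)      # g1,g2 both present at S1
  expect_equal(d["m01", "S3"], 0)
  expect_equal(d["m02", "S3"], 1)
  perm <- c(3, 1, 4, 2)
  d2 <- site_distribution(assign, pres[, perm])
  expect_equal(d2, d[, perm])
})

test_that("rank-sum homogeneity test reproduces the exact enumeration value", {
  # fully separated samples of 3 vs 3: the exact two-sided p is
  # 2 / choose(6, 3) = 0.1
  res <- homogeneity_test(c(1, 2, 3), c(10, 11, 12))
  expect_equal(res$p_value, 0.1)
  # symmetric in its arguments
  res_sw <- homogeneity_test(c(10, 11, 12), c(1, 2, 3))
  expect_equal(res_sw$p_value, res$p_value)
  # identical samples sit at the null centre
  res_id <- homogeneity_test(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(res_id$p_value, 1)
  # all values tied: uninformative, flagged
  res_tied <- homogeneity_test(rep(2, 4), rep(2, 5))
  expect_equal(res_tied$p_value, 1)
  expect_true(res_tied$tie_flag)
})

test_that("Holm adjustment matches the closed form and the reference oracle", {
  expect_equal(holm_adjust(c(0.01, 0.02, 0.04)), c(0.03, 0.04, 0.04))
  for (s in 1:25) {
    set.seed(s)
    m <- sample(1:50, 1)
    p <- runif(m)
    got <- holm_adjust(p)
    expect_equal(got, p.adjust(p, method = "holm"))
    expect_true(all(got >= p))
    expect_true(all(diff(got[order(p)]) >= -1e-15))  # monotone in raw order
  }
})

test_that("pairwise Welch tests with Holm control behave on degenerate input", {
  set.seed(5)
  vals <- list(S1 = rnorm(8), S2 = rnorm(8), S3 = rnorm(8) + 3)
  res <- pairwise_site_tests(vals)
  expect_true(all(res$p_adjusted >= res$p_raw, na.rm = TRUE))
  expect_true(res$significant["S1", "S3"])
  expect_false(res$significant["S1", "S2"])
  # identical constant samples: p = 1, flagged, never significant
  same <- list(S1 = rep(1, 4), S2 = rep(1, 4), S3 = rep(1, 4))
  res2 <- pairwise_site_tests(same)
  expect_true(all(res2$p_adjusted[upper.tri(res2$p_adjusted)] == 1))
  expect_equal(length(res2$degenerate_pairs), 3L)
  expect_error(pairwise_site_tests(vals[1]), class = "gfn_parameter_error")
})

test_that("phylo-functional correlation computes r, t-based p and flags", {
  sites <- sprintf("S%02d", 1:10)
  f <- rbind(fa = seq(0.1, 1, length.out = 10), fb = runif(10))
  colnames(f) <- sites
  p <- rbind(pa = f["fa", ], pb = rep(0.5, 10))
  colnames(p) <- sites
  rep <- phylo_functional_correlation(f, p)
  expect_equal(rep$r["fa", "pa"], 1)
  expect_true(rep$significant["fa", "pa"])
  expect_true(is.na(rep$r["fa", "pb"]))      # constant vector: undefined
  expect_false(rep$significant["fa", "pb"])
  # p agrees with cor.test on a nondegenerate cell
  ct <- cor.test(f["fb", ], p["pa", ])
  expect_equal(rep$p["fb", "pa"], ct$p.value)
  expect_error(phylo_functional_correlation(f[, 1:3], p[, 1:3]),
               class = "gfn_insufficient_data_error")
})
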