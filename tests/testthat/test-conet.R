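test_that("co-occurrence linking applies the symmetric conditional rule", {
  p <- matrix(0, 3, 10,
              dimnames = list(c("gi", "gj", "gk"), sprintf("S%02d", 1:10)))
  p["gi", 1:5] <- 1      # i present at s1..s5
  p["gj", 1:4] <- 1      # j at s1..s4: P(j|i)=0.8, P(i|j)=1.0 -> linked
  p["gk", 1:3] <- 1      # k at s1..s3: P(k|i)=0.6 -> not linked to i
  el <- cooccurrence_links(p, frac = 0.8)
  key <- paste(el$gene_a, el$gene_b)
  expect_true("gi gj" %in% key)
  expect_false("gi gk" %in% key)
  expect_false("gj gk" %in% key) # P(k|j) = 3/4 < 0.8 -> excluded
})

test_that("identical site sets are always linked; threshold is monotone", {
  set.seed(3)
  p <- random_presence(40, 10, p = 0.5, seed = 3)
  p <- p[rowSums(p) > 0, ]
  p <- rbind(p, twin = p[1, ])
  el1 <- cooccurrence_links(p, frac = 1)
  expect_true(paste(sort(c(rownames(p)[1], "twin")), collapse = " ") %in%
              paste(el1$gene_a, el1$gene_b))
  el08 <- cooccurrence_links(p, frac = 0.8)
  expect_true(all(paste(el1$gene_a, el1$gene_b) %in%
                  paste(el08$gene_a, el08$gene_b)))
  # directional rule is a superset of the symmetric rule
  eld <- cooccurrence_links(p, frac = 0.8, rule = "directional")
  expect_true(all(paste(el08$gene_a, el08$gene_b) %in%
                  paste(eld$gene_a, eld$gene_b)))
})

test_that("profile correlation matches hand-computed Pearson values", {
  m <- rbind(a = c(1, 0, 1, 0),
             b = c(1, 1, 0, 0),
             a2 = c(1, 0, 1, 0),
             comp = c(0, 1, 0, 1),
             flat = c(1, 1, 1, 1))
  colnames(m) <- paste0("S", 1:4)
  r <- profile_correlation(m)
  expect_equal(r["a", "a2"], 1)
  expect_equal(r["a", "comp"], -1)
  expect_equal(r["a", "b"], 0)        # hand: cov = 1/4 - 1/2*1/2 = 0
  expect_equal(unname(r["flat", "a"]), 0)  # zero-variance row zeroed
  expect_equal(attr(r, "flagged"), "flat")
  expect_error(profile_correlation(m[, 1:2]), class = "gfn_parameter_error")
})

test_that("soft adjacency is |r|^power with excluded diagonal", {
  r <- matrix(c(1, -0.5, 0, -0.5, 1, 1, 0, 1, 1), 3, 3)
  a <- soft_adjacency(r, 10)
  expect_equal(a[1, 2], 0.5^10)
  expect_equal(a[1, 3], 0)
  expect_equal(a[2, 3], 1)
  expect_equal(diag(a), rep(0, 3))
  expect_error(soft_adjacency(r, 0), class = "gfn_parameter_error")
})

test_that("scale-free fit separates preferential-attachment from random graphs", {
  skip_if_not_installed("igraph")
  set.seed(21)
  ba <- igraph::as_adjacency_matrix(igraph::sample_pa(300, m = 2,
                                                      directed = FALSE),
                                    sparse = FALSE)
  er <- igraph::as_adjacency_matrix(igraph::sample_gnp(300, 0.05),
                                    sparse = FALSE)
  # treat the 0/1 graph as a degenerate "correlation" so power 1 keeps it
  scan_ba <- soft_threshold_scan(ba, powers = 1)
  scan_er <- soft_threshold_scan(er, powers = 1)
  expect_gte(scan_ba$table$fit_r2[1], 0.8)
  expect_lt(scan_er$table$fit_r2[1], 0.5)
  # single power: selected equals it when fit qualifies, else fallback 10
  expect_equal(scan_ba$selected_power, 1)
  expect_equal(scan_er$selected_power, 10)
  expect_error(soft_threshold_scan(ba, powers = numeric(0)),
               class = "gfn_parameter_error")
})

test_that("topological overlap matches direct scalar evaluation", {
  a <- matrix(c(0, .5, .2,
                .5, 0, .4,
                .2, .4, 0), 3, 3)
  tom <- topological_overlap(a)
  # independent scalar evaluation of the formula for the 1-2 entry
  expect_equal(tom[1, 2], (0.2 * 0.4 + 0.5) / (min(0.7, 0.9) + 1 - 0.5))
  expect_equal(diag(tom), rep(1, 3))

  # limits: identical neighbourhoods with a_ij = 1 give TOM = 1
  b <- matrix(1, 4, 4); diag(b) <- 0
  expect_equal(topological_overlap(b)[1, 2], 1)
  # no direct link, no shared neighbours: TOM = 0
  c2 <- matrix(0, 4, 4); c2[1, 2] <- c2[2, 1] <- 0   # isolated pair
  c2[3, 4] <- c2[4, 3] <- 1
  expect_equal(topological_overlap(c2)[1, 2], 0)
})

test_that("TOM is symmetric with entries in [0,1] on random adjacencies", {
  for (s in 1:10) {
    a <- random_adjacency(12, seed = s)
    tom <- topological_overlap(a)
    expect_equal(tom, t(tom))
    expect_true(all(tom >= 0 & tom <= 1))
    expect_equal(diag(tom), rep(1, 12), ignore_attr = TRUE)
  }
})

test_that("module detection separates perfect blocks and pools small branches", {
  n1 <- 15; n2 <- 12
  tom <- matrix(0, n1 + n2, n1 + n2)
  tom[1:n1, 1:n1] <- 1
  tom[(n1 + 1):(n1 + n2), (n1 + 1):(n1 + n2)] <- 1
  dimnames(tom) <- list(sprintf("g%02d", 1:(n1 + n2)),
                        sprintf("g%02d", 1:(n1 + n2)))
  m <- detect_modules(tom, min_module_size = 10)
  expect_equal(length(setdiff(unique(m), "unassigned")), 2L)
  expect_equal(unname(m[1]), "m01")    # larger block gets the first label
  expect_true(all(m[1:n1] == "m01") && all(m[(n1 + 1):(n1 + n2)] == "m02"))

  # a 5-gene branch below min_module_size 10 becomes unassigned
  tom5 <- matrix(0, 20, 20); tom5[1:15, 1:15] <- 1; tom5[16:20, 16:20] <- 1
  dimnames(tom5) <- list(sprintf("g%02d", 1:20), sprintf("g%02d", 1:20))
  m5 <- detect_modules(tom5, min_module_size = 10)
  expect_true(all(m5[16:20] == "unassigned"))
})

test_that("module detection is invariant to gene order and recovers planted blocks", {
  cfg <- sim_config(n_genes = 400, n_modules = 5, n_marker_genes = 30,
                    n_taxa = 10, noise_flip_rate = 0.05, seed = 5)
  sim <- generate_community(cfg)
  fp <- binarize(sim$signal)[!sim$gene_table$is_phylo, ]
  tom <- topological_overlap(soft_adjacency(profile_correlation(fp), 10))
  m <- detect_modules(tom, 10, refine_with = fp)
  ari <- mclust::adjustedRandIndex(m, sim$truth$module[names(m)])
  expect_gte(ari, 0.9)

  perm <- sample(nrow(tom))
  m_perm <- detect_modules(tom[perm, perm], 10, refine_with = fp[perm, ])
  # same partition up to label names
  expect_equal(mclust::adjustedRandIndex(m_perm[names(m)], m), 1)
})

test_that("eigengenes equal the leading singular vector and orient positively", {
  set.seed(8)
  x <- matrix(rnorm(10 * 8), 10, 8,
              dimnames = list(sprintf("g%02d", 1:10), sprintf("S%02d", 1:8)))
  assign <- setNames(rep("m01", 10), rownames(x))
  eg <- module_eigengene(x, assign)
  xs <- t(scale(t(x)))
  v_oracle <- svd(xs)$v[, 1]
  got <- unname(eg$m01$vector)
  expect_equal(abs(sum(got * v_oracle)), 1, tolerance = 1e-8)  # same axis
  expect_equal(sqrt(sum(got^2)), 1)
  cors <- apply(xs, 1, function(g) cor(g, got))
  expect_gte(mean(cors), 0)

  # rank-1 module: explained variance exactly 1
  base <- rnorm(8)
  x1 <- rbind(a = 2 * base + 3, b = -1 * base, c = 0.5 * base + 1)
  colnames(x1) <- sprintf("S%02d", 1:8)
  eg1 <- module_eigengene(x1, setNames(rep("m01", 3), rownames(x1)))
  expect_equal(eg1$m01$explained_variance, 1)

  xc <- rbind(a = rep(1, 8), b = rnorm(8))
  colnames(xc) <- sprintf("S%02d", 1:8)
  expect_error(module_eigengene(xc, setNames(rep("m01", 2), rownames(xc))),
               class = "gfn_degenerate_module_error")
})

test_that("topology report flags hub-dominated graphs as non-ER", {
  n <- 51
  star <- matrix(0, n, n); star[1, 2:n] <- 1; star[2:n, 1] <- 1
  dimnames(star) <- list(sprintf("g%02d", 1:n), sprintf("g%02d", 1:n))
  assign <- setNames(rep("m01", n), rownames(star))
  rep1 <- topology_report(star, assign, tau = 0.5)
  expect_gt(rep1$degree_vmr, 2)
  expect_false(rep1$classification == "ER-like")
  # modules with fewer than 5 genes are skipped
  tiny <- setNames(c(rep("m01", n - 3), rep("m02", 3)), rownames(star))
  expect_message(rep2 <- topology_report(star, tiny, tau = 0.5), "skipped")
  expect_equal(rep2$module, "m01")
})
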