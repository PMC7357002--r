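# Functional-representation statistics: how functional categories
# distribute over network modules, KMeans++ clusters and sites, whether
# that distribution is even, and how per-category gene counts scale with
# group size.

# Normalize the three supported group sources into a named list:
# group label -> character vector of member gene ids.
group_members <- function(groups) {
  if (inherits(groups, "cluster_assignment")) {
    labels <- sort(unique(unlist(groups$membership)))
    out <- lapply(labels, function(l)
      names(groups$membership)[vapply(groups$membership,
                                      function(m) l %in% m, logical(1))])
    names(out) <- labels
    return(out)
  }
  if (is.matrix(groups)) {                      # presence matrix: sites as groups
    out <- lapply(colnames(groups), function(s)
      rownames(groups)[groups[, s] != 0])
    names(out) <- colnames(groups)
    return(out)
  }
  if (is.character(groups) && !is.null(names(groups))) {   # module assignment
    labels <- setdiff(sort(unique(groups)), "unassigned")
    out <- lapply(labels, function(l) names(groups)[groups == l])
    names(out) <- labels
    return(out)
  }
  gfn_stop("gfn_parameter_error", "unsupported group specification")
}

#' Functional profile of gene groups
#'
#' For every group (network module, KMeans++ cluster, or site) and every
#' functional category: the raw gene count, the standardized
#' representation (count divided by the category's total gene count on the
#' array) and the composition share (count divided by group size).
#' Multi-membership genes count once in every owning group.
#'
#' @param groups A module assignment (named character vector), a
#'   `cluster_assignment`, or a binary presence matrix (sites as groups).
#' @param gene_table Gene table annotating all assigned genes.
#' @return data.frame of class `functional_profile` with columns `group`,
#'   `category`, `count`, `standardized`, `share`, plus a `group_sizes`
#'   attribute.
#' @export
functional_profile <- function(groups, gene_table) {
  members <- group_members(groups)
  # phylogenetic marker probes are not functional categories; counting
  # their always-empty category would deflate the pooled scaling slope
  gene_table <- gene_table[!gene_table$is_phylo, , drop = FALSE]
  cats <- sort(unique(gene_table$category))
  cat_sizes <- table(factor(gene_table$category, levels = cats))
  if (any(cat_sizes == 0))
    gfn_stop("gfn_division_guard_error", "category with zero array genes: %s",
             paste(names(cat_sizes)[cat_sizes == 0], collapse = ", "))
  cat_of <- stats::setNames(gene_table$category, gene_table$gene_id)
  rows <- lapply(names(members), function(g) {
    genes <- members[[g]]
    if (anyNA(cat_of[genes]))
      gfn_stop("gfn_crossref_error", "group %s has unannotated gene(s)", g)
    counts <- table(factor(cat_of[genes], levels = cats))
    data.frame(group = g, category = cats,
               count = as.integer(counts),
               standardized = as.integer(counts) / as.integer(cat_sizes),
               share = if (length(genes) > 0)
                 as.integer(counts) / length(genes) else 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "group_sizes") <- vapply(members, length, integer(1))
  class(out) <- c("functional_profile", "data.frame")
  out
}

#' Scaling of per-category gene counts with group size
#'
#' Ordinary least squares of the per-group gene count of each category on
#' the total gene count of the group, across groups. When functional
#' categories are represented at a common proportion in every group, each
#' per-category slope equals that proportion and the fits are nearly
#' perfect; the pooled slope (one OLS over all category-group points)
#' summarizes the common share.
#'
#' @param profile A `functional_profile` over >= 3 groups.
#' @return List of class `scaling_fit`: `per_category` data.frame
#'   (category, slope, intercept, r_squared, degenerate flag) and
#'   `pooled_slope`.
#' @export
scaling_regression <- function(profile) {
  sizes <- attr(profile, "group_sizes")
  if (length(sizes) < 3)
    gfn_stop("gfn_parameter_error", "need at least 3 groups")
  if (stats::var(sizes) == 0)
    gfn_stop("gfn_degenerate_regressor_error", "all groups have equal size")
  totals <- sizes[profile$group]
  per_cat <- lapply(split(seq_len(nrow(profile)), profile$category),
                    function(idx) {
    y <- profile$count[idx]; x <- totals[idx]
    if (stats::var(y) == 0) {
      return(data.frame(category = profile$category[idx][1],
                        slope = 0, intercept = y[1], r_squared = 0,
                        degenerate = TRUE, stringsAsFactors = FALSE))
    }
    fit <- stats::lm(y ~ x)
    # R^2 from the residuals directly; summary.lm warns on perfect fits
    r2 <- 1 - sum(stats::resid(fit)^2) / sum((y - mean(y))^2)
    data.frame(category = profile$category[idx][1],
               slope = unname(stats::coef(fit)[2]),
               intercept = unname(stats::coef(fit)[1]),
               r_squared = r2,
               degenerate = FALSE, stringsAsFactors = FALSE)
  })
  per_cat <- do.call(rbind, per_cat)
  rownames(per_cat) <- NULL
  pooled <- stats::lm(profile$count ~ totals)
  structure(list(per_category = per_cat,
                 pooled_slope = unname(stats::coef(pooled)[2]),
                 pooled_intercept = unname(stats::coef(pooled)[1])),
            class = "scaling_fit")
}

#' @export
print.scaling_fit <- function(x, ...) {
  cat("Scaling of per-category gene counts with group size\n")
  cat(sprintf("pooled slope (common share): %.4f\n", x$pooled_slope))
  cat(sprintf("per-category R^2: %.3f - %.3f\n",
              min(x$per_category$r_squared[!x$per_category$degenerate]),
              max(x$per_category$r_squared[!x$per_category$degenerate])))
  invisible(x)
}

#' Per-group site distribution
#'
#' For each group, the fraction of its genes detected at each site — the
#' geographic footprint of a module or cluster on the unit scale.
#'
#' @param groups Module assignment or `cluster_assignment`.
#' @param presence Binary gene-by-site matrix covering the assigned genes.
#' @return Group-by-site numeric matrix in \[0, 1\]; empty groups are
#'   dropped with a message.
#' @export
site_distribution <- function(groups, presence) {
  members <- group_members(groups)
  empty <- names(members)[lengths(members) == 0]
  if (length(empty) > 0) {
    message("empty group(s) excluded: ", paste(empty, collapse = ", "))
    members <- members[lengths(members) > 0]
  }
  out <- t(vapply(members, function(genes)
    colMeans(presence[genes, , drop = FALSE] != 0), numeric(ncol(presence))))
  colnames(out) <- colnames(presence)
  out
}

#' Wilcoxon rank-sum homogeneity test
#'
#' Two-sided rank-sum test of whether two samples of representation values
#' (e.g. per-category shares at Arctic vs Antarctic sites) come from the
#' same distribution. Exact p-values for combined sample sizes up to 20
#' without ties; normal approximation with tie correction otherwise. When
#' every value is tied across both samples the test is uninformative and
#' p = 1 is returned with `tie_flag`.
#'
#' @param x,y Numeric samples, each of length >= 3.
#' @return List: `statistic` (rank-sum W), `p_value`, `tie_flag`.
#' @export
homogeneity_test <- function(x, y) {
  if (length(x) < 3 || length(y) < 3)
    gfn_stop("gfn_parameter_error", "each sample needs >= 3 values")
  if (length(unique(c(x, y))) == 1L)
    return(list(statistic = length(x) * length(y) / 2, p_value = 1,
                tie_flag = TRUE))
  ties <- any(duplicated(c(x, y)))
  exact <- (length(x) + length(y) <= 20) && !ties
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = !exact))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       tie_flag = ties)
}

#' Holm step-down adjustment
#'
#' Classic step-down multiple-testing correction: with raw p-values sorted
#' ascending, the i-th adjusted value is the running maximum of
#' `min(1, (m - j + 1) * p_j)` over `j <= i`.
#'
#' @param p Numeric vector of raw p-values.
#' @return Adjusted p-values in the original order.
#' @export
holm_adjust <- function(p) {
  m <- length(p)
  if (m == 0) return(numeric(0))
  o <- order(p)
  adj <- pmin(1, (m - seq_len(m) + 1) * p[o])
  adj <- cummax(adj)
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Pairwise Welch tests across sites with Holm adjustment
#'
#' Welch two-sample t-tests for every pair of sites (unequal variances not
#' assumed away), with Holm step-down adjustment over all pairs. A pair in
#' which both samples have zero variance gets p = 1 and a flag.
#'
#' @param values_by_site Named list of numeric vectors (>= 2 values each),
#'   one per site.
#' @param alpha Significance level for the flags (default 0.05).
#' @return List: `p_adjusted` (symmetric site-by-site matrix), `p_raw`,
#'   `significant` (logical matrix), `degenerate_pairs`.
#' @export
pairwise_site_tests <- function(values_by_site, alpha = 0.05) {
  sites <- names(values_by_site)
  ns <- length(sites)
  if (ns < 2) gfn_stop("gfn_parameter_error", "need >= 2 sites")
  if (any(lengths(values_by_site) < 2))
    gfn_stop("gfn_parameter_error", "each site needs >= 2 values")
  pairs <- utils::combn(ns, 2)
  degen <- character(0)
  p_raw <- apply(pairs, 2, function(pr) {
    a <- values_by_site[[pr[1]]]; b <- values_by_site[[pr[2]]]
    if (stats::var(a) == 0 && stats::var(b) == 0) {
      degen <<- c(degen, paste(sites[pr[1]], sites[pr[2]], sep = ":"))
      return(1)
    }
    stats::t.test(a, b, var.equal = FALSE)$p.value
  })
  p_adj <- holm_adjust(p_raw)
  mk <- function(v) {
    m <- matrix(NA_real_, ns, ns, dimnames = list(sites, sites))
    for (j in seq_len(ncol(pairs))) {
      m[pairs[1, j], pairs[2, j]] <- v[j]
      m[pairs[2, j], pairs[1, j]] <- v[j]
    }
    m
  }
  list(p_adjusted = mk(p_adj), p_raw = mk(p_raw),
       significant = mk(p_adj) < alpha, degenerate_pairs = degen)
}

#' Correlation of phylogenetic and functional module distributions
#'
#' Tests whether the geographic distribution of functional modules follows
#' that of phylogenetic (marker-gene) modules: all pairwise Pearson
#' correlations between functional-module and phylogenetic-module site
#' vectors, with two-sided Student t-tests
#' (`t = r * sqrt((n - 2) / (1 - r^2))`, n - 2 degrees of freedom) flagged
#' at `alpha`. Pairs involving a zero-variance vector are undefined (NA,
#' not flagged).
#'
#' @param func_dist Functional-module by site matrix
#'   (see [site_distribution()]).
#' @param phylo_dist Phylogenetic-module by site matrix, same sites,
#'   >= 4 sites.
#' @param alpha Significance level (default 0.05).
#' @return List of class `correlation_report`: `r`, `p`, `significant`
#'   matrices (functional modules x phylogenetic modules), `n_sites`.
#' @export
phylo_functional_correlation <- function(func_dist, phylo_dist,
                                         alpha = 0.05) {
  if (!identical(colnames(func_dist), colnames(phylo_dist)))
    gfn_stop("gfn_parameter_error", "site sets differ")
  n <- ncol(func_dist)
  if (n < 4)
    gfn_stop("gfn_insufficient_data_error", "need >= 4 sites, got %d", n)
  nf <- nrow(func_dist); np <- nrow(phylo_dist)
  r <- matrix(NA_real_, nf, np,
              dimnames = list(rownames(func_dist), rownames(phylo_dist)))
  for (i in seq_len(nf)) for (j in seq_len(np)) {
    fi <- func_dist[i, ]; pj <- phylo_dist[j, ]
    if (stats::var(fi) == 0 || stats::var(pj) == 0) next
    r[i, j] <- stats::cor(fi, pj)
  }
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  structure(list(r = r, p = p, significant = !is.na(p) & p < alpha,
                 n_sites = n, alpha = alpha),
            class = "correlation_report")
}
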