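# Co-occurrence network construction and module detection.
#
# The flow mirrors weighted correlation network analysis adapted to
# presence/absence gene profiles over a small number of sites: Pearson
# correlation between gene profiles, soft-threshold (power) adjacency,
# topological overlap, average-linkage clustering of 1 - TOM with a static
# tree cut, and per-module eigengenes. A direct conditional co-occurrence
# linking rule (genes linked when each is found in >= 80% of the other's
# sites) is provided alongside the TOM flow.

#' Conditional co-occurrence links
#'
#' Links gene pairs that co-occur in a high fraction of their detection
#' sites. Under the default symmetric rule, genes i and j are linked iff
#' `#sites(both)/#sites(i) >= frac` AND `#sites(both)/#sites(j) >= frac`.
#' With `rule = "directional"` a single direction
#' (`#sites(both)/#sites(i) >= frac` for either i or j) suffices.
#' Genes detected nowhere are excluded (with a message, not an error).
#'
#' @param presence Binary gene-by-site matrix.
#' @param frac Co-occurrence fraction threshold in (0, 1], default 0.8.
#' @param rule `"symmetric"` (default) or `"directional"`.
#' @return A data.frame link set with columns `gene_a`, `gene_b`, `weight`
#'   (the smaller of the two conditional fractions), each unordered pair
#'   once, `gene_a < gene_b`.
#' @export
cooccurrence_links <- function(presence, frac = 0.8,
                               rule = c("symmetric", "directional")) {
  rule <- match.arg(rule)
  if (frac <= 0 || frac > 1)
    gfn_stop("gfn_parameter_error", "frac must be in (0, 1]")
  p <- (presence != 0) * 1
  n_pres <- rowSums(p)
  if (any(n_pres == 0)) {
    message(sum(n_pres == 0), " gene(s) never present; excluded from linking")
    p <- p[n_pres > 0, , drop = FALSE]
    n_pres <- n_pres[n_pres > 0]
  }
  both <- tcrossprod(p)                      # sites where both present
  fi <- both / n_pres                        # row i: both / #sites(i)
  fj <- t(fi)
  keep <- if (rule == "symmetric") fi >= frac & fj >= frac
          else fi >= frac | fj >= frac
  diag(keep) <- FALSE
  idx <- which(keep & upper.tri(keep), arr.ind = TRUE)
  genes <- rownames(p)
  el <- data.frame(
    gene_a = genes[idx[, 1]],
    gene_b = genes[idx[, 2]],
    weight = pmin(fi[idx], fj[idx]),
    stringsAsFactors = FALSE
  )
  swap <- el$gene_a > el$gene_b
  tmp <- el$gene_a[swap]; el$gene_a[swap] <- el$gene_b[swap]; el$gene_b[swap] <- tmp
  el[order(el$gene_a, el$gene_b), , drop = FALSE]
}

#' Pairwise profile correlation
#'
#' Pearson correlation between gene site-profiles (rows) computed across
#' sites. Rows with zero variance cannot be correlated: their rows and
#' columns are set to 0 and the gene ids returned in the `"flagged"`
#' attribute so they can be excluded from adjacency.
#'
#' @param mat Gene-by-site matrix (binary presence or real signal), >= 3 sites.
#' @return Symmetric correlation matrix, diagonal 1, attribute `flagged`
#'   listing zero-variance genes.
#' @export
profile_correlation <- function(mat) {
  if (ncol(mat) < 3)
    gfn_stop("gfn_parameter_error", "need at least 3 sites for correlations")
  v <- apply(mat, 1, stats::var)
  flagged <- rownames(mat)[v == 0]
  r <- suppressWarnings(stats::cor(t(mat)))
  r[is.na(r)] <- 0
  diag(r) <- 1
  attr(r, "flagged") <- flagged
  r
}

#' Soft-threshold adjacency
#'
#' Unsigned weighted adjacency `a_ij = |r_ij|^power`. Raising correlations
#' to a power suppresses weak, noise-driven correlations while preserving
#' the ranking of strong ones (soft thresholding). Zero-variance genes
#' flagged by [profile_correlation()] get zero adjacency.
#'
#' @param corr Correlation matrix from [profile_correlation()].
#' @param power Soft threshold power (integer >= 1), default 10.
#' @return Symmetric adjacency matrix in \[0, 1\], diagonal 0.
#' @export
soft_adjacency <- function(corr, power = 10) {
  if (!is.numeric(power) || power < 1)
    gfn_stop("gfn_parameter_error", "power must be >= 1")
  a <- abs(corr)^power
  flagged <- attr(corr, "flagged")
  if (length(flagged) > 0) {
    a[flagged, ] <- 0
    a[, flagged] <- 0
  }
  diag(a) <- 0
  a
}

# Scale-free topology fit index: R^2 of log10(frequency) on log10(mean k)
# over equal-width connectivity bins (degree-distribution linearity on
# log-log axes). Returns 0 when fewer than 3 usable bins.
scale_free_fit <- function(k, n_bins = 10) {
  k <- k[k > 0]
  if (length(k) < 3 || diff(range(k)) == 0) return(0)
  cuts <- cut(k, breaks = n_bins)
  freq <- tapply(k, cuts, length)
  mean_k <- tapply(k, cuts, mean)
  ok <- !is.na(freq) & freq > 0 & mean_k > 0
  if (sum(ok) < 3) return(0)
  fit <- stats::lm(log10(freq[ok]) ~ log10(mean_k[ok]))
  summary(fit)$r.squared
}

#' Soft-threshold power scan
#'
#' For each candidate power, computes the connectivity distribution of the
#' resulting adjacency and its scale-free topology fit index (R^2 of the
#' log-log degree-frequency regression over binned connectivities). The
#' selected power is the lowest with fit R^2 >= `r2_cut`; when none
#' qualifies the configured fallback (default 10) is used.
#'
#' @param corr Correlation matrix.
#' @param powers Ascending vector of candidate powers.
#' @param r2_cut Scale-free fit threshold for selection (default 0.8).
#' @param fallback Power used when no candidate reaches `r2_cut` (default 10).
#' @return List with `table` (data.frame: power, fit_r2, mean_connectivity)
#'   and `selected_power`.
#' @export
soft_threshold_scan <- function(corr, powers = c(1:10, 12, 14, 16),
                                r2_cut = 0.8, fallback = 10) {
  if (length(powers) == 0 || is.unsorted(powers))
    gfn_stop("gfn_parameter_error", "powers must be nonempty and ascending")
  rows <- lapply(powers, function(p) {
    a <- soft_adjacency(corr, p)
    k <- rowSums(a)
    data.frame(power = p,
               fit_r2 = scale_free_fit(k),
               mean_connectivity = mean(k),
               all_isolated = all(k == 0))
  })
  tab <- do.call(rbind, rows)
  hit <- tab$power[tab$fit_r2 >= r2_cut]
  list(table = tab,
       selected_power = if (length(hit) > 0) hit[1] else fallback)
}

#' Topological overlap matrix
#'
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` for
#' i != j, with connectivity `k_i = sum_j a_ij`; `TOM_ii = 1`. Two genes
#' have high topological overlap when they are directly linked and share
#' many neighbours, which is more robust to single spurious correlations
#' than raw adjacency.
#'
#' @param adj Symmetric adjacency matrix in \[0, 1\] (diagonal ignored).
#' @return Symmetric TOM matrix in \[0, 1\], diagonal 1.
#' @export
topological_overlap <- function(adj) {
  a <- adj
  diag(a) <- 0
  k <- rowSums(a)
  shared <- crossprod(a)            # sum_u a_iu a_uj (a symmetric)
  kmin <- outer(k, k, pmin)
  tom <- (shared + a) / (kmin + 1 - a)
  diag(tom) <- 1
  # guard tiny negative / >1 from floating point
  tom[tom < 0] <- 0
  tom[tom > 1] <- 1
  dimnames(tom) <- dimnames(adj)
  tom
}

#' Detect co-occurrence modules
#'
#' Average-linkage hierarchical clustering of the topological-overlap
#' dissimilarity `1 - TOM`, with a static cut at `cut_height` times the
#' dendrogram height. Branches smaller than `min_module_size` are pooled
#' into the reserved label `"unassigned"`. Module labels are deterministic:
#' `m01`, `m02`, ... in decreasing size order (ties broken by first gene
#' position).
#'
#' With `refine_with` (a gene-by-site matrix over the same genes), the
#' static cut is followed by a consensus-profile refinement: each module's
#' mean site-profile is computed and every gene is reassigned to the
#' module with the nearest (squared Euclidean) consensus profile, iterated
#' to a fixed point (at most `max_refine` passes). With only ~10 sites the
#' dendrogram resolves the module structure reliably but the leaf
#' placement of individually noise-corrupted genes is unstable; the
#' refinement polishes exactly those memberships.
#'
#' @param tom TOM matrix from [topological_overlap()].
#' @param min_module_size Smallest reportable module (default 10).
#' @param cut_height Cut as a fraction of the maximum merge height
#'   (default 0.95).
#' @param refine_with Optional gene-by-site matrix (presence or signal)
#'   enabling consensus-profile membership refinement.
#' @param max_refine Maximum refinement passes (default 5).
#' @return Named character vector: gene id to module label.
#' @export
detect_modules <- function(tom, min_module_size = 10, cut_height = 0.95,
                           refine_with = NULL, max_refine = 5) {
  genes <- rownames(tom)
  n <- nrow(tom)
  if (n < min_module_size) {
    warning("fewer genes than min_module_size; all unassigned")
    out <- rep("unassigned", n); names(out) <- genes
    return(out)
  }
  d <- stats::as.dist(1 - tom)
  tree <- stats::hclust(d, method = "average")
  # average linkage is monotone; repair sub-epsilon float inversions
  tree$height <- cummax(tree$height)
  h <- cut_height * max(tree$height)
  raw <- stats::cutree(tree, h = h)
  lab <- pool_small_branches(as.character(raw), min_module_size)
  names(lab) <- genes
  if (!is.null(refine_with)) {
    x <- refine_with[genes, , drop = FALSE] * 1.0
    for (pass in seq_len(max_refine)) {
      mods <- setdiff(sort(unique(lab)), "unassigned")
      if (length(mods) < 2) break
      prof <- t(vapply(mods, function(m)
        colMeans(x[lab == m, , drop = FALSE]), numeric(ncol(x))))
      d2 <- sq_dist_to_centroids(x, prof)
      new <- mods[apply(d2, 1, which.min)]
      names(new) <- genes
      if (all(new == lab)) break
      lab <- new
    }
    lab <- pool_small_branches(lab, min_module_size)
    names(lab) <- genes
  }
  lab
}

# Pool branches below the size threshold into "unassigned" and relabel
# deterministically: m01, m02, ... by decreasing size, ties broken by
# first occurrence.
pool_small_branches <- function(raw, min_module_size) {
  sizes <- table(raw)
  keep <- setdiff(names(sizes)[sizes >= min_module_size], "unassigned")
  lab <- rep("unassigned", length(raw))
  if (length(keep) > 0) {
    first_pos <- vapply(keep, function(cl) min(which(raw == cl)), integer(1))
    ord <- keep[order(-sizes[keep], first_pos)]
    new_names <- sprintf("m%02d", seq_along(ord))
    for (i in seq_along(ord)) lab[raw == ord[i]] <- new_names[i]
  }
  lab
}

#' Module colour aliases
#'
#' Maps size-ranked module labels to the conventional colour names used in
#' weighted network analysis reports (`"unassigned"` maps to `"grey"`).
#'
#' @param labels Character vector of module labels (`m01`, ..., `"unassigned"`).
#' @return Character vector of colour names, same length.
#' @export
module_colors <- function(labels) {
  palette <- c("turquoise", "blue", "brown", "yellow", "green", "red",
               "black", "pink", "magenta", "purple", "greenyellow", "tan",
               "salmon", "cyan", "midnightblue", "lightcyan", "grey60",
               "lightgreen", "lightyellow", "royalblue", "darkred",
               "darkgreen", "darkturquoise", "darkgrey", "orange",
               "darkorange", "white", "skyblue", "saddlebrown", "steelblue")
  out <- rep("grey", length(labels))
  idx <- suppressWarnings(as.integer(sub("^m", "", labels)))
  ok <- !is.na(idx) & idx >= 1 & idx <= length(palette)
  out[ok] <- palette[idx[ok]]
  names(out) <- names(labels)
  out
}

#' Module eigengenes
#'
#' The eigengene of a module is the first principal component of the
#' site-profiles of its genes: gene rows are standardized to zero mean and
#' unit variance across sites, and the leading right singular vector gives
#' one value per site. The vector has unit norm and is sign-oriented so
#' that its mean correlation with the module's gene profiles is
#' nonnegative.
#'
#' @param mat Gene-by-site matrix (signal or presence) covering the
#'   assigned genes.
#' @param assignment Module assignment from [detect_modules()]
#'   (`"unassigned"` genes are skipped).
#' @return List of class `eigengene_set`: per module a list with `vector`
#'   (named per-site values) and `explained_variance`.
#' @export
module_eigengene <- function(mat, assignment) {
  mods <- setdiff(sort(unique(assignment)), "unassigned")
  out <- lapply(mods, function(m) {
    genes <- names(assignment)[assignment == m]
    if (length(genes) < 2)
      gfn_stop("gfn_parameter_error", "module %s has fewer than 2 genes", m)
    x <- mat[genes, , drop = FALSE]
    sds <- apply(x, 1, stats::sd)
    if (any(sds == 0))
      gfn_stop("gfn_degenerate_module_error",
               "module %s contains constant gene profiles", m)
    xs <- t(scale(t(x)))               # standardize rows across sites
    sv <- svd(xs, nu = 0, nv = 1)
    v <- sv$v[, 1]
    if (mean(apply(xs, 1, function(g) stats::cor(g, v))) < 0) v <- -v
    names(v) <- colnames(mat)
    list(vector = v,
         explained_variance = sv$d[1]^2 / sum(sv$d^2))
  })
  names(out) <- mods
  structure(out, class = "eigengene_set")
}

# Degree statistics and scale-free fit for one undirected simple graph
# given a 0/1 adjacency submatrix.
module_topology_stats <- function(bin_sub) {
  deg <- rowSums(bin_sub)
  mean_deg <- mean(deg)
  vmr <- if (mean_deg > 0) stats::var(deg) / mean_deg else 0
  r2 <- scale_free_fit(deg)
  label <- if (r2 >= 0.8 && vmr > 2) "scale-free-like"
           else if (r2 < 0.5 && vmr <= 2) "ER-like"
           else "indeterminate"
  list(n_genes = nrow(bin_sub), mean_degree = mean_deg,
       degree_vmr = vmr, fit_r2 = r2, classification = label)
}

#' Per-module topology report
#'
#' Classifies the internal wiring of each module on the binarized graph
#' (adjacency >= `tau`, or an explicit link set). A module is called
#' scale-free-like when its degree distribution is close to a power law
#' (fit R^2 >= 0.8) and heterogeneous (degree variance/mean > 2); ER-like
#' when the fit is poor (R^2 < 0.5) and degrees homogeneous
#' (variance/mean <= 2); otherwise indeterminate. Modules with fewer than
#' 5 genes are skipped with a message.
#'
#' @param adj Adjacency matrix, or a link-set data.frame
#'   (`gene_a`, `gene_b`, ...) as from [cooccurrence_links()].
#' @param assignment Module assignment on the same genes.
#' @param tau Binarization threshold on adjacency weights (default 0.1);
#'   ignored for link sets.
#' @return data.frame of class `topology_report`: module, n_genes,
#'   mean_degree, degree_vmr, fit_r2, classification.
#' @export
topology_report <- function(adj, assignment, tau = 0.1) {
  genes <- names(assignment)
  if (is.data.frame(adj)) {
    bin <- matrix(0, length(genes), length(genes),
                  dimnames = list(genes, genes))
    ia <- match(adj$gene_a, genes); ib <- match(adj$gene_b, genes)
    ok <- !is.na(ia) & !is.na(ib)
    bin[cbind(ia[ok], ib[ok])] <- 1
    bin[cbind(ib[ok], ia[ok])] <- 1
  } else {
    bin <- (adj >= tau) * 1
    diag(bin) <- 0
    bin <- bin[genes, genes, drop = FALSE]
  }
  mods <- setdiff(sort(unique(assignment)), "unassigned")
  rows <- list()
  for (m in mods) {
    g <- genes[assignment == m]
    if (length(g) < 5) {
      message("module ", m, " has fewer than 5 genes; skipped")
      next
    }
    st <- module_topology_stats(bin[g, g, drop = FALSE])
    rows[[m]] <- data.frame(module = m, n_genes = st$n_genes,
                            mean_degree = st$mean_degree,
                            degree_vmr = st$degree_vmr,
                            fit_r2 = st$fit_r2,
                            classification = st$classification,
                            stringsAsFactors = FALSE)
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(module = character(0), n_genes = integer(0),
               mean_degree = numeric(0), degree_vmr = numeric(0),
               fit_r2 = numeric(0), classification = character(0))
  rownames(out) <- NULL
  class(out) <- c("topology_report", "data.frame")
  out
}
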