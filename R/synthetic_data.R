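# Synthetic GeoChip-like communities with planted structure: genes
# partitioned into co-occurring modules with known site profiles, fixed
# functional composition within each module, phylogenetic marker blocks
# decoupled from the functional modules, and Bernoulli flip noise. Ground
# truth is returned next to the data so every pipeline stage can be
# validated without any array download.

# Integer apportionment by largest remainder: exact totals, exact planted
# shares wherever they are representable.
largest_remainder <- function(total, shares) {
  raw <- total * shares / sum(shares)
  base <- floor(raw)
  left <- total - sum(base)
  if (left > 0) {
    ord <- order(raw - base, decreasing = TRUE)
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  as.integer(base)
}

#' Simulation configuration
#'
#' Defines a synthetic functional-gene-array community. Genes are divided
#' into `n_modules` co-occurrence modules with sizes proportional to
#' geometric-decay weights `rho^i` (some modules much larger than others);
#' within each module the functional categories follow `category_shares`
#' exactly (largest-remainder apportionment). Each module is "on" at a
#' random subset of sites (distinct between modules, pairwise symmetric
#' difference >= 2, so planted modules are identifiable from 10 sites) and
#' every presence cell is flipped independently with `noise_flip_rate`.
#' Phylogenetic marker genes form separate blocks whose site profiles are
#' drawn independently of the functional modules.
#'
#' @param n_sites Number of sites (default 10).
#' @param n_genes Number of functional genes (default 5000).
#' @param n_categories Number of functional categories (default 10); used
#'   only when `category_shares` is unnamed/default.
#' @param category_shares Named numeric vector summing to 1 (default even).
#' @param n_modules Number of planted modules (default 12).
#' @param rho Geometric decay of module sizes in (0, 1) (default 0.8).
#' @param profile_size_range Range (min, max) of sites "on" per module
#'   profile (default c(4, 8)).
#' @param noise_flip_rate Independent cell flip probability in \[0, 0.5)
#'   (default 0.05).
#' @param n_phylo_blocks,n_marker_genes,n_taxa Phylogenetic marker block
#'   structure (defaults 3 blocks, 120 markers, 40 taxa).
#' @param intensity_meanlog,intensity_sdlog LogNormal intensity parameters
#'   for detected wells (defaults 1 and 0.5).
#' @param seed RNG seed (default 1).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_sites = 10, n_genes = 5000, n_categories = 10,
                       category_shares = NULL, n_modules = 12, rho = 0.8,
                       profile_size_range = c(4, 8),
                       noise_flip_rate = 0.05, n_phylo_blocks = 3,
                       n_marker_genes = 120, n_taxa = 40,
                       intensity_meanlog = 1, intensity_sdlog = 0.5,
                       seed = 1) {
  if (is.null(category_shares)) {
    category_shares <- stats::setNames(
      rep(1 / n_categories, n_categories),
      sprintf("cat%02d", seq_len(n_categories)))
  }
  if (abs(sum(category_shares) - 1) > 1e-9)
    gfn_stop("gfn_config_error", "category_shares must sum to 1")
  if (noise_flip_rate < 0 || noise_flip_rate >= 0.5)
    gfn_stop("gfn_config_error", "noise_flip_rate must be in [0, 0.5)")
  if (rho <= 0 || rho >= 1)
    gfn_stop("gfn_config_error", "rho must be in (0, 1)")
  if (profile_size_range[1] < 1 || profile_size_range[2] > n_sites)
    gfn_stop("gfn_config_error", "profile sizes must fit within n_sites")
  structure(list(
    n_sites = n_sites, n_genes = n_genes,
    category_shares = category_shares, n_modules = n_modules, rho = rho,
    profile_size_range = profile_size_range,
    noise_flip_rate = noise_flip_rate,
    n_phylo_blocks = n_phylo_blocks, n_marker_genes = n_marker_genes,
    n_taxa = n_taxa, intensity_meanlog = intensity_meanlog,
    intensity_sdlog = intensity_sdlog, seed = seed
  ), class = "sim_config")
}

#' Array-like preset configuration
#'
#' A configuration shaped like a polar-ocean functional gene array study:
#' 10 sites, 5000 genes, 12 modules, and category shares anchored to the
#' composition reported for such arrays — carbon cycling 15%, stress 21%,
#' carbon degradation 0.5%, the remainder spread evenly over seven further
#' categories. Module site-profiles span 2-5 of 10 sites so that, with 5%
#' flip noise, the expected well coverage is about 0.35.
#'
#' @param seed RNG seed (default 1).
#' @param even_shares If `TRUE`, keep the preset geometry but use even
#'   category shares (1/10 each) — the variant with an exactly known
#'   common scaling proportion.
#' @return A `sim_config`.
#' @export
preset_paperlike <- function(seed = 1, even_shares = FALSE) {
  others <- c("nitrogen_cycling", "phosphorus_cycling", "sulphur_cycling",
              "energy_metabolism", "antibiotic_resistance",
              "metal_resistance", "organic_remediation")
  shares <- c(carbon_cycling = 0.15, stress = 0.21,
              carbon_degradation = 0.005,
              stats::setNames(rep((1 - 0.365) / 7, 7), others))
  if (even_shares)
    shares <- stats::setNames(rep(0.1, 10), names(shares))
  sim_config(n_sites = 10, n_genes = 5000, category_shares = shares,
             n_modules = 12, rho = 0.8, profile_size_range = c(2, 5),
             noise_flip_rate = 0.05, seed = seed)
}

# Draw n distinct site subsets, pairwise symmetric difference >= 2 and
# pairwise |profile correlation| <= max_cor: with only ~10 sites, planted
# modules must have clearly distinct geographic footprints to be
# identifiable at all, so near-collinear profiles are rejected; the bound
# is on the absolute value because an unsigned co-occurrence network also
# conflates complementary (anti-correlated) profiles.
draw_profiles <- function(n, n_sites, size_range, max_cor = 0.5) {
  profs <- list()
  tries <- 0
  while (length(profs) < n) {
    tries <- tries + 1
    if (tries > 20000)
      gfn_stop("gfn_config_error",
               "cannot place %d distinct module profiles on %d sites",
               n, n_sites)
    size <- sample(seq(size_range[1], size_range[2]), 1)
    cand <- rep(0L, n_sites)
    cand[sample.int(n_sites, size)] <- 1L
    ok <- all(vapply(profs, function(p)
      sum(p != cand) >= 2 && abs(stats::cor(p, cand)) <= max_cor, logical(1)))
    if (ok) profs[[length(profs) + 1L]] <- cand
  }
  do.call(rbind, profs)
}

#' Generate a synthetic community
#'
#' Realizes a `sim_config`: builds the planted module partition, category
#' assignment, per-module site profiles, flip noise and LogNormal-scaled
#' intensities, plus independent phylogenetic marker blocks. Fully
#' deterministic given `config$seed`.
#'
#' @param config A `sim_config`.
#' @return List with `signal` (gene-by-site intensity matrix), `gene_table`
#'   (annotation data.frame) and `truth` (planted module / block / profile
#'   ground truth plus the config).
#' @export
generate_community <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_sites <- config$n_sites
  sites <- sprintf("S%02d", seq_len(n_sites))

  # module partition
  w <- config$rho^seq_len(config$n_modules)
  mod_sizes <- largest_remainder(config$n_genes, w)
  if (any(mod_sizes < 1))
    gfn_stop("gfn_config_error", "a module received zero genes; raise rho")
  module_of <- rep(sprintf("M%02d", seq_len(config$n_modules)), mod_sizes)

  # categories per module, exact shares
  shares <- config$category_shares
  category_of <- unlist(lapply(seq_len(config$n_modules), function(m) {
    counts <- largest_remainder(mod_sizes[m], shares)
    rep(names(shares), counts)
  }), use.names = FALSE)

  gene_ids <- sprintf("g%05d", seq_len(config$n_genes))

  # module site profiles (distinct, symmetric difference >= 2)
  profiles <- draw_profiles(config$n_modules, n_sites,
                            config$profile_size_range)
  rownames(profiles) <- sprintf("M%02d", seq_len(config$n_modules))
  colnames(profiles) <- sites

  presence <- profiles[module_of, , drop = FALSE]
  rownames(presence) <- gene_ids

  # phylo marker blocks, independent of functional modules
  block_profiles <- draw_profiles(config$n_phylo_blocks, n_sites,
                                  config$profile_size_range)
  rownames(block_profiles) <- sprintf("P%02d", seq_len(config$n_phylo_blocks))
  colnames(block_profiles) <- sites
  block_of <- rep(sprintf("P%02d", seq_len(config$n_phylo_blocks)),
                  largest_remainder(config$n_marker_genes,
                                    rep(1, config$n_phylo_blocks)))
  taxon_block <- rep(sprintf("P%02d", seq_len(config$n_phylo_blocks)),
                     largest_remainder(config$n_taxa,
                                       rep(1, config$n_phylo_blocks)))
  taxa <- sprintf("taxon%03d", seq_len(config$n_taxa))
  taxon_of <- vapply(block_of, function(b)
    sample(taxa[taxon_block == b], 1), character(1))
  marker_ids <- sprintf("p%05d", seq_len(config$n_marker_genes))
  marker_presence <- block_profiles[block_of, , drop = FALSE]
  rownames(marker_presence) <- marker_ids

  all_presence <- rbind(presence, marker_presence)

  # flip noise
  f <- config$noise_flip_rate
  if (f > 0) {
    flips <- matrix(stats::runif(length(all_presence)) < f,
                    nrow(all_presence))
    all_presence <- (all_presence != flips) * 1L
  }

  # intensities: LogNormal-scaled presence
  signal <- all_presence *
    matrix(stats::rlnorm(length(all_presence), config$intensity_meanlog,
                         config$intensity_sdlog), nrow(all_presence))
  dimnames(signal) <- list(c(gene_ids, marker_ids), sites)

  gene_table <- data.frame(
    gene_id = c(gene_ids, marker_ids),
    category = c(category_of, rep("phylogenetic_marker",
                                  config$n_marker_genes)),
    is_phylo = c(rep(FALSE, config$n_genes),
                 rep(TRUE, config$n_marker_genes)),
    taxon = c(rep("", config$n_genes), taxon_of),
    stringsAsFactors = FALSE
  )
  validate_gene_table(gene_table)

  truth <- list(
    module = stats::setNames(module_of, gene_ids),
    category = stats::setNames(category_of, gene_ids),
    phylo_block = stats::setNames(block_of, marker_ids),
    taxon = stats::setNames(taxon_of, marker_ids),
    module_profiles = profiles,
    block_profiles = block_profiles,
    config = config
  )
  list(signal = signal, gene_table = gene_table, truth = truth)
}

#' Expected coverage of a configuration
#'
#' Closed-form expectation of the well coverage implied by the module
#' profiles and flip rate: for planted presence probability d (mean
#' on-fraction of the realized profiles, size-weighted over genes) and
#' flip rate f, coverage = d (1 - f) + (1 - d) f.
#'
#' @param truth The `truth` element of [generate_community()] output.
#' @return Expected fraction of positive wells among functional genes.
#' @export
expected_coverage <- function(truth) {
  cfg <- truth$config
  sizes <- table(truth$module)[rownames(truth$module_profiles)]
  d <- sum(rowMeans(truth$module_profiles) * as.numeric(sizes)) / sum(sizes)
  f <- cfg$noise_flip_rate
  d * (1 - f) + (1 - d) * f
}

#' Degrade a presence matrix
#'
#' Robustness tool: `"dropout"` zeroes each positive cell independently
#' with probability `rate`; `"flip"` toggles any cell with probability
#' `rate`. Seeded and deterministic.
#'
#' @param presence Binary gene-by-site matrix.
#' @param mode `"dropout"` or `"flip"`.
#' @param rate Probability in \[0, 1).
#' @param seed RNG seed.
#' @return Degraded binary matrix, same dimnames.
#' @export
degrade <- function(presence, mode = c("dropout", "flip"), rate, seed) {
  mode <- match.arg(mode)
  if (rate < 0 || rate >= 1)
    gfn_stop("gfn_parameter_error", "rate must be in [0, 1)")
  set.seed(seed)
  hit <- matrix(stats::runif(length(presence)) < rate, nrow(presence))
  out <- presence
  if (mode == "dropout") {
    out[hit & presence != 0] <- 0L
  } else {
    out[hit] <- 1L - out[hit]
  }
  dimnames(out) <- dimnames(presence)
  out
}
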