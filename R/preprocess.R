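#' Call presence/absence from hybridization intensities
#'
#' A well is called present when its intensity strictly exceeds
#' `threshold`. The default threshold of 0 treats any positive signal as
#' detection, appropriate when upstream array processing has already
#' removed background; a positive threshold gives a signal-to-noise style
#' cutoff.
#'
#' @param signal Numeric gene-by-site matrix, intensities >= 0.
#' @param threshold Detection cutoff (>= 0); presence is `signal > threshold`.
#' @return Binary (0/1) matrix with the same dimnames.
#' @export
binarize <- function(signal, threshold = 0) {
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold < 0)
    gfn_stop("gfn_parameter_error", "threshold must be a single value >= 0")
  validate_signal_matrix(signal)
  out <- (signal > threshold) * 1L
  dimnames(out) <- dimnames(signal)
  out
}

#' Array coverage
#'
#' Fraction of wells showing hybridization: the number of 1 entries over
#' the total number of entries of a presence matrix.
#'
#' @param presence Binary gene-by-site matrix.
#' @return A single fraction in \[0, 1\].
#' @export
coverage <- function(presence) {
  if (length(presence) == 0L)
    gfn_stop("gfn_undefined_input_error", "coverage of an empty matrix is undefined")
  sum(presence != 0) / length(presence)
}

#' Prevalence filter
#'
#' Retains genes detected in at least `min_sites` sites. Genes present at
#' few sites cannot support meaningful cross-site correlations, so network
#' construction is run on the prevalent fraction; the excluded rare genes
#' can be analysed separately with the same downstream operations.
#'
#' @param presence Binary gene-by-site matrix.
#' @param min_sites Minimum number of sites a gene must be detected in
#'   (default 6).
#' @return The presence matrix restricted to prevalent genes, row order
#'   preserved.
#' @export
prevalence_filter <- function(presence, min_sites = 6) {
  n_sites <- ncol(presence)
  if (min_sites < 1 || min_sites > n_sites)
    gfn_stop("gfn_parameter_error",
             "min_sites must be between 1 and %d", n_sites)
  keep <- rowSums(presence != 0) >= min_sites
  presence[keep, , drop = FALSE]
}

#' Species richness per site
#'
#' Counts, for each site, the number of distinct taxa with at least one
#' detected phylogenetic-marker gene (e.g. gyrB probes). Non-marker genes
#' are ignored; several detected markers of the same taxon count once.
#'
#' @param presence Binary gene-by-site matrix (may include non-marker genes).
#' @param gene_table Gene table with `is_phylo` and `taxon` columns.
#' @return Named integer vector, one count per site.
#' @export
richness_per_site <- function(presence, gene_table) {
  markers <- gene_table[gene_table$is_phylo & gene_table$taxon != "", ,
                        drop = FALSE]
  if (nrow(markers) == 0L)
    gfn_stop("gfn_empty_marker_error",
             "gene table contains no phylogenetic-marker genes")
  markers <- markers[markers$gene_id %in% rownames(presence), , drop = FALSE]
  sub <- presence[markers$gene_id, , drop = FALSE]
  out <- vapply(seq_len(ncol(sub)), function(s) {
    length(unique(markers$taxon[sub[, s] != 0]))
  }, integer(1))
  names(out) <- colnames(presence)
  out
}
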