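# Stop with a classed condition so callers/tests can distinguish error kinds.
gfn_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "gfn_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

#' Read a gene annotation table
#'
#' Reads a tab-separated gene table with columns `gene_id`, `category`,
#' `is_phylo` and `taxon`. Each probe on a functional gene array is
#' unambiguously assigned to one functional category (carbon cycling,
#' nitrogen cycling, stress, ...); phylogenetic-marker probes (e.g. gyrB)
#' additionally carry a taxon label and `is_phylo = TRUE`.
#'
#' @param path Path to a TSV file with a header row.
#' @return A `data.frame` with columns `gene_id` (character), `category`
#'   (character), `is_phylo` (logical) and `taxon` (character, `""` for
#'   non-marker genes), in file row order.
#' @export
read_gene_table <- function(path) {
  if (!file.exists(path)) gfn_stop("gfn_io_error", "file not found: %s", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", na.strings = NULL)
  needed <- c("gene_id", "category", "is_phylo", "taxon")
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0L)
    gfn_stop("gfn_format_error", "gene table missing column(s): %s",
             paste(missing, collapse = ", "))
  gt <- data.frame(
    gene_id  = df$gene_id,
    category = df$category,
    is_phylo = toupper(df$is_phylo) %in% c("TRUE", "T", "1"),
    taxon    = df$taxon,
    stringsAsFactors = FALSE
  )
  validate_gene_table(gt)
  gt
}

#' Validate a gene table
#'
#' Checks uniqueness of `gene_id`, presence of exactly one category per
#' gene, and that a nonempty `taxon` implies `is_phylo`.
#'
#' @param gt A gene table `data.frame` (see [read_gene_table()]).
#' @return `gt`, invisibly, if valid.
#' @export
validate_gene_table <- function(gt) {
  stopifnot(is.data.frame(gt))
  dup <- unique(gt$gene_id[duplicated(gt$gene_id)])
  if (length(dup) > 0L)
    gfn_stop("gfn_validation_error", "duplicate gene_id(s): %s",
             paste(dup, collapse = ", "))
  if (any(is.na(gt$category) | gt$category == ""))
    gfn_stop("gfn_validation_error", "every gene needs a nonempty category")
  bad <- gt$gene_id[gt$taxon != "" & !gt$is_phylo]
  if (length(bad) > 0L)
    gfn_stop("gfn_validation_error",
             "taxon set for non-phylogenetic gene(s): %s",
             paste(bad, collapse = ", "))
  invisible(gt)
}

#' Read a signal matrix
#'
#' Reads a gene-by-site matrix of hybridization intensities. The first
#' column must be `gene_id`; remaining columns are one per site. All genes
#' must be annotated in the companion gene table and intensities must be
#' nonnegative (absence is encoded as 0, never as a missing cell).
#'
#' @param path Path to a TSV file with a header row.
#' @param gene_table Companion gene table (see [read_gene_table()]).
#' @return Numeric matrix with genes as rownames, sites as colnames.
#' @export
read_signal_matrix <- function(path, gene_table) {
  if (!file.exists(path)) gfn_stop("gfn_io_error", "file not found: %s", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          check.names = FALSE)
  if (names(df)[1] != "gene_id")
    gfn_stop("gfn_format_error", "first column must be gene_id")
  genes <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- genes
  unknown <- setdiff(genes, gene_table$gene_id)
  if (length(unknown) > 0L)
    gfn_stop("gfn_crossref_error", "gene(s) absent from gene table: %s",
             paste(unknown, collapse = ", "))
  validate_signal_matrix(m)
  m
}

#' @keywords internal
validate_signal_matrix <- function(m) {
  if (anyNA(m))
    gfn_stop("gfn_validation_error", "missing intensity cells are not allowed")
  if (any(m < 0)) {
    idx <- which(m < 0, arr.ind = TRUE)[1, ]
    gfn_stop("gfn_validation_error",
             "negative intensity at gene %s, site %s",
             rownames(m)[idx[1]], colnames(m)[idx[2]])
  }
  invisible(m)
}

#' Write and read gene-to-group assignments
#'
#' Module assignments (single membership, from network analysis) are named
#' character vectors mapping gene to module label, with the reserved label
#' `"unassigned"`. Cluster assignments (possible multi-membership, from
#' KMeans++) are objects of class `cluster_assignment` holding a
#' gene-to-label-set membership list and the cluster centroids. Both
#' round-trip exactly through JSON.
#'
#' @param assignment A named character vector (module assignment) or a
#'   `cluster_assignment` object.
#' @param path Output (input) file path.
#' @return `read_assignments()` returns the stored object;
#'   `write_assignments()` returns `path` invisibly.
#' @export
write_assignments <- function(assignment, path) {
  if (inherits(assignment, "cluster_assignment")) {
    cent <- assignment$centroids
    obj <- list(
      type = "cluster",
      membership = lapply(assignment$membership, as.list),
      # row-wise named lists: a bare matrix would drop its dimnames in JSON
      centroids = lapply(setNames(rownames(cent), rownames(cent)),
                         function(r) as.list(cent[r, ])),
      sites = colnames(cent)
    )
  } else {
    stopifnot(is.character(assignment))
    obj <- list(type = "module", assignment = as.list(assignment))
  }
  # 17 significant digits: doubles survive the round trip bit-exactly
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_assignments
#' @export
read_assignments <- function(path) {
  if (!file.exists(path)) gfn_stop("gfn_io_error", "file not found: %s", path)
  obj <- jsonlite::read_json(path)
  if (identical(obj$type, "module")) {
    out <- vapply(obj$assignment, as.character, character(1))
    return(out)
  }
  if (identical(obj$type, "cluster")) {
    membership <- lapply(obj$membership, function(x)
      vapply(x, as.character, character(1)))
    cent <- obj$centroids
    centroids <- do.call(rbind, lapply(cent, function(r)
      vapply(r, as.numeric, numeric(1))))
    if (is.null(centroids)) centroids <- matrix(numeric(0), 0, 0)
    rownames(centroids) <- names(cent)
    colnames(centroids) <- vapply(obj$sites, as.character, character(1))
    return(new_cluster_assignment(membership, centroids))
  }
  gfn_stop("gfn_format_error", "unknown assignment type in %s", path)
}

#' Write a weighted edge list
#'
#' Writes the off-diagonal entries of a symmetric weight matrix at or above
#' a threshold as a TSV edge list (`gene_a`, `gene_b`, `weight`), each
#' unordered pair once with the lexicographically smaller gene first, rows
#' sorted for deterministic, diff-friendly output.
#'
#' @param adjacency Square symmetric numeric matrix with gene rownames, or
#'   a data.frame link set with columns `gene_a`, `gene_b`, `weight`.
#' @param path Output file path.
#' @param threshold Minimum weight retained (default 0).
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(adjacency, path, threshold = 0) {
  if (is.matrix(adjacency)) {
    if (nrow(adjacency) != ncol(adjacency) ||
        !isTRUE(all.equal(adjacency, t(adjacency), tolerance = 1e-12,
                          check.attributes = FALSE)))
      gfn_stop("gfn_validation_error", "adjacency must be square symmetric")
    genes <- rownames(adjacency)
    idx <- which(upper.tri(adjacency) & adjacency >= threshold, arr.ind = TRUE)
    el <- data.frame(
      gene_a = genes[idx[, 1]],
      gene_b = genes[idx[, 2]],
      weight = adjacency[idx],
      stringsAsFactors = FALSE
    )
  } else {
    el <- as.data.frame(adjacency)[, c("gene_a", "gene_b", "weight")]
    el <- el[el$weight >= threshold, , drop = FALSE]
  }
  swap <- el$gene_a > el$gene_b
  tmp <- el$gene_a[swap]; el$gene_a[swap] <- el$gene_b[swap]; el$gene_b[swap] <- tmp
  el <- el[order(el$gene_a, el$gene_b), , drop = FALSE]
  utils::write.table(el, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a gene table or matrix to TSV
#'
#' Companions to the readers: `write_gene_table()` writes the annotation
#' table; `write_signal_matrix()` writes any gene-by-site matrix (signal or
#' presence) with a `gene_id` first column.
#'
#' @param gt Gene table data.frame.
#' @param m Gene-by-site matrix with dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_table <- function(gt, path) {
  utils::write.table(gt, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_gene_table
#' @export
write_signal_matrix <- function(m, path) {
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
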