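# Small in-code fixtures shared across tests.

tiny_gene_table <- function() {
  data.frame(
    gene_id  = c("g1", "g2", "g3", "g4", "p1", "p2", "p3"),
    category = c("carbon", "carbon", "nitrogen", "stress",
                 rep("phylogenetic_marker", 3)),
    is_phylo = c(rep(FALSE, 4), rep(TRUE, 3)),
    taxon    = c(rep("", 4), "taxA", "taxA", "taxB"),
    stringsAsFactors = FALSE
  )
}

tiny_presence <- function() {
  m <- rbind(
    g1 = c(1, 1, 0, 0),
    g2 = c(1, 1, 0, 0),
    g3 = c(0, 0, 1, 1),
    g4 = c(1, 0, 1, 0),
    p1 = c(1, 0, 0, 0),
    p2 = c(1, 1, 0, 0),
    p3 = c(0, 1, 1, 0)
  )
  colnames(m) <- paste0("S", 1:4)
  m
}

write_tsv_fixture <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# Random binary matrix with named dims.
random_presence <- function(n_genes, n_sites, p = 0.4, seed = 1) {
  set.seed(seed)
  m <- matrix(rbinom(n_genes * n_sites, 1, p), n_genes, n_sites,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              sprintf("S%02d", seq_len(n_sites))))
  m
}

# Symmetric random adjacency in [0,1] with zero diagonal.
random_adjacency <- function(n, seed = 1) {
  set.seed(seed)
  a <- matrix(runif(n * n), n, n)
  a <- (a + t(a)) / 2
  diag(a) <- 0
  dimnames(a) <- list(sprintf("g%02d", 1:n), sprintf("g%02d", 1:n))
  a
}
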