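# Apriori frequent-itemset and association-rule mining. Transactions are
# typically sites, items the functional groups represented there; the
# algorithm finds sets of functions that co-occur across locations and
# rules "where X occurs, Y occurs too" scored by confidence.

itemset_key <- function(items) paste(sort(items), collapse = ",")

#' Build transactions from a presence matrix
#'
#' Encodes each site as a transaction whose items are the functional
#' categories sufficiently represented there: a category is an item when
#' the fraction of its array genes detected at the site exceeds
#' `min_fraction` (default 0 = any presence). With `items = "genes"` each
#' site's detected gene ids are the items instead.
#'
#' @param presence Binary gene-by-site matrix.
#' @param gene_table Gene table annotating the genes.
#' @param min_fraction Representation threshold for category items.
#' @param items `"functions"` (default) or `"genes"`.
#' @return Named list of character item vectors, one per site.
#' @export
as_transactions <- function(presence, gene_table,
                            min_fraction = 0,
                            items = c("functions", "genes")) {
  items <- match.arg(items)
  sites <- colnames(presence)
  if (items == "genes") {
    tx <- lapply(sites, function(s) rownames(presence)[presence[, s] != 0])
  } else {
    # functional categories only: phylogenetic markers are not functions
    func <- gene_table[!gene_table$is_phylo, , drop = FALSE]
    presence <- presence[rownames(presence) %in% func$gene_id, ,
                         drop = FALSE]
    gt <- func[match(rownames(presence), func$gene_id), ]
    cat_sizes <- table(func$category)
    tx <- lapply(sites, function(s) {
      detected <- table(gt$category[presence[, s] != 0])
      frac <- as.numeric(detected) / as.numeric(cat_sizes[names(detected)])
      names(detected)[frac > min_fraction | (min_fraction == 0 & frac > 0)]
    })
  }
  names(tx) <- sites
  tx
}

#' Frequent itemsets by the Apriori algorithm
#'
#' Level-wise generation with candidate pruning: every candidate of size
#' `l` is kept for counting only if all of its size `l - 1` subsets are
#' frequent; an itemset is frequent when its support (fraction of
#' transactions containing it) is at least `min_support`. Output order is
#' deterministic: by size, then lexicographically.
#'
#' @param tx List of character item vectors (one per transaction).
#' @param min_support Minimum support in (0, 1].
#' @return data.frame with columns `itemset` (comma-joined sorted items),
#'   `size` and `support`.
#' @export
frequent_itemsets <- function(tx, min_support) {
  if (min_support <= 0 || min_support > 1)
    gfn_stop("gfn_parameter_error", "min_support must be in (0, 1]")
  n <- length(tx)
  empty <- data.frame(itemset = character(0), size = integer(0),
                      support = numeric(0), stringsAsFactors = FALSE)
  if (n == 0L) {
    warning("no transactions; empty result")
    return(empty)
  }
  tx <- lapply(tx, unique)
  support_of <- function(items) {
    mean(vapply(tx, function(t) all(items %in% t), logical(1)))
  }
  # level 1
  items1 <- sort(unique(unlist(tx)))
  sup1 <- vapply(items1, function(i) support_of(i), numeric(1))
  frequent <- list()
  level <- items1[sup1 >= min_support]
  if (length(level) > 0)
    frequent[[1]] <- data.frame(itemset = level, size = 1L,
                                support = unname(sup1[sup1 >= min_support]),
                                stringsAsFactors = FALSE)
  prev_sets <- lapply(level, identity)
  l <- 2L
  while (length(prev_sets) > 1) {
    prev_keys <- vapply(prev_sets, itemset_key, character(1))
    # candidate generation: union of pairs sharing their first l-2 items
    cand <- list()
    for (i in seq_along(prev_sets)) {
      a <- sort(prev_sets[[i]])
      for (j in seq_along(prev_sets)) {
        if (j <= i) next
        b <- sort(prev_sets[[j]])
        if (l == 2L || identical(a[1:(l - 2)], b[1:(l - 2)])) {
          u <- sort(union(a, b))
          if (length(u) == l) cand[[itemset_key(u)]] <- u
        }
      }
    }
    # prune: all (l-1)-subsets must be frequent
    cand <- Filter(function(s) {
      subs <- vapply(seq_along(s), function(d) itemset_key(s[-d]), character(1))
      all(subs %in% prev_keys)
    }, cand)
    if (length(cand) == 0) break
    sup <- vapply(cand, support_of, numeric(1))
    keep <- sup >= min_support
    if (any(keep)) {
      frequent[[l]] <- data.frame(
        itemset = unname(vapply(cand[keep], itemset_key, character(1))),
        size = l, support = unname(sup[keep]), stringsAsFactors = FALSE)
    }
    prev_sets <- unname(cand[keep])
    l <- l + 1L
  }
  if (length(frequent) == 0) return(empty)
  out <- do.call(rbind, frequent)
  out <- out[order(out$size, out$itemset), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Association rules from frequent itemsets
#'
#' Generates every rule X -> Y with X and Y disjoint, X union Y frequent
#' and confidence = support(X union Y) / support(X). Rules meeting
#' `min_confidence` are returned; weaker rules (interesting in this domain
#' precisely because strong function-level associations are absent) are
#' attached as the `"sub_threshold"` attribute.
#'
#' @param frequent Output of [frequent_itemsets()] on the same transactions.
#' @param tx The transaction list (to compute antecedent supports that may
#'   fall below `min_support` coverage of the frequent table).
#' @param min_confidence Minimum confidence in \[0, 1\].
#' @return data.frame with columns `antecedent`, `consequent` (comma-joined),
#'   `support`, `confidence`; attribute `sub_threshold` holds the rejected
#'   rules in the same layout.
#' @export
association_rules <- function(frequent, tx, min_confidence) {
  sup_env <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_len(nrow(frequent)))
    assign(frequent$itemset[i], frequent$support[i], envir = sup_env)
  support_of <- function(items) {
    key <- itemset_key(items)
    if (!is.null(s <- sup_env[[key]])) return(s)
    s <- mean(vapply(tx, function(t) all(items %in% t), logical(1)))
    assign(key, s, envir = sup_env)
    s
  }
  chunks <- lapply(which(frequent$size >= 2), function(r) {
    z <- strsplit(frequent$itemset[r], ",", fixed = TRUE)[[1]]
    supp_z <- frequent$support[r]
    n_z <- length(z)
    masks <- seq_len(2^n_z - 2)
    bits <- 2^(seq_len(n_z) - 1)
    ante <- character(length(masks)); cons <- character(length(masks))
    conf <- numeric(length(masks))
    for (i in seq_along(masks)) {
      in_x <- bitwAnd(masks[i], bits) > 0
      x <- z[in_x]
      ante[i] <- itemset_key(x)
      cons[i] <- itemset_key(z[!in_x])
      conf[i] <- supp_z / support_of(x)
    }
    data.frame(antecedent = ante, consequent = cons, support = supp_z,
               confidence = conf, stringsAsFactors = FALSE)
  })
  all_rules <- if (length(chunks) > 0) do.call(rbind, chunks) else
    data.frame(antecedent = character(0), consequent = character(0),
               support = numeric(0), confidence = numeric(0))
  all_rules <- all_rules[order(all_rules$antecedent, all_rules$consequent), ,
                         drop = FALSE]
  rownames(all_rules) <- NULL
  keep <- all_rules$confidence >= min_confidence
  out <- all_rules[keep, , drop = FALSE]
  rownames(out) <- NULL
  sub <- all_rules[!keep, , drop = FALSE]
  rownames(sub) <- NULL
  attr(out, "sub_threshold") <- sub
  out
}
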