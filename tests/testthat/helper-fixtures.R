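# Shared fixtures built in code.

# An 80-chromosome sample shaped like the Kii coding-region data: six
# distinct haplotypes at counts 32/17/1/6/23/1, with the 23-copy haplotype
# private to the focal population and the rest shared with a neighbour.
kii_like_sample <- function() {
  counts <- c(A = 32, B = 17, F = 1, J = 6, K = 23, Q = 1)
  haps <- c(A = "AAAAA", B = "AAAAT", F = "AAATT", J = "AATTT",
            K = "TTTTT", Q = "TAATA")
  focal_seqs <- haps[rep(names(counts), counts)]
  focal_ids <- unlist(mapply(function(nm, k) paste0("kii_", nm, seq_len(k)),
                             names(counts), counts, SIMPLIFY = FALSE))
  shared <- rep(c("A", "B", "F", "J", "Q"), 2)
  nb_seqs <- haps[shared]
  nb_ids <- paste0("nbr_", seq_along(nb_seqs))
  aln <- haplotype_alignment(c(focal_seqs, nb_seqs), c(focal_ids, nb_ids))
  map <- population_map(c(focal_ids, nb_ids),
                        c(rep("Kii", length(focal_ids)),
                          rep("Neighbour", length(nb_ids))),
                        alignment = aln)
  list(alignment = aln, map = map, counts = counts)
}

# Total weight of the cheapest tree connecting the given haplotype state
# rows, allowing at most one Steiner (unobserved) node drawn from the full
# state product: a brute-force oracle for tiny median-joining instances.
steiner_min_weight <- function(states, weights) {
  dist_fun <- function(a, b) sum(weights[a != b])
  mst_weight <- function(rows) {
    k <- nrow(rows)
    d <- matrix(0, k, k)
    for (i in seq_len(k - 1))
      for (j in seq.int(i + 1, k))
        d[i, j] <- d[j, i] <- dist_fun(rows[i, ], rows[j, ])
    g <- igraph::graph_from_adjacency_matrix(d, mode = "undirected",
                                             weighted = TRUE)
    sum(igraph::E(igraph::mst(g))$weight)
  }
  best <- mst_weight(states)
  alphabets <- lapply(seq_len(ncol(states)), function(j) unique(states[, j]))
  cand <- as.matrix(expand.grid(alphabets, stringsAsFactors = FALSE))
  for (r in seq_len(nrow(cand))) {
    best <- min(best, mst_weight(rbind(states, cand[r, ])))
  }
  best
}
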