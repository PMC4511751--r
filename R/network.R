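# Median-joining haplotype networks (Bandelt-style) and a four-gamete scan
# that localizes recombination between incompatible polymorphic sites.

# Encode an alignment as multi-state polymorphic characters: one character
# per substitution column (weight 1) and one per maximal run of contiguous
# indel columns (weight = indel_weight, state = the run's gap pattern).
haplotype_characters <- function(alignment, indel_weight = 2) {
  classes <- alignment$site_classes
  mat <- alignment$matrix
  chars <- list()
  labels <- integer(0)
  weights <- numeric(0)
  is_indel <- classes == "indel"
  runs <- rle(is_indel)
  col <- 1L
  for (r in seq_along(runs$lengths)) {
    len <- runs$lengths[r]
    cols <- seq.int(col, col + len - 1L)
    if (runs$values[r]) {
      state <- apply(mat[, cols, drop = FALSE], 1L, paste, collapse = "")
      if (length(unique(state)) > 1L) {
        chars <- c(chars, list(state))
        labels <- c(labels, alignment$positions[cols[1L]])
        weights <- c(weights, indel_weight)
      }
    } else {
      for (cc in cols[classes[cols] == "substitution"]) {
        chars <- c(chars, list(mat[, cc]))
        labels <- c(labels, alignment$positions[cc])
        weights <- c(weights, 1)
      }
    }
    col <- col + len
  }
  state <- do.call(cbind, chars)
  if (is.null(state)) state <- matrix(character(0), nrow = nrow(mat))
  rownames(state) <- alignment$ids
  list(states = state, positions = labels, weights = weights)
}

char_dist <- function(a, b, weights) sum(weights[a != b])

# Minimum spanning network with tolerance epsilon: an edge (u, v) is kept
# when d(u, v) <= bottleneck(u, v) + epsilon, where the bottleneck is the
# largest edge on the minimum-spanning-tree path between u and v.
msn_edges <- function(d, epsilon = 0) {
  n <- nrow(d)
  if (n < 2L) return(matrix(numeric(0), ncol = 3))
  g <- igraph::graph_from_adjacency_matrix(d, mode = "undirected",
                                           weighted = TRUE)
  mst <- igraph::mst(g)
  bottleneck <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      p <- igraph::shortest_paths(mst, i, j, output = "epath")$epath[[1L]]
      bottleneck[i, j] <- bottleneck[j, i] <- max(igraph::E(mst)$weight[p])
    }
  }
  out <- NULL
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      if (d[i, j] <= bottleneck[i, j] + epsilon + 1e-9)
        out <- rbind(out, c(i, j, d[i, j]))
    }
  }
  out
}

median_state <- function(a, b, c) {
  vapply(seq_along(a), function(k) {
    s <- c(a[k], b[k], c[k])
    tab <- sort(table(s), decreasing = TRUE)
    if (tab[1L] >= 2L) names(tab)[1L] else sort(s)[1L]
  }, character(1))
}

#' Build a median-joining haplotype network
#'
#' Collapses identical sequences, encodes polymorphic columns as weighted
#' characters (substitutions weight 1; each contiguous gap run one indel
#' character, weight `indel_weight`), and iteratively augments the
#' epsilon-relaxed minimum spanning network with median vectors (majority
#' consensus of connected triples) until no new median arises. Median
#' vectors that end with network degree <= 2 are pruned. Node order and all
#' tie-breaks are lexicographic, so the result is deterministic.
#'
#' @param alignment a [haplotype_alignment()] of phased haplotypes.
#' @param epsilon non-negative tolerance widening the feasible-link set
#'   (default 0).
#' @param indel_weight cost of one indel event relative to a substitution
#'   (default 2).
#' @param map optional [population_map()] used to annotate nodes with
#'   population composition.
#' @param outgroup optional chromosome id marking the rooting outgroup. The
#'   network stays undirected; the node carrying the outgroup gets
#'   `outgroup = TRUE` as metadata so root-adjacent nodes can be read off.
#' @return an `igraph` graph. Vertex attributes: `name`, `type`
#'   (`"observed"`/`"median"`), `multiplicity` (chromosome count, 0 for
#'   medians), `members` (comma-joined chromosome ids), and `outgroup` when
#'   requested. Edge attributes: `weight` (summed event weights) and
#'   `positions` (comma-joined column anchors of the differing characters).
#' @export
build_mj_network <- function(alignment, epsilon = 0, indel_weight = 2,
                             map = NULL, outgroup = NULL) {
  stopifnot(inherits(alignment, "haplotype_alignment"), epsilon >= 0,
            indel_weight > 0)
  enc <- haplotype_characters(alignment, indel_weight)
  seq_keys <- apply(enc$states, 1L, paste, collapse = "\r")
  uniq <- !duplicated(seq_keys)
  states <- enc$states[uniq, , drop = FALSE]
  node_members <- split(alignment$ids, match(seq_keys, seq_keys[uniq]))
  node_labels <- vapply(node_members, function(m) m[[1L]], character(1))
  ord <- order(node_labels)
  states <- states[ord, , drop = FALSE]
  node_members <- node_members[ord]
  node_labels <- node_labels[ord]
  node_type <- rep("observed", length(node_labels))
  if (length(node_labels) == 1L) {
    warning("single distinct haplotype; returning a one-node graph")
    g <- igraph::make_empty_graph(1L, directed = FALSE)
    igraph::V(g)$name <- node_labels
    igraph::V(g)$type <- "observed"
    igraph::V(g)$multiplicity <- length(node_members[[1L]])
    igraph::V(g)$members <- paste(node_members[[1L]], collapse = ",")
    return(g)
  }
  w <- enc$weights
  n_mv <- 0L
  for (iter in 1:25) {
    k <- nrow(states)
    d <- matrix(0, k, k)
    for (i in seq_len(k - 1L))
      for (j in seq.int(i + 1L, k))
        d[i, j] <- d[j, i] <- char_dist(states[i, ], states[j, ], w)
    edges <- msn_edges(d, epsilon)
    adj <- lapply(seq_len(k), function(i)
      sort(unique(c(edges[edges[, 1] == i, 2], edges[edges[, 2] == i, 1]))))
    new_states <- NULL
    for (e in seq_len(nrow(edges))) {
      u <- edges[e, 1L]; v <- edges[e, 2L]
      for (wv in sort(unique(c(adj[[u]], adj[[v]])))) {
        if (wv == u || wv == v) next
        med <- median_state(states[u, ], states[v, ], states[wv, ])
        key <- paste(med, collapse = "\r")
        keys <- apply(rbind(states, new_states), 1L, paste, collapse = "\r")
        if (!key %in% keys) new_states <- rbind(new_states, med)
      }
    }
    if (is.null(new_states)) break
    for (r in seq_len(nrow(new_states))) {
      n_mv <- n_mv + 1L
      node_labels <- c(node_labels, sprintf("mv-%d", n_mv))
    }
    node_type <- c(node_type, rep("median", nrow(new_states)))
    node_members <- c(node_members,
                      rep(list(character(0)), nrow(new_states)))
    states <- rbind(states, new_states)
  }
  # prune median vectors that are not junctions (degree <= 2)
  repeat {
    k <- nrow(states)
    d <- matrix(0, k, k)
    for (i in seq_len(k - 1L))
      for (j in seq.int(i + 1L, k))
        d[i, j] <- d[j, i] <- char_dist(states[i, ], states[j, ], w)
    edges <- msn_edges(d, epsilon)
    deg <- tabulate(c(edges[, 1L], edges[, 2L]), nbins = k)
    drop <- which(node_type == "median" & deg <= 2L)
    if (length(drop) == 0L) break
    states <- states[-drop, , drop = FALSE]
    node_labels <- node_labels[-drop]
    node_type <- node_type[-drop]
    node_members <- node_members[-drop]
  }
  g <- igraph::make_empty_graph(length(node_labels), directed = FALSE)
  igraph::V(g)$name <- node_labels
  igraph::V(g)$type <- node_type
  igraph::V(g)$multiplicity <- vapply(node_members, length, integer(1))
  igraph::V(g)$members <- vapply(node_members, paste, character(1),
                                 collapse = ",")
  if (!is.null(map)) {
    igraph::V(g)$populations <- vapply(node_members, function(m) {
      if (length(m) == 0L) return("")
      p <- map$population[match(m, map$chromosome_id)]
      paste(names(table(droplevels(p))), table(droplevels(p)),
            sep = ":", collapse = ",")
    }, character(1))
  }
  if (!is.null(outgroup)) {
    if (!outgroup %in% alignment$ids)
      stop("outgroup id not found in alignment: ", outgroup)
    igraph::V(g)$outgroup <- vapply(node_members, function(m)
      outgroup %in% m, logical(1))
  }
  for (e in seq_len(nrow(edges))) {
    i <- edges[e, 1L]; j <- edges[e, 2L]
    diffc <- which(states[i, ] != states[j, ])
    g <- igraph::add_edges(g, c(i, j),
                           weight = sum(w[diffc]),
                           positions = paste(enc$positions[diffc],
                                             collapse = ","))
  }
  g
}

#' Scan an alignment for four-gamete incompatibilities
#'
#' Two biallelic sites showing all four allele combinations cannot descend
#' from a single non-recombining genealogy under infinite sites; such pairs
#' localize recombination. Only biallelic substitution columns are
#' considered; rows missing (`N`) at either site are skipped for that pair.
#' The reported breakpoint interval is the narrowest incompatible pair (by
#' anchor-position separation; ties resolved to the leftmost), i.e. the
#' tightest bracket on a crossover.
#'
#' @param alignment a [haplotype_alignment()].
#' @return list with `pairs` (data.frame of incompatible site pairs:
#'   `site_i`, `site_j` column indices and `pos_i`, `pos_j` anchors) and
#'   `breakpoint` (length-2 vector of anchor positions, or `NULL` when the
#'   alignment is tree-compatible).
#' @export
four_gamete_scan <- function(alignment) {
  stopifnot(inherits(alignment, "haplotype_alignment"))
  mat <- alignment$matrix
  cand <- which(alignment$site_classes == "substitution")
  cand <- cand[vapply(cand, function(cc) {
    a <- mat[, cc]; length(unique(a[a != "N"])) == 2L
  }, logical(1))]
  pairs <- NULL
  if (length(cand) >= 2L) {
    for (ii in seq_len(length(cand) - 1L)) {
      for (jj in seq.int(ii + 1L, length(cand))) {
        ci <- cand[ii]; cj <- cand[jj]
        a <- mat[, ci]; b <- mat[, cj]
        ok <- a != "N" & b != "N"
        if (length(unique(paste(a[ok], b[ok]))) == 4L)
          pairs <- rbind(pairs, data.frame(
            site_i = ci, site_j = cj,
            pos_i = alignment$positions[ci],
            pos_j = alignment$positions[cj]))
      }
    }
  }
  if (is.null(pairs))
    return(list(pairs = data.frame(site_i = integer(0), site_j = integer(0),
                                   pos_i = integer(0), pos_j = integer(0)),
                breakpoint = NULL))
  sep <- abs(pairs$pos_j - pairs$pos_i)
  best <- which(sep == min(sep))
  best <- best[which.min(pairs$pos_i[best])]
  list(pairs = pairs,
       breakpoint = sort(c(pairs$pos_i[best], pairs$pos_j[best])))
}
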