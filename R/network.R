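#' Encode genotypes as multistate character vectors
#'
#' Each genotype is coded per locus and per allele slot (slots in canonical
#' sorted-pair order): repeat copy numbers are ordered integer characters
#' (distance = absolute difference) and flanking SNV states are unordered
#' characters over \code{A/C/G/T/-} (distance 0/1; the gap is a legal second
#' state). Alleles whose cluster structure is not homologous with the slot's
#' modal motif inventory are coded as a presence/absence character (distance
#' 1) with a warning.
#'
#' @param gt a \code{\link{genotype_table}}.
#' @param alleles an \code{allele_set}.
#' @param ids genotype ids to encode (default all).
#' @return object of class \code{genotype_codes}: list with \code{repeat_mat}
#'   (numeric matrix, genotypes x repeat characters, NA = non-homologous),
#'   \code{snv_mat} (character matrix of SNV states), \code{ids}.
#' @export
encode_genotypes <- function(gt, alleles, ids = gt$genotypes$id) {
  geno <- gt$genotypes[match(ids, gt$genotypes$id), , drop = FALSE]
  rep_cols <- list()
  snv_cols <- list()
  for (loc in gt$loci) {
    recs <- lapply(1:2, function(s)
      lapply(geno[[paste0(loc, "_a", s)]], function(l) {
        r <- alleles[[allele_key(loc, l)]]
        if (is.null(r)) stopf("allele %s|%s not in allele set", loc, l)
        r
      }))
    for (s in 1:2) {
      motifs_by_g <- lapply(recs[[s]], function(r) r$clusters$motif)
      inv <- vapply(motifs_by_g, paste, character(1), collapse = ",")
      modal_inv <- names(which.max(table(inv)))
      modal <- motifs_by_g[[match(modal_inv, inv)]]
      homol <- inv == modal_inv
      if (!all(homol))
        warning(sprintf(
          "locus %s slot %d: non-homologous cluster structure in %d genotype(s); coded presence/absence",
          loc, s, sum(!homol)), call. = FALSE)
      for (ci in seq_along(modal)) {
        col <- vapply(seq_along(recs[[s]]), function(i)
          if (homol[i]) as.numeric(recs[[s]][[i]]$clusters$copies[ci])
          else NA_real_, numeric(1))
        rep_cols[[sprintf("%s.s%d.%s%d", loc, s, modal[ci], ci)]] <- col
      }
      profs <- vapply(recs[[s]], `[[`, character(1), "snv_profile")
      if (any(nzchar(profs))) {
        width <- max(nchar(profs))
        for (pi in seq_len(width)) {
          snv_cols[[sprintf("%s.s%d.snv%d", loc, s, pi)]] <-
            substr(profs, pi, pi)
        }
      }
    }
  }
  structure(list(
    repeat_mat = do.call(cbind, rep_cols) %||%
      matrix(numeric(), nrow(geno), 0),
    snv_mat = do.call(cbind, snv_cols) %||%
      matrix(character(), nrow(geno), 0),
    ids = ids), class = "genotype_codes")
}

#' Pairwise mutational step distances between encoded genotypes
#'
#' @param codes a \code{\link{encode_genotypes}} result.
#' @return symmetric numeric matrix of step counts, dimnames = genotype ids.
#' @export
code_distances <- function(codes) {
  n <- length(codes$ids)
  D <- matrix(0, n, n, dimnames = list(codes$ids, codes$ids))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    dr <- abs(codes$repeat_mat[i, ] - codes$repeat_mat[j, ])
    na <- is.na(codes$repeat_mat[i, ]) != is.na(codes$repeat_mat[j, ])
    dr[is.na(dr)] <- 0
    ds <- sum(codes$snv_mat[i, ] != codes$snv_mat[j, ])
    D[i, j] <- D[j, i] <- sum(dr) + sum(na) + ds
  }
  D
}

#' Build a parsimony mutation network linking clones
#'
#' A minimum-spanning network: candidate edges (genotype pairs with step
#' distance within \code{connection_limit}) are processed in increasing step
#' order; an edge joining two components is kept, and equally parsimonious
#' alternatives at the joining step level are all retained (a network, not a
#' tree). Edges spanning \eqn{s > 1} steps materialize \eqn{s - 1} unsampled
#' intermediate nodes, the computer-predicted genotypes of a statistical
#' parsimony graph.
#'
#' @param gt a \code{\link{genotype_table}}.
#' @param alleles an \code{allele_set}.
#' @param ids genotype ids to connect (>= 2; typically the members of one
#'   founder class, within which all differences are mutational).
#' @param connection_limit maximum steps for a candidate edge (default
#'   \code{Inf}: unlimited within the supplied set).
#' @return object of class \code{clone_network}: list with \code{graph}
#'   (igraph; sampled nodes carry \code{count} and \code{populations},
#'   intermediates have \code{sampled = FALSE}), \code{edges} (data frame of
#'   retained genotype-pair edges with steps), \code{nodes}, \code{ids},
#'   \code{connection_limit}.
#' @export
clone_network <- function(gt, alleles, ids = gt$genotypes$id,
                          connection_limit = Inf) {
  if (length(ids) < 2L) stopf("need >= 2 genotypes to build a network")
  codes <- encode_genotypes(gt, alleles, ids)
  D <- code_distances(codes)
  if (any(D[upper.tri(D)] == 0))
    stopf("identical codes among genotypes %s; deduplicate upstream",
          paste(ids, collapse = ","))
  cand <- which(upper.tri(D), arr.ind = TRUE)
  edges <- data.frame(from = ids[cand[, 1]], to = ids[cand[, 2]],
                      steps = D[cand])
  edges <- edges[edges$steps <= connection_limit, , drop = FALSE]
  edges <- edges[order(edges$steps, pmin(edges$from, edges$to),
                       pmax(edges$from, edges$to)), , drop = FALSE]
  comp <- setNames(ids, ids)
  find <- function(x) { while (comp[[as.character(x)]] != x)
    x <- comp[[as.character(x)]]; x }
  keep <- logical(nrow(edges))
  for (lev in unique(edges$steps)) {
    at <- which(edges$steps == lev)
    snapshot <- vapply(ids, find, numeric(1))
    names(snapshot) <- ids
    joins <- at[snapshot[as.character(edges$from[at])] !=
                  snapshot[as.character(edges$to[at])]]
    keep[joins] <- TRUE
    for (e in joins) {
      ra <- find(edges$from[e]); rb <- find(edges$to[e])
      if (ra != rb) comp[[as.character(ra)]] <- rb
    }
  }
  edges <- edges[keep, , drop = FALSE]
  rownames(edges) <- NULL
  # node table: sampled genotypes + materialized intermediates
  geno <- gt$genotypes[match(ids, gt$genotypes$id), , drop = FALSE]
  popstr <- vapply(ids, function(i) {
    cnt <- gt$counts[as.character(i), ]
    paste(sprintf("%s:%d", names(cnt)[cnt > 0], cnt[cnt > 0]), collapse = ",")
  }, character(1))
  nodes <- data.frame(name = as.character(ids), count = geno$total,
                      sampled = TRUE, populations = popstr,
                      stringsAsFactors = FALSE)
  gedges <- list()
  for (e in seq_len(nrow(edges))) {
    s <- edges$steps[e]
    a <- as.character(edges$from[e]); b <- as.character(edges$to[e])
    if (s <= 1) {
      gedges[[length(gedges) + 1L]] <- data.frame(from = a, to = b)
    } else {
      mids <- sprintf("u%s-%s.%d", a, b, seq_len(s - 1))
      nodes <- rbind(nodes, data.frame(name = mids, count = 0L,
                                       sampled = FALSE, populations = "",
                                       stringsAsFactors = FALSE))
      chain <- c(a, mids, b)
      for (i in seq_len(length(chain) - 1L))
        gedges[[length(gedges) + 1L]] <-
          data.frame(from = chain[i], to = chain[i + 1L])
    }
  }
  g <- igraph::graph_from_data_frame(
    if (length(gedges)) do.call(rbind, gedges)
    else data.frame(from = character(), to = character()),
    directed = FALSE, vertices = nodes)
  structure(list(graph = g, edges = edges, nodes = nodes, ids = ids,
                 connection_limit = connection_limit),
            class = "clone_network")
}

#' @export
print.clone_network <- function(x, ...) {
  cat(sprintf(
    "<clone network> %d sampled genotypes, %d inferred intermediates, %d edges (max %g steps)\n",
    sum(x$nodes$sampled), sum(!x$nodes$sampled), nrow(x$edges),
    if (nrow(x$edges)) max(x$edges$steps) else 0))
  invisible(x)
}

#' Plot a clone network
#'
#' Sampled clones are drawn as circles scaled by individual count;
#' inferred intermediates as small black dots.
#'
#' @param x a \code{\link{clone_network}}.
#' @param ... passed to \code{igraph::plot.igraph}.
#' @export
plot.clone_network <- function(x, ...) {
  g <- x$graph
  size <- ifelse(igraph::V(g)$sampled,
                 8 + 4 * sqrt(igraph::V(g)$count), 2.5)
  color <- ifelse(igraph::V(g)$sampled, "lightsteelblue", "black")
  label <- ifelse(igraph::V(g)$sampled, igraph::V(g)$name, NA)
  igraph::plot.igraph(g, vertex.size = size, vertex.color = color,
                      vertex.label = label, ...)
  invisible(x)
}

#' Degree, eccentricity and centrality ranking of network nodes
#'
#' Quantifies star-likeness: in a perfect star the hub has eccentricity 1
#' (in steps) and maximal degree. Distances are counted in mutational steps
#' (paths traverse inferred intermediate nodes). Requires a connected
#' network.
#'
#' @param net a \code{\link{clone_network}}.
#' @return data frame over sampled nodes: \code{id}, \code{degree},
#'   \code{eccentricity} (steps to the farthest sampled node), \code{rank}
#'   (1 = highest degree; ties share a rank).
#' @export
hub_statistics <- function(net) {
  g <- net$graph
  if (igraph::components(g)$no != 1L)
    stopf("network is not connected; hub statistics need one component")
  sampled <- igraph::V(g)$name[igraph::V(g)$sampled]
  dist <- igraph::distances(g, v = sampled, to = sampled)
  deg <- igraph::degree(g, v = sampled)
  ecc <- apply(dist, 1L, max)
  rank <- match(-deg, sort(unique(-deg)))
  out <- data.frame(id = sampled, degree = as.integer(deg),
                    eccentricity = as.numeric(ecc), rank = rank,
                    stringsAsFactors = FALSE)
  out[order(out$rank, out$id), ]
}

#' Export a clone network
#'
#' @param net a \code{\link{clone_network}}.
#' @param graphml optional path for GraphML export (igraph writer).
#' @param edges_tsv optional path for an edge-list TSV (from, to, steps).
#' @return \code{net}, invisibly.
#' @export
write_network <- function(net, graphml = NULL, edges_tsv = NULL) {
  if (!is.null(graphml))
    igraph::write_graph(net$graph, graphml, format = "graphml")
  if (!is.null(edges_tsv))
    write.table(net$edges, edges_tsv, sep = "\t", quote = FALSE,
                row.names = FALSE)
  invisible(net)
}
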