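# Per-lineage and per-repertoire statistics, branch-of-interest detection
# and position frequency matrices for sequence logos.

treeGraph <- function(tree) {
  igraph::graph_from_data_frame(
    tree@edges[, c("parent", "child"), drop = FALSE],
    directed = TRUE,
    vertices = data.frame(name = names(tree@nodes)))
}

#' Depth of a lineage tree
#'
#' The edge count along the longest root-to-leaf path; single-node lineages
#' have depth zero.
#'
#' @param tree a \code{\linkS4class{LineageTree}}.
#' @return non-negative integer.
#' @export
treeDepth <- function(tree) {
  if (nrow(tree@edges) == 0L) return(0L)
  g <- treeGraph(tree)
  d <- igraph::distances(g, v = tree@root, mode = "out")
  as.integer(max(d[is.finite(d)]))
}

#' Dominant isotype of a lineage
#'
#' The isotype held by a strict majority (>50 percent) of nodes, else
#' "mixed". Dummy roots are excluded from the count.
#'
#' @param tree a \code{\linkS4class{LineageTree}}.
#' @return isotype label or "mixed".
#' @export
dominantIsotype <- function(tree) {
  iso <- vapply(Filter(function(n) !isTRUE(n$is_dummy), tree@nodes),
                function(n) n$node_isotype, character(1))
  counts <- table(iso)
  top <- which(counts > length(iso) / 2)
  if (length(top) == 1L && names(counts)[top] != "mixed")
    names(counts)[top] else "mixed"
}

#' Clonal expansion level of a lineage
#'
#' The maximum node size (number of cells/sequences sharing one clonotype)
#' within the tree.
#'
#' @param tree a \code{\linkS4class{LineageTree}}.
#' @return positive integer.
#' @export
expansionLevel <- function(tree) {
  max(vapply(tree@nodes, function(n) n$size, numeric(1)))
}

#' Per-lineage statistics row
#'
#' @param tree a \code{\linkS4class{LineageTree}}.
#' @return one-row data.frame with lineage_id, tree_name, depth,
#'   dominant_isotype, expansion and size (node count, dummy root excluded).
#' @export
lineageStats <- function(tree) {
  realNodes <- Filter(function(n) !isTRUE(n$is_dummy), tree@nodes)
  data.frame(
    lineage_id = tree@lineageId,
    tree_name = tree@treeName,
    depth = treeDepth(tree),
    dominant_isotype = dominantIsotype(tree),
    expansion = as.integer(expansionLevel(tree)),
    size = length(realNodes),
    stringsAsFactors = FALSE)
}

#' Detect deep, large branches of closely related nodes
#'
#' Removes edges heavier than \code{wMax} (normalized edit distance) and
#' takes the connected components of what remains; components whose
#' internal longest path has at least \code{dMin} edges and which contain
#' at least \code{sMin} nodes are reported as branches of interest.
#'
#' @param tree a \code{\linkS4class{LineageTree}}.
#' @param wMax relatedness threshold on edge weight (default 0.1).
#' @param dMin minimum branch depth in edges (default 2).
#' @param sMin minimum branch node count (default 5).
#' @return list of branches: each a list with \code{tree_name},
#'   \code{node_names}, \code{branch_depth}, \code{branch_size}.
#' @export
findBranches <- function(tree, wMax = 0.1, dMin = 2L, sMin = 5L) {
  keep <- tree@edges[tree@edges$weight <= wMax, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    keep[, c("parent", "child"), drop = FALSE], directed = TRUE,
    vertices = data.frame(name = names(tree@nodes)))
  comp <- igraph::components(g, mode = "weak")
  out <- list()
  for (ci in seq_len(comp$no)) {
    vs <- names(comp$membership)[comp$membership == ci]
    if (length(vs) < sMin) next
    sub <- igraph::induced_subgraph(g, vs)
    d <- igraph::distances(sub, mode = "out")
    depth <- as.integer(max(d[is.finite(d)]))
    if (depth < dMin) next
    out[[length(out) + 1L]] <- list(
      tree_name = tree@treeName, node_names = vs,
      branch_depth = depth, branch_size = length(vs))
  }
  out
}

translateCdrs <- function(cdrSeqs) {
  aa <- vapply(cdrSeqs, function(s) {
    if (nchar(s) %% 3 != 0)
      stop("CDR nucleotide length not a multiple of 3; cannot translate")
    as.character(Biostrings::translate(Biostrings::DNAString(s),
                                       if.fuzzy.codon = "X"))
  }, character(1))
  paste(aa, collapse = "")
}

#' Position frequency matrix of a branch
#'
#' Per-position symbol frequencies over the branch's node sequences
#' (clonotype nucleotide sequences, or the translated concatenated CDRs at
#' amino-acid level), each node weighted by its size. Every position's
#' frequencies sum to 1. Dummy roots (size 0) are excluded.
#'
#' @param branch a branch from \code{\link{findBranches}}.
#' @param nodes the tree's named node list (\code{treeNodes(tree)}).
#' @param level "nt" or "aa".
#' @return matrix (positions x symbols) of frequencies.
#' @export
logoMatrix <- function(branch, nodes, level = c("nt", "aa")) {
  level <- match.arg(level)
  use <- Filter(function(n) !isTRUE(n$is_dummy), nodes[branch$node_names])
  if (length(use) == 0L) stop("branch has no non-dummy nodes")
  seqs <- vapply(use, function(n) {
    if (level == "nt") n$clonotype_seq else translateCdrs(n$cdr_seqs)
  }, character(1))
  if (length(unique(nchar(seqs))) != 1L)
    stop("branch sequences differ in length (indels); no logo matrix")
  w <- vapply(use, function(n) n$size, numeric(1))
  chars <- do.call(rbind, strsplit(seqs, ""))
  symbols <- sort(unique(as.vector(chars)))
  L <- ncol(chars)
  freq <- matrix(0, nrow = L, ncol = length(symbols),
                 dimnames = list(seq_len(L), symbols))
  for (pos in seq_len(L)) {
    tab <- tapply(w, chars[, pos], sum)
    freq[pos, names(tab)] <- tab / sum(w)
  }
  freq
}

#' Summarize lineage statistics over a repertoire
#'
#' Single-node lineages (depth 0) represent naive or distant memory cells
#' whose ancestry is unobserved and are excluded from the distributions.
#' Lineages with depth at least \code{depthMin} are flagged deep.
#'
#' @param stats data.frame of per-lineage rows (\code{\link{lineageStats}}).
#' @param depthMin deep-lineage depth threshold (default 2).
#' @return list with \code{perLineage} (the retained rows plus a
#'   \code{deep} flag), distribution tables \code{depth}, \code{isotype},
#'   \code{expansion}, \code{size}, and counts \code{nDeep},
#'   \code{nExcluded}.
#' @export
summarizeRepertoire <- function(stats, depthMin = 2L) {
  keep <- stats[stats$depth > 0, , drop = FALSE]
  keep$deep <- keep$depth >= depthMin
  list(
    perLineage = keep,
    depth = table(keep$depth),
    isotype = table(keep$dominant_isotype),
    expansion = table(keep$expansion),
    size = table(keep$size),
    nDeep = sum(keep$deep),
    nExcluded = nrow(stats) - nrow(keep))
}
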