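# Graph-edit-distance scoring of reconstructed trees against simulated
# ground truth.

#' Graph edit distance between two trees over the same labelled node set
#'
#' With identical, uniquely labelled node sets and zero relabel cost, graph
#' edit distance reduces exactly to the number of directed-edge deletions
#' plus insertions, i.e. the cardinality of the symmetric difference of the
#' two edge sets. For two trees this equals twice the number of nodes whose
#' parent differs.
#'
#' @param trueEdges,reconEdges data.frames with columns parent, child
#'   (node labels).
#' @param trueLabels,reconLabels full node-label sets of the two trees.
#' @return non-negative integer.
#' @export
graphEditDistance <- function(trueEdges, reconEdges,
                              trueLabels, reconLabels) {
  if (!setequal(trueLabels, reconLabels))
    stop("trees are over different node-label sets")
  a <- paste(trueEdges$parent, trueEdges$child, sep = "\r")
  b <- paste(reconEdges$parent, reconEdges$child, sep = "\r")
  length(setdiff(a, b)) + length(setdiff(b, a))
}

#' Reconstruct a simulated lineage and score it
#'
#' Converts the simulated tree to clonotype nodes, rebuilds it with the
#' SHM-ordered inheritance tree algorithm, and returns the graph edit
#' distance between true and reconstructed edges.
#'
#' @param sim a \code{\linkS4class{SimTree}}.
#' @return integer GED.
#' @export
scoreReconstruction <- function(sim) {
  recon <- buildTree(simToCloneNodes(sim), treeName = "sim")
  graphEditDistance(sim@edges, recon@edges[, c("parent", "child")],
                    names(sim@nodes), names(recon@nodes))
}

#' Default benchmark parameter grid
#'
#' Sequence lengths 100 and 200 (single/paired-chain full-CDR scale), node
#' caps 100 and 200, branching means 2, 3 and 4; mutation means 1 and 2 are
#' pooled within each row at run time.
#'
#' @return data.frame with columns L, N, lambdaC (12 rows).
#' @export
defaultBenchmarkGrid <- function() {
  g <- expand.grid(lambdaC = c(2, 3, 4), N = c(100L, 200L),
                   L = c(100L, 200L))
  g[, c("L", "N", "lambdaC")]
}

#' Run the simulation benchmark
#'
#' For each grid row, simulates \code{reps} trees per mutation mean in
#' \code{lambdaMs}, reconstructs each with the SHM-ordered inheritance tree
#' algorithm, and reports the pooled mean graph edit distance.
#' Deterministic for a fixed \code{seed}: tree k uses seed
#' \code{seed + k}.
#'
#' @param grid data.frame with columns L, N, lambdaC (default
#'   \code{\link{defaultBenchmarkGrid}()}).
#' @param reps simulations per (row, lambdaM) combination (default 50).
#' @param lambdaMs mutation means pooled within a row (default c(1, 2)).
#' @param seed base RNG seed.
#' @return data.frame with columns SeqL, N_nodes, lambda_c, lambda_m,
#'   N_trees, mean_GED; per-tree distances are attached as the
#'   \code{"perTree"} attribute (a list of integer vectors).
#' @export
runBenchmark <- function(grid = defaultBenchmarkGrid(), reps = 50L,
                         lambdaMs = c(1, 2), seed = 1L) {
  rows <- list()
  perTree <- list()
  k <- 0L
  for (i in seq_len(nrow(grid))) {
    ged <- integer(0)
    for (lm in lambdaMs) {
      for (r in seq_len(reps)) {
        k <- k + 1L
        sim <- simulateTree(L = grid$L[i], N = grid$N[i],
                            lambdaC = grid$lambdaC[i], lambdaM = lm,
                            seed = seed + k)
        ged <- c(ged, scoreReconstruction(sim))
      }
    }
    rows[[i]] <- data.frame(
      SeqL = grid$L[i], N_nodes = grid$N[i], lambda_c = grid$lambdaC[i],
      lambda_m = paste(lambdaMs, collapse = ", "),
      N_trees = length(ged), mean_GED = mean(ged),
      stringsAsFactors = FALSE)
    perTree[[i]] <- ged
  }
  out <- do.call(rbind, rows)
  attr(out, "perTree") <- perTree
  out
}
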