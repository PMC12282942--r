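# Germinal-centre lineage simulator: ground-truth trees for benchmarking.

applyMutations <- function(germline, muts) {
  if (length(muts) == 0L) return(germline)
  chars <- strsplit(germline, "")[[1]]
  chars[as.integer(names(muts))] <- unname(muts)
  paste(chars, collapse = "")
}

#' Draw a random germline sequence
#'
#' Uniform i.i.d. bases over A/C/G/T.
#'
#' @param L sequence length (>= 1).
#' @return a nucleotide string of length \code{L}.
#' @export
simulateGermline <- function(L) {
  if (L < 1L) stop("L must be >= 1")
  paste(sample(NT, L, replace = TRUE), collapse = "")
}

rztpois <- function(lambda) {
  repeat {
    m <- stats::rpois(1L, lambda)
    if (m >= 1L) return(m)
  }
}

#' Simulate a ground-truth B-cell lineage tree
#'
#' Grows a tree breadth-first from a random germline root. Each node's
#' child count is Poisson(\code{lambdaC}); each child acquires a
#' zero-truncated Poisson(\code{lambdaM}) number of new substitutions at
#' previously unmutated positions (so all parental mutations are inherited
#' and no position ever reverts), with hotspot positions
#' (\code{hotspotFrac} of the sequence) weighted \code{hotspotMult}-fold in
#' position sampling. The mutated base is uniform over the three
#' alternatives. Children whose sequence duplicates an existing node are
#' redrawn (bounded retries) so node sequences stay pairwise distinct.
#' Growth stops the moment the node count reaches \code{N} or a node's
#' mutated fraction reaches \code{stopFrac}.
#'
#' @param L germline length.
#' @param N node cap.
#' @param lambdaC mean children per node.
#' @param lambdaM mean new mutations per child (zero-truncated).
#' @param hotspotFrac fraction of positions designated hotspots (default 0.10).
#' @param hotspotMult relative mutation weight of hotspots (default 3).
#' @param stopFrac mutated-position fraction that terminates growth
#'   (default 0.95).
#' @param seed optional RNG seed (set for reproducibility).
#' @return a \code{\linkS4class{SimTree}}.
#' @export
simulateTree <- function(L = 100L, N = 100L, lambdaC = 2, lambdaM = 1,
                         hotspotFrac = 0.10, hotspotMult = 3,
                         stopFrac = 0.95, seed = NULL) {
  if (L < 1L || N < 1L) stop("L and N must be >= 1")
  stopifnot(lambdaC > 0, lambdaM > 0,
            hotspotFrac > 0, hotspotFrac < 1, stopFrac > 0, stopFrac < 1)
  if (!is.null(seed)) set.seed(seed)
  germline <- simulateGermline(L)
  hotspots <- sort(sample.int(L, max(1L, round(hotspotFrac * L))))
  gchars <- strsplit(germline, "")[[1]]
  weights <- rep(1, L)
  weights[hotspots] <- hotspotMult
  nodes <- list(n1 = stats::setNames(character(0), character(0)))
  seqs <- c(n1 = germline)
  edges <- list()
  queue <- "n1"
  stopped <- FALSE
  while (length(queue) > 0L && !stopped) {
    pid <- queue[1]
    queue <- queue[-1]
    nChildren <- stats::rpois(1L, lambdaC)
    for (j in seq_len(nChildren)) {
      if (length(nodes) >= N) { stopped <- TRUE; break }
      pmut <- nodes[[pid]]
      available <- setdiff(seq_len(L), as.integer(names(pmut)))
      if (length(available) == 0L) break
      child <- NULL
      for (try in 1:25) {
        m <- min(rztpois(lambdaM), length(available))
        pos <- if (length(available) == 1L) available else
          sample(available, m, prob = weights[available])
        bases <- vapply(pos, function(p)
          sample(setdiff(NT, gchars[p]), 1L), character(1))
        cmut <- c(pmut, stats::setNames(bases, pos))
        cseq <- applyMutations(germline, cmut)
        if (!cseq %in% seqs) { child <- list(mut = cmut, seq = cseq); break }
      }
      if (is.null(child)) next
      cid <- paste0("n", length(nodes) + 1L)
      nodes[[cid]] <- child$mut
      seqs[cid] <- child$seq
      edges[[length(edges) + 1L]] <- data.frame(
        parent = pid, child = cid, stringsAsFactors = FALSE)
      queue <- c(queue, cid)
      if (length(child$mut) / L >= stopFrac) { stopped <- TRUE; break }
      if (length(nodes) >= N) { stopped <- TRUE; break }
    }
  }
  edgeDf <- if (length(edges)) do.call(rbind, edges) else
    data.frame(parent = character(0), child = character(0),
               stringsAsFactors = FALSE)
  methods::new("SimTree", germline = germline, hotspots = as.integer(hotspots),
               nodes = nodes, edges = edgeDf, rootId = "n1",
               params = list(L = L, N = N, lambdaC = lambdaC,
                             lambdaM = lambdaM, hotspotFrac = hotspotFrac,
                             hotspotMult = hotspotMult, stopFrac = stopFrac))
}

#' Convert a simulated tree to clonotype nodes
#'
#' Adapter feeding \code{\link{buildTree}}: one node per simulated node,
#' whole sequence treated as a single CDR region, SHM rate = mutation count
#' over sequence length, size 1, isotype unknown.
#'
#' @param sim a \code{\linkS4class{SimTree}}.
#' @return list of clonotype nodes.
#' @export
simToCloneNodes <- function(sim) {
  L <- nchar(sim@germline)
  lapply(names(sim@nodes), function(id) {
    muts <- sim@nodes[[id]]
    keys <- if (length(muts)) mutKey("sim", names(muts), unname(muts))
            else character(0)
    list(
      node_name = id,
      clonotype_seq = applyMutations(sim@germline, muts),
      size = 1L,
      isotype_counts = stats::setNames(1L, "unknown"),
      node_isotype = "unknown",
      shm_rate = length(muts) / L,
      cdr_mutations = keys,
      cdr_seqs = list(),
      member_ids = id,
      members = data.frame(sequence_id = id, cell_id = id,
                           isotype = "unknown", stringsAsFactors = FALSE),
      is_dummy = FALSE
    )
  })
}

#' Write a simulated tree as FASTA plus a true-edge table
#'
#' FASTA holds the node sequences (germline first); the TSV holds the true
#' directed edges (parent_id, child_id).
#'
#' @param sim a \code{\linkS4class{SimTree}}.
#' @param fastaPath,edgesPath output paths.
#' @export
writeSimTree <- function(sim, fastaPath, edgesPath) {
  ids <- c(sim@rootId, setdiff(names(sim@nodes), sim@rootId))
  lines <- unlist(lapply(ids, function(id)
    c(paste0(">", id), applyMutations(sim@germline, sim@nodes[[id]]))))
  writeLines(lines, fastaPath)
  utils::write.table(
    stats::setNames(sim@edges, c("parent_id", "child_id")),
    edgesPath, sep = "\t", quote = FALSE, row.names = FALSE)
}
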