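# The SHM-ordered inheritance tree algorithm.
#
# Nodes (unique clonotypes) are attached in ascending SHM order to the
# closest already-placed node whose CDR mutation set they fully inherit,
# giving a rooted tree with (i) child SHM >= parent SHM on every edge and
# (ii) parent mutations a subset of child mutations on every non-fallback
# edge.

#' Positionwise consensus with 'D' at ambiguous positions
#'
#' Combines equal-length candidate root sequences into a dummy-root
#' sequence: positions where all candidates agree keep the base, any
#' disagreement becomes 'D' (which mismatches every nucleotide in all
#' distance computations).
#'
#' @param seqs character vector of >= 2 equal-length nucleotide strings.
#' @return the consensus string over the alphabet A/C/G/T/D.
#' @export
makeDummyRoot <- function(seqs) {
  if (length(seqs) < 2L) stop("need at least two candidate sequences")
  if (length(unique(nchar(seqs))) != 1L)
    stop("candidate sequences differ in length; cannot form a consensus")
  mat <- do.call(rbind, strsplit(toupper(seqs), ""))
  cons <- apply(mat, 2, function(col)
    if (length(unique(col)) == 1L) col[1] else "D")
  paste(cons, collapse = "")
}

#' Select the root clonotype of a lineage
#'
#' The clonotype with the lowest SHM rate (least diverged from germline)
#' roots the tree. Ties are broken in favour of an unswitched isotype
#' (IgM/IgD) when exactly one tied candidate is unswitched; if ties remain,
#' a dummy root is created: its sequence is the 'D'-consensus of the tied
#' candidates, its SHM rate the tied minimum, and its mutation set the
#' intersection of the tied candidates' mutation sets (so all candidates
#' remain valid children).
#'
#' @param nodes list of clonotype nodes.
#' @return list(root = node, is_dummy = logical).
#' @export
selectRoot <- function(nodes) {
  if (length(nodes) == 0L) stop("cannot select a root from zero nodes")
  shm <- vapply(nodes, function(n) n$shm_rate, numeric(1))
  tied <- which(shm <= min(shm) + 1e-12)
  if (length(tied) == 1L)
    return(list(root = nodes[[tied]], is_dummy = FALSE))
  unswitched <- tied[vapply(nodes[tied], function(n)
    n$node_isotype %in% UNSWITCHED, logical(1))]
  if (length(unswitched) == 1L)
    return(list(root = nodes[[unswitched]], is_dummy = FALSE))
  if (length(unswitched) > 1L) tied <- unswitched
  seqs <- vapply(nodes[tied], function(n) n$clonotype_seq, character(1))
  mutsList <- lapply(nodes[tied], function(n) n$cdr_mutations)
  root <- list(
    node_name = "R",
    clonotype_seq = makeDummyRoot(seqs),
    size = 0L,
    isotype_counts = integer(0),
    node_isotype = "dummy",
    shm_rate = min(shm),
    cdr_mutations = Reduce(intersect, mutsList),
    cdr_seqs = list(),
    member_ids = character(0),
    members = data.frame(sequence_id = character(0),
                         cell_id = character(0),
                         isotype = character(0), stringsAsFactors = FALSE),
    is_dummy = TRUE
  )
  list(root = root, is_dummy = TRUE)
}

#' Test complete inheritance of parental CDR mutations
#'
#' TRUE iff every parent mutation (region, position, observed base) is also
#' present in the child's mutation set. A child carrying a different base at
#' the same position has a different mutation and does not inherit.
#'
#' @param parentMut,childMut character vectors of mutation keys.
#' @return logical.
#' @export
inheritsMutations <- function(parentMut, childMut) {
  all(parentMut %in% childMut)
}

levDist <- function(a, b) {
  as.integer(utils::adist(a, b))
}

#' Normalized edge weight between parent and child sequences
#'
#' Levenshtein distance divided by the parent sequence length. 'D' bases in
#' a dummy-root sequence mismatch every nucleotide.
#'
#' @param parentSeq,childSeq nucleotide strings.
#' @return fraction.
#' @export
edgeWeight <- function(parentSeq, childSeq) {
  if (nchar(parentSeq) == 0L) stop("parent sequence is empty")
  levDist(parentSeq, childSeq) / nchar(parentSeq)
}

#' Build the SHM-ordered inheritance tree of one lineage
#'
#' The root is chosen by \code{\link{selectRoot}}. Remaining nodes are
#' processed in ascending SHM order (ties broken by sequence); each is
#' attached to the candidate parent with the smallest Levenshtein distance
#' among the already-placed nodes whose mutation set it inherits. The root
#' is always a candidate parent (universal-root fallback): when a node
#' inherits no placed node's mutations it still attaches to the root, and
#' that edge is flagged \code{fallback}. Distance ties are broken by higher
#' parent SHM (preferring the most derived valid ancestor), then by parent
#' sequence. Edge weights are Levenshtein distance normalized by parent
#' sequence length.
#'
#' @param nodes list of clonotype nodes (from \code{\link{buildClonotypes}}
#'   or \code{\link{simToCloneNodes}}).
#' @param treeName tree identifier.
#' @param lineageId lineage identifier.
#' @param sampleName sample label carried into output tables.
#' @return a \code{\linkS4class{LineageTree}}.
#' @export
buildTree <- function(nodes, treeName = "tree", lineageId = "L0001",
                      sampleName = "sample") {
  sel <- selectRoot(nodes)
  root <- sel$root
  if (sel$is_dummy) {
    U <- nodes
  } else {
    rootIdx <- which(vapply(nodes, function(n)
      identical(n$clonotype_seq, root$clonotype_seq), logical(1)))[1]
    U <- nodes[-rootIdx]
  }
  shm <- vapply(U, function(n) n$shm_rate, numeric(1))
  sq <- vapply(U, function(n) n$clonotype_seq, character(1))
  U <- U[order(shm, sq, method = "radix")]

  placed <- list(root)
  names(placed) <- root$node_name
  edges <- data.frame(parent = character(0), child = character(0),
                      weight = numeric(0), fallback = logical(0),
                      stringsAsFactors = FALSE)
  for (child in U) {
    pSeqs <- vapply(placed, function(n) n$clonotype_seq, character(1))
    pShm <- vapply(placed, function(n) n$shm_rate, numeric(1))
    valid <- vapply(placed, function(n)
      inheritsMutations(n$cdr_mutations, child$cdr_mutations), logical(1))
    valid[1] <- TRUE  # universal-root fallback: root always a candidate
    cand <- which(valid)
    d <- as.integer(utils::adist(child$clonotype_seq, pSeqs[cand]))
    # smallest distance; ties -> higher parent SHM, then parent sequence
    best <- cand[order(d, -pShm[cand], pSeqs[cand], method = "radix")[1]]
    isFallback <- !inheritsMutations(placed[[best]]$cdr_mutations,
                                     child$cdr_mutations)
    edges <- rbind(edges, data.frame(
      parent = placed[[best]]$node_name, child = child$node_name,
      weight = edgeWeight(pSeqs[best], child$clonotype_seq),
      fallback = isFallback, stringsAsFactors = FALSE))
    placed[[child$node_name]] <- child
  }
  methods::new("LineageTree", treeName = treeName, lineageId = lineageId,
               nodes = placed, edges = edges, root = root$node_name,
               sampleName = sampleName)
}
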