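#' @import methods
NULL

ALLOWED_LOCI <- c("IGH", "IGK", "IGL")
ISOTYPES <- c("IgM", "IgD", "IgG", "IgA", "IgE", "unknown")
UNSWITCHED <- c("IgM", "IgD")

#' BCRRepertoire: a parsed B-cell receptor repertoire
#'
#' Container for one repertoire sample. Chain-level records are kept as a
#' data.frame (one row per AIRR rearrangement row retained at parse time);
#' \code{cells} holds the cell-level view used by all downstream steps: in
#' bulk mode one cell per heavy-chain record, in single-cell mode one cell
#' per barcode with exactly one productive heavy and one productive light
#' chain.
#'
#' @slot records data.frame of accepted AIRR rows (required columns intact).
#' @slot cells list of cell objects; each is a list with elements
#'   \code{cell_id}, \code{heavy}, \code{light} (or NULL), \code{isotype}.
#' @slot mode "single_cell" or "bulk".
#' @slot sampleName sample label used in tree names and output tables.
#' @exportClass BCRRepertoire
setClass("BCRRepertoire",
  representation(
    records = "data.frame",
    cells = "list",
    mode = "character",
    sampleName = "character"
  ),
  prototype(records = data.frame(), cells = list(), mode = "bulk",
            sampleName = "sample")
)

setValidity("BCRRepertoire", function(object) {
  msg <- character()
  if (!object@mode %in% c("single_cell", "bulk"))
    msg <- c(msg, "mode must be 'single_cell' or 'bulk'")
  if (object@mode == "single_cell" && length(object@cells) > 0L) {
    ids <- vapply(object@cells, function(c) c$cell_id, character(1))
    if (anyDuplicated(ids))
      msg <- c(msg, "single_cell mode requires distinct cell_ids")
  }
  if (length(msg)) msg else TRUE
})

#' LineageTree: an SHM-ordered inheritance tree over clonotype nodes
#'
#' Rooted directed tree for one clonal lineage. Nodes are unique clonotypes
#' (possibly plus one dummy root); every edge points from parent to child,
#' child SHM rate >= parent SHM rate on all edges, and on every non-fallback
#' edge the parent's CDR mutation set is a subset of the child's.
#'
#' @slot treeName text identifier (sample, V genes, CDR lengths).
#' @slot lineageId identifier of the source lineage.
#' @slot nodes named list of clonotype nodes (see \code{\link{buildClonotypes}}).
#' @slot edges data.frame with columns parent, child, weight (normalized
#'   Levenshtein distance), fallback (logical: attached through the
#'   universal-root fallback).
#' @slot root node name of the root.
#' @slot sampleName sample the lineage came from.
#' @exportClass LineageTree
setClass("LineageTree",
  representation(
    treeName = "character",
    lineageId = "character",
    nodes = "list",
    edges = "data.frame",
    root = "character",
    sampleName = "character"
  ),
  prototype(sampleName = "sample")
)

setValidity("LineageTree", function(object) {
  msg <- character()
  nn <- names(object@nodes)
  e <- object@edges
  if (nrow(e) != length(object@nodes) - 1L)
    msg <- c(msg, "edge count must be node count - 1")
  if (!object@root %in% nn)
    msg <- c(msg, "root must be a node")
  if (nrow(e) > 0L) {
    if (anyDuplicated(e$child))
      msg <- c(msg, "every non-root node must have exactly one parent")
    if (object@root %in% e$child)
      msg <- c(msg, "root cannot have a parent")
    shm <- vapply(object@nodes, function(n) n$shm_rate, numeric(1))
    if (any(shm[e$child] < shm[e$parent] - 1e-12))
      msg <- c(msg, "SHM ordering violated: child shm < parent shm on an edge")
    for (i in seq_len(nrow(e))) {
      if (isTRUE(e$fallback[i])) next
      pm <- object@nodes[[e$parent[i]]]$cdr_mutations
      cm <- object@nodes[[e$child[i]]]$cdr_mutations
      if (!all(pm %in% cm)) {
        msg <- c(msg, "inheritance violated on a non-fallback edge")
        break
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' SimTree: a simulated ground-truth B-cell lineage
#'
#' Ground truth produced by \code{\link{simulateTree}}: a germline root plus
#' descendants, each carrying its parent's mutations and at least one new
#' substitution, with known true edges and hotspot positions.
#'
#' @slot germline germline nucleotide sequence (the root sequence).
#' @slot hotspots integer positions (1-based) with elevated mutation weight.
#' @slot nodes named list; each element is a named character vector mapping
#'   1-based positions to mutated bases (empty for the root).
#' @slot edges data.frame with columns parent, child (node ids).
#' @slot rootId id of the germline node.
#' @slot params the simulation parameter list.
#' @exportClass SimTree
setClass("SimTree",
  representation(
    germline = "character",
    hotspots = "integer",
    nodes = "list",
    edges = "data.frame",
    rootId = "character",
    params = "list"
  )
)

setValidity("SimTree", function(object) {
  msg <- character()
  if (length(object@nodes[[object@rootId]]) != 0L)
    msg <- c(msg, "root mutation set must be empty")
  e <- object@edges
  for (i in seq_len(nrow(e))) {
    pm <- object@nodes[[e$parent[i]]]
    cm <- object@nodes[[e$child[i]]]
    if (length(pm) >= length(cm) ||
        !all(paste0(names(pm), pm) %in% paste0(names(cm), cm))) {
      msg <- c(msg, "child mutations must strictly contain parent mutations")
      break
    }
  }
  seqs <- vapply(names(object@nodes), function(id)
    applyMutations(object@germline, object@nodes[[id]]), character(1))
  if (anyDuplicated(seqs))
    msg <- c(msg, "node sequences must be pairwise distinct")
  if (length(msg)) msg else TRUE
})

# ---- accessors ----

#' @describeIn BCRRepertoire-accessors cell list
#' @export
setGeneric("cells", function(x) standardGeneric("cells"))
#' @export
setMethod("cells", "BCRRepertoire", function(x) x@cells)

#' Accessors for repertoire, tree and simulation objects
#'
#' @param x a \code{BCRRepertoire}, \code{LineageTree} or \code{SimTree}.
#' @name accessors
#' @aliases cells repertoireMode sampleName airrRecords treeNodes treeEdges
#'   rootName treeName simGermline simNodes simEdges simHotspots
NULL

#' @rdname accessors
#' @export
setGeneric("repertoireMode", function(x) standardGeneric("repertoireMode"))
setMethod("repertoireMode", "BCRRepertoire", function(x) x@mode)

#' @rdname accessors
#' @export
setGeneric("sampleName", function(x) standardGeneric("sampleName"))
setMethod("sampleName", "BCRRepertoire", function(x) x@sampleName)

#' @rdname accessors
#' @export
setGeneric("airrRecords", function(x) standardGeneric("airrRecords"))
setMethod("airrRecords", "BCRRepertoire", function(x) x@records)

#' @rdname accessors
#' @export
setGeneric("treeNodes", function(x) standardGeneric("treeNodes"))
setMethod("treeNodes", "LineageTree", function(x) x@nodes)

#' @rdname accessors
#' @export
setGeneric("treeEdges", function(x) standardGeneric("treeEdges"))
setMethod("treeEdges", "LineageTree", function(x) x@edges)

#' @rdname accessors
#' @export
setGeneric("rootName", function(x) standardGeneric("rootName"))
setMethod("rootName", "LineageTree", function(x) x@root)

#' @rdname accessors
#' @export
setGeneric("treeName", function(x) standardGeneric("treeName"))
setMethod("treeName", "LineageTree", function(x) x@treeName)

#' @rdname accessors
#' @export
setGeneric("simGermline", function(x) standardGeneric("simGermline"))
setMethod("simGermline", "SimTree", function(x) x@germline)

#' @rdname accessors
#' @export
setGeneric("simNodes", function(x) standardGeneric("simNodes"))
setMethod("simNodes", "SimTree", function(x) x@nodes)

#' @rdname accessors
#' @export
setGeneric("simEdges", function(x) standardGeneric("simEdges"))
setMethod("simEdges", "SimTree", function(x) x@edges)

#' @rdname accessors
#' @export
setGeneric("simHotspots", function(x) standardGeneric("simHotspots"))
setMethod("simHotspots", "SimTree", function(x) x@hotspots)

setMethod("show", "BCRRepertoire", function(object) {
  cat("BCRRepertoire '", object@sampleName, "' (", object@mode, ")\n",
      sep = "")
  cat("  ", length(object@cells), " cells, ", nrow(object@records),
      " chain records\n", sep = "")
})

setMethod("show", "LineageTree", function(object) {
  cat("LineageTree '", object@treeName, "'\n", sep = "")
  cat("  ", length(object@nodes), " nodes, ", nrow(object@edges),
      " edges, root = ", object@root,
      ", depth = ", treeDepth(object), "\n", sep = "")
})

setMethod("show", "SimTree", function(object) {
  cat("SimTree: ", length(object@nodes), " nodes, germline length ",
      nchar(object@germline), ", ", length(object@hotspots),
      " hotspot positions\n", sep = "")
})
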