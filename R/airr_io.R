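# Reading, validating and pairing AIRR rearrangement records.

AIRR_REQUIRED <- c(
  "sequence_id", "sequence", "productive", "locus", "v_call", "j_call",
  "sequence_alignment", "germline_alignment",
  "fwr1", "fwr1_aa", "cdr1", "cdr1_aa",
  "fwr2", "fwr2_aa", "cdr2", "cdr2_aa",
  "fwr3", "fwr3_aa", "cdr3", "cdr3_aa",
  "fwr4", "fwr4_aa"
)

parseProductive <- function(x) {
  out <- rep(NA, length(x))
  out[x %in% c("T", "TRUE", "true")] <- TRUE
  out[x %in% c("F", "FALSE", "false")] <- FALSE
  out
}

# cell barcode: explicit cell_id column, else the 10x-style contig prefix
# (sequence_id up to the last "_").
deriveCellId <- function(df) {
  if ("cell_id" %in% names(df) && any(nzchar(df$cell_id))) {
    df$cell_id
  } else {
    sub("_[^_]*$", "", df$sequence_id)
  }
}

isotypeFromCcall <- function(c_call) {
  if (is.null(c_call) || is.na(c_call) || !nzchar(c_call)) return("unknown")
  if (startsWith(c_call, "IGHM")) return("IgM")
  if (startsWith(c_call, "IGHD")) return("IgD")
  if (startsWith(c_call, "IGHG")) return("IgG")
  if (startsWith(c_call, "IGHA")) return("IgA")
  if (startsWith(c_call, "IGHE")) return("IgE")
  "unknown"
}

recordToChain <- function(row) {
  chain <- as.list(row)
  chain$productive <- parseProductive(row[["productive"]])
  chain
}

#' Read an AIRR rearrangement TSV into a repertoire
#'
#' Parses a tab-separated AIRR rearrangement file, validates that all
#' required columns are present, and assembles cells: one cell per
#' heavy-chain record in bulk mode, or one cell per barcode with exactly one
#' productive heavy and one productive light chain in single-cell mode
#' (ambiguous barcodes are dropped with a message).
#'
#' Rows whose \code{productive} value is not one of T/TRUE/true/F/FALSE/false,
#' or whose \code{sequence_alignment} and \code{germline_alignment} lengths
#' differ, are rejected with a warning.
#'
#' @param path path to the TSV file.
#' @param mode "single_cell" (paired heavy/light) or "bulk" (heavy only).
#' @param sampleName sample label (defaults to the file name without
#'   extension).
#' @return a \code{\linkS4class{BCRRepertoire}}.
#' @export
readAIRR <- function(path, mode = c("bulk", "single_cell"),
                     sampleName = NULL) {
  mode <- match.arg(mode)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sampleName))
    sampleName <- sub("\\.[^.]*$", "", basename(path))
  df <- utils::read.delim(path, colClasses = "character",
                          check.names = FALSE, stringsAsFactors = FALSE)
  missing <- setdiff(AIRR_REQUIRED, names(df))
  if (length(missing))
    stop("missing required AIRR column(s): ", paste(missing, collapse = ", "))
  if (nrow(df) > 0L) {
    prod <- parseProductive(df$productive)
    badProd <- is.na(prod)
    badLen <- nchar(df$sequence_alignment) != nchar(df$germline_alignment)
    drop <- badProd | badLen
    if (any(badProd))
      warning(sum(badProd), " row(s) rejected: unparseable 'productive' value")
    if (any(badLen))
      warning(sum(badLen),
              " row(s) rejected: sequence/germline alignment length mismatch")
    df <- df[!drop, , drop = FALSE]
  }
  cellList <- if (mode == "bulk") bulkCells(df) else pairCells(df)
  methods::new("BCRRepertoire", records = df, cells = cellList,
               mode = mode, sampleName = sampleName)
}

bulkCells <- function(df) {
  keep <- which(df$locus == "IGH")
  if (length(keep) < nrow(df))
    message(nrow(df) - length(keep), " non-IGH record(s) ignored in bulk mode")
  lapply(keep, function(i) {
    heavy <- recordToChain(df[i, ])
    list(cell_id = deriveCellId(df[i, , drop = FALSE]),
         heavy = heavy, light = NULL,
         isotype = isotypeFromCcall(heavy$c_call))
  })
}

#' Pair heavy and light chains into cells
#'
#' Groups records by cell barcode and keeps barcodes having exactly one
#' productive heavy (IGH) and exactly one productive light (IGK/IGL) chain;
#' barcodes with zero or multiple productive chains of either class are
#' dropped and counted in a message.
#'
#' @param df data.frame of AIRR records (character columns).
#' @return list of cell objects.
#' @export
pairCells <- function(df) {
  if (nrow(df) == 0L) return(list())
  df$.cell_id <- deriveCellId(df)
  prod <- parseProductive(df$productive)
  out <- list()
  dropped <- 0L
  for (cid in unique(df$.cell_id)) {
    rows <- df[df$.cell_id == cid, , drop = FALSE]
    p <- prod[df$.cell_id == cid]
    hIdx <- which(rows$locus == "IGH" & p)
    lIdx <- which(rows$locus %in% c("IGK", "IGL") & p)
    if (length(hIdx) != 1L || length(lIdx) != 1L) {
      dropped <- dropped + 1L
      next
    }
    heavy <- recordToChain(rows[hIdx, setdiff(names(rows), ".cell_id")])
    light <- recordToChain(rows[lIdx, setdiff(names(rows), ".cell_id")])
    out[[length(out) + 1L]] <- list(
      cell_id = cid, heavy = heavy, light = light,
      isotype = isotypeFromCcall(heavy$c_call))
  }
  if (dropped > 0L)
    message(dropped, " barcode(s) dropped: not exactly one productive ",
            "heavy and one productive light chain")
  out
}

chainFunctional <- function(chain) {
  isTRUE(chain$productive) &&
    chain$locus %in% ALLOWED_LOCI &&
    nzchar(chain$cdr1) && nzchar(chain$cdr2) && nzchar(chain$cdr3)
}

#' Keep only functional cells
#'
#' Retains cells whose chains are all productive, on a recognized locus
#' (IGH/IGK/IGL), and carry non-empty CDR1, CDR2 and CDR3 nucleotide fields.
#' Filtering never errors; the number of dropped cells is reported in a
#' message. Idempotent.
#'
#' @param rep a \code{\linkS4class{BCRRepertoire}}.
#' @return the filtered repertoire.
#' @export
filterFunctional <- function(rep) {
  keep <- vapply(rep@cells, function(cell) {
    ok <- chainFunctional(cell$heavy)
    if (!is.null(cell$light)) ok <- ok && chainFunctional(cell$light)
    ok
  }, logical(1))
  if (length(keep) && any(!keep))
    message(sum(!keep), " cell(s) dropped by functional filter")
  methods::initialize(rep, cells = rep@cells[keep])
}

#' Write repertoire records back to an AIRR TSV
#'
#' Writes the retained chain-level records (all required AIRR columns, plus
#' any optional columns present at read time) as a tab-separated file.
#'
#' @param rep a \code{\linkS4class{BCRRepertoire}}.
#' @param path output path.
#' @export
writeAIRR <- function(rep, path) {
  utils::write.table(rep@records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
}

#' Write the cell-to-node mapping table
#'
#' One row per member cell/sequence across all trees, with the node each
#' member collapsed into, the node's size, isotype and SHM rate, and the
#' node's parent and incoming edge weight (empty for roots).
#'
#' @param trees list of \code{\linkS4class{LineageTree}} objects.
#' @param path output CSV path.
#' @return the table, invisibly.
#' @export
writeNodeTable <- function(trees, path) {
  cols <- c("sequence_id", "cell_id", "sample", "lineage_id", "tree_name",
            "node_name", "node_size", "isotype", "shm_rate", "parent_node",
            "edge_weight")
  rows <- list()
  for (tr in trees) {
    e <- tr@edges
    for (nm in names(tr@nodes)) {
      node <- tr@nodes[[nm]]
      if (isTRUE(node$is_dummy)) next
      ei <- match(nm, e$child)
      parent <- if (is.na(ei)) "" else e$parent[ei]
      weight <- if (is.na(ei)) "" else format(e$weight[ei])
      mem <- node$members
      for (i in seq_len(nrow(mem))) {
        rows[[length(rows) + 1L]] <- data.frame(
          sequence_id = mem$sequence_id[i], cell_id = mem$cell_id[i],
          sample = tr@sampleName, lineage_id = tr@lineageId,
          tree_name = tr@treeName, node_name = nm,
          node_size = node$size, isotype = node$node_isotype,
          shm_rate = node$shm_rate, parent_node = parent,
          edge_weight = weight, stringsAsFactors = FALSE)
      }
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    stats::setNames(data.frame(matrix(nrow = 0, ncol = length(cols))), cols)
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(tab)
}
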