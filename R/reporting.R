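# End-to-end repertoire analysis and report/figure-twin assembly.

ISO_LETTER <- c(IgM = "M", IgD = "D", IgG = "G", IgA = "A", IgE = "E",
                unknown = "U")

#' Isotype/size annotation label of a node
#'
#' Letters (A/D/E/G/M, U for unknown) with member counts in alphabetical
#' order -- "G2" for two IgG cells, "A1G1" for one IgA and one IgG cell --
#' followed by the SHM rate in scientific notation with three decimals.
#'
#' @param node a clonotype node.
#' @return label text.
#' @export
annotateNodeLabel <- function(node) {
  counts <- node$isotype_counts
  if (length(counts) == 0L) {
    iso <- "dummy"
  } else {
    letters <- ISO_LETTER[names(counts)]
    ord <- order(letters, method = "radix")
    iso <- paste0(letters[ord], counts[ord], collapse = "")
  }
  paste0(node$node_name, "|", iso, "|", sprintf("%.3e", node$shm_rate))
}

isotypeShape <- function(isotype) {
  switch(isotype,
         IgM = , IgD = "triangle",
         IgG = "circle",
         IgA = "rectangle",
         dummy = "diamond",
         "ellipse")
}

#' Tree name following the sample/V-genes/CDR-lengths convention
#'
#' Sample name, heavy V gene, light V gene (single-cell), then the CDR
#' lengths in the order CDRH1, CDRL1, CDRH2, CDRL2, CDRH3, CDRL3, joined by
#' underscores.
#'
#' @param sampleName sample label.
#' @param key a lineage key (\code{\link{lineageKey}}).
#' @return text.
#' @export
treeNameFor <- function(sampleName, key) {
  lens <- key$cdr_lengths
  parts <- c(sampleName, key$v_heavy)
  if (!is.na(key$v_light)) {
    parts <- c(parts, key$v_light,
               lens["cdrh1"], lens["cdrl1"], lens["cdrh2"],
               lens["cdrl2"], lens["cdrh3"], lens["cdrl3"])
  } else {
    parts <- c(parts, lens["cdrh1"], lens["cdrh2"], lens["cdrh3"])
  }
  paste(parts, collapse = "_")
}

#' Write a lineage tree as a Graphviz DOT file
#'
#' Node shape encodes isotype (triangle = unswitched IgM/IgD, circle = IgG,
#' rectangle = IgA), node area is proportional to node size, labels carry
#' \code{\link{annotateNodeLabel}} annotations, and edges are labelled with
#' the normalized edit distance to three significant digits.
#'
#' @param tree a \code{\linkS4class{LineageTree}}.
#' @param path output path.
#' @export
writeTreeDot <- function(tree, path) {
  lines <- c(sprintf("digraph \"%s\" {", tree@treeName))
  for (nm in names(tree@nodes)) {
    n <- tree@nodes[[nm]]
    width <- 0.5 * sqrt(max(n$size, 1))
    lines <- c(lines, sprintf(
      "  \"%s\" [label=\"%s\", shape=%s, width=%.3f, height=%.3f, fixedsize=true];",
      nm, annotateNodeLabel(n), isotypeShape(n$node_isotype), width, width))
  }
  e <- tree@edges
  for (i in seq_len(nrow(e))) {
    lines <- c(lines, sprintf(
      "  \"%s\" -> \"%s\" [label=\"%s\"%s];",
      e$parent[i], e$child[i], format(signif(e$weight[i], 3)),
      if (isTRUE(e$fallback[i])) ", style=dashed" else ""))
  }
  writeLines(c(lines, "}"), path)
}

#' Write a lineage tree as machine-readable JSON
#'
#' @param tree a \code{\linkS4class{LineageTree}}.
#' @param path output path.
#' @export
writeTreeJSON <- function(tree, path) {
  nodes <- lapply(tree@nodes, function(n) list(
    name = n$node_name, sequence = n$clonotype_seq, size = n$size,
    isotype = n$node_isotype,
    isotype_counts = as.list(n$isotype_counts),
    shm_rate = n$shm_rate, is_dummy = isTRUE(n$is_dummy),
    members = n$members$sequence_id))
  jsonlite::write_json(
    list(tree_name = tree@treeName, lineage_id = tree@lineageId,
         sample = tree@sampleName, root = tree@root,
         nodes = unname(nodes), edges = tree@edges),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

writeLogoTsv <- function(freq, path) {
  df <- data.frame(position = seq_len(nrow(freq)), freq,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full repertoire analysis
#'
#' Reads an AIRR TSV, filters to functional cells, groups lineages, builds
#' one SHM-ordered inheritance tree per lineage, and writes to
#' \code{outDir}: per-lineage DOT and JSON trees (lineages with depth >=
#' \code{depthMin}, or all when \code{all = TRUE}), the cell-to-node mapping
#' CSV (\code{nodes.csv}, all lineages), branch logo matrices
#' (nucleotide and amino-acid TSVs) for branches of interest, per-lineage
#' statistics (\code{lineage_stats.tsv}) and the repertoire summary
#' distributions (\code{summary.tsv}). Outputs are deterministic for a
#' fixed input and configuration.
#'
#' @param input path to an AIRR rearrangement TSV.
#' @param outDir output directory (created if needed).
#' @param mode "bulk" or "single_cell".
#' @param grouping "strict" or "loose" clonal grouping.
#' @param clonotype node definition, "vregion" or "fullcdr".
#' @param shm SHM combination method, "mean" (default), "max" or "heavy".
#' @param depthMin depth threshold for emitting tree files (default 2).
#' @param wMax,dMin,sMin branch-of-interest parameters (defaults 0.1, 2, 5).
#' @param all emit tree files for every lineage regardless of depth.
#' @param sampleName sample label (defaults to the input file name).
#' @return invisibly, a list with \code{trees}, \code{stats} and
#'   \code{summary}.
#' @export
runRepertoire <- function(input, outDir, mode = c("bulk", "single_cell"),
                          grouping = c("strict", "loose"),
                          clonotype = c("vregion", "fullcdr"),
                          shm = c("mean", "max", "heavy"),
                          depthMin = 2L, wMax = 0.1, dMin = 2L, sMin = 5L,
                          all = FALSE, sampleName = NULL) {
  mode <- match.arg(mode)
  grouping <- match.arg(grouping)
  clonotype <- match.arg(clonotype)
  shm <- match.arg(shm)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  rep <- readAIRR(input, mode = mode, sampleName = sampleName)
  rep <- filterFunctional(rep)
  if (length(rep@cells) == 0L) {
    warning("no functional cells after filtering; writing empty outputs")
    writeNodeTable(list(), file.path(outDir, "nodes.csv"))
    return(invisible(list(trees = list(), stats = NULL, summary = NULL)))
  }
  lineages <- groupLineages(rep, criteria = grouping)
  trees <- lapply(lineages, function(lin) {
    nodes <- buildClonotypes(lin, definition = clonotype, shmMethod = shm)
    buildTree(nodes, treeName = treeNameFor(rep@sampleName, lin$key),
              lineageId = lin$lineage_id, sampleName = rep@sampleName)
  })
  stats <- do.call(rbind, lapply(trees, lineageStats))
  writeNodeTable(trees, file.path(outDir, "nodes.csv"))
  utils::write.table(stats, file.path(outDir, "lineage_stats.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  summ <- summarizeRepertoire(stats, depthMin = depthMin)
  summLines <- c("metric\tvalue\tcount")
  for (metric in c("depth", "isotype", "expansion", "size")) {
    tab <- summ[[metric]]
    summLines <- c(summLines, sprintf("%s\t%s\t%d", metric, names(tab),
                                      as.integer(tab)))
  }
  summLines <- c(summLines, sprintf("deep_lineages\t>=%d\t%d", depthMin,
                                    summ$nDeep))
  writeLines(summLines, file.path(outDir, "summary.tsv"))
  for (tr in trees) {
    if (!all && treeDepth(tr) < depthMin) next
    base <- file.path(outDir, tr@treeName)
    writeTreeDot(tr, paste0(base, ".dot"))
    writeTreeJSON(tr, paste0(base, ".json"))
    branches <- findBranches(tr, wMax = wMax, dMin = dMin, sMin = sMin)
    for (bi in seq_along(branches)) {
      for (level in c("nt", "aa")) {
        freq <- tryCatch(
          logoMatrix(branches[[bi]], tr@nodes, level = level),
          error = function(e) {
            message("no ", level, " logo for ", tr@treeName, " branch ",
                    bi, ": ", conditionMessage(e))
            NULL
          })
        if (!is.null(freq))
          writeLogoTsv(freq, sprintf("%s_branch%d_%s.tsv", base, bi, level))
      }
    }
  }
  invisible(list(trees = trees, stats = stats, summary = summ))
}
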