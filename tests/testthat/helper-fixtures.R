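# Fixture builders and independent oracles shared by the test files.

# Independent Levenshtein oracle: plain dynamic-programming implementation,
# deliberately separate from the distance used inside the package.
levOracle <- function(a, b) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  prev <- 0:m
  for (i in seq_len(n)) {
    cur <- c(i, rep(0L, m))
    for (j in seq_len(m)) {
      cur[j + 1] <- min(prev[j + 1] + 1L, cur[j] + 1L,
                        prev[j] + (x[i] != y[j]))
    }
    prev <- cur
  }
  prev[m + 1]
}

HEAVY_FWR <- list(fwr1 = "AAAC", fwr2 = "CCCC", fwr3 = "TTTT", fwr4 = "GGGG")
LIGHT_FWR <- list(fwr1 = "AACA", fwr2 = "CCGC", fwr3 = "TTAT", fwr4 = "GGCG")

# One AIRR rearrangement row as a named character vector. Alignments are
# ungapped concatenations FWR1+CDR1+...+FWR4; the germline differs from the
# observed sequence only in the germline CDR arguments.
airrRow <- function(id, cell = NULL, locus = "IGH",
                    v = "IGHV1-1*01", j = "IGHJ4*02", c_call = "IGHG1",
                    productive = "T",
                    cdr1 = "TGGTAC", cdr2 = "GGTACC", cdr3 = "TGCGCGCGA",
                    gcdr1 = cdr1, gcdr2 = cdr2, gcdr3 = cdr3,
                    seq_align = NULL, germ_align = NULL) {
  fwr <- if (locus == "IGH") HEAVY_FWR else LIGHT_FWR
  seqnt <- paste0(fwr$fwr1, cdr1, fwr$fwr2, cdr2, fwr$fwr3, cdr3, fwr$fwr4)
  germ <- paste0(fwr$fwr1, gcdr1, fwr$fwr2, gcdr2, fwr$fwr3, gcdr3, fwr$fwr4)
  row <- c(
    sequence_id = id, sequence = seqnt, productive = productive,
    locus = locus, v_call = v, j_call = j,
    sequence_alignment = if (is.null(seq_align)) seqnt else seq_align,
    germline_alignment = if (is.null(germ_align)) germ else germ_align,
    fwr1 = fwr$fwr1, fwr1_aa = "X", cdr1 = cdr1, cdr1_aa = "X",
    fwr2 = fwr$fwr2, fwr2_aa = "X", cdr2 = cdr2, cdr2_aa = "X",
    fwr3 = fwr$fwr3, fwr3_aa = "X", cdr3 = cdr3, cdr3_aa = "X",
    fwr4 = fwr$fwr4, fwr4_aa = "X", c_call = c_call)
  if (!is.null(cell)) row <- c(row, cell_id = cell)
  row
}

writeAirrFixture <- function(rows, path, dropCols = character(0)) {
  df <- if (length(rows) == 0L) {
    as.data.frame(rbind(airrRow("template")),
                  stringsAsFactors = FALSE)[0, , drop = FALSE]
  } else {
    as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  }
  df <- df[, setdiff(names(df), dropCols), drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  path
}

readFixture <- function(rows, mode = "bulk", ...) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeAirrFixture(rows, path, ...)
  readAIRR(path, mode = mode)
}

# Minimal clonotype node for direct tree-building tests.
mkNode <- function(name, seq, muts = character(0), shm = length(muts) / nchar(seq),
                   iso = "IgG", size = 1L) {
  list(node_name = name, clonotype_seq = seq, size = size,
       isotype_counts = stats::setNames(as.integer(size), iso),
       node_isotype = iso, shm_rate = shm, cdr_mutations = muts,
       cdr_seqs = list(),
       member_ids = paste0(name, "_m", seq_len(size)),
       members = data.frame(sequence_id = paste0(name, "_m", seq_len(size)),
                            cell_id = paste0(name, "_m", seq_len(size)),
                            isotype = iso, stringsAsFactors = FALSE),
       is_dummy = FALSE)
}

mut <- function(pos, base) paste("sim", pos, base, sep = "|")

# Apply "sim|pos|base" mutation keys (1-based positions) to a sequence.
applyMut <- function(seq, muts) {
  chars <- strsplit(seq, "")[[1]]
  for (m in muts) {
    parts <- strsplit(m, "|", fixed = TRUE)[[1]]
    chars[as.integer(parts[2])] <- parts[3]
  }
  paste(chars, collapse = "")
}

# 6-node chain over a length-20 germline; each step substitutes
# mutsPerStep positions spread 5 apart (so substitution counts equal
# Levenshtein distances), giving uniform edge weights mutsPerStep / 20.
chainTreeWeighted <- function(mutsPerStep) {
  germ <- paste(rep("ACGTA", 4), collapse = "")
  nodes <- list(mkNode("1", germ, character(0), 0))
  acc <- character(0)
  for (i in 1:5) {
    pos <- seq(i, 20, by = 5)[seq_len(mutsPerStep)]
    acc <- c(acc, vapply(pos, function(p) {
      base <- setdiff(c("A", "C", "G", "T"), substr(germ, p, p))[1]
      mut(p, base)
    }, character(1)))
    nodes[[i + 1]] <- mkNode(as.character(i + 1), applyMut(germ, acc), acc,
                             length(acc) / 20)
  }
  buildTree(nodes)
}

# Germline-rooted chain: each node adds one substitution on top of its
# parent's mutations.
chainNodes <- function(germline = "ACGTACGTAC",
                       steps = list(mut(3, "A"), mut(7, "T"), mut(10, "G"))) {
  nodes <- list(mkNode("1", germline, character(0), 0))
  acc <- character(0)
  for (i in seq_along(steps)) {
    acc <- c(acc, steps[[i]])
    nodes[[i + 1]] <- mkNode(as.character(i + 1), applyMut(germline, acc),
                             acc, length(acc) / nchar(germline))
  }
  nodes
}
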