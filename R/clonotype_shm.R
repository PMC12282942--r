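# Clonotype collapsing, SHM rate calculation and CDR mutation calling.

NT <- c("A", "C", "G", "T")

mutKey <- function(region, pos, base) paste(region, pos, base, sep = "|")

#' Mutation fraction of one chain against its germline
#'
#' Fraction of mismatching positions between the gapped V-region sequence
#' alignment and the gapped germline alignment. A position is comparable
#' only when both characters are unambiguous nucleotides (A/C/G/T); gaps,
#' dots and N are excluded from numerator and denominator. Returns 0 when
#' no position is comparable.
#'
#' @param seqAlign gapped observed nucleotide string.
#' @param germAlign gapped germline nucleotide string, same length.
#' @return mutation fraction in [0, 1].
#' @export
computeChainSHM <- function(seqAlign, germAlign) {
  if (nchar(seqAlign) != nchar(germAlign))
    stop("sequence and germline alignments differ in length")
  s <- strsplit(toupper(seqAlign), "")[[1]]
  g <- strsplit(toupper(germAlign), "")[[1]]
  comparable <- s %in% NT & g %in% NT
  if (!any(comparable)) return(0)
  sum(s[comparable] != g[comparable]) / sum(comparable)
}

#' Combine heavy- and light-chain SHM rates
#'
#' @param h heavy-chain SHM fraction.
#' @param l light-chain SHM fraction, or NULL.
#' @param method "heavy" (heavy alone), "max", or "mean" (the default used
#'   throughout the pipeline for paired data).
#' @return combined fraction.
#' @export
combineSHM <- function(h, l = NULL, method = c("mean", "max", "heavy")) {
  method <- match.arg(method)
  if (method == "heavy") return(h)
  if (is.null(l))
    stop("method '", method, "' requires a light-chain SHM rate")
  switch(method, max = max(h, l), mean = (h + l) / 2)
}

# map each position of the ungapped sequence to its column in the gapped
# alignment
ungappedToAligned <- function(alignChars) {
  which(!alignChars %in% c(".", "-"))
}

chainCdrMutations <- function(chain, regions) {
  s <- strsplit(toupper(chain$sequence_alignment), "")[[1]]
  g <- strsplit(toupper(chain$germline_alignment), "")[[1]]
  map <- ungappedToAligned(s)
  ungapped <- paste(s[map], collapse = "")
  muts <- character()
  cdrFields <- c("cdr1", "cdr2", "cdr3")
  for (i in seq_along(regions)) {
    cdr <- toupper(chain[[cdrFields[i]]])
    at <- regexpr(cdr, ungapped, fixed = TRUE)[1]
    if (at < 0)
      stop("CDR field '", cdrFields[i],
           "' not found inside the sequence alignment of ",
           chain$sequence_id)
    cols <- map[at:(at + nchar(cdr) - 1L)]
    start <- cols[1]
    for (col in cols) {
      if (s[col] %in% NT && g[col] %in% NT && s[col] != g[col])
        muts <- c(muts, mutKey(regions[i], col - start, s[col]))
    }
  }
  muts
}

#' Call CDR mutations of a cell against its germline
#'
#' Compares each CDR (heavy cdrh1-3 and, when present, light cdrl1-3)
#' against the germline alignment and returns the set of substitutions as
#' strings "region|position|base", where position is the 0-based offset
#' within the gapped CDR slice of the alignment and base is the observed
#' nucleotide. Only positions where both observed and germline characters
#' are A/C/G/T are considered. The observed base is part of the mutation's
#' identity: a different base at the same site is a different mutation.
#'
#' @param cell a cell object.
#' @return character vector of mutation keys (possibly empty).
#' @export
callCdrMutations <- function(cell) {
  muts <- chainCdrMutations(cell$heavy, c("cdrh1", "cdrh2", "cdrh3"))
  if (!is.null(cell$light))
    muts <- c(muts, chainCdrMutations(cell$light, c("cdrl1", "cdrl2", "cdrl3")))
  muts
}

ungap <- function(x) gsub("[.-]", "", x)

clonotypeSeq <- function(cell, definition) {
  if (definition == "vregion") {
    s <- ungap(cell$heavy$sequence_alignment)
    if (!is.null(cell$light)) s <- paste0(s, ungap(cell$light$sequence_alignment))
  } else {
    s <- paste0(cell$heavy$cdr1, cell$heavy$cdr2, cell$heavy$cdr3)
    if (!is.null(cell$light))
      s <- paste0(s, cell$light$cdr1, cell$light$cdr2, cell$light$cdr3)
  }
  toupper(s)
}

majorityIsotype <- function(counts) {
  total <- sum(counts)
  top <- which(counts > total / 2)
  if (length(top) == 1L) names(counts)[top] else "mixed"
}

#' Collapse lineage members into clonotype nodes
#'
#' Each node is one unique clonotype: either the full V-region nucleotide
#' sequence or the concatenation of all CDR nucleotide sequences (heavy then
#' light). Member-level SHM is always computed on the V-region alignment
#' (combined across chains by \code{shmMethod}); the node SHM rate is the
#' mean over members sharing the clonotype. The node isotype is the strict
#' (>50 percent) majority isotype of members, else "mixed". Node names are
#' assigned in ascending node-SHM order (ties broken by sequence).
#'
#' @param lineage a lineage from \code{\link{groupLineages}}.
#' @param definition "vregion" or "fullcdr".
#' @param shmMethod "mean" (default), "max" or "heavy"; cells without a
#'   light chain always use heavy alone.
#' @return list of clonotype nodes. Each node is a list with
#'   \code{node_name}, \code{clonotype_seq}, \code{size},
#'   \code{isotype_counts}, \code{node_isotype}, \code{shm_rate},
#'   \code{cdr_mutations}, \code{cdr_seqs}, \code{member_ids},
#'   \code{members} (data.frame) and \code{is_dummy}.
#' @export
buildClonotypes <- function(lineage, definition = c("vregion", "fullcdr"),
                            shmMethod = c("mean", "max", "heavy")) {
  definition <- match.arg(definition)
  shmMethod <- match.arg(shmMethod)
  members <- lineage$members
  if (length(members) == 0L) stop("lineage has no members")
  seqs <- vapply(members, clonotypeSeq, character(1), definition = definition)
  memberShm <- vapply(members, function(cell) {
    h <- computeChainSHM(cell$heavy$sequence_alignment,
                         cell$heavy$germline_alignment)
    if (is.null(cell$light)) return(combineSHM(h, NULL, "heavy"))
    l <- computeChainSHM(cell$light$sequence_alignment,
                         cell$light$germline_alignment)
    combineSHM(h, l, shmMethod)
  }, numeric(1))
  nodes <- lapply(unique(seqs), function(sq) {
    idx <- which(seqs == sq)
    first <- members[[idx[1]]]
    iso <- vapply(members[idx], function(cell) cell$isotype, character(1))
    counts <- table(factor(iso, levels = ISOTYPES))
    counts <- counts[counts > 0]
    cdrSeqs <- list(cdrh1 = toupper(first$heavy$cdr1),
                    cdrh2 = toupper(first$heavy$cdr2),
                    cdrh3 = toupper(first$heavy$cdr3))
    if (!is.null(first$light))
      cdrSeqs <- c(cdrSeqs, list(cdrl1 = toupper(first$light$cdr1),
                                 cdrl2 = toupper(first$light$cdr2),
                                 cdrl3 = toupper(first$light$cdr3)))
    list(
      node_name = NA_character_,
      clonotype_seq = sq,
      size = length(idx),
      isotype_counts = stats::setNames(as.integer(counts), names(counts)),
      node_isotype = majorityIsotype(counts),
      shm_rate = mean(memberShm[idx]),
      cdr_mutations = callCdrMutations(first),
      cdr_seqs = cdrSeqs,
      member_ids = vapply(members[idx], function(cell) cell$cell_id,
                          character(1)),
      members = data.frame(
        sequence_id = vapply(members[idx],
                             function(cell) cell$heavy$sequence_id,
                             character(1)),
        cell_id = vapply(members[idx], function(cell) cell$cell_id,
                         character(1)),
        isotype = iso, stringsAsFactors = FALSE),
      is_dummy = FALSE
    )
  })
  shm <- vapply(nodes, function(n) n$shm_rate, numeric(1))
  sq <- vapply(nodes, function(n) n$clonotype_seq, character(1))
  ord <- order(shm, sq, method = "radix")
  nodes <- nodes[ord]
  for (i in seq_along(nodes)) nodes[[i]]$node_name <- as.character(i)
  nodes
}
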