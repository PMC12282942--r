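# Clonal grouping: partition a repertoire into lineages by V-gene usage and
# CDR lengths.

stripAllele <- function(v_call) {
  first <- strsplit(v_call, ",", fixed = TRUE)[[1]][1]
  sub("\\*.*$", "", trimws(first))
}

#' Compute the lineage grouping key of one cell
#'
#' The key is the heavy-chain V gene (allele designation stripped, first
#' call taken when several are listed) plus the nucleotide lengths of
#' CDRH1-3; in single-cell mode the light-chain V gene and CDRL1-3 lengths
#' are included as well.
#'
#' @param cell a cell object (see \code{\link{readAIRR}}).
#' @param mode "single_cell" or "bulk".
#' @return list with elements \code{v_heavy}, \code{v_light} (NA in bulk),
#'   \code{cdr_lengths} (named integer vector) and \code{key} (a canonical
#'   string encoding).
#' @export
lineageKey <- function(cell, mode = c("bulk", "single_cell")) {
  mode <- match.arg(mode)
  vh <- stripAllele(cell$heavy$v_call)
  lens <- c(cdrh1 = nchar(cell$heavy$cdr1),
            cdrh2 = nchar(cell$heavy$cdr2),
            cdrh3 = nchar(cell$heavy$cdr3))
  vl <- NA_character_
  if (mode == "single_cell") {
    if (is.null(cell$light))
      stop("single_cell lineage key requires a light chain")
    vl <- stripAllele(cell$light$v_call)
    lens <- c(lens,
              cdrl1 = nchar(cell$light$cdr1),
              cdrl2 = nchar(cell$light$cdr2),
              cdrl3 = nchar(cell$light$cdr3))
  }
  key <- paste(c(vh, if (!is.na(vl)) vl, lens), collapse = "|")
  list(v_heavy = vh, v_light = vl, cdr_lengths = lens, key = key)
}

sameVGenes <- function(k1, k2) {
  k1$v_heavy == k2$v_heavy &&
    (is.na(k1$v_light) == is.na(k2$v_light)) &&
    (is.na(k1$v_light) || k1$v_light == k2$v_light)
}

#' Group a repertoire into clonal lineages
#'
#' Strict criteria: cells sharing an identical key (same V gene(s), same
#' CDR1/2/3 length(s)) form one lineage. Loose criteria: strict keys are
#' sorted by descending member count (ties broken lexicographically) and
#' greedily merged -- each key joins the first existing group whose founder
#' key has identical V genes and total CDR-length difference (L1 distance
#' over all CDRs) at most \code{maxLenDiff}, otherwise it founds a new group.
#'
#' @param rep a filtered \code{\linkS4class{BCRRepertoire}}.
#' @param criteria "strict" or "loose".
#' @param maxLenDiff loose-mode total CDR length difference bound (default 3).
#' @return list of lineages; each is a list with \code{lineage_id},
#'   \code{key}, \code{members} (list of cells).
#' @export
groupLineages <- function(rep, criteria = c("strict", "loose"),
                          maxLenDiff = 3L) {
  criteria <- match.arg(criteria)
  cellsL <- rep@cells
  if (length(cellsL) == 0L) return(list())
  keys <- lapply(cellsL, lineageKey, mode = rep@mode)
  keyStr <- vapply(keys, function(k) k$key, character(1))
  byKey <- split(seq_along(cellsL), keyStr)
  # deterministic order: descending member count, then lexicographic key
  ord <- order(-lengths(byKey), names(byKey), method = "radix")
  byKey <- byKey[ord]
  groups <- list()  # each: list(founder = key object, idx = integer vector)
  if (criteria == "strict") {
    groups <- lapply(names(byKey), function(k)
      list(founder = keys[[byKey[[k]][1]]], idx = byKey[[k]]))
  } else {
    for (k in names(byKey)) {
      idx <- byKey[[k]]
      key <- keys[[idx[1]]]
      joined <- FALSE
      for (gi in seq_along(groups)) {
        f <- groups[[gi]]$founder
        if (sameVGenes(key, f) &&
            sum(abs(key$cdr_lengths - f$cdr_lengths)) <= maxLenDiff) {
          groups[[gi]]$idx <- c(groups[[gi]]$idx, idx)
          joined <- TRUE
          break
        }
      }
      if (!joined)
        groups[[length(groups) + 1L]] <- list(founder = key, idx = idx)
    }
  }
  lapply(seq_along(groups), function(i) {
    list(lineage_id = sprintf("L%04d", i),
         key = groups[[i]]$founder,
         members = cellsL[groups[[i]]$idx])
  })
}
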