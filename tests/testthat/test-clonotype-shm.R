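test_that("chain SHM counts mismatches over comparable positions only", {
  expect_equal(computeChainSHM("ACGT", "ACGT"), 0)
  expect_equal(computeChainSHM("ACGA", "ACGT"), 0.25)
  # gap and N excluded: 3 comparable positions, 0 mismatches
  expect_equal(computeChainSHM("AC-TN", "ACGTA"), 0)
  expect_error(computeChainSHM("ACG", "ACGT"), "length")
  # no comparable positions -> 0
  expect_equal(computeChainSHM("---", "NNN"), 0)
})

test_that("chain SHM is symmetric in its arguments", {
  set.seed(42)
  for (i in 1:20) {
    a <- paste(sample(c("A", "C", "G", "T", "N", "-"), 30, replace = TRUE),
               collapse = "")
    b <- paste(sample(c("A", "C", "G", "T", "N", "-"), 30, replace = TRUE),
               collapse = "")
    expect_equal(computeChainSHM(a, b), computeChainSHM(b, a))
  }
})

test_that("SHM combination implements heavy, max and mean", {
  expect_equal(combineSHM(0.02, 0.04, "mean"), 0.03)
  expect_equal(combineSHM(0.02, 0.04, "max"), 0.04)
  expect_equal(combineSHM(0.02, 0.04, "heavy"), 0.02)
  expect_equal(combineSHM(0.02, NULL, "heavy"), 0.02)
  expect_error(combineSHM(0.02, NULL, "mean"), "light")
  expect_error(combineSHM(0.02, NULL, "max"), "light")
})

test_that("CDR mutation calling reports (region, 0-based position, observed base)", {
  # germline cdr1 TGGTAC, observed TGGTAT: one substitution at offset 5
  rep <- readFixture(list(airrRow("s1", cdr1 = "TGGTAT", gcdr1 = "TGGTAC")))
  expect_equal(callCdrMutations(cells(rep)[[1]]), "cdrh1|5|T")

  # identical CDRs -> empty set
  rep2 <- readFixture(list(airrRow("s1")))
  expect_length(callCdrMutations(cells(rep2)[[1]]), 0)

  # two mismatches in cdrh3 -> exactly two elements
  rep3 <- readFixture(list(airrRow("s1", cdr3 = "TACGCGCGT",
                                   gcdr3 = "TGCGCGCGA")))
  expect_setequal(callCdrMutations(cells(rep3)[[1]]),
                  c("cdrh3|1|A", "cdrh3|8|T"))

  # light-chain mutations are keyed by cdrl regions
  rows <- list(airrRow("c1_h", cell = "c1"),
               airrRow("c1_l", cell = "c1", locus = "IGK",
                       v = "IGKV1-39*01", cdr2 = "GGTACT",
                       gcdr2 = "GGTACC"))
  cell <- cells(readFixture(rows, mode = "single_cell"))[[1]]
  expect_equal(callCdrMutations(cell), "cdrl2|5|T")
})

test_that("mutation positions are mapped through IMGT-style alignment gaps", {
  # alignment carries germline-side dots before the CDR; positions stay
  # relative to the gapped CDR slice
  base <- airrRow("s1", cdr1 = "TGGTAT", gcdr1 = "TGGTAC")
  seqnt <- base[["sequence"]]
  gapped <- paste0(substr(seqnt, 1, 4), "..", substr(seqnt, 5, nchar(seqnt)))
  germ <- paste0("AAAC", "..", "TGGTAC",
                 substr(seqnt, 11, nchar(seqnt)))
  rep <- readFixture(list(airrRow("s1", cdr1 = "TGGTAT", gcdr1 = "TGGTAC",
                                  seq_align = gapped, germ_align = germ)))
  expect_equal(callCdrMutations(cells(rep)[[1]]), "cdrh1|5|T")
})

test_that("clonotype collapsing averages member SHM and resolves isotypes", {
  # three cells, identical CDRs (fullcdr clonotype), 0/1/2 FWR-free CDR
  # mutations would change the clonotype, so vary SHM through distinct
  # V-regions is impossible under fullcdr; instead vary germline CDRs
  rows <- list(
    airrRow("s1", c_call = "IGHA1"),
    airrRow("s2", gcdr3 = "TGCGCGCGT"),                      # 1 mismatch
    airrRow("s3", gcdr3 = "TGCGCGATT"))                      # 3 mismatches
  lin <- groupLineages(readFixture(rows), "strict")[[1]]
  nodes <- buildClonotypes(lin, definition = "fullcdr")
  expect_length(nodes, 1)
  expect_equal(nodes[[1]]$size, 3)
  shms <- vapply(cells(readFixture(rows)), function(cell)
    computeChainSHM(cell$heavy$sequence_alignment,
                    cell$heavy$germline_alignment), numeric(1))
  expect_equal(nodes[[1]]$shm_rate, mean(shms))
  expect_equal(nodes[[1]]$node_isotype, "IgG")  # 2 of 3 IgG
  expect_equal(sort(names(nodes[[1]]$isotype_counts)), c("IgA", "IgG"))
})

test_that("vregion distinguishes clonotypes that fullcdr merges", {
  # same CDRs, different FWR base -> different V-region
  base <- airrRow("s1")
  seqnt <- base[["sequence"]]
  mutated <- sub("^AAAC", "TAAC", seqnt)
  rows <- list(airrRow("s1"),
               airrRow("s2", seq_align = mutated))
  lin <- groupLineages(readFixture(rows), "strict")[[1]]
  expect_length(buildClonotypes(lin, definition = "vregion"), 2)
  expect_length(buildClonotypes(lin, definition = "fullcdr"), 1)
})

test_that("node sizes sum to the lineage member count and ties give mixed isotype", {
  rows <- list(airrRow("s1", c_call = "IGHA1"), airrRow("s2"),
               airrRow("s3", cdr3 = "TGCGCGCGT"))
  lin <- groupLineages(readFixture(rows), "strict")[[1]]
  nodes <- buildClonotypes(lin, "fullcdr")
  expect_equal(sum(vapply(nodes, function(n) n$size, numeric(1))), 3)
  shared <- nodes[[which(vapply(nodes, function(n) n$size, numeric(1)) == 2)]]
  expect_equal(shared$node_isotype, "mixed")  # 1 IgA + 1 IgG: no majority
  expect_equal(annotateNodeLabel(shared),
               paste0(shared$node_name, "|A1G1|",
                      sprintf("%.3e", shared$shm_rate)))
})
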