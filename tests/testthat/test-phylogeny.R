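test_that("identical sequences align without gaps; a deletion yields one gap run", {
  aln <- align_progressive(c(a = "ACGTACGTAC", b = "ACGTACGTAC"))
  expect_equal(unname(unlist(aln$rows)), rep("ACGTACGTAC", 2))
  aln2 <- align_progressive(c(a = "ACGTAACCGGTTACGT", b = "ACGTAAGGTTACGT"))
  expect_equal(aln2$length, 16L)
  expect_equal(gsub("-", "", aln2$rows[["b"]]), "ACGTAAGGTTACGT")
  expect_equal(nchar(gsub("[^-]", "", aln2$rows[["b"]])), 2L)
})

test_that("codon-mode alignment only introduces gaps in multiples of three", {
  set.seed(91)
  code <- genetic_code(4)
  nonstop <- setdiff(names(code$codons), c("TAA", "TAG"))
  body <- sample(nonstop, 50, TRUE)
  s1 <- paste(c("ATG", body, "TAA"), collapse = "")
  s2 <- paste(c("ATG", body[-c(10, 11)], "TAA"), collapse = "")
  s3 <- paste(c("ATG", body[-25], "TAA"), collapse = "")
  aln <- align_progressive(c(a = s1, b = s2, c = s3), codon = TRUE)
  for (row in aln$rows) {
    runs <- regmatches(row, gregexpr("-+", row))[[1]]
    if (length(runs)) expect_true(all(nchar(runs) %% 3L == 0L))
  }
  # rows are the inputs with gaps interleaved, nothing more
  expect_equal(gsub("-", "", aln$rows[["a"]]), s1)
  expect_equal(gsub("-", "", aln$rows[["b"]]), s2)
  expect_equal(gsub("-", "", aln$rows[["c"]]), s3)
})

test_that("gap-heavy columns are trimmed, codon-wise for coding alignments", {
  msa <- structure(list(rows = list(a = "ATG---AAA", b = "ATGCCCAAA",
                                    c = "ATG---AAA"),
                        length = 9L, alphabet = "dna"), class = "msa")
  tr <- trim_columns(msa, max_gap_fraction = 0.5, codon = TRUE)
  expect_equal(unname(unlist(tr$rows)), c("ATGAAA", "ATGAAA", "ATGAAA"))
  tr2 <- trim_columns(msa, max_gap_fraction = 0.7, codon = TRUE)
  expect_equal(tr2$length, 9L)
})

test_that("supermatrix kinds have the expected column arithmetic", {
  coh <- test_cohort()
  alns <- cohort_gene_alignments(coh$genomes)
  pcg <- build_supermatrix(alns, "PCG")
  expect_equal(length(pcg$rows), 16L)
  expect_equal(pcg$length, sum(vapply(alns[CONSERVED_PCGS], `[[`, 1L,
                                      "length")))
  expect_equal(nrow(pcg$partitions), 14L)
  expect_false("rps3" %in% pcg$partitions$marker)
  pcg12 <- build_supermatrix(alns, "PCG12")
  expect_equal(pcg12$length, pcg$length * 2L / 3L)
  aa <- build_supermatrix(alns, "AA")
  expect_equal(aa$length, pcg$length / 3L)
  expect_equal(aa$alphabet, "protein")
  pcgr <- build_supermatrix(alns, "PCGR")
  expect_equal(pcgr$length,
               pcg$length + alns$rnl$length + alns$rns$length)
  expect_true(all(c("rnl", "rns") %in% pcgr$partitions$marker))
  # partitions tile the matrix contiguously
  expect_equal(pcgr$partitions$start,
               c(1L, head(pcgr$partitions$end, -1L) + 1L))
  expect_equal(tail(pcgr$partitions$end, 1L), pcgr$length)
})

test_that("species absent from one marker are gap-padded and flagged", {
  m1 <- structure(list(rows = list(a = "AAAAAA", b = "AAATAA", c = "AAAAAA"),
                       length = 6L, alphabet = "dna"), class = "msa")
  m2 <- structure(list(rows = list(a = "CCCCCC", b = "CCCCCC"),
                       length = 6L, alphabet = "dna"), class = "msa")
  sm <- build_supermatrix(list(cox1 = m1, cox2 = m2), "PCG")
  expect_equal(sm$padded, "cox2")
  expect_equal(substr(sm$rows[["c"]], 7, 12), "------")
})

test_that("supermatrix K2P distances agree with the ape K80 oracle", {
  coh <- test_cohort()
  alns <- cohort_gene_alignments(coh$genomes, genes = c("cox1", "nad3"))
  sm <- build_supermatrix(alns, "PCG")
  d <- supermatrix_distances(sm)
  m <- do.call(rbind, strsplit(tolower(unlist(sm$rows)), ""))
  rownames(m) <- names(sm$rows)
  d_ape <- as.matrix(ape::dist.dna(ape::as.DNAbin(m), model = "K80",
                                   pairwise.deletion = TRUE))
  expect_equal(d[rownames(d_ape), colnames(d_ape)], d_ape,
               tolerance = 1e-10)
})

test_that("NJ reconstructs an additive four-taxon distance matrix exactly", {
  # tree ((A:2,B:3):1,C:4,D:5) gives these additive distances
  dm <- matrix(0, 4, 4, dimnames = list(c("A", "B", "C", "D"),
                                        c("A", "B", "C", "D")))
  dm["A", "B"] <- dm["B", "A"] <- 5
  dm["A", "C"] <- dm["C", "A"] <- 7
  dm["A", "D"] <- dm["D", "A"] <- 8
  dm["B", "C"] <- dm["C", "B"] <- 8
  dm["B", "D"] <- dm["D", "B"] <- 9
  dm["C", "D"] <- dm["D", "C"] <- 9
  tr <- nj_tree(dm)
  expect_equal(attr(tr, "clamped"), 0L)
  expect_equal(unname(as.matrix(cophenetic(tr))[rownames(dm), colnames(dm)]),
               unname(dm), tolerance = 1e-12)
  # AB|CD split present
  expect_true(is_monophyletic(tr, c("A", "B")))
  expect_false(is_monophyletic(tr, c("A", "C")))
})

test_that("NJ trees on missing or asymmetric input are refused", {
  dm <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(nj_tree(dm), "symmetric")
  dm2 <- matrix(c(0, NA, NA, 0), 2, 2)
  expect_error(nj_tree(dm2), "missing")
})

test_that("the cohort PCG tree matches the generating topology with full support", {
  coh <- test_cohort()
  alns <- cohort_gene_alignments(coh$genomes)
  sm <- build_supermatrix(alns, "PCG")
  tr <- bootstrap_support(sm, n_replicates = 100, seed = 1)
  rf <- ape::dist.topo(ape::unroot(tr), ape::unroot(coh$truth$tree))
  expect_equal(as.numeric(rf), 0)
  expect_true(all(tr$node.label[-1] >= 50)) # root label excluded
  # bootstrap is reproducible
  tr2 <- bootstrap_support(sm, n_replicates = 100, seed = 1)
  expect_equal(tr$node.label, tr2$node.label)
})

test_that("the planted Sanghuangporus-like clade is monophyletic on the PCG tree", {
  coh <- test_cohort()
  alns <- cohort_gene_alignments(coh$genomes)
  sm <- build_supermatrix(alns, "PCG")
  tr <- nj_tree(supermatrix_distances(sm))
  trio <- c("Sanghuangporus_sanghuang", "Sanghuangporus_vaninii",
            "Phellinus_gilvus")
  expect_true(is_monophyletic(tr, trio))
  poro <- grep("^Porodaedalea", tr$tip.label, value = TRUE)
  expect_true(is_monophyletic(tr, poro))
})

test_that("monophyly is evaluated on bipartitions, either side of the split", {
  tr <- ape::read.tree(text = "((a,b),(c,(d,e)));")
  expect_true(is_monophyletic(tr, c("a", "b")))
  expect_true(is_monophyletic(tr, c("c", "d", "e")))
  # complement of a clade is a clade on an unrooted tree
  expect_true(is_monophyletic(ape::unroot(tr), c("a", "b", "c")))
  expect_false(is_monophyletic(tr, c("b", "c")))
  expect_error(is_monophyletic(tr, c("a", "zz")), "not all")
})

test_that("Fitch parsimony equals the phangorn oracle on random data", {
  set.seed(92)
  for (rep in 1:4) {
    ntax <- 8
    labs <- paste0("t", 1:ntax)
    m <- matrix(sample(c("a", "c", "g", "t", "-"), ntax * 60, TRUE,
                       prob = c(0.24, 0.24, 0.24, 0.24, 0.04)),
                nrow = ntax, dimnames = list(labs, NULL))
    tr <- ape::rtree(ntax, tip.label = labs)
    rows <- setNames(apply(toupper(m), 1, paste, collapse = ""), labs)
    mine <- parsimony_score(tr, rows)
    pd <- phangorn::phyDat(m, type = "DNA")
    oracle <- phangorn::fitch(tr, pd)
    expect_equal(mine, as.integer(oracle))
  }
})

test_that("parsimony prefers the generating topology over a random one", {
  coh <- small_cohort()
  alns <- cohort_gene_alignments(coh$genomes, genes = c("cox1", "cob"))
  sm <- build_supermatrix(alns, "PCG")
  true_tr <- coh$truth$tree
  s_true <- parsimony_score(true_tr, sm)
  alt <- ape::read.tree(text = "((A:1,C:1):1,(B:1,D:1):1);")
  s_alt <- parsimony_score(alt, sm)
  expect_lt(s_true, s_alt)
})
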