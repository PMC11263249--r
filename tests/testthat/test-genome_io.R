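test_that("mitogenome constructor enforces alphabet and feature bounds", {
  expect_error(mitogenome("x", "ACGU"), "outside")
  expect_error(
    mitogenome("x", "ACGT", features = list(
      gene_feature("CDS", "cox1", "+", cbind(0, 9)))),
    "bounds")
  g <- mitogenome("x", "acgtn")
  expect_equal(g$sequence, "ACGTN")
  expect_equal(g$length, 5L)
  expect_equal(g$topology, "circular")
})

test_that("gene_feature validates segments", {
  expect_error(gene_feature("CDS", "cox1", "+", cbind(5, 5)), "start < end")
  expect_error(gene_feature("CDS", "cox1", "+", rbind(c(0, 10), c(5, 20))),
               "overlap")
  expect_error(gene_feature("CDS", "cox1", "*", cbind(0, 9)), "strand")
  f <- gene_feature("CDS", "cox1", "-", list(c(0, 9), c(12, 18)))
  expect_equal(nrow(f$segments), 2L)
})

test_that("reverse complement is an involution with the expected image", {
  expect_equal(reverse_complement("ACGTN"), "NACGT")
  set.seed(1)
  s <- paste(sample(c("A", "C", "G", "T", "N"), 200, TRUE), collapse = "")
  expect_equal(reverse_complement(reverse_complement(s)), s)
})

test_that("translation table 4 reads TGA as tryptophan", {
  code <- genetic_code(4)
  expect_equal(unname(code$codons[["TGA"]]), "W")
  expect_equal(translate_dna("ATGTGA"), "MW")
  expect_equal(translate_dna("ATGAAATAA"), "MK")
})

test_that("genetic code 4 agrees codon-by-codon with the Biostrings table", {
  code <- genetic_code(4)
  ref <- Biostrings::getGeneticCode("4")
  expect_equal(as.character(code$codons[names(ref)]), as.character(ref))
  expect_true(setequal(code$starts, c("ATG", "GTG", "TTG")))
})

test_that("internal stop handling is configurable", {
  s <- "ATGTAAAAATAA" # internal TAA at codon 2
  expect_warning(translate_dna(s, on_internal_stop = "warn"), "stop")
  expect_error(translate_dna(s, on_internal_stop = "error"), "stop")
  expect_equal(translate_dna(s, on_internal_stop = "keep"), "M*K")
})

test_that("gene extraction honours strand and multi-segment joins", {
  g <- toy_genome()
  tp <- attr(g, "toy_parts")
  expect_equal(extract_gene_sequence(g, g$features[[1]]), tp$cds1)
  # minus-strand CDS stored reverse-complemented on the deposited strand
  expect_equal(extract_gene_sequence(g, g$features[[2]]), tp$cds2)
  # joined CDS: exon lengths 51 and 61 concatenated in order
  set.seed(3)
  s <- paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")
  gj <- mitogenome("j", s, features = list(
    gene_feature("CDS", "nad5", "+", rbind(c(99, 150), c(299, 360)))))
  got <- extract_gene_sequence(gj, gj$features[[1]])
  expect_equal(nchar(got), 51L + 61L)
  expect_equal(got, paste0(substr(s, 100, 150), substr(s, 300, 360)))
})

test_that("origin-spanning segments concatenate across the circle", {
  set.seed(4)
  s <- paste(sample(c("A", "C", "G", "T"), 100, TRUE), collapse = "")
  g <- mitogenome("o", s, features = list(
    gene_feature("other", "dloop", "+", rbind(c(95, 100), c(0, 5)))))
  expect_equal(extract_gene_sequence(g, g$features[[1]]),
               paste0(substr(s, 96, 100), substr(s, 1, 5)))
})

test_that("ORF finder recovers a single planted ORF and matches a brute-force oracle", {
  set.seed(9)
  code <- genetic_code(4)
  nonstop <- setdiff(names(code$codons), c("TAA", "TAG"))
  body <- paste(sample(nonstop, 98, TRUE), collapse = "")
  region <- paste0("ATG", body, "TAA") # 100 codons = 300 nt
  pad <- paste(rep("C", 50), collapse = "") # stopless padding
  g <- mitogenome("orf", paste0(pad, region, pad))
  orfs <- find_orfs(g, min_orf_codons = 50L)
  longest <- orfs[which.max(orfs$length_codons), ]
  expect_equal(longest$length_codons, 99L) # ATG + 98 body codons
  expect_equal(longest$start, 50L)
  expect_equal(longest$end, 350L)          # includes the stop codon
  # six-frame brute-force oracle: per frame, each stop-terminated codon run
  # contributes one ORF if its first start codon leaves >= 50 codons
  stops <- names(code$codons)[code$codons == "*"]
  oracle <- 0L
  for (sq in c(g$sequence, reverse_complement(g$sequence))) {
    for (fr in 0:2) {
      n <- nchar(sq)
      at <- seq(1L + fr, n - 2L, 3L)
      codons <- substring(sq, at, at + 2L)
      prev_stop <- 0L
      for (j in which(codons %in% stops)) {
        run <- if (j > prev_stop + 1L) codons[(prev_stop + 1L):(j - 1L)]
          else character(0)
        st <- which(run %in% code$starts)
        if (length(st) && length(run) - st[1] + 1L >= 50L)
          oracle <- oracle + 1L
        prev_stop <- j
      }
    }
  }
  expect_equal(nrow(orfs), oracle)
})

test_that("FASTA round-trips including ids with description text", {
  recs <- c("seq one extra words" = "ACGTACGTACGT",
            "plain" = paste(rep("ACGT", 40), collapse = ""))
  path <- tempfile(fileext = ".fasta")
  write_fasta(recs, path)
  back <- read_fasta(path)
  expect_equal(names(back)[1], "seq")  # first token
  expect_equal(as.character(back), as.character(recs))
  expect_equal(attr(back, "description")[1], "seq one extra words")
})

test_that("GenBank writing and parsing round-trip an annotated genome", {
  g <- small_cohort()$genomes[[1]]
  path <- tempfile(fileext = ".gb")
  write_genbank(list(g), path)
  back <- read_genbank(path)[[1]]
  expect_equal(back$sequence, g$sequence)
  expect_equal(back$length, g$length)
  expect_equal(back$topology, "circular")
  key <- function(x) {
    o <- order(vapply(x$features, feature_start, 1L),
               vapply(x$features, `[[`, "", "kind"))
    lapply(x$features[o], function(f)
      list(f$kind, f$gene, f$strand, unname(f$segments)))
  }
  expect_equal(key(back), key(g))
})

test_that("GenBank location strings handle join and complement", {
  set.seed(5)
  s <- paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")
  g <- mitogenome("LOC1", s, features = list(
    gene_feature("CDS", "nad5", "+", rbind(c(99, 150), c(299, 360))),
    gene_feature("CDS", "nad3", "-", cbind(200, 260))))
  path <- tempfile(fileext = ".gb")
  write_genbank(list(g), path)
  txt <- readLines(path)
  expect_true(any(grepl("join(100..150,300..360)", txt, fixed = TRUE)))
  expect_true(any(grepl("complement(201..260)", txt, fixed = TRUE)))
  back <- read_genbank(path)[[1]]
  expect_equal(unname(back$features[[1]]$segments),
               unname(g$features[[1]]$segments))
  expect_equal(back$features[[2]]$strand, "-")
})
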