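test_that("intron coding positions are recovered from a plus-strand annotation", {
  coh <- test_cohort()
  g <- coh$genomes[["Sanghuangporus_sanghuang"]]
  rec <- intron_records(g)
  expect_equal(rec$species_cds_pos, c(209L, 728L, 1104L))
  expect_equal(rec$ordinal, 1:3)
  # the exon structure reassembles to a full-length cox1 CDS
  kinds <- vapply(g$features, `[[`, "", "kind")
  genes <- vapply(g$features, `[[`, "", "gene")
  cds <- g$features[[which(genes == "cox1" & kinds == "CDS")]]
  expect_equal(nrow(cds$segments), 4L)
  expect_equal(nchar(extract_gene_sequence(g, cds)), 1596L)
})

test_that("intron coding positions are strand-aware on a minus-strand host", {
  # coding sequence 30 nt, intron after coding position 9
  set.seed(81)
  code <- genetic_code(4)
  nonstop <- setdiff(names(code$codons), c("TAA", "TAG"))
  cds <- paste(c("ATG", sample(nonstop, 8, TRUE), "TAA"), collapse = "")
  exon1 <- substr(cds, 1, 9); exon2 <- substr(cds, 10, 30)
  intron <- paste(sample(c("A", "C", "G", "T"), 40, TRUE), collapse = "")
  pad <- paste(sample(c("A", "C", "G", "T"), 20, TRUE), collapse = "")
  # minus-strand layout, left to right: rc(exon2) | intron | rc(exon1)
  s <- paste0(pad, reverse_complement(exon2), intron,
              reverse_complement(exon1), pad)
  o1 <- 20L                                     # rc(exon2) start
  o2 <- o1 + 21L                                # intron start
  o3 <- o2 + 40L                                # rc(exon1) start
  g <- mitogenome("m", s, features = list(
    gene_feature("CDS", "cox1", "-", rbind(c(o1, o2), c(o3, o3 + 9L))),
    gene_feature("intron", "cox1", "-", cbind(o2, o3))))
  expect_equal(extract_gene_sequence(g, g$features[[1]]), cds)
  rec <- intron_records(g)
  expect_equal(rec$species_cds_pos, 9L)
  expect_equal(rec$flank, substr(cds, 1, 9))
})

test_that("insertion positions map through identical sequences unchanged", {
  set.seed(82)
  code <- genetic_code(4)
  nonstop <- setdiff(names(code$codons), c("TAA", "TAG"))
  ref <- paste(c("ATG", sample(nonstop, 100, TRUE), "TAA"), collapse = "")
  m <- map_insertion_position(209L, ref, ref)
  expect_equal(as.integer(m), 209L)
  expect_false(attr(m, "flagged"))
})

test_that("a codon insertion upstream shifts the mapped position by three", {
  set.seed(83)
  code <- genetic_code(4)
  nonstop <- setdiff(names(code$codons), c("TAA", "TAG"))
  body <- sample(nonstop, 60, TRUE)
  ref <- paste(c("ATG", body, "TAA"), collapse = "")
  # species carries one extra codon inserted after codon 10
  sp <- paste(c("ATG", body[1:9], "GGT", body[10:60], "TAA"), collapse = "")
  # intron after species coding position 100 (inside codon-aligned region,
  # downstream of the insertion) -> reference position 97
  m <- map_insertion_position(100L, sp, ref)
  expect_equal(as.integer(m), 97L)
  expect_false(attr(m, "flagged"))
  # upstream of the insertion the position is unchanged
  m2 <- map_insertion_position(24L, sp, ref)
  expect_equal(as.integer(m2), 24L)
})

test_that("positions falling in a reference gap are flagged to the upstream codon", {
  set.seed(84)
  code <- genetic_code(4)
  nonstop <- setdiff(names(code$codons), c("TAA", "TAG"))
  body <- sample(nonstop, 40, TRUE)
  ref <- paste(c("ATG", body, "TAA"), collapse = "")
  sp <- paste(c("ATG", body[1:20], "GGTGGAGGC", body[21:40], "TAA"),
              collapse = "")
  # a position inside the species-only insert has no reference image
  m <- map_insertion_position((21 + 2) * 3L, sp, ref)
  expect_true(attr(m, "flagged"))
  expect_equal(as.integer(m), 63L) # end of the last shared upstream codon
})

test_that("the cohort Pcl catalog equals the planted intron design", {
  coh <- test_cohort()
  introns <- do.call(rbind, lapply(coh$genomes, intron_records))
  cds <- lapply(coh$genomes, function(g) {
    kinds <- vapply(g$features, `[[`, "", "kind")
    genes <- vapply(g$features, `[[`, "", "gene")
    extract_gene_sequence(g, g$features[[which(genes == "cox1" &
                                                 kinds == "CDS")]])
  })
  cat <- build_pcl_catalog(introns, cds,
                           cds[["Sanghuangporus_sanghuang"]])
  plan <- coh$truth$intron_plan
  expected_pos <- sort(unique(unlist(plan)))
  expect_equal(cat$position, expected_pos)
  expect_equal(cat$name, paste0("P", expected_pos))
  for (i in seq_len(nrow(cat))) {
    members <- sort(names(plan)[vapply(plan, function(p)
      cat$position[i] %in% p, TRUE)])
    expect_equal(cat$members[i], paste(members, collapse = ","))
    expect_equal(cat$n_members[i], length(members))
  }
})

test_that("common/rare classification uses the ceiling of the species fraction", {
  cat <- data.frame(name = c("P1", "P2", "P3"), position = 1:3,
                    n_members = c(4L, 3L, 5L),
                    members = c("a", "b", "c"), stringsAsFactors = FALSE)
  class(cat) <- c("pcl_catalog", "data.frame")
  out <- classify_common_rare(cat, n_species = 16, threshold = 0.20)
  expect_equal(attr(out, "min_common_members"), 4)  # ceiling(3.2)
  expect_equal(out$status, c("common", "rare", "common"))
  # exact-multiple boundary: 20% of 10 species needs exactly 2
  out2 <- classify_common_rare(cat, n_species = 10, threshold = 0.20)
  expect_equal(attr(out2, "min_common_members"), 2)
})

test_that("only the two triple-shared Pcls of the cohort are common", {
  coh <- test_cohort()
  introns <- do.call(rbind, lapply(coh$genomes, intron_records))
  cds <- lapply(coh$genomes, function(g) {
    kinds <- vapply(g$features, `[[`, "", "kind")
    genes <- vapply(g$features, `[[`, "", "gene")
    extract_gene_sequence(g, g$features[[which(genes == "cox1" &
                                                 kinds == "CDS")]])
  })
  cat <- build_pcl_catalog(introns, cds, cds[["Sanghuangporus_sanghuang"]])
  cat <- classify_common_rare(cat, n_species = length(coh$genomes))
  common <- cat$name[cat$status == "common"]
  expect_true(setequal(common, c("P209", "P728")))
})

test_that("the species-by-Pcl matrix tallies members and carries intron types", {
  coh <- test_cohort()
  introns <- do.call(rbind, lapply(coh$genomes, intron_records))
  cds <- lapply(coh$genomes, function(g) {
    kinds <- vapply(g$features, `[[`, "", "kind")
    genes <- vapply(g$features, `[[`, "", "gene")
    extract_gene_sequence(g, g$features[[which(genes == "cox1" &
                                                 kinds == "CDS")]])
  })
  cat <- build_pcl_catalog(introns, cds, cds[["Sanghuangporus_sanghuang"]])
  m <- pcl_matrix(cat)
  expect_equal(unname(colSums(m != "")), cat$n_members[order(cat$position)])
  expect_true(all(m[m != ""] %in% c("IA", "IB", "I (derived)")))
  expect_equal(sum(m != ""), nrow(introns))
})

test_that("two introns of one species at one reference position are rejected", {
  set.seed(85)
  code <- genetic_code(4)
  nonstop <- setdiff(names(code$codons), c("TAA", "TAG"))
  ref <- paste(c("ATG", sample(nonstop, 100, TRUE), "TAA"), collapse = "")
  introns <- data.frame(
    species = c("x", "x"), gene = "cox1", ordinal = 1:2,
    start = c(1L, 2L), end = c(2L, 3L),
    species_cds_pos = c(100L, 100L),
    flank = "", intron_type = "IA", stringsAsFactors = FALSE)
  expect_error(build_pcl_catalog(introns, list(x = ref), ref), "map to position")
})
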