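# Shared synthetic cohort, built once per test run. The generator defaults
# are the study conditions; seed 7 is the canonical validation cohort.
cohort_spec <- function() simulation_spec(seed = 7)

.cohort_cache <- new.env(parent = emptyenv())

test_cohort <- function() {
  if (is.null(.cohort_cache$cohort))
    .cohort_cache$cohort <- make_cohort(cohort_spec())
  .cohort_cache$cohort
}

# small 4-taxon cohort for cheaper end-to-end checks
small_spec <- function() {
  simulation_spec(
    tree = "((A:0.05,B:0.05):0.03,(C:0.04,D:0.06):0.03);",
    seed = 11,
    intron_plan = list(A = c(209, 728), B = 209),
    rearrangement_plan = list(
      D = list(list(type = "inversion", from = 5, to = 7))))
}

.small_cache <- new.env(parent = emptyenv())

small_cohort <- function() {
  if (is.null(.small_cache$cohort))
    .small_cache$cohort <- make_cohort(small_spec())
  .small_cache$cohort
}

# a feature-bearing toy genome used by io/composition tests: one forward CDS,
# one reverse CDS, one rRNA, one tRNA, the rest intergenic. Offsets are
# computed from the part lengths so the annotation is correct by construction.
toy_genome <- function() {
  set.seed(42)
  pad <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
  cds1 <- paste0("ATG", "AAATTTGGGCCCACGTGG", "TAA")   # + strand, 24 nt
  cds2 <- paste0("ATG", "TGAAAACAT", "TAG")            # coding strand, 15 nt
  trna <- pad(72)
  rrna <- pad(120)
  parts <- list(pad(40), cds1, pad(30), reverse_complement(cds2),
                pad(25), trna, pad(10), rrna, pad(20))
  lens <- vapply(parts, nchar, 1L)
  off <- cumsum(c(0L, lens))   # 0-based start of each part
  feats <- list(
    gene_feature("CDS", "cox1", "+", cbind(off[2], off[2] + lens[2])),
    gene_feature("CDS", "nad3", "-", cbind(off[4], off[4] + lens[4])),
    gene_feature("tRNA", "trnA", "+", cbind(off[6], off[6] + lens[6])),
    gene_feature("rRNA", "rns", "+", cbind(off[8], off[8] + lens[8])))
  g <- mitogenome(id = "TOY1", sequence = paste(unlist(parts), collapse = ""),
                  species = "toy", features = feats)
  attr(g, "toy_parts") <- list(cds1 = cds1, cds2 = cds2, off = off, lens = lens)
  g
}
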