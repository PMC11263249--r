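test_that("K2P distance matches the closed form at P=0.1, Q=0.05", {
  # 20 sites: 2 transitions (A<->G), 1 transversion (A<->C)
  a <- paste(rep("A", 20), collapse = "")
  b <- paste(c("G", "G", "C", rep("A", 17)), collapse = "")
  k <- k2p_distance(a, b)
  expect_equal(k$P, 0.1)
  expect_equal(k$Q, 0.05)
  expect_equal(k$d, -0.5 * log(0.75) - 0.25 * log(0.9), tolerance = 1e-12)
  expect_equal(k$d, 0.17018, tolerance = 5e-5)
  expect_false(k$saturated)
})

test_that("K2P is zero on identity, symmetric, and flags saturation", {
  set.seed(41)
  s <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
  expect_equal(k2p_distance(s, s)$d, 0)
  t <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
  expect_equal(k2p_distance(s, t)$d, k2p_distance(t, s)$d)
  # all-transition pair: P = 1 -> log argument <= 0
  sat <- k2p_distance(paste(rep("A", 50), collapse = ""),
                      paste(rep("G", 50), collapse = ""))
  expect_true(sat$saturated)
  expect_true(is.na(sat$d))
})

test_that("K2P approaches the p-distance at low divergence", {
  # P + Q = 0.01 over 1000 sites
  a <- paste(rep("A", 1000), collapse = "")
  bb <- rep("A", 1000); bb[1:6] <- "G"; bb[7:10] <- "T"
  k <- k2p_distance(a, paste(bb, collapse = ""))
  p_dist <- 0.01
  expect_lt(abs(k$d / p_dist - 1), 0.02)
})

test_that("gap and N columns are excluded pairwise", {
  k <- k2p_distance("ACGT-NA", "ACGAAAA")
  expect_equal(k$sites_compared, 5L)
  expect_equal(k$P, 0)        # T->A at site 4 is a transversion
  expect_equal(k$Q, 1 / 5)
})

test_that("K2P agrees with the ape K80 estimator on random alignments", {
  set.seed(42)
  for (rep in 1:5) {
    m <- matrix(sample(c("a", "c", "g", "t"), 2 * 600, TRUE), nrow = 2)
    d_ape <- ape::dist.dna(ape::as.DNAbin(m), model = "K80",
                           pairwise.deletion = TRUE)
    mine <- k2p_distance(paste(toupper(m[1, ]), collapse = ""),
                         paste(toupper(m[2, ]), collapse = ""))
    if (is.na(mine$d)) expect_true(is.nan(as.numeric(d_ape)) ||
                                     is.na(as.numeric(d_ape)))
    else expect_equal(mine$d, as.numeric(d_ape), tolerance = 1e-10)
  }
})

test_that("NG86 fixture 10xGGT vs 9xGGT+1xGGC gives the hand-derived values", {
  a <- paste(rep("GGT", 10), collapse = "")
  b <- paste(c(rep("GGT", 9), "GGC"), collapse = "")
  kk <- ng86_kaks(a, b)
  expect_equal(kk$S, 10)
  expect_equal(kk$N, 20)
  expect_equal(kk$Sd, 1)
  expect_equal(kk$Nd, 0)
  expect_equal(kk$Ka, 0)
  expect_equal(kk$Ks, -0.75 * log(1 - 0.4 / 3), tolerance = 1e-12)
  expect_equal(kk$Ks, 0.10733, tolerance = 5e-5)
  expect_equal(kk$ratio, 0) # Ka = 0 over a positive Ks
})

test_that("identical coding sequences give Ka = Ks = 0 with missing ratio", {
  s <- "ATGGGTAAACCCTGA"
  kk <- ng86_kaks(s, s)
  expect_equal(kk$Ka, 0)
  expect_equal(kk$Ks, 0)
  expect_true(is.na(kk$ratio))
})

test_that("NG86 conserves sites: S + N equals three times the codons compared", {
  set.seed(43)
  code <- genetic_code(4)
  nonstop <- names(code$codons)[code$codons != "*"]
  for (rep in 1:5) {
    a <- paste(sample(nonstop, 60, TRUE), collapse = "")
    b <- paste(sample(nonstop, 60, TRUE), collapse = "")
    kk <- ng86_kaks(a, b)
    expect_equal(kk$S + kk$N, 3 * kk$codons_compared, tolerance = 1e-9)
  }
})

test_that("NG86 site and difference counts match an independent enumeration", {
  set.seed(44)
  code <- genetic_code(4)
  bases <- c("A", "C", "G", "T")
  tr <- function(cd) unname(code$codons[cd])
  # independent syn-site count: enumerate the 9 single-base mutants directly
  syn_sites_oracle <- function(cd) {
    tot <- 0
    for (p in 1:3) for (b in bases) {
      mut <- cd; substr(mut, p, p) <- b
      if (mut != cd && tr(mut) == tr(cd)) tot <- tot + 1 / 3
    }
    tot
  }
  # independent pathway averaging via recursive enumeration
  diffs_oracle <- function(c1, c2) {
    pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
    if (!length(pos)) return(c(0, 0))
    walk <- function(cur, remaining) {
      if (!length(remaining)) return(list(c(0, 0, FALSE)))
      out <- list()
      for (p in remaining) {
        nxt <- cur; substr(nxt, p, p) <- substr(c2, p, p)
        step_syn <- tr(cur) == tr(nxt)
        hit_stop <- tr(nxt) == "*" && nxt != c2
        for (tail in walk(nxt, setdiff(remaining, p)))
          out[[length(out) + 1L]] <- c(tail[1] + step_syn,
                                       tail[2] + !step_syn,
                                       tail[3] || hit_stop)
      }
      out
    }
    paths <- do.call(rbind, walk(c1, pos))
    keep <- paths[, 3] == 0
    if (!any(keep)) keep <- rep(TRUE, nrow(paths))
    colMeans(paths[keep, 1:2, drop = FALSE])
  }
  nonstop <- names(code$codons)[code$codons != "*"]
  cods <- sample(nonstop, 12)
  for (cd in cods)
    expect_equal(mitocomp:::ng86_syn_sites(cd, code), syn_sites_oracle(cd))
  for (i in 1:6) {
    c1 <- cods[2 * i - 1]; c2 <- cods[2 * i]
    got <- mitocomp:::ng86_diffs(c1, c2, code)
    expect_equal(unname(got), unname(diffs_oracle(c1, c2)), tolerance = 1e-12)
  }
})

test_that("per-gene summary averages records and counts missing pairs", {
  rec <- data.frame(gene = c("a", "a", "b"), d = c(0.1, 0.3, NA),
                    Ka = c(0.02, 0.04, 0.1), Ks = c(0.2, 0.2, 0.5),
                    ratio = c(0.1, 0.2, 0.2))
  s <- per_gene_summary(rec)
  expect_equal(s$mean_d[s$gene == "a"], 0.2)
  expect_equal(s$n_missing[s$gene == "b"], 1L)
  expect_equal(s$n_pairs[s$gene == "a"], 2L)
})

test_that("gene-specific simulated rates rank fast rps3 above slow atp9", {
  coh <- test_cohort()
  rec <- cohort_rate_records(coh$genomes, genes = c("rps3", "atp9", "nad3"))
  s <- per_gene_summary(rec)
  d <- setNames(s$mean_d, s$gene)
  expect_gt(d[["rps3"]], d[["nad3"]])
  expect_gt(d[["nad3"]], d[["atp9"]])
  # 16 species -> 120 unordered pairs per gene
  expect_equal(sum(rec$gene == "rps3"), 120L)
})

test_that("two-taxon simulation at true distance 0.1 is estimated without bias", {
  base <- simulation_spec(
    tree = "(A:0.05,B:0.05);", gene_lengths = c(cox1 = 9999),
    rate_multipliers = c(cox1 = 1), intron_plan = list(),
    rearrangement_plan = list(), seed = 1)
  est <- vapply(1:30, function(r) {
    sim <- simulate_alignment_on_tree(base, genes = "cox1", seed = 1000 + r)
    k2p_distance(sim$genes$cox1[["A"]], sim$genes$cox1[["B"]])$d
  }, 1)
  expect_lt(abs(mean(est) - 0.1), 0.005)
})
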