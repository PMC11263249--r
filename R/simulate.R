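## Seeded generator of annotated circular mitogenomes with known ground
## truth: coding sequences evolved on a fixed tree under a two-rate
## (transition/transversion) substitution model, introns planted in cox1 at
## chosen coding positions, repeats planted in intergenic DNA, and gene
## orders rearranged per species.

DEFAULT_TREE <- paste0(
  "(((Inonotus_hispidus:0.06,Inonotus_obliquus:0.06):0.04,",
  "(Sanghuangporus_sanghuang:0.05,(Sanghuangporus_vaninii:0.03,",
  "Phellinus_gilvus:0.03):0.03):0.04):0.03,",
  "((Porodaedalea_pini:0.04,Porodaedalea_niemelaei:0.04):0.03,",
  "(Porodaedalea_chrysoloma:0.04,Porodaedalea_laricis:0.04):0.03):0.04,",
  "(((Phellinus_lamaoensis:0.05,Phellinus_noxius:0.05):0.03,",
  "(Phellinus_viticola:0.05,(Coniferiporia_sulphurascens:0.04,",
  "Phellinus_ferrugineofuscus:0.04):0.02):0.03):0.02,",
  "(Phellinus_tuberculosus:0.06,Tropicoporus_linteus:0.06):0.03):0.03);")

DEFAULT_GENE_LENGTHS <- c(
  cox1 = 1596, cox2 = 750, cox3 = 810, cob = 1164, nad1 = 1086, nad2 = 1662,
  nad3 = 420, nad4 = 1476, nad4l = 270, nad5 = 2004, nad6 = 630, atp6 = 768,
  atp8 = 147, atp9 = 225, rps3 = 1338, rnl = 3150, rns = 1560)

# the shared base arrangement: cox1 first, as gene orders are conventionally
# reported for these fungi
DEFAULT_GENE_ORDER <- c("cox1", "nad4l", "nad5", "atp9", "cox2", "cob",
                        "cox3", "atp6", "nad1", "rnl", "nad4", "rns", "rps3",
                        "atp8", "nad6", "nad2", "nad3")

DEFAULT_RATE_MULT <- c(rps3 = 2.0, nad3 = 1.6, nad6 = 1.4, atp9 = 0.3,
                       cox1 = 0.6, atp8 = 1.2)

default_intron_plan <- function() list(
  Sanghuangporus_sanghuang = c(209, 728, 1104),
  Sanghuangporus_vaninii = c(209, 728),
  Phellinus_gilvus = c(209, 728),
  Inonotus_hispidus = c(209, 393, 1302),
  Inonotus_obliquus = c(393, 728),
  Porodaedalea_pini = c(209, 237),
  Porodaedalea_niemelaei = c(237, 951),
  Phellinus_lamaoensis = 406,
  Phellinus_viticola = c(728, 1104))

default_rearrangement_plan <- function() list(
  # Porodaedalea group shares one transposition; two species carry inversions
  Porodaedalea_pini = list(list(type = "transposition", from = 11, to = 13, at = 3)),
  Porodaedalea_niemelaei = list(list(type = "transposition", from = 11, to = 13, at = 3)),
  Porodaedalea_chrysoloma = list(list(type = "transposition", from = 11, to = 13, at = 3)),
  Porodaedalea_laricis = list(list(type = "transposition", from = 11, to = 13, at = 3)),
  Phellinus_lamaoensis = list(list(type = "inversion", from = 5, to = 7)),
  Tropicoporus_linteus = list(list(type = "inversion", from = 14, to = 16)))

#' Specification of a synthetic mitogenome cohort
#'
#' Defaults emulate a 16-species cohort of hymenochaetoid fungi: AT-rich
#' (~73% AT) circular genomes of roughly 45-60 kb, 15 core protein-coding
#' genes plus rnl/rns and a complement of tRNAs, species-specific cox1
#' introns at known coding positions, planted dispersed/tandem repeats, and
#' gene orders differing by inversion/transposition events.
#'
#' @param tree Newick string with branch lengths in expected
#'   substitutions/site.
#' @param kappa Transition/transversion rate ratio.
#' @param base_freqs Named A/C/G/T frequencies.
#' @param gene_lengths Named vector of marker lengths (nt).
#' @param rate_multipliers Named per-gene rate multipliers (others 1).
#' @param base_order Base circular marker order.
#' @param intron_plan Named list species -> cox1 coding positions (1-based nt).
#' @param rearrangement_plan Named list species -> list of events
#'   (`list(type = "inversion"|"transposition", from, to, at)`, marker
#'   indices into the base order).
#' @param repeat_plan List with `dispersed` (length, identity) and `tandem`
#'   (unit, copies) applied to every genome.
#' @param trna_count tRNA genes per genome.
#' @param intergenic_meanlog,intergenic_sdlog Log-normal spacer-length
#'   parameters.
#' @param seed Integer seed fixing all outputs.
#' @return List of class `simulation_spec`.
#' @export
simulation_spec <- function(tree = DEFAULT_TREE,
                            kappa = 2,
                            base_freqs = c(A = 0.36, C = 0.125, G = 0.14,
                                           T = 0.375),
                            gene_lengths = DEFAULT_GENE_LENGTHS,
                            rate_multipliers = DEFAULT_RATE_MULT,
                            base_order = DEFAULT_GENE_ORDER,
                            intron_plan = default_intron_plan(),
                            rearrangement_plan = default_rearrangement_plan(),
                            repeat_plan = list(
                              dispersed = list(length = 500L, identity = 100),
                              tandem = list(unit = "ACGTT", copies = 8L)),
                            trna_count = 25L,
                            intergenic_meanlog = log(600),
                            intergenic_sdlog = 0.7,
                            seed = 1L) {
  stopifnot(kappa > 0, all(base_freqs > 0),
            abs(sum(base_freqs) - 1) < 1e-8,
            all(gene_lengths %% 3 == 0 | names(gene_lengths) %in% RRNA_GENES))
  if (length(intron_plan))
    stopifnot(all(unlist(intron_plan) >= 1),
              all(unlist(intron_plan) < gene_lengths[["cox1"]]))
  structure(list(tree = tree, kappa = kappa, base_freqs = base_freqs,
                 gene_lengths = gene_lengths,
                 rate_multipliers = rate_multipliers,
                 base_order = base_order, intron_plan = intron_plan,
                 rearrangement_plan = rearrangement_plan,
                 repeat_plan = repeat_plan, trna_count = as.integer(trna_count),
                 intergenic_meanlog = intergenic_meanlog,
                 intergenic_sdlog = intergenic_sdlog,
                 seed = as.integer(seed)),
            class = "simulation_spec")
}

BASES <- c("A", "C", "G", "T")

random_dna <- function(n, freqs) {
  paste(sample(BASES, n, replace = TRUE, prob = freqs[BASES]), collapse = "")
}

# codon-bias weight profiles for root coding sequences
codon_profile <- function(kind = c("pcg", "uorf"), base_freqs, code) {
  kind <- match.arg(kind)
  codons <- names(code$codons)
  chars <- strsplit(codons, "")
  w <- vapply(chars, function(ch) prod(base_freqs[ch]), 1)
  names(w) <- codons
  if (kind == "pcg") {
    w[c("TTA", "TTT", "ATT", "AAA", "TTG")] <- w[c("TTA", "TTT", "ATT",
                                                   "AAA", "TTG")] * 3
  } else {
    gc <- vapply(chars, function(ch) sum(ch %in% c("G", "C")), 1)
    w <- w * (1.8 ^ gc) # uORFs are markedly GC-richer than core genes
  }
  w[code$codons == "*"] <- 0
  w / sum(w)
}

random_cds <- function(n_codons, profile, code) {
  inner <- sample(names(profile), n_codons - 2L, replace = TRUE,
                  prob = profile)
  paste(c("ATG", inner, "TAA"), collapse = "")
}

# evolve an integer-coded sequence along one branch under the two-rate model
k80_evolve <- function(x, t, kappa) {
  if (t <= 0) return(x)
  beta <- 1 / (kappa + 2); alpha <- kappa * beta
  e1 <- exp(-4 * beta * t); e2 <- exp(-2 * (alpha + beta) * t)
  p_ts <- 0.25 + 0.25 * e1 - 0.5 * e2
  p_tv <- 0.25 - 0.25 * e1 # each of the two transversions
  u <- runif(length(x))
  ts_map <- c(3L, 4L, 1L, 2L)
  tv1 <- c(2L, 1L, 2L, 1L); tv2 <- c(4L, 3L, 4L, 3L)
  out <- x
  sel <- u < p_ts
  out[sel] <- ts_map[x[sel]]
  sel2 <- !sel & u < p_ts + p_tv
  out[sel2] <- tv1[x[sel2]]
  sel3 <- !sel & !sel2 & u < p_ts + 2 * p_tv
  out[sel3] <- tv2[x[sel3]]
  out
}

dna_to_int <- function(s) match(strsplit(s, "")[[1]], BASES)
int_to_dna <- function(x) paste(BASES[x], collapse = "")

#' Simulate per-gene sequences on the spec's tree
#'
#' Root sequences are drawn from the codon-bias profile (coding markers) or
#' base frequencies (rRNA markers) and evolved edge by edge under the
#' two-rate transition/transversion model, scaled by per-gene rate
#' multipliers. Sequences contain no indels, so the per-gene sets are
#' alignments by construction.
#'
#' @param spec A [simulation_spec()].
#' @param genes Markers to simulate (default: all in `spec$gene_lengths`).
#' @param seed Overrides `spec$seed` when given.
#' @return List: `genes` (per marker, named character vector of species
#'   sequences), `truth` (`tree` as [ape::phylo], `distances` = patristic
#'   expected substitutions/site at multiplier 1).
#' @export
simulate_alignment_on_tree <- function(spec, genes = NULL, seed = NULL) {
  set.seed(seed %||% spec$seed)
  tr <- ape::read.tree(text = spec$tree)
  if (is.null(tr$edge.length)) stop("tree must carry branch lengths")
  if (is.null(genes)) genes <- names(spec$gene_lengths)
  code <- genetic_code(4)
  ntip <- length(tr$tip.label)
  prof <- codon_profile("pcg", spec$base_freqs, code)
  po <- ape::reorder.phylo(tr, "postorder")
  # preorder edge walk: parents before children
  edges <- po$edge[rev(seq_len(nrow(po$edge))), , drop = FALSE]
  elens <- po$edge.length[rev(seq_len(nrow(po$edge)))]
  out <- list()
  for (g in genes) {
    L <- spec$gene_lengths[[g]]
    mult <- if (g %in% names(spec$rate_multipliers))
      spec$rate_multipliers[[g]] else 1
    root_seq <- if (g %in% RRNA_GENES || !is.null(attr(genes, "noncoding")))
      random_dna(L, spec$base_freqs) else random_cds(L / 3, prof, code)
    nseq <- vector("list", ntip + tr$Nnode)
    nseq[[ntip + 1L]] <- dna_to_int(root_seq)
    for (i in seq_len(nrow(edges))) {
      par <- edges[i, 1]; chd <- edges[i, 2]
      nseq[[chd]] <- k80_evolve(nseq[[par]], elens[i] * mult, spec$kappa)
    }
    seqs <- vapply(seq_len(ntip), function(i) int_to_dna(nseq[[i]]), "")
    names(seqs) <- tr$tip.label
    out[[g]] <- seqs
  }
  dm <- cophenetic(tr)
  list(genes = out, truth = list(tree = tr, distances = dm))
}

apply_rearrangements <- function(order, events) {
  # order: character vector of signed labels; indices refer to current order
  for (ev in events) {
    i <- ev$from; j <- ev$to
    if (ev$type == "inversion") {
      seg <- rev(negate_marker(order[i:j]))
      order <- append(order[-(i:j)], seg, after = i - 1L)
    } else if (ev$type == "transposition") {
      seg <- order[i:j]
      rest <- order[-(i:j)]
      order <- append(rest, seg, after = ev$at)
    } else stop("unknown rearrangement type: ", ev$type)
  }
  order
}

#' Assemble a full annotated mitogenome for one species
#'
#' Lays the species' (possibly rearranged) marker order on the circle with
#' log-normal intergenic spacers, inserts introns into cox1 at the planted
#' coding positions (random intron DNA, one carrying a planted uORF when
#' long enough), adds tRNA genes, and plants the dispersed and tandem
#' repeats of the repeat plan into intergenic DNA.
#'
#' @param spec A [simulation_spec()].
#' @param species Species name (a tip of the tree).
#' @param gene_seqs Named list marker -> named species-sequence vector, as
#'   from [simulate_alignment_on_tree()].
#' @return List: `genome` ([mitogenome()]), `truth` (planted gene order,
#'   intron positions, repeat/tandem loci, region class lengths).
#' @export
assemble_mitogenome <- function(spec, species, gene_seqs) {
  order0 <- spec$base_order
  events <- spec$rearrangement_plan[[species]]
  order <- if (is.null(events)) order0 else apply_rearrangements(order0, events)
  intron_pos <- sort(spec$intron_plan[[species]])
  code <- genetic_code(4)
  uprof <- codon_profile("uorf", spec$base_freqs, code)

  parts <- character(0)   # sequence chunks
  pos <- 0L               # running 0-based position
  feats <- list()
  truth_repeats <- list(); truth_tandem <- list()
  class_len <- c(protein_coding = 0L, rna_gene = 0L, uorf = 0L, intron = 0L)
  trna_after <- rep_len(seq_along(order), spec$trna_count)

  spacer <- function() {
    n <- max(50L, round(rlnorm(1, spec$intergenic_meanlog,
                               spec$intergenic_sdlog)))
    random_dna(n, spec$base_freqs)
  }
  push <- function(s) { parts[[length(parts) + 1L]] <<- s; pos <<- pos + nchar(s) }

  # dispersed repeat: two copies in the spacers after markers 3 and 10
  rp <- spec$repeat_plan$dispersed
  rep_seq <- random_dna(rp$length, spec$base_freqs)
  rep_copy2 <- rep_seq
  if (rp$identity < 100) {
    nmut <- round((1 - rp$identity / 100) * rp$length)
    if (nmut > 0) {
      ch <- dna_to_int(rep_copy2)
      at <- sample(rp$length, nmut)
      ch[at] <- ((ch[at] + sample(1:3, nmut, replace = TRUE) - 1L) %% 4L) + 1L
      rep_copy2 <- int_to_dna(ch)
    }
  }
  tp <- spec$repeat_plan$tandem
  tandem_seq <- strrep(tp$unit, tp$copies)

  for (mi in seq_along(order)) {
    push(spacer())
    if (mi == 4L && !is.null(rp)) {
      truth_repeats[[1]] <- c(start = pos + 1L, end = pos + nchar(rep_seq))
      push(rep_seq); push(spacer())
    }
    if (mi == 7L && !is.null(tp)) {
      truth_tandem[[1]] <- c(start = pos + 1L, end = pos + nchar(tandem_seq))
      push(tandem_seq); push(spacer())
    }
    if (mi == 11L && !is.null(rp)) {
      truth_repeats[[2]] <- c(start = pos + 1L, end = pos + nchar(rep_copy2))
      push(rep_copy2); push(spacer())
    }
    marker <- order[mi]
    gname <- signed_name(marker)
    strand <- if (grepl("^-", marker)) "-" else "+"
    gseq <- gene_seqs[[gname]][[species]]
    kind <- if (gname %in% RRNA_GENES) "rRNA" else "CDS"
    if (gname == "cox1" && length(intron_pos)) {
      # split the CDS at the planted coding positions
      bounds <- c(0L, intron_pos, nchar(gseq))
      exons <- substring(gseq, head(bounds, -1L) + 1L, bounds[-1L])
      segs <- list(); in_feats <- list()
      gpos <- pos
      for (e in seq_along(exons)) {
        segs[[e]] <- c(gpos, gpos + nchar(exons[e]))
        push2 <- exons[e]
        parts[[length(parts) + 1L]] <- push2; gpos <- gpos + nchar(push2)
        class_len["protein_coding"] <- class_len["protein_coding"] +
          nchar(push2)
        if (e < length(exons)) {
          orf_len <- 0L
          if (e == 1L) { # plant a uORF inside the first intron
            orf <- random_cds(110L, uprof, code)
            orf_len <- nchar(orf)
            iseq <- paste0(random_dna(60L, spec$base_freqs), orf,
                           random_dna(240L, spec$base_freqs))
            in_feats[[length(in_feats) + 1L]] <- gene_feature(
              "uORF", paste0("orf", e), "+",
              matrix(c(gpos + 60L, gpos + 60L + orf_len), ncol = 2))
            class_len["uorf"] <- class_len["uorf"] + orf_len
          } else {
            iseq <- random_dna(420L + 180L * e, spec$base_freqs)
          }
          in_feats[[length(in_feats) + 1L]] <- gene_feature(
            "intron", gname, "+", matrix(c(gpos, gpos + nchar(iseq)), ncol = 2),
            qualifiers = list(intron_type = c("IA", "IB", "I (derived)")[
              (e - 1L) %% 3L + 1L]))
          class_len["intron"] <- class_len["intron"] + nchar(iseq) - orf_len
          parts[[length(parts) + 1L]] <- iseq; gpos <- gpos + nchar(iseq)
        }
      }
      pos <- gpos
      feats[[length(feats) + 1L]] <- gene_feature("CDS", gname, "+",
                                                  do.call(rbind, segs))
      feats <- c(feats, in_feats)
    } else {
      s <- if (strand == "-") reverse_complement(gseq) else gseq
      feats[[length(feats) + 1L]] <- gene_feature(
        kind, gname, strand, matrix(c(pos, pos + nchar(s)), ncol = 2))
      if (kind == "CDS")
        class_len["protein_coding"] <- class_len["protein_coding"] + nchar(s)
      else class_len["rna_gene"] <- class_len["rna_gene"] + nchar(s)
      push(s)
    }
    # tRNAs assigned to this slot
    for (tn in which(trna_after == mi)) {
      push(spacer())
      tseq <- random_dna(72L, spec$base_freqs)
      feats[[length(feats) + 1L]] <- gene_feature(
        "tRNA", sprintf("trn%s", LETTERS[(tn - 1L) %% 26L + 1L]), "+",
        matrix(c(pos, pos + 72L), ncol = 2),
        qualifiers = list(copy = as.character(tn)))
      class_len["rna_gene"] <- class_len["rna_gene"] + 72L
      push(tseq)
    }
  }
  push(spacer())
  seqn <- paste(parts, collapse = "")
  g <- mitogenome(id = species, sequence = seqn, species = species,
                  topology = "circular", features = feats)
  total <- nchar(seqn)
  truth <- list(
    gene_order = order,
    intron_positions = intron_pos,
    dispersed_repeats = do.call(rbind, truth_repeats),
    tandem_repeats = do.call(rbind, truth_tandem),
    region_lengths = c(class_len,
                       intergenic = total - sum(class_len)),
    total_length = total)
  list(genome = g, truth = truth)
}

#' Generate a full synthetic cohort with ground truth
#'
#' One genome per tree leaf plus the ground-truth bundle; byte-identical for
#' identical seeds.
#'
#' @param spec A [simulation_spec()].
#' @return List of class `mito_cohort`: `genomes` (named list of
#'   [mitogenome()]), `truth` (tree, distances, per-species gene orders,
#'   intron plan, repeat loci, region lengths).
#' @export
make_cohort <- function(spec) {
  sim <- simulate_alignment_on_tree(spec)
  species <- sim$truth$tree$tip.label
  genomes <- list(); truths <- list()
  for (sp in species) {
    res <- assemble_mitogenome(spec, sp, sim$genes)
    genomes[[sp]] <- res$genome
    truths[[sp]] <- res$truth
  }
  structure(list(genomes = genomes,
                 truth = list(tree = sim$truth$tree,
                              distances = sim$truth$distances,
                              genes = sim$genes,
                              per_species = truths,
                              intron_plan = spec$intron_plan,
                              spec = spec)),
            class = "mito_cohort")
}

#' @export
print.mito_cohort <- function(x, ...) {
  lens <- vapply(x$genomes, `[[`, 1L, "length")
  cat(sprintf("<mito_cohort> %d genomes, %d-%d bp\n", length(x$genomes),
              min(lens), max(lens)))
  invisible(x)
}
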