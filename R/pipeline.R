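#' Per-gene alignments for a set of genomes
#'
#' Extracts each marker's sequence from every genome; equal-length sets (the
#' common case for conserved mitochondrial genes) are used as-is, others are
#' aligned (codon-aware for coding markers).
#'
#' @param genomes List of [mitogenome()].
#' @param genes Marker labels.
#' @param code A [genetic_code()].
#' @return Named list of `msa` objects.
#' @export
cohort_gene_alignments <- function(genomes, genes = CORE_MARKERS,
                                   code = genetic_code(4)) {
  out <- list()
  for (gene in genes) {
    seqs <- character(0)
    for (g in genomes) {
      kinds <- vapply(g$features, `[[`, "", "kind")
      labels <- vapply(g$features, `[[`, "", "gene")
      hit <- which(labels == gene & kinds %in% c("CDS", "rRNA"))
      if (length(hit))
        seqs[[g$species]] <- extract_gene_sequence(g, g$features[[hit[1]]])
    }
    if (length(seqs) < 2L) next
    if (length(unique(nchar(seqs))) == 1L) {
      out[[gene]] <- structure(list(rows = as.list(seqs),
                                    length = nchar(seqs[[1]]),
                                    alphabet = "dna"), class = "msa")
    } else {
      out[[gene]] <- align_progressive(seqs, alphabet = "dna",
                                       codon = !(gene %in% RRNA_GENES),
                                       code = code)
    }
  }
  out
}

#' Run the full comparative pipeline over a set of genomes
#'
#' Executes every analysis stage — composition and region partition, codon
#' usage/RSCU with PCA, K2P and Ka/Ks, repeat detection, cox1 Pcl
#' classification, gene-order and synteny comparison, and NJ phylogenetics
#' on the requested concatenated datasets — and returns the result bundle,
#' optionally writing TSV/Newick outputs.
#'
#' @param genomes List of [mitogenome()] (or a directory/file path of
#'   GenBank records).
#' @param outdir Output directory for TSV/Newick files, or NULL to skip
#'   writing.
#' @param reference_species Reference for Pcl naming (default: first genome
#'   with cox1 introns).
#' @param dataset_kinds Concatenated datasets to build.
#' @param bootstrap_replicates Bootstrap replicates for the PCG tree.
#' @param common_pcl_threshold Fraction of species for a common Pcl.
#' @param synteny_min_identity,synteny_min_len Synteny block thresholds.
#' @param seed Seed for the bootstrap.
#' @return List of class `mito_report` with one element per stage.
#' @export
run_pipeline <- function(genomes, outdir = NULL,
                         reference_species = NULL,
                         dataset_kinds = c("PCG", "PCGR"),
                         bootstrap_replicates = 100L,
                         common_pcl_threshold = 0.20,
                         synteny_min_identity = 70,
                         synteny_min_len = 500L,
                         seed = 1L) {
  if (is.character(genomes)) {
    paths <- if (dir.exists(genomes))
      list.files(genomes, pattern = "\\.(gb|gbk|genbank)$", full.names = TRUE)
    else genomes
    genomes <- unlist(lapply(paths, read_genbank), recursive = FALSE)
  }
  if (length(genomes) < 2L) stop("need at least 2 genomes")
  species <- vapply(genomes, `[[`, "", "species")
  names(genomes) <- species
  code <- genetic_code(4)

  composition <- genome_composition_table(genomes)
  partitions <- lapply(genomes, partition_regions)
  per_gene <- per_gene_length_table(genomes)

  rscu_pcg <- cohort_rscu_matrix(genomes, "CDS", genes = CORE_PCGS,
                                 code = code)
  rscu_uorf <- cohort_rscu_matrix(genomes, "uORF", code = code)
  rscu_mat <- rbind(rscu_pcg, rscu_uorf)
  pca <- if (!is.null(rscu_mat) && nrow(rscu_mat) >= 3L)
    tryCatch(rscu_pca(rscu_mat), error = function(e) NULL) else NULL

  rates <- cohort_rate_records(genomes, code = code)
  rate_summary <- if (!is.null(rates) && nrow(rates)) per_gene_summary(rates)
    else NULL

  repeats <- lapply(genomes, function(g) {
    disp <- find_dispersed_repeats(g)
    tand <- find_tandem_repeats(g)
    list(dispersed = disp, tandem = tand,
         summary = repeat_summary(g, disp, tand))
  })

  # cox1 intron position classes
  introns <- do.call(rbind, lapply(genomes, intron_records))
  pcl <- NULL
  if (!is.null(introns) && nrow(introns)) {
    cds <- list()
    for (g in genomes) {
      kinds <- vapply(g$features, `[[`, "", "kind")
      labels <- vapply(g$features, `[[`, "", "gene")
      hit <- which(labels == "cox1" & kinds == "CDS")
      if (length(hit)) cds[[g$species]] <-
          extract_gene_sequence(g, g$features[[hit[1]]])
    }
    ref <- if (!is.null(reference_species)) cds[[reference_species]]
      else cds[[introns$species[1]]]
    pcl <- build_pcl_catalog(introns, cds, ref, code)
    pcl <- classify_common_rare(pcl, n_species = length(genomes),
                                threshold = common_pcl_threshold)
  }

  orders <- lapply(genomes, extract_gene_order)
  groups <- order_groups(orders)
  n <- length(genomes)
  bp <- matrix(0L, n, n, dimnames = list(species, species))
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    bp[i, j] <- bp[j, i] <- breakpoint_distance(orders[[i]], orders[[j]])

  synteny <- list()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    key <- paste(species[i], species[j], sep = "|")
    synteny[[key]] <- find_synteny_blocks(
      genomes[[i]], genomes[[j]], min_identity = synteny_min_identity,
      min_len = synteny_min_len)
  }

  alns <- cohort_gene_alignments(genomes, code = code)
  phylo <- list()
  for (kind in dataset_kinds) {
    sm <- build_supermatrix(alns, kind, code = code)
    tr <- bootstrap_support(sm, n_replicates = bootstrap_replicates,
                            seed = seed)
    phylo[[kind]] <- list(supermatrix = sm, tree = tr)
  }

  bundle <- structure(list(
    composition = composition, partitions = partitions, per_gene = per_gene,
    rscu = rscu_mat, pca = pca, rates = rates, rate_summary = rate_summary,
    repeats = repeats, pcl = pcl, orders = orders, order_groups = groups,
    breakpoints = bp, synteny = synteny, phylo = phylo,
    config = list(dataset_kinds = dataset_kinds,
                  bootstrap_replicates = bootstrap_replicates,
                  common_pcl_threshold = common_pcl_threshold,
                  synteny_min_identity = synteny_min_identity,
                  synteny_min_len = synteny_min_len, seed = seed)),
    class = "mito_report")

  if (!is.null(outdir)) write_report(bundle, outdir)
  bundle
}

write_report <- function(bundle, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(x, name) utils::write.table(
    x, file.path(outdir, paste0(name, ".tsv")), sep = "\t",
    quote = FALSE, row.names = FALSE)
  tsv(bundle$composition, "composition")
  part <- do.call(rbind, lapply(names(bundle$partitions), function(sp) {
    p <- bundle$partitions[[sp]]; p$species <- sp; p
  }))
  tsv(part, "region_partition")
  tsv(bundle$per_gene, "per_gene_stats")
  if (!is.null(bundle$rates)) tsv(bundle$rates, "pairwise_rates")
  if (!is.null(bundle$rate_summary)) tsv(bundle$rate_summary, "rate_summary")
  if (!is.null(bundle$pcl)) tsv(as.data.frame(bundle$pcl), "pcl_catalog")
  ords <- data.frame(
    species = vapply(bundle$orders, attr, "", "species"),
    order = vapply(bundle$orders, function(o)
      paste(unclass(o), collapse = " "), ""))
  tsv(ords, "gene_orders")
  utils::write.table(bundle$breakpoints,
                     file.path(outdir, "breakpoint_matrix.tsv"),
                     sep = "\t", quote = FALSE)
  for (kind in names(bundle$phylo))
    ape::write.tree(bundle$phylo[[kind]]$tree,
                    file.path(outdir, paste0("tree_", kind, ".nwk")))
  invisible(outdir)
}

#' One-page text summary of a pipeline report
#'
#' @param bundle A [run_pipeline()] result.
#' @param clades Optional named list of species sets whose monophyly on each
#'   inferred tree is reported.
#' @return Character vector of summary lines (also printed).
#' @export
pipeline_summary <- function(bundle, clades = NULL) {
  lines <- character(0)
  add <- function(...) lines <<- c(lines, sprintf(...))
  comp <- bundle$composition
  add("Genomes: %d (%d-%d bp)", nrow(comp), min(comp$length),
      max(comp$length))
  add("GC content: %.2f-%.2f%%; GC skew: %+.4f to %+.4f",
      100 * min(comp$gc_content), 100 * max(comp$gc_content),
      min(comp$gc_skew), max(comp$gc_skew))
  ig <- vapply(bundle$partitions, function(p)
    p$percent[p$class == "intergenic"], 1)
  add("Mean intergenic fraction: %.2f%%", mean(ig))
  if (!is.null(bundle$pcl))
    add("cox1 Pcls: %d (%d common, %d rare)", nrow(bundle$pcl),
        sum(bundle$pcl$status == "common"), sum(bundle$pcl$status == "rare"))
  else add("cox1 Pcls: skipped (no introns)")
  add("Gene-arrangement groups: %s",
      paste(lengths(bundle$order_groups), collapse = "+"))
  for (kind in names(bundle$phylo)) {
    tr <- bundle$phylo[[kind]]$tree
    add("%s tree: %d taxa, %d columns", kind, length(tr$tip.label),
        bundle$phylo[[kind]]$supermatrix$length)
    for (cl in names(clades)) {
      ok <- is_monophyletic(tr, clades[[cl]])
      add("  %s monophyletic on %s tree: %s", cl, kind,
          ifelse(ok, "yes", "no"))
    }
  }
  cat(paste(lines, collapse = "\n"), "\n")
  invisible(lines)
}
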