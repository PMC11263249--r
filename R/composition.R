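#' Base-composition statistics of a DNA sequence
#'
#' GC content = (G+C)/(A+C+G+T), GC skew = (G-C)/(G+C), AT skew =
#' (A-T)/(A+T). N is excluded from every denominator; a zero denominator
#' yields NA.
#'
#' @param sequence DNA string.
#' @return List with `gc_content`, `gc_skew`, `at_skew`, and `counts`
#'   (A/C/G/T/N tallies).
#' @export
composition_stats <- function(sequence) {
  if (!nzchar(sequence)) stop("empty sequence")
  s <- Biostrings::DNAString(toupper(sequence))
  cnt <- Biostrings::letterFrequency(s, c("A", "C", "G", "T", "N"))
  a <- cnt[["A"]]; c_ <- cnt[["C"]]; g <- cnt[["G"]]; t <- cnt[["T"]]
  acgt <- a + c_ + g + t
  list(
    gc_content = if (acgt > 0) (g + c_) / acgt else NA_real_,
    gc_skew    = if (g + c_ > 0) (g - c_) / (g + c_) else NA_real_,
    at_skew    = if (a + t > 0) (a - t) / (a + t) else NA_real_,
    counts = c(A = a, C = c_, G = g, T = t, N = cnt[["N"]])
  )
}

## region class codes in precedence order (highest wins)
REGION_CLASSES <- c("protein_coding", "rna_gene", "uorf", "intron", "intergenic")

#' Partition a genome into functional region classes
#'
#' Every position is assigned to exactly one of five classes with precedence
#' core-PCG exon > RNA gene > uORF > intron > intergenic, so overlapping
#' annotations (e.g. a uORF inside an intron) are resolved deterministically
#' and core-gene lengths are conservative.
#'
#' @param genome A [mitogenome()].
#' @return data.frame with one row per class: class, length_nt, percent
#'   (of total genome length); attribute `"total"` holds the genome length.
#' @export
partition_regions <- function(genome) {
  L <- genome$length
  cls <- rep.int(5L, L) # intergenic by default
  assign_class <- function(feats, code) {
    for (f in feats) for (i in seq_len(nrow(f$segments))) {
      idx <- (f$segments[i, 1] + 1L):f$segments[i, 2]
      cls[idx] <<- pmin(cls[idx], code)
    }
  }
  kinds <- vapply(genome$features, `[[`, "", "kind")
  genes <- vapply(genome$features, `[[`, "", "gene")
  # precedence applied via pmin with class codes 1..5
  assign_class(genome$features[kinds == "intron"], 4L)
  assign_class(genome$features[kinds == "uORF"], 3L)
  assign_class(genome$features[kinds %in% c("rRNA", "tRNA")], 2L)
  core <- kinds == "CDS" & genes %in% CORE_PCGS
  if (any(kinds == "CDS" & !core))
    assign_class(genome$features[kinds == "CDS" & !core], 3L) # accessory ORFs
  assign_class(genome$features[core], 1L)
  tab <- tabulate(cls, nbins = 5L)
  out <- data.frame(class = REGION_CLASSES, length_nt = tab,
                    percent = 100 * tab / L, stringsAsFactors = FALSE)
  attr(out, "total") <- L
  out
}

#' Per-gene length and composition table across genomes
#'
#' One row per (species, core gene): coding length and GC content / GC skew /
#' AT skew measured on the coding strand. Genes absent from a genome appear
#' as NA rows.
#'
#' @param genomes List of [mitogenome()].
#' @param genes Canonical labels to tabulate (default the 15 core PCGs).
#' @return data.frame with columns species, gene, length, gc_content,
#'   gc_skew, at_skew.
#' @export
per_gene_length_table <- function(genomes, genes = CORE_PCGS) {
  rows <- list()
  for (g in genomes) {
    kinds <- vapply(g$features, `[[`, "", "kind")
    labels <- vapply(g$features, `[[`, "", "gene")
    for (gene in genes) {
      hit <- which(labels == gene & kinds %in% c("CDS", "rRNA"))
      if (length(hit)) {
        s <- extract_gene_sequence(g, g$features[[hit[1]]])
        cs <- composition_stats(s)
        rows[[length(rows) + 1L]] <- data.frame(
          species = g$species, gene = gene, length = nchar(s),
          gc_content = cs$gc_content, gc_skew = cs$gc_skew,
          at_skew = cs$at_skew, stringsAsFactors = FALSE)
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          species = g$species, gene = gene, length = NA_integer_,
          gc_content = NA_real_, gc_skew = NA_real_, at_skew = NA_real_,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Whole-genome composition table
#'
#' @param genomes List of [mitogenome()].
#' @return data.frame: species, id, length, gc_content, gc_skew, at_skew.
#' @export
genome_composition_table <- function(genomes) {
  do.call(rbind, lapply(genomes, function(g) {
    cs <- composition_stats(g$sequence)
    data.frame(species = g$species, id = g$id, length = g$length,
               gc_content = cs$gc_content, gc_skew = cs$gc_skew,
               at_skew = cs$at_skew, stringsAsFactors = FALSE)
  }))
}
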