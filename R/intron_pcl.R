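#' Collect cox1 intron records from an annotated genome
#'
#' The host gene's exon segments and intron features are walked in coding
#' order; each intron's insertion point is expressed as the coding-sequence
#' position (1-based nt) immediately 5' of the intron in this species' own
#' CDS.
#'
#' @param genome A [mitogenome()].
#' @param gene Host gene label (default "cox1").
#' @param anchor_len Length of upstream-exon flank recorded per intron.
#' @return data.frame: species, gene, ordinal, start, end (0-based half-open
#'   genome interval), species_cds_pos, flank, intron_type.
#' @export
intron_records <- function(genome, gene = "cox1", anchor_len = 20L) {
  kinds <- vapply(genome$features, `[[`, "", "kind")
  labels <- vapply(genome$features, `[[`, "", "gene")
  cds_i <- which(labels == gene & kinds == "CDS")
  empty <- data.frame(species = character(), gene = character(),
                      ordinal = integer(), start = integer(), end = integer(),
                      species_cds_pos = integer(), flank = character(),
                      intron_type = character(), stringsAsFactors = FALSE)
  if (!length(cds_i)) return(empty)
  cds <- genome$features[[cds_i[1]]]
  introns <- genome$features[kinds == "intron" & labels == gene]
  if (!length(introns)) return(empty)
  cds_seq <- extract_gene_sequence(genome, cds)
  segs <- cds$segments
  # exon segments in coding order (already stored ordered along the feature;
  # minus strand reads them from the far end)
  if (cds$strand == "-") segs <- segs[rev(seq_len(nrow(segs))), , drop = FALSE]
  exon_lens <- segs[, 2] - segs[, 1]
  cum <- cumsum(exon_lens)
  rows <- list()
  for (f in introns) {
    s <- f$segments[1, 1]; e <- f$segments[nrow(f$segments), 2]
    # coding position immediately 5' of the intron = total exon length
    # upstream of the intron interval
    if (cds$strand == "+") {
      upstream <- sum(pmin(pmax(s - segs[, 1], 0L), exon_lens))
    } else {
      upstream <- sum(pmin(pmax(segs[, 2] - e, 0L), exon_lens))
    }
    if (upstream < 1L || upstream >= sum(exon_lens))
      stop("intron at [", s, ",", e, ") not inside host gene ", gene)
    flank <- substr(cds_seq, max(1L, upstream - anchor_len + 1L), upstream)
    rows[[length(rows) + 1L]] <- data.frame(
      species = genome$species, gene = gene, ordinal = NA_integer_,
      start = s, end = e, species_cds_pos = upstream, flank = flank,
      intron_type = f$qualifiers$intron_type %||% "unknown",
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  res <- res[order(res$species_cds_pos), , drop = FALSE]
  res$ordinal <- seq_len(nrow(res))
  res
}

#' Map a species intron insertion position onto a reference CDS
#'
#' Protein-guided mapping: the species and reference coding sequences are
#' translated, the translations globally aligned, and the species coding
#' position back-mapped through the alignment to a reference nucleotide
#' position (1-based). If the species residue aligns to a reference gap, the
#' nearest upstream reference-aligned position is used and flagged.
#'
#' @param species_cds_pos Coding position (1-based nt) immediately 5' of the
#'   intron in the species CDS.
#' @param species_cds,reference_cds In-frame DNA strings.
#' @param code A [genetic_code()].
#' @return Integer reference position with attribute `"flagged"` (TRUE when
#'   the position fell in a reference gap).
#' @export
map_insertion_position <- function(species_cds_pos, species_cds,
                                   reference_cds, code = genetic_code(4)) {
  if (identical(toupper(species_cds), toupper(reference_cds)))
    return(structure(as.integer(species_cds_pos), flagged = FALSE))
  pa <- suppressWarnings(translate_dna(species_cds, code, "keep"))
  pb <- suppressWarnings(translate_dna(reference_cds, code, "keep"))
  al <- nw_align_cpp(pa, pb, 2, -1, -8, -1)
  arow <- strsplit(al$a, "")[[1]]; brow <- strsplit(al$b, "")[[1]]
  # species aa index containing the insertion point, and offset within codon
  aa_idx <- ((species_cds_pos - 1L) %/% 3L) + 1L
  offset <- ((species_cds_pos - 1L) %% 3L) + 1L
  ai <- cumsum(arow != "-")
  bi <- cumsum(brow != "-")
  col <- match(aa_idx, ai * (arow != "-"))
  if (is.na(col)) col <- which(ai == aa_idx & arow != "-")[1]
  flagged <- FALSE
  if (is.na(col)) stop("insertion position beyond aligned species CDS")
  if (brow[col] == "-") {
    flagged <- TRUE
    prev <- which(brow[seq_len(col)] != "-")
    if (!length(prev)) stop("no upstream reference-aligned position")
    col <- max(prev)
    ref_pos <- bi[col] * 3L # end of the nearest upstream reference codon
  } else {
    ref_pos <- (bi[col] - 1L) * 3L + offset
  }
  structure(as.integer(ref_pos), flagged = flagged)
}

#' Build the Pcl catalog from all species' intron records
#'
#' Introns mapping to the same reference coding position form one position
#' class (Pcl), named `P<position>`.
#'
#' @param introns data.frame as from [intron_records()] over all species
#'   (rows must carry species, species_cds_pos, intron_type).
#' @param species_cds Named list of cox1 CDS strings per species.
#' @param reference_cds Reference cox1 CDS (positions are named relative to
#'   it); defaults to the first species' CDS.
#' @param code A [genetic_code()].
#' @return data.frame of class `pcl_catalog`: name, position, n_members,
#'   members (comma-separated), with attribute `"introns"` (the per-intron
#'   table with mapped positions).
#' @export
build_pcl_catalog <- function(introns, species_cds, reference_cds = NULL,
                              code = genetic_code(4)) {
  if (is.null(reference_cds)) reference_cds <- species_cds[[1]]
  introns$ref_pos <- vapply(seq_len(nrow(introns)), function(i) {
    sp <- introns$species[i]
    if (!sp %in% names(species_cds)) stop("no CDS supplied for ", sp)
    as.integer(map_insertion_position(introns$species_cds_pos[i],
                                      species_cds[[sp]], reference_cds, code))
  }, 1L)
  dup <- duplicated(introns[c("species", "ref_pos")])
  if (any(dup))
    stop("two introns of one species map to position ",
         paste(unique(introns$ref_pos[dup]), collapse = ","))
  pos <- sort(unique(introns$ref_pos))
  cat_rows <- lapply(pos, function(p) {
    m <- introns$species[introns$ref_pos == p]
    data.frame(name = paste0("P", p), position = p, n_members = length(m),
               members = paste(sort(m), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, cat_rows)
  if (is.null(out)) out <- data.frame(name = character(), position = integer(),
                                      n_members = integer(),
                                      members = character(),
                                      stringsAsFactors = FALSE)
  class(out) <- c("pcl_catalog", "data.frame")
  attr(out, "introns") <- introns
  attr(out, "reference_length") <- nchar(reference_cds)
  out
}

#' Classify Pcls as common or rare
#'
#' A Pcl occurring in at least `threshold` of the species (>= 20% by the
#' usual convention, i.e. ceiling(threshold * n_species) members) is common;
#' all others are rare.
#'
#' @param catalog A [build_pcl_catalog()] result.
#' @param n_species Number of species surveyed.
#' @param threshold Fraction of species required for "common".
#' @return The catalog with a `status` column added.
#' @export
classify_common_rare <- function(catalog, n_species, threshold = 0.20) {
  stopifnot(n_species >= 1)
  need <- ceiling(threshold * n_species)
  catalog$status <- ifelse(catalog$n_members >= need, "common", "rare")
  attr(catalog, "min_common_members") <- need
  catalog
}

#' Species x Pcl presence/type matrix
#'
#' @param catalog A [build_pcl_catalog()] result (attribute `introns` used).
#' @param species_order Row order (default: sorted species with introns).
#' @return Character matrix, rows = species, columns = Pcls sorted by
#'   position; cells carry the pass-through intron-type label or "".
#' @export
pcl_matrix <- function(catalog, species_order = NULL) {
  introns <- attr(catalog, "introns")
  if (is.null(species_order)) species_order <- sort(unique(introns$species))
  cols <- catalog$name[order(catalog$position)]
  m <- matrix("", length(species_order), length(cols),
              dimnames = list(species_order, cols))
  for (i in seq_len(nrow(introns))) {
    nm <- paste0("P", introns$ref_pos[i])
    if (introns$species[i] %in% species_order)
      m[introns$species[i], nm] <- introns$intron_type[i]
  }
  m
}

#' @export
print.pcl_catalog <- function(x, ...) {
  cat(sprintf("<pcl_catalog> %d Pcls, %d introns\n", nrow(x),
              nrow(attr(x, "introns"))))
  print(as.data.frame(x), ...)
  invisible(x)
}
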