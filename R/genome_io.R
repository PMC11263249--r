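## Coordinate model: all feature segments are 0-based half-open [start, end)
## on the deposited strand. GenBank I/O converts to/from 1-based inclusive.
## Circular genomes are never rotated implicitly; a feature crossing the
## origin carries two segments ([x, L) then [0, y)).

#' Construct an annotated mitochondrial genome record
#'
#' @param id Accession or name.
#' @param sequence DNA string over A/C/G/T/N (case-insensitive; stored upper).
#' @param species Species name.
#' @param topology `"circular"` or `"linear"`.
#' @param features List of [gene_feature()] objects.
#' @return An object of class `mitogenome`.
#' @export
mitogenome <- function(id, sequence, species = id, topology = "circular",
                       features = list()) {
  sequence <- toupper(sequence)
  if (nzchar(sequence) && grepl("[^ACGTN]", sequence))
    stop("sequence contains characters outside {A,C,G,T,N}")
  topology <- match.arg(topology, c("circular", "linear"))
  len <- nchar(sequence)
  for (f in features) {
    if (!inherits(f, "gene_feature")) stop("features must be gene_feature objects")
    if (any(f$segments < 0L) || any(f$segments[, 2] > len))
      stop("feature '", f$gene, "' exceeds sequence bounds")
  }
  structure(list(id = id, species = species, sequence = sequence,
                 topology = topology, length = len, features = features),
            class = "mitogenome")
}

#' @export
print.mitogenome <- function(x, ...) {
  kinds <- table(vapply(x$features, `[[`, "", "kind"))
  cat(sprintf("<mitogenome> %s (%s), %s, %d bp, %d features\n",
              x$id, x$species, x$topology, x$length, length(x$features)))
  if (length(kinds))
    cat("  ", paste(sprintf("%s: %d", names(kinds), kinds), collapse = ", "), "\n")
  invisible(x)
}

#' Construct a genome feature
#'
#' @param kind One of CDS, tRNA, rRNA, intron, uORF, other.
#' @param gene Canonical gene label (e.g. "cox1") or free label.
#' @param strand `"+"` or `"-"`.
#' @param segments Two-column matrix (or list of length-2 vectors) of 0-based
#'   half-open intervals, ordered along the feature; multiple segments are the
#'   exons of an intron-containing gene.
#' @param qualifiers Named character list (e.g. anticodon, intron_type).
#' @return An object of class `gene_feature`.
#' @export
gene_feature <- function(kind, gene, strand = "+", segments,
                         qualifiers = list()) {
  kind <- match.arg(kind, c("CDS", "tRNA", "rRNA", "intron", "uORF", "other"))
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  if (is.list(segments)) segments <- do.call(rbind, segments)
  segments <- matrix(as.integer(segments), ncol = 2,
                     dimnames = list(NULL, c("start", "end")))
  if (nrow(segments) == 0L) stop("segments must be non-empty")
  if (any(segments[, 2] <= segments[, 1])) stop("segments must satisfy start < end")
  if (nrow(segments) > 1L) {
    o <- order(segments[, 1])
    s <- segments[o, , drop = FALSE]
    if (any(s[-nrow(s), 2] > s[-1, 1]))
      stop("segments within a feature must not overlap")
  }
  if (kind == "CDS" && sum(segments[, 2] - segments[, 1]) < 3L)
    stop("CDS shorter than one codon")
  structure(list(kind = kind, gene = gene, strand = strand,
                 segments = segments, qualifiers = qualifiers),
            class = "gene_feature")
}

feature_length <- function(f) sum(f$segments[, 2] - f$segments[, 1])

feature_start <- function(f) min(f$segments[, 1])

#' Reverse complement of a DNA string
#'
#' @param s DNA string (A/C/G/T/N).
#' @return The reverse complement.
#' @export
reverse_complement <- function(s) {
  if (!nzchar(s)) return(s)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Genetic code table
#'
#' Wraps the NCBI translation tables; table 4 (mold/protozoan mitochondrial)
#' translates TGA as tryptophan and is the default throughout the package.
#' Start codons follow the ORF-scanning convention {ATG, GTG, TTG}.
#'
#' @param table_id NCBI translation table number.
#' @return List with `table_id`, `codons` (named 64-entry vector, stops `"*"`)
#'   and `starts`.
#' @export
genetic_code <- function(table_id = 4) {
  tab <- Biostrings::getGeneticCode(as.character(table_id))
  stopifnot(length(tab) == 64L)
  list(table_id = as.integer(table_id), codons = tab,
       starts = c("ATG", "GTG", "TTG"))
}

#' Extract the nucleotide sequence of a feature
#'
#' Segments are concatenated in feature order; minus-strand features are
#' reverse-complemented after concatenation, so the result always reads in
#' coding orientation.
#'
#' @param genome A [mitogenome()].
#' @param feature A [gene_feature()] belonging to `genome`.
#' @return DNA string.
#' @export
extract_gene_sequence <- function(genome, feature) {
  segs <- feature$segments
  parts <- substring(genome$sequence, segs[, 1] + 1L, segs[, 2])
  s <- paste(parts, collapse = "")
  if (feature$strand == "-") s <- reverse_complement(s)
  s
}

#' Translate a coding sequence
#'
#' Codon-wise translation under the given code. A trailing stop codon is
#' dropped; an incomplete trailing codon is dropped with a warning; codons
#' containing N translate to `X`.
#'
#' @param cds In-frame DNA string, length >= 3.
#' @param code A [genetic_code()].
#' @param on_internal_stop `"warn"`, `"error"`, or `"keep"`.
#' @return Amino-acid string.
#' @export
translate_dna <- function(cds, code = genetic_code(4),
                          on_internal_stop = c("warn", "error", "keep")) {
  on_internal_stop <- match.arg(on_internal_stop)
  cds <- toupper(cds)
  n <- nchar(cds)
  if (n < 3L) stop("coding sequence shorter than one codon")
  if (n %% 3L != 0L) {
    warning("CDS length not divisible by 3; trailing ", n %% 3L, " nt dropped")
    n <- n - n %% 3L
  }
  codons <- substring(cds, seq(1L, n, 3L), seq(3L, n, 3L))
  aa <- unname(code$codons[codons])
  aa[is.na(aa)] <- "X" # codons containing N or other ambiguity
  if (length(aa) && aa[length(aa)] == "*") aa <- aa[-length(aa)]
  if (any(aa == "*")) {
    msg <- paste("internal stop codon at codon",
                 paste(which(aa == "*"), collapse = ","))
    if (on_internal_stop == "error") stop(msg)
    if (on_internal_stop == "warn") warning(msg)
  }
  paste(aa, collapse = "")
}

## ---- open reading frame scanning -------------------------------------------

#' Scan regions of a genome for open reading frames
#'
#' Both strands and all three frames of each region are scanned; only regions
#' at least `min_region_nt` long are considered (the conventional 300 bp
#' cut-off for intergenic/intronic ORF searches). An ORF runs from an allowed
#' start codon to the first in-frame stop; overlapping ORFs in the same frame
#' are reduced to the longest.
#'
#' @param genome A [mitogenome()].
#' @param regions Two-column matrix of 0-based half-open intervals, or NULL
#'   for the whole sequence.
#' @param min_region_nt Minimum region length scanned.
#' @param min_orf_codons Minimum ORF length in codons (excluding the stop).
#' @param code A [genetic_code()].
#' @return data.frame with columns start, end (0-based half-open, genome
#'   coordinates of the ORF including its stop codon), strand, length_codons,
#'   protein.
#' @export
find_orfs <- function(genome, regions = NULL, min_region_nt = 300L,
                      min_orf_codons = 100L, code = genetic_code(4)) {
  if (is.null(regions)) regions <- matrix(c(0L, genome$length), ncol = 2)
  if (is.list(regions)) regions <- do.call(rbind, regions)
  out <- list()
  for (r in seq_len(nrow(regions))) {
    a <- regions[r, 1]; b <- regions[r, 2]
    if (b - a < min_region_nt) next
    reg <- substring(genome$sequence, a + 1L, b)
    for (strand in c("+", "-")) {
      s <- if (strand == "+") reg else reverse_complement(reg)
      hits <- scan_orfs_one_strand(s, min_orf_codons, code)
      if (is.null(hits)) next
      for (i in seq_len(nrow(hits))) {
        # hits are 0-based half-open within the (possibly revcomp'd) region
        if (strand == "+") {
          gs <- a + hits$start[i]; ge <- a + hits$end[i]
        } else {
          gs <- b - hits$end[i]; ge <- b - hits$start[i]
        }
        out[[length(out) + 1L]] <- data.frame(
          start = gs, end = ge, strand = strand,
          length_codons = hits$length_codons[i], protein = hits$protein[i],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(start = integer(), end = integer(),
                      strand = character(), length_codons = integer(),
                      protein = character(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res[order(res$start, res$end, res$strand), , drop = FALSE]
}

# ORFs on the forward strand of s (all 3 frames); coordinates 0-based
# half-open within s, end includes the stop codon when present.
scan_orfs_one_strand <- function(s, min_orf_codons, code) {
  n <- nchar(s)
  res <- list()
  for (frame in 0:2) {
    if (1L + frame > n - 2L) next
    starts <- seq(1L + frame, n - 2L, 3L)
    codons <- substring(s, starts, starts + 2L)
    aa <- unname(code$codons[codons]); aa[is.na(aa)] <- "X"
    is_stop <- aa == "*"
    is_start <- codons %in% code$starts
    # walk: for each start not inside an already-used ORF, find next stop
    i <- 1L; ncod <- length(codons)
    while (i <= ncod) {
      if (!is_start[i]) { i <- i + 1L; next }
      j <- i
      while (j <= ncod && !is_stop[j]) j <- j + 1L
      len <- j - i # codons before the stop
      if (j <= ncod && len >= min_orf_codons) {
        res[[length(res) + 1L]] <- data.frame(
          start = starts[i] - 1L, end = starts[i] - 1L + 3L * (len + 1L),
          length_codons = len,
          protein = paste(aa[i:(j - 1L)], collapse = ""),
          stringsAsFactors = FALSE)
      }
      # longest-ORF-per-stop: skip past this stop (ORFs sharing the stop are
      # nested; the first (longest) wins)
      i <- j + 1L
    }
  }
  if (!length(res)) return(NULL)
  do.call(rbind, res)
}

## ---- FASTA -----------------------------------------------------------------

#' Write sequences to a FASTA file
#'
#' @param records Named character vector or list of sequences; names are ids.
#' @param path Output file.
#' @param width Line width (default 60).
#' @export
write_fasta <- function(records, path, width = 60L) {
  records <- unlist(records)
  if (anyDuplicated(names(records))) stop("duplicate FASTA ids")
  if (!length(records)) { file.create(path); return(invisible(path)) }
  x <- Biostrings::BStringSet(records)
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' Read a FASTA file
#'
#' @param path FASTA file.
#' @return Named character vector (names are the first token of each header;
#'   full headers kept in attribute `"description"`).
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  out <- as.character(x)
  desc <- names(out)
  names(out) <- vapply(strsplit(desc, "[ \t]+"), `[`, "", 1L)
  attr(out, "description") <- desc
  out
}

## ---- GenBank flat files ----------------------------------------------------

gb_kind_map <- c(CDS = "CDS", tRNA = "tRNA", rRNA = "rRNA", intron = "intron",
                 misc_feature = "other")

#' Read mitogenomes from a GenBank flat file
#'
#' Parses LOCUS, FEATURES (gene/CDS/tRNA/rRNA/intron/misc_feature keys with
#' `complement()` and `join()` locations) and ORIGIN for each record.
#' Coordinates are converted from 1-based inclusive to the package's 0-based
#' half-open convention. A `misc_feature` with a `/note` containing "uORF" is
#' read back as a uORF feature.
#'
#' @param path GenBank flat file (possibly multi-record).
#' @return List of [mitogenome()] objects.
#' @export
read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^LOCUS", lines)
  if (!length(starts)) stop("not a GenBank flat file (no LOCUS line): ", path)
  ends <- c(starts[-1] - 1L, length(lines))
  lapply(seq_along(starts), function(i)
    parse_genbank_record(lines[starts[i]:ends[i]], path))
}

parse_genbank_record <- function(lines, path) {
  locus <- strsplit(trimws(lines[1]), "[ \t]+")[[1]]
  if (length(locus) < 3L) stop("malformed LOCUS line in ", path)
  id <- locus[2]
  topology <- if (any(tolower(locus) == "circular")) "circular" else "linear"
  species <- id
  org <- grep("^ {2}ORGANISM", lines, value = TRUE)
  if (length(org)) species <- trimws(sub("^ {2}ORGANISM", "", org[1]))
  defline <- grep("^DEFINITION", lines)
  if (!length(org) && length(defline))
    species <- trimws(sub("^DEFINITION +", "", lines[defline[1]]))

  fstart <- grep("^FEATURES", lines)
  ostart <- grep("^ORIGIN", lines)
  if (!length(ostart)) stop("malformed GenBank record (no ORIGIN) in ", path)
  seq_lines <- lines[(ostart[1] + 1L):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))

  features <- list()
  if (length(fstart)) {
    fl <- lines[(fstart[1] + 1L):(ostart[1] - 1L)]
    # feature headers start at column 6; qualifier/continuation lines at 22
    hdr <- grepl("^ {5}\\S", fl)
    idx <- which(hdr)
    for (k in seq_along(idx)) {
      block <- fl[idx[k]:(if (k < length(idx)) idx[k + 1L] - 1L else length(fl))]
      key <- sub("^ {5}(\\S+).*$", "\\1", block[1])
      if (!key %in% names(gb_kind_map)) next
      loctxt <- sub("^ {5}\\S+ +", "", block[1])
      quals <- block[-1]
      # location may continue onto non-qualifier lines
      while (length(quals) && !grepl("^ +/", quals[1])) {
        loctxt <- paste0(loctxt, trimws(quals[1])); quals <- quals[-1]
      }
      loc <- parse_gb_location(loctxt, path)
      q <- parse_gb_qualifiers(quals)
      kind <- gb_kind_map[[key]]
      if (kind == "other" && !is.null(q$note) && grepl("uORF", q$note))
        kind <- "uORF"
      gene <- q$gene %||% q$product %||% key
      features[[length(features) + 1L]] <-
        gene_feature(kind, gene, loc$strand, loc$segments, q)
    }
  }
  g <- mitogenome(id, sequence, species, topology, features)
  g
}

parse_gb_location <- function(txt, path) {
  txt <- gsub("[<>]", "", gsub("[[:space:]]", "", txt))
  strand <- "+"
  if (grepl("^complement\\(", txt)) {
    strand <- "-"
    txt <- sub("^complement\\((.*)\\)$", "\\1", txt)
  }
  if (grepl("^join\\(", txt)) txt <- sub("^join\\((.*)\\)$", "\\1", txt)
  parts <- strsplit(txt, ",")[[1]]
  segs <- lapply(parts, function(p) {
    m <- regmatches(p, regexec("^(\\d+)\\.\\.(\\d+)$", p))[[1]]
    if (length(m) != 3L) {
      m1 <- regmatches(p, regexec("^(\\d+)$", p))[[1]]
      if (length(m1) == 2L) return(c(as.integer(m1[2]) - 1L, as.integer(m1[2])))
      stop("cannot parse GenBank location '", p, "' in ", path)
    }
    c(as.integer(m[2]) - 1L, as.integer(m[3])) # 1-based inclusive -> 0-based half-open
  })
  # complement(join(a,b)) lists segments in genome order; feature order for a
  # minus-strand feature is the reverse
  if (strand == "-") segs <- rev(segs)
  list(strand = strand, segments = do.call(rbind, segs))
}

parse_gb_qualifiers <- function(lines) {
  lines <- trimws(lines)
  out <- list()
  cur <- NULL
  for (ln in lines) {
    if (grepl("^/", ln)) {
      eq <- regexpr("=", ln, fixed = TRUE)
      if (eq > 0) {
        cur <- substr(ln, 2L, eq - 1L)
        out[[cur]] <- gsub("\"", "", substr(ln, eq + 1L, nchar(ln)))
      } else {
        cur <- sub("^/", "", ln); out[[cur]] <- ""
      }
    } else if (!is.null(cur)) {
      out[[cur]] <- paste(out[[cur]], gsub("\"", "", ln))
    }
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write mitogenomes to a GenBank flat file
#'
#' @param genomes A [mitogenome()] or list of them.
#' @param path Output file.
#' @export
write_genbank <- function(genomes, path) {
  if (inherits(genomes, "mitogenome")) genomes <- list(genomes)
  con <- file(path, "w")
  on.exit(close(con))
  rev_kind <- c(CDS = "CDS", tRNA = "tRNA", rRNA = "rRNA", intron = "intron",
                uORF = "misc_feature", other = "misc_feature")
  for (g in genomes) {
    writeLines(sprintf("LOCUS       %s %d bp    DNA     %s   UNA %s",
                       g$id, g$length, g$topology,
                       format(Sys.Date(), "%d-%b-%Y")), con)
    writeLines(sprintf("DEFINITION  %s mitochondrion, complete genome.",
                       g$species), con)
    writeLines("SOURCE      synthetic or user-supplied record", con)
    writeLines(sprintf("  ORGANISM  %s", g$species), con)
    writeLines("FEATURES             Location/Qualifiers", con)
    writeLines(sprintf("     source          1..%d", g$length), con)
    writeLines(sprintf("                     /organism=\"%s\"", g$species), con)
    for (f in g$features) {
      segs <- f$segments
      if (f$strand == "-") segs <- segs[rev(seq_len(nrow(segs))), , drop = FALSE]
      loc <- paste(sprintf("%d..%d", segs[, 1] + 1L, segs[, 2]), collapse = ",")
      if (nrow(segs) > 1L) loc <- sprintf("join(%s)", loc)
      if (f$strand == "-") loc <- sprintf("complement(%s)", loc)
      writeLines(sprintf("     %-15s %s", rev_kind[[f$kind]], loc), con)
      writeLines(sprintf("                     /gene=\"%s\"", f$gene), con)
      if (f$kind == "uORF")
        writeLines("                     /note=\"uORF\"", con)
      for (qn in setdiff(names(f$qualifiers), c("gene", "note")))
        writeLines(sprintf("                     /%s=\"%s\"", qn,
                           f$qualifiers[[qn]]), con)
    }
    writeLines("ORIGIN", con)
    pos <- seq(1L, g$length, 60L)
    for (p in pos) {
      chunk <- substring(g$sequence, p, min(p + 59L, g$length))
      sub10 <- substring(chunk, seq(1L, nchar(chunk), 10L),
                         pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
      writeLines(sprintf("%9d %s", p, paste(tolower(sub10), collapse = " ")), con)
    }
    writeLines("//", con)
  }
  invisible(path)
}

#' Export the feature table of a set of genomes
#'
#' @param genomes List of [mitogenome()].
#' @return data.frame with one row per feature: genome_id, species, gene,
#'   kind, strand, segments (as "start-end;..." 0-based half-open), length.
#' @export
feature_table <- function(genomes) {
  if (inherits(genomes, "mitogenome")) genomes <- list(genomes)
  rows <- lapply(genomes, function(g) {
    if (!length(g$features)) return(NULL)
    data.frame(
      genome_id = g$id, species = g$species,
      gene = vapply(g$features, `[[`, "", "gene"),
      kind = vapply(g$features, `[[`, "", "kind"),
      strand = vapply(g$features, `[[`, "", "strand"),
      segments = vapply(g$features, function(f)
        paste(sprintf("%d-%d", f$segments[, 1], f$segments[, 2]),
              collapse = ";"), ""),
      length = vapply(g$features, feature_length, 1L),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
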