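# ---- trinucleotide context space --------------------------------------------

BASES <- c("A", "C", "G", "T")
PYRIMIDINES <- c("C", "T")
IMPACT_LEVELS <- c("synonymous", "nonsynonymous", "other")

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' The 96 pyrimidine-centered trinucleotide context labels
#'
#' Single-nucleotide substitutions are collapsed onto the strand whose
#' reference base is a pyrimidine (C or T), giving 6 substitution types
#' times 16 flanking-base combinations = 96 categories, the convention
#' used throughout mutational-signature analysis.  Labels have the form
#' `"A[C>T]G"`: 5' flank, reference>alternate, 3' flank.
#'
#' @return Character vector of the 96 labels, in a fixed canonical order
#'   (substitution type major, then 5' flank, then 3' flank).
#' @export
#' @examples
#' head(trinuc_contexts())
trinuc_contexts <- function() {
  labs <- character(0)
  for (ref in PYRIMIDINES) {
    for (alt in setdiff(BASES, ref)) {
      for (up in BASES) {
        for (down in BASES) {
          labs <- c(labs, paste0(up, "[", ref, ">", alt, "]", down))
        }
      }
    }
  }
  labs
}

.CONTEXTS <- NULL  # filled at load time

.context_labels <- function() {
  if (is.null(.CONTEXTS)) trinuc_contexts() else .CONTEXTS
}

.onLoad <- function(libname, pkgname) {
  # cache the canonical label order
  utils::assignInMyNamespace(".CONTEXTS", trinuc_contexts())
}

#' Reverse-complement of a DNA string (vectorized)
#' @param x character vector of ACGT strings
#' @return character vector
#' @keywords internal
revcomp <- function(x) {
  vapply(strsplit(x, ""), function(b) {
    paste(rev(unname(COMPLEMENT[b])), collapse = "")
  }, character(1))
}

#' Collapse a raw trinucleotide substitution onto the 96-context space
#'
#' Purine-centered inputs (center base A or G) are reverse-complemented
#' before lookup, so every valid single-base substitution maps to exactly
#' one of the 96 pyrimidine-centered labels.
#'
#' @param ref_trinuc character vector of 3-mers around the mutated base
#'   (reference strand, mutated base in the middle).
#' @param alt_base character vector of alternate alleles for the center base.
#' @return character vector of context labels, e.g. `"A[C>T]A"`.
#' @export
#' @examples
#' collapse_context("ACA", "T")  # "A[C>T]A"
#' collapse_context("TGT", "A")  # also "A[C>T]A" (reverse-complement strand)
collapse_context <- function(ref_trinuc, alt_base) {
  ref_trinuc <- toupper(ref_trinuc)
  alt_base <- toupper(alt_base)
  n <- max(length(ref_trinuc), length(alt_base))
  ref_trinuc <- rep_len(ref_trinuc, n)
  alt_base <- rep_len(alt_base, n)
  if (any(nchar(ref_trinuc) != 3L)) {
    stop("ref_trinuc must be 3-mers")
  }
  bad <- grepl("[^ACGT]", ref_trinuc) | !(alt_base %in% BASES)
  if (any(bad)) {
    stop("non-ACGT base in context at position(s): ",
         paste(which(bad), collapse = ", "))
  }
  center <- substr(ref_trinuc, 2, 2)
  if (any(center == alt_base)) {
    stop("alt allele equals the reference center base at position(s): ",
         paste(which(center == alt_base), collapse = ", "))
  }
  flip <- center %in% c("A", "G")
  ref_trinuc[flip] <- revcomp(ref_trinuc[flip])
  alt_base[flip] <- unname(COMPLEMENT[alt_base[flip]])
  paste0(substr(ref_trinuc, 1, 1), "[", substr(ref_trinuc, 2, 2), ">",
         alt_base, "]", substr(ref_trinuc, 3, 3))
}

# ---- codon-table annotation --------------------------------------------------

# standard genetic code, indexed by codon
GENETIC_CODE_TABLE <- local({
  aa <- c(
    TTT = "F", TTC = "F", TTA = "L", TTG = "L",
    CTT = "L", CTC = "L", CTA = "L", CTG = "L",
    ATT = "I", ATC = "I", ATA = "I", ATG = "M",
    GTT = "V", GTC = "V", GTA = "V", GTG = "V",
    TCT = "S", TCC = "S", TCA = "S", TCG = "S",
    CCT = "P", CCC = "P", CCA = "P", CCG = "P",
    ACT = "T", ACC = "T", ACA = "T", ACG = "T",
    GCT = "A", GCC = "A", GCA = "A", GCG = "A",
    TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
    CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
    AAT = "N", AAC = "N", AAA = "K", AAG = "K",
    GAT = "D", GAC = "D", GAA = "E", GAG = "E",
    TGT = "C", TGC = "C", TGA = "*", TGG = "W",
    CGT = "R", CGC = "R", CGA = "R", CGG = "R",
    AGT = "S", AGC = "S", AGA = "R", AGG = "R",
    GGT = "G", GGC = "G", GGA = "G", GGG = "G"
  )
  aa
})

#' Enumerate every possible single-nucleotide change in a coding sequence
#'
#' Each base of an in-frame coding sequence is changed to the other three
#' nucleotides; the functional impact of each change is determined by
#' comparing the mutated codon's amino acid with the original under the
#' standard genetic code (amino-acid-preserving changes are synonymous,
#' everything else -- missense, nonsense, stop-loss -- is non-synonymous).
#' Trinucleotide contexts at the sequence ends use the supplied flanks.
#'
#' @param coding_sequence in-frame coding DNA string (length divisible by 3,
#'   alphabet ACGT).
#' @param flank5,flank3 single bases immediately up/downstream of the
#'   sequence, used for terminal contexts.
#' @return data.frame with columns `pos` (1-based position in the coding
#'   sequence), `ref`, `alt`, `context` (96-category label), `impact`.
#'   Exactly `3 * nchar(coding_sequence)` rows.
#' @export
enumerate_possible_mutations <- function(coding_sequence, flank5 = "A",
                                         flank3 = "A") {
  s <- toupper(coding_sequence)
  L <- nchar(s)
  if (L %% 3L != 0L) {
    stop("coding sequence length (", L, ") is not divisible by 3")
  }
  b <- strsplit(s, "")[[1]]
  bad <- which(!(b %in% BASES))
  if (length(bad)) {
    stop("non-ACGT base at position(s): ", paste(bad, collapse = ", "))
  }
  flank5 <- toupper(flank5); flank3 <- toupper(flank3)
  if (!(flank5 %in% BASES) || !(flank3 %in% BASES)) {
    stop("flanks must be single ACGT bases")
  }
  padded <- c(flank5, b, flank3)
  pos <- rep(seq_len(L), each = 3L)
  ref <- b[pos]
  alt <- unlist(lapply(b, function(x) setdiff(BASES, x)), use.names = FALSE)
  up <- padded[pos]          # base before (padded index pos = original pos-1+1)
  down <- padded[pos + 2L]
  context <- collapse_context(paste0(up, ref, down), alt)

  codon_idx <- (pos - 1L) %/% 3L            # 0-based codon
  within <- (pos - 1L) %% 3L + 1L           # position in codon 1..3
  codons <- vapply(seq_len(L %/% 3L), function(i) {
    paste(b[(3L * i - 2L):(3L * i)], collapse = "")
  }, character(1))
  ref_codon <- codons[codon_idx + 1L]
  alt_codon <- ref_codon
  substr(alt_codon, within, within) <- alt
  impact <- ifelse(GENETIC_CODE_TABLE[ref_codon] == GENETIC_CODE_TABLE[alt_codon],
                   "synonymous", "nonsynonymous")
  data.frame(pos = pos, ref = ref, alt = alt, context = context,
             impact = unname(impact), stringsAsFactors = FALSE)
}

# ---- exome annotation container ---------------------------------------------

#' Construct an ExomeAnnotation object
#'
#' The per-gene "exposure" structure of the background model: for every
#' gene, the count of possible single-base changes stratified by the 96
#' trinucleotide contexts and impact class.
#'
#' @param counts 3-d array `[gene, context, impact]`; context dimension must
#'   be the 96 canonical labels, impact dimension
#'   `c("synonymous","nonsynonymous","other")`.
#' @param gene_intervals optional data.frame (`gene`, `chrom`, `start`, `end`,
#'   0-based half-open) locating each gene's coding territory; used for
#'   panel construction and subsetting.
#' @return object of class `ExomeAnnotation` with elements `genes`, `counts`,
#'   `coding_length` (bases, `= rowSums(counts)/3`), `exome_mb`,
#'   `gene_intervals`.
#' @export
exome_annotation <- function(counts, gene_intervals = NULL) {
  stopifnot(length(dim(counts)) == 3L)
  if (dim(counts)[2] != 96L) stop("context dimension must have 96 levels")
  if (!identical(dimnames(counts)[[3]], IMPACT_LEVELS)) {
    stop("impact dimension must be ", paste(IMPACT_LEVELS, collapse = "/"))
  }
  if (any(counts < 0)) stop("negative possible-change counts")
  genes <- dimnames(counts)[[1]]
  coding_length <- apply(counts, 1, sum) / 3
  structure(list(
    genes = genes,
    counts = counts,
    coding_length = coding_length,
    exome_mb = sum(coding_length) / 1e6,
    gene_intervals = gene_intervals
  ), class = "ExomeAnnotation")
}

#' @export
print.ExomeAnnotation <- function(x, ...) {
  cat("ExomeAnnotation:", length(x$genes), "genes,",
      format(x$exome_mb, digits = 4), "Mb coding\n")
  invisible(x)
}

#' Subset an annotation to a set of genes
#'
#' Used to restrict exposures to the genes covered by a whole-gene panel.
#'
#' @param annot ExomeAnnotation
#' @param genes character vector of gene identifiers
#' @return ExomeAnnotation covering only `genes`
#' @export
subset_annotation <- function(annot, genes) {
  stopifnot(inherits(annot, "ExomeAnnotation"))
  keep <- intersect(annot$genes, genes)
  if (!length(keep)) stop("no requested genes present in annotation")
  gi <- annot$gene_intervals
  if (!is.null(gi)) gi <- gi[gi$gene %in% keep, , drop = FALSE]
  exome_annotation(annot$counts[keep, , , drop = FALSE], gene_intervals = gi)
}

# ---- building from sequence --------------------------------------------------

.read_fasta <- function(path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    ss <- Biostrings::readDNAStringSet(path)
    out <- as.character(ss)
    names(out) <- sub("\\s.*$", "", names(ss))
    return(out)
  }
  # minimal fallback reader (uncompressed FASTA)
  lines <- readLines(path)
  hdr <- grepl("^>", lines)
  id <- sub("^>(\\S+).*$", "\\1", lines[hdr])
  grp <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], grp[!hdr]),
                 function(x) toupper(paste(x, collapse = "")), character(1))
  names(seqs) <- id
  seqs
}

#' Build an ExomeAnnotation from gene models and a reference FASTA
#'
#' Enumerates all possible coding single-nucleotide changes for one
#' transcript per gene (protein-coding only; the longest transcript wins,
#' ties broken lexicographically by transcript ID) and aggregates them
#' into per-gene context-by-impact exposure counts.  Gene-model intervals
#' are 1-based inclusive.  When `panel` is given, only changes at genomic
#' positions covered by the panel's intervals (0-based half-open) are
#' counted -- impact is still determined from the full transcript, so
#' partial-gene panels get exact, not proportionally scaled, exposures.
#'
#' @param gene_models data.frame with columns `gene_id`, `transcript_id`,
#'   `chrom`, `start`, `end`, `strand`, `phase`; one row per CDS interval.
#' @param reference path to a FASTA file, or a named character vector of
#'   contig sequences.
#' @param panel optional `PanelDefinition` restricting counted positions.
#' @return ExomeAnnotation
#' @export
build_exome_annotation <- function(gene_models, reference, panel = NULL) {
  req <- c("gene_id", "transcript_id", "chrom", "start", "end", "strand")
  miss <- setdiff(req, names(gene_models))
  if (length(miss)) stop("gene model table lacks column(s): ",
                         paste(miss, collapse = ", "))
  seqs <- if (is.character(reference) && length(reference) == 1L &&
              file.exists(reference)) .read_fasta(reference) else reference

  # transcript priority: longest total CDS, ties lexicographic by ID
  gm <- gene_models
  gm$len <- gm$end - gm$start + 1L
  tx_len <- stats::aggregate(len ~ gene_id + transcript_id, gm, sum)
  tx_len <- tx_len[order(tx_len$gene_id, -tx_len$len, tx_len$transcript_id), ]
  chosen <- tx_len[!duplicated(tx_len$gene_id), c("gene_id", "transcript_id")]

  ctx <- .context_labels()
  genes <- sort(unique(chosen$gene_id))
  counts <- array(0L, dim = c(length(genes), 96L, 3L),
                  dimnames = list(genes, ctx, IMPACT_LEVELS))
  ivl_rows <- list()

  for (i in seq_len(nrow(chosen))) {
    g <- chosen$gene_id[i]; tx <- chosen$transcript_id[i]
    rows <- gm[gm$gene_id == g & gm$transcript_id == tx, , drop = FALSE]
    chrom <- rows$chrom[1]
    if (!chrom %in% names(seqs)) stop("contig ", chrom, " (gene ", g,
                                      ") not in reference")
    contig <- seqs[[chrom]]
    if (any(rows$start < 1L | rows$end > nchar(contig))) {
      stop("CDS interval outside contig bounds for gene ", g)
    }
    rows <- rows[order(rows$start), , drop = FALSE]
    if (nrow(rows) > 1L && any(rows$start[-1] <= rows$end[-nrow(rows)])) {
      stop("overlapping CDS intervals within transcript ", tx, " of gene ", g)
    }
    # genomic positions of coding bases, 5'->3' on the coding strand
    gpos <- unlist(mapply(seq, rows$start, rows$end, SIMPLIFY = FALSE))
    strand <- rows$strand[1]
    bases <- strsplit(substr(contig, 1, nchar(contig)), "")[[1]]
    cds_fwd <- bases[gpos]
    if (strand == "-") {
      gpos <- rev(gpos)
      cds <- rev(unname(COMPLEMENT[cds_fwd]))
    } else {
      cds <- cds_fwd
    }
    # flanks from the reference where available
    flank_at <- function(p) {
      if (p >= 1L && p <= length(bases)) bases[p] else "A"
    }
    if (strand == "-") {
      f5 <- COMPLEMENT[[flank_at(gpos[1] + 1L)]]
      f3 <- COMPLEMENT[[flank_at(gpos[length(gpos)] - 1L)]]
    } else {
      f5 <- flank_at(gpos[1] - 1L)
      f3 <- flank_at(gpos[length(gpos)] + 1L)
    }
    enum <- enumerate_possible_mutations(paste(cds, collapse = ""), f5, f3)
    enum$gpos <- gpos[enum$pos]
    if (!is.null(panel)) {
      keep <- in_intervals(chrom, enum$gpos - 1L, panel$intervals)
      enum <- enum[keep, , drop = FALSE]
    }
    if (nrow(enum)) {
      tab <- table(factor(enum$context, levels = ctx),
                   factor(enum$impact, levels = IMPACT_LEVELS))
      counts[g, , ] <- counts[g, , ] + unclass(tab)
    }
    ivl_rows[[g]] <- data.frame(gene = g, chrom = chrom,
                                start = rows$start - 1L, end = rows$end,
                                stringsAsFactors = FALSE)
  }
  exome_annotation(counts, gene_intervals = do.call(rbind, ivl_rows))
}

# ---- serialization -----------------------------------------------------------

#' Write an ExomeAnnotation to a TSV file
#'
#' Columns `gene_id`, `context_label`, `impact`, `count`, sorted by gene,
#' context index, impact; zero-count cells are omitted.
#'
#' @param annot ExomeAnnotation
#' @param path output file
#' @export
write_annotation <- function(annot, path) {
  stopifnot(inherits(annot, "ExomeAnnotation"))
  ctx <- .context_labels()
  df <- expand.grid(impact = IMPACT_LEVELS, context_label = ctx,
                    gene_id = annot$genes, stringsAsFactors = FALSE)
  df <- df[, c("gene_id", "context_label", "impact")]
  df$count <- as.vector(aperm(annot$counts, c(3, 2, 1)))
  df <- df[df$count > 0, , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an ExomeAnnotation from its TSV format
#' @param path file written by [write_annotation()] or produced externally
#'   with the same columns.
#' @param gene_intervals optional interval table to attach.
#' @return ExomeAnnotation
#' @export
read_annotation <- function(path, gene_intervals = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("gene_id", "context_label", "impact", "count")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("annotation table lacks column(s): ",
                         paste(miss, collapse = ", "))
  ctx <- .context_labels()
  badc <- setdiff(unique(df$context_label), ctx)
  if (length(badc)) stop("unknown context label(s): ",
                         paste(utils::head(badc, 3), collapse = ", "))
  badi <- setdiff(unique(df$impact), IMPACT_LEVELS)
  if (length(badi)) stop("unknown impact class(es): ",
                         paste(badi, collapse = ", "))
  genes <- sort(unique(df$gene_id))
  counts <- array(0L, dim = c(length(genes), 96L, 3L),
                  dimnames = list(genes, ctx, IMPACT_LEVELS))
  counts[cbind(match(df$gene_id, genes), match(df$context_label, ctx),
               match(df$impact, IMPACT_LEVELS))] <- df$count
  exome_annotation(counts, gene_intervals = gene_intervals)
}
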