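# ---- interval helpers --------------------------------------------------------

#' Normalize a set of genomic intervals
#'
#' Sorts and merges overlapping/adjacent intervals per chromosome
#' (0-based half-open).
#' @param intervals data.frame with `chrom`, `start`, `end`
#' @return normalized data.frame
#' @keywords internal
normalize_intervals <- function(intervals) {
  stopifnot(all(c("chrom", "start", "end") %in% names(intervals)))
  if (!nrow(intervals)) return(intervals)
  out <- lapply(split(intervals, intervals$chrom), function(d) {
    d <- d[order(d$start, d$end), , drop = FALSE]
    s <- d$start; e <- d$end
    ks <- s[1]; ke <- e[1]; res_s <- c(); res_e <- c()
    for (i in seq_along(s)[-1]) {
      if (s[i] <= ke) ke <- max(ke, e[i])
      else { res_s <- c(res_s, ks); res_e <- c(res_e, ke); ks <- s[i]; ke <- e[i] }
    }
    data.frame(chrom = d$chrom[1], start = c(res_s, ks), end = c(res_e, ke),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Test genomic positions for membership in interval set
#'
#' @param chrom,pos parallel vectors; `pos` is 0-based (convert 1-based
#'   mutation coordinates with `pos - 1` before calling, or use
#'   [subset_to_panel()]).
#' @param intervals normalized 0-based half-open intervals
#' @return logical vector
#' @keywords internal
in_intervals <- function(chrom, pos, intervals) {
  chrom <- rep_len(chrom, length(pos))
  hit <- logical(length(pos))
  for (ch in unique(chrom)) {
    ivl <- intervals[intervals$chrom == ch, , drop = FALSE]
    sel <- chrom == ch
    if (!nrow(ivl)) next
    ivl <- ivl[order(ivl$start), , drop = FALSE]
    idx <- findInterval(pos[sel], ivl$start)
    ok <- idx >= 1L
    ok[ok] <- pos[sel][ok] < ivl$end[idx[ok]]
    hit[sel] <- ok
  }
  hit
}

# in_intervals assumes pre-0-based positions for panel membership of a
# genomic base; mutation records store 1-based positions.

# ---- MutationTable -----------------------------------------------------------

MAF_CLASS_MAP <- c(
  Silent = "synonymous",
  Missense_Mutation = "nonsynonymous",
  Nonsense_Mutation = "nonsynonymous",
  Nonstop_Mutation = "nonsynonymous",
  Splice_Site = "nonsynonymous",
  Frame_Shift_Del = "indel",
  Frame_Shift_Ins = "indel",
  In_Frame_Del = "indel",
  In_Frame_Ins = "indel"
)

.as_mutation_table <- function(df) {
  class(df) <- c("MutationTable", "data.frame")
  df
}

#' Construct a MutationTable from bare vectors
#' @param sample_id,gene,chrom,pos,ref,alt,variant_class,context parallel
#'   vectors; `pos` 1-based; `variant_class` one of
#'   synonymous/nonsynonymous/indel/other; `context` 96-category label or NA.
#' @return MutationTable (a data.frame subclass)
#' @export
mutation_table <- function(sample_id, gene, chrom, pos, ref, alt,
                           variant_class, context = NA_character_) {
  n <- max(length(sample_id), length(gene), length(pos),
           length(variant_class))
  sample_id <- rep_len(as.character(sample_id), n)
  gene <- rep_len(as.character(gene), n)
  chrom <- rep_len(as.character(chrom), n)
  pos <- rep_len(pos, n)
  ref <- rep_len(as.character(ref), n)
  alt <- rep_len(as.character(alt), n)
  variant_class <- rep_len(as.character(variant_class), n)
  context <- rep_len(as.character(context), n)
  df <- data.frame(sample_id = as.character(sample_id),
                   gene = as.character(gene),
                   chrom = as.character(chrom),
                   pos = as.integer(pos),
                   ref = as.character(ref), alt = as.character(alt),
                   variant_class = as.character(variant_class),
                   context = as.character(context),
                   stringsAsFactors = FALSE)
  if (any(df$ref == df$alt)) stop("ref equal to alt in mutation record(s)")
  .as_mutation_table(df)
}

#' Read somatic mutation calls from a MAF-style TSV
#'
#' Requires the seven canonical columns (`Hugo_Symbol`, `Chromosome`,
#' `Start_Position`, `Reference_Allele`, `Tumor_Seq_Allele2`,
#' `Variant_Classification`, `Tumor_Sample_Barcode`; header matched
#' case-insensitively, extra columns ignored).  Variant classes are
#' collapsed to synonymous / nonsynonymous / indel / other; splice-site
#' calls count as non-synonymous by default.  SNV trinucleotide contexts
#' are taken from a `CONTEXT` column (raw reference 3-mer around the
#' variant) when present, else from `reference` when provided, else NA.
#'
#' @param path MAF-style TSV file
#' @param reference optional FASTA path or named character vector of contigs,
#'   used to derive SNV contexts.
#' @param splice_as_nonsynonymous logical; map `Splice_Site` to
#'   nonsynonymous (default) or to other.
#' @return MutationTable
#' @export
read_maf <- function(path, reference = NULL, splice_as_nonsynonymous = TRUE) {
  # everything as character: allele columns like "T" must not become logical
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#",
                          check.names = FALSE, colClasses = "character")
  req <- c("Hugo_Symbol", "Chromosome", "Start_Position", "Reference_Allele",
           "Tumor_Seq_Allele2", "Variant_Classification",
           "Tumor_Sample_Barcode")
  lownames <- tolower(names(df))
  idx <- match(tolower(req), lownames)
  if (anyNA(idx)) {
    stop("MAF lacks required column(s): ",
         paste(req[is.na(idx)], collapse = ", "))
  }
  names(df)[idx] <- req
  if (!nrow(df)) {
    return(mutation_table(character(0), character(0), character(0), integer(0),
                          character(0), character(0), character(0),
                          character(0)))
  }
  pos <- suppressWarnings(as.integer(df$Start_Position))
  if (anyNA(pos)) {
    bad <- which(is.na(pos))[1]
    stop("unparseable Start_Position at data line ", bad + 1L,
         " of ", path)
  }
  cls_map <- MAF_CLASS_MAP
  if (!splice_as_nonsynonymous) cls_map[["Splice_Site"]] <- "other"
  vc <- unname(cls_map[df$Variant_Classification])
  vc[is.na(vc)] <- "other"

  ref <- toupper(df$Reference_Allele)
  alt <- toupper(df$Tumor_Seq_Allele2)
  is_len_indel <- nchar(ref) != nchar(alt) | ref == "-" | alt == "-"
  vc[is_len_indel] <- "indel"

  context <- rep(NA_character_, nrow(df))
  is_snv <- vc %in% c("synonymous", "nonsynonymous", "other") &
    nchar(ref) == 1L & nchar(alt) == 1L & ref %in% BASES & alt %in% BASES
  ctx_col <- which(lownames == "context")
  if (length(ctx_col)) {
    raw <- toupper(df[[ctx_col[1]]])
    ok <- is_snv & !is.na(raw) & nchar(raw) == 3L & !grepl("[^ACGT]", raw)
    if (any(ok)) context[ok] <- collapse_context(raw[ok], alt[ok])
  } else if (!is.null(reference)) {
    seqs <- if (is.character(reference) && length(reference) == 1L &&
                file.exists(reference)) .read_fasta(reference) else reference
    for (ch in unique(df$Chromosome[is_snv])) {
      if (!ch %in% names(seqs)) next
      sel <- which(is_snv & df$Chromosome == ch & pos > 1 &
                     pos < nchar(seqs[[ch]]))
      if (!length(sel)) next
      raw <- substring(seqs[[ch]], pos[sel] - 1L, pos[sel] + 1L)
      usable <- !grepl("[^ACGT]", raw) & substr(raw, 2, 2) == ref[sel]
      if (any(usable)) {
        context[sel[usable]] <- collapse_context(raw[usable], alt[sel[usable]])
      }
    }
  }
  mutation_table(df$Tumor_Sample_Barcode, df$Hugo_Symbol, df$Chromosome,
                 pos, ref, alt, vc, context)
}

#' Write a MutationTable as a MAF-style TSV
#'
#' Inverse of [read_maf()] up to column naming: emits the seven required
#' MAF columns plus a `CONTEXT` column carrying the raw pyrimidine-strand
#' trinucleotide for SNVs so contexts survive a round trip.
#' @param muts MutationTable
#' @param path output file
#' @export
write_maf <- function(muts, path) {
  inv_map <- c(synonymous = "Silent", nonsynonymous = "Missense_Mutation",
               indel = "Frame_Shift_Del", other = "Translation_Start_Site")
  # context written on the record's own strand so ref/alt round-trip
  pyr <- paste0(substr(muts$context, 1, 1), substr(muts$context, 3, 3),
                substr(muts$context, 7, 7))
  on_purine <- !is.na(muts$context) & muts$ref != substr(muts$context, 3, 3)
  raw_ctx <- ifelse(is.na(muts$context), "",
                    ifelse(on_purine, revcomp(pyr), pyr))
  out <- data.frame(
    Hugo_Symbol = muts$gene, Chromosome = muts$chrom,
    Start_Position = muts$pos, Reference_Allele = muts$ref,
    Tumor_Seq_Allele2 = muts$alt,
    Variant_Classification = unname(inv_map[muts$variant_class]),
    Tumor_Sample_Barcode = muts$sample_id,
    CONTEXT = raw_ctx, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}


# ---- panels ------------------------------------------------------------------

#' Construct a PanelDefinition
#'
#' @param intervals data.frame `chrom`, `start`, `end` (0-based half-open);
#'   normalized (sorted, overlaps merged) on construction.
#' @param name panel name
#' @param annot optional ExomeAnnotation whose `gene_intervals` are used to
#'   compute the exonic (coding) size of the panel and the covered gene set.
#' @return object of class `PanelDefinition`: `name`, `intervals`,
#'   `exonic_mb`, `gene_set`.
#' @export
panel_definition <- function(intervals, name = "panel", annot = NULL) {
  intervals <- normalize_intervals(intervals)
  if (any(intervals$end <= intervals$start)) stop("empty or inverted interval")
  exonic_mb <- sum(intervals$end - intervals$start) / 1e6
  gene_set <- character(0)
  if (!is.null(annot) && !is.null(annot$gene_intervals)) {
    gi <- annot$gene_intervals
    cov_bases <- vapply(seq_len(nrow(gi)), function(i) {
      ivl <- intervals[intervals$chrom == gi$chrom[i], , drop = FALSE]
      if (!nrow(ivl)) return(0)
      sum(pmax(0, pmin(ivl$end, gi$end[i]) - pmax(ivl$start, gi$start[i])))
    }, numeric(1))
    gene_set <- unique(gi$gene[cov_bases > 0])
    exonic_mb <- sum(cov_bases) / 1e6
  }
  if (exonic_mb <= 0) stop("panel has zero exonic size")
  structure(list(name = name, intervals = intervals, exonic_mb = exonic_mb,
                 gene_set = gene_set), class = "PanelDefinition")
}

#' Read a BED3 file into a PanelDefinition
#' @param path BED file (0-based half-open, no header)
#' @inheritParams panel_definition
#' @export
read_bed <- function(path, name = basename(path), annot = NULL) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop("BED file needs at least 3 columns")
  panel_definition(data.frame(chrom = as.character(df[[1]]),
                              start = as.integer(df[[2]]),
                              end = as.integer(df[[3]]),
                              stringsAsFactors = FALSE),
                   name = name, annot = annot)
}

#' Write a PanelDefinition as BED3
#' @param panel PanelDefinition
#' @param path output file
#' @export
write_bed <- function(panel, path) {
  utils::write.table(panel$intervals, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Restrict mutations to a panel's target regions
#'
#' A record at 1-based position `p` is retained iff `p - 1` falls in one of
#' the panel's 0-based half-open intervals.  Record order is preserved.
#' @param muts MutationTable
#' @param panel PanelDefinition
#' @return MutationTable
#' @export
subset_to_panel <- function(muts, panel) {
  stopifnot(inherits(panel, "PanelDefinition"))
  keep <- in_intervals(muts$chrom, muts$pos - 1L, panel$intervals)
  .as_mutation_table(muts[keep, , drop = FALSE])
}

# ---- hotspot filtering -------------------------------------------------------

#' Read a hotspot/blacklist variant list
#' @param path TSV with columns `chrom`, `pos`, `ref`, `alt`
#' @return data.frame
#' @export
read_hotspots <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  miss <- setdiff(c("chrom", "pos", "ref", "alt"), names(df))
  if (length(miss)) stop("hotspot table lacks column(s): ",
                         paste(miss, collapse = ", "))
  df$pos <- as.integer(df$pos)
  df
}

#' Remove known hotspot variants from a mutation table
#'
#' Exact-key removal on (chrom, pos, ref, alt) -- the counting-with-
#' database-filtering baseline for panel TMB.
#' @param muts MutationTable
#' @param hotspots data.frame with `chrom`, `pos`, `ref`, `alt`
#' @return MutationTable
#' @export
filter_hotspots <- function(muts, hotspots) {
  if (is.null(hotspots) || !nrow(hotspots)) return(muts)
  key <- function(ch, p, r, a) paste(ch, p, toupper(r), toupper(a), sep = ":")
  drop <- key(muts$chrom, muts$pos, muts$ref, muts$alt) %in%
    key(hotspots$chrom, hotspots$pos, hotspots$ref, hotspots$alt)
  .as_mutation_table(muts[!drop, , drop = FALSE])
}

# ---- covariates --------------------------------------------------------------

#' Read the per-gene covariate table
#'
#' Columns `gene_id`, `expression`, `replication_timing`.  Genes requested
#' via `genes` but absent from the table are imputed with the column
#' medians (with a warning), so the downstream GLM always has a complete
#' design.
#' @param path TSV file
#' @param genes optional character vector of genes the table must cover
#' @return data.frame with rownames = gene ids
#' @export
read_covariates <- function(path, genes = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("gene_id", "expression", "replication_timing"), names(df))
  if (length(miss)) stop("covariate table lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(df$gene_id)) stop("duplicate gene_id in covariate table")
  if (any(df$expression < 0, na.rm = TRUE)) stop("negative expression level")
  out <- df[, c("expression", "replication_timing")]
  rownames(out) <- df$gene_id
  if (!is.null(genes)) out <- impute_covariates(out, genes)
  out
}

#' Median-impute covariates for missing genes
#' @param cov data.frame with rownames = gene ids
#' @param genes genes that must be present
#' @return covariate data.frame covering all `genes`
#' @export
impute_covariates <- function(cov, genes) {
  missing <- setdiff(genes, rownames(cov))
  med <- vapply(cov, stats::median, numeric(1), na.rm = TRUE)
  if (length(missing)) {
    warning(length(missing), " gene(s) absent from covariate table; ",
            "imputed with cohort medians")
    add <- as.data.frame(as.list(med))[rep(1, length(missing)), , drop = FALSE]
    rownames(add) <- missing
    cov <- rbind(cov, add)
  }
  for (j in seq_along(cov)) cov[[j]][is.na(cov[[j]])] <- med[j]
  cov[genes, , drop = FALSE]
}
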