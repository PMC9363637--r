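#' Read a count matrix and its sample table
#'
#' The counts file is a TSV whose first column holds feature ids and whose
#' header names the samples; the sample table is a TSV with columns
#' `sample_id` and `group` (optionally user labels mapped to the canonical
#' `P1/P2/F1a/F1b` vocabulary via `group_map`). Columns of the returned
#' matrix are reordered to the sample-table order. Readers reject rather
#' than coerce: non-integer or negative cells, duplicate feature ids and
#' samples missing from the counts header are errors.
#'
#' @param path Path to the counts TSV.
#' @param sample_table_path Path to the sample-table TSV.
#' @param group_map Optional named character vector mapping the sample
#'   table's group labels to canonical ones, e.g.
#'   `c(WW = "P1", YY = "P2", WY = "F1a", YW = "F1b")`.
#' @return A list with `counts` (integer matrix) and `samples` (data frame).
#' @export
read_counts <- function(path, sample_table_path, group_map = NULL) {
  samples <- read_sample_table(sample_table_path, group_map = group_map)
  raw <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(raw[[1]])
  if (anyDuplicated(ids)) {
    stop2("duplicate feature id(s): ",
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  mat <- as.matrix(raw[, -1, drop = FALSE])
  missing <- setdiff(samples$sample_id, colnames(mat))
  if (length(missing) > 0) {
    stop2("sample(s) missing from counts header: ",
          paste(missing, collapse = ", "))
  }
  if (!is.numeric(mat) || any(!is.finite(mat)) || any(mat != floor(mat))) {
    stop2("counts must be finite integers")
  }
  if (any(mat < 0)) stop2("counts must be non-negative")
  storage.mode(mat) <- "integer"
  rownames(mat) <- ids
  list(counts = mat[, samples$sample_id, drop = FALSE], samples = samples)
}

#' @rdname read_counts
#' @param counts Matrix to write.
#' @param feature_column Header name for the feature-id column.
#' @export
write_counts <- function(counts, path, feature_column = "feature_id") {
  df <- data.frame(rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- feature_column
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a sample table
#'
#' @inheritParams read_counts
#' @return Data frame with unique `sample_id` and `group`.
#' @export
read_sample_table <- function(path, group_map = NULL) {
  samples <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% names(samples))) {
    stop2("sample table needs 'sample_id' and 'group' columns")
  }
  if (anyDuplicated(samples$sample_id)) stop2("duplicate sample_id(s)")
  if (!is.null(group_map)) {
    unknown <- setdiff(unique(samples$group), names(group_map))
    if (length(unknown) > 0) {
      stop2("group label(s) not covered by group_map: ",
            paste(unknown, collapse = ", "))
    }
    samples$group <- unname(group_map[samples$group])
  }
  samples
}

#' @rdname read_sample_table
#' @param samples Data frame to write.
#' @export
write_sample_table <- function(samples, path) {
  write.table(samples, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a long phenotype table
#'
#' TSV with columns `individual_id`, `group`, `trait`, `value`; one value per
#' (individual, trait) pair is enforced.
#'
#' @param path File path.
#' @return Data frame.
#' @export
read_phenotypes <- function(path) {
  ph <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("individual_id", "group", "trait", "value")
  if (!all(need %in% names(ph))) {
    stop2("phenotype table needs columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(ph[, c("individual_id", "trait")])) {
    stop2("more than one value for some (individual, trait) pair")
  }
  if (!is.numeric(ph$value)) stop2("phenotype values must be numeric")
  ph
}

#' @rdname read_phenotypes
#' @param phenotypes Data frame to write.
#' @export
write_phenotypes <- function(phenotypes, path) {
  write.table(phenotypes, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a coding-potential score table
#'
#' TSV with columns `transcript_id`, `cnci`, `cpc`, `plek`, `pfam_evalue`.
#' Missing values are allowed (empty cells or `NA`); negative E-values and
#' duplicate transcript ids are rejected.
#'
#' @param path File path.
#' @return Typed data frame.
#' @export
read_coding_scores <- function(path) {
  s <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("transcript_id", "cnci", "cpc", "plek", "pfam_evalue")
  if (!all(need %in% names(s))) {
    stop2("score table needs columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(s$transcript_id)) {
    stop2("duplicate transcript_id(s): ",
          paste(unique(s$transcript_id[duplicated(s$transcript_id)]), collapse = ", "))
  }
  for (col in c("cnci", "cpc", "plek", "pfam_evalue")) s[[col]] <- as.numeric(s[[col]])
  if (any(s$pfam_evalue < 0, na.rm = TRUE)) stop2("Pfam E-values must be >= 0")
  s
}

#' @rdname read_coding_scores
#' @param scores Data frame to write.
#' @export
write_coding_scores <- function(scores, path) {
  write.table(scores, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a transcript catalog from GTF (plus optional FASTA)
#'
#' Parses `transcript` and `exon` features (via [rtracklayer::import()]) into
#' a per-transcript catalog: chromosome, span, strand, exon count, spliced
#' length (sum of exon widths) and the assembly `class_code` attribute
#' (defaulting to `"."` when absent). An exon outside its transcript's
#' declared span expands the span with a warning. When a FASTA is given,
#' sequences are attached by transcript id; ids without a FASTA entry are
#' left without sequence with a warning.
#'
#' @param gtf_path Path to a GTF file (1-based inclusive coordinates).
#' @param fasta_path Optional path to transcript sequences in FASTA.
#' @return Catalog data frame: `transcript_id`, `gene_id`, `chrom`, `start`,
#'   `end`, `strand`, `exon_count`, `spliced_length`, `class_code`,
#'   `sequence` (NA when unavailable).
#' @export
read_transcript_catalog <- function(gtf_path, fasta_path = NULL) {
  gr <- rtracklayer::import(gtf_path, format = "gtf")
  md <- S4Vectors::mcols(gr)
  if (!"transcript_id" %in% names(md)) stop2("GTF lacks transcript_id attributes")
  tx <- gr[md$type == "transcript"]
  ex <- gr[md$type == "exon"]
  if (length(tx) == 0) stop2("GTF contains no transcript features")

  tx_id <- S4Vectors::mcols(tx)$transcript_id
  ex_id <- S4Vectors::mcols(ex)$transcript_id
  spliced <- tapply(GenomicRanges::width(ex), ex_id, sum)
  n_exon <- tapply(ex_id, ex_id, length)
  ex_min <- tapply(GenomicRanges::start(ex), ex_id, min)
  ex_max <- tapply(GenomicRanges::end(ex), ex_id, max)

  start <- GenomicRanges::start(tx); end <- GenomicRanges::end(tx)
  emin <- ex_min[tx_id]; emax <- ex_max[tx_id]
  outside <- !is.na(emin) & (emin < start | emax > end)
  if (any(outside)) {
    warning(sum(outside), " transcript(s) have exons outside the declared ",
            "span; span expanded", call. = FALSE)
    start[outside] <- pmin(start[outside], emin[outside])
    end[outside] <- pmax(end[outside], emax[outside])
  }

  code <- if ("class_code" %in% names(S4Vectors::mcols(tx))) {
    cc <- S4Vectors::mcols(tx)$class_code
    ifelse(is.na(cc), ".", cc)
  } else rep(".", length(tx))

  catalog <- data.frame(
    transcript_id = tx_id,
    gene_id = if ("gene_id" %in% names(S4Vectors::mcols(tx))) {
      S4Vectors::mcols(tx)$gene_id
    } else NA_character_,
    chrom = as.character(GenomicRanges::seqnames(tx)),
    start = start, end = end,
    strand = as.character(GenomicRanges::strand(tx)),
    exon_count = as.integer(n_exon[tx_id]),
    spliced_length = as.integer(spliced[tx_id]),
    class_code = code,
    sequence = NA_character_,
    stringsAsFactors = FALSE
  )
  catalog$strand[catalog$strand == "*"] <- "."
  if (!is.null(fasta_path)) {
    fa <- Biostrings::readDNAStringSet(fasta_path)
    hit <- match(catalog$transcript_id, names(fa))
    if (anyNA(hit)) {
      warning(sum(is.na(hit)), " transcript(s) without a matching FASTA ",
              "entry; sequence left unset", call. = FALSE)
    }
    catalog$sequence[!is.na(hit)] <- as.character(fa[hit[!is.na(hit)]])
  }
  catalog
}

#' Write a transcript catalog (with exons) to GTF
#'
#' Emits `transcript` and `exon` rows with `gene_id`, `transcript_id` and
#' `class_code` attributes, readable back with [read_transcript_catalog()].
#'
#' @param catalog Catalog data frame (as from [simulate_transcript_set()]).
#' @param exons Per-exon data frame (`transcript_id`, `chrom`, `start`,
#'   `end`, `strand`).
#' @param path Output path.
#' @export
write_transcript_gtf <- function(catalog, exons, path) {
  star <- function(s) ifelse(s == ".", "*", s)
  tx <- GenomicRanges::GRanges(catalog$chrom,
                               IRanges::IRanges(catalog$start, catalog$end),
                               strand = star(catalog$strand))
  S4Vectors::mcols(tx) <- S4Vectors::DataFrame(
    source = "heterosisTx", type = "transcript",
    gene_id = catalog$gene_id, transcript_id = catalog$transcript_id,
    class_code = catalog$class_code
  )
  gidx <- match(exons$transcript_id, catalog$transcript_id)
  ex <- GenomicRanges::GRanges(exons$chrom,
                               IRanges::IRanges(exons$start, exons$end),
                               strand = star(exons$strand))
  S4Vectors::mcols(ex) <- S4Vectors::DataFrame(
    source = "heterosisTx", type = "exon",
    gene_id = catalog$gene_id[gidx], transcript_id = exons$transcript_id,
    class_code = catalog$class_code[gidx]
  )
  rtracklayer::export(c(tx, ex), path, format = "gtf")
  invisible(path)
}

#' Write transcript sequences to FASTA
#'
#' @param catalog Catalog data frame with `transcript_id` and `sequence`.
#' @param path Output path.
#' @export
write_transcript_fasta <- function(catalog, path) {
  keep <- !is.na(catalog$sequence) & catalog$sequence != ""
  seqs <- Biostrings::DNAStringSet(catalog$sequence[keep])
  names(seqs) <- catalog$transcript_id[keep]
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
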