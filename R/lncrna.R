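#' Basic lncRNA candidate filter
#'
#' Retains transcripts with spliced length >= `min_length` (the boundary is
#' inclusive: "shorter than 200 bp" removes only < 200), a definite strand
#' (`+` or `-`) and assembly class code `i` (intronic), `u` (intergenic) or
#' `x` (antisense exonic overlap). Missing class codes are treated as
#' non-retained.
#'
#' @param catalog Transcript catalog data frame with columns
#'   `spliced_length`, `strand`, `class_code` (see
#'   [read_transcript_catalog()] / [simulate_transcript_set()]).
#' @param min_length Minimum spliced length in bp.
#' @return The retained subset of `catalog`.
#' @export
basic_filter <- function(catalog, min_length = 200) {
  stopifnot(all(c("spliced_length", "strand", "class_code") %in% names(catalog)))
  code <- catalog$class_code
  code[is.na(code)] <- "."
  keep <- catalog$spliced_length >= min_length &
    catalog$strand %in% c("+", "-") &
    code %in% c("i", "u", "x")
  catalog[keep, , drop = FALSE]
}

#' Match candidates against a reference set of known lncRNAs
#'
#' A candidate is "known" when its sequence aligns ungapped and full length
#' against some reference sequence at identity >= `identity_min` with full
#' query coverage. At the default `identity_min = 1` this is exact sequence
#' identity, resolved through a hash lookup; for relaxed thresholds a
#' Hamming comparison against equal-length references is used (full
#' coverage, no gaps).
#'
#' @param candidates Catalog data frame with a `sequence` column; rows with
#'   missing sequences are excluded from matching with a warning.
#' @param reference A [Biostrings::DNAStringSet] (or named character vector)
#'   of known lncRNA sequences.
#' @param identity_min Minimum fraction of identical bases.
#' @return A list with `known` and `remainder`, both subsets of `candidates`.
#' @export
match_known <- function(candidates, reference, identity_min = 1.0) {
  stopifnot("sequence" %in% names(candidates),
            identity_min > 0, identity_min <= 1)
  ref <- as.character(reference)
  seqs <- candidates$sequence
  no_seq <- is.na(seqs) | seqs == ""
  if (any(no_seq)) {
    warning(sum(no_seq), " candidate(s) without sequence excluded from ",
            "known-lncRNA matching", call. = FALSE)
  }
  is_known <- rep(FALSE, nrow(candidates))
  if (length(ref) > 0) {
    is_known[!no_seq] <- seqs[!no_seq] %in% ref
    if (identity_min < 1) {
      todo <- which(!is_known & !no_seq)
      by_len <- split(seq_along(ref), nchar(ref))
      for (i in todo) {
        hits <- by_len[[as.character(nchar(seqs[i]))]]
        for (j in hits) {
          q <- charToRaw(seqs[i]); r <- charToRaw(ref[j])
          if (sum(q == r) / length(q) >= identity_min) {
            is_known[i] <- TRUE
            break
          }
        }
      }
    }
  }
  list(known = candidates[is_known, , drop = FALSE],
       remainder = candidates[!is_known, , drop = FALSE])
}

#' Coding-potential consensus filter
#'
#' Declares a transcript a putative lncRNA when CNCI, CPC and PLEK scores are
#' all strictly negative and the Pfam criterion holds. Two Pfam
#' interpretations are available because the conventional printed rule
#' (`pfam_evalue < 1e-5`) selects transcripts *with* a protein-domain hit,
#' which is the opposite of what a noncoding filter wants:
#' * `"as_printed"` -- `pfam_evalue < 1e-5`, applied literally;
#' * `"no_hit_required"` -- `pfam_evalue >= 1e-5` or absent (no significant
#'   protein-domain hit).
#'
#' Transcripts missing any required score (CNCI/CPC/PLEK always; the Pfam
#' E-value only under `"as_printed"`) are excluded.
#'
#' @param remainder Catalog subset to screen (e.g. the `remainder` of
#'   [match_known()]).
#' @param scores Coding-score table with columns `transcript_id`, `cnci`,
#'   `cpc`, `plek`, `pfam_evalue`.
#' @param pfam_logic `"as_printed"` or `"no_hit_required"`.
#' @return The putative-lncRNA subset of `remainder`, with the four score
#'   columns attached.
#' @export
coding_consensus <- function(remainder, scores,
                             pfam_logic = c("as_printed", "no_hit_required")) {
  pfam_logic <- match.arg(pfam_logic)
  stopifnot(all(c("transcript_id", "cnci", "cpc", "plek", "pfam_evalue") %in% names(scores)))
  idx <- match(remainder$transcript_id, scores$transcript_id)
  s <- scores[idx, , drop = FALSE]
  have_core <- !is.na(s$cnci) & !is.na(s$cpc) & !is.na(s$plek) & !is.na(idx)
  noncoding_scores <- have_core & s$cnci < 0 & s$cpc < 0 & s$plek < 0
  pfam_ok <- if (pfam_logic == "as_printed") {
    !is.na(s$pfam_evalue) & s$pfam_evalue < 1e-5
  } else {
    is.na(s$pfam_evalue) | s$pfam_evalue >= 1e-5
  }
  keep <- noncoding_scores & pfam_ok
  keep[is.na(keep)] <- FALSE
  out <- remainder[keep, , drop = FALSE]
  out$cnci <- s$cnci[keep]; out$cpc <- s$cpc[keep]
  out$plek <- s$plek[keep]; out$pfam_evalue <- s$pfam_evalue[keep]
  out
}

#' Positional classification of lncRNAs
#'
#' Maps assembly class codes onto the standard positional vocabulary:
#' `u` -> intergenic, `i` -> intronic, `x` -> antisense. Transcripts with a
#' missing code (`"."`) fall back to a coordinate rule against a gene
#' annotation: wholly contained in an annotated gene but overlapping no exon
#' -> intronic; overlapping an exon on the opposite strand -> antisense;
#' otherwise intergenic.
#'
#' @param catalog Catalog data frame (`transcript_id`, `chrom`, `start`,
#'   `end`, `strand`, `class_code`).
#' @param genes Optional gene annotation for the fallback: data frame with
#'   `gene_id`, `chrom`, `start`, `end`, `strand` and optional logical
#'   `is_exon` rows (rows with `is_exon = TRUE` are exon intervals; others
#'   are gene spans). Without it, code `"."` maps to intergenic.
#' @return Character vector (`intergenic` / `intronic` / `antisense`)
#'   parallel to `catalog` rows.
#' @export
positional_class <- function(catalog, genes = NULL) {
  code <- catalog$class_code
  code[is.na(code)] <- "."
  out <- rep(NA_character_, nrow(catalog))
  out[code == "u"] <- "intergenic"
  out[code == "i"] <- "intronic"
  out[code == "x"] <- "antisense"
  rest <- which(is.na(out))
  if (length(rest) > 0) {
    out[rest] <- "intergenic"
    if (!is.null(genes) && nrow(genes) > 0) {
      if (!"is_exon" %in% names(genes)) genes$is_exon <- FALSE
      q <- GenomicRanges::GRanges(catalog$chrom[rest],
                                  IRanges::IRanges(catalog$start[rest], catalog$end[rest]),
                                  strand = catalog$strand[rest])
      spans <- genes[!genes$is_exon, , drop = FALSE]
      exons <- genes[genes$is_exon, , drop = FALSE]
      g_span <- GenomicRanges::GRanges(spans$chrom,
                                       IRanges::IRanges(spans$start, spans$end),
                                       strand = spans$strand)
      g_exon <- GenomicRanges::GRanges(exons$chrom,
                                       IRanges::IRanges(exons$start, exons$end),
                                       strand = exons$strand)
      within_gene <- IRanges::overlapsAny(q, g_span, type = "within",
                                          ignore.strand = TRUE)
      hits_exon <- IRanges::overlapsAny(q, g_exon, ignore.strand = TRUE)
      anti_exon <- rep(FALSE, length(q))
      if (length(g_exon) > 0) {
        ov <- GenomicRanges::findOverlaps(q, g_exon, ignore.strand = TRUE)
        qs <- as.character(GenomicRanges::strand(q))[S4Vectors::queryHits(ov)]
        ss <- as.character(GenomicRanges::strand(g_exon))[S4Vectors::subjectHits(ov)]
        opp <- qs %in% c("+", "-") & ss %in% c("+", "-") & qs != ss
        anti_exon[unique(S4Vectors::queryHits(ov)[opp])] <- TRUE
      }
      out[rest[anti_exon]] <- "antisense"
      out[rest[within_gene & !hits_exon & !anti_exon]] <- "intronic"
    }
  }
  out
}

#' Run the full lncRNA identification cascade
#'
#' Convenience wrapper: [basic_filter()] -> [match_known()] ->
#' [coding_consensus()] -> [positional_class()]. Known and putative sets are
#' disjoint by construction and both passed the basic filter.
#'
#' @inheritParams basic_filter
#' @inheritParams match_known
#' @inheritParams coding_consensus
#' @param genes Optional gene annotation for [positional_class()].
#' @return Catalog data frame of all identified lncRNAs with `status`
#'   (`known` / `putative`) and `position` columns.
#' @export
build_lncrna_catalog <- function(catalog, reference, scores,
                                 min_length = 200, identity_min = 1.0,
                                 pfam_logic = "as_printed", genes = NULL) {
  cand <- basic_filter(catalog, min_length = min_length)
  m <- match_known(cand, reference, identity_min = identity_min)
  put <- coding_consensus(m$remainder, scores, pfam_logic = pfam_logic)
  known <- m$known
  if (nrow(known) > 0) known$status <- "known"
  if (nrow(put) > 0) put$status <- "putative"
  shared <- intersect(names(known), names(put))
  out <- rbind(known[, shared, drop = FALSE], put[, shared, drop = FALSE])
  if (nrow(out) > 0) out$position <- positional_class(out, genes = genes)
  out
}

#' Summarise an lncRNA catalog
#'
#' Length histogram, exon-count distribution, per-chromosome counts with
#' percentages and positional-class composition.
#'
#' @param catalog Catalog data frame (needs `spliced_length`, `exon_count`,
#'   `chrom`; `position` and `status` used when present).
#' @param length_breaks Histogram breakpoints for spliced length (bp).
#' @return A list of data frames: `length_hist`, `exon_dist`, `chrom_dist`,
#'   and `class_dist` when `position` is available. Percentages in each
#'   table sum to 100.
#' @export
summarize_catalog <- function(catalog,
                              length_breaks = seq(0, 10000, by = 200)) {
  if (nrow(catalog) == 0) stop2("catalog is empty")
  n <- nrow(catalog)
  br <- unique(c(length_breaks, max(length_breaks, max(catalog$spliced_length))))
  cut_len <- cut(catalog$spliced_length, breaks = br, include.lowest = TRUE)
  length_hist <- as.data.frame(table(bin = cut_len), stringsAsFactors = FALSE)
  names(length_hist)[2] <- "n"
  length_hist$percent <- 100 * length_hist$n / n
  exon_dist <- as.data.frame(table(exons = catalog$exon_count), stringsAsFactors = FALSE)
  names(exon_dist)[2] <- "n"
  exon_dist$percent <- 100 * exon_dist$n / n
  chrom_dist <- as.data.frame(table(chrom = catalog$chrom), stringsAsFactors = FALSE)
  names(chrom_dist)[2] <- "n"
  chrom_dist$percent <- 100 * chrom_dist$n / n
  out <- list(length_hist = length_hist, exon_dist = exon_dist,
              chrom_dist = chrom_dist)
  if ("position" %in% names(catalog)) {
    class_dist <- as.data.frame(table(position = catalog$position),
                                stringsAsFactors = FALSE)
    names(class_dist)[2] <- "n"
    class_dist$percent <- 100 * class_dist$n / n
    out$class_dist <- class_dist
  }
  out
}

#' Predict cis/trans lncRNA-gene target pairs
#'
#' For every (lncRNA, gene) pair whose expression profiles correlate with
#' `|Pearson r| >= r_min` across all samples (on `log2(normalized + 1)`
#' counts), the pair is called *cis* when both lie on the same chromosome
#' within `window` bp (gap distance; 0 for overlapping spans) and *trans*
#' otherwise (different chromosome = infinite distance). Pairs with a
#' constant expression vector on either side are skipped with a warning.
#'
#' @param lncrnas Catalog data frame of lncRNAs (`transcript_id`, `chrom`,
#'   `start`, `end`).
#' @param genes Gene table (`gene_id`, `chrom`, `start`, `end`).
#' @param counts Count matrix containing rows for both lncRNA transcript ids
#'   and gene ids.
#' @param window Maximum gap in bp for a cis call.
#' @param r_min Minimum absolute Pearson correlation.
#' @return Data frame: `lncrna_id`, `gene_id`, `mode` (`cis` / `trans`),
#'   `distance` (bp; `Inf` across chromosomes), `r`.
#' @export
predict_targets <- function(lncrnas, genes, counts,
                            window = 1e5, r_min = 0.9) {
  counts <- as.matrix(counts)
  need <- c(lncrnas$transcript_id, genes$gene_id)
  missing <- setdiff(need, rownames(counts))
  if (length(missing) > 0) {
    stop2("expression rows missing for: ", paste(head(missing, 5), collapse = ", "))
  }
  expr <- normalize_log2(counts)
  lx <- expr[lncrnas$transcript_id, , drop = FALSE]
  gx <- expr[genes$gene_id, , drop = FALSE]
  const_l <- apply(lx, 1L, function(x) sd(x) == 0)
  const_g <- apply(gx, 1L, function(x) sd(x) == 0)
  if (any(const_l) || any(const_g)) {
    warning("skipping ", sum(const_l) + sum(const_g),
            " feature(s) with constant expression", call. = FALSE)
  }
  lncrnas <- lncrnas[!const_l, , drop = FALSE]
  genes <- genes[!const_g, , drop = FALSE]
  if (nrow(lncrnas) == 0 || nrow(genes) == 0) {
    return(data.frame(lncrna_id = character(), gene_id = character(),
                      mode = character(), distance = numeric(), r = numeric(),
                      stringsAsFactors = FALSE))
  }
  r_mat <- cor(t(lx[!const_l, , drop = FALSE]), t(gx[!const_g, , drop = FALSE]))
  hit <- which(abs(r_mat) >= r_min, arr.ind = TRUE)
  if (nrow(hit) == 0) {
    return(data.frame(lncrna_id = character(), gene_id = character(),
                      mode = character(), distance = numeric(), r = numeric(),
                      stringsAsFactors = FALSE))
  }
  gr_l <- GenomicRanges::GRanges(lncrnas$chrom,
                                 IRanges::IRanges(lncrnas$start, lncrnas$end))
  gr_g <- GenomicRanges::GRanges(genes$chrom,
                                 IRanges::IRanges(genes$start, genes$end))
  d <- GenomicRanges::distance(gr_l[hit[, 1]], gr_g[hit[, 2]], ignore.strand = TRUE)
  d <- ifelse(is.na(d), Inf, as.numeric(d))
  data.frame(lncrna_id = lncrnas$transcript_id[hit[, 1]],
             gene_id = genes$gene_id[hit[, 2]],
             mode = ifelse(d <= window, "cis", "trans"),
             distance = d,
             r = r_mat[hit],
             row.names = NULL, stringsAsFactors = FALSE)
}
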