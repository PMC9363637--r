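#' Simulate a transcript catalog with coding scores and a known-lncRNA set
#'
#' Generates the fixtures the lncRNA identification cascade consumes:
#' a transcript catalog (lengths, strands, class codes, genomic positions,
#' sequences), a coding-potential score table (CNCI/CPC/PLEK scores and Pfam
#' E-value per transcript) and a reference FASTA of "known" lncRNAs whose
#' sequences are copied verbatim from the catalog.
#'
#' Spliced lengths are log-normal (a tail falls below 200 bp), a configurable
#' fraction of transcripts is unstranded, and class codes are drawn over
#' `i/u/x/j/=/c`. Transcripts that pass the basic lncRNA filter (length
#' >= 200, definite strand, class code `i`, `u` or `x`) are eligible to be
#' "known"; `known_fraction` of them are copied into the reference FASTA.
#' Among the remaining transcripts, `coding_fraction` are labelled coding and
#' draw their three scores from `Normal(+score_separation, 1)` with Pfam
#' E-value < 1e-5 (a protein-domain hit); noncoding transcripts draw from
#' `Normal(-score_separation, 1)` with large E-values.
#'
#' @param n Number of transcripts; `n = 0` returns empty tables.
#' @param seed Integer seed.
#' @param known_fraction Fraction of basic-filter survivors copied into the
#'   reference FASTA as known lncRNAs.
#' @param coding_fraction Fraction of the non-known transcripts that are
#'   truly protein coding.
#' @param score_separation Distance of each score distribution's centre from
#'   zero; larger values separate coding from noncoding more cleanly.
#' @param unstranded_fraction Fraction of transcripts with strand `"."`.
#' @return A list with `catalog` (data frame: `transcript_id`, `gene_id`,
#'   `chrom`, `start`, `end`, `strand`, `exon_count`, `spliced_length`,
#'   `class_code`, `sequence`), `exons` (per-exon data frame), `scores`
#'   (coding-score data frame), `reference` (a [Biostrings::DNAStringSet] of
#'   known lncRNA sequences) and `truth` (`transcript_id`, `known`, `coding`,
#'   `passes_basic`).
#' @export
simulate_transcript_set <- function(n = 400L,
                                    seed = 1L,
                                    known_fraction = 0.3,
                                    coding_fraction = 0.3,
                                    score_separation = 3,
                                    unstranded_fraction = 0.1) {
  stopifnot(known_fraction >= 0, known_fraction <= 1,
            coding_fraction >= 0, coding_fraction <= 1,
            unstranded_fraction >= 0, unstranded_fraction <= 1,
            score_separation > 0)
  if (n == 0) {
    empty_cat <- data.frame(transcript_id = character(), gene_id = character(),
                            chrom = character(), start = integer(), end = integer(),
                            strand = character(), exon_count = integer(),
                            spliced_length = integer(), class_code = character(),
                            sequence = character(), stringsAsFactors = FALSE)
    return(list(catalog = empty_cat, exons = NULL,
                scores = data.frame(transcript_id = character(), cnci = numeric(),
                                    cpc = numeric(), plek = numeric(),
                                    pfam_evalue = numeric(), stringsAsFactors = FALSE),
                reference = Biostrings::DNAStringSet(),
                truth = data.frame(transcript_id = character(), known = logical(),
                                   coding = logical(), passes_basic = logical(),
                                   stringsAsFactors = FALSE)))
  }
  with_seed(seed, {
    id <- sprintf("TX%05d", seq_len(n))
    spliced <- pmax(60L, as.integer(round(rlnorm(n, meanlog = log(900), sdlog = 0.9))))
    strand <- sample(c("+", "-", "."), n, replace = TRUE,
                     prob = c((1 - unstranded_fraction) / 2,
                              (1 - unstranded_fraction) / 2,
                              unstranded_fraction))
    class_code <- sample(c("i", "u", "x", "j", "=", "c"), n, replace = TRUE,
                         prob = c(0.20, 0.30, 0.15, 0.15, 0.10, 0.10))
    chrom <- sample(paste0("chr", 1:5), n, replace = TRUE)
    exon_count <- sample(1:4, n, replace = TRUE, prob = c(0.25, 0.45, 0.2, 0.1))

    # split the spliced length into exon widths and separate them by introns
    exon_rows <- vector("list", n)
    start <- integer(n); end <- integer(n)
    for (i in seq_len(n)) {
      k <- exon_count[i]
      w <- rep(spliced[i] %/% k, k)
      w[1] <- w[1] + spliced[i] %% k
      introns <- if (k > 1) sample(100:5000, k - 1, replace = TRUE) else integer(0)
      s <- sample(1:2000000, 1)
      es <- s + c(0L, cumsum(w[-k] + introns))
      ee <- es + w - 1L
      start[i] <- s; end[i] <- ee[k]
      exon_rows[[i]] <- data.frame(transcript_id = id[i], chrom = chrom[i],
                                   start = es, end = ee, strand = strand[i],
                                   stringsAsFactors = FALSE)
    }
    sequence <- random_dna(spliced)

    passes_basic <- spliced >= 200 & strand %in% c("+", "-") & class_code %in% c("i", "u", "x")
    eligible <- which(passes_basic)
    n_known <- round(known_fraction * length(eligible))
    known_idx <- if (n_known > 0) sort(sample(eligible, n_known)) else integer(0)
    known <- seq_len(n) %in% known_idx

    not_known <- which(!known)
    n_coding <- round(coding_fraction * length(not_known))
    coding_idx <- if (n_coding > 0) sort(sample(not_known, n_coding)) else integer(0)
    coding <- seq_len(n) %in% coding_idx

    shift <- ifelse(coding, score_separation, -score_separation)
    scores <- data.frame(
      transcript_id = id,
      cnci = rnorm(n, shift, 1),
      cpc = rnorm(n, shift, 1),
      plek = rnorm(n, shift, 1),
      pfam_evalue = ifelse(coding, 10^runif(n, -30, -6), 10^runif(n, -4, 1)),
      stringsAsFactors = FALSE
    )

    reference <- Biostrings::DNAStringSet(sequence[known])
    names(reference) <- sprintf("REFLNC%05d", seq_len(sum(known)))

    catalog <- data.frame(
      transcript_id = id,
      gene_id = sub("^TX", "GENE", id),
      chrom = chrom, start = start, end = end, strand = strand,
      exon_count = exon_count, spliced_length = spliced,
      class_code = class_code, sequence = sequence,
      stringsAsFactors = FALSE
    )
    truth <- data.frame(transcript_id = id, known = known, coding = coding,
                        passes_basic = passes_basic, stringsAsFactors = FALSE)
    list(catalog = catalog, exons = do.call(rbind, exon_rows),
         scores = scores, reference = reference, truth = truth)
  })
}

#' Simulate block-structured expression with a module-driven trait
#'
#' Each planted module has a latent per-sample factor; a member gene is
#' `loading * factor + Normal(0, noise_sd)` with loadings of random sign, so
#' at `noise_sd = 0` within-module correlations are exactly +/-1. The trait
#' equals module 1's factor plus `Normal(0, trait_noise_sd)`.
#'
#' @param n_genes Total genes, split as evenly as possible over modules.
#' @param n_samples Number of samples.
#' @param n_modules Number of planted modules (>= 1).
#' @param noise_sd Gene-level residual standard deviation (>= 0).
#' @param trait_noise_sd Noise added to the trait on top of module 1's factor.
#' @param seed Integer seed.
#' @return A list with `expr` (numeric matrix, genes x samples, roughly
#'   log-scale expression), `trait` (numeric vector over samples) and `truth`
#'   (data frame: `feature_id`, `module`).
#' @export
simulate_module_structure <- function(n_genes = 300L,
                                      n_samples = 24L,
                                      n_modules = 3L,
                                      noise_sd = 0.5,
                                      trait_noise_sd = 0.2,
                                      seed = 7L) {
  if (n_modules < 1) stop2("n_modules must be >= 1")
  if (noise_sd < 0) stop2("noise_sd must be >= 0")
  with_seed(seed, {
    sizes <- apportion(n_genes, rep(1 / n_modules, n_modules))
    module <- rep(seq_len(n_modules), times = sizes)
    factors <- matrix(rnorm(n_samples * n_modules), nrow = n_samples)
    loading <- runif(n_genes, 0.6, 1) * sample(c(-1, 1), n_genes, replace = TRUE)
    expr <- loading * t(factors[, module, drop = FALSE]) +
      matrix(rnorm(n_genes * n_samples, sd = noise_sd), nrow = n_genes)
    dimnames(expr) <- list(sprintf("gene%04d", seq_len(n_genes)),
                           sprintf("S%02d", seq_len(n_samples)))
    trait <- factors[, 1] + rnorm(n_samples, sd = trait_noise_sd)
    names(trait) <- colnames(expr)
    list(expr = expr, trait = trait,
         truth = data.frame(feature_id = rownames(expr), module = module,
                            stringsAsFactors = FALSE))
  })
}
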