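#' Median-of-ratios size factors
#'
#' For each sample, the factor is the median over all-positive features of
#' `count / geometric-mean-across-samples`, rescaled so the factors have
#' geometric mean 1. When no feature is positive in every sample the function
#' falls back to upper-quartile scaling (75th percentile of each sample's
#' non-zero counts) with a warning; an all-zero matrix yields unit factors
#' with a warning.
#'
#' @param counts Non-negative count matrix, features x samples.
#' @return Positive numeric vector of per-sample factors (geometric mean 1).
#' @examples
#' m <- cbind(A = c(10, 20, 5), B = c(20, 40, 10))
#' size_factors(m) # c(1/sqrt(2), sqrt(2))
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop2("counts must be non-negative")
  all_pos <- rowSums(counts > 0) == ncol(counts)
  if (any(all_pos)) {
    lg <- log(counts[all_pos, , drop = FALSE])
    geo <- rowMeans(lg)
    f <- apply(exp(lg - geo), 2L, median)
  } else {
    warning("no feature is positive in every sample; ",
            "falling back to upper-quartile scaling", call. = FALSE)
    f <- apply(counts, 2L, function(x) {
      x <- x[x > 0]
      if (length(x) == 0) NA_real_ else quantile(x, 0.75, names = FALSE)
    })
    if (all(is.na(f))) {
      warning("all counts are zero; using unit size factors", call. = FALSE)
      f <- rep(1, ncol(counts))
    }
    f[is.na(f)] <- exp(mean(log(f[!is.na(f)])))
  }
  f <- f / exp(mean(log(f)))
  setNames(f, colnames(counts))
}

#' Two-group negative-binomial Wald test
#'
#' A self-contained differential-expression test on counts: samples are
#' normalised by [size_factors()], the log2 fold change is the log-ratio of
#' normalised group means (a pseudocount of 0.5 is added to both means
#' whenever either is zero), and a per-feature NB dispersion is estimated by
#' the method of moments pooled across the two groups, floored at `1e-8` and
#' shrunk 50/50 toward the 10%-trimmed mean dispersion across features. The
#' delta-method standard error of the log2 fold change is
#' `se = (1/ln 2) * sqrt((1 + a*m_a)/(n_a*m_a) + (1 + a*m_b)/(n_b*m_b))`,
#' the Wald statistic `z = log2fc / se` is referred to a standard normal, and
#' p values are adjusted by [adjust_bh()].
#'
#' This is deliberately not a reimplementation of any published DE package:
#' there is no trended dispersion fit, no fold-change shrinkage and no
#' independent filtering; the simplicity makes every quantity checkable in
#' closed form.
#'
#' @param counts Count matrix, features x samples.
#' @param samples Data frame with `sample_id` and `group`; `sample_id` must
#'   match the column names of `counts`.
#' @param group_a,group_b The two groups; the fold change is `group_b` vs
#'   `group_a` (positive `log2fc` means higher in `group_b`).
#' @param alpha Adjusted-p threshold for directional calls.
#' @param lfc_min Minimum `|log2fc|` for directional calls.
#' @param factors Optional precomputed size factors for all columns of
#'   `counts` (e.g. computed once across every group of a larger design).
#' @return Data frame: `feature_id`, `contrast` (`"B_vs_A"`), `mean_a`,
#'   `mean_b`, `log2fc`, `se`, `wald_z`, `p_value`, `padj`, `call`
#'   (`up` / `down` / `ns`).
#' @export
de_contrast <- function(counts, samples, group_a, group_b,
                        alpha = 0.05, lfc_min = 1, factors = NULL) {
  counts <- as.matrix(counts)
  stopifnot(all(c("sample_id", "group") %in% names(samples)))
  if (!all(samples$sample_id %in% colnames(counts))) {
    stop2("sample table contains samples absent from the count matrix")
  }
  check_group_sizes(samples, c(group_a, group_b))
  ids_a <- samples$sample_id[samples$group == group_a]
  ids_b <- samples$sample_id[samples$group == group_b]
  sub <- counts[, c(ids_a, ids_b), drop = FALSE]
  if (is.null(factors)) {
    f <- size_factors(sub)
  } else {
    f <- factors[colnames(sub)]
    if (any(is.na(f))) stop2("supplied factors do not cover both groups")
  }
  norm <- sweep(sub, 2L, f, "/")
  na <- length(ids_a); nb <- length(ids_b)
  xa <- norm[, ids_a, drop = FALSE]; xb <- norm[, ids_b, drop = FALSE]
  m_a <- rowMeans(xa); m_b <- rowMeans(xb)
  v_a <- apply(xa, 1L, var); v_b <- apply(xb, 1L, var)

  # method-of-moments dispersion per group, pooled by residual df
  mom <- function(v, m) ifelse(m > 0, (v - m) / m^2, NA_real_)
  wa <- na - 1; wb <- nb - 1
  da <- mom(v_a, m_a); db <- mom(v_b, m_b)
  num <- ifelse(is.na(da), 0, wa * da) + ifelse(is.na(db), 0, wb * db)
  den <- ifelse(is.na(da), 0, wa) + ifelse(is.na(db), 0, wb)
  disp <- ifelse(den > 0, num / den, NA_real_)
  disp <- pmax(disp, 1e-8)
  overall <- mean(disp, trim = 0.1, na.rm = TRUE)
  if (!is.finite(overall)) overall <- 1e-8
  disp[is.na(disp)] <- overall
  disp <- 0.5 * disp + 0.5 * overall

  zero <- m_a == 0 | m_b == 0
  ma <- m_a + 0.5 * zero
  mb <- m_b + 0.5 * zero
  log2fc <- log2(mb / ma)
  se <- (1 / log(2)) * sqrt((1 + disp * ma) / (na * ma) + (1 + disp * mb) / (nb * mb))
  z <- ifelse(log2fc == 0, 0, log2fc / se)
  p <- 2 * pnorm(-abs(z))
  padj <- adjust_bh(p)
  call <- ifelse(padj < alpha & log2fc > lfc_min, "up",
                 ifelse(padj < alpha & log2fc < -lfc_min, "down", "ns"))
  data.frame(feature_id = rownames(counts),
             contrast = paste0(group_b, "_vs_", group_a),
             mean_a = m_a, mean_b = m_b,
             log2fc = log2fc, se = se, wald_z = z,
             p_value = p, padj = padj, call = call,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' The five standard reciprocal-cross contrasts
#'
#' Runs [de_contrast()] for `P2 vs P1`, and each cross against each parent
#' (`F1a vs P1`, `F1a vs P2`, `F1b vs P1`, `F1b vs P2`), using one set of
#' size factors estimated across all samples so normalisation is consistent
#' between contrasts.
#'
#' @inheritParams de_contrast
#' @return Named list of contrast tables (`P2_vs_P1`, `F1a_vs_P1`, ...).
#' @export
de_standard_contrasts <- function(counts, samples, alpha = 0.05, lfc_min = 1) {
  f <- size_factors(as.matrix(counts)[, samples$sample_id, drop = FALSE])
  pairs <- list(c("P1", "P2"), c("P1", "F1a"), c("P2", "F1a"),
                c("P1", "F1b"), c("P2", "F1b"))
  out <- lapply(pairs, function(p) {
    de_contrast(counts, samples, p[1], p[2], alpha = alpha,
                lfc_min = lfc_min, factors = f)
  })
  names(out) <- vapply(pairs, function(p) paste0(p[2], "_vs_", p[1]), character(1))
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Classic FDR step-up: with p-values sorted ascending,
#' `q_(i) = min_{j >= i} p_(j) * m / j`, capped at 1 and returned in the
#' input order. Kept as an explicit, oracle-testable primitive because the
#' directional calls of the whole pipeline hinge on it.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]` (NA not allowed).
#' @return Adjusted values, same length and order as the input.
#' @examples
#' adjust_bh(c(0.01, 0.02, 0.03, 0.04)) # all 0.04
#' @export
adjust_bh <- function(p_values) {
  p <- as.numeric(p_values)
  if (length(p) == 0) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1)) stop2("p-values must lie in [0, 1]")
  m <- length(p)
  o <- order(p)
  q <- pmin(1, rev(cummin(rev((m / seq_len(m)) * p[o]))))
  q[order(o)]
}
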