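#' Mid-parent heterosis with a one-sample significance test
#'
#' Computes the mid-parent heterosis percentage
#' `H% = (F1bar - MP) / MP * 100` with `MP = (PMbar + PFbar) / 2`, and tests
#' whether the F1 mean deviates from the mid-parent value. The parental means
#' are treated as fixed constants, so the test reduces to a one-sample t test
#' of the F1 values against `MP`:
#' `t = (F1bar - MP) / (s_F1 / sqrt(N))`, `df = N - 1`, two-sided p. This is
#' algebraically `H% * MP * sqrt(N) / (100 * s_F1)` and is invariant under a
#' common rescaling of all phenotypes.
#'
#' A literal variant of the historical printed statistic,
#' `t = H% / sqrt(s_F1^2 / ((PMbar + PFbar) * N))`, is exposed via
#' `literal_t = TRUE` for comparison only; it is not scale invariant and is
#' not endorsed.
#'
#' @param f1_values Phenotype values of the F1 individuals (>= 2).
#' @param pm_values Phenotype values of the maternal purebred (>= 2).
#' @param pf_values Phenotype values of the paternal purebred (>= 2).
#' @param trait,cross Labels copied into the result.
#' @param literal_t Also report the literal printed statistic as `t_literal`.
#' @return One-row data frame: `trait`, `cross`, `f1_mean`, `pm_mean`,
#'   `pf_mean`, `midparent`, `n`, `f1_sd`, `h_percent`, `t_stat`, `df`,
#'   `p_value`, `p_underflow` (TRUE when the F1 values are constant but off
#'   the mid-parent value, so p is reported at the smallest positive double).
#' @examples
#' heterosis_test(c(17, 18, 19), c(10, 10, 10), c(20, 20, 20))
#' @export
heterosis_test <- function(f1_values, pm_values, pf_values,
                           trait = "trait", cross = "F1a",
                           literal_t = FALSE) {
  f1 <- as.numeric(f1_values); pm <- as.numeric(pm_values); pf <- as.numeric(pf_values)
  if (length(f1) < 2 || length(pm) < 2 || length(pf) < 2) {
    stop2("each group needs at least 2 values")
  }
  if (!all(is.finite(c(f1, pm, pf)))) stop2("non-finite phenotype values")
  n <- length(f1)
  f1m <- mean(f1); pmm <- mean(pm); pfm <- mean(pf)
  mid <- (pmm + pfm) / 2
  if (mid == 0) stop2("mid-parent value is zero; H% is undefined")
  h <- (f1m - mid) / mid * 100
  s <- sd(f1)
  underflow <- FALSE
  if (s == 0) {
    if (f1m == mid) {
      t_stat <- 0; p <- 1
    } else {
      t_stat <- sign(f1m - mid) * Inf
      p <- .Machine$double.xmin
      underflow <- TRUE
    }
  } else {
    t_stat <- (f1m - mid) / (s / sqrt(n))
    p <- 2 * pt(-abs(t_stat), df = n - 1)
    if (p == 0) { p <- .Machine$double.xmin; underflow <- TRUE }
  }
  out <- data.frame(trait = trait, cross = cross,
                    f1_mean = f1m, pm_mean = pmm, pf_mean = pfm,
                    midparent = mid, n = n, f1_sd = s,
                    h_percent = h, t_stat = t_stat, df = n - 1,
                    p_value = p, p_underflow = underflow,
                    stringsAsFactors = FALSE)
  if (literal_t) {
    out$t_literal <- if (s == 0) t_stat else h / sqrt(s^2 / ((pmm + pfm) * n))
  }
  out
}

#' Heterosis for every trait and cross in a phenotype table
#'
#' Applies [heterosis_test()] to each trait for both reciprocal crosses,
#' using the purebred groups `P1` and `P2` as the (fixed) parents.
#'
#' @param phenotypes Long data frame with columns `individual_id`, `group`
#'   (`P1`, `P2`, `F1a`, `F1b`), `trait`, `value`.
#' @param crosses Crosses to evaluate.
#' @inheritParams heterosis_test
#' @return Data frame with one row per trait x cross.
#' @export
heterosis_all <- function(phenotypes, crosses = c("F1a", "F1b"),
                          literal_t = FALSE) {
  stopifnot(all(c("group", "trait", "value") %in% names(phenotypes)))
  rows <- list()
  for (tr in unique(phenotypes$trait)) {
    sub <- phenotypes[phenotypes$trait == tr, ]
    for (cr in crosses) {
      rows[[length(rows) + 1L]] <- heterosis_test(
        sub$value[sub$group == cr],
        sub$value[sub$group == "P1"],
        sub$value[sub$group == "P2"],
        trait = tr, cross = cr, literal_t = literal_t
      )
    }
  }
  do.call(rbind, rows)
}

#' Relative qPCR fold change by the 2^-ddCt method
#'
#' `fold = 2^-((Ct_target,case - Ct_ref,case) - (Ct_target,ctrl - Ct_ref,ctrl))`.
#' All arguments are vectorised and recycled.
#'
#' @param ct_target_case,ct_ref_case Ct of target and reference gene in the
#'   case (e.g. crossbred) sample.
#' @param ct_target_ctrl,ct_ref_ctrl Ct of target and reference gene in the
#'   control (e.g. purebred) sample.
#' @return Numeric fold change(s).
#' @examples
#' ddct_fold_change(20, 18, 22, 18) # ddCt = -2 -> fold 4
#' @export
ddct_fold_change <- function(ct_target_case, ct_ref_case,
                             ct_target_ctrl, ct_ref_ctrl) {
  args <- cbind(ct_target_case, ct_ref_case, ct_target_ctrl, ct_ref_ctrl)
  if (!all(is.finite(args))) stop2("Ct values must be finite")
  ddct <- (args[, 1] - args[, 2]) - (args[, 3] - args[, 4])
  unname(2^(-ddct))
}
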