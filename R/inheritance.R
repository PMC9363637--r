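# Fixed lookup from the three directional calls to the twelve inheritance
# bins. Calls are oriented so "up" means the first-named member of the
# contrast is higher: (P2 vs P1, F vs P1, F vs P2).
.bin_table <- data.frame(
  c1 = c("ns", "up", "up", "up", "up", "up", "ns", "down", "down", "down", "down", "down"),
  c2 = c("up", "up", "up", "up", "ns", "down", "down", "down", "down", "down", "ns", "up"),
  c3 = c("up", "up", "ns", "down", "down", "down", "down", "down", "ns", "up", "up", "up"),
  bin = c("I", "II", "III", "IV", "V", "VI", "VII", "VIII", "IX", "X", "XI", "XII"),
  stringsAsFactors = FALSE
)

.pattern_of_bin <- c(
  I = "overdominant", II = "overdominant", III = "dominant", IV = "additive",
  V = "dominant", VI = "overdominant", VII = "overdominant", VIII = "overdominant",
  IX = "dominant", X = "additive", XI = "dominant", XII = "overdominant",
  conserved = "conserved", ambiguous = "ambiguous"
)

#' Classify a feature's inheritance bin from three directional calls
#'
#' Maps the triple of directional calls (P2 vs P1, F vs P1, F vs P2) onto the
#' twelve inheritance bins I-XII, `conserved` (all three `ns`) or `ambiguous`
#' (the remaining 14 of the 27 combinations). Bins group into the three
#' inheritance patterns: additivity = \{IV, X\} (F significantly between the
#' two parents), dominance = \{III, V, IX, XI\} (F indistinguishable from one
#' parent, different from the other), overdominance = \{I, II, VI, VII, VIII,
#' XII\} (F above or below both parents).
#'
#' All three arguments are vectorised; `"up"` means the first-named member of
#' the contrast is higher (e.g. `call_f_vs_p1 = "up"` means F > P1).
#'
#' @param call_p2_vs_p1,call_f_vs_p1,call_f_vs_p2 Directional calls, each in
#'   `up` / `down` / `ns`.
#' @return Data frame with columns `bin` and `pattern`.
#' @examples
#' classify_feature("up", "up", "down") # bin IV, additive
#' @export
classify_feature <- function(call_p2_vs_p1, call_f_vs_p1, call_f_vs_p2) {
  calls <- cbind(call_p2_vs_p1, call_f_vs_p1, call_f_vs_p2)
  if (!all(calls %in% c("up", "down", "ns"))) {
    stop2("calls must be 'up', 'down' or 'ns'")
  }
  key <- paste(calls[, 1], calls[, 2], calls[, 3])
  lut <- setNames(.bin_table$bin, paste(.bin_table$c1, .bin_table$c2, .bin_table$c3))
  bin <- unname(lut[key])
  bin[is.na(bin) & key == "ns ns ns"] <- "conserved"
  bin[is.na(bin)] <- "ambiguous"
  data.frame(bin = bin, pattern = unname(.pattern_of_bin[bin]),
             stringsAsFactors = FALSE)
}

#' Classify every feature of one cross
#'
#' Takes the three contrast tables of one cross -- (P2 vs P1), (F vs P1),
#' (F vs P2), as produced by [de_contrast()] -- and assigns each feature an
#' inheritance bin and pattern. Directional calls for classification are
#' recomputed from `padj` and the sign of `log2fc` at `alpha`, by default
#' without a fold-change floor (`lfc_min = 0`): the bin definitions are about
#' statistical ordering of the three group means, whereas the stricter
#' DE-universe criterion (the tables' own `call` column, typically
#' `padj < 0.05` and `|log2fc| > 1`) defines which features count as
#' differentially expressed at all. The returned `de_any` column records
#' membership in that DE universe (DE in at least one of the three
#' contrasts).
#'
#' @param tab_p2_vs_p1,tab_f_vs_p1,tab_f_vs_p2 Contrast tables covering
#'   identical feature sets; their `contrast` labels are checked for
#'   consistent orientation (same parent names, same cross name).
#' @param cross Label copied into the result (e.g. `"F1a"`).
#' @param alpha Adjusted-p threshold for the classification calls.
#' @param lfc_min Fold-change floor for the classification calls (default 0).
#' @return Data frame: `feature_id`, `cross`, `bin`, `pattern`, the three
#'   recomputed calls, and `de_any`.
#' @export
classify_all <- function(tab_p2_vs_p1, tab_f_vs_p1, tab_f_vs_p2,
                         cross = "F1", alpha = 0.05, lfc_min = 0) {
  tabs <- list(tab_p2_vs_p1, tab_f_vs_p1, tab_f_vs_p2)
  ids <- tabs[[1]]$feature_id
  for (k in 2:3) {
    if (!identical(sort(tabs[[k]]$feature_id), sort(ids))) {
      off <- union(setdiff(tabs[[k]]$feature_id, ids),
                   setdiff(ids, tabs[[k]]$feature_id))
      stop2("contrast tables cover different feature sets; offenders: ",
            paste(head(off, 5), collapse = ", "),
            if (length(off) > 5) ", ..." else "")
    }
    tabs[[k]] <- tabs[[k]][match(ids, tabs[[k]]$feature_id), ]
  }

  # orientation check: contrasts must be X_vs_Y, Z_vs_Y, Z_vs_X
  lab <- vapply(tabs, function(t) t$contrast[1], character(1))
  parts <- strsplit(lab, "_vs_", fixed = TRUE)
  ok <- all(lengths(parts) == 2) &&
    parts[[2]][2] == parts[[1]][2] &&   # F vs P1 shares P1 with P2 vs P1
    parts[[3]][2] == parts[[1]][1] &&   # F vs P2 compares against P2
    parts[[2]][1] == parts[[3]][1]      # same cross in both F contrasts
  if (!ok) {
    stop2("contrast orientation mismatch: expected (P2 vs P1, F vs P1, F vs P2), got ",
          paste(lab, collapse = ", "))
  }

  dir_call <- function(t) {
    ifelse(t$padj < alpha & t$log2fc > lfc_min, "up",
           ifelse(t$padj < alpha & t$log2fc < -lfc_min, "down", "ns"))
  }
  c1 <- dir_call(tabs[[1]]); c2 <- dir_call(tabs[[2]]); c3 <- dir_call(tabs[[3]])
  cls <- classify_feature(c1, c2, c3)
  de_any <- tabs[[1]]$call != "ns" | tabs[[2]]$call != "ns" | tabs[[3]]$call != "ns"
  data.frame(feature_id = ids, cross = cross, bin = cls$bin,
             pattern = cls$pattern,
             call_p2_vs_p1 = c1, call_f_vs_p1 = c2, call_f_vs_p2 = c3,
             de_any = de_any, row.names = NULL, stringsAsFactors = FALSE)
}

#' Summarise inheritance patterns across the two reciprocal crosses
#'
#' Counts and proportions by pattern per cross (the denominator is the
#' cross's DE universe: features differentially expressed in at least one of
#' its three contrasts), plus the nonadditive (dominant or overdominant)
#' feature sets and their shared/unique decomposition across the crosses.
#'
#' @param calls_f1a,calls_f1b Call tables from [classify_all()].
#' @return A list: `summary` (data frame `cross`, `pattern`, `n`,
#'   `proportion`), `nonadditive` (named list of feature-id vectors),
#'   `shared` (ids nonadditive in both crosses), `unique` (named list of ids
#'   nonadditive in only that cross).
#' @export
summarize_crosses <- function(calls_f1a, calls_f1b) {
  summarise_one <- function(calls) {
    de <- calls[calls$de_any, , drop = FALSE]
    pats <- c("additive", "dominant", "overdominant", "conserved", "ambiguous")
    n <- vapply(pats, function(p) sum(de$pattern == p), integer(1))
    prop <- if (nrow(de) > 0) n / nrow(de) else rep(0, length(pats))
    list(tab = data.frame(cross = calls$cross[1], pattern = pats,
                          n = n, proportion = unname(prop),
                          row.names = NULL, stringsAsFactors = FALSE),
         nonadditive = de$feature_id[de$pattern %in% c("dominant", "overdominant")])
  }
  a <- summarise_one(calls_f1a)
  b <- summarise_one(calls_f1b)
  shared <- intersect(a$nonadditive, b$nonadditive)
  cross_a <- calls_f1a$cross[1]; cross_b <- calls_f1b$cross[1]
  out <- list(summary = rbind(a$tab, b$tab),
              nonadditive = setNames(list(a$nonadditive, b$nonadditive),
                                     c(cross_a, cross_b)),
              shared = shared,
              unique = setNames(list(setdiff(a$nonadditive, shared),
                                     setdiff(b$nonadditive, shared)),
                                c(cross_a, cross_b)))
  out
}
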