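#' Keep the most variable features
#'
#' Ranks features by variance -- of `log2(normalized + 1)` counts when
#' `transform = "log2norm"`, or of the matrix as given when `"none"` (for
#' data already on a homoskedastic scale) -- and keeps the top
#' `ceiling(fraction * n)`. Ties are broken by feature id so the selection is
#' deterministic.
#'
#' @param mat Numeric matrix, features x samples.
#' @param fraction Fraction of features to keep, in (0, 1].
#' @param transform `"log2norm"` (size-factor normalise then `log2(x + 1)`)
#'   or `"none"`.
#' @return The reduced matrix on the transformed scale.
#' @export
variance_filter <- function(mat, fraction = 0.40,
                            transform = c("log2norm", "none")) {
  transform <- match.arg(transform)
  mat <- as.matrix(mat)
  if (fraction <= 0 || fraction > 1) stop2("fraction must be in (0, 1]")
  x <- if (transform == "log2norm") normalize_log2(mat) else mat
  v <- apply(x, 1L, var)
  keep_n <- ceiling(fraction * nrow(x))
  ord <- order(-v, rownames(x))
  x[sort(ord[seq_len(keep_n)]), , drop = FALSE]
}

# Scale-free topology fit index for one candidate power: R^2 of the log-log
# regression of the binned connectivity distribution, required with a
# negative slope.
scale_free_r2 <- function(adj) {
  k <- rowSums(adj) - 1
  if (sd(k) == 0) return(0)
  bins <- cut(k, breaks = 10)
  pk <- tapply(k, bins, length) / length(k)
  km <- tapply(k, bins, mean)
  ok <- !is.na(pk) & pk > 0 & km > 0
  if (sum(ok) < 3) return(0)
  fit <- lm(log10(pk[ok]) ~ log10(km[ok]))
  r2 <- summary(fit)$r.squared
  if (coef(fit)[2] < 0) r2 else 0
}

#' Unsigned weighted adjacency and topological overlap
#'
#' Builds the unsigned weighted co-expression network
#' `a_ij = |cor(x_i, x_j)|^beta` (Pearson, across samples; `a_ii = 1`) and
#' its topological overlap matrix
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with the
#' sum over `u != i, j` and `k_i = sum_{u != i} a_iu`; `TOM_ii = 1`.
#'
#' With `beta = "auto"`, the smallest power in 1..20 whose connectivity
#' distribution reaches a scale-free fit `R^2 >= 0.8` (negative slope) is
#' chosen; if none qualifies, `beta = 6` is used with a warning.
#'
#' @param mat Numeric matrix, features x samples (>= 3 samples), already on
#'   the correlation scale (see [variance_filter()]).
#' @param beta Soft-thresholding power: a positive integer or `"auto"`.
#' @return A list: `adjacency`, `tom` (both features x features), `beta`.
#' @export
build_network <- function(mat, beta = "auto") {
  mat <- as.matrix(mat)
  if (ncol(mat) < 3) stop2("at least 3 samples are required")
  r <- abs(cor(t(mat)))
  if (identical(beta, "auto")) {
    beta_used <- NA_integer_
    for (b in 1:20) {
      if (scale_free_r2(r^b) >= 0.8) { beta_used <- b; break }
    }
    if (is.na(beta_used)) {
      warning("no power in 1..20 reaches scale-free fit R^2 >= 0.8; using beta = 6",
              call. = FALSE)
      beta_used <- 6L
    }
  } else {
    stopifnot(is.numeric(beta), beta >= 1)
    beta_used <- as.integer(beta)
  }
  a <- r^beta_used
  diag(a) <- 1
  k <- rowSums(a) - 1
  num <- a %*% a - a           # (A^2)_ij - 2 a_ij + a_ij, since diag(a) = 1
  den <- outer(k, k, pmin) + 1 - a
  tom <- num / den
  tom <- (tom + t(tom)) / 2    # guard against round-off asymmetry
  diag(tom) <- 1
  list(adjacency = a, tom = tom, beta = beta_used)
}

#' Detect co-expression modules from a topological overlap matrix
#'
#' Average-linkage hierarchical clustering on `1 - TOM`, followed by a
#' simplified adaptive cut and an eigengene-merge step:
#' 1. the dendrogram is cut into `k` clusters for every
#'    `k = 2, ..., k_max`, and the `k` retained is the one maximising the
#'    number of *valid* clusters (smallest such `k` on ties). A cluster is
#'    valid when it has at least `min_module_size` members and is coherent:
#'    the first principal component of its standardized expression explains
#'    at least `pve_min` of the cluster's variance. The coherence rule is
#'    what keeps pure-noise data unclustered -- for independent features the
#'    leading-eigenvalue share of a size-50+ cluster stays near
#'    `(sqrt(m) + sqrt(n_samples))^2 / (m * n_samples)`, far below the
#'    default 0.3, while a genuine co-expression module concentrates most of
#'    its variance on the eigengene;
#' 2. features outside valid clusters are unassigned (module 0);
#' 3. modules whose eigengenes correlate above `1 - merge_cut_height` are
#'    merged iteratively until stable.
#'
#' Surviving modules are relabelled 1, 2, ... by decreasing size.
#'
#' @param tom Square symmetric TOM from [build_network()].
#' @param expr Expression matrix (features x samples) matching `tom`'s rows;
#'   used for the coherence check and the eigengene-merge step.
#' @param min_module_size Smallest retained module.
#' @param merge_cut_height Eigengene-dissimilarity threshold below which
#'   modules merge.
#' @param pve_min Minimum fraction of within-cluster variance the leading
#'   principal component must explain.
#' @param k_max Largest cluster count scanned.
#' @return Named integer vector of module assignments (0 = unassigned).
#' @export
detect_modules <- function(tom, expr,
                           min_module_size = 50,
                           merge_cut_height = 0.25,
                           pve_min = 0.3,
                           k_max = 40L) {
  tom <- as.matrix(tom)
  expr <- as.matrix(expr)
  stopifnot(nrow(tom) == ncol(tom), isTRUE(all.equal(tom, t(tom))),
            nrow(expr) == nrow(tom))
  n <- nrow(tom)
  hc <- hclust(as.dist(1 - tom), method = "average")

  cluster_pve <- function(members) {
    x <- expr[members, , drop = FALSE]
    sds <- apply(x, 1L, sd)
    x <- x[sds > 0, , drop = FALSE]
    if (nrow(x) < 2) return(0)
    xs <- (x - rowMeans(x)) / sds[sds > 0]
    d2 <- svd(xs, nu = 0, nv = 0)$d^2
    d2[1] / sum(d2)
  }
  valid_clusters <- function(cl) {
    keep <- integer(0)
    for (g in unique(cl)) {
      members <- which(cl == g)
      if (length(members) < min_module_size) next
      if (cluster_pve(members) >= pve_min) keep <- c(keep, g)
    }
    keep
  }

  # scan well past n / min_module_size: stragglers split off as small
  # clusters before genuinely distinct modules separate
  ks <- 2:max(2L, min(as.integer(k_max), n - 1L))
  best <- list(score = -1L, cl = NULL, keep = NULL)
  for (k in ks) {
    cl <- cutree(hc, k = k)
    keep <- valid_clusters(cl)
    if (length(keep) > best$score) {
      best <- list(score = length(keep), cl = cl, keep = keep)
    }
  }
  assignment <- integer(n)
  for (i in seq_along(best$keep)) {
    assignment[best$cl == best$keep[i]] <- i
  }
  names(assignment) <- rownames(tom)
  assignment <- relabel_by_size(assignment)

  if (max(assignment) > 1) {
    repeat {
      me <- module_eigengenes(expr, assignment)
      if (ncol(me) < 2) break
      ec <- cor(me)
      diag(ec) <- -Inf
      top <- which(ec == max(ec), arr.ind = TRUE)[1, ]
      if (ec[top[1], top[2]] <= 1 - merge_cut_height) break
      ids <- as.integer(sub("^ME", "", colnames(me)[top]))
      assignment[assignment == max(ids)] <- min(ids)
      assignment <- relabel_by_size(assignment)
    }
  }
  assignment
}

# Relabel modules 1, 2, ... by decreasing size; exact size ties break on the
# lexicographically smallest member feature, so labels are invariant to the
# order features arrive in.
relabel_by_size <- function(assignment) {
  ids <- unique(assignment[assignment > 0])
  if (length(ids) == 0) return(assignment)
  size <- vapply(ids, function(g) sum(assignment == g), integer(1))
  first <- vapply(ids, function(g) min(names(assignment)[assignment == g]),
                  character(1))
  old <- ids[order(-size, first)]
  map <- setNames(seq_along(old), old)
  out <- assignment
  out[assignment > 0] <- map[as.character(assignment[assignment > 0])]
  out
}

#' Module eigengenes
#'
#' The eigengene of a module is the first left singular direction over
#' samples of its standardized (per-feature mean 0, sd 1) expression
#' submatrix, scaled to unit variance and signed so that its mean
#' correlation with the member features is positive. A single-feature
#' module's eigengene is that feature's standardized profile.
#'
#' @param expr Expression matrix, features x samples.
#' @param assignment Module assignment as from [detect_modules()]; module 0
#'   is ignored.
#' @return Numeric matrix, samples x modules, columns `ME1`, `ME2`, ...
#' @export
module_eigengenes <- function(expr, assignment) {
  expr <- as.matrix(expr)
  mods <- sort(unique(assignment[assignment > 0]))
  if (length(mods) == 0) stop2("no assigned modules")
  out <- matrix(NA_real_, nrow = ncol(expr), ncol = length(mods),
                dimnames = list(colnames(expr), paste0("ME", mods)))
  for (i in seq_along(mods)) {
    members <- names(assignment)[assignment == mods[i]]
    x <- expr[members, , drop = FALSE]
    sds <- apply(x, 1L, sd)
    if (any(sds == 0)) {
      stop2("module ", mods[i], " contains constant feature(s): ",
            paste(head(members[sds == 0], 3), collapse = ", "))
    }
    xs <- (x - rowMeans(x)) / sds
    e <- svd(t(xs), nu = 1, nv = 0)$u[, 1]
    e <- e / sd(e)
    if (mean(cor(e, t(xs))) < 0) e <- -e
    out[, i] <- e
  }
  out
}

#' Module-trait correlation
#'
#' Pearson correlation of each module eigengene with each trait, with the
#' usual t-based p-value: `t = r * sqrt(n - 2) / sqrt(1 - r^2)`, `df = n - 2`,
#' two-sided. Zero-variance traits yield `NA` with a warning.
#'
#' @param eigengenes Samples x modules matrix from [module_eigengenes()].
#' @param traits Numeric vector (one trait) or samples x traits matrix/data
#'   frame; must cover every sample.
#' @return Data frame: `module`, `trait`, `r`, `p_value`.
#' @export
module_trait <- function(eigengenes, traits) {
  eigengenes <- as.matrix(eigengenes)
  if (is.null(dim(traits))) traits <- matrix(traits, ncol = 1,
                                             dimnames = list(NULL, "trait"))
  traits <- as.matrix(traits)
  if (nrow(traits) != nrow(eigengenes)) {
    stop2("traits must be defined for every sample")
  }
  n <- nrow(eigengenes)
  rows <- list()
  for (m in colnames(eigengenes)) {
    for (tr in colnames(traits)) {
      tv <- traits[, tr]
      if (sd(tv) == 0) {
        warning("trait '", tr, "' has zero variance; correlation undefined",
                call. = FALSE)
        r <- NA_real_; p <- NA_real_
      } else {
        r <- cor(eigengenes[, m], tv)
        if (abs(r) >= 1) {
          p <- 0
        } else {
          t_stat <- r * sqrt(n - 2) / sqrt(1 - r^2)
          p <- 2 * pt(-abs(t_stat), df = n - 2)
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(module = m, trait = tr,
                                              r = r, p_value = p,
                                              stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Export the strongest within-module edges
#'
#' Within each module, feature pairs are ranked by absolute Pearson
#' correlation and the top `ceiling(fraction * n_pairs)` are kept (never
#' fewer than one per module with >= 2 features).
#'
#' @param mat Expression matrix (features x samples) on the correlation
#'   scale.
#' @param assignment Module assignment; module 0 is skipped.
#' @param fraction Fraction of each module's pairs to keep.
#' @return Data frame: `feature_a`, `feature_b`, `r`, `module`.
#' @export
top_edges <- function(mat, assignment, fraction = 0.01) {
  mat <- as.matrix(mat)
  out <- list()
  for (m in sort(unique(assignment[assignment > 0]))) {
    members <- names(assignment)[assignment == m]
    if (length(members) < 2) next
    r <- cor(t(mat[members, , drop = FALSE]))
    idx <- which(upper.tri(r), arr.ind = TRUE)
    edges <- data.frame(feature_a = members[idx[, 1]],
                        feature_b = members[idx[, 2]],
                        r = r[idx], module = m, stringsAsFactors = FALSE)
    keep <- max(1L, ceiling(fraction * nrow(edges)))
    ord <- order(-abs(edges$r), edges$feature_a, edges$feature_b)
    out[[length(out) + 1L]] <- edges[ord[seq_len(keep)], ]
  }
  if (length(out) == 0) {
    return(data.frame(feature_a = character(), feature_b = character(),
                      r = numeric(), module = integer(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
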