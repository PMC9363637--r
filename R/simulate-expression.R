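#' Configuration for a simulated reciprocal-cross expression experiment
#'
#' Bundles and validates the parameters of [simulate_expression_experiment()].
#' The defaults emulate the study design the package targets: four groups
#' (two purebreds, two reciprocal F1 crosses) with six biological replicates
#' each, a four-fold expression difference between the parent lines for
#' non-conserved features, and moderate biological dispersion.
#'
#' Counts follow a negative binomial with mean `mu` and dispersion `alpha`
#' parameterised so that `Var = mu + alpha * mu^2`; `dispersion = 0` is the
#' Poisson limit.
#'
#' @param n_features Number of features (genes/lncRNAs) to simulate.
#' @param n_replicates Biological replicates per group (>= 2).
#' @param mode_fractions Named proportions over the inheritance modes
#'   `additive`, `dominant_P1`, `dominant_P2`, `overdominant_up`,
#'   `overdominant_down`, `conserved`; must sum to 1. The number of features
#'   per mode is fixed deterministically by largest-remainder rounding, so a
#'   fraction of 0.2 over 1000 features always yields exactly 200.
#' @param base_mean Expected count of the low parent for non-conserved
#'   features (and of every group for conserved ones).
#' @param fold_change Ratio between the parental means for non-conserved
#'   features; must exceed 1.
#' @param dispersion Negative-binomial dispersion `alpha >= 0`.
#' @param seed Integer seed; identical configurations give identical output.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_features = 2000L,
                              n_replicates = 6L,
                              mode_fractions = c(additive = 0.20,
                                                 dominant_P1 = 0.15,
                                                 dominant_P2 = 0.15,
                                                 overdominant_up = 0.10,
                                                 overdominant_down = 0.10,
                                                 conserved = 0.30),
                              base_mean = 100,
                              fold_change = 4,
                              dispersion = 0.05,
                              seed = 1L) {
  modes <- c("additive", "dominant_P1", "dominant_P2",
             "overdominant_up", "overdominant_down", "conserved")
  if (!setequal(names(mode_fractions), modes)) {
    stop2("mode_fractions must be named over: ", paste(modes, collapse = ", "))
  }
  mode_fractions <- mode_fractions[modes]
  if (any(mode_fractions < 0) || abs(sum(mode_fractions) - 1) > 1e-9) {
    stop2("mode_fractions must be non-negative and sum to 1")
  }
  if (n_replicates < 2) stop2("n_replicates must be >= 2")
  if (!is.finite(base_mean) || base_mean <= 0) stop2("base_mean must be a positive finite number")
  if (!is.finite(fold_change) || fold_change <= 1) stop2("fold_change must be > 1")
  if (!is.finite(dispersion) || dispersion < 0) stop2("dispersion must be >= 0")
  structure(list(n_features = as.integer(n_features),
                 n_replicates = as.integer(n_replicates),
                 mode_fractions = mode_fractions,
                 base_mean = base_mean,
                 fold_change = fold_change,
                 dispersion = dispersion,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# NB draw with Var = mu + alpha mu^2; alpha = 0 is Poisson.
rnbinom_mu <- function(n, mu, dispersion) {
  if (dispersion == 0) rpois(n, lambda = mu) else rnbinom(n, mu = mu, size = 1 / dispersion)
}

#' Simulate a four-group reciprocal-cross count matrix with planted modes
#'
#' Each feature is assigned one inheritance mode. Parental means are
#' `base_mean` and `base_mean * fold_change` (which parent is high is chosen
#' at random per feature); the F1 mean is the mid-parent value for additive
#' features, the matched parent's mean for dominant features, one further
#' `fold_change` beyond the extreme parent for overdominant features, and
#' equal to the parents for conserved features. Both reciprocal crosses share
#' the same planted mode and mean.
#'
#' @param config A [simulation_config()].
#' @return A list with `counts` (integer matrix, features x samples),
#'   `samples` (data frame: `sample_id`, `group` in `P1/P2/F1a/F1b`) and
#'   `truth` (data frame: `feature_id`, `mode`, `mu_P1`, `mu_P2`, `mu_F1`).
#' @examples
#' sim <- simulate_expression_experiment(simulation_config(n_features = 50, seed = 1))
#' table(sim$truth$mode)
#' @export
simulate_expression_experiment <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed, {
    n <- config$n_features
    modes <- names(config$mode_fractions)
    n_per_mode <- apportion(n, config$mode_fractions)
    mode <- sample(rep(modes, times = n_per_mode))

    lo <- config$base_mean
    hi <- config$base_mean * config$fold_change
    # random orientation: which parent carries the high mean
    p1_high <- runif(n) < 0.5
    mu_p1 <- ifelse(p1_high, hi, lo)
    mu_p2 <- ifelse(p1_high, lo, hi)
    conserved <- mode == "conserved"
    mu_p1[conserved] <- config$base_mean
    mu_p2[conserved] <- config$base_mean

    mu_f1 <- (mu_p1 + mu_p2) / 2
    mu_f1[mode == "dominant_P1"] <- mu_p1[mode == "dominant_P1"]
    mu_f1[mode == "dominant_P2"] <- mu_p2[mode == "dominant_P2"]
    up <- mode == "overdominant_up"
    mu_f1[up] <- pmax(mu_p1[up], mu_p2[up]) * config$fold_change
    dn <- mode == "overdominant_down"
    mu_f1[dn] <- pmin(mu_p1[dn], mu_p2[dn]) / config$fold_change
    mu_f1[conserved] <- config$base_mean
    if (any(!is.finite(c(mu_p1, mu_p2, mu_f1)))) stop2("non-finite simulated means")

    groups <- c("P1", "P2", "F1a", "F1b")
    nr <- config$n_replicates
    samples <- data.frame(
      sample_id = paste0(rep(groups, each = nr), "_", rep(seq_len(nr), times = 4)),
      group = rep(groups, each = nr),
      stringsAsFactors = FALSE
    )
    group_mu <- cbind(P1 = mu_p1, P2 = mu_p2, F1a = mu_f1, F1b = mu_f1)
    counts <- matrix(0L, nrow = n, ncol = nrow(samples),
                     dimnames = list(sprintf("feat%05d", seq_len(n)), samples$sample_id))
    for (j in seq_len(nrow(samples))) {
      counts[, j] <- rnbinom_mu(n, group_mu[, samples$group[j]], config$dispersion)
    }
    storage.mode(counts) <- "integer"
    truth <- data.frame(feature_id = rownames(counts), mode = mode,
                        mu_P1 = mu_p1, mu_P2 = mu_p2, mu_F1 = mu_f1,
                        stringsAsFactors = FALSE)
    list(counts = counts, samples = samples, truth = truth)
  })
}

#' Simulate individual phenotypes with a planted heterosis percentage
#'
#' Individuals are drawn as `Normal(group mean, cv * group mean)`; the F1
#' group means are placed at `midparent * (1 + H/100)` so the planted `H%`
#' directly inverts the mid-parent heterosis estimator. The default trait
#' table mirrors a layer-chicken maturation study: pubic space and oviduct
#' length show positive heterosis in both crosses, age at first egg (AFE)
#' negative heterosis.
#'
#' @param traits Data frame with columns `trait`, `mean_P1`, `mean_P2`,
#'   `h_F1a`, `h_F1b` (planted heterosis percentages per cross).
#' @param n_per_group Individuals per group.
#' @param cv Within-group coefficient of variation (sd / mean, applied on the
#'   absolute group mean).
#' @param seed Integer seed.
#' @return A list with `phenotypes` (long data frame: `individual_id`,
#'   `group`, `trait`, `value`) and `truth` (the trait table with the planted
#'   `H%` values).
#' @export
simulate_phenotypes <- function(traits = data.frame(
                                  trait = c("pubic_space", "oviduct_length", "AFE"),
                                  mean_P1 = c(60, 60, 150),
                                  mean_P2 = c(40, 45, 175),
                                  h_F1a = c(25.79, 30.55, -5),
                                  h_F1b = c(32.45, 20.15, -5),
                                  stringsAsFactors = FALSE),
                                n_per_group = 30L,
                                cv = 0.1,
                                seed = 1L) {
  stopifnot(all(c("trait", "mean_P1", "mean_P2", "h_F1a", "h_F1b") %in% names(traits)),
            n_per_group >= 2, cv >= 0)
  with_seed(seed, {
    groups <- c("P1", "P2", "F1a", "F1b")
    out <- list()
    for (i in seq_len(nrow(traits))) {
      mid <- (traits$mean_P1[i] + traits$mean_P2[i]) / 2
      means <- c(P1 = traits$mean_P1[i],
                 P2 = traits$mean_P2[i],
                 F1a = mid * (1 + traits$h_F1a[i] / 100),
                 F1b = mid * (1 + traits$h_F1b[i] / 100))
      for (g in groups) {
        out[[length(out) + 1L]] <- data.frame(
          individual_id = paste0(g, "_", seq_len(n_per_group)),
          group = g,
          trait = traits$trait[i],
          value = rnorm(n_per_group, mean = means[[g]], sd = cv * abs(means[[g]])),
          stringsAsFactors = FALSE
        )
      }
    }
    list(phenotypes = do.call(rbind, out), truth = traits)
  })
}
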