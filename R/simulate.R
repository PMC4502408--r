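#' Configuration for the technical-replicate simulator
#'
#' Describes a two-phenotype clonal cell-line experiment measured with a few
#' technical replicates per phenotype: every replicate of a phenotype shares
#' the same true expression profile (no biological variance) and differs only
#' by intensity-dependent measurement noise, applied on the log2 scale with
#' standard deviation `noise_a + noise_b / sqrt(intensity)` — so low-intensity
#' genes have unstable fold changes while high-intensity genes are measured
#' precisely. Differential expression is planted in two regimes mirroring
#' what difference- and ratio-based rankings each favour: `n_high` genes at
#' high baseline expression shifted by an additive linear-scale effect (large
#' |PD|, modest fold change) and `n_low` genes at low baseline scaled by a
#' multiplicative effect (large fold change, small |PD|). Planted directions
#' (up or down in the resistant phenotype) are assigned at random.
#'
#' @param n_genes total genes (default 2000).
#' @param n_rep_r,n_rep_s technical replicates per phenotype (default 3 vs 3).
#' @param baseline_log2_mean,baseline_log2_sd log2 baseline distribution of
#'   unplanted genes (defaults 7 and 1.5, a typical microarray spread).
#' @param noise_a,noise_b intensity-dependent log2 noise sd parameters
#'   (defaults 0.05 and 2: sd ~ 0.07 at intensity 10000, ~ 0.47 at 25).
#' @param n_high,high_effect count and additive linear effect of
#'   high-expression planted genes (defaults 100 and 3000; their log2
#'   baseline is drawn from N(`high_baseline_log2`, 0.5)).
#' @param n_low,low_effect count and fold effect of low-expression planted
#'   genes (defaults 100 and 6; log2 baseline N(`low_baseline_log2`, 0.5)).
#' @param high_baseline_log2,low_baseline_log2 planted-gene baseline centres
#'   (defaults 11 and 4.5).
#' @param corrupt_samples sample ids whose measurements are re-drawn from the
#'   unplanted baseline profile with independent noise, emulating a failed
#'   replicate that carries no reproducible signal.
#' @param seed integer RNG seed; a fixed seed makes the output byte-identical.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_genes = 2000L, n_rep_r = 3L, n_rep_s = 3L,
                       baseline_log2_mean = 7, baseline_log2_sd = 1.5,
                       noise_a = 0.05, noise_b = 2,
                       n_high = 100L, high_effect = 3000,
                       n_low = 100L, low_effect = 6,
                       high_baseline_log2 = 11, low_baseline_log2 = 4.5,
                       corrupt_samples = NULL, seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes), n_rep_r = as.integer(n_rep_r),
              n_rep_s = as.integer(n_rep_s),
              baseline_log2_mean = baseline_log2_mean,
              baseline_log2_sd = baseline_log2_sd,
              noise_a = noise_a, noise_b = noise_b,
              n_high = as.integer(n_high), high_effect = high_effect,
              n_low = as.integer(n_low), low_effect = low_effect,
              high_baseline_log2 = high_baseline_log2,
              low_baseline_log2 = low_baseline_log2,
              corrupt_samples = corrupt_samples, seed = as.integer(seed))
  if (cfg$n_genes < 1L || cfg$n_rep_r < 1L || cfg$n_rep_s < 1L)
    stop("need >= 1 gene and >= 1 replicate per phenotype", call. = FALSE)
  if (cfg$n_high + cfg$n_low > cfg$n_genes)
    stop("more planted genes than genes", call. = FALSE)
  if ((cfg$n_high > 0L && cfg$high_effect <= 0) ||
      (cfg$n_low > 0L && cfg$low_effect <= 1))
    stop("planted effects must be positive (additive) / > 1 (fold)", call. = FALSE)
  if (cfg$noise_a < 0 || cfg$noise_b < 0)
    stop("noise parameters must be non-negative", call. = FALSE)
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a technical-replicate expression experiment
#'
#' Draws the experiment described by a [sim_config]: per-gene phenotype means
#' with planted effects, then i.i.d. intensity-dependent log2 noise per
#' replicate. Sample ids are `R1..Rr` and `S1..Ss`.
#'
#' @param config a [sim_config].
#' @return List with `x` (an [expr_matrix]) and `truth` (named character
#'   vector per gene: `"up"`, `"down"`, or `"null"`, with attribute
#'   `"regime"` marking planted genes as `"high"` or `"low"`).
#' @export
simulate_expression <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)  # single seeded stream; all draws below flow from it
  n <- config$n_genes
  genes <- sprintf("g%04d", seq_len(n))
  idx_high <- if (config$n_high) seq_len(config$n_high) else integer(0)
  idx_low <- if (config$n_low) config$n_high + seq_len(config$n_low) else integer(0)

  base_log2 <- stats::rnorm(n, config$baseline_log2_mean, config$baseline_log2_sd)
  base_log2[idx_high] <- stats::rnorm(length(idx_high), config$high_baseline_log2, 0.5)
  base_log2[idx_low] <- stats::rnorm(length(idx_low), config$low_baseline_log2, 0.5)
  base <- 2^base_log2

  truth <- rep("null", n)
  regime <- rep(NA_character_, n)
  regime[idx_high] <- "high"
  regime[idx_low] <- "low"
  planted <- c(idx_high, idx_low)
  truth[planted] <- sample(c("up", "down"), length(planted), replace = TRUE)

  mean_r <- mean_s <- base
  up_high <- intersect(idx_high, which(truth == "up"))
  dn_high <- intersect(idx_high, which(truth == "down"))
  mean_r[up_high] <- base[up_high] + config$high_effect
  mean_s[dn_high] <- base[dn_high] + config$high_effect
  up_low <- intersect(idx_low, which(truth == "up"))
  dn_low <- intersect(idx_low, which(truth == "down"))
  mean_r[up_low] <- base[up_low] * config$low_effect
  mean_s[dn_low] <- base[dn_low] * config$low_effect

  noisy <- function(mu) {
    sd <- config$noise_a + config$noise_b / sqrt(mu)
    2^(log2(mu) + stats::rnorm(length(mu), 0, sd))
  }
  r_ids <- paste0("R", seq_len(config$n_rep_r))
  s_ids <- paste0("S", seq_len(config$n_rep_s))
  cols <- c(lapply(r_ids, function(id) noisy(mean_r)),
            lapply(s_ids, function(id) noisy(mean_s)))
  vals <- do.call(cbind, cols)
  dimnames(vals) <- list(genes, c(r_ids, s_ids))

  for (sid in config$corrupt_samples) {
    if (!sid %in% colnames(vals)) stop("unknown corrupt sample: ", sid, call. = FALSE)
    # failed replicate: profile re-drawn independently of the genes' true
    # levels, so the sample carries no reproducible signal at all
    fresh <- 2^stats::rnorm(n, config$baseline_log2_mean, config$baseline_log2_sd)
    vals[, sid] <- noisy(fresh)
  }

  ph <- stats::setNames(rep(c("R", "S"), c(length(r_ids), length(s_ids))),
                        c(r_ids, s_ids))
  names(truth) <- genes
  attr(truth, "regime") <- stats::setNames(regime, genes)
  list(x = expr_matrix(vals, ph), truth = truth, config = config)
}

#' Worked reproducibility fixtures for the printed consistency examples
#'
#' Builds, for each reported duo comparison of the cell-line datasets
#' (CP70/A2780, MDA-MB-231, LCC2/MCF7, HCT116), a pair of direction-annotated
#' gene lists sharing exactly K genes of which S agree in direction, so that
#' [consistency()] reproduces the reference consistency scores (e.g. K = 147,
#' S = 136, score 92.52% for the HCT116 pair1-2 comparison) and their binomial
#' p bounds. Each fixture also carries non-shared filler genes on both sides.
#'
#' @return Data frame with columns `dataset`, `comparison`, `k`, `s`,
#'   `score_pct` (the reference score) and a list-column `lists`, each entry
#'   holding the two named direction vectors `a` and `b`.
#' @export
consistency_examples <- function() {
  rows <- data.frame(
    dataset = c(rep("CP70/A2780", 3L), rep("MDA-MB-231", 3L),
                "LCC2/MCF7", "HCT116"),
    comparison = c("pair1-2", "pair1-3", "pair2-3",
                   "pair1-2", "pair1-3", "pair2-3", "pair1-2", "pair1-2"),
    k = c(267L, 151L, 155L, 200L, 186L, 179L, 196L, 147L),
    s = c(267L, 142L, 146L, 194L, 174L, 167L, 190L, 136L),
    score_pct = c(100.00, 94.04, 94.19, 97.00, 93.55, 93.30, 96.94, 92.52),
    stringsAsFactors = FALSE)
  rows$lists <- lapply(seq_len(nrow(rows)), function(i) {
    k <- rows$k[i]; s <- rows$s[i]
    shared <- sprintf("sh%03d", seq_len(k))
    a <- stats::setNames(rep(c("up", "down"), length.out = k), shared)
    b <- a
    if (s < k) b[(s + 1L):k] <- ifelse(a[(s + 1L):k] == "up", "down", "up")
    a <- c(a, stats::setNames(rep("up", 5L), sprintf("onlyA%02d", 1:5)))
    b <- c(b, stats::setNames(rep("down", 5L), sprintf("onlyB%02d", 1:5)))
    list(a = a, b = b)
  })
  rows
}
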