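#' Reproducibility-based differential expression for technical replicates
#'
#' Fits the full reproducibility-based PD/PFC procedure to a genes-by-samples
#' intensity matrix with two clonal phenotypes (R = resistant, S = sensitive)
#' measured by technical replicates: (1) optional log2 + quantile
#' normalisation; (2) per-sample-pair ranking of all genes by pairwise
#' difference (PD) and/or pairwise fold change (PFC); (3) selection of
#' reproducible independent sample pairs by top-`top_n` direction consistency
#' (exact binomial test, seed duo = smallest p, admission at p < 0.01);
#' (4) block-wise consistency search with step halving between every duo of
#' selected pairs; (5) merge across duos, deleting direction conflicts. When
#' both score rules are requested their DE sets are additionally combined
#' (union, direction conflicts dropped), since the difference ranking favours
#' strongly expressed genes and the ratio ranking recovers dysregulation at
#' low intensities.
#'
#' @param x an [expr_matrix] (or a plain named numeric matrix, in which case
#'   `phenotype` must be given).
#' @param phenotype optional named character vector of `"R"`/`"S"` per sample,
#'   used when `x` is not already an [expr_matrix].
#' @param score score rules to run: subset of `c("pd", "pfc")`.
#' @param ct consistency threshold of the block search (default 0.90).
#' @param init_step initial block size (default 300 genes).
#' @param min_step smallest block size reached by step halving (default 1).
#' @param top_n top-ranked genes used for sample-pair screening (default 300).
#' @param floor intensity floor applied before ratio scoring (default 1).
#' @param normalize logical; apply [quantile_normalize_log2()] first.
#' @return An object of class `repde`: list with `call`, `params`, one
#'   result per score rule in `fits` (each holding the `pair_selection` and
#'   the `de_gene_set`), and — when both rules ran — `combined` (union DE set
#'   with conflicts dropped).
#' @seealso [select_reproducible_pairs()], [multi_pair_de()], [enrich()]
#' @examples
#' sim <- simulate_expression(sim_config(n_genes = 300, n_high = 30,
#'                                       n_low = 30, seed = 7))
#' fit <- repde(sim$x, score = "pd", init_step = 50)
#' fit
#' head(de_genes(fit, "pd"))
#' @export
repde <- function(x, phenotype = NULL, score = c("pd", "pfc"), ct = 0.90,
                  init_step = 300L, min_step = 1L, top_n = 300L, floor = 1,
                  normalize = FALSE) {
  cl <- match.call()
  if (!inherits(x, "expr_matrix")) {
    if (is.null(phenotype))
      stop("`phenotype` is required when `x` is not an expr_matrix", call. = FALSE)
    x <- expr_matrix(as.matrix(x), phenotype)
  }
  score <- match.arg(score, several.ok = TRUE)
  params <- search_params(ct = ct, init_step = init_step, min_step = min_step)
  if (normalize) x <- quantile_normalize_log2(floor_values(x, floor))

  fits <- lapply(score, function(rule) {
    sel <- select_reproducible_pairs(x, score = rule, top_n = top_n, floor = floor)
    lists <- sel$ranked[sel$selected$pair_id]
    nonempty <- all(vapply(lists, nrow, integer(1L)) > 0L)
    de <- if (length(lists) >= 2L && nonempty) multi_pair_de(lists, params) else
      new_de_gene_set(stats::setNames(character(0), character(0)),
                      integer(0), character(0), params)
    list(selection = sel, de = de)
  })
  names(fits) <- score

  combined <- NULL
  if (length(score) == 2L) {
    sets <- lapply(fits, function(f)
      stats::setNames(f$de$genes$direction, f$de$genes$gene_id))
    genes <- sort(unique(c(names(sets[[1L]]), names(sets[[2L]]))))
    dirs <- lapply(genes, function(g)
      unique(unname(unlist(lapply(sets, function(s) s[g][!is.na(s[g])])))))
    conflicted <- genes[lengths(dirs) > 1L]
    kept <- setdiff(genes, conflicted)
    support <- vapply(kept, function(g)
      sum(vapply(sets, function(s) g %in% names(s), logical(1L))), integer(1L))
    combined <- new_de_gene_set(
      stats::setNames(vapply(dirs[match(kept, genes)], `[[`, character(1L), 1L), kept),
      support, conflicted, params)
  }

  structure(list(call = cl, params = params, top_n = as.integer(top_n),
                 floor = floor, n_genes = nrow(x), n_samples = ncol(x),
                 phenotype = phenotypes(x), fits = fits, combined = combined),
            class = "repde")
}

#' Extract the DE gene table from a repde fit
#'
#' @param object a `repde` fit.
#' @param score `"pd"`, `"pfc"`, or `"combined"` (default: the single fitted
#'   rule, or `"combined"` when both were fitted).
#' @return Data frame `gene_id`, `direction`, `n_support`.
#' @export
de_genes <- function(object, score = NULL) {
  stopifnot(inherits(object, "repde"))
  if (is.null(score))
    score <- if (!is.null(object$combined)) "combined" else names(object$fits)[1L]
  if (score == "combined") {
    if (is.null(object$combined)) stop("no combined fit available", call. = FALSE)
    return(object$combined$genes)
  }
  object$fits[[score]]$de$genes
}

#' @export
print.repde <- function(x, ...) {
  cat("Reproducibility-based DE fit\n")
  cat(sprintf("  data: %d genes, %d samples (%d R, %d S)\n", x$n_genes,
              x$n_samples, sum(x$phenotype == "R"), sum(x$phenotype == "S")))
  cat(sprintf("  params: CT = %.0f%%, initial step = %d, top_n = %d\n",
              100 * x$params$ct, x$params$init_step, x$top_n))
  for (rule in names(x$fits)) {
    f <- x$fits[[rule]]
    cat(sprintf("  %s: %d/%d sample pairs selected, %d DE genes\n",
                toupper(rule), nrow(f$selection$selected),
                nrow(f$selection$selected) + nrow(f$selection$excluded),
                nrow(f$de$genes)))
  }
  if (!is.null(x$combined))
    cat(sprintf("  combined PD+PFC: %d DE genes (%d direction conflict(s) dropped)\n",
                nrow(x$combined$genes), length(x$combined$dropped_conflicts)))
  invisible(x)
}

#' @export
summary.repde <- function(object, ...) {
  structure(list(fit = object), class = "summary.repde")
}

#' @export
print.summary.repde <- function(x, ...) {
  print(x$fit)
  for (rule in names(x$fit$fits)) {
    f <- x$fit$fits[[rule]]
    cat(sprintf("\n%s pair comparisons (top %d genes):\n", toupper(rule), x$fit$top_n))
    print(pair_report(f$selection), row.names = FALSE)
    if (nrow(f$selection$excluded)) {
      cat("excluded pairs:\n")
      print(f$selection$excluded, row.names = FALSE)
    }
    up <- sum(f$de$genes$direction == "up")
    cat(sprintf("%s DE genes: %d (%d up, %d down)\n", toupper(rule),
                nrow(f$de$genes), up, nrow(f$de$genes) - up))
  }
  invisible(x)
}

#' Plot average phenotype expression of detected DE genes
#'
#' Scatter of the per-gene mean intensity in resistant vs sensitive samples,
#' DE genes highlighted by direction — the standard picture of where on the
#' intensity range each score rule finds its genes (differences at high
#' intensity, fold changes reaching down to low intensity).
#'
#' @param x a `repde` fit.
#' @param data the [expr_matrix] the fit was produced from.
#' @param score which DE set to highlight (as in [de_genes()]).
#' @param log logical; plot on log axes (default `TRUE`).
#' @param ... passed to [graphics::plot()].
#' @export
plot.repde <- function(x, data, score = NULL, log = TRUE, ...) {
  stopifnot(inherits(data, "expr_matrix"))
  ph <- phenotypes(data)
  mr <- rowMeans(unclass(data)[, ph == "R", drop = FALSE])
  ms <- rowMeans(unclass(data)[, ph == "S", drop = FALSE])
  de <- de_genes(x, score)
  col <- rep("grey70", nrow(data))
  names(col) <- rownames(data)
  col[de$gene_id[de$direction == "up"]] <- "firebrick"
  col[de$gene_id[de$direction == "down"]] <- "navy"
  graphics::plot(ms, mr, col = col, pch = 20, cex = 0.6,
                 log = if (log) "xy" else "",
                 xlab = "mean intensity, sensitive (S)",
                 ylab = "mean intensity, resistant (R)", ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}
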