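#' Direction-annotated ranked gene lists from pairwise scores
#'
#' For one sample pair — one resistant (R) and one sensitive (S) technical
#' replicate — every gene receives a score on the linear intensity scale:
#' the pairwise difference PD = E_R - E_S, or the pairwise fold change
#' PFC = E_R / E_S. Genes are annotated `up` (PD > 0, PFC > 1) or `down`
#' (PD < 0, PFC < 1) in the resistant sample and sorted by decreasing score
#' magnitude; the magnitude is |PD| for differences and max(PFC, 1/PFC) for
#' fold changes, so an x-fold increase and an x-fold decrease rank equally.
#' Genes with PD = 0 (or PFC = 1) carry no direction and are excluded.
#' Equal magnitudes are ordered by gene id so rankings are reproducible
#' across platforms.
#'
#' @param x an [expr_matrix].
#' @param r_sample,s_sample sample ids with phenotype `"R"` and `"S"`.
#' @return A `ranked_list`: a data frame with columns `gene_id`, `score`,
#'   `magnitude`, `direction` (`"up"`/`"down"`), sorted by decreasing
#'   magnitude, with attributes `pair_id` and `score_rule`.
#' @seealso [fc_baseline()] for the plain average-fold-change ranking.
#' @examples
#' m <- matrix(c(100, 40, 55, 80, 50, 53), nrow = 3,
#'             dimnames = list(paste0("g", 1:3), c("R1", "S1")))
#' x <- expr_matrix(m, c(R1 = "R", S1 = "S"))
#' pd_scores(x, "R1", "S1")
#' pfc_scores(x, "R1", "S1")
#' @export
pd_scores <- function(x, r_sample, s_sample) {
  v <- pair_columns(x, r_sample, s_sample)
  score <- v$r - v$s
  new_ranked_list(rownames(x), score, abs(score), score > 0, score != 0,
                  pair_id = paste0(r_sample, "-", s_sample), score_rule = "PD")
}

#' @rdname pd_scores
#' @export
pfc_scores <- function(x, r_sample, s_sample) {
  v <- pair_columns(x, r_sample, s_sample)
  bad <- v$r <= 0 | v$s <= 0
  if (any(bad))
    stop("non-positive intensity for gene ", rownames(x)[which(bad)[1L]],
         "; apply floor_values() first", call. = FALSE)
  score <- v$r / v$s
  new_ranked_list(rownames(x), score, pmax(score, 1 / score), score > 1, score != 1,
                  pair_id = paste0(r_sample, "-", s_sample), score_rule = "PFC")
}

#' Average fold-change baseline ranking
#'
#' Ranks genes by the ratio of phenotype-mean intensities,
#' mean(R samples) / mean(S samples), with the same symmetric magnitude and
#' direction rules as [pfc_scores()]. Provided only as the conventional
#' fold-change baseline that the reproducibility-based rankings improve on.
#'
#' @inheritParams pd_scores
#' @return A `ranked_list` with `pair_id = "FCmean"`.
#' @export
fc_baseline <- function(x) {
  ph <- phenotypes(x)
  if (!any(ph == "R") || !any(ph == "S"))
    stop("need at least one sample per phenotype", call. = FALSE)
  mr <- rowMeans(unclass(x)[, ph == "R", drop = FALSE])
  ms <- rowMeans(unclass(x)[, ph == "S", drop = FALSE])
  bad <- mr <= 0 | ms <= 0
  if (any(bad))
    stop("non-positive mean intensity for gene ", rownames(x)[which(bad)[1L]],
         "; apply floor_values() first", call. = FALSE)
  score <- mr / ms
  new_ranked_list(rownames(x), score, pmax(score, 1 / score), score > 1, score != 1,
                  pair_id = "FCmean", score_rule = "FC")
}

pair_columns <- function(x, r_sample, s_sample) {
  stopifnot(inherits(x, "expr_matrix"))
  ph <- phenotypes(x)
  for (s in c(r_sample, s_sample))
    if (!s %in% colnames(x)) stop("unknown sample id: ", s, call. = FALSE)
  if (ph[[r_sample]] != "R" || ph[[s_sample]] != "S")
    stop("pair must be (R sample, S sample); got (", ph[[r_sample]], ", ",
         ph[[s_sample]], ")", call. = FALSE)
  list(r = unclass(x)[, r_sample], s = unclass(x)[, s_sample])
}

new_ranked_list <- function(gene_id, score, magnitude, up, keep, pair_id, score_rule) {
  df <- data.frame(gene_id = gene_id, score = score, magnitude = magnitude,
                   direction = ifelse(up, "up", "down"),
                   stringsAsFactors = FALSE)[keep, , drop = FALSE]
  df <- df[order(-df$magnitude, df$gene_id), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, pair_id = pair_id, score_rule = score_rule,
            class = c("ranked_list", "data.frame"))
}

#' @export
print.ranked_list <- function(x, n = 6L, ...) {
  cat(sprintf("ranked_list (%s, pair %s): %d genes\n",
              attr(x, "score_rule"), attr(x, "pair_id"), nrow(x)))
  print.data.frame(utils::head(x, n))
  if (nrow(x) > n) cat("... and", nrow(x) - n, "more\n")
  invisible(x)
}

#' Write a ranked list as TSV
#'
#' Columns: rank, gene_id, score, magnitude, direction.
#'
#' @param x a `ranked_list`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ranked_list <- function(x, path) {
  df <- data.frame(rank = seq_len(nrow(x)), x, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# named direction vector from a ranked list (or anything direction-annotated)
directions <- function(x) {
  if (inherits(x, "data.frame")) {
    stopifnot(all(c("gene_id", "direction") %in% names(x)))
    return(stats::setNames(x$direction, x$gene_id))
  }
  if (is.character(x) && !is.null(names(x))) return(x)
  stop("cannot extract directions from object of class ", class(x)[1L], call. = FALSE)
}
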