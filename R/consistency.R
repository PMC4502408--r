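#' Direction-concordance of two gene lists with an exact binomial test
#'
#' Two differential-expression gene lists that both carry a dysregulation
#' direction per gene (`up`/`down` in the resistant phenotype) are compared on
#' their k shared genes; s of them agree in direction, giving the consistency
#' score s/k. Under the null that directions agree independently with
#' probability `p_e` (0.5 for two unrelated experiments), the probability of
#' observing at least s agreements is the upper binomial tail
#' P(X >= s) = sum_{i=s}^{k} C(k,i) p_e^i (1-p_e)^(k-i).
#' The tail is computed with survival-function arithmetic and returned both as
#' a double and as log10, so extreme scores (far below 1e-300) remain
#' comparable. A comparison is declared significantly reproducible downstream
#' when the p-value is below 0.01.
#'
#' @param a,b direction-annotated lists: `ranked_list` objects, data frames
#'   with `gene_id` and `direction` columns, or named character vectors of
#'   `"up"`/`"down"` keyed by gene id.
#' @param p_e null probability of direction agreement, in (0, 1); default 0.5.
#' @return A `consistency_result`: list with `k` (shared genes), `s` (same
#'   direction), `score` (s/k, `NA` when k = 0), `p_value`, `log10_p`, `p_e`
#'   and `evaluable` (`FALSE` when the lists share no genes).
#' @examples
#' a <- c(g1 = "up", g2 = "down", g3 = "up")
#' b <- c(g2 = "down", g3 = "down", g4 = "up")
#' consistency(a, b)
#' @export
consistency <- function(a, b, p_e = 0.5) {
  if (!is.numeric(p_e) || length(p_e) != 1L || p_e <= 0 || p_e >= 1)
    stop("`p_e` must be a single probability in (0, 1)", call. = FALSE)
  da <- directions(a)
  db <- directions(b)
  ok <- c(da, db) %in% c("up", "down")
  if (!all(ok)) stop("invalid direction value: ", c(da, db)[!ok][1L], call. = FALSE)
  shared <- intersect(names(da), names(db))
  k <- length(shared)
  if (k == 0L)
    return(new_consistency(0L, 0L, NA_real_, NA_real_, NA_real_, p_e, FALSE))
  s <- sum(da[shared] == db[shared])
  # P(X >= s) as an upper-tail survival value; exact at s = 0 (p = 1)
  p <- stats::pbinom(s - 1L, k, p_e, lower.tail = FALSE)
  lp <- stats::pbinom(s - 1L, k, p_e, lower.tail = FALSE, log.p = TRUE) / log(10)
  new_consistency(k, s, s / k, p, lp, p_e, TRUE)
}

new_consistency <- function(k, s, score, p, lp, p_e, evaluable) {
  structure(list(k = k, s = s, score = score, p_value = p, log10_p = lp,
                 p_e = p_e, evaluable = evaluable),
            class = "consistency_result")
}

#' @export
print.consistency_result <- function(x, ...) {
  if (!x$evaluable) {
    cat("consistency: not evaluable (no shared genes)\n")
  } else {
    cat(sprintf("consistency: k = %d shared, s = %d same direction, score = %.2f%%\n",
                x$k, x$s, 100 * x$score))
    cat("binomial p", format_p(x$p_value), sprintf(" (log10 p = %.2f)\n", x$log10_p))
  }
  invisible(x)
}

# display convention: exact doubles are kept internally, the familiar
# "< 2.2e-16" bound is formatting only
format_p <- function(p) {
  if (is.na(p)) "NA" else if (p < 2.2e-16) "< 2.2e-16" else paste0("= ", format(p, digits = 3))
}

#' Consistency of the top-n genes of two ranked lists
#'
#' Truncates each ranking to its first `min(n, length)` entries and applies
#' [consistency()]. Used with n = 300 when screening sample pairs.
#'
#' @param a,b `ranked_list` objects (or direction-annotated data frames).
#' @param n positive number of top genes per list.
#' @inheritParams consistency
#' @return A `consistency_result`.
#' @export
topn_consistency <- function(a, b, n = 300L, p_e = 0.5) {
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop("`n` must be a positive integer", call. = FALSE)
  if (nrow(a) == 0L || nrow(b) == 0L)
    return(new_consistency(0L, 0L, NA_real_, NA_real_, NA_real_, p_e, FALSE))
  consistency(utils::head(a, n), utils::head(b, n), p_e = p_e)
}
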