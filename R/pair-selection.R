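#' Enumerate resistant-sensitive sample pairs
#'
#' With r1 resistant and s1 sensitive technical replicates there are r1 x s1
#' ways to pair one R sample with one S sample; each pairing is treated as one
#' experiment. Pairs are returned in R-sample-order x S-sample-order.
#'
#' @param x an [expr_matrix].
#' @return Data frame with columns `pair_id`, `r_sample`, `s_sample`.
#' @export
enumerate_pairs <- function(x) {
  ph <- phenotypes(x)
  rs <- names(ph)[ph == "R"]
  ss <- names(ph)[ph == "S"]
  if (length(rs) == 0L || length(ss) == 0L)
    stop("need at least one sample per phenotype", call. = FALSE)
  grid <- expand.grid(s_sample = ss, r_sample = rs,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- data.frame(pair_id = paste0(grid$r_sample, "-", grid$s_sample),
                    r_sample = grid$r_sample, s_sample = grid$s_sample,
                    stringsAsFactors = FALSE)
  if (nrow(out) == 1L)
    message("only one sample pair exists; no independent comparison is possible")
  out
}

#' Are two sample pairs independent?
#'
#' Two experiments are independent when they share no technical sample, i.e.
#' all four sample ids are distinct.
#'
#' @param a,b single rows of the [enumerate_pairs()] data frame (or any list
#'   with `r_sample` and `s_sample`).
#' @return `TRUE` iff the pairs share no sample.
#' @export
pairs_independent <- function(a, b) {
  length(unique(c(a$r_sample, a$s_sample, b$r_sample, b$s_sample))) == 4L
}

#' Select reproducible independent sample pairs
#'
#' Screens all r1 x s1 sample pairs for reproducible differential-expression
#' signal: (i) genes are ranked per pair by PD or PFC; (ii) among all duos of
#' independent pairs, the duo whose top-n direction consistency has the
#' smallest binomial p-value is selected as the seed (ties: higher score, then
#' lexicographic pair ids); (iii) remaining pairs sharing no sample with any
#' selected pair are admitted one by one when their top-n consistency with at
#' least one selected pair has p < `p_threshold`. Pairs left out are reported
#' with a reason (`not-independent` or `inconsistent`) — the latter is how a
#' corrupted replicate is diagnosed and excluded.
#'
#' @param x an [expr_matrix] with >= 2 samples per phenotype.
#' @param score `"pd"` or `"pfc"` ranking rule.
#' @param top_n number of top-ranked genes compared per duo (default 300).
#' @param p_threshold admission threshold on the consistency p-value
#'   (default 0.01).
#' @param floor intensity floor applied before PFC ranking (default 1).
#' @return A `pair_selection` object: list with `selected` (pair data frame),
#'   `excluded` (pair data frame with `reason`), `comparisons` (per-duo k, s,
#'   score, p), `ranked` (named list of `ranked_list`s for every pair),
#'   `top_n`, `score_rule`.
#' @export
select_reproducible_pairs <- function(x, score = c("pd", "pfc"), top_n = 300L,
                                      p_threshold = 0.01, floor = 1) {
  score <- match.arg(score)
  ph <- phenotypes(x)
  if (sum(ph == "R") < 2L || sum(ph == "S") < 2L)
    stop("insufficient replicates: need >= 2 samples per phenotype", call. = FALSE)
  if (score == "pfc") x <- floor_values(x, floor)
  pairs <- enumerate_pairs(x)
  pairs <- pairs[order(pairs$pair_id), , drop = FALSE]  # permutation-stable
  rownames(pairs) <- NULL
  scorer <- if (score == "pd") pd_scores else pfc_scores
  ranked <- lapply(seq_len(nrow(pairs)), function(i)
    scorer(x, pairs$r_sample[i], pairs$s_sample[i]))
  names(ranked) <- pairs$pair_id

  # all independent duos, with their top-n consistency
  duos <- utils::combn(nrow(pairs), 2L)
  indep <- apply(duos, 2L, function(ij)
    pairs_independent(pairs[ij[1L], ], pairs[ij[2L], ]))
  duos <- duos[, indep, drop = FALSE]
  if (ncol(duos) == 0L)
    stop("insufficient replicates: no independent pair duo exists", call. = FALSE)
  comp <- do.call(rbind, lapply(seq_len(ncol(duos)), function(j) {
    i1 <- duos[1L, j]; i2 <- duos[2L, j]
    cr <- topn_consistency(ranked[[i1]], ranked[[i2]], n = top_n)
    data.frame(pair_a = pairs$pair_id[i1], pair_b = pairs$pair_id[i2],
               k = cr$k, s = cr$s, score = cr$score,
               p_value = cr$p_value, log10_p = cr$log10_p,
               stringsAsFactors = FALSE)
  }))

  # seed duo: smallest p (log10 scale to resolve underflow), then higher
  # score, then lexicographic pair ids
  ord <- order(comp$log10_p, -comp$score, comp$pair_a, comp$pair_b, na.last = TRUE)
  seed <- comp[ord[1L], ]
  if (is.na(seed$log10_p))
    warning("no independent duo shares any ranked gene; seeding with the ",
            "first duo (no further pair can qualify)", call. = FALSE)
  selected <- c(seed$pair_a, seed$pair_b)

  repeat {
    remaining <- setdiff(pairs$pair_id, selected)
    if (length(remaining) == 0L) break
    sel_rows <- pairs[match(selected, pairs$pair_id), , drop = FALSE]
    candidate <- NULL
    for (pid in sort(remaining)) {
      row <- pairs[pairs$pair_id == pid, ]
      indep_all <- all(vapply(seq_len(nrow(sel_rows)), function(i)
        pairs_independent(row, sel_rows[i, ]), logical(1L)))
      if (!indep_all) next
      pc <- comp[(comp$pair_a == pid & comp$pair_b %in% selected) |
                 (comp$pair_b == pid & comp$pair_a %in% selected), , drop = FALSE]
      if (nrow(pc) && any(!is.na(pc$p_value) & pc$p_value < p_threshold)) {
        candidate <- pid
        if (any(!is.na(pc$p_value) & pc$p_value >= p_threshold))
          warning("pair ", pid, " admitted but inconsistent (p >= ",
                  p_threshold, ") with some selected pair", call. = FALSE)
        break
      }
    }
    if (is.null(candidate)) break
    selected <- c(selected, candidate)
  }

  excl_ids <- setdiff(pairs$pair_id, selected)
  excluded <- pairs[match(excl_ids, pairs$pair_id), , drop = FALSE]
  if (nrow(excluded)) {
    sel_rows <- pairs[match(selected, pairs$pair_id), , drop = FALSE]
    excluded$reason <- vapply(seq_len(nrow(excluded)), function(i) {
      indep_all <- all(vapply(seq_len(nrow(sel_rows)), function(j)
        pairs_independent(excluded[i, ], sel_rows[j, ]), logical(1L)))
      if (indep_all) "inconsistent" else "not-independent"
    }, character(1L))
  } else {
    excluded$reason <- character(0)
  }
  rownames(excluded) <- NULL

  structure(list(selected = pairs[match(selected, pairs$pair_id), , drop = FALSE],
                 excluded = excluded, comparisons = comp, ranked = ranked,
                 top_n = as.integer(top_n), score_rule = toupper(score)),
            class = "pair_selection")
}

#' @export
print.pair_selection <- function(x, ...) {
  cat(sprintf("pair_selection (%s, top %d genes): %d selected, %d excluded\n",
              x$score_rule, x$top_n, nrow(x$selected), nrow(x$excluded)))
  cat("selected:", paste(x$selected$pair_id, collapse = ", "), "\n")
  if (nrow(x$excluded))
    cat("excluded:", paste0(x$excluded$pair_id, " (", x$excluded$reason, ")",
                            collapse = ", "), "\n")
  invisible(x)
}

#' Per-duo consistency report
#'
#' Tabulates every independent-duo comparison (samples, K shared genes, S
#' same-direction genes, consistency score in percent, binomial p) in the
#' layout used to report reproducibility of the top-ranked genes.
#'
#' @param x a `pair_selection`.
#' @param path optional TSV output path.
#' @return The report data frame, invisibly if `path` is given.
#' @export
pair_report <- function(x, path = NULL) {
  comp <- x$comparisons
  rep <- data.frame(
    comparison = paste(comp$pair_a, "vs", comp$pair_b),
    K = comp$k, S = comp$s,
    `S/K(%)` = round(100 * comp$score, 2),
    p = vapply(comp$p_value, format_p, character(1L)),
    check.names = FALSE, stringsAsFactors = FALSE)
  if (is.null(path)) return(rep)
  utils::write.table(rep, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(rep)
}
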