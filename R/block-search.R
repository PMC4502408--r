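#' Search parameters for the block-wise consistency search
#'
#' @param ct consistency threshold in (0.5, 1]; a block of list A is accepted
#'   when the direction-consistency of its genes shared with the cumulative
#'   top prefix of list B reaches `ct`. Default 0.90.
#' @param init_step initial block size k (>= 2 genes), default 300. Large
#'   steps let weakly consistent genes at the bottom of a block ride along
#'   with the strong top; very small steps make the score unstable and stop
#'   the search early.
#' @param min_step smallest block size the step-halving may reach (default 1;
#'   halving always stops before blocks of fewer than 2 genes).
#' @return A `search_params` list.
#' @export
search_params <- function(ct = 0.90, init_step = 300L, min_step = 1L) {
  if (!is.numeric(ct) || length(ct) != 1L || ct <= 0.5 || ct > 1)
    stop("`ct` must lie in (0.5, 1]", call. = FALSE)
  if (!is.numeric(init_step) || length(init_step) != 1L || init_step < 2)
    stop("`init_step` must be an integer >= 2", call. = FALSE)
  if (!is.numeric(min_step) || length(min_step) != 1L || min_step < 1)
    stop("`min_step` must be an integer >= 1", call. = FALSE)
  structure(list(ct = ct, init_step = as.integer(init_step),
                 min_step = as.integer(min_step)),
            class = "search_params")
}

#' Block-wise consistency search over two ranked lists (degAB)
#'
#' Finds the genes of ranked list A that are reproducibly dysregulated, in the
#' same direction, within the top-ranked region of list B. Both lists are
#' partitioned into consecutive blocks of `init_step` genes (a shorter
#' trailing block keeps the remainder). Walking down list A, block A(i) is
#' compared against the cumulative prefix B(1)..B(i): the consistency score of
#' their shared genes must reach `ct` for the block to be accepted, in which
#' case its shared same-direction genes are collected. On the first failing
#' block m the search looks one block ahead — a pass of A(m+1) vs B(1)..B(m+1)
#' resumes the walk there (block m itself is not admitted, guarding against a
#' small unstable overlap ending the search early). If the lookahead also
#' fails, the step is halved and both lists are re-partitioned from the start
#' of block m with the finer step, recovering any consistently ranked genes at
#' the top of the failed block; halving repeats until blocks would shrink
#' below 2 genes (or below `min_step`), or until a failing block shares no
#' gene with the prefix.
#'
#' @param list_a,list_b `ranked_list` objects (data frames with `gene_id` and
#'   `direction`, ordered by decreasing score magnitude).
#' @param params a [search_params] object.
#' @param trace logical; if `TRUE`, attach a data frame logging every block
#'   decision (attribute `"trace"`).
#' @return Named character vector of directions (`"up"`/`"down"`) for the
#'   genes of A accepted as reproducible in B.
#' @export
block_search <- function(list_a, list_b, params = search_params(), trace = FALSE) {
  stopifnot(inherits(params, "search_params"))
  if (nrow(list_a) == 0L || nrow(list_b) == 0L)
    stop("both ranked lists must be non-empty", call. = FALSE)
  ga <- list_a$gene_id
  gb <- list_b$gene_id
  da <- stats::setNames(list_a$direction, list_a$gene_id)
  db <- stats::setNames(list_b$direction, list_b$gene_id)
  na <- length(ga); nb <- length(gb)
  rank_b <- stats::setNames(seq_len(nb), gb)

  accepted <- character(0)
  log_rows <- list()
  off <- 0L                       # genes of A already partitioned at coarser steps
  k <- params$init_step
  kmin <- max(params$min_step, 2L)

  eval_block <- function(a_lo, a_hi, b_hi) {
    # consistency of A[a_lo:a_hi] against the cumulative prefix B[1:b_hi]
    blk <- ga[a_lo:a_hi]
    rb <- rank_b[blk]
    shared <- blk[!is.na(rb) & rb <= b_hi]
    kk <- length(shared)
    ss <- if (kk) sum(da[shared] == db[shared]) else 0L
    list(k = kk, s = ss, score = if (kk) ss / kk else NA_real_, shared = shared)
  }
  block_at <- function(t) {
    a_lo <- off + (t - 1L) * k + 1L
    if (a_lo > na) return(NULL)
    list(a_lo = a_lo, a_hi = min(off + t * k, na), b_hi = min(off + t * k, nb))
  }
  note <- function(t, ev, action) {
    log_rows[[length(log_rows) + 1L]] <<- data.frame(
      offset = off, step = k, block = t, k_shared = ev$k, s = ev$s,
      score = ev$score, action = action, stringsAsFactors = FALSE)
  }

  done <- FALSE
  while (!done) {
    t <- 1L
    repeat {
      blk <- block_at(t)
      if (is.null(blk)) { done <- TRUE; break }   # walked off the end of A
      ev <- eval_block(blk$a_lo, blk$a_hi, blk$b_hi)
      pass <- ev$k > 0L && ev$score >= params$ct
      if (pass) {
        note(t, ev, "accept")
        agree <- ev$shared[da[ev$shared] == db[ev$shared]]
        accepted <- union(accepted, agree)
        t <- t + 1L
        next
      }
      # lookahead one block to avoid early termination on an unstable score
      la <- block_at(t + 1L)
      if (!is.null(la)) {
        ev2 <- eval_block(la$a_lo, la$a_hi, la$b_hi)
        if (ev2$k > 0L && ev2$score >= params$ct) {
          note(t, ev, "lookahead-skip")
          note(t + 1L, ev2, "accept")
          agree <- ev2$shared[da[ev2$shared] == db[ev2$shared]]
          accepted <- union(accepted, agree)
          t <- t + 2L
          next
        }
      }
      # no overlap left to recover: exit; otherwise halve the step and
      # re-partition both lists from the start of the failed block
      if (ev$k == 0L) { note(t, ev, "exit-no-overlap"); done <- TRUE; break }
      off <- off + (t - 1L) * k
      k <- k %/% 2L
      note(t, ev, if (k < kmin) "exit-min-step" else "halve")
      if (k < kmin) done <- TRUE
      break
    }
  }

  out <- da[accepted]
  if (trace)
    attr(out, "trace") <- if (length(log_rows)) do.call(rbind, log_rows) else
      data.frame(offset = integer(0), step = integer(0), block = integer(0),
                 k_shared = integer(0), s = integer(0), score = numeric(0),
                 action = character(0))
  out
}

#' Reproducible DE genes for one duo of independent sample pairs
#'
#' Runs the block-wise search in both orientations — genes of A reproducible
#' in the top of B (degAB) and genes of B reproducible in the top of A
#' (degBA) — and merges the two. Membership requires identical direction in
#' both lists, so the merge cannot create a direction conflict (asserted).
#'
#' @inheritParams block_search
#' @return A `de_gene_set`: list with `genes` (data frame `gene_id`,
#'   `direction`, `n_support`), `dropped_conflicts` (character vector) and
#'   `params`.
#' @export
reproducible_de <- function(list_a, list_b, params = search_params()) {
  ab <- block_search(list_a, list_b, params)
  ba <- block_search(list_b, list_a, params)
  both <- intersect(names(ab), names(ba))
  stopifnot(all(ab[both] == ba[both]))
  merged <- c(ab, ba[setdiff(names(ba), names(ab))])
  new_de_gene_set(merged, rep(1L, length(merged)), character(0), params)
}

#' Merge reproducible DE genes across all duos of sample pairs
#'
#' Applies [reproducible_de()] to every unordered duo of ranked lists (one
#' list per selected independent sample pair) and merges the per-duo results,
#' deleting any gene whose dysregulation direction differs between two duo
#' results.
#'
#' @param ranked_lists list of >= 2 `ranked_list` objects from pairwise
#'   independent sample pairs.
#' @inheritParams block_search
#' @return A `de_gene_set`; `genes$n_support` counts the duo results each
#'   gene appeared in, `dropped_conflicts` lists direction-conflicted genes.
#' @export
multi_pair_de <- function(ranked_lists, params = search_params()) {
  if (!is.list(ranked_lists) || length(ranked_lists) < 2L)
    stop("need at least two ranked lists", call. = FALSE)
  duos <- utils::combn(length(ranked_lists), 2L)
  results <- lapply(seq_len(ncol(duos)), function(j)
    reproducible_de(ranked_lists[[duos[1L, j]]], ranked_lists[[duos[2L, j]]], params))
  all_dirs <- lapply(results, function(r)
    stats::setNames(r$genes$direction, r$genes$gene_id))
  genes <- sort(unique(unlist(lapply(all_dirs, names))))
  per_gene <- lapply(genes, function(g)
    unname(unlist(lapply(all_dirs, function(d) d[g][!is.na(d[g])]))))
  names(per_gene) <- genes
  conflicted <- genes[vapply(per_gene, function(d) length(unique(d)) > 1L, logical(1L))]
  kept <- setdiff(genes, conflicted)
  dirs <- vapply(per_gene[kept], `[[`, character(1L), 1L)
  support <- vapply(per_gene[kept], length, integer(1L))
  new_de_gene_set(stats::setNames(dirs, kept), support, conflicted, params)
}

new_de_gene_set <- function(dirs, support, conflicts, params) {
  if (length(dirs) == 0L) dirs <- stats::setNames(character(0), character(0))
  ord <- order(names(dirs))
  genes <- data.frame(gene_id = names(dirs)[ord],
                      direction = unname(dirs)[ord],
                      n_support = unname(support)[ord],
                      stringsAsFactors = FALSE)
  rownames(genes) <- NULL
  structure(list(genes = genes, dropped_conflicts = sort(conflicts),
                 params = params),
            class = "de_gene_set")
}

#' @export
print.de_gene_set <- function(x, ...) {
  cat(sprintf("de_gene_set: %d genes (%d up, %d down), %d direction conflict(s) dropped\n",
              nrow(x$genes), sum(x$genes$direction == "up"),
              sum(x$genes$direction == "down"), length(x$dropped_conflicts)))
  invisible(x)
}

#' Write a DE gene set (and its conflicts) as TSV
#'
#' @param x a `de_gene_set`.
#' @param path output path for the gene table.
#' @param conflicts_path optional path for the dropped direction conflicts.
#' @return `path`, invisibly.
#' @export
write_de_genes <- function(x, path, conflicts_path = NULL) {
  utils::write.table(x$genes, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(conflicts_path))
    utils::write.table(data.frame(gene_id = x$dropped_conflicts),
                       conflicts_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
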