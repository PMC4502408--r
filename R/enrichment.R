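#' Upper-tail hypergeometric enrichment p-value
#'
#' Probability of observing at least `x` genes of a pathway among `k` DE
#' genes drawn from a universe of `n` genes of which `m` belong to the
#' pathway: P(count >= x) = 1 - sum_{i=0}^{x-1} C(m,i) C(n-m,k-i) / C(n,k).
#'
#' @param x DE genes inside the set (0 <= x <= min(m, k)).
#' @param m set size; `k` DE list size; `n` universe size.
#' @param k,n see above.
#' @return The upper-tail p-value (exactly 1 when `x = 0`).
#' @export
hypergeom_test <- function(x, m, k, n) {
  if (any(c(x, m, k, n) < 0) || m > n || k > n || x > min(m, k))
    stop("inconsistent counts: need 0 <= x <= min(m, k) and m, k <= n", call. = FALSE)
  stats::phyper(x - 1, m, n - m, k, lower.tail = FALSE)
}

#' Read a GMT gene-set collection
#'
#' One set per line: `set_id<TAB>description<TAB>member1<TAB>member2...`.
#'
#' @param path GMT file path.
#' @return A named list of character vectors of member gene ids, with a
#'   `description` attribute (named character vector).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty gene-set collection", call. = FALSE)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3L
  if (any(bad))
    stop("malformed GMT line (need id, description, >= 1 member): line ",
         which(bad)[1L], call. = FALSE)
  ids <- vapply(parts, `[[`, character(1L), 1L)
  if (anyDuplicated(ids)) stop("duplicate set id in GMT", call. = FALSE)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- ids
  attr(sets, "description") <- stats::setNames(
    vapply(parts, `[[`, character(1L), 2L), ids)
  sets
}

#' Hypergeometric over-representation of a DE gene list
#'
#' Tests every gene set for over-representation of the DE genes within the
#' gene universe (all measured genes after preprocessing) and adjusts the
#' p-values with the Benjamini-Hochberg step-up procedure. The number of
#' tests is the number of sets with at least one universe member; only sets
#' actually hit by a DE gene (X >= 1) are reported. DE genes outside the
#' universe are dropped with a message.
#'
#' @param de DE genes: a `de_gene_set` or a character vector of gene ids.
#' @param gene_sets named list of member-id vectors (see [read_gmt()]).
#' @param universe character vector of background gene ids.
#' @param fdr_level significance level on the adjusted p (default 0.05).
#' @return Data frame with one row per hit set: `set_id`, `description`,
#'   `X`, `M`, `K`, `N`, `p_value`, `fdr`, `significant`, ordered by p-value.
#' @export
enrich <- function(de, gene_sets, universe, fdr_level = 0.05) {
  if (inherits(de, "de_gene_set")) de <- de$genes$gene_id
  de <- unique(as.character(de))
  universe <- unique(as.character(universe))
  if (!is.list(gene_sets) || length(gene_sets) == 0L)
    stop("empty gene-set collection", call. = FALSE)
  outside <- setdiff(de, universe)
  if (length(outside)) {
    message(length(outside), " DE gene(s) outside the universe dropped")
    de <- intersect(de, universe)
  }
  desc <- attr(gene_sets, "description")
  members <- lapply(gene_sets, intersect, universe)
  testable <- lengths(members) >= 1L
  n_tests <- sum(testable)
  if (n_tests == 0L) stop("no gene set overlaps the universe", call. = FALSE)
  members <- members[testable]
  n <- length(universe)
  k <- length(de)
  rows <- data.frame(
    set_id = names(members),
    description = if (is.null(desc)) NA_character_ else unname(desc[names(members)]),
    X = vapply(members, function(mm) length(intersect(mm, de)), integer(1L)),
    M = lengths(members), K = k, N = n,
    stringsAsFactors = FALSE)
  rows$p_value <- mapply(hypergeom_test, rows$X, rows$M,
                         MoreArgs = list(k = k, n = n))
  # BH over all testable sets, even those reported away below
  rows$fdr <- stats::p.adjust(rows$p_value, method = "BH", n = n_tests)
  rows <- rows[rows$X >= 1L, , drop = FALSE]
  rows$significant <- rows$fdr < fdr_level
  rows <- rows[order(rows$p_value, rows$set_id), , drop = FALSE]
  rownames(rows) <- NULL
  rows
}
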