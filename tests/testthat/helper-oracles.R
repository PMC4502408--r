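# Independent reference implementations used as oracles. These are literal,
# unoptimised transcriptions kept free of any code shared with the package.

# Upper binomial tail P(X >= s) for X ~ Bin(k, pe).
# Exhaustive term-by-term summation (exact for small k); log-space
# log-sum-exp for large k where direct terms underflow.
oracle_binom_tail <- function(s, k, pe = 0.5) {
  if (s <= 0) return(1)
  i <- s:k
  sum(choose(k, i) * pe^i * (1 - pe)^(k - i))
}

oracle_binom_tail_log10 <- function(s, k, pe = 0.5) {
  if (s <= 0) return(0)
  i <- s:k
  lt <- lchoose(k, i) + i * log(pe) + (k - i) * log1p(-pe)
  m <- max(lt)
  (m + log(sum(exp(lt - m)))) / log(10)
}

# Literal transcription of the block-wise consistency search: explicit block
# lists, explicit gene-by-gene agreement counting. Decision rules (lookahead
# does not admit the failed block; halving re-partitions both lists from the
# start of the failed block; exit when a failing block shares no gene with
# the prefix or when the halved step drops below max(min_step, 2)) mirror the
# package's documented conventions.
oracle_block_search <- function(ga, da, gb, db, ct, k0, min_step = 1) {
  accepted <- character(0)
  off <- 0
  k <- k0
  kmin <- max(min_step, 2)
  repeat {
    # explicit partition of A[off+1 .. end] into blocks of k (short tail kept)
    rest <- if (off < length(ga)) ga[(off + 1):length(ga)] else character(0)
    blocks <- list()
    while (length(rest) > 0) {
      take <- min(k, length(rest))
      blocks[[length(blocks) + 1]] <- rest[seq_len(take)]
      rest <- rest[-seq_len(take)]
    }
    consis <- function(t) {
      blk <- blocks[[t]]
      b_hi <- min(off + t * k, length(gb))
      prefix <- gb[seq_len(b_hi)]
      sh <- character(0)
      agree <- character(0)
      for (g in blk) {
        if (g %in% prefix) {
          sh <- c(sh, g)
          if (da[[g]] == db[[g]]) agree <- c(agree, g)
        }
      }
      list(k = length(sh), score = if (length(sh)) length(agree) / length(sh) else NA,
           agree = agree)
    }
    t <- 1
    state <- "walk"
    while (t <= length(blocks)) {
      ev <- consis(t)
      if (ev$k > 0 && ev$score >= ct) {
        accepted <- union(accepted, ev$agree)
        t <- t + 1
        next
      }
      if (t + 1 <= length(blocks)) {
        ev2 <- consis(t + 1)
        if (ev2$k > 0 && ev2$score >= ct) {
          accepted <- union(accepted, ev2$agree)
          t <- t + 2
          next
        }
      }
      if (ev$k == 0) return(da[accepted])      # no overlap left to recover
      state <- "halve"
      break
    }
    if (state != "halve") return(da[accepted]) # walked off the end of A
    off <- off + (t - 1) * k
    k <- k %/% 2
    if (k < kmin) return(da[accepted])
  }
}

# Build a ranked_list directly from an ordered gene/direction specification,
# with strictly decreasing synthetic magnitudes so the stated order is kept.
ranked_fixture <- function(genes, dirs, pair_id = "fx", rule = "PD") {
  stopifnot(length(genes) == length(dirs))
  mag <- seq(length(genes), 1)
  structure(
    data.frame(gene_id = genes, score = ifelse(dirs == "up", mag, -mag),
               magnitude = mag, direction = dirs, stringsAsFactors = FALSE),
    pair_id = pair_id, score_rule = rule, class = c("ranked_list", "data.frame"))
}

# Random direction-annotated ranked-list duo over a shared gene universe.
random_list_duo <- function(n_universe, n_a, n_b) {
  universe <- sprintf("g%02d", seq_len(n_universe))
  ga <- sample(universe, n_a)
  gb <- sample(universe, n_b)
  list(a = ranked_fixture(ga, sample(c("up", "down"), n_a, replace = TRUE)),
       b = ranked_fixture(gb, sample(c("up", "down"), n_b, replace = TRUE)))
}

# Expression fixture from named sample columns; phenotype taken from the
# first letter of each sample id (R1 -> R, S2 -> S).
mk_expr <- function(..., genes = NULL) {
  vals <- cbind(...)
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(vals)))
  rownames(vals) <- genes
  ph <- setNames(substr(colnames(vals), 1, 1), colnames(vals))
  expr_matrix(vals, ph)
}

# Tiny deterministic expression fixture: 2 R + 2 S samples, identical
# replicates within phenotype, planted linear differences.
tiny_expr <- function() {
  vals <- cbind(R1 = c(100, 40, 55, 10), R2 = c(100, 40, 55, 10),
                S1 = c(80, 50, 53, 10), S2 = c(80, 50, 53, 10))
  rownames(vals) <- paste0("g", 1:4)
  expr_matrix(vals, c(R1 = "R", R2 = "R", S1 = "S", S2 = "S"))
}
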