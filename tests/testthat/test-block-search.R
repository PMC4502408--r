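test_that("identical lists are returned in full; disjoint lists give nothing", {
  genes <- sprintf("g%04d", 1:1000)
  dirs <- rep(c("up", "down"), 500)
  rl <- ranked_fixture(genes, dirs)
  out <- block_search(rl, rl, search_params(ct = 0.9, init_step = 300))
  expect_setequal(names(out), genes)
  expect_identical(unname(out[genes]), dirs)
  other <- ranked_fixture(sprintf("h%03d", 1:100), rep("up", 100))
  expect_length(block_search(rl, other), 0L)
  expect_error(block_search(rl[0, ], rl), "non-empty")
})

test_that("a failing block is skipped on lookahead success and recovered only by halving", {
  # 40 genes, step 10: block 1 consistent, block 2 at 80% (fails), block 3
  # consistent (lookahead passes), block 4 at 80% with nothing after it
  genes <- sprintf("g%02d", 1:40)
  da <- setNames(rep("up", 40), genes)
  db <- da
  db[c(13, 16)] <- "down"   # block 2 of A shares 10 genes, 8 agree -> 0.8
  db[c(33, 36)] <- "down"   # block 4 likewise
  la <- ranked_fixture(genes, unname(da))
  lb <- ranked_fixture(genes, unname(db[genes]))
  p <- search_params(ct = 0.9, init_step = 10)
  out <- block_search(la, lb, p, trace = TRUE)
  tr <- attr(out, "trace")
  expect_identical(tr$action[1:3], c("accept", "lookahead-skip", "accept"))
  expect_true("halve" %in% tr$action)
  # block 1 and the lookahead block 3 are admitted; block 2 is NOT admitted on
  # lookahead success; halving at block 4 recovers only its clean leading run
  # (g31, g32: the 2-gene sub-blocks before the first flip at g33)
  expect_setequal(names(out), c(genes[1:10], genes[21:30], "g31", "g32"))
  expect_false(any(genes[11:20] %in% names(out)))
  expect_identical(unname(out[names(out)]), unname(da[names(out)]))
  # oracle agreement on this engineered instance
  orc <- oracle_block_search(genes, da, genes, db, 0.9, 10)
  expect_setequal(names(out), names(orc))
})

test_that("the search equals a literal transcription of the block procedure on random instances", {
  set.seed(100)
  n_cases <- 500
  for (case in seq_len(n_cases)) {
    n_uni <- sample(10:60, 1)
    duo <- random_list_duo(n_uni, sample(5:n_uni, 1), sample(5:n_uni, 1))
    k0 <- sample(2:10, 1)
    ct <- sample(c(0.6, 0.7, 0.75, 0.8, 0.9, 0.95), 1)
    impl <- block_search(duo$a, duo$b, search_params(ct = ct, init_step = k0))
    orc <- oracle_block_search(
      duo$a$gene_id, setNames(duo$a$direction, duo$a$gene_id),
      duo$b$gene_id, setNames(duo$b$direction, duo$b$gene_id), ct, k0)
    expect_identical(impl[order(names(impl))], orc[order(names(orc))],
                     label = paste("case", case))
  }
})

test_that("membership requires presence in both lists with one direction", {
  set.seed(17)
  for (case in 1:25) {
    duo <- random_list_duo(40, 30, 30)
    de <- reproducible_de(duo$a, duo$b, search_params(ct = 0.7, init_step = 5))
    da <- setNames(duo$a$direction, duo$a$gene_id)
    db <- setNames(duo$b$direction, duo$b$gene_id)
    for (i in seq_len(nrow(de$genes))) {
      g <- de$genes$gene_id[i]
      expect_true(g %in% names(da) && g %in% names(db))
      expect_identical(da[[g]], db[[g]])
      expect_identical(de$genes$direction[i], da[[g]])
    }
  }
})

test_that("random direction noise at the null yields an empty or near-empty set", {
  set.seed(55)
  admitted <- replicate(100, {
    genes <- sprintf("g%03d", 1:200)
    a <- ranked_fixture(sample(genes), sample(c("up", "down"), 200, TRUE))
    b <- ranked_fixture(sample(genes), sample(c("up", "down"), 200, TRUE))
    nrow(reproducible_de(a, b, search_params(ct = 0.9, init_step = 50))$genes)
  })
  # step-halving lets the odd 2-gene sub-block pass by chance, so a handful
  # of genes can slip through; the admission rate stays a small fraction
  expect_lte(mean(admitted) / 200, 0.05)
  expect_gte(mean(admitted <= 10), 0.85)
  expect_gte(mean(admitted == 0), 0.25)
})

test_that("direction conflicts between duo results are deleted at the merge", {
  genes <- sprintf("g%02d", 1:20)
  dirs <- rep("up", 20)
  l1 <- ranked_fixture(genes, dirs)
  l2 <- ranked_fixture(genes, dirs)
  flipped <- replace(dirs, 1:20, "down")
  l3 <- ranked_fixture(genes, flipped)
  out <- multi_pair_de(list(l1, l2, l3), search_params(ct = 0.9, init_step = 5))
  # duo (1,2) admits everything as up; duos with l3 admit nothing (0% score),
  # so no conflicts arise and all genes survive
  expect_setequal(out$genes$gene_id, genes)
  expect_length(out$dropped_conflicts, 0L)
  # force a genuine conflict: l4 agrees with l3 (down) on the same genes
  l4 <- ranked_fixture(genes, flipped)
  out2 <- multi_pair_de(list(l1, l2, l3, l4), search_params(ct = 0.9, init_step = 5))
  expect_setequal(out2$dropped_conflicts, genes)
  expect_equal(nrow(out2$genes), 0L)
  expect_error(multi_pair_de(list(l1)), "at least two")
})

test_that("three identical lists merge to the full set with support counts", {
  genes <- sprintf("g%02d", 1:30)
  dirs <- rep(c("up", "down"), 15)
  ls <- replicate(3, ranked_fixture(genes, dirs), simplify = FALSE)
  out <- multi_pair_de(ls, search_params(ct = 0.9, init_step = 10))
  expect_setequal(out$genes$gene_id, genes)
  expect_true(all(out$genes$n_support == 3L))
  expect_length(out$dropped_conflicts, 0L)
})
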