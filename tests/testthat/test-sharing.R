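test_that("presence uses a strict relative-abundance threshold", {
  m <- cbind(s1 = c(1, 2, 9997), s2 = c(0, 5, 9995))
  ct <- count_table(m, otu_ids = c("A", "B", "C"))
  pres <- presence_matrix(ct, threshold = 1e-4)
  # count 1 of 10,000 is exactly 0.01% -> absent under the strict rule
  expect_false(pres["A", "s1"])
  expect_true(pres["B", "s1"])
  expect_error(presence_matrix(count_table(cbind(s1 = 0L), otu_ids = "A")),
               "zero-total")

  # brute-force oracle on random tables; monotone in the threshold
  set.seed(41)
  for (r in 1:10) {
    ct <- random_count_table(20, 6)
    pres <- presence_matrix(ct, threshold = 0.02)
    brute <- ct$counts
    for (j in seq_len(ncol(brute))) {
      brute[, j] <- ct$counts[, j] / sum(ct$counts[, j]) > 0.02
    }
    expect_identical(pres, brute > 0)
    tighter <- presence_matrix(ct, threshold = 0.05)
    expect_true(all(tighter <= pres))
  }
})

test_that("shared counts are symmetric intersections bounded by richness", {
  m <- cbind(x = c(5, 5, 5, 0), y = c(0, 9, 9, 9), z = c(0, 0, 0, 0) + 1)
  ct <- count_table(m, otu_ids = c("A", "B", "C", "D"))
  pres <- presence_matrix(ct, threshold = 0)
  expect_identical(shared_count(pres, "x", "y"), 2L)
  expect_identical(shared_count(pres, "x", "y"), shared_count(pres, "y", "x"))
  expect_identical(shared_count(pres, "x", "x"), sum(pres[, "x"]))
  expect_lte(shared_count(pres, "x", "z"), min(sum(pres[, "x"]),
                                               sum(pres[, "z"])))
  expect_error(shared_count(pres, "x", "nope"), "unknown")

  # disjoint presence sets share nothing
  ct2 <- count_table(cbind(a = c(4, 0), b = c(0, 4)), otu_ids = c("A", "B"))
  expect_identical(shared_count(presence_matrix(ct2, 0), "a", "b"), 0L)
})

test_that("pair sets link children to their own mothers within window and source", {
  meta <- data.frame(
    sample_id = c("c1", "c2", "c3", "m1", "m2", "k1", "milk1"),
    subject_id = c("C1", "C2", "C3", "M1", "M2", "M3", "M1"),
    mother_subject_id = c("M1", "M2", NA, NA, NA, NA, NA),
    age_days = c(2L, 4L, 3L, NA, NA, NA, NA),
    age_bin = c("DOL 0-5", "DOL 0-5", "DOL 0-5", "Mother-wk1", "Mother-wk1",
                "Mother-wk1", "Milk-wk1"),
    sample_type = c(rep("child_stool", 3), rep("mother_stool", 3),
                    "breast_milk"),
    domain = "bacteria_16S", batch = c(rep("stool", 6), "milk"),
    stringsAsFactors = FALSE
  )
  ps <- build_pair_set(meta, "mother_stool", "wk1")
  expect_identical(ps$related$child_sample, c("c1", "c2"))
  expect_identical(ps$related$mother_sample, c("m1", "m2"))
  # 3 children x 3 mothers minus 2 related
  expect_identical(nrow(ps$unrelated), 7L)
  expect_identical(nrow(merge(ps$related, ps$unrelated)), 0L)

  ps_milk <- build_pair_set(meta, "breast_milk", "wk1")
  expect_identical(ps_milk$related$mother_sample, "milk1")
  expect_error(build_pair_set(meta, "mother_stool", "wk4"), "wk4")
})

test_that("an exchangeable unrelated pool yields a null sharing comparison", {
  # unrelated pool constructed from the same composition as related pairs
  set.seed(42)
  n_otu <- 60
  n <- 10
  mk <- function(prefix) {
    m <- matrix(rpois(n_otu * n, 3), n_otu, n)
    colnames(m) <- paste0(prefix, seq_len(n))
    m
  }
  m <- cbind(mk("c"), mk("m"))
  ct <- count_table(m, otu_ids = sprintf("O%02d", 1:n_otu))
  pres <- presence_matrix(ct, threshold = 0)
  pairs <- structure(list(
    related = data.frame(child_sample = paste0("c", 1:n),
                         mother_sample = paste0("m", 1:n),
                         stringsAsFactors = FALSE),
    unrelated = expand.grid(child_sample = paste0("c", 1:n),
                            mother_sample = paste0("m", 1:n),
                            stringsAsFactors = FALSE)[-(seq_len(n) * (n + 1) - n), ],
    source = "mother_stool", window = "wk1"
  ), class = "pair_set")
  res <- related_vs_unrelated(pres, pairs, n_draws = 5, seed = 7)
  expect_gt(res$p, 0.1)
  expect_identical(dim(res$unrelated_counts), c(10L, 5L))

  # draw reproducibility: identical seed, identical subsets and p-values
  res2 <- related_vs_unrelated(pres, pairs, n_draws = 5, seed = 7)
  expect_identical(res$unrelated_counts, res2$unrelated_counts)
  expect_identical(res$raw_p, res2$raw_p)

  # error paths
  small <- pairs
  small$related <- small$related[1:2, ]
  expect_error(related_vs_unrelated(pres, small), "fewer than 3")
  tiny <- pairs
  tiny$unrelated <- tiny$unrelated[1:4, ]
  expect_error(related_vs_unrelated(pres, tiny), "fewer unrelated")
})

test_that("top shared OTUs match a brute-force pair loop with abundance annotation", {
  set.seed(43)
  ct <- random_count_table(25, 12)
  pres <- presence_matrix(ct, threshold = 1e-3)
  pairs <- structure(list(
    related = data.frame(child_sample = ct$sample_ids[1:5],
                         mother_sample = ct$sample_ids[6:10],
                         stringsAsFactors = FALSE),
    unrelated = data.frame(child_sample = character(),
                           mother_sample = character()),
    source = "mother_stool", window = "wk1"
  ), class = "pair_set")
  top <- top_shared_otus(pres, pairs, ct)
  brute <- sapply(ct$otu_ids, function(o) {
    sum(vapply(1:5, function(k) {
      pres[o, pairs$related$child_sample[k]] &&
        pres[o, pairs$related$mother_sample[k]]
    }, logical(1)))
  })
  expect_equal(stats::setNames(top$n_pairs, top$otu_id),
               brute[order(-brute, names(brute))])
  expect_true(!is.unsorted(rev(top$n_pairs)))

  # an OTU present in both members of every pair tops the ranking
  m <- ct$counts
  m[1, ] <- 5000L
  ct2 <- count_table(m)
  top2 <- top_shared_otus(presence_matrix(ct2, 1e-3), pairs, ct2)
  expect_identical(top2$otu_id[1], ct2$otu_ids[1])
  expect_equal(top2$n_pairs[1], 5)
})
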