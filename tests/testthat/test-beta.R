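test_that("Bray-Curtis matches its closed forms and the brute-force oracle", {
  ct <- count_table(cbind(a = c(2, 0, 1), b = c(1, 1, 0), c = c(2, 0, 1)),
                    otu_ids = paste0("O", 1:3))
  d <- bray_curtis(ct)
  expect_equal(d["a", "b"], 0.6, tolerance = 1e-12)
  expect_equal(d["a", "c"], 0)

  # disjoint supports are maximally dissimilar
  ct2 <- count_table(cbind(x = c(5, 0), y = c(0, 7)), otu_ids = c("A", "B"))
  expect_equal(bray_curtis(ct2)["x", "y"], 1)

  expect_error(bray_curtis(count_table(cbind(s1 = c(0, 0), s2 = c(1, 1)))),
               "s1")

  set.seed(31)
  for (r in 1:10) {
    ct <- random_count_table(15, 7)
    d <- bray_curtis(ct)
    expect_equal(d, bray_brute(ct$counts), tolerance = 1e-12)
    expect_equal(d, t(d), tolerance = 1e-15)
    expect_true(all(d >= 0 & d <= 1))
    expect_true(all(diag(d) == 0))
  }
})

test_that("pseudo-F agrees with the explicit trace formula and vegan", {
  set.seed(32)
  for (n in c(6, 8)) {
    ct <- random_count_table(20, n)
    dm <- bray_curtis(ct)
    z <- rnorm(n)
    fit <- permanova_continuous(dm, z, n_perm = 49, seed = 1)
    brute <- permanova_brute(dm, z)
    expect_equal(fit$pseudo_f, brute$f, tolerance = 1e-10)
    expect_equal(fit$r_squared, brute$r2, tolerance = 1e-10)
    # SS additivity: R2 consistent with SS_model / SS_total
    expect_equal(brute$ss_model + (brute$ss_total - brute$ss_model),
                 brute$ss_total, tolerance = 1e-9)
    # independent implementation: vegan adonis2 on the same inputs
    df <- data.frame(z = z)
    va <- vegan::adonis2(stats::as.dist(dm) ~ z, data = df, permutations = 2)
    expect_equal(fit$pseudo_f, va$F[1], tolerance = 1e-8)
    expect_equal(fit$r_squared, va$R2[1], tolerance = 1e-8)
  }
})

test_that("permutation p equals exhaustive enumeration for small n", {
  set.seed(33)
  ct <- random_count_table(12, 5)
  dm <- bray_curtis(ct)
  z <- c(2, 9, 4, 7, 1)
  fit <- permanova_continuous(dm, z, n_perm = 150, seed = 4)
  expect_identical(fit$method, "exhaustive")
  expect_identical(fit$n_permutations, 120L)
  expect_equal(fit$p_value, permanova_enum_p(dm, z), tolerance = 1e-12)
})

test_that("a 1-D gradient is nearly fully explained with p at the floor", {
  z <- seq_len(10)
  dm <- abs(outer(z, z, "-")) / max(abs(outer(z, z, "-")))
  dimnames(dm) <- list(paste0("s", z), paste0("s", z))
  fit <- permanova_continuous(dm, z, n_perm = 199, seed = 5)
  expect_gt(fit$r_squared, 0.9)
  expect_equal(fit$p_value, 1 / (199 + 1), tolerance = 1e-12)
})

test_that("r-squared is invariant under affine covariate rescaling", {
  set.seed(34)
  ct <- random_count_table(20, 9)
  dm <- bray_curtis(ct)
  z <- rnorm(9)
  f1 <- permanova_continuous(dm, z, n_perm = 19, seed = 1)
  f2 <- permanova_continuous(dm, 1000 + 3.7 * z, n_perm = 19, seed = 1)
  expect_equal(f1$r_squared, f2$r_squared, tolerance = 1e-10)
  expect_equal(f1$pseudo_f, f2$pseudo_f, tolerance = 1e-10)
  expect_error(permanova_continuous(dm, rep(1, 9), 19), "constant")
})

test_that("distances to the reference bin match a brute-force double loop", {
  set.seed(35)
  ct <- random_count_table(15, 12)
  dm <- bray_curtis(ct)
  meta <- data.frame(
    sample_id = ct$sample_ids,
    age_bin = rep(c("DOL 0-5", "MOL 22-26", "MOL 57-63"), each = 4),
    stringsAsFactors = FALSE
  )
  bd <- distances_to_reference(dm, meta, "MOL 57-63")
  ref <- meta$sample_id[meta$age_bin == "MOL 57-63"]
  for (b in names(bd$bins)) {
    ids <- meta$sample_id[meta$age_bin == b]
    brute <- c()
    for (i in ids) for (j in ref) brute <- c(brute, dm[i, j])
    expect_equal(sort(bd$bins[[b]]), sort(brute), tolerance = 1e-15)
    expect_length(bd$bins[[b]], length(ids) * length(ref))
  }
  # within-reference distances: each unordered pair exactly once
  expect_length(bd$reference_within, choose(length(ref), 2))

  # a reference bin of identical samples has all-zero within distances
  ct0 <- count_table(cbind(r1 = c(3, 1), r2 = c(3, 1), q = c(1, 5)),
                     otu_ids = c("A", "B"))
  meta0 <- data.frame(sample_id = c("r1", "r2", "q"),
                      age_bin = c("ref", "ref", "DOL 0-5"),
                      stringsAsFactors = FALSE)
  bd0 <- distances_to_reference(bray_curtis(ct0), meta0, "ref")
  expect_equal(bd0$reference_within, 0)
  expect_length(bd0$bins[["DOL 0-5"]], 2)
})

test_that("bin distance tests use the rank-sum null and Bonferroni scaling", {
  # identical multisets -> p = 1
  bd <- structure(list(reference_bin = "ref",
                       reference_within = c(.1, .2, .3, .4),
                       bins = list(binA = c(.1, .2, .3, .4))),
                  class = "bin_distances")
  res <- bin_distance_test(bd)
  expect_equal(res$raw_p, 1)

  # Bonferroni over 8 bins: raw 0.004 -> adjusted 0.032
  set.seed(36)
  bins <- lapply(1:8, function(i) runif(6))
  names(bins) <- paste0("bin", 1:8)
  bd8 <- structure(list(reference_bin = "ref", reference_within = runif(6),
                        bins = bins), class = "bin_distances")
  res8 <- bin_distance_test(bd8)
  expect_equal(res8$adjusted_p, pmin(1, res8$raw_p * 8))
  expect_true(all(res8$adjusted_p >= res8$raw_p))
})
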