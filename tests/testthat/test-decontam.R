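test_that("dispersion score matches the geometric-mean-plus-SD formula", {
  expect_identical(dispersion_score(c(0, 0, 0)), 0)
  expect_equal(dispersion_score(7), 7, tolerance = 1e-12)
  # independent arithmetic evaluation
  expect_equal(dispersion_score(c(50, 70)),
               (exp((log(51) + log(71)) / 2) - 1) + sd(c(50, 70)),
               tolerance = 1e-12)
  expect_error(dispersion_score(numeric()), "empty")
})

test_that("blank prevalence counts strictly positive blanks", {
  ct <- count_table(matrix(c(5, 0, 0, 0), 2, 2),
                    otu_ids = c("A", "B"), sample_ids = c("b1", "b2"))
  prev <- blank_prevalence(ct, c("b1", "b2"))
  expect_equal(unname(prev), c(0.5, 0))
  expect_error(blank_prevalence(ct, character()), "skip")

  # brute-force oracle on a random table
  set.seed(5)
  ct <- random_count_table(20, 6)
  blanks <- ct$sample_ids[1:3]
  brute <- apply(ct$counts[, blanks], 1L, function(x) mean(x > 0))
  expect_equal(blank_prevalence(ct, blanks), brute)
})

test_that("classification separates removal, subtraction, and the strict 50% boundary", {
  build <- function(blank_counts, spec_counts) {
    m <- rbind(OtuX = c(blank_counts, spec_counts))
    count_table(m, sample_ids = c(paste0("b", seq_along(blank_counts)),
                                  paste0("s", seq_along(spec_counts))))
  }
  blanks <- c("b1", "b2"); specs <- c("s1", "s2", "s3")

  # blank-dominated OTU -> remove
  d <- classify_contaminants(build(c(50, 70), c(2, 0, 1)), blanks, specs)
  expect_identical(d$action, "remove")
  expect_gt(d$blank_dispersion, d$sample_dispersion)

  # specimen-dominated but blank-recurrent OTU -> subtract
  d <- classify_contaminants(build(c(3, 2), c(500, 800, 650)), blanks, specs)
  expect_identical(d$action, "subtract")

  # exactly 50% prevalence stays (threshold is strict)
  d <- classify_contaminants(build(c(90, 0), c(1, 0, 0)), blanks, specs)
  expect_identical(d$action, "keep")
  expect_equal(d$blank_prevalence, 0.5)

  expect_error(classify_contaminants(build(c(1, 1), c(1, 1, 1)),
                                     blanks, c("b1", "s1")), "overlap")
})

test_that("applying decisions floors subtracted counts and drops control columns", {
  m <- rbind(OtuS = c(8, 12, 100, 8), OtuK = c(0, 0, 9, 9))
  ct <- count_table(m, sample_ids = c("b1", "b2", "s1", "s2"))
  dec <- classify_contaminants(ct, c("b1", "b2"), c("s1", "s2"))
  expect_identical(dec$action, c("subtract", "keep"))
  # blank background = mean(8,12) + sd = 10 + 2.828... -> floor(100 - bg) = 87
  cleaned <- apply_decontam(ct, dec, c("s1", "s2"))
  expect_equal(unname(cleaned$counts["OtuS", ]),
               c(floor(100 - (10 + sd(c(8, 12)))), 0))
  expect_identical(cleaned$sample_ids, c("s1", "s2"))
  expect_identical(unname(cleaned$counts["OtuK", ]), c(9L, 9L))

  # hand-specified background exercising the printed example
  dec2 <- dec
  dec2$blank_background <- c(10.5, 0)
  cleaned2 <- apply_decontam(ct, dec2, c("s1", "s2"))
  expect_identical(unname(cleaned2$counts["OtuS", ]), c(89L, 0L))

  # all-keep is the identity on specimen columns
  dec3 <- dec; dec3$action <- "keep"
  expect_identical(apply_decontam(ct, dec3, c("s1", "s2"))$counts,
                   ct$counts[, c("s1", "s2")])

  # remove-all annihilates
  dec4 <- dec; dec4$action <- "remove"
  expect_identical(nrow(apply_decontam(ct, dec4, c("s1", "s2"))$counts), 0L)
})

test_that("depth filter drops strictly-below-threshold samples only", {
  m <- matrix(c(999, 1000, 12000), 1, 3)
  ct <- count_table(m, otu_ids = "O", sample_ids = c("a", "b", "c"))
  flt <- filter_low_depth(ct, 1000)
  expect_identical(flt$table$sample_ids, c("b", "c"))
  expect_identical(flt$dropped$sample_id, "a")
  expect_identical(flt$dropped$total, 999)

  expect_identical(filter_low_depth(ct, 0)$table$sample_ids, ct$sample_ids)
  expect_error(filter_low_depth(ct, 1e6), "inspect")

  set.seed(6)
  rt <- random_count_table(10, 12, max_count = 9)
  flt <- filter_low_depth(rt, 25)
  expect_identical(flt$table$sample_ids,
                   rt$sample_ids[colSums(rt$counts) >= 25])
})

test_that("strata are decontaminated independently and recombined", {
  # contaminant spiked into stool blanks only; present at trace in both strata
  m <- rbind(
    Contam = c(80, 90, 1, 0, 0, 0, 1, 0),
    Real1  = c(0, 0, 2000, 1800, 2200, 1500, 1600, 1700),
    Real2  = c(0, 1, 1000, 900, 1100, 800, 850, 900)
  )
  ids <- c("bs1", "bs2", "st1", "st2", "st3", "bm_spec1", "bm_spec2",
           "bm_spec3")
  ct <- count_table(m, sample_ids = ids)
  strata <- list(
    stool = list(blank_ids = c("bs1", "bs2"),
                 specimen_ids = c("st1", "st2", "st3")),
    milk = list(blank_ids = character(),
                specimen_ids = c("bm_spec1", "bm_spec2", "bm_spec3"))
  )
  cfg <- analysis_config(min_sample_depth = 0)
  expect_warning(res <- run_decontam(ct, strata, cfg), "no blanks")
  # removed from stool stratum, untouched in the blank-less milk stratum
  expect_identical(unname(res$table$counts["Contam", c("st1", "st2", "st3")]),
                   c(0L, 0L, 0L))
  expect_identical(unname(res$table$counts["Contam",
                                           c("bm_spec1", "bm_spec2")]),
                   c(0L, 1L))
  # blank columns are gone
  expect_false(any(c("bs1", "bs2") %in% res$table$sample_ids))
})

test_that("single stratum equals the classify -> apply -> filter composition", {
  set.seed(7)
  ct <- random_count_table(15, 10, max_count = 400)
  blanks <- ct$sample_ids[1:3]
  specs <- ct$sample_ids[4:10]
  cfg <- analysis_config(min_sample_depth = 100)
  res <- run_decontam(ct, list(all = list(blank_ids = blanks,
                                          specimen_ids = specs)), cfg)
  dec <- classify_contaminants(ct, blanks, specs, cfg)
  manual <- filter_low_depth(apply_decontam(ct, dec, specs), 100)
  expect_identical(res$table$counts, manual$table$counts)
  expect_identical(res$reports$all$dropped_samples, manual$dropped)
})

test_that("decontamination never increases counts and partitions decisions", {
  set.seed(8)
  for (r in 1:20) {
    ct <- random_count_table(25, 9, max_count = 300)
    blanks <- ct$sample_ids[1:4]
    specs <- ct$sample_ids[5:9]
    dec <- classify_contaminants(ct, blanks, specs)
    expect_identical(sort(dec$otu_id), sort(ct$otu_ids))
    expect_true(all(dec$action %in% c("keep", "remove", "subtract")))
    flagged <- dec$blank_prevalence > 0.5
    expect_true(all(dec$action[!flagged] == "keep"))
    cleaned <- apply_decontam(ct, dec, specs)
    expect_true(all(cleaned$counts <=
                      ct$counts[cleaned$otu_ids, specs, drop = FALSE]))
    expect_true(all(cleaned$counts >= 0))
    # OTUs absent from every blank are never removed or subtracted
    absent <- rowSums(ct$counts[, blanks, drop = FALSE]) == 0
    expect_true(all(dec$action[absent] == "keep"))
  }
})

test_that("rerunning decontamination without blanks is the identity", {
  st <- simulate_study(simulation_config(seed = 31))
  m16 <- st$metadata[st$metadata$domain == "bacteria_16S", ]
  first <- run_decontam(st$bacteria, default_strata(m16))
  cleaned_meta <- m16[m16$sample_id %in% first$table$sample_ids, ]
  strata2 <- list(stool = list(
    blank_ids = character(),
    specimen_ids = first$table$sample_ids
  ))
  expect_warning(second <- run_decontam(first$table, strata2), "no blanks")
  expect_identical(second$table$counts, first$table$counts)
})

test_that("labelled contaminants in a simulated study are all recovered", {
  st <- simulate_study(simulation_config(seed = 32))
  m16 <- st$metadata[st$metadata$domain == "bacteria_16S", ]
  res <- run_decontam(st$bacteria, default_strata(m16))
  stool_dec <- res$reports$stool$decisions
  removed <- stool_dec$otu_id[stool_dec$action == "remove"]
  expect_true(all(st$truth$contaminants$stool_bacteria %in% removed))
  milk_dec <- res$reports$milk$decisions
  expect_true(all(st$truth$contaminants$milk_bacteria %in%
                    milk_dec$otu_id[milk_dec$action == "remove"]))
  # the abundant blank-recurrent class is subtracted, not removed
  expect_true(all(stool_dec$action[stool_dec$otu_id %in%
                                     st$truth$subtract_class] == "subtract"))
})
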