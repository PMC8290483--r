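test_that("succession profiles are normalized with the printed dominance pattern", {
  prof <- succession_profiles("ghana_default")
  expect_equal(unname(rowSums(prof$bacteria$profiles)),
               rep(1, nrow(prof$bacteria$profiles)), tolerance = 1e-12)
  expect_equal(unname(rowSums(prof$fungi$profiles)),
               rep(1, nrow(prof$fungi$profiles)), tolerance = 1e-12)
  argmax <- function(m, bin) colnames(m)[which.max(m[bin, ])]
  b <- prof$bacteria$profiles
  expect_identical(argmax(b, "DOL 0-5"), "Escherichia")
  expect_identical(argmax(b, "MOL 57-63"), "Prevotella")
  expect_identical(argmax(b, "DOL 83-115"), "Bifidobacterium")
  expect_identical(argmax(b, "Mother-wk4"), "Prevotella")
  # week-1 mothers: Escherichia-rich, Prevotella-poor
  expect_gt(b["Mother-wk1", "Escherichia"], b["Mother-wk4", "Escherichia"])
  expect_lt(b["Mother-wk1", "Prevotella"], b["Mother-wk4", "Prevotella"])
  # fungal stool profiles carry no age trend
  f <- prof$fungi$profiles
  child <- default_age_bins()$age_bin
  expect_true(all(apply(f[child, ], 2, function(x) diff(range(x))) < 1e-15))
  expect_identical(argmax(f, "Milk-wk1"), "Malassezia")
  expect_error(succession_profiles("nope"), "unknown preset")
})

test_that("the study generator is deterministic given its seed", {
  a <- simulate_study(simulation_config(seed = 61))
  b <- simulate_study(simulation_config(seed = 61))
  expect_identical(a$bacteria$counts, b$bacteria$counts)
  expect_identical(a$fungi$counts, b$fungi$counts)
  expect_identical(a$metadata, b$metadata)
  expect_identical(a$truth, b$truth)
  c <- simulate_study(simulation_config(seed = 62))
  expect_false(identical(a$bacteria$counts, c$bacteria$counts))
})

test_that("simulated studies satisfy their structural contracts", {
  st <- simulate_study(simulation_config(seed = 63))
  validate_metadata(st$metadata)
  validate_taxonomy(st$taxonomy)
  # truth labels reference existing OTUs and samples
  expect_true(all(unlist(st$truth$contaminants) %in%
                    c(st$bacteria$otu_ids, st$fungi$otu_ids)))
  expect_true(all(names(st$truth$transmitted) %in% st$metadata$sample_id))
  expect_true(all(unlist(st$truth$transmitted) %in% st$bacteria$otu_ids))

  # transmitted OTUs sit above the presence threshold in the child
  pres <- presence_matrix(st$bacteria, st$config$presence_threshold)
  for (child in names(st$truth$transmitted)) {
    expect_true(all(pres[st$truth$transmitted[[child]], child]))
  }

  # fungal tables contain fungus-free specimens; bacterial tables do not
  mI <- st$metadata[st$metadata$domain == "fungi_ITS2" &
                      st$metadata$sample_type %in%
                      c("child_stool", "mother_stool", "breast_milk"), ]
  expect_gt(sum(colSums(st$fungi$counts[, mI$sample_id]) == 0), 0)
  m16 <- st$metadata[st$metadata$domain == "bacteria_16S" &
                       st$metadata$sample_type %in%
                       c("child_stool", "mother_stool", "breast_milk"), ]
  expect_true(all(colSums(st$bacteria$counts[, m16$sample_id]) > 0))
})

test_that("specimen depth tracks the configured log-normal mean", {
  cfg <- simulation_config(seed = 64)
  st1 <- simulate_study(cfg)
  st2 <- simulate_study(simulation_config(seed = 65))
  totals <- c()
  for (st in list(st1, st2)) {
    m16 <- st$metadata[st$metadata$domain == "bacteria_16S" &
                         st$metadata$sample_type %in%
                         c("child_stool", "mother_stool", "breast_milk"), ]
    # community reads only: spiked contaminants and the positive-control
    # spike ride on top of the configured depth
    community <- setdiff(st$bacteria$otu_ids,
                         c(st$config$contamination$otu_id, "Otu16S_SPIKE"))
    totals <- c(totals,
                colSums(st$bacteria$counts[community, m16$sample_id]))
  }
  expect_gte(length(totals), 200)
  p <- cfg$depth_bacteria
  lf <- cfg$low_depth_fraction[["bacteria"]]
  expected <- (1 - lf) * exp(p$meanlog + p$sdlog^2 / 2) +
    lf * mean(cfg$low_depth_range)
  expect_lt(abs(mean(totals) - expected) / expected, 0.05)
})

test_that("written studies read back validly with truth passed through", {
  dir <- withr::local_tempdir()
  st <- simulate_study(simulation_config(seed = 66))
  write_study(st, dir)
  back <- read_study(dir)
  expect_identical(back$bacteria$counts, st$bacteria$counts)
  expect_identical(back$fungi$counts, st$fungi$counts)
  expect_identical(back$metadata$sample_id, st$metadata$sample_id)
  expect_identical(sort(back$truth$contaminants$stool_bacteria),
                   sort(st$truth$contaminants$stool_bacteria))
  # re-read tables satisfy the count-table invariants by construction
  expect_s3_class(back$bacteria, "count_table")
  tax_back <- back$taxonomy
  expect_identical(tax_back$genus[match(st$taxonomy$otu_id, tax_back$otu_id)],
                   st$taxonomy$genus)
})
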