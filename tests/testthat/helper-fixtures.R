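# shared fixtures and independent brute-force oracles

random_count_table <- function(n_otu = 20, n_samp = 8, max_count = 50,
                               sparsity = 0.3) {
  m <- matrix(rpois(n_otu * n_samp, lambda = max_count / 3), n_otu, n_samp)
  m[runif(length(m)) < sparsity] <- 0L
  # guarantee positive totals per sample
  for (j in which(colSums(m) == 0)) m[sample.int(n_otu, 1), j] <- 1L
  count_table(m,
              otu_ids = sprintf("Otu%03d", seq_len(n_otu)),
              sample_ids = sprintf("S%02d", seq_len(n_samp)))
}

# brute-force Bray-Curtis: direct double loop over the formula
bray_brute <- function(m) {
  n <- ncol(m)
  d <- matrix(0, n, n, dimnames = list(colnames(m), colnames(m)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      d[i, j] <- sum(abs(m[, i] - m[, j])) / sum(m[, i] + m[, j])
    }
  }
  d
}

# brute-force pseudo-F from explicit hat and Gower matrices
permanova_brute <- function(dm, z) {
  m <- as.matrix(dm)
  n <- nrow(m)
  J <- diag(n) - matrix(1 / n, n, n)
  G <- -0.5 * J %*% (m^2) %*% J
  X <- cbind(1, z)
  H <- X %*% solve(t(X) %*% X) %*% t(X)
  ss_model <- sum(diag(H %*% G %*% H))
  ss_total <- sum(diag(G))
  f <- (ss_model / 1) / ((ss_total - ss_model) / (n - 2))
  list(f = f, r2 = ss_model / ss_total, ss_model = ss_model,
       ss_total = ss_total)
}

# exhaustive permutation p-value via its own permutation generator
permanova_enum_p <- function(dm, z) {
  n <- length(z)
  perm_rec <- function(v) {
    if (length(v) == 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perm_rec(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    }
    out
  }
  f_obs <- permanova_brute(dm, z)$f
  fs <- vapply(perm_rec(seq_len(n)),
               function(idx) permanova_brute(dm, z[idx])$f, numeric(1))
  mean(fs >= f_obs - 1e-12)
}

# small taxonomy fixture builder
toy_taxonomy <- function(otu_ids, genera,
                         family = "Lachnospiraceae") {
  n <- length(otu_ids)
  data.frame(
    otu_id = otu_ids,
    kingdom = "Bacteria", phylum = "Firmicutes", class = "Clostridia",
    order = "Clostridiales", family = family,
    genus = genera, species = NA_character_,
    stringsAsFactors = FALSE
  )
}
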