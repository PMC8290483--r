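BACT_LINEAGES <- list(
  Escherichia     = c("Proteobacteria", "Gammaproteobacteria", "Enterobacteriales", "Enterobacteriaceae"),
  Bifidobacterium = c("Actinobacteria", "Actinobacteria", "Bifidobacteriales", "Bifidobacteriaceae"),
  Bacteroides     = c("Bacteroidetes", "Bacteroidia", "Bacteroidales", "Bacteroidaceae"),
  Prevotella      = c("Bacteroidetes", "Bacteroidia", "Bacteroidales", "Prevotellaceae"),
  Faecalibacterium = c("Firmicutes", "Clostridia", "Clostridiales", "Ruminococcaceae"),
  Blautia         = c("Firmicutes", "Clostridia", "Clostridiales", "Lachnospiraceae"),
  Streptococcus   = c("Firmicutes", "Bacilli", "Lactobacillales", "Streptococcaceae"),
  Staphylococcus  = c("Firmicutes", "Bacilli", "Bacillales", "Staphylococcaceae"),
  Enterococcus    = c("Firmicutes", "Bacilli", "Lactobacillales", "Enterococcaceae"),
  Veillonella     = c("Firmicutes", "Negativicutes", "Veillonellales", "Veillonellaceae"),
  Lactobacillus   = c("Firmicutes", "Bacilli", "Lactobacillales", "Lactobacillaceae"),
  Clostridium     = c("Firmicutes", "Clostridia", "Clostridiales", "Clostridiaceae"),
  Ruminococcus    = c("Firmicutes", "Clostridia", "Clostridiales", "Ruminococcaceae"),
  Corynebacterium = c("Actinobacteria", "Actinobacteria", "Corynebacteriales", "Corynebacteriaceae"),
  Akkermansia     = c("Verrucomicrobia", "Verrucomicrobiae", "Verrucomicrobiales", "Akkermansiaceae"),
  Ralstonia       = c("Proteobacteria", "Betaproteobacteria", "Burkholderiales", "Burkholderiaceae"),
  Sphingomonas    = c("Proteobacteria", "Alphaproteobacteria", "Sphingomonadales", "Sphingomonadaceae"),
  Methylobacterium = c("Proteobacteria", "Alphaproteobacteria", "Rhizobiales", "Methylobacteriaceae"),
  Pseudomonas     = c("Proteobacteria", "Gammaproteobacteria", "Pseudomonadales", "Pseudomonadaceae"),
  Acinetobacter   = c("Proteobacteria", "Gammaproteobacteria", "Pseudomonadales", "Moraxellaceae"),
  Bradyrhizobium  = c("Proteobacteria", "Alphaproteobacteria", "Rhizobiales", "Bradyrhizobiaceae"),
  Burkholderia    = c("Proteobacteria", "Betaproteobacteria", "Burkholderiales", "Burkholderiaceae")
)

FUNG_LINEAGES <- list(
  Candida      = c("Ascomycota", "Saccharomycetes", "Saccharomycetales", "Saccharomycetaceae"),
  Malassezia   = c("Basidiomycota", "Malasseziomycetes", "Malasseziales", "Malasseziaceae"),
  Aspergillus  = c("Ascomycota", "Eurotiomycetes", "Eurotiales", "Aspergillaceae"),
  Saccharomyces = c("Ascomycota", "Saccharomycetes", "Saccharomycetales", "Saccharomycetaceae"),
  Cladosporium = c("Ascomycota", "Dothideomycetes", "Capnodiales", "Cladosporiaceae"),
  Penicillium  = c("Ascomycota", "Eurotiomycetes", "Eurotiales", "Aspergillaceae"),
  Rhodotorula  = c("Basidiomycota", "Microbotryomycetes", "Sporidiobolales", "Sporidiobolaceae"),
  Debaryomyces = c("Ascomycota", "Saccharomycetes", "Saccharomycetales", "Debaryomycetaceae"),
  Wallemia     = c("Basidiomycota", "Wallemiomycetes", "Wallemiales", "Wallemiaceae"),
  Alternaria   = c("Ascomycota", "Dothideomycetes", "Pleosporales", "Pleosporaceae"),
  Fusarium     = c("Ascomycota", "Sordariomycetes", "Hypocreales", "Nectriaceae")
)

#' Built-in per-bin genus composition profiles
#'
#' Mean relative-abundance profiles for every age bin, emulating the staged
#' succession of a rural West-African cohort: Escherichia-dominated newborn
#' stool, Bifidobacterium-dominated (with prominent Bacteroides) infancy,
#' and a Prevotella-dominated adult-like community from the second year on,
#' with richness increasing along the way. Child-bin profiles are mixtures
#' `(1 - t) * stage + t * adult` with a mixing weight `t` that increases
#' with age, so communities converge on the adult (5-year / maternal week-4)
#' profile. The week-1 maternal profile is Escherichia-rich and
#' Prevotella-poor with elevated Faecalibacterium and Blautia; breast milk
#' is dominated by skin taxa (Streptococcus, Staphylococcus,
#' Corynebacterium). Fungal stool profiles are identical across all bins
#' (no configured age trend), dominated by Candida; milk fungi by
#' Malassezia. Profiles are qualitative by design: they reproduce ranked
#' dominance patterns, not measured abundances.
#'
#' @param preset currently only `"ghana_default"`.
#' @return List with elements `bacteria` and `fungi`, each a list of
#'   `genera` (character) and `profiles` (bin x genus matrix, rows summing
#'   to 1), plus `mix_weight` (the named `t` path over child bins).
#' @export
succession_profiles <- function(preset = "ghana_default") {
  if (!identical(preset, "ghana_default")) {
    stop("unknown preset: ", preset, call. = FALSE)
  }
  bg <- c("Escherichia", "Bifidobacterium", "Bacteroides", "Prevotella",
          "Faecalibacterium", "Blautia", "Streptococcus", "Staphylococcus",
          "Enterococcus", "Veillonella", "Lactobacillus", "Clostridium",
          "Ruminococcus", "Corynebacterium", "Akkermansia")
  pr <- function(...) {
    v <- c(...)
    stopifnot(setequal(names(v), bg))
    v[bg] / sum(v)
  }
  adult <- pr(Escherichia = .04, Bifidobacterium = .05, Bacteroides = .09,
              Prevotella = .28, Faecalibacterium = .12, Blautia = .07,
              Streptococcus = .04, Staphylococcus = .01, Enterococcus = .02,
              Veillonella = .03, Lactobacillus = .03, Clostridium = .07,
              Ruminococcus = .08, Corynebacterium = .01, Akkermansia = .06)
  newborn <- pr(Escherichia = .70, Bifidobacterium = .08, Bacteroides = .005,
                Prevotella = .001, Faecalibacterium = .001, Blautia = .001,
                Streptococcus = .09, Staphylococcus = .03, Enterococcus = .07,
                Veillonella = .01, Lactobacillus = .01, Clostridium = .001,
                Ruminococcus = .001, Corynebacterium = .005, Akkermansia = .001)
  infancy <- pr(Escherichia = .10, Bifidobacterium = .52, Bacteroides = .22,
                Prevotella = .002, Faecalibacterium = .002, Blautia = .005,
                Streptococcus = .04, Staphylococcus = .002, Enterococcus = .02,
                Veillonella = .05, Lactobacillus = .03, Clostridium = .005,
                Ruminococcus = .002, Corynebacterium = .002, Akkermansia = .005)
  mother_wk1 <- pr(Escherichia = .26, Bifidobacterium = .03, Bacteroides = .09,
                   Prevotella = .02, Faecalibacterium = .16, Blautia = .12,
                   Streptococcus = .06, Staphylococcus = .005,
                   Enterococcus = .02, Veillonella = .05, Lactobacillus = .02,
                   Clostridium = .08, Ruminococcus = .07,
                   Corynebacterium = .005, Akkermansia = .03)
  milk <- pr(Escherichia = .03, Bifidobacterium = .05, Bacteroides = .03,
             Prevotella = .005, Faecalibacterium = .005, Blautia = .005,
             Streptococcus = .36, Staphylococcus = .26, Enterococcus = .02,
             Veillonella = .02, Lactobacillus = .03, Clostridium = .005,
             Ruminococcus = .005, Corynebacterium = .16, Akkermansia = .005)

  child_bins <- default_age_bins()$age_bin
  t_path <- c(`DOL 0-5` = .02, `DOL 13-17` = .19, `DOL 26-35` = .27,
              `DOL 83-115` = .33, `DOL 165-200` = .42, `MOL 11-13` = .53,
              `MOL 22-26` = .68, `MOL 33-39` = .90, `MOL 57-63` = 1)
  stage <- list(`DOL 0-5` = newborn, `DOL 13-17` = newborn,
                `DOL 26-35` = newborn, `DOL 83-115` = infancy,
                `DOL 165-200` = infancy, `MOL 11-13` = infancy,
                `MOL 22-26` = infancy, `MOL 33-39` = infancy,
                `MOL 57-63` = adult)
  bac <- t(vapply(child_bins, function(b) {
    (1 - t_path[[b]]) * stage[[b]] + t_path[[b]] * adult
  }, numeric(length(bg))))
  bac <- rbind(bac,
               `Mother-wk1` = mother_wk1, `Mother-wk4` = adult,
               `Milk-wk1` = milk, `Milk-wk4` = milk)
  bac <- bac / rowSums(bac)

  fg <- c("Candida", "Malassezia", "Aspergillus", "Saccharomyces",
          "Cladosporium", "Penicillium", "Rhodotorula", "Debaryomyces")
  stool_fungi <- c(Candida = .45, Malassezia = .15, Aspergillus = .12,
                   Saccharomyces = .10, Cladosporium = .07, Penicillium = .05,
                   Rhodotorula = .03, Debaryomyces = .03)
  milk_fungi <- c(Candida = .15, Malassezia = .55, Aspergillus = .05,
                  Saccharomyces = .05, Cladosporium = .08, Penicillium = .05,
                  Rhodotorula = .04, Debaryomyces = .03)
  fun <- rbind(
    matrix(rep(stool_fungi[fg] / sum(stool_fungi), length(child_bins) + 2L),
           ncol = length(fg), byrow = TRUE,
           dimnames = list(c(child_bins, "Mother-wk1", "Mother-wk4"), fg)),
    `Milk-wk1` = milk_fungi[fg] / sum(milk_fungi),
    `Milk-wk4` = milk_fungi[fg] / sum(milk_fungi)
  )
  list(bacteria = list(genera = bg, profiles = bac),
       fungi = list(genera = fg, profiles = fun),
       mix_weight = t_path)
}

# contaminant design: blank-dominant "reagent" OTUs that meet the removal
# rule by construction, plus specimen-abundant OTUs recurrent in blanks that
# exercise the subtraction branch
default_contamination <- function() {
  data.frame(
    otu_id = c("Contam16S_01", "Contam16S_02", "Contam16S_03",
               "Sub16S_01", "Sub16S_02",
               "ContamMilk16S_01", "ContamMilk16S_02",
               "ContamITS_01", "ContamITS_02", "ContamMilkITS_01"),
    genus = c("Ralstonia", "Sphingomonas", "Methylobacterium",
              "Pseudomonas", "Acinetobacter",
              "Bradyrhizobium", "Burkholderia",
              "Wallemia", "Alternaria", "Fusarium"),
    domain = c(rep("bacteria_16S", 7), rep("fungi_ITS2", 3)),
    stratum = c("stool", "stool", "stool", "stool", "stool", "milk", "milk",
                "stool", "stool", "milk"),
    blank_mean = c(80, 80, 60, 3, 3, 80, 60, 60, 60, 60),
    specimen_mean = c(.5, .5, .5, 300, 200, .5, .5, .3, .3, .3),
    class = c("reagent", "reagent", "reagent", "high_abundance",
              "high_abundance", "reagent", "reagent", "reagent", "reagent",
              "reagent"),
    stringsAsFactors = FALSE
  )
}

#' Configuration of a simulated mother-infant amplicon study
#'
#' Defaults describe the emulated study conditions: nine child age bins of
#' 12 stool samples (15 in the two mother-paired newborn bins), 15
#' mother-infant pairs per postpartum window (each mother contributing stool
#' and breast milk), four stool and two breast-milk template-free blanks,
#' two positive controls, log-normal sequencing depth centred near 10,000
#' reads with a small fraction of samples forced under 1,000, fungal samples
#' with an independent chance of carrying no fungi at all, Dirichlet
#' concentration 50 around the per-bin mean profiles, and 30 maternally
#' seeded OTUs per related infant.
#'
#' @param preset profile preset passed to [succession_profiles].
#' @param n_per_bin child stool samples per age bin.
#' @param n_pairs named vector, mother-infant pairs per window
#'   (`wk1`, `wk4`).
#' @param otus_per_genus OTUs splitting each genus's abundance.
#' @param concentration Dirichlet concentration of specimen compositions
#'   (larger = less compositional noise).
#' @param depth_bacteria,depth_fungi lists with `meanlog`, `sdlog` of the
#'   log-normal read-depth distribution.
#' @param low_depth_fraction named vector (`bacteria`, `fungi`): fraction of
#'   specimens forced below 1,000 reads.
#' @param low_depth_range integer range the forced-low depths are drawn from.
#' @param fungal_zero_fraction probability a specimen carries no detectable
#'   fungi (zero ITS2 reads).
#' @param carriage_cutoff OTU-level mean relative abundance below which
#'   carriage is individual-specific rather than universal.
#' @param carriage_prob probability a given subject carries a given
#'   below-cutoff OTU. Individual-specific carriage of rare taxa is what
#'   makes mother-infant sharing informative beyond the shared species pool.
#' @param transmission_n_otus maternally seeded OTUs per related infant
#'   (bacterial domain; 0 disables transmission).
#' @param presence_threshold relative-abundance threshold the seeded OTUs
#'   are pushed above in the infant.
#' @param contamination data frame describing spiked contaminant OTUs
#'   (columns `otu_id`, `genus`, `domain`, `stratum`, `blank_mean`,
#'   `specimen_mean`, `class`).
#' @param n_blanks named vector of blanks per stratum (`stool`, `milk`).
#' @param n_pos_controls positive-control samples (excluded from analyses).
#' @param seed integer seed; the whole study is deterministic given it.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(preset = "ghana_default",
                              n_per_bin = 12L,
                              n_pairs = c(wk1 = 15L, wk4 = 15L),
                              otus_per_genus = 5L,
                              concentration = 50,
                              depth_bacteria = list(meanlog = log(10000), sdlog = 0.4),
                              depth_fungi = list(meanlog = log(5000), sdlog = 0.6),
                              low_depth_fraction = c(bacteria = 0.03, fungi = 0.12),
                              low_depth_range = c(200L, 999L),
                              fungal_zero_fraction = 0.35,
                              carriage_cutoff = 0.01,
                              carriage_prob = 0.4,
                              transmission_n_otus = 30L,
                              presence_threshold = 1e-4,
                              contamination = default_contamination(),
                              n_blanks = c(stool = 4L, milk = 2L),
                              n_pos_controls = 2L,
                              seed = 1L) {
  cfg <- list(preset = preset, profiles = succession_profiles(preset),
              n_per_bin = as.integer(n_per_bin),
              n_pairs = c(wk1 = as.integer(n_pairs[["wk1"]]),
                          wk4 = as.integer(n_pairs[["wk4"]])),
              otus_per_genus = as.integer(otus_per_genus),
              concentration = concentration,
              depth_bacteria = depth_bacteria, depth_fungi = depth_fungi,
              low_depth_fraction = low_depth_fraction,
              low_depth_range = as.integer(low_depth_range),
              fungal_zero_fraction = fungal_zero_fraction,
              carriage_cutoff = carriage_cutoff,
              carriage_prob = carriage_prob,
              transmission_n_otus = as.integer(transmission_n_otus),
              presence_threshold = presence_threshold,
              contamination = contamination,
              n_blanks = c(stool = as.integer(n_blanks[["stool"]]),
                           milk = as.integer(n_blanks[["milk"]])),
              n_pos_controls = as.integer(n_pos_controls),
              seed = as.integer(seed))
  if (cfg$n_per_bin < 2L) stop("n_per_bin must be >= 2")
  if (cfg$otus_per_genus < 1L) stop("otus_per_genus must be >= 1")
  if (cfg$concentration <= 0) stop("concentration must be > 0")
  if (cfg$fungal_zero_fraction < 0 || cfg$fungal_zero_fraction > 1) {
    stop("fungal_zero_fraction must be in [0, 1]")
  }
  if (any(cfg$low_depth_fraction < 0) || any(cfg$low_depth_fraction > 1)) {
    stop("low_depth_fraction must be in [0, 1]")
  }
  if (cfg$transmission_n_otus < 0) stop("transmission_n_otus must be >= 0")
  if (cfg$carriage_prob < 0 || cfg$carriage_prob > 1) {
    stop("carriage_prob must be in [0, 1]")
  }
  structure(cfg, class = "simulation_config")
}

#' Simulate a truth-labelled mother-infant amplicon study
#'
#' Generates paired bacterial and fungal count tables, metadata, taxonomy,
#' and ground-truth labels under the configured study design: per specimen,
#' a composition is drawn from a Dirichlet around its bin's mean profile and
#' reads are drawn multinomially at a log-normal depth; a configured
#' fraction of specimens falls under 1,000 reads and fungal specimens are
#' zeroed with probability `fungal_zero_fraction`; related infants receive
#' `transmission_n_otus` OTUs seeded from their mother's realized stool
#' composition at low abundance (above the presence threshold); blanks carry
#' spiked contaminant OTUs (Poisson counts) with low-level Poisson leakage
#' into the specimens of their stratum, plus a trace of sample carryover.
#' Fully deterministic given `cfg$seed`.
#'
#' @param cfg a [simulation_config].
#' @return A list of class `simulated_study` with elements `bacteria` and
#'   `fungi` ([count_table]s including blanks and controls), `metadata`,
#'   `taxonomy`, `truth` (contaminant ids per domain and stratum,
#'   subtraction-class ids, transmitted OTUs per child sample, and the
#'   configured age-mixing path), and `config`.
#' @export
simulate_study <- function(cfg = simulation_config()) {
  stopifnot(inherits(cfg, "simulation_config"))
  with_seed(cfg$seed, {
    base <- build_sample_frame(cfg)
    bact <- simulate_domain(cfg, base, "bacteria_16S")
    fung <- simulate_domain(cfg, base, "fungi_ITS2")
    transmitted <- list()
    if (cfg$transmission_n_otus > 0L) {
      res <- seed_transmission(cfg, base, bact)
      bact$counts_matrix <- res$m
      transmitted <- res$transmitted
    }
    meta <- rbind(domain_metadata(base, bact$suffix, "bacteria_16S"),
                  domain_metadata(base, fung$suffix, "fungi_ITS2"))
    tax <- rbind(bact$taxonomy, fung$taxonomy)
    truth <- list(
      contaminants = list(
        stool_bacteria = reagent_ids(cfg, "bacteria_16S", "stool"),
        milk_bacteria = reagent_ids(cfg, "bacteria_16S", "milk"),
        stool_fungi = reagent_ids(cfg, "fungi_ITS2", "stool"),
        milk_fungi = reagent_ids(cfg, "fungi_ITS2", "milk")
      ),
      subtract_class = cfg$contamination$otu_id[
        cfg$contamination$class == "high_abundance"],
      transmitted = transmitted,
      mix_weight = as.list(cfg$profiles$mix_weight)
    )
    structure(list(
      bacteria = count_table(bact$counts_matrix),
      fungi = count_table(fung$counts_matrix),
      metadata = meta,
      taxonomy = tax,
      truth = truth,
      config = cfg
    ), class = "simulated_study")
  })
}

reagent_ids <- function(cfg, domain, stratum) {
  con <- cfg$contamination
  con$otu_id[con$domain == domain & con$stratum == stratum &
               con$class == "reagent"]
}

# base (domain-agnostic) sample frame: one physical specimen per row
build_sample_frame <- function(cfg) {
  bins <- default_age_bins()
  rows <- list()
  subj <- 0L
  for (i in seq_len(nrow(bins))) {
    b <- bins$age_bin[i]
    n <- cfg$n_per_bin
    if (b == "DOL 0-5") n <- max(n, cfg$n_pairs[["wk1"]])
    if (b == "DOL 26-35") n <- max(n, cfg$n_pairs[["wk4"]])
    ids <- sprintf("C%03d", subj + seq_len(n))
    subj <- subj + n
    rows[[b]] <- data.frame(
      subject_id = ids, mother_subject_id = NA_character_,
      age_days = sample(bins$min_days[i]:bins$max_days[i], n, replace = TRUE),
      age_bin = b, sample_type = "child_stool", stratum = "stool",
      stringsAsFactors = FALSE
    )
  }
  for (w in c("wk1", "wk4")) {
    n <- cfg$n_pairs[[w]]
    mids <- sprintf("M%s_%02d", w, seq_len(n))
    child_bin <- if (w == "wk1") "DOL 0-5" else "DOL 26-35"
    rows[[child_bin]]$mother_subject_id[seq_len(n)] <- mids
    rows[[paste0("Mother-", w)]] <- data.frame(
      subject_id = mids, mother_subject_id = NA_character_,
      age_days = NA_integer_, age_bin = paste0("Mother-", w),
      sample_type = "mother_stool", stratum = "stool",
      stringsAsFactors = FALSE
    )
    rows[[paste0("Milk-", w)]] <- data.frame(
      subject_id = mids, mother_subject_id = NA_character_,
      age_days = NA_integer_, age_bin = paste0("Milk-", w),
      sample_type = "breast_milk", stratum = "milk",
      stringsAsFactors = FALSE
    )
  }
  for (s in c("stool", "milk")) {
    n <- cfg$n_blanks[[s]]
    if (n > 0L) {
      rows[[paste0("blank_", s)]] <- data.frame(
        subject_id = sprintf("Blank_%s_%d", s, seq_len(n)),
        mother_subject_id = NA_character_, age_days = NA_integer_,
        age_bin = NA_character_, sample_type = "blank", stratum = s,
        stringsAsFactors = FALSE
      )
    }
  }
  if (cfg$n_pos_controls > 0L) {
    rows[["poscon"]] <- data.frame(
      subject_id = sprintf("Poscon_%d", seq_len(cfg$n_pos_controls)),
      mother_subject_id = NA_character_, age_days = NA_integer_,
      age_bin = NA_character_, sample_type = "positive_control",
      stratum = "stool", stringsAsFactors = FALSE
    )
  }
  base <- do.call(rbind, rows)
  rownames(base) <- NULL
  base$base_id <- sprintf("S%03d", seq_len(nrow(base)))
  base
}

domain_metadata <- function(base, suffix, domain) {
  data.frame(
    sample_id = paste0(base$base_id, ".", suffix),
    subject_id = base$subject_id,
    mother_subject_id = base$mother_subject_id,
    age_days = base$age_days,
    age_bin = base$age_bin,
    sample_type = base$sample_type,
    domain = domain,
    batch = base$stratum,
    stringsAsFactors = FALSE
  )
}

# count matrix + taxonomy for one domain; consumes the RNG stream
simulate_domain <- function(cfg, base, domain) {
  is_bact <- domain == "bacteria_16S"
  suffix <- if (is_bact) "16S" else "ITS2"
  prof <- if (is_bact) cfg$profiles$bacteria else cfg$profiles$fungi
  lineages <- if (is_bact) BACT_LINEAGES else FUNG_LINEAGES
  kingdom <- if (is_bact) "Bacteria" else "Fungi"
  depth_par <- if (is_bact) cfg$depth_bacteria else cfg$depth_fungi
  low_frac <- cfg$low_depth_fraction[[if (is_bact) "bacteria" else "fungi"]]

  genera <- prof$genera
  m_per <- cfg$otus_per_genus
  otu_genus <- rep(genera, each = m_per)
  otu_ids <- sprintf("Otu%s_%03d", suffix, seq_along(otu_genus))
  # within-genus abundance split, fixed for the study
  weights <- unlist(lapply(genera, function(g) rdirichlet1(rep(2, m_per))),
                    use.names = FALSE)
  # bin x OTU mean profiles
  otu_profiles <- prof$profiles[, otu_genus, drop = FALSE] *
    matrix(weights, nrow(prof$profiles), length(weights), byrow = TRUE)

  con <- cfg$contamination[cfg$contamination$domain == domain, , drop = FALSE]
  spike_id <- paste0("Otu", suffix, "_SPIKE")
  all_otus <- c(otu_ids, con$otu_id, spike_id)
  n_samples <- nrow(base)
  sample_ids <- paste0(base$base_id, ".", suffix)
  M <- matrix(0L, length(all_otus), n_samples,
              dimnames = list(all_otus, sample_ids))

  spec <- base$sample_type %in% c("child_stool", "mother_stool", "breast_milk")
  depth <- integer(n_samples)
  d <- round(stats::rlnorm(sum(spec), depth_par$meanlog, depth_par$sdlog))
  low <- stats::runif(sum(spec)) < low_frac
  d[low] <- sample(cfg$low_depth_range[1]:cfg$low_depth_range[2], sum(low),
                   replace = TRUE)
  if (!is_bact) {
    d[stats::runif(sum(spec)) < cfg$fungal_zero_fraction] <- 0
  }
  depth[spec] <- as.integer(d)

  for (i in which(spec)) {
    if (depth[i] == 0L) next
    p <- otu_profiles[base$age_bin[i], ]
    # individual-specific carriage: each subject hosts only a random subset
    # of the panel's low-abundance OTUs
    rare <- p < cfg$carriage_cutoff * max(1e-12, sum(p))
    carried <- !rare | (stats::runif(length(p)) < cfg$carriage_prob)
    alpha <- p * carried * cfg$concentration
    comp <- rdirichlet1(alpha)
    M[seq_along(otu_ids), i] <- stats::rmultinom(1L, depth[i], comp)[, 1]
  }

  # blanks: trace carryover of real community OTUs, then spiked contaminants
  blanks <- which(base$sample_type == "blank")
  for (i in blanks) {
    M[seq_along(otu_ids), i] <- stats::rpois(length(otu_ids), 0.01)
  }
  for (k in seq_len(nrow(con))) {
    otu <- con$otu_id[k]
    st_blanks <- blanks[base$stratum[blanks] == con$stratum[k]]
    M[otu, st_blanks] <- stats::rpois(length(st_blanks), con$blank_mean[k])
    st_spec <- which(spec & base$stratum == con$stratum[k])
    M[otu, st_spec] <- stats::rpois(length(st_spec), con$specimen_mean[k])
  }
  # positive controls: dominated by the cloned spike
  pos <- which(base$sample_type == "positive_control")
  for (i in pos) {
    M[spike_id, i] <- as.integer(round(stats::rlnorm(1, log(20000), 0.2)))
    M[seq_along(otu_ids), i] <- stats::rpois(length(otu_ids), 0.01)
  }

  # taxonomy; one community OTU left unresolved at genus per domain to
  # exercise deepest-rank labelling downstream
  tax <- data.frame(otu_id = all_otus, kingdom = kingdom,
                    phylum = NA_character_, class = NA_character_,
                    order = NA_character_, family = NA_character_,
                    genus = NA_character_, species = NA_character_,
                    stringsAsFactors = FALSE)
  fill <- function(ids, genus) {
    lin <- lineages[[genus]]
    idx <- match(ids, tax$otu_id)
    tax$phylum[idx] <<- lin[1]; tax$class[idx] <<- lin[2]
    tax$order[idx] <<- lin[3]; tax$family[idx] <<- lin[4]
    tax$genus[idx] <<- genus
  }
  for (g in genera) fill(otu_ids[otu_genus == g], g)
  for (k in seq_len(nrow(con))) fill(con$otu_id[k], con$genus[k])
  unresolved <- otu_ids[match(if (is_bact) "Blautia" else "Candida",
                              otu_genus)]
  tax$genus[tax$otu_id == unresolved] <- NA_character_
  tax$species[tax$otu_id == unresolved] <- NA_character_
  # spike: a partial lineage only
  tax[tax$otu_id == spike_id,
      c("phylum", "class")] <- if (is_bact) {
    c("Proteobacteria", "Gammaproteobacteria")
  } else c("Ascomycota", "Saccharomycetes")

  list(counts_matrix = M, taxonomy = tax, suffix = suffix,
       otu_ids = otu_ids, depth = depth)
}

# push transmission_n_otus maternal stool OTUs above the presence threshold
# in each related infant's bacterial sample
seed_transmission <- function(cfg, base, bact) {
  M <- bact$counts_matrix
  community <- bact$otu_ids
  transmitted <- list()
  children <- which(base$sample_type == "child_stool" &
                      !is.na(base$mother_subject_id))
  for (i in children) {
    j <- which(base$sample_type == "mother_stool" &
                 base$subject_id == base$mother_subject_id[i])
    if (!length(j)) next
    mcol <- M[community, j[1]]
    total_m <- sum(mcol)
    child_depth <- sum(M[community, i])
    if (total_m == 0 || child_depth == 0) next
    present <- community[mcol > 0]
    sel <- sample(present, min(cfg$transmission_n_otus, length(present)))
    rel <- mcol[sel] / total_m
    # seeded at low abundance: proportional to the maternal fraction but
    # capped so the infant's staged community still dominates
    target <- pmin(pmax(rel, 4 * cfg$presence_threshold), 0.002)
    add <- pmax(2L, as.integer(ceiling(target * child_depth)))
    M[sel, i] <- M[sel, i] + add
    child_sample <- paste0(base$base_id[i], ".", bact$suffix)
    transmitted[[child_sample]] <- sel
  }
  list(m = M, transmitted = transmitted)
}

#' Default QC strata for a simulated or compatible study
#'
#' Stool and breast-milk specimens are extracted and amplified separately,
#' each with their own blanks, so QC runs per stratum. Positive controls are
#' excluded from both blank and specimen sets (and hence from all analyses).
#'
#' @param meta metadata for one domain (rows of one `domain` value).
#' @return Named list (`stool`, `milk`) of `blank_ids` / `specimen_ids`,
#'   suitable for [run_decontam]. Strata without samples are dropped.
#' @export
default_strata <- function(meta) {
  out <- list()
  for (s in c("stool", "milk")) {
    blanks <- meta$sample_id[meta$sample_type == "blank" & meta$batch == s]
    specs <- meta$sample_id[meta$batch == s &
                              meta$sample_type %in%
                              c("child_stool", "mother_stool", "breast_milk")]
    if (length(specs)) {
      out[[s]] <- list(blank_ids = blanks, specimen_ids = specs)
    }
  }
  out
}

#' Write a simulated study to disk
#'
#' Emits `counts_16s.tsv`, `counts_its2.tsv`, `taxonomy.tsv`,
#' `metadata.tsv`, and `truth.json` into `out_dir` — the inputs every other
#' pipeline stage consumes, plus the ground-truth labels.
#'
#' @param study a `simulated_study` from [simulate_study].
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_study <- function(study, out_dir) {
  stopifnot(inherits(study, "simulated_study"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_count_table(study$bacteria, file.path(out_dir, "counts_16s.tsv"))
  write_count_table(study$fungi, file.path(out_dir, "counts_its2.tsv"))
  write_taxonomy(study$taxonomy, file.path(out_dir, "taxonomy.tsv"))
  write_metadata(study$metadata, file.path(out_dir, "metadata.tsv"))
  jsonlite::write_json(
    c(study$truth, list(seed = study$config$seed)),
    file.path(out_dir, "truth.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA, null = "null"
  )
  invisible(out_dir)
}

#' Read a study written by [write_study]
#'
#' @param dir directory containing the study files.
#' @return List with `bacteria`, `fungi`, `metadata`, `taxonomy`, `truth`.
#' @export
read_study <- function(dir) {
  list(
    bacteria = read_count_table(file.path(dir, "counts_16s.tsv")),
    fungi = read_count_table(file.path(dir, "counts_its2.tsv")),
    metadata = read_metadata(file.path(dir, "metadata.tsv")),
    taxonomy = read_taxonomy(file.path(dir, "taxonomy.tsv")),
    truth = jsonlite::read_json(file.path(dir, "truth.json"),
                                simplifyVector = TRUE)
  )
}
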