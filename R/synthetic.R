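# Synthetic populations for end-to-end testing of the authentication
# pipeline. The generator emulates the statistical structure of a large
# cell-line collection: unique individuals genotyped on the 96-marker SNP
# panel under Hardy-Weinberg equilibrium, technical/biological replicates
# (re-assays with no-call and genotype error), same-patient derivatives
# (loss-of-heterozygosity drift), chromosome-Y loss in a fraction of male
# lines, STR profiles with microsatellite-instability slippage, and
# per-locus aneuploid copy numbers. Markers are simulated as independent
# (no linkage disequilibrium) and the population is unstructured (one
# allele-frequency law, no ancestry strata).

#' Configuration for the synthetic population generator
#'
#' Captures every rate and size the generator uses; a fixed `seed` makes
#' all downstream generation byte-identical. Defaults mirror the
#' benchmark dataset the pipeline is designed around: a 96-marker panel
#' (46 fingerprinting SNPs at allele frequency 0.5, 44
#' ancestry-informative SNPs with frequencies uniform on (0.1, 0.9), 3
#' chromosome X and 3 chromosome Y SNPs), an autosomal no-call rate of
#' 0.0066 (a 99.34% call rate), and whole-chromosome Y loss in 42% of
#' male lines.
#'
#' @param n_individuals Number of unique individuals (default 200).
#' @param n_fingerprint,n_ancestry,n_x,n_y Panel composition (defaults
#'   46, 44, 3, 3).
#' @param fingerprint_freq Alternate-allele frequency of fingerprinting
#'   SNPs (default 0.5).
#' @param ancestry_freq_range Range of the uniform law for
#'   ancestry-informative SNP frequencies (default `c(0.1, 0.9)`).
#' @param no_call_rate Per-genotype autosomal no-call probability
#'   (default 0.0066).
#' @param genotype_error_rate Per-locus perturbation probability when
#'   deriving a replicate (default 0.005).
#' @param loh_rate Per-heterozygous-locus collapse probability when
#'   deriving a same-patient line (default 0.1).
#' @param chry_loss_rate Probability that a male line has lost its whole
#'   chromosome Y (default 0.42).
#' @param msi_slippage_rate Per-allele STR repeat slippage probability
#'   for MSI derivatives (default 0.15).
#' @param male_fraction Fraction of male individuals (default 0.5).
#' @param n_replicates,n_synonymous Number of planted replicate and
#'   same-patient derivative samples (defaults 8 and 8).
#' @param seed Integer seed (default 1).
#' @return A validated list of class `cellauth_synth_config`.
#' @export
synth_config <- function(n_individuals = 200,
                         n_fingerprint = 46, n_ancestry = 44,
                         n_x = 3, n_y = 3,
                         fingerprint_freq = 0.5,
                         ancestry_freq_range = c(0.1, 0.9),
                         no_call_rate = 0.0066,
                         genotype_error_rate = 0.005,
                         loh_rate = 0.1,
                         chry_loss_rate = 0.42,
                         msi_slippage_rate = 0.15,
                         male_fraction = 0.5,
                         n_replicates = 8,
                         n_synonymous = 8,
                         seed = 1L) {
  cfg <- list(
    n_individuals = as.integer(n_individuals),
    n_fingerprint = as.integer(n_fingerprint),
    n_ancestry = as.integer(n_ancestry),
    n_x = as.integer(n_x), n_y = as.integer(n_y),
    fingerprint_freq = fingerprint_freq,
    ancestry_freq_range = ancestry_freq_range,
    no_call_rate = no_call_rate,
    genotype_error_rate = genotype_error_rate,
    loh_rate = loh_rate,
    chry_loss_rate = chry_loss_rate,
    msi_slippage_rate = msi_slippage_rate,
    male_fraction = male_fraction,
    n_replicates = as.integer(n_replicates),
    n_synonymous = as.integer(n_synonymous),
    seed = as.integer(seed)
  )
  rates <- c("no_call_rate", "genotype_error_rate", "loh_rate",
             "chry_loss_rate", "msi_slippage_rate", "male_fraction",
             "fingerprint_freq")
  for (r in rates) {
    if (!is.numeric(cfg[[r]]) || cfg[[r]] < 0 || cfg[[r]] > 1) {
      abort(paste0(r, " must be in [0, 1]"))
    }
  }
  if (cfg$n_individuals < 1) abort("n_individuals must be positive")
  if (cfg$n_replicates + cfg$n_synonymous > cfg$n_individuals) {
    abort("more planted replicate/synonymous samples than individuals")
  }
  if (length(cfg$ancestry_freq_range) != 2 ||
      any(cfg$ancestry_freq_range <= 0 | cfg$ancestry_freq_range >= 1)) {
    abort("ancestry_freq_range must be two frequencies inside (0, 1)")
  }
  structure(cfg, class = "cellauth_synth_config")
}

# HWE genotype strings for one biallelic marker: "A", "A/B", "B".
hwe_genotypes <- function(n, p_alt) {
  g <- sample.int(3L, n, replace = TRUE,
                  prob = c((1 - p_alt)^2, 2 * p_alt * (1 - p_alt), p_alt^2))
  c("A", "A/B", "B")[g]
}

#' Generate a synthetic population
#'
#' Draws a marker panel and a population of genotype profiles under the
#' configuration: autosomal genotypes are Hardy-Weinberg draws at each
#' marker's allele frequency, independent across markers and individuals;
#' sex is assigned by `male_fraction`; males carry hemizygous chromosome
#' X and Y calls unless chromosome Y loss is sampled (all three Y assays
#' blank, the whole-chromosome loss seen in miscalled male lines);
#' no-calls are sprinkled on autosomes at `no_call_rate`. Planted
#' replicate samples (via [derive_replicate()]) and same-patient
#' derivatives (via [derive_synonymous()]) are appended with annotations
#' recording the planted truth, so classification results can be scored
#' against it.
#'
#' @param config A [synth_config()].
#' @return A list: `panel`, `profiles` (long tibble), `annotations`,
#'   `cn` (diploid copy-number tibble for the called genotypes) and
#'   `truth` (tibble of per-individual sex and chromosome-Y-loss status).
#' @examples
#' pop <- generate_population(synth_config(n_individuals = 20, seed = 42))
#' dplyr::count(pop$annotations, replicate_type)
#' @export
generate_population <- function(config) {
  stopifnot(inherits(config, "cellauth_synth_config"))
  withr::with_seed(config$seed, generate_population_impl(config))
}

generate_population_impl <- function(cfg) {
  panel <- snptrace_panel(cfg$n_fingerprint, cfg$n_ancestry, cfg$n_x, cfg$n_y,
                          fingerprint_freq = cfg$fingerprint_freq)
  anc <- panel$role == "autosomal_ancestry"
  panel$alt_freq[anc] <- runif(sum(anc), cfg$ancestry_freq_range[1],
                               cfg$ancestry_freq_range[2])

  n <- cfg$n_individuals
  ids <- sprintf("S%04d", seq_len(n))
  sexes <- ifelse(runif(n) < cfg$male_fraction, "male", "female")
  y_lost <- sexes == "male" & runif(n) < cfg$chry_loss_rate

  auto <- panel[panel$role %in% c("autosomal_fingerprint", "autosomal_ancestry"), ]
  x_markers <- panel$marker_id[panel$role == "chrX"]
  y_markers <- panel$marker_id[panel$role == "chrY"]

  geno_auto <- purrr::map(auto$alt_freq, function(p) {
    g <- hwe_genotypes(n, p)
    g[runif(n) < cfg$no_call_rate] <- NA_character_
    g
  })
  profiles_auto <- tibble(
    sample_id = rep(ids, times = nrow(auto)),
    marker_id = rep(auto$marker_id, each = n),
    genotype = unlist(geno_auto, use.names = FALSE)
  )

  is_male <- sexes == "male"
  geno_x <- purrr::map(x_markers, function(mk) {
    g <- hwe_genotypes(n, 0.5)
    g[is_male] <- ifelse(runif(sum(is_male)) < 0.5, "A", "B")
    g
  })
  geno_y <- purrr::map(y_markers, function(mk) {
    g <- rep(NA_character_, n)
    present <- is_male & !y_lost
    g[present] <- ifelse(runif(sum(present)) < 0.5, "A", "B")
    g
  })
  profiles_allo <- tibble(
    sample_id = rep(ids, times = cfg$n_x + cfg$n_y),
    marker_id = rep(c(x_markers, y_markers), each = n),
    genotype = unlist(c(geno_x, geno_y), use.names = FALSE)
  )
  profiles <- bind_rows(profiles_auto, profiles_allo) %>%
    arrange(match(sample_id, ids), match(marker_id, panel$marker_id))

  annotations <- tibble(
    sample_id = ids,
    cell_line_name = sprintf("LINE-%04d", seq_len(n)),
    clid = sprintf("CL%05d", seq_len(n)),
    annotated_sex = sexes,
    replicate_type = "none",
    replicate_group = NA_character_,
    synonym_group = NA_character_
  )

  # planted replicates and same-patient derivatives
  parents <- sample(ids, cfg$n_replicates + cfg$n_synonymous)
  rep_parents <- parents[seq_len(cfg$n_replicates)]
  syn_parents <- parents[-seq_len(cfg$n_replicates)]

  for (i in seq_along(rep_parents)) {
    pid <- rep_parents[i]
    new_id <- paste0(pid, "r")
    profiles <- bind_rows(profiles, derive_replicate(
      profiles, pid, new_id,
      no_call_rate = cfg$no_call_rate,
      genotype_error_rate = cfg$genotype_error_rate
    ))
    grp <- paste0("rg_", pid)
    annotations$replicate_group[annotations$sample_id == pid] <- grp
    annotations <- bind_rows(annotations, tibble(
      sample_id = new_id,
      cell_line_name = annotations$cell_line_name[annotations$sample_id == pid],
      clid = annotations$clid[annotations$sample_id == pid],
      annotated_sex = sexes[ids == pid],
      replicate_type = if (i %% 2 == 0) "biological" else "technical",
      replicate_group = grp,
      synonym_group = NA_character_
    ))
  }
  for (pid in syn_parents) {
    new_id <- paste0(pid, "s")
    profiles <- bind_rows(profiles, derive_synonymous(
      profiles, pid, new_id, loh_rate = cfg$loh_rate
    ))
    grp <- paste0("sg_", pid)
    annotations$synonym_group[annotations$sample_id == pid] <- grp
    annotations <- bind_rows(annotations, tibble(
      sample_id = new_id,
      cell_line_name = paste0(
        annotations$cell_line_name[annotations$sample_id == pid], "-D"),
      clid = sprintf("CL%05dD", which(ids == pid)),
      annotated_sex = sexes[ids == pid],
      replicate_type = "none",
      replicate_group = NA_character_,
      synonym_group = grp
    ))
  }

  cn <- diploid_cn(profiles)
  truth <- tibble(sample_id = ids, sex = sexes, chry_lost = y_lost)
  list(panel = panel, profiles = profiles, annotations = annotations,
       cn = cn, truth = truth)
}

# Even diploid copy-number table: 2 copies split across called alleles.
diploid_cn <- function(profiles) {
  called <- profiles %>% filter(!is.na(genotype))
  al <- genotype_alleles(called$genotype)
  k <- lengths(al)
  tibble(
    sample_id = rep(called$sample_id, k),
    marker_id = rep(called$marker_id, k),
    allele = unlist(al, use.names = FALSE),
    copies = rep(2 / k, k)
  )
}

# Allele universe per marker: panel ref/alt when available, otherwise
# every allele observed in the profile set.
marker_universe <- function(profiles, panel = NULL) {
  al <- genotype_alleles(profiles$genotype)
  uni <- lapply(split(al, profiles$marker_id),
                function(a) sort_alleles(unique(unlist(a, use.names = FALSE))))
  if (!is.null(panel)) {
    snp <- panel$marker_id[marker_kind(panel$role) == "snp" &
                             !is.na(panel$ref_allele) & !is.na(panel$alt_allele)]
    for (mk in intersect(snp, names(uni))) {
      i <- match(mk, panel$marker_id)
      uni[[mk]] <- sort_alleles(unique(c(
        uni[[mk]], panel$ref_allele[i], panel$alt_allele[i])))
    }
  }
  uni
}

#' Derive a replicate sample from a parent profile
#'
#' Re-assays a profile: each called locus independently drops to no-call
#' with probability `no_call_rate`, and each surviving genotype is
#' perturbed with probability `genotype_error_rate` (a heterozygous call
#' loses one allele, a homozygous call gains one from the marker's allele
#' universe — the two directions a miscalled cluster can take).
#'
#' @param profiles Long profile tibble containing the parent (other
#'   samples contribute to each marker's allele universe).
#' @param parent_id,new_id Parent sample id and the id for the derived
#'   sample.
#' @param no_call_rate,genotype_error_rate Perturbation rates.
#' @param seed Optional integer seed; by default the ambient RNG stream
#'   is used (so calls inside [generate_population()] stay reproducible).
#' @param panel Optional panel used to complete allele universes.
#' @return A long profile tibble for the new sample.
#' @export
derive_replicate <- function(profiles, parent_id, new_id,
                             no_call_rate = 0.0066,
                             genotype_error_rate = 0.005,
                             seed = NULL, panel = NULL) {
  run <- function() {
    parent <- profiles %>% filter(sample_id == parent_id)
    if (nrow(parent) == 0) abort(paste0("no profile for ", parent_id))
    uni <- marker_universe(profiles, panel)
    g <- parent$genotype
    drop <- !is.na(g)
    drop[drop] <- runif(sum(drop)) < no_call_rate
    g[drop] <- NA_character_
    perturb <- !is.na(g) & runif(length(g)) < genotype_error_rate
    for (i in which(perturb)) {
      alleles <- genotype_alleles(g[i])[[1]]
      if (length(alleles) >= 2) {
        alleles <- alleles[-sample.int(length(alleles), 1)]
      } else {
        others <- setdiff(uni[[parent$marker_id[i]]], alleles)
        if (length(others) > 0) {
          alleles <- c(alleles, others[sample.int(length(others), 1)])
        }
      }
      g[i] <- genotype(alleles)
    }
    tibble(sample_id = new_id, marker_id = parent$marker_id, genotype = g)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Derive a same-patient (synonymous) line from a parent profile
#'
#' Emulates the genotype drift between lines derived from one patient:
#' each heterozygous locus independently collapses to a single allele
#' (loss of heterozygosity) with probability `loh_rate`. For moderate
#' rates the derivative scores below replicates but clearly above
#' unrelated pairs.
#'
#' @inheritParams derive_replicate
#' @param loh_rate Per-heterozygous-locus collapse probability.
#' @return A long profile tibble for the new sample.
#' @export
derive_synonymous <- function(profiles, parent_id, new_id, loh_rate = 0.1,
                              seed = NULL) {
  run <- function() {
    parent <- profiles %>% filter(sample_id == parent_id)
    if (nrow(parent) == 0) abort(paste0("no profile for ", parent_id))
    g <- parent$genotype
    al <- genotype_alleles(g)
    het <- lengths(al) >= 2
    collapse <- het & runif(length(g)) < loh_rate
    for (i in which(collapse)) {
      g[i] <- al[[i]][sample.int(length(al[[i]]), 1)]
    }
    tibble(sample_id = new_id, marker_id = parent$marker_id, genotype = g)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Generate synthetic STR profiles
#'
#' Draws tetranucleotide-style STR genotypes: at each autosomal locus two
#' alleles are sampled uniformly from a locus-specific integer repeat
#' range (duplicates collapse to a homozygous call), and amelogenin is
#' set from the sample's sex (`X` or `X/Y`).
#'
#' @param n Number of samples.
#' @param panel STR marker panel (default [powerplex_panel()]).
#' @param sexes Optional character vector of length `n` (`"male"` /
#'   `"female"`); drawn 50/50 when omitted.
#' @param seed Optional integer seed.
#' @return A list: `profiles` (long tibble, sample ids `STR0001`, ...)
#'   and `sexes`.
#' @export
generate_str_profiles <- function(n, panel = powerplex_panel(), sexes = NULL,
                                  seed = NULL) {
  run <- function() {
    validate_panel(panel)
    ids <- sprintf("STR%04d", seq_len(n))
    if (is.null(sexes)) {
      sexes <- ifelse(runif(n) < 0.5, "male", "female")
    }
    stopifnot(length(sexes) == n)
    loci <- panel$marker_id[panel$role == "str_autosomal"]
    base <- sample(5:12, length(loci), replace = TRUE)
    rows <- purrr::map2(loci, base, function(mk, b) {
      a1 <- sample(b:(b + 7), n, replace = TRUE)
      a2 <- sample(b:(b + 7), n, replace = TRUE)
      g <- vapply(seq_len(n), function(i) genotype(c(a1[i], a2[i])), character(1))
      tibble(sample_id = ids, marker_id = mk, genotype = g)
    }) %>% bind_rows()
    amel <- tibble(
      sample_id = ids, marker_id = "AMEL",
      genotype = ifelse(sexes == "male", "X/Y", "X")
    )
    profiles <- bind_rows(rows, amel) %>%
      arrange(match(sample_id, ids), match(marker_id, panel$marker_id))
    list(profiles = profiles, sexes = sexes)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Derive a microsatellite-unstable line from an STR profile
#'
#' Replication slippage model: every allele at every autosomal STR locus
#' independently shifts by one full repeat (+1 or -1, equiprobable) with
#' probability `slippage_rate`; amelogenin and other non-numeric alleles
#' are untouched. Because slippage moves repeat counts but not SNPs, an
#' MSI derivative keeps a perfect SNP identity to its parent while its
#' STR identity degrades — the signature by which MSI lines confound
#' STR-only authentication.
#'
#' @inheritParams derive_replicate
#' @param slippage_rate Per-allele shift probability.
#' @return A long profile tibble for the new sample.
#' @export
derive_msi <- function(profiles, parent_id, new_id, slippage_rate = 0.15,
                       seed = NULL) {
  run <- function() {
    parent <- profiles %>% filter(sample_id == parent_id)
    if (nrow(parent) == 0) abort(paste0("no profile for ", parent_id))
    g <- vapply(parent$genotype, function(gt) {
      if (is.na(gt)) return(NA_character_)
      alleles <- genotype_alleles(gt)[[1]]
      num <- grepl("^[0-9]+(\\.[0-9]+)?$", alleles)
      slip <- num & runif(length(alleles)) < slippage_rate
      if (any(slip)) {
        shift <- sample(c(-1, 1), sum(slip), replace = TRUE)
        v <- as.numeric(alleles[slip]) + shift
        alleles[slip] <- normalize_str_allele(format(v, trim = TRUE))
      }
      genotype(alleles)
    }, character(1), USE.NAMES = FALSE)
    tibble(sample_id = new_id, marker_id = parent$marker_id, genotype = g)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Generate an aneuploid copy-number profile
#'
#' Draws a per-locus total copy number from `copies` (with optional
#' probabilities `prob`) for every called genotype of every sample, and
#' splits it across the locus's alleles (even split, remainder assigned
#' to random alleles). A point mass at 2 reproduces the diploid setting;
#' the default 1-6 range emulates the aneuploidy of cancer lines, which
#' is what makes reciprocal contamination detection asymmetric.
#'
#' @param profiles Long profile tibble.
#' @param copies Integer vector of possible total copy numbers (default
#'   `1:6`).
#' @param prob Optional sampling weights for `copies`.
#' @param seed Optional integer seed.
#' @return A copy-number tibble: `sample_id`, `marker_id`, `allele`,
#'   `copies`.
#' @export
generate_aneuploid_cn <- function(profiles, copies = 1:6, prob = NULL,
                                  seed = NULL) {
  run <- function() {
    called <- profiles %>% filter(!is.na(genotype))
    al <- genotype_alleles(called$genotype)
    k <- lengths(al)
    totals <- if (length(copies) == 1) {
      rep(as.integer(copies), nrow(called))
    } else {
      sample(copies, nrow(called), replace = TRUE, prob = prob)
    }
    base <- totals %/% k
    rem <- totals %% k
    extra <- purrr::map2(k, rem, function(kk, rr) {
      e <- integer(kk)
      if (rr > 0) {
        picks <- sample.int(kk, rr)
        e[picks] <- 1L
      }
      e
    })
    tibble(
      sample_id = rep(called$sample_id, k),
      marker_id = rep(called$marker_id, k),
      allele = unlist(al, use.names = FALSE),
      copies = rep(base, k) + unlist(extra, use.names = FALSE)
    )
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
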