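# Independent oracles and small fixture builders shared across tests.

# Brute-force allele-sharing identity: naive set operations on lists of
# allele vectors (NULL / character(0) = no-call). Independent of the
# package's bitmask engine.
oracle_tanabe <- function(a, b) {
  loci <- union(names(a), names(b))
  shared <- 0L
  t1 <- 0L
  t2 <- 0L
  n_loci <- 0L
  for (loc in loci) {
    aa <- unique(a[[loc]])
    bb <- unique(b[[loc]])
    if (length(aa) == 0 || length(bb) == 0) next
    n_loci <- n_loci + 1L
    t1 <- t1 + length(aa)
    t2 <- t2 + length(bb)
    shared <- shared + length(intersect(aa, bb))
  }
  if (n_loci == 0) {
    return(list(defined = FALSE))
  }
  list(defined = TRUE, shared = shared, total_a = t1, total_b = t2,
       n_loci = n_loci, score = 2 * shared / (t1 + t2))
}

# Long profile tibble for two samples from named allele-vector lists.
profiles_from_lists <- function(a, b, ids = c("a", "b")) {
  gt <- function(x) if (length(x) == 0) NA_character_ else genotype(x)
  dplyr::bind_rows(
    tibble::tibble(sample_id = ids[1], marker_id = names(a),
                   genotype = vapply(a, gt, character(1))),
    tibble::tibble(sample_id = ids[2], marker_id = names(b),
                   genotype = vapply(b, gt, character(1)))
  )
}

# Standard normal CDF via an erf power series (|x| < 2.5) and a
# continued fraction for erfc (|x| >= 2.5). Written from the classical
# formulas; shares no code with stats::pnorm.
oracle_phi <- function(z) {
  vapply(z, function(zz) 0.5 * oracle_erfc(-zz / sqrt(2)), numeric(1))
}

oracle_erfc <- function(x) {
  if (x < 0) {
    return(2 - oracle_erfc(-x))
  }
  if (x < 2.5) {
    # erf(x) = 2/sqrt(pi) * sum (-1)^n x^(2n+1) / (n! (2n+1))
    term <- x
    total <- x
    n <- 0
    while (abs(term) > 1e-20) {
      n <- n + 1
      term <- term * (-x * x) / n
      total <- total + term / (2 * n + 1)
    }
    1 - 2 / sqrt(pi) * total
  } else {
    # erfc(x) = exp(-x^2)/sqrt(pi) / (x + (1/2)/(x + 1/(x + (3/2)/(x + ...))))
    f <- x
    for (n in 60:1) {
      f <- x + (n / 2) / f
    }
    exp(-x * x) / sqrt(pi) / f
  }
}

# Deterministic fully informative diploid pair: host homozygous "A" and
# contaminant homozygous "B" at every locus.
opposite_homozygous_pair <- function(n_loci = 90) {
  markers <- sprintf("m%03d", seq_len(n_loci))
  dplyr::bind_rows(
    tibble::tibble(sample_id = "host", marker_id = markers, genotype = "A"),
    tibble::tibble(sample_id = "cont", marker_id = markers, genotype = "B")
  )
}

# Uniform copy-number table at a fixed total per locus, even split.
flat_cn <- function(profiles, total) {
  called <- profiles[!is.na(profiles$genotype), ]
  al <- genotype_alleles(called$genotype)
  k <- lengths(al)
  tibble::tibble(
    sample_id = rep(called$sample_id, k),
    marker_id = rep(called$marker_id, k),
    allele = unlist(al, use.names = FALSE),
    copies = rep(total / k, k)
  )
}
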