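#' Marker panel constructors
#'
#' A marker panel is a tibble with one row per marker and columns
#' `marker_id`, `chromosome`, `role`, `ref_allele`, `alt_allele` and
#' `alt_freq`. Roles distinguish the autosomal fingerprinting and
#' ancestry-informative SNPs used for identity scoring from the allosome
#' SNPs used for sex typing, and STR loci from the amelogenin sex marker.
#'
#' `snptrace_panel()` builds a 96-marker SNP fingerprinting panel in the
#' layout of commercial sample-tracking assays: 90 autosomal SNPs
#' (fingerprinting SNPs at a fixed population allele frequency plus
#' ancestry-informative SNPs whose frequencies vary) and 6 allosome SNPs
#' (3 on chromosome X, 3 on chromosome Y) carried for redundancy in sex
#' calling. Marker identifiers are synthetic placeholders in dbSNP "rs"
#' style; supply your own panel file via [read_panel()] to score a real
#' assay.
#'
#' `powerplex_panel()` builds the 16-locus STR panel used for forensic-style
#' profiling: the 13 CODIS core loci plus Penta D, Penta E and the
#' amelogenin sex marker.
#'
#' @param n_fingerprint,n_ancestry Number of autosomal fingerprinting and
#'   ancestry-informative SNPs.
#' @param n_x,n_y Number of chromosome X and chromosome Y SNPs.
#' @param fingerprint_freq Population alternate-allele frequency recorded
#'   for the fingerprinting SNPs.
#' @return A marker-panel tibble.
#' @examples
#' snptrace_panel()
#' powerplex_panel()
#' @export
snptrace_panel <- function(n_fingerprint = 46, n_ancestry = 44, n_x = 3, n_y = 3,
                           fingerprint_freq = 0.5) {
  n_auto <- n_fingerprint + n_ancestry
  auto_chr <- as.character(rep_len(1:22, n_auto))
  tibble(
    marker_id = c(
      sprintf("rs%06d", 100000L + seq_len(n_auto)),
      sprintf("rs%06d", 200000L + seq_len(n_x)),
      sprintf("rs%06d", 300000L + seq_len(n_y))
    ),
    chromosome = c(auto_chr, rep("X", n_x), rep("Y", n_y)),
    role = c(
      rep("autosomal_fingerprint", n_fingerprint),
      rep("autosomal_ancestry", n_ancestry),
      rep("chrX", n_x),
      rep("chrY", n_y)
    ),
    ref_allele = "A",
    alt_allele = "B",
    alt_freq = c(
      rep(fingerprint_freq, n_fingerprint),
      rep(NA_real_, n_ancestry),
      rep(0.5, n_x + n_y)
    )
  )
}

#' @rdname snptrace_panel
#' @export
powerplex_panel <- function() {
  loci <- c(
    D3S1358 = "3", TH01 = "11", D21S11 = "21", D18S51 = "18",
    PentaE = "15", D5S818 = "5", D13S317 = "13", D7S820 = "7",
    D16S539 = "16", CSF1PO = "5", PentaD = "21", vWA = "12",
    D8S1179 = "8", TPOX = "2", FGA = "4"
  )
  tibble(
    marker_id = c(names(loci), "AMEL"),
    chromosome = c(unname(loci), "X"),
    role = c(rep("str_autosomal", length(loci)), "amelogenin"),
    ref_allele = NA_character_,
    alt_allele = NA_character_,
    alt_freq = NA_real_
  )
}

panel_roles <- c(
  "autosomal_fingerprint", "autosomal_ancestry", "chrX", "chrY",
  "amelogenin", "str_autosomal"
)

autosomal_roles <- c("autosomal_fingerprint", "autosomal_ancestry", "str_autosomal")

#' Select markers used for identity scoring
#'
#' Identity scoring uses autosomal markers only: the sex markers (allosome
#' SNPs, amelogenin) would inflate apparent relatedness between same-sex
#' samples and are excluded by default.
#'
#' @param panel A marker-panel tibble.
#' @return Character vector of autosomal marker ids, in panel order.
#' @export
autosomal_markers <- function(panel) {
  validate_panel(panel)
  panel$marker_id[panel$role %in% autosomal_roles]
}

validate_panel <- function(panel, call = rlang::caller_env()) {
  required <- c("marker_id", "chromosome", "role")
  missing <- setdiff(required, names(panel))
  if (length(missing) > 0) {
    abort(paste0("panel lacks column(s): ", paste(missing, collapse = ", ")), call = call)
  }
  if (anyDuplicated(panel$marker_id)) {
    dup <- unique(panel$marker_id[duplicated(panel$marker_id)])
    abort(paste0("duplicate marker_id in panel: ", paste(dup, collapse = ", ")), call = call)
  }
  bad <- setdiff(unique(panel$role), panel_roles)
  if (length(bad) > 0) {
    abort(paste0("unknown panel role(s): ", paste(bad, collapse = ", ")), call = call)
  }
  invisible(panel)
}

#' Read or write a marker panel definition file
#'
#' Panel files are CSV with columns `marker_id`, `chromosome`, `role`,
#' `ref_allele`, `alt_allele`, `alt_freq`.
#'
#' @param path File path.
#' @param panel A marker-panel tibble.
#' @return `read_panel()` returns the panel tibble; `write_panel()` returns
#'   `path` invisibly.
#' @export
read_panel <- function(path) {
  panel <- readr::read_csv(path, col_types = readr::cols(
    marker_id = readr::col_character(),
    chromosome = readr::col_character(),
    role = readr::col_character(),
    ref_allele = readr::col_character(),
    alt_allele = readr::col_character(),
    alt_freq = readr::col_double()
  ))
  validate_panel(panel)
  panel
}

#' @rdname read_panel
#' @export
write_panel <- function(panel, path) {
  validate_panel(panel)
  readr::write_csv(panel, path)
  invisible(path)
}
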