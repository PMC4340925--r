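# Genotype call representation.
#
# A profile table is a long tibble with columns sample_id, marker_id and
# genotype. A genotype is the set of distinct alleles observed at the
# marker, stored as a "/"-joined sorted string ("A", "A/B", "9/9.3",
# "X/Y"); NA_character_ is a no-call. Homozygous calls collapse to a
# single allele because identity scoring counts distinct alleles only.

NO_CALL_TOKENS <- c("no call", "nc", "nocall", "", "—")
NO_CALL_OUT <- "No Call"

is_no_call_token <- function(x) {
  tolower(trimws(x)) %in% NO_CALL_TOKENS | is.na(x)
}

# Order alleles numerically when numeric (STR repeat counts), otherwise
# lexically (SNP bases, amelogenin X/Y); numeric before non-numeric.
sort_alleles <- function(alleles) {
  num <- suppressWarnings(as.numeric(alleles))
  alleles[order(is.na(num), num, alleles)]
}

#' Build and inspect genotype strings
#'
#' Genotype calls are stored as `"/"`-joined sorted strings of distinct
#' alleles (`"A/B"`, `"9/9.3"`), with `NA` meaning no-call. `genotype()`
#' builds the canonical string from an allele vector, `genotype_alleles()`
#' splits one back into alleles, and `is_no_call()` tests for no-calls.
#'
#' @param alleles Character vector of allele labels (duplicates collapse).
#' @param x Character vector of genotype strings.
#' @return `genotype()` a string; `genotype_alleles()` a list of character
#'   vectors (`NA` entries give `character(0)`); `is_no_call()` a logical
#'   vector.
#' @examples
#' genotype(c("A", "A"))    # "A"
#' genotype(c("B", "A"))    # "A/B"
#' genotype_alleles("9/9.3")
#' @export
genotype <- function(alleles) {
  alleles <- unique(as.character(alleles))
  if (length(alleles) == 0 || any(is.na(alleles)) || any(!nzchar(alleles))) {
    abort("a genotype needs at least one non-missing allele; use NA for no-call")
  }
  paste(sort_alleles(alleles), collapse = "/")
}

#' @rdname genotype
#' @export
genotype_alleles <- function(x) {
  out <- strsplit(x, "/", fixed = TRUE)
  out[is.na(x)] <- list(character(0))
  out
}

#' @rdname genotype
#' @export
is_no_call <- function(x) {
  is.na(x)
}

# --- token dialect -----------------------------------------------------

# "9.30" -> "9.3", "09" -> "9", "10.0" -> "10"
normalize_str_allele <- function(x) {
  x <- sub("^0+(?=[0-9])", "", x, perl = TRUE)
  has_dec <- grepl(".", x, fixed = TRUE)
  x[has_dec] <- sub("0+$", "", x[has_dec])
  x[has_dec] <- sub("\\.$", "", x[has_dec])
  x
}

# Parse one table cell into a genotype string, or NA for a no-call.
# `kind` is "snp" (letters, 1-2 alleles) or "str" (comma-separated repeat
# counts / amelogenin X,Y). Unparseable tokens raise a classed error so
# the reader can report row/column.
parse_genotype_token <- function(token, kind = c("snp", "str")) {
  kind <- arg_match(kind)
  if (is_no_call_token(token)) {
    return(NA_character_)
  }
  token <- trimws(token)
  if (kind == "snp") {
    compact <- toupper(gsub("[/: ]", "", token))
    if (!grepl("^[A-Z]{1,2}$", compact)) {
      abort(paste0("unparseable SNP genotype token: '", token, "'"),
            class = "cellauth_parse_error")
    }
    alleles <- strsplit(compact, "", fixed = TRUE)[[1]]
  } else {
    alleles <- trimws(strsplit(token, "[,;/]")[[1]])
    alleles <- alleles[nzchar(alleles)]
    if (length(alleles) == 0) {
      abort(paste0("unparseable STR genotype token: '", token, "'"),
            class = "cellauth_parse_error")
    }
    is_sex <- toupper(alleles) %in% c("X", "Y")
    is_num <- grepl("^[0-9]+(\\.[0-9]+)?$", alleles)
    if (!all(is_sex | is_num)) {
      abort(paste0("unparseable STR genotype token: '", token, "'"),
            class = "cellauth_parse_error")
    }
    alleles[is_sex] <- toupper(alleles[is_sex])
    alleles[is_num] <- normalize_str_allele(alleles[is_num])
  }
  genotype(alleles)
}

# Canonical output token for one genotype string.
format_genotype_token <- function(g, kind = c("snp", "str")) {
  kind <- arg_match(kind)
  if (is.na(g)) {
    return(NO_CALL_OUT)
  }
  alleles <- genotype_alleles(g)[[1]]
  if (kind == "snp") {
    if (length(alleles) == 1) paste0(alleles, alleles) else paste(alleles, collapse = "")
  } else {
    paste(alleles, collapse = ",")
  }
}

marker_kind <- function(role) {
  ifelse(role %in% c("str_autosomal", "amelogenin"), "str", "snp")
}

# --- bitmask encoding for fast pairwise scoring ------------------------

.cellauth_env <- new.env(parent = emptyenv())

popcount16 <- function() {
  if (is.null(.cellauth_env$pc16)) {
    x <- 0:65535
    r <- integer(65536)
    for (b in 0:15) r <- r + bitwAnd(bitwShiftR(x, b), 1L)
    .cellauth_env$pc16 <- r
  }
  .cellauth_env$pc16
}

popcount <- function(x) {
  pc <- popcount16()
  pc[bitwAnd(x, 65535L) + 1L] + pc[bitwShiftR(x, 16L) + 1L]
}

# Encode profiles over a marker set as per-sample allele bitmasks.
# Returns list(samples, markers, masks [n x m integer, 0 = no-call],
# counts [n x m distinct-allele counts], universes per marker).
encode_profiles <- function(profiles, markers, samples = NULL) {
  stopifnot(all(c("sample_id", "marker_id", "genotype") %in% names(profiles)))
  if (is.null(samples)) {
    samples <- unique(profiles$sample_id)
  }
  rows <- profiles[profiles$marker_id %in% markers & profiles$sample_id %in% samples, ]
  n <- length(samples)
  m <- length(markers)
  masks <- matrix(0L, n, m, dimnames = list(samples, markers))
  universes <- vector("list", m)
  names(universes) <- markers
  al <- genotype_alleles(rows$genotype)
  si <- match(rows$sample_id, samples)
  mi <- match(rows$marker_id, markers)
  by_marker <- split(seq_along(al), mi)
  for (k in names(by_marker)) {
    kk <- as.integer(k)
    idx <- by_marker[[k]]
    uni <- sort_alleles(unique(unlist(al[idx], use.names = FALSE)))
    if (length(uni) > 30) {
      abort(paste0("more than 30 distinct alleles at marker ", markers[kk]))
    }
    universes[[kk]] <- uni
    mk <- vapply(al[idx], function(a) {
      if (length(a) == 0) 0L else sum(bitwShiftL(1L, match(a, uni) - 1L))
    }, integer(1))
    masks[cbind(si[idx], kk)] <- mk
  }
  list(samples = samples, markers = markers, masks = masks,
       counts = matrix(popcount(masks), n, m, dimnames = dimnames(masks)),
       universes = universes)
}
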