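#' Additive, dominance and imprinting coding matrices
#'
#' Builds the three SNP coding matrices used by the mixture models from phased
#' genotypes and allele frequencies `p_j` of the counted allele A2:
#'
#' * additive `M_a`: A1A1 -> `-2p`, heterozygote -> `1 - 2p`, A2A2 -> `2 - 2p`
#'   (the centred allele count);
#' * dominance `M_d`: A1A1 -> `-2p^2`, heterozygote -> `2p(1 - p)`,
#'   A2A2 -> `-2(1 - p)^2` (centred heterozygosity contrast);
#' * imprinting `M_i`: homozygotes -> `0`, A1A2 (paternal A1, maternal A2)
#'   -> `+1`, A2A1 (paternal A2) -> `-1` (signed reciprocal-heterozygote
#'   contrast).
#'
#' Under Hardy-Weinberg genotype frequencies all three columns have zero mean,
#' and their variances are `2p(1-p)` (additive), `(2p(1-p))^2` (dominance) and
#' `2p(1-p)` (imprinting, under random mating) - the per-SNP scalings used in
#' [additive_variance()] and friends.
#'
#' @param genotypes A [phased_genotypes] object.
#' @param freqs Allele frequencies used for centring; by default recomputed
#'   from `genotypes` (in a training/validation analysis, pass the
#'   training-set frequencies). All must lie strictly in (0, 1).
#' @param missing_action How to treat missing genotypes: `"fill"` (default)
#'   sets the entry to the coding-column expectation, which is 0 for all three
#'   centred/signed codings, leaving column means unchanged; `"error"` stops.
#' @return For the individual coding functions, an individuals x SNPs numeric
#'   matrix. For `design_matrices()`, an object of class `design_matrix_set`:
#'   a list with the requested matrices (`M_a`, `M_d`, `M_i`), the `freqs`
#'   used, and the `effects` included.
#' @export
design_matrices <- function(genotypes,
                            freqs = NULL,
                            effects = c("additive", "dominance", "imprinting"),
                            missing_action = c("fill", "error")) {
  effects <- match.arg(effects, several.ok = TRUE)
  missing_action <- match.arg(missing_action)
  if (is.null(freqs)) freqs <- allele_frequency(genotypes)
  out <- list(freqs = freqs, effects = effects,
              sample_ids = genotypes$sample_ids,
              snp_ids = genotypes$snp_ids)
  if ("additive" %in% effects) {
    out$M_a <- additive_codes(genotypes, freqs, missing_action)
  }
  if ("dominance" %in% effects) {
    out$M_d <- dominance_codes(genotypes, freqs, missing_action)
  }
  if ("imprinting" %in% effects) {
    out$M_i <- imprinting_codes(genotypes, missing_action)
  }
  structure(out, class = "design_matrix_set")
}

#' @export
print.design_matrix_set <- function(x, ...) {
  cat("<design_matrix_set> ", length(x$sample_ids), " x ", length(x$snp_ids),
      "; effects: ", paste(x$effects, collapse = ", "), "\n", sep = "")
  invisible(x)
}

check_freqs <- function(freqs, m) {
  if (length(freqs) != m) stop("length(freqs) must equal the number of SNPs")
  if (any(!is.finite(freqs)) || any(freqs <= 0) || any(freqs >= 1)) {
    stop("allele frequencies must lie strictly in (0, 1)")
  }
  invisible(freqs)
}

#' @rdname design_matrices
#' @export
additive_codes <- function(genotypes, freqs,
                           missing_action = c("fill", "error")) {
  missing_action <- match.arg(missing_action)
  g <- genotype_dosage(genotypes)
  check_freqs(freqs, ncol(g))
  miss <- is.na(g)
  if (any(miss) && missing_action == "error") {
    stop("missing genotypes present; use missing_action = \"fill\"")
  }
  M <- sweep(ifelse(miss, 0, g), 2, 2 * freqs)
  M[miss] <- 0
  dimnames(M) <- dimnames(g)
  M
}

#' @rdname design_matrices
#' @export
dominance_codes <- function(genotypes, freqs,
                            missing_action = c("fill", "error")) {
  missing_action <- match.arg(missing_action)
  g <- genotype_dosage(genotypes)
  check_freqs(freqs, ncol(g))
  miss <- is.na(g)
  if (any(miss) && missing_action == "error") {
    stop("missing genotypes present; use missing_action = \"fill\"")
  }
  p <- matrix(freqs, nrow = nrow(g), ncol = ncol(g), byrow = TRUE)
  M <- matrix(0, nrow(g), ncol(g), dimnames = dimnames(g))
  M[!miss & g == 0L] <- (-2 * p^2)[!miss & g == 0L]
  M[!miss & g == 1L] <- (2 * p * (1 - p))[!miss & g == 1L]
  M[!miss & g == 2L] <- (-2 * (1 - p)^2)[!miss & g == 2L]
  M
}

#' @rdname design_matrices
#' @export
imprinting_codes <- function(genotypes,
                             missing_action = c("fill", "error")) {
  missing_action <- match.arg(missing_action)
  pat <- genotypes$paternal
  mat <- genotypes$maternal
  miss <- is.na(pat)
  if (any(miss) && missing_action == "error") {
    stop("missing phase/genotype present; use missing_action = \"fill\"")
  }
  M <- matrix(0, nrow(pat), ncol(pat), dimnames = dimnames(pat))
  M[!miss & pat == 0L & mat == 1L] <- 1
  M[!miss & pat == 1L & mat == 0L] <- -1
  M
}
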