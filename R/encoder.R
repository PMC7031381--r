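#' Prepare an HLA sequence for encoding
#'
#' Normalizes an HLA class I protein sequence to the fixed encoder length of
#' 183 residues (the alpha-1/alpha-2 peptide-binding window of the mature
#' chain). Shorter sequences are right-padded with the neutral token `X`
#' (zero energy against every residue); longer sequences are truncated to
#' their first 183 residues. The locus (A or B) is parsed from the allele
#' name.
#'
#' @param allele Allele name, e.g. `"HLA-A*02:01"`.
#' @param sequence Amino-acid sequence (20-letter alphabet).
#' @return An `hla_sequence`: list with `allele`, `locus` and `residues`
#'   (character scalar of length exactly 183).
#' @export
prepare_hla <- function(allele, sequence) {
  m <- regmatches(allele, regexec("^HLA-([AB])", allele))[[1]]
  if (length(m) < 2)
    np_stop(sprintf("cannot parse locus from allele name '%s'", allele),
            "neopred_allele_error")
  locus <- m[2]
  if (nchar(sequence) == 0)
    np_stop("empty HLA sequence", "neopred_alphabet_error")
  check_alphabet(sequence, sprintf("HLA sequence for %s", allele))
  n <- nchar(sequence)
  residues <- if (n >= HLA_LENGTH) {
    substr(sequence, 1L, HLA_LENGTH)
  } else {
    paste0(sequence, strrep(AA_PAD, HLA_LENGTH - n))
  }
  structure(list(allele = allele, locus = locus, residues = residues),
            class = "hla_sequence")
}

#' @exportS3Method base::print
print.hla_sequence <- function(x, ...) {
  cat(sprintf("<hla_sequence> %s (locus %s), %d residues\n",
              x$allele, x$locus, nchar(x$residues)))
  invisible(x)
}

# 21 x 21 lookup with the neutral pad token as a zero row/column.
augment_energy <- function(E) {
  V <- rbind(cbind(E$values, 0), 0)
  dimnames(V) <- list(c(AA_ALPHABET, AA_PAD), c(AA_ALPHABET, AA_PAD))
  V
}

#' Peptide x HLA interaction map
#'
#' Encodes a peptide/HLA pair as the two-dimensional interaction map used as
#' CNN input: cell `(i, j)` holds the contact-potential energy between
#' peptide residue `i` and HLA residue `j`. Padding columns (neutral token)
#' are exactly zero.
#'
#' @param peptide 9- or 10-mer amino-acid string.
#' @param hla An `hla_sequence` from [prepare_hla()].
#' @param energy An `energy_matrix`.
#' @return An `interaction_map`: list with `values` (P x 183 matrix),
#'   `peptide`, `allele`.
#' @export
interaction_map <- function(peptide, hla, energy) {
  if (!nchar(peptide) %in% c(9L, 10L))
    np_stop("peptide must be a 9-mer or 10-mer", "neopred_config_error")
  check_alphabet(peptide, "peptide")
  if (!inherits(hla, "hla_sequence"))
    np_stop("hla must come from prepare_hla()", "neopred_config_error")
  V <- augment_energy(energy)
  p <- split_chars(peptide)
  h <- split_chars(hla$residues)
  vals <- V[p, h, drop = FALSE]
  dimnames(vals) <- NULL
  structure(list(values = vals, peptide = peptide, allele = hla$allele),
            class = "interaction_map")
}

#' Sum-of-preferences baseline score
#'
#' The naive binding score used as a baseline: the plain sum of all entries
#' of the interaction map. Because preferences are encoded as energies,
#' lower sums are more binder-like; callers rank candidates ascending.
#'
#' @param map An `interaction_map` (or bare matrix).
#' @return Numeric scalar.
#' @export
sum_preference_score <- function(map) {
  if (inherits(map, "interaction_map")) map <- map$values
  sum(map)
}

#' Encode a batch of peptides against one HLA
#'
#' Stacks interaction maps for equal-length peptides into the
#' `n x P x 183` array consumed by the CNN trainer.
#'
#' @param peptides Character vector of equal-length 9- or 10-mers.
#' @param hla An `hla_sequence`.
#' @param energy An `energy_matrix`.
#' @return Numeric array of dimension `(n, P, 183)`.
#' @export
encode_batch <- function(peptides, hla, energy) {
  P <- unique(nchar(peptides))
  if (length(P) != 1L || !P %in% c(9L, 10L))
    np_stop("all peptides must share one length of 9 or 10",
            "neopred_config_error")
  V <- augment_energy(energy)
  h <- split_chars(hla$residues)
  hi <- match(h, colnames(V))
  out <- array(0, c(length(peptides), P, HLA_LENGTH))
  pm <- matrix(unlist(strsplit(peptides, "", fixed = TRUE)),
               nrow = length(peptides), byrow = TRUE)
  pi_ <- matrix(match(pm, rownames(V)), nrow = length(peptides))
  if (anyNA(pi_))
    np_stop("invalid residue letter(s) in peptides", "neopred_alphabet_error")
  for (i in seq_len(P)) out[, i, ] <- V[pi_[, i], hi, drop = FALSE]
  out
}
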