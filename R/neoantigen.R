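#' A somatic mutation record
#'
#' @param sample,gene Identifiers.
#' @param position 1-based protein position.
#' @param ref,alt Reference and alternate amino-acid letters.
#' @param class `"missense"`, `"synonymous"` or `"indel"`.
#' @param sift_damaging,provean_deleterious Functionality flags as called
#'   by SIFT / PROVEAN (consumed as input, never computed here).
#' @return A `mutation_record` (one-row data frame).
#' @export
mutation_record <- function(sample, gene, position, ref, alt,
                            class = c("missense", "synonymous", "indel"),
                            sift_damaging = NA, provean_deleterious = NA) {
  class <- match.arg(class)
  position <- as.integer(position)
  if (position < 1) np_stop("position must be >= 1", "neopred_value_error")
  if (class == "missense" && identical(ref, alt))
    np_stop("missense mutation requires ref != alt", "neopred_value_error")
  out <- data.frame(sample = sample, gene = gene, position = position,
                    ref = ref, alt = alt, class = class,
                    sift_damaging = sift_damaging,
                    provean_deleterious = provean_deleterious,
                    stringsAsFactors = FALSE)
  class(out) <- c("mutation_record", "data.frame")
  out
}

#' Mutant peptides covering a missense mutation
#'
#' Applies a single amino-acid substitution to a protein sequence and
#' returns every k-mer window of the mutant protein that contains the
#' mutated position, i.e. windows starting at
#' `max(1, pos - k + 1) ... min(pos, L - k + 1)`.
#'
#' @param protein Protein amino-acid sequence (character scalar).
#' @param mutation A `mutation_record` of class `"missense"`. Indels are
#'   supported only by passing the caller-built mutant protein directly as
#'   `protein` with a synthetic missense record marking the first changed
#'   position.
#' @param k Peptide length, 9 or 10.
#' @return Character vector of k-mers (possibly empty when `L < k`).
#' @export
mutant_peptides <- function(protein, mutation, k = 9L) {
  k <- as.integer(k)
  if (!k %in% c(9L, 10L))
    np_stop("k must be 9 or 10", "neopred_value_error")
  if (mutation$class != "missense")
    np_stop(sprintf("mutation class '%s' not supported for window enumeration",
                    mutation$class), "neopred_value_error")
  L <- nchar(protein)
  pos <- mutation$position
  if (pos > L)
    np_stop(sprintf("position %d beyond protein length %d", pos, L),
            "neopred_value_error")
  if (substr(protein, pos, pos) != mutation$ref)
    np_stop(sprintf(
      "reference mismatch for %s/%s at position %d: protein has %s, record %s",
      mutation$sample, mutation$gene, pos, substr(protein, pos, pos),
      mutation$ref), "neopred_reference_mismatch")
  mut <- protein
  substr(mut, pos, pos) <- mutation$alt
  lo <- max(1L, pos - k + 1L)
  hi <- min(pos, L - k + 1L)
  if (hi < lo) return(character(0))
  vapply(lo:hi, function(s) substr(mut, s, s + k - 1L), character(1))
}

#' Score peptides against HLA alleles with trained binding models
#'
#' Every peptide x allele combination is scored with the model keyed by the
#' allele's locus and the peptide's length; a combination whose key has no
#' model is skipped with a warning (counted in the output attribute
#' `n_skipped`). A peptide is called a binder when its probability is at
#' least 0.5 (inclusive boundary).
#'
#' @param peptides Character vector of 9-/10-mers.
#' @param alleles Character vector of allele names.
#' @param models Named list of `binding_model`s keyed `"<locus><length>"`
#'   (e.g. `"A9"`).
#' @param hla_table Data frame with columns `allele`, `sequence`.
#' @param energy An `energy_matrix`.
#' @return Data frame with columns `peptide`, `allele`, `probability`,
#'   `binder`.
#' @export
call_binders <- function(peptides, alleles, models, hla_table, energy) {
  out <- data.frame(peptide = character(0), allele = character(0),
                    probability = numeric(0), binder = logical(0))
  n_skipped <- 0L
  if (length(peptides) == 0 || length(alleles) == 0) {
    attr(out, "n_skipped") <- n_skipped
    return(out)
  }
  res <- list()
  for (al in unique(alleles)) {
    row <- match(al, hla_table$allele)
    if (is.na(row)) {
      warning(sprintf("allele %s has no sequence; skipped", al))
      n_skipped <- n_skipped + length(peptides)
      next
    }
    hla <- prepare_hla(al, hla_table$sequence[row])
    for (len in unique(nchar(peptides))) {
      key <- paste0(hla$locus, len)
      pep <- peptides[nchar(peptides) == len]
      if (is.null(models[[key]])) {
        warning(sprintf("no model for key %s; %d call(s) skipped",
                        key, length(pep)))
        n_skipped <- n_skipped + length(pep)
        next
      }
      maps <- encode_batch(pep, hla, energy)
      prob <- predict(models[[key]], maps)
      res[[length(res) + 1L]] <-
        data.frame(peptide = pep, allele = al, probability = prob,
                   binder = prob >= 0.5, stringsAsFactors = FALSE)
    }
  }
  if (length(res) > 0) out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Per-sample neoantigen load
#'
#' The load of a sample is the number of distinct mutant peptide sequences
#' predicted to bind at least one of the sample's HLA alleles (a peptide
#' binding several alleles counts once).
#'
#' @param calls Data frame as returned by [call_binders()] plus a `sample`
#'   column.
#' @return Named integer vector of loads, one entry per sample present in
#'   `calls`.
#' @export
neoantigen_load <- function(calls) {
  stopifnot(all(c("sample", "peptide", "binder") %in% names(calls)))
  samples <- unique(calls$sample)
  load <- vapply(samples, function(s) {
    sub <- calls[calls$sample == s & calls$binder, , drop = FALSE]
    length(unique(sub$peptide))
  }, integer(1))
  names(load) <- samples
  load
}

#' Neoantigen groups and resistance labels
#'
#' Two thresholds coexist by definition: the survival-style high/low split
#' uses `load >= threshold`, while the resistance label is strict
#' (`load > threshold` and no clinical benefit). Samples with unknown
#' benefit get `NA` resistance.
#'
#' @param load Named numeric vector of per-sample neoantigen counts.
#' @param benefit Logical vector aligned with `load` (clinical benefit);
#'   may contain `NA`.
#' @param threshold Neoantigen count threshold (default 70).
#' @return A `load_table` data frame: `sample`, `load`, `group`
#'   (`"high"`/`"low"`), `benefit`, `resistant`.
#' @export
assign_groups <- function(load, benefit = NA, threshold = 70) {
  stopifnot(threshold > 0)
  n <- length(load)
  benefit <- rep_len(benefit, n)
  out <- data.frame(
    sample = if (is.null(names(load))) as.character(seq_len(n)) else
      names(load),
    load = as.numeric(load),
    group = ifelse(load >= threshold, "high", "low"),
    benefit = benefit,
    resistant = ifelse(is.na(benefit), NA, load > threshold & !benefit),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("load_table", "data.frame")
  out
}
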