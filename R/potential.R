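#' Parse a protein chain from PDB-format text
#'
#' Reads `ATOM` records from PDB text and assembles one chain as an ordered
#' residue list with C-alpha and all-atom coordinates. Only the first model
#' (records before the first `ENDMDL`) and the first alternate location
#' (blank or `A`) are retained. Residues that are not one of the 20 canonical
#' amino acids are skipped with a warning.
#'
#' @param pdb_text Character scalar (whole file) or character vector of lines.
#' @param chain Chain identifier to extract; `NULL` selects the first chain
#'   that appears.
#' @return An object of class `residue_structure`: a list with elements
#'   `chain`, `resno` (1-based, strictly increasing), `resname` (one-letter
#'   codes), `calpha` (n x 3 matrix, Angstrom) and `atoms` (list of m x 3
#'   matrices, one per residue, C-alpha included).
#' @export
parse_structure <- function(pdb_text, chain = NULL) {
  lines <- if (length(pdb_text) == 1L && grepl("\n", pdb_text, fixed = TRUE))
    strsplit(pdb_text, "\n", fixed = TRUE)[[1]] else pdb_text
  endm <- which(startsWith(lines, "ENDMDL"))
  if (length(endm) > 0) lines <- lines[seq_len(endm[1] - 1L)]
  atom <- lines[startsWith(lines, "ATOM")]
  if (length(atom) == 0)
    np_stop("no ATOM records with canonical residues found",
            "neopred_empty_structure")

  fld <- function(x, a, b) trimws(substring(x, a, b))
  rec <- data.frame(
    atom_name = fld(atom, 13, 16),
    altloc    = substring(atom, 17, 17),
    resname   = fld(atom, 18, 20),
    chain     = substring(atom, 22, 22),
    resno     = suppressWarnings(as.integer(fld(atom, 23, 26))),
    x = suppressWarnings(as.numeric(fld(atom, 31, 38))),
    y = suppressWarnings(as.numeric(fld(atom, 39, 46))),
    z = suppressWarnings(as.numeric(fld(atom, 47, 54))),
    line = seq_along(atom),
    stringsAsFactors = FALSE)
  bad <- which(is.na(rec$x) | is.na(rec$y) | is.na(rec$z) | is.na(rec$resno))
  if (length(bad) > 0)
    np_stop(sprintf("malformed coordinate/residue field in ATOM record %d: %s",
                    bad[1], atom[bad[1]]), "neopred_parse_error")

  rec <- rec[rec$altloc %in% c(" ", "", "A"), , drop = FALSE]
  if (is.null(chain)) chain <- rec$chain[1]
  rec <- rec[rec$chain == chain, , drop = FALSE]

  noncanon <- setdiff(unique(rec$resname), names(AA_THREE_TO_ONE))
  if (length(noncanon) > 0) {
    warning(sprintf("skipping non-canonical residue(s): %s",
                    paste(noncanon, collapse = ", ")))
    rec <- rec[rec$resname %in% names(AA_THREE_TO_ONE), , drop = FALSE]
  }
  if (nrow(rec) == 0)
    np_stop("no ATOM records with canonical residues found",
            "neopred_empty_structure")

  ord <- order(rec$resno, rec$line)
  rec <- rec[ord, , drop = FALSE]
  resno <- sort(unique(rec$resno))
  resname <- character(length(resno))
  calpha <- matrix(NA_real_, length(resno), 3)
  atoms <- vector("list", length(resno))
  for (i in seq_along(resno)) {
    ri <- rec[rec$resno == resno[i], , drop = FALSE]
    resname[i] <- AA_THREE_TO_ONE[[ri$resname[1]]]
    atoms[[i]] <- cbind(ri$x, ri$y, ri$z)
    ca <- which(ri$atom_name == "CA")
    if (length(ca) == 0)
      np_stop(sprintf("residue %d has no C-alpha atom", resno[i]),
              "neopred_parse_error")
    calpha[i, ] <- c(ri$x[ca[1]], ri$y[ca[1]], ri$z[ca[1]])
  }
  structure(list(chain = chain, resno = resno, resname = resname,
                 calpha = calpha, atoms = atoms),
            class = "residue_structure")
}

#' Construct a residue structure from coordinates
#'
#' Programmatic constructor used by the synthetic-structure generator and in
#' tests; validates the `residue_structure` invariants.
#'
#' @param resno Strictly increasing 1-based integer residue indices.
#' @param resname One-letter residue codes.
#' @param calpha n x 3 matrix of C-alpha coordinates (Angstrom).
#' @param atoms Optional list of per-residue m x 3 atom coordinate matrices;
#'   defaults to the C-alpha alone.
#' @param chain Chain identifier.
#' @return A `residue_structure`.
#' @export
residue_structure <- function(resno, resname, calpha, atoms = NULL,
                              chain = "A") {
  resno <- as.integer(resno)
  if (any(diff(resno) <= 0))
    np_stop("residue indices must be strictly increasing",
            "neopred_parse_error")
  stopifnot(length(resname) == length(resno), nrow(calpha) == length(resno))
  bad <- setdiff(unique(resname), AA_ALPHABET)
  if (length(bad) > 0)
    np_stop(sprintf("non-canonical residue name(s): %s",
                    paste(bad, collapse = ", ")), "neopred_parse_error")
  if (is.null(atoms))
    atoms <- lapply(seq_along(resno), function(i) calpha[i, , drop = FALSE])
  structure(list(chain = chain, resno = resno, resname = resname,
                 calpha = calpha, atoms = atoms),
            class = "residue_structure")
}

#' @exportS3Method base::print
print.residue_structure <- function(x, ...) {
  cat(sprintf("<residue_structure> chain %s, %d residues (%d-%d)\n",
              x$chain, length(x$resno), min(x$resno), max(x$resno)))
  invisible(x)
}

#' Residue-residue contact pairs
#'
#' Finds residue pairs in spatial contact. In `calpha` mode two residues are
#' in contact when their C-alpha distance is at most 6.5 Angstrom, excluding
#' sequence neighbours with `|i - j| <= 1`. In `allatom` mode contact means
#' any-atom minimum distance at most 4.5 Angstrom, excluding `|i - j| <= 2`.
#' Distance comparisons are inclusive at the cutoff.
#'
#' @param struct A `residue_structure`.
#' @param mode `"calpha"` or `"allatom"`.
#' @return Integer matrix with two columns (`i`, `j`), residue sequence
#'   indices with `i < j`, one row per contact; zero rows when none.
#' @export
contact_pairs <- function(struct, mode = c("calpha", "allatom")) {
  if (!inherits(struct, "residue_structure"))
    np_stop("struct must be a residue_structure", "neopred_config_error")
  if (length(mode) != 1L || !mode %in% c("calpha", "allatom")) {
    mode <- tryCatch(match.arg(mode),
                     error = function(e)
                       np_stop("unknown contact mode", "neopred_config_error"))
  }
  n <- length(struct$resno)
  cutoff <- if (mode == "calpha") 6.5 else 4.5
  excl <- if (mode == "calpha") 1L else 2L
  out <- matrix(integer(0), ncol = 2,
                dimnames = list(NULL, c("i", "j")))
  if (n < 2) return(out)
  pairs <- list()
  for (a in seq_len(n - 1L)) {
    for (b in seq(a + 1L, n)) {
      ia <- struct$resno[a]; ib <- struct$resno[b]
      if (abs(ia - ib) <= excl) next
      d <- if (mode == "calpha") {
        sqrt(sum((struct$calpha[a, ] - struct$calpha[b, ])^2))
      } else {
        A <- struct$atoms[[a]]; B <- struct$atoms[[b]]
        # min over the atom-atom cross distances
        d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
        sqrt(max(min(d2), 0))
      }
      if (d <= cutoff) pairs[[length(pairs) + 1L]] <- c(ia, ib)
    }
  }
  if (length(pairs) > 0) out <- do.call(rbind, pairs)
  colnames(out) <- c("i", "j")
  out
}

#' Aggregate amino-acid contact counts over structures
#'
#' Tallies, over a set of structures, how often each unordered pair of
#' residue types is found in contact. The returned matrix is symmetric;
#' a contact between types a and b increments both `[a, b]` and `[b, a]`
#' (diagonal contacts are counted once per contact).
#'
#' @param structures A `residue_structure` or list of them.
#' @param mode Passed to [contact_pairs()].
#' @return A `contact_counts` object: list with `counts` (20 x 20 named
#'   integer matrix), `mode`, `n_structures`.
#' @export
count_contacts <- function(structures, mode = c("calpha", "allatom")) {
  mode <- match.arg(mode)
  if (inherits(structures, "residue_structure")) structures <- list(structures)
  if (length(structures) < 1)
    np_stop("at least one structure required", "neopred_config_error")
  counts <- matrix(0L, 20, 20, dimnames = list(AA_ALPHABET, AA_ALPHABET))
  for (s in structures) {
    cp <- contact_pairs(s, mode)
    if (nrow(cp) == 0) next
    idx <- match(cp, s$resno)       # both columns at once
    dim(idx) <- dim(cp)
    ta <- s$resname[idx[, 1]]
    tb <- s$resname[idx[, 2]]
    for (r in seq_along(ta)) {
      counts[ta[r], tb[r]] <- counts[ta[r], tb[r]] + 1L
      if (ta[r] != tb[r]) counts[tb[r], ta[r]] <- counts[tb[r], ta[r]] + 1L
    }
  }
  structure(list(counts = counts, mode = mode,
                 n_structures = length(structures)),
            class = "contact_counts")
}

#' Quasi-chemical contact energies from contact counts
#'
#' Converts contact counts into an energy-like log-odds preference matrix:
#' `e(a, b) = -ln( f(a, b) / (f(a) * f(b)) )` with `f(a, b) = c[a, b] / T`,
#' where `T` is the total number of (unordered) contacts and `f(a)` the
#' row-sum frequency of type `a`. Lower values mean a more preferred
#' (energetically favourable) pairing. Residue types never seen in any
#' contact get a zero (neutral) row/column with a warning; pairs never
#' observed between two observed types are imputed to the maximum finite
#' entry (the most unfavourable observed level) with a warning.
#'
#' @param counts A `contact_counts` object.
#' @return An `energy_matrix` object: list with `values` (symmetric 20 x 20
#'   named matrix), `variant` (from `counts$mode`), `seed = NULL`.
#' @export
energy_matrix <- function(counts) {
  if (!inherits(counts, "contact_counts"))
    np_stop("counts must be a contact_counts object", "neopred_config_error")
  cm <- counts$counts
  total <- sum(cm[upper.tri(cm, diag = TRUE)])
  if (total <= 0)
    np_stop("zero total contacts: energies undefined",
            "neopred_degenerate_counts")
  f_pair <- cm / total
  f_marg <- rowSums(cm) / total
  E <- -log(f_pair / outer(f_marg, f_marg))
  undef <- f_marg == 0
  if (any(undef)) {
    warning(sprintf("residue type(s) with no contacts imputed to 0: %s",
                    paste(AA_ALPHABET[undef], collapse = ", ")))
    E[undef, ] <- 0
    E[, undef] <- 0
  }
  inf <- !is.finite(E)
  if (any(inf)) {
    mx <- max(E[!inf])
    warning(sprintf("%d unobserved pair(s) imputed to max finite energy %.4g",
                    sum(inf & upper.tri(inf, diag = TRUE)), mx))
    E[inf] <- mx
  }
  new_energy_matrix(E, variant = counts$mode)
}

#' Wrap a numeric 20 x 20 matrix as an energy matrix
#'
#' Validates symmetry and dimensions and returns an `energy_matrix` of
#' variant `"loaded"` (used for externally supplied potentials).
#'
#' @param values Symmetric 20 x 20 numeric matrix, rows/columns in the
#'   alphabetical one-letter order.
#' @param variant Variant tag.
#' @return An `energy_matrix`.
#' @export
as_energy_matrix <- function(values, variant = "loaded") {
  new_energy_matrix(values, variant)
}

new_energy_matrix <- function(values, variant, seed = NULL) {
  stopifnot(is.matrix(values), nrow(values) == 20, ncol(values) == 20)
  dimnames(values) <- list(AA_ALPHABET, AA_ALPHABET)
  if (max(abs(values - t(values))) > 1e-9)
    np_stop("energy matrix must be symmetric", "neopred_config_error")
  values <- (values + t(values)) / 2   # enforce exact symmetry
  structure(list(values = values, variant = variant, seed = seed),
            class = "energy_matrix")
}

#' @exportS3Method base::print
print.energy_matrix <- function(x, ...) {
  cat(sprintf("<energy_matrix> variant=%s, range [%.3f, %.3f]\n",
              x$variant, min(x$values), max(x$values)))
  invisible(x)
}

#' Permuted and null control matrices
#'
#' Builds the negative-control counterparts of an energy matrix: `permuted`
#' randomly permutes the multiset of upper-triangle entries (diagonal
#' included) under the given seed and mirrors back to symmetry; `null` is
#' identically zero, so every interaction map encoded with it is the zero
#' map.
#'
#' @param base An `energy_matrix`.
#' @param kind `"permuted"` or `"null"`.
#' @param seed Integer seed (permuted only).
#' @return An `energy_matrix` with `variant` set to `kind`.
#' @export
control_matrix <- function(base, kind = c("permuted", "null"), seed = 1L) {
  if (!inherits(base, "energy_matrix"))
    np_stop("base must be an energy_matrix", "neopred_config_error")
  if (length(kind) != 1L || !kind %in% c("permuted", "null"))
    np_stop("unknown control kind", "neopred_config_error")
  if (kind == "null")
    return(new_energy_matrix(matrix(0, 20, 20), variant = "null"))
  V <- base$values
  ut <- upper.tri(V, diag = TRUE)
  vals <- V[ut]
  perm <- withr::with_seed(as.integer(seed), sample(vals))
  P <- matrix(0, 20, 20)
  P[ut] <- perm
  P <- P + t(P) - diag(diag(P))
  new_energy_matrix(P, variant = "permuted", seed = as.integer(seed))
}

#' Write / read an energy matrix as TSV
#'
#' The on-disk form is a 21 x 21 tab-separated table: a header row and a
#' leading column of one-letter codes around the 20 x 20 values, printed at
#' full precision so the round trip is bit-exact.
#'
#' @param E An `energy_matrix`.
#' @param path File path.
#' @return `write_energy_matrix` returns `path` invisibly;
#'   `read_energy_matrix` returns an `energy_matrix` with variant
#'   `"loaded"`.
#' @export
write_energy_matrix <- function(E, path) {
  V <- E$values
  lines <- c(paste(c("", colnames(V)), collapse = "\t"),
             vapply(seq_len(20), function(i)
               paste(c(rownames(V)[i], sprintf("%.17g", V[i, ])),
                     collapse = "\t"), character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_energy_matrix
#' @export
read_energy_matrix <- function(path) {
  tab <- read.delim(path, row.names = 1, check.names = FALSE)
  V <- as.matrix(tab)
  if (!identical(rownames(V), AA_ALPHABET) ||
      !identical(colnames(V), AA_ALPHABET))
    np_stop("energy matrix TSV must be indexed by the 20 one-letter codes",
            "neopred_config_error")
  new_energy_matrix(V, variant = "loaded")
}
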