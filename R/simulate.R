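#' Planted anchor-motif specification
#'
#' Describes the ground-truth binding rule planted into synthetic binding
#' data: anchor positions (conventionally position 2 and the C-terminus),
#' the preferred residues at each anchor, and the log-odds effect of a
#' matched anchor on top of a background binder rate. Under the
#' `"additive"` rule the binder log-odds rise by `effect` per matched
#' anchor; under the `"all"` rule the full effect applies only when every
#' anchor is matched (a position-specific, non-additive combination).
#'
#' The defaults encode a strongly anchor-driven world (background binder
#' rate 1 percent, +6 log-odds per matched anchor), chosen so that the
#' Bayes-optimal AUC of the planted rule is about 0.95 and a well-trained
#' classifier can exceed 0.90 held out.
#'
#' @param anchors Anchor positions within the peptide.
#' @param preferred List (one element per anchor) of preferred residue
#'   vectors.
#' @param effect Log-odds contribution per matched anchor (>= 0).
#' @param background Background binder rate in (0, 1).
#' @param rule `"additive"` or `"all"`.
#' @return A `motif_spec`.
#' @export
motif_spec <- function(anchors = c(2L, 9L),
                       preferred = list(c("L", "M", "I", "V"),
                                        c("V", "L", "I", "F")),
                       effect = 6, background = 0.01,
                       rule = c("additive", "all")) {
  rule <- match.arg(rule)
  if (effect < 0)
    np_stop("motif effect must be nonnegative", "neopred_config_error")
  stopifnot(length(preferred) == length(anchors),
            background > 0, background < 1)
  structure(list(anchors = as.integer(anchors), preferred = preferred,
                 effect = effect, background = background, rule = rule),
            class = "motif_spec")
}

#' Derive anchor preferences from an energy matrix
#'
#' Builds a [motif_spec()] whose preferred residues at each anchor are the
#' energetically most favourable residues against an anchor-specific HLA
#' pocket position, so that the planted motif is aligned with the real
#' interaction map (and misaligned with a permuted control).
#'
#' @param energy An `energy_matrix`.
#' @param hla An `hla_sequence` (the pocket residues are read from it).
#' @param anchors Anchor positions.
#' @param n_preferred Preferred residues per anchor.
#' @param ... Passed to [motif_spec()] (`effect`, `background`, `rule`).
#' @return A `motif_spec`.
#' @export
motif_from_energy <- function(energy, hla, anchors = c(2L, 9L),
                              n_preferred = 4L, ...) {
  h <- split_chars(hla$residues)
  preferred <- lapply(seq_along(anchors), function(k) {
    col <- ((anchors[k] * 37L) %% HLA_LENGTH) + 1L   # fixed pocket position
    pocket <- h[col]
    if (pocket == AA_PAD) pocket <- h[1]
    names(sort(energy$values[, pocket]))[seq_len(n_preferred)]
  })
  motif_spec(anchors = anchors, preferred = preferred, ...)
}

n_matched_anchors <- function(peptides, motif) {
  m <- matrix(0L, length(peptides), length(motif$anchors))
  for (k in seq_along(motif$anchors))
    m[, k] <- substr(peptides, motif$anchors[k], motif$anchors[k]) %in%
      motif$preferred[[k]]
  rowSums(m)
}

#' Synthetic HLA allele pool
#'
#' Seeded random full-length (183-residue) HLA sequences with synthetic
#' allele names, in the allele/sequence table layout consumed by
#' [call_binders()].
#'
#' @param n Number of alleles.
#' @param locus `"A"` or `"B"`.
#' @param seed Integer seed.
#' @return Data frame with columns `allele`, `sequence`.
#' @export
gen_hla_pool <- function(n = 2L, locus = "A", seed = 1L) {
  stopifnot(locus %in% c("A", "B"))
  withr::with_seed(as.integer(seed), {
    seqs <- vapply(seq_len(n), function(i)
      paste(sample(AA_ALPHABET, HLA_LENGTH, replace = TRUE), collapse = ""),
      character(1))
  })
  data.frame(allele = sprintf("HLA-%s*%02d:01", locus, seq_len(n)),
             sequence = seqs, stringsAsFactors = FALSE)
}

#' Synthetic peptide-binding dataset with a planted motif
#'
#' Draws peptides uniformly over the 20-letter alphabet, assigns each a
#' binder label with probability `logistic(qlogis(background) + effect *
#' matched)` where `matched` counts matched anchors (under the `"all"`
#' rule, the effect applies only when every anchor matches), and assigns
#' IC50 values log-uniform on (10, 500) nM for binders and (500, 50000) nM
#' for non-binders. Pure function of its arguments and the seed.
#'
#' @param n Number of examples (>= 10).
#' @param motif A [motif_spec()].
#' @param hla_pool Allele/sequence table (see [gen_hla_pool()]); each
#'   example is assigned one allele uniformly.
#' @param seed Integer seed.
#' @param peptide_length 9 or 10.
#' @return List with `table` (peptide, allele, affinity_nM, label),
#'   `matched` (anchor match counts) and `seed`.
#' @export
gen_binding_data <- function(n, motif = motif_spec(),
                             hla_pool = gen_hla_pool(seed = 1L), seed = 1L,
                             peptide_length = 9L) {
  stopifnot(n >= 10)
  if (max(motif$anchors) > peptide_length)
    np_stop("motif anchors outside peptide length", "neopred_config_error")
  withr::with_seed(as.integer(seed), {
    pm <- matrix(sample(AA_ALPHABET, n * peptide_length, replace = TRUE),
                 n, peptide_length)
    peptides <- apply(pm, 1, paste, collapse = "")
    matched <- n_matched_anchors(peptides, motif)
    k <- length(motif$anchors)
    eff <- if (motif$rule == "additive") matched else
      ifelse(matched == k, k, 0)
    prob <- stats::plogis(stats::qlogis(motif$background) +
                            motif$effect * eff)
    label <- rbinom(n, 1, prob)
    affinity <- ifelse(label == 1,
                       exp(runif(n, log(10), log(500))),
                       exp(runif(n, log(500), log(50000))))
    allele <- sample(hla_pool$allele, n, replace = TRUE)
  })
  list(table = data.frame(peptide = peptides, allele = allele,
                          affinity_nM = affinity, label = label,
                          stringsAsFactors = FALSE),
       matched = matched, seed = as.integer(seed))
}

#' Synthetic cohort specification
#'
#' States the cohort world used for resistance-classification tests:
#' sample and gene counts, the planted resistance genes whose functional
#' mutations are enriched in resistant samples by a fixed odds ratio,
#' background functional and synonymous mutation rates, and the fraction of
#' designated immune evaders whose marker expression is suppressed.
#'
#' @param n_samples,n_genes Cohort dimensions.
#' @param n_planted Number of planted resistance genes (the first genes).
#' @param odds_ratio Functional-mutation odds ratio of planted genes in
#'   resistant vs non-resistant samples (> 1).
#' @param background_rate Functional-mutation rate of unplanted genes (and
#'   of planted genes in non-resistant samples).
#' @param synonymous_rate Label-independent synonymous mutation rate.
#' @param p_resistant Resistant-sample fraction.
#' @param evader_fraction Fraction of samples designated immune evaders.
#' @param seed Integer seed.
#' @return A `cohort_spec`.
#' @export
cohort_spec <- function(n_samples = 120L, n_genes = 100L, n_planted = 5L,
                        odds_ratio = 8, background_rate = 0.10,
                        synonymous_rate = 0.15, p_resistant = 1 / 3,
                        evader_fraction = 0.15, seed = 1L) {
  stopifnot(n_planted <= n_genes, odds_ratio > 1,
            background_rate > 0, background_rate < 1,
            synonymous_rate > 0, synonymous_rate < 1,
            p_resistant > 0, p_resistant < 1)
  odds1 <- odds_ratio * background_rate / (1 - background_rate)
  p1 <- odds1 / (1 + odds1)
  if (p1 >= 1)
    np_stop("odds ratio pushes mutation probability to 1",
            "neopred_config_error")
  structure(list(n_samples = as.integer(n_samples),
                 n_genes = as.integer(n_genes),
                 n_planted = as.integer(n_planted),
                 odds_ratio = odds_ratio, background_rate = background_rate,
                 synonymous_rate = synonymous_rate,
                 p_resistant = p_resistant,
                 evader_fraction = evader_fraction,
                 p_planted_resistant = p1, seed = as.integer(seed)),
            class = "cohort_spec")
}

random_protein_change <- function(n) {
  ref <- sample(AA_ALPHABET, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(AA_ALPHABET, r), 1),
                character(1))
  list(ref = unname(ref), alt = unname(alt),
       position = sample.int(400L, n, replace = TRUE))
}

#' Generate a synthetic immunotherapy cohort
#'
#' Draws resistance labels first, then mutations: planted genes acquire
#' functional mutations with the odds-ratio-raised probability in resistant
#' samples, unplanted genes at the background rate, and synonymous
#' mutations label-independently. Neoantigen loads are consistent with the
#' labels (resistant samples have load > 70 and no benefit). Immune-marker
#' expression rises with load except in the designated evaders, where it is
#' suppressed.
#'
#' @param spec A [cohort_spec()].
#' @return List with `mutations` (record table with functional flags and
#'   synonymous records), `samples`, `genes`, `load`, `benefit`,
#'   `expression` (samples x genes matrix including the immune markers),
#'   and `truth` (resistant, evaders, planted_genes, spec).
#' @export
gen_cohort <- function(spec = cohort_spec()) {
  ns <- spec$n_samples; ng <- spec$n_genes
  samples <- sprintf("S%03d", seq_len(ns))
  genes <- sprintf("G%03d", seq_len(ng))
  planted <- genes[seq_len(spec$n_planted)]
  markers <- unlist(immune_marker_sets(), use.names = FALSE)
  withr::with_seed(spec$seed, {
    resistant <- runif(ns) < spec$p_resistant
    # guarantee both classes at any n
    if (!any(resistant)) resistant[1] <- TRUE
    if (all(resistant)) resistant[1] <- FALSE

    pmat <- matrix(spec$background_rate, ns, ng,
                   dimnames = list(samples, genes))
    pmat[resistant, planted] <- spec$p_planted_resistant
    func <- matrix(runif(ns * ng), ns, ng) < pmat
    syn <- matrix(runif(ns * ng), ns, ng) < spec$synonymous_rate
    nonfunc <- matrix(runif(ns * ng), ns, ng) < 0.05

    recs <- list()
    add_records <- function(hits, class, sift, provean) {
      idx <- which(hits, arr.ind = TRUE)
      if (nrow(idx) == 0) return(NULL)
      pc <- random_protein_change(nrow(idx))
      data.frame(sample = samples[idx[, 1]], gene = genes[idx[, 2]],
                 position = pc$position, ref = pc$ref,
                 alt = if (class == "synonymous") pc$ref else pc$alt,
                 class = class, sift_damaging = sift,
                 provean_deleterious = provean, stringsAsFactors = FALSE)
    }
    mutations <- rbind(
      add_records(func, "missense", TRUE, TRUE),
      add_records(nonfunc & !func, "missense", TRUE, FALSE),
      add_records(syn, "synonymous", NA, NA))

    # loads consistent with the resistance definition (load > 70, no benefit)
    load <- integer(ns)
    load[resistant] <- 71L + stats::rnbinom(sum(resistant), size = 5,
                                            mu = 60)
    load[!resistant] <- stats::rnbinom(sum(!resistant), size = 3, mu = 40)
    benefit <- logical(ns)
    benefit[resistant] <- FALSE
    nr <- which(!resistant)
    benefit[nr] <- ifelse(load[nr] > 70, TRUE, runif(length(nr)) < 0.5)

    # designated evaders come from the high-load tail
    n_ev <- max(1L, round(spec$evader_fraction * ns))
    evaders <- logical(ns)
    evaders[order(-load)[seq_len(n_ev)]] <- TRUE

    z <- as.numeric(scale(load))
    expr_markers <- sapply(markers, function(g)
      5 + 2 * z + rnorm(ns, sd = 0.5))
    expr_markers[evaders, ] <- expr_markers[evaders, ] -
      (2 * z[evaders] + 4)
    bg_genes <- sprintf("BG%03d", seq_len(20))
    expr_bg <- matrix(rnorm(ns * length(bg_genes), 5, 1), ns,
                      dimnames = list(NULL, bg_genes))
    expression <- cbind(expr_markers, expr_bg)
    rownames(expression) <- samples
  })
  names(load) <- samples
  list(mutations = mutations, samples = samples, genes = genes,
       load = load, benefit = benefit, expression = expression,
       truth = list(resistant = resistant, evaders = evaders,
                    planted_genes = planted, spec = spec))
}

#' Synthetic protein-structure fixture
#'
#' Builds an ideal-geometry backbone (alpha-helix: radius 2.3 A, rise 1.5
#' A, 100 degrees per residue; extended: a straight chain at 3.8 A spacing)
#' with seeded random residue types. Each residue carries its C-alpha plus
#' one pseudo side-chain atom 1.5 A radially outward, so all-atom contacts
#' differ from C-alpha contacts.
#'
#' @param n_residues At least 4.
#' @param geometry `"helix"` or `"extended"`.
#' @param seed Integer seed.
#' @return A `residue_structure`.
#' @export
gen_structure_fixture <- function(n_residues, geometry = c("helix",
                                                           "extended"),
                                  seed = 1L) {
  geometry <- match.arg(geometry)
  if (n_residues < 4)
    np_stop("need at least 4 residues", "neopred_config_error")
  i <- seq_len(n_residues)
  if (geometry == "helix") {
    theta <- (i - 1) * 100 * pi / 180
    ca <- cbind(2.3 * cos(theta), 2.3 * sin(theta), 1.5 * (i - 1))
    side <- cbind(3.8 * cos(theta), 3.8 * sin(theta), 1.5 * (i - 1))
  } else {
    ca <- cbind(3.8 * (i - 1), 0, 0)
    side <- cbind(3.8 * (i - 1), 1.5, 0)
  }
  resname <- withr::with_seed(as.integer(seed),
                              sample(AA_ALPHABET, n_residues,
                                     replace = TRUE))
  atoms <- lapply(i, function(j) rbind(ca[j, ], side[j, ]))
  residue_structure(resno = i, resname = resname, calpha = ca,
                    atoms = atoms)
}

#' Write a residue structure as PDB-format text
#'
#' Minimal PDB writer (ATOM records with CA and a pseudo side-chain atom
#' CB) so generated fixtures can round-trip through [parse_structure()].
#'
#' @param struct A `residue_structure`.
#' @param path Optional file path; when `NULL` the lines are returned.
#' @return Character vector of PDB lines (invisibly when written).
#' @export
write_pdb <- function(struct, path = NULL) {
  one_to_three <- names(AA_THREE_TO_ONE)
  names(one_to_three) <- unname(AA_THREE_TO_ONE)
  lines <- character(0)
  serial <- 0L
  for (j in seq_along(struct$resno)) {
    A <- struct$atoms[[j]]
    for (a in seq_len(nrow(A))) {
      serial <- serial + 1L
      name <- if (a == 1) "CA" else "CB"
      lines <- c(lines, sprintf(
        "ATOM  %5d  %-3s %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
        serial, name, one_to_three[[struct$resname[j]]], struct$chain,
        struct$resno[j], A[a, 1], A[a, 2], A[a, 3]))
    }
  }
  lines <- c(lines, "END")
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
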