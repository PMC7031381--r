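#' Read tabular pipeline inputs
#'
#' Thin TSV readers for the standard input tables: mutation tables
#' (MAF-like, with `protein_change` such as `p.A50V` parsed into
#' position/ref/alt), per-sample HLA allele lists, expression matrices and
#' gene-interaction edge lists.
#'
#' @param path File path to a tab-separated file.
#' @return `read_mutations`: a data frame with columns `sample`, `gene`,
#'   `position`, `ref`, `alt`, `class`, `sift_damaging`,
#'   `provean_deleterious`.
#' @export
read_mutations <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "gene", "class")
  if (!all(need %in% names(tab)))
    np_stop(sprintf("mutation table must have columns: %s",
                    paste(need, collapse = ", ")), "neopred_config_error")
  if (!"position" %in% names(tab) && "protein_change" %in% names(tab)) {
    m <- regmatches(tab$protein_change,
                    regexec("^p\\.([A-Y])(\\d+)([A-Y])$",
                            tab$protein_change))
    tab$ref <- vapply(m, function(x) if (length(x) == 4) x[2] else
      NA_character_, character(1))
    tab$position <- vapply(m, function(x) if (length(x) == 4)
      as.integer(x[3]) else NA_integer_, integer(1))
    tab$alt <- vapply(m, function(x) if (length(x) == 4) x[4] else
      NA_character_, character(1))
  }
  for (col in c("sift_damaging", "provean_deleterious"))
    if (!col %in% names(tab)) tab[[col]] <- NA
  tab$sift_damaging <- as.logical(tab$sift_damaging)
  tab$provean_deleterious <- as.logical(tab$provean_deleterious)
  tab
}

#' @rdname read_mutations
#' @return `read_hla_alleles`: a data frame `sample`, `allele` (one row per
#'   sample-allele pair; the file stores comma-separated alleles).
#' @export
read_hla_alleles <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("sample", "alleles") %in% names(tab)))
  parts <- strsplit(tab$alleles, ",", fixed = TRUE)
  data.frame(sample = rep(tab$sample, lengths(parts)),
             allele = trimws(unlist(parts)), stringsAsFactors = FALSE)
}

#' @rdname read_mutations
#' @return `read_expression`: numeric samples x genes matrix.
#' @export
read_expression <- function(path) {
  as.matrix(read.delim(path, row.names = 1, check.names = FALSE))
}

#' @rdname read_mutations
#' @return `read_edges`: two-column data frame of undirected edges.
#' @export
read_edges <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  tab[, 1:2]
}

#' Read sequences from FASTA
#'
#' Uses Biostrings when available, otherwise a minimal fallback reader.
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    x <- Biostrings::readAAStringSet(path)
    out <- as.character(x)
    names(out) <- sub("\\s.*$", "", names(x))
    return(out)
  }
  lines <- readLines(path)
  hdr <- grepl("^>", lines)
  id <- sub("\\s.*$", "", sub("^>", "", lines[hdr]))
  grp <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], grp[!hdr]), paste, character(1),
                 collapse = "")
  names(seqs) <- id
  seqs
}

#' Serialize / restore a binding model as structured text
#'
#' Versioned JSON dump containing the configuration, geometry, key and all
#' weight matrices at full precision; the round trip restores bit-identical
#' weights.
#'
#' @param model A `binding_model`.
#' @param path File path.
#' @return `write_binding_model` returns `path` invisibly;
#'   `read_binding_model` the restored model.
#' @export
write_binding_model <- function(model, path) {
  payload <- list(
    format = "neopred_binding_model", version = 1L,
    config = unclass(model$config), dims = model$dims, key = model$key,
    # %.17g strings survive the JSON round trip bit-exactly
    W1 = sprintf("%.17g", model$W1), W2 = sprintf("%.17g", model$W2),
    Wfc = sprintf("%.17g", model$Wfc),
    Wout = sprintf("%.17g", model$Wout))
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_binding_model
#' @export
read_binding_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "neopred_binding_model"))
    np_stop("not a binding model file", "neopred_config_error")
  cfg <- p$config
  class(cfg) <- "model_config"
  d <- lapply(p$dims, function(v) if (is.numeric(v)) as.integer(v) else v)
  model <- list(config = cfg, dims = d, key = as.character(p$key),
                W1 = matrix(as.numeric(p$W1), d$M1 * d$C, d$n1),
                W2 = matrix(as.numeric(p$W2), d$M2 * d$n1, d$n2),
                Wfc = matrix(as.numeric(p$Wfc), d$P2 * d$n2, d$h),
                Wout = matrix(as.numeric(p$Wout), d$h, 1))
  class(model) <- "binding_model"
  model
}
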