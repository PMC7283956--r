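# Attribute features: reduced-alphabet 3-mer protein composition and drug
# substructure fingerprint bit-vectors; assembly of per-pair feature rows.

# The 20 standard residues collapsed into 4 side-chain-polarity categories.
REDUCED_ALPHABET_GROUPS <- list(
  c("A", "V", "L", "I", "M", "F", "W", "P"),
  c("G", "S", "T", "C", "N", "Q", "Y"),
  c("R", "K", "H"),
  c("D", "E")
)

#' Reduced amino-acid alphabet
#'
#' Maps each of the 20 canonical residues to one of four side-chain
#' polarity categories (0-3), so a protein sequence has 4^3 = 64 possible
#' 3-mers.
#'
#' @return named integer vector: residue letter to category in 0..3.
#' @export
reduced_alphabet <- function() {
  cats <- rep(0:3, times = lengths(REDUCED_ALPHABET_GROUPS))
  stats::setNames(cats, unlist(REDUCED_ALPHABET_GROUPS))
}

#' Reduced-alphabet 3-mer composition of a protein sequence
#'
#' Slides a window of 3 residues along the sequence, maps each window to
#' its category triplet `(c0, c1, c2)` and counts it at index
#' `16 c0 + 4 c1 + c2 + 1`; counts are divided by the number of counted
#' windows, so the 64 entries sum to 1. Windows containing a non-standard
#' letter (B, J, O, U, X, Z) are skipped rather than failing — real FASTA
#' contains them. Parsing is case-insensitive and `*` stop characters are
#' removed.
#'
#' @param seq amino-acid sequence string.
#' @param id optional identifier used in error messages.
#' @return numeric vector of length 64 summing to 1.
#' @export
protein_kmer_vector <- function(seq, id = NULL) {
  stopifnot(is.character(seq), length(seq) == 1L)
  alpha <- reduced_alphabet()
  chars <- strsplit(gsub("*", "", toupper(seq), fixed = TRUE), "")[[1L]]
  cats <- unname(alpha[chars])           # NA for non-standard letters
  n <- length(cats)
  out <- numeric(64L)
  n_windows <- 0L
  if (n >= 3L) {
    c0 <- cats[1:(n - 2L)]; c1 <- cats[2:(n - 1L)]; c2 <- cats[3:n]
    idx <- 16L * c0 + 4L * c1 + c2 + 1L
    idx <- idx[!is.na(idx)]
    n_windows <- length(idx)
    if (n_windows > 0L) {
      tab <- tabulate(idx, nbins = 64L)
      out <- tab / n_windows
    }
  }
  if (n_windows == 0L) {
    stop(sprintf("sequence%s has no valid 3-mer window",
                 if (is.null(id)) "" else paste0(" '", id, "'")),
         call. = FALSE)
  }
  out
}

#' Read protein sequences from FASTA
#'
#' @param path FASTA file; record ids must match the protein raw ids used
#'   in the edge lists.
#' @return named character vector of sequences, names namespaced as
#'   `protein:<id>`.
#' @export
read_protein_fasta <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  out <- as.character(seqs)
  ids <- sub("\\s.*$", "", names(seqs))
  names(out) <- ifelse(grepl("^protein:", ids), ids,
                       make_node_id("protein", ids))
  out
}

#' 3-mer feature matrix for a set of proteins
#'
#' @param seqs named character vector of sequences (see
#'   [read_protein_fasta()]).
#' @return numeric matrix, one 64-column row per protein.
#' @export
protein_kmer_matrix <- function(seqs) {
  m <- t(vapply(seq_along(seqs),
                function(i) protein_kmer_vector(seqs[[i]], names(seqs)[i]),
                numeric(64L)))
  rownames(m) <- names(seqs)
  m
}

#' Load drug fingerprint bit-vectors
#'
#' Reads a TSV of `drug_id <TAB> bitstring`. The declared dialect fixes
#' the bit length for the whole run: the MACCS key dictionary has 166
#' substructure patterns; hashed circular (Morgan-style) fingerprints use
#' a configurable length.
#'
#' @param path TSV file path.
#' @param dialect `"maccs"` (166 bits) or `"circular"`.
#' @param nbits bit length for the circular dialect (default 1024).
#' @return binary matrix, one row per drug, row names namespaced as
#'   `drug:<id>`.
#' @export
load_fingerprints <- function(path, dialect = c("maccs", "circular"),
                              nbits = 1024L) {
  dialect <- match.arg(dialect)
  f_len <- if (dialect == "maccs") 166L else assert_scalar_int(nbits, "nbits")
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    m <- matrix(integer(), nrow = 0L, ncol = f_len)
    return(m)
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 2L)) {
    i <- which(lengths(parts) != 2L)[1L]
    stop(sprintf("line %d of %s: expected 2 tab-separated columns",
                 line_no[i], path), call. = FALSE)
  }
  ids <- vapply(parts, `[[`, character(1L), 1L)
  bits <- vapply(parts, `[[`, character(1L), 2L)
  if (anyDuplicated(ids)) {
    stop("duplicate drug id in ", path, ": ", ids[duplicated(ids)][1L],
         call. = FALSE)
  }
  bad_len <- nchar(bits) != f_len
  if (any(bad_len)) {
    i <- which(bad_len)[1L]
    stop(sprintf("line %d of %s: bitstring length %d, %s dialect requires %d",
                 line_no[i], path, nchar(bits[i]), dialect, f_len),
         call. = FALSE)
  }
  if (any(grepl("[^01]", bits))) {
    i <- which(grepl("[^01]", bits))[1L]
    stop(sprintf("line %d of %s: bitstring contains a non-0/1 character",
                 line_no[i], path), call. = FALSE)
  }
  m <- t(vapply(strsplit(bits, "", fixed = TRUE),
                function(b) as.integer(b), integer(f_len)))
  rownames(m) <- ifelse(grepl("^drug:", ids), ids, make_node_id("drug", ids))
  m
}

#' Assemble per-pair feature rows
#'
#' Each drug-protein pair becomes the concatenation of the drug's vector
#' followed by the protein's vector — the same order for both
#' representations, so behavior and attribute rows are directly
#' comparable. Pairs whose drug or protein has no feature vector are
#' dropped with a count.
#'
#' @param pairs data.frame with columns `drug`, `protein`, `label`.
#' @param drug_features matrix of drug vectors, row names = drug node ids
#'   (fingerprints, or behavior vectors restricted to drugs).
#' @param protein_features matrix of protein vectors, row names = protein
#'   node ids.
#' @param tag `"attribute"` or `"behavior"`.
#' @return a `pair_dataset`: list with `pairs` (the retained rows),
#'   `features` (numeric matrix), `tag`, `n_dropped`.
#' @export
build_pair_features <- function(pairs, drug_features, protein_features,
                                tag = c("attribute", "behavior")) {
  tag <- match.arg(tag)
  stopifnot(all(c("drug", "protein", "label") %in% names(pairs)))
  ok <- pairs$drug %in% rownames(drug_features) &
    pairs$protein %in% rownames(protein_features)
  n_dropped <- sum(!ok)
  if (!any(ok)) {
    stop("no pair has features for both its drug and its protein",
         call. = FALSE)
  }
  kept <- pairs[ok, , drop = FALSE]
  rownames(kept) <- NULL
  x <- cbind(drug_features[kept$drug, , drop = FALSE],
             protein_features[kept$protein, , drop = FALSE])
  dimnames(x) <- list(NULL,
                      c(paste0("drug_", seq_len(ncol(drug_features))),
                        paste0("prot_", seq_len(ncol(protein_features)))))
  structure(list(pairs = kept, features = x, tag = tag,
                 n_dropped = n_dropped),
            class = "pair_dataset")
}

#' @export
print.pair_dataset <- function(x, ...) {
  cat(sprintf("pair_dataset (%s): %d pairs (%d positive), %d features%s\n",
              x$tag, nrow(x$pairs), sum(x$pairs$label == 1L),
              ncol(x$features),
              if (x$n_dropped > 0L)
                sprintf(", %d pairs dropped (missing features)", x$n_dropped)
              else ""))
  invisible(x)
}
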