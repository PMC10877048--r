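#' k-mer composition (CDK) of a nucleotide sequence
#'
#' Sliding-window k-mer frequencies: the entry for k-mer `w` is the number
#' of windows equal to `w` divided by `L - k + 1`, where `L` is the
#' sequence length. Windows containing an ambiguous base are excluded from
#' the numerator; the denominator always stays `L - k + 1`, so ambiguous
#' sequences sum to less than 1.
#'
#' @param seq A nucleotide string (A/C/G/T plus IUPAC ambiguity codes).
#' @param k k-mer length (default 3, giving 64 features).
#' @param id Optional sequence ID used in error messages.
#' @return Named numeric vector of length `4^k`, k-mers in lexicographic
#'   order.
#' @export
cdk <- function(seq, k = 3L, id = NULL) {
  L <- nchar(seq)
  if (L < k) {
    stop("sequence ", if (!is.null(id)) paste0("'", id, "' "),
         "is shorter than k = ", k)
  }
  counts <- Biostrings::oligonucleotideFrequency(Biostrings::DNAString(seq),
                                                 width = k)
  counts / (L - k + 1)
}

#' Canonical reverse-complement k-mer composition (RDK)
#'
#' k-mer frequencies collapsed over reverse-complement pairs: each window is
#' attributed to the canonical class `{w, revcomp(w)}`, named by the
#' lexicographically smaller member. Palindromic k-mers (their own reverse
#' complement) form singleton classes, so for k = 4 there are
#' (256 - 16) / 2 + 16 = 136 classes. The result is strand-symmetric:
#' `rdk(s) == rdk(revcomp(s))`.
#'
#' @inheritParams cdk
#' @param k k-mer length (default 4, giving 136 features).
#' @return Named numeric vector over canonical classes in lexicographic
#'   order of the representative.
#' @export
rdk <- function(seq, k = 4L, id = NULL) {
  counts <- cdk(seq, k = k, id = id)
  classes <- canonical_kmers(k)
  reps <- canonical_of(names(counts))
  sums <- tapply(counts, reps, sum)
  out <- stats::setNames(numeric(length(classes)), classes)
  out[names(sums)] <- as.numeric(sums)
  out
}

#' Reverse complement of nucleotide strings
#'
#' @param x Character vector of A/C/G/T strings.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1L]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

canonical_of <- function(kmers) {
  rc <- revcomp(kmers)
  ifelse(kmers <= rc, kmers, rc)
}

#' Canonical reverse-complement k-mer classes
#'
#' @param k k-mer length.
#' @return Sorted character vector of class representatives (the
#'   lexicographic minimum of each `{w, revcomp(w)}` pair); 136 entries
#'   for k = 4.
#' @export
canonical_kmers <- function(k) {
  all_k <- all_kmers(k)
  sort(unique(canonical_of(all_k)))
}

all_kmers <- function(k) {
  grid <- do.call(expand.grid,
                  c(rep(list(c("A", "C", "G", "T")), k),
                    stringsAsFactors = FALSE))
  # expand.grid varies the first factor fastest; reverse for lexicographic
  sort(do.call(paste0, rev(grid)))
}

#' Feature configuration for the composition pipeline
#'
#' @param cdk_k k-mer length for the plain composition block (default 3).
#' @param rdk_k k-mer length for the canonical reverse-complement block
#'   (default 4).
#' @return A list of class `kmer_config`.
#' @export
kmer_config <- function(cdk_k = 3L, rdk_k = 4L) {
  stopifnot(cdk_k >= 1L, rdk_k >= 1L)
  structure(list(cdk_k = as.integer(cdk_k), rdk_k = as.integer(rdk_k)),
            class = "kmer_config")
}

#' Names of the combined feature vector
#'
#' @param config A [kmer_config()].
#' @return Character vector, `CDK<k>_<kmer>` names followed by
#'   `RDK<k>_<canonical kmer>` names; 200 entries with the defaults.
#' @export
feature_names <- function(config = kmer_config()) {
  c(paste0("CDK", config$cdk_k, "_", all_kmers(config$cdk_k)),
    paste0("RDK", config$rdk_k, "_", canonical_kmers(config$rdk_k)))
}

#' Compute the combined composition feature matrix
#'
#' For each sequence, the `4^cdk_k` plain k-mer frequencies are concatenated
#' with the canonical reverse-complement k-mer frequencies (64 + 136 = 200
#' features with defaults).
#'
#' @param records Data.frame with `id` and `seq` columns.
#' @param config A [kmer_config()].
#' @return Numeric matrix, one row per record (rownames = IDs), columns
#'   named as in [feature_names()].
#' @export
featurize <- function(records, config = kmer_config()) {
  fn <- feature_names(config)
  if (nrow(records) == 0L) {
    return(matrix(numeric(0), nrow = 0L, ncol = length(fn),
                  dimnames = list(character(0), fn)))
  }
  kmin <- max(config$cdk_k, config$rdk_k)
  short <- records$id[nchar(records$seq) < kmin]
  if (length(short) > 0L) {
    stop("sequence(s) shorter than ", kmin, " nt: ",
         paste(short, collapse = ", "))
  }
  X <- t(mapply(function(s, id) {
    c(cdk(s, config$cdk_k, id), rdk(s, config$rdk_k, id))
  }, records$seq, records$id))
  dimnames(X) <- list(records$id, fn)
  X
}

#' Export a feature matrix as TSV
#'
#' @param X Feature matrix from [featurize()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_features <- function(X, path) {
  df <- data.frame(id = rownames(X), X, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
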