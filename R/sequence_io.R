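#' Canonical subcellular location order
#'
#' The six compartments in the fixed order used everywhere in the package:
#' label vectors, model outputs, motif sets and report rows all follow this
#' order. An mRNA present only in the ribosome and the nucleus is encoded
#' `c(1, 0, 0, 0, 1, 0)`.
#'
#' @return Character vector of the six location names.
#' @export
locations <- function() {
  c("ribosome", "cytosol", "er", "membrane", "nucleus", "exosome")
}

#' Read nucleotide sequences from a FASTA file
#'
#' Sequences are uppercased and `U` is mapped to `T`, so RNA-alphabet input
#' is accepted; all downstream work is in the DNA alphabet. Ambiguous IUPAC
#' bases (N, R, Y, ...) are retained in the sequence but records where they
#' exceed 10\% of the length are rejected, since k-mer windows containing
#' them carry no usable composition signal.
#'
#' @param path Path to a FASTA file. Multi-line sequences are allowed; the
#'   record ID is the first whitespace-delimited token of the header.
#' @param max_ambiguous_frac Maximum tolerated fraction of non-A/C/G/T bases
#'   per sequence (default 0.1).
#' @return A data.frame with columns `id`, `seq` (normalized sequence) and
#'   `raw_length` (nucleotides before normalization; identical to the
#'   normalized length since normalization is per-base).
#' @export
read_fasta <- function(path, max_ambiguous_frac = 0.1) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("FASTA file is empty: ", path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L)
  if (anyNA(ids) || any(!nzchar(ids))) stop("FASTA entry with empty ID")
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    stop("duplicate FASTA IDs: ", paste(unique(dup), collapse = ", "))
  }
  raw <- as.character(set)
  seqs <- normalize_seq(raw)
  empty <- !nzchar(seqs)
  if (any(empty)) {
    stop("empty sequence after normalization for ID(s): ",
         paste(ids[empty], collapse = ", "))
  }
  amb <- ambiguous_fraction(seqs)
  bad <- amb > max_ambiguous_frac
  if (any(bad)) {
    stop("sequence(s) with more than ", round(100 * max_ambiguous_frac),
         "% ambiguous bases: ", paste(ids[bad], collapse = ", "))
  }
  data.frame(id = ids, seq = unname(seqs), raw_length = nchar(raw),
             stringsAsFactors = FALSE)
}

#' Write sequence records to FASTA
#'
#' @param records Data.frame with `id` and `seq` columns (as from
#'   [read_fasta()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  set <- Biostrings::BStringSet(records$seq)
  names(set) <- records$id
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

normalize_seq <- function(x) {
  chartr("u", "T", chartr("U", "T", toupper(x)))
}

ambiguous_fraction <- function(seqs) {
  n_acgt <- nchar(gsub("[^ACGT]", "", seqs))
  1 - n_acgt / nchar(seqs)
}

#' Read multi-label location annotations
#'
#' Accepts a TSV with a header whose first column is the sequence ID,
#' followed by either the six binary indicator columns in canonical order
#' (see [locations()]) or a single column of comma-separated location names
#' (matched case-insensitively; "er" and "endoplasmic reticulum" are both
#' accepted).
#'
#' @param path Path to the label TSV.
#' @param ids Character vector of sequence IDs that must all be annotated.
#' @return An integer matrix with one row per element of `ids` (in that
#'   order, rownames = `ids`) and the six locations as columns.
#' @export
read_labels <- function(path, ids) {
  if (!file.exists(path)) stop("label file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  if (nrow(tab) == 0L) stop("label file has no rows: ", path)
  lab_ids <- tab[[1L]]
  if (anyDuplicated(lab_ids)) {
    stop("duplicate IDs in label file: ",
         paste(unique(lab_ids[duplicated(lab_ids)]), collapse = ", "))
  }
  if (ncol(tab) == 7L) {
    Y <- vapply(tab[2:7], function(col) {
      v <- suppressWarnings(as.integer(col))
      if (anyNA(v) || any(v != 0L & v != 1L)) {
        stop("binary label columns must contain only 0 or 1")
      }
      v
    }, integer(nrow(tab)))
    Y <- matrix(Y, nrow = nrow(tab),
                dimnames = list(lab_ids, locations()))
  } else if (ncol(tab) == 2L) {
    Y <- t(vapply(tab[[2L]], parse_location_names, integer(6L)))
    dimnames(Y) <- list(lab_ids, locations())
  } else {
    stop("label file must have 2 (id, names) or 7 (id + 6 flags) columns; ",
         "got ", ncol(tab))
  }
  extra <- setdiff(lab_ids, ids)
  if (length(extra) > 0L) {
    warning("label file annotates IDs absent from the sequence set: ",
            paste(utils::head(extra, 5L), collapse = ", "))
  }
  missing <- setdiff(ids, lab_ids)
  if (length(missing) > 0L) {
    stop("no labels for sequence ID(s): ",
         paste(utils::head(missing, 5L), collapse = ", "))
  }
  Y[ids, , drop = FALSE]
}

parse_location_names <- function(x) {
  out <- integer(6L)
  names(out) <- locations()
  x <- trimws(x)
  if (!nzchar(x)) return(out)
  parts <- tolower(trimws(strsplit(x, ",")[[1L]]))
  parts[parts == "endoplasmic reticulum"] <- "er"
  unknown <- setdiff(parts, locations())
  if (length(unknown) > 0L) {
    stop("unknown location name(s): ", paste(unknown, collapse = ", "))
  }
  out[parts] <- 1L
  out
}

#' Write a label matrix as TSV
#'
#' @param Y Label matrix (rows = sequences, rownames = IDs, six columns).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(Y, path) {
  df <- data.frame(id = rownames(Y), Y, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Encode location names as a binary label vector
#'
#' @param names Character vector of location names (subset of
#'   [locations()]).
#' @return Named integer vector of six 0/1 flags in canonical order.
#' @export
encode_labels <- function(names) {
  parse_location_names(paste(names, collapse = ","))
}

#' Decode a binary label vector into location names
#'
#' @param v Vector of six 0/1 flags in canonical order.
#' @return Character vector of the locations flagged 1 (possibly empty).
#' @export
decode_labels <- function(v) {
  stopifnot(length(v) == 6L, all(v %in% c(0L, 1L)))
  locations()[v == 1L]
}
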