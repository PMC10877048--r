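#' Configuration for discriminative motif discovery
#'
#' @param min_len Minimum motif length (default 8).
#' @param max_len Maximum motif length (default 30).
#' @param min_support Minimum number of distinct positive sequences that
#'   must contain the motif (default 1).
#' @param max_negative_occurrences Maximum number of negative sequences
#'   allowed to contain the motif (default 0: strictly discriminative).
#' @return A list of class `motif_config`.
#' @export
motif_config <- function(min_len = 8L, max_len = 30L, min_support = 1L,
                         max_negative_occurrences = 0L) {
  stopifnot(min_len >= 1L, min_len <= max_len, min_support >= 1L,
            max_negative_occurrences >= 0L)
  structure(list(min_len = as.integer(min_len),
                 max_len = as.integer(max_len),
                 min_support = as.integer(min_support),
                 max_negative_occurrences = as.integer(max_negative_occurrences)),
            class = "motif_config")
}

#' Discover discriminative sequence motifs
#'
#' Finds every maximal ungapped A/C/G/T motif that occurs (as an exact
#' substring) in at least `min_support` positive sequences and in at most
#' `max_negative_occurrences` negative sequences. "Maximal" means no
#' returned motif is a substring of another returned motif with an
#' identical set of supporting positive sequences; two maximal motifs with
#' the same support set, neither a substring of the other, are both kept.
#'
#' The search extends candidate motifs base by base to the right, seeding
#' from the four nucleotides. Positive support can only shrink under
#' extension, so candidates falling below `min_support` are pruned along
#' with all their extensions; the negative filter is applied only to
#' candidates within the length range, and each extension's support is
#' re-counted within its parent's supporting sequences only.
#'
#' @param positives,negatives Data.frames with `id` and `seq` columns;
#'   disjoint, non-empty sets.
#' @param config A [motif_config()].
#' @return Data.frame with columns `pattern` and `positive_hits`, sorted by
#'   `positive_hits` decreasing then pattern; zero rows when nothing
#'   discriminates.
#' @export
discover_motifs <- function(positives, negatives, config = motif_config()) {
  if (nrow(positives) == 0L) stop("positive set is empty")
  if (nrow(negatives) == 0L) stop("negative set is empty")
  if (length(intersect(positives$id, negatives$id)) > 0L) {
    stop("positive and negative sets share IDs")
  }
  pos <- positives$seq
  neg <- negatives$seq
  bases <- c("A", "C", "G", "T")

  supp <- function(pattern, idx) {
    idx[vapply(pos[idx], grepl, logical(1), pattern = pattern,
               fixed = TRUE, USE.NAMES = FALSE)]
  }
  neg_occ <- function(pattern) {
    sum(vapply(neg, grepl, logical(1), pattern = pattern, fixed = TRUE,
               USE.NAMES = FALSE))
  }
  found_pat <- character(0)
  found_sup <- list()
  frontier_pat <- character(0)
  frontier_sup <- list()
  for (b in bases) {
    s <- supp(b, seq_along(pos))
    if (length(s) >= config$min_support) {
      frontier_pat <- c(frontier_pat, b)
      frontier_sup <- c(frontier_sup, list(s))
    }
  }
  len <- 1L
  while (length(frontier_pat) > 0L && len < config$max_len) {
    new_pat <- character(0)
    new_sup <- list()
    for (i in seq_along(frontier_pat)) {
      p <- frontier_pat[i]
      for (b in bases) {
        cand <- paste0(p, b)
        s <- supp(cand, frontier_sup[[i]])
        if (length(s) >= config$min_support) {
          new_pat <- c(new_pat, cand)
          new_sup <- c(new_sup, list(s))
        }
      }
    }
    len <- len + 1L
    frontier_pat <- new_pat
    frontier_sup <- new_sup
    if (len >= config$min_len && len <= config$max_len) {
      for (i in seq_along(frontier_pat)) {
        if (neg_occ(frontier_pat[i]) <= config$max_negative_occurrences) {
          found_pat <- c(found_pat, frontier_pat[i])
          found_sup <- c(found_sup, list(frontier_sup[[i]]))
        }
      }
    }
  }
  if (config$min_len == 1L) {
    # single-base seeds are candidates too when the range allows them
    for (b in bases) {
      s <- supp(b, seq_along(pos))
      if (length(s) >= config$min_support &&
          neg_occ(b) <= config$max_negative_occurrences) {
        found_pat <- c(found_pat, b)
        found_sup <- c(found_sup, list(s))
      }
    }
  }
  keep <- maximal_filter(found_pat, found_sup)
  out <- data.frame(pattern = found_pat[keep],
                    positive_hits = vapply(found_sup[keep], length,
                                           integer(1)),
                    stringsAsFactors = FALSE)
  out[order(-out$positive_hits, out$pattern), , drop = FALSE] |>
    (\(d) { rownames(d) <- NULL; d })()
}

# drop any motif that is a substring of another motif with an identical
# positive-support set
maximal_filter <- function(patterns, supports) {
  n <- length(patterns)
  if (n == 0L) return(logical(0))
  keys <- vapply(supports, function(s) paste(sort(s), collapse = ","),
                 character(1))
  keep <- rep(TRUE, n)
  for (key in unique(keys)) {
    grp <- which(keys == key)
    if (length(grp) == 1L) next
    pats <- patterns[grp]
    for (i in seq_along(grp)) {
      others <- pats[-i]
      if (any(nchar(others) > nchar(pats[i]) &
              vapply(others, grepl, logical(1), pattern = pats[i],
                     fixed = TRUE, USE.NAMES = FALSE))) {
        keep[grp[i]] <- FALSE
      }
    }
  }
  keep
}

#' Discover motif sets for all six locations
#'
#' For each location the sequence set is split into positives (label 1) and
#' negatives (label 0) and [discover_motifs()] is run on the split.
#'
#' @param records Data.frame with `id` and `seq`.
#' @param Y Label matrix aligned with `records` (rownames = IDs).
#' @param config A [motif_config()].
#' @return Named list (one element per location) of motif data.frames.
#' @export
discover_motif_sets <- function(records, Y, config = motif_config()) {
  stopifnot(identical(rownames(Y), records$id))
  out <- lapply(locations(), function(loc) {
    pos <- records[Y[, loc] == 1L, , drop = FALSE]
    neg <- records[Y[, loc] == 0L, , drop = FALSE]
    if (nrow(pos) == 0L || nrow(neg) == 0L) {
      return(data.frame(pattern = character(0),
                        positive_hits = integer(0)))
    }
    discover_motifs(pos, neg, config)
  })
  names(out) <- locations()
  out
}

#' Scan a sequence against per-location motif sets
#'
#' @param seq A normalized nucleotide string.
#' @param motif_sets Named list of motif data.frames, one per location
#'   (empty data.frames allowed).
#' @return Integer vector of six 0/1 flags (canonical order): 1 when any
#'   motif of that location occurs as an exact substring.
#' @export
scan_motifs <- function(seq, motif_sets) {
  stopifnot(all(locations() %in% names(motif_sets)))
  vapply(locations(), function(loc) {
    pats <- motif_sets[[loc]]$pattern
    if (length(pats) == 0L || !nzchar(seq)) return(0L)
    as.integer(any(vapply(pats, grepl, logical(1), x = seq, fixed = TRUE,
                          USE.NAMES = FALSE)))
  }, integer(1))
}

#' Scan many sequences against motif sets
#'
#' @param records Data.frame with `id` and `seq`.
#' @inheritParams scan_motifs
#' @return Integer matrix (records x 6 locations) of hit flags.
#' @export
scan_motifs_all <- function(records, motif_sets) {
  H <- t(vapply(records$seq, scan_motifs, integer(6L),
                motif_sets = motif_sets))
  dimnames(H) <- list(records$id, locations())
  H
}

#' Write a motif set to a per-location TSV file
#'
#' Two tab-separated columns (`pattern`, `positive_hits`) with a header;
#' `#` comment lines are permitted when reading back.
#'
#' @param motifs Motif data.frame from [discover_motifs()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_motifs <- function(motifs, path) {
  utils::write.table(motifs[, c("pattern", "positive_hits")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a motif set from TSV
#'
#' @param path Path written by [write_motifs()].
#' @return Motif data.frame with `pattern` and `positive_hits` columns.
#' @export
read_motifs <- function(path) {
  if (!file.exists(path)) stop("motif file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines)]
  if (length(lines) <= 1L) {
    return(data.frame(pattern = character(0), positive_hits = integer(0)))
  }
  body <- lines[-1L]
  parts <- strsplit(body, "\t", fixed = TRUE)
  for (i in seq_along(parts)) {
    if (length(parts[[i]]) != 2L || grepl("[^ACGT]", parts[[i]][1L])) {
      stop("malformed motif line ", i + 1L, " in ", path, ": ", body[i])
    }
  }
  data.frame(pattern = vapply(parts, `[`, character(1), 1L),
             positive_hits = as.integer(vapply(parts, `[`, character(1), 2L)),
             stringsAsFactors = FALSE)
}

#' Write one motif file per location
#'
#' Files are named `<location>.motifs.tsv` under `dir`.
#'
#' @param motif_sets Named list of motif data.frames.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_motif_sets <- function(motif_sets, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (loc in locations()) {
    write_motifs(motif_sets[[loc]], file.path(dir, paste0(loc, ".motifs.tsv")))
  }
  invisible(dir)
}

#' Read per-location motif files from a directory
#'
#' @param dir Directory holding `<location>.motifs.tsv` files; a missing
#'   file yields an empty motif set for that location.
#' @return Named list of motif data.frames.
#' @export
read_motif_sets <- function(dir) {
  out <- lapply(locations(), function(loc) {
    f <- file.path(dir, paste0(loc, ".motifs.tsv"))
    if (!file.exists(f)) {
      return(data.frame(pattern = character(0), positive_hits = integer(0)))
    }
    read_motifs(f)
  })
  names(out) <- locations()
  out
}
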