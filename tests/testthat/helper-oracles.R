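# Independent reference implementations used to cross-check the package's
# fast paths. These deliberately use naive string/loop algorithms.

windows_of <- function(seq, k) {
  L <- nchar(seq)
  substring(seq, 1:(L - k + 1), k:L)
}

# naive k-mer frequencies: enumerate every window, string-compare
oracle_cdk <- function(seq, k) {
  all_k <- sort(apply(expand.grid(rep(list(c("A", "C", "G", "T")), k)), 1,
                      function(r) paste(rev(r), collapse = "")))
  w <- windows_of(seq, k)
  w <- w[!grepl("[^ACGT]", w)]
  counts <- vapply(all_k, function(m) sum(w == m), numeric(1))
  counts / (nchar(seq) - k + 1)
}

oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}

oracle_rdk <- function(seq, k) {
  v <- oracle_cdk(seq, k)
  reps <- vapply(names(v), function(w) min(w, oracle_revcomp(w)),
                 character(1))
  out <- tapply(v, reps, sum)
  classes <- sort(unique(reps))
  setNames(as.numeric(out[classes]), classes)
}

# brute-force discriminative motif discovery: enumerate every substring in
# the length range, filter on support, then reduce to maximal motifs
oracle_discover <- function(pos, neg, min_len, max_len, min_support = 1,
                            max_neg = 0) {
  subs <- unique(unlist(lapply(pos, function(s) {
    L <- nchar(s)
    unlist(lapply(min_len:min(max_len, L), function(k) windows_of(s, k)))
  })))
  subs <- subs[!grepl("[^ACGT]", subs)]
  supp <- lapply(subs, function(m) {
    which(vapply(pos, grepl, logical(1), pattern = m, fixed = TRUE))
  })
  nocc <- vapply(subs, function(m) {
    sum(vapply(neg, grepl, logical(1), pattern = m, fixed = TRUE))
  }, numeric(1))
  keep <- vapply(supp, length, integer(1)) >= min_support & nocc <= max_neg
  subs <- subs[keep]
  supp <- supp[keep]
  keys <- vapply(supp, paste, character(1), collapse = ",")
  maximal <- vapply(seq_along(subs), function(i) {
    !any(keys == keys[i] & nchar(subs) > nchar(subs[i]) &
           vapply(subs, function(o) grepl(subs[i], o, fixed = TRUE),
                  logical(1)))
  }, logical(1))
  df <- data.frame(pattern = subs[maximal],
                   positive_hits = vapply(supp[maximal], length, integer(1)),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$positive_hits, df$pattern), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# O(n^2) pairwise AUROC: probability a random positive outscores a random
# negative, ties counted half
oracle_auroc <- function(scores, truth) {
  sp <- scores[truth == 1]
  sn <- scores[truth == 0]
  tot <- 0
  for (a in sp) for (b in sn) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sn))
}

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

empty_motif_sets <- function() {
  sets <- lapply(mlsubloc::locations(), function(l) {
    data.frame(pattern = character(0), positive_hits = integer(0))
  })
  names(sets) <- mlsubloc::locations()
  sets
}
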