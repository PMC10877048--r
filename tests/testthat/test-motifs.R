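rec_df <- function(seqs, prefix = "s") {
  data.frame(id = paste0(prefix, seq_along(seqs)), seq = seqs,
             stringsAsFactors = FALSE)
}

test_that("discovery finds the maximal shared discriminative substring", {
  pos <- rec_df(c("AAACGTACGA", "TTACGTACGT"), "p")
  neg <- rec_df("AAAAAAAAAA", "n")
  got <- discover_motifs(pos, neg,
                         motif_config(min_len = 4, max_len = 10,
                                      min_support = 2))
  expect_true("ACGTACG" %in% got$pattern)
  expect_equal(got$positive_hits[got$pattern == "ACGTACG"], 2L)
})

test_that("identical positive and negative content yields no motifs", {
  pos <- rec_df("ACGTACGT", "p")
  neg <- rec_df("ACGTACGT", "n")
  got <- discover_motifs(pos, neg, motif_config(min_len = 2, max_len = 8))
  expect_equal(nrow(got), 0L)
})

test_that("discovery matches brute-force enumeration on random instances", {
  set.seed(19)
  for (i in 1:12) {
    npos <- sample(2:5, 1)
    nneg <- sample(2:5, 1)
    # short alphabet-limited sequences so shared substrings are common
    pos <- rec_df(replicate(npos, random_dna(sample(20:60, 1),
                                             alphabet = c("A", "C", "G"))),
                  "p")
    neg <- rec_df(replicate(nneg, random_dna(sample(20:60, 1),
                                             alphabet = c("A", "C", "G"))),
                  "n")
    min_support <- sample(1:2, 1)
    got <- discover_motifs(pos, neg,
                           motif_config(min_len = 3, max_len = 10,
                                        min_support = min_support))
    want <- oracle_discover(pos$seq, neg$seq, 3, 10,
                            min_support = min_support)
    expect_equal(got, want)
  }
})

test_that("rescanning discovered motifs confirms their support counts", {
  set.seed(23)
  pos <- rec_df(replicate(6, random_dna(40, c("A", "C", "T"))), "p")
  neg <- rec_df(replicate(6, random_dna(40, c("A", "C", "T"))), "n")
  got <- discover_motifs(pos, neg, motif_config(min_len = 4, max_len = 12,
                                                min_support = 2))
  for (j in seq_len(nrow(got))) {
    p <- got$pattern[j]
    expect_equal(sum(grepl(p, pos$seq, fixed = TRUE)), got$positive_hits[j])
    expect_equal(sum(grepl(p, neg$seq, fixed = TRUE)), 0L)
  }
})

test_that("support threshold and negative set act monotonically", {
  set.seed(29)
  pos <- rec_df(replicate(5, random_dna(50, c("A", "C"))), "p")
  neg <- rec_df(replicate(4, random_dna(50, c("A", "C"))), "n")
  cfgs <- lapply(1:3, function(s) motif_config(min_len = 3, max_len = 8,
                                               min_support = s))
  sets <- lapply(cfgs, function(cf) discover_motifs(pos, neg, cf)$pattern)
  expect_true(all(sets[[2]] %in% sets[[1]]))
  expect_true(all(sets[[3]] %in% sets[[2]]))
  # shrinking the negative set never removes a motif
  smaller <- discover_motifs(pos, neg[1:2, ], cfgs[[1]])$pattern
  expect_true(all(sets[[1]] %in% smaller))
})

test_that("scan flags exactly the locations whose motifs occur", {
  sets <- empty_motif_sets()
  sets$ribosome <- data.frame(pattern = "ATTTGAAGACCA", positive_hits = 5L)
  sets$cytosol <- data.frame(pattern = "TTTT", positive_hits = 1L)
  hit <- scan_motifs(paste0("GGG", "ATTTGAAGACCA", "GGG"), sets)
  expect_equal(unname(hit), c(1L, 0L, 0L, 0L, 0L, 0L))
  # overlapping occurrences still count as presence
  sets$cytosol <- data.frame(pattern = "AA", positive_hits = 1L)
  expect_equal(unname(scan_motifs("AAAA", sets)),
               c(0L, 1L, 0L, 0L, 0L, 0L))
  expect_equal(unname(scan_motifs("GGGG", empty_motif_sets())), rep(0L, 6))
})

test_that("motif files round-trip and malformed lines are rejected", {
  set.seed(31)
  motifs <- data.frame(pattern = replicate(10, random_dna(sample(4:12, 1))),
                       positive_hits = sample(1:50, 10),
                       stringsAsFactors = FALSE)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_motifs(motifs, f)
  expect_equal(read_motifs(f), motifs)

  writeLines(c("pattern\tpositive_hits", "# a comment", "ACGT\t5"), f)
  expect_equal(read_motifs(f)$pattern, "ACGT")
  writeLines(c("pattern\tpositive_hits", "ACGU\t2"), f)
  expect_error(read_motifs(f), "malformed")
})

test_that("per-location motif directories round-trip, including empties", {
  sets <- empty_motif_sets()
  sets$nucleus <- data.frame(pattern = c("ACGTACGT", "TTTTAAAA"),
                             positive_hits = c(3L, 1L))
  d <- withr::local_tempdir()
  write_motif_sets(sets, d)
  expect_true(file.exists(file.path(d, "er.motifs.tsv")))
  back <- read_motif_sets(d)
  expect_equal(back$nucleus, sets$nucleus)
  expect_equal(nrow(back$exosome), 0L)
})
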