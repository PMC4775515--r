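# fixture builders: alignments from strings, temp FASTA files

make_aln <- function(seqs, labels = NULL, offset = 0L) {
  labels <- labels %||% sprintf("ES%02d_All%d", (seq_along(seqs) + 1) %/% 2,
                                (seq_along(seqs) - 1) %% 2 + 1)
  m <- do.call(rbind, strsplit(toupper(seqs), ""))
  rownames(m) <- labels
  meta <- tryCatch(poldiv:::parse_labels(labels), error = function(e) NULL)
  new_alignment(m, meta, offset = offset)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_fasta_tmp <- function(seqs, labels = NULL) {
  labels <- labels %||% sprintf("ES%02d_All%d", (seq_along(seqs) + 1) %/% 2,
                                (seq_along(seqs) - 1) %% 2 + 1)
  path <- tempfile(fileext = ".fasta")
  writeLines(as.vector(rbind(paste0(">", labels), seqs)), path)
  path
}

# random ACGT alignment (not necessarily coding-clean; for site-count tests)
random_aln <- function(n, L, seed = 1) {
  set.seed(seed)
  m <- matrix(sample(c("A", "C", "G", "T"), n * L, replace = TRUE), n, L)
  rownames(m) <- sprintf("ES%02d_All%d", (1:n + 1) %/% 2, (1:n - 1) %% 2 + 1)
  new_alignment(m, poldiv:::parse_labels(rownames(m)))
}
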