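#' Coding-sequence alignment of phased alleles
#'
#' An `aln` object stores an equal-length alignment of phased coding alleles as
#' an upper-case character matrix (rows = sequences, columns = positions) plus
#' per-sequence metadata (species, individual, allele index) parsed from the
#' FASTA labels. Coordinates are 0-based half-open internally; every report
#' uses 1-based positions.
#'
#' @param seqs character matrix of single characters in `A,C,G,T,N,-`, rows
#'   named by sequence label.
#' @param meta data.frame with columns `label`, `species`, `individual`,
#'   `allele`; one row per sequence, same order as `seqs`.
#' @param offset 0-based reading-frame offset (first codon starts at column
#'   `offset + 1`).
#' @return object of class `aln`.
#' @export
new_alignment <- function(seqs, meta = NULL, offset = 0L) {
  if (!is.matrix(seqs) || !is.character(seqs)) stop("seqs must be a character matrix")
  seqs[] <- toupper(seqs)
  bad <- !(seqs %in% c("A", "C", "G", "T", "N", "-"))
  if (any(bad)) stop("alphabet restricted to A,C,G,T,N,-; offending characters: ",
                     paste(unique(seqs[bad]), collapse = " "))
  if (is.null(rownames(seqs))) rownames(seqs) <- paste0("seq", seq_len(nrow(seqs)))
  if (anyDuplicated(rownames(seqs))) stop("labels must be unique")
  if (is.null(meta)) {
    meta <- data.frame(label = rownames(seqs), species = NA_character_,
                       individual = NA_character_, allele = NA_integer_,
                       stringsAsFactors = FALSE)
  }
  stopifnot(nrow(meta) == nrow(seqs))
  structure(list(seqs = seqs, meta = meta, offset = as.integer(offset)),
            class = "aln")
}

#' @export
print.aln <- function(x, ...) {
  cat(sprintf("<aln> %d sequences x %d bp (frame offset %d)\n",
              nrow(x$seqs), ncol(x$seqs), x$offset))
  sp <- table(x$meta$species, useNA = "ifany")
  cat("  species:", paste(sprintf("%s=%d", names(sp), sp), collapse = ", "), "\n")
  invisible(x)
}

n_seq <- function(aln) nrow(aln$seqs)
aln_len <- function(aln) ncol(aln$seqs)

#' Default label schema
#'
#' Matches labels of the form `EC12_All1`, `ES7-2`, `Eus78_all1`-like variants:
#' a species token (`EC`/`ES`, case-insensitive; `Euc`/`Eus` also accepted),
#' an individual number, a separator, an optional `All` and the allele number.
#'
#' @export
default_label_schema <- "^(E[CS]|EU[CS])[-_]?0*([0-9]+)[-_](?:ALL)?([0-9]+)$"

parse_labels <- function(labels, schema = default_label_schema) {
  up <- toupper(labels)
  m <- regmatches(up, regexec(schema, up, perl = TRUE))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad)) {
    stop("labels not matching schema '", schema, "': ",
         paste(utils::head(labels[bad], 5), collapse = ", "))
  }
  sp <- vapply(m, `[[`, "", 2L)
  sp <- c(EC = "Euc", ES = "Eus", EUC = "Euc", EUS = "Eus")[sp]
  data.frame(label = labels, species = unname(sp),
             individual = vapply(m, `[[`, "", 3L),
             allele = as.integer(vapply(m, `[[`, "", 4L)),
             stringsAsFactors = FALSE)
}

#' Read a phased coding alignment from FASTA
#'
#' @param path FASTA file of equal-length sequences.
#' @param label_schema regex with three capture groups (species, individual,
#'   allele) applied case-insensitively to the labels; `NULL` to skip metadata
#'   parsing.
#' @param offset 0-based reading-frame offset.
#' @return an [new_alignment()] object.
#' @export
read_alignment <- function(path, label_schema = default_label_schema, offset = 0L) {
  if (!file.exists(path)) stop("no such file: ", path)
  d <- ape::read.FASTA(path)
  lens <- lengths(d)
  if (length(unique(lens)) != 1L) {
    off <- names(d)[lens != lens[1]][1]
    stop("ragged alignment: record '", off, "' has ", lens[lens != lens[1]][1],
         " bp, expected ", lens[1])
  }
  mat <- toupper(do.call(rbind, as.character(d)))
  rownames(mat) <- names(d)
  meta <- if (is.null(label_schema)) NULL else parse_labels(names(d), label_schema)
  new_alignment(mat, meta, offset = offset)
}

#' Write an alignment to FASTA
#'
#' @param aln alignment.
#' @param path output file.
#' @export
write_alignment <- function(aln, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(n_seq(aln))) {
    writeLines(c(paste0(">", rownames(aln$seqs)[i]),
                 paste(aln$seqs[i, ], collapse = "")), con)
  }
  invisible(path)
}

#' Subset an alignment by sequence and/or column
#'
#' @param aln alignment.
#' @param i sequence selector (indices, labels or logical).
#' @param j column selector (1-based).
#' @return alignment.
#' @export
aln_subset <- function(aln, i = NULL, j = NULL) {
  s <- aln$seqs
  m <- aln$meta
  if (!is.null(i)) {
    s <- s[i, , drop = FALSE]
    m <- m[match(rownames(s), m$label), , drop = FALSE]
  }
  if (!is.null(j)) s <- s[, j, drop = FALSE]
  new_alignment(s, m, offset = if (is.null(j)) aln$offset else 0L)
}

#' Split an alignment by species
#'
#' @param aln alignment with parsed species metadata.
#' @return named list of alignments, one per species.
#' @export
split_species <- function(aln) {
  sp <- aln$meta$species
  lapply(split(seq_len(n_seq(aln)), sp), function(i) aln_subset(aln, i))
}

#' Segregating (polymorphic) sites of an alignment
#'
#' A column enters the table when it carries at least two distinct non-gap,
#' non-N states (pairwise deletion of gaps and Ns: missing characters never
#' create or mask polymorphism in the count). Columns whose variation involves
#' only gaps/N are excluded. For coding alignments each site is classified as
#' synonymous, nonsynonymous or ambiguous by substituting the alternative
#' state into the consensus codon background.
#'
#' @param aln alignment with `n >= 2`.
#' @param classify classify sites as synonymous/nonsynonymous (requires a
#'   codon-clean frame)? Default `TRUE` when the frame length is divisible by 3.
#' @return data.frame of class `site_table` with columns `pos` (1-based),
#'   `states` (e.g. `"A/G"`), `counts`, `n_states`, `biallelic`, `singleton`,
#'   `class`, `minor_count`. Attribute `S` is the number of rows; attribute
#'   `S_complete` is the count under complete deletion (columns with any gap/N
#'   dropped entirely), logged for cross-checking other tools' conventions.
#' @export
segregating_sites <- function(aln, classify = NULL) {
  if (n_seq(aln) < 2) stop("need >=2 sequences")
  s <- aln$seqs
  L <- ncol(s)
  if (is.null(classify)) classify <- (L - aln$offset) %% 3 == 0
  pos <- integer(0); states <- character(0); counts <- character(0)
  n_states <- integer(0); biall <- logical(0); singl <- logical(0)
  minor <- integer(0); has_missing <- logical(0)
  varying <- which(colSums(s != s[rep(1L, nrow(s)), , drop = FALSE]) > 0)
  for (j in varying) {
    col <- s[, j]
    keep <- col %in% DNA_BASES
    tab <- table(col[keep])
    if (length(tab) >= 2L) {
      tab <- sort(tab, decreasing = TRUE)
      pos <- c(pos, j)
      states <- c(states, paste(names(tab), collapse = "/"))
      counts <- c(counts, paste(as.integer(tab), collapse = "/"))
      n_states <- c(n_states, length(tab))
      biall <- c(biall, length(tab) == 2L)
      singl <- c(singl, sum(tab == min(tab)) >= 1L && min(tab) == 1L)
      minor <- c(minor, as.integer(min(tab)))
      has_missing <- c(has_missing, any(!keep))
    }
  }
  cls <- rep(NA_character_, length(pos))
  if (classify && length(pos)) cls <- classify_sites(aln, pos)
  out <- data.frame(pos = pos, states = states, counts = counts,
                    n_states = n_states, biallelic = biall, singleton = singl,
                    class = cls, minor_count = minor,
                    stringsAsFactors = FALSE)
  class(out) <- c("site_table", "data.frame")
  attr(out, "S") <- nrow(out)
  attr(out, "S_complete") <- sum(!has_missing)
  attr(out, "n") <- n_seq(aln)
  out
}

# syn/nonsyn class of segregating sites: substitute each observed alternative
# state into the majority codon background; "ambiguous" when pathways disagree
# or the codon carries other polymorphism/missing data.
classify_sites <- function(aln, pos) {
  s <- aln$seqs
  off <- aln$offset
  vapply(pos, function(j) {
    cidx <- (j - 1 - off) %/% 3          # codon index, 0-based
    if (cidx < 0) return(NA_character_)
    cstart <- off + cidx * 3 + 1
    if (cstart + 2 > ncol(s)) return(NA_character_)
    cod <- s[, cstart:(cstart + 2), drop = FALSE]
    ok <- apply(cod, 1, function(r) all(r %in% DNA_BASES))
    if (!any(ok)) return("ambiguous")
    cods <- apply(cod[ok, , drop = FALSE], 1, paste, collapse = "")
    aas <- translate_codon(cods)
    u <- unique(cods)
    if (length(unique(aas)) == 1L) "synonymous"
    else {
      # nonsynonymous iff variation at THIS site changes the amino acid in
      # at least one observed codon background
      within_pos <- j - cstart + 1
      other <- setdiff(1:3, within_pos)
      bg <- apply(cod[ok, other, drop = FALSE], 1, paste, collapse = "")
      changes <- vapply(unique(bg), function(b) {
        here <- unique(cods[bg == b])
        length(unique(translate_codon(here))) > 1L
      }, logical(1))
      if (any(changes)) "nonsynonymous" else "ambiguous"
    }
  }, character(1))
}

#' Collapse an alignment to its distinct haplotypes
#'
#' Sequences differing only at positions where one of them is `N` are treated
#' as the same haplotype (ambiguity is a wildcard), which maximises use of
#' partially resolved cloned alleles.
#'
#' @param aln alignment.
#' @return data.frame with `haplotype` (sequence string), `count`, `members`
#'   (semicolon-joined labels), sorted by decreasing count.
#' @export
collapse_haplotypes <- function(aln) {
  s <- aln$seqs
  n <- nrow(s)
  grp <- integer(n)
  reps <- list()  # representative character vectors
  for (i in seq_len(n)) {
    hit <- 0L
    for (g in seq_along(reps)) {
      r <- reps[[g]]
      cmp <- r == s[i, ] | r == "N" | s[i, ] == "N"
      if (all(cmp)) { hit <- g; break }
    }
    if (hit == 0L) {
      reps[[length(reps) + 1L]] <- s[i, ]
      hit <- length(reps)
    } else {
      # refine representative where it had N but the new sequence is resolved
      r <- reps[[hit]]
      r[r == "N"] <- s[i, r == "N"]
      reps[[hit]] <- r
    }
    grp[i] <- hit
  }
  tab <- table(grp)
  out <- data.frame(
    haplotype = vapply(reps, paste, "", collapse = ""),
    count = as.integer(tab[as.character(seq_along(reps))]),
    members = vapply(seq_along(reps), function(g)
      paste(rownames(s)[grp == g], collapse = ";"), ""),
    stringsAsFactors = FALSE)
  out[order(-out$count), , drop = FALSE]
}

#' Partition sequences into allelic lineages at diagnostic sites
#'
#' Each sequence is assigned to the group whose diagnostic states it matches
#' best (majority over informative diagnostics); ties or all-missing
#' diagnostics leave the sequence unassigned. Mismatches to the winning
#' group's diagnostics are reported.
#'
#' @param aln alignment.
#' @param diagnostics data.frame with columns `pos` (1-based) and one column
#'   per group naming the expected state, e.g.
#'   `data.frame(pos = 5, K = "A", M = "C")`.
#' @return list with `groups` (named character vector label -> group or NA),
#'   `mismatch_fraction` per sequence, `table` of per-sequence scores.
#' @export
partition_lineages <- function(aln, diagnostics) {
  stopifnot(is.data.frame(diagnostics), "pos" %in% names(diagnostics))
  if (any(diagnostics$pos > aln_len(aln))) stop("diagnostic position beyond alignment length")
  gcols <- setdiff(names(diagnostics), "pos")
  if (length(gcols) < 2) stop("need >=2 groups")
  s <- aln$seqs
  score <- matrix(0L, n_seq(aln), length(gcols), dimnames = list(rownames(s), gcols))
  informative <- integer(n_seq(aln))
  for (k in seq_len(nrow(diagnostics))) {
    col <- s[, diagnostics$pos[k]]
    ok <- col %in% DNA_BASES
    informative <- informative + ok
    for (g in seq_along(gcols)) {
      score[, g] <- score[, g] + (ok & col == toupper(diagnostics[[gcols[g]]][k]))
    }
  }
  best <- apply(score, 1, function(r) {
    w <- which(r == max(r))
    if (max(r) == 0L || length(w) > 1L) NA_character_ else gcols[w]
  })
  if (all(is.na(best))) stop("diagnostics uninformative")
  mism <- ifelse(informative > 0,
                 (informative - score[cbind(seq_len(nrow(score)),
                                            match(best, gcols))]) / informative,
                 NA_real_)
  mism[is.na(best)] <- NA_real_
  list(groups = best, mismatch_fraction = mism,
       table = data.frame(label = rownames(s), score, informative = informative,
                          group = best, stringsAsFactors = FALSE))
}
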