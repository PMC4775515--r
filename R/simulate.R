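# Coalescent synthetic-data generator: codon-aware two-species alignments
# under constant size, sudden expansion, bottleneck/sweep contraction and
# balanced allelic classes. Infinite-sites mutations are mapped onto a finite
# codon sequence with collision-free site assignment, so analytic expectations
# (E[S] = theta * a_{n-1} * L, E[pi] = theta) hold exactly while the output is
# ordinary coding FASTA the whole pipeline can ingest.

# ---- demography clocks: map effective coalescent time -> real time ---------

# demography: list(type = "constant")
#             list(type = "event", T = .., S = ..)      contraction burst
#             list(type = "stepchange", T = .., ratio = ..)  sudden expansion
#                 (looking back, coalescent rate multiplies by `ratio` beyond
#                  T; ratio = theta1/theta0 > 1 emulates expansion)
#             list(type = "growth", g = ..)             exponential growth
real_time_of <- function(demography) {
  d <- demography
  switch(d$type,
    constant = function(te) te,
    event = function(te) {
      ifelse(te <= d$T, te, ifelse(te <= d$T + d$S, d$T, te - d$S))
    },
    stepchange = function(te) {
      ifelse(te <= d$T, te, d$T + (te - d$T) / d$ratio)
    },
    growth = function(te) log(1 + d$g * te) / d$g,
    stop("unknown demography type: ", d$type)
  )
}

# ---- genealogy simulation ---------------------------------------------------

#' Simulate a coalescent genealogy
#'
#' Standard n-coalescent under the given size history, in units of 2N
#' generations. Under constant size `E[T_MRCA] = 2(1 - 1/n)` and the expected
#' total length is `2 a_{n-1}`.
#'
#' @param n number of leaves (>= 2).
#' @param demography list; see Details in the package vignette. Default
#'   constant size. Supported: `constant`, `event(T, S)` (instantaneous
#'   contraction), `stepchange(T, ratio)` (sudden expansion looking forward),
#'   `growth(g)`.
#' @param seed optional integer seed.
#' @return object of class `coal_tree`: `n`, `time` (node times, leaves
#'   first), `parent` (0 for root), `leaf_sets` (list of leaf index vectors
#'   per node).
#' @export
simulate_genealogy <- function(n, demography = list(type = "constant"),
                               seed = NULL) {
  if (n < 2) stop("n must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  clock <- real_time_of(demography)
  n_nodes <- 2L * n - 1L
  time <- numeric(n_nodes)
  parent <- integer(n_nodes)
  active <- seq_len(n)
  nxt <- n + 1L
  te <- 0
  while (length(active) > 1L) {
    k <- length(active)
    te <- te + stats::rexp(1, k * (k - 1) / 2)
    pick <- sample(k, 2)
    time[nxt] <- clock(te)
    parent[active[pick]] <- nxt
    active <- c(active[-pick], nxt)
    nxt <- nxt + 1L
  }
  build_tree(n, time, parent)
}

build_tree <- function(n, time, parent, species = NULL) {
  n_nodes <- length(time)
  kids <- vector("list", n_nodes)
  for (v in seq_len(n_nodes - 1L)) {
    p <- parent[v]
    if (p > 0) kids[[p]] <- c(kids[[p]], v)
  }
  leaf_sets <- vector("list", n_nodes)
  for (v in seq_len(n)) leaf_sets[[v]] <- v
  for (v in (n + 1L):n_nodes) {
    leaf_sets[[v]] <- sort(unlist(leaf_sets[kids[[v]]]))
  }
  structure(list(n = n, time = time, parent = parent, leaf_sets = leaf_sets,
                 species = species), class = "coal_tree")
}

#' @export
print.coal_tree <- function(x, ...) {
  cat(sprintf("<coal_tree> %d leaves, TMRCA = %.3f, total length = %.3f (2N units)\n",
              x$n, tree_tmrca(x), tree_total_length(x)))
  invisible(x)
}

branch_lengths <- function(tree) {
  len <- numeric(length(tree$time))
  has_p <- tree$parent > 0
  len[has_p] <- tree$time[tree$parent[has_p]] - tree$time[has_p]
  len
}

#' Total branch length of a genealogy (2N units)
#' @param tree a `coal_tree`.
#' @export
tree_total_length <- function(tree) sum(branch_lengths(tree))

#' Time to the most recent common ancestor (2N units)
#' @param tree a `coal_tree`.
#' @export
tree_tmrca <- function(tree) max(tree$time)

# per-class (number of subtended leaves) branch lengths, classes 1..n-1
tree_class_lengths <- function(tree) {
  len <- branch_lengths(tree)
  cls <- vapply(tree$leaf_sets, length, 1L)
  out <- numeric(tree$n - 1)
  for (v in which(tree$parent > 0)) {
    if (cls[v] < tree$n) out[cls[v]] <- out[cls[v]] + len[v]
  }
  out
}

# two-species isolation genealogy: independent coalescents below split_T,
# pooled (same 2N) above. Species vector marks leaves 1..nA as "A", rest "B".
simulate_genealogy_2sp <- function(nA, nB, split_T, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nA + nB
  n_nodes <- 2L * n - 1L
  time <- numeric(n_nodes)
  parent <- integer(n_nodes)
  pools <- list(A = seq_len(nA), B = nA + seq_len(nB))
  nxt <- n + 1L
  t <- 0
  repeat {
    kA <- length(pools$A); kB <- length(pools$B)
    rA <- kA * (kA - 1) / 2; rB <- kB * (kB - 1) / 2
    if (rA + rB == 0) { t <- split_T; break }
    dt <- stats::rexp(1, rA + rB)
    if (t + dt >= split_T) { t <- split_T; break }
    t <- t + dt
    d <- if (stats::runif(1) < rA / (rA + rB)) "A" else "B"
    pick <- sample(length(pools[[d]]), 2)
    time[nxt] <- t
    parent[pools[[d]][pick]] <- nxt
    pools[[d]] <- c(pools[[d]][-pick], nxt)
    nxt <- nxt + 1L
  }
  active <- c(pools$A, pools$B)
  while (length(active) > 1L) {
    k <- length(active)
    t <- t + stats::rexp(1, k * (k - 1) / 2)
    pick <- sample(k, 2)
    time[nxt] <- t
    parent[active[pick]] <- nxt
    active <- c(active[-pick], nxt)
    nxt <- nxt + 1L
  }
  build_tree(n, time, parent, species = rep(c("A", "B"), c(nA, nB)))
}

# structured coalescent with two allelic classes (balancing-selection
# emulation): each class holds half the population; lineages migrate between
# classes at rate m per lineage per 2N generations.
simulate_genealogy_2class <- function(n_per_class, m, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- 2L * n_per_class
  n_nodes <- 2L * n - 1L
  time <- numeric(n_nodes)
  parent <- integer(n_nodes)
  cls <- rep(c(1L, 2L), each = n_per_class)   # class of each active lineage
  active <- seq_len(n)
  acls <- cls
  nxt <- n + 1L
  t <- 0
  while (length(active) > 1L) {
    k1 <- sum(acls == 1L); k2 <- sum(acls == 2L)
    # deme size N/2 doubles the pair-coalescence rate within a class
    rc1 <- k1 * (k1 - 1); rc2 <- k2 * (k2 - 1)
    rmig <- m * (k1 + k2)
    tot <- rc1 + rc2 + rmig
    t <- t + stats::rexp(1, tot)
    u <- stats::runif(1) * tot
    if (u < rc1 + rc2) {
      d <- if (u < rc1) 1L else 2L
      idx <- which(acls == d)
      pick <- idx[sample(length(idx), 2)]
      time[nxt] <- t
      parent[active[pick]] <- nxt
      active <- c(active[-pick], nxt)
      acls <- c(acls[-pick], d)
      nxt <- nxt + 1L
    } else {
      i <- sample(length(active), 1)
      acls[i] <- 3L - acls[i]
    }
  }
  tr <- build_tree(n, time, parent)
  tr$class <- cls
  tr
}

# ---- codon-aware mutation dropping -----------------------------------------

# random ancestral coding sequence: uniform over non-stop codons
random_coding_sequence <- function(L) {
  stopifnot(L %% 3 == 0)
  ok <- names(GENETIC_CODE_STD)[GENETIC_CODE_STD != "*"]
  cods <- sample(ok, L / 3, replace = TRUE)
  unlist(strsplit(cods, ""))
}

# synonymous opportunities at third positions: for each codon, the set of
# alternative third-position bases that keep the amino acid (and are not
# stops). Covers 4-fold and 2-fold degenerate codons; Met/Trp contribute none.
synonymous_third_alternatives <- function(anc) {
  L <- length(anc)
  out <- vector("list", L / 3)
  pos <- integer(L / 3)
  for (k in seq_len(L / 3)) {
    stem <- paste(anc[(3 * k - 2):(3 * k - 1)], collapse = "")
    cur <- anc[3 * k]
    aas <- GENETIC_CODE_STD[paste0(stem, DNA_BASES)]
    cur_aa <- GENETIC_CODE_STD[[paste0(stem, cur)]]
    out[[k]] <- DNA_BASES[aas == cur_aa & DNA_BASES != cur]
    pos[k] <- 3 * k
  }
  keep <- lengths(out) > 0
  list(pos = pos[keep], alts = out[keep])
}

#' Drop infinite-sites mutations on a genealogy, codon-aware
#'
#' Mutation count is Poisson(theta * L * total_length / 2); each mutation is
#' placed on a branch with probability proportional to (weighted) branch
#' length and assigned a distinct alignment site: with probability
#' `syn_fraction` a third codon position carrying a synonymous alternative
#' (the derived base drawn from the synonymous set), else a first/second
#' codon position with a derived base chosen to be nonsynonymous and
#' stop-free.
#'
#' @param tree a `coal_tree`.
#' @param theta per-site theta (4N mu).
#' @param L alignment length (multiple of 3).
#' @param syn_fraction probability a mutation is synonymous (default 0.8).
#' @param seed optional integer seed.
#' @param weights optional per-node branch weight vector (polymorphism
#'   thinning/inflation); default 1 for every branch.
#' @param labels leaf labels (default `ES<i>_All<a>` style pairing).
#' @return alignment (`aln`) with attribute `mutations` (data.frame: site,
#'   branch node, class, derived base, carrier count).
#' @export
drop_mutations <- function(tree, theta, L, syn_fraction = 0.8, seed = NULL,
                           weights = NULL, labels = NULL) {
  if (theta < 0) stop("theta must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  n <- tree$n
  len <- branch_lengths(tree)
  w <- weights %||% rep(1, length(len))
  eff <- len * w
  n_mut <- stats::rpois(1, theta * L * sum(eff) / 2)
  anc <- random_coding_sequence(L)
  syn_opp <- synonymous_third_alternatives(anc)
  syn_pool <- syn_opp$pos
  syn_alts <- syn_opp$alts
  nonsyn_pool <- setdiff(seq_len(L), seq(3, L, by = 3))
  if (n_mut > 0 && n_mut > length(syn_pool) + length(nonsyn_pool)) {
    stop("L too small for ", n_mut, " mutations")
  }
  seqs <- matrix(rep(anc, each = n), nrow = n)
  muts <- list()
  if (n_mut > 0) {
    branches <- sample(seq_along(eff), n_mut, replace = TRUE, prob = eff)
    is_syn <- stats::runif(n_mut) < syn_fraction
    if (sum(is_syn) > length(syn_pool)) stop("L too small: synonymous site pool exhausted")
    if (sum(!is_syn) > length(nonsyn_pool)) stop("L too small: nonsynonymous site pool exhausted")
    syn_pick <- if (any(is_syn)) sample(seq_along(syn_pool), sum(is_syn)) else integer(0)
    non_sites <- if (any(!is_syn)) sample(nonsyn_pool, sum(!is_syn)) else integer(0)
    si <- 1L; ni <- 1L
    for (k in seq_len(n_mut)) {
      if (is_syn[k]) { site <- syn_pool[syn_pick[si]] }
      else { site <- non_sites[ni]; ni <- ni + 1L }
      cur <- anc[site]
      if (is_syn[k]) {
        alts <- syn_alts[[syn_pick[si]]]
        si <- si + 1L
        derived <- sample(rep(alts, 2), 1)
      } else {
        cidx <- (site - 1) %/% 3
        cs <- cidx * 3 + 1
        cod <- anc[cs:(cs + 2)]
        within <- site - cs + 1
        cand <- setdiff(DNA_BASES, cur)
        okb <- vapply(cand, function(b) {
          cod2 <- cod; cod2[within] <- b
          aa2 <- GENETIC_CODE_STD[paste(cod2, collapse = "")]
          aa2 != "*" && aa2 != GENETIC_CODE_STD[paste(cod, collapse = "")]
        }, logical(1))
        if (!any(okb)) next  # unmutable background (rare); drop the mutation
        derived <- sample(rep(cand[okb], 2), 1)
      }
      carriers <- tree$leaf_sets[[branches[k]]]
      seqs[carriers, site] <- derived
      muts[[length(muts) + 1]] <- data.frame(
        site = site, branch = branches[k],
        class = if (is_syn[k]) "synonymous" else "nonsynonymous",
        derived = derived, carriers = length(carriers),
        stringsAsFactors = FALSE)
    }
  }
  # rare collision: two mutations in one codon can combine into a stop in
  # leaves carrying both; undo the most recent offending mutation(s)
  if (length(muts) > 1) {
    repeat {
      cods <- matrix(GENETIC_CODE_STD[apply(seqs, 1, function(r)
        paste0(r[c(TRUE, FALSE, FALSE)], r[c(FALSE, TRUE, FALSE)],
               r[c(FALSE, FALSE, TRUE)]))], nrow = L / 3)
      bad <- which(cods == "*", arr.ind = TRUE)
      if (nrow(bad) == 0) break
      cidx <- bad[1, 1]
      span <- (3 * cidx - 2):(3 * cidx)
      in_codon <- which(vapply(muts, function(m) m$site %in% span, logical(1)))
      k <- in_codon[length(in_codon)]
      seqs[tree$leaf_sets[[muts[[k]]$branch]], muts[[k]]$site] <- anc[muts[[k]]$site]
      muts[[k]] <- NULL
    }
  }
  if (is.null(labels)) {
    sp <- tree$species %||% rep("B", n)
    tag <- ifelse(sp == "A", "EC", "ES")
    ind <- stats::ave(seq_len(n), sp, FUN = function(i) (seq_along(i) + 1) %/% 2)
    alle <- stats::ave(seq_len(n), sp, FUN = function(i) (seq_along(i) - 1) %% 2 + 1)
    labels <- sprintf("%s%02d_All%d", tag, ind, alle)
  }
  rownames(seqs) <- labels
  meta <- parse_labels(labels)
  out <- new_alignment(seqs, meta, offset = 0L)
  attr(out, "mutations") <- if (length(muts)) do.call(rbind, muts) else
    data.frame(site = integer(0), branch = integer(0), class = character(0),
               derived = character(0), carriers = integer(0))
  out
}

# ---- scenario-level simulators ---------------------------------------------

#' Scenario specification for the synthetic generator
#'
#' Defaults state a world shaped like a two-sister-species, four-locus coding
#' study: 24 alleles per species, locus lengths 558-892 bp, per-site theta
#' 0.0006-0.022, species split deep enough to give divergences of a few to
#' ~15 percent.
#'
#' @param n_per_species alleles sampled per species.
#' @param loci named vector of locus lengths (bp, multiples of 3).
#' @param theta per-site theta per locus (recycled).
#' @param c_i inheritance scalar per locus (0.25 for mtDNA).
#' @param split_T species divergence in 2N-generation units.
#' @param syn_fraction probability a mutation is synonymous.
#' @param demography within-species demography (see [simulate_genealogy()]).
#' @param thin optional list(species = "A"|"B", locus = name, factor = x):
#'   multiply the mutation rate of branches private to that species by x
#'   (x < 1 emulates a sweep, x > 1 balancing-driven excess).
#' @param seed integer seed fixing the full output.
#' @return list of class `scenario_spec`.
#' @export
scenario_spec <- function(n_per_species = 24,
                          loci = c(locusA = 891, locusB = 891,
                                   locusC = 849, mt1 = 558),
                          theta = c(0.004, 0.01, 0.012, 0.011),
                          c_i = c(1, 1, 1, 0.25),
                          split_T = 5, syn_fraction = 0.8,
                          demography = list(type = "constant"),
                          thin = NULL, seed = 1) {
  stopifnot(all(loci %% 3 == 0), all(theta >= 0), split_T >= 0)
  structure(list(n_per_species = n_per_species, loci = loci,
                 theta = rep(theta, length.out = length(loci)),
                 c_i = rep(c_i, length.out = length(loci)),
                 split_T = split_T, syn_fraction = syn_fraction,
                 demography = demography, thin = thin, seed = seed),
            class = "scenario_spec")
}

#' Simulate a multilocus two-species dataset
#'
#' Isolation model: independent coalescents within each species below the
#' split, a single ancestral population above. Mutations are codon-aware
#' (see [drop_mutations()]); per-locus theta is scaled by the inheritance
#' scalar `c_i`. Optional private-polymorphism thinning/inflation emulates a
#' sweep or balancing selection at one locus.
#'
#' @param spec a [scenario_spec()].
#' @return named list per locus: `aln` (both species; split with
#'   [split_species()]), `tree`, plus a `manifest` attribute with the
#'   parameters and seed.
#' @export
simulate_two_species <- function(spec) {
  if (spec$split_T <= 0) stop("species_split_T must be > 0")
  set.seed(spec$seed)
  out <- list()
  for (i in seq_along(spec$loci)) {
    lname <- names(spec$loci)[i]
    nA <- spec$n_per_species; nB <- spec$n_per_species
    tr <- simulate_genealogy_2sp(nA, nB, spec$split_T)
    w <- rep(1, length(tr$time))
    if (!is.null(spec$thin) && identical(spec$thin$locus, lname)) {
      spl <- if (spec$thin$species == "A") seq_len(nA) else nA + seq_len(nB)
      priv <- vapply(tr$leaf_sets, function(s)
        all(s %in% spl) && length(s) < length(spl), logical(1))
      w[priv] <- spec$thin$factor
    }
    a <- drop_mutations(tr, spec$theta[i] * spec$c_i[i], spec$loci[i],
                        spec$syn_fraction, weights = w)
    out[[lname]] <- list(aln = a, tree = tr)
  }
  attr(out, "manifest") <- unclass(spec)
  out
}

#' Simulate one locus with two ancient balanced allelic classes
#'
#' Structured coalescent with two allelic classes of equal size and
#' class-exchange rate `m` per lineage per 2N generations. Small `m` yields
#' deep inter-class divergence, intermediate-frequency linked sites, positive
#' Tajima's D and a bimodal mismatch spectrum; `m -> Inf` recovers panmixia.
#'
#' @param n_per_class alleles per class.
#' @param theta per-site theta.
#' @param L length (multiple of 3).
#' @param m class-exchange rate.
#' @param syn_fraction probability a mutation is synonymous.
#' @param seed integer seed.
#' @return alignment with attribute `lineage_class` (leaf class vector) and
#'   `mutations`.
#' @export
simulate_balanced_lineages <- function(n_per_class, theta, L, m = 0.1,
                                       syn_fraction = 0.8, seed = 1) {
  set.seed(seed)
  tr <- simulate_genealogy_2class(n_per_class, m)
  a <- drop_mutations(tr, theta, L, syn_fraction)
  attr(a, "lineage_class") <- tr$class
  a
}

#' Write a simulated scenario to FASTA plus a JSON manifest
#'
#' @param sim result of [simulate_two_species()].
#' @param dir output directory (created if needed).
#' @return invisibly, the manifest path.
#' @export
write_scenario <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (lname in names(sim)) {
    write_alignment(sim[[lname]]$aln, file.path(dir, paste0(lname, ".fasta")))
  }
  man <- attr(sim, "manifest")
  man$demography <- man$demography$type
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
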