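## maturation: SSM pool counting, per-mutation enrichment, the dual
## independent-enrichment selection rule, and degenerate-codon
## combinatorial library design under a diversity cap.

#' Pool counts container
#'
#' @param counts data.frame with columns position, from, to, count
#'   (one row per single mutation).
#' @param wt_count Wild-type (zero-difference) read count.
#' @param pool_id Identifier.
#' @param condition One of naive, affinity_sort, specificity_sort.
#' @param parent Parent amino-acid sequence string.
#' @param discarded Reads dropped (multi-mutant, stops, bad length).
#' @param truth Optional ground-truth frequencies (generator bookkeeping).
#' @return A `pool_counts` object.
#' @export
pool_counts <- function(counts, wt_count = 0, pool_id = "pool",
                        condition = c("naive", "affinity_sort", "specificity_sort"),
                        parent = NULL, discarded = 0, truth = NULL) {
  condition <- match.arg(condition)
  stopifnot(all(counts$count >= 0))
  obj <- structure(list(counts = counts, wt_count = wt_count, pool_id = pool_id,
                        condition = condition, parent = parent,
                        discarded = discarded,
                        total = sum(counts$count) + wt_count + discarded),
                   class = "pool_counts")
  if (!is.null(truth)) attr(obj, "truth") <- truth
  obj
}

#' @export
print.pool_counts <- function(x, ...) {
  cat(sprintf("pool_counts '%s' (%s): %d mutations, wt %d, discarded %d, total %d\n",
              x$pool_id, x$condition, nrow(x$counts), x$wt_count,
              x$discarded, x$total))
  invisible(x)
}

#' Tally single-mutant reads against a parent sequence
#'
#' Reads identical to the parent count as wild type; reads with exactly
#' one amino-acid difference are tallied under (position, from, to); reads
#' with two or more differences, stops (`*`), or incompatible length are
#' discarded and reported (SSM pools are single-substitution by
#' construction).
#'
#' @param reads Character vector of amino-acid reads.
#' @param parent `protein_sequence` or string.
#' @param pool_id,condition Passed to [pool_counts()].
#' @return A `pool_counts`.
#' @export
count_variants <- function(reads, parent, pool_id = "pool", condition = "naive") {
  pseq <- as_sequence_string(parent)
  L <- nchar(pseq)
  pv <- strsplit(pseq, "")[[1]]
  tall <- new.env(parent = emptyenv())
  wt <- 0L; disc <- 0L
  for (r in reads) {
    if (nchar(r) != L || grepl("\\*", r)) { disc <- disc + 1L; next }
    rv <- strsplit(toupper(r), "")[[1]]
    diffpos <- which(rv != pv)
    if (length(diffpos) == 0) wt <- wt + 1L
    else if (length(diffpos) == 1) {
      key <- paste(diffpos, pv[diffpos], rv[diffpos], sep = "|")
      tall[[key]] <- (tall[[key]] %||% 0L) + 1L
    } else disc <- disc + 1L
  }
  keys <- ls(tall)
  df <- if (length(keys)) {
    kk <- do.call(rbind, strsplit(keys, "|", fixed = TRUE))
    data.frame(position = as.integer(kk[, 1]), from = kk[, 2], to = kk[, 3],
               count = vapply(keys, function(k) tall[[k]], 0L),
               stringsAsFactors = FALSE, row.names = NULL)
  } else data.frame(position = integer(), from = character(),
                    to = character(), count = integer())
  pool_counts(df, wt_count = wt, pool_id = pool_id, condition = condition,
              parent = pseq, discarded = disc)
}

#' Per-mutation enrichment between naive and selected pools
#'
#' Frequency-ratio log2 enrichment with additive pseudocount:
#' `e_m = log2( (c_sel+p)/(T_sel+p*M) / ((c_naive+p)/(T_naive+p*M)) )`
#' over the M mutations tracked in the naive pool. A mutation is flagged
#' enriched when `e_m > threshold` and its naive coverage is at least
#' `min_coverage`.
#'
#' @param naive,selected `pool_counts` over the same parent.
#' @param pseudocount Additive pseudocount p (default 0.5).
#' @param threshold Enrichment flag threshold (log2 units, default 1).
#' @param min_coverage Minimum naive count (default 10).
#' @return An `enrichment_result`: data.frame (position, from, to,
#'   naive_count, selected_count, log2_enrichment, enriched) plus settings.
#' @export
enrichment <- function(naive, selected, pseudocount = 0.5, threshold = 1.0,
                       min_coverage = 10) {
  if (!is.null(naive$parent) && !is.null(selected$parent) &&
      naive$parent != selected$parent)
    stop("pools do not share a parent sequence")
  if (naive$total == 0 || selected$total == 0) stop("zero-total pool")
  nv <- naive$counts
  sv <- selected$counts
  key <- paste(nv$position, nv$from, nv$to)
  skey <- paste(sv$position, sv$from, sv$to)
  sel_count <- sv$count[match(key, skey)]
  sel_count[is.na(sel_count)] <- 0L
  M <- nrow(nv)
  p <- pseudocount
  fn <- (nv$count + p) / (naive$total + p * M)
  fs <- (sel_count + p) / (selected$total + p * M)
  e <- log2(fs / fn)
  tab <- data.frame(position = nv$position, from = nv$from, to = nv$to,
                    naive_count = nv$count, selected_count = sel_count,
                    log2_enrichment = e,
                    enriched = e > threshold & nv$count >= min_coverage,
                    stringsAsFactors = FALSE)
  structure(list(table = tab, pseudocount = p, threshold = threshold,
                 min_coverage = min_coverage, condition = selected$condition,
                 parent = naive$parent),
            class = "enrichment_result")
}

#' Dual independent-enrichment selection
#'
#' The selection rule feeding combinatorial libraries: only mutations
#' independently enriched under BOTH the affinity sort and the specificity
#' sort are kept. Wild-type identities can never be selected (they are not
#' mutations). The result is ranked by `min(e_aff, e_spec)` descending.
#'
#' @param aff,spec `enrichment_result`s over the same parent.
#' @return data.frame (position, from, to, e_aff, e_spec, min_e).
#' @export
dual_select <- function(aff, spec) {
  if (!is.null(aff$parent) && !is.null(spec$parent) && aff$parent != spec$parent)
    stop("results do not share a parent")
  ta <- aff$table[aff$table$enriched, , drop = FALSE]
  ts <- spec$table[spec$table$enriched, , drop = FALSE]
  key <- intersect(paste(ta$position, ta$from, ta$to),
                   paste(ts$position, ts$from, ts$to))
  if (!length(key))
    return(data.frame(position = integer(), from = character(), to = character(),
                      e_aff = numeric(), e_spec = numeric(), min_e = numeric()))
  ka <- paste(ta$position, ta$from, ta$to)
  ks <- paste(ts$position, ts$from, ts$to)
  ia <- match(key, ka); is_ <- match(key, ks)
  out <- data.frame(position = ta$position[ia], from = ta$from[ia],
                    to = ta$to[ia],
                    e_aff = ta$log2_enrichment[ia],
                    e_spec = ts$log2_enrichment[is_],
                    stringsAsFactors = FALSE)
  out <- out[out$from != out$to, , drop = FALSE]
  out$min_e <- pmin(out$e_aff, out$e_spec)
  out[order(-out$min_e), , drop = FALSE]
}

## ---- degenerate codon algebra ----

IUPAC_NT <- list(A = "A", C = "C", G = "G", T = "T",
                 R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                 W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                 B = c("C", "G", "T"), D = c("A", "G", "T"),
                 H = c("A", "C", "T"), V = c("A", "C", "G"),
                 N = c("A", "C", "G", "T"))

## Standard genetic code (via Biostrings when available; local fallback).
genetic_code <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    gc <- if (requireNamespace("Biostrings", quietly = TRUE)) {
      gc0 <- Biostrings::GENETIC_CODE
      stats::setNames(as.character(gc0), names(gc0))
    } else {
      b <- c("T", "C", "A", "G")
      ## codon order: first base slowest, matching the canonical table string
      codons <- paste0(rep(b, each = 16), rep(rep(b, each = 4), 4), rep(b, 16))
      aas <- strsplit(paste0(
        "FFLLSSSSYY**CC*W", "LLLLPPPPHHQQRRRR",
        "IIIMTTTTNNKKSSRR", "VVVVAAAADDEEGGGG"), "")[[1]]
      stats::setNames(aas, codons)
    }
    cache <<- gc
    cache
  }
})

## Expand a 3-letter degenerate codon into its concrete codons.
expand_degenerate_codon <- function(codon) {
  letters3 <- strsplit(toupper(codon), "")[[1]]
  if (length(letters3) != 3 || !all(letters3 %in% names(IUPAC_NT)))
    stop("invalid degenerate codon: ", codon)
  as.vector(outer(outer(IUPAC_NT[[letters3[1]]], IUPAC_NT[[letters3[2]]], paste0),
                  IUPAC_NT[[letters3[3]]], paste0))
}

#' Amino acids encoded by a degenerate codon
#' @param codon 3-letter IUPAC degenerate codon (e.g. "NNK").
#' @return List: `aas` (sorted unique 1-letter codes, stops excluded),
#'   `n_codons` (DNA multiplicity), `n_stop` (stop codons included).
#' @export
degenerate_codon_aas <- function(codon) {
  codons <- expand_degenerate_codon(codon)
  gc <- genetic_code()
  aa <- unname(gc[codons])
  list(aas = sort(unique(aa[aa != "*"])), n_codons = length(codons),
       n_stop = sum(aa == "*"))
}

## All 3375 degenerate codons with their encoded sets, built once.
degenerate_codon_table <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    letters15 <- names(IUPAC_NT)
    cods <- as.vector(outer(outer(letters15, letters15, paste0), letters15, paste0))
    gc <- genetic_code()
    info <- lapply(cods, function(cd) {
      codons <- expand_degenerate_codon(cd)
      aa <- unname(gc[codons])
      list(aas = sort(unique(aa[aa != "*"])), n_codons = length(codons),
           n_stop = sum(aa == "*"))
    })
    cache <<- list(codon = cods,
                   aas = lapply(info, `[[`, "aas"),
                   n_codons = vapply(info, `[[`, 0L, "n_codons"),
                   n_stop = vapply(info, `[[`, 0L, "n_stop"),
                   n_aas = vapply(info, function(i) length(i$aas), 0L))
    cache
  }
})

#' Minimal degenerate codon covering an amino-acid set
#'
#' Chooses the degenerate codon whose encoded set covers `aas` with the
#' smallest DNA multiplicity; ties broken by fewest extra amino acids,
#' then fewest stop codons, then lexicographic codon.
#'
#' @param aas Character vector of required 1-letter amino acids.
#' @param no_stop Disallow codons encoding any stop.
#' @return List: `codon`, `aas` (encoded set), `n_codons`, `n_stop`.
#' @export
best_degenerate_codon <- function(aas, no_stop = FALSE) {
  aas <- sort(unique(toupper(aas)))
  tab <- degenerate_codon_table()
  cover <- vapply(tab$aas, function(s) all(aas %in% s), TRUE)
  if (no_stop) cover <- cover & tab$n_stop == 0
  if (!any(cover)) stop("no degenerate codon covers: ", paste(aas, collapse = ","))
  idx <- which(cover)
  ord <- order(tab$n_codons[idx], tab$n_aas[idx] - length(aas),
               tab$n_stop[idx], tab$codon[idx])
  i <- idx[ord[1]]
  list(codon = tab$codon[i], aas = tab$aas[[i]], n_codons = tab$n_codons[i],
       n_stop = tab$n_stop[i])
}

#' Design a degenerate-codon combinatorial library
#'
#' Per position carrying selected mutations, picks the minimal degenerate
#' codon covering {parent AA} U {selected AAs}. If the product of encoded
#' amino-acid set sizes (protein diversity, stops excluded) exceeds the
#' cap, the lowest-ranked mutations (ascending `min_e`, or input order)
#' are dropped greedily until the library fits; drops are reported.
#'
#' @param parent `protein_sequence` or string.
#' @param selected data.frame with columns `position`, `to` (and
#'   optionally `min_e` for drop ranking), e.g. from [dual_select()].
#' @param cap Protein diversity cap (default 4e7, exclusive bound).
#' @param no_stop Disallow stop-containing codons.
#' @return A `combinatorial_library`: per-position codons/AA sets,
#'   `dna_diversity`, `protein_diversity`, `dropped` (data.frame).
#' @export
design_combinatorial_library <- function(parent, selected, cap = 4e7,
                                         no_stop = FALSE) {
  pseq <- as_sequence_string(parent)
  pv <- strsplit(pseq, "")[[1]]
  if (nrow(selected) && (any(selected$position < 1) ||
                         any(selected$position > length(pv))))
    stop("selected mutations reference positions outside the parent")
  sel <- selected
  if (!is.null(sel$min_e)) sel <- sel[order(-sel$min_e), , drop = FALSE]
  dropped <- sel[0, , drop = FALSE]
  repeat {
    lib <- build_library_positions(pv, sel, no_stop)
    if (lib$protein_diversity < cap || !nrow(sel)) break
    ## drop the lowest-ranked surviving mutation
    dropped <- rbind(dropped, sel[nrow(sel), , drop = FALSE])
    sel <- sel[-nrow(sel), , drop = FALSE]
  }
  structure(list(parent = pseq, positions = lib$positions,
                 dna_diversity = lib$dna_diversity,
                 protein_diversity = lib$protein_diversity,
                 diversity_cap = cap, dropped = dropped,
                 selected = sel),
            class = "combinatorial_library")
}

build_library_positions <- function(pv, sel, no_stop) {
  pos_list <- list()
  if (nrow(sel)) {
    for (p in sort(unique(sel$position))) {
      want <- unique(c(pv[p], sel$to[sel$position == p]))
      cd <- best_degenerate_codon(want, no_stop)
      pos_list[[as.character(p)]] <- c(list(position = p, parent = pv[p],
                                            required = sort(want)), cd)
    }
  }
  dna <- prod(vapply(pos_list, function(x) as.numeric(x$n_codons), 0))
  prot <- prod(vapply(pos_list, function(x) as.numeric(length(x$aas)), 0))
  if (!length(pos_list)) { dna <- 1; prot <- 1 }
  list(positions = pos_list, dna_diversity = dna, protein_diversity = prot)
}

#' @export
print.combinatorial_library <- function(x, ...) {
  cat(sprintf("combinatorial library: %d position(s), protein diversity %g (cap %g), DNA %g\n",
              length(x$positions), x$protein_diversity, x$diversity_cap,
              x$dna_diversity))
  for (p in x$positions)
    cat(sprintf("  pos %d (%s): %s -> {%s}\n", p$position, p$parent, p$codon,
                paste(p$aas, collapse = "")))
  if (nrow(x$dropped)) cat("  dropped", nrow(x$dropped), "mutation(s) to meet cap\n")
  invisible(x)
}

#' Library diversity (exact integer products)
#'
#' @param lib A `combinatorial_library`.
#' @return List: `dna` (product of codon multiplicities) and `protein`
#'   (product of encoded amino-acid set sizes, stops excluded).
#' @export
library_diversity <- function(lib) {
  list(dna = lib$dna_diversity, protein = lib$protein_diversity)
}

#' Enumerate all protein variants of a small library
#' @param lib A `combinatorial_library` with protein diversity <= `limit`.
#' @param limit Safety bound.
#' @return Character vector of full-length variant sequences.
#' @export
enumerate_library <- function(lib, limit = 1e5) {
  if (lib$protein_diversity > limit) stop("library too large to enumerate")
  pv <- strsplit(lib$parent, "")[[1]]
  if (!length(lib$positions)) return(paste0(pv, collapse = ""))
  sets <- lapply(lib$positions, `[[`, "aas")
  grid <- expand.grid(sets, stringsAsFactors = FALSE)
  posn <- vapply(lib$positions, `[[`, 0, "position")
  apply(grid, 1, function(row) {
    v <- pv
    v[posn] <- unlist(row)
    paste0(v, collapse = "")
  })
}
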