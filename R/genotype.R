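#' @keywords internal
"_PACKAGE"

#' RNA alphabet used throughout the package
#'
#' The four ribonucleotides, in the fixed order used by all encodings.
#' @export
RNA_BASES <- c("A", "C", "G", "U")

#' Offset between core-relative and full-ribozyme coordinates
#'
#' Position 1 of the 35-nt catalytic core corresponds to position 45 of the
#' full-length ribozyme, so absolute = relative + 44.
#' @export
CORE_OFFSET <- 44L

.chars <- function(seq) strsplit(seq, "", fixed = TRUE)[[1L]]

#' Validate a genotype sequence
#'
#' A genotype is a fixed-length RNA string over `A`, `C`, `G`, `U`
#' representing the catalytic core of the ribozyme.
#'
#' @param seq Character scalar.
#' @param L Required length, or `NULL` to accept any length.
#' @return The sequence, invisibly, after validation.
#' @export
validate_genotype <- function(seq, L = NULL) {
  stopifnot(is.character(seq), length(seq) == 1L, !is.na(seq))
  if (!is.null(L) && nchar(seq) != L) {
    stop("genotype has length ", nchar(seq), ", expected ", L)
  }
  if (grepl(paste0("[^", paste(RNA_BASES, collapse = ""), "]"), seq)) {
    stop("genotype contains characters outside {A,C,G,U}: ", seq)
  }
  invisible(seq)
}

#' Hamming distance between equal-length sequences
#'
#' @param a Character scalar reference sequence.
#' @param b Character vector of sequences of the same length as `a`.
#' @return Integer vector of pairwise distances between `a` and each
#'   element of `b`.
#' @examples
#' hamming("ACGU", "ACGA")
#' @export
hamming <- function(a, b) {
  if (any(nchar(b) != nchar(a))) {
    stop("hamming distance requires equal-length sequences")
  }
  ra <- charToRaw(a)
  vapply(b, function(s) sum(charToRaw(s) != ra), integer(1L), USE.NAMES = FALSE)
}

#' Enumerate all single mutants of a sequence
#'
#' Every sequence at Hamming distance 1, in deterministic position-major
#' order with substituted bases in alphabetical order, giving `3 * L`
#' variants for a length-`L` core.
#'
#' @param seq Genotype sequence.
#' @return Character vector of `3 * nchar(seq)` mutant sequences.
#' @export
enumerate_single_mutants <- function(seq) {
  validate_genotype(seq)
  ch <- .chars(seq)
  L <- length(ch)
  out <- character(3L * L)
  k <- 0L
  for (pos in seq_len(L)) {
    for (base in setdiff(RNA_BASES, ch[pos])) {
      k <- k + 1L
      mut <- ch
      mut[pos] <- base
      out[k] <- paste(mut, collapse = "")
    }
  }
  out
}

#' Enumerate all double mutants of a sequence
#'
#' Every sequence at Hamming distance 2: `choose(L, 2) * 9` variants.
#' Ordered by the first mutated position, then the second, then bases.
#'
#' @inheritParams enumerate_single_mutants
#' @return Character vector of mutant sequences.
#' @export
enumerate_double_mutants <- function(seq) {
  validate_genotype(seq)
  ch <- .chars(seq)
  L <- length(ch)
  if (L < 2L) stop("double mutants require a sequence of length >= 2")
  out <- vector("list", choose(L, 2L))
  k <- 0L
  for (i in seq_len(L - 1L)) {
    bi <- setdiff(RNA_BASES, ch[i])
    for (j in (i + 1L):L) {
      bj <- setdiff(RNA_BASES, ch[j])
      k <- k + 1L
      block <- character(9L)
      m <- 0L
      for (x in bi) for (y in bj) {
        m <- m + 1L
        mut <- ch
        mut[i] <- x
        mut[j] <- y
        block[m] <- paste(mut, collapse = "")
      }
      out[[k]] <- block
    }
  }
  unlist(out, use.names = FALSE)
}

#' Sample unique k-mutants of a sequence
#'
#' Draws `n` distinct sequences at exactly Hamming distance `k` from
#' `seq`, uniformly without replacement (rejection sampling over the
#' `choose(L, k) * 3^k` distinct k-mutants).
#'
#' @param seq Genotype sequence.
#' @param k Number of substitutions per variant.
#' @param n Number of unique variants to return.
#' @return Character vector of `n` unique mutant sequences.
#' @export
sample_k_mutants <- function(seq, k, n) {
  validate_genotype(seq)
  ch <- .chars(seq)
  L <- length(ch)
  stopifnot(k >= 1L, k <= L)
  total <- choose(L, k) * 3^k
  if (n > total) {
    stop("requested ", n, " variants but only ", total, " distinct ",
         k, "-mutants exist")
  }
  seen <- new.env(hash = TRUE, parent = emptyenv())
  out <- character(n)
  got <- 0L
  while (got < n) {
    pos <- sort(sample.int(L, k))
    mut <- ch
    for (p in pos) mut[p] <- sample(setdiff(RNA_BASES, ch[p]), 1L)
    s <- paste(mut, collapse = "")
    if (is.null(seen[[s]])) {
      seen[[s]] <- TRUE
      got <- got + 1L
      out[got] <- s
    }
  }
  out
}

#' Mutation-set naming
#'
#' A mutation set is a data frame with integer column `pos` (1-based
#' position in the core) and character column `base` (the substituted
#' base). Its canonical name joins `posBASE` tokens with `/`, e.g.
#' `"7G/8C/19U"`; the empty set is named `"WT"`.
#'
#' @param mutations Data frame with columns `pos` and `base`.
#' @return Character scalar variant name.
#' @seealso [parse_variant()], [mutations_between()], [apply_mutations()]
#' @export
name_variant <- function(mutations) {
  stopifnot(is.data.frame(mutations), all(c("pos", "base") %in% names(mutations)))
  if (nrow(mutations) == 0L) return("WT")
  if (is.unsorted(mutations$pos, strictly = TRUE)) {
    stop("mutation positions must be strictly increasing")
  }
  if (!all(mutations$base %in% RNA_BASES)) stop("invalid substituted base")
  paste0(mutations$pos, mutations$base, collapse = "/")
}

#' Parse a variant name into a mutation set
#'
#' @param name Variant name such as `"7G/8C/19U"` or `"WT"`.
#' @param L Optional core length used to range-check positions.
#' @return Data frame with columns `pos` and `base`.
#' @export
parse_variant <- function(name, L = NULL) {
  stopifnot(is.character(name), length(name) == 1L)
  if (identical(name, "WT")) {
    return(data.frame(pos = integer(0), base = character(0)))
  }
  tokens <- strsplit(name, "/", fixed = TRUE)[[1L]]
  ok <- grepl("^[0-9]+[ACGU]$", tokens)
  if (!all(ok)) stop("malformed variant token(s): ",
                     paste(tokens[!ok], collapse = ", "))
  pos <- as.integer(sub("[ACGU]$", "", tokens))
  base <- sub("^[0-9]+", "", tokens)
  if (is.unsorted(pos, strictly = TRUE)) {
    stop("positions in a variant name must be strictly increasing")
  }
  if (!is.null(L) && any(pos < 1L | pos > L)) {
    stop("position out of range in variant name: ", name)
  }
  data.frame(pos = pos, base = base)
}

#' Mutations separating a sequence from a reference
#'
#' @param ref Reference genotype.
#' @param seq Genotype of the same length.
#' @return Mutation-set data frame (columns `pos`, `base`), positions
#'   increasing; empty for `seq == ref`.
#' @export
mutations_between <- function(ref, seq) {
  if (nchar(ref) != nchar(seq)) stop("sequences differ in length")
  rc <- .chars(ref)
  sc <- .chars(seq)
  pos <- which(rc != sc)
  data.frame(pos = pos, base = sc[pos])
}

#' Apply a mutation set to a reference sequence
#'
#' @param ref Reference genotype.
#' @param mutations Mutation-set data frame.
#' @return Mutated genotype sequence.
#' @export
apply_mutations <- function(ref, mutations) {
  ch <- .chars(ref)
  if (nrow(mutations) > 0L) {
    if (any(mutations$pos < 1L | mutations$pos > length(ch))) {
      stop("mutation position out of range")
    }
    if (any(ch[mutations$pos] == mutations$base)) {
      stop("mutation does not change the reference base")
    }
    ch[mutations$pos] <- mutations$base
  }
  paste(ch, collapse = "")
}

#' Biallelic locus map between two genotypes
#'
#' Defines the projection of a combinatorial library onto `N` biallelic
#' loci: the positions at which a distant anchor (`mut`) differs from the
#' wild type (`wt`), each with its wild and mutant allele. Locus 1 is the
#' lowest core position and maps to the least-significant bit of the
#' binary encoding.
#'
#' @param wt Wild-type genotype (allele 0 at every locus).
#' @param mut Anchor genotype carrying the mutant allele at every locus.
#' @return An object of class `locus_map`: list with `positions`, `wild`,
#'   `mutant`, `wt_sequence`, and locus count `N`.
#' @export
locus_map <- function(wt, mut) {
  validate_genotype(wt)
  validate_genotype(mut, L = nchar(wt))
  ms <- mutations_between(wt, mut)
  if (nrow(ms) == 0L) stop("wt and mut are identical; no loci to map")
  structure(
    list(positions = ms$pos,
         wild = .chars(wt)[ms$pos],
         mutant = ms$base,
         wt_sequence = wt,
         N = nrow(ms)),
    class = "locus_map")
}

#' @export
print.locus_map <- function(x, ...) {
  cat("Biallelic locus map: N =", x$N, "loci over a", nchar(x$wt_sequence),
      "nt core\n")
  cat(paste0(" locus ", seq_len(x$N), ": pos ", x$positions, " ",
             x$wild, "->", x$mutant), sep = "\n")
  invisible(x)
}

#' Encode a genotype as a biallelic bit vector
#'
#' Bit i is 1 when the genotype carries the mutant allele at locus i.
#' The genotype must match the wild-type sequence outside the mapped
#' positions and one of the two alleles at each mapped position.
#'
#' @param g Genotype sequence.
#' @param map A [locus_map()].
#' @return Integer vector of 0/1 of length `map$N`.
#' @export
encode_binary <- function(g, map) {
  stopifnot(inherits(map, "locus_map"))
  validate_genotype(g, L = nchar(map$wt_sequence))
  gc <- .chars(g)
  wc <- .chars(map$wt_sequence)
  outside <- setdiff(seq_along(gc), map$positions)
  if (any(gc[outside] != wc[outside])) {
    stop("genotype differs from the wild type outside the mapped loci")
  }
  at <- gc[map$positions]
  bits <- ifelse(at == map$mutant, 1L, ifelse(at == map$wild, 0L, NA_integer_))
  if (anyNA(bits)) {
    bad <- which(is.na(bits))
    stop("genotype carries a non-allelic base at locus ",
         paste(bad, collapse = ", "))
  }
  as.integer(bits)
}

#' Decode a bit vector into a genotype
#'
#' @param bits Integer 0/1 vector of length `map$N`.
#' @inheritParams encode_binary
#' @return Genotype sequence.
#' @export
decode_binary <- function(bits, map) {
  stopifnot(inherits(map, "locus_map"), length(bits) == map$N,
            all(bits %in% c(0L, 1L)))
  ch <- .chars(map$wt_sequence)
  ch[map$positions] <- ifelse(bits == 1L, map$mutant, map$wild)
  paste(ch, collapse = "")
}

#' Convert bit vectors to 0-based landscape indices and back
#'
#' Locus 1 is the least-significant bit, fixing the "binary order" in
#' which complete landscapes are stored: a genotype's index is the
#' integer value of its bit vector.
#'
#' @param bits Integer 0/1 vector.
#' @return `bits_to_index`: 0-based integer index.
#' @export
bits_to_index <- function(bits) {
  sum(as.integer(bits) * 2L^(seq_along(bits) - 1L))
}

#' @rdname bits_to_index
#' @param index 0-based integer index (vectorised).
#' @param N Number of loci.
#' @return `index_to_bits`: for a scalar index an integer 0/1 vector; for
#'   a vector of indices a matrix with one row per index.
#' @export
index_to_bits <- function(index, N) {
  m <- vapply(seq_len(N) - 1L,
              function(b) bitwAnd(bitwShiftR(as.integer(index), b), 1L),
              integer(length(index)))
  if (length(index) == 1L) as.integer(m) else matrix(m, nrow = length(index))
}

#' Number of set bits of non-negative integers
#'
#' @param x Integer vector.
#' @return Integer vector of popcounts; the interaction order of a
#'   Walsh-Hadamard term is the popcount of its index.
#' @export
popcount <- function(x) {
  x <- as.integer(x)
  out <- integer(length(x))
  while (any(x > 0L)) {
    out <- out + bitwAnd(x, 1L)
    x <- bitwShiftR(x, 1L)
  }
  out
}

#' One-hot encode genotype sequences
#'
#' Position-major flattening with bases in `A,C,G,U` order: a length-`L`
#' sequence becomes a binary vector of length `4 * L` with exactly `L`
#' ones (`1 x 140` for the 35-nt core).
#'
#' @param seqs Character vector of equal-length genotype sequences.
#' @return Integer matrix with one row per sequence and `4 * L` columns.
#' @export
one_hot <- function(seqs) {
  stopifnot(is.character(seqs), length(seqs) >= 1L)
  L <- nchar(seqs[1L])
  if (any(nchar(seqs) != L)) stop("sequences must share one length")
  n <- length(seqs)
  chm <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
                nrow = n, byrow = TRUE)
  idx <- match(chm, RNA_BASES)
  if (anyNA(idx)) stop("sequences contain characters outside {A,C,G,U}")
  idx <- matrix(idx, nrow = n)
  out <- matrix(0L, nrow = n, ncol = 4L * L)
  cols <- sweep(idx, 2L, (seq_len(L) - 1L) * 4L, "+")
  out[cbind(rep(seq_len(n), L), as.vector(cols))] <- 1L
  colnames(out) <- paste0("p", rep(seq_len(L), each = 4L), "_",
                          rep(RNA_BASES, L))
  out
}

#' Read and write genotype sets as FASTA
#'
#' Thin wrappers over Biostrings; sequences are stored as RNA.
#'
#' @param path File path.
#' @return `read_genotypes_fasta`: named character vector of sequences.
#' @export
read_genotypes_fasta <- function(path) {
  x <- Biostrings::readRNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' @rdname read_genotypes_fasta
#' @param seqs Named character vector of genotype sequences.
#' @export
write_genotypes_fasta <- function(seqs, path) {
  x <- Biostrings::RNAStringSet(seqs)
  if (is.null(names(seqs))) names(x) <- paste0("variant_", seq_along(seqs))
  Biostrings::writeXStringSet(x, filepath = path)
  invisible(path)
}
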