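# Two-locus genotype algebra for the female-killing (K/k) and anti-pathogen
# (A/a) loci. Genotypes are indexed 1..9 in a fixed order (AA block, then Aa,
# then aa; within each block KK, Kk, kk) used consistently across all arrays,
# trajectories and file columns.

GENOTYPE_LABELS <- c("KKAA", "KkAA", "kkAA",
                     "KKAa", "KkAa", "kkAa",
                     "KKaa", "Kkaa", "kkaa")
GENOTYPE_NK <- c(2L, 1L, 0L, 2L, 1L, 0L, 2L, 1L, 0L)
GENOTYPE_NA <- c(2L, 2L, 2L, 1L, 1L, 1L, 0L, 0L, 0L)
GAMETE_LABELS <- c("KA", "Ka", "kA", "ka")

#' Enumerate the nine two-locus genotypes
#'
#' The model tracks two independently segregating autosomal loci: the
#' female-killing locus (alleles K/k) and the anti-pathogen locus (A/a),
#' giving nine genotypes. The ordering returned here is the canonical index
#' used everywhere in the package (state vectors, the inheritance tensor,
#' trajectory columns).
#'
#' @return A tibble with columns `index` (1-9), `label` (e.g. `"KkAa"`),
#'   `n_K` and `n_A` (copy number of the transgenic allele at each locus).
#' @examples
#' genotypes()
#' @export
genotypes <- function() {
  tibble::tibble(
    index = 1:9,
    label = GENOTYPE_LABELS,
    n_K = GENOTYPE_NK,
    n_A = GENOTYPE_NA
  )
}

# Resolve a genotype given as label ("KkAa") or index (1..9) to its index.
genotype_index <- function(g) {
  if (is.character(g)) {
    idx <- match(g, GENOTYPE_LABELS)
    if (anyNA(idx)) {
      stop("unknown genotype label(s): ",
           paste(g[is.na(idx)], collapse = ", "),
           "; valid labels are ", paste(GENOTYPE_LABELS, collapse = ", "),
           call. = FALSE)
    }
    return(idx)
  }
  idx <- as.integer(g)
  if (anyNA(idx) || any(idx < 1L | idx > 9L)) {
    stop("genotype index must be an integer in 1..9", call. = FALSE)
  }
  idx
}

# Integer gamete counts out of 4 equiprobable draws (2 per locus, independent):
# count(KA) = n_K * n_A, count(Ka) = n_K * (2 - n_A), etc. Exact arithmetic.
gamete_counts <- function(idx) {
  nk <- GENOTYPE_NK[idx]
  na <- GENOTYPE_NA[idx]
  c(KA = nk * na, Ka = nk * (2L - na), kA = (2L - nk) * na,
    ka = (2L - nk) * (2L - na))
}

#' Gamete segregation probabilities for one genotype
#'
#' Each parental allele is transmitted with probability 1/2 and the two loci
#' segregate independently, so the gamete distribution is the product of the
#' per-locus Mendelian distributions.
#'
#' @param g Genotype, as a label (`"KkAa"`) or index (1-9).
#' @return A named numeric vector of probabilities over the four gamete types
#'   `KA`, `Ka`, `kA`, `ka`, summing to 1.
#' @examples
#' gamete_distribution("KkAa")
#' @export
gamete_distribution <- function(g) {
  idx <- genotype_index(g)
  if (length(idx) != 1L) stop("one genotype at a time", call. = FALSE)
  gamete_counts(idx) / 4
}

#' Mendelian inheritance tensor
#'
#' `Pr[i | m, n]`: the probability that an offspring of a mating between a
#' mother of genotype `m` and a father of genotype `n` has genotype `i`,
#' under independent Mendelian segregation at both loci. Built once in exact
#' integer arithmetic (all probabilities are multiples of 1/16) and converted
#' to double at the end, so the most-reused object in the model carries no
#' rounding error.
#'
#' @return A 9 x 9 x 9 array with dimensions `offspring`, `mother`, `father`
#'   (genotype labels as dimnames). Each `[, m, n]` slice sums to 1, and the
#'   tensor is symmetric in the two parental roles.
#' @examples
#' P <- inheritance_tensor()
#' P["KkAa", "KKAA", "kkaa"]  # forced double heterozygote
#' @export
inheritance_tensor <- function() {
  # offspring genotype index from a maternal x paternal gamete pair
  gam_nk <- c(1L, 1L, 0L, 0L)  # K copies carried by gamete KA,Ka,kA,ka
  gam_na <- c(1L, 0L, 1L, 0L)
  # index = (2 - n_A) * 3 + (3 - n_K) maps (n_K, n_A) back to table order
  offspring_idx <- matrix(0L, 4L, 4L)
  for (gm in 1:4) {
    for (gf in 1:4) {
      nk <- gam_nk[gm] + gam_nk[gf]
      na <- gam_na[gm] + gam_na[gf]
      offspring_idx[gm, gf] <- (2L - na) * 3L + (3L - nk)
    }
  }
  P16 <- array(0L, dim = c(9L, 9L, 9L))
  for (m in 1:9) {
    cm <- gamete_counts(m)   # counts out of 4
    for (n in 1:9) {
      cn <- gamete_counts(n)
      for (gm in 1:4) {
        if (cm[gm] == 0L) next
        for (gf in 1:4) {
          if (cn[gf] == 0L) next
          i <- offspring_idx[gm, gf]
          P16[i, m, n] <- P16[i, m, n] + cm[gm] * cn[gf]
        }
      }
    }
  }
  P <- P16 / 16
  dimnames(P) <- list(offspring = GENOTYPE_LABELS, mother = GENOTYPE_LABELS,
                      father = GENOTYPE_LABELS)
  P
}

#' Egg-to-larva fitness of each genotype
#'
#' Fitness is the fraction of eggs that survive and hatch into larvae,
#' relative to wild type. Costs are additive within a locus (a heterozygote
#' pays half the homozygote cost) and multiplicative across loci:
#' `w_i = (1 - n_A/2 * c_A) * (1 - n_K/2 * c_K)`.
#'
#' @param c_K Fitness cost of homozygosity for the female-killing allele,
#'   in \[0, 1\].
#' @param c_A Fitness cost of homozygosity for the anti-pathogen allele,
#'   in \[0, 1\].
#' @return Named numeric vector `w` of length 9 in genotype order; the
#'   wild-type entry (`kkaa`) is always 1.
#' @examples
#' fitness_vector(c_K = 0.2, c_A = 0.1)
#' @export
fitness_vector <- function(c_K = 0, c_A = 0) {
  for (nm in c("c_K", "c_A")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1) {
      stop("`", nm, "` must be a single number in [0, 1], got ",
           deparse(v), call. = FALSE)
    }
  }
  w <- (1 - GENOTYPE_NA / 2 * c_A) * (1 - GENOTYPE_NK / 2 * c_K)
  names(w) <- GENOTYPE_LABELS
  w
}

#' Female viability coefficients at emergence
#'
#' The female-killing transgene acts at adult emergence: females carrying at
#' least one K allele die as they emerge (`gamma = 0`), females with no K
#' allele survive (`gamma = 1`). Transgenic females reared on tetracycline
#' are viable as *released* adults despite `gamma = 0`; the model therefore
#' places released females directly into adult compartments, bypassing
#' emergence.
#'
#' @return Named 0/1 vector of length 9 in genotype order; 1 exactly for
#'   `kkAA`, `kkAa`, `kkaa`.
#' @export
viability_vector <- function() {
  g <- as.numeric(GENOTYPE_NK == 0L)
  names(g) <- GENOTYPE_LABELS
  g
}

#' Allele frequencies of a genotype-indexed pool
#'
#' @param counts Nonnegative per-genotype densities (length 9, genotype
#'   order), not all zero.
#' @return A one-row tibble with columns `freq_K` and `freq_A`, the
#'   frequencies of the transgenic allele at each locus.
#' @examples
#' allele_frequencies(c(0, 0, 0, 0, 1, 0, 0, 0, 1))
#' @export
allele_frequencies <- function(counts) {
  counts <- check_counts(counts)
  tot <- sum(counts)
  tibble::tibble(
    freq_K = sum(GENOTYPE_NK * counts) / (2 * tot),
    freq_A = sum(GENOTYPE_NA * counts) / (2 * tot)
  )
}

check_counts <- function(counts) {
  counts <- as.numeric(counts)
  if (length(counts) != 9L || anyNA(counts)) {
    stop("`counts` must be 9 non-missing per-genotype values", call. = FALSE)
  }
  if (any(counts < 0)) stop("`counts` must be nonnegative", call. = FALSE)
  if (sum(counts) == 0) {
    stop("allele frequency undefined for an all-zero pool", call. = FALSE)
  }
  counts
}

#' Composite linkage disequilibrium between the two transgenic alleles
#'
#' Burrows' composite disequilibrium computed from genotype (not gamete)
#' counts: with `X` and `Y` the per-individual K- and A-allele copy numbers,
#' `Delta = E[XY]/2 - 2 p_K p_A`. Gametic phase is not tracked by the model,
#' so the composite statistic is the appropriate genotype-based measure; under
#' random union of gametes it reduces to the gametic `D`. Zero whenever the
#' joint genotype distribution factorizes across loci, and defined as 0 for a
#' monomorphic pool.
#'
#' @param counts Nonnegative per-genotype densities (length 9), positive total.
#' @return A single number.
#' @export
composite_ld <- function(counts) {
  counts <- check_counts(counts)
  f <- counts / sum(counts)
  p_K <- sum(GENOTYPE_NK * f) / 2
  p_A <- sum(GENOTYPE_NA * f) / 2
  if (p_K %in% c(0, 1) || p_A %in% c(0, 1)) return(0)
  sum(GENOTYPE_NK * GENOTYPE_NA * f) / 2 - 2 * p_K * p_A
}
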