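test_that("genotype enumeration is the canonical 3x3 table", {
  g <- genotypes()
  expect_equal(nrow(g), 9L)
  expect_equal(g$label[1], "KKAA")
  expect_equal(g$label[9], "kkaa")
  expect_equal(anyDuplicated(g$label), 0L)
  # bijection with (n_K, n_A)
  expect_equal(anyDuplicated(g[, c("n_K", "n_A")]), 0L)
  expect_true(all(g$n_K %in% 0:2) && all(g$n_A %in% 0:2))
  # labels encode the copy numbers
  expect_equal(g$n_K, vapply(strsplit(g$label, ""), function(x)
    sum(x == "K"), integer(1)))
  expect_equal(g$n_A, vapply(strsplit(g$label, ""), function(x)
    sum(x == "A"), integer(1)))
})

test_that("gamete segregation is the product of per-locus Mendelian halves", {
  expect_equal(gamete_distribution("KKAA"),
               c(KA = 1, Ka = 0, kA = 0, ka = 0))
  expect_equal(gamete_distribution("KkAa"),
               c(KA = 0.25, Ka = 0.25, kA = 0.25, ka = 0.25))
  expect_equal(gamete_distribution("Kkaa"),
               c(KA = 0, Ka = 0.5, kA = 0, ka = 0.5))
  for (lab in genotypes()$label) {
    expect_equal(sum(gamete_distribution(lab)), 1)
  }
  expect_error(gamete_distribution("KKXX"), "unknown genotype")
})

test_that("inheritance tensor matches exhaustive gamete-pair enumeration exactly", {
  P <- inheritance_tensor()
  labs <- genotypes()$label
  for (m in labs) {
    for (n in labs) {
      expect_identical(unname(P[, m, n] * 16),
                       unname(as.numeric(oracle_offspring_counts(m, n))))
    }
  }
})

test_that("inheritance tensor is normalized and parent-symmetric", {
  P <- inheritance_tensor()
  sums <- apply(P, c(2, 3), sum)
  expect_identical(unname(sums), matrix(1, 9, 9))
  expect_identical(unname(P), unname(aperm(P, c(1, 3, 2))))
  expect_true(all(P >= 0))
  # forced double heterozygote and the classic 1/16 double-recessive cross
  expect_identical(unname(P["KkAa", "KKAA", "kkaa"]), 1)
  expect_identical(unname(P["kkaa", "KkAa", "KkAa"]), 1 / 16)
})

test_that("fitness is additive within loci, multiplicative across, anchored at 1", {
  expect_equal(unname(fitness_vector(0, 0)), rep(1, 9))
  w <- fitness_vector(c_K = 0.2, c_A = 0.1)
  expect_equal(unname(w["KkAa"]), (1 - 0.05) * (1 - 0.10))  # = 0.855
  w1 <- fitness_vector(c_K = 1, c_A = 0)
  expect_equal(unname(w1["KKAA"]), 0)
  expect_equal(unname(w1["kkaa"]), 1)
  # wild type always cost-free; componentwise monotone in each cost
  costs <- seq(0, 1, by = 0.25)
  for (i in seq_len(length(costs) - 1)) {
    expect_true(all(fitness_vector(costs[i + 1], 0.3) <=
                      fitness_vector(costs[i], 0.3)))
    expect_true(all(fitness_vector(0.3, costs[i + 1]) <=
                      fitness_vector(0.3, costs[i])))
    expect_equal(unname(fitness_vector(costs[i], costs[i + 1])["kkaa"]), 1)
  }
  expect_error(fitness_vector(c_K = -0.1), "c_K")
  expect_error(fitness_vector(c_A = 1.5), "c_A")
})

test_that("female viability marks exactly the K-free genotypes", {
  g <- viability_vector()
  expect_equal(unname(g), as.numeric(genotypes()$n_K == 0))
  expect_equal(unname(g["kkAa"]), 1)
  expect_equal(unname(g["KKaa"]), 0)
  expect_equal(sum(g), 3)
})

test_that("allele frequencies count transgenic copies over the pool", {
  only <- function(i) replace(numeric(9), i, 1)
  expect_equal(allele_frequencies(only(9)),
               tibble::tibble(freq_K = 0, freq_A = 0))
  expect_equal(allele_frequencies(only(5)),
               tibble::tibble(freq_K = 0.5, freq_A = 0.5))
  expect_equal(allele_frequencies(only(1) + only(9)),
               tibble::tibble(freq_K = 0.5, freq_A = 0.5))
  expect_error(allele_frequencies(numeric(9)), "all-zero")
  expect_error(allele_frequencies(-only(2)), "nonnegative")
})

test_that("offspring pools conserve parental gamete-pool allele frequencies", {
  # no selection: offspring distribution from the tensor has allele
  # frequencies equal to the mid-parent (female pool, male frequency pool)
  P <- inheritance_tensor()
  set.seed(42)
  for (rep in 1:20) {
    Fv <- stats::runif(9)
    Mv <- stats::runif(9)
    off <- numeric(9)
    Mf <- Mv / sum(Mv)
    for (i in 1:9) off[i] <- sum(outer(Fv / sum(Fv), Mf) * P[i, , ])
    fo <- allele_frequencies(off)
    fF <- allele_frequencies(Fv)
    fM <- allele_frequencies(Mv)
    expect_equal(fo$freq_K, (fF$freq_K + fM$freq_K) / 2, tolerance = 1e-12)
    expect_equal(fo$freq_A, (fF$freq_A + fM$freq_A) / 2, tolerance = 1e-12)
  }
})

test_that("composite disequilibrium is zero under factorization, maximal under coupling", {
  only <- function(i) replace(numeric(9), i, 1)
  # single-genotype double heterozygote: product construction at freq 1/2
  expect_equal(composite_ld(only(5)), 0)
  # full coupling of the two homozygotes: E[XY]/2 - 2 pK pA = 2 - 0.5
  expect_equal(composite_ld(only(1) + only(9)), 0.5)
  # monomorphic pools
  expect_equal(composite_ld(only(1)), 0)
  expect_equal(composite_ld(only(9)), 0)
  # joint distribution factorized across loci (HWE at both, independent)
  pK <- 0.3; pA <- 0.6
  hw <- function(p) c(p^2, 2 * p * (1 - p), (1 - p)^2)  # (2,1,0) copies
  counts <- numeric(9)
  for (nk in 0:2) for (na in 0:2) {
    counts[(2 - na) * 3 + (3 - nk)] <- hw(pK)[3 - nk] * hw(pA)[3 - na]
  }
  expect_equal(composite_ld(counts), 0, tolerance = 1e-12)
})
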