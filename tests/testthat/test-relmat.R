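test_that("tabular A reproduces textbook relationships", {
  # unrelated non-inbred parents with one offspring
  trio <- as_pedigree(data.frame(animal = c("s", "d", "o"),
                                 sire = c(NA, NA, "s"), dam = c(NA, NA, "d")))
  A <- pedigree_A(trio)
  expect_equal(A["s", "o"], 0.5)
  expect_equal(A["o", "o"], 1)
  expect_equal(A["s", "d"], 0)

  # full sibs from unrelated parents, then a full-sib mating
  fs <- as_pedigree(data.frame(
    animal = c("p1", "p2", "s1", "s2", "x"),
    sire = c(NA, NA, "p1", "p1", "s1"),
    dam = c(NA, NA, "p2", "p2", "s2")))
  A <- pedigree_A(fs)
  expect_equal(A["s1", "s2"], 0.5)
  expect_equal(A["x", "x"], 1.25)        # F = 0.25 from full-sib mating
  expect_equal(A["s1", "x"], 0.75)       # parent + sib path

  # founders only
  f <- as_pedigree(data.frame(animal = letters[1:4], sire = NA, dam = NA))
  expect_equal(unclass(pedigree_A(f)), diag(4), ignore_attr = TRUE)
})

test_that("A is symmetric positive definite with diagonal 1 + F on random pedigrees", {
  set.seed(101)
  for (rep in 1:5) {
    ped <- random_pedigree(sample(30:120, 1))
    A <- pedigree_A(ped)
    expect_lt(max(abs(A - t(A))), 1e-12)
    expect_true(all(diag(A) >= 1 - 1e-12))
    expect_silent(chol(unclass(A)))
  }
})

test_that("A22 extraction equals brute-force row/column selection", {
  set.seed(7)
  ped <- random_pedigree(40)
  A <- pedigree_A(ped)
  ids <- ped$animal[ped$genotyped]
  A22 <- extract_A22(A, ids)
  expect_identical(attr(A22, "kind"), "A22")
  expect_equal(unclass(A22), unclass(A)[ids, ids], ignore_attr = TRUE)
  # pedigree input form and trivial cases
  expect_equal(unclass(extract_A22(A, ped)), unclass(A)[ids, ids],
               ignore_attr = TRUE)
  ped_all <- ped; ped_all$genotyped <- TRUE
  expect_equal(unclass(extract_A22(A, ped_all)), unclass(A),
               ignore_attr = TRUE)
  ped_none <- ped; ped_none$genotyped <- FALSE
  expect_error(extract_A22(A, ped_none), "empty")
})

test_that("VanRaden G matches element-by-element evaluation and its edge cases", {
  M <- matrix(c(0, 1, 2, 1, 0,
                2, 1, 0, 0, 1,
                1, 1, 1, 2, 0), nrow = 3, byrow = TRUE,
              dimnames = list(c("a", "b", "c"), NULL))
  p <- c(0.5, 0.5, 0.5, 0.5, 1 / 6)
  G <- vanraden_G(M, p)
  # independent route: explicit double loop over animals and SNPs
  denom <- 2 * sum(p * (1 - p))
  Gexp <- matrix(0, 3, 3)
  for (i in 1:3) for (k in 1:3) {
    Gexp[i, k] <- sum((M[i, ] - 2 * p) * (M[k, ] - 2 * p)) / denom
  }
  expect_equal(unclass(G), Gexp, ignore_attr = TRUE, tolerance = 1e-12)

  # identical genotype rows give identical relationship entries
  M2 <- rbind(a = c(0, 1, 2), b = c(0, 1, 2), c = c(2, 1, 0))
  G2 <- vanraden_G(M2, c(0.4, 0.5, 0.6))
  expect_equal(G2["a", "a"], G2["b", "b"])
  expect_equal(G2["a", "b"], G2["a", "a"])

  # degenerate allele frequencies must have been filtered upstream
  expect_error(vanraden_G(M2, c(0, 0.5, 0.5)), "degenerate")
  expect_error(vanraden_G(M2, c(0.5, 1, 0.5)), "degenerate")
  Mna <- M2; Mna[1, 1] <- NA
  expect_error(vanraden_G(Mna, c(0.4, 0.5, 0.6)), "missing")
})

test_that("G centred with its own frequencies has near-unit mean diagonal", {
  set.seed(31)
  cfg <- sim_config(n_sires = 6, n_ref_cows = 60, n_val_cows = 10,
                    n_dams_nongeno = 3, n_halfsibs_per_sire = 2,
                    n_snps = 800, maf_min = 0.05, seed = 31)
  pop <- sim_population(cfg)
  G <- vanraden_G(pop$genotypes)
  expect_equal(mean(diag(G)), 1, tolerance = 0.05)
  expect_lt(max(abs(G - t(G))), 1e-12)
})

test_that("moment adjustment solves its defining 2x2 system", {
  # identity case: G already on the pedigree scale
  set.seed(5)
  ped <- random_pedigree(30)
  A22 <- extract_A22(pedigree_A(ped), ped)
  idG <- adjust_G(A22, A22)
  expect_equal(idG$adjustment$beta, 1, tolerance = 1e-12)
  expect_equal(idG$adjustment$alpha, 0, tolerance = 1e-12)
  expect_equal(unclass(idG$Ga), unclass(A22), ignore_attr = TRUE)

  # prescribed moments resolve to the independent linear-solver solution
  mk <- function(dg, og, ids) {
    m <- matrix(og, 3, 3, dimnames = list(ids, ids)); diag(m) <- dg; m
  }
  ids <- c("x", "y", "z")
  G <- new_relmat(mk(1.2, 0.1, ids), "G")
  A22p <- new_relmat(mk(1.05, 0.02, ids), "A22")
  adj <- adjust_G(G, A22p)$adjustment
  sol <- solve(rbind(c(1.2, 1), c(0.1, 1)), c(1.05, 0.02))
  expect_equal(adj$beta, sol[1], tolerance = 1e-12)
  expect_equal(adj$alpha, sol[2], tolerance = 1e-12)

  # degenerate moments: diagonal average equals off-diagonal average
  flat <- new_relmat(mk(0.3, 0.3, ids), "G")
  expect_error(adjust_G(flat, A22p), "singular")
})

test_that("moment identities hold to 1e-10 on arbitrary simulated input", {
  set.seed(19)
  for (rep in 1:10) {
    q <- sample(5:40, 1)
    G <- new_relmat(random_K(q), "G")
    A22 <- new_relmat(random_K(q, rownames(G)), "A22")
    res <- adjust_G(G, A22)
    off <- function(m) (sum(m) - sum(diag(m))) / (nrow(m) * (nrow(m) - 1))
    expect_equal(mean(diag(res$Ga)), mean(diag(A22)), tolerance = 1e-10)
    expect_equal(off(res$Ga), off(A22), tolerance = 1e-10)
  }
})

test_that("H blending matches independent block evaluation on a small pedigree", {
  # 4 animals, 2 genotyped; G perturbed away from A22
  ped <- as_pedigree(data.frame(
    animal = c("s", "d", "o1", "o2"),
    sire = c(NA, NA, "s", "s"), dam = c(NA, NA, "d", "d"),
    genotyped = c(FALSE, FALSE, TRUE, TRUE)))
  A <- pedigree_A(ped)
  idg <- c("o1", "o2")
  set.seed(2)
  P <- matrix(rnorm(4, sd = 0.05), 2); P <- (P + t(P)) / 2
  G <- new_relmat(unclass(A)[idg, idg] + P, "G")

  H <- blend_H(A, G)
  Au <- unclass(A); Gu <- unclass(G)
  idn <- c("s", "d")
  A22i <- solve(Au[idg, idg])
  H11 <- Au[idn, idn] +
    Au[idn, idg] %*% A22i %*% (Gu - Au[idg, idg]) %*% A22i %*% t(Au[idn, idg])
  H12 <- Au[idn, idg] %*% A22i %*% Gu
  expect_equal(unclass(H)[idn, idn], H11, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(unclass(H)[idn, idg], H12, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(unclass(H)[idg, idg], Gu, tolerance = 0, ignore_attr = TRUE)
})

test_that("H collapses to A when G equals A22, and unrelated rows pass through", {
  set.seed(77)
  for (rep in 1:3) {
    ped <- random_pedigree(80)
    A <- pedigree_A(ped)
    ids <- ped$animal[ped$genotyped]
    G <- new_relmat(unclass(A)[ids, ids], "G")
    H <- blend_H(A, G)
    expect_lt(max(abs(unclass(H)[rownames(A), rownames(A)] - unclass(A))), 1e-8)
  }

  # a non-genotyped animal unrelated to every genotyped one keeps its A row
  ped <- as_pedigree(data.frame(
    animal = c("u", "g1", "g2", "k"),
    sire = c(NA, NA, NA, "g1"), dam = c(NA, NA, NA, "g2"),
    genotyped = c(FALSE, TRUE, TRUE, TRUE)))
  A <- pedigree_A(ped)
  G <- new_relmat(unclass(A)[c("g1", "g2", "k"), c("g1", "g2", "k")] +
                    diag(0.1, 3), "G")
  H <- blend_H(A, G)
  expect_equal(unclass(H)["u", c("u", "g1", "g2", "k")],
               unclass(A)["u", c("u", "g1", "g2", "k")], tolerance = 1e-12)
})

test_that("G converges towards A22 as the number of unlinked SNPs grows", {
  # founder-rich design so allele frequencies are well estimated and the
  # marker-sampling term dominates the deviation
  devs <- sapply(c(500, 2000, 10000), function(m) {
    mean(sapply(1:3, function(r) {
      cfg <- sim_config(n_sires = 30, n_ref_cows = 60, n_val_cows = 10,
                        n_dams_nongeno = 2, n_halfsibs_per_sire = 2,
                        n_snps = m, maf_min = 0.05, seed = 400 + r)
      pop <- sim_population(cfg)
      A22 <- extract_A22(pedigree_A(pop$pedigree), pop$pedigree)
      G <- vanraden_G(pop$genotypes)
      mean(abs(unclass(G) - unclass(A22)[rownames(G), rownames(G)]))
    }))
  })
  expect_true(all(diff(devs) < 0))
})

test_that("matrix text writers round-trip and stabilisation shrinks towards A22", {
  set.seed(13)
  ped <- random_pedigree(15)
  A <- pedigree_A(ped)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_relmat_dense(A, f)
  back <- read_relmat_dense(f, "A")
  expect_equal(unclass(back), unclass(A), tolerance = 1e-9, ignore_attr = TRUE)

  fs <- withr::local_tempfile(fileext = ".tsv")
  write_relmat_sparse(A, fs)
  tab <- read.delim(fs)
  expect_identical(nrow(tab), nrow(A) * (nrow(A) + 1L) %/% 2L)

  ids <- ped$animal[ped$genotyped]
  A22 <- extract_A22(A, ids)
  G <- new_relmat(unclass(A22) + diag(0.2, length(ids)), "G")
  Gs <- stabilize_G(G, A22, tau = 0.95)
  expect_equal(unclass(Gs), 0.95 * unclass(G) + 0.05 * unclass(A22),
               ignore_attr = TRUE)
})
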