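#' Configuration for the cow-reference population simulator
#'
#' Defines a dairy-cattle population of the kind used for cow-reference
#' genomic prediction: a set of genotyped, progeny-tested sires with highly
#' reliable proofs; genotyped reference cows; a younger genotyped validation
#' cow cohort; non-genotyped dams of part of the validation cohort that
#' carry DRP; and large paternal half-sib groups (non-genotyped daughters
#' of the reference sires) that also carry DRP.
#'
#' Reliability arguments may be a single value (all animals get exactly that
#' reliability) or a range `c(lo, hi)` from which per-animal reliabilities
#' are drawn uniformly.  Defaults span from the customary inclusion floors
#' (0.40 for cows, 0.80 for progeny-tested bulls) up to 0.95.
#'
#' @param n_sires number of genotyped reference sires (founders).
#' @param n_ref_cows number of genotyped reference cows.
#' @param n_val_cows number of genotyped validation cows.
#' @param n_dams_nongeno number of non-genotyped dams carrying DRP.
#' @param p_dam_nongeno fraction of validation cows whose dam is one of the
#'   non-genotyped dams; the remainder get genotyped reference-cow dams.
#' @param n_halfsibs_per_sire non-genotyped daughters (with DRP) per sire.
#' @param n_snps,n_qtl simulated SNP count and number of causal SNPs.
#' @param maf_min founder allele frequencies are drawn uniformly on
#'   `(maf_min, 1 - maf_min)`; SNPs with realized MAF below this among
#'   genotyped animals are removed, mirroring the usual MAF < 0.01 edit.
#' @param h2 narrow-sense heritability of the phenotype-like record
#'   (used only by [simulate_phenotypes()]).
#' @param rel_cow,rel_bull target DRP/EBV reliability (value or range) for
#'   cows and bulls respectively.
#' @param drp_mode `"direct"` derives each animal's DRP by dividing its EBV
#'   by its own reliability (exact single-animal deregression); `"deregress"`
#'   routes EBV through [deregress()], removing parent averages.
#' @param seed integer master seed; each stage (pedigree, genotypes, traits)
#'   derives its own sub-seed so stages are independently reproducible.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_sires = 24, n_ref_cows = 400, n_val_cows = 80,
                       n_dams_nongeno = 40, p_dam_nongeno = 0.5,
                       n_halfsibs_per_sire = 25,
                       n_snps = 2000, n_qtl = 200,
                       maf_min = 0.01, h2 = 0.30,
                       rel_cow = c(0.40, 0.95), rel_bull = c(0.80, 0.95),
                       drp_mode = c("direct", "deregress"),
                       seed = 1L) {
  cfg <- list(
    n_sires = as.integer(n_sires), n_ref_cows = as.integer(n_ref_cows),
    n_val_cows = as.integer(n_val_cows),
    n_dams_nongeno = as.integer(n_dams_nongeno),
    p_dam_nongeno = p_dam_nongeno,
    n_halfsibs_per_sire = as.integer(n_halfsibs_per_sire),
    n_snps = as.integer(n_snps), n_qtl = as.integer(n_qtl),
    maf_min = maf_min, h2 = h2,
    rel_cow = .rel_range(rel_cow, 0.40), rel_bull = .rel_range(rel_bull, 0.80),
    drp_mode = match.arg(drp_mode), seed = as.integer(seed))
  counts <- cfg[c("n_sires", "n_ref_cows", "n_val_cows", "n_dams_nongeno",
                  "n_halfsibs_per_sire", "n_snps", "n_qtl")]
  if (any(vapply(counts, function(x) is.na(x) || x < 1L, logical(1)))) {
    stop("all population and marker counts must be >= 1")
  }
  if (cfg$n_qtl > cfg$n_snps) stop("n_qtl must not exceed n_snps")
  if (!(cfg$maf_min > 0 && cfg$maf_min <= 0.5)) stop("maf_min must lie in (0, 0.5]")
  if (!(cfg$h2 > 0 && cfg$h2 < 1)) stop("h2 must lie in (0, 1)")
  if (!(cfg$p_dam_nongeno >= 0 && cfg$p_dam_nongeno <= 1)) {
    stop("p_dam_nongeno must lie in [0, 1]")
  }
  class(cfg) <- "sim_config"
  cfg
}

.rel_range <- function(x, floor_) {
  if (length(x) == 1L) x <- c(x, x)
  stopifnot(length(x) == 2L, x[1] <= x[2])
  if (x[1] < floor_ || x[2] >= 1) {
    stop(sprintf("reliability range [%g, %g] must lie within [%g, 1)",
                 x[1], x[2], floor_))
  }
  x
}

# Stage sub-seeds: deterministic, distinct, and < 2^31.
.stage_seed <- function(seed, stage) {
  off <- c(pedigree = 11L, genotypes = 211L, traits = 3011L,
           phenotypes = 40009L)[[stage]]
  as.integer((as.double(seed) * 48271 + off) %% 2147483647)
}

.draw_rel <- function(n, range) {
  if (range[1] == range[2]) rep(range[1], n) else stats::runif(n, range[1], range[2])
}

#' Simulate a cow-reference pedigree
#'
#' Founder sires come first, then the non-genotyped dams (founders), the
#' reference cows, the paternal half-sib groups, and finally the validation
#' cows, so that the row order is topological by construction.  Every
#' validation cow has a known sire drawn from the genotyped sires; a
#' fraction `p_dam_nongeno` of them get a non-genotyped dam (with DRP) and
#' the rest a genotyped reference-cow dam.  Half-sib daughters and reference
#' cows have unknown dams (treated as unrelated founders).
#'
#' @param config a [sim_config()].
#' @return a pedigree data frame (see [as_pedigree()]) with columns
#'   `animal,sire,dam,order,genotyped,cohort,sex`.
#' @export
simulate_pedigree <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(.stage_seed(config$seed, "pedigree"))
  ns <- config$n_sires
  sires <- sprintf("S%03d", seq_len(ns))
  dams <- sprintf("D%04d", seq_len(config$n_dams_nongeno))
  refc <- sprintf("R%04d", seq_len(config$n_ref_cows))
  hs <- sprintf("H%05d", seq_len(ns * config$n_halfsibs_per_sire))
  val <- sprintf("V%04d", seq_len(config$n_val_cows))

  n_nd <- round(config$p_dam_nongeno * config$n_val_cows)
  # dams of validation cows: first n_nd from the non-genotyped dam pool
  # (recycled if the pool is smaller), remainder from the reference cows
  nd_assign <- if (n_nd > 0) {
    pool <- if (length(dams) >= n_nd) sample(dams, n_nd) else
      sample(rep_len(sample(dams), n_nd))
    pool
  } else character(0)
  n_gd <- config$n_val_cows - n_nd
  if (n_gd > config$n_ref_cows) {
    stop("not enough reference cows to serve as genotyped dams of validation cows")
  }
  gd_assign <- if (n_gd > 0) sample(refc, n_gd) else character(0)
  val_dam <- c(nd_assign, gd_assign)[sample.int(config$n_val_cows)]

  ped <- rbind(
    data.frame(animal = sires, sire = NA, dam = NA, genotyped = TRUE,
               cohort = "ref_bull", sex = "M"),
    data.frame(animal = dams, sire = NA, dam = NA, genotyped = FALSE,
               cohort = "nongeno_dam", sex = "F"),
    data.frame(animal = refc, sire = sample(sires, config$n_ref_cows, TRUE),
               dam = NA, genotyped = TRUE, cohort = "ref_cow", sex = "F"),
    data.frame(animal = hs, sire = rep(sires, each = config$n_halfsibs_per_sire),
               dam = NA, genotyped = FALSE, cohort = "nongeno_halfsib", sex = "F"),
    data.frame(animal = val, sire = sample(sires, config$n_val_cows, TRUE),
               dam = val_dam, genotyped = TRUE, cohort = "val_cow", sex = "F"))
  ped$order <- seq_len(nrow(ped))
  as_pedigree(ped[c("animal", "sire", "dam", "order", "genotyped", "cohort", "sex")])
}

#' Gene-drop SNP genotypes through a pedigree
#'
#' Founder alleles are drawn per SNP as Bernoulli(p_j) with p_j uniform on
#' `(maf_min, 1 - maf_min)`; every non-founder receives one allele from each
#' parent by Mendelian sampling (an unknown parent transmits a fresh founder
#' allele).  SNPs are unlinked.  After dropping, allele frequencies are
#' computed from the genotyped animals and SNPs with MAF below
#' `config$maf_min` are removed.
#'
#' @param ped pedigree from [simulate_pedigree()] (topologically ordered).
#' @param config the matching [sim_config()].
#' @return an object of class `genotype_matrix`: list with `counts`
#'   (genotyped animals x SNPs, allele counts 0/1/2), `freqs` (per-SNP
#'   reference-allele frequency among genotyped animals), `animal_ids`,
#'   `snp_ids`, and `drawn_freqs` (the founder sampling frequencies, useful
#'   for checking realized against target frequencies).  The full matrix
#'   over all animals is kept internally (used by [simulate_traits()]) but
#'   is not part of the exposed surface.
#' @export
simulate_genotypes <- function(ped, config) {
  ped <- as_pedigree(ped)
  stopifnot(inherits(config, "sim_config"), "genotyped" %in% names(ped))
  set.seed(.stage_seed(config$seed, "genotypes"))
  n <- nrow(ped)
  m <- config$n_snps
  p <- stats::runif(m, config$maf_min, 1 - config$maf_min)
  si <- attr(ped, "sire_idx")
  di <- attr(ped, "dam_idx")
  h1 <- matrix(0L, n, m)   # paternal haplotype
  h2 <- matrix(0L, n, m)   # maternal haplotype
  founder_allele <- function() as.integer(stats::runif(m) < p)
  for (i in seq_len(n)) {
    h1[i, ] <- if (is.na(si[i])) founder_allele() else {
      ifelse(stats::runif(m) < 0.5, h1[si[i], ], h2[si[i], ])
    }
    h2[i, ] <- if (is.na(di[i])) founder_allele() else {
      ifelse(stats::runif(m) < 0.5, h1[di[i], ], h2[di[i], ])
    }
  }
  counts_all <- h1 + h2
  rownames(counts_all) <- ped$animal
  colnames(counts_all) <- sprintf("snp%05d", seq_len(m))
  geno_rows <- which(ped$genotyped)
  freq <- colMeans(counts_all[geno_rows, , drop = FALSE]) / 2
  keep <- pmin(freq, 1 - freq) >= config$maf_min
  structure(list(
    counts = counts_all[geno_rows, keep, drop = FALSE],
    freqs = freq[keep],
    animal_ids = ped$animal[geno_rows],
    snp_ids = colnames(counts_all)[keep],
    drawn_freqs = p[keep],
    counts_all = counts_all[, keep, drop = FALSE]),
    class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("Genotypes:", nrow(x$counts), "genotyped animals x", ncol(x$counts),
      "SNPs (allele counts 0/1/2)\n")
  cat("Allele frequencies: ", sprintf("%.3f", min(x$freqs)), "-",
      sprintf("%.3f", max(x$freqs)), "\n")
  invisible(x)
}

#' Simulate additive genetic merit, EBV and DRP
#'
#' A random subset of `n_qtl` SNPs receives i.i.d. normal effects; an
#' animal's true breeding value is the sum of its allele counts weighted by
#' those effects, centred and scaled to unit variance (the genetic SD is the
#' trait unit).  EBV are generated as BLUP-like shrunken evaluations: for
#' target reliability \eqn{r^2}, \eqn{ebv = r^2 (tbv + \epsilon)} with
#' \eqn{Var(\epsilon) = (1 - r^2)/r^2}, so the squared correlation between
#' EBV and true merit is \eqn{r^2} and the regression of EBV on true merit
#' has slope \eqn{r^2}, as for a posterior mean.  Deregression (either the
#' exact own-record form or the parent-average form, per `drp_mode`) then
#' yields DRP whose regression on true merit has slope 1.
#'
#' EBV noise is independent across animals: real evaluations induce
#' covariances between relatives' EBVs that deregression is designed to
#' mitigate; this simplification is deliberate.
#'
#' @param ped pedigree; @param geno result of [simulate_genotypes()];
#' @param config the matching [sim_config()].
#' @return data frame of class `trait_records` with columns `animal`,
#'   `cohort`, `genotyped`, `true_bv`, `rel_ebv`, `ebv`, `drp`, `rel_drp`,
#'   `included` (passes the cohort reliability floor and has usable DRP).
#' @export
simulate_traits <- function(ped, geno, config) {
  ped <- as_pedigree(ped)
  stopifnot(inherits(config, "sim_config"), inherits(geno, "genotype_matrix"))
  set.seed(.stage_seed(config$seed, "traits"))
  M <- geno$counts_all
  stopifnot(identical(rownames(M), ped$animal))
  m <- ncol(M)
  qtl <- sample.int(m, min(config$n_qtl, m))
  a <- stats::rnorm(length(qtl))
  tbv <- drop(M[, qtl, drop = FALSE] %*% a)
  tbv <- tbv - mean(tbv)
  s <- stats::sd(tbv)
  if (s > 0) tbv <- tbv / s   # genetic SD = 1; degenerate architectures stay at 0

  n <- nrow(ped)
  is_bull <- ped$cohort %in% c("ref_bull", "founder_sire")
  rel <- numeric(n)
  rel[is_bull] <- .draw_rel(sum(is_bull), config$rel_bull)
  rel[!is_bull] <- .draw_rel(sum(!is_bull), config$rel_cow)
  # BLUP-like EBV: shrunken towards 0, noise variance on the unit genetic scale
  eps <- stats::rnorm(n, 0, sqrt((1 - rel) / rel))
  ebv <- rel * (tbv + eps)

  rec <- data.frame(animal = ped$animal, cohort = ped$cohort,
                    genotyped = ped$genotyped, true_bv = tbv,
                    rel_ebv = rel, ebv = ebv,
                    stringsAsFactors = FALSE)
  if (config$drp_mode == "direct") {
    rec$drp <- ebv / rel
    rec$rel_drp <- rel
    rec$excluded <- FALSE
  } else {
    dr <- deregress(rec[c("animal", "ebv", "rel_ebv")], ped)
    rec$drp <- dr$drp
    rec$rel_drp <- dr$rel_drp
    rec$excluded <- dr$excluded
  }
  rec <- apply_reliability_filters(rec)
  class(rec) <- c("trait_records", "data.frame")
  rec
}

#' Phenotype-like records under a given heritability
#'
#' Adds an environmental deviation to each animal's true breeding value so
#' that the ratio of genetic to total variance is `config$h2`; useful for
#' checking that REML recovers the simulated heritability.
#'
#' @inheritParams simulate_traits
#' @param traits result of [simulate_traits()].
#' @return numeric vector of phenotypes named by animal.
#' @export
simulate_phenotypes <- function(traits, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(.stage_seed(config$seed, "phenotypes"))
  ve <- (1 - config$h2) / config$h2   # genetic variance is 1 by construction
  y <- traits$true_bv + stats::rnorm(nrow(traits), 0, sqrt(ve))
  names(y) <- traits$animal
  y
}

#' Simulate a full population
#'
#' Runs [simulate_pedigree()], [simulate_genotypes()] and
#' [simulate_traits()] under one configuration.  Identical seed and
#' configuration give identical output.
#'
#' @param config a [sim_config()].
#' @return list of class `sim_population` with elements `pedigree`,
#'   `genotypes`, `traits`, `config`.
#' @export
sim_population <- function(config = sim_config()) {
  ped <- simulate_pedigree(config)
  geno <- simulate_genotypes(ped, config)
  traits <- simulate_traits(ped, geno, config)
  structure(list(pedigree = ped, genotypes = geno, traits = traits,
                 config = config), class = "sim_population")
}

#' @export
print.sim_population <- function(x, ...) {
  tab <- table(x$pedigree$cohort)
  cat("Simulated population:", nrow(x$pedigree), "animals,",
      ncol(x$genotypes$counts), "SNPs after MAF edit\n")
  print(tab)
  invisible(x)
}

#' Write simulated genotypes
#'
#' `write_genotypes_raw()` writes a PLINK `.raw`-compatible whitespace table
#' (FID IID PAT MAT SEX PHENOTYPE then one 0/1/2 column per SNP);
#' `write_genotypes_tsv()` writes a compact animal x SNP TSV.
#'
#' @param geno a `genotype_matrix`.
#' @param file output path.
#' @export
write_genotypes_raw <- function(geno, file) {
  out <- data.frame(FID = geno$animal_ids, IID = geno$animal_ids,
                    PAT = 0, MAT = 0, SEX = 0, PHENOTYPE = -9,
                    geno$counts, check.names = FALSE)
  utils::write.table(out, file, row.names = FALSE, quote = FALSE, sep = " ")
  invisible(file)
}

#' @rdname write_genotypes_raw
#' @export
write_genotypes_tsv <- function(geno, file) {
  out <- data.frame(animal = geno$animal_ids, geno$counts, check.names = FALSE)
  utils::write.table(out, file, row.names = FALSE, quote = FALSE, sep = "\t")
  invisible(file)
}

#' Write trait records as TSV
#' @param traits a `trait_records` data frame.
#' @param file output path.
#' @export
write_traits <- function(traits, file) {
  utils::write.table(as.data.frame(traits), file, row.names = FALSE,
                     quote = FALSE, sep = "\t")
  invisible(file)
}

#' Read trait records written by [write_traits()]
#' @param file TSV path.
#' @export
read_traits <- function(file) {
  rec <- utils::read.delim(file, stringsAsFactors = FALSE)
  class(rec) <- c("trait_records", "data.frame")
  rec
}
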